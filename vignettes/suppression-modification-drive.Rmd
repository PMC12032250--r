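---
title: "Modelling a suppression-modification homing gene drive"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a suppression-modification homing gene drive}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suppdrive)
```

## The system being modelled

`suppdrive` models a CRISPR homing gene drive inserted into an essential-but-
survivable locus of *Anopheles gambiae* — a drive that disrupts its target
gene (a loss-of-function, LOF, allele) and therefore both *suppresses*
population fitness and, by reaching fixation, can *modify* the population,
including by mobilising a second, non-autonomous antimalarial effector
construct. Three linked questions are addressed by three simulators sharing
one inheritance engine:

1. **Inheritance** (`gamete_distribution`, `cross_distribution`,
   `deterministic_step`): what exactly does a given parent transmit, and how
   do allele frequencies evolve in an infinite random-mating population?
2. **Cage invasion** (`cage_config`, `run_experiment`): does the drive invade
   a 500-adult laboratory cage population seeded at 20% allele frequency,
   and what do the fluorescence/PCR screening readouts look like?
3. **Field transmission** (`epi_config`, `run_scenario`, `run_sweep`): after
   a single release of 1000 drive-homozygous males, how do drive fitness
   phenotypes translate into clinical-malaria reduction, local elimination
   and possible vector eradication across transmission intensities?

## The inheritance model

Two loci are modelled. The **drive locus** carries alleles W (wild type),
D (drive), R1 (functional resistance) and R2 (non-functional resistance);
the functional class is {W, R1} and the LOF class is {D, R2}. The **effector
locus** carries C (wild-type target), E (effector) and CR (cleavage-resistant
target variant, treated as functionally wild type).

In a D/W heterozygote of sex $s$, the transmitted drive allele is

$$P(D) = h_s,\qquad P(W) = (1-h_s)\,u,\qquad
P(R1) = (1-h_s)(1-u)f,\qquad P(R2) = (1-h_s)(1-u)(1-f)$$

with $h_s$ the sex-specific homing (inheritance) probability, $u$ the
fraction of non-drive gametes that remain wild type ("uncut"), and $f$ the
functional fraction of newly generated resistance alleles. Every other drive
genotype segregates Mendelianly: homing requires one drive and one cleavable
wild-type allele. The effector locus behaves identically with parameters
$(h_E, u_E)$, except that homing additionally requires at least one D allele
in the same individual — the effector carries only a gRNA and depends on the
drive's Cas9 supplied in trans.

Defaults are the measured inheritance rates $h_f = 0.996$, $h_m = 0.971$ and
full conversion of residuals ($u = 0$), matching the modelled setting in
which all non-homed alleles from heterozygotes become resistance alleles;
$u$ is exposed so cleavage-failure-without-repair scenarios are expressible.
With $h = 0.5, u = 1$ the locus is exactly Mendelian, which the tests use as
a null.

**Linkage.** Homing is modelled as in-situ germline conversion of the
cleavable allele on the homologous chromosome *before* meiosis: the target
homologue becomes D with probability $2h-1$ (which reproduces the
gamete-level marginal $P(D)=h$), and recombination between the two loci then
occurs at fraction $r$. The mechanistic route requires $h \ge 0.5$ wherever
conversion is active; at the default $r = 0.5$ (unlinked) the joint gamete
distribution reduces to the product of the marginals above, which is defined
for any $h$. The two real loci sit 5.87 Mb apart on the same chromosome, but
no genetic map is available, so unlinked is the default and $r$ is
configurable. Maternal deposition is not modelled (none was detected for the
germline promoter used), and sex is autosomal Bernoulli(0.5).

**Fitness classes.** Fitness attaches only to the three drive-locus classes:
daily mortality hazard is multiplied by $m_{hom}$ in LOF homozygotes and, by
the half-impact rule, $1 + (m_{hom}-1)/2$ in heterozygotes; a blood-meal
mortality $b$ applies per meal to LOF-homozygous females only; fecundity and
mating-weight multipliers default to 1 (no fecundity effect was measured).
The effector locus is fitness-neutral.

## The cage simulator

`run_experiment` reproduces one maintenance cycle per generation:

1. adult attrition over the 6-day mating window, daily survival
   $p_0^{m}$ with $p_0 = 0.5^{1/35}$ (the wild-type 35-day median lifespan
   under a constant-hazard model) and $m$ the class multiplier;
2. each surviving female mates once (*Anopheles* females are effectively
   monandrous), partner drawn proportional to male count × mating weight;
3. one blood meal; LOF-homozygous females die with probability $b$ before
   oviposition;
4. eggs per surviving female are Poisson with mean
   `mean_eggs_per_female` (default 60, interpreted as hatched larvae per
   female so that hatch rate folds into the single parameter) times the
   class fecundity multiplier;
5. 525 larvae (5 trays × 105) are sampled from the egg pool *without
   replacement*, with genotypes drawn from each mating pair's exact cross
   distribution;
6. observation: 100 larvae are screened for drive-carrier status
   (fluorescent marker) and 92 for effector genotype (PCR), both
   hypergeometrically, since screened larvae are physically removed.

Extinction (no surviving adults of either sex, or zero eggs) is a flagged
terminal state, not an error. All randomness flows from `config$seed`;
replicate cage $i$ uses `seed + i - 1`.

**Calibration of the fitness costs.** The measured homozygote phenotypes
bound the cost parameters: lifespan medians give hazard multipliers
$35/25 = 1.4$ (females) and $32/20 = 1.6$ (males); up to 40% of homozygotes
failed to initiate flight, bounding the mating weight at about 0.6; and
post-blood-meal mortality was severe under the standard feeding protocol,
bounding $b$ below but near 1 (homozygous colonies remain rearable, so
$b < 1$). The cage reproduction test uses the strongest measured-supported
combination ($m_{hom} = 1.6$, $b = 0.9$, mating weight 0.6). A structural
point worth stating plainly: because homing acts in heterozygotes, whose
costs are small, wild-type exhaustion is largely insensitive to
homozygote-only costs — the simulated median fixation generation saturates
around 9–10 under any cost combination in the measured ranges, earlier than
the published cage observation of fixation around generation 14. The model
therefore reproduces the *regime* (initial generation-1 carrier dip in most
replicates, then fixation in every cage) but compresses the published
timescale; unmeasured frictions (reduced effective homing under cage
conditions, heterozygote costs, assortative mating) would be required to
stretch it.

## The transmission simulator

`run_scenario` is a daily-timestep stochastic cohort model: adult females
stratified by (own drive-locus genotype × mate genotype × gonotrophic state
× infection state), adult males by genotype, larvae by genotype × age. All
transitions are binomial/multinomial, making the model distributionally
equivalent to an agent description while running at desk scale. Females mate
once at emergence against the current male pool; an "unmated" stratum covers
male-free states. Females attempt a blood meal daily until the first success
and every `cycle_days` (= 3) thereafter; oviposition occurs on completing
each cycle, so a female's first reproduction requires surviving her first
blood meal — with $b = 1$, LOF-homozygous females never reproduce, the
limiting behaviour in which vector eradication becomes possible.

The within-host side is a declared simplification: humans follow a two-state
SIS process, clinical incidence is proxied by new human infections per
capita, and treatment collapses into one clearance rate. Absolute case
counts are therefore **not** comparable to a full agent-based within-host
model; only relative reductions and qualitative regimes are interpreted.

Constants the source experiment does not print are declared defaults, all
overridable in `epi_config()`:

| parameter | default | meaning |
|---|---|---|
| `adult_daily_survival` | 0.9 | wild-type adult daily survival (field-typical) |
| `feed_success` | 0.9 | daily success probability of a seeking female |
| `eggs_per_batch` | 40 | eggs per completed gonotrophic cycle |
| `larval_duration` | 10 d | egg-to-adult development |
| `larval_daily_survival` | 0.9 | low-density larval daily survival |
| `eip_days` | 11 d | extrinsic incubation period (fixed, no seasonality) |
| `mosq_infect_prob` | 0.2 | acquisition per bite per unit human prevalence |
| `human_infect_prob` | 0.3 | human infection per infectious bite |
| `human_clear_rate` | 1/60 d⁻¹ | human clearance incl. treatment |

Larval density dependence is a logistic-type daily survival scaling
$s_L = s_0/(1 + L/K)$ with $K$ the larval capacity; $K$ is the tuning knob
that sets transmission intensity, and `calibrate_density()` bisects it until
the no-release equilibrium annual entomological inoculation rate (EIR) is
within 20% of the 15/35/65 bites-per-person-year targets, averaging over
replicate burn-ins. Infectious bites are counted before blood-meal death is
applied (the bite precedes the death).

One behaviour of this structure deserves a flag: over a *reduced* two-year
horizon, full blood-meal lethality ($b = 1$) can yield slightly *less* case
reduction than $b = 0.5$ at low functional resistance, because homozygous
females that never reproduce relieve larval competition and transiently
boost the emergence of transmitting (functional-class) females during the
spread phase, while the eradication dividend of $b = 1$ accrues mostly after
the window closes. Both cells collapse transmission over the full six-year
protocol. The property tests record this honestly rather than asserting a
monotonicity the reduced window does not support.

## Estimators and synthetic data

- `estimate_transmission()` — exact (Clopper–Pearson) binomial inference on
  pooled cross progeny counts.
- `daily_survival_from_median()` / `mortality_multiplier_from_medians()` —
  constant-hazard conversions ($p = 0.5^{1/\mathrm{median}}$; multiplier
  $= \mathrm{median}_{ref}/\mathrm{median}_{alt}$), chosen because the
  simulators apply constant daily mortality; full survival-curve machinery
  is out of scope here.
- `carrier_to_allele_freq()` — Hardy–Weinberg inversion
  $q = 1 - \sqrt{1 - c}$; approximate in the first post-seeding generations
  when founders are homozygous.
- `fit_egg_trend()` — least-squares quadratic in generation, excluding the
  setup generation by default, with pointwise standard errors.
- `calibrate_bloodmeal_mort()` — fits $b$ by minimising squared distance
  between observed and simulated carrier trajectories; simple and
  documented rather than likelihood-based, and only weakly identified
  because carrier trajectories respond mildly to homozygote-only costs.

The generators (`gen_cross_progeny`, `gen_survival_table`,
`gen_cage_screen`) emit binomial, geometric and hypergeometric data with the
ground truth attached, emulating the statistical structure of the laboratory
readouts: pooled GFP screens, daily dead counts, per-generation larval
screens. They do **not** emulate environmental fluctuation in egg output,
between-replicate overdispersion, or genotyping error — so passing recovery
tests demonstrates estimator correctness under the declared model, not
robustness to real-data messiness.

## Numerical and scale choices

Distributions are exact to 1e-12 (verified against independent enumeration
oracles); diplotypes are canonicalised by lexicographic haplotype sort so
unordered genotypes have unique labels. Degenerate inputs (empty founder
census, all-zero fitness weights, zero-case baselines) raise informative
errors; population extinction never does. The test suite runs the cage
mean-field check at $10^5$ larvae over 20 seeds, the cage regime check at 50
replicate cages over 30 generations, and the transmission sweep at a
3×3×3 grid × 10 replicates with 200 humans over 2 years — sizes chosen to
keep the full suite in the minutes range on a single core while leaving
Monte-Carlo error well below the effect sizes under test. The full published
protocol (1000 humans, 6 years, 40 replicates) is available by default in
`epi_config()`.

## Known limitations

- No age structure within the cage generation; no larval density dependence
  inside the cage (the 525-larva bottleneck dominates).
- The transmission model omits seasonality, human age structure (incidence
  is all-age, the published evaluation was 0–5-year-olds), importation and
  multi-species vector communities.
- Effector-locus resistance (CR) is assumed functionally wild type and
  fitness-neutral; multi-gRNA designs and sex-linked drives are out of
  scope.
- The mapping from measured laboratory phenotypes to cage demography is
  under-determined; the cost channels (mating weight, attrition, blood-meal
  mortality) are explicit parameters so calibration can redistribute the
  cost, but the data cannot separate them.
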