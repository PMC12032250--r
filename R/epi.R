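# Daily-timestep stochastic vector-population and malaria-transmission model.
# Mirrors the structure of an agent-based gene-drive transmission experiment
# (single release of drive-homozygous males into a calibrated vector
# population, parameter sweep over resistance rates, mortality multipliers,
# blood-meal mortality and transmission intensity) but replaces the
# within-host parasite/immune machinery with a two-state human SIS process
# and a clinical-incidence proxy (new human infections per capita).
# Absolute case counts are therefore not comparable to a full within-host
# model; relative reductions and qualitative regimes are the outputs.
#
# The vector population is represented as stratified counts (a cohort model):
# adult females by (own drive-locus genotype x mate genotype x gonotrophic
# state x infection state), adult males by genotype, larvae by genotype x
# age. All daily transitions are binomial/multinomial draws, so the model is
# distributionally equivalent to the per-agent description.

EPI_N_GENO <- 10L

#' Transmission-model configuration
#'
#' Defaults mirror the published sweep protocol: ~1000 humans, a single
#' release of 1000 drive-homozygous males 200 days into the simulation, a
#' 6-year horizon, 40 stochastic replicates, and target transmission
#' intensities of 15/35/65 infectious bites per person per year set via the
#' larval carrying capacity. Baseline vector and transmission constants that
#' the source experiment does not print are declared package defaults here
#' and are all overridable.
#'
#' @param human_population Number of humans (default 1000).
#' @param larval_capacity Larval carrying capacity `K` of the breeding sites;
#'   tuned per transmission scenario via [calibrate_density()].
#' @param target_EIR Target entomological inoculation rate, infectious
#'   bites/person/year (15, 35 or 65 in the published sweep).
#' @param eip_days Extrinsic incubation period in days (default 11).
#' @param cycle_days Gonotrophic cycle: days between blood meals after the
#'   first successful meal (default 3). Females attempt to feed daily until
#'   they first succeed.
#' @param feed_success Daily probability that a seeking female obtains a
#'   blood meal (default 0.9).
#' @param release_size Males of genotype D/D released (default 1000).
#' @param release_day Day of the release (default 200).
#' @param horizon_days Total simulated days (default 6 x 365).
#' @param drive A [drive_params()] object; the published sweep uses 99%
#'   homing in both sexes.
#' @param fitness A [fitness_params()] object.
#' @param replicates Stochastic replicates for sweeps (default 40).
#' @param seed Integer seed.
#' @param adult_daily_survival Baseline wild-type adult daily survival
#'   (default 0.9, a typical field value for *Anopheles*).
#' @param eggs_per_batch Eggs laid per completed gonotrophic cycle
#'   (default 40).
#' @param larval_duration Days from egg to adult emergence (default 10).
#' @param larval_daily_survival Low-density larval daily survival
#'   (default 0.9); realised survival is
#'   `larval_daily_survival / (1 + L/K)`, a logistic-type density dependence.
#' @param mosq_infect_prob Probability a susceptible female acquires
#'   infection when biting, per unit human prevalence (default 0.2).
#' @param human_infect_prob Probability an infectious bite on a susceptible
#'   human causes an infection (default 0.3).
#' @param human_clear_rate Daily human clearance probability; collapses
#'   natural recovery and treatment seeking into one rate (default 1/60).
#' @param init_adults Wild-type adults of each sex at day 0 (default 500).
#' @param init_genotype Drive-locus genotype of the founding vector
#'   population (default `"W/W"`).
#' @param init_human_prev Initial human infection prevalence (default 0.3).
#' @return An object of class `epi_config`.
#' @export
epi_config <- function(human_population = 1000,
                       larval_capacity = 20000,
                       target_EIR = 35,
                       eip_days = 11,
                       cycle_days = 3,
                       feed_success = 0.9,
                       release_size = 1000,
                       release_day = 200,
                       horizon_days = 6 * 365,
                       drive = drive_params(homing_female = 0.99,
                                            homing_male = 0.99,
                                            functional_fraction = 0.001),
                       fitness = fitness_params(),
                       replicates = 40,
                       seed = 1L,
                       adult_daily_survival = 0.9,
                       eggs_per_batch = 40,
                       larval_duration = 10,
                       larval_daily_survival = 0.9,
                       mosq_infect_prob = 0.2,
                       human_infect_prob = 0.3,
                       human_clear_rate = 1 / 60,
                       init_adults = 500,
                       init_genotype = "W/W",
                       init_human_prev = 0.3) {
  stopifnot(inherits(drive, "drive_params"), inherits(fitness, "fitness_params"))
  if (release_day >= horizon_days)
    stop("epi_config: 'release_day' must be < 'horizon_days'", call. = FALSE)
  for (nm in c("feed_success", "mosq_infect_prob", "human_infect_prob",
               "human_clear_rate", "adult_daily_survival",
               "larval_daily_survival", "init_human_prev")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0 || v > 1)
      stop("epi_config: '", nm, "' must be in [0, 1]", call. = FALSE)
  }
  if (larval_capacity < 0)
    stop("epi_config: 'larval_capacity' must be >= 0", call. = FALSE)
  cfg <- list(human_population = as.integer(human_population),
              larval_capacity = larval_capacity, target_EIR = target_EIR,
              eip_days = as.integer(eip_days),
              cycle_days = as.integer(cycle_days),
              feed_success = feed_success,
              release_size = as.integer(release_size),
              release_day = as.integer(release_day),
              horizon_days = as.integer(horizon_days),
              drive = drive, fitness = fitness,
              replicates = as.integer(replicates), seed = as.integer(seed),
              adult_daily_survival = adult_daily_survival,
              eggs_per_batch = eggs_per_batch,
              larval_duration = as.integer(larval_duration),
              larval_daily_survival = larval_daily_survival,
              mosq_infect_prob = mosq_infect_prob,
              human_infect_prob = human_infect_prob,
              human_clear_rate = human_clear_rate,
              init_adults = as.integer(init_adults),
              init_genotype = init_genotype,
              init_human_prev = init_human_prev)
  structure(cfg, class = "epi_config")
}

# Precompute genotype-indexed quantities: fitness classes, survival vectors,
# gamete distributions and the 10 x 10 -> 10 offspring genotype map.
epi_precompute <- function(cfg) {
  genos <- drive_genotypes()
  nG <- length(genos)
  alleles <- strsplit(genos, "/", fixed = TRUE)
  cls <- vapply(alleles, drive_fitness_class, character(1L))
  s_adult <- cfg$adult_daily_survival ^ cfg$fitness$mort_mult[cls]
  bm_surv <- ifelse(cls == "homozygous_LOF", 1 - cfg$fitness$bloodmeal_mort, 1)
  fec <- cfg$fitness$fecundity[cls]
  gamF <- t(vapply(genos, function(g)
    drive_gamete_for(g, cfg$drive$homing_female, cfg$drive), numeric(4L)))
  gamM <- t(vapply(genos, function(g)
    drive_gamete_for(g, cfg$drive$homing_male, cfg$drive), numeric(4L)))
  pair_idx <- matrix(0L, 4L, 4L)
  k <- 0L
  for (i in 1:4) for (j in i:4) {
    k <- k + 1L
    pair_idx[i, j] <- k; pair_idx[j, i] <- k
  }
  off <- array(0, dim = c(nG, nG, nG))
  for (gf in seq_len(nG)) for (gm in seq_len(nG)) {
    joint <- outer(gamF[gf, ], gamM[gm, ])
    for (i in 1:4) for (j in 1:4)
      off[gf, gm, pair_idx[i, j]] <- off[gf, gm, pair_idx[i, j]] + joint[i, j]
  }
  n_feed <- cfg$cycle_days + 1L       # 1 = pre-first-meal seeking,
                                      # 2..cycle_days = resting,
                                      # cycle_days+1 = seeking
  n_inf <- cfg$eip_days + 2L          # 1 = S, 2..eip+1 = incubating, last = I
  n_mate <- nG + 1L                   # last level = unmated
  d_f <- c(nG, n_mate, n_feed, n_inf)
  allele_count <- t(vapply(alleles, function(a) {
    out <- setNames(numeric(4L), DRIVE_ALLELES)
    out[a[1L]] <- out[a[1L]] + 1; out[a[2L]] <- out[a[2L]] + 1
    out
  }, numeric(4L)))
  list(genos = genos, nG = nG, cls = cls, s_adult = s_adult,
       bm_surv = bm_surv, fec = fec, off = off,
       n_feed = n_feed, n_inf = n_inf, n_mate = n_mate, d_f = d_f,
       pF_surv = rep(s_adult, times = prod(d_f[-1L])),
       allele_count = allele_count)
}

epi_init_state <- function(cfg, pre) {
  F <- array(0L, dim = pre$d_f)
  M <- setNames(integer(pre$nG), pre$genos)
  g0 <- match(cfg$init_genotype, pre$genos)
  if (is.na(g0)) stop("epi_config: unknown 'init_genotype'", call. = FALSE)
  F[g0, g0, 1L, 1L] <- cfg$init_adults
  M[g0] <- cfg$init_adults
  L <- matrix(0L, pre$nG, cfg$larval_duration,
              dimnames = list(pre$genos, NULL))
  I0 <- round(cfg$init_human_prev * cfg$human_population)
  list(F = F, M = M, L = L,
       hum_S = cfg$human_population - I0, hum_I = I0,
       day = 0L, cum_cases = 0L)
}

# One simulated day. Returns the updated state plus the day's summaries.
epi_step_day <- function(state, cfg, pre) {
  nG <- pre$nG; n_mate <- pre$n_mate; n_feed <- pre$n_feed; n_inf <- pre$n_inf
  F <- state$F
  alive_f <- sum(F)

  # adult survival (daily hazard scaled by fitness class)
  F <- array(rbinom(length(F), F, pre$pF_surv), dim = pre$d_f)
  M <- rbinom(nG, state$M, pre$s_adult)
  deaths_f <- alive_f - sum(F)

  # extrinsic incubation progression (pre-existing infections)
  if (n_inf > 2L) {
    FI <- F
    FI[, , , n_inf] <- F[, , , n_inf] + F[, , , n_inf - 1L]
    FI[, , , 3:(n_inf - 1L)] <- F[, , , 2:(n_inf - 2L)]
    FI[, , , 2L] <- 0L
    F <- FI
  }

  prev <- state$hum_I / cfg$human_population
  p_acq <- cfg$mosq_infect_prob * prev

  newF <- array(0L, dim = pre$d_f)
  # resting females advance one day
  if (n_feed > 3L)
    newF[, , 3:(n_feed - 1L), ] <- F[, , 2:(n_feed - 2L), ]
  # females completing the cycle oviposit and start seeking
  layers <- matrix(0, nG, n_mate)
  ripe <- F[, , n_feed - 1L, , drop = FALSE]
  if (sum(ripe) > 0) {
    layers <- apply(array(ripe, dim = c(nG, n_mate, n_inf)), c(1, 2), sum)
    newF[, , n_feed, ] <- newF[, , n_feed, ] + F[, , n_feed - 1L, ]
  }

  i_bites <- 0L
  bm_surv_arr <- rep(pre$bm_surv, times = n_mate * n_inf)
  for (st in c(1L, n_feed)) {
    seek <- F[, , st, ]
    tot <- sum(seek)
    if (tot == 0L) next
    succ <- array(rbinom(length(seek), seek, cfg$feed_success),
                  dim = c(nG, n_mate, n_inf))
    fail <- seek - succ
    newF[, , st, ] <- newF[, , st, ] + fail
    # the bite happens before any blood-meal death, so infectious bites are
    # counted on all successful feeds
    i_bites <- i_bites + sum(succ[, , n_inf])
    # blood-meal mortality (homozygous-LOF females only)
    if (cfg$fitness$bloodmeal_mort > 0)
      succ <- array(rbinom(length(succ), succ, bm_surv_arr),
                    dim = c(nG, n_mate, n_inf))
    # infection acquisition by susceptible feeders
    s_slice <- succ[, , 1L]
    acq <- if (p_acq > 0)
      matrix(rbinom(length(s_slice), s_slice, p_acq), nG, n_mate)
    else matrix(0L, nG, n_mate)
    succ[, , 1L] <- s_slice - acq
    newF[, , 2L, ] <- newF[, , 2L, ] + succ
    newF[, , 2L, 2L] <- newF[, , 2L, 2L] + acq
  }
  F <- newF

  # human infection dynamics (SIS with a clinical-incidence proxy)
  new_inf <- 0L
  if (i_bites > 0L && state$hum_S > 0L) {
    p_hit <- cfg$human_infect_prob * state$hum_S / cfg$human_population
    new_inf <- min(state$hum_S, rbinom(1L, i_bites, p_hit))
  }
  recov <- rbinom(1L, state$hum_I, cfg$human_clear_rate)
  hum_S <- state$hum_S - new_inf + recov
  hum_I <- state$hum_I + new_inf - recov

  # egg laying by females that completed a cycle today
  L <- state$L
  new_eggs <- numeric(nG)
  lay_idx <- which(layers > 0, arr.ind = TRUE)
  if (nrow(lay_idx) > 0L) {
    for (r in seq_len(nrow(lay_idx))) {
      gf <- lay_idx[r, 1L]; gm <- lay_idx[r, 2L]
      if (gm > nG) next  # unmated females lay no viable eggs
      n <- layers[gf, gm]
      eggs <- rpois(1L, n * cfg$eggs_per_batch * pre$fec[gf])
      if (eggs > 0L)
        new_eggs <- new_eggs + rmultinom(1L, eggs, pre$off[gf, gm, ])[, 1L]
    }
  }

  # larval survival (density dependent), ageing and emergence
  l_tot <- sum(L)
  if (l_tot > 0L) {
    s_L <- cfg$larval_daily_survival /
      (1 + l_tot / max(cfg$larval_capacity, 1e-9))
    L <- matrix(rbinom(length(L), L, s_L), nG, cfg$larval_duration)
  }
  emerged <- L[, cfg$larval_duration]
  if (cfg$larval_duration > 1L)
    L[, 2:cfg$larval_duration] <- L[, 1:(cfg$larval_duration - 1L)]
  L[, 1L] <- as.integer(round(new_eggs))

  # emergence: sex split, mating of new females against the male pool
  if (sum(emerged) > 0L) {
    new_f <- rbinom(nG, emerged, 0.5)
    new_m <- emerged - new_f
    tot_m <- sum(M)
    for (g in which(new_f > 0L)) {
      if (tot_m > 0L) {
        mates <- rmultinom(1L, new_f[g], M / tot_m)[, 1L]
        for (gm in which(mates > 0L))
          F[g, gm, 1L, 1L] <- F[g, gm, 1L, 1L] + mates[gm]
      } else {
        F[g, n_mate, 1L, 1L] <- F[g, n_mate, 1L, 1L] + new_f[g]
      }
    }
    M <- M + new_m
  }

  state$F <- F; state$M <- M; state$L <- L
  state$hum_S <- hum_S; state$hum_I <- hum_I
  state$day <- state$day + 1L
  state$cum_cases <- state$cum_cases + new_inf
  state$last <- list(new_inf = new_inf, i_bites = i_bites,
                     deaths_f = deaths_f, alive_f = alive_f)
  state
}

# Adult drive-locus allele frequencies (females by own genotype + males).
epi_allele_freqs <- function(state, pre) {
  f_by_g <- apply(array(state$F, dim = pre$d_f), 1L, sum)
  n <- f_by_g + state$M
  if (sum(n) == 0L) return(setNames(rep(NA_real_, 4L), DRIVE_ALLELES))
  cnt <- colSums(n * pre$allele_count)
  cnt / sum(cnt)
}

#' Run one transmission scenario
#'
#' Burns in to `release_day`, releases `release_size` D/D males, and
#' simulates to `horizon_days`, recording daily drive-locus allele
#' frequencies, adult counts, infectious bites and new human infections.
#' Reproducible given `seed`.
#'
#' @param config An [epi_config()] object.
#' @param seed Seed for this run (default `config$seed`).
#' @param record_every Record a summary row every this many days (default 1).
#' @return Data frame with columns `day`, `q_W`, `q_D`, `q_R1`, `q_R2`,
#'   `adult_females`, `adult_males`, `human_prev`, `new_infections`,
#'   `infectious_bites`, `female_deaths`, `female_days`.
#' @export
run_scenario <- function(config, seed = config$seed, record_every = 1L) {
  stopifnot(inherits(config, "epi_config"))
  set.seed(seed)
  pre <- epi_precompute(config)
  state <- epi_init_state(config, pre)
  days <- config$horizon_days
  keep <- seq(1L, days, by = record_every)
  rec <- matrix(NA_real_, length(keep), 12L)
  colnames(rec) <- c("day", "q_W", "q_D", "q_R1", "q_R2", "adult_females",
                     "adult_males", "human_prev", "new_infections",
                     "infectious_bites", "female_deaths", "female_days")
  ri <- 0L
  g_dd <- match("D/D", pre$genos)
  for (d in seq_len(days)) {
    if (d == config$release_day && config$release_size > 0L)
      state$M[g_dd] <- state$M[g_dd] + config$release_size
    state <- epi_step_day(state, config, pre)
    if (d %in% keep) {
      ri <- ri + 1L
      q <- epi_allele_freqs(state, pre)
      rec[ri, ] <- c(d, q, sum(state$F), sum(state$M),
                     state$hum_I / config$human_population,
                     state$last$new_inf, state$last$i_bites,
                     state$last$deaths_f, state$last$alive_f)
    }
  }
  out <- as.data.frame(rec)
  attr(out, "final_state") <- state
  out
}

#' Annualised EIR over a day window
#'
#' @param traj Output of [run_scenario()].
#' @param config The matching [epi_config()].
#' @param days Vector of days to average over (default: all recorded days).
#' @return Infectious bites per person per year.
#' @export
annual_EIR <- function(traj, config, days = traj$day) {
  idx <- traj$day %in% days
  sum(traj$infectious_bites[idx]) * 365 /
    (config$human_population * sum(idx))
}

#' Calibrate larval capacity to a target transmission intensity
#'
#' Bisection (on log capacity) such that the no-release equilibrium annual
#' EIR is within `tol` (default 20%) of `config$target_EIR`, averaged over
#' `cal_replicates` replicate burn-ins.
#'
#' @param config An [epi_config()] object.
#' @param cal_burn_days Days discarded before measuring EIR (default 150).
#' @param cal_days Days over which EIR is measured (default 250).
#' @param cal_replicates Replicate burn-ins averaged per evaluation
#'   (default 5).
#' @param tol Relative tolerance on the achieved EIR (default 0.2).
#' @param K_range Initial bracket for the capacity search.
#' @param max_iter Maximum bisection steps (default 14).
#' @return The calibrated capacity, with attributes `achieved_EIR` and
#'   `evaluations` (a data frame of all capacity/EIR evaluations).
#' @export
calibrate_density <- function(config, cal_burn_days = 150, cal_days = 250,
                              cal_replicates = 5, tol = 0.2,
                              K_range = c(100, 1e6), max_iter = 14) {
  stopifnot(inherits(config, "epi_config"))
  target <- config$target_EIR
  if (is.null(target) || target <= 0)
    stop("calibrate_density: 'target_EIR' must be set and positive",
         call. = FALSE)
  evals <- data.frame(capacity = numeric(0), EIR = numeric(0))
  eval_K <- function(K) {
    cfg <- config
    cfg$larval_capacity <- K
    cfg$release_size <- 0L
    cfg$horizon_days <- as.integer(cal_burn_days + cal_days)
    cfg$release_day <- cfg$horizon_days - 1L  # inert, size 0
    eirs <- vapply(seq_len(cal_replicates), function(i) {
      tr <- run_scenario(cfg, seed = config$seed + 7919L * i)
      annual_EIR(tr, cfg, days = (cal_burn_days + 1):cfg$horizon_days)
    }, numeric(1L))
    m <- mean(eirs)
    evals[nrow(evals) + 1L, ] <<- c(K, m)
    m
  }
  lo <- K_range[1L]; hi <- K_range[2L]
  e_lo <- eval_K(lo)
  if (abs(e_lo - target) / target <= tol) {
    return(structure(lo, achieved_EIR = e_lo, evaluations = evals))
  }
  e_hi <- eval_K(hi)
  if (abs(e_hi - target) / target <= tol) {
    return(structure(hi, achieved_EIR = e_hi, evaluations = evals))
  }
  if ((e_lo - target) * (e_hi - target) > 0)
    stop("calibrate_density: target EIR ", target,
         " not bracketed by capacities [", lo, ", ", hi, "] (achieved ",
         signif(e_lo, 3), " and ", signif(e_hi, 3), ")", call. = FALSE)
  for (it in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)
    e_mid <- eval_K(mid)
    if (abs(e_mid - target) / target <= tol)
      return(structure(mid, achieved_EIR = e_mid, evaluations = evals))
    if ((e_lo - target) * (e_mid - target) < 0) {
      hi <- mid; e_hi <- e_mid
    } else {
      lo <- mid; e_lo <- e_mid
    }
  }
  stop("calibrate_density: failed to reach EIR ", target, " within ",
       100 * tol, "% after ", max_iter, " bisection steps; last achieved ",
       signif(e_mid, 3), call. = FALSE)
}

#' Percentage reduction in clinical cases versus baseline
#'
#' @param scenario_cases,baseline_cases Case counts (scalars) accumulated
#'   over matching post-release windows.
#' @return `100 * (1 - scenario/baseline)`.
#' @export
case_reduction <- function(scenario_cases, baseline_cases) {
  if (length(scenario_cases) != length(baseline_cases))
    stop("case_reduction: mismatched lengths", call. = FALSE)
  if (any(baseline_cases == 0))
    stop("case_reduction: baseline has zero cases; reduction undefined",
         call. = FALSE)
  100 * (1 - scenario_cases / baseline_cases)
}

# Per-replicate post-release summaries of one scenario trajectory.
epi_summarise_replicate <- function(traj, config) {
  post <- traj$day > config$release_day
  final_year <- traj$day > config$horizon_days - 365L
  list(cases_post = sum(traj$new_infections[post]),
       cases_final_year = sum(traj$new_infections[final_year]),
       eradicated = {
         last <- traj[nrow(traj), ]
         (last$adult_females + last$adult_males) == 0
       },
       final_q_D = traj$q_D[nrow(traj)],
       final_q_R1 = traj$q_R1[nrow(traj)])
}

#' Parameter sweep over drive fitness and resistance scenarios
#'
#' Runs every combination of functional-resistance fraction, homozygote
#' daily-mortality multiplier and blood-meal mortality, each with
#' `config$replicates` stochastic replicates, against shared no-release
#' baseline replicates. Replicate `i` of every cell uses seed
#' `config$seed + i`, so cells share random seeds for paired comparisons.
#'
#' @param config An [epi_config()] object (its `larval_capacity` defines the
#'   transmission scenario; calibrate first via [calibrate_density()]).
#' @param functional_fractions,mort_mults,bloodmeal_morts Grid values of the
#'   three drive-phenotype axes.
#' @return An object of class `sweep_result`: a data frame with one row per
#'   parameter combination (mean percentage case reduction over the
#'   post-release window, elimination probability = fraction of replicates
#'   with zero new infections in the final year, vector-eradication count,
#'   mean final drive and R1 frequencies), with the per-replicate baseline
#'   case counts as attribute `"baseline_cases"`.
#' @export
run_sweep <- function(config,
                      functional_fractions = c(0.001, 0.01, 0.1),
                      mort_mults = c(1, 1.75, 2.5),
                      bloodmeal_morts = c(0, 0.5, 1)) {
  stopifnot(inherits(config, "epi_config"))
  reps <- config$replicates
  base_cfg <- config
  base_cfg$release_size <- 0L
  baseline <- vapply(seq_len(reps), function(i) {
    tr <- run_scenario(base_cfg, seed = config$seed + i)
    epi_summarise_replicate(tr, base_cfg)$cases_post
  }, numeric(1L))
  grid <- expand.grid(functional_fraction = functional_fractions,
                      mort_mult = mort_mults,
                      bloodmeal_mort = bloodmeal_morts,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    cfg <- config
    cfg$drive$functional_fraction <- grid$functional_fraction[k]
    cfg$fitness <- fitness_params(
      daily_mort_mult_hom = grid$mort_mult[k],
      bloodmeal_mort_hom = grid$bloodmeal_mort[k],
      fecundity_mult = config$fitness$fecundity,
      mating_weight = config$fitness$mating_weight)
    sums <- lapply(seq_len(reps), function(i) {
      tr <- run_scenario(cfg, seed = config$seed + i)
      epi_summarise_replicate(tr, cfg)
    })
    cases <- vapply(sums, `[[`, numeric(1L), "cases_post")
    data.frame(
      functional_fraction = grid$functional_fraction[k],
      mort_mult = grid$mort_mult[k],
      bloodmeal_mort = grid$bloodmeal_mort[k],
      target_EIR = config$target_EIR,
      mean_case_reduction = case_reduction(mean(cases), mean(baseline)),
      elimination_prob = mean(vapply(sums, function(s)
        s$cases_final_year == 0, logical(1L))),
      eradication_count = sum(vapply(sums, `[[`, logical(1L), "eradicated")),
      mean_final_q_D = mean(vapply(sums, `[[`, numeric(1L), "final_q_D")),
      mean_final_q_R1 = mean(vapply(sums, `[[`, numeric(1L), "final_q_R1")),
      replicates = reps)
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline_cases") <- baseline
  class(out) <- c("sweep_result", class(out))
  out
}
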