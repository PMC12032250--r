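#' @importFrom stats rbinom rpois rhyper rmultinom rgeom qbeta binom.test lm
#'   predict coef vcov optimise setNames median sd quantile
#' @importFrom utils modifyList write.csv read.csv
NULL

# Allele universes. At the drive locus the functional class is {W, R1} and the
# loss-of-function (LOF) class is {D, R2}; the effector locus carries the
# wild-type target (C), the trans-acting effector (E) and a cleavage-resistant
# target variant (CR) that is treated as functionally wild type.
DRIVE_ALLELES <- c("W", "D", "R1", "R2")
EFFECTOR_ALLELES <- c("C", "E", "CR")
LOF_ALLELES <- c("D", "R2")

HAPLOTYPES <- as.vector(outer(DRIVE_ALLELES, EFFECTOR_ALLELES,
                              function(d, e) paste(d, e, sep = ":")))

#' Drive and effector inheritance parameters
#'
#' Bundles the parameters of the homing model: sex-specific drive homing
#' probabilities, the fate of non-homed alleles (uncut fraction and the
#' functional fraction of newly formed resistance alleles), the analogous
#' parameters for the trans-acting effector locus, and the recombination
#' fraction between the two loci.
#'
#' `homing_female`/`homing_male` are the probabilities that a drive/wild-type
#' heterozygote parent transmits the drive allele (the measured inheritance
#' rates, 0.996 and 0.971). Non-drive gametes from such a parent remain
#' wild type with share `uncut_fraction`; the remainder become resistance
#' alleles, of which a share `functional_fraction` retain target-gene function
#' (R1) and the rest do not (R2). The effector locus homes with probability
#' `effector_homing` only in individuals that also carry a drive allele
#' (Cas9 in trans); its residual split uses `effector_uncut_fraction` with the
#' non-uncut residual becoming the cleavage-resistant variant CR.
#' `recombination_fraction` is the meiotic recombination fraction between the
#' two loci (0.5 = unlinked, the default).
#'
#' With `homing = 0.5` and `uncut_fraction = 1` the drive locus is Mendelian.
#'
#' @param homing_female,homing_male Probability of drive transmission from a
#'   D/W heterozygote mother/father, in `[0, 1]`.
#' @param uncut_fraction Share `u` of non-drive gametes from D/W parents that
#'   remain wild type (default 0: all residual alleles become resistance).
#' @param functional_fraction Share `f` of newly generated resistance alleles
#'   that are functional (R1); e.g. 1/10, 1/100, 1/1000.
#' @param effector_homing Probability of effector transmission from an E/C
#'   heterozygote that carries at least one drive allele.
#' @param effector_uncut_fraction Share of non-effector gametes from such
#'   individuals that remain the cleavable target C.
#' @param recombination_fraction Recombination fraction `r` between the drive
#'   and effector loci, in `[0, 0.5]`.
#' @return An object of class `drive_params`.
#' @export
drive_params <- function(homing_female = 0.996,
                         homing_male = 0.971,
                         uncut_fraction = 0,
                         functional_fraction = 0.1,
                         effector_homing = 0.95,
                         effector_uncut_fraction = 0,
                         recombination_fraction = 0.5) {
  p <- list(homing_female = homing_female,
            homing_male = homing_male,
            uncut_fraction = uncut_fraction,
            functional_fraction = functional_fraction,
            effector_homing = effector_homing,
            effector_uncut_fraction = effector_uncut_fraction,
            recombination_fraction = recombination_fraction)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("drive_params: '", nm, "' must be a single probability in [0, 1]",
           call. = FALSE)
  }
  if (p$recombination_fraction > 0.5)
    stop("drive_params: 'recombination_fraction' must be <= 0.5", call. = FALSE)
  structure(p, class = "drive_params")
}

#' Genotype-to-fitness parameters
#'
#' Maps the three drive-locus fitness classes (functional, heterozygous LOF,
#' homozygous LOF) to demographic rates. Daily mortality is scaled by a hazard
#' multiplier: `daily_mort_mult_hom` for LOF homozygotes (modelled range
#' 1–2.5) and, by the half-impact rule, `1 + (m_hom - 1)/2` for heterozygotes
#' unless overridden. `bloodmeal_mort_hom` is the probability that a
#' LOF-homozygous female dies as a consequence of taking a blood meal; it
#' applies to homozygotes only. Fecundity and mating-weight multipliers
#' default to 1 for every class (no measurable effect on fertility or
#' fecundity); they may be given as a single number applied to LOF homozygotes
#' or as a named vector over the three classes.
#'
#' @param daily_mort_mult_hom Daily mortality hazard multiplier for
#'   LOF homozygotes (>= 1 in the modelled range, any positive value allowed).
#' @param daily_mort_mult_het Multiplier for heterozygotes; default
#'   `1 + (daily_mort_mult_hom - 1)/2`.
#' @param bloodmeal_mort_hom Per-blood-meal death probability for
#'   LOF-homozygous females, in `[0, 1]`.
#' @param fecundity_mult,mating_weight Scalar (applied to the homozygous-LOF
#'   class) or named vector over classes `functional`, `heterozygous_LOF`,
#'   `homozygous_LOF`.
#' @return An object of class `fitness_params` with per-class vectors
#'   `mort_mult`, `fecundity`, `mating_weight` and scalar `bloodmeal_mort`.
#' @export
fitness_params <- function(daily_mort_mult_hom = 1,
                           daily_mort_mult_het = NULL,
                           bloodmeal_mort_hom = 0,
                           fecundity_mult = 1,
                           mating_weight = 1) {
  if (!is.numeric(daily_mort_mult_hom) || daily_mort_mult_hom <= 0)
    stop("fitness_params: 'daily_mort_mult_hom' must be positive", call. = FALSE)
  if (is.null(daily_mort_mult_het))
    daily_mort_mult_het <- 1 + (daily_mort_mult_hom - 1) / 2
  if (!is.numeric(bloodmeal_mort_hom) || bloodmeal_mort_hom < 0 ||
      bloodmeal_mort_hom > 1)
    stop("fitness_params: 'bloodmeal_mort_hom' must be in [0, 1]", call. = FALSE)
  classes <- c("functional", "heterozygous_LOF", "homozygous_LOF")
  expand <- function(x, what) {
    if (length(x) == 1L && is.null(names(x)))
      x <- c(functional = 1, heterozygous_LOF = 1, homozygous_LOF = x)
    if (!all(classes %in% names(x)))
      stop("fitness_params: '", what, "' must name all three fitness classes",
           call. = FALSE)
    x <- x[classes]
    if (any(x < 0)) stop("fitness_params: '", what, "' must be >= 0",
                         call. = FALSE)
    x
  }
  structure(list(
    mort_mult = c(functional = 1,
                  heterozygous_LOF = daily_mort_mult_het,
                  homozygous_LOF = daily_mort_mult_hom),
    bloodmeal_mort = bloodmeal_mort_hom,
    fecundity = expand(fecundity_mult, "fecundity_mult"),
    mating_weight = expand(mating_weight, "mating_weight")),
    class = "fitness_params")
}

#' Construct a two-locus diplotype
#'
#' A diplotype is the phased two-locus genotype of one individual: two
#' haplotypes, each a (drive allele, effector allele) pair, plus a sex.
#' Haplotypes are canonicalised by lexicographic sort so that a swap of the
#' two homologues yields an identical object.
#'
#' @param drive Character vector of two drive-locus alleles from
#'   `c("W", "D", "R1", "R2")`; `drive[i]` pairs with `effector[i]`.
#' @param effector Character vector of two effector-locus alleles from
#'   `c("C", "E", "CR")`.
#' @param sex `"female"` or `"male"`.
#' @return An object of class `diplotype` with elements `drive`, `effector`,
#'   `sex`.
#' @export
diplotype <- function(drive, effector = c("C", "C"), sex = "female") {
  if (length(drive) != 2L || !all(drive %in% DRIVE_ALLELES))
    stop("diplotype: 'drive' must be two alleles from {W, D, R1, R2}",
         call. = FALSE)
  if (length(effector) != 2L || !all(effector %in% EFFECTOR_ALLELES))
    stop("diplotype: 'effector' must be two alleles from {C, E, CR}",
         call. = FALSE)
  sex <- match.arg(sex, c("female", "male"))
  haps <- paste(drive, effector, sep = ":")
  o <- order(haps)
  structure(list(drive = drive[o], effector = effector[o], sex = sex),
            class = "diplotype")
}

#' @export
print.diplotype <- function(x, ...) {
  cat(sprintf("<diplotype %s, %s>\n", genotype_label(x), x$sex))
  invisible(x)
}

#' Canonical genotype label of a diplotype
#'
#' @param x A `diplotype`.
#' @return A string such as `"D:C/W:C"` (haplotypes sorted).
#' @export
genotype_label <- function(x) {
  paste(paste(x$drive, x$effector, sep = ":"), collapse = "/")
}

#' Parse a canonical genotype label into a diplotype
#'
#' @param label Genotype string such as `"D:C/W:C"`.
#' @param sex `"female"` or `"male"`.
#' @return A `diplotype`.
#' @export
parse_genotype <- function(label, sex = "female") {
  haps <- strsplit(label, "/", fixed = TRUE)[[1L]]
  if (length(haps) != 2L)
    stop("parse_genotype: expected 'd1:e1/d2:e2'", call. = FALSE)
  parts <- strsplit(haps, ":", fixed = TRUE)
  diplotype(drive = c(parts[[1L]][1L], parts[[2L]][1L]),
            effector = c(parts[[1L]][2L], parts[[2L]][2L]),
            sex = sex)
}

#' Drive-locus fitness class of a genotype
#'
#' The drive allele and non-functional resistance are equivalent in fitness,
#' as are wild type and functional resistance. An individual is
#' `homozygous_LOF` iff both drive-locus alleles are in `{D, R2}`,
#' `functional` iff both are in `{W, R1}`, else `heterozygous_LOF`.
#'
#' @param x A `diplotype`, or a character vector of two drive alleles.
#' @return One of `"functional"`, `"heterozygous_LOF"`, `"homozygous_LOF"`.
#' @export
drive_fitness_class <- function(x) {
  drive <- if (inherits(x, "diplotype")) x$drive else x
  n_lof <- sum(drive %in% LOF_ALLELES)
  switch(n_lof + 1L, "functional", "heterozygous_LOF", "homozygous_LOF")
}

# Marginal gamete distribution at the drive locus for an unordered pair of
# alleles, given the sex-appropriate homing probability h.
drive_gamete_marginal <- function(drive, h, params) {
  out <- setNames(numeric(4L), DRIVE_ALLELES)
  if (("D" %in% drive) && ("W" %in% drive)) {
    u <- params$uncut_fraction
    f <- params$functional_fraction
    out["D"] <- h
    out["W"] <- (1 - h) * u
    out["R1"] <- (1 - h) * (1 - u) * f
    out["R2"] <- (1 - h) * (1 - u) * (1 - f)
  } else {
    out[drive[1L]] <- out[drive[1L]] + 0.5
    out[drive[2L]] <- out[drive[2L]] + 0.5
  }
  out
}

# Marginal gamete distribution at the effector locus; homing is active only
# when the individual carries a drive allele and is an E/C heterozygote.
effector_gamete_marginal <- function(effector, has_drive, params) {
  out <- setNames(numeric(3L), EFFECTOR_ALLELES)
  if (has_drive && ("E" %in% effector) && ("C" %in% effector)) {
    hE <- params$effector_homing
    uE <- params$effector_uncut_fraction
    out["E"] <- hE
    out["C"] <- (1 - hE) * uE
    out["CR"] <- (1 - hE) * (1 - uE)
  } else {
    out[effector[1L]] <- out[effector[1L]] + 0.5
    out[effector[2L]] <- out[effector[2L]] + 0.5
  }
  out
}

#' Gamete distribution of a diplotype
#'
#' Computes the exact distribution over transmitted haplotypes. At the drive
#' locus a D/W heterozygote transmits D with the sex-specific homing
#' probability; the residual splits into W (share `uncut_fraction`), R1 and
#' R2. Any other drive genotype segregates Mendelianly. The effector locus
#' homes analogously, but only in individuals carrying at least one drive
#' allele. Homing is modelled as in-situ conversion of the cleavable allele on
#' the homologous chromosome before meiosis, followed by recombination at
#' fraction `r`; with `r = 0.5` (default) the two loci segregate
#' independently.
#'
#' @param dip A `diplotype`.
#' @param params A `drive_params` object.
#' @return Named numeric vector of probabilities over the 12 haplotypes
#'   `"W:C"` ... `"R2:CR"`, summing to 1.
#' @export
gamete_distribution <- function(dip, params) {
  stopifnot(inherits(dip, "diplotype"), inherits(params, "drive_params"))
  h <- if (dip$sex == "female") params$homing_female else params$homing_male
  has_drive <- "D" %in% dip$drive
  r <- params$recombination_fraction

  dm <- drive_gamete_marginal(dip$drive, h, params)
  em <- effector_gamete_marginal(dip$effector, has_drive, params)

  joint <- function(d, e) outer(d, e, "*")

  drive_het <- ("D" %in% dip$drive) && ("W" %in% dip$drive)
  eff_het <- has_drive && ("E" %in% dip$effector) && ("C" %in% dip$effector)
  both_segregating <- length(unique(dip$drive)) > 1L &&
    length(unique(dip$effector)) > 1L

  if (r == 0.5 || !both_segregating) {
    g <- joint(dm, em)
  } else {
    # Chromosome model: per-homologue post-conversion allele distributions,
    # then segregation with recombination. Conversion probability 2h - 1 on
    # the target homologue reproduces the gamete-level marginal P(D) = h;
    # this mechanistic route requires h >= 0.5 where conversion is active.
    if (drive_het && h < 0.5)
      stop("gamete_distribution: linked inheritance (r < 0.5) requires ",
           "homing >= 0.5 in a D/W heterozygote", call. = FALSE)
    if (eff_het && params$effector_homing < 0.5)
      stop("gamete_distribution: linked inheritance (r < 0.5) requires ",
           "effector homing >= 0.5 in an E/C drive carrier", call. = FALSE)
    conv_drive <- lapply(1:2, function(i) {
      a <- dip$drive[i]
      out <- setNames(numeric(4L), DRIVE_ALLELES)
      if (drive_het && a == "W") {
        u <- params$uncut_fraction; f <- params$functional_fraction
        out["D"] <- 2 * h - 1
        out["W"] <- 2 * (1 - h) * u
        out["R1"] <- 2 * (1 - h) * (1 - u) * f
        out["R2"] <- 2 * (1 - h) * (1 - u) * (1 - f)
      } else out[a] <- 1
      out
    })
    conv_eff <- lapply(1:2, function(i) {
      a <- dip$effector[i]
      out <- setNames(numeric(3L), EFFECTOR_ALLELES)
      if (eff_het && a == "C") {
        hE <- params$effector_homing; uE <- params$effector_uncut_fraction
        out["E"] <- 2 * hE - 1
        out["C"] <- 2 * (1 - hE) * uE
        out["CR"] <- 2 * (1 - hE) * (1 - uE)
      } else out[a] <- 1
      out
    })
    g <- matrix(0, 4L, 3L, dimnames = list(DRIVE_ALLELES, EFFECTOR_ALLELES))
    for (i in 1:2) for (j in 1:2) {
      w <- 0.5 * (if (i == j) 1 - r else r)
      g <- g + w * joint(conv_drive[[i]], conv_eff[[j]])
    }
  }
  setNames(as.vector(g), HAPLOTYPES)
}

#' Expected drive inheritance rate from a heterozygous parent
#'
#' @param params A `drive_params` object.
#' @param sex `"female"` or `"male"`.
#' @return The probability that a D/W parent of the given sex transmits the
#'   drive allele (its sex-specific homing probability).
#' @export
expected_inheritance <- function(params, sex = c("female", "male")) {
  sex <- match.arg(sex)
  if (sex == "female") params$homing_female else params$homing_male
}

#' Offspring genotype distribution of a cross
#'
#' Outer product of the parental gamete distributions, collapsed onto
#' canonical (unordered) offspring genotypes. Offspring sex is independent
#' Bernoulli(0.5) and is not part of the returned table.
#'
#' @param mother,father `diplotype` objects with `sex` `"female"` and
#'   `"male"` respectively.
#' @param params A `drive_params` object.
#' @return Named numeric vector of probabilities over canonical genotype
#'   labels, summing to 1.
#' @export
cross_distribution <- function(mother, father, params) {
  if (!inherits(mother, "diplotype") || mother$sex != "female")
    stop("cross_distribution: 'mother' must be a female diplotype",
         call. = FALSE)
  if (!inherits(father, "diplotype") || father$sex != "male")
    stop("cross_distribution: 'father' must be a male diplotype",
         call. = FALSE)
  gm <- gamete_distribution(mother, params)
  gf <- gamete_distribution(father, params)
  nz_m <- which(gm > 0); nz_f <- which(gf > 0)
  out <- new.env(parent = emptyenv())
  for (i in nz_m) for (j in nz_f) {
    haps <- sort(c(HAPLOTYPES[i], HAPLOTYPES[j]))
    key <- paste(haps, collapse = "/")
    prev <- if (is.null(out[[key]])) 0 else out[[key]]
    out[[key]] <- prev + gm[[i]] * gf[[j]]
  }
  keys <- sort(ls(out))
  setNames(vapply(keys, function(k) out[[k]], numeric(1L)), keys)
}

#' Probability that an offspring carries a given allele
#'
#' Convenience summary of a `cross_distribution` result.
#'
#' @param dist Named probability vector over genotype labels.
#' @param allele Allele identity, e.g. `"D"` or `"E"`.
#' @return Probability that the offspring carries at least one copy.
#' @export
carrier_probability <- function(dist, allele = "D") {
  hit <- vapply(names(dist), function(lbl) {
    alleles <- unlist(strsplit(unlist(strsplit(lbl, "/", fixed = TRUE)),
                               ":", fixed = TRUE))
    allele %in% alleles
  }, logical(1L))
  sum(dist[hit])
}

# All 10 unordered drive-locus genotypes, in a fixed order.
drive_genotypes <- function() {
  out <- character(0)
  for (i in seq_along(DRIVE_ALLELES)) for (j in i:length(DRIVE_ALLELES))
    out <- c(out, paste(DRIVE_ALLELES[i], DRIVE_ALLELES[j], sep = "/"))
  out
}

# Drive-locus-only gamete distribution for a genotype "a/b" given homing h.
drive_gamete_for <- function(geno, h, params) {
  drive_gamete_marginal(strsplit(geno, "/", fixed = TRUE)[[1L]], h, params)
}

#' Deterministic one-generation allele-frequency recursion
#'
#' Infinite-population recursion at the drive locus: forms Hardy-Weinberg
#' genotype frequencies from the current allele frequencies, weights
#' genotypes by their fitness-class relative weight, applies the gamete
#' distribution of each genotype (sex-specific homing, averaged over the two
#' parental sexes), and returns the normalised next-generation allele
#' frequency vector. Serves as the mean-field oracle for the stochastic
#' simulators.
#'
#' @param freqs Named numeric vector of frequencies over `W, D, R1, R2`,
#'   summing to 1.
#' @param params A `drive_params` object.
#' @param genotype_weights Named relative weights for the classes
#'   `functional`, `heterozygous_LOF`, `homozygous_LOF`.
#' @return Named frequency vector over `W, D, R1, R2` summing to 1.
#' @export
deterministic_step <- function(freqs, params,
                               genotype_weights = c(functional = 1,
                                                    heterozygous_LOF = 1,
                                                    homozygous_LOF = 1)) {
  stopifnot(inherits(params, "drive_params"))
  freqs <- freqs[DRIVE_ALLELES]
  if (any(is.na(freqs)) || any(freqs < 0))
    stop("deterministic_step: 'freqs' must be named over {W, D, R1, R2} and ",
         "non-negative", call. = FALSE)
  if (abs(sum(freqs) - 1) > 1e-8)
    stop("deterministic_step: frequencies must sum to 1", call. = FALSE)
  genos <- drive_genotypes()
  gf <- vapply(genos, function(g) {
    a <- strsplit(g, "/", fixed = TRUE)[[1L]]
    if (a[1L] == a[2L]) freqs[[a[1L]]]^2 else 2 * freqs[[a[1L]]] * freqs[[a[2L]]]
  }, numeric(1L))
  cls <- vapply(genos, function(g)
    drive_fitness_class(strsplit(g, "/", fixed = TRUE)[[1L]]), character(1L))
  w <- gf * genotype_weights[cls]
  if (sum(w) <= 0)
    stop("deterministic_step: all genotype weights are zero (degenerate ",
         "population)", call. = FALSE)
  w <- w / sum(w)
  gam <- setNames(numeric(4L), DRIVE_ALLELES)
  for (k in seq_along(genos)) {
    if (w[k] == 0) next
    gam <- gam + w[k] * 0.5 *
      (drive_gamete_for(genos[k], params$homing_female, params) +
       drive_gamete_for(genos[k], params$homing_male, params))
  }
  gam / sum(gam)
}

#' Iterate the deterministic recursion
#'
#' @param freqs Initial allele frequency vector over `W, D, R1, R2`.
#' @param params A `drive_params` object.
#' @param generations Number of generations to iterate.
#' @param genotype_weights Passed to [deterministic_step()].
#' @return Matrix with `generations + 1` rows (including generation 0) and
#'   columns `W, D, R1, R2`.
#' @export
deterministic_trajectory <- function(freqs, params, generations,
                                     genotype_weights = c(functional = 1,
                                                          heterozygous_LOF = 1,
                                                          homozygous_LOF = 1)) {
  out <- matrix(NA_real_, generations + 1L, 4L,
                dimnames = list(NULL, DRIVE_ALLELES))
  out[1L, ] <- freqs[DRIVE_ALLELES]
  f <- freqs
  for (g in seq_len(generations)) {
    f <- deterministic_step(f, params, genotype_weights)
    out[g + 1L, ] <- f
  }
  out
}
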