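# Estimators linking experimental readouts (cross progeny counts, survival
# medians, screened carrier frequencies, egg output series) to the simulator
# parameters, plus parameter-recovery harnesses on synthetic data.

#' Exact binomial estimate of a transmission rate
#'
#' Point estimate and Clopper-Pearson exact interval for the drive
#' transmission probability from pooled cross progeny counts.
#'
#' @param n_drive_carriers Progeny carrying the drive marker.
#' @param n_progeny Total scored progeny (> 0).
#' @param conf_level Confidence level (default 0.95).
#' @return List with `estimate`, `lower`, `upper`, `conf_level`, `n`.
#' @export
estimate_transmission <- function(n_drive_carriers, n_progeny,
                                  conf_level = 0.95) {
  if (length(n_progeny) != 1L || n_progeny <= 0)
    stop("estimate_transmission: 'n_progeny' must be a single positive count",
         call. = FALSE)
  if (n_drive_carriers < 0 || n_drive_carriers > n_progeny)
    stop("estimate_transmission: carriers must be in [0, n_progeny]",
         call. = FALSE)
  bt <- binom.test(n_drive_carriers, n_progeny, conf.level = conf_level)
  list(estimate = n_drive_carriers / n_progeny,
       lower = bt$conf.int[1L], upper = bt$conf.int[2L],
       conf_level = conf_level, n = n_progeny)
}

#' Daily survival probability from a median lifespan
#'
#' Under the constant-hazard (geometric lifetime) model used by the
#' simulators, a median lifespan of `m` days corresponds to a daily survival
#' `p` with `p^m = 0.5`.
#'
#' @param median_days Median lifespan in days (>= 1).
#' @return Daily survival probability `0.5^(1/median_days)`.
#' @export
daily_survival_from_median <- function(median_days) {
  if (any(median_days < 1))
    stop("daily_survival_from_median: median must be >= 1 day", call. = FALSE)
  0.5 ^ (1 / median_days)
}

#' Mortality hazard multiplier from two median lifespans
#'
#' Constant-hazard conversion of a lifespan reduction into the daily
#' mortality multiplier used by the simulators: the hazard `-log p` scales
#' inversely with the median, so the multiplier is `median_ref/median_alt`.
#'
#' @param median_ref Reference (wild-type) median lifespan in days.
#' @param median_alt Median lifespan of the affected genotype.
#' @return Hazard-ratio multiplier.
#' @export
mortality_multiplier_from_medians <- function(median_ref, median_alt) {
  if (any(median_ref < 1) || any(median_alt < 1))
    stop("mortality_multiplier_from_medians: medians must be >= 1 day",
         call. = FALSE)
  median_ref / median_alt
}

#' Convert a carrier frequency to an allele frequency
#'
#' Under Hardy-Weinberg proportions the fraction of individuals carrying at
#' least one transgene copy is `1 - (1 - q)^2`; this inverts that map.
#' Approximate in the first generations after seeding, when founders are
#' homozygous and genotypes are not yet at Hardy-Weinberg proportions.
#'
#' @param carrier_freq Carrier frequency in `[0, 1]`.
#' @return Allele frequency `1 - sqrt(1 - carrier_freq)`.
#' @export
carrier_to_allele_freq <- function(carrier_freq) {
  if (any(carrier_freq < 0 | carrier_freq > 1))
    stop("carrier_to_allele_freq: input must be in [0, 1]", call. = FALSE)
  1 - sqrt(1 - carrier_freq)
}

#' @rdname carrier_to_allele_freq
#' @param allele_freq Allele frequency in `[0, 1]`.
#' @export
allele_to_carrier_freq <- function(allele_freq) {
  if (any(allele_freq < 0 | allele_freq > 1))
    stop("allele_to_carrier_freq: input must be in [0, 1]", call. = FALSE)
  1 - (1 - allele_freq)^2
}

#' Quadratic trend of egg output over generations
#'
#' Least-squares quadratic in the generation index, optionally excluding the
#' setup generation (generation 0, in which all transgene carriers are
#' homozygous), with pointwise standard errors of the fitted line.
#'
#' @param generation Generation indices.
#' @param egg_output Egg counts per generation (same length).
#' @param exclude_generation_zero Drop generation 0 before fitting
#'   (default TRUE).
#' @return List with `coefficients` (intercept, linear, quadratic),
#'   `std_errors` (of the coefficients), `fitted` (data frame `generation`,
#'   `fit`, `se`), and the underlying `lm` fit as `model`.
#' @export
fit_egg_trend <- function(generation, egg_output,
                          exclude_generation_zero = TRUE) {
  stopifnot(length(generation) == length(egg_output))
  keep <- !is.na(egg_output)
  if (exclude_generation_zero) keep <- keep & generation != 0
  g <- generation[keep]; y <- egg_output[keep]
  if (length(g) < 4L)
    stop("fit_egg_trend: need at least 4 points after exclusion",
         call. = FALSE)
  fit <- lm(y ~ g + I(g^2))
  pr <- predict(fit, newdata = data.frame(g = g), se.fit = TRUE)
  list(coefficients = setNames(coef(fit),
                               c("intercept", "linear", "quadratic")),
       std_errors = setNames(sqrt(diag(vcov(fit))),
                             c("intercept", "linear", "quadratic")),
       fitted = data.frame(generation = g, fit = pr$fit, se = pr$se.fit),
       model = fit)
}

#' Calibrate blood-meal mortality against a carrier-frequency trajectory
#'
#' Fits the blood-meal mortality parameter of the cage simulator by
#' minimising the mean squared difference between an observed drive
#' carrier-frequency trajectory and simulated trajectories, averaged over
#' replicate simulated cages.
#'
#' @param observed Numeric vector of drive carrier frequencies by generation
#'   (generation 0 first).
#' @param config A [cage_config()] describing the cage protocol; its
#'   `fitness$bloodmeal_mort` is the parameter being fitted.
#' @param interval Search interval for the mortality (default `c(0, 1)`).
#' @param replicates Simulated replicates per evaluation (default 4).
#' @return List with `estimate` and `objective`.
#' @export
calibrate_bloodmeal_mort <- function(observed, config, interval = c(0, 1),
                                     replicates = 4) {
  objective <- function(b) {
    cfg <- config
    cfg$fitness$bloodmeal_mort <- b
    cfg$generations <- length(observed) - 1L
    sim <- run_cages(cfg, replicates)
    agg <- tapply(sim$drive_carrier_freq, sim$generation, mean, na.rm = TRUE)
    gens <- as.integer(names(agg))
    obs <- observed[gens + 1L]
    mean((agg - obs)^2, na.rm = TRUE)
  }
  opt <- optimise(objective, interval = interval, tol = 0.02)
  list(estimate = opt$minimum, objective = opt$objective)
}

#' Parameter recovery on synthetic data
#'
#' Runs the estimator matching a synthetic-data scenario against data with
#' known ground truth and reports bias and interval coverage.
#'
#' @param model One of `"cross"` (transmission-rate recovery over replicate
#'   synthetic cross tables), `"survival"` (daily survival from simulated
#'   lifetimes) or `"cage"` (blood-meal mortality from simulated cage
#'   trajectories).
#' @param truth The true parameter value.
#' @param n_replicates Number of synthetic datasets.
#' @param n_per_replicate Progeny per cross or individuals per survival
#'   table.
#' @param config For `model = "cage"`, the [cage_config()] to simulate and
#'   refit.
#' @param seed Seed for data generation.
#' @param conf_level Interval level for coverage (default 0.95).
#' @return List with `estimates`, `mean_estimate`, `bias` and (for
#'   `"cross"`) `coverage` of the exact interval.
#' @export
recover_parameters <- function(model = c("cross", "survival", "cage"),
                               truth, n_replicates = 200,
                               n_per_replicate = 200, config = NULL,
                               seed = 1L, conf_level = 0.95) {
  model <- match.arg(model)
  set.seed(seed)
  if (model == "cross") {
    tab <- gen_cross_progeny(n_replicates, n_per_replicate, truth, seed = seed)
    fits <- lapply(seq_len(nrow(tab)), function(i)
      estimate_transmission(tab$n_drive_carriers[i], tab$n_progeny[i],
                            conf_level))
    est <- vapply(fits, `[[`, numeric(1L), "estimate")
    cover <- vapply(fits, function(f)
      f$lower <= truth && truth <= f$upper, logical(1L))
    list(estimates = est, mean_estimate = mean(est),
         bias = mean(est) - truth, coverage = mean(cover))
  } else if (model == "survival") {
    p <- daily_survival_from_median(truth)
    tab <- gen_survival_table(n_per_replicate, p, horizon = 5L * truth,
                              seed = seed)
    med <- survival_table_median(tab)
    list(estimates = med, mean_estimate = med, bias = med - truth)
  } else {
    stopifnot(inherits(config, "cage_config"))
    fit <- calibrate_bloodmeal_mort(
      observed = run_experiment(config)$drive_carrier_freq,
      config = config)
    list(estimates = fit$estimate, mean_estimate = fit$estimate,
         bias = fit$estimate - truth)
  }
}

#' Empirical median lifespan of a survival table
#'
#' @param tab A survival table from [gen_survival_table()].
#' @return The day by which half of the initial cohort has died (the
#'   empirical median lifetime), `NA` if fewer than half died before
#'   censoring.
#' @export
survival_table_median <- function(tab) {
  n0 <- tab$at_risk[1L]
  cum <- cumsum(tab$deaths)
  hit <- which(cum >= n0 / 2)
  if (length(hit) == 0L) NA_real_ else tab$day[min(hit)]
}
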