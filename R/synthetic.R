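# Seeded generators for synthetic datasets with the statistical structure of
# the experimental readouts: binomial cross progeny counts, geometric
# lifetimes in daily survival tables, and hypergeometric screening of cage
# trajectories. Every generator stores its ground truth alongside the data
# (as attributes) so estimator recovery can be tested without external data.

#' Synthetic drive-cross progeny counts
#'
#' Binomial draws of drive-carrier progeny per replicate cross at a known
#' transmission rate, shaped like a pooled screening table.
#'
#' @param n_replicates Number of replicate crosses.
#' @param n_per_replicate Progeny scored per replicate.
#' @param true_t True transmission probability in `[0, 1]`.
#' @param parent_sex Recorded parent sex column (`"female"` or `"male"`).
#' @param seed Integer seed.
#' @return Data frame with columns `replicate`, `parent_sex`, `n_progeny`,
#'   `n_drive_carriers`; ground truth in attribute `"truth"`.
#' @export
gen_cross_progeny <- function(n_replicates, n_per_replicate, true_t,
                              parent_sex = "female", seed = 1L) {
  if (true_t < 0 || true_t > 1)
    stop("gen_cross_progeny: 'true_t' must be in [0, 1]", call. = FALSE)
  set.seed(seed)
  out <- data.frame(replicate = seq_len(n_replicates),
                    parent_sex = parent_sex,
                    n_progeny = n_per_replicate,
                    n_drive_carriers = rbinom(n_replicates, n_per_replicate,
                                              true_t))
  attr(out, "truth") <- list(true_t = true_t, seed = seed)
  out
}

#' Synthetic daily survival table
#'
#' Geometric lifetimes at a known daily survival probability,
#' right-censored at a horizon, tabulated as daily deaths and at-risk
#' counts (the format of a daily dead-count survival assay).
#'
#' @param n Individuals at day 0.
#' @param daily_p Daily survival probability in `(0, 1]`.
#' @param horizon Censoring day.
#' @param seed Integer seed.
#' @return Data frame with columns `day`, `at_risk`, `deaths`; ground truth
#'   in attribute `"truth"`.
#' @export
gen_survival_table <- function(n, daily_p, horizon, seed = 1L) {
  if (daily_p <= 0 || daily_p > 1)
    stop("gen_survival_table: 'daily_p' must be in (0, 1]", call. = FALSE)
  set.seed(seed)
  horizon <- as.integer(horizon)
  if (n == 0L) {
    out <- data.frame(day = integer(0), at_risk = integer(0),
                      deaths = integer(0))
    attr(out, "truth") <- list(daily_p = daily_p, seed = seed)
    return(out)
  }
  # lifetime = day of death; P(death on day d) = p^(d-1) (1-p)
  lifetimes <- if (daily_p == 1) rep(Inf, n) else rgeom(n, 1 - daily_p) + 1L
  days <- seq_len(horizon)
  deaths <- vapply(days, function(d) sum(lifetimes == d), integer(1L))
  at_risk <- n - c(0L, cumsum(deaths)[-horizon])
  out <- data.frame(day = days, at_risk = at_risk, deaths = deaths)
  attr(out, "truth") <- list(daily_p = daily_p, seed = seed)
  out
}

#' Synthetic screening of a cage trajectory
#'
#' Re-screens the full-census trajectory of a simulated cage with
#' hypergeometric draws (larvae are physically removed for screening, hence
#' sampling without replacement), emulating the per-generation GFP and PCR
#' readouts. Ground-truth census carrier frequencies are kept as columns for
#' testing.
#'
#' @param records Trajectory from [run_experiment()] (needs the census
#'   allele-frequency columns).
#' @param census_size Total individuals represented by each generation's
#'   census (the larval pool screened from).
#' @param screen_gfp_n,screen_pcr_n Screening sample sizes.
#' @param seed Integer seed.
#' @return Data frame with columns `generation`, `true_drive_carrier`,
#'   `obs_drive_carrier`, `true_effector_carrier`, `obs_effector_carrier`.
#' @export
gen_cage_screen <- function(records, census_size = 525,
                            screen_gfp_n = 100, screen_pcr_n = 92,
                            seed = 1L) {
  set.seed(seed)
  truth_d <- records$drive_carrier_census
  if (is.null(truth_d)) {
    # fall back: treat the recorded (screened) frequency as the pool truth
    truth_d <- records$drive_carrier_freq
  }
  truth_e <- records$effector_carrier_census
  if (is.null(truth_e)) truth_e <- records$effector_carrier_freq
  n <- nrow(records)
  obs_d <- obs_e <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!is.na(truth_d[i])) {
      k <- round(truth_d[i] * census_size)
      m <- min(screen_gfp_n, census_size)
      obs_d[i] <- rhyper(1L, k, census_size - k, m) / m
    }
    if (!is.na(truth_e[i])) {
      k <- round(truth_e[i] * census_size)
      m <- min(screen_pcr_n, census_size)
      obs_e[i] <- rhyper(1L, k, census_size - k, m) / m
    }
  }
  out <- data.frame(generation = records$generation,
                    true_drive_carrier = truth_d,
                    obs_drive_carrier = obs_d,
                    true_effector_carrier = truth_e,
                    obs_effector_carrier = obs_e)
  attr(out, "truth") <- list(census_size = census_size, seed = seed)
  out
}
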