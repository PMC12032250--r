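# Stochastic discrete-generation simulator of the population-cage invasion
# protocol: ~6 days of mating with genotype-dependent adult attrition, one
# blood meal, oviposition, larval sampling to seed the next generation, and a
# GFP/PCR screening observation model.

#' Founder census tables
#'
#' Convenience constructors for the two published cage seeding schemes, each
#' giving a 20% starting allele frequency per transgene.
#'
#' @param n_wt,n_dd,n_ee Adults of each genotype *per sex*.
#' @return A founder census data frame with columns `genotype`, `female`,
#'   `male`.
#' @export
founders_drive_only <- function(n_wt = 200, n_dd = 50) {
  data.frame(genotype = c("W:C/W:C", "D:C/D:C"),
             female = c(n_wt, n_dd), male = c(n_wt, n_dd),
             stringsAsFactors = FALSE)
}

#' @rdname founders_drive_only
#' @export
founders_two_locus <- function(n_wt = 150, n_dd = 50, n_ee = 50) {
  data.frame(genotype = c("W:C/W:C", "D:C/D:C", "W:E/W:E"),
             female = c(n_wt, n_dd, n_ee), male = c(n_wt, n_dd, n_ee),
             stringsAsFactors = FALSE)
}

#' Cage experiment configuration
#'
#' Mirrors the laboratory protocol: adults mate for `mating_days`, are blood
#' fed, oviposit, and `larvae_next_gen` larvae (5 trays of 105) are sampled to
#' seed the next generation; `screen_gfp_n` further larvae are screened for
#' the fluorescent drive marker and `screen_pcr_n` are genotyped by PCR at the
#' effector locus.
#'
#' @param founders Founder census data frame (`genotype`, `female`, `male`).
#' @param generations Number of generations to simulate after generation 0.
#' @param drive A [drive_params()] object.
#' @param fitness A [fitness_params()] object.
#' @param mating_days Length of the mating window in days (default 6).
#' @param larvae_next_gen Larvae sampled to seed the next generation
#'   (default 525 = 5 trays x 105).
#' @param screen_gfp_n Larvae screened for drive-carrier status (default 100).
#' @param screen_pcr_n Larvae genotyped at the effector locus (default 92).
#' @param mean_eggs_per_female Mean hatched eggs contributed per surviving
#'   mated female (Poisson mean before fecundity multipliers).
#' @param baseline_daily_survival Wild-type adult daily survival during the
#'   mating window; default `0.5^(1/35)` (35-day wild-type median lifespan
#'   under the constant-hazard model).
#' @param seed Integer seed; all randomness in [run_experiment()] flows from
#'   it.
#' @return An object of class `cage_config`.
#' @export
cage_config <- function(founders = founders_drive_only(),
                        generations = 20,
                        drive = drive_params(),
                        fitness = fitness_params(),
                        mating_days = 6,
                        larvae_next_gen = 525,
                        screen_gfp_n = 100,
                        screen_pcr_n = 92,
                        mean_eggs_per_female = 60,
                        baseline_daily_survival = 0.5^(1 / 35),
                        seed = 1L) {
  stopifnot(inherits(drive, "drive_params"), inherits(fitness, "fitness_params"))
  if (!is.data.frame(founders) ||
      !all(c("genotype", "female", "male") %in% names(founders)))
    stop("cage_config: 'founders' needs columns genotype, female, male",
         call. = FALSE)
  if (any(founders$female < 0) || any(founders$male < 0))
    stop("cage_config: founder counts must be non-negative", call. = FALSE)
  if (larvae_next_gen <= 0)
    stop("cage_config: 'larvae_next_gen' must be positive", call. = FALSE)
  if (mean_eggs_per_female <= 0)
    stop("cage_config: 'mean_eggs_per_female' must be positive", call. = FALSE)
  if (baseline_daily_survival <= 0 || baseline_daily_survival > 1)
    stop("cage_config: 'baseline_daily_survival' must be in (0, 1]",
         call. = FALSE)
  structure(list(founders = founders, generations = generations,
                 drive = drive, fitness = fitness,
                 mating_days = mating_days,
                 larvae_next_gen = larvae_next_gen,
                 screen_gfp_n = screen_gfp_n, screen_pcr_n = screen_pcr_n,
                 mean_eggs_per_female = mean_eggs_per_female,
                 baseline_daily_survival = baseline_daily_survival,
                 seed = as.integer(seed)),
            class = "cage_config")
}

#' Initialise a cage state from its founder census
#'
#' @param config A [cage_config()] object.
#' @return An object of class `cage_state`: generation index, adult census by
#'   genotype and sex, egg count, extinction flag.
#' @export
init_cage <- function(config) {
  stopifnot(inherits(config, "cage_config"))
  census <- config$founders
  census$female <- as.integer(round(census$female))
  census$male <- as.integer(round(census$male))
  census <- census[census$female + census$male > 0, , drop = FALSE]
  if (nrow(census) == 0L || sum(census$female) + sum(census$male) == 0L)
    stop("init_cage: founder census is empty", call. = FALSE)
  # canonicalise labels
  census$genotype <- vapply(census$genotype,
                            function(g) genotype_label(parse_genotype(g)),
                            character(1L))
  structure(list(generation = 0L, census = census, egg_output = NA_real_,
                 extinct = FALSE),
            class = "cage_state")
}

# Parse genotype labels of a census into drive/effector allele matrices.
census_alleles <- function(census) {
  parts <- strsplit(census$genotype, "[/:]")
  drive <- t(vapply(parts, function(p) p[c(1L, 3L)], character(2L)))
  eff <- t(vapply(parts, function(p) p[c(2L, 4L)], character(2L)))
  list(drive = drive, effector = eff)
}

#' Per-locus allele frequencies of a cage state
#'
#' Exact frequencies of `W, D, R1, R2` and `C, E, CR` from the full census.
#'
#' @param state A `cage_state`.
#' @return Named list with numeric vectors `drive` and `effector`, each
#'   summing to 1.
#' @export
allele_census <- function(state) {
  stopifnot(inherits(state, "cage_state"))
  n <- state$census$female + state$census$male
  if (sum(n) == 0L)
    stop("allele_census: cage is extinct (empty census)", call. = FALSE)
  al <- census_alleles(state$census)
  dcount <- setNames(numeric(4L), DRIVE_ALLELES)
  ecount <- setNames(numeric(3L), EFFECTOR_ALLELES)
  for (i in seq_along(n)) {
    for (a in al$drive[i, ]) dcount[a] <- dcount[a] + n[i]
    for (a in al$effector[i, ]) ecount[a] <- ecount[a] + n[i]
  }
  list(drive = dcount / sum(dcount), effector = ecount / sum(ecount))
}

# Multivariate hypergeometric draw: sample k items without replacement from
# categories with the given counts.
rmvhyper1 <- function(k, counts) {
  out <- integer(length(counts))
  rem <- sum(counts)
  k <- min(k, rem)
  for (i in seq_along(counts)) {
    if (k <= 0L) break
    x <- rhyper(1L, counts[i], rem - counts[i], k)
    out[i] <- x
    k <- k - x
    rem <- rem - counts[i]
  }
  out
}

# Carrier indicator per census row for a given allele at a given locus.
census_carrier <- function(census, allele, locus = c("drive", "effector")) {
  locus <- match.arg(locus)
  al <- census_alleles(census)
  apply(al[[locus]], 1L, function(a) allele %in% a)
}

#' Advance a cage by one generation
#'
#' Executes the event sequence of one maintenance cycle: adult attrition over
#' the mating window (genotype daily mortality), single mating per female
#' (partner proportional to male mating weight), blood-meal mortality for
#' LOF-homozygous females, Poisson egg production, offspring sampling through
#' the parental cross distributions, larval sampling without replacement to
#' seed the next generation, and the GFP/PCR screening observation.
#' Extinction (no surviving females or males) yields a terminal state flagged
#' `extinct` rather than an error.
#'
#' @param state A `cage_state`.
#' @param config A [cage_config()] object.
#' @return List with elements `state` (next `cage_state`) and `record` (one
#'   observation row, see [run_experiment()]).
#' @export
run_generation <- function(state, config) {
  stopifnot(inherits(state, "cage_state"), inherits(config, "cage_config"))
  census <- state$census
  cls <- vapply(strsplit(census$genotype, "[/:]"),
                function(p) drive_fitness_class(p[c(1L, 3L)]), character(1L))
  fit <- config$fitness

  # (1) attrition over the mating window
  surv_day <- config$baseline_daily_survival ^ fit$mort_mult[cls]
  p_surv <- surv_day ^ config$mating_days
  females <- rbinom(nrow(census), census$female, p_surv)
  males <- rbinom(nrow(census), census$male, p_surv)

  if (sum(females) == 0L || sum(males) == 0L) {
    st <- structure(list(generation = state$generation + 1L,
                         census = census[0L, , drop = FALSE],
                         egg_output = 0, extinct = TRUE),
                    class = "cage_state")
    return(list(state = st, record = observe_cage(st, config, egg_output = 0)))
  }

  # (2) mating: one partner per female, proportional to male mating weight
  male_w <- males * fit$mating_weight[cls]
  pair_counts <- matrix(0L, nrow(census), nrow(census))
  for (i in which(females > 0L)) {
    pair_counts[i, ] <- as.integer(rmultinom(1L, females[i],
                                             male_w / sum(male_w)))
  }

  # (3) blood meal: LOF-homozygous females die with probability b
  b <- fit$bloodmeal_mort
  if (b > 0) {
    for (i in which(cls == "homozygous_LOF")) {
      if (sum(pair_counts[i, ]) > 0L)
        pair_counts[i, ] <- vapply(pair_counts[i, ], function(n)
          rbinom(1L, n, 1 - b), integer(1L))
    }
  }

  # (4) eggs per mating-pair cell
  lambda <- config$mean_eggs_per_female * fit$fecundity[cls]
  eggs <- matrix(0L, nrow(census), nrow(census))
  for (i in seq_len(nrow(census))) for (j in seq_len(nrow(census))) {
    n <- pair_counts[i, j]
    if (n > 0L) eggs[i, j] <- rpois(1L, n * lambda[i])
  }
  egg_output <- sum(eggs)

  if (egg_output == 0L) {
    st <- structure(list(generation = state$generation + 1L,
                         census = census[0L, , drop = FALSE],
                         egg_output = 0, extinct = TRUE),
                    class = "cage_state")
    return(list(state = st, record = observe_cage(st, config, egg_output = 0)))
  }

  # (5)-(6) larvae sampled without replacement across pair cells, offspring
  # genotypes via the exact cross distribution of each pair
  n_take <- min(config$larvae_next_gen, egg_output)
  take <- rmvhyper1(n_take, as.vector(eggs))
  take <- matrix(take, nrow(census), nrow(census))
  offspring <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(census))) for (j in seq_len(nrow(census))) {
    n <- take[i, j]
    if (n == 0L) next
    mo <- parse_genotype(census$genotype[i], "female")
    fa <- parse_genotype(census$genotype[j], "male")
    dist <- cross_distribution(mo, fa, config$drive)
    draw <- as.integer(rmultinom(1L, n, dist))
    for (k in which(draw > 0L)) {
      key <- names(dist)[k]
      prev <- if (is.null(offspring[[key]])) 0L else offspring[[key]]
      offspring[[key]] <- prev + draw[k]
    }
  }
  genos <- sort(ls(offspring))
  counts <- vapply(genos, function(g) offspring[[g]], integer(1L))
  fem <- rbinom(length(counts), counts, 0.5)
  new_census <- data.frame(genotype = genos, female = fem,
                           male = counts - fem, stringsAsFactors = FALSE)

  st <- structure(list(generation = state$generation + 1L,
                       census = new_census, egg_output = egg_output,
                       extinct = FALSE),
                  class = "cage_state")
  list(state = st, record = observe_cage(st, config, egg_output = egg_output))
}

# Screening observation: hypergeometric samples of larvae for drive-carrier
# status (GFP) and effector genotype (PCR), plus ground-truth census columns.
observe_cage <- function(state, config, egg_output) {
  census <- state$census
  total <- sum(census$female + census$male)
  if (total == 0L) {
    return(data.frame(generation = state$generation,
                      drive_carrier_freq = NA_real_,
                      effector_carrier_freq = NA_real_,
                      drive_carrier_census = NA_real_,
                      effector_carrier_census = NA_real_,
                      egg_output = egg_output,
                      q_W = NA_real_, q_D = NA_real_, q_R1 = NA_real_,
                      q_R2 = NA_real_, e_C = NA_real_, e_E = NA_real_,
                      e_CR = NA_real_, extinct = TRUE))
  }
  n <- census$female + census$male
  d_carrier <- census_carrier(census, "D", "drive")
  e_carrier <- census_carrier(census, "E", "effector")
  n_d <- sum(n[d_carrier])
  n_e <- sum(n[e_carrier])
  k_gfp <- min(config$screen_gfp_n, total)
  k_pcr <- min(config$screen_pcr_n, total)
  obs_d <- if (k_gfp > 0) rhyper(1L, n_d, total - n_d, k_gfp) / k_gfp else NA_real_
  obs_e <- if (k_pcr > 0) rhyper(1L, n_e, total - n_e, k_pcr) / k_pcr else NA_real_
  ac <- allele_census(state)
  data.frame(generation = state$generation,
             drive_carrier_freq = obs_d,
             effector_carrier_freq = obs_e,
             drive_carrier_census = n_d / total,
             effector_carrier_census = n_e / total,
             egg_output = egg_output,
             q_W = ac$drive[["W"]], q_D = ac$drive[["D"]],
             q_R1 = ac$drive[["R1"]], q_R2 = ac$drive[["R2"]],
             e_C = ac$effector[["C"]], e_E = ac$effector[["E"]],
             e_CR = ac$effector[["CR"]],
             extinct = state$extinct)
}

#' Run a seeded cage experiment
#'
#' Simulates `config$generations` maintenance cycles from the founder census
#' with a seeded generator; fully reproducible given `config$seed`. The
#' generation-0 record reports the founder census (screening equals census at
#' setup, where genotypes are known).
#'
#' @param config A [cage_config()] object.
#' @param keep_state Return the final `cage_state` as attribute `"state"`.
#' @return Data frame of per-generation observations with columns
#'   `generation`, `drive_carrier_freq`, `effector_carrier_freq`,
#'   `egg_output`, census allele frequencies `q_W, q_D, q_R1, q_R2`
#'   (drive locus) and `e_C, e_E, e_CR` (effector locus), and `extinct`.
#' @export
run_experiment <- function(config, keep_state = FALSE) {
  stopifnot(inherits(config, "cage_config"))
  set.seed(config$seed)
  state <- init_cage(config)
  ac <- allele_census(state)
  n <- state$census$female + state$census$male
  carrier_d0 <- sum(n[census_carrier(state$census, "D", "drive")]) / sum(n)
  carrier_e0 <- sum(n[census_carrier(state$census, "E", "effector")]) / sum(n)
  rec0 <- data.frame(generation = 0L,
                     drive_carrier_freq = carrier_d0,
                     effector_carrier_freq = carrier_e0,
                     drive_carrier_census = carrier_d0,
                     effector_carrier_census = carrier_e0,
                     egg_output = NA_real_,
                     q_W = ac$drive[["W"]], q_D = ac$drive[["D"]],
                     q_R1 = ac$drive[["R1"]], q_R2 = ac$drive[["R2"]],
                     e_C = ac$effector[["C"]], e_E = ac$effector[["E"]],
                     e_CR = ac$effector[["CR"]], extinct = FALSE)
  records <- list(rec0)
  g <- 0L
  while (g < config$generations && !state$extinct) {
    step <- run_generation(state, config)
    state <- step$state
    records[[length(records) + 1L]] <- step$record
    g <- g + 1L
  }
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  if (keep_state) attr(out, "state") <- state
  out
}

#' Run replicate cages
#'
#' Replicate cage `i` uses seed `config$seed + i - 1`.
#'
#' @param config A [cage_config()] object.
#' @param replicates Number of replicate cages.
#' @return Data frame stacking [run_experiment()] outputs with a leading
#'   `cage_id` column.
#' @export
run_cages <- function(config, replicates) {
  out <- lapply(seq_len(replicates), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    cbind(cage_id = i, run_experiment(cfg))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generation of drive fixation in a cage trajectory
#'
#' Fixation is the first generation at which no wild-type allele remains at
#' the drive locus in the full census.
#'
#' @param records Output of [run_experiment()].
#' @return Integer generation, or `NA` if wild type was never exhausted.
#' @export
fixation_generation <- function(records) {
  hit <- which(!is.na(records$q_W) & records$q_W == 0)
  if (length(hit) == 0L) NA_integer_ else records$generation[min(hit)]
}
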