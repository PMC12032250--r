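# Shared configuration, seeding and tabular I/O: YAML experiment configs with
# schema validation and defaults, CSV result writing with a reproducibility
# manifest (config snapshot, seed, file checksums).

cage_config_keys <- function() {
  c("founders", "generations", "mating_days", "larvae_next_gen",
    "screen_gfp_n", "screen_pcr_n", "mean_eggs_per_female",
    "baseline_daily_survival", "seed", "drive", "fitness")
}

epi_config_keys <- function() {
  c("human_population", "larval_capacity", "target_EIR", "eip_days",
    "cycle_days", "feed_success", "release_size", "release_day",
    "horizon_days", "replicates", "seed", "adult_daily_survival",
    "eggs_per_batch", "larval_duration", "larval_daily_survival",
    "mosq_infect_prob", "human_infect_prob", "human_clear_rate",
    "init_adults", "init_genotype", "init_human_prev", "drive", "fitness")
}

drive_param_keys <- function() {
  c("homing_female", "homing_male", "uncut_fraction", "functional_fraction",
    "effector_homing", "effector_uncut_fraction", "recombination_fraction")
}

fitness_param_keys <- function() {
  c("daily_mort_mult_hom", "daily_mort_mult_het", "bloodmeal_mort_hom",
    "fecundity_mult", "mating_weight")
}

#' Load and validate an experiment configuration
#'
#' Reads a YAML file describing a cage or transmission experiment, rejects
#' unknown keys (reporting their paths), validates every value through the
#' typed constructors and fills defaults for everything omitted. Nested
#' `drive:` and `fitness:` blocks map onto [drive_params()] and
#' [fitness_params()]; a cage `founders:` block is a mapping from genotype
#' labels to `{female: n, male: n}`.
#'
#' @param path Path to a YAML file with a single top-level key `cage:` or
#'   `epi:` (or the bare fields plus a `kind:` field).
#' @return A validated [cage_config()] or [epi_config()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("load_config: file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw) || length(raw) == 0L)
    stop("load_config: empty configuration; required: a 'cage:' or 'epi:' ",
         "block (see ?cage_config / ?epi_config for keys)", call. = FALSE)
  kind <- NULL
  if (!is.null(raw$cage)) {
    kind <- "cage"; body <- raw$cage
    extra <- setdiff(names(raw), "cage")
  } else if (!is.null(raw$epi)) {
    kind <- "epi"; body <- raw$epi
    extra <- setdiff(names(raw), "epi")
  } else {
    stop("load_config: expected a top-level 'cage:' or 'epi:' block; found ",
         "keys: ", paste(names(raw), collapse = ", "), call. = FALSE)
  }
  if (length(extra) > 0L)
    stop("load_config: unknown top-level keys: ",
         paste(extra, collapse = ", "), call. = FALSE)
  allowed <- if (kind == "cage") cage_config_keys() else epi_config_keys()
  unknown <- setdiff(names(body), allowed)
  if (length(unknown) > 0L)
    stop("load_config: unknown keys under '", kind, "': ",
         paste(paste0(kind, ".", unknown), collapse = ", "), call. = FALSE)
  args <- body[setdiff(names(body), c("drive", "fitness", "founders"))]
  if (!is.null(body$drive)) {
    bad <- setdiff(names(body$drive), drive_param_keys())
    if (length(bad) > 0L)
      stop("load_config: unknown keys under '", kind, ".drive': ",
           paste(bad, collapse = ", "), call. = FALSE)
    args$drive <- do.call(drive_params, body$drive)
  }
  if (!is.null(body$fitness)) {
    bad <- setdiff(names(body$fitness), fitness_param_keys())
    if (length(bad) > 0L)
      stop("load_config: unknown keys under '", kind, ".fitness': ",
           paste(bad, collapse = ", "), call. = FALSE)
    fargs <- body$fitness
    for (nm in c("fecundity_mult", "mating_weight"))
      if (is.list(fargs[[nm]])) fargs[[nm]] <- unlist(fargs[[nm]])
    args$fitness <- do.call(fitness_params, fargs)
  }
  if (kind == "cage" && !is.null(body$founders)) {
    fl <- body$founders
    args$founders <- data.frame(
      genotype = names(fl),
      female = vapply(fl, function(x) as.numeric(x$female %||% 0), numeric(1L)),
      male = vapply(fl, function(x) as.numeric(x$male %||% 0), numeric(1L)),
      stringsAsFactors = FALSE)
  }
  if (kind == "cage") do.call(cage_config, args) else do.call(epi_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Serialisable snapshot of a config object (params flattened to plain lists).
config_snapshot <- function(config) {
  snap <- unclass(config)
  for (nm in c("drive", "fitness"))
    if (!is.null(snap[[nm]])) snap[[nm]] <- lapply(unclass(snap[[nm]]), as.vector)
  if (!is.null(snap$founders)) snap$founders <- as.list(snap$founders)
  snap
}

#' Write result tables with a reproducibility manifest
#'
#' Writes each table as a CSV (comma separator, header row, UTF-8, `.`
#' decimal) and a `manifest.json` capturing the configuration snapshot, the
#' seed, the package version, a timestamp and an MD5 checksum per file.
#' Re-running the producing function with the manifest's config and seed
#' reproduces byte-identical CSVs.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if missing).
#' @param config Optional configuration object stored in the manifest.
#' @param seed Optional seed stored in the manifest.
#' @return The manifest, invisibly (also written to
#'   `file.path(out_dir, "manifest.json")`).
#' @export
write_results <- function(tables, out_dir, config = NULL, seed = NULL) {
  if (!is.list(tables) || (length(tables) > 0L && is.null(names(tables))))
    stop("write_results: 'tables' must be a named list of data frames",
         call. = FALSE)
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, mode = 2L) != 0L)
    stop("write_results: cannot write to directory: ", out_dir, call. = FALSE)
  inventory <- list()
  for (nm in names(tables)) {
    f <- file.path(out_dir, paste0(nm, ".csv"))
    write.csv(tables[[nm]], f, row.names = FALSE, fileEncoding = "UTF-8")
    inventory[[nm]] <- list(file = basename(f),
                            md5 = unname(tools::md5sum(f)))
  }
  manifest <- list(
    package = "suppdrive",
    version = as.character(utils::packageVersion("suppdrive")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = if (!is.null(config)) config_snapshot(config) else NULL,
    files = inventory)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(manifest)
}

#' Write a config object back to YAML
#'
#' Inverse of [load_config()]: `load_config(write_config(cfg, path))`
#' reproduces `cfg`.
#'
#' @param config A [cage_config()] or [epi_config()] object.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  kind <- if (inherits(config, "cage_config")) "cage" else "epi"
  snap <- unclass(config)
  for (nm in c("drive", "fitness"))
    snap[[nm]] <- lapply(unclass(snap[[nm]]), as.vector)
  # fitness_params stores derived per-class vectors; re-express as the
  # constructor arguments so the round trip goes through validation
  fit <- config$fitness
  snap$fitness <- list(
    daily_mort_mult_hom = unname(fit$mort_mult[["homozygous_LOF"]]),
    daily_mort_mult_het = unname(fit$mort_mult[["heterozygous_LOF"]]),
    bloodmeal_mort_hom = fit$bloodmeal_mort,
    fecundity_mult = as.list(fit$fecundity),
    mating_weight = as.list(fit$mating_weight))
  if (kind == "cage") {
    f <- config$founders
    snap$founders <- setNames(lapply(seq_len(nrow(f)), function(i)
      list(female = f$female[i], male = f$male[i])), f$genotype)
  }
  yaml::write_yaml(setNames(list(snap), kind), path)
  invisible(path)
}
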