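#' Define a baseline-versus-comparative experiment
#'
#' An experiment runs a burn-in under the baseline conditions to bring the
#' population to mutation-selection-drift balance, then initializes every
#' arm (the baseline plus named variants that differ from it only in the
#' declared keys) from the shared burn-in snapshot, with replicate seeds
#' paired across arms.
#'
#' @param baseline A [sim_config()]; its `steps` is the per-arm run length.
#' @param variants Named list of override lists in [modify_config()] dotted
#'   notation, e.g. `list(high_mut = list("traits" = ...))`.
#' @param burn_in_steps Steps of burn-in under baseline conditions (0 skips
#'   burn-in and arms start de novo).
#' @param replicates Replicates per arm.
#' @param seed Master seed; replicate `r` of every arm uses `seed + r`
#'   (paired across arms), and the burn-in uses `seed`.
#' @return An object of class `experiment_plan`.
#' @export
experiment_plan <- function(baseline, variants = list(), burn_in_steps = 0L,
                            replicates = 1L, seed = 1L) {
  stopifnot(inherits(baseline, "sim_config"))
  if (length(variants)) {
    if (is.null(names(variants)) || any(names(variants) == "")) {
      stop("variants must be a named list", call. = FALSE)
    }
    for (nm in names(variants)) {
      modify_config(baseline, variants[[nm]]) # validates the declared keys
    }
  }
  structure(list(baseline = baseline, variants = variants,
                 burn_in_steps = as.integer(burn_in_steps),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "experiment_plan")
}

#' Run a comparative experiment
#'
#' @param plan An [experiment_plan()].
#' @param keep `"none"`, `"snapshot"` (keep each arm-replicate's final
#'   snapshot) or `"run"` (keep full `sim_run` objects).
#' @param quiet Suppress progress messages.
#' @return An object of class `experiment_result`: list with `plan`,
#'   `burn_in` (metadata and snapshot of the shared burn-in, or `NULL`),
#'   `comparison` (tibble: one row per arm x replicate with observed and
#'   intrinsic life-history summaries) and, per `keep`, `snapshots` or
#'   `runs` (named `arm.replicate`).
#' @export
run_experiment <- function(plan, keep = "none", quiet = TRUE) {
  stopifnot(inherits(plan, "experiment_plan"))
  keep <- match.arg(keep, c("none", "snapshot", "run"))

  burn_in <- NULL
  burn_snap <- NULL
  if (plan$burn_in_steps > 0L) {
    cfg_b <- plan$baseline
    cfg_b$seed <- plan$seed
    if (!quiet) message("burn-in: ", plan$burn_in_steps, " steps")
    rb <- run_simulation(cfg_b, steps = plan$burn_in_steps)
    if (rb$metadata$extinct) {
      stop("burn-in population went extinct at step ",
           rb$metadata$extinction_step,
           "; adjust the baseline conditions", call. = FALSE)
    }
    burn_snap <- rb$final
    burn_in <- list(metadata = rb$metadata, snapshot = burn_snap,
                    snapshot_hash = config_hash(burn_snap$genomes))
  }

  arms <- c(list(baseline = list()), plan$variants)
  rows <- list()
  kept <- list()
  for (arm in names(arms)) {
    cfg_arm <- modify_config(plan$baseline, arms[[arm]])
    for (rep in seq_len(plan$replicates)) {
      cfg_r <- cfg_arm
      cfg_r$seed <- plan$seed + rep
      cfg_r$init_from <- burn_snap
      if (!quiet) message("arm ", arm, " replicate ", rep)
      run <- run_simulation(cfg_r)
      rows[[paste(arm, rep, sep = ".")]] <- arm_summary(run, arm, rep)
      if (keep == "snapshot") {
        kept[[paste(arm, rep, sep = ".")]] <- run$final
      } else if (keep == "run") {
        kept[[paste(arm, rep, sep = ".")]] <- run
      }
    }
  }
  out <- list(plan = plan, burn_in = burn_in,
              comparison = dplyr::bind_rows(rows))
  if (keep == "snapshot") out$snapshots <- kept
  if (keep == "run") out$runs <- kept
  structure(out, class = "experiment_result")
}

arm_summary <- function(run, arm, rep) {
  sm <- tryCatch(summary_metrics(run), error = function(e) NULL)
  ic <- tryCatch(summary_metrics(intrinsic_curves(run)),
                 error = function(e) NULL)
  adult <- run$config$reproduction$maturity_age
  mim <- tryCatch({
    curves <- intrinsic_curves(run)
    mean(curves$mortality[curves$age_class >= adult], na.rm = TRUE)
  }, error = function(e) NA_real_)
  tibble::tibble(
    arm = arm, replicate = rep, seed = run$metadata$seed,
    extinct = run$metadata$extinct,
    steps_run = run$metadata$steps_run,
    final_living = run$metadata$final_living,
    mean_popsize = mean(run$ledgers$popsize$n),
    median_lifespan = if (is.null(sm)) NA_real_ else sm$median_lifespan,
    life_expectancy = if (is.null(sm)) NA_real_ else sm$life_expectancy,
    median_intrinsic_lifespan = if (is.null(ic)) NA_real_ else
      ic$median_lifespan,
    mean_adult_intrinsic_mortality = mim
  )
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result> ", length(unique(x$comparison$arm)), " arms x ",
      x$plan$replicates, " replicates",
      if (!is.null(x$burn_in)) paste0("; shared burn-in ",
                                      x$plan$burn_in_steps, " steps"),
      "\n", sep = "")
  print(summarize_experiment(x))
  invisible(x)
}

#' Across-replicate summary of an experiment
#'
#' A pure function of the per-replicate comparison table: arm-level means
#' and standard deviations of the evolved life-history summaries.
#'
#' @param x An `experiment_result` or its `comparison` tibble.
#' @return A tibble with one row per arm.
#' @export
summarize_experiment <- function(x) {
  cmp <- if (inherits(x, "experiment_result")) x$comparison else x
  dplyr::summarise(
    dplyr::group_by(cmp, .data$arm),
    replicates = dplyr::n(),
    median_lifespan = mean(.data$median_lifespan, na.rm = TRUE),
    median_intrinsic_lifespan = mean(.data$median_intrinsic_lifespan,
                                     na.rm = TRUE),
    sd_median_intrinsic_lifespan = stats::sd(.data$median_intrinsic_lifespan,
                                             na.rm = TRUE),
    mean_adult_intrinsic_mortality = mean(.data$mean_adult_intrinsic_mortality,
                                          na.rm = TRUE),
    .groups = "drop"
  )
}

#' Preset: delayed-reproduction selection experiment
#'
#' Recreates a classical laboratory selection design with two arms of
#' oviparous, non-overlapping-generation populations (all eggs hatch once
#' the adult cohort is extinct; at most `K` eggs are carried over). In the
#' baseline arm `B` the next generation is seeded from the earliest-laid
#' eggs; in arm `O` eggs are ranked by laying step descending, so only the
#' latest-laid eggs -- the offspring of the longest-lived, late-fertile
#' parents -- are carried over. Both arms start from a shared burn-in
#' evolved under `B` conditions. A wild-like extension re-runs the evolved
#' snapshots with overlapping generations (viviparity) and resource
#' limitation.
#'
#' @param K Carrying capacity (and egg carry-over cap).
#' @param maturity Age class at maturity.
#' @param steps Evolution-phase length per arm, in steps.
#' @param burn_in_steps Shared burn-in length under `B` conditions.
#' @param replicates Replicate pairs.
#' @param seed Master seed.
#' @param n_age_classes Age classes (maximum laying day is
#'   `n_age_classes - 1`).
#' @param wild_steps Length of the wild-like extension runs.
#' @return An object of class `rose_plan`: the [experiment_plan()] plus the
#'   wild-like extension overrides.
#' @export
preset_rose <- function(K = 1000L, maturity = 14L, steps = 1000L,
                        burn_in_steps = 3000L, replicates = 10L, seed = 1L,
                        n_age_classes = 50L, wild_steps = 150L) {
  base <- sim_config(
    steps = steps, K = K, n_age_classes = n_age_classes, init_n = K,
    reproduction = reproduction_params(
      mode = "sexual", maturity_age = maturity, oviparous = TRUE,
      hatching_policy = "when_adults_extinct",
      egg_selection = "earliest", egg_cap = K
    ),
    seed = seed, record_window = 100L
  )
  plan <- experiment_plan(
    base,
    variants = list(O = list("reproduction.egg_selection" = "latest")),
    burn_in_steps = burn_in_steps, replicates = replicates, seed = seed
  )
  structure(list(plan = plan,
                 wild_overrides = list(
                   "reproduction.oviparous" = FALSE,
                   "reproduction.hatching_policy" = "fixed_incubation",
                   "reproduction.egg_selection" = "all",
                   "reproduction.egg_cap" = Inf
                 ),
                 wild_steps = as.integer(wild_steps)),
            class = "rose_plan")
}

#' Run the delayed-reproduction preset
#'
#' Executes the shared burn-in, the B and O evolution arms, and the
#' wild-like extension from each evolved snapshot; summarizes, per
#' replicate pair, the evolved median intrinsic lifespan of each arm and
#' the observed survivorship of the evolved populations under wild-like
#' conditions.
#'
#' @param rose A [preset_rose()] plan.
#' @param quiet Suppress progress messages.
#' @return A list of class `rose_result`: `evolution` (the evolution-phase
#'   `experiment_result`), `lifespans` (tibble: replicate, arm, median
#'   intrinsic lifespan), `wild` (tibble: per replicate x arm observed
#'   survivorship curves under wild-like conditions).
#' @export
run_rose <- function(rose, quiet = TRUE) {
  stopifnot(inherits(rose, "rose_plan"))
  evo <- run_experiment(rose$plan, keep = "snapshot", quiet = quiet)
  lifespans <- evo$comparison[, c("arm", "replicate",
                                  "median_intrinsic_lifespan")]
  lifespans$arm <- ifelse(lifespans$arm == "baseline", "B", lifespans$arm)

  wild_cfg <- modify_config(rose$plan$baseline, rose$wild_overrides)
  wild_cfg$record_window <- rose$wild_steps
  wild <- list()
  for (nm in names(evo$snapshots)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    arm <- if (parts[1] == "baseline") "B" else parts[1]
    rep <- as.integer(parts[2])
    cfg <- wild_cfg
    cfg$seed <- rose$plan$seed + 10000L + rep
    cfg$init_from <- evo$snapshots[[nm]]
    run <- run_simulation(cfg, steps = rose$wild_steps)
    lt <- tryCatch(life_table_observed(run), error = function(e) NULL)
    if (!is.null(lt)) {
      wild[[nm]] <- tibble::tibble(arm = arm, replicate = rep,
                                   age_class = lt$age_class,
                                   survivorship = lt$survivorship,
                                   mortality = lt$mortality)
    }
  }
  structure(list(evolution = evo, lifespans = lifespans,
                 wild = dplyr::bind_rows(wild)),
            class = "rose_result")
}

#' @export
print.rose_result <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$lifespans, names_from = "arm",
                             values_from = "median_intrinsic_lifespan")
  frac <- mean(wide$O > wide$B, na.rm = TRUE)
  cat("<rose_result> ", nrow(wide), " replicate pairs; O > B (median ",
      "intrinsic lifespan) in ", round(100 * frac), "% of pairs\n", sep = "")
  invisible(x)
}

#' Run a simulation from the command line surface
#'
#' Reads a YAML configuration, applies dotted-key overrides and an optional
#' seed override, runs the simulation and writes the output tree (ledgers,
#' genotype dump with layout sidecar, metadata, final snapshot and a
#' manifest). Validation failures raise errors naming the offending key.
#'
#' @param config_path Path to a YAML configuration file.
#' @param output_dir Output directory.
#' @param seed Optional seed override.
#' @param overrides Named list of dotted-key overrides.
#' @return The `sim_run`, invisibly.
#' @export
cli_run <- function(config_path, output_dir, seed = NULL,
                    overrides = list()) {
  cfg <- read_config(config_path)
  if (length(overrides)) cfg <- modify_config(cfg, overrides)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  run <- run_simulation(cfg)
  write_run_outputs(run, output_dir)
  save_snapshot(run, file.path(output_dir, "final_snapshot.rds"))
  manifest <- list(
    outputs = c("deaths.csv", "births.csv", "demography.csv", "popsize.csv",
                "steps.csv", "genotypes.csv", "genotype_layout.csv",
                "metadata.json", "final_snapshot.rds"),
    seed = cfg$seed,
    steps_run = run$metadata$steps_run,
    version = run$metadata$version
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(run)
}
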