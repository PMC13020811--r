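#' Simulation configuration
#'
#' Assembles and validates all parameters of a run. Defaults describe a
#' sexually reproducing, viviparous population with evolvable age-specific
#' survival (bounds `[0, 1]`) and reproduction (bounds `[0, 0.5]`), a
#' constant germline mutation rate of `1e-3` per bit, 50 age classes,
#' maturity at age class 10, carrying capacity 1000 with gradual starvation,
#' all other extrinsic hazards off, and environmental drift off.
#'
#' @param steps Number of simulation steps.
#' @param K Carrying capacity (living, non-egg individuals).
#' @param n_age_classes Number of age classes; individuals reaching this age
#'   die with cause `age_limit`.
#' @param init_n Initial population size (de novo initialization).
#' @param ones_fraction Initialization fractions for [init_genomes()]
#'   (`NULL`: derived from each trait's `initial`).
#' @param traits List of [trait_spec()]s; must include `survival` and
#'   `reproduction`.
#' @param reproduction A [reproduction_params()].
#' @param mutation_asymmetry Mutation asymmetry ratio (see
#'   [mutate_genomes()]).
#' @param abiotic An [abiotic_wave()].
#' @param infection An [infection_params()].
#' @param initial_infected Number of initially infected individuals.
#' @param predation A [predation_params()].
#' @param starvation A [starvation_params()].
#' @param process_order Permutation of a subset of `intrinsic`, `abiotic`,
#'   `infection`, `predation`, `starvation`, `reproduction`, `aging`,
#'   `drift`; `aging` must appear exactly once.
#' @param drift_rate Expected drift-map bit flips per step (0 disables
#'   environmental drift).
#' @param seed Integer master seed; every stochastic process draws from its
#'   own named stream spawned from this seed.
#' @param record_window Aggregation window (steps) for the demographic
#'   ledgers.
#' @param record_phenotypes_every,record_genotypes_every Cadence (steps) of
#'   full phenotype/genotype snapshots; 0 records the final state only.
#' @param record_birth_details Logical; additionally keep a per-birth ledger
#'   (step, parental age class, offspring id, egg flag).
#' @param init_from Optional `sim_snapshot` (or path to one) to initialize
#'   the population from instead of de novo generation.
#' @param resume_rng Logical; when initializing from a snapshot, continue
#'   its RNG streams and step counter (exact continuation of the saved run)
#'   instead of reseeding from `seed`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(steps = 1000L,
                       K = 1000L,
                       n_age_classes = 50L,
                       init_n = K,
                       ones_fraction = NULL,
                       traits = default_traits(),
                       reproduction = reproduction_params(),
                       mutation_asymmetry = 1,
                       abiotic = abiotic_wave(),
                       infection = infection_params(),
                       initial_infected = 0L,
                       predation = predation_params(),
                       starvation = starvation_params(),
                       process_order = default_process_order(),
                       drift_rate = 0,
                       seed = 1L,
                       record_window = 100L,
                       record_phenotypes_every = 0L,
                       record_genotypes_every = 0L,
                       record_birth_details = FALSE,
                       init_from = NULL,
                       resume_rng = FALSE) {
  if (inherits(traits, "trait_spec")) traits <- list(traits)
  names(traits) <- vapply(traits, function(t) t$name, character(1))
  cfg <- structure(
    list(steps = as.integer(steps), K = as.integer(K),
         n_age_classes = as.integer(n_age_classes),
         init_n = as.integer(init_n), ones_fraction = ones_fraction,
         traits = traits, reproduction = reproduction,
         mutation_asymmetry = mutation_asymmetry, abiotic = abiotic,
         infection = infection, initial_infected = as.integer(initial_infected),
         predation = predation, starvation = starvation,
         process_order = process_order, drift_rate = drift_rate,
         seed = as.integer(seed), record_window = as.integer(record_window),
         record_phenotypes_every = as.integer(record_phenotypes_every),
         record_genotypes_every = as.integer(record_genotypes_every),
         record_birth_details = isTRUE(record_birth_details),
         init_from = init_from, resume_rng = isTRUE(resume_rng)),
    class = "sim_config"
  )
  validate_config(cfg)
  cfg
}

#' @rdname sim_config
#' @export
default_traits <- function() {
  list(
    trait_spec("survival", age_dependent = TRUE, bits_per_block = 8L,
               lower = 0, upper = 1, initial = 1),
    trait_spec("reproduction", age_dependent = TRUE, bits_per_block = 8L,
               lower = 0, upper = 0.5, initial = 0.25),
    trait_spec("mutation_rate", age_dependent = FALSE, evolvable = FALSE,
               lower = 0, upper = 1, initial = 1e-3)
  )
}

#' @rdname sim_config
#' @export
default_process_order <- function() {
  c("intrinsic", "abiotic", "infection", "predation", "starvation",
    "reproduction", "aging", "drift")
}

#' Validate a simulation configuration
#'
#' @param cfg A `sim_config`.
#' @return `cfg`, invisibly; errors describe the offending setting.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$steps < 0L) stop("steps must be >= 0", call. = FALSE)
  if (cfg$K < 1L) stop("carrying capacity K must be >= 1", call. = FALSE)
  if (cfg$n_age_classes < 1L) stop("n_age_classes must be >= 1", call. = FALSE)
  if (cfg$init_n < 1L) stop("init_n must be >= 1", call. = FALSE)
  if (cfg$record_window < 1L) stop("record_window must be >= 1", call. = FALSE)
  if (cfg$drift_rate < 0) stop("drift_rate must be >= 0", call. = FALSE)

  known <- c("intrinsic", "abiotic", "infection", "predation", "starvation",
             "reproduction", "aging", "drift")
  bad <- setdiff(cfg$process_order, known)
  if (length(bad)) {
    stop("unknown process in process_order: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(cfg$process_order)) {
    stop("process_order must not repeat a process", call. = FALSE)
  }
  if (sum(cfg$process_order == "aging") != 1L) {
    stop("process_order must contain 'aging' exactly once", call. = FALSE)
  }

  nms <- vapply(cfg$traits, function(t) t$name, character(1))
  if (!all(c("survival", "reproduction") %in% nms)) {
    stop("traits must include 'survival' and 'reproduction'", call. = FALSE)
  }
  rp <- cfg$reproduction
  if (rp$maturity_age >= cfg$n_age_classes) {
    stop("maturity_age must be below n_age_classes", call. = FALSE)
  }
  if (!is.null(rp$menopause_age) && rp$menopause_age > cfg$n_age_classes) {
    stop("menopause_age must be <= n_age_classes", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$steps, " steps, K = ", x$K, ", ",
      x$n_age_classes, " age classes, seed ", x$seed, "\n", sep = "")
  cat("  reproduction: ", x$reproduction$mode,
      if (x$reproduction$oviparous) ", oviparous" else ", viviparous",
      ", maturity ", x$reproduction$maturity_age, "\n", sep = "")
  cat("  starvation: ", x$starvation$model,
      ", process order: ", paste(x$process_order, collapse = " > "),
      "\n", sep = "")
  invisible(x)
}

#' Modify a configuration with dotted-key overrides
#'
#' Applies named overrides such as `reproduction.maturity_age = 14` or
#' `drift_rate = 0.1` to a configuration; keys address nested parameter
#' blocks with dots. Used by the experiment harness and the command line.
#'
#' @param cfg A `sim_config`.
#' @param overrides Named list of overrides.
#' @return The modified, re-validated `sim_config`.
#' @export
modify_config <- function(cfg, overrides) {
  for (key in names(overrides)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    node <- cfg
    for (p in parts[-length(parts)]) {
      if (!p %in% names(node)) {
        stop("unknown configuration key: ", key, call. = FALSE)
      }
      node <- node[[p]]
    }
    leaf <- parts[length(parts)]
    if (!leaf %in% names(node)) {
      stop("unknown configuration key: ", key, call. = FALSE)
    }
    value <- overrides[[key]]
    expr <- paste0("cfg", paste0("[['", parts, "']]", collapse = ""))
    eval(parse(text = paste0(expr, " <- value")))
  }
  validate_config(cfg)
  cfg
}

config_yaml_schema <- function() {
  list(
    scalars = c("steps", "K", "n_age_classes", "init_n", "seed",
                "drift_rate", "record_window", "mutation_asymmetry",
                "initial_infected", "record_phenotypes_every",
                "record_genotypes_every", "record_birth_details",
                "process_order", "init_from", "ones_fraction"),
    traits = c("name", "age_dependent", "bits_per_block", "lower", "upper",
               "evolvable", "initial"),
    reproduction = c("mode", "maturity_age", "menopause_age", "oviparous",
                     "incubation", "hatching_policy", "recombination_rate",
                     "egg_selection", "egg_cap"),
    abiotic = c("shape", "amplitude", "period", "phase", "baseline"),
    infection = c("transmissibility", "fatality_rate", "recovery_rate",
                  "background_infection"),
    predation = c("predator_growth_rate", "vulnerability",
                  "initial_predators"),
    starvation = c("model", "m", "age_weighting")
  )
}

#' Read a simulation configuration from a YAML file
#'
#' Parameter files mirror [sim_config()]: top-level scalar keys plus nested
#' `traits` (a list of trait blocks), `reproduction`, `abiotic`,
#' `infection`, `predation` and `starvation` blocks. Unknown keys are
#' rejected with an error naming the offending key.
#'
#' @param path Path to a YAML file.
#' @return A validated `sim_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop("configuration file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("configuration file must be a YAML mapping",
                          call. = FALSE)
  schema <- config_yaml_schema()
  blocks <- setdiff(names(schema), c("scalars", "traits"))
  allowed_top <- c(schema$scalars, "traits", blocks)
  bad <- setdiff(names(raw), allowed_top)
  if (length(bad)) {
    stop("unknown configuration key: ", bad[[1]], call. = FALSE)
  }
  check_block <- function(block, allowed, label) {
    bad <- setdiff(names(block), allowed)
    if (length(bad)) {
      stop("unknown configuration key: ", label, ".", bad[[1]],
           call. = FALSE)
    }
  }

  args <- raw[intersect(names(raw), schema$scalars)]
  if (!is.null(raw$traits)) {
    args$traits <- lapply(raw$traits, function(tb) {
      check_block(tb, schema$traits, "traits")
      do.call(trait_spec, tb)
    })
  }
  ctor <- list(reproduction = reproduction_params, abiotic = abiotic_wave,
               infection = infection_params, predation = predation_params,
               starvation = starvation_params)
  for (b in blocks) {
    if (!is.null(raw[[b]])) {
      check_block(raw[[b]], schema[[b]], b)
      args[[b]] <- do.call(ctor[[b]], raw[[b]])
    }
  }
  do.call(sim_config, args)
}
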