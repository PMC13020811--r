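DEATH_CAUSES <- c("intrinsic", "abiotic", "infection", "predation",
                  "starvation", "age_limit")

# --- RNG stream management -------------------------------------------------
# One master seed spawns a named L'Ecuyer-CMRG stream per stochastic
# process, so toggling one process never perturbs another's draws.

init_streams <- function(seed, names) {
  set.seed(seed, kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", envir = globalenv())
  env <- new.env(parent = emptyenv())
  for (nm in names) {
    s <- parallel::nextRNGStream(s)
    assign(nm, s, envir = env)
  }
  env
}

stream_names <- function() {
  c("init", "intrinsic", "abiotic", "infection", "predation", "starvation",
    "reproduction", "drift")
}

use_stream <- function(streams, nm) {
  assign(".Random.seed", get(nm, envir = streams), envir = globalenv())
}

keep_stream <- function(streams, nm) {
  assign(nm, get(".Random.seed", envir = globalenv()), envir = streams)
}

with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(expr)
}

# Tiny FNV-1a hash over a serialized object; used to stamp snapshots with
# the configuration they came from.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 3L))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

# --- population store ------------------------------------------------------

new_state <- function(cfg, arch) {
  st <- new.env(parent = emptyenv())
  st$L <- arch$total_bits
  st$n_age <- arch$n_age_classes
  st$arch <- arch
  st$cap <- max(min(4L * cfg$K, 8L * cfg$init_n), 2L * cfg$init_n, 256L)
  st$top <- 0L
  st$genome <- matrix(0L, nrow = 2L * st$L, ncol = st$cap)
  st$age <- integer(st$cap)
  st$alive <- logical(st$cap)
  st$infected <- integer(st$cap)
  st$birth_step <- integer(st$cap)
  st$id <- integer(st$cap)
  st$next_id <- 1L
  st$surv <- matrix(0, st$n_age, st$cap)
  st$fert <- matrix(0, st$n_age, st$cap)
  mt <- arch$traits$mutation_rate
  st$mrate_by_age <- !is.null(mt) && mt$evolvable && mt$age_dependent
  st$mrate <- if (st$mrate_by_age) matrix(0, st$n_age, st$cap)
              else numeric(st$cap)
  st$eggs <- new.env(parent = emptyenv())
  st$eggs$cap <- 0L
  st$eggs$n <- 0L
  st$eggs$genome <- matrix(0L, nrow = 2L * st$L, ncol = 0L)
  st$eggs$laid <- integer(0)
  st$eggs$parent_age <- integer(0)
  st$eggs$id <- integer(0)
  st
}

grow_state <- function(st, need) {
  new_cap <- max(2L * st$cap, st$cap + need)
  extra <- new_cap - st$cap
  st$genome <- cbind(st$genome, matrix(0L, nrow(st$genome), extra))
  st$age <- c(st$age, integer(extra))
  st$alive <- c(st$alive, logical(extra))
  st$infected <- c(st$infected, integer(extra))
  st$birth_step <- c(st$birth_step, integer(extra))
  st$id <- c(st$id, integer(extra))
  st$surv <- cbind(st$surv, matrix(0, st$n_age, extra))
  st$fert <- cbind(st$fert, matrix(0, st$n_age, extra))
  st$mrate <- if (st$mrate_by_age) cbind(st$mrate, matrix(0, st$n_age, extra))
              else c(st$mrate, numeric(extra))
  st$cap <- new_cap
  invisible(st)
}

egg_push <- function(st, kids, laid_step, parent_age, ids = integer(ncol(kids))) {
  k <- ncol(kids)
  if (k == 0L) return(invisible(st))
  eg <- st$eggs
  if (eg$n + k > eg$cap) {
    new_cap <- max(2L * eg$cap, eg$n + k, 64L)
    g <- matrix(0L, nrow = 2L * st$L, ncol = new_cap)
    if (eg$n) g[, seq_len(eg$n)] <- eg$genome[, seq_len(eg$n)]
    eg$genome <- g
    eg$laid <- c(eg$laid, integer(new_cap - length(eg$laid)))
    eg$parent_age <- c(eg$parent_age, integer(new_cap - length(eg$parent_age)))
    eg$id <- c(eg$id, integer(new_cap - length(eg$id)))
    eg$cap <- new_cap
  }
  idx <- eg$n + seq_len(k)
  cpp_set_cols_int(eg$genome, idx, kids)
  eg$laid[idx] <- laid_step
  eg$parent_age[idx] <- parent_age
  eg$id[idx] <- ids
  eg$n <- eg$n + k
  invisible(st)
}

egg_keep <- function(st, keep) {
  eg <- st$eggs
  n <- length(keep)
  g <- matrix(0L, nrow = 2L * st$L, ncol = max(n, 0L))
  if (n) g[] <- eg$genome[, keep]
  eg$genome <- g
  eg$laid <- eg$laid[keep]
  eg$parent_age <- eg$parent_age[keep]
  eg$id <- eg$id[keep]
  eg$cap <- n
  eg$n <- n
  invisible(st)
}

# --- recorders -------------------------------------------------------------

init_recorders <- function(st, cfg, start_step) {
  st$win_deaths <- matrix(0, st$n_age, length(DEATH_CAUSES),
                          dimnames = list(NULL, DEATH_CAUSES))
  st$win_births <- numeric(st$n_age)
  st$win_entering <- numeric(st$n_age)
  st$win_start <- start_step + 1L
  st$windows <- list()
  st$popsize <- numeric(cfg$steps)
  st$step_cols <- c("living_start", DEATH_CAUSES, "births", "hatched")
  st$step_mat <- matrix(0, cfg$steps, length(st$step_cols),
                        dimnames = list(NULL, st$step_cols))
  st$step_now <- stats::setNames(numeric(length(st$step_cols)), st$step_cols)
  st$living_end <- numeric(cfg$steps)
  st$pheno_snaps <- list()
  st$geno_snaps <- list()
  st$birth_rows <- list()
  invisible(st)
}

record_kill <- function(st, idx, cause, ages = st$age[idx]) {
  st$alive[idx] <- FALSE
  counts <- tabulate(ages + 1L, st$n_age)
  st$win_deaths[, cause] <- st$win_deaths[, cause] + counts
  st$step_now[cause] <- st$step_now[cause] + length(idx)
  invisible(st)
}

flush_window <- function(st, end_step) {
  st$windows[[length(st$windows) + 1L]] <- list(
    step_start = st$win_start, step_end = end_step,
    deaths = st$win_deaths, births = st$win_births,
    entering = st$win_entering,
    age_struct = tabulate(st$age[st$alive] + 1L, st$n_age)
  )
  st$win_deaths[] <- 0
  st$win_births[] <- 0
  st$win_entering[] <- 0
  st$win_start <- end_step + 1L
  invisible(st)
}

take_pheno_snap <- function(st, cfg, step) {
  idx <- which(st$alive)
  st$pheno_snaps[[length(st$pheno_snaps) + 1L]] <- list(
    step = step, n = length(idx),
    survival = st$surv[, idx, drop = FALSE],
    reproduction = st$fert[, idx, drop = FALSE]
  )
  invisible(st)
}

take_geno_snap <- function(st, cfg, step) {
  idx <- which(st$alive)
  pool <- new_genome_pool(st$genome[, idx, drop = FALSE], st$L)
  st$geno_snaps[[length(st$geno_snaps) + 1L]] <- list(
    step = step, haplotypes = genome_haplotypes(pool),
    drift = st$env$drift
  )
  invisible(st)
}

# --- individual placement --------------------------------------------------

# Compact the store, preserving the relative order of living individuals
# (placement order is part of the deterministic contract: draws are made in
# living-slot order, and snapshots must resume identically).
compact_state <- function(st) {
  idx <- which(st$alive[seq_len(st$top)])
  n <- length(idx)
  if (n < st$top) {
    cpp_move_cols_int(st$genome, idx)
    cpp_move_cols_num(st$surv, idx)
    cpp_move_cols_num(st$fert, idx)
    if (st$mrate_by_age) cpp_move_cols_num(st$mrate, idx)
    else st$mrate[seq_len(n)] <- st$mrate[idx]
    st$age[seq_len(n)] <- st$age[idx]
    st$infected[seq_len(n)] <- st$infected[idx]
    st$birth_step[seq_len(n)] <- st$birth_step[idx]
    st$id[seq_len(n)] <- st$id[idx]
    st$alive[] <- FALSE
    st$alive[seq_len(n)] <- TRUE
  }
  st$top <- n
  invisible(st)
}

place_individuals <- function(st, cfg, kids, step, count_as = NULL,
                              ids = NULL) {
  k <- ncol(kids)
  if (k == 0L) return(integer(0))
  if (is.null(ids)) {
    ids <- st$next_id + seq_len(k) - 1L
    st$next_id <- st$next_id + k
  }
  # never compact here: slot indices held by the step loop must stay valid
  # within a step, so mid-step shortfalls grow the store instead
  if (st$top + k > st$cap) {
    grow_state(st, st$top + k - st$cap)
  }
  free <- st$top + seq_len(k)
  st$top <- st$top + k
  rp <- cfg$reproduction
  ph <- interpret_phenotypes(new_genome_pool(kids, st$L), st$arch,
                             drift = st$env$drift,
                             maturity = rp$maturity_age,
                             menopause = rp$menopause_age)
  cpp_set_cols_int(st$genome, free, kids)
  st$age[free] <- 0L
  st$infected[free] <- 0L
  st$birth_step[free] <- step
  st$id[free] <- ids
  st$alive[free] <- TRUE
  cpp_set_cols_num(st$surv, free, ph$survival)
  cpp_set_cols_num(st$fert, free, ph$reproduction)
  mr <- ph$mutation_rate
  if (st$mrate_by_age) cpp_set_cols_num(st$mrate, free, mr)
  else st$mrate[free] <- mr
  st$win_entering[1L] <- st$win_entering[1L] + k
  if (!is.null(count_as)) {
    st$step_now[count_as] <- st$step_now[count_as] + k
  }
  free
}

refresh_phenotypes <- function(st, cfg) {
  idx <- which(st$alive)
  if (!length(idx)) return(invisible(st))
  rp <- cfg$reproduction
  ph <- interpret_phenotypes(new_genome_pool(st$genome[, idx, drop = FALSE],
                                             st$L),
                             st$arch, drift = st$env$drift,
                             maturity = rp$maturity_age,
                             menopause = rp$menopause_age)
  cpp_set_cols_num(st$surv, idx, ph$survival)
  cpp_set_cols_num(st$fert, idx, ph$reproduction)
  if (st$mrate_by_age) cpp_set_cols_num(st$mrate, idx, ph$mutation_rate)
  else st$mrate[idx] <- ph$mutation_rate
  invisible(st)
}

#' Apply environmental drift to a drift map
#'
#' A Poisson(`rate`) number of uniformly chosen, distinct drift-map bits
#' flip, reversing which allele is beneficial at those loci. Rate 0 (the
#' default: drift deactivated) leaves the map untouched.
#'
#' @param drift_map Integer 0/1 vector (per-locus beneficial bit value).
#' @param rate Expected number of bit flips per step.
#' @return The updated drift map.
#' @export
drift_environment <- function(drift_map, rate) {
  if (rate < 0) stop("drift rate must be >= 0", call. = FALSE)
  if (rate == 0) return(drift_map)
  nf <- stats::rpois(1L, rate)
  if (nf > 0L) {
    pos <- sample.int(length(drift_map), min(nf, length(drift_map)))
    drift_map[pos] <- 1L - drift_map[pos]
  }
  drift_map
}

# --- reproduction within a step -------------------------------------------

do_reproduction <- function(st, cfg, living, step) {
  if (!length(living)) return(invisible(st))
  rp <- cfg$reproduction
  ages <- st$age[living]
  fr <- st$fert[cbind(ages + 1L, living)]
  el <- eligible_parents(ages, fr, rp)
  att <- living[el$attempting]
  if (rp$mode == "sexual") {
    pm <- pair_mates(att)
    pa <- pm$pairs[, 1L]
    pb <- pm$pairs[, 2L]
  } else {
    pa <- att
    pb <- NULL
  }
  k <- length(pa)
  if (k == 0L) return(invisible(st))
  sexual <- rp$mode == "sexual"
  kids <- cpp_offspring(st$genome, st$L, pa,
                        if (sexual) pb else pa, rp$recombination_rate,
                        sexual)
  rates <- if (st$mrate_by_age) st$mrate[cbind(st$age[pa] + 1L, pa)]
           else st$mrate[pa]
  if (cfg$mutation_asymmetry == 1) {
    cpp_mutate_sym(kids, as.numeric(rates))
  } else {
    kids <- mutate_core(kids, rates, cfg$mutation_asymmetry)
  }
  st$win_births <- st$win_births + tabulate(st$age[pa] + 1L, st$n_age)
  ids <- st$next_id + seq_len(k) - 1L
  st$next_id <- st$next_id + k
  if (isTRUE(cfg$record_birth_details)) {
    st$birth_rows[[length(st$birth_rows) + 1L]] <- cbind(
      step = step, parent_age = st$age[pa], offspring_id = ids,
      egg = as.integer(rp$oviparous)
    )
  }
  if (rp$oviparous) {
    st$step_now["births"] <- st$step_now["births"] + k
    egg_push(st, kids, step, st$age[pa], ids = ids)
    prune_eggs(st, rp)
  } else {
    place_individuals(st, cfg, kids, step, count_as = "births", ids = ids)
  }
  invisible(st)
}

# Keep the egg pool within egg_cap according to the carry-over policy;
# only meaningful for ranked policies (earliest / latest). Pruning is lazy
# (triggered at twice the cap) to bound memory without rebuilding the pool
# every step; the hatch-time selection applies the policy exactly, so
# deferral never changes which eggs are carried over.
prune_eggs <- function(st, rp, force = FALSE) {
  if (!is.finite(rp$egg_cap) || rp$egg_selection == "all") return(invisible(st))
  eg <- st$eggs
  if (eg$n <= rp$egg_cap || (!force && eg$n < 2L * rp$egg_cap)) {
    return(invisible(st))
  }
  keep <- select_eggs(eg$laid[seq_len(eg$n)], rp$egg_selection, rp$egg_cap)
  egg_keep(st, sort(keep))
  invisible(st)
}

do_hatching <- function(st, cfg, step) {
  rp <- cfg$reproduction
  if (!rp$oviparous || st$eggs$n == 0L) return(invisible(st))
  eg <- st$eggs
  active <- seq_len(eg$n)
  if (rp$hatching_policy == "fixed_incubation") {
    ready <- active[eg$laid[active] + rp$incubation <= step]
    if (!length(ready)) return(invisible(st))
    kids <- eg$genome[, ready, drop = FALSE]
    ids <- eg$id[ready]
    egg_keep(st, setdiff(active, ready))
  } else {
    if (sum(st$alive) > 0L) return(invisible(st))
    sel <- select_eggs(eg$laid[active], rp$egg_selection,
                       min(rp$egg_cap, length(active)))
    kids <- eg$genome[, sel, drop = FALSE]
    ids <- eg$id[sel]
    egg_keep(st, integer(0))
  }
  place_individuals(st, cfg, kids, step, count_as = "hatched", ids = ids)
  invisible(st)
}

# --- main loop -------------------------------------------------------------

#' Run a simulation
#'
#' Executes the three phases (initialization, stepwise simulation,
#' termination) of an individual-based run. Each step executes the
#' configured process order; within each mortality process all individuals
#' are updated in parallel from the state at the start of that process, and
#' deaths are committed before the next process reads the state. Identical
#' configuration and seed produce bit-identical outputs. Extinction
#' terminates the run early and is recorded, not raised.
#'
#' @param config A [sim_config()].
#' @param steps Optional override of `config$steps`.
#' @return An object of class `sim_run` with elements `config`,
#'   `ledgers` (tibbles `deaths`, `births`, `demography`, `popsize`,
#'   `steps`), `phenotypes` and `genotypes` (snapshot lists), `final` (a
#'   `sim_snapshot`) and `metadata`.
#' @export
run_simulation <- function(config, steps = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(steps)) config$steps <- as.integer(steps)
  validate_config(config)
  t0 <- proc.time()[["elapsed"]]
  with_preserved_rng({
    arch <- build_architecture(config$traits, config$n_age_classes)
    st <- initialize_run(config, arch)
    simulate_steps(st, config)
    build_run(st, config, arch, t0)
  })
}

initialize_run <- function(cfg, arch) {
  st <- new_state(cfg, arch)
  snap <- cfg$init_from
  if (is.character(snap)) snap <- load_snapshot(snap)
  if (!is.null(snap)) {
    check_snapshot_compat(snap, arch)
    st$streams <- if (cfg$resume_rng) {
      env <- new.env(parent = emptyenv())
      for (nm in names(snap$rng_streams)) {
        assign(nm, snap$rng_streams[[nm]], envir = env)
      }
      env
    } else init_streams(cfg$seed, stream_names())
    n <- ncol(snap$genomes)
    if (n > st$cap) grow_state(st, n - st$cap)
    idx <- seq_len(n)
    st$top <- n
    cpp_set_cols_int(st$genome, idx, snap$genomes)
    st$age[idx] <- snap$age
    st$infected[idx] <- snap$infected
    st$birth_step[idx] <- snap$birth_step
    if (!is.null(snap$id)) {
      st$id[idx] <- snap$id
      st$next_id <- snap$next_id
    } else {
      st$id[idx] <- idx
      st$next_id <- n + 1L
    }
    st$alive[idx] <- TRUE
    if (!is.null(snap$eggs) && ncol(snap$eggs$genome) > 0L) {
      eids <- snap$eggs$id
      if (is.null(eids)) eids <- integer(ncol(snap$eggs$genome))
      egg_push(st, snap$eggs$genome, snap$eggs$laid, snap$eggs$parent_age,
               ids = eids)
    }
    st$env <- list(step = if (cfg$resume_rng) snap$env$step else 0L,
                   streak = snap$env$streak,
                   predators = snap$env$predators,
                   drift = snap$env$drift)
    refresh_phenotypes(st, cfg)
    init_recorders(st, cfg, st$env$step)
    st$win_entering <- st$win_entering +
      tabulate(st$age[st$alive] + 1L, st$n_age)
  } else {
    st$streams <- init_streams(cfg$seed, stream_names())
    st$env <- list(step = 0L, streak = 0L,
                   predators = cfg$predation$initial_predators,
                   drift = default_drift_map(arch))
    init_recorders(st, cfg, 0L)
    use_stream(st$streams, "init")
    pool <- init_genomes(cfg$init_n, arch, cfg$ones_fraction)
    idx <- place_individuals(st, cfg, unclass_pool(pool), 0L)
    st$win_entering[] <- 0
    st$win_entering <- tabulate(st$age[st$alive] + 1L, st$n_age)
    if (cfg$initial_infected > 0L) {
      inf <- idx[sample.int(length(idx),
                            min(cfg$initial_infected, length(idx)))]
      st$infected[inf] <- 1L
    }
    keep_stream(st$streams, "init")
  }
  st
}

unclass_pool <- function(pool) {
  mat <- unclass(pool)
  attr(mat, "n_loci") <- NULL
  mat
}

simulate_steps <- function(st, cfg) {
  n_steps <- cfg$steps
  start <- st$env$step
  rp <- cfg$reproduction
  has_repro <- "reproduction" %in% cfg$process_order
  st$steps_run <- 0L
  st$extinct <- FALSE
  st$extinction_step <- NA_integer_

  for (row in seq_len(n_steps)) {
    s <- start + row
    st$env$step <- s
    if (st$top > st$cap - (st$cap %/% 4L)) compact_state(st)
    living <- which(st$alive)
    st$step_now[] <- 0
    st$step_now["living_start"] <- length(living)

    for (proc in cfg$process_order) {
      if (proc == "intrinsic") {
        if (length(living)) {
          use_stream(st$streams, "intrinsic")
          sv <- st$surv[cbind(st$age[living] + 1L, living)]
          dead <- intrinsic_deaths(sv)
          keep_stream(st$streams, "intrinsic")
          if (any(dead)) {
            record_kill(st, living[dead], "intrinsic")
            living <- living[!dead]
          }
        }
      } else if (proc == "abiotic") {
        if (length(living) &&
            (cfg$abiotic$baseline > 0 || cfg$abiotic$amplitude > 0)) {
          use_stream(st$streams, "abiotic")
          dead <- abiotic_deaths(length(living), cfg$abiotic, s)
          keep_stream(st$streams, "abiotic")
          if (any(dead)) {
            record_kill(st, living[dead], "abiotic")
            living <- living[!dead]
          }
        }
      } else if (proc == "infection") {
        if (length(living) &&
            (any(st$infected[living] == 1L) ||
             cfg$infection$background_infection > 0)) {
          use_stream(st$streams, "infection")
          res <- infection_step(st$infected[living], cfg$infection)
          keep_stream(st$streams, "infection")
          st$infected[living] <- res$status
          if (any(res$deaths)) {
            record_kill(st, living[res$deaths], "infection")
            living <- living[!res$deaths]
          }
        }
      } else if (proc == "predation") {
        if (length(living) && st$env$predators > 0) {
          use_stream(st$streams, "predation")
          res <- predation_step(length(living), st$env$predators,
                                cfg$predation)
          keep_stream(st$streams, "predation")
          st$env$predators <- res$predators
          if (any(res$deaths)) {
            record_kill(st, living[res$deaths], "predation")
            living <- living[!res$deaths]
          }
        }
      } else if (proc == "starvation") {
        if (length(living)) {
          use_stream(st$streams, "starvation")
          res <- starvation_step(st$age[living], st$env$streak, cfg$K,
                                 cfg$starvation)
          keep_stream(st$streams, "starvation")
          st$env$streak <- res$streak
          if (any(res$deaths)) {
            record_kill(st, living[res$deaths], "starvation")
            living <- living[!res$deaths]
          }
        } else {
          st$env$streak <- 0L
        }
      } else if (proc == "reproduction") {
        use_stream(st$streams, "reproduction")
        do_reproduction(st, cfg, living, s)
        keep_stream(st$streams, "reproduction")
        cpp_set1_num(st$popsize, row, sum(st$alive))
      } else if (proc == "aging") {
        if (length(living)) {
          st$age[living] <- st$age[living] + 1L
          newa <- st$age[living]
          out <- newa >= st$n_age
          if (any(out)) {
            record_kill(st, living[out], "age_limit",
                        ages = rep.int(st$n_age - 1L, sum(out)))
          }
          stay <- newa[!out]
          if (length(stay)) {
            st$win_entering <- st$win_entering +
              tabulate(stay + 1L, st$n_age)
          }
          living <- living[!out]
        }
      } else if (proc == "drift") {
        if (cfg$drift_rate > 0) {
          use_stream(st$streams, "drift")
          new_map <- drift_environment(st$env$drift, cfg$drift_rate)
          keep_stream(st$streams, "drift")
          if (!identical(new_map, st$env$drift)) {
            st$env$drift <- new_map
            refresh_phenotypes(st, cfg)
          }
        }
      }
    }

    use_stream(st$streams, "reproduction")
    do_hatching(st, cfg, s)
    keep_stream(st$streams, "reproduction")
    if (!has_repro) cpp_set1_num(st$popsize, row, sum(st$alive))
    n_end <- sum(st$alive)
    cpp_set1_num(st$living_end, row, n_end)
    cpp_set_row_num(st$step_mat, row, st$step_now)
    st$steps_run <- row

    if (cfg$record_phenotypes_every > 0L &&
        s %% cfg$record_phenotypes_every == 0L) {
      take_pheno_snap(st, cfg, s)
    }
    if (cfg$record_genotypes_every > 0L &&
        s %% cfg$record_genotypes_every == 0L) {
      take_geno_snap(st, cfg, s)
    }
    if (s %% cfg$record_window == 0L) flush_window(st, s)

    if (n_end == 0 && st$eggs$n == 0L) {
      st$extinct <- TRUE
      st$extinction_step <- s
      break
    }
  }
  if (st$win_start <= st$env$step) flush_window(st, st$env$step)
  invisible(st)
}

build_run <- function(st, cfg, arch, t0) {
  nw <- length(st$windows)
  n_age <- st$n_age
  ages <- 0:(n_age - 1L)
  deaths <- purrr::imap_dfr(st$windows, function(w, i) {
    tibble::tibble(window = i, step_start = w$step_start,
                   step_end = w$step_end,
                   cause = rep(DEATH_CAUSES, each = n_age),
                   age_class = rep.int(ages, length(DEATH_CAUSES)),
                   deaths = as.numeric(w$deaths))
  })
  births <- purrr::imap_dfr(st$windows, function(w, i) {
    tibble::tibble(window = i, step_start = w$step_start,
                   step_end = w$step_end, age_class = ages,
                   births = as.numeric(w$births))
  })
  demography <- purrr::imap_dfr(st$windows, function(w, i) {
    tibble::tibble(window = i, step_start = w$step_start,
                   step_end = w$step_end, age_class = ages,
                   entering = as.numeric(w$entering),
                   alive_at_end = as.numeric(w$age_struct))
  })
  rows <- seq_len(st$steps_run)
  start <- st$env$step - st$steps_run
  popsize <- tibble::tibble(step = start + rows, n = st$popsize[rows])
  steps <- tibble::as_tibble(st$step_mat[rows, , drop = FALSE])
  steps <- dplyr::mutate(steps, step = start + rows,
                         living_end = st$living_end[rows],
                         .before = 1L)

  np <- length(st$pheno_snaps)
  if (np == 0L || st$pheno_snaps[[np]]$step != st$env$step) {
    take_pheno_snap(st, cfg, st$env$step)
  }
  ng <- length(st$geno_snaps)
  if (ng == 0L || st$geno_snaps[[ng]]$step != st$env$step) {
    take_geno_snap(st, cfg, st$env$step)
  }

  runtime <- proc.time()[["elapsed"]] - t0
  structure(
    list(config = cfg, architecture = arch,
         ledgers = list(deaths = deaths, births = births,
                        demography = demography, popsize = popsize,
                        steps = steps,
                        births_detail = if (isTRUE(cfg$record_birth_details))
                          tibble::as_tibble(do.call(rbind, st$birth_rows))),
         phenotypes = st$pheno_snaps, genotypes = st$geno_snaps,
         final = build_snapshot(st, cfg, arch),
         metadata = list(seed = cfg$seed, steps_requested = cfg$steps,
                         steps_run = st$steps_run, extinct = st$extinct,
                         extinction_step = st$extinction_step,
                         final_living = sum(st$alive),
                         final_eggs = st$eggs$n,
                         runtime_sec = runtime,
                         version = as.character(utils::packageVersion("senesim")))),
    class = "sim_run"
  )
}

#' @export
print.sim_run <- function(x, ...) {
  md <- x$metadata
  cat("<sim_run> ", md$steps_run, " steps (seed ", md$seed, "); final: ",
      md$final_living, " living, ", md$final_eggs, " eggs",
      if (md$extinct) paste0("; EXTINCT at step ", md$extinction_step) else "",
      "\n", sep = "")
  invisible(x)
}

#' One-row summary of a simulation run
#'
#' @param x A `sim_run`.
#' @param ... Unused.
#' @return A one-row tibble: steps run, extinction flag, final counts, mean
#'   population size, and observed median lifespan and life expectancy over
#'   the final recording window.
#' @export
glance.sim_run <- function(x, ...) {
  sm <- tryCatch(summary_metrics(x), error = function(e) NULL)
  tibble::tibble(
    steps_run = x$metadata$steps_run,
    extinct = x$metadata$extinct,
    final_living = x$metadata$final_living,
    final_eggs = x$metadata$final_eggs,
    mean_popsize = mean(x$ledgers$popsize$n),
    median_lifespan = if (is.null(sm)) NA_real_ else sm$median_lifespan,
    life_expectancy = if (is.null(sm)) NA_real_ else sm$life_expectancy
  )
}

#' Tidy a simulation run into its per-step population series
#'
#' @param x A `sim_run`.
#' @param ... Unused.
#' @return The per-step population-size tibble (`step`, `n`), the series
#'   recorded immediately after reproduction each step.
#' @export
tidy.sim_run <- function(x, ...) {
  x$ledgers$popsize
}

# --- snapshots -------------------------------------------------------------

build_snapshot <- function(st, cfg, arch) {
  idx <- which(st$alive)
  eg <- st$eggs
  en <- seq_len(eg$n)
  structure(
    list(format = 1L,
         architecture = arch,
         config = cfg,
         config_hash = config_hash(strip_config(cfg)),
         genomes = st$genome[, idx, drop = FALSE],
         age = st$age[idx],
         infected = st$infected[idx],
         birth_step = st$birth_step[idx],
         id = st$id[idx],
         next_id = st$next_id,
         eggs = list(genome = eg$genome[, en, drop = FALSE],
                     laid = eg$laid[en], parent_age = eg$parent_age[en],
                     id = eg$id[en]),
         env = st$env,
         rng_streams = mget(sort(names(st$streams)), envir = st$streams)),
    class = "sim_snapshot"
  )
}

# Configuration stripped of run-length and bookkeeping fields, so a hash
# identifies the evolutionary conditions rather than the run.
strip_config <- function(cfg) {
  cfg$steps <- NULL
  cfg$seed <- NULL
  cfg$init_from <- NULL
  cfg$resume_rng <- NULL
  cfg$record_window <- NULL
  cfg$record_phenotypes_every <- NULL
  cfg$record_genotypes_every <- NULL
  unclass(cfg)
}

check_snapshot_compat <- function(snap, arch) {
  if (!inherits(snap, "sim_snapshot")) {
    stop("not a sim_snapshot object", call. = FALSE)
  }
  if (!identical(snap$format, 1L)) {
    stop("unsupported snapshot format version: ", snap$format, call. = FALSE)
  }
  if (snap$architecture$total_bits != arch$total_bits ||
      snap$architecture$n_age_classes != arch$n_age_classes) {
    stop("snapshot architecture (", snap$architecture$total_bits, " bits, ",
         snap$architecture$n_age_classes, " age classes) is incompatible ",
         "with the configured architecture (", arch$total_bits, " bits, ",
         arch$n_age_classes, " age classes)", call. = FALSE)
  }
  invisible(snap)
}

#' Save / load a population snapshot
#'
#' A snapshot is a lossless serialization of the population and environment
#' state: genomes, ages, life phases, infection statuses, the egg pool, the
#' environment counters (step, starvation streak, predators, drift map) and
#' the per-process RNG stream states, together with the genome architecture
#' and a hash of the evolutionary conditions. Loading a snapshot into a
#' configuration with an incompatible architecture raises a versioned error.
#'
#' @param x A `sim_run` (its final state is saved) or a `sim_snapshot`.
#' @param path File path.
#' @return `save_snapshot()` returns `path` invisibly; `load_snapshot()`
#'   returns the `sim_snapshot`.
#' @export
save_snapshot <- function(x, path) {
  snap <- if (inherits(x, "sim_run")) x$final else x
  if (!inherits(snap, "sim_snapshot")) {
    stop("x must be a sim_run or sim_snapshot", call. = FALSE)
  }
  saveRDS(snap, path)
  invisible(path)
}

#' @rdname save_snapshot
#' @export
load_snapshot <- function(path) {
  snap <- readRDS(path)
  if (!inherits(snap, "sim_snapshot")) {
    stop("file does not contain a sim_snapshot: ", path, call. = FALSE)
  }
  snap
}

#' @export
print.sim_snapshot <- function(x, ...) {
  cat("<sim_snapshot> step ", x$env$step, ": ", ncol(x$genomes),
      " living, ", length(x$eggs$laid), " eggs; ",
      x$architecture$total_bits, " bits/haplotype\n", sep = "")
  invisible(x)
}
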