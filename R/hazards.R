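#' Periodic abiotic hazard specification
#'
#' Abiotic mortality models periodic, age- and genotype-independent death
#' (weather, seasonality). The per-step hazard is
#' `baseline + amplitude * waveform((step - phase) / period)` where the
#' waveform has range `[0, 1]`:
#' `flat` is identically 0 (hazard = baseline); `sinusoid` is
#' `(1 - cos(2*pi*x)) / 2` (trough at `step = phase`, peak half a period
#' later); `square` is 1 on the first half of each period; `triangle` rises
#' linearly to 1 at mid-period and back; `sawtooth` rises linearly over the
#' period.
#'
#' @param shape One of `"flat"`, `"sinusoid"`, `"square"`, `"triangle"`,
#'   `"sawtooth"`.
#' @param amplitude,baseline Probabilities with `baseline + amplitude <= 1`.
#' @param period Period in steps (>= 1).
#' @param phase Phase offset in steps.
#' @return An object of class `abiotic_wave`.
#' @export
abiotic_wave <- function(shape = "flat", amplitude = 0, period = 1,
                         phase = 0, baseline = 0) {
  shape <- match.arg(shape,
                     c("flat", "sinusoid", "square", "triangle", "sawtooth"))
  if (amplitude < 0 || baseline < 0 || baseline + amplitude > 1) {
    stop("abiotic wave requires amplitude, baseline >= 0 and ",
         "baseline + amplitude <= 1", call. = FALSE)
  }
  if (period < 1) stop("abiotic wave period must be >= 1", call. = FALSE)
  structure(list(shape = shape, amplitude = amplitude, period = period,
                 phase = phase, baseline = baseline),
            class = "abiotic_wave")
}

#' Evaluate the abiotic hazard at given steps
#'
#' @param wave An [abiotic_wave()].
#' @param step Step number(s).
#' @return Hazard probability in `[0, 1]`, vectorized over `step`.
#' @export
wave_hazard <- function(wave, step) {
  x <- ((step - wave$phase) / wave$period) %% 1
  w <- switch(wave$shape,
    flat = rep.int(0, length(x)),
    sinusoid = (1 - cos(2 * pi * x)) / 2,
    square = as.numeric(x < 0.5),
    triangle = 1 - abs(2 * x - 1),
    sawtooth = x
  )
  wave$baseline + wave$amplitude * w
}

#' Intrinsic (genetic) mortality draw
#'
#' Each living, non-egg individual of age `a` dies with probability
#' `1 - survival(a)`, where `survival(a)` is its genetically encoded
#' intrinsic survival probability at its current age.
#'
#' @param survival Vector of per-individual intrinsic survival probabilities
#'   at each individual's current age.
#' @return Logical death mask.
#' @export
intrinsic_deaths <- function(survival) {
  stopifnot(all(survival >= 0 & survival <= 1))
  stats::runif(length(survival)) >= survival
}

#' Abiotic mortality draw
#'
#' @param n Number of living, non-egg individuals exposed.
#' @param wave An [abiotic_wave()].
#' @param step Current step.
#' @return Logical death mask of length `n`.
#' @export
abiotic_deaths <- function(n, wave, step) {
  stats::runif(n) < wave_hazard(wave, step)
}

#' Infection (SIS) parameters
#'
#' Communicable-disease mortality, independent of age and genotype.
#' Susceptible individuals are infected with probability
#' `background + transmissibility * infected_fraction` (clipped to 1);
#' infected individuals die with `fatality_rate`, otherwise recover back to
#' susceptible with `recovery_rate`, otherwise stay infected.
#'
#' @param transmissibility Per-step force-of-infection scale in `[0, 1]`.
#' @param fatality_rate,recovery_rate Per-step probabilities with
#'   `fatality_rate + recovery_rate <= 1`.
#' @param background_infection Environment-borne infection probability.
#' @return An object of class `infection_params`.
#' @export
infection_params <- function(transmissibility = 0, fatality_rate = 0,
                             recovery_rate = 0, background_infection = 0) {
  vals <- c(transmissibility, fatality_rate, recovery_rate,
            background_infection)
  if (any(vals < 0 | vals > 1)) {
    stop("infection parameters must be probabilities in [0, 1]",
         call. = FALSE)
  }
  if (fatality_rate + recovery_rate > 1) {
    stop("fatality_rate + recovery_rate must be <= 1", call. = FALSE)
  }
  structure(list(transmissibility = transmissibility,
                 fatality_rate = fatality_rate,
                 recovery_rate = recovery_rate,
                 background_infection = background_infection),
            class = "infection_params")
}

#' One step of the infection process
#'
#' All transitions use start-of-process counts (parallel update).
#'
#' @param status Integer vector over living non-egg individuals: 0 = healthy,
#'   1 = infected.
#' @param params An [infection_params()].
#' @return A list with `status` (updated vector; entries for dead individuals
#'   are retained but flagged in `deaths`) and `deaths` (logical mask).
#' @export
infection_step <- function(status, params) {
  n <- length(status)
  deaths <- logical(n)
  if (n == 0L) return(list(status = status, deaths = deaths))
  infected <- status == 1L
  p_inf <- min(1, params$background_infection +
                  params$transmissibility * sum(infected) / n)
  if (p_inf > 0 && any(!infected)) {
    healthy <- which(!infected)
    newly <- healthy[stats::runif(length(healthy)) < p_inf]
    status[newly] <- 1L
  }
  if (any(infected)) {
    idx <- which(infected)
    u <- stats::runif(length(idx))
    deaths[idx[u < params$fatality_rate]] <- TRUE
    rec <- u >= params$fatality_rate &
           u < params$fatality_rate + params$recovery_rate
    status[idx[rec]] <- 0L
  }
  list(status = status, deaths = deaths)
}

#' Predation parameters
#'
#' @param predator_growth_rate Intrinsic per-step growth rate of the predator
#'   population.
#' @param vulnerability Prey vulnerability scale in `[0, 1]`.
#' @param initial_predators Starting predator count (>= 0).
#' @return An object of class `predation_params`.
#' @export
predation_params <- function(predator_growth_rate = 0, vulnerability = 0,
                             initial_predators = 0) {
  if (vulnerability < 0 || vulnerability > 1) {
    stop("vulnerability must be in [0, 1]", call. = FALSE)
  }
  if (initial_predators < 0) {
    stop("initial_predators must be >= 0", call. = FALSE)
  }
  structure(list(predator_growth_rate = predator_growth_rate,
                 vulnerability = vulnerability,
                 initial_predators = initial_predators),
            class = "predation_params")
}

#' One step of the predation process
#'
#' Per-prey kill probability is a saturating functional response,
#' `vulnerability * (1 - exp(-predators / n_prey))`, using start-of-process
#' counts; afterwards the predator population updates by a discrete logistic
#' law capped by the prey count, `P' = P + r * P * (1 - P / n_prey)`, floored
#' at 0 (and set to 0 when there is no prey).
#'
#' @param n_prey Number of living, non-egg individuals (eggs excluded).
#' @param predators Current predator count.
#' @param params A [predation_params()].
#' @return A list with `deaths` (logical mask of length `n_prey`) and
#'   `predators` (updated count).
#' @export
predation_step <- function(n_prey, predators, params) {
  if (n_prey == 0L) {
    return(list(deaths = logical(0), predators = 0))
  }
  p_kill <- params$vulnerability * (1 - exp(-predators / n_prey))
  deaths <- stats::runif(n_prey) < p_kill
  p_new <- predators + params$predator_growth_rate * predators *
           (1 - predators / n_prey)
  list(deaths = deaths, predators = max(0, p_new))
}

#' Starvation parameters
#'
#' Starvation engages when the living, non-egg population exceeds the
#' carrying capacity `K`. The `instantaneous` model kills exactly the excess
#' (uniformly chosen); under the `gradual` model every individual survives a
#' step with probability `(1 - m)^t` where `t` is the number of consecutive
#' steps spent above `K`, optionally weighted by age.
#'
#' @param model `"gradual"` or `"instantaneous"`.
#' @param m Starvation susceptibility in `(0, 1]` (gradual model).
#' @param age_weighting Optional non-negative vector over age classes;
#'   weights are normalized to mean 1 over the exposed individuals, so the
#'   age-flat case reduces exactly to the unweighted law.
#' @return An object of class `starvation_params`.
#' @export
starvation_params <- function(model = "gradual", m = 0.1,
                              age_weighting = NULL) {
  model <- match.arg(model, c("gradual", "instantaneous"))
  if (model == "gradual" && (m <= 0 || m > 1)) {
    stop("starvation susceptibility m must be in (0, 1]", call. = FALSE)
  }
  if (!is.null(age_weighting) && any(age_weighting < 0)) {
    stop("age_weighting must be non-negative", call. = FALSE)
  }
  structure(list(model = model, m = m, age_weighting = age_weighting),
            class = "starvation_params")
}

#' One step of the starvation process
#'
#' @param ages Integer ages of the living, non-egg individuals (used for the
#'   optional age weighting; its length is the exposed count `N`).
#' @param streak Number of consecutive previous steps spent above `K`.
#' @param K Carrying capacity (>= 1).
#' @param params A [starvation_params()].
#' @return A list with `deaths` (logical mask over the `N` individuals) and
#'   `streak` (updated counter: 0 when `N <= K`, else incremented before the
#'   mortality draw).
#' @export
starvation_step <- function(ages, streak, K, params) {
  n <- length(ages)
  if (n <= K) {
    return(list(deaths = logical(n), streak = 0L))
  }
  streak <- streak + 1L
  if (params$model == "instantaneous") {
    deaths <- logical(n)
    deaths[sample.int(n, n - K)] <- TRUE
  } else {
    m_i <- params$m
    if (!is.null(params$age_weighting)) {
      w <- params$age_weighting[pmin(ages, length(params$age_weighting) - 1L) + 1L]
      m_i <- pmin(1, params$m * w / mean(w))
    }
    p_die <- 1 - (1 - m_i)^streak
    deaths <- stats::runif(n) < p_die
  }
  list(deaths = deaths, streak = streak)
}

#' Expected death structure under sequentially applied hazards
#'
#' Mortality sources act in order on the survivors of the previous source.
#' A source with hazard `h` applied to `s` survivors yields `s * h` expected
#' deaths; the observed population-level rate divides those deaths by the
#' starting cohort size. The total number of deaths is invariant under
#' permutation of the hazards, but the per-source death structure is not.
#'
#' @param n Starting cohort size (>= 0).
#' @param hazards Ordered vector of per-source hazards, each in `[0, 1]`.
#' @return A list of class `sequential_mortality` with `per_source` (a tibble
#'   with columns `source`, `hazard`, `survivors_before`, `expected_deaths`,
#'   `observed_rate`), `total_deaths` and `total_rate`
#'   (`1 - prod(1 - hazards)`).
#' @examples
#' sm <- expected_sequential_mortality(1000, c(0.4, 0.8))
#' sm$per_source$expected_deaths # 400 480
#' sm$total_deaths               # 880
#' @export
expected_sequential_mortality <- function(n, hazards) {
  if (n < 0) stop("cohort size must be >= 0", call. = FALSE)
  if (any(hazards < 0 | hazards > 1)) {
    stop("hazards must be probabilities in [0, 1]", call. = FALSE)
  }
  surv_before <- n * cumprod(c(1, 1 - hazards))[seq_along(hazards)]
  deaths <- surv_before * hazards
  per_source <- tibble::tibble(
    source = seq_along(hazards),
    hazard = as.numeric(hazards),
    survivors_before = surv_before,
    expected_deaths = deaths,
    observed_rate = if (n > 0) deaths / n else rep(0, length(hazards))
  )
  structure(list(per_source = per_source,
                 total_deaths = sum(deaths),
                 total_rate = 1 - prod(1 - hazards)),
            class = "sequential_mortality")
}

#' @export
print.sequential_mortality <- function(x, ...) {
  print(x$per_source)
  cat("total deaths: ", format(x$total_deaths),
      "  total rate: ", format(x$total_rate), "\n", sep = "")
  invisible(x)
}
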