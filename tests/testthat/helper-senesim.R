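# Small builders shared across the test files.

tiny_arch <- function(n_age = 4L, bits = 2L) {
  build_architecture(list(
    trait_spec("survival", age_dependent = TRUE, bits_per_block = bits,
               lower = 0, upper = 1, initial = 1),
    trait_spec("reproduction", age_dependent = TRUE, bits_per_block = bits,
               lower = 0, upper = 0.5, initial = 0.25)
  ), n_age_classes = n_age)
}

# A fast default-like configuration for engine-level tests.
quick_config <- function(steps = 50L, K = 100L, seed = 1L, ...) {
  sim_config(
    steps = steps, K = K, init_n = K, n_age_classes = 10L,
    traits = list(
      trait_spec("survival", TRUE, 4L, lower = 0, upper = 1, initial = 1),
      trait_spec("reproduction", TRUE, 4L, lower = 0, upper = 0.5,
                 initial = 0.25),
      trait_spec("mutation_rate", FALSE, evolvable = FALSE, initial = 1e-3)
    ),
    reproduction = reproduction_params(maturity_age = 2L),
    seed = seed, record_window = 10L, ...
  )
}

# Configuration with flat, deterministic phenotypes (non-evolvable traits
# pinned by zero-width bounds): useful when a known hazard is needed.
flat_config <- function(survival, fertility, steps = 50L, K = 10000L,
                        init_n = 500L, n_age = 10L, maturity = 0L,
                        seed = 1L, ...) {
  sim_config(
    steps = steps, K = K, init_n = init_n, n_age_classes = n_age,
    traits = list(
      trait_spec("survival", TRUE, 1L, lower = survival, upper = survival,
                 initial = survival),
      trait_spec("reproduction", TRUE, 1L, lower = fertility,
                 upper = fertility, evolvable = FALSE, initial = fertility),
      trait_spec("mutation_rate", FALSE, evolvable = FALSE, initial = 0)
    ),
    reproduction = reproduction_params(maturity_age = maturity),
    seed = seed, record_window = max(steps, 1L), ...
  )
}

# 3-sigma binomial band check.
expect_binomial <- function(observed, n, p, label = "binomial draw") {
  se <- sqrt(n * p * (1 - p))
  expect_lt(abs(observed - n * p), 3 * se + 1e-9,
            label = paste0(label, " |", observed, " - ", n * p, "|"))
}

# Neutral-drift study conditions: constant census N = 200 with
# non-overlapping 20-step generations, 100 zero-effect loci (survival
# pinned at [1, 1]), fertility 1, no mutation, near-free recombination.
# Each generation lays 2000 eggs; instantaneous starvation culls the
# hatchlings uniformly back to 200.
neutral_drift_config <- function(seed, steps = 2000L) {
  sim_config(
    steps = steps, K = 200L, init_n = 200L, n_age_classes = 20L,
    ones_fraction = 0.5,
    traits = list(
      trait_spec("survival", TRUE, 5L, lower = 1, upper = 1, initial = 1),
      trait_spec("reproduction", TRUE, 1L, lower = 0, upper = 1,
                 evolvable = FALSE, initial = 1),
      trait_spec("mutation_rate", FALSE, evolvable = FALSE, initial = 0)
    ),
    reproduction = reproduction_params(
      mode = "sexual", maturity_age = 0L, oviparous = TRUE,
      hatching_policy = "when_adults_extinct", recombination_rate = 20
    ),
    starvation = starvation_params("instantaneous"),
    seed = seed, record_window = steps
  )
}

# Independent haploid Wright-Fisher oracle at the variance-effective size
# of the neutral-drift conditions (Crow's Ne = (4N - 2)/(Vk + 2), with the
# offspring-number variance Vk of hypergeometric culling of 200 survivors
# from 2000 eggs in families of 20). The final model state is the gen-99
# gamete pool, hence G = 99.
wright_fisher_oracle <- function(n_rep, loci = 100L, G = 99L) {
  N <- 200; pool <- 2000; fam <- 20
  Vk <- N * (fam / pool) * (1 - fam / pool) * ((pool - N) / (pool - 1))
  ne2 <- round(2 * (4 * N - 2) / (Vk + 2))
  replicate(n_rep, {
    x <- stats::rbinom(loci, ne2, 0.5)
    for (g in seq_len(G)) x <- stats::rbinom(loci, ne2, x / ne2)
    x / ne2
  })
}
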