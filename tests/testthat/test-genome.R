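test_that("architecture layout allocates one block per age class per trait", {
  arch <- build_architecture(list(
    trait_spec("survival", TRUE, 8L),
    trait_spec("reproduction", TRUE, 8L)
  ), n_age_classes = 50L)
  expect_equal(arch$total_bits, 800L)
  expect_equal(nrow(arch$layout), 800L)
  # bit -> (trait, age class, offset) is a bijection over allocated bits
  expect_equal(arch$layout$bit, 0:799)
  expect_false(anyDuplicated(arch$layout[, c("trait", "age_class",
                                             "offset")]) > 0)

  arch1 <- build_architecture(list(
    trait_spec("survival", FALSE, 4L)
  ), n_age_classes = 7L)
  expect_equal(arch1$total_bits, 4L)

  arch2 <- build_architecture(list(
    trait_spec("survival", TRUE, 8L),
    trait_spec("reproduction", TRUE, 8L),
    trait_spec("mutation_rate", FALSE, 8L, lower = 0, upper = 0.01,
               initial = 0.001)
  ), n_age_classes = 50L)
  expect_equal(arch2$total_bits, 808L)
})

test_that("architecture rejects inconsistent bounds and zero age classes", {
  expect_error(trait_spec("survival", TRUE, 8L, lower = 0.8, upper = 0.2),
               "bounds")
  expect_error(build_architecture(list(trait_spec("survival")), 0L),
               "n_age_classes")
  expect_error(trait_spec("nonsense"))
})

test_that("genome initialization hits the interpretation bounds at the extremes", {
  arch <- tiny_arch()
  set.seed(1)
  g1 <- init_genomes(5, arch, ones_fraction = 1)
  ph1 <- interpret_phenotypes(g1, arch)
  expect_true(all(ph1$survival == 1))
  expect_true(all(ph1$reproduction == 0.5))

  g0 <- init_genomes(5, arch, ones_fraction = 0)
  ph0 <- interpret_phenotypes(g0, arch)
  expect_true(all(ph0$survival == 0))
  expect_true(all(ph0$reproduction == 0))
})

test_that("initialization fraction gives binomial bit counts per block", {
  arch <- build_architecture(list(trait_spec("survival", TRUE, 8L)), 5L)
  set.seed(42)
  g <- init_genomes(10000, arch, ones_fraction = 0.5)
  total_ones <- sum(g)
  expect_binomial(total_ones, length(g), 0.5, "init bits")
  # mean bits set per block (both haplotypes, 8-bit blocks) = 8
  per_block <- total_ones / (10000 * 5)
  expect_lt(abs(per_block - 8), 3 * sqrt(16 * 0.25 / (10000 * 5)) * 16)
})

test_that("interpretation is linear in matching bits and drift-aware", {
  arch <- build_architecture(list(
    trait_spec("survival", TRUE, 4L, lower = 0, upper = 0.5)
  ), 2L)
  g <- init_genomes(1, arch, ones_fraction = 1)
  # set exactly half the bits of every block to 0
  L <- arch$total_bits
  g[c(1, 2, 5, 6, 9, 10, 13, 14), 1] <- 0L # two bits per block per haplotype
  ph <- interpret_phenotypes(g, arch)
  expect_equal(unname(ph$survival[, 1]), c(0.25, 0.25))

  # all-ones genome under all-zeros drift map gives the lower bound
  g1 <- init_genomes(1, arch, ones_fraction = 1)
  ph_inv <- interpret_phenotypes(g1, arch, drift = rep(0L, L))
  expect_true(all(ph_inv$survival == 0))
})

test_that("interpretation is deterministic and monotone in matching bits", {
  arch <- tiny_arch(n_age = 3L, bits = 4L)
  set.seed(7)
  g <- init_genomes(20, arch, ones_fraction = 0.5)
  ph_a <- interpret_phenotypes(g, arch)
  ph_b <- interpret_phenotypes(g, arch)
  expect_identical(ph_a, ph_b)

  # flipping any non-matching bit to match never decreases the trait value
  drift <- default_drift_map(arch)
  for (trial in 1:25) {
    i <- sample(ncol(g), 1)
    pos <- sample(nrow(g), 1)
    if (g[pos, i] == 1L) next # already matches the all-ones map
    g2 <- g
    g2[pos, i] <- 1L
    before <- interpret_phenotypes(g, arch, drift)
    after <- interpret_phenotypes(g2, arch, drift)
    expect_true(all(after$survival[, i] >= before$survival[, i]))
    expect_true(all(after$reproduction[, i] >= before$reproduction[, i]))
  }
})

test_that("mean interpreted value converges to lower + f * (upper - lower)", {
  arch <- build_architecture(list(
    trait_spec("survival", TRUE, 8L, lower = 0.2, upper = 0.8)
  ), 2L)
  f <- 0.3
  set.seed(11)
  g <- init_genomes(10000, arch, ones_fraction = f)
  ph <- interpret_phenotypes(g, arch)
  expected <- 0.2 + f * 0.6
  # SE of the mean of n block means, each an average of 16 Bernoulli bits
  se <- 0.6 * sqrt(f * (1 - f) / 16) / sqrt(10000)
  expect_lt(abs(mean(ph$survival) - expected), 3 * se)
})

test_that("mutation respects rate 0, rate 1, and the binomial flip count", {
  arch <- tiny_arch(n_age = 5L, bits = 8L)
  set.seed(3)
  g <- init_genomes(200, arch, ones_fraction = 0.5)
  expect_identical(mutate_genomes(g, 0), g)
  expect_true(all(mutate_genomes(g, 1) == 1L - g))
  expect_error(mutate_genomes(g, -0.1), "rate")

  # 0.001 per bit over 2 x 80 bits: mean flips/genome = 0.16
  flips <- sum(mutate_genomes(g, 0.001) != g)
  expect_binomial(flips, length(g), 0.001, "mutation flips")
})

test_that("asymmetric mutation biases direction but keeps the mean rate", {
  arch <- build_architecture(list(trait_spec("survival", TRUE, 8L)), 25L)
  set.seed(9)
  g <- init_genomes(400, arch, ones_fraction = 0.5)
  gm <- mutate_genomes(g, 0.01, asymmetry = 3)
  up <- sum(gm == 1L & g == 0L)
  down <- sum(gm == 0L & g == 1L)
  n0 <- sum(g == 0L)
  n1 <- sum(g == 1L)
  expect_binomial(up, n0, 0.015, "0->1 flips")
  expect_binomial(down, n1, 0.005, "1->0 flips")
})

test_that("recombination conserves the unordered bit pair at every locus", {
  set.seed(5)
  for (trial in 1:200) {
    h <- matrix(sample(0:1, 32, replace = TRUE), nrow = 2) # 16-bit toy
    r <- recombine(h, rate = runif(1, 0, 4))
    expect_equal(pmin(r[1, ], r[2, ]), pmin(h[1, ], h[2, ]))
    expect_equal(pmax(r[1, ], r[2, ]), pmax(h[1, ], h[2, ]))
  }
})

test_that("recombination with rate 0 is the identity and a single crossover swaps a suffix", {
  h <- rbind(rep(0L, 10), rep(1L, 10))
  expect_identical(recombine(h, 0), h)

  set.seed(2)
  seen_swap <- FALSE
  for (i in 1:50) {
    r <- recombine(h, rate = 1e-9 + 1) # expect 0-2 crossovers
    # every locus is either (0,1) or (1,0); segments alternate, so the
    # first differing position onward alternates in blocks
    expect_true(all(r[1, ] + r[2, ] == 1L))
    if (!identical(r, h)) seen_swap <- TRUE
  }
  expect_true(seen_swap)
})

test_that("assortment picks one haplotype from each parent uniformly", {
  L <- 8L
  a <- rbind(rep(0L, L), rep(1L, L)) # heterozygous parent
  b <- rbind(rep(0L, L), rep(0L, L)) # homozygous parent
  set.seed(8)
  picks <- replicate(10000, assort(a, b)[1, 1])
  expect_binomial(sum(picks == 1L), 10000, 0.5, "haplotype choice")

  ones <- rbind(rep(1L, L), rep(1L, L))
  expect_true(all(assort(ones, ones) == 1L))
})

test_that("asexual offspring with zero mutation are bit-identical to the parent", {
  arch <- tiny_arch()
  set.seed(4)
  g <- init_genomes(3, arch, ones_fraction = 0.5)
  kids <- generate_offspring(g, parents_a = c(1L, 3L), parents_b = NULL,
                             mutation_rate = 0, recombination_rate = 5)
  expect_equal(unclass(kids)[, 1], unclass(g)[, 1])
  expect_equal(unclass(kids)[, 2], unclass(g)[, 3])

  # sexual, both parents homozygous all-ones -> offspring all-ones
  g1 <- init_genomes(2, arch, ones_fraction = 1)
  kid <- generate_offspring(g1, 1L, 2L, mutation_rate = 0,
                            recombination_rate = 2)
  expect_true(all(kid == 1L))
})
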