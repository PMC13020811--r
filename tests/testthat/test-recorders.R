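test_that("observed life table recovers known flat hazards on a synthetic cohort", {
  # independent oracle: survival 0.8 per step, no other mortality while the
  # population is far below K, so q(a) should be 0.2 at every age
  cfg <- flat_config(survival = 0.8, fertility = 0.35, steps = 60,
                     init_n = 1000, K = 1e6, n_age = 10L, seed = 23)
  run <- run_simulation(cfg)
  lt <- life_table_observed(run)
  expect_s3_class(lt, "life_history_curves")
  q <- lt$mortality[1:9] # last age class closes at 1 via the age cap
  exp_q <- 0.2
  for (a in seq_along(q)) {
    se <- sqrt(exp_q * (1 - exp_q) / lt$exposure[a])
    expect_lt(abs(q[a] - exp_q), 4 * se)
  }
  expect_equal(lt$mortality[10], 1) # age cap
  expect_equal(lt$survivorship[1], 1)
  expect_true(all(diff(lt$survivorship) <= 1e-12))
})

test_that("intrinsic curves follow the stated cumulative-product convention", {
  ph <- structure(list(
    survival = matrix(c(0.9, 0.8), nrow = 2, ncol = 5),
    reproduction = matrix(0.3, nrow = 2, ncol = 5)
  ), class = "phenotype_table")
  ic <- intrinsic_curves(ph)
  expect_equal(ic$mortality, c(0.1, 0.2, NA))
  expect_equal(ic$survivorship, c(1, 0.9, 0.72))
  # identical genomes: zero between-individual variance by construction
  expect_equal(ic$fertility, c(0.3, 0.3, NA))
})

test_that("intrinsic survivorship matches a Monte-Carlo cohort under intrinsic-only death", {
  mu <- c(0.05, 0.1, 0.2, 0.4)
  set.seed(31)
  n <- 2e5
  alive <- rep(TRUE, n)
  observed <- numeric(length(mu) + 1)
  observed[1] <- 1
  for (a in seq_along(mu)) {
    alive[alive] <- runif(sum(alive)) >= mu[a]
    observed[a + 1] <- mean(alive)
  }
  ph <- structure(list(
    survival = matrix(1 - mu, nrow = 4, ncol = 3),
    reproduction = matrix(0, nrow = 4, ncol = 3)
  ), class = "phenotype_table")
  ic <- intrinsic_curves(ph)
  expect_lt(max(abs(ic$survivorship - observed)), 0.005)
})

test_that("observed curves converge to intrinsic curves in an intrinsic-only run", {
  cfg <- flat_config(survival = 0.85, fertility = 0.4, steps = 80,
                     init_n = 2000, K = 1e7, n_age = 12L, seed = 37)
  run <- run_simulation(cfg)
  lt <- life_table_observed(run)
  ic <- intrinsic_curves(run)
  keep <- 1:10 # well-populated ages
  expect_lt(max(abs(lt$mortality[keep] - ic$mortality[keep])), 0.03)
})

test_that("site frequencies, fixed-locus exclusion and effect annotation are correct", {
  arch <- build_architecture(list(
    trait_spec("survival", TRUE, 2L, lower = 0, upper = 1)
  ), 2L)
  haps <- matrix(0L, nrow = 10, ncol = 4)
  haps[1:3, 1] <- 1L   # freq 0.3
  haps[, 2] <- 1L      # fixed at 1
  haps[1:5, 3] <- 1L   # freq 0.5
  # locus 4 fixed at 0
  sfs <- compute_sfs(haps, arch = arch, bins = 10)
  expect_equal(sfs$loci$frequency, c(0.3, 1, 0.5, 0))
  expect_equal(sum(sfs$spectrum$count), 2) # fixed loci excluded
  expect_equal(sfs$loci$effect, rep(0.25, 4)) # (1-0)/(2*2), all beneficial

  drift <- c(1L, 0L, 1L, 1L)
  sfs2 <- compute_sfs(haps, arch = arch, drift = drift)
  expect_equal(sfs2$loci$effect, c(0.25, -0.25, 0.25, 0.25))

  sfs3 <- compute_sfs(haps, arch = arch, include_fixed = TRUE)
  expect_equal(sum(sfs3$spectrum$count), 4)
  expect_error(compute_sfs(haps[1, , drop = FALSE], arch = arch),
               "2 haplotypes")
})

test_that("summary metrics follow the documented discrete conventions", {
  lc <- structure(
    tibble::tibble(age_class = 0:2, mortality = c(0.5, 1, NA),
                   survivorship = c(1, 0.5, 0),
                   fertility = c(0, 0, NA), flavor = "observed"),
    class = c("life_history_curves", class(tibble::tibble()))
  )
  sm <- summary_metrics(lc)
  expect_equal(sm$life_expectancy, 1.5)
  expect_equal(sm$median_lifespan, 1) # crosses 0.5 exactly at age 1

  # median and maximum from the death ledger of a real run
  cfg <- flat_config(survival = 0.7, fertility = 0.4, steps = 60,
                     init_n = 500, K = 1e6, n_age = 15L, seed = 41)
  run <- run_simulation(cfg)
  sm2 <- summary_metrics(run)
  d <- run$ledgers$deaths
  agg <- stats::aggregate(deaths ~ age_class, data = d, FUN = sum)
  death_ages <- rep(agg$age_class, agg$deaths)
  expect_equal(sm2$median_lifespan, median(death_ages))
  expect_equal(sm2$max_lifespan, max(death_ages))
  expect_equal(sm2$n_deaths, length(death_ages))
})

test_that("removing extrinsic hazards rectangularizes the survivorship curve", {
  # same seeds with and without crowding mortality: the intrinsic-only runs
  # concentrate deaths into late ages (lower variance of age at death)
  var_age_at_death <- function(run) {
    d <- run$ledgers$deaths
    agg <- stats::aggregate(deaths ~ age_class, data = d, FUN = sum)
    ages <- rep(agg$age_class, agg$deaths)
    var(ages)
  }
  # homogeneous high intrinsic survival: intrinsic-only deaths pile up at
  # the age cap (rectangular type-I curve), crowding mortality spreads them
  vs_ext <- vs_int <- numeric(6)
  for (i in 1:6) {
    crowded <- flat_config(survival = 1, fertility = 0.4, steps = 60,
                           init_n = 400, K = 400, n_age = 20L, seed = 50 + i)
    crowded$starvation <- starvation_params("gradual", m = 0.2)
    free <- flat_config(survival = 1, fertility = 0.05, steps = 60,
                        init_n = 400, K = 1e7, n_age = 20L, seed = 50 + i)
    vs_ext[i] <- var_age_at_death(run_simulation(crowded))
    vs_int[i] <- var_age_at_death(run_simulation(free))
  }
  expect_lt(mean(vs_int), mean(vs_ext))
})

test_that("tidy and glance methods return the documented shapes", {
  run <- run_simulation(quick_config(steps = 20, seed = 61))
  g <- glance(run)
  expect_equal(nrow(g), 1L)
  expect_true(all(c("steps_run", "extinct", "mean_popsize") %in% names(g)))
  td <- tidy(run)
  expect_equal(names(td), c("step", "n"))

  arch <- tiny_arch(n_age = 2L, bits = 1L)
  ph <- interpret_phenotypes(init_genomes(3, arch, 1), arch)
  tp <- tidy(ph)
  expect_equal(nrow(tp), 3 * 2 * 2)
  expect_true(all(tp$value[tp$trait == "survival"] == 1))
})

test_that("plot builders return ggplot objects", {
  run <- run_simulation(quick_config(steps = 20, seed = 62))
  expect_s3_class(autoplot(run), "ggplot")
  expect_s3_class(autoplot(intrinsic_curves(run)), "ggplot")
  sfs <- compute_sfs(run)
  expect_s3_class(autoplot(sfs, color_by = "effect"), "ggplot")
})
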