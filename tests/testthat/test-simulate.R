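test_that("degenerate probabilities give deterministic matrices", {
  sc <- simulation_scenario(n1 = 90, n2 = 10, p1 = 1, p2 = 0, n_reps = 3, seed = 1)
  for (r in 1:3)
    expect_equal(unname(sample_matrix(sc, r)$z),
                 matrix(c(90, 0, 0, 10), 2, byrow = TRUE))
})

test_that("sampling is deterministic in (seed, scenario, rep) and order-free", {
  sc <- simulation_scenario(n1 = 50, n2 = 20, p1 = 0.7, p2 = 0.3,
                            n_reps = 5, seed = 123)
  a <- lapply(1:5, function(r) sample_matrix(sc, r, scenario_index = 2))
  b <- lapply(5:1, function(r) sample_matrix(sc, r, scenario_index = 2))
  expect_identical(a, rev(b))
  sc2 <- simulation_scenario(n1 = 50, n2 = 20, p1 = 0.7, p2 = 0.3,
                             n_reps = 5, seed = 124)
  expect_false(identical(sample_matrix(sc, 1)$z, sample_matrix(sc2, 1)$z))
  # sampling must not disturb the caller's RNG stream
  set.seed(99); r1 <- runif(1)
  set.seed(99); invisible(sample_matrix(sc, 3)); r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("row-binomial means are calibrated", {
  sc <- simulation_scenario(n1 = 1000, n2 = 1000, p1 = 0.5, p2 = 0.5,
                            n_reps = 500, seed = 77)
  z1 <- vapply(1:500, function(r) sample_matrix(sc, r)$z[1, 1], numeric(1))
  se <- sqrt(0.25 / 1000) / sqrt(500)
  expect_lt(abs(mean(z1 / 1000) - 0.5), 3 * se)
})

test_that("scenario validation rejects bad probabilities", {
  expect_error(simulation_scenario(10, 10, p1 = 1.2, p2 = 0.5), "probabilities")
  expect_error(simulation_scenario(10, 10, p1 = 0.5, p2 = -0.1), "probabilities")
})

test_that("the bundled deterministic cases reproduce the metric-vs-evidence pattern", {
  scen <- read_scenarios(system.file("extdata", "fig1_cases.json",
                                     package = "bfindep"))
  res <- run_comparison(scen)
  d <- res$replicates
  expect_equal(nrow(d), 4L)
  a <- d[d$scenario == "a_always_dominant", ]
  b <- d[d$scenario == "b_errors_in_dominant", ]
  cc <- d[d$scenario == "c_perfect", ]
  dd <- d[d$scenario == "d_random", ]
  # same accuracy, opposite evidence for (a) vs (b)
  expect_equal(a$pa, 0.90); expect_equal(b$pa, 0.90)
  expect_true(is.na(a$mcc)); expect_equal(a$kappa, 0)
  expect_equal(a$evidence, "negative")
  expect_equal(b$evidence, "decisive")
  # perfect prediction: everything 1, decisive
  expect_equal(unlist(cc[c("pa", "mcc", "f1", "kappa", "youden_j")],
                      use.names = FALSE), rep(1, 5))
  expect_equal(cc$evidence, "decisive")
  # random prediction: zeros except F1, negative evidence
  expect_equal(unlist(dd[c("mcc", "kappa", "youden_j")], use.names = FALSE),
               rep(0, 3))
  expect_equal(dd$f1, 1 / 6)
  expect_equal(dd$evidence, "negative")
})

test_that("comparison tables are reproducible and summarised per scenario", {
  scen <- list(simulation_scenario(30, 10, 0.9, 0.2, n_reps = 8, seed = 42),
               simulation_scenario(30, 10, 0.5, 0.5, n_reps = 8, seed = 43))
  r1 <- run_comparison(scen)
  r2 <- run_comparison(scen)
  expect_identical(r1, r2)
  expect_equal(nrow(r1$summary), 2L)
  frac <- rowSums(r1$summary[, grep("^frac_", names(r1$summary))])
  expect_equal(unname(frac), c(1, 1))
  expect_equal(r1$summary$n_reps, c(8L, 8L))
})

test_that("under H0 the conservative test rarely claims positive evidence", {
  sc <- simulation_scenario(n1 = 90, n2 = 10, p1 = 0.8, p2 = 0.8,
                            n_reps = 200, seed = 2024)
  res <- run_comparison(sc)
  frac_claim <- mean(res$replicates$log_b10_min >= 1)  # positive or stronger
  expect_lte(frac_claim, 0.10)
})

test_that("evidence under H1 grows with the test-set size", {
  small <- simulation_scenario(n1 = 18, n2 = 2, p1 = 0.9, p2 = 0.1,
                               n_reps = 50, seed = 314)
  large <- simulation_scenario(n1 = 90, n2 = 10, p1 = 0.9, p2 = 0.1,
                               n_reps = 50, seed = 314)
  res <- run_comparison(list(small, large))
  med <- res$summary$median_log_b10
  expect_true(med[2] > med[1])
})

test_that("row swap leaves the minimum unchanged for exchangeable designs", {
  set.seed(55)
  for (k in 1:20) {
    n <- sample(3:15, 1)
    z1 <- sample(0:n, 1); z2 <- sample(0:n, 1)
    cm <- cm_of(c(z1, n - z1, z2, n - z2))
    expect_equal(min_log_bayes_factor(cm)$log_b10_min,
                 min_log_bayes_factor(swap_rows(cm))$log_b10_min,
                 tolerance = 1e-10)
  }
})

test_that("dividing counts by 5 shrinks evidence but not the standard metrics", {
  mb <- metric_report(case_b()); mb5 <- metric_report(case_b5())
  expect_equal(unclass(mb), unclass(mb5))
  expect_gt(min_log_bayes_factor(case_b())$log_b10_min,
            min_log_bayes_factor(case_b5())$log_b10_min)
})
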