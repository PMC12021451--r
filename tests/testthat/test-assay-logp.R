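test_that("per-replicate log P is the log peak-area ratio", {
  expect_equal(logp_single(100, 100), 0)
  expect_equal(logp_single(1, 100), -2)
  expect_equal(logp_single(3.27, 100), log10(0.0327), tolerance = 1e-12)
  expect_equal(logp_single(3.27, 100), -1.4855, tolerance = 1e-4)
  expect_error(logp_single(0, 100), class = "papartition_data_error")
  expect_error(logp_single(10, -1), class = "papartition_data_error")
})

test_that("pooled estimate averages both directions with sample SD", {
  ms <- dplyr::bind_rows(
    make_partition(log_ratios = rep(-1.26, 3), direction = "from_organic"),
    make_partition(log_ratios = rep(-1.26, 3), direction = "from_aqueous"))
  est <- estimate_logp(ms)
  expect_equal(est$mean, -1.26, tolerance = 1e-12)
  expect_equal(est$sd, 0, tolerance = 1e-12)
  expect_equal(est$n, 6L)
  expect_equal(est$mean_from_organic, -1.26, tolerance = 1e-12)

  est2 <- estimate_logp(make_partition(log_ratios = c(-1.0, -1.2, -1.4)))
  expect_equal(est2$mean, -1.2, tolerance = 1e-12)
  expect_equal(est2$sd, 0.2, tolerance = 1e-12)
  expect_true(is.na(est2$mean_from_aqueous))

  # n = 1 convention: sd is 0, not NA
  expect_equal(estimate_logp(make_partition(log_ratios = -0.5))$sd, 0)

  mixed <- dplyr::bind_rows(make_partition("a", -1),
                            make_partition("b", -1))
  expect_error(estimate_logp(mixed), class = "papartition_usage_error")
})

test_that("estimate is invariant to response rescaling and negates on swap", {
  set.seed(101)
  ms <- dplyr::bind_rows(
    make_partition(log_ratios = rnorm(3, -1, 0.1),
                   direction = "from_organic"),
    make_partition(log_ratios = rnorm(3, -1, 0.1),
                   direction = "from_aqueous"))
  base <- estimate_logp(ms)
  for (scale in c(1e-3, 7.3, 1e4)) {
    scaled <- ms
    scaled$area_octanol <- scaled$area_octanol * scale
    scaled$area_water <- scaled$area_water * scale
    expect_equal(estimate_logp(scaled)$mean, base$mean, tolerance = 1e-12)
    expect_equal(estimate_logp(scaled)$sd, base$sd, tolerance = 1e-12)
  }
  swapped <- ms
  swapped$area_octanol <- ms$area_water
  swapped$area_water <- ms$area_octanol
  expect_equal(estimate_logp(swapped)$mean, -base$mean, tolerance = 1e-12)
})

test_that("direction effect test separates shifted groups, not identical ones", {
  same <- dplyr::bind_rows(
    make_partition(log_ratios = rep(-1, 3), direction = "from_organic"),
    make_partition(log_ratios = rep(-1, 3), direction = "from_aqueous"))
  res <- direction_effect(same)
  expect_false(res$significant)

  set.seed(7)
  apart <- dplyr::bind_rows(
    make_partition(log_ratios = -1 + rnorm(3, 0, 1e-4),
                   direction = "from_organic"),
    make_partition(log_ratios = -2 + rnorm(3, 0, 1e-4),
                   direction = "from_aqueous"))
  expect_true(direction_effect(apart)$significant)

  one_sided <- make_partition(log_ratios = rep(-1, 4))
  expect_error(direction_effect(one_sided),
               class = "papartition_insufficient_data_error")
})

test_that("method validation reports R^2, accuracy and precision flags", {
  det <- tibble::tibble(compound = c("a", "b", "c", "d"),
                        mean = c(-1, 0, 1, 2),
                        sd = c(0.05, 0.02, 0.03, 0.5))
  lit <- c(a = -1, b = 0, c = 1, d = 2)
  v <- validate_logp_method(det, lit)
  expect_equal(v$r_squared, 1, tolerance = 1e-12)
  expect_true(all(v$results$accuracy_pass))

  # one compound offset past the 0.2 log-unit accuracy limit
  det$mean[2] <- 0.5
  v2 <- validate_logp_method(det, lit)
  expect_false(v2$results$accuracy_pass[v2$results$compound == "b"])
  expect_true(all(v2$results$accuracy_pass[v2$results$compound != "b"]))

  # precision: RSD of compound d is 25% > 10%; near-zero mean is NA
  expect_false(v2$results$precision_pass[v2$results$compound == "d"])
  det3 <- tibble::tibble(compound = c("a", "b", "c"),
                         mean = c(0, 1, 2), sd = c(0.01, 0.01, 0.01))
  v3 <- validate_logp_method(det3, c(a = 0, b = 1, c = 2))
  expect_true(is.na(v3$results$rsd_pct[v3$results$compound == "a"]))
  expect_true(is.na(v3$results$precision_pass[v3$results$compound == "a"]))

  expect_error(validate_logp_method(det[1:2, ], lit),
               class = "papartition_insufficient_data_error")
})

test_that("noise-free synthetic shake-flask data are recovered exactly", {
  cfg <- simulation_config(seed = 11, noise_cv = 0)
  est <- estimate_logp(simulate_shake_flask(-1.93, cfg))
  expect_equal(est$mean, -1.93, tolerance = 1e-12)
  expect_equal(est$sd, 0, tolerance = 1e-12)
})
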