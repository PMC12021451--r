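test_that("log P deviations reproduce the published per-compound bands", {
  t1 <- pa_table1()
  dev <- logp_deviations(t1, logp_predictions_from_table(t1))
  kw <- dev[dev$method == "kowwin", ]
  mono <- kw[kw$compound == "Monocrotaline", ]
  expect_equal(mono$signed_dev, 0.74, tolerance = 1e-9)
  expect_equal(as.character(mono$band), "lt_1_logunit")
  las <- kw[kw$compound == "Lasiocarpine", ]
  expect_equal(las$signed_dev, 2.917, tolerance = 1e-9)
  expect_equal(as.character(las$band), "ge_1_logunit_up")
  # threshold strictness: retrorsine/KowWIN sits at exactly 1.01 >= 1
  ret <- kw[kw$compound == "Retrorsine", ]
  expect_equal(ret$signed_dev, 1.01, tolerance = 1e-9)
  expect_equal(as.character(ret$band), "ge_1_logunit_up")
})

test_that("band thresholds are closed/open exactly as specified", {
  exp_tbl <- tibble::tibble(compound = c("a", "b", "c"), value = c(0, 0, 0))
  preds <- tibble::tibble(compound = c("a", "b", "c"),
                          method = "m", value = c(1.0, 0.999999, -1.0))
  dev <- logp_deviations(exp_tbl, preds)
  expect_equal(as.character(dev$band),
               c("ge_1_logunit_up", "lt_1_logunit", "ge_1_logunit_down"))

  exp_rb <- tibble::tibble(compound = c("a", "b", "c"), value = c(1, 1, 1))
  pred_rb <- tibble::tibble(compound = c("a", "b", "c"), method = "m",
                            value = c(1.1, 1.5, 1.0999999))
  devr <- rb_deviations(exp_rb, pred_rb)
  # exactly 10% falls in the middle band ("less than 10%" is strict),
  # exactly 50% in the top band
  expect_equal(as.character(devr$band),
               c("10_to_50pct", "ge_50pct", "lt_10pct"))
  expect_true(all(devr$pct_dev >= 0))
})

test_that("Rb deviations reproduce the published classification", {
  t2 <- pa_table2()
  dev <- rb_deviations(t2, rb_predictions_from_table(t2))
  ab <- dev[dev$method == "acid_base", ]
  expect_equal(ab$pct_dev[ab$compound == "Monocrotaline"], 6.54,
               tolerance = 1e-2)
  expect_equal(
    as.character(ab$band[ab$compound == "Intermedine N-oxide"]),
    "10_to_50pct")
  expect_equal(ab$pct_dev[ab$compound == "Intermedine N-oxide"], 45.1,
               tolerance = 1e-2)
  # within 10% of experiment: monocrotaline and retrorsine only
  expect_setequal(ab$compound[ab$band == "lt_10pct"],
                  c("Monocrotaline", "Retrorsine"))
  mech <- dev[dev$method == "mechanistic", ]
  expect_setequal(mech$compound[mech$band == "lt_10pct"],
                  "Monocrotaline N-oxide")
  # fold deviation is the symmetric counterpart of the percent metric
  expect_true(all(dev$fold_dev >= 1))
  under <- dev$predicted < dev$experimental
  expect_equal(dev$fold_dev[under], 1 / (1 - dev$pct_dev[under] / 100),
               tolerance = 1e-9)
  expect_equal(dev$fold_dev[!under], 1 + dev$pct_dev[!under] / 100,
               tolerance = 1e-9)
})

test_that("band counts use per-method denominators and sum to n", {
  t1 <- pa_table1()
  dev <- logp_deviations(t1, logp_predictions_from_table(t1))
  kw <- band_counts(dev, "kowwin")
  expect_equal(kw$n, 8L)
  expect_equal(kw$upward_ge_1, 5L)
  expect_equal(sum(kw$counts), kw$n)
  sp <- band_counts(dev, "sparc")
  expect_equal(sp$n, 4L)  # missing PANO predictions leave the denominator
  expect_equal(sp$upward_ge_1, 3L)
  spl <- band_counts(dev, "splogp")
  expect_equal(spl$n, 8L)
  expect_equal(spl$upward_ge_1, 3L)
  expect_error(band_counts(dev, "nonexistent"),
               class = "papartition_usage_error")
})

test_that("experiment summaries report extremes, pair differences, ranking", {
  t1 <- pa_table1()
  s <- summarize_experiment(t1, "logp")
  expect_equal(s$min, -1.93)
  expect_identical(s$argmin, "Intermedine")
  expect_equal(s$max, -0.302)
  expect_identical(s$argmax, "Lasiocarpine N-oxide")
  ret_diff <- s$pair_differences$difference[
    s$pair_differences$pa == "Retrorsine"]
  expect_equal(ret_diff, 0.02, tolerance = 1e-9)
  expect_identical(s$pa_ranking, c("Intermedine", "Monocrotaline",
                                   "Retrorsine", "Lasiocarpine"))
  s2 <- summarize_experiment(pa_table2(), "rb")
  expect_equal(s2$min, 0.689)
  expect_equal(s2$max, 1.12)
  expect_error(
    summarize_experiment(tibble::tibble(compound = "a", value = 1), "rb"),
    class = "papartition_insufficient_data_error")
})

test_that("deviation functions reject unusable inputs", {
  exp_tbl <- tibble::tibble(compound = "a", value = 1)
  preds <- tibble::tibble(compound = "zzz", method = "m", value = 1)
  expect_error(logp_deviations(exp_tbl, preds),
               class = "papartition_data_error")
  bad_exp <- tibble::tibble(compound = "a", value = -0.2)
  expect_error(
    rb_deviations(bad_exp,
                  tibble::tibble(compound = "a", method = "m", value = 1)),
    class = "papartition_data_error")
})
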