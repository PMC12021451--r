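test_that("effective class at pH reclassifies fully neutral bases only", {
  expect_identical(classify_at_ph(ionizable_compound("x"), 7.4), "neutral")
  # base pKa 9 at pH 7.4: ~97.6% ionized, stays a base
  expect_identical(classify_at_ph(base_compound(9), 7.4), "base")
  # base pKa 4 at pH 7.4: ionized fraction ~4e-4 < 1%, behaves neutral
  expect_identical(classify_at_ph(base_compound(4), 7.4), "neutral")
  # acids are never reclassified by the rule
  expect_identical(classify_at_ph(acid_compound(4), 7.4), "acid")
})

test_that("acid/base classification rule returns the two fixed values", {
  expect_equal(rb_acid_base("base"), 1.0)
  expect_equal(rb_acid_base("neutral"), 1.0)
  expect_equal(rb_acid_base("acid"), 0.55)
  expect_equal(rb_acid_base("zwitterion"), 0.55)
})

test_that("K_rbc,pla is the composition-weighted affinity sum", {
  p <- blood_params(hct = 0.45, f_rbc_water = 0.6, f_rbc_lipids = 0.1,
                    f_rbc_prot = 0.3, k_prot = 0.5)
  expect_equal(k_rbc_pla(0, p), 0.6 + 0.1 + 0.15, tolerance = 1e-12)
  # zero lipid fraction removes the log P dependence
  p0 <- blood_params(f_rbc_lipids = 0, f_rbc_water = 0.65,
                     f_rbc_prot = 0.33, k_prot = 0.2)
  expect_equal(k_rbc_pla(-3, p0), k_rbc_pla(3, p0), tolerance = 1e-12)
  # single-expression oracle at a study-like log P
  pd <- default_blood_params()
  expect_equal(k_rbc_pla(-1.93, pd),
               0.63 + 0.005 * 10^(-1.93) + 0.33 * 0.2, tolerance = 1e-12)
  # strictly increasing in log P when lipids are present
  ks <- vapply(seq(-3, 3, by = 0.5), k_rbc_pla, numeric(1), params = pd)
  expect_true(all(diff(ks) > 0))
})

test_that("mechanistic Rb obeys its mass-balance limits and monotonicity", {
  p <- blood_params(hct = 0.45)
  expect_identical(rb_mechanistic(0, 0.5, p), 1 - 0.45)
  expect_identical(rb_mechanistic(2, 0.5, p), 1)  # k * fu_p = 1 fixed point
  expect_identical(rb_mechanistic(1 / 0.9, 0.9, p), 1)
  # monotone in k and fu_p; floor at 1 - hct
  rbs <- vapply(seq(0, 5, by = 0.25), rb_mechanistic, numeric(1),
                fu_p = 0.8, params = p)
  expect_true(all(diff(rbs) > 0))
  expect_true(all(rbs >= 1 - p$hct))
  # hct direction flips with the sign of k * fu_p - 1
  lo <- blood_params(hct = 0.2)
  hi <- blood_params(hct = 0.6)
  expect_lt(rb_mechanistic(0.5, 0.5, hi), rb_mechanistic(0.5, 0.5, lo))
  expect_gt(rb_mechanistic(4, 0.8, hi), rb_mechanistic(4, 0.8, lo))
  expect_error(rb_mechanistic(1, 0, p), class = "papartition_usage_error")
})

test_that("blood parameter validation and YAML round-trip work", {
  expect_error(blood_params(hct = 1.2), class = "papartition_config_error")
  expect_error(blood_params(f_rbc_water = 0.7, f_rbc_lipids = 0.2,
                            f_rbc_prot = 0.2),
               class = "papartition_config_error")
  path <- tempfile(fileext = ".yaml")
  writeLines(c("hct: 0.40", "k_prot: 0.5"), path)
  p <- read_blood_params(path)
  expect_equal(p$hct, 0.40)
  expect_equal(p$k_prot, 0.5)
  expect_equal(p$f_rbc_water, 0.63)  # unspecified keys keep defaults
})

test_that("prediction table runs both models and collects per-compound errors", {
  reg <- pa_compounds()
  t1 <- pa_table1()
  logp <- setNames(t1$logp_exp_mean, t1$compound)
  fu <- pa_fu_p()
  preds <- predict_rb_table(reg, logp = logp, fu_p = fu)
  expect_equal(sum(preds$method == "acid_base"), 8L)
  expect_equal(sum(preds$method == "mechanistic"), 8L)
  expect_true(all(preds$value[preds$method == "acid_base"] == 1))
  expect_equal(nrow(attr(preds, "errors")), 0L)

  # drop one fu,p: mechanistic errors for that compound, acid/base survives
  fu2 <- fu[names(fu) != "Retrorsine"]
  preds2 <- predict_rb_table(reg, logp = logp, fu_p = fu2)
  errs <- attr(preds2, "errors")
  expect_equal(errs$compound, "Retrorsine")
  expect_equal(errs$method, "mechanistic")
  expect_true(any(preds2$compound == "Retrorsine" &
                    preds2$method == "acid_base"))
  expect_false(any(preds2$compound == "Retrorsine" &
                     preds2$method == "mechanistic"))
})

test_that("ionization correction scales only the lipid term", {
  reg <- pa_compounds()
  p_on <- blood_params(ionization_correction = TRUE)
  t1 <- pa_table1()
  logp <- setNames(t1$logp_exp_mean, t1$compound)
  off <- predict_rb_table(reg, logp = logp)
  on <- predict_rb_table(reg, params = p_on, logp = logp)
  m_off <- off$value[off$method == "mechanistic"]
  m_on <- on$value[on$method == "mechanistic"]
  # partially ionized compounds lose (a little) lipid affinity
  expect_true(all(m_on <= m_off + 1e-12))
  expect_identical(on$value[on$method == "acid_base"],
                   off$value[off$method == "acid_base"])
})
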