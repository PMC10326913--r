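noiseless <- function(...) {
  instrument_model(noise_cv = 0, rt_jitter_sd = 0, ...)
}

test_that("pure thiol-state truth yields signal in that state only", {
  tr <- ground_truth(thiol = c("2xSH" = 1, "1xSH1xCys" = 0, "2xCys" = 0,
                               iDSB = 0),
                     reduction = c(heavy_light = 0, heavy_heavy = 0))
  pk <- simulate_peak_table(tr, noiseless(), seed = 1)
  th <- pk[grepl("^(2xSH|1xSH1xCys|2xCys|iDSB)\\.", pk$compound_id), ]
  expect_true(all(th$area[th$compound_id == "2xSH.y5"] > 0))
  expect_true(all(th$area[th$compound_id != "2xSH.y5"] == 0))
  rep <- quantify_attributes(pk, isotype = "lambda")
  th_pct <- rep[rep$attribute_class == "thiol_state", ]
  expect_equal(th_pct$value_percent[th_pct$analyte == "2xSH"], 100)
  expect_equal(sum(th_pct$value_percent), 100, tolerance = 1e-9)
})

test_that("a biased response factor distorts the raw proportion as expected", {
  # 20 % iDSB with RF 0.9 -> raw share 0.18 / 0.98 = 18.367 %
  tr <- ground_truth(thiol = c("2xSH" = 0.8, "1xSH1xCys" = 0, "2xCys" = 0,
                               iDSB = 0.2),
                     reduction = c(heavy_light = 0, heavy_heavy = 0))
  inst <- noiseless(response_factors = c(iDSB = 0.9))
  pk <- simulate_peak_table(tr, inst, seed = 1)
  rep <- quantify_attributes(pk, isotype = "lambda")
  idsb <- rep$value_percent[rep$analyte == "iDSB"]
  expect_equal(idsb, 100 * 0.18 / 0.98, tolerance = 1e-9)
})

test_that("simulation is deterministic under a fixed seed", {
  tr <- ground_truth()
  a <- simulate_peak_table(tr, n_samples = 3, seed = 99)
  b <- simulate_peak_table(tr, n_samples = 3, seed = 99)
  expect_identical(a, b)
  c2 <- simulate_peak_table(tr, n_samples = 3, seed = 100)
  expect_false(identical(a$area, c2$area))
})

test_that("quadratic bias adds a second-order term to expected areas", {
  tr <- ground_truth(thiol = c("2xSH" = 0.6, "1xSH1xCys" = 0, "2xCys" = 0,
                               iDSB = 0.4),
                     reduction = c(heavy_light = 0, heavy_heavy = 0))
  inst <- noiseless(bias_quadratic = c(iDSB = 0.5))
  pk <- simulate_peak_table(tr, inst, seed = 1)
  expect_equal(pk$area[pk$compound_id == "iDSB.y5"], 0.4 + 0.5 * 0.16,
               tolerance = 1e-12)
})

test_that("blend series are convex combinations, exact at the endpoints", {
  a <- ground_truth(thiol = c("2xSH" = 1, "1xSH1xCys" = 0, "2xCys" = 0,
                              iDSB = 0))
  b <- ground_truth(thiol = c("2xSH" = 0, "1xSH1xCys" = 0, "2xCys" = 0,
                              iDSB = 1))
  blends <- generate_blend_series(a, b, levels = c(0, 0.5, 1))
  expect_equal(blends[[1]]$thiol, a$thiol)
  expect_equal(blends[[3]]$thiol, b$thiol)
  expect_equal(as.numeric(blends[[2]]$thiol[c("2xSH", "iDSB")]), c(0.5, 0.5))

  levels <- seq(0, 1, by = 0.1)
  series <- generate_blend_series(a, b, levels)
  idsb <- vapply(series, function(t) t$thiol[["iDSB"]], numeric(1))
  # fractions are affine in the blend level
  fit <- stats::lm(idsb ~ levels)
  expect_equal(unname(stats::coef(fit)), c(0, 1), tolerance = 1e-12)
  expect_error(generate_blend_series(a, b, levels = 1.2), "0, 1")
})

test_that("in-source fragmentation conserves total glycoform area", {
  tr <- ground_truth()
  panel <- build_default_panel()
  pk <- simulate_peak_table(tr, noiseless(), panel, seed = 3)
  src <- source_params(desolvation_temp_C = 450, desolvation_gasflow_Lh = 900)
  inst <- instrument_model()
  f <- insource_fraction(src, inst)
  expect_gt(f, 0)
  leaked <- apply_insource_model(pk, panel, src, inst)
  gly <- panel$compound_id[panel$attribute_class == "glycosylation"]
  expect_equal(sum(leaked$area[leaked$compound_id %in% gly]),
               sum(pk$area[pk$compound_id %in% gly]), tolerance = 1e-9)
  # donors shed exactly f, single-step acceptors gain it
  a0 <- stats::setNames(pk$area, pk$compound_id)
  a1 <- stats::setNames(leaked$area, leaked$compound_id)
  expect_equal(a1[["G2FS2.oxonium138"]], (1 - f) * a0[["G2FS2.oxonium138"]],
               tolerance = 1e-12)
  expect_equal(a1[["G1F.oxonium138"]],
               a0[["G1F.oxonium138"]] + f * a0[["G1FS.oxonium138"]],
               tolerance = 1e-12)

  # cold source: identity
  cold <- instrument_model(insource = list(f_max = 0, temp_mid = 420,
                                           temp_scale = 25, gasflow_coef = 0,
                                           capillary_coef = 0))
  expect_identical(apply_insource_model(pk, panel, src, cold), pk)
})

test_that("leak fraction is monotone in desolvation temperature", {
  inst <- instrument_model()
  temps <- seq(300, 500, by = 25)
  f <- vapply(temps, function(tc) {
    insource_fraction(source_params(desolvation_temp_C = tc), inst)
  }, numeric(1))
  expect_true(all(diff(f) >= 0))
})

test_that("chromatogram traces integrate back to the table areas", {
  tr <- ground_truth()
  panel <- build_default_panel()
  pk <- simulate_peak_table(tr, noiseless(), panel, seed = 7)
  ch <- simulate_chromatograms(pk, panel, dt = 0.002, noiseless())
  for (cid in c("2xSH.y5", "G0F.oxonium138", "standard.y3")) {
    trc <- ch[ch$compound_id == cid, ]
    area <- sum(diff(trc$time_min) *
                  (head(trc$intensity, -1) + tail(trc$intensity, -1)) / 2)
    expect_equal(area, pk$area[pk$compound_id == cid], tolerance = 0.01)
  }
  # zero area -> flat zero trace
  pk0 <- pk[pk$compound_id == "kappa_reduced.b4", ]
  expect_equal(pk0$area, 0)
  trc0 <- ch[ch$compound_id == "kappa_reduced.b4", ]
  expect_true(all(trc0$intensity == 0))
  # no jitter -> apex at the window midpoint
  trc <- ch[ch$compound_id == "standard.y3", ]
  expect_equal(trc$time_min[which.max(trc$intensity)], (5.10 + 5.60) / 2,
               tolerance = 0.003)
  expect_error(simulate_chromatograms(pk, panel, dt = 0.2), "wider than")
})

test_that("ground truth validation enforces simplex and range constraints", {
  expect_error(ground_truth(thiol = c("2xSH" = 0.5, "1xSH1xCys" = 0.2,
                                      "2xCys" = 0.2, iDSB = 0.2)), "sum to 1")
  expect_error(ground_truth(reduction = c(heavy_light = 1.2,
                                          heavy_heavy = 0)), "\\[0, 1\\]")
  expect_error(ground_truth(abundance = 0), "positive")
  expect_error(ground_truth(fragmentation = c(Frag1 = 0, Frag2 = 0.6,
                                              Frag3 = 0, Frag4 = 0.6)),
               "share the wildtype parent")
})
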