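test_that("peak integration matches closed-form areas", {
  # unit-height rectangle, 1 min wide
  rect <- data.frame(time_min = seq(0, 2, by = 0.01),
                     intensity = as.numeric(seq(0, 2, by = 0.01) >= 0.5 &
                                              seq(0, 2, by = 0.01) <= 1.5))
  res <- integrate_peak(rect, baseline = FALSE)
  expect_equal(res$area, 1.0, tolerance = 0.02)

  tt <- seq(0, 2, by = 0.002)
  gauss <- data.frame(time_min = tt, intensity = 3 * stats::dnorm(tt, 1, 0.08))
  res <- integrate_peak(gauss, window = c(0.5, 1.5), baseline = FALSE)
  expect_equal(res$area, 3, tolerance = 0.01)
  expect_identical(res$flag, "ok")

  # a constant offset is removed by the edge baseline
  gauss$intensity <- gauss$intensity + 0.7
  res_bl <- integrate_peak(gauss, window = c(0.5, 1.5), baseline = TRUE)
  expect_equal(res_bl$area, 3, tolerance = 0.01)

  zero <- data.frame(time_min = tt, intensity = 0)
  res0 <- integrate_peak(zero)
  expect_equal(res0$area, 0)
  expect_identical(res0$flag, "no_peak")

  expect_error(integrate_peak(data.frame(time_min = c(1, 0.5),
                                         intensity = c(0, 1))), "sorted")
  expect_error(integrate_peak(gauss, window = c(-1, 1)), "outside")
})

test_that("thiol percentages implement signal-over-cumulative-signal", {
  eq <- thiol_percentages(c("2xSH" = 2, "1xSH1xCys" = 2, "2xCys" = 2,
                            iDSB = 2))
  expect_equal(as.numeric(eq), rep(25, 4))

  corr <- correction_model(factors = c(iDSB = 0.9), provenance = "blend-fit")
  pct <- thiol_percentages(c("2xSH" = 0.8, "1xSH1xCys" = 0, "2xCys" = 0,
                             iDSB = 0.18), corr)
  expect_equal(pct[["iDSB"]], 20, tolerance = 1e-9)
  expect_equal(pct[["2xSH"]], 80, tolerance = 1e-9)

  single <- thiol_percentages(c("2xSH" = 0, "1xSH1xCys" = 0, "2xCys" = 5,
                                iDSB = 0))
  expect_equal(single[["2xCys"]], 100)

  expect_error(thiol_percentages(c("2xSH" = 0, "1xSH1xCys" = 0, "2xCys" = 0,
                                   iDSB = 0)), "no signal")
  expect_error(thiol_percentages(c("2xSH" = 1)), "1xSH1xCys")
})

test_that("reduction percentages follow reduced over reduced-plus-linked", {
  base <- c("2xSH" = 0.2, "1xSH1xCys" = 0.2, "2xCys" = 0.4, iDSB = 0.2,
            heavy_reduced = 0, lambda_linked = 1, lambda_reduced = 0)
  pct <- reduction_percentages(base)
  expect_equal(as.numeric(pct), c(0, 0))
  expect_identical(attr(pct, "isotype"), "lambda")

  areas <- base
  areas[["lambda_reduced"]] <- 0.25
  areas[["lambda_linked"]] <- 0.75
  corr <- correction_model(factors = c(lambda_reduced = 0.8),
                           provenance = "equimolar-mix")
  pct <- reduction_percentages(areas, corr)
  expect_equal(pct[["heavy_light"]], 100 * 0.3125 / 1.0625, tolerance = 1e-9)

  # the equimolar-mix correction forces 50 % on the mix itself
  mix <- c(base, kappa_linked = 0)
  mix[["lambda_reduced"]] <- 0.37   # biased signal of an equimolar sample
  mix[["lambda_linked"]] <- 0.63
  cm <- equimolar_mix_factors(mix)
  pct <- reduction_percentages(mix, cm)
  expect_equal(pct[["heavy_light"]], 50, tolerance = 1e-9)

  expect_error(reduction_percentages(c(base, kappa_linked = 0,
                                       lambda_linked = 0)[-6]),
               "specify isotype")
})

test_that("glycoform percentages apply conversions then renormalize", {
  pct <- glyco_percentages(c(G0F = 1, G1F = 1))
  expect_equal(as.numeric(pct), c(50, 50))
  expect_equal(attr(pct, "sialylated"), 0)

  corr <- correction_model(conversions = c(G2FS2 = 2),
                           provenance = "orthogonal-bridge")
  # corrected areas (6, 3, 2) renormalize over their own sum
  pct <- glyco_percentages(c(G0F = 6, G1F = 3, G2FS2 = 1), corr)
  expect_equal(as.numeric(pct), 100 * c(6, 3, 2) / 11, tolerance = 1e-9)
  expect_equal(attr(pct, "sialylated"), 100 * 2 / 11, tolerance = 1e-9)
  expect_equal(sum(pct), 100, tolerance = 1e-9)

  lone <- glyco_percentages(c(G1FS = 3))
  expect_equal(as.numeric(lone), 100)
  expect_equal(attr(lone, "sialylated"), 100)
  expect_error(glyco_percentages(c(G0F = 0)), "no signal")
})

test_that("fragmentation modes split vs-parent and vs-standard", {
  areas <- c(Frag2 = 0.3, wildtype = 0.3, Frag1 = 0.12, standard = 0.60)
  df <- fragmentation_percentages(areas)
  expect_equal(df$value_percent[df$analyte == "Frag2"], 50)
  expect_identical(df$mode[df$analyte == "Frag2"], "vs-parent")
  expect_equal(df$value_percent[df$analyte == "Frag1"], 20)
  expect_identical(df$mode[df$analyte == "Frag1"], "vs-standard")

  z <- fragmentation_percentages(c(Frag2 = 0, wildtype = 1))
  expect_equal(z$value_percent, 0)
  # vs-standard ratios are not capped at 100
  big <- fragmentation_percentages(c(Frag3 = 3, standard = 1))
  expect_gt(big$value_percent, 100)
  expect_error(fragmentation_percentages(c(Frag1 = 1, standard = 0)),
               "standard")
  expect_error(fragmentation_percentages(c(Frag2 = 1)), "parent")
})

test_that("normalization, scale invariance and round-trip identity hold", {
  panel <- build_default_panel()
  inst0 <- instrument_model(noise_cv = 0, rt_jitter_sd = 0)
  set.seed(202)
  for (i in 1:10) {
    tr <- random_truth()
    pk <- simulate_peak_table(tr, inst0, panel, seed = i)
    rep <- quantify_attributes(pk, panel)
    th <- rep$value_percent[rep$attribute_class == "thiol_state"]
    expect_equal(sum(th), 100, tolerance = 1e-9)
    gl <- rep$value_percent[rep$attribute_class == "glycosylation" &
                              rep$analyte != "sialylated"]
    expect_equal(sum(gl), 100, tolerance = 1e-9)

    # scale invariance
    pk2 <- pk
    pk2$area <- pk2$area * 37.5
    rep2 <- quantify_attributes(pk2, panel)
    expect_equal(rep2$value_percent, rep$value_percent, tolerance = 1e-9)

    # noiseless round trip against the closed-form truth
    tru <- truth_report(tr)
    m <- merge(rep, tru, by = c("attribute_class", "analyte"))
    expect_equal(m$value_percent.x, m$value_percent.y, tolerance = 1e-9)
  }
})

test_that("correction preserves ordering between equal-factor states", {
  a <- c("2xSH" = 0.5, "1xSH1xCys" = 0.3, "2xCys" = 0.15, iDSB = 0.05)
  corr <- correction_model(factors = c("2xSH" = 0.7, "1xSH1xCys" = 0.7),
                           provenance = "blend-fit")
  pct <- thiol_percentages(a, corr)
  expect_gt(pct[["2xSH"]], pct[["1xSH1xCys"]])
})

test_that("quantify rejects malformed peak tables", {
  panel <- build_default_panel()
  pk <- simulate_peak_table(ground_truth(), panel = panel, seed = 1)
  expect_error(quantify_attributes(pk[0, ], panel), "no samples")
  bad <- pk
  bad$compound_id[1] <- "mystery.y1"
  expect_error(quantify_attributes(bad, panel), "mystery.y1")
  dup <- rbind(pk, pk[1, ])
  expect_error(quantify_attributes(dup, panel), "duplicate")
  neg <- pk
  neg$area[1] <- -1
  expect_error(quantify_attributes(neg, panel), ">= 0")
})
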