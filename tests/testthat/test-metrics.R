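test_that("loading efficiency follows the blank-subtracted ratio and its bounds", {
  expect_equal(loading_efficiency(44, 400), 11)
  expect_equal(loading_efficiency(0, 400), 0)
  expect_equal(loading_efficiency(400, 400), 100)
  expect_equal(loading_efficiency(105, 1005, blank = 5), 10)
  # monotone in the encapsulated signal
  enc <- seq(0, 400, by = 50)
  expect_true(all(diff(loading_efficiency(enc, 400)) > 0))
  # clamping below the blank
  expect_warning(le <- loading_efficiency(2, 400, blank = 5), "clamped")
  expect_equal(le, 0)
  expect_error(loading_efficiency(10, 4, blank = 5), "exceed the blank")
  expect_error(loading_efficiency(-1, 400), "non-negative")
})

test_that("MFIR is the plain ratio to untreated cells and is gain-invariant", {
  expect_equal(mfir(200, 100), 2)
  expect_equal(mfir(100, 100), 1)
  tab <- expand.grid(conc = c(20, 40, 80), time = c(3, 6))
  tab$mfi <- c(1.2, 1.8, 2.9, 1.9, 3.1, 4.8) * 100
  ratios <- mfir(tab$mfi, 100)
  expect_equal(ratios, vapply(tab$mfi, mfir, numeric(1),
                              untreated_mfi = 100))
  gain <- 3.7
  expect_equal(mfir(gain * tab$mfi, gain * 100), ratios, tolerance = 1e-12)
  expect_error(mfir(10, 0), "positive")
})

test_that("gene suppression is computed on protein-normalized group means", {
  ctrl <- data.frame(luminescence = c(950, 1000, 1050),
                     protein = c(1, 1, 1))
  trt <- data.frame(luminescence = 0.473 * c(950, 1000, 1050),
                    protein = c(1, 1, 1))
  out <- suppression_ratio(trt, ctrl)
  expect_equal(out$suppression_pct, 52.7, tolerance = 1e-9)
  expect_equal(suppression_ratio(ctrl, ctrl)$suppression_pct, 0)
  trt2 <- data.frame(luminescence = 0.148 * 1000, protein = 1)
  expect_equal(suppression_ratio(trt2, ctrl)$suppression_pct, 85.2,
               tolerance = 1e-9)

  # invariance to rescaling all luminescence or all protein values
  s0 <- suppression_ratio(trt, ctrl)$suppression_pct
  scale_lum <- function(g, f) transform(g, luminescence = luminescence * f)
  scale_pro <- function(g, f) transform(g, protein = protein * f)
  expect_equal(suppression_ratio(scale_lum(trt, 7), scale_lum(ctrl, 7)
                                 )$suppression_pct, s0, tolerance = 1e-12)
  expect_equal(suppression_ratio(scale_pro(trt, 0.2), scale_pro(ctrl, 0.2)
                                 )$suppression_pct, s0, tolerance = 1e-12)
  expect_true(out$sd_pct >= 0)
  expect_error(suppression_ratio(trt[0, ], ctrl), "non-empty")
  expect_error(
    suppression_ratio(trt, transform(ctrl, protein = c(0, 1, 1))),
    "positive")
})

test_that("co-localized fractions require both channels above threshold", {
  profile <- data.frame(
    fraction = 1:11,
    sirna = c(80, 100, 60, 0, 0, 0, 0, 70, 55, 2, 1),
    particles = c(0, 0, 0, 0, 0, 0, 0, 9e9, 7e9, 1e7, 5e6))
  expect_equal(colocalized_fractions(profile), c(8L, 9L))
  zero <- data.frame(fraction = 1:11, sirna = 0, particles = 0)
  expect_equal(colocalized_fractions(zero), integer(0))
  pos <- data.frame(fraction = 1:4, sirna = 1:4, particles = 4:1)
  expect_equal(colocalized_fractions(pos, 0, 0), 1:4)
  expect_error(colocalized_fractions(profile, -1, 0), "non-negative")
  expect_error(colocalized_fractions(data.frame(fraction = 1)), "columns")
})

test_that("peak-area ratios normalize analytes to the internal standard", {
  expect_equal(peak_area_ratio(2, 1), 2)
  expect_equal(peak_area_ratio(3.5, 3.5), 1)
  areas <- c(PC = 12.1, PE = 8.4, PI = 0.9, PS = 0.4)
  expect_equal(peak_area_ratio(areas, 2),
               vapply(areas, peak_area_ratio, numeric(1), is_area = 2))
  gain <- 5
  expect_equal(peak_area_ratio(gain * areas, gain * 2),
               peak_area_ratio(areas, 2), tolerance = 1e-12)
  expect_error(peak_area_ratio(1, 0), "positive")
  is_spec <- default_internal_standard()
  expect_equal(is_spec$concentration, 0.38)
  expect_match(is_spec$lipid, "17:0-20:4")
})
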