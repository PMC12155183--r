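gaussian_spec <- function(mu = 1645, sigma = 40, grid = seq(1300, 2000, 1),
                          amp = 1, label = NULL) {
  spectrum_curve(grid, amp * exp(-(grid - mu)^2 / (2 * sigma^2)), label = label)
}

split_gaussian_spec <- function(mu, sL, sR, grid, amp = 1, label = NULL) {
  s <- ifelse(grid < mu, sL, sR)
  spectrum_curve(grid, amp * exp(-(grid - mu)^2 / (2 * s^2)), label = label)
}

test_that("total-area normalization is exact, idempotent and scale-free", {
  s <- gaussian_spec()
  n1 <- normalize_total_area(s)
  tz <- function(sp) sum(diff(sp$wavenumber) *
                           (sp$intensity[-1] + sp$intensity[-length(sp$intensity)])) / 2
  expect_equal(tz(n1), 1, tolerance = 1e-12)
  expect_equal(normalize_total_area(n1)$intensity, n1$intensity,
               tolerance = 1e-12)
  s7 <- spectrum_curve(s$wavenumber, 7 * s$intensity)
  expect_equal(normalize_total_area(s7)$intensity, n1$intensity,
               tolerance = 1e-12)
  zero <- spectrum_curve(1:10, rep(0, 10))
  expect_error(normalize_total_area(zero), "non-positive")
})

test_that("difference spectra subtract pointwise and resample mixed grids", {
  s <- gaussian_spec()
  expect_equal(difference_spectrum(s, s)$intensity,
               rep(0, length(s$wavenumber)))
  # offset grids: result matches the analytic difference of the smooth curves
  f <- function(x) exp(-(x - 1600)^2 / (2 * 50^2))
  g <- function(x) 0.8 * exp(-(x - 1650)^2 / (2 * 70^2))
  xa <- seq(1300, 2000, 1)
  xb <- xa + 0.5
  d <- difference_spectrum(spectrum_curve(xa, f(xa)),
                           spectrum_curve(xb, g(xb)))
  expect_lt(max(abs(d$intensity - (f(d$wavenumber) - g(d$wavenumber)))), 1e-4)
  # linearity against a zero reference
  zero <- spectrum_curve(xa, rep(0, length(xa)))
  a <- spectrum_curve(xa, f(xa)); b <- spectrum_curve(xa, g(xa))
  ab <- spectrum_curve(xa, f(xa) + g(xa))
  expect_equal(difference_spectrum(ab, zero)$intensity,
               difference_spectrum(a, zero)$intensity +
                 difference_spectrum(b, zero)$intensity)
  far <- spectrum_curve(seq(4000, 4100, 1), rep(1, 101))
  expect_error(difference_spectrum(s, far), "disjoint")
})

test_that("second-derivative minima locate hidden components", {
  x <- seq(3000, 3800, 1)
  one <- spectrum_curve(x, exp(-(x - 3400)^2 / (2 * 80^2)))
  c1 <- second_derivative_components(one)
  expect_equal(nrow(c1), 1)
  expect_lt(abs(c1$position - 3400), 2)

  # two Gaussians 60 cm^-1 apart, sigma 30: a single maximum in the raw sum
  y2 <- exp(-(x - 3370)^2 / (2 * 30^2)) + exp(-(x - 3430)^2 / (2 * 30^2))
  two <- spectrum_curve(x, y2)
  expect_equal(sum(diff(sign(diff(y2))) == -2), 1)  # unresolved in the sum
  c2 <- second_derivative_components(two)
  expect_equal(nrow(c2), 2)
  expect_lt(abs(c2$position[1] - 3370), 10)
  expect_lt(abs(c2$position[2] - 3430), 10)

  # pure noise yields no components at the default settings
  for (s in 1:50) {
    set.seed(s)
    noise <- spectrum_curve(x, rnorm(length(x), sd = 1))
    expect_equal(nrow(second_derivative_components(noise)), 0)
  }
  expect_error(second_derivative_components(one, smooth_window = 2001),
               "larger than the data")
  expect_error(second_derivative_components(one, smooth_window = 4), "odd")
})

test_that("isosbestic location recovers the exact two-state crossing", {
  spec <- spectrum_series_spec(
    labels = seq(5, 80, 15), grid = c(3000, 3800, 1),
    components = data.frame(position = numeric(0), sigma_left = numeric(0),
                            sigma_right = numeric(0), amplitude = numeric(0)),
    two_state = list(position_a = 3300, sigma_a = 120, position_b = 3560,
                     sigma_b = 120, amplitude = 1))
  gen <- generate_spectrum_series(spec)
  iso <- find_isosbestic(gen$spectra, c(3100, 3700))
  expect_lt(abs(iso$wavenumber - gen$crossing), 1 + 1e-9)  # one grid step
  expect_true(iso$clear)

  same <- replicate(4, gen$spectra[[1]], simplify = FALSE)
  deg <- find_isosbestic(same, c(3100, 3700))
  expect_false(deg$unique)

  # 0.5% noise over 50 seeds: within 3 grid steps
  for (s in 1:50) {
    spec_n <- spectrum_series_spec(
      labels = seq(5, 80, 15), grid = c(3000, 3800, 1),
      components = spec$components, two_state = spec$two_state,
      noise_sd = 0.005, seed = s)
    gn <- generate_spectrum_series(spec_n)
    ison <- find_isosbestic(gn$spectra, c(3200, 3650))
    expect_lt(abs(ison$wavenumber - gn$crossing), 3 + 1e-9)
  }
  expect_error(find_isosbestic(gen$spectra[1:2], c(3100, 3700)), "at least 3")
})

test_that("mirror analysis reproduces closed-form widths and skew signs", {
  grid <- seq(1300, 2100, 1)
  # symmetric Gaussian: total FWHM = 2 sqrt(2 ln 2) sigma, zero skewness
  sym <- gaussian_spec(1645, 40, grid)
  mb <- mirror_band_analysis(sym, c(1400, 2000))
  expect_equal(mb$fwhm_total, 2 * sqrt(2 * log(2)) * 40, tolerance = 0.02)
  expect_lt(abs(mb$skewness), 0.02)
  expect_equal(mb$half_fwhm_left, mb$half_fwhm_right, tolerance = 1e-6)
  expect_equal(mb$peak_position, 1645, tolerance = 0.01)

  # split Gaussian: total FWHM = sqrt(2 ln 2) (sigma_L + sigma_R)
  asym <- split_gaussian_spec(1645, 30, 50, grid)
  ma <- mirror_band_analysis(asym, c(1400, 2000))
  expect_equal(ma$fwhm_total, sqrt(2 * log(2)) * 80, tolerance = 0.02)
  expect_gt(ma$skewness, 0)
  set.seed(23)
  for (k in 1:20) {
    sL <- runif(1, 20, 70); sR <- runif(1, 20, 70)
    sp <- split_gaussian_spec(1645, sL, sR, seq(1200, 2200, 1))
    m <- mirror_band_analysis(sp, c(1250, 2150))
    expect_equal(m$fwhm_total, sqrt(2 * log(2)) * (sL + sR),
                 tolerance = 0.05)
    if (abs(sR - sL) > 2)
      expect_equal(sign(m$skewness), sign(sR - sL))
  }

  # coarsening the grid 5x changes the total FWHM by < 1%
  coarse <- split_gaussian_spec(1645, 30, 50, seq(1300, 2100, 5))
  mc <- mirror_band_analysis(coarse, c(1400, 2000))
  expect_lt(abs(mc$fwhm_total / ma$fwhm_total - 1), 0.01)

  # intensity rescaling leaves every shape statistic unchanged
  sc <- spectrum_curve(asym$wavenumber, 5 * asym$intensity)
  ms <- mirror_band_analysis(sc, c(1400, 2000))
  expect_equal(ms$fwhm_total, ma$fwhm_total, tolerance = 1e-9)
  expect_equal(ms$skewness, ma$skewness, tolerance = 1e-9)
  expect_equal(ms$integral_intensity, 5 * ma$integral_intensity,
               tolerance = 1e-9)

  # maximum on the window edge is an error
  ramp <- spectrum_curve(grid, grid)
  expect_error(mirror_band_analysis(ramp, c(1400, 2000)), "edge")
})

test_that("mirror FWHM equals the direct FWHM for symmetric line shapes", {
  grid <- seq(500, 2500, 1)
  for (shape in c("gaussian", "lorentzian")) {
    y <- if (shape == "gaussian") exp(-(grid - 1500)^2 / (2 * 80^2))
         else 1 / (1 + ((grid - 1500) / 90)^2)
    fwhm_direct <- if (shape == "gaussian") 2 * sqrt(2 * log(2)) * 80
                   else 2 * 90
    m <- mirror_band_analysis(spectrum_curve(grid, y), c(600, 2400),
                              baseline = "none")
    expect_equal(m$fwhm_total, fwhm_direct, tolerance = 1.5)  # ~1 grid step
  }
})

test_that("combination-mode arithmetic returns the three assignments", {
  cm <- combination_mode_positions(mode_fundamentals(1645, 680, 395))
  expect_equal(unname(cm["delta+L2"]), 2325)
  expect_equal(unname(cm["2L2+2L1"]), 2150)
  expect_equal(unname(cm["delta+2L1"]), 2435)
  cm2 <- combination_mode_positions(mode_fundamentals(1600, 700, 400))
  expect_equal(unname(cm2), c(2300, 2200, 2400))
})

test_that("temperature series tables track generator ground truth", {
  labels <- seq(5, 80, 5)
  # linearly increasing integral intensity
  spec <- spectrum_series_spec(
    labels, grid = c(1300, 2000, 1),
    components = data.frame(position = 1645, sigma_left = 45, sigma_right = 60,
                            amplitude = 1, amplitude_slope = 0.01))
  gen <- generate_spectrum_series(spec)
  tab <- band_temperature_series(gen$spectra, c(1400, 2000))
  fitl <- lm(integral_intensity ~ as.numeric(label), data = tab$stats)
  slope_rel <- coef(fitl)[2] / tab$stats$integral_intensity[1]
  expect_equal(unname(slope_rel), 0.01, tolerance = 0.0002)

  # constant band: identical rows
  spec_c <- spectrum_series_spec(labels, grid = c(1300, 2000, 1))
  gen_c <- generate_spectrum_series(spec_c)
  tab_c <- band_temperature_series(gen_c$spectra, c(1400, 2000))
  expect_equal(max(apply(tab_c$stats[-1], 2, function(v) diff(range(v)))), 0,
               tolerance = 1e-9)

  # FWHM shrinking with proportional skewness: linear correlation r > 0.99
  spec_f <- spectrum_series_spec(
    labels, grid = c(1200, 2100, 1),
    components = data.frame(position = 1645, sigma_left = 45,
                            sigma_left_slope = -0.1, sigma_right = 75,
                            sigma_right_slope = -0.3, amplitude = 1))
  gen_f <- generate_spectrum_series(spec_f)
  tab_f <- band_temperature_series(gen_f$spectra, c(1300, 2000))
  expect_gt(cor(tab_f$stats$fwhm_total, tab_f$stats$skewness), 0.99)
  # FWHM slope against label matches the generator ramp within 2%
  fwhm_fit <- lm(fwhm_total ~ as.numeric(label), data = tab_f$stats)
  expect_equal(unname(coef(fwhm_fit)[2]), sqrt(2 * log(2)) * (-0.1 - 0.3),
               tolerance = 0.02 * sqrt(2 * log(2)) * 0.4)

  # failures carry the offending label
  bad <- gen$spectra
  bad[[3]] <- spectrum_curve(seq(1300, 2000, 1), rep(0, 701), label = "15")
  expect_error(band_temperature_series(bad, c(1400, 2000)), "'15'")
})
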