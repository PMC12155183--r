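make_cosine_traj <- function(wavenumber = 680, n_steps = 4096, dt = 1,
                             amplitude = 1e-3, seed = 1, damping = Inf) {
  generate_oscillator_trajectory(
    data.frame(wavenumber = wavenumber, amplitude = amplitude,
               damping = damping),
    n_molecules = 2, dt = dt, n_steps = n_steps, seed = seed)
}

test_that("VACF limits: constant, cosine, and white-noise velocities", {
  box <- simulation_box(5)
  nf <- 512
  # constant velocity: C(t) = 1 for all lags
  vel <- array(0.001, dim = c(6, 3, nf))
  pos <- array(0.5, dim = c(6, 3, nf))
  traj <- water_trajectory(pos, box, times = seq_len(nf) - 1, velocities = vel)
  v <- velocity_autocorrelation(traj, "both", max_lag = 200)
  expect_equal(v$C, rep(1, 201), tolerance = 1e-12)

  # single cosine: C(t) tracks cos(omega t) up to discretization
  tr <- make_cosine_traj(500, n_steps = 8192)
  v2 <- velocity_autocorrelation(tr, "both", max_lag = 300)
  omega <- wavenumber_to_angular(500)
  expect_lt(max(abs(v2$C - cos(omega * v2$lag))), 0.05)

  # independent white noise: C(t >= 1) near zero within the sampling bound
  set.seed(8)
  n_sites <- 30; nf2 <- 2048
  vel3 <- array(rnorm(n_sites * 3 * nf2), dim = c(n_sites, 3, nf2))
  traj3 <- water_trajectory(array(0.5, dim = dim(vel3)), box,
                            times = seq_len(nf2) - 1, velocities = vel3)
  v3 <- velocity_autocorrelation(traj3, "both", max_lag = 100)
  bound <- 3 / sqrt(nf2 * n_sites * 3)
  expect_lt(max(abs(v3$C[-1])), bound)

  expect_error(velocity_autocorrelation(
    water_trajectory(array(0.5, dim = c(6, 3, 10)), box, times = 0:9)),
    "velocities")
  expect_error(velocity_autocorrelation(traj, max_lag = 400),
               "half")
})

test_that("spectral density puts a cosine mode at its wavenumber", {
  tr <- make_cosine_traj(680)
  v <- velocity_autocorrelation(tr, "both", max_lag = 2000)
  for (win in c("hann", "rectangular")) {
    ps <- suppressMessages(spectral_density(v, win))
    peak <- ps$wavenumber[which.max(ps$intensity)]
    expect_lt(abs(peak - 680), ps$resolution)
  }
  expect_equal(suppressMessages(spectral_density(v))$resolution,
               1 / (2 * 2.99792458e-5 * 2000), tolerance = 1e-9)
})

test_that("white-noise velocities give a flat spectrum", {
  set.seed(31)
  box <- simulation_box(5)
  nf <- 4096; n_sites <- 24
  vel <- array(rnorm(n_sites * 3 * nf), dim = c(n_sites, 3, nf))
  traj <- water_trajectory(array(0.5, dim = dim(vel)), box,
                           times = seq_len(nf) - 1, velocities = vel)
  v <- velocity_autocorrelation(traj, "both", max_lag = 64)
  ps <- suppressMessages(spectral_density(v, "rectangular"))
  inner <- ps$intensity[2:(length(ps$intensity) - 1)]
  expect_lt(sd(inner) / mean(inner), 0.05)
})

test_that("the discrete transform satisfies Parseval's identity", {
  tr <- make_cosine_traj(680, damping = 500)
  v <- velocity_autocorrelation(tr, "both", max_lag = 1000)
  M <- length(v$lag) - 1
  for (win in c("rectangular", "hann")) {
    ps <- suppressMessages(spectral_density(v, win))
    # without clipping: recompute the raw transform for the identity
    w <- if (win == "hann") 0.5 * (1 + cos(pi * (0:M) / M)) else rep(1, M + 1)
    x <- v$C * w
    S_raw <- Re(stats::fft(c(x, rev(x[2:M]))))[1:(M + 1)] * v$dt / (2 * pi)
    d_omega <- 2 * pi / (2 * M * v$dt)
    # sum over the full (even-extended) grid: ends count once, interior twice
    total <- (2 * sum(S_raw) - S_raw[1] - S_raw[M + 1]) * d_omega
    expect_equal(total, v$C[1] * w[1], tolerance = 1e-6)
  }
})

test_that("band skewness is zero for symmetric, matches the skew-normal form", {
  x <- seq(1000, 2000, by = 0.5)
  sym <- spectrum_curve(x, exp(-(x - 1500)^2 / (2 * 60^2)))
  expect_lt(abs(band_skewness(sym, c(1000, 2000))), 1e-6)
  expect_lt(abs(band_skewness(sym, c(1000, 2000), baseline = "none")), 1e-6)

  # skew-normal with shape a = 4: closed-form skewness
  a <- 4
  xg <- seq(-6, 8, by = 0.002)
  dens <- 2 * dnorm(xg) * pnorm(a * xg)
  sn <- spectrum_curve(1500 + 100 * xg, dens)
  delta <- a / sqrt(1 + a^2)
  g1 <- (4 - pi) / 2 * (delta * sqrt(2 / pi))^3 /
    (1 - 2 * delta^2 / pi)^(3 / 2)
  expect_equal(band_skewness(sn, range(sn$wavenumber), baseline = "none"),
               g1, tolerance = 1e-3)

  # invariances: intensity rescaling; rigid translation of window + band
  skew1 <- band_skewness(sn, c(1100, 2100), baseline = "none")
  sn7 <- spectrum_curve(sn$wavenumber, 7 * sn$intensity)
  expect_equal(band_skewness(sn7, c(1100, 2100), baseline = "none"), skew1,
               tolerance = 1e-12)
  snT <- spectrum_curve(sn$wavenumber + 250, sn$intensity)
  expect_equal(band_skewness(snT, c(1350, 2350), baseline = "none"), skew1,
               tolerance = 1e-9)

  expect_error(band_skewness(sym, c(100, 200)), "beyond")
  flat <- spectrum_curve(x, rep(1, length(x)))
  expect_error(band_skewness(flat, c(1200, 1800)), "degenerate")
})

test_that("two-Gaussian decomposition recovers known parameters", {
  x <- seq(1400, 2000, by = 1)
  truth <- data.frame(omega_max = c(1650, 1780), W_half = c(60, 110),
                      S_max = c(1, 0.45))
  model <- function(x, p) {
    rowSums(vapply(seq_len(nrow(p)), function(i)
      p$S_max[i] * exp(-(x - p$omega_max[i])^2 * log(2) / p$W_half[i]^2),
      numeric(length(x))))
  }
  clean <- spectrum_curve(x, model(x, truth))
  fit <- gaussian_two_component_fit(clean, c(1400, 2000))
  expect_true(fit$converged)
  got <- fit$components[order(fit$components$omega_max), ]
  expect_equal(got$omega_max, truth$omega_max, tolerance = 1e-6)
  expect_equal(got$W_half, truth$W_half, tolerance = 1e-6)
  expect_equal(got$S_max, truth$S_max, tolerance = 1e-6)
  expect_named(fit$table, c("1omega_max", "1W_1/2", "1S_max",
                            "2omega_max", "2W_1/2", "2S_max"))
  # the taller component is listed first
  expect_gte(fit$table[["1S_max"]], fit$table[["2S_max"]])

  # 1% additive noise, 50 seeds: median parameter error below 2%
  errs <- sapply(1:50, function(s) {
    set.seed(s)
    noisy <- spectrum_curve(x, model(x, truth) + rnorm(length(x), sd = 0.01))
    f <- gaussian_two_component_fit(noisy, c(1400, 2000))
    g <- f$components[order(f$components$omega_max), ]
    max(abs(g$omega_max / truth$omega_max - 1),
        abs(g$W_half / truth$W_half - 1),
        abs(g$S_max / truth$S_max - 1))
  })
  expect_lt(median(errs), 0.02)
})

test_that("two components never fit worse than one", {
  x <- seq(1400, 2000, by = 1)
  set.seed(4)
  y <- exp(-(x - 1620)^2 / (2 * 45^2)) + 0.6 * exp(-(x - 1750)^2 / (2 * 90^2)) +
    rnorm(length(x), sd = 0.005)
  s <- spectrum_curve(x, y)
  f1 <- gaussian_band_fit(s, c(1400, 2000), n_components = 1)
  f2 <- gaussian_band_fit(s, c(1400, 2000), n_components = 2)
  expect_lte(f2$residual_norm, f1$residual_norm + 1e-9)
})

test_that("oscillator spectra order peak heights by squared amplitude", {
  tr <- generate_oscillator_trajectory(
    data.frame(wavenumber = c(1645, 3400), amplitude = c(1e-3, 2e-3)),
    n_molecules = 3, dt = 0.5, n_steps = 8192, seed = 9)
  v <- velocity_autocorrelation(tr, "both", max_lag = 2000)
  ps <- suppressMessages(spectral_density(v))
  near <- function(nu) {
    sel <- abs(ps$wavenumber - nu) < 60
    max(ps$intensity[sel])
  }
  ratio <- near(3400) / near(1645)
  expect_equal(ratio, 4, tolerance = 0.35)
})
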