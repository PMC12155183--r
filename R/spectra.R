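#' Velocity autocorrelation function of trajectory sites
#'
#' Ensemble- and time-origin-averaged dot-product autocorrelation, computed
#' per site species and normalized to C(0) = 1. The combined curve is the
#' sum of the normalized H and O curves (renormalized to C(0) = 1), or a
#' mass-weighted sum on request.
#'
#' @param traj a [water_trajectory()] with velocities
#' @param species `"both"` (default), `"H"` or `"O"`
#' @param max_lag fs; must not exceed half the trajectory length
#' @param mass_weighted use site masses as weights when combining species
#' @return object of class `vacf`: `lag` (fs), `C` (normalized), `species`,
#'   `dt`, and `components` (list of per-species normalized curves)
#' @export
velocity_autocorrelation <- function(traj, species = c("both", "H", "O"),
                                     max_lag = NULL, mass_weighted = FALSE) {
  stopifnot(inherits(traj, "water_trajectory"))
  if (is.null(traj$velocities))
    stop("trajectory has no velocities (positions-only mode)")
  species <- match.arg(species)
  dt <- traj$sampling_interval
  nf <- traj$n_frames
  if (is.null(max_lag)) max_lag <- floor(nf / 2) * dt
  m_lag <- as.integer(round(max_lag / dt))
  if (m_lag > nf / 2)
    stop("max_lag exceeds half the trajectory length")
  n <- 3 * traj$n_molecules
  o_rows <- 3 * (seq_len(traj$n_molecules) - 1) + 1
  rows <- switch(species, O = o_rows, H = sort(c(o_rows + 1, o_rows + 2)),
                 both = seq_len(n))

  acf_rows <- function(r) {
    # FFT autocorrelation over all site components, summed
    v <- matrix(aperm(traj$velocities[r, , , drop = FALSE], c(3, 1, 2)),
                nrow = nf)
    nfft <- 2^ceiling(log2(2 * nf))
    vp <- rbind(v, matrix(0, nfft - nf, ncol(v)))
    F <- stats::mvfft(vp)
    ac <- Re(stats::mvfft(F * Conj(F), inverse = TRUE))[1:(m_lag + 1), ,
                                                        drop = FALSE] / nfft
    rowSums(ac) / (nf - 0:m_lag)  # unbiased in lag
  }
  if (species == "both") {
    cH <- acf_rows(setdiff(rows, o_rows)); cH <- cH / cH[1]
    cO <- acf_rows(o_rows); cO <- cO / cO[1]
    C <- if (mass_weighted) {
      w <- c(H = 2 * water_constants$mass_H, O = water_constants$mass_O)
      (w["H"] * cH + w["O"] * cO) / sum(w)
    } else (cH + cO) / 2
    comp <- list(H = cH, O = cO)
  } else {
    C <- acf_rows(rows); C <- C / C[1]
    comp <- stats::setNames(list(C), species)
  }
  structure(list(lag = (0:m_lag) * dt, C = C, species = species, dt = dt,
                 max_lag = m_lag * dt, components = comp), class = "vacf")
}

#' @export
print.vacf <- function(x, ...) {
  cat(sprintf("VACF (%s sites): %d lags up to %g fs (dt = %g fs)\n",
              x$species, length(x$lag), x$max_lag, x$dt))
  invisible(x)
}

#' Spectral density (power spectrum) of a velocity autocorrelation function
#'
#' Real cosine transform of the even-extended VACF,
#' `S(omega) = (1/2 pi) int C(t) exp(-i omega t) dt`, with a taper window
#' applied before the transform. The output grid is in cm^-1 with spacing
#' equal to the stated resolution `1/(2 c max_lag)`.
#'
#' @param vacf a [velocity_autocorrelation()] result (uniform lag grid)
#' @param window `"hann"` (default) or `"rectangular"`
#' @return object of class `power_spectrum`: `wavenumber` (cm^-1),
#'   `intensity` (= S, arbitrary units), `window`, `resolution` (cm^-1)
#' @export
spectral_density <- function(vacf, window = c("hann", "rectangular")) {
  stopifnot(inherits(vacf, "vacf"))
  window <- match.arg(window)
  lag <- vacf$lag
  if (length(lag) > 2) {
    dl <- diff(lag)
    if (max(abs(dl - dl[1])) > 1e-9 * dl[1]) stop("non-uniform lag grid")
  }
  M <- length(lag) - 1
  dt <- vacf$dt
  w <- switch(window,
    hann = 0.5 * (1 + cos(pi * (0:M) / M)),  # one-sided taper, w(0) = 1
    rectangular = rep(1, M + 1))
  x <- vacf$C * w
  y <- c(x, rev(x[2:M]))  # even extension, length 2M
  S <- Re(stats::fft(y)) * dt / (2 * pi)
  S <- S[1:(M + 1)]
  if (any(S < 0)) {
    neg <- min(S)
    if (neg < -1e-8 * max(abs(S)))
      message(sprintf("spectral_density: clipping negative lobes (min %.3g) to 0", neg))
    S[S < 0] <- 0
  }
  wavenumber <- (0:M) / (2 * M * dt * water_constants$c_cm_fs)
  structure(list(
    wavenumber = wavenumber, intensity = S, window = window,
    resolution = 1 / (2 * water_constants$c_cm_fs * vacf$max_lag),
    dt = dt
  ), class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("power spectrum: 0..%.0f cm^-1, resolution %.2f cm^-1 (%s window)\n",
              max(x$wavenumber), x$resolution, x$window))
  invisible(x)
}

get_xy <- function(spectrum) {
  if (inherits(spectrum, "power_spectrum"))
    list(x = spectrum$wavenumber, y = spectrum$intensity)
  else if (inherits(spectrum, "spectrum_curve"))
    list(x = spectrum$wavenumber, y = spectrum$intensity)
  else stop("expected a power_spectrum or spectrum_curve")
}

#' Skewness of a spectral band
#'
#' Moment skewness `g1 = m3 / m2^(3/2)` of the intensity-weighted wavenumber
#' distribution inside the window, after subtracting a linear baseline
#' through the window endpoints (`baseline = "linear"`, the default) or no
#' baseline (`"none"`, appropriate for power spectra that decay to zero).
#' Positive values indicate a longer right tail.
#'
#' @param spectrum a [spectral_density()] result or a [spectrum_curve()]
#' @param window `c(lo, hi)` in cm^-1, inside the grid
#' @param baseline `"linear"` or `"none"`
#' @return skewness coefficient (dimensionless)
#' @export
band_skewness <- function(spectrum, window, baseline = c("linear", "none")) {
  baseline <- match.arg(baseline)
  xy <- get_xy(spectrum)
  if (window[1] < min(xy$x) - 1e-9 || window[2] > max(xy$x) + 1e-9)
    stop("window extends beyond the spectral grid")
  sel <- xy$x >= window[1] & xy$x <= window[2]
  x <- xy$x[sel]; y <- xy$y[sel]
  if (baseline == "linear") {
    slope <- (y[length(y)] - y[1]) / (x[length(x)] - x[1])
    y <- y - (y[1] + slope * (x - x[1]))
  }
  w <- pmax(y, 0)
  if (sum(w) <= 0) stop("degenerate band: no positive intensity in window")
  m1 <- sum(w * x) / sum(w)
  m2 <- sum(w * (x - m1)^2) / sum(w)
  m3 <- sum(w * (x - m1)^3) / sum(w)
  m3 / m2^1.5
}

#' Multi-Gaussian band fit of a spectral window
#'
#' Nonlinear least squares of
#' `S(x) ~ sum_i S_i exp(-(x - omega_i)^2 ln2 / W_i^2)` over the window,
#' where `W_i` is the half-width at half maximum of component i. Components
#' are returned ordered by descending height.
#'
#' @param spectrum a [spectral_density()] result or a [spectrum_curve()]
#' @param window `c(lo, hi)` in cm^-1
#' @param n_components number of Gaussian components (1 or 2)
#' @param init optional data.frame with columns omega_max, W_half, S_max to
#'   start from
#' @param n_restarts jittered restarts tried on non-convergence
#' @return list with `components` (data.frame: omega_max, W_half, fwhm,
#'   S_max), `residual_norm`, `converged`, `fitted` (function of wavenumber)
#' @export
gaussian_band_fit <- function(spectrum, window, n_components = 2, init = NULL,
                              n_restarts = 8) {
  stopifnot(n_components %in% 1:2)
  xy <- get_xy(spectrum)
  if (window[1] < min(xy$x) - 1e-9 || window[2] > max(xy$x) + 1e-9)
    stop("window extends beyond the spectral grid")
  sel <- xy$x >= window[1] & xy$x <= window[2]
  x <- xy$x[sel]; y <- xy$y[sel]
  span <- diff(range(x))
  peak <- x[which.max(y)]
  if (is.null(init)) {
    init <- if (n_components == 2) {
      data.frame(omega_max = c(peak, peak + 0.15 * span),
                 W_half = c(span / 8, span / 4),
                 S_max = c(max(y), max(y) / 3))
    } else {
      data.frame(omega_max = peak, W_half = span / 6, S_max = max(y))
    }
  }
  stopifnot(nrow(init) == n_components)
  df <- data.frame(x = x, y = y)
  form <- if (n_components == 2)
    y ~ s1 * exp(-(x - w1)^2 * log(2) / h1^2) + s2 * exp(-(x - w2)^2 * log(2) / h2^2)
  else
    y ~ s1 * exp(-(x - w1)^2 * log(2) / h1^2)
  mk_start <- function(ini) {
    s <- list(w1 = ini$omega_max[1], h1 = ini$W_half[1], s1 = ini$S_max[1])
    if (n_components == 2)
      s <- c(s, list(w2 = ini$omega_max[2], h2 = ini$W_half[2], s2 = ini$S_max[2]))
    s
  }
  fit <- NULL; best <- NULL; best_rss <- Inf
  tries <- c(list(init), lapply(seq_len(n_restarts), function(k) {
    jit <- init
    jit$omega_max <- init$omega_max + span * (k %% 4 - 1.5) / 8
    jit$W_half <- init$W_half * (1 + 0.3 * ((k %/% 2) %% 3 - 1))
    jit
  }))
  # keep components inside the window with sane widths and heights
  h_grid <- mean(diff(x))
  lo <- c(w1 = window[1], h1 = h_grid, s1 = 0)
  up <- c(w1 = window[2], h1 = 2 * span, s1 = 3 * max(y))
  if (n_components == 2) {
    lo <- c(lo, w2 = window[1], h2 = h_grid, s2 = 0)
    up <- c(up, w2 = window[2], h2 = 2 * span, s2 = 3 * max(y))
  }
  clamp <- function(s) {
    v <- unlist(s)
    as.list(pmin(pmax(v, lo[names(v)] + 1e-9), up[names(v)] - 1e-9))
  }
  for (ini in tries) {
    f <- tryCatch(
      suppressWarnings(
        minpack.lm::nlsLM(form, data = df, start = clamp(mk_start(ini)),
                          lower = lo, upper = up,
                          control = minpack.lm::nls.lm.control(maxiter = 400))),
      error = function(e) NULL)
    if (!is.null(f)) {
      rss <- sum(stats::residuals(f)^2)
      if (rss < best_rss) { best <- f; best_rss <- rss }
      if (rss <= best_rss && f$convInfo$isConv) { fit <- f; break }
    }
  }
  if (is.null(fit)) fit <- best
  if (is.null(fit))
    stop("gaussian band fit failed to produce any solution")
  cf <- stats::coef(fit)
  comp <- data.frame(
    omega_max = cf[paste0("w", seq_len(n_components))],
    W_half = abs(cf[paste0("h", seq_len(n_components))]),
    S_max = cf[paste0("s", seq_len(n_components))])
  comp$fwhm <- 2 * comp$W_half
  comp <- comp[order(-comp$S_max), c("omega_max", "W_half", "fwhm", "S_max")]
  rownames(comp) <- NULL
  cfv <- as.list(cf)
  fitted_fun <- function(xx) {
    s <- cfv$s1 * exp(-(xx - cfv$w1)^2 * log(2) / cfv$h1^2)
    if (n_components == 2)
      s <- s + cfv$s2 * exp(-(xx - cfv$w2)^2 * log(2) / cfv$h2^2)
    s
  }
  list(components = comp, residual_norm = sqrt(best_rss),
       converged = isTRUE(fit$convInfo$isConv), fitted = fitted_fun)
}

#' Two-Gaussian decomposition of a spectral band
#'
#' Convenience wrapper around [gaussian_band_fit()] with two components,
#' returning the component table in the conventional layout
#' (1omega_max, 1W_1/2, 1S_max, 2omega_max, 2W_1/2, 2S_max; component 1 is
#' the higher one).
#'
#' @inheritParams gaussian_band_fit
#' @return as [gaussian_band_fit()], plus `table` (named numeric vector in
#'   the conventional layout)
#' @export
gaussian_two_component_fit <- function(spectrum, window, init = NULL,
                                       n_restarts = 8) {
  res <- gaussian_band_fit(spectrum, window, n_components = 2, init = init,
                           n_restarts = n_restarts)
  cc <- res$components
  res$table <- c(`1omega_max` = cc$omega_max[1], `1W_1/2` = cc$W_half[1],
                 `1S_max` = cc$S_max[1], `2omega_max` = cc$omega_max[2],
                 `2W_1/2` = cc$W_half[2], `2S_max` = cc$S_max[2])
  res
}
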