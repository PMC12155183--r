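#' Normalize a spectrum to unit integral intensity
#'
#' Divides intensities by the trapezoid integral over the window (default:
#' the whole recorded range), so the area under the returned spectrum is 1.
#'
#' @param spectrum a [spectrum_curve()]
#' @param window optional `c(lo, hi)` integration window, cm^-1
#' @return normalized [spectrum_curve()]
#' @export
normalize_total_area <- function(spectrum, window = NULL) {
  stopifnot(inherits(spectrum, "spectrum_curve"))
  x <- spectrum$wavenumber; y <- spectrum$intensity
  if (!is.null(window)) {
    sel <- x >= window[1] & x <= window[2]
    a <- trapz(x[sel], y[sel])
  } else {
    a <- trapz(x, y)
  }
  if (!is.finite(a) || a <= 0)
    stop("cannot normalize: non-positive integral intensity")
  spectrum_curve(x, y / a, label = spectrum$label)
}

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)])) / 2

#' Difference spectrum relative to a reference
#'
#' Pointwise `s - reference`. When the grids differ, both curves are
#' linearly resampled onto the coarser grid restricted to the overlapping
#' wavenumber range.
#'
#' @param s,reference [spectrum_curve()] objects with overlapping ranges
#' @return a [spectrum_curve()] of differences
#' @export
difference_spectrum <- function(s, reference) {
  stopifnot(inherits(s, "spectrum_curve"), inherits(reference, "spectrum_curve"))
  if (identical(s$wavenumber, reference$wavenumber)) {
    return(spectrum_curve(s$wavenumber, s$intensity - reference$intensity,
                          label = s$label))
  }
  lo <- max(min(s$wavenumber), min(reference$wavenumber))
  hi <- min(max(s$wavenumber), max(reference$wavenumber))
  if (lo >= hi) stop("spectra have disjoint wavenumber ranges")
  coarser <- if (mean(diff(s$wavenumber)) >= mean(diff(reference$wavenumber)))
    s$wavenumber else reference$wavenumber
  grid <- coarser[coarser >= lo & coarser <= hi]
  ys <- stats::approx(s$wavenumber, s$intensity, xout = grid)$y
  yr <- stats::approx(reference$wavenumber, reference$intensity, xout = grid)$y
  spectrum_curve(grid, ys - yr, label = s$label)
}

#' Locate band components from the smoothed second derivative
#'
#' The spectrum is smoothed with a Savitzky-Golay polynomial filter,
#' differentiated twice through the same filter, and smoothed again.
#' Interior local minima of the second derivative with depth of at least
#' `min_prominence` times the largest absolute second-derivative value, and
#' whose surrounding negative-curvature run is at least `min_width` points
#' wide, are returned sorted by position. The width requirement encodes the
#' resolution floor of the smoothing filter: minima narrower than the filter
#' support are noise artifacts, while real band components produce
#' negative-curvature regions spanning their core. Overlapping components
#' that leave no separate maxima in the raw sum still show up as separate
#' second-derivative minima.
#'
#' @param spectrum a [spectrum_curve()] (uniform grid)
#' @param smooth_window filter window length, points (odd, > smooth_order)
#' @param smooth_order polynomial order
#' @param min_prominence fraction of `max(abs(d2))` a minimum must reach
#' @param min_width minimum width (grid points) of the contiguous negative
#'   second-derivative run containing the minimum; defaults to three times
#'   the smoothing window (lower it for bands narrower than the filter
#'   support)
#' @return data.frame with columns position (cm^-1), amplitude (second
#'   derivative at the minimum), label (integer, by position)
#' @export
second_derivative_components <- function(spectrum, smooth_window = 15,
                                         smooth_order = 3,
                                         min_prominence = 0.1,
                                         min_width = 3 * smooth_window) {
  stopifnot(inherits(spectrum, "spectrum_curve"))
  x <- spectrum$wavenumber; y <- spectrum$intensity
  if (smooth_window %% 2 != 1 || smooth_window <= smooth_order)
    stop("smooth_window must be odd and greater than smooth_order")
  if (smooth_window > length(x)) stop("smoothing window larger than the data")
  h <- mean(diff(x))
  if (max(abs(diff(x) - h)) > 1e-6 * h)
    stop("second-derivative analysis needs a uniform wavenumber grid")
  ys <- signal::sgolayfilt(y, p = smooth_order, n = smooth_window)
  d2 <- signal::sgolayfilt(ys, p = smooth_order, n = smooth_window, m = 2) / h^2
  d2 <- signal::sgolayfilt(d2, p = smooth_order, n = smooth_window)
  scale <- max(abs(d2))
  if (scale == 0) {
    return(data.frame(position = numeric(0), amplitude = numeric(0),
                      label = integer(0)))
  }
  n <- length(d2)
  i <- 2:(n - 1)
  is_min <- d2[i] < d2[i - 1] & d2[i] <= d2[i + 1] &
    d2[i] <= -min_prominence * scale
  pos <- i[is_min]
  # width of the contiguous negative-curvature run containing each minimum
  neg <- d2 < 0
  runs <- rle(neg)
  run_id <- rep(seq_along(runs$lengths), runs$lengths)
  wide <- vapply(pos, function(p) runs$lengths[run_id[p]] >= min_width,
                 logical(1))
  pos <- pos[wide]
  out <- data.frame(position = x[pos], amplitude = d2[pos])
  out <- out[order(out$position), , drop = FALSE]
  out$label <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Locate an isosbestic point across a temperature series of spectra
#'
#' Finds the wavenumber inside the search window that minimizes the
#' across-spectra standard deviation of intensity. In a two-state
#' interconverting system all normalized spectra cross there.
#'
#' @param spectra list of at least 3 [spectrum_curve()] objects on a common
#'   grid
#' @param window `c(lo, hi)` search window, cm^-1
#' @param clear_fraction dispersion below this fraction of the local mean
#'   intensity flags the point as "clear"
#' @return list with `wavenumber`, `dispersion` (sd across spectra at the
#'   point), `clear` (flag), and `unique` (FALSE when the dispersion is zero
#'   everywhere, e.g. identical spectra)
#' @export
find_isosbestic <- function(spectra, window, clear_fraction = 0.02) {
  if (length(spectra) < 3)
    stop("isosbestic location needs at least 3 spectra")
  g <- spectra[[1]]$wavenumber
  for (s in spectra) {
    stopifnot(inherits(s, "spectrum_curve"))
    if (!isTRUE(all.equal(s$wavenumber, g)))
      stop("spectra must share a common wavenumber grid")
  }
  sel <- which(g >= window[1] & g <= window[2])
  if (length(sel) == 0) stop("empty search window")
  Y <- vapply(spectra, function(s) s$intensity[sel], numeric(length(sel)))
  sds <- apply(Y, 1, stats::sd)
  mu <- rowMeans(Y)
  if (max(sds) == 0) {
    return(list(wavenumber = NA_real_, dispersion = 0, clear = FALSE,
                unique = FALSE))
  }
  i <- which.min(sds)
  list(wavenumber = g[sel][i], dispersion = sds[i],
       clear = sds[i] < clear_fraction * abs(mu[i]), unique = TRUE)
}

#' Mirror-FWHM analysis of an asymmetric band
#'
#' The band maximum is located with 3-point parabolic refinement and shifted
#' to zero. The band is split at the maximum; each branch, reflected about
#' the intensity axis, defines a symmetric band whose FWHM is measured by
#' linear interpolation at half maximum. The total FWHM is the sum of half
#' the FWHM of the two mirrored symmetric lines (equivalently, the sum of
#' the left and right half-widths at half maximum). The skewness
#' coefficient of the band is computed as in [band_skewness()].
#'
#' @param spectrum a [spectrum_curve()] or [spectral_density()] result
#' @param window `c(lo, hi)`, cm^-1; must contain a unique interior maximum
#' @param baseline `"linear"` (through the window endpoints) or `"none"`
#' @return object of class `band_shape_stats`: peak_position,
#'   peak_intensity, integral_intensity, half_fwhm_left, half_fwhm_right,
#'   fwhm_total (= left + right), skewness, baseline
#' @export
mirror_band_analysis <- function(spectrum, window,
                                 baseline = c("linear", "none")) {
  baseline <- match.arg(baseline)
  xy <- get_xy(spectrum)
  sel <- xy$x >= window[1] & xy$x <= window[2]
  if (sum(sel) < 5) stop("window too narrow: fewer than 5 samples")
  x <- xy$x[sel]; y <- xy$y[sel]
  if (baseline == "linear") {
    slope <- (y[length(y)] - y[1]) / (x[length(x)] - x[1])
    y <- y - (y[1] + slope * (x - x[1]))
  }
  ymax <- max(y)
  imaxes <- which(y == ymax)
  if (length(imaxes) > 1)
    message("mirror_band_analysis: multiple equal maxima; using the lowest wavenumber")
  im <- imaxes[1]
  if (im == 1 || im == length(x))
    stop("band maximum lies on the window edge: window too narrow")
  # 3-point parabolic refinement of peak position and height
  y3 <- y[(im - 1):(im + 1)]; x3 <- x[(im - 1):(im + 1)]
  denom <- y3[1] - 2 * y3[2] + y3[3]
  if (denom < 0) {
    d <- 0.5 * (y3[1] - y3[3]) / denom
    x0 <- x3[2] + d * (x3[2] - x3[1])
    y0 <- y3[2] - 0.25 * (y3[1] - y3[3]) * d
  } else {
    x0 <- x3[2]; y0 <- y3[2]
  }
  half <- y0 / 2
  cross_towards <- function(xs, ys) {
    # first downward crossing of `half` walking away from the peak
    below <- which(ys <= half)
    if (length(below) == 0)
      stop("band does not fall to half maximum inside the window")
    b <- below[1]
    if (b == 1) return(abs(xs[1] - x0))
    x1 <- xs[b - 1]; x2 <- xs[b]; y1 <- ys[b - 1]; y2 <- ys[b]
    xc <- x1 + (half - y1) * (x2 - x1) / (y2 - y1)
    abs(xc - x0)
  }
  left <- order(x[x <= x3[2]], decreasing = TRUE)  # walk left from peak
  xl <- x[x <= x3[2]][left]; yl <- y[x <= x3[2]][left]
  hw_left <- cross_towards(xl, yl)
  xr <- x[x >= x3[2]]; yr <- y[x >= x3[2]]
  hw_right <- cross_towards(xr, yr)
  structure(list(
    peak_position = x0, peak_intensity = y0,
    integral_intensity = trapz(x, y),
    half_fwhm_left = hw_left, half_fwhm_right = hw_right,
    fwhm_total = hw_left + hw_right,
    skewness = band_skewness(spectrum, window, baseline = baseline),
    baseline = baseline
  ), class = "band_shape_stats")
}

#' @export
print.band_shape_stats <- function(x, ...) {
  cat(sprintf("band at %.2f cm^-1: total FWHM %.2f (left %.2f + right %.2f), skewness %.3f\n",
              x$peak_position, x$fwhm_total, x$half_fwhm_left,
              x$half_fwhm_right, x$skewness))
  invisible(x)
}

#' Reference fundamental mode positions of liquid water
#'
#' @param delta bending mode, cm^-1 (reference 1645)
#' @param L2 major libration, cm^-1 (reference 680)
#' @param L1 minor libration, cm^-1 (reference 395)
#' @return object of class `mode_fundamentals`
#' @export
mode_fundamentals <- function(delta = 1645, L2 = 680, L1 = 395) {
  stopifnot(delta > 0, L2 > 0, L1 > 0)
  structure(list(delta = delta, L2 = L2, L1 = L1),
            class = "mode_fundamentals")
}

#' Combination-mode band positions from fundamentals
#'
#' Candidate assignments of the association band between 1800 and
#' 2600 cm^-1: bending + major libration, the sum of the first overtones of
#' both librations, and bending + minor-libration overtone.
#'
#' @param modes a [mode_fundamentals()]
#' @return named numeric vector: `delta+L2`, `2L2+2L1`, `delta+2L1`, cm^-1
#' @export
combination_mode_positions <- function(modes = mode_fundamentals()) {
  stopifnot(inherits(modes, "mode_fundamentals"))
  c(`delta+L2` = modes$delta + modes$L2,
    `2L2+2L1` = 2 * modes$L2 + 2 * modes$L1,
    `delta+2L1` = modes$delta + 2 * modes$L1)
}

#' Band statistics across a labeled temperature series
#'
#' Runs [mirror_band_analysis()] and [second_derivative_components()] on
#' each labeled spectrum and collects a tidy table for inspection of trends
#' and kinks.
#'
#' @param spectra list of [spectrum_curve()] objects; labels are taken from
#'   each curve's `label` (falling back to list names or the index)
#' @param window `c(lo, hi)`, cm^-1
#' @param baseline passed to [mirror_band_analysis()]
#' @param derivative_args list of arguments for
#'   [second_derivative_components()]
#' @return list with `stats` (data.frame: label, peak_position, fwhm_total,
#'   half_fwhm_left, half_fwhm_right, skewness, integral_intensity) and
#'   `components` (data.frame: label, position, amplitude)
#' @export
band_temperature_series <- function(spectra, window, baseline = "linear",
                                    derivative_args = list()) {
  if (length(spectra) < 2) stop("a series needs at least 2 labeled spectra")
  labels <- vapply(seq_along(spectra), function(i) {
    lab <- spectra[[i]]$label
    if (!is.null(lab)) as.character(lab)
    else if (!is.null(names(spectra)[i]) && nzchar(names(spectra)[i]))
      names(spectra)[i]
    else as.character(i)
  }, "")
  stats_rows <- vector("list", length(spectra))
  comp_rows <- vector("list", length(spectra))
  for (i in seq_along(spectra)) {
    res <- tryCatch({
      bs <- mirror_band_analysis(spectra[[i]], window, baseline = baseline)
      sub <- spectrum_window(spectra[[i]], window)
      cmp <- do.call(second_derivative_components,
                     c(list(spectrum = sub), derivative_args))
      list(bs = bs, cmp = cmp)
    }, error = function(e)
      stop("band analysis failed for label '", labels[i], "': ",
           conditionMessage(e), call. = FALSE))
    bs <- res$bs
    stats_rows[[i]] <- data.frame(
      label = labels[i], peak_position = bs$peak_position,
      fwhm_total = bs$fwhm_total, half_fwhm_left = bs$half_fwhm_left,
      half_fwhm_right = bs$half_fwhm_right, skewness = bs$skewness,
      integral_intensity = bs$integral_intensity)
    if (nrow(res$cmp))
      comp_rows[[i]] <- data.frame(label = labels[i],
                                   position = res$cmp$position,
                                   amplitude = res$cmp$amplitude)
  }
  list(stats = do.call(rbind, stats_rows),
       components = do.call(rbind, comp_rows))
}

#' Restrict a spectrum to a wavenumber window
#' @param spectrum a [spectrum_curve()]
#' @param window `c(lo, hi)`, cm^-1
#' @return a [spectrum_curve()] over the window
#' @export
spectrum_window <- function(spectrum, window) {
  stopifnot(inherits(spectrum, "spectrum_curve"))
  sel <- spectrum$wavenumber >= window[1] & spectrum$wavenumber <= window[2]
  spectrum_curve(spectrum$wavenumber[sel], spectrum$intensity[sel],
                 label = spectrum$label)
}
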