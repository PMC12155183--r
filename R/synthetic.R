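#' Ice-like lattice network with known ground-truth hydrogen bonds
#'
#' Places oxygens on a diamond-cubic lattice (the four-coordinated topology
#' of cubic ice) under periodic boundaries, orients every lattice bond along
#' an Eulerian circuit of the 4-regular bond graph — which yields exactly
#' two donor and two acceptor bonds per molecule (the ice rules) — and then
#' deletes each bond independently with probability `p`. Hydrogens are
#' placed along the two donor directions. The returned directed bond list
#' is exact ground truth for network statistics, bypassing energetic
#' detection.
#'
#' @param n_cells diamond-cubic unit cells per axis (8 molecules per cell)
#' @param bond_removal_p probability of deleting each lattice bond
#' @param seed RNG seed
#' @param r_nn nearest-neighbor O-O distance, nm (default 0.276)
#' @param r_e O-H bond length for hydrogen placement, nm
#' @return list with `frame` (an [md_frame()]), `bonds` (data.frame donor,
#'   h_site, acceptor), `n_molecules`, and `box`
#' @export
generate_lattice_network <- function(n_cells, bond_removal_p = 0, seed = 1,
                                     r_nn = 0.276, r_e = 0.09572) {
  stopifnot(n_cells >= 1, bond_removal_p >= 0, bond_removal_p <= 1)
  a <- 4 * r_nn / sqrt(3)
  # diamond cubic: fcc lattice + basis (0,0,0) and (1/4,1/4,1/4)
  fcc <- rbind(c(0, 0, 0), c(0, .5, .5), c(.5, 0, .5), c(.5, .5, 0))
  cells <- as.matrix(expand.grid(x = 0:(n_cells - 1), y = 0:(n_cells - 1),
                                 z = 0:(n_cells - 1)))
  frac <- NULL
  for (b in c(0, 0.25)) {
    for (i in seq_len(nrow(fcc))) {
      frac <- rbind(frac, sweep(cells, 2, fcc[i, ] + b, `+`))
    }
  }
  n <- nrow(frac)                        # 8 per cell
  o_pos <- frac * a
  L <- n_cells * a
  box <- simulation_box(L)
  # neighbors: sublattice A (basis 0) bonds to the 4 B sites at
  # (1/4,1/4,1/4) + fcc translations
  nA <- n / 2
  shifts <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) *
    (a / 4)
  # map positions to indices via rounded fractional keys
  key <- function(p) {
    q <- p / a * 4
    q <- round(q) %% (4 * n_cells)
    paste(q[, 1], q[, 2], q[, 3])
  }
  idx <- stats::setNames(seq_len(n), key(o_pos))
  edges <- NULL
  for (s in seq_len(4)) {
    tgt <- sweep(o_pos[seq_len(nA), , drop = FALSE], 2, shifts[s, ], `+`)
    j <- idx[key(tgt)]
    edges <- rbind(edges, cbind(seq_len(nA), as.integer(j)))
  }
  stopifnot(!anyNA(edges[, 2]))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  cyc <- igraph::eulerian_cycle(g)$vpath
  vc <- as.integer(cyc)
  donors <- vc[-length(vc)]
  acceptors <- vc[-1]
  set.seed(seed)
  keep <- stats::runif(length(donors)) >= bond_removal_p
  bonds <- data.frame(donor = donors, acceptor = acceptors)[keep, , drop = FALSE]
  # h_site: order of appearance among each donor's outgoing bonds (the full
  # orientation defines two H directions per molecule; removal keeps sites)
  full <- data.frame(donor = donors, acceptor = acceptors)
  full$h_site <- stats::ave(full$donor, full$donor, FUN = seq_along)
  stopifnot(max(full$h_site) == 2)
  bonds <- full[keep, c("donor", "h_site", "acceptor")]
  rownames(bonds) <- NULL
  # hydrogens along the two donor directions
  pos <- matrix(NA_real_, 3 * n, 3)
  pos[3 * (seq_len(n) - 1) + 1, ] <- o_pos
  for (r in seq_len(nrow(full))) {
    d <- full$donor[r]; acc <- full$acceptor[r]
    u <- minimum_image_displacement(o_pos[d, ], o_pos[acc, ], box)
    u <- u / sqrt(sum(u^2))
    pos[3 * (d - 1) + 1 + full$h_site[r], ] <- o_pos[d, ] + r_e * u
  }
  list(frame = md_frame(pos, box), bonds = bonds, n_molecules = n, box = box)
}

#' Synthetic trajectory of damped oscillating site velocities
#'
#' Per-site velocities are sums of damped cosines at prescribed wavenumbers
#' with site- and mode-specific random phases (plus optional white noise);
#' positions follow by cumulative integration. Ground truth for validating
#' autocorrelation and spectral-density estimates.
#'
#' @param modes data.frame with columns `wavenumber` (cm^-1), `amplitude`
#'   (nm/fs), and optionally `damping` (time constant, fs; Inf = none)
#' @param n_molecules number of three-site molecules to emulate
#' @param dt sampling interval, fs; must resolve the highest mode
#'   (`dt < 1/(10 c max(wavenumber))`)
#' @param n_steps number of stored frames
#' @param noise_sd white-noise velocity amplitude, nm/fs
#' @param seed RNG seed
#' @param box_edge box edge for the synthetic frame, nm
#' @return a [water_trajectory()] with velocities
#' @export
generate_oscillator_trajectory <- function(modes, n_molecules = 4, dt = 1,
                                           n_steps = 4096, noise_sd = 0,
                                           seed = 1, box_edge = 10) {
  stopifnot(is.data.frame(modes), all(modes$wavenumber > 0), n_steps >= 4)
  if (is.null(modes$damping)) modes$damping <- Inf
  numax <- max(modes$wavenumber)
  if (dt >= 1 / (10 * water_constants$c_cm_fs * numax))
    stop(sprintf(
      "dt = %g fs aliases the %g cm^-1 mode: need dt < %.3g fs",
      dt, numax, 1 / (10 * water_constants$c_cm_fs * numax)))
  set.seed(seed)
  n_sites <- 3 * n_molecules
  t <- (seq_len(n_steps) - 1) * dt
  vel <- array(0, dim = c(n_sites, 3, n_steps))
  for (m in seq_len(nrow(modes))) {
    omega <- wavenumber_to_angular(modes$wavenumber[m])
    damp <- if (is.finite(modes$damping[m])) exp(-t / modes$damping[m]) else 1
    for (s in seq_len(n_sites)) {
      for (d in 1:3) {
        phase <- stats::runif(1, 0, 2 * pi)
        vel[s, d, ] <- vel[s, d, ] +
          modes$amplitude[m] * damp * cos(omega * t + phase)
      }
    }
  }
  if (noise_sd > 0)
    vel <- vel + array(stats::rnorm(length(vel), sd = noise_sd), dim = dim(vel))
  box <- simulation_box(box_edge)
  pos <- array(0, dim = dim(vel))
  base <- matrix(stats::runif(n_sites * 3, 0, box_edge), n_sites, 3)
  for (d in 1:3) {
    disp <- t(apply(vel[, d, , drop = FALSE][, 1, ], 1, cumsum)) * dt
    pos[, d, ] <- (base[, d] + disp) %% box_edge
  }
  water_trajectory(pos, box, times = t, velocities = vel)
}

#' Specification for a synthetic temperature series of spectra
#'
#' Each spectrum is a sum of split-Gaussian components whose parameters ramp
#' linearly with the label, optionally plus an exact two-state pair
#' `x f + (1-x) g` (all members crossing where f = g) and white noise.
#'
#' @param labels numeric labels (e.g. temperatures, deg C)
#' @param grid wavenumber grid specification `c(from, to, by)`, cm^-1
#' @param components data.frame with columns position, sigma_left,
#'   sigma_right, amplitude and optional *_slope columns (per unit label,
#'   relative to the first label)
#' @param two_state NULL or list(position_a, sigma_a, position_b, sigma_b,
#'   amplitude, fractions) where `fractions` (one per label, in `[0,1]`)
#'   defaults to a linear ramp from 1 to 0
#' @param noise_sd additive white-noise amplitude
#' @param seed RNG seed
#' @return object of class `spectrum_series_spec`
#' @export
spectrum_series_spec <- function(labels, grid = c(1000, 2200, 1),
                                 components = data.frame(
                                   position = 1645, sigma_left = 45,
                                   sigma_right = 60, amplitude = 1),
                                 two_state = NULL, noise_sd = 0, seed = 1) {
  stopifnot(length(labels) >= 2, length(grid) == 3, grid[3] > 0)
  for (col in c("position_slope", "sigma_left_slope", "sigma_right_slope",
                "amplitude_slope"))
    if (is.null(components[[col]])) components[[col]] <- rep(0, nrow(components))
  if (!is.null(two_state)) {
    if (is.null(two_state$fractions))
      two_state$fractions <- seq(1, 0, length.out = length(labels))
    stopifnot(length(two_state$fractions) == length(labels),
              all(two_state$fractions >= 0), all(two_state$fractions <= 1))
  }
  structure(list(labels = labels, grid = grid, components = components,
                 two_state = two_state, noise_sd = noise_sd, seed = seed),
            class = "spectrum_series_spec")
}

split_gaussian <- function(x, position, sigma_left, sigma_right, amplitude) {
  s <- ifelse(x < position, sigma_left, sigma_right)
  amplitude * exp(-(x - position)^2 / (2 * s^2))
}

#' Generate a labeled temperature series of synthetic spectra
#'
#' @param spec a [spectrum_series_spec()]
#' @return list with `spectra` (list of labeled [spectrum_curve()]),
#'   `truth` (data.frame of the exact per-label component parameters), and
#'   `crossing` (exact two-state crossing wavenumber, or NA)
#' @export
generate_spectrum_series <- function(spec) {
  stopifnot(inherits(spec, "spectrum_series_spec"))
  x <- seq(spec$grid[1], spec$grid[2], by = spec$grid[3])
  set.seed(spec$seed)
  truth <- NULL
  spectra <- vector("list", length(spec$labels))
  crossing <- NA_real_
  ts <- spec$two_state
  if (!is.null(ts)) {
    fa <- function(z) ts$amplitude * exp(-(z - ts$position_a)^2 / (2 * ts$sigma_a^2))
    fb <- function(z) ts$amplitude * exp(-(z - ts$position_b)^2 / (2 * ts$sigma_b^2))
    crossing <- stats::uniroot(function(z) fa(z) - fb(z),
                               lower = min(ts$position_a, ts$position_b),
                               upper = max(ts$position_a, ts$position_b))$root
  }
  for (i in seq_along(spec$labels)) {
    dl <- spec$labels[i] - spec$labels[1]
    y <- numeric(length(x))
    for (k in seq_len(nrow(spec$components))) {
      co <- spec$components[k, ]
      pars <- data.frame(
        label = spec$labels[i], component = k,
        position = co$position + dl * co$position_slope,
        sigma_left = co$sigma_left + dl * co$sigma_left_slope,
        sigma_right = co$sigma_right + dl * co$sigma_right_slope,
        amplitude = co$amplitude + dl * co$amplitude_slope)
      truth <- rbind(truth, pars)
      y <- y + split_gaussian(x, pars$position, pars$sigma_left,
                              pars$sigma_right, pars$amplitude)
    }
    if (!is.null(ts)) {
      frac <- ts$fractions[i]
      y <- y + frac * fa(x) + (1 - frac) * fb(x)
    }
    if (spec$noise_sd > 0) y <- y + stats::rnorm(length(x), sd = spec$noise_sd)
    spectra[[i]] <- spectrum_curve(x, y, label = spec$labels[i])
  }
  list(spectra = spectra, truth = truth, crossing = crossing)
}
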