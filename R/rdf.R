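#' Partial radial distribution function from a trajectory
#'
#' Histogram of minimum-image pair distances divided by the ideal-gas shell
#' expectation `4 pi r^2 dr * rho_pair * n_frames`. Pair densities: like
#' species (OO) use `N(N-1)/2 / V`; intermolecular O-H uses `2N(N-1) / V`
#' (all O-H pairs excluding same-molecule ones); intramolecular O-H uses the
#' uncorrelated-sites convention `2N^2 / V`, under which
#' `4 pi rho_H int g r^2 dr` over the bond peak equals 2 hydrogens per
#' oxygen.
#'
#' @param traj a [water_trajectory()]
#' @param species `"OO"`, `"OH_inter"` or `"OH_intra"`
#' @param bin_width nm (default 0.002)
#' @param r_max nm; defaults to L/2 and must not exceed it
#' @param frame_stride analyze every `frame_stride`-th stored frame
#' @return object of class `radial_distribution`: data fields `r` (bin
#'   centers, nm), `g`, plus `species`, `bin_width`, `r_max`, `n_frames`
#' @export
radial_distribution <- function(traj, species = c("OO", "OH_inter", "OH_intra"),
                                bin_width = 0.002, r_max = NULL,
                                frame_stride = 1) {
  stopifnot(inherits(traj, "water_trajectory"), bin_width > 0)
  species <- match.arg(species)
  L <- traj$box$edge_length
  if (is.null(r_max)) r_max <- L / 2
  if (r_max > L / 2 + 1e-12)
    stop("r_max must not exceed half the box edge (L/2 = ", L / 2, " nm)")
  n <- traj$n_molecules
  frames <- seq(1, traj$n_frames, by = max(1L, as.integer(frame_stride)))
  pos <- traj$positions[, , frames, drop = FALSE]
  o_idx <- 3L * (seq_len(n) - 1L)           # 0-based for the C++ kernel
  h_idx <- sort(c(o_idx + 1L, o_idx + 2L))
  counts <- switch(species,
    OO = .cpp_pair_hist(pos, o_idx, o_idx, 2L, L, bin_width, r_max),
    OH_inter = .cpp_pair_hist(pos, h_idx, o_idx, 0L, L, bin_width, r_max),
    OH_intra = .cpp_pair_hist(pos, h_idx, o_idx, 1L, L, bin_width, r_max))
  n_pairs <- switch(species,
    OO = n * (n - 1) / 2,
    OH_inter = 2 * n * (n - 1),
    OH_intra = 2 * n^2)
  nb <- length(counts)
  r <- (seq_len(nb) - 0.5) * bin_width
  shell <- 4 * pi * r^2 * bin_width * n_pairs / L^3
  structure(list(
    r = r, g = counts / (shell * length(frames)),
    species = species, bin_width = bin_width, r_max = r_max,
    n_frames = length(frames)
  ), class = "radial_distribution")
}

#' @export
print.radial_distribution <- function(x, ...) {
  imax <- which.max(x$g)
  cat(sprintf("g_%s: %d bins of %.3g nm over %d frames; first maximum %.3f at r = %.3f nm\n",
              x$species, length(x$r), x$bin_width, x$n_frames,
              x$g[imax], x$r[imax]))
  invisible(x)
}

#' First-peak position of a radial distribution function
#' @param rdf a [radial_distribution()]
#' @param r_min,r_max search window, nm
#' @return position of the maximum of g within the window, nm
#' @export
rdf_peak_position <- function(rdf, r_min = 0, r_max = Inf) {
  stopifnot(inherits(rdf, "radial_distribution"))
  sel <- rdf$r >= r_min & rdf$r <= r_max
  if (!any(sel)) stop("empty search window")
  rdf$r[sel][which.max(rdf$g[sel])]
}

#' Write a radial distribution function as CSV
#' @param rdf a [radial_distribution()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_rdf <- function(rdf, path) {
  stopifnot(inherits(rdf, "radial_distribution"))
  utils::write.csv(data.frame(r_nm = rdf$r, g = rdf$g), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
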