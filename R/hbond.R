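#' Hydrogen-bond detection criteria
#'
#' A donor-H/acceptor pair is counted as hydrogen bonded when all three
#' criteria hold: (i) molecule-pair interaction energy below `energy_max`;
#' (ii) H(donor)..O(acceptor) distance below `r_oh_max`; (iii) inclination
#' of the donor O-H bond to the O(donor)-O(acceptor) line below `alpha_max`.
#'
#' @param energy_max kJ/mol (negative; default -8)
#' @param r_oh_max nm (default 0.25)
#' @param alpha_max degrees (default 30)
#' @return object of class `hbond_criteria`
#' @export
hbond_criteria <- function(energy_max = -8, r_oh_max = 0.25, alpha_max = 30) {
  stopifnot(energy_max < 0, r_oh_max > 0, alpha_max > 0, alpha_max < 90)
  structure(list(energy_max = energy_max, r_oh_max = r_oh_max,
                 alpha_max = alpha_max), class = "hbond_criteria")
}

#' Detect hydrogen bonds in a frame
#'
#' Every donor-hydrogen/acceptor pair satisfying all three criteria is
#' emitted exactly once. Geometry is computed under minimum image; alpha is
#' the angle between the donor O-H vector and the donor-O to acceptor-O
#' line.
#'
#' @param frame an [md_frame()] with positions
#' @param params a [potential_params()] (needed for the energetic criterion)
#' @param criteria an [hbond_criteria()]
#' @param energy optional precomputed [pair_energy_matrix()] for this frame
#' @return data.frame with columns donor, h_site (1 or 2), acceptor,
#'   energy (kJ/mol), r_oh (nm), alpha (degrees)
#' @export
detect_hbonds <- function(frame, params = potential_params(),
                          criteria = hbond_criteria(), energy = NULL) {
  stopifnot(inherits(frame, "md_frame"), inherits(criteria, "hbond_criteria"))
  if (is.null(params) && is.null(energy))
    stop("the energetic criterion needs the potential: supply params or energy")
  n <- frame$n_molecules
  box <- frame$box
  pos <- frame$positions
  o_idx <- 3 * (seq_len(n) - 1) + 1
  if (is.null(energy)) energy <- pair_energy_matrix(frame, params)

  o_pos <- pos[o_idx, , drop = FALSE]
  out <- vector("list", 2)
  for (hs in 1:2) {
    h_pos <- pos[o_idx + hs, , drop = FALSE]
    # intramolecular O-H vector (minimum image; molecules may straddle wrap)
    oh <- minimum_image_displacement(o_pos, h_pos, box)
    oh_len <- sqrt(rowSums(oh^2))
    # pairwise H(donor) .. O(acceptor) distances and O(d)..O(a) geometry
    L <- box$edge_length
    mi <- function(m) m - L * floor(m / L + 0.5)
    dx <- mi(outer(h_pos[, 1], o_pos[, 1], `-`) * -1)
    dy <- mi(outer(h_pos[, 2], o_pos[, 2], `-`) * -1)
    dz <- mi(outer(h_pos[, 3], o_pos[, 3], `-`) * -1)
    r_ho <- sqrt(dx^2 + dy^2 + dz^2)  # [donor, acceptor]
    ox <- mi(outer(o_pos[, 1], o_pos[, 1], `-`) * -1)
    oy <- mi(outer(o_pos[, 2], o_pos[, 2], `-`) * -1)
    oz <- mi(outer(o_pos[, 3], o_pos[, 3], `-`) * -1)
    r_oo <- sqrt(ox^2 + oy^2 + oz^2)
    cosa <- (oh[, 1] * ox + oh[, 2] * oy + oh[, 3] * oz) / (oh_len * r_oo)
    cosa[cosa > 1] <- 1
    cosa[cosa < -1] <- -1
    alpha <- acos(cosa) * 180 / pi  # matrix [donor, acceptor]
    ok <- r_ho < criteria$r_oh_max & alpha < criteria$alpha_max &
      energy < criteria$energy_max
    diag(ok) <- FALSE
    idx <- which(ok, arr.ind = TRUE)
    out[[hs]] <- data.frame(
      donor = idx[, 1], h_site = if (nrow(idx)) hs else integer(0),
      acceptor = idx[, 2],
      energy = energy[idx], r_oh = r_ho[idx], alpha = alpha[idx])
  }
  bonds <- rbind(out[[1]], out[[2]])
  bonds[order(bonds$donor, bonds$h_site, bonds$acceptor), , drop = FALSE]
}

#' Histogram of per-molecule hydrogen-bond counts
#'
#' Per-molecule degree counts participation as donor or acceptor. Molecules
#' with more than 5 bonds are pooled into the displayed n_hb = 5
#' ("bifurcated") bin but counted exactly in the mean.
#'
#' @param bonds bond table from [detect_hbonds()]
#' @param n_molecules number of molecules
#' @return object of class `bond_count_histogram`: `percent` (named vector
#'   over n_hb = 0..5, summing to 100), `mean_nhb`, `n_bonds`
#' @export
bond_count_histogram <- function(bonds, n_molecules) {
  deg <- hbond_degrees(bonds, n_molecules)$degree
  shown <- pmin(deg, 5L)
  counts <- vapply(0:5, function(k) sum(shown == k), 0)
  structure(list(
    percent = stats::setNames(100 * counts / n_molecules, 0:5),
    mean_nhb = sum(deg) / n_molecules,
    n_bonds = nrow(bonds)
  ), class = "bond_count_histogram")
}

#' @export
print.bond_count_histogram <- function(x, ...) {
  cat("hydrogen bonds per molecule (%):\n")
  print(round(x$percent, 2))
  cat(sprintf("<n_hb> = %.3f\n", x$mean_nhb))
  invisible(x)
}

#' Per-molecule donor/acceptor/total bond counts
#' @param bonds bond table from [detect_hbonds()]
#' @param n_molecules number of molecules
#' @return data.frame with columns molecule, n_donor, n_acceptor, degree
#' @export
hbond_degrees <- function(bonds, n_molecules) {
  n_donor <- tabulate(bonds$donor, nbins = n_molecules)
  n_acceptor <- tabulate(bonds$acceptor, nbins = n_molecules)
  data.frame(molecule = seq_len(n_molecules), n_donor = n_donor,
             n_acceptor = n_acceptor, degree = n_donor + n_acceptor)
}

#' Cluster-size distribution of the hydrogen-bond network
#'
#' Connected components of the undirected graph whose vertices are molecules
#' and whose edges are hydrogen bonds. Isolated molecules count as clusters
#' of size 1. Both the per-cluster mean size and the per-molecule weighted
#' mean (the expected size of the cluster containing a random molecule) are
#' reported.
#'
#' @param bonds bond table from [detect_hbonds()]
#' @param n_molecules number of molecules
#' @return object of class `cluster_size_distribution`: `sizes` (per-cluster
#'   sizes), `distribution` (data.frame size/probability, normalized),
#'   `mean_cluster`, `mean_molecule`, `largest`
#' @export
hbond_components <- function(bonds, n_molecules) {
  g <- igraph::graph_from_edgelist(
    cbind(bonds$donor, bonds$acceptor)[!duplicated(paste(
      pmin(bonds$donor, bonds$acceptor),
      pmax(bonds$donor, bonds$acceptor))), , drop = FALSE],
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n_molecules - igraph::vcount(g)))
  sizes <- as.numeric(igraph::components(g)$csize)
  tab <- table(sizes)
  structure(list(
    sizes = sizes,
    distribution = data.frame(size = as.integer(names(tab)),
                              probability = as.numeric(tab) / length(sizes)),
    mean_cluster = mean(sizes),
    mean_molecule = sum(sizes^2) / sum(sizes),
    largest = max(sizes)
  ), class = "cluster_size_distribution")
}

#' @export
print.cluster_size_distribution <- function(x, ...) {
  cat(sprintf(
    "H-bond clusters: %d clusters, largest %d; <N>_cluster = %.2f, <N>_molecule = %.2f\n",
    length(x$sizes), x$largest, x$mean_cluster, x$mean_molecule))
  invisible(x)
}

#' Patch-size distribution g(N4) of connected four-bonded molecules
#'
#' A molecule is four-bonded when it participates in exactly two bonds as
#' donor and exactly two as acceptor. Patches are connected components of
#' the subgraph induced on four-bonded molecules, with edges restricted to
#' hydrogen bonds whose both endpoints are four-bonded.
#'
#' @param bonds bond table from [detect_hbonds()]
#' @param n_molecules number of molecules
#' @param include_bifurcated when TRUE, molecules with at least (rather than
#'   exactly) two donor and two acceptor bonds qualify as four-bonded
#' @return object of class `patch_distribution`: `sizes`, `distribution`
#'   (size/probability over N4, normalized when any patch exists),
#'   `mean_n4` (0 when no patch), `fraction_in_patches`, `four_bonded`
#'   (logical per molecule)
#' @export
patch_distribution <- function(bonds, n_molecules, include_bifurcated = FALSE) {
  deg <- hbond_degrees(bonds, n_molecules)
  fb <- if (include_bifurcated) deg$n_donor >= 2 & deg$n_acceptor >= 2
        else deg$n_donor == 2 & deg$n_acceptor == 2
  if (!any(fb)) {
    return(structure(list(
      sizes = numeric(0),
      distribution = data.frame(size = integer(0), probability = numeric(0)),
      mean_n4 = 0, fraction_in_patches = 0, four_bonded = fb
    ), class = "patch_distribution"))
  }
  keep <- fb[bonds$donor] & fb[bonds$acceptor]
  sub <- bonds[keep, , drop = FALSE]
  # relabel four-bonded molecules 1..m for the induced subgraph
  map <- integer(n_molecules); map[which(fb)] <- seq_len(sum(fb))
  el <- cbind(map[sub$donor], map[sub$acceptor])
  el <- el[!duplicated(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))),
           , drop = FALSE]
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, sum(fb) - igraph::vcount(g)))
  sizes <- as.numeric(igraph::components(g)$csize)
  tab <- table(sizes)
  structure(list(
    sizes = sizes,
    distribution = data.frame(size = as.integer(names(tab)),
                              probability = as.numeric(tab) / length(sizes)),
    mean_n4 = mean(sizes),
    fraction_in_patches = sum(fb) / n_molecules,
    four_bonded = fb
  ), class = "patch_distribution")
}

#' @export
print.patch_distribution <- function(x, ...) {
  if (length(x$sizes) == 0) {
    cat("no four-bonded molecules; no patches\n")
  } else {
    cat(sprintf("patches: %d, <N4> = %.2f, fraction of molecules four-bonded = %.3f\n",
                length(x$sizes), x$mean_n4, x$fraction_in_patches))
  }
  invisible(x)
}

#' Percolation check on a cluster-size distribution
#'
#' @param dist a [hbond_components()] result
#' @param n_molecules number of molecules
#' @param threshold fraction of molecules the largest cluster must reach to
#'   count as a space-filling network (default 0.95)
#' @return list with `percolating` (flag) and `largest_fraction`
#' @export
percolation_check <- function(dist, n_molecules, threshold = 0.95) {
  stopifnot(inherits(dist, "cluster_size_distribution"))
  frac <- dist$largest / n_molecules
  list(percolating = frac >= threshold, largest_fraction = frac)
}

#' Frame-averaged hydrogen-bond network statistics for a trajectory
#'
#' Detects bonds on frames sampled every `frame_stride` fs (to reduce serial
#' correlation) and aggregates: the bond-count histogram is averaged over
#' frames, cluster and patch statistics are pooled.
#'
#' @param traj a [water_trajectory()]
#' @param params a [potential_params()]
#' @param criteria an [hbond_criteria()]
#' @param frame_stride fs between analyzed frames (default 100)
#' @return list with `histogram`, `clusters`, `patches`,
#'   `mean_largest_fraction`, `n_frames`, and `per_frame` (data.frame with
#'   mean_nhb, mean_n4, largest_fraction per analyzed frame)
#' @export
hbond_statistics <- function(traj, params = potential_params(),
                             criteria = hbond_criteria(), frame_stride = 100) {
  stopifnot(inherits(traj, "water_trajectory"))
  stride <- max(1L, as.integer(round(frame_stride / traj$sampling_interval)))
  frames <- seq(1, traj$n_frames, by = stride)
  n <- traj$n_molecules
  percent_acc <- stats::setNames(numeric(6), 0:5)
  mean_nhb_acc <- 0; n_bonds_acc <- 0
  cluster_sizes <- patch_sizes <- numeric(0)
  per_frame <- data.frame(frame = frames, mean_nhb = NA_real_,
                          mean_n4 = NA_real_, largest_fraction = NA_real_)
  n_fb <- 0
  for (k in seq_along(frames)) {
    fr <- trajectory_frame(traj, frames[k])
    bonds <- detect_hbonds(fr, params, criteria)
    h <- bond_count_histogram(bonds, n)
    percent_acc <- percent_acc + h$percent
    mean_nhb_acc <- mean_nhb_acc + h$mean_nhb
    n_bonds_acc <- n_bonds_acc + h$n_bonds
    cl <- hbond_components(bonds, n)
    pa <- patch_distribution(bonds, n)
    cluster_sizes <- c(cluster_sizes, cl$sizes)
    patch_sizes <- c(patch_sizes, pa$sizes)
    n_fb <- n_fb + sum(pa$four_bonded)
    per_frame$mean_nhb[k] <- 2 * nrow(bonds) / n
    per_frame$mean_n4[k] <- if (length(pa$sizes)) mean(pa$sizes) else 0
    per_frame$largest_fraction[k] <- cl$largest / n
  }
  nf <- length(frames)
  hist <- structure(list(percent = percent_acc / nf,
                         mean_nhb = mean_nhb_acc / nf,
                         n_bonds = n_bonds_acc / nf),
                    class = "bond_count_histogram")
  ctab <- table(cluster_sizes)
  ptab <- table(patch_sizes)
  list(
    histogram = hist,
    clusters = list(
      distribution = data.frame(size = as.integer(names(ctab)),
                                probability = as.numeric(ctab) / length(cluster_sizes)),
      mean_cluster = mean(cluster_sizes),
      mean_molecule = sum(cluster_sizes^2) / sum(cluster_sizes)),
    patches = list(
      distribution = data.frame(size = as.integer(names(ptab)),
                                probability = if (length(patch_sizes))
                                  as.numeric(ptab) / length(patch_sizes) else numeric(0)),
      mean_n4 = if (length(patch_sizes)) mean(patch_sizes) else 0,
      fraction_four_bonded = n_fb / (n * length(frames))),
    mean_largest_fraction = mean(per_frame$largest_fraction),
    n_frames = length(frames),
    per_frame = per_frame
  )
}
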