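#' Surrogate flexible three-site water potential parameters
#'
#' A self-contained parameterization of a flexible three-site water model:
#' partial charges on O and H, a quartic intramolecular power series in the
#' internal coordinates (two O-H stretches and the H-O-H bend, with
#' stretch-stretch and stretch-bend couplings), Buckingham-form short-range
#' site-site terms per pair species, and Ewald parameters for the long-range
#' Coulomb sum. Every coefficient lives in this one block so an alternative
#' literature set can be dropped in.
#'
#' Intramolecular energy (s1, s2 = r_OH - r_e in nm; st = theta - theta_e in
#' rad):
#' `V = k_r/2 (s1^2+s2^2) + k_r3 (s1^3+s2^3) + k_r4 (s1^4+s2^4)
#'    + k_theta/2 st^2 + k_rr s1 s2 + k_rtheta (s1+s2) st`
#'
#' `ewald_alpha` and `r_cut` default to NA and are resolved against the box
#' at use time (alpha = 5/L, r_cut just under L/2); see
#' [resolve_potential_params()].
#'
#' @param q_H hydrogen partial charge, e (oxygen carries -2*q_H)
#' @param r_e equilibrium O-H length, nm
#' @param theta_e equilibrium H-O-H angle, degrees
#' @param k_r,k_r3,k_r4 stretch force constants, kJ/mol/nm^2, nm^3, nm^4
#' @param k_theta bend force constant, kJ/mol/rad^2
#' @param k_rr stretch-stretch coupling, kJ/mol/nm^2
#' @param k_rtheta stretch-bend coupling, kJ/mol/(nm rad)
#' @param buck_A,buck_b,buck_C6 Buckingham A exp(-b r) - C6/r^6 coefficients
#'   for pair species (OO, OH, HH); kJ/mol, 1/nm, kJ nm^6/mol
#' @param hbond_D,hbond_r0,hbond_gamma Gaussian hydrogen-bond well
#'   `-D exp(-gamma (r - r0)^2)` per pair species (kJ/mol, nm, 1/nm^2);
#'   by default only the intermolecular O-H pair carries a well, centred at
#'   the H-bond contact distance. This term supplies the directional-contact
#'   cohesion that central-force water models place in their O-H short-range
#'   function.
#' @param ewald_alpha Ewald splitting parameter, 1/nm (NA: 5/L)
#' @param r_cut real-space and short-range cutoff, nm (NA: just under L/2)
#' @param kmax2 reciprocal-space cutoff on the squared integer index |n|^2
#' @return object of class `potential_params`
#' @export
potential_params <- function(q_H = 0.33,
                             r_e = 0.09572,
                             theta_e = 104.52,
                             k_r = 4.0e5,
                             k_r3 = -4.4e6,
                             k_r4 = 5.5e7,
                             k_theta = 545,
                             k_rr = -1.0e4,
                             k_rtheta = -5.0e3,
                             buck_A = c(OO = 7.0e5, OH = 2.0e3, HH = 7.0e2),
                             buck_b = c(OO = 40, OH = 37, HH = 40),
                             buck_C6 = c(OO = 2.5e-3, OH = 0, HH = 0),
                             hbond_D = c(OO = 0, OH = 20, HH = 0),
                             hbond_r0 = c(OO = 0, OH = 0.175, HH = 0),
                             hbond_gamma = c(OO = 0, OH = 1500, HH = 0),
                             ewald_alpha = NA_real_,
                             r_cut = NA_real_,
                             kmax2 = 27L) {
  stopifnot(r_e > 0, theta_e > 0, theta_e < 180, length(buck_A) == 3,
            length(buck_b) == 3, length(buck_C6) == 3, length(hbond_D) == 3,
            length(hbond_r0) == 3, length(hbond_gamma) == 3, kmax2 >= 1)
  structure(list(
    q_H = q_H, q_O = -2 * q_H,
    r_e = r_e, theta_e = theta_e, theta_e_rad = theta_e * pi / 180,
    k_r = k_r, k_r3 = k_r3, k_r4 = k_r4, k_theta = k_theta,
    k_rr = k_rr, k_rtheta = k_rtheta,
    buck_A = unname(buck_A), buck_b = unname(buck_b), buck_C6 = unname(buck_C6),
    hbond_D = unname(hbond_D), hbond_r0 = unname(hbond_r0),
    hbond_gamma = unname(hbond_gamma),
    ewald_alpha = ewald_alpha, r_cut = r_cut, kmax2 = as.integer(kmax2)
  ), class = "potential_params")
}

#' Resolve box-dependent potential parameters
#'
#' Fills `ewald_alpha = 5/L` and `r_cut` just under `L/2` where unset, and
#' validates cutoffs against the box.
#'
#' @param params a [potential_params()]
#' @param box a [simulation_box()]
#' @return a fully resolved `potential_params`
#' @export
resolve_potential_params <- function(params, box) {
  stopifnot(inherits(params, "potential_params"), inherits(box, "simulation_box"))
  L <- box$edge_length
  if (is.na(params$ewald_alpha)) params$ewald_alpha <- 5 / L
  if (is.na(params$r_cut)) params$r_cut <- 0.4999 * L
  if (params$r_cut >= L / 2) stop("r_cut must be < L/2")
  params
}

#' @export
print.potential_params <- function(x, ...) {
  cat(sprintf(
    "flexible 3-site water surrogate: q_H=%+.2fe, r_e=%.5g nm, theta_e=%.4g deg\n",
    x$q_H, x$r_e, x$theta_e))
  cat(sprintf("  k_r=%.3g, k_theta=%.3g, couplings k_rr=%.3g k_rtheta=%.3g\n",
              x$k_r, x$k_theta, x$k_rr, x$k_rtheta))
  invisible(x)
}

#' Forces and potential-energy decomposition for one frame
#'
#' Forces are the exact negative gradient of the implemented potential:
#' intramolecular series, Ewald real + reciprocal + self/exclusion Coulomb
#' terms, and shifted-force Buckingham short-range terms.
#'
#' @param frame an [md_frame()]
#' @param params a [potential_params()]
#' @return list with `forces` (n_sites x 3, kJ/(mol nm)) and `energy`
#'   (named list: intramolecular, coulomb_real, coulomb_reciprocal,
#'   self_exclusion, short_range, potential; kJ/mol)
#' @export
compute_forces_energies <- function(frame, params = potential_params()) {
  stopifnot(inherits(frame, "md_frame"))
  params <- resolve_potential_params(params, frame$box)
  q <- site_charges(frame$n_molecules, params$q_H)
  .cpp_forces(frame$positions, q, unclass(params), frame$box$edge_length)
}

#' Full unscreened molecule-pair interaction energies
#'
#' Sum of the 9 intermolecular site-site terms (bare Coulomb plus Buckingham
#' short-range, no cutoff) between every molecule pair under minimum image.
#' This is the pair energy entering the energetic hydrogen-bond criterion,
#' which is only well defined outside the Ewald lattice-sum decomposition.
#'
#' @param frame an [md_frame()]
#' @param params a [potential_params()]
#' @return symmetric n_mol x n_mol matrix, kJ/mol (diagonal 0)
#' @export
pair_energy_matrix <- function(frame, params = potential_params()) {
  stopifnot(inherits(frame, "md_frame"))
  params <- resolve_potential_params(params, frame$box)
  q <- site_charges(frame$n_molecules, params$q_H)
  .cpp_pair_energy_matrix(frame$positions, q, unclass(params),
                          frame$box$edge_length)
}

#' Interaction energy of one molecule pair
#'
#' @param i,j molecule indices (1-based, distinct)
#' @param frame an [md_frame()]
#' @param params a [potential_params()]
#' @return pair interaction energy, kJ/mol
#' @export
pair_interaction_energy <- function(i, j, frame, params = potential_params()) {
  stopifnot(inherits(frame, "md_frame"))
  if (i == j) stop("pair interaction energy requires two distinct molecules")
  if (i < 1 || j < 1 || i > frame$n_molecules || j > frame$n_molecules)
    stop("molecule index out of range")
  params <- resolve_potential_params(params, frame$box)
  f <- water_constants$f_coulomb
  qs <- c(params$q_O, params$q_H, params$q_H)
  type <- c(0L, 1L, 1L)  # 0 = O, 1 = H
  si <- 3 * (i - 1) + 1:3
  sj <- 3 * (j - 1) + 1:3
  e <- 0
  for (a in 1:3) for (b in 1:3) {
    d <- minimum_image_displacement(frame$positions[si[a], ],
                                    frame$positions[sj[b], ], frame$box)
    r <- sqrt(sum(d^2))
    t <- type[a] + type[b] + 1L
    e <- e + f * qs[a] * qs[b] / r +
      params$buck_A[t] * exp(-params$buck_b[t] * r) - params$buck_C6[t] / r^6 -
      params$hbond_D[t] * exp(-params$hbond_gamma[t] * (r - params$hbond_r0[t])^2)
  }
  e
}
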