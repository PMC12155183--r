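# Independent brute-force oracles and shared fixtures.

# minimum image by exhaustive search over all 27 periodic images
brute_min_image <- function(r1, r2, L) {
  best <- NULL
  best_n <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    d <- (r2 + L * c(ix, iy, iz)) - r1
    n2 <- sum(d^2)
    if (n2 < best_n) { best_n <- n2; best <- d }
  }
  best
}

# connected components by exhaustive reachability (repeated neighborhood
# expansion), independent of any graph library
brute_components <- function(edges, n) {
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(edges))) {
      a <- edges[r, 1]; b <- edges[r, 2]
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[comp == comp[a] | comp == comp[b]] <- m
        changed <- TRUE
      }
    }
    if (!changed || nrow(edges) == 0) break
  }
  as.numeric(sort(table(comp), decreasing = TRUE))
}

# patch sizes by explicit enumeration: classify four-bonded molecules from
# the raw bond table, then component sizes on the induced subgraph
brute_patches <- function(bonds, n) {
  nd <- tabulate(bonds$donor, nbins = n)
  na <- tabulate(bonds$acceptor, nbins = n)
  fb <- which(nd == 2 & na == 2)
  if (length(fb) == 0) return(numeric(0))
  keep <- bonds$donor %in% fb & bonds$acceptor %in% fb
  sub <- bonds[keep, , drop = FALSE]
  map <- match(seq_len(n), fb)
  edges <- cbind(map[sub$donor], map[sub$acceptor])
  brute_components(edges, length(fb))
}

# random bond table on n molecules: directed donor(h_site) -> acceptor with
# per-donor-H at most one bond (as detection guarantees)
random_bond_table <- function(n, p = 0.15) {
  rows <- list()
  for (d in seq_len(n)) for (hs in 1:2) {
    if (stats::runif(1) < p) {
      acc <- sample(setdiff(seq_len(n), d), 1)
      rows[[length(rows) + 1]] <- data.frame(donor = d, h_site = hs,
                                             acceptor = acc)
    }
  }
  if (length(rows) == 0)
    return(data.frame(donor = integer(0), h_site = integer(0),
                      acceptor = integer(0)))
  do.call(rbind, rows)
}

# ideal hydrogen-bond dimer: donor O-H pointing straight at the acceptor O
# along +x; acceptor hydrogens tilted away. Angles in degrees bend the donor
# O-H off the O..O line; stretching moves the acceptor along +x.
make_dimer_frame <- function(r_oo = 0.28, alpha_deg = 0,
                             params = potential_params(), box_edge = 4) {
  th <- params$theta_e * pi / 180
  a <- alpha_deg * pi / 180
  don <- rbind(c(0, 0, 0),
               params$r_e * c(cos(a), sin(a), 0),
               params$r_e * c(cos(a + th), sin(a + th), 0))
  base <- c(r_oo, 0, 0)
  acc <- rbind(base,
               base + params$r_e * c(cos(th / 2), sin(th / 2) * cos(1),
                                     sin(th / 2) * sin(1)),
               base + params$r_e * c(cos(th / 2), -sin(th / 2) * cos(1),
                                     -sin(th / 2) * sin(1)))
  md_frame(rbind(don, acc) + box_edge / 2, simulation_box(box_edge))
}

# short cached liquid runs shared by several tests
small_liquid_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- md_config(16, density = 0.997, target_temperature = 299,
                       n_production_steps = 2000, annealing_stage_steps = 600,
                       store_interval = 1, seed = 42)
      cache <<- run_nve(cfg)
    }
    cache
  }
})

medium_liquid_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- md_config(100, density = 0.997, target_temperature = 299,
                       n_production_steps = 6000, annealing_stage_steps = 1200,
                       store_interval = 2, seed = 41)
      cache <<- run_nve(cfg)
    }
    cache
  }
})

# finite-difference gradient check (5-point central differences)
fd_force_check <- function(frame, params, n_checks = 10, h = 1e-6, seed = 7) {
  params <- resolve_potential_params(params, frame$box)
  fe <- compute_forces_energies(frame, params)
  epot <- function(pos) {
    f <- frame; f$positions <- pos
    compute_forces_energies(f, params)$energy$potential
  }
  set.seed(seed)
  n <- nrow(frame$positions)
  idx <- cbind(sample(n, n_checks, replace = TRUE),
               sample(3, n_checks, replace = TRUE))
  err <- numeric(n_checks)
  for (k in seq_len(n_checks)) {
    i <- idx[k, 1]; d <- idx[k, 2]
    at <- function(s) {
      p <- frame$positions; p[i, d] <- p[i, d] + s; epot(p)
    }
    # 5-point central difference: O(h^4) truncation
    fd <- -(8 * (at(h) - at(-h)) - (at(2 * h) - at(-2 * h))) / (12 * h)
    err[k] <- abs(fd - fe$forces[i, d]) / max(abs(fd), 1)
  }
  max(err)
}
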