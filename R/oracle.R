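## Synthetic "surrogate electronic structure" for water: rigid molecules with
## four pseudo-Wannier centres whose positions respond linearly to the local
## effective field, plus simple classical forces (Lennard-Jones + point-charge
## Coulomb). Every quantity has a known ground truth, so the full learning
## pipeline can be validated without any external data.

#' Parameters of the synthetic water oracle
#'
#' The reference centres sit in the molecular frame: two bond centres along
#' the O-H bonds and two lone-pair centres tilted out of the molecular plane.
#' Each centre responds to the local effective field at the oxygen as
#' `dr = -alpha/(2 ke) * E`, which makes the molecular polarizability volume
#' exactly `4 alpha` (Angstrom^3). The response is solved self-consistently
#' with the same `v1`-screened interaction used by the model, so the learning
#' target is exactly representable by the linear long-range network.
#'
#' @param alpha Per-centre polarizability (Angstrom^3); default 0.48 gives a
#'   molecular polarizability of 1.92 A^3, i.e. a high-frequency dielectric
#'   constant near 1.8 at liquid-water density (dilute estimate), close to
#'   real water.
#' @param bond_offset,lone_offset Distances of the bond and lone-pair
#'   reference centres from the oxygen (Angstrom).
#' @param lone_tilt Tilt of the lone-pair centres out of the molecular plane
#'   (degrees from the back-bisector, default tetrahedral).
#' @param dipole Optional target molecular dipole (Debye). When given, all
#'   four reference centres are shifted along the bisector so the rigid
#'   molecule has this dipole; NULL keeps the natural value (about 2.8 D).
#' @param r_oh,theta Rigid geometry: O-H bond length (Angstrom) and H-O-H
#'   angle (degrees).
#' @param lj_eps,lj_sigma O-O Lennard-Jones parameters (eV, Angstrom);
#'   defaults are the common water values.
#' @param bond_k,angle_k Intramolecular harmonic stiffness used only by the
#'   molecular-dynamics engine (eV/A^2, eV/rad^2).
#' @param wall_oh,wall_hh Intermolecular `B/r^12` repulsion strengths
#'   (eV Angstrom^12) between O-H and H-H sites, used only by the dynamics
#'   engine; the classical stand-in for Pauli repulsion that keeps the bare
#'   charge sites from fusing.
#' @param sigma Long-range split length of the screened interaction (Angstrom).
#' @return Object of class `oracle_params`.
#' @export
oracle_params <- function(alpha = 0.48, bond_offset = 0.52, lone_offset = 0.3,
                          lone_tilt = 54.7356, dipole = NULL,
                          r_oh = 0.9572, theta = 104.52,
                          lj_eps = 0.006737, lj_sigma = 3.166,
                          bond_k = 45, angle_k = 3.3, sigma = 4.2,
                          wall_oh = 42, wall_hh = 20) {
  stopifnot(alpha >= 0, bond_offset < 0.6, lone_offset < 0.6)
  p <- list(alpha = alpha, bond_offset = bond_offset,
            lone_offset = lone_offset, lone_tilt = lone_tilt,
            r_oh = r_oh, theta = theta, lj_eps = lj_eps, lj_sigma = lj_sigma,
            bond_k = bond_k, angle_k = angle_k, sigma = sigma,
            wall_oh = wall_oh, wall_hh = wall_hh)
  p$centers_local <- reference_centers_local(p, shift = 0)
  mu_nat <- oracle_rigid_dipole(p)
  if (!is.null(dipole)) {
    mu_target <- dipole / DEBYE_PER_EA
    # each centre carries -2 e0; a shift s along the bisector changes the
    # dipole magnitude by -8 s
    shift <- (mu_nat - mu_target) / 8
    p$centers_local <- reference_centers_local(p, shift = shift)
  }
  p$mu_rigid <- oracle_rigid_dipole(p)
  class(p) <- "oracle_params"
  p
}

# template molecule in its own local frame (y along O-H1, plane = xy)
template_molecule_local <- function(p) {
  th <- p$theta * pi / 180
  rbind(O = c(0, 0, 0),
        H1 = c(0, p$r_oh, 0),
        H2 = c(-sin(th) * p$r_oh, cos(th) * p$r_oh, 0))
}

reference_centers_local <- function(p, shift = 0) {
  tm <- template_molecule_local(p)
  u1 <- tm["H1", ] / p$r_oh
  u2 <- tm["H2", ] / p$r_oh
  yb <- (u1 + u2) / sqrt(sum((u1 + u2)^2))
  phi <- p$lone_tilt * pi / 180
  zhat <- c(0, 0, 1)
  l1 <- -yb * cos(phi) + zhat * sin(phi)
  l2 <- -yb * cos(phi) - zhat * sin(phi)
  ctr <- rbind(bond1 = p$bond_offset * u1,
               bond2 = p$bond_offset * u2,
               lone1 = p$lone_offset * l1,
               lone2 = p$lone_offset * l2)
  sweep(ctr, 2, -shift * yb, "-")
}

# signed dipole magnitude (along the bisector) of the rigid molecule, e0 A
oracle_rigid_dipole <- function(p) {
  tm <- template_molecule_local(p)
  u1 <- tm["H1", ] / p$r_oh
  u2 <- tm["H2", ] / p$r_oh
  yb <- (u1 + u2) / sqrt(sum((u1 + u2)^2))
  mu_vec <- tm["H1", ] + tm["H2", ] - 2 * colSums(p$centers_local)
  sum(mu_vec * yb)
}

#' @export
print.oracle_params <- function(x, ...) {
  cat(sprintf(
    "synthetic water oracle: alpha = %.3f A^3/centre, rigid dipole = %.3f D, sigma = %.2f A\n",
    x$alpha, x$mu_rigid * DEBYE_PER_EA, x$sigma))
  invisible(x)
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
        c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
        c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

#' Generate bulk water configurations
#'
#' Rigid molecules on a jittered lattice with random orientations, rejected
#' and re-drawn until no O-O pair is closer than `min_oo` (minimum image).
#'
#' @param n_molecules Number of molecules.
#' @param density Mass density in g/cm^3 (default 0.997; 64 molecules then
#'   sit in a cubic box of edge ~12.42 Angstrom).
#' @param n_configs Number of independent configurations.
#' @param seed RNG seed.
#' @param params [oracle_params()] (rigid geometry).
#' @param min_oo Minimum O-O distance (Angstrom).
#' @return List of [atomic_config()] (a single config if `n_configs = 1` is
#'   still returned as a length-1 list).
#' @export
generate_configs <- function(n_molecules, density = 0.997, n_configs = 1,
                             seed = 1, params = oracle_params(),
                             min_oo = 2.4) {
  stopifnot(density > 0, n_molecules >= 1)
  n_dens <- density * 0.6022140757 / 18.015  # molecules per A^3
  L <- (n_molecules / n_dens)^(1 / 3)
  cl <- cell(L)
  tm <- template_molecule_local(params)
  set.seed(seed)
  out <- vector("list", n_configs)
  species <- rep(c("O", "H", "H"), n_molecules)
  h_min <- 1.5  # reject intermolecular atom-atom contacts closer than this
  for (cfg in seq_len(n_configs)) {
    done <- FALSE
    for (attempt in 1:200) {
      if (n_molecules == 1) {
        centers <- matrix(L / 2, 1, 3)
      } else {
        m <- ceiling(n_molecules^(1 / 3))
        a <- L / m
        grid <- as.matrix(expand.grid(0:(m - 1), 0:(m - 1), 0:(m - 1)))
        sites <- (grid + 0.5) * a
        sel <- sample(nrow(sites), n_molecules)
        jit <- max(0, min(0.12 * a, 0.45 * (a - min_oo)))
        centers <- sites[sel, , drop = FALSE] +
          matrix(stats::runif(3 * n_molecules, -jit, jit), n_molecules, 3)
        do <- minimum_image(
          centers[rep(1:n_molecules, n_molecules), , drop = FALSE] -
            centers[rep(1:n_molecules, each = n_molecules), , drop = FALSE],
          cl)
        dd <- matrix(sqrt(rowSums(do^2)), n_molecules, n_molecules)
        diag(dd) <- Inf
        if (min(dd) < min_oo) next
      }
      # orient molecules one by one, avoiding intermolecular atom clashes
      pos <- matrix(0, 3 * n_molecules, 3)
      all_ok <- TRUE
      for (i in seq_len(n_molecules)) {
        placed <- if (i > 1) pos[seq_len(3 * (i - 1)), , drop = FALSE] else NULL
        ok <- FALSE
        for (try in 1:80) {
          Q <- random_rotation()
          block <- sweep(tm %*% t(Q), 2, centers[i, ], "+")
          if (is.null(placed)) { ok <- TRUE; break }
          d <- minimum_image(
            placed[rep(seq_len(nrow(placed)), 3), , drop = FALSE] -
              block[rep(1:3, each = nrow(placed)), , drop = FALSE], cl)
          if (min(sqrt(rowSums(d^2))) >= h_min) { ok <- TRUE; break }
        }
        if (!ok) { all_ok <- FALSE; break }
        pos[(3 * i - 2):(3 * i), ] <- block
      }
      if (all_ok) { done <- TRUE; break }
    }
    if (!done) stop("could not place molecules at this density without ",
                    "overlap; lower the density or the contact limits")
    out[[cfg]] <- atomic_config(species, pos, cl)
  }
  out
}

#' Ground-truth Wannier centres of the oracle
#'
#' Reference centres rotated to the lab frame plus a linear response
#' `dr = -alpha/(2 ke) E_loc` per centre, where the local field at each
#' molecule's oxygen (applied field plus the `v1`-screened field of all
#' charges, including the displaced centres) is solved self-consistently by
#' fixed-point iteration. The response is exactly linear in the applied
#' field by construction.
#'
#' @param config An [atomic_config()].
#' @param E_applied Applied uniform field vector (V/Angstrom).
#' @param params [oracle_params()].
#' @param mols,frames,kv Optional precomputed topology, frames and
#'   reciprocal-space vectors.
#' @param tol Convergence tolerance on centre displacements (Angstrom).
#' @return A [wannier_set()]; attribute `induced` holds the per-molecule
#'   induced displacement (n_mol x 3) and attribute `field` the converged
#'   per-molecule local field.
#' @export
oracle_wannier <- function(config, E_applied = c(0, 0, 0),
                           params = oracle_params(), mols = NULL,
                           frames = NULL, kv = NULL, tol = 1e-11) {
  if (is.null(mols)) mols <- detect_water_topology(config)
  if (is.null(frames)) frames <- build_frames(config, mols)
  n <- nrow(mols)
  ref <- matrix(0, 4 * n, 3)
  for (i in seq_len(n)) {
    ref[(4 * i - 3):(4 * i), ] <-
      sweep(to_lab(params$centers_local, frames[[i]]), 2,
            frames[[i]]$origin, "+")
  }
  mol_rep <- rep(seq_len(n), each = 4)
  if (params$alpha == 0) {
    w <- wannier_set(ref, mol_rep)
    attr(w, "induced") <- matrix(0, n, 3)
    return(w)
  }
  if (is.null(kv)) kv <- kspace_vectors(config$cell, params$sigma)
  o_pos <- config$positions[mols$o, , drop = FALSE]
  gain <- -params$alpha / (2 * KE)
  delta <- matrix(0, n, 3)
  prev_change <- Inf
  grow <- 0L
  E <- NULL
  for (it in 1:200) {
    w <- wannier_set(ref + delta[mol_rep, , drop = FALSE], mol_rep)
    ch <- assemble_charges(config, w)
    E <- effective_field(ch, o_pos, config$cell, E_ext = E_applied,
                         sigma = params$sigma, kv = kv)$site_fields
    delta_new <- gain * E
    change <- max(abs(delta_new - delta))
    delta <- delta_new
    if (change < tol) break
    if (change > prev_change) grow <- grow + 1L else grow <- 0L
    if (grow >= 3) stop("oracle self-consistent response diverges ",
                        "(alpha too large)")
    prev_change <- change
    if (it == 200) stop("oracle self-consistent response did not converge")
  }
  w <- wannier_set(ref + delta[mol_rep, , drop = FALSE], mol_rep)
  attr(w, "induced") <- delta
  attr(w, "field") <- E
  w
}

# Ewald split parameters used internally for the oracle's *full* Coulomb sum
oracle_ewald <- function(cl) {
  s <- min(min(cl$lengths) / 6, 2.5)
  list(sigma = s, rcut = 3 * s)
}

#' Oracle energy (Lennard-Jones + full periodic Coulomb)
#'
#' Full `1/r` Coulomb among all point charges (nuclei and centres, no
#' exclusions) evaluated by Ewald summation, plus O-O Lennard-Jones.
#'
#' @inheritParams oracle_wannier
#' @param wannier A [wannier_set()] consistent with `config`.
#' @return Energy in eV.
#' @export
oracle_energy <- function(config, wannier, params = oracle_params(),
                          mols = NULL) {
  if (is.null(mols)) mols <- detect_water_topology(config)
  ch <- assemble_charges(config, wannier)
  ew <- oracle_ewald(config$cell)
  kv <- kspace_vectors(config$cell, ew$sigma, tol = 1e-10)
  rs <- realspace_coulomb_cpp(ch$positions, ch$q,
                              seq_along(ch$q), config$cell$lengths,
                              ew$sigma, ew$rcut, KE)
  ks <- kspace_coulomb_cpp(ch$positions, ch$q, kv$n, kv$L, kv$coeff)
  o_pos <- config$positions[mols$o, , drop = FALSE]
  lj <- lj_cpp(o_pos, config$cell$lengths, params$lj_eps, params$lj_sigma,
               min(config$cell$lengths) / 2 * 0.999)
  rs$energy + ks$energy + lj$energy
}

#' Oracle forces on the nuclei
#'
#' Lennard-Jones (O-O), full periodic Coulomb among all point charges, and
#' the applied-field force on each charge. Centre charges ride with their
#' oxygen: forces on Wannier centres are attributed to the parent O.
#'
#' @inheritParams oracle_energy
#' @param E_applied Applied uniform field (V/Angstrom).
#' @return n_atoms x 3 force matrix (eV/Angstrom).
#' @export
oracle_forces <- function(config, wannier, E_applied = c(0, 0, 0),
                          params = oracle_params(), mols = NULL) {
  if (is.null(mols)) mols <- detect_water_topology(config)
  ch <- assemble_charges(config, wannier)
  ew <- oracle_ewald(config$cell)
  kv <- kspace_vectors(config$cell, ew$sigma, tol = 1e-10)
  rs <- realspace_coulomb_cpp(ch$positions, ch$q,
                              seq_along(ch$q), config$cell$lengths,
                              ew$sigma, ew$rcut, KE)
  ks <- kspace_coulomb_cpp(ch$positions, ch$q, kv$n, kv$L, kv$coeff)
  Fq <- rs$forces + ks$forces +
    outer(ch$q, as.numeric(E_applied))
  n_at <- nrow(config$positions)
  F <- matrix(0, n_at, 3)
  for (i in seq_along(ch$q)) {
    F[ch$parent[i], ] <- F[ch$parent[i], ] + Fq[i, ]
  }
  o_pos <- config$positions[mols$o, , drop = FALSE]
  lj <- lj_cpp(o_pos, config$cell$lengths, params$lj_eps, params$lj_sigma,
               min(config$cell$lengths) / 2 * 0.999)
  F[mols$o, ] <- F[mols$o, ] + lj$forces
  F
}

#' Generate a grouped synthetic training set
#'
#' For each of `n_configs` nuclear configurations, reference Wannier centres
#' and forces are generated at every applied field strength (fields along z
#' by default, matching the 0 / 0.1 / 0.2 V/Angstrom protocol). Samples that
#' share a configuration share a `group_id` and identical nuclear positions.
#'
#' @param n_configs Number of nuclear configurations (groups).
#' @param n_molecules Molecules per configuration.
#' @param fields Numeric vector of applied field magnitudes (V/Angstrom,
#'   applied along z); must include 0.
#' @param params [oracle_params()].
#' @param seed RNG seed.
#' @param density Mass density (g/cm^3).
#' @param forces Compute reference forces (set FALSE to skip, e.g. when only
#'   the electronic response is studied).
#' @return Object of class `oracle_dataset`: list of training samples (each
#'   with `config`, `applied_field`, `wannier`, `forces`, `group_id`) with
#'   the ground-truth `params` attached.
#' @export
generate_dataset <- function(n_configs, n_molecules = 64,
                             fields = c(0, 0.1, 0.2),
                             params = oracle_params(), seed = 1,
                             density = 0.997, forces = TRUE) {
  if (!any(fields == 0)) stop("the zero-field anchor must be included")
  configs <- generate_configs(n_molecules, density, n_configs, seed, params)
  samples <- list()
  kv <- NULL
  for (g in seq_len(n_configs)) {
    config <- configs[[g]]
    mols <- detect_water_topology(config)
    frames <- build_frames(config, mols)
    if (is.null(kv)) kv <- kspace_vectors(config$cell, params$sigma)
    for (f in fields) {
      E_app <- c(0, 0, f)
      w <- oracle_wannier(config, E_app, params, mols, frames, kv)
      Fr <- if (forces) oracle_forces(config, w, E_app, params, mols) else NULL
      samples[[length(samples) + 1L]] <-
        structure(list(config = config, applied_field = E_app, wannier = w,
                       forces = Fr, group_id = g),
                  class = "training_sample")
    }
  }
  structure(samples, class = "oracle_dataset", params = params, seed = seed)
}

#' @export
print.oracle_dataset <- function(x, ...) {
  groups <- length(unique(vapply(x, `[[`, integer(1), "group_id")))
  cat(sprintf("synthetic training set: %d samples in %d groups\n",
              length(x), groups))
  print(attr(x, "params"))
  invisible(x)
}
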