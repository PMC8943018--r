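## NVT molecular dynamics: velocity-Verlet with Berendsen velocity rescaling,
## constant-E or constant-D electrostatic boundary conditions, driven either
## by the classical synthetic force field or by a fitted model.

#' Molecular dynamics settings
#'
#' @param steps Number of integration steps.
#' @param dt Timestep (fs), default 0.5.
#' @param temperature Target temperature (K).
#' @param tau Berendsen time constant (fs); `Inf` disables the thermostat.
#' @param stride Snapshot interval (steps).
#' @param seed Seed for initial velocities.
#' @param equilibration Steps discarded before snapshots are recorded.
#' @return List of class `md_config`.
#' @export
md_config <- function(steps = 1000, dt = 0.5, temperature = 300, tau = 100,
                      stride = 50, seed = 1, equilibration = 0) {
  stopifnot(dt > 0, temperature > 0, steps >= 1)
  structure(list(steps = steps, dt = dt, temperature = temperature,
                 tau = tau, stride = stride, seed = seed,
                 equilibration = equilibration),
            class = "md_config")
}

#' Classical synthetic-water force engine
#'
#' The molecular-dynamics face of the synthetic oracle: flexible molecules
#' (harmonic bonds and angle), O-O Lennard-Jones, and point-charge
#' electrostatics with the Gaussian split evaluated by Ewald summation
#' (short-range real-space part plus reciprocal-space `v1` part;
#' intramolecular Coulomb excluded). For dynamics the four centres are tied
#' to the nuclei by fixed linear combinations (two bond centres along the
#' O-H bonds, two combined lone-pair centres on the back bisector, chosen to
#' reproduce the rigid-geometry dipole of `params`), so centre forces are
#' redistributed to the nuclei exactly and the force field is conservative.
#'
#' With `long_range = FALSE` the reciprocal-space part and the uniform-field
#' coupling are dropped: the purely short-range (Gaussian-truncated) control
#' used to demonstrate missing dielectric screening.
#'
#' @param params [oracle_params()].
#' @param config0 Initial [atomic_config()] (fixes topology and cell).
#' @param boundary `list(E = <vec>)` or `list(D = <vec>)` (V/Angstrom).
#' @param long_range Include the long-range (`v1`) part.
#' @param sigma_ff Ewald split length for the force field (Angstrom);
#'   default `min(L)/6` capped at 2.0.
#' @param k_tol Reciprocal-space truncation tolerance for the force field.
#' @return Engine closure `function(positions)` returning `forces`,
#'   `dipoles`, `P`, `E_unif`, `energy`.
#' @export
oracle_md_engine <- function(params, config0, boundary = list(E = c(0, 0, 0)),
                             long_range = TRUE, sigma_ff = NULL,
                             k_tol = 1e-8) {
  cl <- config0$cell
  L <- cl$lengths
  V <- cell_volume(cl)
  mols <- detect_water_topology(config0)
  n_mol <- nrow(mols)
  n_at <- nrow(config0$positions)
  constant_d <- !is.null(boundary$D)
  if (is.null(sigma_ff)) sigma_ff <- min(min(L) / 6, 2.1)
  rcut <- min(3 * sigma_ff, min(L) / 2 * 0.999)
  kv <- if (long_range) kspace_vectors(cl, sigma_ff, tol = k_tol) else NULL
  fb <- params$bond_offset / params$r_oh
  span <- 2 * params$r_oh * cos(params$theta * pi / 180 / 2)
  g <- (1 - 2 * fb - params$mu_rigid / span) / 4
  mu_coef <- 1 - 2 * fb - 4 * g
  q <- c(ifelse(config0$species == "O", 6, 1), rep(-2, 4 * n_mol))
  molid_at <- integer(n_at)
  for (i in seq_len(n_mol))
    molid_at[c(mols$o[i], mols$h1[i], mols$h2[i])] <- i
  molid <- c(molid_at, rep(seq_len(n_mol), times = 4))
  qeff_O <- -2 + 4 * fb + 8 * g
  qeff_H <- 1 - 2 * fb - 4 * g
  th0 <- params$theta * pi / 180
  intra_mode <- if (long_range) 0L else 1L
  spec_int <- as.integer(config0$species == "O")

  function(pos) {
    O <- pos[mols$o, , drop = FALSE]
    d1 <- minimum_image(pos[mols$h1, , drop = FALSE] - O, cl)
    d2 <- minimum_image(pos[mols$h2, , drop = FALSE] - O, cl)
    cb1 <- O + fb * d1
    cb2 <- O + fb * d2
    clp <- O + g * (d1 + d2)
    qpos <- rbind(pos, cb1, cb2, clp, clp)
    rs <- realspace_coulomb_cpp(qpos, q, molid, L, sigma_ff, rcut, KE,
                                intra_mode)
    U <- rs$energy
    Fq <- rs$forces
    if (long_range) {
      ks <- kspace_coulomb_cpp(qpos, q, kv$n, kv$L, kv$coeff)
      U <- U + ks$energy
      Fq <- Fq + ks$forces
    }
    dip <- mu_coef * (d1 + d2)
    P <- colSums(dip) / V
    # the uniform-field coupling is part of the long-range physics: the
    # short-range-only control has no field coupling of any kind
    E_unif <- if (!long_range) c(0, 0, 0)
              else if (constant_d) as.numeric(boundary$D) - 4 * pi * KE * P
              else as.numeric(boundary$E)
    # redistribute charge-site forces to the nuclei
    F <- Fq[seq_len(n_at), , drop = FALSE]
    Fb1 <- Fq[n_at + seq_len(n_mol), , drop = FALSE]
    Fb2 <- Fq[n_at + n_mol + seq_len(n_mol), , drop = FALSE]
    Fl <- Fq[n_at + 2 * n_mol + seq_len(n_mol), , drop = FALSE] +
      Fq[n_at + 3 * n_mol + seq_len(n_mol), , drop = FALSE]
    F[mols$o, ] <- F[mols$o, ] + (1 - fb) * (Fb1 + Fb2) + (1 - 2 * g) * Fl
    F[mols$h1, ] <- F[mols$h1, ] + fb * Fb1 + g * Fl
    F[mols$h2, ] <- F[mols$h2, ] + fb * Fb2 + g * Fl
    if (long_range || any(E_unif != 0)) {
      qeff <- ifelse(config0$species == "O", qeff_O, qeff_H)
      F <- F + outer(qeff, E_unif)
    }
    lj <- lj_cpp(O, L, params$lj_eps, params$lj_sigma, min(L) / 2 * 0.999)
    U <- U + lj$energy
    F[mols$o, ] <- F[mols$o, ] + lj$forces
    wl <- r12_walls_cpp(pos, spec_int, molid_at, L, params$wall_oh,
                        params$wall_hh, min(4, min(L) / 2 * 0.999))
    U <- U + wl$energy
    F <- F + wl$forces
    # intramolecular harmonic bonds and angle
    r1 <- sqrt(rowSums(d1^2)); r2 <- sqrt(rowSums(d2^2))
    u1 <- d1 / r1; u2 <- d2 / r2
    U <- U + sum(0.5 * params$bond_k * ((r1 - params$r_oh)^2 +
                                          (r2 - params$r_oh)^2))
    fb1 <- -params$bond_k * (r1 - params$r_oh) * u1
    fb2 <- -params$bond_k * (r2 - params$r_oh) * u2
    cth <- pmin(1, pmax(-1, rowSums(u1 * u2)))
    th <- acos(cth)
    sth <- pmax(sqrt(1 - cth^2), 1e-8)
    U <- U + sum(0.5 * params$angle_k * (th - th0)^2)
    coef <- params$angle_k * (th - th0) / sth
    fa1 <- coef / r1 * (u2 - cth * u1)
    fa2 <- coef / r2 * (u1 - cth * u2)
    F[mols$h1, ] <- F[mols$h1, ] + fb1 + fa1
    F[mols$h2, ] <- F[mols$h2, ] + fb2 + fa2
    F[mols$o, ] <- F[mols$o, ] - fb1 - fb2 - fa1 - fa2
    list(forces = F, dipoles = dip, P = P, E_unif = E_unif, energy = U)
  }
}

#' Model-driven force engine
#'
#' Runs the self-consistent loop at each call (warm-started from the
#' previous step's centres) and evaluates the short- plus long-range force
#' networks.
#'
#' @param model A fitted [scfnn()] model with force networks.
#' @param config0 Initial configuration (fixes topology and cell).
#' @param boundary Electrostatic boundary condition.
#' @return Engine closure as in [oracle_md_engine()].
#' @export
scfnn_md_engine <- function(model, config0, boundary = list(E = c(0, 0, 0))) {
  mols <- detect_water_topology(config0)
  kv <- kspace_vectors(config0$cell, model$sigma)
  V <- cell_volume(config0$cell)
  prev_w <- NULL
  function(pos) {
    config <- atomic_config(config0$species, pos, config0$cell)
    frames <- build_frames(config, mols)
    geom <- pair_geometry(config)
    scf <- scf_solve(config, model, boundary, warm_start = prev_w,
                     mols = mols, frames = frames, kv = kv, geom = geom)
    prev_w <<- scf$wannier$positions
    dip <- molecular_dipoles(config, scf$wannier, mols)
    list(forces = scfnn_forces(config, model, scf, mols, frames, geom),
         dipoles = dip, P = colSums(dip) / V,
         E_unif = scf$field$uniform, energy = NA_real_,
         scf_iterations = scf$iterations)
  }
}

#' Relax a configuration by capped gradient descent
#'
#' Moves atoms along the engine forces with a per-step displacement cap,
#' halving the step whenever the energy rises. Used to remove the strain of
#' generated packings before dynamics.
#'
#' @param config An [atomic_config()].
#' @param engine Force engine.
#' @param steps Maximum descent steps.
#' @param max_step Displacement cap per step (Angstrom).
#' @param ftol Stop when the maximum force falls below this (eV/Angstrom).
#' @return The relaxed [atomic_config()].
#' @export
relax_config <- function(config, engine, steps = 200, max_step = 0.05,
                         ftol = 0.5) {
  pos <- config$positions
  ev <- engine(pos)
  gamma <- 0.02
  for (s in seq_len(steps)) {
    fmax <- max(abs(ev$forces))
    if (fmax < ftol) break
    step <- ev$forces * gamma
    too_big <- sqrt(rowSums(step^2)) > max_step
    if (any(too_big))
      step[too_big, ] <- step[too_big, ] * max_step /
        sqrt(rowSums(step[too_big, , drop = FALSE]^2))
    cand <- pos + step
    ev2 <- engine(cand)
    if (ev2$energy <= ev$energy) {
      pos <- cand; ev <- ev2
      gamma <- min(gamma * 1.2, 0.1)
    } else {
      gamma <- gamma / 2
      if (gamma < 1e-5) break
    }
  }
  atomic_config(config$species, pos, config$cell)
}

kinetic_temperature <- function(v, mass, ndof) {
  ke <- 0.5 * sum(mass * rowSums(v^2)) / ACC_CONV
  2 * ke / (ndof * KB)
}

#' Run NVT molecular dynamics
#'
#' Velocity-Verlet integration with Berendsen velocity rescaling
#' (`lambda = sqrt(1 + dt/tau (T0/T - 1))`, clamped to [0.8, 1.25]).
#' Initial velocities are Maxwell-Boltzmann at the target temperature with
#' the centre-of-mass motion removed. Aborts if non-bonded atoms approach
#' closer than 0.5 Angstrom.
#'
#' @param config Initial [atomic_config()].
#' @param engine Force engine ([oracle_md_engine()] or [scfnn_md_engine()]).
#' @param mdconf An [md_config()].
#' @return Object of class `scfnn_trajectory`: snapshot list (`positions`,
#'   `dipoles`, `P`, `E_unif`, `temperature`, `step`), topology, cell and
#'   settings; `final_state` holds positions and velocities for restarts.
#' @export
run_nvt <- function(config, engine, mdconf = md_config()) {
  pos <- config$positions
  n <- nrow(pos)
  mass <- ATOMIC_MASSES[config$species]
  mols <- detect_water_topology(config)
  set.seed(mdconf$seed)
  v <- matrix(stats::rnorm(3 * n), n, 3) *
    sqrt(KB * mdconf$temperature * ACC_CONV / mass)
  v <- sweep(v, 2, colSums(v * mass) / sum(mass), "-")
  ndof <- 3 * n - 3
  ev <- engine(pos)
  a <- ev$forces * ACC_CONV / mass
  frames <- list()
  temps <- numeric(0)
  if (mdconf$stride > mdconf$steps)
    warning("snapshot stride larger than the number of steps: ",
            "at most one snapshot will be recorded")
  for (step in seq_len(mdconf$steps)) {
    v <- v + 0.5 * mdconf$dt * a
    pos <- pos + mdconf$dt * v
    ev <- engine(pos)
    a <- ev$forces * ACC_CONV / mass
    v <- v + 0.5 * mdconf$dt * a
    Tinst <- kinetic_temperature(v, mass, ndof)
    temps <- c(temps, Tinst)
    if (is.finite(mdconf$tau) && Tinst > 0) {
      lam <- sqrt(max(0, 1 + mdconf$dt / mdconf$tau *
                        (mdconf$temperature / Tinst - 1)))
      v <- v * min(max(lam, 0.8), 1.25)
    }
    if (step %% 200 == 0) check_overlap(pos, mols, config$cell)
    if (step > mdconf$equilibration && step %% mdconf$stride == 0) {
      frames[[length(frames) + 1L]] <-
        list(positions = pos, dipoles = ev$dipoles, P = ev$P,
             E_unif = ev$E_unif, temperature = Tinst, step = step)
    }
  }
  structure(list(frames = frames, species = config$species, mols = mols,
                 cell = config$cell, mdconf = mdconf,
                 temperature_series = temps,
                 final_state = list(positions = pos, velocities = v)),
            class = "scfnn_trajectory")
}

check_overlap <- function(pos, mols, cl) {
  n <- nrow(pos)
  if (n > 600 || n < 4) return(invisible())
  molid <- integer(n)
  for (i in seq_len(nrow(mols)))
    molid[c(mols$o[i], mols$h1[i], mols$h2[i])] <- i
  d <- minimum_image(pos[rep(1:n, n), ] - pos[rep(1:n, each = n), ], cl)
  dd <- matrix(sqrt(rowSums(d^2)), n, n)
  same <- outer(molid, molid, "==")
  dd[same] <- Inf
  if (min(dd) < 0.5)
    stop(sprintf("non-bonded atom overlap (%.2f A < 0.5 A); simulation unstable",
                 min(dd)))
  invisible()
}

#' @export
print.scfnn_trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d snapshots of %d atoms (dt = %.2f fs, stride %d)\n",
              length(x$frames), length(x$species), x$mdconf$dt,
              x$mdconf$stride))
  if (length(x$temperature_series))
    cat(sprintf("mean temperature: %.1f K\n", mean(x$temperature_series)))
  invisible(x)
}

#' Finite-field run at constant displacement field
#'
#' @param config Initial configuration.
#' @param params [oracle_params()] for the classical engine, or a fitted
#'   [scfnn()] model.
#' @param D Displacement field magnitude along z (V/Angstrom), or a length-3
#'   vector.
#' @param mdconf An [md_config()].
#' @param ... Passed to the engine factory.
#' @return A `scfnn_trajectory`; snapshots record the polarization for the
#'   P(D) response curve.
#' @export
run_finite_d <- function(config, params, D, mdconf = md_config(), ...) {
  Dvec <- if (length(D) == 1) c(0, 0, D) else as.numeric(D)
  engine <- if (inherits(params, "scfnn"))
    scfnn_md_engine(params, config, boundary = list(D = Dvec))
  else oracle_md_engine(params, config, boundary = list(D = Dvec), ...)
  run_nvt(config, engine, mdconf)
}

#' Build a liquid-vapour slab from a bulk configuration
#'
#' Extends the cell along z by a vacuum region on both sides, keeping
#' molecules whole across the old boundary.
#'
#' @param config Bulk [atomic_config()].
#' @param vacuum Vacuum length added on each side (Angstrom).
#' @return An [atomic_config()] with the enlarged cell.
#' @export
make_slab <- function(config, vacuum) {
  if (vacuum == 0) {
    warning("zero vacuum: returning the configuration unchanged")
    return(config)
  }
  if (vacuum < 4.2)
    warning("vacuum thinner than the long-range split length; ",
            "slab electrostatics will be degraded")
  mols <- detect_water_topology(config)
  pos <- config$positions
  Lz <- config$cell$lengths[3]
  for (i in seq_len(nrow(mols))) {
    o <- pos[mols$o[i], ]
    o[3] <- o[3] - Lz * floor(o[3] / Lz)  # wrap O into [0, Lz)
    for (h in c(mols$h1[i], mols$h2[i]))
      pos[h, ] <- o + minimum_image(pos[h, ] - pos[mols$o[i], ], config$cell)
    pos[mols$o[i], ] <- o
  }
  pos[, 3] <- pos[, 3] + vacuum
  newcell <- cell(c(config$cell$lengths[1:2], Lz + 2 * vacuum),
                  config$cell$periodic)
  atomic_config(config$species, pos, newcell)
}
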