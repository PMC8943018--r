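## Structural and dielectric observables. All dielectric formulas are carried
## in the Gaussian convention adapted to the package's internal units
## (Angstrom, e0, eV, fields in V/Angstrom): every occurrence of "4 pi"
## multiplying a polarization or dipole-fluctuation term carries one factor
## of the Coulomb constant ke = 14.399645 eV A/e0^2, which is the single
## documented conversion between the SI-style printed forms and the internal
## ones.

traj_frame_dipoles <- function(traj) lapply(traj$frames, `[[`, "dipoles")

#' Radial distribution function
#'
#' Shell-normalized pair histogram between two species, averaged over
#' snapshots; tends to 1 at large r in a uniform fluid.
#'
#' @param traj A `scfnn_trajectory`.
#' @param pair Character pair of species, e.g. `c("O", "O")`.
#' @param dr Bin width (Angstrom).
#' @param r_max Maximum distance; must not exceed half the shortest box edge.
#' @return data.frame of class `correlation_curve` with columns `r`, `value`
#'   (g(r)), `count`.
#' @export
rdf <- function(traj, pair = c("O", "O"), dr = 0.05, r_max = NULL) {
  L <- traj$cell$lengths
  if (is.null(r_max)) r_max <- min(L) / 2
  if (r_max > min(L) / 2 + 1e-9)
    stop("r_max exceeds half the shortest box edge")
  ia <- which(traj$species == pair[1])
  ib <- which(traj$species == pair[2])
  same <- pair[1] == pair[2]
  edges <- seq(0, r_max, by = dr)
  counts <- numeric(length(edges) - 1)
  V <- cell_volume(traj$cell)
  for (fr in traj$frames) {
    pa <- fr$positions[ia, , drop = FALSE]
    pb <- fr$positions[ib, , drop = FALSE]
    d <- minimum_image(pb[rep(seq_along(ib), each = length(ia)), ] -
                         pa[rep(seq_along(ia), length(ib)), ], traj$cell)
    r <- sqrt(rowSums(d^2))
    if (same) r <- r[r > 1e-9]
    counts <- counts + graphics::hist(r[r < r_max], breaks = edges,
                                      plot = FALSE)$counts
  }
  nf <- length(traj$frames)
  shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  npairs <- if (same) length(ia) * (length(ib) - 1) else
    length(ia) * length(ib)
  gr <- counts / (nf * npairs * shell / V)
  structure(data.frame(r = edges[-length(edges)] + dr / 2, value = gr,
                       count = counts),
            class = c("correlation_curve", "data.frame"),
            abscissa = "r [A]", observable = sprintf("g_%s%s(r)",
                                                     pair[1], pair[2]))
}

#' Longitudinal polarization correlation in reciprocal space
#'
#' `chi_zz(k) = <|sum_l p_lz exp(-i k z_l)|^2> / V` for wavevectors along z,
#' algebraically identical to the molecular double sum with the longitudinal
#' projector; `z_l` is the oxygen position of molecule l. Only wavevectors
#' commensurate with the box (`k = 2 pi n / Lz`, integer n >= 1) are allowed.
#'
#' @param traj A `scfnn_trajectory` (snapshots carry molecular dipoles).
#' @param n_k Integer vector of mode numbers.
#' @return `correlation_curve` with columns `k` (1/Angstrom), `value`
#'   (e0^2/Angstrom), `se` (standard error over snapshots).
#' @export
chi_zz <- function(traj, n_k = 1:8) {
  if (any(n_k < 1) || any(n_k != round(n_k)))
    stop("wavevectors must be k = 2 pi n / Lz with integer n >= 1")
  Lz <- traj$cell$lengths[3]
  V <- cell_volume(traj$cell)
  k <- 2 * pi * n_k / Lz
  o_idx <- traj$mols$o
  vals <- matrix(0, length(traj$frames), length(k))
  for (f in seq_along(traj$frames)) {
    fr <- traj$frames[[f]]
    pz <- fr$dipoles[, 3]
    z <- fr$positions[o_idx, 3]
    for (j in seq_along(k)) {
      s <- sum(pz * exp(-1i * k[j] * z))
      vals[f, j] <- Mod(s)^2 / V
    }
  }
  structure(data.frame(k = k, value = colMeans(vals),
                       se = apply(vals, 2, stats::sd) /
                         sqrt(nrow(vals))),
            class = c("correlation_curve", "data.frame"),
            abscissa = "k [1/A]", observable = "chi_zz(k)")
}

#' Homogeneous longitudinal polarization fluctuation (the k = 0 member)
#'
#' In the constant-D ensemble the homogeneous longitudinal mode is not
#' quenched by the depolarization field, so `<M_z^2>/V` is the k -> 0 member
#' of the longitudinal correlation of [chi_zz()] and tends to the same
#' screening limit. At desk-scale box sizes the smallest nonzero wavevector
#' can lie above the screening crossover, making this the only accessible
#' point in the true k -> 0 regime.
#'
#' @param traj A `scfnn_trajectory` from a constant-D run (D along z).
#' @param blocks Number of blocks for the standard-error estimate.
#' @return List: `value` (e0^2/Angstrom), `se` (block standard error).
#' @export
chi_zero <- function(traj, blocks = 5) {
  V <- cell_volume(traj$cell)
  mz2 <- vapply(traj$frames, function(f) sum(f$dipoles[, 3])^2,
                numeric(1)) / V
  bl <- split(mz2, cut(seq_along(mz2), blocks, labels = FALSE))
  bm <- vapply(bl, mean, numeric(1))
  list(value = mean(mz2), se = stats::sd(bm) / sqrt(length(bm)))
}

#' Consistency of the chi_zz(k -> 0) plateau with the dielectric constant
#'
#' Compares the small-k plateau of the longitudinal correlation with the
#' limit `kB T (eps - 1) / (4 pi ke eps)` implied by dielectric screening.
#' When a [chi_zero()] estimate from a constant-D run is supplied it anchors
#' the plateau at k = 0 proper; otherwise the mean of the lowest-k curve
#' points is used.
#'
#' @param chi A curve from [chi_zz()].
#' @param epsilon Dielectric constant from an independent route.
#' @param temperature Temperature (K).
#' @param n_plateau Number of lowest-k points averaged.
#' @param chi0 Optional [chi_zero()] result used as the k -> 0 anchor.
#' @return List: `ratio` (plateau / limit), `se`, `plateau`, `limit`,
#'   `flagged` (TRUE when no k = 0 anchor is given and the lowest-k points
#'   are strictly monotone, i.e. no plateau is identifiable).
#' @export
chi_limit_consistency <- function(chi, epsilon, temperature = 300,
                                  n_plateau = 3, chi0 = NULL) {
  stopifnot(nrow(chi) >= n_plateau)
  lim <- KB * temperature * (epsilon - 1) / (4 * pi * KE * epsilon)
  if (!is.null(chi0)) {
    return(list(ratio = chi0$value / lim, se = chi0$se / lim,
                plateau = chi0$value, limit = lim, flagged = FALSE))
  }
  low <- chi[seq_len(n_plateau), ]
  dv <- diff(low$value)
  flagged <- all(dv > 0) || all(dv < 0)
  plateau <- mean(low$value)
  se <- sqrt(sum(low$se^2)) / n_plateau
  list(ratio = if (flagged) NA_real_ else plateau / lim,
       se = se / lim, plateau = plateau, limit = lim, flagged = flagged)
}

#' Distance-resolved Kirkwood factor
#'
#' `G_K(r) = <mu_1 . M_1(r)> / <|mu|^2>` where `M_1(r)` is the total dipole
#' within distance r of the origin molecule, including the origin molecule
#' itself, averaged over all origins and snapshots.
#'
#' @param traj A `scfnn_trajectory`.
#' @param r_grid Radii (Angstrom); must stay below half the shortest edge.
#' @return `correlation_curve` with columns `r`, `value`; attribute `mu_sq`
#'   holds the ensemble mean squared dipole (e0^2 A^2).
#' @export
kirkwood_gk <- function(traj, r_grid = seq(0.5, 6, by = 0.25)) {
  if (max(r_grid) > min(traj$cell$lengths) / 2 + 1e-9)
    stop("r grid extends beyond half the box")
  o_idx <- traj$mols$o
  n <- length(o_idx)
  acc <- numeric(length(r_grid))
  musq <- 0
  nfr <- length(traj$frames)
  for (fr in traj$frames) {
    o <- fr$positions[o_idx, , drop = FALSE]
    mu <- fr$dipoles
    musq <- musq + mean(rowSums(mu^2))
    d <- minimum_image(o[rep(1:n, n), ] - o[rep(1:n, each = n), ],
                       traj$cell)
    dd <- matrix(sqrt(rowSums(d^2)), n, n)  # dd[j, i] = |r_j - r_i|
    dots <- mu %*% t(mu)                    # dots[i, j] = mu_i . mu_j
    for (g in seq_along(r_grid)) {
      within <- t(dd) <= r_grid[g]
      acc[g] <- acc[g] + mean(rowSums(dots * within))
    }
  }
  musq <- musq / nfr
  structure(data.frame(r = r_grid, value = acc / (nfr * musq)),
            class = c("correlation_curve", "data.frame"),
            abscissa = "r [A]", observable = "G_K(r)", mu_sq = musq)
}

#' Composite Kirkwood factor from E = 0 and D = 0 ensembles
#'
#' `G_Kc(r) = (2 G_K(r)_{E=0} + G_K(r)_{D=0}) / 3`; its plateau is the
#' Kirkwood factor entering the dielectric relation.
#'
#' @param gk_E0,gk_D0 Curves from [kirkwood_gk()] on matching r grids.
#' @param window Plateau window (Angstrom range) for the `g_K` estimate.
#' @return `correlation_curve`; attributes `g_K` (plateau mean), `g_K_se`
#'   and `mu_sq` (average of the two ensembles).
#' @export
composite_gk <- function(gk_E0, gk_D0, window = c(4.5, 6)) {
  if (!isTRUE(all.equal(gk_E0$r, gk_D0$r))) stop("r grids do not match")
  v <- (2 * gk_E0$value + gk_D0$value) / 3
  sel <- gk_E0$r >= window[1] & gk_E0$r <= window[2]
  if (!any(sel)) stop("plateau window contains no grid points")
  out <- structure(data.frame(r = gk_E0$r, value = v),
                   class = c("correlation_curve", "data.frame"),
                   abscissa = "r [A]", observable = "G_Kc(r)")
  attr(out, "g_K") <- mean(v[sel])
  attr(out, "g_K_se") <- stats::sd(v[sel]) / sqrt(sum(sel))
  attr(out, "mu_sq") <- mean(c(attr(gk_E0, "mu_sq"), attr(gk_D0, "mu_sq")))
  out
}

#' Dielectric constant from the Kirkwood relation for polarizable molecules
#'
#' Solves `4 pi ke beta N mu^2 g_K / V = (eps-1)(2 eps+1)/eps -
#' (eps_inf-1)(2 eps_inf+1)/eps_inf` for eps (positive root of the
#' quadratic; the discriminant is always positive).
#'
#' @param g_K Kirkwood factor.
#' @param N Number of molecules.
#' @param V Volume (Angstrom^3).
#' @param temperature Temperature (K).
#' @param mu_sq Mean squared molecular dipole (e0^2 Angstrom^2).
#' @param epsilon_infinity High-frequency dielectric constant.
#' @return Dielectric constant (>= 1 for non-negative couplings).
#' @export
epsilon_from_gk <- function(g_K, N, V, temperature = 300, mu_sq,
                            epsilon_infinity = 1) {
  stopifnot(is.finite(g_K), epsilon_infinity >= 1)
  beta <- 1 / (KB * temperature)
  A <- 4 * pi * KE * beta * N * mu_sq * g_K / V
  B <- (epsilon_infinity - 1) * (2 * epsilon_infinity + 1) / epsilon_infinity
  s <- 1 + A + B
  eps <- (s + sqrt(s^2 + 8)) / 4
  if (A + B < 0 && eps < 1)
    warning("negative orientational coupling: eps < 1 returned")
  eps
}

# forward form of the same relation (used for round-trip identities)
gk_from_epsilon <- function(epsilon, N, V, temperature = 300, mu_sq,
                            epsilon_infinity = 1) {
  beta <- 1 / (KB * temperature)
  B <- (epsilon_infinity - 1) * (2 * epsilon_infinity + 1) / epsilon_infinity
  A <- (epsilon - 1) * (2 * epsilon + 1) / epsilon - B
  A * V / (4 * pi * KE * beta * N * mu_sq)
}

#' Dielectric constant from the polarization response to D
#'
#' Least-squares line through the mean polarization at each displacement
#' field; in the Gaussian convention `dP/dD = (1 - 1/eps) / (4 pi ke)`.
#'
#' @param D Vector of displacement-field magnitudes (V/Angstrom).
#' @param trajs List of `scfnn_trajectory` runs at those D values (or a
#'   numeric vector of pre-averaged P_z values).
#' @return List: `slope`, `epsilon`, `P` (mean P_z per run), `se` (standard
#'   errors), `nonlinearity` (max |residual| / max |fit|).
#' @export
fit_p_vs_d <- function(D, trajs) {
  if (length(D) < 2) stop("need at least two D values")
  if (is.numeric(trajs)) {
    P <- trajs; se <- rep(NA_real_, length(P))
  } else {
    P <- vapply(trajs, function(tr)
      mean(vapply(tr$frames, function(f) f$P[3], numeric(1))), numeric(1))
    se <- vapply(trajs, function(tr) {
      x <- vapply(tr$frames, function(f) f$P[3], numeric(1))
      stats::sd(x) / sqrt(length(x))
    }, numeric(1))
  }
  fit <- stats::lm(P ~ D)
  slope <- stats::coef(fit)[["D"]]
  eps <- 1 / (1 - 4 * pi * KE * slope)
  nl <- if (length(D) > 2)
    max(abs(stats::resid(fit))) / max(abs(stats::fitted(fit))) else 0
  list(slope = slope, epsilon = eps, P = P, se = se, nonlinearity = nl)
}

#' High-frequency dielectric constant from the electronic response
#'
#' Applies uniform fields to fixed nuclear configurations, lets only the
#' electronic degrees of freedom (the centres) respond, and fits the induced
#' polarization: `eps_inf = 1 + 4 pi ke dP/dE`.
#'
#' @param predict_P Function `(config, E_vector) -> P vector` returning the
#'   polarization with nuclei fixed (e.g. wrapping [predict.scfnn()] or
#'   [oracle_wannier()]).
#' @param configs List of configurations (averaged over).
#' @param E Field magnitudes along z (V/Angstrom).
#' @return List: `epsilon_infinity`, `slope`, `P` (mean P_z per field),
#'   `nonlinearity`.
#' @export
fit_eps_infinity <- function(predict_P, configs, E = c(0, 0.1, 0.2)) {
  P <- vapply(E, function(e) {
    mean(vapply(configs, function(cf) predict_P(cf, c(0, 0, e))[3],
                numeric(1)))
  }, numeric(1))
  fit <- stats::lm(P ~ E)
  slope <- stats::coef(fit)[["E"]]
  nl <- if (length(E) > 2)
    max(abs(stats::resid(fit))) / max(1e-300, max(abs(stats::fitted(fit))))
  else 0
  list(epsilon_infinity = 1 + 4 * pi * KE * slope, slope = slope, P = P,
       nonlinearity = nl)
}

#' Distribution of molecular dipole moments
#'
#' @param traj A `scfnn_trajectory` (or a list with `frames`).
#' @param breaks Histogram breaks (Debye) or a bin count.
#' @return List: `mids`, `density` (normalized to unit integral), `mean`
#'   (Debye).
#' @export
dipole_distribution <- function(traj, breaks = 40) {
  mu <- unlist(lapply(traj$frames, function(f)
    sqrt(rowSums(f$dipoles^2)))) * DEBYE_PER_EA
  h <- graphics::hist(mu, breaks = breaks, plot = FALSE)
  list(mids = h$mids, density = h$density, mean = mean(mu))
}

#' Interfacial density and orientation profiles
#'
#' Bins molecules by the z coordinate of their oxygen: mass density (g/cm^3)
#' and the mean cosine of the angle between the molecular dipole and the
#' +z surface normal. Empty bins are reported as NA.
#'
#' @param traj A slab `scfnn_trajectory` (normal along z).
#' @param dz Bin width (Angstrom).
#' @return data.frame: `z`, `density`, `cos_theta`, `count`.
#' @export
interface_profiles <- function(traj, dz = 1) {
  Lz <- traj$cell$lengths[3]
  A <- prod(traj$cell$lengths[1:2])
  edges <- seq(0, Lz, by = dz)
  nb <- length(edges) - 1
  cnt <- numeric(nb); cs <- numeric(nb)
  o_idx <- traj$mols$o
  for (fr in traj$frames) {
    z <- fr$positions[o_idx, 3] %% Lz
    mu <- fr$dipoles
    ct <- mu[, 3] / pmax(sqrt(rowSums(mu^2)), 1e-12)
    b <- pmin(pmax(floor(z / dz) + 1, 1), nb)
    for (i in seq_along(b)) {
      cnt[b[i]] <- cnt[b[i]] + 1
      cs[b[i]] <- cs[b[i]] + ct[i]
    }
  }
  nfr <- length(traj$frames)
  m_h2o <- sum(ATOMIC_MASSES[c("O", "H", "H")])
  dens <- cnt / nfr * m_h2o / (A * dz) / 0.6022140757
  data.frame(z = edges[-length(edges)] + dz / 2, density = dens,
             cos_theta = ifelse(cnt > 0, cs / cnt, NA_real_), count = cnt)
}
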