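## Coulomb split, point-charge assembly, effective field, dipoles.

erfc_ <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)
erf_ <- function(x) 1 - erfc_(x)

#' Gaussian split of the Coulomb potential
#'
#' `v0(r) = erfc(r/sigma)/r` is the short-range (Gaussian-truncated) part and
#' `v1(r) = erf(r/sigma)/r` the slowly varying long-range part; their sum is
#' the bare `1/r`. `v1` is regular at the origin, `v1(0) = 2/(sigma sqrt(pi))`.
#' Values are in 1/Angstrom; multiply by `ke * q` for an energy.
#'
#' @param r Distances (Angstrom), `r >= 0`.
#' @param sigma Split length (Angstrom), default 4.2 (8 Bohr).
#' @return Numeric vector.
#' @export
v0 <- function(r, sigma = 4.2) {
  stopifnot(sigma > 0)
  if (any(r < 0)) stop("r must be non-negative")
  erfc_(r / sigma) / r
}

#' @rdname v0
#' @export
v1 <- function(r, sigma = 4.2) {
  stopifnot(sigma > 0)
  if (any(r < 0)) stop("r must be non-negative")
  out <- ifelse(r == 0, 2 / (sigma * sqrt(pi)), erf_(r / sigma) / r)
  out
}

#' Set of Wannier centres
#'
#' Four centres per molecule, each carrying charge -2 e0.
#'
#' @param positions (4 n_mol) x 3 matrix of centre positions (Angstrom, lab
#'   frame), grouped by molecule.
#' @param molecule Integer vector mapping each centre to its molecule.
#' @param label Optional character labels (`bond1`, `bond2`, `lone1`, `lone2`).
#' @return Object of class `wannier_set`.
#' @export
wannier_set <- function(positions, molecule,
                        label = rep(c("bond1", "bond2", "lone1", "lone2"),
                                    length.out = nrow(positions))) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, nrow(positions) == length(molecule))
  if (any(table(molecule) != 4))
    stop("each molecule must have exactly 4 Wannier centres")
  structure(list(positions = positions, molecule = as.integer(molecule),
                 label = label),
            class = "wannier_set")
}

#' Assemble the point-charge representation of a configuration
#'
#' Valence nuclear charges (+6 e0 on O, +1 e0 on H) plus four -2 e0 Wannier
#' centres per molecule; the total is neutral.
#'
#' @param config An [atomic_config()].
#' @param wannier A [wannier_set()] with 4 centres per molecule.
#' @return List of class `charge_set`: `positions`, `q`, and `parent` (the
#'   atom index each charge is attached to; centres ride with their oxygen).
#' @export
assemble_charges <- function(config, wannier) {
  sp <- config$species
  if (!all(sp %in% c("O", "H"))) stop("non-water species in configuration")
  n_mol <- sum(sp == "O")
  if (nrow(wannier$positions) != 4 * n_mol)
    stop("wannier set must contain exactly 4 centres per molecule")
  qa <- ifelse(sp == "O", 6, 1)
  o_idx <- which(sp == "O")
  parent <- c(seq_along(sp), o_idx[wannier$molecule])
  structure(list(positions = rbind(config$positions, wannier$positions),
                 q = c(qa, rep(-2, nrow(wannier$positions))),
                 parent = parent),
            class = "charge_set")
}

#' Reciprocal-space lattice vectors for the long-range kernel
#'
#' Enumerates k-vectors of the orthorhombic cell with
#' `exp(-k^2 sigma^2 / 4) >= tol`; because the Fourier transform of `v1`
#' carries this Gaussian factor, the reciprocal sum alone converges and no
#' real-space Ewald term is needed. The k = 0 term is excluded.
#'
#' @param cell An [cell()] object (all axes periodic).
#' @param sigma Split length (Angstrom).
#' @param tol Gaussian damping factor below which shells are dropped.
#' @return List with `k` (n_k x 3 matrix, 1/Angstrom) and `coeff`
#'   (`4 pi ke exp(-k^2 sigma^2/4) / (V k^2)`).
#' @export
kspace_vectors <- function(cell, sigma = 4.2, tol = 1e-12) {
  if (!all(cell$periodic)) stop("reciprocal-space sum requires a fully periodic cell")
  L <- cell$lengths
  kcut <- 2 * sqrt(-log(tol)) / sigma
  nmax <- ceiling(kcut * L / (2 * pi))
  g <- as.matrix(expand.grid(nx = -nmax[1]:nmax[1], ny = -nmax[2]:nmax[2],
                             nz = -nmax[3]:nmax[3]))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  k <- sweep(g, 2, 2 * pi / L, "*")
  k2 <- rowSums(k^2)
  damp <- exp(-k2 * sigma^2 / 4)
  keep <- damp >= tol
  V <- cell_volume(cell)
  list(k = k[keep, , drop = FALSE],
       n = matrix(as.integer(g[keep, , drop = FALSE]), ncol = 3),
       L = L,
       coeff = 4 * pi * KE * damp[keep] / (V * k2[keep]))
}

#' Effective long-range field at a set of points
#'
#' The effective field is the external field plus the field generated by the
#' instantaneous charge density through the slowly varying kernel `v1`,
#' evaluated as a reciprocal-space lattice sum under tinfoil boundary
#' conditions (no k = 0 / surface-dipole term). Self-contributions vanish
#' smoothly because `grad v1 -> 0` as `r -> 0`, so all charges are included.
#'
#' @param charges A `charge_set` from [assemble_charges()] (or any list with
#'   `positions` and `q`).
#' @param eval_points m x 3 matrix of evaluation points (Angstrom).
#' @param cell An [cell()] object.
#' @param E_ext Uniform external field vector (V/Angstrom).
#' @param sigma Split length (Angstrom).
#' @param tol Reciprocal-space truncation tolerance (see [kspace_vectors()]).
#' @param kv Optional precomputed [kspace_vectors()] result.
#' @return List of class `effective_field` with `site_fields` (m x 3,
#'   V/Angstrom) and `uniform` (the applied uniform component).
#' @export
effective_field <- function(charges, eval_points, cell, E_ext = c(0, 0, 0),
                            sigma = 4.2, tol = 1e-12, kv = NULL) {
  eval_points <- matrix(as.numeric(eval_points), ncol = 3)
  if (is.null(kv)) kv <- kspace_vectors(cell, sigma, tol)
  if (length(charges$q) == 0L) {
    E <- matrix(rep(E_ext, each = nrow(eval_points)), ncol = 3)
  } else {
    E <- kspace_field_cpp(charges$positions, charges$q, eval_points,
                          kv$n, kv$L, kv$coeff)
    E <- sweep(E, 2, E_ext, "+")
  }
  structure(list(site_fields = E, uniform = as.numeric(E_ext)),
            class = "effective_field")
}

#' Molecular dipole moments
#'
#' Dipole of each molecule from its 7 point charges (O, 2 H, 4 centres),
#' measured relative to the oxygen with minimum-image displacements; the
#' molecule is neutral, so the dipole is origin-independent.
#'
#' @param config An [atomic_config()].
#' @param wannier A [wannier_set()].
#' @param mols Topology from [detect_water_topology()] (computed if missing).
#' @return n_mol x 3 matrix of dipoles in e0 Angstrom (multiply by
#'   `scfnn_constants()$debye_per_eA` for Debye).
#' @export
molecular_dipoles <- function(config, wannier, mols = NULL) {
  if (is.null(mols)) mols <- detect_water_topology(config)
  n <- nrow(mols)
  p <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    o <- config$positions[mols$o[i], ]
    dh1 <- minimum_image(config$positions[mols$h1[i], ] - o, config$cell)
    dh2 <- minimum_image(config$positions[mols$h2[i], ] - o, config$cell)
    cw <- wannier$positions[wannier$molecule == i, , drop = FALSE]
    dcw <- minimum_image(sweep(cw, 2, o, "-"), config$cell)
    p[i, ] <- dh1 + dh2 - 2 * colSums(dcw)
  }
  p
}

#' Cell polarization
#'
#' Molecular (itinerant-free) polarization: sum of molecular dipoles divided
#' by the cell volume.
#'
#' @inheritParams molecular_dipoles
#' @return Length-3 vector in e0/Angstrom^2.
#' @export
cell_polarization <- function(config, wannier, mols = NULL) {
  colSums(molecular_dipoles(config, wannier, mols)) / cell_volume(config$cell)
}
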