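#' Orthorhombic simulation cell
#'
#' @param lengths Numeric length-3 vector of edge lengths (Angstrom). A single
#'   number is recycled to a cubic cell.
#' @param periodic Logical length-3 vector of per-axis periodic flags.
#' @return Object of class `scfnn_cell`.
#' @export
cell <- function(lengths, periodic = c(TRUE, TRUE, TRUE)) {
  if (length(lengths) == 1) lengths <- rep(lengths, 3)
  stopifnot(length(lengths) == 3, length(periodic) == 3)
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("cell edge lengths must be positive and finite")
  structure(list(lengths = as.numeric(lengths), periodic = as.logical(periodic)),
            class = "scfnn_cell")
}

#' @export
print.scfnn_cell <- function(x, ...) {
  cat(sprintf("orthorhombic cell: %.4f x %.4f x %.4f A, periodic: %s\n",
              x$lengths[1], x$lengths[2], x$lengths[3],
              paste(ifelse(x$periodic, "T", "F"), collapse = "")))
  invisible(x)
}

cell_volume <- function(cell) prod(cell$lengths)

#' Minimum-image convention for displacement vectors
#'
#' Reduces each periodic component of a displacement to the interval
#' `(-L/2, L/2]`. Non-periodic axes are left unchanged.
#'
#' @param d Displacement: numeric length-3 vector or an n x 3 matrix.
#' @param cell An [cell()] object.
#' @return Same shape as `d`.
#' @export
minimum_image <- function(d, cell) {
  vec <- is.null(dim(d))
  m <- if (vec) matrix(d, ncol = 3) else d
  for (a in 1:3) {
    if (cell$periodic[a]) {
      L <- cell$lengths[a]
      m[, a] <- m[, a] - L * ceiling(m[, a] / L - 0.5)
    }
  }
  if (vec) drop(m) else m
}

#' Atomic configuration
#'
#' @param species Character vector of element symbols ("O"/"H"), one per atom.
#' @param positions n x 3 matrix of Cartesian coordinates (Angstrom).
#' @param cell An [cell()] object.
#' @return Object of class `atomic_config`.
#' @export
atomic_config <- function(species, positions, cell) {
  positions <- as.matrix(positions)
  stopifnot(is.character(species), nrow(positions) == length(species),
            ncol(positions) == 3, inherits(cell, "scfnn_cell"))
  structure(list(species = species, positions = positions, cell = cell),
            class = "atomic_config")
}

#' @export
print.atomic_config <- function(x, ...) {
  tab <- table(x$species)
  cat(sprintf("atomic configuration: %d atoms (%s)\n", length(x$species),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  print(x$cell)
  invisible(x)
}

#' Detect water molecules from O/H positions
#'
#' Assigns every hydrogen to its nearest oxygen under the minimum-image
#' convention. Errors if an H has no O within `bond_cutoff`, if the nearest O
#' is ambiguous (two O equidistant), or if any O ends up with a number of
#' bonded H different from two.
#'
#' @param config An [atomic_config()].
#' @param bond_cutoff O-H bond cutoff in Angstrom (default 1.25, well above
#'   the ~0.97 A covalent bond and below hydrogen-bond distances).
#' @return data.frame with columns `o`, `h1`, `h2` (atom indices, `h1 < h2`),
#'   one row per molecule.
#' @export
detect_water_topology <- function(config, bond_cutoff = 1.25) {
  sp <- config$species
  if (!all(sp %in% c("O", "H")))
    stop("only O/H species are supported for water topology detection")
  o_idx <- which(sp == "O")
  h_idx <- which(sp == "H")
  if (length(h_idx) != 2 * length(o_idx))
    stop("atom counts inconsistent with pure water (need 2 H per O)")
  assigned <- integer(length(h_idx))
  for (i in seq_along(h_idx)) {
    d <- minimum_image(sweep(config$positions[o_idx, , drop = FALSE], 2,
                             config$positions[h_idx[i], ], "-"), config$cell)
    r <- sqrt(rowSums(d^2))
    j <- which.min(r)
    if (r[j] > bond_cutoff)
      stop(sprintf("H atom %d has no O within the bond cutoff (%.2f A)",
                   h_idx[i], bond_cutoff))
    if (sum(abs(r - r[j]) < 1e-9) > 1)
      stop(sprintf("H atom %d is equidistant from two O atoms", h_idx[i]))
    assigned[i] <- j
  }
  mols <- lapply(seq_along(o_idx), function(j) {
    hs <- h_idx[assigned == j]
    if (length(hs) != 2)
      stop(sprintf("O atom %d has %d bonded H (expected 2)", o_idx[j],
                   length(hs)))
    sort(hs)
  })
  data.frame(o = o_idx,
             h1 = vapply(mols, `[`, integer(1), 1),
             h2 = vapply(mols, `[`, integer(1), 2))
}

#' Local molecular frame of a water molecule
#'
#' The frame is anchored on the oxygen: the y-axis points along the O-H1 bond
#' (H1 = bonded hydrogen with the smaller atom index), the z-axis is normal to
#' the molecular plane (`OH1 x OH2`), and x completes a right-handed triad.
#'
#' @param mol One-row data.frame (or list) with `o`, `h1`, `h2` atom indices.
#' @param config An [atomic_config()].
#' @return List with `origin` (O position) and `axes` (3 x 3 orthonormal
#'   matrix; rows are the local x, y, z axes in lab coordinates).
#' @export
build_local_frame <- function(mol, config) {
  o <- config$positions[mol$o, ]
  u1 <- minimum_image(config$positions[mol$h1, ] - o, config$cell)
  u2 <- minimum_image(config$positions[mol$h2, ] - o, config$cell)
  y <- u1 / sqrt(sum(u1^2))
  zc <- c(u1[2] * u2[3] - u1[3] * u2[2],
          u1[3] * u2[1] - u1[1] * u2[3],
          u1[1] * u2[2] - u1[2] * u2[1])
  nz <- sqrt(sum(zc^2))
  if (nz < 1e-8 * sqrt(sum(u1^2)) * sqrt(sum(u2^2)))
    stop("degenerate molecular plane: O-H bonds are parallel")
  z <- zc / nz
  x <- c(y[2] * z[3] - y[3] * z[2],
         y[3] * z[1] - y[1] * z[3],
         y[1] * z[2] - y[2] * z[1])
  list(origin = o, axes = rbind(x = x, y = y, z = z))
}

#' Frames for every molecule in a configuration
#'
#' @param config An [atomic_config()].
#' @param mols Topology from [detect_water_topology()].
#' @return List of frames as returned by [build_local_frame()].
#' @export
build_frames <- function(config, mols) {
  lapply(seq_len(nrow(mols)), function(i) build_local_frame(mols[i, ], config))
}

#' Transform vectors between lab and local frames
#'
#' `to_local()` expresses lab-frame vectors in the frame's basis;
#' `to_lab()` is the inverse. Both act on a length-3 vector or the rows of an
#' n x 3 matrix. Pure rotations: origins are not involved.
#'
#' @param v Length-3 vector or n x 3 matrix.
#' @param frame Frame from [build_local_frame()].
#' @return Same shape as `v`.
#' @export
to_local <- function(v, frame) {
  if (is.null(dim(v))) return(unname(drop(frame$axes %*% v)))
  out <- v %*% t(frame$axes)
  dimnames(out) <- dimnames(v)
  out
}

#' @rdname to_local
#' @export
to_lab <- function(v, frame) {
  if (is.null(dim(v))) return(unname(drop(t(frame$axes) %*% v)))
  out <- v %*% frame$axes
  dimnames(out) <- dimnames(v)
  out
}
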