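## Symmetry functions evaluated in local molecular frames: the scalar radial
## (type-2) and axis-projected angular (type-4) functions for the short-range
## networks, and the field-weighted radial functions for the linear long-range
## networks. Parameter grids are data (inst/extdata/descriptor_params.yaml),
## not code.

#' Behler cosine cutoff function
#'
#' `fc(r) = 0.5 (cos(pi r / r_c) + 1)` for `r <= r_c`, else 0; both the value
#' and the slope vanish at `r_c`.
#'
#' @param r Distances (Angstrom).
#' @param r_c Radial cutoff (Angstrom).
#' @return Numeric vector in `[0, 1]`.
#' @export
cutoff_fn <- function(r, r_c) {
  ifelse(r <= r_c, 0.5 * (cos(pi * r / r_c) + 1), 0)
}

#' Load descriptor parameter sets
#'
#' Reads the ordered symmetry-function records for the four networks from a
#' YAML file (lengths in Bohr, Gaussian widths in 1/Bohr^2, converted to
#' Angstrom units on load) and computes a content hash that trained models
#' carry so that descriptor/network mismatches are detected.
#'
#' @param path YAML file; default is the parameter set shipped with the
#'   package (cutoff 12 Bohr, log-spaced Gaussian widths).
#' @return Object of class `descriptor_params`: list with `r_c` (Angstrom),
#'   per-network record data.frames, input counts, and `hash`.
#' @export
descriptor_params <- function(path = system.file("extdata",
                                                 "descriptor_params.yaml",
                                                 package = "scfnn")) {
  raw <- yaml::read_yaml(path)
  r_c <- raw$cutoff_bohr * BOHR
  nets <- lapply(raw$networks, function(recs) {
    df <- do.call(rbind, lapply(recs, function(r) {
      data.frame(type = r$type,
                 species = if (is.null(r$species)) "all" else r$species,
                 eta = if (is.null(r$eta)) 0 else r$eta / BOHR^2,
                 rs = if (is.null(r$rs)) 0 else r$rs * BOHR,
                 zeta = if (is.null(r$zeta)) 1 else r$zeta,
                 lambda = if (is.null(r$lambda)) 1 else r$lambda)
    }))
    rownames(df) <- NULL
    df
  })
  counts <- vapply(nets, function(df)
    sum(ifelse(df$type == "g2", 1L, 3L)), integer(1))
  obj <- list(r_c = r_c, networks = nets, n_inputs = counts)
  obj$hash <- descriptor_hash(obj)
  class(obj) <- "descriptor_params"
  obj
}

# deterministic rolling hash of the parameter content
descriptor_hash <- function(params) {
  s <- paste(c(sprintf("%.12g", params$r_c),
               unlist(lapply(params$networks, function(df)
                 apply(df, 1, paste, collapse = ",")))), collapse = ";")
  b <- utf8ToInt(s)
  h <- 17
  for (x in b) h <- (h * 31 + x) %% 2147483647
  sprintf("%08x", h)
}

#' @export
print.descriptor_params <- function(x, ...) {
  cat(sprintf("descriptor parameter sets (r_c = %.4f A, hash %s):\n",
              x$r_c, x$hash))
  for (nm in names(x$networks))
    cat(sprintf("  %-7s %3d inputs (%d records)\n", nm, x$n_inputs[[nm]],
                nrow(x$networks[[nm]])))
  invisible(x)
}

# Minimum-image pair geometry for one configuration: displacement array
# d[i, j, ] = r_j - r_i and the distance matrix.
pair_geometry <- function(config) {
  pos <- config$positions
  n <- nrow(pos)
  disp <- array(0, c(n, n, 3))
  for (a in 1:3) {
    d <- outer(rep(1, n), pos[, a]) - outer(pos[, a], rep(1, n))
    if (config$cell$periodic[a]) {
      L <- config$cell$lengths[a]
      d <- d - L * ceiling(d / L - 0.5)
    }
    disp[, , a] <- d
  }
  dist <- sqrt(disp[, , 1]^2 + disp[, , 2]^2 + disp[, , 3]^2)
  list(disp = disp, dist = dist)
}

# Scalar type-2 sum for one center.
g2_sum <- function(r, eta, rs, r_c) {
  if (length(r) == 0) return(0)
  sum(exp(-eta * (r - rs)^2) * cutoff_fn(r, r_c))
}

# Axis-projected type-4 values (one per local axis) for one center.
g4_sum <- function(d, r, axes, zeta, lambda, eta, r_c) {
  if (length(r) == 0) return(c(0, 0, 0))
  w <- exp(-eta * r^2) * cutoff_fn(r, r_c)
  cosang <- (d %*% t(axes)) / r  # n x 3, cos(theta) to each axis
  as.numeric(2^(1 - zeta) * colSums((1 + lambda * cosang)^zeta * w))
}

# Field-weighted radial vector sum, expressed in the local frame.
eg2_sum <- function(d, r, E, axes, eta, rs, r_c) {
  if (length(r) == 0) return(c(0, 0, 0))
  w <- exp(-eta * (r - rs)^2) * cutoff_fn(r, r_c)
  as.numeric(axes %*% colSums(E * w))
}

#' Evaluate one network's descriptor set for a list of centers
#'
#' Low-level driver shared by the molecule-centred (networks 1S/1L) and
#' atom-centred (networks 2S/2L) descriptor builders. Scalar records (`g2`)
#' contribute one input; vector records (`g4`, `eg2`) contribute three, one
#' per local axis, in x/y/z order.
#'
#' @param config An [atomic_config()].
#' @param centers Integer vector of central atom indices.
#' @param axes_list List of 3 x 3 local axis matrices, one per center.
#' @param table One network's record data.frame from [descriptor_params()].
#' @param r_c Radial cutoff (Angstrom).
#' @param fields Optional n_atoms x 3 matrix of per-atom effective fields
#'   (V/Angstrom); required when the table contains `eg2` records. For `eg2`
#'   the central atom itself is included in the sum (its field is the leading
#'   term of the local response).
#' @param geom Optional precomputed [pair_geometry()] result.
#' @return length(centers) x n_inputs numeric matrix.
#' @export
evaluate_descriptors <- function(config, centers, axes_list, table, r_c,
                                 fields = NULL, geom = NULL) {
  if (is.null(geom)) geom <- pair_geometry(config)
  needs_field <- any(table$type == "eg2")
  if (needs_field) {
    if (is.null(fields)) stop("eg2 descriptors require per-atom fields")
    fields <- as.matrix(fields)
    if (nrow(fields) != nrow(config$positions))
      stop("field/atom count mismatch")
  }
  sp <- config$species
  n_in <- sum(ifelse(table$type == "g2", 1L, 3L))
  out <- matrix(0, length(centers), n_in)
  for (ci in seq_along(centers)) {
    c_at <- centers[ci]
    axes <- axes_list[[ci]]
    r_all <- geom$dist[c_at, ]
    within <- r_all <= r_c
    col <- 1L
    for (k in seq_len(nrow(table))) {
      rec <- table[k, ]
      self_ok <- rec$type == "eg2"
      sel <- within & (seq_along(sp) != c_at | self_ok)
      if (rec$species != "all") sel <- sel & sp == rec$species
      j <- which(sel)
      d <- geom$disp[c_at, j, , drop = FALSE]
      dim(d) <- c(length(j), 3)
      r <- r_all[j]
      if (rec$type == "g2") {
        out[ci, col] <- g2_sum(r, rec$eta, rec$rs, r_c)
        col <- col + 1L
      } else if (rec$type == "g4") {
        out[ci, col:(col + 2L)] <-
          g4_sum(d, r, axes, rec$zeta, rec$lambda, rec$eta, r_c)
        col <- col + 3L
      } else {  # eg2
        out[ci, col:(col + 2L)] <-
          eg2_sum(d, r, fields[j, , drop = FALSE], axes, rec$eta, rec$rs, r_c)
        col <- col + 3L
      }
    }
  }
  out
}

#' Descriptor matrices for the four networks
#'
#' Builds the full set of network inputs for one configuration: per-molecule
#' inputs for networks 1S (scalar geometry) and 1L (field-weighted), and
#' per-atom inputs for 2S and 2L. Molecule-centred descriptors use the frame
#' of [build_local_frame()] anchored on the oxygen; hydrogen-centred
#' descriptors reuse the parent molecule's axes with the origin translated to
#' the hydrogen.
#'
#' @param config An [atomic_config()].
#' @param params A [descriptor_params()] object.
#' @param mols,frames Topology and frames (computed if missing).
#' @param fields Optional n_atoms x 3 field matrix; when NULL only the
#'   geometry-based sets (`net1S`, `net2S_*`) are built.
#' @param which Character vector of network names to build.
#' @param geom Optional precomputed [pair_geometry()].
#' @return Named list of descriptor matrices; per-atom sets are split into
#'   `O` and `H` blocks with `idx` giving atom indices.
#' @export
build_descriptor_sets <- function(config, params, mols = NULL, frames = NULL,
                                  fields = NULL,
                                  which = names(params$networks),
                                  geom = NULL) {
  if (is.null(mols)) mols <- detect_water_topology(config)
  if (is.null(frames)) frames <- build_frames(config, mols)
  if (is.null(geom)) geom <- pair_geometry(config)
  sp <- config$species
  mol_of_atom <- integer(length(sp))
  for (i in seq_len(nrow(mols)))
    mol_of_atom[c(mols$o[i], mols$h1[i], mols$h2[i])] <- i
  axes_of_atom <- lapply(mol_of_atom, function(m) frames[[m]]$axes)
  o_centers <- mols$o
  o_axes <- lapply(frames, `[[`, "axes")
  out <- list()
  for (nm in which) {
    tab <- params$networks[[nm]]
    if (nm %in% c("net1S", "net1L")) {
      if (nm == "net1L" && is.null(fields)) next
      out[[nm]] <- evaluate_descriptors(config, o_centers, o_axes, tab,
                                        params$r_c, fields, geom)
    } else if (nm %in% c("net2S_O", "net2S_H")) {
      el <- if (nm == "net2S_O") "O" else "H"
      idx <- which(sp == el)
      m <- evaluate_descriptors(config, idx, axes_of_atom[idx], tab,
                                params$r_c, NULL, geom)
      out[[nm]] <- structure(m, idx = idx)
    } else if (nm == "net2L") {
      if (is.null(fields)) next
      for (el in c("O", "H")) {
        idx <- which(sp == el)
        m <- evaluate_descriptors(config, idx, axes_of_atom[idx], tab,
                                  params$r_c, fields, geom)
        out[[paste0("net2L_", el)]] <- structure(m, idx = idx)
      }
    }
  }
  out
}
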