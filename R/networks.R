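## Forward evaluation of the four networks. The S-networks are small tanh
## multilayer perceptrons; the L-networks are strictly linear maps with no
## bias, so zero field gives exactly zero response.

NETWORK_ARCHS <- list(
  `1S` = list(hidden = c(24, 16), n_out = 12, linear = FALSE),
  `1L` = list(hidden = integer(0), n_out = 12, linear = TRUE),
  `2S` = list(hidden = c(25, 25), n_out = 3, linear = FALSE),
  `2L` = list(hidden = integer(0), n_out = 3, linear = TRUE)
)

#' Create a network model
#'
#' Architectures: 1S maps 36 molecular symmetry functions through hidden
#' layers of 24 and 16 tanh nodes to the 12 local coordinates of the four
#' Wannier centres; 1L maps the 36 field-weighted inputs linearly (no hidden
#' layer, no bias) to the 12 centre displacements; 2S maps 30 (O) or 27 (H)
#' inputs through two hidden layers of 25 tanh nodes to the local force
#' vector; 2L maps the 36 field-weighted inputs linearly to the local force.
#'
#' @param arch One of "1S", "1L", "2S", "2L".
#' @param n_in Number of inputs.
#' @param element For per-element networks ("O" or "H").
#' @param hash Descriptor-parameter hash the model is tied to.
#' @param seed Seed for weight initialization.
#' @param scale Initial weight scale (multiplied by `1/sqrt(fan_in)`).
#' @return Object of class `scfnn_network`.
#' @export
network_init <- function(arch, n_in, element = NULL, hash = "",
                         seed = 1, scale = 0.1) {
  spec <- NETWORK_ARCHS[[arch]]
  if (is.null(spec)) stop("unknown architecture tag: ", arch)
  sizes <- c(n_in, spec$hidden, spec$n_out)
  old <- .Random.seed_save()
  set.seed(seed)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1)) {
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1], -1, 1) *
                       scale / sqrt(sizes[l]), sizes[l], sizes[l + 1])
    b[l] <- if (spec$linear) list(NULL) else list(rep(0, sizes[l + 1]))
  }
  .Random.seed_restore(old)
  structure(list(arch = arch, element = element, sizes = sizes,
                 W = W, b = b, linear = spec$linear, hash = hash,
                 x_center = rep(0, n_in), x_scale = rep(1, n_in),
                 y_center = rep(0, spec$n_out), y_scale = rep(1, spec$n_out)),
            class = "scfnn_network")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.scfnn_network <- function(x, ...) {
  cat(sprintf("network %s%s: %s%s\n", x$arch,
              if (is.null(x$element)) "" else paste0(" (", x$element, ")"),
              paste(x$sizes, collapse = " -> "),
              if (x$linear) " [linear, no bias]" else " [tanh]"))
  invisible(x)
}

#' Forward pass of a network
#'
#' @param net A `scfnn_network`.
#' @param X n x n_in input matrix.
#' @return n x n_out output matrix. Linear networks bypass input/output
#'   standardization so that the map is exactly homogeneous.
#' @export
network_forward <- function(net, X) {
  X <- matrix(as.numeric(X), ncol = net$sizes[1])
  if (net$linear) {
    H <- X
    for (W in net$W) H <- H %*% W
    return(H)
  }
  H <- sweep(sweep(X, 2, net$x_center, "-"), 2, net$x_scale, "/")
  nl <- length(net$W)
  for (l in seq_len(nl)) {
    H <- sweep(H %*% net$W[[l]], 2, net$b[[l]], "+")
    if (l < nl) H <- tanh(H)
  }
  sweep(sweep(H, 2, net$y_scale, "*"), 2, net$y_center, "+")
}

check_hash <- function(net, params) {
  if (nzchar(net$hash) && nzchar(params$hash) && net$hash != params$hash)
    stop("descriptor-parameter hash mismatch: network was trained with a ",
         "different parameter set")
}

#' Evaluate network 1S: Wannier centres of the short-range system
#'
#' @param desc n_mol x 36 matrix of molecular symmetry functions.
#' @param net The trained 1S network.
#' @param frames Per-molecule frames.
#' @param params Descriptor parameters (hash check); optional.
#' @return [wannier_set()] with centres in the lab frame (4 per molecule,
#'   local outputs rotated by the frame and shifted to the oxygen origin).
#' @export
eval_1s <- function(desc, net, frames, params = NULL) {
  if (!is.null(params)) check_hash(net, params)
  out <- network_forward(net, desc)
  n <- nrow(out)
  pos <- matrix(0, 4 * n, 3)
  for (i in seq_len(n)) {
    loc <- matrix(out[i, ], 4, 3, byrow = TRUE)
    pos[(4 * i - 3):(4 * i), ] <- sweep(to_lab(loc, frames[[i]]), 2,
                                        frames[[i]]$origin, "+")
  }
  wannier_set(pos, rep(seq_len(n), each = 4))
}

#' Evaluate network 1L: field-induced centre displacements
#'
#' Strictly linear in the field descriptors; zero field gives exactly zero
#' displacement.
#'
#' @param desc n_mol x 36 matrix of field-weighted symmetry functions.
#' @inheritParams eval_1s
#' @return (4 n_mol) x 3 matrix of lab-frame displacements (Angstrom).
#' @export
eval_1l <- function(desc, net, frames, params = NULL) {
  if (!is.null(params)) check_hash(net, params)
  out <- network_forward(net, desc)
  n <- nrow(out)
  dpos <- matrix(0, 4 * n, 3)
  for (i in seq_len(n)) {
    loc <- matrix(out[i, ], 4, 3, byrow = TRUE)
    dpos[(4 * i - 3):(4 * i), ] <- to_lab(loc, frames[[i]])
  }
  dpos
}

# shared driver for the per-element force networks
eval_force_nets <- function(descs, nets, frames_of_atom, n_atoms,
                            params = NULL) {
  F <- matrix(0, n_atoms, 3)
  for (el in names(descs)) {
    m <- descs[[el]]
    idx <- attr(m, "idx")
    net <- nets[[el]]
    if (!is.null(params)) check_hash(net, params)
    out <- network_forward(net, m)
    for (jj in seq_along(idx)) {
      F[idx[jj], ] <- to_lab(out[jj, ], frames_of_atom[[idx[jj]]])
    }
  }
  F
}

#' Evaluate network 2S: short-range forces on the nuclei
#'
#' @param descs Named list (`O`, `H`) of per-atom descriptor matrices, each
#'   carrying an `idx` attribute of atom indices.
#' @param nets Named list of trained per-element 2S networks.
#' @param frames_of_atom List of frames, one per atom (local force output is
#'   rotated to the lab frame).
#' @param n_atoms Total atom count.
#' @param params Descriptor parameters (hash check); optional.
#' @return n_atoms x 3 force matrix (eV/Angstrom).
#' @export
eval_2s <- function(descs, nets, frames_of_atom, n_atoms, params = NULL) {
  eval_force_nets(descs, nets, frames_of_atom, n_atoms, params)
}

#' Evaluate network 2L: long-range (field-induced) forces
#'
#' Strictly linear in the field descriptors.
#' @inheritParams eval_2s
#' @return n_atoms x 3 force matrix (eV/Angstrom).
#' @export
eval_2l <- function(descs, nets, frames_of_atom, n_atoms, params = NULL) {
  eval_force_nets(descs, nets, frames_of_atom, n_atoms, params)
}
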