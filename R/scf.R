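## Self-consistent coupling of Wannier-centre positions and the effective
## long-range field: the centres source the field through v1, and the linear
## network moves the centres in response, iterated to a fixed point.

#' Self-consistent solution of centres and effective field
#'
#' Starting from the short-range (network 1S) centre positions, iterates
#' `w -> w_GT + 1L(field(w))` until the largest centre displacement between
#' successive iterations falls below `tol`. Under constant displacement field
#' the uniform field component is recomputed from the instantaneous
#' polarization each iteration (`E = D - 4 pi ke P`, Gaussian convention in
#' the package's eV/Angstrom/e0 units); under constant E it is fixed
#' (tinfoil boundary conditions).
#'
#' @param config An [atomic_config()].
#' @param model A fitted [scfnn()] object (or any list with `net1s`, `net1l`,
#'   `descriptors`, `sigma`).
#' @param boundary `list(E = <vector>)` for constant applied field or
#'   `list(D = <vector>)` for constant displacement field (V/Angstrom).
#' @param tol Convergence tolerance on the maximum centre displacement
#'   (Angstrom); default 2.6e-4.
#' @param max_iter Maximum iterations (default 50).
#' @param mixing Linear mixing fraction in (0, 1]; 1 is plain fixed-point.
#' @param warm_start Optional (4 n_mol) x 3 matrix of centre positions used
#'   as the initial guess instead of the short-range centres.
#' @param mols,frames,kv,geom Optional precomputed topology, frames,
#'   reciprocal vectors and pair geometry.
#' @return List of class `scf_result`: `wannier`, `field` (effective field at
#'   the nuclei), `gt_wannier`, `iterations`, `history` (max displacement per
#'   iteration), `converged`, `P` (cell polarization).
#' @export
scf_solve <- function(config, model, boundary = list(E = c(0, 0, 0)),
                      tol = 2.6e-4, max_iter = 50, mixing = 1,
                      warm_start = NULL, mols = NULL, frames = NULL,
                      kv = NULL, geom = NULL) {
  stopifnot(mixing > 0, mixing <= 1)
  constant_d <- !is.null(boundary$D)
  if (!constant_d && is.null(boundary$E))
    stop("boundary must specify either E or D")
  if (is.null(mols)) mols <- detect_water_topology(config)
  if (is.null(frames)) frames <- build_frames(config, mols)
  if (is.null(geom)) geom <- pair_geometry(config)
  if (is.null(kv)) kv <- kspace_vectors(config$cell, model$sigma)
  dp <- model$descriptors
  n <- nrow(mols)
  mol_rep <- rep(seq_len(n), each = 4)

  d1s <- build_descriptor_sets(config, dp, mols, frames, which = "net1S",
                               geom = geom)$net1S
  w_gt <- eval_1s(d1s, model$net1s, frames, dp)
  w_pos <- if (is.null(warm_start)) w_gt$positions else as.matrix(warm_start)

  history <- numeric(0)
  grow <- 0L
  field <- NULL
  for (it in seq_len(max_iter)) {
    w <- wannier_set(w_pos, mol_rep)
    if (constant_d) {
      P <- cell_polarization(config, w, mols)
      E_unif <- as.numeric(boundary$D) - 4 * pi * KE * P
    } else {
      E_unif <- as.numeric(boundary$E)
    }
    ch <- assemble_charges(config, w)
    field <- effective_field(ch, config$positions, config$cell,
                             E_ext = E_unif, sigma = model$sigma, kv = kv)
    d1l <- build_descriptor_sets(config, dp, mols, frames,
                                 fields = field$site_fields,
                                 which = "net1L", geom = geom)$net1L
    delta <- eval_1l(d1l, model$net1l, frames, dp)
    w_new <- w_gt$positions + delta
    w_next <- (1 - mixing) * w_pos + mixing * w_new
    disp <- max(abs(w_next - w_pos))
    history <- c(history, disp)
    w_pos <- w_next
    if (disp < tol) break
    if (it > 1 && disp > history[it - 1]) grow <- grow + 1L else grow <- 0L
    if (grow >= 3)
      stop(errorCondition(
        "self-consistent iteration diverges; try a smaller mixing fraction",
        history = history, class = c("scfnn_scf_divergence", "error",
                                     "condition")))
    if (it == max_iter)
      stop(errorCondition(
        sprintf("self-consistent loop did not converge in %d iterations (last change %.3g A)",
                max_iter, disp),
        history = history, class = c("scfnn_scf_nonconvergence", "error",
                                     "condition")))
  }
  w <- wannier_set(w_pos, mol_rep)
  structure(list(wannier = w, field = field, gt_wannier = w_gt,
                 iterations = length(history), history = history,
                 converged = TRUE,
                 P = cell_polarization(config, w, mols)),
            class = "scf_result")
}

#' @export
print.scf_result <- function(x, ...) {
  cat(sprintf("SCF converged in %d iteration(s); last change %.3g A\n",
              x$iterations, x$history[length(x$history)]))
  cat(sprintf("polarization: (%.5g, %.5g, %.5g) e0/A^2\n",
              x$P[1], x$P[2], x$P[3]))
  invisible(x)
}

#' Forces from a converged SCF state
#'
#' Short-range forces (network 2S on geometric descriptors) plus the
#' field-induced forces (network 2L on field-weighted descriptors evaluated
#' with the converged effective field).
#'
#' @param config An [atomic_config()].
#' @param model A fitted [scfnn()] object.
#' @param scf An `scf_result` from [scf_solve()].
#' @param mols,frames,geom Optional precomputed pieces.
#' @return n_atoms x 3 force matrix (eV/Angstrom).
#' @export
scfnn_forces <- function(config, model, scf, mols = NULL, frames = NULL,
                         geom = NULL) {
  if (is.null(mols)) mols <- detect_water_topology(config)
  if (is.null(frames)) frames <- build_frames(config, mols)
  if (is.null(geom)) geom <- pair_geometry(config)
  dp <- model$descriptors
  sets <- build_descriptor_sets(config, dp, mols, frames,
                                fields = scf$field$site_fields,
                                which = c("net2S_O", "net2S_H", "net2L"),
                                geom = geom)
  mol_of_atom <- integer(nrow(config$positions))
  for (i in seq_len(nrow(mols)))
    mol_of_atom[c(mols$o[i], mols$h1[i], mols$h2[i])] <- i
  frames_of_atom <- lapply(mol_of_atom, function(m) frames[[m]])
  n_at <- nrow(config$positions)
  Fs <- eval_2s(list(O = sets$net2S_O, H = sets$net2S_H), model$net2s,
                frames_of_atom, n_at, dp)
  Fl <- eval_2l(list(O = sets$net2L_O, H = sets$net2L_H), model$net2l,
                frames_of_atom, n_at, dp)
  Fs + Fl
}
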