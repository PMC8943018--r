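#' Fit a self-consistent field neural network water model
#'
#' Two-stage fit of the four networks from a grouped training set of water
#' configurations with reference Wannier centres and forces at several
#' applied field strengths. Stage one fits the linear long-range networks
#' (1L for centre displacements, 2L for forces) to pairwise field
#' differences; their predictions are then subtracted from the references to
#' expose the short-range (Gaussian-truncated) system, and stage two fits the
#' short-range networks (1S, 2S) to that.
#'
#' @param data A list of grouped training samples, e.g. from
#'   [generate_dataset()] or [read_training_xyz()]. Each sample holds a
#'   configuration, applied field, reference centres, optional forces, and a
#'   `group_id` linking field strengths of the same nuclei.
#' @param descriptors A [descriptor_params()] object.
#' @param sigma Long-range split length (Angstrom), default 4.2 (8 Bohr).
#' @param split Fraction of groups used for training (rest is the test set).
#' @param seed Seed controlling the split and weight initialization.
#' @param forces Fit the force networks (Module 2) as well.
#' @param epochs,lr,patience Optimizer settings for the short-range networks
#'   (see [mlp_train()]).
#' @param verbose Print stage progress.
#' @return Object of class `scfnn` with components `net1s`, `net1l`, `net2s`,
#'   `net2l`, `descriptors`, `sigma`, `metrics`, `split_seed`. Methods:
#'   [print.scfnn()], [summary.scfnn()], [coef.scfnn()], [predict.scfnn()],
#'   [simulate.scfnn()], [plot.scfnn()].
#' @export
scfnn <- function(data, descriptors = descriptor_params(), sigma = 4.2,
                  split = 2 / 3, seed = 1, forces = TRUE, epochs = 2000,
                  lr = 2e-3, patience = 30, verbose = FALSE) {
  cl <- match.call()
  parts <- split_dataset(data, ratio = split, seed = seed)
  if (verbose)
    message(sprintf("stage 1: fitting long-range networks on %d samples",
                    length(parts$train)))
  lr_fit <- train_long(parts$train, parts$test, descriptors, sigma)
  if (verbose)
    message("stage 2: subtracting long-range response, fitting ",
            "short-range networks")
  gt_tr <- extract_gt_targets(parts$train, lr_fit$net1l, lr_fit$net2l,
                              descriptors, sigma, features = lr_fit$features)
  gt_te <- if (length(parts$test))
    extract_gt_targets(parts$test, lr_fit$net1l, lr_fit$net2l, descriptors,
                       sigma, features = lr_fit$features_test) else NULL
  sr_fit <- train_short(gt_tr, gt_te, descriptors, sigma, seed = seed,
                        epochs = epochs, lr = lr, patience = patience,
                        forces = forces)
  structure(list(net1s = sr_fit$net1s, net1l = lr_fit$net1l,
                 net2s = sr_fit$net2s, net2l = lr_fit$net2l,
                 descriptors = descriptors, sigma = sigma,
                 metrics = c(lr_fit$metrics, sr_fit$metrics),
                 group_spread = gt_tr$group_spread,
                 n_train = length(parts$train), n_test = length(parts$test),
                 split_seed = seed, call = cl),
            class = "scfnn")
}

#' @export
print.scfnn <- function(x, ...) {
  cat("self-consistent field neural network water model\n")
  cat(sprintf("  split sigma: %.2f A; descriptor hash: %s\n", x$sigma,
              x$descriptors$hash))
  cat(sprintf("  trained on %d samples (%d held out)\n", x$n_train, x$n_test))
  has_forces <- !is.null(x$net2s)
  cat(sprintf("  networks: 1S, 1L%s\n",
              if (has_forces) ", 2S (O/H), 2L (O/H)" else
                " (force networks not fitted)"))
  if (!is.null(x$metrics$test_mae_wannier))
    cat(sprintf("  held-out MAE, field-induced centre displacements: %.3g A\n",
                x$metrics$test_mae_wannier))
  invisible(x)
}

#' @export
summary.scfnn <- function(object, ...) {
  m <- object$metrics
  df <- data.frame(metric = names(m), value = unlist(m), row.names = NULL)
  out <- list(metrics = df, group_spread = object$group_spread,
              sigma = object$sigma, n_train = object$n_train,
              n_test = object$n_test)
  class(out) <- "summary.scfnn"
  out
}

#' @export
print.summary.scfnn <- function(x, ...) {
  cat("scfnn model summary\n")
  cat(sprintf("  samples: %d train / %d test; sigma = %.2f A\n",
              x$n_train, x$n_test, x$sigma))
  cat(sprintf("  within-group spread of short-range targets: %.3g A\n",
              x$group_spread))
  print(x$metrics, digits = 4)
  invisible(x)
}

#' @export
coef.scfnn <- function(object, ...) {
  out <- list(net1s = object$net1s$W, net1l = object$net1l$W[[1]])
  if (!is.null(object$net2s))
    out <- c(out, list(net2s_O = object$net2s$O$W, net2s_H = object$net2s$H$W,
                       net2l_O = object$net2l$O$W[[1]],
                       net2l_H = object$net2l$H$W[[1]]))
  out
}

#' @export
plot.scfnn <- function(x, ...) {
  h <- attr(x$net1s, "history")
  if (is.null(h)) stop("no training history stored")
  it <- seq_along(h$train) * 10
  graphics::plot(it, h$train, type = "l", log = "y", xlab = "epoch",
                 ylab = "standardized MSE",
                 main = "short-range centre network training", ...)
  graphics::lines(it, h$val, lty = 2)
  graphics::legend("topright", c("train", "validation"), lty = 1:2,
                   bty = "n")
  invisible(x)
}

#' Predict with a fitted model
#'
#' Runs the self-consistent loop on a new configuration under the requested
#' electrostatic boundary condition and returns the requested quantity.
#'
#' @param object A fitted [scfnn()] model.
#' @param newdata An [atomic_config()] (or list of them).
#' @param boundary `list(E = <vector>)` or `list(D = <vector>)` (V/Angstrom).
#' @param type `"wannier"` (centre positions), `"forces"`, `"dipoles"`
#'   (per-molecule, e0 Angstrom), or `"polarization"` (e0/Angstrom^2).
#' @param ... Passed to [scf_solve()] (`tol`, `max_iter`, `mixing`, ...).
#' @return The requested quantity, or a list of them for a list input.
#' @export
predict.scfnn <- function(object, newdata, boundary = list(E = c(0, 0, 0)),
                          type = c("wannier", "forces", "dipoles",
                                   "polarization"), ...) {
  type <- match.arg(type)
  one <- function(config) {
    mols <- detect_water_topology(config)
    frames <- build_frames(config, mols)
    geom <- pair_geometry(config)
    scf <- scf_solve(config, object, boundary, mols = mols, frames = frames,
                     geom = geom, ...)
    switch(type,
           wannier = scf$wannier,
           forces = scfnn_forces(config, object, scf, mols, frames, geom),
           dipoles = molecular_dipoles(config, scf$wannier, mols),
           polarization = scf$P)
  }
  if (inherits(newdata, "atomic_config")) one(newdata) else lapply(newdata, one)
}

#' Simulate a trajectory with a fitted model
#'
#' Thermostatted molecular dynamics driven by the model's forces, with the
#' self-consistent loop warm-started from the previous step's centres.
#'
#' @param object A fitted [scfnn()] model (with force networks).
#' @param nsim Number of MD steps.
#' @param seed RNG seed for initial velocities.
#' @param config Initial [atomic_config()].
#' @param boundary Electrostatic boundary condition (as in [predict.scfnn()]).
#' @param ... Further [md_config()] settings (`dt`, `temperature`, `tau`,
#'   `stride`, ...).
#' @return A `scfnn_trajectory` (see [run_nvt()]).
#' @export
simulate.scfnn <- function(object, nsim = 100, seed = 1, config,
                           boundary = list(E = c(0, 0, 0)), ...) {
  if (is.null(object$net2s))
    stop("model was fitted without force networks; cannot simulate")
  engine <- scfnn_md_engine(object, config, boundary)
  run_nvt(config, engine, md_config(steps = nsim, seed = seed, ...))
}
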