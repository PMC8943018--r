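## Two-stage training: the linear long-range networks are fitted first from
## field-difference targets (the difference of centre positions / forces
## between two applied fields isolates the long-range response), their
## predictions are subtracted to expose the short-range system, and the
## short-range networks are fitted to what remains.

#' Split a grouped dataset into training and test parts
#'
#' Splitting is by group: all field strengths of one nuclear configuration
#' stay together, so no configuration leaks across the split.
#'
#' @param samples List of training samples (each with a `group_id`).
#' @param ratio Fraction of groups assigned to training (floor convention).
#' @param seed RNG seed; the split is deterministic given the seed.
#' @return List with elements `train` and `test`.
#' @export
split_dataset <- function(samples, ratio = 2 / 3, seed = 1) {
  gid <- vapply(samples, `[[`, numeric(1), "group_id")
  groups <- unique(gid)
  set.seed(seed)
  perm <- sample(groups)
  n_train <- floor(ratio * length(groups))
  if (n_train == length(groups))
    warning("empty test set (ratio too close to 1)")
  train_groups <- perm[seq_len(n_train)]
  list(train = samples[gid %in% train_groups],
       test = samples[!gid %in% train_groups])
}

# Per-sample features used in training: effective field at the atoms computed
# directly from the reference centres (no SCF needed during training) and the
# field-weighted descriptors; geometric descriptors are shared within a group.
prepare_sample_features <- function(sample, dparams, sigma, cache = NULL) {
  config <- sample$config
  key <- as.character(sample$group_id)
  if (!is.null(cache) && !is.null(cache[[key]])) {
    geomset <- cache[[key]]
  } else {
    mols <- detect_water_topology(config)
    frames <- build_frames(config, mols)
    geom <- pair_geometry(config)
    gsets <- build_descriptor_sets(config, dparams, mols, frames,
                                   which = c("net1S", "net2S_O", "net2S_H"),
                                   geom = geom)
    kv <- kspace_vectors(config$cell, sigma)
    geomset <- list(mols = mols, frames = frames, geom = geom, gsets = gsets,
                    kv = kv)
    if (!is.null(cache)) cache[[key]] <- geomset
  }
  ch <- assemble_charges(config, sample$wannier)
  field <- effective_field(ch, config$positions, config$cell,
                           E_ext = sample$applied_field, sigma = sigma,
                           kv = geomset$kv)
  fsets <- build_descriptor_sets(config, dparams, geomset$mols,
                                 geomset$frames, fields = field$site_fields,
                                 which = c("net1L", "net2L"),
                                 geom = geomset$geom)
  c(geomset, list(fsets = fsets, field = field))
}

# local-frame 12-vector of the 4 centre positions/displacements of molecule i
wannier_local_vec <- function(pos4, frame, origin = TRUE) {
  m <- if (origin) sweep(pos4, 2, frame$origin, "-") else pos4
  as.numeric(t(to_local(m, frame)))
}

#' Field-difference targets within a group (long-range training data)
#'
#' For every unordered pair of samples that share a nuclear configuration,
#' the difference of reference centre positions equals the difference of the
#' field-induced perturbations, and likewise for the forces; these
#' differences are directly observable and train the linear networks.
#'
#' @param group List of training samples with a common `group_id`.
#' @return List of pair targets: `d_wannier` ((4 n_mol) x 3, lab frame),
#'   `d_forces` (n_atoms x 3 or NULL), sample indices `a`, `b`.
#' @export
field_difference_targets <- function(group) {
  if (length(group) < 2)
    stop("need at least two field strengths per group")
  pos0 <- group[[1]]$config$positions
  for (s in group[-1])
    if (max(abs(s$config$positions - pos0)) > 1e-12)
      stop("samples in a group must share nuclear positions")
  pairs <- utils::combn(length(group), 2)
  out <- vector("list", ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1, p]; b <- pairs[2, p]
    dw <- group[[a]]$wannier$positions - group[[b]]$wannier$positions
    df <- if (!is.null(group[[a]]$forces))
      group[[a]]$forces - group[[b]]$forces else NULL
    out[[p]] <- list(a = a, b = b,
                     field_a = group[[a]]$applied_field,
                     field_b = group[[b]]$applied_field,
                     d_wannier = dw, d_forces = df)
  }
  out
}

# assemble the linear least-squares systems for networks 1L and 2L
assemble_long_range_system <- function(samples, dparams, sigma,
                                       features = NULL) {
  gid <- vapply(samples, `[[`, numeric(1), "group_id")
  if (is.null(features)) {
    cache <- new.env()
    features <- lapply(samples, prepare_sample_features, dparams, sigma,
                       cache)
  }
  X1 <- list(); Y1 <- list()
  X2 <- list(O = list(), H = list()); Y2 <- list(O = list(), H = list())
  for (g in unique(gid)) {
    idx <- which(gid == g)
    targets <- field_difference_targets(samples[idx])
    f0 <- features[[idx[1]]]
    n_mol <- nrow(f0$mols)
    sp <- samples[[idx[1]]]$config$species
    for (t in targets) {
      fa <- features[[idx[t$a]]]; fb <- features[[idx[t$b]]]
      X1[[length(X1) + 1L]] <- fa$fsets$net1L - fb$fsets$net1L
      yl <- matrix(0, n_mol, 12)
      for (i in seq_len(n_mol)) {
        rows <- (4 * i - 3):(4 * i)
        yl[i, ] <- wannier_local_vec(t$d_wannier[rows, , drop = FALSE],
                                     f0$frames[[i]], origin = FALSE)
      }
      Y1[[length(Y1) + 1L]] <- yl
      if (!is.null(t$d_forces)) {
        for (el in c("O", "H")) {
          dm <- fa$fsets[[paste0("net2L_", el)]] -
            fb$fsets[[paste0("net2L_", el)]]
          ai <- attr(fa$fsets[[paste0("net2L_", el)]], "idx")
          yf <- matrix(0, length(ai), 3)
          mol_of_atom <- integer(length(sp))
          for (i in seq_len(n_mol))
            mol_of_atom[c(f0$mols$o[i], f0$mols$h1[i], f0$mols$h2[i])] <- i
          for (jj in seq_along(ai))
            yf[jj, ] <- to_local(t$d_forces[ai[jj], ],
                                 f0$frames[[mol_of_atom[ai[jj]]]])
          X2[[el]][[length(X2[[el]]) + 1L]] <- dm
          Y2[[el]][[length(Y2[[el]]) + 1L]] <- yf
        }
      }
    }
  }
  list(X1 = do.call(rbind, X1), Y1 = do.call(rbind, Y1),
       X2 = lapply(X2, function(l) if (length(l)) do.call(rbind, l) else NULL),
       Y2 = lapply(Y2, function(l) if (length(l)) do.call(rbind, l) else NULL),
       features = features)
}

solve_linear_net <- function(X, Y, arch, hash, element = NULL) {
  fit <- stats::lm.fit(X, Y)
  W <- fit$coefficients
  W[is.na(W)] <- 0
  net <- network_init(arch, ncol(X), element = element, hash = hash,
                      scale = 0)
  net$W[[1]] <- matrix(W, ncol(X), ncol(Y))
  net
}

#' Fit the linear long-range networks (1L and 2L)
#'
#' The pairwise field-difference loss of a linear no-bias network is an
#' ordinary least-squares problem (the prediction difference equals the
#' network applied to the descriptor difference), solved directly; the
#' zero-field anchor is structural (no bias term). Train/test mean absolute
#' errors of the predicted differences are reported.
#'
#' @param train,test Lists of training samples (grouped).
#' @param dparams [descriptor_params()].
#' @param sigma Long-range split length (Angstrom).
#' @return List: `net1l`, `net2l` (per-element list), `metrics`, and cached
#'   per-sample `features` for reuse.
#' @export
train_long <- function(train, test = list(), dparams, sigma = 4.2) {
  sys_tr <- assemble_long_range_system(train, dparams, sigma)
  net1l <- solve_linear_net(sys_tr$X1, sys_tr$Y1, "1L", dparams$hash)
  net2l <- NULL
  if (!is.null(sys_tr$X2$O)) {
    net2l <- list(O = solve_linear_net(sys_tr$X2$O, sys_tr$Y2$O, "2L",
                                       dparams$hash, "O"),
                  H = solve_linear_net(sys_tr$X2$H, sys_tr$Y2$H, "2L",
                                       dparams$hash, "H"))
  }
  mae <- function(X, Y, net) if (is.null(X)) NA_real_ else
    mean(abs(network_forward(net, X) - Y))
  metrics <- list(train_mae_wannier = mae(sys_tr$X1, sys_tr$Y1, net1l),
                  train_mae_force_O = if (is.null(net2l)) NA_real_ else
                    mae(sys_tr$X2$O, sys_tr$Y2$O, net2l$O),
                  train_mae_force_H = if (is.null(net2l)) NA_real_ else
                    mae(sys_tr$X2$H, sys_tr$Y2$H, net2l$H))
  features_test <- NULL
  if (length(test)) {
    sys_te <- assemble_long_range_system(test, dparams, sigma)
    metrics$test_mae_wannier <- mae(sys_te$X1, sys_te$Y1, net1l)
    if (!is.null(net2l)) {
      metrics$test_mae_force_O <- mae(sys_te$X2$O, sys_te$Y2$O, net2l$O)
      metrics$test_mae_force_H <- mae(sys_te$X2$H, sys_te$Y2$H, net2l$H)
    }
    features_test <- sys_te$features
  }
  list(net1l = net1l, net2l = net2l, metrics = metrics,
       features = sys_tr$features, features_test = features_test)
}

#' Expose the short-range system by subtracting the long-range response
#'
#' For every sample (including those at non-zero applied field) the trained
#' linear networks predict the field-induced part of the centre positions and
#' forces from that sample's effective field; subtracting it leaves
#' short-range targets. The spread of these targets within a group (whose
#' members differ only in the applied field) is reported as a diagnostic:
#' a large spread flags an under-fitted long-range model.
#'
#' @param samples List of training samples.
#' @param net1l,net2l Trained long-range networks.
#' @param dparams,sigma Descriptor parameters and split length.
#' @param features Optional cached features from [train_long()].
#' @return List: `samples` (augmented with `gt_wannier`, `gt_forces`),
#'   `group_spread` (max within-group spread of short-range centre targets).
#' @export
extract_gt_targets <- function(samples, net1l, net2l, dparams, sigma = 4.2,
                               features = NULL) {
  if (is.null(features)) {
    cache <- new.env()
    features <- lapply(samples, prepare_sample_features, dparams, sigma,
                       cache)
  }
  out <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    f <- features[[i]]
    delta <- eval_1l(f$fsets$net1L, net1l, f$frames, dparams)
    s$gt_wannier <- wannier_set(s$wannier$positions - delta,
                                s$wannier$molecule)
    if (!is.null(s$forces) && !is.null(net2l)) {
      n_at <- nrow(s$config$positions)
      mol_of_atom <- integer(n_at)
      for (m in seq_len(nrow(f$mols)))
        mol_of_atom[c(f$mols$o[m], f$mols$h1[m], f$mols$h2[m])] <- m
      frames_of_atom <- lapply(mol_of_atom, function(m) f$frames[[m]])
      Fl <- eval_2l(list(O = f$fsets$net2L_O, H = f$fsets$net2L_H), net2l,
                    frames_of_atom, n_at, dparams)
      s$gt_forces <- s$forces - Fl
    }
    out[[i]] <- s
  }
  gid <- vapply(out, `[[`, numeric(1), "group_id")
  spread <- 0
  for (g in unique(gid)) {
    idx <- which(gid == g)
    if (length(idx) < 2) next
    ws <- lapply(out[idx], function(s) s$gt_wannier$positions)
    ref <- ws[[1]]
    for (w in ws[-1]) spread <- max(spread, max(abs(w - ref)))
  }
  list(samples = out, group_spread = spread, features = features)
}

## ---- generic small MLP trainer (full-batch Adam) ----

mlp_grad <- function(net, X, Y) {
  nl <- length(net$W)
  A <- list(X)
  Z <- list()
  H <- X
  for (l in seq_len(nl)) {
    Z[[l]] <- sweep(H %*% net$W[[l]], 2, net$b[[l]], "+")
    H <- if (l < nl) tanh(Z[[l]]) else Z[[l]]
    A[[l + 1]] <- H
  }
  n <- nrow(X)
  delta <- 2 * (A[[nl + 1]] - Y) / (n * ncol(Y))
  gW <- vector("list", nl); gb <- vector("list", nl)
  for (l in nl:1) {
    gW[[l]] <- t(A[[l]]) %*% delta
    gb[[l]] <- colSums(delta)
    if (l > 1) delta <- (delta %*% t(net$W[[l]])) * (1 - A[[l]]^2)
  }
  list(gW = gW, gb = gb, loss = mean((A[[nl + 1]] - Y)^2))
}

#' Train a short-range network by full-batch Adam
#'
#' Inputs and targets are standardized internally (scalers are stored in the
#' network); training minimizes the mean squared error with early stopping on
#' a validation set.
#'
#' @param net An initialized `scfnn_network` (tanh architecture).
#' @param X,Y Training inputs/targets.
#' @param Xval,Yval Validation inputs/targets (default: training data).
#' @param epochs Maximum epochs.
#' @param lr Adam learning rate.
#' @param patience Early-stopping patience (validation checks every 10
#'   epochs).
#' @return The trained network with a `history` attribute (train/validation
#'   loss trace).
#' @export
mlp_train <- function(net, X, Y, Xval = NULL, Yval = NULL, epochs = 2000,
                      lr = 2e-3, patience = 30) {
  stopifnot(!net$linear)
  net$x_center <- colMeans(X)
  net$x_scale <- pmax(apply(X, 2, stats::sd), 1e-8)
  net$y_center <- colMeans(Y)
  net$y_scale <- pmax(apply(Y, 2, stats::sd), 1e-8)
  Xs <- sweep(sweep(X, 2, net$x_center, "-"), 2, net$x_scale, "/")
  Ys <- sweep(sweep(Y, 2, net$y_center, "-"), 2, net$y_scale, "/")
  if (is.null(Xval)) { Xvs <- Xs; Yvs <- Ys } else {
    Xvs <- sweep(sweep(Xval, 2, net$x_center, "-"), 2, net$x_scale, "/")
    Yvs <- sweep(sweep(Yval, 2, net$y_center, "-"), 2, net$y_scale, "/")
  }
  nl <- length(net$W)
  mW <- lapply(net$W, function(w) w * 0); vW <- mW
  mb <- lapply(net$b, function(b) b * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best <- list(loss = Inf, W = net$W, b = net$b, epoch = 0)
  hist_tr <- numeric(0); hist_val <- numeric(0)
  bad <- 0
  inner <- net
  inner$x_center[] <- 0; inner$x_scale[] <- 1
  inner$y_center[] <- 0; inner$y_scale[] <- 1
  for (ep in seq_len(epochs)) {
    inner$W <- net$W; inner$b <- net$b
    g <- mlp_grad(inner, Xs, Ys)
    for (l in seq_len(nl)) {
      mW[[l]] <- b1 * mW[[l]] + (1 - b1) * g$gW[[l]]
      vW[[l]] <- b2 * vW[[l]] + (1 - b2) * g$gW[[l]]^2
      mb[[l]] <- b1 * mb[[l]] + (1 - b1) * g$gb[[l]]
      vb[[l]] <- b2 * vb[[l]] + (1 - b2) * g$gb[[l]]^2
      mh <- mW[[l]] / (1 - b1^ep); vh <- vW[[l]] / (1 - b2^ep)
      net$W[[l]] <- net$W[[l]] - lr * mh / (sqrt(vh) + eps)
      mhb <- mb[[l]] / (1 - b1^ep); vhb <- vb[[l]] / (1 - b2^ep)
      net$b[[l]] <- net$b[[l]] - lr * mhb / (sqrt(vhb) + eps)
    }
    if (ep %% 10 == 0 || ep == epochs) {
      inner$W <- net$W; inner$b <- net$b
      pred <- network_forward(inner, Xvs)
      vloss <- mean((pred - Yvs)^2)
      hist_tr <- c(hist_tr, g$loss); hist_val <- c(hist_val, vloss)
      if (vloss < best$loss * (1 - 1e-6)) {
        best <- list(loss = vloss, W = net$W, b = net$b, epoch = ep)
        bad <- 0
      } else {
        bad <- bad + 1
        if (bad >= patience) break
      }
    }
    if (!is.finite(g$loss)) stop("training diverged (non-finite loss)")
  }
  net$W <- best$W; net$b <- best$b
  attr(net, "history") <- list(train = hist_tr, val = hist_val,
                               best_epoch = best$epoch)
  net
}

#' Fit the short-range networks (1S and 2S)
#'
#' Network 1S is trained on the local-frame coordinates of the short-range
#' centre targets; the per-element 2S networks on local-frame short-range
#' force components.
#'
#' @param gt List from [extract_gt_targets()] for the training samples.
#' @param gt_test Optional, likewise for the test samples.
#' @param dparams,sigma Descriptor parameters and split length.
#' @param seed Seed for weight initialization.
#' @param epochs,lr,patience Optimizer settings (see [mlp_train()]).
#' @param forces Train the force networks as well.
#' @return List: `net1s`, `net2s` (per-element), `metrics`.
#' @export
train_short <- function(gt, gt_test = NULL, dparams, sigma = 4.2, seed = 1,
                        epochs = 2000, lr = 2e-3, patience = 30,
                        forces = TRUE) {
  build_xy <- function(gtobj) {
    samples <- gtobj$samples; features <- gtobj$features
    X1 <- list(); Y1 <- list()
    X2 <- list(O = list(), H = list()); Y2 <- list(O = list(), H = list())
    for (i in seq_along(samples)) {
      s <- samples[[i]]; f <- features[[i]]
      n_mol <- nrow(f$mols)
      X1[[i]] <- f$gsets$net1S
      yl <- matrix(0, n_mol, 12)
      for (m in seq_len(n_mol)) {
        rows <- (4 * m - 3):(4 * m)
        yl[m, ] <- wannier_local_vec(
          s$gt_wannier$positions[rows, , drop = FALSE], f$frames[[m]])
      }
      Y1[[i]] <- yl
      if (forces && !is.null(s$gt_forces)) {
        mol_of_atom <- integer(nrow(s$config$positions))
        for (m in seq_len(n_mol))
          mol_of_atom[c(f$mols$o[m], f$mols$h1[m], f$mols$h2[m])] <- m
        for (el in c("O", "H")) {
          dm <- f$gsets[[paste0("net2S_", el)]]
          ai <- attr(dm, "idx")
          yf <- matrix(0, length(ai), 3)
          for (jj in seq_along(ai))
            yf[jj, ] <- to_local(s$gt_forces[ai[jj], ],
                                 f$frames[[mol_of_atom[ai[jj]]]])
          X2[[el]][[length(X2[[el]]) + 1L]] <- dm
          Y2[[el]][[length(Y2[[el]]) + 1L]] <- yf
        }
      }
    }
    list(X1 = do.call(rbind, X1), Y1 = do.call(rbind, Y1),
         X2 = lapply(X2, function(l) if (length(l)) do.call(rbind, l)),
         Y2 = lapply(Y2, function(l) if (length(l)) do.call(rbind, l)))
  }
  tr <- build_xy(gt)
  te <- if (!is.null(gt_test)) build_xy(gt_test) else NULL
  net1s <- network_init("1S", ncol(tr$X1), hash = dparams$hash, seed = seed)
  net1s <- mlp_train(net1s, tr$X1, tr$Y1,
                     Xval = if (is.null(te)) NULL else te$X1,
                     Yval = if (is.null(te)) NULL else te$Y1,
                     epochs = epochs, lr = lr, patience = patience)
  metrics <- list(train_mae_gt_wannier =
                    mean(abs(network_forward(net1s, tr$X1) - tr$Y1)))
  if (!is.null(te))
    metrics$test_mae_gt_wannier <-
      mean(abs(network_forward(net1s, te$X1) - te$Y1))
  net2s <- NULL
  if (forces && !is.null(tr$X2$O)) {
    net2s <- list()
    for (el in c("O", "H")) {
      nn <- network_init("2S", ncol(tr$X2[[el]]), element = el,
                         hash = dparams$hash, seed = seed + 1)
      nn <- mlp_train(nn, tr$X2[[el]], tr$Y2[[el]],
                      Xval = if (is.null(te)) NULL else te$X2[[el]],
                      Yval = if (is.null(te)) NULL else te$Y2[[el]],
                      epochs = epochs, lr = lr, patience = patience)
      net2s[[el]] <- nn
      metrics[[paste0("train_mae_gt_force_", el)]] <-
        mean(abs(network_forward(nn, tr$X2[[el]]) - tr$Y2[[el]]))
      if (!is.null(te))
        metrics[[paste0("test_mae_gt_force_", el)]] <-
          mean(abs(network_forward(nn, te$X2[[el]]) - te$Y2[[el]]))
    }
  }
  list(net1s = net1s, net2s = net2s, metrics = metrics)
}

#' Canonical ordering of four Wannier centres
#'
#' Assigns the four centres of one molecule to the reference sites (two bond
#' sites along the O-H bonds, two lone-pair sites tilted out of the plane) by
#' exhaustive minimization of the total squared distance over all 4!
#' assignments; ties are broken deterministically by assignment order.
#'
#' @param centers 4 x 3 matrix of centre positions (lab frame).
#' @param mol One-row topology (with `o`, `h1`, `h2`).
#' @param config An [atomic_config()].
#' @param params [oracle_params()] supplying the reference geometry.
#' @return List: `order` (permutation such that `centers[order, ]` is in
#'   bond1/bond2/lone1/lone2 order), `labels`, `total_distance`.
#' @export
match_centers <- function(centers, mol, config, params = oracle_params()) {
  centers <- as.matrix(centers)
  stopifnot(nrow(centers) == 4)
  frame <- build_local_frame(mol, config)
  d_o <- minimum_image(sweep(centers, 2, frame$origin, "-"), config$cell)
  if (any(sqrt(rowSums(d_o^2)) > 1))
    stop("centre farther than 1 A from its oxygen: not a water-like centre")
  ref <- to_lab(params$centers_local, frame)
  perms <- perms4()
  cost <- apply(perms, 1, function(p) sum((d_o[p, ] - ref)^2))
  best <- which.min(cost)  # first minimum: deterministic tie-break
  list(order = unname(perms[best, ]),
       labels = c("bond1", "bond2", "lone1", "lone2"),
       total_distance = unname(sqrt(cost[best])))
}

perms4 <- function() {
  p <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  p <- p[apply(p, 1, function(r) length(unique(r)) == 4), ]
  as.matrix(p[order(p$a, p$b, p$c, p$d), ])
}
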