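dp <- descriptor_params()

test_that("group splitting uses the floor convention and is deterministic", {
  samples <- lapply(1:1571, function(g) list(group_id = g))
  sp <- split_dataset(samples, ratio = 2 / 3, seed = 42)
  expect_equal(length(sp$train), 1047)
  expect_equal(length(sp$test), 524)
  sp2 <- split_dataset(samples, ratio = 2 / 3, seed = 42)
  expect_identical(vapply(sp$train, `[[`, numeric(1), "group_id"),
                   vapply(sp2$train, `[[`, numeric(1), "group_id"))
  # no group straddles the split
  g_tr <- vapply(sp$train, `[[`, numeric(1), "group_id")
  g_te <- vapply(sp$test, `[[`, numeric(1), "group_id")
  expect_length(intersect(g_tr, g_te), 0)
  expect_warning(split_dataset(samples[1:3], ratio = 1), "empty test")
})

p_small <- oracle_params()
ds_small <- generate_dataset(4, n_molecules = 8, params = p_small, seed = 30,
                             forces = FALSE)

test_that("field-difference targets are antisymmetric and group-checked", {
  gid <- vapply(ds_small, `[[`, numeric(1), "group_id")
  group <- ds_small[gid == 1]
  tg <- field_difference_targets(group)
  expect_length(tg, 3)  # three unordered pairs from three field strengths
  # antisymmetry: (a,b) target equals minus the (b,a) difference
  dw_ab <- tg[[1]]$d_wannier
  dw_ba <- group[[tg[[1]]$b]]$wannier$positions -
    group[[tg[[1]]$a]]$wannier$positions
  expect_identical(dw_ab, -dw_ba)
  # identical fields give zero targets
  twice <- list(group[[1]], group[[1]])
  expect_equal(max(abs(field_difference_targets(twice)[[1]]$d_wannier)), 0)
  # mismatched nuclei rejected
  bad <- group
  bad[[2]]$config$positions[1, 1] <- bad[[2]]$config$positions[1, 1] + 0.1
  expect_error(field_difference_targets(bad), "share nuclear positions")
})

test_that("the linear long-range fit recovers a realizable response exactly", {
  sp <- split_dataset(ds_small, seed = 1)
  fit <- train_long(sp$train, sp$test, dp, sigma = p_small$sigma)
  # the oracle response lies in the descriptor span: near-exact recovery
  expect_lt(fit$metrics$train_mae_wannier, 1e-8)
  expect_lt(fit$metrics$test_mae_wannier, 1e-8)
})

test_that("direct least squares agrees with explicit normal equations", {
  sp <- split_dataset(ds_small, seed = 1)
  sys <- scfnn:::assemble_long_range_system(sp$train, dp, p_small$sigma)
  W_qr <- stats::lm.fit(sys$X1, sys$Y1)$coefficients
  W_qr[is.na(W_qr)] <- 0
  # independent route: ridge-free normal equations via pseudo-inverse
  sv <- svd(sys$X1)
  keep <- sv$d > max(sv$d) * 1e-10
  W_ne <- sv$v[, keep] %*% diag(1 / sv$d[keep], sum(keep)) %*%
    t(sv$u[, keep]) %*% sys$Y1
  # compare predictions (weights may differ in the null space)
  expect_lt(max(abs(sys$X1 %*% W_qr - sys$X1 %*% W_ne)) /
              max(abs(sys$Y1)), 1e-6)
})

test_that("subtracting the long-range response exposes field-free targets", {
  sp <- split_dataset(ds_small, seed = 1)
  fit <- train_long(sp$train, sp$test, dp, sigma = p_small$sigma)
  gt <- extract_gt_targets(sp$train, fit$net1l, fit$net2l, dp,
                           p_small$sigma, features = fit$features)
  # perfect linear model: short-range targets identical across fields
  expect_lt(gt$group_spread, 1e-7)
  # zero-weight long-range nets leave raw references untouched
  z1 <- network_init("1L", 36, hash = dp$hash, scale = 0)
  gt0 <- extract_gt_targets(sp$train[1:2], z1, NULL, dp, p_small$sigma)
  expect_identical(gt0$samples[[1]]$gt_wannier$positions,
                   sp$train[[1]]$wannier$positions)
})

test_that("short-range training fits the rigid reference geometry", {
  sp <- split_dataset(ds_small, seed = 1)
  fit <- train_long(sp$train, sp$test, dp, sigma = p_small$sigma)
  gt <- extract_gt_targets(sp$train, fit$net1l, fit$net2l, dp,
                           p_small$sigma, features = fit$features)
  gte <- extract_gt_targets(sp$test, fit$net1l, fit$net2l, dp,
                            p_small$sigma, features = fit$features_test)
  sr <- train_short(gt, gte, dp, sigma = p_small$sigma, seed = 2,
                    epochs = 1500, lr = 5e-3, forces = FALSE)
  # targets are constant in the local frame: the net must fit them closely
  expect_lt(sr$metrics$test_mae_gt_wannier, 1e-3)
})

test_that("teacher-student recovery reaches small test error", {
  # targets generated by a frozen network of the same architecture,
  # evaluated on descriptors of independent configurations
  cfgs <- generate_configs(8, n_configs = 40, seed = 30, params = p_small)
  X <- do.call(rbind, lapply(cfgs, function(cf) {
    mols <- detect_water_topology(cf)
    frames <- build_frames(cf, mols)
    build_descriptor_sets(cf, dp, mols, frames, which = "net1S")$net1S
  }))
  teacher <- network_init("1S", 36, seed = 77, scale = 0.3)
  teacher$b[[3]] <- stats::rnorm(12, sd = 0.1)
  Y <- network_forward(teacher, X)
  student <- network_init("1S", 36, seed = 78)
  idx <- seq_len(256)
  student <- mlp_train(student, X[idx, ], Y[idx, ], X[-idx, ], Y[-idx, ],
                       epochs = 20000, lr = 3e-3, patience = 400)
  mae <- mean(abs(network_forward(student, X[-idx, ]) - Y[-idx, ]))
  expect_lt(mae, 1e-4)
})

test_that("centre matching is exact at the references and stable to noise", {
  p <- oracle_params()
  cfg <- one_molecule(c(10, 10, 10), free_cell(20))
  mols <- detect_water_topology(cfg)
  fr <- build_local_frame(mols[1, ], cfg)
  ref <- sweep(to_lab(p$centers_local, fr), 2, fr$origin, "+")
  m0 <- match_centers(ref, mols[1, ], cfg, p)
  expect_equal(m0$order, 1:4)
  expect_lt(m0$total_distance, 1e-12)
  set.seed(9)
  for (i in 1:10) {
    pert <- ref + matrix(rnorm(12, sd = 0.03), 4, 3)
    perm <- sample(4)
    m <- match_centers(pert[perm, ], mols[1, ], cfg, p)
    expect_equal(m$order, order(perm))  # undoes the shuffle
  }
  # coincident centres: deterministic tie-break
  dup <- ref; dup[2, ] <- dup[1, ]
  m1 <- match_centers(dup, mols[1, ], cfg, p)
  m2 <- match_centers(dup, mols[1, ], cfg, p)
  expect_identical(m1$order, m2$order)
  # far-away centre rejected
  far <- ref; far[1, ] <- far[1, ] + c(2, 0, 0)
  expect_error(match_centers(far, mols[1, ], cfg, p), "farther than 1 A")
})

test_that("a zero-response oracle trains a long-range network of zeros", {
  p0 <- oracle_params(alpha = 0)
  ds0 <- generate_dataset(2, n_molecules = 6, params = p0, seed = 31,
                          forces = FALSE)
  fit <- train_long(ds0, list(), dp, sigma = p0$sigma)
  expect_lt(max(abs(fit$net1l$W[[1]])), 1e-6)
})
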