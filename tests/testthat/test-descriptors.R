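dp <- descriptor_params()

test_that("cutoff function has the stated boundary behaviour", {
  rc <- dp$r_c
  expect_equal(cutoff_fn(0, rc), 1)
  expect_equal(cutoff_fn(rc, rc), 0)
  expect_equal(cutoff_fn(rc / 2, rc), 0.5)
  expect_equal(cutoff_fn(rc + 0.1, rc), 0)
  # slope vanishes at the cutoff
  h <- 1e-6
  expect_lt(abs(cutoff_fn(rc - h, rc) - cutoff_fn(rc - 2 * h, rc)) / h, 1e-5)
})

test_that("parameter sets have the published input counts and a stable hash", {
  expect_equal(unname(dp$n_inputs[c("net1S", "net1L", "net2S_O", "net2S_H",
                                    "net2L")]),
               c(36L, 36L, 30L, 27L, 36L))
  expect_identical(dp$hash, descriptor_params()$hash)
})

test_that("radial sums match term-by-term evaluation", {
  cl <- free_cell(60)
  set.seed(11)
  n <- 6
  pos <- rbind(c(30, 30, 30),
               sweep(matrix(rnorm(3 * (n - 1), sd = 2), n - 1, 3), 2,
                     c(30, 30, 30), "+"))
  cfg <- atomic_config(c("O", rep("H", n - 1)), pos, cl)
  geom <- scfnn:::pair_geometry(cfg)
  tab <- data.frame(type = "g2", species = "H", eta = 0.7, rs = 0.5,
                    zeta = 1, lambda = 1)
  val <- evaluate_descriptors(cfg, 1L, list(diag(3)), tab, dp$r_c,
                              geom = geom)
  r <- sqrt(rowSums(sweep(pos[-1, ], 2, pos[1, ], "-")^2))
  hand <- sum(ifelse(r <= dp$r_c,
                     exp(-0.7 * (r - 0.5)^2) * 0.5 * (cos(pi * r / dp$r_c) + 1),
                     0))
  expect_equal(drop(val), hand, tolerance = 1e-12)
  # single neighbour at r = rs contributes exactly fc(rs)
  cfg1 <- atomic_config(c("O", "H"), rbind(c(30, 30, 30), c(30.5, 30, 30)), cl)
  v1_ <- evaluate_descriptors(cfg1, 1L, list(diag(3)), tab, dp$r_c)
  expect_equal(drop(v1_), cutoff_fn(0.5, dp$r_c), tolerance = 1e-12)
  # no neighbours inside the cutoff
  cfg0 <- atomic_config(c("O", "H"), rbind(c(5, 5, 5), c(50, 50, 50)), cl)
  expect_equal(drop(evaluate_descriptors(cfg0, 1L, list(diag(3)), tab,
                                         dp$r_c)), 0)
})

test_that("axis-projected angular sums follow the closed form", {
  cl <- free_cell(60)
  r0 <- 2.5
  cfg <- atomic_config(c("O", "H"),
                       rbind(c(30, 30, 30), c(30, 30 + r0, 30)), cl)
  tab <- data.frame(type = "g4", species = "all", eta = 0.2, rs = 0,
                    zeta = 1, lambda = 1)
  v <- evaluate_descriptors(cfg, 1L, list(diag(3)), tab, dp$r_c)
  w <- exp(-0.2 * r0^2) * cutoff_fn(r0, dp$r_c)
  # neighbour along +y: cos(theta) = 1 for the y axis -> 2^(1-1)*(1+1)^1*w
  expect_equal(v[1, 2], 2 * w, tolerance = 1e-12)
  # perpendicular axes: angular factor (1 + lambda*0)^zeta = 1, any lambda
  tabm <- tab; tabm$lambda <- -1
  vm <- evaluate_descriptors(cfg, 1L, list(diag(3)), tabm, dp$r_c)
  expect_equal(v[1, 1], vm[1, 1], tolerance = 1e-14)
  expect_equal(v[1, 1], w, tolerance = 1e-12)
})

test_that("field-weighted sums are exactly linear and rotate covariantly", {
  cl <- free_cell(60)
  set.seed(12)
  pos <- rbind(c(30, 30, 30), c(31.5, 30, 30), c(30, 32, 30.5))
  cfg <- atomic_config(c("O", "H", "H"), pos, cl)
  E <- matrix(rnorm(9), 3, 3)
  tab <- data.frame(type = "eg2", species = "all", eta = 0.3, rs = 0,
                    zeta = 1, lambda = 1)
  v <- evaluate_descriptors(cfg, 1L, list(diag(3)), tab, dp$r_c, fields = E)
  # zero fields -> exactly zero; homogeneity exact
  v0_ <- evaluate_descriptors(cfg, 1L, list(diag(3)), tab, dp$r_c,
                              fields = E * 0)
  expect_identical(drop(v0_), c(0, 0, 0))
  v2 <- evaluate_descriptors(cfg, 1L, list(diag(3)), tab, dp$r_c,
                             fields = 2.5 * E)
  expect_equal(drop(v2), drop(2.5 * v), tolerance = 1e-15)
  va <- evaluate_descriptors(cfg, 1L, list(diag(3)), tab, dp$r_c,
                             fields = E + 2 * E)
  expect_equal(drop(va), drop(3 * v), tolerance = 1e-15)
  # hand summation (centre included with weight exp(-eta rs^2) fc(0) = 1)
  r <- c(0, sqrt(sum((pos[2, ] - pos[1, ])^2)),
         sqrt(sum((pos[3, ] - pos[1, ])^2)))
  w <- exp(-0.3 * r^2) * cutoff_fn(r, dp$r_c)
  expect_equal(drop(v), colSums(E * w), tolerance = 1e-12)
  # rotating geometry and fields rotates the local-frame output covariantly
  Q <- random_rotation_matrix()
  cfg_r <- rotate_config(cfg, Q)
  axes_r <- diag(3) %*% t(Q)
  v_r <- evaluate_descriptors(cfg_r, 1L, list(axes_r), tab, dp$r_c,
                              fields = E %*% t(Q))
  expect_equal(drop(v_r), drop(v), tolerance = 1e-10)
})

test_that("full descriptor sets are invariant under rigid motions", {
  p <- oracle_params()
  cfg <- generate_configs(4, seed = 13, params = p)[[1]]
  # re-house in a free box so the rotation needs no periodic wrap
  cfg <- atomic_config(cfg$species, cfg$positions, free_cell(200))
  mols <- detect_water_topology(cfg)
  frames <- build_frames(cfg, mols)
  set.seed(14)
  E <- matrix(rnorm(3 * nrow(cfg$positions), sd = 0.1),
              nrow(cfg$positions), 3)
  sets <- build_descriptor_sets(cfg, dp, mols, frames, fields = E)
  Q <- random_rotation_matrix()
  shift <- c(40, -20, 13)
  cfg2 <- rotate_config(cfg, Q, shift)
  mols2 <- detect_water_topology(cfg2)
  frames2 <- build_frames(cfg2, mols2)
  sets2 <- build_descriptor_sets(cfg2, dp, mols2, frames2, fields = E %*% t(Q))
  for (nm in names(sets))
    expect_equal(unclass(sets2[[nm]]), unclass(sets[[nm]]), tolerance = 1e-10,
                 ignore_attr = TRUE)
})

test_that("descriptors vary smoothly as a neighbour crosses the cutoff", {
  cl <- free_cell(60)
  tab <- data.frame(type = "g2", species = "H", eta = 0.05, rs = 0,
                    zeta = 1, lambda = 1)
  val_at <- function(r) {
    cfg <- atomic_config(c("O", "H"), rbind(c(30, 30, 30),
                                            c(30 + r, 30, 30)), cl)
    drop(evaluate_descriptors(cfg, 1L, list(diag(3)), tab, dp$r_c))
  }
  h <- 1e-6
  d_in <- (val_at(dp$r_c - h) - val_at(dp$r_c - 2 * h)) / h
  d_out <- (val_at(dp$r_c + 2 * h) - val_at(dp$r_c + h)) / h
  expect_lt(abs(d_in - d_out), 1e-7)
})
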