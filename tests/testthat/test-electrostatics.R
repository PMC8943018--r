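test_that("Coulomb split reconstructs 1/r and has the stated limits", {
  r <- exp(seq(log(1e-3), log(50), length.out = 400))
  rel <- abs(v0(r) + v1(r) - 1 / r) * r
  expect_lt(max(rel), 1e-14)
  expect_equal(v1(0), 2 / (4.2 * sqrt(pi)))
  # long-range tail: v1(r) * r -> 1
  expect_equal(v1(50) * 50, 1, tolerance = 1e-12)
  # short-range part decays fast beyond ~2 sigma
  expect_lt(v0(3 * 4.2), 1e-5)
  expect_error(v0(-1), "non-negative")
})

test_that("v0 at r = sigma matches an independent series evaluation of erfc", {
  # erf(1) from the Maclaurin series, 25 terms
  n <- 0:24
  erf1 <- 2 / sqrt(pi) * sum((-1)^n / (factorial(n) * (2 * n + 1)))
  expect_equal(v0(4.2, sigma = 4.2), (1 - erf1) / 4.2, tolerance = 1e-14)
})

test_that("charge assembly gives a neutral valence + centre set", {
  cfg <- generate_configs(8, seed = 1)[[1]]
  w <- oracle_wannier(cfg, params = oracle_params(alpha = 0))
  ch <- assemble_charges(cfg, w)
  expect_equal(length(ch$q), 8 * 7)
  expect_equal(sum(ch$q), 0)
  expect_setequal(unique(ch$q), c(6, 1, -2))
  # centres ride with their oxygen
  mols <- detect_water_topology(cfg)
  expect_true(all(ch$parent[25:56] %in% mols$o))
  # malformed inputs
  bad <- atomic_config(c("O", "H", "N"), cfg$positions[1:3, ], cfg$cell)
  expect_error(assemble_charges(bad, w), "non-water")
  w_bad <- wannier_set(w$positions[1:4, , drop = FALSE], rep(1, 4))
  expect_error(assemble_charges(cfg, w_bad), "4 centres per molecule")
})

test_that("effective field reduces to E_ext without sources and superposes", {
  cl <- cell(20)
  pts <- rbind(c(1, 2, 3), c(10, 10, 10))
  f0 <- effective_field(list(positions = matrix(0, 0, 3), q = numeric(0)),
                        pts, cl, E_ext = c(0.1, -0.2, 0.3))
  expect_equal(f0$site_fields,
               matrix(rep(c(0.1, -0.2, 0.3), each = 2), ncol = 3))
  set.seed(5)
  pos1 <- matrix(runif(6, 2, 18), 2, 3); q1 <- c(1, -1)
  pos2 <- matrix(runif(6, 2, 18), 2, 3); q2 <- c(2, -2)
  fa <- effective_field(list(positions = pos1, q = q1), pts, cl)$site_fields
  fb <- effective_field(list(positions = pos2, q = q2), pts, cl)$site_fields
  fab <- effective_field(list(positions = rbind(pos1, pos2), q = c(q1, q2)),
                         pts, cl)$site_fields
  expect_lt(max(abs(fab - fa - fb)), 1e-12)
  # adding a uniform field shifts every site field by exactly that amount
  fe <- effective_field(list(positions = pos1, q = q1), pts, cl,
                        E_ext = c(0, 0, 0.25))$site_fields
  expect_lt(max(abs(fe - fa - rep(c(0, 0, 0.25), each = 2))), 1e-14)
})

test_that("field is invariant under rigid translation of charges and points", {
  cl <- cell(17)
  set.seed(6)
  pos <- matrix(runif(9, 2, 15), 3, 3); q <- c(1, 1, -2)
  pts <- matrix(runif(6, 0, 17), 2, 3)
  f1 <- effective_field(list(positions = pos, q = q), pts, cl)$site_fields
  s <- c(3.3, -2.1, 7.9)
  f2 <- effective_field(list(positions = sweep(pos, 2, s, "+"), q = q),
                        sweep(pts, 2, s, "+"), cl)$site_fields
  expect_lt(max(abs(f1 - f2)), 1e-10)
})

test_that("reciprocal-space truncation keeps the damping below tolerance", {
  cl <- cell(12.4)
  kv <- kspace_vectors(cl, sigma = 4.2, tol = 1e-12)
  k2 <- rowSums(kv$k^2)
  expect_true(all(exp(-k2 * 4.2^2 / 4) >= 1e-12))
  # the sum is small: efficiency of the method hinges on this
  expect_lt(nrow(kv$k), 600)
  # tightening the tolerance changes the field negligibly
  pos <- rbind(c(2, 3, 4), c(7, 8, 9)); q <- c(1, -1)
  pts <- matrix(c(5, 5, 5), 1, 3)
  f1 <- effective_field(list(positions = pos, q = q), pts, cl, tol = 1e-12)
  f2 <- effective_field(list(positions = pos, q = q), pts, cl, tol = 1e-16)
  expect_lt(max(abs(f1$site_fields - f2$site_fields)), 1e-10)
})

test_that("molecular dipoles match hand summation and are translation-invariant", {
  cl <- free_cell(40)
  pos <- rbind(c(20, 20, 20), c(20.76, 20.59, 20), c(19.24, 20.59, 20))
  cfg <- atomic_config(c("O", "H", "H"), pos, cl)
  w <- wannier_set(matrix(rep(pos[1, ], 4), 4, 3, byrow = TRUE), rep(1, 4))
  mols <- detect_water_topology(cfg)
  p <- molecular_dipoles(cfg, w, mols)
  expect_equal(drop(p), c(0, 1.18, 0), tolerance = 1e-12)
  cfg2 <- atomic_config(cfg$species, sweep(pos, 2, c(5, -3, 2), "+"), cl)
  w2 <- wannier_set(sweep(w$positions, 2, c(5, -3, 2), "+"), rep(1, 4))
  expect_equal(molecular_dipoles(cfg2, w2, mols), p)
  # symmetric cancellation: centre barycentre on the charge barycentre
  wsym <- wannier_set(rbind(pos[2, ], pos[3, ],
                            2 * pos[1, ] - pos[2, ], 2 * pos[1, ] - pos[3, ]) *
                        0 + matrix(rep(pos[1, ], 4), 4, 3, byrow = TRUE) +
                        rbind(c(0, 0.1475, 0), c(0, 0.1475, 0),
                              c(0, 0.1475, 0), c(0, 0.1475, 0)),
                      rep(1, 4))
  psym <- molecular_dipoles(cfg, wsym, mols)
  expect_equal(drop(psym), c(0, 0, 0), tolerance = 1e-12)
})

test_that("cell polarization equals the direct per-charge sum", {
  p <- oracle_params(alpha = 0)
  cfg <- generate_configs(6, seed = 8, params = p)[[1]]
  # wrap molecules whole so the direct per-charge sum has no branch issue
  mols <- detect_water_topology(cfg)
  w <- oracle_wannier(cfg, params = p, mols = mols)
  P <- cell_polarization(cfg, w, mols)
  ch <- assemble_charges(cfg, w)
  # direct per-charge sum with each charge referenced to its molecule's O
  molid <- integer(nrow(cfg$positions))
  for (k in seq_len(nrow(mols)))
    molid[c(mols$o[k], mols$h1[k], mols$h2[k])] <- k
  o_of_charge <- mols$o[molid[ch$parent]]
  Pd <- c(0, 0, 0)
  for (i in seq_along(ch$q)) {
    d <- minimum_image(ch$positions[i, ] - cfg$positions[o_of_charge[i], ],
                       cfg$cell)
    Pd <- Pd + ch$q[i] * d
  }
  Pd <- Pd / prod(cfg$cell$lengths)
  expect_equal(P, Pd, tolerance = 1e-12)
  # additivity: N identical dipoles
  expect_equal(cell_polarization(cfg, w, mols),
               colSums(molecular_dipoles(cfg, w, mols)) /
                 prod(cfg$cell$lengths))
})
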