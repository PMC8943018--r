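make_dipole_traj <- function(n_mol, n_frames, L, dipole_fn, seed = 1) {
  set.seed(seed)
  cl <- cell(L)
  frames <- list()
  o_idx <- seq(1, 3 * n_mol, by = 3)
  mols <- data.frame(o = o_idx, h1 = o_idx + 1, h2 = o_idx + 2)
  for (f in seq_len(n_frames)) {
    pos <- matrix(runif(9 * n_mol, 0, L), 3 * n_mol, 3)
    frames[[f]] <- list(positions = pos, dipoles = dipole_fn(n_mol, pos),
                        P = c(0, 0, 0), E_unif = c(0, 0, 0),
                        temperature = 300, step = f)
  }
  fake_traj(frames, rep(c("O", "H", "H"), n_mol), mols, cl)
}

test_that("chi_zz equals the explicit molecular double sum", {
  tr <- make_dipole_traj(10, 3, 12, function(n, pos)
    matrix(rnorm(3 * n), n, 3), seed = 2)
  chi <- chi_zz(tr, 1:5)
  Lz <- 12; V <- 12^3
  for (j in 1:5) {
    k <- 2 * pi * j / Lz
    acc <- 0
    for (fr in tr$frames) {
      z <- fr$positions[tr$mols$o, 3]
      pz <- fr$dipoles[, 3]
      s <- 0
      for (l in 1:10) for (m in 1:10)
        s <- s + pz[l] * pz[m] * exp(-1i * k * (z[l] - z[m]))
      acc <- acc + Re(s) / V
    }
    expect_equal(chi$value[j], acc / 3, tolerance = 1e-12)
  }
  expect_error(chi_zz(tr, c(0.5)), "integer")
})

test_that("single molecule gives p_z^2 / V at every wavevector", {
  tr <- make_dipole_traj(1, 1, 10, function(n, pos)
    matrix(c(0.3, -0.1, 0.7), 1, 3))
  chi <- chi_zz(tr, 1:4)
  expect_equal(chi$value, rep(0.7^2 / 1000, 4), tolerance = 1e-14)
})

test_that("uncorrelated dipoles give a flat curve at N<p_z^2>/V", {
  tr <- make_dipole_traj(40, 60, 15, function(n, pos)
    matrix(rnorm(3 * n, sd = 0.2), n, 3), seed = 3)
  chi <- chi_zz(tr, 1:6)
  expected <- 40 * 0.2^2 / 15^3
  expect_lt(abs(mean(chi$value) / expected - 1), 0.35)
  expect_lt(stats::sd(chi$value) / mean(chi$value), 0.4)
})

test_that("the plateau consistency check follows the screening limit", {
  # construct a curve exactly at the limit for eps = 20 at 300 K
  lim <- KB_T * 300 * (20 - 1) / (4 * pi * KE_T * 20)
  chi <- structure(data.frame(k = c(0.5, 1, 1.5, 2), value = rep(lim, 4),
                              se = rep(lim * 0.01, 4)),
                   class = c("correlation_curve", "data.frame"))
  cc <- chi_limit_consistency(chi, epsilon = 20, temperature = 300)
  expect_false(cc$flagged)
  expect_equal(cc$ratio, 1, tolerance = 1e-12)
  # eps = 1: limit is zero
  expect_equal(chi_limit_consistency(chi, 1, 300)$limit, 0)
  # strictly monotone low-k points: flagged, no ratio
  chi$value <- c(1, 2, 3, 4) * lim
  expect_true(chi_limit_consistency(chi, 20, 300)$flagged)
})

test_that("Kirkwood factor is 1 at r -> 0 and counts aligned neighbours", {
  # three identical parallel dipoles within the sphere
  cl <- cell(20)
  o_idx <- c(1, 4, 7)
  mols <- data.frame(o = o_idx, h1 = o_idx + 1, h2 = o_idx + 2)
  pos <- matrix(0, 9, 3)
  pos[o_idx, ] <- rbind(c(5, 5, 5), c(7, 5, 5), c(5, 7, 5))
  fr <- list(positions = pos,
             dipoles = matrix(rep(c(0, 0, 1), 3), 3, 3, byrow = TRUE),
             P = c(0, 0, 0), E_unif = c(0, 0, 0), temperature = 300,
             step = 1)
  tr <- fake_traj(list(fr), rep(c("O", "H", "H"), 3), mols, cl)
  gk <- kirkwood_gk(tr, r_grid = c(0.5, 5))
  expect_equal(gk$value[1], 1)        # self term only
  expect_equal(gk$value[2], 3)        # all three aligned dipoles inside
  expect_error(kirkwood_gk(tr, r_grid = c(1, 50)), "beyond")
  # random orientations: G_K near 1 at all r
  trr <- make_dipole_traj(30, 40, 14, function(n, pos)
    matrix(rnorm(3 * n), n, 3), seed = 4)
  gkr <- kirkwood_gk(trr, r_grid = c(1, 3, 6))
  expect_equal(gkr$value, rep(1, 3), tolerance = 0.25)
})

test_that("the composite factor is the stated ensemble combination", {
  g1 <- structure(data.frame(r = 1:5, value = rep(2, 5)),
                  class = c("correlation_curve", "data.frame"), mu_sq = 0.01)
  g2 <- structure(data.frame(r = 1:5, value = rep(5, 5)),
                  class = c("correlation_curve", "data.frame"), mu_sq = 0.03)
  gc <- composite_gk(g1, g2, window = c(2, 4))
  expect_equal(gc$value, rep((2 * 2 + 5) / 3, 5))
  expect_equal(attr(gc, "g_K"), 3)
  expect_equal(attr(gc, "mu_sq"), 0.02)
  g3 <- g2; g3$r <- g3$r + 0.1
  expect_error(composite_gk(g1, g3), "match")
  # both inputs identically 1 -> output identically 1
  gone <- g1; gone$value <- rep(1, 5)
  expect_equal(composite_gk(gone, gone, c(2, 4))$value, rep(1, 5))
})

test_that("the Kirkwood dielectric relation inverts exactly", {
  N <- 1000; V <- 31.2^3; musq <- (2.9 / 4.80321)^2
  # round trip seeded at the bulk-water scale: eps 100, eps_inf 1.65
  gk <- scfnn:::gk_from_epsilon(100, N, V, 300, musq, 1.65)
  eps <- epsilon_from_gk(gk, N, V, 300, musq, 1.65)
  expect_equal(eps, 100, tolerance = 1e-10)
  # identity across the whole range
  for (e in c(1, 2, 5, 20, 80, 200)) for (ei in c(1, 1.65, 3)) {
    g <- scfnn:::gk_from_epsilon(e, N, V, 300, musq, ei)
    expect_equal(epsilon_from_gk(g, N, V, 300, musq, ei), e,
                 tolerance = 1e-10 * e)
  }
  # vacuum limit and monotonicity
  expect_equal(epsilon_from_gk(0, N, V, 300, musq * 0, 1), 1)
  e1 <- epsilon_from_gk(1, N, V, 300, musq, 1)
  e2 <- epsilon_from_gk(2, N, V, 300, musq, 1)
  expect_gt(e2, e1)
})

test_that("P(D) fits recover the slope limits", {
  D <- c(0, 0.2, 0.4)
  # zero response: eps = 1
  f0 <- fit_p_vs_d(D, c(0, 0, 0))
  expect_equal(f0$epsilon, 1)
  # conductor limit: slope 1/(4 pi ke)
  fC <- fit_p_vs_d(D, D / (4 * pi * KE_T) * 0.999999)
  expect_gt(fC$epsilon, 1e4)
  expect_error(fit_p_vs_d(0.1, 1), "at least two")
})

test_that("the electronic response fit matches the dilute closed form", {
  p <- oracle_params(alpha = 0.48)
  cfg0 <- generate_configs(1, seed = 50, params = p)[[1]]
  # dilute: one molecule in a large box
  big <- atomic_config(cfg0$species, cfg0$positions + 14, cell(40))
  mols <- detect_water_topology(big)
  predict_P <- function(cf, E) {
    w <- oracle_wannier(cf, E, p)
    cell_polarization(cf, w, mols)
  }
  fit <- fit_eps_infinity(predict_P, list(big), E = c(0, 0.05, 0.1))
  alpha_mol <- 4 * p$alpha
  eps_dilute <- 1 + 4 * pi * alpha_mol / 40^3
  expect_equal(fit$epsilon_infinity, eps_dilute,
               tolerance = (eps_dilute - 1) * 0.05)
  # zero electronic response: exactly 1
  p0 <- oracle_params(alpha = 0)
  predict_P0 <- function(cf, E) {
    w <- oracle_wannier(cf, E, p0)
    cell_polarization(cf, w, mols)
  }
  fit0 <- fit_eps_infinity(predict_P0, list(big), E = c(0, 0.1))
  expect_equal(fit0$epsilon_infinity, 1, tolerance = 1e-12)
})

test_that("dipole histograms are normalized and degenerate inputs collapse", {
  # identical dipoles: delta-like histogram, mean equal to the common value
  tr <- make_dipole_traj(20, 5, 12, function(n, pos)
    matrix(rep(c(0, 0, 0.5), n), n, 3, byrow = TRUE))
  dd <- dipole_distribution(tr, breaks = 20)
  expect_equal(dd$mean, 0.5 * 4.80321, tolerance = 1e-10)
  expect_equal(sum(dd$density > 0), 1)
  # spread dipoles: density integrates to one
  trs <- make_dipole_traj(20, 5, 12, function(n, pos)
    matrix(rnorm(3 * n, sd = 0.3), n, 3), seed = 9)
  ds <- dipole_distribution(trs, breaks = 25)
  widths <- diff(ds$mids)[1]
  expect_equal(sum(ds$density) * widths, 1, tolerance = 1e-6)
})

test_that("interface profiles detect alignment and respect isotropy", {
  trz <- make_dipole_traj(30, 10, 15, function(n, pos)
    matrix(rep(c(0, 0, 1), n), n, 3, byrow = TRUE), seed = 5)
  prof <- interface_profiles(trz, dz = 3)
  expect_equal(prof$cos_theta[prof$count > 0],
               rep(1, sum(prof$count > 0)))
  # isotropic dipoles: profile consistent with zero everywhere
  tri <- make_dipole_traj(40, 40, 15, function(n, pos)
    matrix(rnorm(3 * n), n, 3), seed = 6)
  profi <- interface_profiles(tri, dz = 3)
  expect_lt(max(abs(profi$cos_theta), na.rm = TRUE), 0.15)
  # empty bins are NA, not zero
  trn <- make_dipole_traj(2, 1, 30, function(n, pos)
    matrix(1, n, 3), seed = 7)
  profn <- interface_profiles(trn, dz = 1)
  expect_true(any(is.na(profn$cos_theta)))
})

test_that("radial distributions normalize to 1 and find lattice peaks", {
  # ideal-gas O positions
  tr <- make_dipole_traj(60, 20, 18, function(n, pos)
    matrix(0, n, 3), seed = 8)
  g <- rdf(tr, c("O", "O"), dr = 0.5)
  far <- g$r > 4
  expect_equal(mean(g$value[far]), 1, tolerance = 0.1)
  expect_error(rdf(tr, c("O", "O"), r_max = 10), "half the shortest")
  # simple-cubic lattice: first peak bin contains the lattice constant
  a <- 3
  gpos <- as.matrix(expand.grid(0:3, 0:3, 0:3)) * a + 0.5
  n <- nrow(gpos)
  pos <- matrix(0, 3 * n, 3)
  pos[seq(1, 3 * n, 3), ] <- gpos
  o_idx <- seq(1, 3 * n, 3)
  mols <- data.frame(o = o_idx, h1 = o_idx + 1, h2 = o_idx + 2)
  fr <- list(positions = pos, dipoles = matrix(0, n, 3), P = c(0, 0, 0),
             E_unif = c(0, 0, 0), temperature = 0, step = 1)
  trl <- fake_traj(list(fr), rep(c("O", "H", "H"), n), mols, cell(12))
  gl <- rdf(trl, c("O", "O"), dr = 0.2, r_max = 5.9)
  first_peak <- gl$r[which(gl$value > 0)[1]]
  expect_lt(abs(first_peak - a), 0.2)
  # intramolecular O-H peak near the bond length on generated water
  p <- oracle_params()
  cfg <- generate_configs(16, seed = 51, params = p)[[1]]
  frw <- list(positions = cfg$positions, dipoles = matrix(0, 16, 3),
              P = c(0, 0, 0), E_unif = c(0, 0, 0), temperature = 300,
              step = 1)
  trw <- fake_traj(list(frw), cfg$species, detect_water_topology(cfg),
                   cfg$cell)
  goh <- rdf(trw, c("O", "H"), dr = 0.05, r_max = 3)
  expect_equal(goh$r[which.max(goh$value)], 0.975, tolerance = 0.05)
})
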