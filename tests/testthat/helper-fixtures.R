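## Shared fixtures and independent oracle implementations used across tests.

KE_T <- 14.399645
KB_T <- 8.617333262e-5

# a free (non-periodic) box for rotation tests
free_cell <- function(L = 100) cell(L, periodic = c(FALSE, FALSE, FALSE))

# one water molecule with O at `origin`, default geometry
one_molecule <- function(origin = c(50, 50, 50), cl = free_cell()) {
  th <- 104.52 * pi / 180
  pos <- rbind(c(0, 0, 0), c(0, 0.9572, 0),
               c(-sin(th) * 0.9572, cos(th) * 0.9572, 0))
  atomic_config(c("O", "H", "H"), sweep(pos, 2, origin, "+"), cl)
}

random_rotation_matrix <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
        c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
        c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

rotate_config <- function(config, Q, shift = c(0, 0, 0)) {
  atomic_config(config$species,
                sweep(config$positions %*% t(Q), 2, shift, "+"),
                config$cell)
}

# independent real-space oracle for the long-range field: sum the v1 field
# kernel over periodic images inside a sphere of image-cells and remove the
# net-dipole surface term (tinfoil boundary conditions)
brute_force_v1_field <- function(pos, q, pts, L, sigma, radius) {
  g <- as.matrix(expand.grid(-radius:radius, -radius:radius, -radius:radius))
  g <- g[rowSums(g^2) <= radius^2, , drop = FALSE]
  shifts <- g * L
  E <- matrix(0, nrow(pts), 3)
  for (p in seq_len(nrow(pts))) {
    for (j in seq_along(q)) {
      src <- sweep(shifts, 2, pos[j, ], "+")
      d <- sweep(-src, 2, pts[p, ], "+")
      r <- sqrt(rowSums(d^2))
      ok <- r > 1e-12
      erf_loc <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
      kern <- KE_T * q[j] * (erf_loc(r[ok] / sigma) / r[ok]^2 -
                               2 / (sqrt(pi) * sigma) *
                                 exp(-(r[ok] / sigma)^2) / r[ok]) / r[ok]
      E[p, ] <- E[p, ] + colSums(d[ok, , drop = FALSE] * kern)
    }
  }
  M <- colSums(pos * q)
  sweep(E, 2, 4 * pi * KE_T * M / (3 * L^3), "+")
}

# a model whose networks reproduce the synthetic oracle exactly: the
# short-range network emits the rigid reference centres (bias only) and the
# linear network reads the central atom's own field off the narrowest
# O-channel descriptor
perfect_model <- function(params = oracle_params(),
                          dp = descriptor_params()) {
  net1s <- network_init("1S", 36, hash = dp$hash, scale = 0)
  net1s$b[[3]] <- as.numeric(t(params$centers_local))
  net1l <- network_init("1L", 36, hash = dp$hash, scale = 0)
  gain <- -params$alpha / (2 * KE_T)
  for (a in 1:3) net1l$W[[1]][15 + a, seq(a, 12, by = 3)] <- gain
  list(net1s = net1s, net1l = net1l, descriptors = dp, sigma = params$sigma)
}

# minimal trajectory container for analysis tests
fake_traj <- function(frames, species, mols, cl) {
  structure(list(frames = frames, species = species, mols = mols, cell = cl,
                 mdconf = md_config(steps = 1), temperature_series = numeric(0)),
            class = "scfnn_trajectory")
}
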