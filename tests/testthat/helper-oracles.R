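# Independent oracles used to validate the geometry kernels.

# Monte-Carlo SASA: uniform points on each atom's expanded sphere,
# rejection against every neighbour's expanded sphere.
mc_sasa_oracle <- function(coords, radii, probe = 1.4, n_mc = 1e5, seed = 42) {
  set.seed(seed)
  n <- nrow(coords)
  R <- radii + probe
  vapply(seq_len(n), function(i) {
    u <- matrix(rnorm(3 * n_mc), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    pts <- sweep(u * R[i], 2, coords[i, ], "+")
    ok <- rep(TRUE, n_mc)
    for (j in seq_len(n)[-i]) {
      d2 <- rowSums(sweep(pts, 2, coords[j, ])^2)
      ok <- ok & d2 >= R[j]^2
    }
    mean(ok) * 4 * pi * R[i]^2
  }, numeric(1))
}

# Brute-force minimal RMSD over rotations: dense random rotation sampling
# followed by local refinement of the best candidates (Nelder-Mead over an
# axis-angle perturbation).  Centres both point sets, so the optimal
# translation is implicit.
rotation_search_rmsd <- function(mobile, reference, n_rot = 4000, seed = 7) {
  set.seed(seed)
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  quat_to_rot <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  }
  score_q <- function(q) {
    Rm <- quat_to_rot(q)
    sqrt(mean(rowSums((P %*% t(Rm) - Q)^2)))
  }
  qs <- matrix(rnorm(4 * n_rot), ncol = 4)
  vals <- apply(qs, 1, score_q)
  best <- order(vals)[1:5]
  refined <- vapply(best, function(b) {
    stats::optim(qs[b, ], score_q, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))$value
  }, numeric(1))
  min(refined)
}
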