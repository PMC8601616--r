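# Independent oracles used to derive frozen expectations. They deliberately
# avoid the package's own code paths.

# Brute-force varimax for a two-column loading matrix: scan the rotation
# angle on a fine grid and return the rotation maximising the raw varimax
# criterion (sum over columns of the variance of squared loadings).
varimax_criterion <- function(L) {
  sum(apply(L^2, 2, function(x) mean(x^2) - mean(x)^2))
}
grid_varimax_2col <- function(L, step = 1e-4) {
  angles <- seq(0, pi / 2, by = step)
  crit <- vapply(angles, function(a) {
    R <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2)
    varimax_criterion(L %*% R)
  }, numeric(1))
  a <- angles[which.max(crit)]
  L %*% matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2)
}

# Brute-force knee of a descending curve: the point farthest above the
# chord joining the first and last points.
brute_knee <- function(y) {
  L <- length(y)
  chord <- y[1] + (y[L] - y[1]) * (seq_len(L) - 1) / (L - 1)
  above <- y - chord
  if (max(above) <= 1e-9) return(NA_integer_)
  which.max(above)
}

# Uniform-distribution moments of the fixtures, derived analytically:
# chain (all fluxes equal, uniform on [0,1] segment); triangle
# (uniform on {v2,v3 >= 0, v2+v3 <= 1}).
chain_oracle <- list(mean = 0.5, var = 1 / 12)
triangle_oracle <- list(mean_in = 2 / 3, mean_out = 1 / 3,
                        var_out = 1 / 18, cov_out = -1 / 36)

# Deterministic rejection sampler over the triangle polytope, independent
# of the package's hit-and-run implementation.
triangle_reference_sample <- function(n, seed) {
  set.seed(seed)
  pts <- matrix(stats::runif(2 * 4 * n), ncol = 2)
  pts <- pts[rowSums(pts) <= 1, , drop = FALSE][seq_len(n), ]
  cbind(v1 = rowSums(pts), v2 = pts[, 1], v3 = pts[, 2])
}
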