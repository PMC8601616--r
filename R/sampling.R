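# Run a function with a private RNG stream: the global .Random.seed is
# restored afterwards so sampling never perturbs the caller's RNG state.
with_private_seed <- function(seed, fun) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fun()
}

#' Empirical flux moments by uniform hit-and-run sampling
#'
#' Draws approximately uniform samples from the polytope
#' \{S v = 0, lb <= v <= ub\} with a hit-and-run Markov chain run in the
#' null-space parametrisation of the stoichiometry: from the current point a
#' random null-space direction is drawn, the feasible segment along it is
#' computed from the box bounds, and the next point is uniform on that
#' segment. The chain starts from the average of the FVA vertex solutions
#' (an interior point), discards `10 * dim` warm-up steps and keeps every
#' `dim`-th step thereafter. A zero-dimensional space returns point-mass
#' moments.
#'
#' @param space A (reduced) [flux_space].
#' @param n_samples Number of retained samples.
#' @param seed RNG seed; identical seeds give identical moments.
#' @param fva Optional precomputed [run_fva()] result (reused for the
#'   starting point); computed when missing.
#' @return A [flux_moments] with method `"sampling"`. The raw samples are
#'   attached as attribute `samples`.
#' @export
sample_moments <- function(space, n_samples = 10000L, seed = 1L, fva = NULL) {
  model <- space$model
  n <- n_reactions(model)
  if (is.null(fva)) fva <- run_fva(space)
  v0 <- rowMeans(attr(fva, "vertices"))
  N <- nullspace_basis(model$S)
  d <- ncol(N)
  if (d == 0L) {
    return(flux_moments(model$reactions$id, v0, rep(0, n), matrix(0, n, n),
                        method = "sampling",
                        convergence = list(n_samples = n_samples, dim = 0L)))
  }
  lb <- unname(model$lb)
  ub <- unname(model$ub)
  warmup <- 10L * d
  thin <- d
  total <- warmup + n_samples * thin
  X <- with_private_seed(seed, function() {
    v <- v0
    out <- matrix(0, n_samples, n)
    kept <- 0L
    tol <- 1e-12
    for (step in seq_len(total)) {
      z <- stats::rnorm(d)
      dir <- as.numeric(N %*% (z / sqrt(sum(z^2))))
      tmin <- -Inf
      tmax <- Inf
      pos <- dir > tol
      neg <- dir < -tol
      if (any(pos)) {
        tmax <- min(tmax, min((ub[pos] - v[pos]) / dir[pos]))
        tmin <- max(tmin, max((lb[pos] - v[pos]) / dir[pos]))
      }
      if (any(neg)) {
        tmax <- min(tmax, min((lb[neg] - v[neg]) / dir[neg]))
        tmin <- max(tmin, max((ub[neg] - v[neg]) / dir[neg]))
      }
      if (is.finite(tmin) && is.finite(tmax) && tmax > tmin)
        v <- pmin(pmax(v + stats::runif(1, tmin, tmax) * dir, lb), ub)
      if (step > warmup && (step - warmup) %% thin == 0L) {
        kept <- kept + 1L
        out[kept, ] <- v
      }
    }
    out
  })
  mom <- flux_moments(model$reactions$id,
                      colMeans(X),
                      apply(X, 2, stats::var),
                      stats::cov(X),
                      method = "sampling",
                      convergence = list(n_samples = n_samples, dim = d,
                                         warmup = warmup, thin = thin,
                                         seed = seed))
  attr(mom, "samples") <- X
  mom
}
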