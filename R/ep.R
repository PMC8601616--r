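#' Expectation-propagation configuration
#'
#' Parameters of the Gaussian EP approximation of the uniform density on the
#' flux polytope. Defaults: at most 1000 iterations, convergence precision
#' 1e-5 on the site parameters, beta 1e8 as the soft-equality precision for
#' `S v = 0`, damping 0.9 on site updates and a 1e-10 variance floor for
#' fixed (zero-width) reactions.
#'
#' @param max_iterations Maximum EP sweeps (>= 1).
#' @param precision Convergence threshold on the largest site-parameter change.
#' @param beta Precision of the soft stoichiometric equality constraint.
#' @param damping Damping factor in \[0, 1) applied to site updates.
#' @param variance_floor Variance reported for zero-width reactions.
#' @return An `ep_config` list.
#' @export
ep_config <- function(max_iterations = 1000L, precision = 1e-5, beta = 1e8,
                      damping = 0.9, variance_floor = 1e-10) {
  stopifnot(max_iterations >= 1L, precision > 0, beta > 0,
            damping >= 0, damping < 1)
  structure(list(max_iterations = as.integer(max_iterations),
                 precision = precision, beta = beta, damping = damping,
                 variance_floor = variance_floor),
            class = "ep_config")
}

# Mean and variance of a normal(m, s2) truncated to [lo, hi], computed via
# tail probabilities so that far-out cavities do not underflow to NaN.
truncnorm_moments <- function(m, s2, lo = 0, hi = 1) {
  s <- sqrt(s2)
  a <- (lo - m) / s
  b <- (hi - m) / s
  # probability mass in [a, b], computed in the better-conditioned tail
  Z <- ifelse(a > 0,
              stats::pnorm(a, lower.tail = FALSE) - stats::pnorm(b, lower.tail = FALSE),
              stats::pnorm(b) - stats::pnorm(a))
  da <- stats::dnorm(a)
  db <- stats::dnorm(b)
  ok <- Z > 1e-300
  r1 <- ifelse(ok, (da - db) / Z, 0)
  r2 <- ifelse(ok, (a * da - b * db) / Z, 0)
  mu <- m + s * r1
  va <- s2 * pmax(1 + r2 - r1^2, 1e-12)
  # degenerate mass: collapse onto the nearer endpoint
  mu[!ok] <- ifelse(m[!ok] < lo, lo, hi)
  va[!ok] <- s2[!ok] * 1e-12
  list(mean = pmin(pmax(mu, lo), hi), var = va)
}

#' Approximate flux moments by expectation propagation
#'
#' Gaussian approximation of the uniform density on the polytope
#' \{S v = 0, lb <= v <= ub\}: the stoichiometric equalities enter as a
#' Gaussian likelihood of precision `beta`, each box constraint is a site
#' approximated by a univariate Gaussian, and sites are refined by moment
#' matching against their truncated-Gaussian tilted marginals until the
#' largest site-parameter change falls below `precision`. Fluxes are
#' affinely rescaled to \[0, 1\] per reaction for conditioning and
#' back-transformed afterwards. The reported means, variances and the
#' covariance matrix are those of the converged Gaussian approximation (the
#' covariance that feeds the downstream decomposition), with means clamped
#' to the flux bounds and the covariance repaired to positive
#' semidefiniteness (negative eigenvalues clipped at zero); the truncated
#' tilted marginals drive the site updates.
#'
#' @param space A (reduced) [flux_space] with finite bounds.
#' @param cfg An [ep_config].
#' @return A [flux_moments] with method `"ep"`. Non-convergence is surfaced
#'   as a warning and recorded in the convergence field.
#' @export
ep_moments <- function(space, cfg = ep_config()) {
  model <- space$model
  lb <- unname(model$lb)
  ub <- unname(model$ub)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("EP requires finite bounds; run FVA preprocessing first")
  n <- length(lb)
  width <- ub - lb
  varying <- width > 0
  nv <- sum(varying)

  mean_out <- lb
  var_out <- rep(0, n)
  C <- matrix(0, n, n)
  conv <- list(iterations = 0L, final_change = 0, converged = TRUE)

  if (nv > 0L) {
    # steady state in rescaled coordinates: v = lb + T w, w in [0,1]^nv
    Sv <- model$S[, varying, drop = FALSE]
    A <- sweep(Sv, 2, width[varying], `*`)
    b <- -as.numeric(model$S %*% lb)
    M <- cfg$beta * crossprod(A)
    h <- cfg$beta * as.numeric(crossprod(A, b))

    a_site <- rep(0.5, nv)
    d_site <- rep(1, nv)
    change <- Inf
    it <- 0L
    while (it < cfg$max_iterations) {
      it <- it + 1L
      P <- M + diag(1 / d_site, nv)
      Sigma <- chol2inv(chol(P))
      mu <- as.numeric(Sigma %*% (h + a_site / d_site))
      sii <- pmax(diag(Sigma), 1e-300)
      cav_prec <- pmax(1 / sii - 1 / d_site, 1e-12)
      cav_var <- 1 / cav_prec
      cav_mean <- cav_var * (mu / sii - a_site / d_site)
      tl <- truncnorm_moments(cav_mean, cav_var)
      new_prec <- pmin(pmax(1 / tl$var - cav_prec, 1e-12), 1e12)
      new_d <- 1 / new_prec
      new_a <- new_d * (tl$mean / tl$var - cav_mean / cav_var)
      change <- max(abs(new_a - a_site), abs(new_d - d_site))
      a_site <- cfg$damping * a_site + (1 - cfg$damping) * new_a
      d_site <- cfg$damping * d_site + (1 - cfg$damping) * new_d
      if (change < cfg$precision) break
    }
    conv <- list(iterations = it, final_change = change,
                 converged = change < cfg$precision)
    if (!conv$converged)
      warning(sprintf("EP did not converge in %d iterations (last change %.3g)",
                      it, change))

    # converged Gaussian approximation, back-transformed to flux units
    P <- M + diag(1 / d_site, nv)
    Sigma <- chol2inv(chol(P))
    mu <- as.numeric(Sigma %*% (h + a_site / d_site))
    wv <- width[varying]
    mean_out[varying] <- pmin(pmax(lb[varying] + wv * mu, lb[varying]),
                              ub[varying])
    C[varying, varying] <- Sigma * tcrossprod(wv)
  }

  C <- psd_repair(C)
  var_out <- pmax(diag(C), 0)
  var_out[!varying] <- pmin(var_out[!varying], cfg$variance_floor)
  flux_moments(model$reactions$id, mean_out, var_out, C,
               method = "ep", convergence = conv)
}
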