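#' Flux moments container
#'
#' Per-reaction mean and variance plus the full reaction-by-reaction
#' covariance of the (approximate) uniform distribution over a flux
#' polytope, together with the method that produced them.
#'
#' @param reaction_ids Ordered reaction ids.
#' @param mean,variance Numeric vectors, one entry per reaction.
#' @param covariance Symmetric reactions x reactions matrix; its diagonal is
#'   forced to `variance`.
#' @param method `"ep"` or `"sampling"`.
#' @param convergence List recording iterations/final change (EP) or chain
#'   settings (sampling).
#' @return An object of class `flux_moments`.
#' @export
flux_moments <- function(reaction_ids, mean, variance, covariance,
                         method = c("ep", "sampling"), convergence = list()) {
  method <- match.arg(method)
  covariance <- (covariance + t(covariance)) / 2
  diag(covariance) <- variance
  dimnames(covariance) <- list(reaction_ids, reaction_ids)
  structure(list(reaction_ids = reaction_ids,
                 mean = stats::setNames(mean, reaction_ids),
                 variance = stats::setNames(variance, reaction_ids),
                 covariance = covariance,
                 method = method,
                 convergence = convergence),
            class = "flux_moments")
}

#' @export
print.flux_moments <- function(x, ...) {
  cat(sprintf("Flux moments (%s) for %d reactions\n", x$method, length(x$mean)))
  if (!is.null(x$convergence$iterations))
    cat(sprintf("  iterations: %d, final change: %.3g, converged: %s\n",
                x$convergence$iterations, x$convergence$final_change,
                isTRUE(x$convergence$converged)))
  invisible(x)
}

# Symmetrise and clip negative eigenvalues to zero so the covariance is
# positive semidefinite for the downstream eigendecomposition.
psd_repair <- function(C) {
  C <- (C + t(C)) / 2
  e <- eigen(C, symmetric = TRUE)
  if (all(e$values >= 0)) return(C)
  lam <- pmax(e$values, 0)
  C2 <- e$vectors %*% (lam * t(e$vectors))
  (C2 + t(C2)) / 2
}

#' Write per-reaction moment statistics as TSV
#' @param moments A `flux_moments`.
#' @param path Output path.
#' @param covariance_path Optional path for the dense covariance (TSV).
#' @return `path`, invisibly.
#' @export
write_moments_tsv <- function(moments, path, covariance_path = NULL) {
  df <- data.frame(reaction_id = moments$reaction_ids,
                   mean = unname(moments$mean),
                   variance = unname(moments$variance),
                   sd = sqrt(unname(moments$variance)),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(covariance_path))
    utils::write.table(moments$covariance, covariance_path, sep = "\t",
                       col.names = NA, quote = FALSE)
  invisible(path)
}
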