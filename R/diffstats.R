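#' Per-reaction differential flux statistics between two conditions
#'
#' For every reaction present in both conditions, quantifies the shift of
#' its flux distribution by the z-score
#' `z = (E2 - E1) / sqrt(Var1 + Var2)` and transforms it into a two-sided
#' Gaussian probability of change `p = 2 * (1 - Phi(|z|))`. Reactions
#' present in only one condition are flagged, not scored. When both
#' variances are zero, equal means give `z = 0` by convention and unequal
#' means give an infinite z flagged as degenerate (p underflows to 0).
#'
#' @param m1,m2 [flux_moments] of the two conditions.
#' @return A `differential_flux` data frame with columns `reaction_id`,
#'   `mean1`, `var1`, `mean2`, `var2`, `z`, `p`, `membership`
#'   (`"both"`, `"cond1_only"`, `"cond2_only"`) and `degenerate`.
#' @export
flux_zscores <- function(m1, m2) {
  shared <- intersect(m1$reaction_ids, m2$reaction_ids)
  if (length(shared) == 0L) stop_degenerate("conditions share no reactions")
  only1 <- setdiff(m1$reaction_ids, m2$reaction_ids)
  only2 <- setdiff(m2$reaction_ids, m1$reaction_ids)
  e1 <- m1$mean[shared]; v1 <- m1$variance[shared]
  e2 <- m2$mean[shared]; v2 <- m2$variance[shared]
  denom <- sqrt(v1 + v2)
  diff <- e2 - e1
  z <- ifelse(denom > 0, diff / denom, ifelse(diff == 0, 0, Inf * sign(diff)))
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  res <- data.frame(
    reaction_id = c(shared, only1, only2),
    mean1 = c(e1, m1$mean[only1], rep(NA_real_, length(only2))),
    var1 = c(v1, m1$variance[only1], rep(NA_real_, length(only2))),
    mean2 = c(e2, rep(NA_real_, length(only1)), m2$mean[only2]),
    var2 = c(v2, rep(NA_real_, length(only1)), m2$variance[only2]),
    z = c(z, rep(NA_real_, length(only1) + length(only2))),
    p = c(p, rep(NA_real_, length(only1) + length(only2))),
    membership = c(rep("both", length(shared)),
                   rep("cond1_only", length(only1)),
                   rep("cond2_only", length(only2))),
    degenerate = c(denom == 0 & diff != 0,
                   rep(FALSE, length(only1) + length(only2))),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("differential_flux", "data.frame")
  res
}

#' Reactions whose flux distribution changed significantly
#'
#' @param result A `differential_flux` from [flux_zscores()].
#' @param alpha Raw significance level; reactions with `p < alpha` are
#'   returned sorted by ascending p (no multiple-testing correction).
#' @return Character vector of reaction ids.
#' @export
significant_reactions <- function(result, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  hit <- result[!is.na(result$p) & result$p < alpha, , drop = FALSE]
  hit$reaction_id[order(hit$p)]
}

#' Write differential flux statistics as TSV
#' @param result A `differential_flux`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_zscore_table <- function(result, path) {
  out <- data.frame(reaction_id = result$reaction_id,
                    mean1 = result$mean1, sd1 = sqrt(result$var1),
                    mean2 = result$mean2, sd2 = sqrt(result$var2),
                    z = result$z, p = result$p, flag = result$membership,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
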