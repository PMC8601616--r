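#' Toy chain model with analytically known flux moments
#'
#' A linear pathway in -> m1 -> ... -> m(k-1) -> out of `length` reactions,
#' all bounded to \[0, 1\]. At steady state every flux is equal, so the
#' uniform distribution on the polytope is uniform on a segment: every
#' reaction has mean 1/2, variance 1/12 and pairwise correlation 1. The
#' null space has dimension 1 for any length.
#'
#' @param length Number of reactions (>= 2).
#' @return A [metabolic_model].
#' @export
make_chain_model <- function(length = 2L) {
  if (length < 2L) stop("chain needs length >= 2")
  k <- as.integer(length)
  mets <- data.frame(id = sprintf("m%d", seq_len(k - 1L)),
                     name = sprintf("M%d", seq_len(k - 1L)),
                     compartment = "c", stringsAsFactors = FALSE)
  rxns <- data.frame(id = sprintf("r%d", seq_len(k)),
                     name = sprintf("step %d", seq_len(k)),
                     subsystem = "chain", reversible = FALSE,
                     gene_rule = "", stringsAsFactors = FALSE)
  S <- matrix(0, k - 1L, k)
  for (i in seq_len(k - 1L)) {
    S[i, i] <- 1
    S[i, i + 1L] <- -1
  }
  metabolic_model("chain", mets, rxns, S, lb = rep(0, k), ub = rep(1, k))
}

#' Toy branch model: uniform distribution on a triangle
#'
#' One metabolite fed by `r1` and drained by `r2` and `r3`, all bounded to
#' \[0, 1\]. The steady-state polytope projects onto the triangle
#' \{v2, v3 >= 0, v2 + v3 <= 1\}, whose uniform moments are analytic:
#' E\[v2\] = 1/3, Var\[v2\] = 1/18, Cov(v2, v3) = -1/36 and E\[v1\] = 2/3.
#' The null space has dimension 2.
#'
#' @return A [metabolic_model].
#' @export
make_triangle_model <- function() {
  mets <- data.frame(id = "m1", name = "M1", compartment = "c",
                     stringsAsFactors = FALSE)
  rxns <- data.frame(id = c("r1", "r2", "r3"),
                     name = c("inflow", "outflow a", "outflow b"),
                     subsystem = "branch", reversible = FALSE,
                     gene_rule = "", stringsAsFactors = FALSE)
  S <- matrix(c(1, -1, -1), 1, 3)
  metabolic_model("triangle", mets, rxns, S, lb = rep(0, 3), ub = rep(1, 3))
}

rlaplace <- function(n, scale = 1) {
  u <- stats::runif(n) - 0.5
  -scale * sign(u) * log(1 - 2 * abs(u))
}

#' Loading matrices with planted super-Gaussian components
#'
#' Builds a pair of rotated-loading matrices (one per condition) for testing
#' condition comparison by ICA. Each planted source mimics a varimax-rotated
#' module component: Laplace weights (excess kurtosis 3, comfortably past
#' the retention bound of 1) on its own random `support` fraction of
#' reactions and zero elsewhere. Sources are assigned round-robin to the two
#' conditions and written, plus Gaussian measurement noise of sd `noise_sd`,
#' into one known column of that condition's matrix. The remaining columns
#' are low-variance Gaussian filler (excess kurtosis 0, so their components
#' are never retained by the kurtosis filter).
#'
#' The default scales are load-bearing for the downstream comparison stage:
#' the sparse unit-scale sources dominate the column variances, so the
#' PCA-whitened subspace that fastICA works in contains them stably across
#' bootstrap resamples, while each source column stays strongly
#' super-Gaussian after low-loading row filtering because the retained rows
#' are mostly other sources' support (where the column is zero). With the
#' defaults roughly a quarter of the reactions survive the filter and every
#' planted column keeps excess kurtosis well above 1.
#'
#' @param n_reactions Number of rows (reactions) per matrix.
#' @param sources Number of planted sparse-Laplace sources.
#' @param noise_sd Gaussian noise added to planted columns.
#' @param seed RNG seed; fixed seed gives byte-identical matrices.
#' @param n_cols Columns per condition matrix (planted + filler).
#' @param filler_sd Standard deviation of the Gaussian filler columns.
#' @param support Fraction of reactions carrying each source's weights.
#' @return List with `lm1`, `lm2` ([loading_matrix] objects, rotated flag
#'   set), `sources` (reactions x sources matrix of ground truth), and
#'   `planted` (data frame: source, condition, column index).
#' @export
make_planted_loadings <- function(n_reactions = 3000L, sources = 3L,
                                  noise_sd = 0.02, seed = 1L,
                                  n_cols = 8L, filler_sd = 0.2,
                                  support = 0.25) {
  if (sources > n_reactions) stop("more sources than reactions")
  set.seed(seed)
  ids <- sprintf("r%05d", seq_len(n_reactions))
  nsup <- max(3L, round(support * n_reactions))
  src <- matrix(0, n_reactions, sources)
  for (s in seq_len(sources))
    src[sample.int(n_reactions, nsup), s] <- rlaplace(nsup)
  mats <- list(matrix(stats::rnorm(n_reactions * n_cols, sd = filler_sd),
                      n_reactions, n_cols),
               matrix(stats::rnorm(n_reactions * n_cols, sd = filler_sd),
                      n_reactions, n_cols))
  cond <- rep_len(1:2, sources)
  col_within <- integer(sources)
  used <- c(0L, 0L)
  for (s in seq_len(sources)) {
    k <- cond[s]
    used[k] <- used[k] + 1L
    col_within[s] <- used[k]
    mats[[k]][, used[k]] <- src[, s] +
      stats::rnorm(n_reactions, sd = noise_sd)
  }
  mk <- function(k) {
    lm <- loading_matrix(ids, mats[[k]],
                         variance_fraction = rep(1 / n_cols, n_cols),
                         condition_label = paste0("cond", k))
    lm$rotated <- TRUE
    lm
  }
  list(lm1 = mk(1), lm2 = mk(2), sources = src,
       planted = data.frame(source = seq_len(sources), condition = cond,
                            column = col_within))
}
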