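#' Loading matrix of a flux-covariance decomposition
#'
#' Rows are reactions, columns are (possibly rotated) principal components
#' of the flux covariance; `variance_fraction` gives each component's share
#' of the total variance.
#'
#' @param reaction_ids Ordered reaction ids (row names).
#' @param loadings Reactions x components numeric matrix.
#' @param variance_fraction Per-component nonnegative variance fractions.
#' @param condition_label Condition the covariance came from.
#' @param rotated Whether a varimax rotation has been applied.
#' @return An object of class `loading_matrix`.
#' @export
loading_matrix <- function(reaction_ids, loadings, variance_fraction,
                           condition_label = "", rotated = FALSE) {
  loadings <- as.matrix(loadings)
  rownames(loadings) <- reaction_ids
  colnames(loadings) <- sprintf("PC%d", seq_len(ncol(loadings)))
  structure(list(reaction_ids = reaction_ids, loadings = loadings,
                 variance_fraction = as.numeric(variance_fraction),
                 rotated = rotated, condition_label = condition_label),
            class = "loading_matrix")
}

#' @export
print.loading_matrix <- function(x, ...) {
  cat(sprintf("Loading matrix%s: %d reactions x %d components%s\n",
              if (nzchar(x$condition_label)) paste0(" [", x$condition_label, "]") else "",
              nrow(x$loadings), ncol(x$loadings),
              if (x$rotated) " (varimax-rotated)" else ""))
  invisible(x)
}

# Deterministic sign convention: flip each column so its largest-magnitude
# entry is positive (first such entry wins ties).
fix_signs <- function(L) {
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (length(i) && L[i, j] < 0) L[, j] <- -L[, j]
  }
  L
}

#' Eigendecomposition of a flux covariance matrix
#'
#' Computes eigenvectors (loadings, columns sorted by eigenvalue
#' descending) and variance fractions (eigenvalues normalised by the trace,
#' negative numerical eigenvalues clipped to zero) of a symmetric
#' covariance matrix.
#'
#' @param cov Square symmetric covariance matrix with reaction ids as
#'   dimnames (or supply `reaction_ids`).
#' @param reaction_ids Optional explicit reaction ids.
#' @param condition_label Condition annotation carried through.
#' @param sym_tol Maximum tolerated asymmetry, `max |C - t(C)|`.
#' @return A [loading_matrix].
#' @export
pca_covariance <- function(cov, reaction_ids = rownames(cov),
                           condition_label = "", sym_tol = 1e-6) {
  cov <- as.matrix(cov)
  if (nrow(cov) != ncol(cov) || max(abs(cov - t(cov))) > sym_tol)
    stop("covariance matrix must be square and symmetric")
  if (is.null(reaction_ids)) reaction_ids <- sprintf("r%d", seq_len(nrow(cov)))
  e <- eigen((cov + t(cov)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  vf <- if (sum(lam) > 0) lam / sum(lam) else lam
  loading_matrix(reaction_ids, fix_signs(e$vectors), vf,
                 condition_label = condition_label, rotated = FALSE)
}

#' Number of components explaining a cumulative variance threshold
#'
#' @param lm A [loading_matrix].
#' @param threshold Cumulative variance-fraction threshold in (0, 1\];
#'   default 0.999.
#' @return Smallest k whose leading components reach the threshold.
#' @export
select_components <- function(lm, threshold = 0.999) {
  stopifnot(threshold > 0, threshold <= 1)
  cum <- cumsum(lm$variance_fraction) / sum(lm$variance_fraction)
  which(cum >= threshold - 1e-12)[1L]
}

#' Varimax rotation of the retained components
#'
#' Rotates the first `k` loading columns by the orthogonal matrix maximising
#' the varimax criterion (variance of squared loadings per component),
#' without Kaiser row normalisation, convergence tolerance 1e-8. Row
#' communalities over the rotated set are preserved by orthogonality. The
#' rotated components' variance fractions are recomputed from the rotated
#' quadratic form of the retained eigenvalues.
#'
#' @param lm An unrotated [loading_matrix] from [pca_covariance()].
#' @param k Number of leading components to rotate and retain.
#' @param eps Varimax convergence tolerance.
#' @return A [loading_matrix] with `k` columns and the rotated flag set.
#' @export
varimax_rotate <- function(lm, k, eps = 1e-8) {
  if (k < 1L) stop("k must be >= 1")
  if (k > ncol(lm$loadings)) stop("k exceeds component count")
  L <- lm$loadings[, seq_len(k), drop = FALSE]
  if (k > 1L) {
    vr <- stats::varimax(L, normalize = FALSE, eps = eps)
    L <- L %*% vr$rotmat
    lam <- lm$variance_fraction[seq_len(k)]
    vf <- diag(t(vr$rotmat) %*% (lam * vr$rotmat))
  } else vf <- lm$variance_fraction[1L]
  loading_matrix(lm$reaction_ids, fix_signs(L), vf,
                 condition_label = lm$condition_label, rotated = TRUE)
}

#' Extract the module of one component by the half-max loading rule
#'
#' A module is the set of reactions whose absolute loadings are at least
#' half of the component's largest absolute loading (threshold inclusive).
#'
#' @param lm A [loading_matrix].
#' @param component Component (column) index.
#' @return A `module`: list with `component`, `condition_label` and
#'   `members` (data frame of reaction id and signed loading).
#' @export
extract_module <- function(lm, component) {
  if (component < 1L || component > ncol(lm$loadings))
    stop("component index out of range")
  l <- lm$loadings[, component]
  mx <- max(abs(l))
  if (mx == 0) stop("component ", component, " has all-zero loadings")
  keep <- abs(l) >= 0.5 * mx
  structure(list(component = as.integer(component),
                 condition_label = lm$condition_label,
                 members = data.frame(reaction_id = lm$reaction_ids[keep],
                                      loading = unname(l[keep]),
                                      stringsAsFactors = FALSE)),
            class = "module")
}

#' @export
print.module <- function(x, ...) {
  cat(sprintf("Module (component %d%s): %d reactions\n", x$component,
              if (nzchar(x$condition_label)) paste0(", ", x$condition_label) else "",
              nrow(x$members)))
  invisible(x)
}

#' Global modules of a condition
#'
#' Extracts one module per retained component of a rotated loading matrix;
#' their collection is the condition's global module set.
#'
#' @param lm A rotated [loading_matrix].
#' @return List with `modules` (list of `module`), `union` (unique reaction
#'   ids across modules) and `membership_count` (named integer vector: how
#'   many modules each union reaction belongs to).
#' @export
global_modules <- function(lm) {
  if (!lm$rotated) stop("global modules are extracted from a rotated loading matrix")
  mods <- lapply(seq_len(ncol(lm$loadings)), function(j) extract_module(lm, j))
  all_ids <- unlist(lapply(mods, function(m) m$members$reaction_id))
  counts <- table(all_ids)
  uni <- lm$reaction_ids[lm$reaction_ids %in% names(counts)]
  list(modules = mods, union = uni,
       membership_count = stats::setNames(as.integer(counts[uni]), uni))
}

#' Write a loading matrix or module set as TSV/JSON
#' @param lm A [loading_matrix].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_loading_matrix <- function(lm, path) {
  utils::write.table(lm$loadings, path, sep = "\t", col.names = NA, quote = FALSE)
  invisible(path)
}

#' @param gm Result of [global_modules()].
#' @param model Optional [metabolic_model] supplying subsystem annotation.
#' @rdname write_loading_matrix
#' @export
write_modules_tsv <- function(gm, path, model = NULL) {
  rows <- do.call(rbind, lapply(gm$modules, function(m)
    data.frame(component = m$component, condition = m$condition_label,
               reaction_id = m$members$reaction_id,
               loading = m$members$loading, stringsAsFactors = FALSE)))
  if (!is.null(model))
    rows$subsystem <- model$reactions$subsystem[match(rows$reaction_id,
                                                      model$reactions$id)]
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
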