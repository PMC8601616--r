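#' Concatenate two conditions' rotated loadings and filter low-loading rows
#'
#' Columns of both rotated loading matrices are concatenated over the union
#' of reaction ids (zero-filled where a reaction is absent from one
#' condition). Each reaction's maximum absolute loading `m` across all
#' columns is computed and rows with `m` below the cutoff
#' `median(m) + mean(|m - mean(m)|)` (median plus mean absolute deviation
#' about the mean) are removed.
#'
#' @param lm1,lm2 Rotated [loading_matrix] objects.
#' @return A `combined_loadings`: list with `reaction_ids`, `loadings`
#'   (retained rows x all columns), `provenance` (data frame: column name,
#'   condition, source component index) and `cutoff`.
#' @export
concat_and_filter <- function(lm1, lm2) {
  if (!lm1$rotated || !lm2$rotated)
    stop("both loading matrices must be varimax-rotated")
  ids <- union(lm1$reaction_ids, lm2$reaction_ids)
  k1 <- ncol(lm1$loadings)
  k2 <- ncol(lm2$loadings)
  M <- matrix(0, length(ids), k1 + k2, dimnames = list(ids, NULL))
  M[lm1$reaction_ids, seq_len(k1)] <- lm1$loadings
  M[lm2$reaction_ids, k1 + seq_len(k2)] <- lm2$loadings
  tag <- function(lm, k) if (k > 0L)
    paste0(lm$condition_label, ".", colnames(lm$loadings)) else character(0)
  prov <- data.frame(
    column = c(tag(lm1, k1), tag(lm2, k2)),
    condition = c(rep(lm1$condition_label, k1), rep(lm2$condition_label, k2)),
    component = c(seq_len(k1), seq_len(k2)),
    stringsAsFactors = FALSE)
  colnames(M) <- prov$column
  m <- apply(abs(M), 1, max)
  cutoff <- stats::median(m) + mean(abs(m - mean(m)))
  keep <- m >= cutoff
  if (!any(keep)) stop_degenerate("low-loading filter removed every reaction")
  structure(list(reaction_ids = ids[keep],
                 loadings = M[keep, , drop = FALSE],
                 provenance = prov, cutoff = cutoff),
            class = "combined_loadings")
}

# Symmetric fixed-point fastICA with the pow3 (kurtosis) nonlinearity.
# X: observations (reactions) x mixed signals. Whitening by PCA of the
# column covariance; initial demixing matrix drawn from the current RNG
# stream. Returns estimated sources (columns, unit variance), the mixing
# matrix A with X_centered ~ S %*% A, and a convergence flag.
fastica_pow3 <- function(X, n_comp, max_iter = 200L, tol = 1e-4) {
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  cv <- crossprod(Xc) / n
  e <- eigen(cv, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-12
  if (sum(pos) < n_comp)
    stop("requested ", n_comp, " components but data rank is ", sum(pos))
  vals <- e$values[seq_len(n_comp)]
  vecs <- e$vectors[, seq_len(n_comp), drop = FALSE]
  K <- vecs %*% diag(1 / sqrt(vals), n_comp)        # whitening, p x c
  K_un <- vecs %*% diag(sqrt(vals), n_comp)         # de-whitening, p x c
  Z <- Xc %*% K                                     # n x c, identity cov
  sym_decor <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decor(matrix(stats::rnorm(n_comp^2), n_comp))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Y <- Z %*% t(W)
    Wn <- sym_decor(crossprod(Y^3, Z) / n - 3 * W)
    delta <- max(1 - abs(rowSums(Wn * W)))
    W <- Wn
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(S = Z %*% t(W), A = W %*% t(K_un), proj = K %*% t(W),
       converged = converged)
}

# Excess (Fisher) kurtosis, population formula: zero for a Gaussian,
# 3 for a Laplace distribution.
excess_kurtosis <- function(x) {
  x <- x - mean(x)
  v <- mean(x^2)
  if (v == 0) return(0)
  mean(x^4) / v^2 - 3
}

# icasso-style per-cluster stability index: mean absolute correlation
# within the cluster minus mean absolute correlation to all components
# outside it.
cluster_stability <- function(abscor, clusters) {
  vapply(sort(unique(clusters)), function(k) {
    inside <- clusters == k
    intra <- mean(abscor[inside, inside])
    extra <- if (all(inside)) 0 else mean(abscor[inside, !inside])
    intra - extra
  }, numeric(1))
}

#' Bootstrapped ICA stability scan over candidate component counts
#'
#' For each candidate N, runs symmetric fastICA with the pow3 nonlinearity
#' `runs` times, each run on a bootstrap resample of the retained reactions
#' and from a random initial condition. Every estimated component is mapped
#' back to the original rows by projecting the full loading matrix through
#' that run's learned unmixing, the pool is clustered into N groups by
#' average-linkage agglomeration on the dissimilarity `1 - |cor|`, and each
#' cluster's stability index (mean within-cluster minus mean
#' between-cluster absolute correlation) is recorded, sorted descending.
#' Components that reflect resample-specific structure rather than a real
#' source do not reappear across bootstraps, so their clusters score low.
#' Non-convergent runs are logged and excluded; if fewer than two
#' convergent runs remain at some N there is no run pair to compare and the
#' profile for that N is empty (nothing reproducible).
#'
#' @param cl A `combined_loadings` from [concat_and_filter()].
#' @param n_range Integer candidate component counts (all below the column
#'   count).
#' @param runs ICA restarts per candidate N (>= 2).
#' @param seed Master RNG seed; the scan is reproducible given the seed.
#' @return A `stability_scan`: list with `profiles` (per-N numeric vectors
#'   of sorted stability indices), `n_range`, `runs`, `n_excluded`,
#'   `nonlinearity` and `seed`.
#' @export
stability_scan <- function(cl, n_range = 2:10, runs = 20L, seed = 1L) {
  stopifnot(runs >= 2L)
  if (max(n_range) >= ncol(cl$loadings))
    stop_degenerate("candidate N must be below the number of loading columns")
  X <- cl$loadings
  excluded <- 0L
  profiles <- with_private_seed(seed, function() {
    out <- list()
    for (N in n_range) {
      comps <- vector("list", runs)
      ok <- logical(runs)
      for (r in seq_len(runs)) {
        idx <- sample.int(nrow(X), replace = TRUE)
        fit <- tryCatch(fastica_pow3(X[idx, , drop = FALSE], N),
                        error = function(e) NULL)
        ok[r] <- !is.null(fit) && fit$converged
        comps[[r]] <- if (is.null(fit)) NULL else X %*% fit$proj
      }
      excluded <<- excluded + sum(!ok)
      comps <- comps[ok]
      if (length(comps) < 2L) {
        # nothing reproducible at this N: no convergent run pair to compare
        out[[as.character(N)]] <- numeric(0)
        next
      }
      pool <- do.call(cbind, comps)
      abscor <- abs(stats::cor(pool))
      hc <- stats::hclust(stats::as.dist(1 - abscor), method = "average")
      clusters <- stats::cutree(hc, k = N)
      out[[as.character(N)]] <- sort(cluster_stability(abscor, clusters),
                                     decreasing = TRUE)
    }
    out
  })
  structure(list(profiles = profiles, n_range = n_range, runs = runs,
                 n_excluded = excluded, nonlinearity = "pow3", seed = seed),
            class = "stability_scan")
}

#' Choose the optimal component count from a stability scan
#'
#' All per-cluster stability values across the scan, indexed by cluster
#' rank, are split by 2-means into a high-stability and a low-stability
#' group (centroids initialised at the extremes). The mean stability at
#' each cluster rank forms a curve that starts on the high-centroid side
#' and descends towards the low centroid; the optimal N is the last rank
#' before this curve crosses the boundary between the two groups (the
#' centroid midpoint), i.e. the last rank whose mean stability still
#' belongs to the high-stability group. If the curve never crosses, the
#' largest rank with data is returned.
#'
#' @param scan A `stability_scan` covering at least 3 candidate N.
#' @return Integer optimal component count.
#' @export
choose_optimal_n <- function(scan) {
  if (length(scan$profiles) < 3L) stop("scan must cover at least 3 values of N")
  long <- do.call(rbind, lapply(names(scan$profiles), function(nm) {
    v <- scan$profiles[[nm]]
    if (length(v) == 0L) return(NULL)
    data.frame(rank = seq_along(v), value = v)
  }))
  if (is.null(long))
    stop_degenerate("no stability values: no candidate N had a convergent run pair")
  if (length(unique(long$value)) < 2L)
    stop_degenerate("degenerate 2-means clustering of stability values")
  km <- stats::kmeans(long$value,
                      centers = matrix(c(max(long$value), min(long$value)), 2))
  if (any(km$size == 0L) || diff(range(km$centers)) == 0)
    stop_degenerate("degenerate 2-means clustering of stability values")
  boundary <- mean(km$centers)
  ranks <- seq_len(max(long$rank))
  m <- vapply(ranks, function(r) mean(long$value[long$rank == r]), numeric(1))
  cross <- which(m < boundary)
  if (length(cross) == 0L) return(max(ranks))
  max(min(cross) - 1L, 1L)
}

#' High-replication ICA with kurtosis filtering
#'
#' Reruns symmetric pow3 fastICA with `n` components once per replicate,
#' seeding each run explicitly with `seed + run index`. Components whose
#' excess kurtosis lies outside `(-kurtosis_bound, kurtosis_bound)` are
#' retained (super- or sub-Gaussian features; a Gaussian component has
#' excess kurtosis 0 and is dropped). Each retained component is assigned
#' to the input column carrying its largest absolute mixing weight (ties to
#' the lower column index) and that column's estimation frequency is
#' incremented.
#'
#' @param cl A `combined_loadings`.
#' @param n Component count (from [choose_optimal_n()]).
#' @param runs Number of replicate runs.
#' @param kurtosis_bound Retention bound on |excess kurtosis| (default 1).
#' @param seed Master seed; run `r` uses `seed + r`.
#' @return A `distinct_features`: list with `optimal_n`, `frequency`
#'   (named per-column counts), `kurtosis` (per retained component records),
#'   `runs`, `n_failed`, `provenance`, and empty `selected`/`knee_index`
#'   until [knee_select()] fills them.
#' @export
final_ica <- function(cl, n, runs = 200L, kurtosis_bound = 1, seed = 1L) {
  stopifnot(n >= 1L)
  X <- cl$loadings
  freq <- stats::setNames(integer(ncol(X)), colnames(X))
  recs <- list()
  failed <- 0L
  for (r in seq_len(runs)) {
    fit <- with_private_seed(seed + r, function() fastica_pow3(X, n))
    if (!fit$converged) {
      failed <- failed + 1L
      next
    }
    for (j in seq_len(n)) {
      k <- excess_kurtosis(fit$S[, j])
      if (abs(k) >= kurtosis_bound) {
        col <- which.max(abs(fit$A[j, ]))
        freq[col] <- freq[col] + 1L
        recs[[length(recs) + 1L]] <- data.frame(
          run = r, ic = j, kurtosis = k, column = colnames(X)[col],
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(optimal_n = as.integer(n), frequency = freq,
                 kurtosis = if (length(recs)) do.call(rbind, recs) else NULL,
                 runs = runs, n_failed = failed, seed = seed,
                 provenance = cl$provenance,
                 selected = NULL, knee_index = NULL),
            class = "distinct_features")
}

#' Knee-point selection of distinct features
#'
#' Sorts the estimation frequencies descending and finds the knee of the
#' curve: the rank whose point lies farthest above the chord joining the
#' first and last points. All columns at or left of the knee are selected
#' as the features distinct between the conditions, with their provenance
#' (condition, source component). A flat or strictly linear curve has no
#' knee; the fallback selects nothing and warns.
#'
#' @param features A `distinct_features` from [final_ica()].
#' @param tol Minimum above-chord height for a knee to count.
#' @return The `distinct_features` with `selected` (provenance rows of the
#'   chosen columns, with frequencies) and `knee_index` filled.
#' @export
knee_select <- function(features, tol = 1e-9) {
  f <- features$frequency
  if (length(f) == 0L) stop("no frequencies to select from")
  ord <- order(f, decreasing = TRUE)
  y <- as.numeric(f[ord])
  L <- length(y)
  if (L < 3L || y[1] == y[L]) {
    warning("frequency curve has no knee; selecting no features")
    features$selected <- features$provenance[0, ]
    features$knee_index <- NA_integer_
    return(features)
  }
  x <- seq_len(L)
  chord <- y[1] + (y[L] - y[1]) * (x - 1) / (L - 1)
  above <- y - chord
  if (max(above) <= tol) {
    warning("frequency curve has no knee; selecting no features")
    features$selected <- features$provenance[0, ]
    features$knee_index <- NA_integer_
    return(features)
  }
  knee <- which.max(above)
  chosen <- names(f)[ord[seq_len(knee)]]
  sel <- features$provenance[match(chosen, features$provenance$column), ]
  sel$frequency <- as.integer(f[chosen])
  rownames(sel) <- NULL
  features$selected <- sel
  features$knee_index <- as.integer(knee)
  features
}

#' Compare two conditions end to end
#'
#' Convenience wrapper chaining [concat_and_filter()], [stability_scan()],
#' [choose_optimal_n()], [final_ica()] and [knee_select()]. Deterministic
#' given the master seed.
#'
#' @param lm1,lm2 Rotated [loading_matrix] objects.
#' @param n_range,scan_runs Stability-scan settings.
#' @param final_runs,kurtosis_bound High-replication ICA settings.
#' @param seed Master seed.
#' @return List with `combined`, `scan`, `optimal_n` and `features` (with
#'   selection filled).
#' @export
compare_conditions <- function(lm1, lm2, n_range = 2:10, scan_runs = 20L,
                               final_runs = 200L, kurtosis_bound = 1,
                               seed = 1L) {
  cl <- concat_and_filter(lm1, lm2)
  scan <- stability_scan(cl, n_range = n_range, runs = scan_runs, seed = seed)
  n_opt <- choose_optimal_n(scan)
  feats <- knee_select(final_ica(cl, n_opt, runs = final_runs,
                                 kurtosis_bound = kurtosis_bound, seed = seed))
  list(combined = cl, scan = scan, optimal_n = n_opt, features = feats)
}

#' Write comparison outputs as TSV/JSON
#' @param features A `distinct_features` (after [knee_select()]).
#' @param path Output TSV path for the frequency table and selection.
#' @return `path`, invisibly.
#' @export
write_features_tsv <- function(features, path) {
  df <- data.frame(column = names(features$frequency),
                   frequency = as.integer(features$frequency),
                   selected = names(features$frequency) %in%
                     features$selected$column,
                   stringsAsFactors = FALSE)
  df <- df[order(-df$frequency, df$column), ]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
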