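lmat <- function(ids, L, label) loading_matrix(ids, L, rep(1 / ncol(as.matrix(L)),
  ncol(as.matrix(L))), condition_label = label, rotated = TRUE)

make_cl <- function(X, label1 = "c1") {
  # build a combined_loadings directly for unit tests of downstream stages
  colnames(X) <- sprintf("%s.PC%d", label1, seq_len(ncol(X)))
  structure(list(reaction_ids = sprintf("r%04d", seq_len(nrow(X))),
                 loadings = X,
                 provenance = data.frame(column = colnames(X),
                                         condition = label1,
                                         component = seq_len(ncol(X)),
                                         stringsAsFactors = FALSE),
                 cutoff = 0), class = "combined_loadings")
}

test_that("row filter cutoff follows the median + mean-deviation rule", {
  ids <- c("r1", "r2", "r3", "r4")
  lm1 <- lmat(ids, cbind(c(1, 0, 0, 0), c(0, 0.9, 0, 0)), "c1")
  lm2 <- lmat(ids, cbind(c(0, 0, 0.1, 0), c(0, 0, 0, 0.05)), "c2")
  cl <- concat_and_filter(lm1, lm2)
  # maxima (1, .9, .1, .05): median .5, mean .5125, mean abs dev .4375
  expect_equal(cl$cutoff, 0.9375)            # [DERIVED: by hand]
  expect_equal(cl$reaction_ids, "r1")        # only the 1.0 row survives
  expect_equal(cl$provenance$column, c("c1.PC1", "c1.PC2", "c2.PC1", "c2.PC2"))
  expect_equal(cl$provenance$condition, c("c1", "c1", "c2", "c2"))
  expect_equal(cl$provenance$component, c(1L, 2L, 1L, 2L))
})

test_that("concatenation zero-fills reactions absent from one condition", {
  lm1 <- lmat(c("a", "b"), cbind(c(2, 2)), "c1")
  lm2 <- lmat(c("b", "c"), cbind(c(2, 2)), "c2")
  cl <- concat_and_filter(lm1, lm2)
  expect_equal(sort(cl$reaction_ids), c("a", "b", "c"))
  expect_equal(unname(cl$loadings["a", ]), c(2, 0))
  expect_equal(unname(cl$loadings["c", ]), c(0, 2))
  un <- lmat(c("a", "b"), cbind(c(2, 2)), "c1"); un$rotated <- FALSE
  expect_error(concat_and_filter(un, lm2), "varimax-rotated")
})

test_that("excess kurtosis separates Laplace from Gaussian", {
  set.seed(21)
  expect_equal(fluxmodules:::excess_kurtosis(fluxmodules:::rlaplace(2e5)),
               3, tolerance = 0.2)           # [DERIVED: Laplace kurtosis 6]
  expect_equal(fluxmodules:::excess_kurtosis(rnorm(2e5)), 0, tolerance = 0.1)
  expect_equal(fluxmodules:::excess_kurtosis(rep(1, 10)), 0)
})

test_that("optimal N is the last rank in the high-stability group", {
  # constructed scan: ranks 1-5 stable at ~0.95, deeper ranks ~0.2
  profiles <- list("4" = rep(0.95, 4),
                   "6" = c(rep(0.95, 5), 0.2),
                   "8" = c(rep(0.95, 5), 0.21, 0.2, 0.19))
  scan <- structure(list(profiles = profiles), class = "stability_scan")
  expect_equal(choose_optimal_n(scan), 5L)   # [DERIVED: boundary ~ 0.58]
  # never crossing: one low outlier at rank 3, but the rank-3 mean stays
  # above the boundary (0.575 < 0.7), so the deepest rank is returned
  allhigh <- structure(list(profiles = list("3" = c(0.95, 0.95, 0.2),
                                            "4" = rep(0.95, 4),
                                            "5" = rep(0.95, 5))),
                       class = "stability_scan")
  expect_equal(choose_optimal_n(allhigh), 5L)  # [DERIVED: by hand]
  expect_error(choose_optimal_n(structure(list(profiles = profiles[1:2]),
                                          class = "stability_scan")),
               "at least 3")
  empty <- structure(list(profiles = list("2" = numeric(0), "3" = numeric(0),
                                          "4" = numeric(0))),
                     class = "stability_scan")
  expect_error(choose_optimal_n(empty), class = "fluxmodules_degenerate")
  flat <- structure(list(profiles = list("2" = c(0.5, 0.5), "3" = rep(0.5, 3),
                                         "4" = rep(0.5, 4))),
                    class = "stability_scan")
  expect_error(choose_optimal_n(flat), class = "fluxmodules_degenerate")
})

test_that("scan rejects candidate N at or above the column count", {
  X <- matrix(rnorm(40), 10, 4)
  expect_error(stability_scan(make_cl(X), n_range = 2:4),
               class = "fluxmodules_degenerate")
})

test_that("knee selection matches the brute-force oracle", {
  f <- structure(list(
    optimal_n = 3L,
    frequency = c(a = 100L, b = 98L, c = 96L, d = 10L, e = 9L, f = 8L),
    provenance = data.frame(column = letters[1:6], condition = "c1",
                            component = 1:6, stringsAsFactors = FALSE)),
    class = "distinct_features")
  out <- knee_select(f)
  expect_equal(out$knee_index, 3L)
  expect_equal(out$knee_index, brute_knee(c(100, 98, 96, 10, 9, 8)))
  expect_setequal(out$selected$column, c("a", "b", "c"))
  expect_equal(out$selected$frequency[out$selected$column == "a"], 100L)
  # strictly linear and flat curves have no knee
  lin <- f; lin$frequency <- c(a = 10L, b = 8L, c = 6L, d = 4L)
  expect_warning(outl <- knee_select(lin), "no knee")
  expect_equal(nrow(outl$selected), 0L)
  flat <- f; flat$frequency <- c(a = 5L, b = 5L, c = 5L)
  expect_warning(outf <- knee_select(flat), "no knee")
  expect_true(is.na(outf$knee_index))
})

test_that("final ICA drops Gaussian components and keeps heavy-tailed ones", {
  set.seed(31)
  # pure Gaussian mixtures: nothing super-Gaussian to retain
  Xg <- matrix(rnorm(600 * 4), 600, 4)
  fg <- final_ica(make_cl(Xg), n = 2L, runs = 10L, seed = 5)
  retained_g <- sum(fg$frequency)
  # two planted Laplace sources mixed into four columns
  S <- cbind(fluxmodules:::rlaplace(600), fluxmodules:::rlaplace(600))
  Xl <- S %*% matrix(c(1, 0.2, 0.1, 1, 0.3, 1, 1, 0.1), 2, 4) +
    0.01 * matrix(rnorm(600 * 4), 600, 4)
  fl <- final_ica(make_cl(Xl), n = 2L, runs = 10L, seed = 5)
  expect_lt(retained_g, (10L - fg$n_failed) * 2L * 0.3)
  expect_equal(sum(fl$frequency), (10L - fl$n_failed) * 2L)
  expect_true(all(fl$kurtosis$kurtosis >= 1))
})

test_that("overfitting a planted two-source mixture lowers stability", {
  set.seed(41)
  S <- cbind(fluxmodules:::rlaplace(500), fluxmodules:::rlaplace(500))
  X <- S %*% matrix(c(1, 0.1, 0.2, 1, 1, 0.4, 0.3, 1), 2, 4) +
    0.01 * matrix(rnorm(500 * 4), 500, 4)
  scan <- stability_scan(make_cl(X), n_range = 2:3, runs = 10L, seed = 2)
  expect_length(scan$profiles[["2"]], 2L)
  expect_length(scan$profiles[["3"]], 3L)
  # only two real sources: the spurious third cluster is clearly less
  # stable than both true-rank clusters  [DERIVED: planted design]
  expect_gt(min(scan$profiles[["2"]]) - scan$profiles[["3"]][3], 0.1)
  expect_true(all(diff(scan$profiles[["3"]]) <= 0))
})

test_that("the full comparison recovers the planted sources deterministically", {
  p <- make_planted_loadings(seed = 7)
  res <- compare_conditions(p$lm1, p$lm2, n_range = 2:5, scan_runs = 10L,
                            final_runs = 40L, seed = 2)
  expect_equal(res$optimal_n, 3L)
  expect_equal(nrow(res$features$selected), 3L)
  # selected columns are exactly the planted ones
  planted_cols <- sprintf("cond%d.PC%d", p$planted$condition, p$planted$column)
  expect_setequal(res$features$selected$column, planted_cols)
  res2 <- compare_conditions(p$lm1, p$lm2, n_range = 2:5, scan_runs = 10L,
                             final_runs = 40L, seed = 2)
  expect_identical(res$features$frequency, res2$features$frequency)
  expect_identical(res$scan$profiles, res2$scan$profiles)
  f <- tempfile(fileext = ".tsv")
  write_features_tsv(res$features, f)
  back <- read.delim(f)
  expect_equal(sum(back$selected), 3L)
  expect_equal(back$frequency[1], max(res$features$frequency))
})
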