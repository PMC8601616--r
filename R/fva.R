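# Linear programming over the flux polytope {S v = 0, lb <= v <= ub}.
# Solved in shifted coordinates x = v - lb >= 0 with the simplex method
# (boot::simplex); equality rows are sign-flipped to keep right-hand sides
# nonnegative as the solver requires.
solve_flux_lp <- function(obj, S, lb, ub, maximize = TRUE, eps = 1e-9) {
  n <- length(lb)
  b3 <- as.numeric(-S %*% lb)
  A3 <- S
  flip <- b3 < 0
  A3[flip, ] <- -A3[flip, , drop = FALSE]
  b3 <- abs(b3)
  keep <- rowSums(A3 != 0) > 0 | b3 != 0
  res <- boot::simplex(a = obj, A1 = diag(n), b1 = ub - lb,
                       A3 = A3[keep, , drop = FALSE], b3 = b3[keep],
                       maxi = maximize, eps = eps,
                       n.iter = max(200L, 20L * n))
  if (res$solved != 1)
    stop("LP ", if (res$solved == 0) "did not converge" else "infeasible",
         " (flux polytope may be empty)")
  v <- as.numeric(res$soln) + lb
  list(value = sum(obj * v), v = v)
}

#' Flux variability analysis
#'
#' For every reaction, minimises and maximises its flux over the steady-state
#' polytope of the space by linear programming, giving the achievable flux
#' range \[vmin, vmax\].
#'
#' @param space A [flux_space].
#' @param eps LP feasibility/optimality tolerance.
#' @return An `fva_result`: data frame with columns `reaction_id`, `vmin`,
#'   `vmax`. The LP vertex solutions are attached as attribute `vertices`
#'   (reactions x 2n matrix); their average is an interior point of the
#'   polytope used to seed the sampler.
#' @export
run_fva <- function(space, eps = 1e-9) {
  model <- space$model
  n <- n_reactions(model)
  vmin <- vmax <- numeric(n)
  verts <- matrix(0, n, 2L * n)
  for (j in seq_len(n)) {
    obj <- numeric(n)
    obj[j] <- 1
    if (model$lb[j] == model$ub[j]) {
      # fixed flux: LP is trivial, but we still need a feasible point
      lo <- solve_flux_lp(obj, model$S, model$lb, model$ub, maximize = FALSE, eps = eps)
      vmin[j] <- vmax[j] <- model$lb[j]
      verts[, 2L * j - 1L] <- verts[, 2L * j] <- lo$v
      next
    }
    lo <- solve_flux_lp(obj, model$S, model$lb, model$ub, maximize = FALSE, eps = eps)
    hi <- solve_flux_lp(obj, model$S, model$lb, model$ub, maximize = TRUE, eps = eps)
    vmin[j] <- max(lo$value, model$lb[j])
    vmax[j] <- min(hi$value, model$ub[j])
    if (vmin[j] > vmax[j]) vmin[j] <- vmax[j] <- (vmin[j] + vmax[j]) / 2
    verts[, 2L * j - 1L] <- lo$v
    verts[, 2L * j] <- hi$v
  }
  res <- data.frame(reaction_id = model$reactions$id, vmin = vmin, vmax = vmax,
                    stringsAsFactors = FALSE)
  class(res) <- c("fva_result", "data.frame")
  attr(res, "vertices") <- verts
  res
}

#' Remove blocked reactions and tighten bounds to FVA ranges
#'
#' Reactions whose flux range lies entirely within `tol` of zero cannot carry
#' flux anywhere in the polytope and are removed; the retained reactions'
#' bounds are replaced by their FVA ranges, which become the box constraints
#' of the moment approximation.
#'
#' @param space A [flux_space].
#' @param fva Result of [run_fva()] on `space`.
#' @param tol Blocked-reaction tolerance in mmol gDW^-1 h^-1.
#' @return A reduced `flux_space` whose `removed_ids` field records the
#'   blocked reactions.
#' @export
remove_blocked <- function(space, fva, tol = 1e-6) {
  model <- space$model
  stopifnot(identical(fva$reaction_id, model$reactions$id))
  blocked <- abs(fva$vmin) < tol & abs(fva$vmax) < tol
  if (all(blocked))
    stop_degenerate("every reaction is blocked at tolerance ", tol)
  keep <- which(!blocked)
  model$S <- model$S[, keep, drop = FALSE]
  model$reactions <- model$reactions[keep, , drop = FALSE]
  rownames(model$reactions) <- NULL
  model$lb <- stats::setNames(fva$vmin[keep], model$reactions$id)
  model$ub <- stats::setNames(fva$vmax[keep], model$reactions$id)
  model$exchange <- detect_exchange(model$S)
  out <- flux_space(model, space$condition_label, space$applied_overrides)
  out$removed_ids <- fva$reaction_id[blocked]
  class(out) <- c("reduced_flux_space", class(out))
  out
}

#' Dimension of the steady-state flux space
#'
#' Number of reactions minus the rank of the stoichiometric matrix, with
#' rank determined from singular values above `rtol` times the largest.
#'
#' @param space A `flux_space` (typically reduced).
#' @param rtol Relative singular-value cutoff.
#' @return Integer null-space dimension.
#' @export
nullspace_dimension <- function(space, rtol = 1e-9) {
  S <- space$model$S
  sv <- svd(S, nu = 0, nv = 0)$d
  ncol(S) - sum(sv > rtol * max(sv, 0) )
}

# Orthonormal null-space basis of S (columns), same cutoff as
# nullspace_dimension.
nullspace_basis <- function(S, rtol = 1e-9) {
  dec <- svd(S, nv = ncol(S))
  r <- sum(dec$d > rtol * max(dec$d, 0))
  if (r == ncol(S)) return(matrix(0, ncol(S), 0))
  dec$v[, (r + 1L):ncol(S), drop = FALSE]
}

#' Write an FVA result and removal log as TSV
#' @param fva An `fva_result`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_fva_table <- function(fva, path) {
  utils::write.table(as.data.frame(fva), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
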