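#' Pipeline run configuration
#'
#' Bundles everything one comparison run needs: the model, two or more
#' named constraint conditions, tolerances, moment-approximation settings,
#' the PCA cumulative-variance threshold and the ICA comparison parameters.
#' Defaults follow the method's standard settings (default bounds +/-1000,
#' blocked tolerance 1e-6, EP 1000 iterations / precision 1e-5 / beta 1e8,
#' PCA threshold 0.999, kurtosis bound 1); the ICA replication is sized by
#' the caller.
#'
#' @param model Either a [metabolic_model] or a path to an SBML file.
#' @param conditions Named list (>= 2 entries); each entry a list with
#'   optional `block` (reaction ids set to zero flux) and `overrides`
#'   (named list of `c(lb, ub)`).
#' @param add_release Optional cytosolic metabolite ids given release
#'   reactions before constraining.
#' @param method `"ep"` or `"sampling"` for the moment stage.
#' @param n_samples Samples when `method = "sampling"`.
#' @param blocked_tol Blocked-reaction tolerance.
#' @param ep An [ep_config].
#' @param pca_threshold Cumulative variance threshold for retained PCs.
#' @param n_range,scan_runs,final_runs,kurtosis_bound ICA comparison
#'   settings.
#' @param seed Master seed for every stochastic stage.
#' @param out_dir Output directory (created if needed).
#' @param cache Reuse content-addressed per-stage caches under `out_dir`.
#' @return A `run_config` list.
#' @export
run_config <- function(model, conditions, add_release = character(),
                       method = c("ep", "sampling"), n_samples = 10000L,
                       blocked_tol = 1e-6, ep = ep_config(),
                       pca_threshold = 0.999, n_range = 2:10,
                       scan_runs = 20L, final_runs = 200L,
                       kurtosis_bound = 1, seed = 1L,
                       out_dir = tempfile("fluxmodules_run_"), cache = TRUE) {
  method <- match.arg(method)
  if (length(conditions) < 2L || is.null(names(conditions)) ||
      any(!nzchar(names(conditions))))
    stop("at least two named conditions are required")
  stopifnot(pca_threshold > 0, pca_threshold <= 1)
  structure(list(model = model, conditions = conditions,
                 add_release = add_release, method = method,
                 n_samples = as.integer(n_samples),
                 blocked_tol = blocked_tol, ep = ep,
                 pca_threshold = pca_threshold, n_range = n_range,
                 scan_runs = as.integer(scan_runs),
                 final_runs = as.integer(final_runs),
                 kurtosis_bound = kurtosis_bound, seed = as.integer(seed),
                 out_dir = out_dir, cache = cache),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with fields mirroring [run_config()] arguments;
#'   `conditions` is a map of condition name to `block`/`overrides`.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$model)) stop("config must name a model file")
  if (is.null(y$conditions)) stop("config must define conditions")
  ep_args <- y$ep %||% list()
  args <- y[setdiff(names(y), c("ep", "n_range"))]
  args$ep <- do.call(ep_config, ep_args)
  if (!is.null(y$n_range)) args$n_range <- y$n_range[1]:y$n_range[2]
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Content-addressed stage cache: the stage result is stored under the md5
# of its serialized inputs, so editing a downstream parameter never
# triggers an upstream recompute.
stage_cached <- function(cfg, stage, inputs, fun) {
  if (!isTRUE(cfg$cache)) return(fun())
  dir <- file.path(cfg$out_dir, "cache")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  saveRDS(inputs, tmp)
  key <- unname(tools::md5sum(tmp))
  f <- file.path(dir, paste0(stage, "-", key, ".rds"))
  if (file.exists(f)) return(readRDS(f))
  res <- fun()
  saveRDS(res, f)
  res
}

#' Run the full comparison pipeline
#'
#' Executes, per condition: constraint application, FVA preprocessing with
#' blocked-reaction removal, moment approximation (EP or sampling), PCA of
#' the flux covariance, varimax rotation of the components reaching the
#' cumulative-variance threshold, and global module extraction. Across the
#' first two conditions it then computes differential flux z-scores, runs
#' the ICA comparison to select the distinct rotated components, extracts
#' the distinct modules, and exports the distinct-modules reaction graph.
#' Every artefact is written under `config$out_dir` together with a JSON
#' manifest recording parameters, seeds and per-stage wall times.
#'
#' @param config A [run_config].
#' @return Invisibly, a list with all stage results (`spaces`, `reduced`,
#'   `moments`, `loadings`, `global_modules`, `zscores`, `comparison`,
#'   `distinct_modules`, `graph`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(parameters = list(
    method = config$method, blocked_tol = config$blocked_tol,
    ep = unclass(config$ep), pca_threshold = config$pca_threshold,
    n_range = range(config$n_range), scan_runs = config$scan_runs,
    final_runs = config$final_runs, kurtosis_bound = config$kurtosis_bound,
    seed = config$seed), stages = list())
  # A stage completes either with its computed result or, when the data are
  # degenerate (classed fluxmodules_degenerate, e.g. every reaction blocked
  # in a condition), with an empty result plus a note in the manifest. Any
  # other error aborts the run with the stage name.
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest$stages[[name]]$seconds <<-
      round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  note <- function(name, msg) {
    manifest$stages[[name]]$note <<- msg
    message("stage '", name, "': ", msg)
  }
  degenerate_or_stop <- function(e, fallback, name) {
    if (!inherits(e, "fluxmodules_degenerate")) stop(e)
    note(name, conditionMessage(e))
    fallback
  }
  empty_moments <- function() flux_moments(character(0), numeric(0), numeric(0),
                                           matrix(0, 0, 0), method = config$method)
  empty_loadings <- function(nm) loading_matrix(character(0), matrix(0, 0, 0),
                                                numeric(0), condition_label = nm,
                                                rotated = TRUE)

  model <- t_stage("read_model", {
    m <- if (is.character(config$model)) read_sbml_model(config$model) else config$model
    if (length(config$add_release))
      m <- add_release_reactions(m, config$add_release)
    m
  })

  cn <- names(config$conditions)
  spaces <- t_stage("constraints", lapply(cn, function(nm) {
    sp <- apply_default_bounds(model, condition_label = nm)
    cd <- config$conditions[[nm]]
    if (!is.null(cd$block) && length(cd$block))
      sp <- block_reactions(sp, unlist(cd$block), condition_label = nm)
    for (r in names(cd$overrides)) {
      b <- as.numeric(cd$overrides[[r]])
      if (!(r %in% sp$model$reactions$id)) stop("override for unknown reaction ", r)
      sp$model$lb[r] <- b[1]
      sp$model$ub[r] <- b[2]
      sp$applied_overrides[[r]] <- c(lb = b[1], ub = b[2])
    }
    validate_model(sp$model)
    sp
  }))
  names(spaces) <- cn

  reduced <- t_stage("preprocess", lapply(cn, function(nm)
    tryCatch(stage_cached(config, "preprocess",
                          list(spaces[[nm]], config$blocked_tol), function() {
      fva <- run_fva(spaces[[nm]])
      remove_blocked(spaces[[nm]], fva, tol = config$blocked_tol)
    }), fluxmodules_degenerate = function(e)
      degenerate_or_stop(e, NULL, "preprocess"))))
  names(reduced) <- cn

  moments <- t_stage("moments", lapply(reduced, function(rs) {
    if (is.null(rs)) return(empty_moments())
    stage_cached(config, paste0("moments_", config$method),
                 list(rs, config$method, config$ep, config$n_samples, config$seed),
                 function() {
      if (config$method == "ep") ep_moments(rs, config$ep)
      else sample_moments(rs, n_samples = config$n_samples, seed = config$seed)
    })
  }))

  loadings <- t_stage("pca_rotation", lapply(cn, function(nm) {
    if (length(moments[[nm]]$reaction_ids) == 0L) return(empty_loadings(nm))
    lm <- pca_covariance(moments[[nm]]$covariance, condition_label = nm)
    k <- select_components(lm, config$pca_threshold)
    varimax_rotate(lm, k)
  }))
  names(loadings) <- cn

  gmods <- t_stage("global_modules", lapply(loadings, global_modules))

  empty_z <- structure(
    data.frame(reaction_id = character(0), mean1 = numeric(0),
               var1 = numeric(0), mean2 = numeric(0), var2 = numeric(0),
               z = numeric(0), p = numeric(0), membership = character(0),
               degenerate = logical(0), stringsAsFactors = FALSE),
    class = c("differential_flux", "data.frame"))
  z <- t_stage("diffstats", tryCatch(flux_zscores(moments[[1]], moments[[2]]),
    fluxmodules_degenerate = function(e)
      degenerate_or_stop(e, empty_z, "diffstats")))
  sig <- significant_reactions(z, 0.05)

  empty_comparison <- list(combined = NULL, scan = NULL,
                           optimal_n = NA_integer_, features = NULL)
  comparison <- t_stage("ica_compare", tryCatch(stage_cached(
    config, "ica_compare",
    list(loadings[[1]], loadings[[2]], config$n_range, config$scan_runs,
         config$final_runs, config$kurtosis_bound, config$seed),
    function() compare_conditions(
      loadings[[1]], loadings[[2]], n_range = config$n_range,
      scan_runs = config$scan_runs, final_runs = config$final_runs,
      kurtosis_bound = config$kurtosis_bound, seed = config$seed)),
    fluxmodules_degenerate = function(e)
      degenerate_or_stop(e, empty_comparison, "ica_compare")))

  distinct <- t_stage("distinct_modules", {
    sel <- comparison$features$selected
    lapply(seq_len(NROW(sel)), function(i)
      extract_module(loadings[[sel$condition[i]]], sel$component[i]))
  })

  graph <- t_stage("networks", {
    mods <- distinct
    if (length(mods) == 0L) mods <- unlist(lapply(gmods, `[[`, "modules"),
                                           recursive = FALSE)
    g <- build_reaction_graph(mods %||% list(), model, significant_ids = sig)
    export_graph(g, file.path(config$out_dir, "distinct_modules"))
    g
  })

  # artefact tables
  for (nm in cn) {
    write_moments_tsv(moments[[nm]],
                      file.path(config$out_dir, paste0("moments_", nm, ".tsv")))
    write_loading_matrix(loadings[[nm]],
                         file.path(config$out_dir, paste0("loadings_", nm, ".tsv")))
    write_modules_tsv(gmods[[nm]],
                      file.path(config$out_dir, paste0("modules_", nm, ".tsv")),
                      model = model)
  }
  write_zscore_table(z, file.path(config$out_dir, "zscores.tsv"))
  if (!is.null(comparison$features))
    write_features_tsv(comparison$features,
                       file.path(config$out_dir, "distinct_features.tsv"))

  manifest$outputs <- list.files(config$out_dir, recursive = FALSE)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(model = model, spaces = spaces, reduced = reduced,
                 moments = moments, loadings = loadings,
                 global_modules = gmods, zscores = z, significant = sig,
                 comparison = comparison, distinct_modules = distinct,
                 graph = graph, manifest = manifest))
}
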