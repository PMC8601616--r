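#' Metabolic model container
#'
#' A `metabolic_model` holds the stoichiometry and annotation of a
#' genome-scale (or toy) metabolic reconstruction: a signed stoichiometric
#' matrix `S` (metabolites x reactions), per-reaction flux bounds in
#' mmol gDW^-1 h^-1, reversibility flags and subsystem/compartment
#' annotation. Boundary species are not part of `S`.
#'
#' @param model_id Character scalar identifying the model.
#' @param metabolites Data frame with columns `id`, `name`, `compartment`.
#' @param reactions Data frame with columns `id`, `name`, `subsystem`,
#'   `reversible` (logical), `gene_rule`.
#' @param S Numeric matrix, metabolites x reactions; dimnames are set from
#'   the id columns.
#' @param lb,ub Numeric vectors of lower/upper flux bounds, one per reaction.
#'
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(model_id, metabolites, reactions, S, lb, ub) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(reactions$subsystem)) reactions$subsystem <- "unassigned"
  reactions$subsystem[is.na(reactions$subsystem) | reactions$subsystem == ""] <- "unassigned"
  if (is.null(reactions$gene_rule)) reactions$gene_rule <- ""
  if (is.null(reactions$name)) reactions$name <- reactions$id
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  S <- as.matrix(S)
  dimnames(S) <- list(metabolites$id, reactions$id)
  m <- structure(list(
    model_id = model_id,
    metabolites = metabolites,
    reactions = reactions,
    S = S,
    lb = stats::setNames(as.numeric(lb), reactions$id),
    ub = stats::setNames(as.numeric(ub), reactions$id),
    exchange = detect_exchange(S)
  ), class = "metabolic_model")
  m$reactions$equation <- reaction_equations(m)
  validate_model(m)
  m
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("Metabolic model '%s': %d reactions, %d metabolites, %d exchange reactions\n",
              x$model_id, n_reactions(x), n_metabolites(x), sum(x$exchange)))
  invisible(x)
}

#' Number of reactions / metabolites in a model
#' @param model A `metabolic_model`.
#' @return Integer count.
#' @export
n_reactions <- function(model) nrow(model$reactions)

#' @rdname n_reactions
#' @export
n_metabolites <- function(model) nrow(model$metabolites)

# Exchange reactions touch exactly one (non-boundary) model metabolite.
detect_exchange <- function(S) {
  stats::setNames(colSums(S != 0) == 1L, colnames(S))
}

validate_model <- function(m) {
  if (nrow(m$reactions) == 0L) stop("model has zero reactions")
  if (ncol(m$S) != nrow(m$reactions) || nrow(m$S) != nrow(m$metabolites))
    stop("stoichiometric matrix dimensions do not match reaction/metabolite tables")
  if (anyDuplicated(m$reactions$id)) stop("duplicate reaction ids")
  if (anyDuplicated(m$metabolites$id)) stop("duplicate metabolite ids")
  if (any(m$lb > m$ub)) stop("lower bound exceeds upper bound for: ",
                             paste(m$reactions$id[m$lb > m$ub], collapse = ", "))
  invisible(TRUE)
}

# Human-readable equation strings rendered from the stoichiometry, with
# metabolite display names suffixed [compartment].
reaction_equations <- function(model) {
  disp <- paste0(model$metabolites$name, "[", model$metabolites$compartment, "]")
  vapply(seq_len(ncol(model$S)), function(j) {
    col <- model$S[, j]
    lhs <- which(col < 0)
    rhs <- which(col > 0)
    fmt <- function(idx, coef) {
      paste(ifelse(abs(coef) == 1, disp[idx],
                   paste(format(abs(coef), trim = TRUE), disp[idx])),
            collapse = " + ")
    }
    arrow <- if (model$reactions$reversible[j]) "<=>" else "=>"
    paste(fmt(lhs, col[lhs]), arrow, fmt(rhs, col[rhs]))
  }, character(1))
}

#' Add irreversible release reactions for cytosolic metabolites
#'
#' Appends, for each listed metabolite, one irreversible reaction moving it
#' from the cytosol to the extracellular space (stoichiometry -1 in the
#' cytosol, +1 extracellular), so that its secretion can appear in the flux
#' space. New reaction ids follow the scheme `EXC_OUT_<metabolite id>`.
#'
#' @param model A `metabolic_model`.
#' @param metabolite_ids Ids of cytosolic metabolites to release.
#' @param cytosol,extracellular Compartment ids of the cytosol and the
#'   extracellular space.
#' @param lb,ub Bounds of the added reactions (irreversible by default).
#' @return The model with the release reactions appended.
#' @export
add_release_reactions <- function(model, metabolite_ids,
                                  cytosol = "c", extracellular = "e",
                                  lb = 0, ub = 1000) {
  for (mid in metabolite_ids) {
    row <- match(mid, model$metabolites$id)
    if (is.na(row)) stop("metabolite not in model: ", mid)
    if (model$metabolites$compartment[row] != cytosol)
      stop("metabolite not cytosolic: ", mid)
    rid <- paste0("EXC_OUT_", mid)
    if (rid %in% model$reactions$id) stop("reaction id already present: ", rid)
    # reuse the extracellular counterpart (same display name) when it exists
    ext <- which(model$metabolites$name == model$metabolites$name[row] &
                   model$metabolites$compartment == extracellular)
    if (length(ext) == 0L) {
      ext_id <- paste0(mid, "_", extracellular)
      model$metabolites <- rbind(model$metabolites, data.frame(
        id = ext_id, name = model$metabolites$name[row],
        compartment = extracellular, stringsAsFactors = FALSE))
      model$S <- rbind(model$S, 0)
      rownames(model$S)[nrow(model$S)] <- ext_id
      ext <- nrow(model$S)
    } else ext <- ext[1L]
    newcol <- numeric(nrow(model$S))
    newcol[row] <- -1
    newcol[ext] <- 1
    model$S <- cbind(model$S, newcol)
    colnames(model$S)[ncol(model$S)] <- rid
    model$reactions <- rbind(model$reactions, data.frame(
      id = rid, name = paste("release of", model$metabolites$name[row]),
      subsystem = "Exchange reactions", reversible = FALSE, gene_rule = "",
      equation = "", stringsAsFactors = FALSE))
    model$lb <- c(model$lb, stats::setNames(lb, rid))
    model$ub <- c(model$ub, stats::setNames(ub, rid))
  }
  model$exchange <- detect_exchange(model$S)
  model$reactions$equation <- reaction_equations(model)
  validate_model(model)
  model
}

#' Define a flux space by applying the default bound set
#'
#' Resets every reaction's bounds from its reversibility flag: reversible
#' reactions to \[-1000, 1000\] and irreversible reactions to \[0, 1000\]
#' mmol gDW^-1 h^-1. The same rule applies to exchange reactions, whatever
#' their original (typically closed) bounds, so that all uptakes and
#' secretions are open in the default condition.
#'
#' @param model A `metabolic_model`.
#' @param condition_label Name of the resulting condition.
#' @param fmax Magnitude of the default bound (1000 by default).
#' @return A `flux_space`: the model with bounds applied plus the condition
#'   label and a record of overrides.
#' @export
apply_default_bounds <- function(model, condition_label = "default", fmax = 1000) {
  rev <- model$reactions$reversible
  model$lb[] <- ifelse(rev, -fmax, 0)
  model$ub[] <- fmax
  flux_space(model, condition_label, overrides = list())
}

#' Construct a flux space
#'
#' A `flux_space` is a model together with a named constraint condition: the
#' steady-state polytope \{v : S v = 0, lb <= v <= ub\}.
#'
#' @param model A `metabolic_model` whose bounds define the polytope.
#' @param condition_label Condition name.
#' @param overrides Named list recording per-reaction `(lb, ub)` overrides
#'   applied on top of the default bounds.
#' @return An object of class `flux_space`.
#' @export
flux_space <- function(model, condition_label, overrides = list()) {
  validate_model(model)
  structure(list(model = model, condition_label = condition_label,
                 applied_overrides = overrides),
            class = "flux_space")
}

#' @export
print.flux_space <- function(x, ...) {
  cat(sprintf("Flux space '%s': %d reactions, %d overrides\n",
              x$condition_label, n_reactions(x$model), length(x$applied_overrides)))
  invisible(x)
}

#' Block reactions in a flux space
#'
#' Sets both bounds of the listed reactions to zero (for example, closing
#' nutrient uptakes) and relabels the condition. The stoichiometry is never
#' altered.
#'
#' @param space A `flux_space`.
#' @param reaction_ids Ids of reactions to block.
#' @param condition_label Label of the new condition.
#' @return A new `flux_space` with the blocks recorded as overrides.
#' @export
block_reactions <- function(space, reaction_ids, condition_label = "constrained") {
  unknown <- setdiff(reaction_ids, space$model$reactions$id)
  if (length(unknown)) stop("unknown reaction id(s): ", paste(unknown, collapse = ", "))
  model <- space$model
  model$lb[reaction_ids] <- 0
  model$ub[reaction_ids] <- 0
  ov <- space$applied_overrides
  for (r in reaction_ids) ov[[r]] <- c(lb = 0, ub = 0)
  flux_space(model, condition_label, ov)
}

#' Write the reaction and metabolite tables of a model
#'
#' @param model A `metabolic_model`.
#' @param reactions_path,metabolites_path TSV output paths (`NULL` to skip).
#' @return Invisibly, the reaction table (with bounds).
#' @export
write_model_tables <- function(model, reactions_path = NULL, metabolites_path = NULL) {
  rt <- cbind(model$reactions, lb = unname(model$lb), ub = unname(model$ub),
              exchange = unname(model$exchange))
  if (!is.null(reactions_path))
    utils::write.table(rt, reactions_path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(metabolites_path))
    utils::write.table(model$metabolites, metabolites_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  invisible(rt)
}

#' Summarise a model as JSON
#' @param model A `metabolic_model`.
#' @param path Output path; `NULL` returns the JSON string.
#' @return The JSON string, invisibly when written to `path`.
#' @export
model_summary_json <- function(model, path = NULL) {
  s <- list(model_id = model$model_id,
            n_reactions = n_reactions(model),
            n_metabolites = n_metabolites(model),
            n_exchange = sum(model$exchange),
            n_reversible = sum(model$reactions$reversible),
            compartments = sort(unique(model$metabolites$compartment)),
            subsystems = sort(unique(model$reactions$subsystem)))
  js <- jsonlite::toJSON(s, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
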