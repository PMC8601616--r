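#' Default ubiquitous (currency) metabolite list
#'
#' Cofactor-like metabolites excluded from the calculation of
#' reaction-reaction connectivity, matched by metabolite base name,
#' compartment-insensitively and case-insensitively.
#'
#' @return Character vector of metabolite names.
#' @export
ubiquitous_metabolites <- function() {
  c("CoA", "ubiquinol", "ubiquinone", "NH3", "O2", "H2O", "H+",
    "ATP", "ADP", "AMP", "dADP", "dATP", "Pi", "PPi",
    "CTP", "CDP", "CMP", "dCTP", "dCDP", "dCMP",
    "UTP", "UDP", "UMP", "dUTP", "dUDP", "dUMP",
    "GTP", "GDP", "GMP", "dGTP", "dGDP", "dGMP",
    "ITP", "IDP", "IMP", "dITP", "dIDP", "dIMP",
    "TTP", "TDP", "TMP", "dTTP", "dTDP", "dTMP",
    "NADH", "NADPH", "NAD+", "NADP+", "FADH2", "FAD",
    "CO2", "Na+", "HCO3-")
}

# Metabolite rows of S that are not on the ubiquitous list (by name,
# compartment- and case-insensitive).
non_ubiquitous_rows <- function(model, ubiq) {
  !(tolower(model$metabolites$name) %in% tolower(ubiq))
}

# Undirected shared-metabolite edges among the given reactions: an edge
# joins two reactions sharing at least one non-ubiquitous metabolite
# (reactant or product, direction ignored), labelled with the shared
# metabolite ids. One edge per pair, no self edges.
shared_metabolite_edges <- function(model, reaction_ids, ubiq) {
  rows <- non_ubiquitous_rows(model, ubiq)
  P <- model$S[rows, reaction_ids, drop = FALSE] != 0
  adj <- crossprod(P)
  met_ids <- model$metabolites$id[rows]
  pairs <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  if (nrow(pairs) == 0L)
    return(data.frame(from = character(), to = character(),
                      metabolites = character(), stringsAsFactors = FALSE))
  data.frame(
    from = reaction_ids[pairs[, 1]],
    to = reaction_ids[pairs[, 2]],
    metabolites = apply(pairs, 1, function(ij)
      paste(met_ids[P[, ij[1]] & P[, ij[2]]], collapse = ",")),
    stringsAsFactors = FALSE)
}

#' Build a reaction graph from a module set
#'
#' Nodes are the union of the modules' reactions; two reactions are
#' connected if they share a non-ubiquitous reactant or product. Node
#' attributes record (1) the number of modules the reaction is involved in,
#' (2) the list of those modules, (3) its subsystem and (4) its chemical
#' equation, plus the condition tag, a significance flag and a hide flag
#' for extracellular-transport reactions (kept in exports, hidden for
#' display).
#'
#' @param modules List of `module` objects (e.g. from [global_modules()],
#'   possibly concatenated over conditions).
#' @param model The [metabolic_model] supplying stoichiometry and
#'   annotation.
#' @param ubiq Ubiquitous metabolite names ([ubiquitous_metabolites()] by
#'   default).
#' @param significant_ids Optional reaction ids to flag as significantly
#'   changed.
#' @param hide_subsystems Subsystems whose reactions get `hidden = TRUE`.
#' @return An [igraph::igraph] with the attributes above; edges carry the
#'   shared metabolite ids.
#' @export
build_reaction_graph <- function(modules, model, ubiq = ubiquitous_metabolites(),
                                 significant_ids = character(),
                                 hide_subsystems = "Extracellular transport") {
  mod_tags <- lapply(modules, function(m)
    paste0(if (nzchar(m$condition_label)) paste0(m$condition_label, ":") else "",
           m$component))
  all_ids <- unlist(lapply(modules, function(m) m$members$reaction_id))
  unknown <- setdiff(all_ids, model$reactions$id)
  if (length(unknown)) stop("module reaction(s) not in model: ",
                            paste(unknown, collapse = ", "))
  nodes <- sort(unique(all_ids))
  tag_of <- stats::setNames(vector("list", length(nodes)), nodes)
  cond_of <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_along(modules)) {
    for (r in modules[[i]]$members$reaction_id) {
      tag_of[[r]] <- c(tag_of[[r]], mod_tags[[i]])
      cond_of[[r]] <- c(cond_of[[r]], modules[[i]]$condition_label)
    }
  }
  ridx <- match(nodes, model$reactions$id)
  vdf <- data.frame(
    name = nodes,
    module_count = vapply(tag_of, length, integer(1)),
    modules = vapply(tag_of, paste, character(1), collapse = ","),
    condition = vapply(cond_of, function(x)
      paste(sort(unique(x)), collapse = "+"), character(1)),
    subsystem = model$reactions$subsystem[ridx],
    equation = model$reactions$equation[ridx],
    significant = nodes %in% significant_ids,
    first_neighbour = FALSE,
    hidden = tolower(model$reactions$subsystem[ridx]) %in% tolower(hide_subsystems),
    stringsAsFactors = FALSE)
  edf <- shared_metabolite_edges(model, nodes, ubiq)
  igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
}

#' Add first-neighbour reactions from the full model
#'
#' Reactions of the model that are not yet in the graph but share a
#' non-ubiquitous metabolite with any current node are added, flagged
#' `first_neighbour = TRUE`, and all shared-metabolite edges are
#' recomputed over the enlarged node set.
#'
#' @param g Graph from [build_reaction_graph()].
#' @param model The same [metabolic_model] the graph was built from.
#' @param ubiq Ubiquitous metabolite names.
#' @return The expanded graph.
#' @export
expand_first_neighbors <- function(g, model, ubiq = ubiquitous_metabolites()) {
  nodes <- igraph::V(g)$name
  rows <- non_ubiquitous_rows(model, ubiq)
  P <- model$S[rows, , drop = FALSE] != 0
  touched <- rowSums(P[, nodes, drop = FALSE]) > 0
  candidates <- setdiff(model$reactions$id[colSums(P[touched, , drop = FALSE]) > 0],
                        nodes)
  if (length(candidates) == 0L) return(g)
  ridx <- match(candidates, model$reactions$id)
  add <- data.frame(
    name = candidates, module_count = 0L, modules = "", condition = "",
    subsystem = model$reactions$subsystem[ridx],
    equation = model$reactions$equation[ridx],
    significant = FALSE, first_neighbour = TRUE,
    hidden = FALSE, stringsAsFactors = FALSE)
  old <- as.data.frame(igraph::vertex_attr(g), stringsAsFactors = FALSE)
  vdf <- rbind(old[, colnames(add)], add)
  vdf <- vdf[order(vdf$name), ]
  edf <- shared_metabolite_edges(model, vdf$name, ubiq)
  igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
}

#' Bipartite metabolite-reaction map of selected subsystems
#'
#' Extracts from a reaction graph the reactions annotated to the given
#' subsystems and builds the bipartite graph of those reactions with their
#' metabolites: directed edges run substrate -> reaction -> product.
#' Metabolite nodes carry their compartment; ubiquitous metabolites are
#' excluded from display by default.
#'
#' @param g A reaction graph.
#' @param subsystems Subsystem names of interest.
#' @param model The underlying [metabolic_model].
#' @param ubiq Ubiquitous names to exclude (set `character()` to keep all).
#' @return A directed bipartite [igraph::igraph]; vertex attribute `type`
#'   is `"metabolite"` or `"reaction"`.
#' @export
build_metabolic_map <- function(g, subsystems, model,
                                ubiq = ubiquitous_metabolites()) {
  keep <- igraph::V(g)$name[igraph::V(g)$subsystem %in% subsystems]
  if (length(keep) == 0L) stop("no reactions in subsystem(s): ",
                               paste(subsystems, collapse = ", "))
  rows <- non_ubiquitous_rows(model, if (length(ubiq)) ubiq else character())
  edges <- NULL
  mets <- character()
  for (r in keep) {
    col <- model$S[, r]
    for (i in which(col != 0 & rows)) {
      mid <- model$metabolites$id[i]
      mets <- c(mets, mid)
      edges <- rbind(edges, if (col[i] < 0) c(mid, r) else c(r, mid))
    }
  }
  mets <- sort(unique(mets))
  midx <- match(mets, model$metabolites$id)
  vdf <- data.frame(
    name = c(mets, sort(keep)),
    type = c(rep("metabolite", length(mets)), rep("reaction", length(keep))),
    label = c(model$metabolites$name[midx], sort(keep)),
    compartment = c(model$metabolites$compartment[midx],
                    rep("", length(keep))),
    stringsAsFactors = FALSE)
  edf <- as.data.frame(edges, stringsAsFactors = FALSE)
  names(edf) <- c("from", "to")
  igraph::graph_from_data_frame(edf, directed = TRUE, vertices = vdf)
}

#' Induced subgraph of a single module
#'
#' @param g A reaction graph whose nodes carry the `modules` attribute.
#' @param module_id Module tag (as stored in the attribute, e.g.
#'   `"unconstrained:3"`).
#' @return The induced subgraph on that module's reactions.
#' @export
single_module_view <- function(g, module_id) {
  has <- vapply(strsplit(igraph::V(g)$modules, ","), function(tags)
    module_id %in% tags, logical(1))
  if (!any(has)) stop("unknown module id: ", module_id)
  igraph::induced_subgraph(g, which(has))
}

#' Export a graph as semicolon-separated tables and GraphML
#'
#' Writes `<prefix>_nodes.txt` and `<prefix>_edges.txt` (semicolon
#' separated, rows sorted lexicographically so exports are byte-stable) and
#' `<prefix>.graphml` with identical content.
#'
#' @param g An [igraph::igraph].
#' @param prefix Output path prefix.
#' @param format One of `"both"`, `"tables"`, `"graphml"`.
#' @return Character vector of written paths, invisibly.
#' @export
export_graph <- function(g, prefix, format = c("both", "tables", "graphml")) {
  format <- match.arg(format)
  written <- character()
  if (format %in% c("both", "tables")) {
    nd <- as.data.frame(igraph::vertex_attr(g), stringsAsFactors = FALSE)
    nd <- nd[order(nd$name), , drop = FALSE]
    el <- igraph::as_edgelist(g)
    ed <- data.frame(source = pmin(el[, 1], el[, 2]),
                     target = pmax(el[, 1], el[, 2]),
                     stringsAsFactors = FALSE)
    for (a in igraph::edge_attr_names(g)) ed[[a]] <- igraph::edge_attr(g, a)
    ed <- ed[order(ed$source, ed$target), , drop = FALSE]
    np <- paste0(prefix, "_nodes.txt")
    ep <- paste0(prefix, "_edges.txt")
    utils::write.table(nd, np, sep = ";", row.names = FALSE, quote = FALSE)
    utils::write.table(ed, ep, sep = ";", row.names = FALSE, quote = FALSE)
    written <- c(written, np, ep)
  }
  if (format %in% c("both", "graphml")) {
    gp <- paste0(prefix, ".graphml")
    igraph::write_graph(g, gp, format = "graphml")
    written <- c(written, gp)
  }
  invisible(written)
}

#' Re-read a graph exported with [export_graph()]
#'
#' @param prefix The prefix passed to [export_graph()].
#' @return The reconstructed undirected [igraph::igraph].
#' @export
read_graph_tables <- function(prefix) {
  nd <- utils::read.table(paste0(prefix, "_nodes.txt"), sep = ";",
                          header = TRUE, stringsAsFactors = FALSE,
                          colClasses = "character")
  ed <- utils::read.table(paste0(prefix, "_edges.txt"), sep = ";",
                          header = TRUE, stringsAsFactors = FALSE,
                          colClasses = "character")
  for (col in c("module_count")) if (col %in% names(nd))
    nd[[col]] <- as.integer(nd[[col]])
  for (col in c("significant", "first_neighbour", "hidden"))
    if (col %in% names(nd)) nd[[col]] <- as.logical(nd[[col]])
  names(ed)[1:2] <- c("from", "to")
  igraph::graph_from_data_frame(ed, directed = FALSE, vertices = nd)
}
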