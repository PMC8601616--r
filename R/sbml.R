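#' Read a metabolic model from SBML
#'
#' Supports SBML Level 2 (bounds in kinetic-law parameters `LOWER_BOUND` /
#' `UPPER_BOUND`, subsystem/gene annotation in the notes body) and Level 3
#' with the fbc extension (bounds as referenced global parameters). Species
#' flagged `boundaryCondition="true"` are excluded from the stoichiometric
#' matrix. When no bounds are declared, reversibility sets them to
#' \[-1000, 1000\] or \[0, 1000\].
#'
#' @param path Path to an SBML file.
#' @return A [metabolic_model].
#' @export
read_sbml_model <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("cannot parse SBML file '", path, "': ", conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  mnode <- xml2::xml_find_first(doc, ".//model")
  if (inherits(mnode, "xml_missing")) stop("no <model> element in ", path)
  model_id <- xml2::xml_attr(mnode, "id")
  if (is.na(model_id)) model_id <- basename(path)

  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (length(sp) == 0L) stop("SBML model declares no species")
  sp_id <- xml2::xml_attr(sp, "id")
  sp_name <- xml2::xml_attr(sp, "name")
  sp_name[is.na(sp_name)] <- sp_id[is.na(sp_name)]
  sp_comp <- xml2::xml_attr(sp, "compartment")
  sp_bnd <- tolower(xml2::xml_attr(sp, "boundaryCondition")) %in% "true"

  # global parameters (fbc flux bounds reference these by id)
  par <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(par, "value")),
                             xml2::xml_attr(par, "id"))

  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (length(rx) == 0L) stop("SBML model declares no reactions")
  n_r <- length(rx)
  keep <- !sp_bnd
  S <- matrix(0, sum(keep), n_r, dimnames = list(sp_id[keep], NULL))

  rid <- xml2::xml_attr(rx, "id")
  rname <- xml2::xml_attr(rx, "name")
  rname[is.na(rname)] <- rid[is.na(rname)]
  rev <- !(tolower(xml2::xml_attr(rx, "reversible")) %in% "false")
  lb <- ifelse(rev, -1000, 0)
  ub <- rep(1000, n_r)
  subsystem <- rep("unassigned", n_r)
  gene_rule <- rep("", n_r)

  for (j in seq_len(n_r)) {
    for (side in c(-1, 1)) {
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      refs <- xml2::xml_find_all(rx[[j]], paste0("./", tag, "/speciesReference"))
      if (length(refs) == 0L) next
      ids <- xml2::xml_attr(refs, "species")
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      bad <- setdiff(ids, sp_id)
      if (length(bad)) stop("reaction '", rid[j], "' references undeclared species: ",
                            paste(bad, collapse = ", "))
      in_s <- ids %in% rownames(S)
      if (any(in_s))
        S[ids[in_s], j] <- S[ids[in_s], j] + side * st[in_s]
    }
    # L2 bounds in kinetic-law local parameters
    kp <- xml2::xml_find_all(rx[[j]], ".//kineticLaw//parameter")
    if (length(kp)) {
      kid <- xml2::xml_attr(kp, "id")
      kval <- as.numeric(xml2::xml_attr(kp, "value"))
      if ("LOWER_BOUND" %in% kid) lb[j] <- kval[match("LOWER_BOUND", kid)]
      if ("UPPER_BOUND" %in% kid) ub[j] <- kval[match("UPPER_BOUND", kid)]
    }
    # L3 fbc bounds reference global parameters (namespace-prefixed attrs)
    at <- xml2::xml_attrs(rx[[j]])
    lbref <- at[grepl("(^|:)lowerFluxBound$", names(at))]
    ubref <- at[grepl("(^|:)upperFluxBound$", names(at))]
    if (length(lbref) && lbref[[1]] %in% names(par_val)) lb[j] <- par_val[[lbref[[1]]]]
    if (length(ubref) && ubref[[1]] %in% names(par_val)) ub[j] <- par_val[[ubref[[1]]]]
    notes <- xml2::xml_find_first(rx[[j]], "./notes")
    if (!inherits(notes, "xml_missing")) {
      ps <- xml2::xml_find_all(notes, ".//p")
      txt <- if (length(ps)) paste(xml2::xml_text(ps), collapse = "\n")
             else xml2::xml_text(notes)
      m <- regmatches(txt, regexec("SUBSYSTEM:\\s*([^\n]+)", txt))[[1]]
      if (length(m) == 2L) subsystem[j] <- trimws(m[2])
      g <- regmatches(txt, regexec("GENE_ASSOCIATION:\\s*([^\n]+)", txt))[[1]]
      if (length(g) == 2L) gene_rule[j] <- trimws(g[2])
    }
  }

  metabolic_model(
    model_id = model_id,
    metabolites = data.frame(id = sp_id[keep], name = sp_name[keep],
                             compartment = sp_comp[keep], stringsAsFactors = FALSE),
    reactions = data.frame(id = rid, name = rname, subsystem = subsystem,
                           reversible = rev, gene_rule = gene_rule,
                           stringsAsFactors = FALSE),
    S = S, lb = lb, ub = ub)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

#' Write a metabolic model to SBML (Level 3, fbc bounds)
#'
#' Emits an SBML Level 3 Version 1 document with flux bounds as fbc-style
#' referenced parameters and the subsystem recorded in each reaction's notes,
#' so that [read_sbml_model()] round-trips ids, bounds and subsystems
#' exactly.
#'
#' @param model A [metabolic_model].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sbml_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" level="3" version="1" fbc:required="false">')
  w('  <model id="%s" fbc:strict="true">', xml_escape(model$model_id))
  w('    <listOfCompartments>')
  for (cmp in unique(model$metabolites$compartment))
    w('      <compartment id="%s" constant="true"/>', xml_escape(cmp))
  w('    </listOfCompartments>')
  w('    <listOfSpecies>')
  for (i in seq_len(n_metabolites(model)))
    w('      <species id="%s" name="%s" compartment="%s" boundaryCondition="false" hasOnlySubstanceUnits="false" constant="false"/>',
      xml_escape(model$metabolites$id[i]), xml_escape(model$metabolites$name[i]),
      xml_escape(model$metabolites$compartment[i]))
  w('    </listOfSpecies>')
  bnds <- sort(unique(c(model$lb, model$ub)))
  bnd_id <- stats::setNames(sprintf("fb_%d", seq_along(bnds)), format(bnds, digits = 17))
  w('    <listOfParameters>')
  for (i in seq_along(bnds))
    w('      <parameter id="fb_%d" value="%s" constant="true"/>',
      i, format(bnds[i], digits = 17))
  w('    </listOfParameters>')
  w('    <listOfReactions>')
  for (j in seq_len(n_reactions(model))) {
    w('      <reaction id="%s" name="%s" reversible="%s" fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">',
      xml_escape(model$reactions$id[j]), xml_escape(model$reactions$name[j]),
      tolower(model$reactions$reversible[j]),
      bnd_id[[format(model$lb[j], digits = 17)]],
      bnd_id[[format(model$ub[j], digits = 17)]])
    w('        <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>SUBSYSTEM: %s</p><p>GENE_ASSOCIATION: %s</p></body></notes>',
      xml_escape(model$reactions$subsystem[j]), xml_escape(model$reactions$gene_rule[j]))
    col <- model$S[, j]
    for (side in c(-1, 1)) {
      idx <- if (side < 0) which(col < 0) else which(col > 0)
      if (length(idx) == 0L) next
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      w('        <%s>', tag)
      for (i in idx)
        w('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
          xml_escape(rownames(model$S)[i]), format(abs(col[i]), digits = 17))
      w('        </%s>', tag)
    }
    w('      </reaction>')
  }
  w('    </listOfReactions>')
  w('  </model>')
  w('</sbml>')
  invisible(path)
}
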