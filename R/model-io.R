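## Model import/export: a JSON dialect (fixture format) and SBML Level 3
## (core + fbc gene-product associations), both mapping onto MetabolicModel.

.gprToList <- function(p) {
    ## JSON GPR: flat array = isozymes; nested arrays = complexes (AND)
    if (is.null(p) || !length(p)) return(list())
    if (is.character(p)) return(as.list(p))
    lapply(p, function(g) as.character(unlist(g)))
}

.buildModelFromParts <- function(mets, rxns, stoichList, proteins, external,
                                 target, source = "model") {
    allIds <- mets$id
    refIds <- unique(unlist(lapply(stoichList, names)))
    bad <- setdiff(refIds, allIds)
    if (length(bad))
        stop(source, ": reaction references undeclared metabolite(s): ",
             paste(bad, collapse = ", "))
    mets$role <- ifelse(mets$id %in% external, "external", "internal")
    S <- matrix(0, nrow(mets), nrow(rxns),
                dimnames = list(mets$id, rxns$id))
    for (j in seq_len(nrow(rxns))) {
        st <- stoichList[[j]]
        if (!length(st)) stop(source, ": reaction ", rxns$id[j],
                              " has empty stoichiometry")
        S[names(st), j] <- as.numeric(st)
    }
    extHit <- colSums(S[mets$id[mets$role == "external"], , drop = FALSE] != 0)
    rxns$is_exchange <- extHit > 0
    if (!length(target) || is.na(target) || !nzchar(target))
        stop(source, ": no target reaction defined")
    if (!(target %in% rxns$id))
        stop(source, ": target reaction '", target, "' not in model")
    MetabolicModel(mets, rxns, S, proteins, target)
}

#' Load a metabolic model
#'
#' Reads a network from the package's JSON dialect or from SBML Level 3
#' (with fbc gene-product associations when present) and returns a
#' validated \linkS4class{MetabolicModel}. Metabolites and reactions are
#' ordered lexicographically by id, so the same network gives identical
#' matrices whichever dialect it came from.
#'
#' In SBML, species are external when they carry
#' \code{boundaryCondition="true"} or live in one of
#' \code{externalCompartments}; in JSON the \code{external} array is
#' explicit.
#'
#' @param path file path.
#' @param dialect "json" or "sbml"; default guessed from the extension.
#' @param target target reaction id; required for SBML, optional for JSON
#'   (overrides the file's \code{target_reaction}).
#' @param externalCompartments compartment ids treated as external in SBML.
#' @return A \linkS4class{MetabolicModel}.
#' @export
loadModel <- function(path, dialect = c("auto", "json", "sbml"),
                      target = NULL, externalCompartments = "e") {
    dialect <- match.arg(dialect)
    if (dialect == "auto")
        dialect <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
            "sbml" else "json"
    if (dialect == "json") .loadModelJSON(path, target)
    else .loadModelSBML(path, target, externalCompartments)
}

.loadModelJSON <- function(path, target = NULL) {
    j <- jsonlite::read_json(path)
    mets <- data.frame(
        id = vapply(j$metabolites, function(m) m$id, ""),
        name = vapply(j$metabolites, function(m) m$name %||% m$id, ""),
        compartment = vapply(j$metabolites,
                             function(m) m$compartment %||% "c", ""),
        role = "internal", stringsAsFactors = FALSE)
    rxns <- data.frame(
        id = vapply(j$reactions, function(r) r$id, ""),
        reversible = vapply(j$reactions,
                            function(r) isTRUE(r$reversible), TRUE),
        is_exchange = FALSE, stringsAsFactors = FALSE)
    stoich <- lapply(j$reactions, function(r) unlist(r$stoichiometry))
    proteins <- lapply(j$reactions, function(r) .gprToList(r$protein_ids))
    names(proteins) <- rxns$id
    target <- target %||% j$target_reaction
    .buildModelFromParts(mets, rxns, stoich, proteins,
                         unlist(j$external), target, basename(path))
}

.loadModelSBML <- function(path, target, externalCompartments) {
    doc <- xml2::read_xml(path)
    xml2::xml_ns_strip(doc)
    spNodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
    if (!length(spNodes)) stop("SBML file declares no species")
    att <- function(nodes, a, default = NA_character_) {
        v <- xml2::xml_attr(nodes, a); ifelse(is.na(v), default, v)
    }
    mets <- data.frame(
        id = xml2::xml_attr(spNodes, "id"),
        name = att(spNodes, "name"),
        compartment = att(spNodes, "compartment", "c"),
        role = "internal", stringsAsFactors = FALSE)
    mets$name[is.na(mets$name)] <- mets$id[is.na(mets$name)]
    boundary <- att(spNodes, "boundaryCondition", "false") == "true"
    external <- mets$id[boundary | mets$compartment %in% externalCompartments]
    rxNodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
    if (!length(rxNodes)) stop("SBML file declares no reactions")
    rxns <- data.frame(
        id = xml2::xml_attr(rxNodes, "id"),
        reversible = att(rxNodes, "reversible", "true") == "true",
        is_exchange = FALSE, stringsAsFactors = FALSE)
    stoich <- lapply(rxNodes, function(nd) {
        side <- function(xp, sign) {
            refs <- xml2::xml_find_all(nd, xp)
            if (!length(refs)) return(numeric(0))
            sp <- xml2::xml_attr(refs, "species")
            co <- as.numeric(att(refs, "stoichiometry", "1"))
            stats::setNames(sign * co, sp)
        }
        c(side("./listOfReactants/speciesReference", -1),
          side("./listOfProducts/speciesReference", +1))
    })
    proteins <- lapply(rxNodes, .sbmlGPR)
    names(proteins) <- rxns$id
    .buildModelFromParts(mets, rxns, stoich, proteins, external, target,
                         basename(path))
}

## fbc geneProductAssociation -> list of AND-groups (namespaces stripped;
## nodes are matched by name rather than xpath, which can miss elements
## that carried a namespace prefix)
.sbmlGPR <- function(nd) {
    kids <- xml2::xml_children(nd)
    hit <- which(xml2::xml_name(kids) == "geneProductAssociation")
    if (!length(hit)) return(list())
    gpa <- kids[[hit[1]]]
    parse <- function(node) {
        nm <- xml2::xml_name(node)
        if (nm == "geneProductRef")
            return(list(xml2::xml_attr(node, "geneProduct")))
        kids <- xml2::xml_children(node)
        parts <- lapply(kids, parse)
        if (nm == "or") return(unlist(parts, recursive = FALSE))
        if (nm == "and")
            return(list(unlist(parts, use.names = FALSE)))
        unlist(parts, recursive = FALSE)
    }
    groups <- parse(gpa)
    lapply(groups, as.character)
}

#' Serialize a model to the JSON dialect
#'
#' @param model \linkS4class{MetabolicModel}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeModelJSON <- function(model, path) {
    S <- stoichiometricMatrix(model, internal = FALSE)
    out <- list(
        metabolites = lapply(seq_len(nrow(model@metabolites)), function(i)
            list(id = model@metabolites$id[i],
                 name = model@metabolites$name[i],
                 compartment = model@metabolites$compartment[i])),
        external = externalMetabolites(model),
        reactions = lapply(seq_along(reactionIds(model)), function(j) {
            rid <- reactionIds(model)[j]
            st <- S[, j]; st <- st[st != 0]
            gpr <- model@proteins[[rid]]
            list(id = rid,
                 reversible = model@reactions$reversible[j],
                 stoichiometry = as.list(st),
                 protein_ids = if (length(gpr)) gpr else list())
        }),
        target_reaction = targetReaction(model))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

#' Serialize a model to SBML Level 3
#'
#' Writes core SBML with boundary external species plus fbc gene-product
#' associations; sufficient for round-tripping through
#' \code{\link{loadModel}}.
#'
#' @param model \linkS4class{MetabolicModel}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeModelSBML <- function(model, path) {
    S <- stoichiometricMatrix(model, internal = FALSE)
    esc <- function(x) gsub("&", "&amp;", x)
    con <- file(path, "w")
    on.exit(close(con))
    w <- function(...) writeLines(paste0(...), con)
    w('<?xml version="1.0" encoding="UTF-8"?>')
    w('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
      'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
      'level="3" version="1" fbc:required="false">')
    w('  <model id="model" fbc:strict="false">')
    w('    <listOfCompartments>')
    for (cp in unique(model@metabolites$compartment))
        w('      <compartment id="', cp, '" constant="true"/>')
    w('    </listOfCompartments>')
    w('    <listOfSpecies>')
    ext <- externalMetabolites(model)
    for (i in seq_len(nrow(model@metabolites))) {
        m <- model@metabolites[i, ]
        w('      <species id="', m$id, '" name="', esc(m$name),
          '" compartment="', m$compartment, '" boundaryCondition="',
          tolower(m$id %in% ext), '" constant="false" ',
          'hasOnlySubstanceUnits="false"/>')
    }
    w('    </listOfSpecies>')
    w('    <listOfReactions>')
    for (j in seq_along(reactionIds(model))) {
        rid <- reactionIds(model)[j]
        st <- S[, j]; st <- st[st != 0]
        w('      <reaction id="', rid, '" reversible="',
          tolower(model@reactions$reversible[j]), '" fast="false">')
        gpr <- model@proteins[[rid]]
        if (length(gpr)) {
            w('        <fbc:geneProductAssociation>')
            wrapOr <- length(gpr) > 1
            if (wrapOr) w('          <fbc:or>')
            for (grp in gpr) {
                if (length(grp) > 1) {
                    w('            <fbc:and>')
                    for (g in grp)
                        w('              <fbc:geneProductRef fbc:geneProduct="',
                          g, '"/>')
                    w('            </fbc:and>')
                } else {
                    w('            <fbc:geneProductRef fbc:geneProduct="',
                      grp, '"/>')
                }
            }
            if (wrapOr) w('          </fbc:or>')
            w('        </fbc:geneProductAssociation>')
        }
        side <- function(tag, sel) {
            part <- st[sel]
            if (!length(part)) return()
            w('        <', tag, '>')
            for (k in seq_along(part))
                w('          <speciesReference species="', names(part)[k],
                  '" stoichiometry="', format(abs(part[k]), digits = 17),
                  '" constant="true"/>')
            w('        </', tag, '>')
        }
        side("listOfReactants", st < 0)
        side("listOfProducts", st > 0)
        w('      </reaction>')
    }
    w('    </listOfReactions>')
    w('  </model>')
    w('</sbml>')
    invisible(path)
}

#' Read a reference flux table
#'
#' @param path TSV with columns reaction_id, v_star.
#' @return Named numeric vector.
#' @export
readReferenceFluxes <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("reaction_id", "v_star") %in% names(tab)))
    stats::setNames(tab$v_star, tab$reaction_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
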