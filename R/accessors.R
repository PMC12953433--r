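#' Construct a MetabolicModel
#'
#' Low-level constructor used by the readers and the synthetic generator.
#' Metabolites and reactions are re-ordered lexicographically by id and the
#' stoichiometric matrix is permuted to match, so the same network yields
#' bit-identical matrices regardless of input order.
#'
#' @param metabolites data.frame with columns id, name, compartment, role.
#' @param reactions data.frame with columns id, reversible, is_exchange.
#' @param stoichiometry matrix or sparse matrix, metabolites x reactions,
#'   with dimnames matching the id columns.
#' @param proteins named list (by reaction id) of GPR associations; each
#'   element a list of character vectors (isozymes of complexes), a plain
#'   character vector (treated as isozymes), or empty.
#' @param targetReaction id of the target (product export) reaction.
#' @return A validated \linkS4class{MetabolicModel}.
#' @export
MetabolicModel <- function(metabolites, reactions, stoichiometry, proteins,
                           targetReaction) {
    metabolites <- metabolites[order(metabolites$id), , drop = FALSE]
    reactions   <- reactions[order(reactions$id), , drop = FALSE]
    rownames(metabolites) <- NULL
    rownames(reactions) <- NULL
    S <- Matrix::Matrix(as.matrix(stoichiometry)[metabolites$id,
                                                 reactions$id, drop = FALSE],
                        sparse = TRUE)
    S <- as(as(S, "CsparseMatrix"), "generalMatrix")
    proteins <- lapply(proteins, function(p) {
        if (is.character(p)) p <- as.list(p)
        lapply(p, as.character)
    })
    missingGpr <- setdiff(reactions$id, names(proteins))
    proteins[missingGpr] <- list(list())
    proteins <- proteins[reactions$id]
    new("MetabolicModel", metabolites = metabolites, reactions = reactions,
        stoichiometry = S, proteins = proteins,
        targetReaction = targetReaction)
}

#' Accessors for MetabolicModel
#'
#' @param x a \linkS4class{MetabolicModel}.
#' @param internal for \code{stoichiometricMatrix}: return only the rows of
#'   internal metabolites (the matrix N of the lin-log system) or the full
#'   species x reaction matrix.
#' @name MetabolicModel-accessors
#' @aliases reactionIds metaboliteIds internalMetabolites externalMetabolites
#'   stoichiometricMatrix targetReaction proteinAssociations exchangeReactions
NULL

#' @rdname MetabolicModel-accessors
#' @export
setMethod("reactionIds", "MetabolicModel", function(x) x@reactions$id)

#' @rdname MetabolicModel-accessors
#' @export
setMethod("metaboliteIds", "MetabolicModel", function(x) x@metabolites$id)

#' @rdname MetabolicModel-accessors
#' @export
setMethod("internalMetabolites", "MetabolicModel",
          function(x) x@metabolites$id[x@metabolites$role == "internal"])

#' @rdname MetabolicModel-accessors
#' @export
setMethod("externalMetabolites", "MetabolicModel",
          function(x) x@metabolites$id[x@metabolites$role == "external"])

#' @rdname MetabolicModel-accessors
#' @export
setMethod("stoichiometricMatrix", "MetabolicModel",
          function(x, internal = TRUE) {
    if (internal)
        as.matrix(x@stoichiometry[internalMetabolites(x), , drop = FALSE])
    else as.matrix(x@stoichiometry)
})

#' @rdname MetabolicModel-accessors
#' @export
setMethod("targetReaction", "MetabolicModel", function(x) x@targetReaction)

#' @rdname MetabolicModel-accessors
#' @export
setMethod("proteinAssociations", "MetabolicModel", function(x) x@proteins)

#' @rdname MetabolicModel-accessors
#' @export
setMethod("exchangeReactions", "MetabolicModel",
          function(x) x@reactions$id[x@reactions$is_exchange])

setMethod("show", "MetabolicModel", function(object) {
    cat("MetabolicModel:", length(reactionIds(object)), "reactions,",
        length(internalMetabolites(object)), "internal +",
        length(externalMetabolites(object)), "external metabolites\n")
    cat("  target flux:", object@targetReaction, "\n")
    nGpr <- sum(vapply(object@proteins, length, 1L) > 0)
    cat("  ", nGpr, " reactions with protein associations, ",
        sum(object@reactions$is_exchange), " exchange reactions\n", sep = "")
})

#' Construct a ReferenceState
#'
#' @param model MetabolicModel the state refers to.
#' @param vStar named numeric of reference fluxes (mmol gDCW^-1 h^-1).
#' @param eStar,xStar,yStar reference enzyme and metabolite levels; default
#'   to 1 for every coordinate (relative-measurement convention).
#' @param check when TRUE (default) require the steady-state invariant
#'   \code{max|N vStar| <= ssTol}.
#' @param ssTol steady-state tolerance.
#' @return A \linkS4class{ReferenceState}.
#' @export
ReferenceState <- function(model, vStar, eStar = NULL, xStar = NULL,
                           yStar = NULL, check = TRUE, ssTol = 1e-8) {
    rid <- reactionIds(model)
    if (is.null(names(vStar)) && length(vStar) == length(rid))
        names(vStar) <- rid
    stopifnot(setequal(names(vStar), rid))
    vStar <- vStar[rid]
    unit <- function(ids) stats::setNames(rep(1, length(ids)), ids)
    if (is.null(eStar)) eStar <- unit(rid)
    if (is.null(xStar)) xStar <- unit(internalMetabolites(model))
    if (is.null(yStar)) yStar <- unit(externalMetabolites(model))
    ref <- new("ReferenceState", vStar = vStar, eStar = eStar[rid],
               xStar = xStar[internalMetabolites(model)],
               yStar = yStar[externalMetabolites(model)])
    if (check) {
        res <- max(abs(stoichiometricMatrix(model) %*% vStar))
        if (res > ssTol)
            stop("vStar is not a steady state: max|N v*| = ",
                 format(res), " > ", ssTol)
    }
    ref
}

#' Accessors for ReferenceState
#' @param x a \linkS4class{ReferenceState}.
#' @name ReferenceState-accessors
#' @aliases vStar eStar xStar yStar
NULL

#' @rdname ReferenceState-accessors
#' @export
setMethod("vStar", "ReferenceState", function(x) x@vStar)
#' @rdname ReferenceState-accessors
#' @export
setMethod("eStar", "ReferenceState", function(x) x@eStar)
#' @rdname ReferenceState-accessors
#' @export
setMethod("xStar", "ReferenceState", function(x) x@xStar)
#' @rdname ReferenceState-accessors
#' @export
setMethod("yStar", "ReferenceState", function(x) x@yStar)

setMethod("show", "ReferenceState", function(object) {
    cat("ReferenceState over", length(object@vStar), "reactions;",
        "flux range [", format(min(object@vStar), digits = 3), ",",
        format(max(object@vStar), digits = 3), "] mmol/gDCW/h\n")
})

#' Construct ElasticityMatrices
#'
#' @param epsX reactions x internal metabolites matrix.
#' @param epsY reactions x external metabolites matrix (may have 0 columns).
#' @return An \linkS4class{ElasticityMatrices}.
#' @export
ElasticityMatrices <- function(epsX, epsY) {
    new("ElasticityMatrices", epsX = as.matrix(epsX), epsY = as.matrix(epsY))
}

#' @rdname ElasticityMatrices-accessors
#' @param x an \linkS4class{ElasticityMatrices}.
#' @name ElasticityMatrices-accessors
#' @export
setMethod("epsX", "ElasticityMatrices", function(x) x@epsX)
#' @rdname ElasticityMatrices-accessors
#' @export
setMethod("epsY", "ElasticityMatrices", function(x) x@epsY)

setMethod("show", "ElasticityMatrices", function(object) {
    cat("ElasticityMatrices:", nrow(object@epsX), "reactions x (",
        ncol(object@epsX), "internal +", ncol(object@epsY),
        "external ) metabolites;",
        sum(object@epsX != 0) + sum(object@epsY != 0), "nonzero entries\n")
})

#' Construct a PerturbationState
#'
#' @param model MetabolicModel.
#' @param eRel named relative enzyme levels; unnamed reactions default to 1.
#' @param yLog named external log-deviations; default 0.
#' @return A \linkS4class{PerturbationState}.
#' @export
PerturbationState <- function(model, eRel = NULL, yLog = NULL) {
    rid <- reactionIds(model)
    ext <- externalMetabolites(model)
    e <- stats::setNames(rep(1, length(rid)), rid)
    if (!is.null(eRel)) {
        stopifnot(all(names(eRel) %in% rid))
        e[names(eRel)] <- eRel
    }
    y <- stats::setNames(rep(0, length(ext)), ext)
    if (!is.null(yLog)) {
        stopifnot(all(names(yLog) %in% ext))
        y[names(yLog)] <- yLog
    }
    new("PerturbationState", eRel = e, yLog = y)
}

setMethod("show", "SteadyStateSolution", function(object) {
    cat("SteadyStateSolution:", length(object@v), "fluxes;",
        if (object@singular) "SINGULAR (pseudoinverse)" else "regular",
        "; cond =", format(object@condNumber, digits = 3), "\n")
})

setMethod("show", "ControlCoefficients", function(object) {
    cat("ControlCoefficients: CJ", nrow(object@CJ), "x", ncol(object@CJ),
        "; max |row sum - 1| =",
        format(max(abs(rowSums(object@CJ) - 1)), digits = 3), "\n")
})

#' @rdname OmicsDataset-accessors
#' @param x an \linkS4class{OmicsDataset}.
#' @name OmicsDataset-accessors
#' @export
setMethod("strains", "OmicsDataset", function(x)
    as.character(SummarizedExperiment::colData(x@proteins)$strain))

#' @rdname OmicsDataset-accessors
#' @param object,assay which block / assay to extract.
#' @export
omicsAssay <- function(x, object = c("proteins", "metabolites", "fluxes"),
                       assay = "value") {
    object <- match.arg(object)
    SummarizedExperiment::assay(slot(x, object), assay)
}

setMethod("show", "OmicsDataset", function(object) {
    nv <- function(se) sum(!is.na(SummarizedExperiment::assay(se, "value")))
    nc <- function(se) sum(SummarizedExperiment::assay(se, "clipped"),
                           na.rm = TRUE)
    cat("OmicsDataset:", ncol(object@proteins), "samples,",
        length(unique(strains(object))), "strains\n")
    cat(sprintf("  proteins:    %d observed (%d clipped)\n",
                nv(object@proteins), nc(object@proteins)))
    cat(sprintf("  metabolites: %d observed (%d clipped)\n",
                nv(object@metabolites), nc(object@metabolites)))
    cat(sprintf("  fluxes:      %d observed\n", nv(object@fluxes)))
    if (!is.na(object@clipBound))
        cat("  clip bound:", object@clipBound, "ln units\n")
})

setMethod("show", "PosteriorSamples", function(object) {
    cat("PosteriorSamples:", object@draws, "draws,",
        dim(object@epsX)[2], "reactions,", dim(object@logE)[2], "strains\n")
    cat("  ELBO iterations:", length(object@elboTrace),
        if (object@converged) "(converged)" else "(iteration cap reached)",
        "\n  final ELBO:",
        format(utils::tail(object@elboTrace, 1), digits = 6), "\n")
})

setMethod("show", "FCCPosterior", function(object) {
    cat("FCCPosterior on", object@target, ":", nrow(object@samples),
        "draws x", ncol(object@samples), "reactions;",
        sum(!object@validMask), "singular draws masked\n")
})

setMethod("show", "SyntheticTruth", function(object) {
    cat("SyntheticTruth (preset '", object@preset, "', seed ", object@seed,
        "): ", length(reactionIds(object@model)), " reactions, ",
        length(object@designs), " strains\n", sep = "")
})

#' Construct a NoiseSpec
#'
#' Defaults emulate the study design the generator mirrors: triplicate
#' sampling, log-scale noise sd 0.1, 80% of features observed per sample,
#' and clipping at 2 natural-log units.
#'
#' @param sdProtein,sdMetabolite log-scale observation noise sds.
#' @param sdFlux flux noise sd as a fraction of |v*|.
#' @param obsFractionProtein,obsFractionMetabolite observed fractions.
#' @param replicates replicates per strain.
#' @param clipBound clipping bound (natural-log units).
#' @param seed integer seed.
#' @return A \linkS4class{NoiseSpec}.
#' @export
NoiseSpec <- function(sdProtein = 0.1, sdMetabolite = 0.1, sdFlux = 0.1,
                      obsFractionProtein = 0.8, obsFractionMetabolite = 0.8,
                      replicates = 3L, clipBound = 2, seed = 1L) {
    new("NoiseSpec", sdProtein = sdProtein, sdMetabolite = sdMetabolite,
        sdFlux = sdFlux, obsFractionProtein = obsFractionProtein,
        obsFractionMetabolite = obsFractionMetabolite,
        replicates = as.integer(replicates), clipBound = clipBound,
        seed = as.integer(seed))
}
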