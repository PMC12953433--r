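#' @rdname MetabolicModel-accessors
#' @export
setGeneric("reactionIds", function(x) standardGeneric("reactionIds"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("metaboliteIds", function(x) standardGeneric("metaboliteIds"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("internalMetabolites",
           function(x) standardGeneric("internalMetabolites"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("externalMetabolites",
           function(x) standardGeneric("externalMetabolites"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("stoichiometricMatrix",
           function(x, internal = TRUE) standardGeneric("stoichiometricMatrix"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("targetReaction", function(x) standardGeneric("targetReaction"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("proteinAssociations",
           function(x) standardGeneric("proteinAssociations"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("exchangeReactions",
           function(x) standardGeneric("exchangeReactions"))

#' @rdname ReferenceState-accessors
#' @export
setGeneric("vStar", function(x) standardGeneric("vStar"))

#' @rdname ReferenceState-accessors
#' @export
setGeneric("eStar", function(x) standardGeneric("eStar"))

#' @rdname ReferenceState-accessors
#' @export
setGeneric("xStar", function(x) standardGeneric("xStar"))

#' @rdname ReferenceState-accessors
#' @export
setGeneric("yStar", function(x) standardGeneric("yStar"))

#' @rdname ElasticityMatrices-accessors
#' @export
setGeneric("epsX", function(x) standardGeneric("epsX"))

#' @rdname ElasticityMatrices-accessors
#' @export
setGeneric("epsY", function(x) standardGeneric("epsY"))

#' @rdname reduceModel
#' @export
setGeneric("reduceModel", function(model, flux, zeroTol = 1e-9)
    standardGeneric("reduceModel"))

#' @rdname removeConservedMoieties
#' @export
setGeneric("removeConservedMoieties", function(model, tol = 1e-9)
    standardGeneric("removeConservedMoieties"))

#' @rdname solveSteadyState
#' @export
setGeneric("solveSteadyState",
           function(model, ref, eps, pert, condThreshold = 1e10,
                    pseudoinverse = FALSE)
    standardGeneric("solveSteadyState"))

#' @rdname controlCoefficients
#' @export
setGeneric("controlCoefficients",
           function(model, ref, epsX, condThreshold = 1e10,
                    pseudoinverse = FALSE)
    standardGeneric("controlCoefficients"))

#' @rdname simulateStrain
#' @export
setGeneric("simulateStrain",
           function(model, ref, eps, design, knockoutFloor = 0.05, ...)
    standardGeneric("simulateStrain"))

#' @rdname clipObservations
#' @export
setGeneric("clipObservations", function(data, bound = 2)
    standardGeneric("clipObservations"))

#' @rdname OmicsDataset-accessors
#' @export
setGeneric("strains", function(x) standardGeneric("strains"))
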