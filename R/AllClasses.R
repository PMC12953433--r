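#' @import methods
#' @importFrom Matrix Matrix sparseMatrix rankMatrix
#' @importClassesFrom Matrix dgCMatrix
NULL

#' MetabolicModel: a stoichiometric network with an internal/external split
#'
#' Holds the metabolite table (with each species assigned an
#' \code{internal} or \code{external} role), the reaction table, the full
#' stoichiometric matrix over all species, gene--protein--reaction (GPR)
#' associations, and the identity of the target (product export) reaction.
#' The internal-species submatrix \code{N} used by the lin-log machinery is
#' obtained with \code{\link{stoichiometricMatrix}}.
#'
#' Metabolites and reactions are kept in lexicographic id order so that all
#' derived matrices are reproducible across runs and serializations.
#'
#' @slot metabolites data.frame with columns id, name, compartment, role.
#' @slot reactions data.frame with columns id, reversible, is_exchange.
#' @slot stoichiometry dgCMatrix, all metabolites x reactions.
#' @slot proteins named list (by reaction id); each element is a list of
#'   character vectors: outer level = isozymes (OR), inner vector = complex
#'   subunits (AND). Empty list for reactions with no associated protein.
#' @slot targetReaction id of the flux whose control is analysed.
#' @export
setClass("MetabolicModel", slots = c(
    metabolites    = "data.frame",
    reactions      = "data.frame",
    stoichiometry  = "dgCMatrix",
    proteins       = "list",
    targetReaction = "character"
))

setValidity("MetabolicModel", function(object) {
    met <- object@metabolites
    rxn <- object@reactions
    S   <- object@stoichiometry
    msg <- character()
    need <- c("id", "name", "compartment", "role")
    if (!all(need %in% names(met)))
        msg <- c(msg, "metabolites must have columns id, name, compartment, role")
    if (anyDuplicated(met$id)) msg <- c(msg, "duplicated metabolite ids")
    if (anyDuplicated(rxn$id)) msg <- c(msg, "duplicated reaction ids")
    if (!all(met$role %in% c("internal", "external")))
        msg <- c(msg, "metabolite role must be 'internal' or 'external'")
    if (is.unsorted(met$id) || is.unsorted(rxn$id))
        msg <- c(msg, "metabolites and reactions must be sorted by id")
    if (!identical(rownames(S), met$id) || !identical(colnames(S), rxn$id))
        msg <- c(msg, "stoichiometry dimnames must match metabolite/reaction ids")
    if (length(object@targetReaction) != 1L ||
        !(object@targetReaction %in% rxn$id))
        msg <- c(msg, "targetReaction must name one reaction of the model")
    if (any(Matrix::colSums(S != 0) == 0))
        msg <- c(msg, "every reaction needs a non-empty stoichiometry")
    internal <- met$id[met$role == "internal"]
    if (length(internal)) {
        orphan <- internal[Matrix::rowSums(S[internal, , drop = FALSE] != 0) == 0]
        if (length(orphan))
            msg <- c(msg, paste("internal metabolite(s) in no reaction:",
                                paste(orphan, collapse = ", ")))
    }
    ext <- met$id[met$role == "external"]
    exch <- rxn$id[rxn$is_exchange]
    if (length(exch)) {
        touch <- Matrix::colSums(S[ext, exch, drop = FALSE] != 0)
        if (any(touch == 0))
            msg <- c(msg, "exchange reaction(s) touching no external species")
    }
    if (!identical(sort(names(object@proteins)), sort(rxn$id)))
        msg <- c(msg, "proteins list must be named by all reaction ids")
    if (length(msg)) msg else TRUE
})

#' ReferenceState: the lin-log linearization point
#'
#' Reference fluxes \code{v*} (mmol gDCW^-1 h^-1), relative enzyme levels
#' \code{e*} (1 by convention, since proteomics are relative measurements),
#' and internal/external metabolite levels \code{x*}, \code{y*}. All vectors
#' are named by reaction or metabolite id.
#'
#' @slot vStar named numeric over reactions.
#' @slot eStar named numeric over reactions, strictly positive.
#' @slot xStar named numeric over internal metabolites, strictly positive.
#' @slot yStar named numeric over external metabolites, strictly positive.
#' @export
setClass("ReferenceState", slots = c(
    vStar = "numeric", eStar = "numeric", xStar = "numeric", yStar = "numeric"
))

setValidity("ReferenceState", function(object) {
    msg <- character()
    for (nm in c("vStar", "eStar", "xStar", "yStar")) {
        v <- slot(object, nm)
        if (length(v) && is.null(names(v)))
            msg <- c(msg, paste(nm, "must be named"))
        if (any(!is.finite(v))) msg <- c(msg, paste(nm, "must be finite"))
    }
    if (any(object@eStar <= 0)) msg <- c(msg, "eStar must be strictly positive")
    if (any(object@xStar <= 0)) msg <- c(msg, "xStar must be strictly positive")
    if (any(object@yStar <= 0)) msg <- c(msg, "yStar must be strictly positive")
    if (length(msg)) msg else TRUE
})

#' ElasticityMatrices: lin-log kinetic parameters
#'
#' \code{epsX} (reactions x internal metabolites) and \code{epsY}
#' (reactions x external metabolites) hold the scaled elasticities
#' d log v / d log x at the reference state; both are dimensionless.
#'
#' @slot epsX numeric matrix, reactions x internal metabolites.
#' @slot epsY numeric matrix, reactions x external metabolites.
#' @export
setClass("ElasticityMatrices", slots = c(epsX = "matrix", epsY = "matrix"))

setValidity("ElasticityMatrices", function(object) {
    msg <- character()
    if (any(!is.finite(object@epsX)) || any(!is.finite(object@epsY)))
        msg <- c(msg, "elasticities must be finite")
    if (nrow(object@epsX) != nrow(object@epsY))
        msg <- c(msg, "epsX and epsY must have one row per reaction")
    if (is.null(dimnames(object@epsX)))
        msg <- c(msg, "epsX needs reaction/metabolite dimnames")
    if (length(msg)) msg else TRUE
})

#' PerturbationState: a strain as seen by the lin-log model
#'
#' Relative enzyme levels e/e* (strictly positive; deletions are encoded by
#' a small floor, see \code{\link{simulateStrain}}) and external log
#' deviations log(y/y*).
#'
#' @slot eRel named numeric over reactions, > 0.
#' @slot yLog named numeric over external metabolites.
#' @export
setClass("PerturbationState", slots = c(eRel = "numeric", yLog = "numeric"))

setValidity("PerturbationState", function(object) {
    if (any(object@eRel <= 0)) "eRel must be strictly positive" else TRUE
})

#' SteadyStateSolution: one lin-log steady state
#'
#' @slot xLog internal metabolite log-deviations log(x/x*).
#' @slot v steady-state fluxes (units of v*).
#' @slot singular TRUE when the linear system was flagged ill-conditioned
#'   and solved by pseudoinverse.
#' @slot condNumber condition number of the solved system.
#' @export
setClass("SteadyStateSolution", slots = c(
    xLog = "numeric", v = "numeric", singular = "logical",
    condNumber = "numeric"
))

#' ControlCoefficients: systems-level sensitivities at the reference state
#'
#' \code{CJ[j, k]} = d log J_j / d log e_k (flux control coefficients),
#' \code{CX[m, k]} = d log x_m / d log e_k (concentration control
#' coefficients). Rows of CJ sum to 1 (summation theorem) and CJ %*% epsX = 0
#' (connectivity theorem); CX rows sum to 0.
#'
#' @slot CJ reactions x reactions matrix.
#' @slot CX internal metabolites x reactions matrix.
#' @slot pseudoinverse TRUE when a Moore-Penrose fallback was used.
#' @export
setClass("ControlCoefficients", slots = c(
    CJ = "matrix", CX = "matrix", pseudoinverse = "logical"
))

#' OmicsDataset: per-sample relative omics observations
#'
#' Three \code{SummarizedExperiment}s sharing a sample axis (colData column
#' \code{strain}): reaction-level protein log-ratios, internal-metabolite
#' log-ratios, and absolute-scale flux estimates. Each carries assays
#' \code{value} (NA = unobserved) and \code{clipped}; after
#' \code{\link{clipObservations}} the pre-clipping values are kept in assay
#' \code{raw}.
#'
#' @slot proteins SummarizedExperiment, reactions x samples.
#' @slot metabolites SummarizedExperiment, internal metabolites x samples.
#' @slot fluxes SummarizedExperiment, reactions x samples.
#' @slot clipBound clipping bound in natural-log units (NA before clipping).
#' @export
setClass("OmicsDataset", slots = c(
    proteins    = "SummarizedExperiment",
    metabolites = "SummarizedExperiment",
    fluxes      = "SummarizedExperiment",
    clipBound   = "numeric"
))

setValidity("OmicsDataset", function(object) {
    msg <- character()
    cn <- colnames(object@proteins)
    if (!identical(cn, colnames(object@metabolites)) ||
        !identical(cn, colnames(object@fluxes)))
        msg <- c(msg, "the three assays must share the same samples in order")
    for (nm in c("proteins", "metabolites", "fluxes")) {
        se <- slot(object, nm)
        if (!all(c("value", "clipped") %in%
                 SummarizedExperiment::assayNames(se)))
            msg <- c(msg, paste(nm, "needs assays 'value' and 'clipped'"))
        if (!("strain" %in% names(SummarizedExperiment::colData(se))))
            msg <- c(msg, paste(nm, "colData needs a 'strain' column"))
    }
    nobs <- sum(!is.na(SummarizedExperiment::assay(object@proteins, "value"))) +
        sum(!is.na(SummarizedExperiment::assay(object@metabolites, "value"))) +
        sum(!is.na(SummarizedExperiment::assay(object@fluxes, "value")))
    if (nobs == 0) msg <- c(msg, "dataset contains no observed entries")
    if (length(msg)) msg else TRUE
})

#' BmcaProblem: a compiled Bayesian inference problem
#'
#' Produced by \code{\link{buildBmcaModel}}; bundles the reduced model, the
#' reference state, the prior specification, per-strain sufficient
#' statistics of the observations, and the index structures used by the
#' variational optimizer. Treat as opaque.
#'
#' @slot model MetabolicModel (reduced).
#' @slot ref ReferenceState.
#' @slot prior list of prior hyperparameters.
#' @slot strains character vector of strain ids (parameter order).
#' @slot yLog matrix strains x external metabolites of known log(y/y*).
#' @slot stats list of precomputed sufficient statistics and indices.
#' @export
setClass("BmcaProblem", slots = c(
    model = "MetabolicModel", ref = "ReferenceState", prior = "list",
    strains = "character", yLog = "matrix", stats = "list"
))

#' PosteriorSamples: draws from the fitted variational posterior
#'
#' @slot draws number of posterior draws.
#' @slot epsX array draws x reactions x internal metabolites.
#' @slot epsY array draws x reactions x external metabolites.
#' @slot logE array draws x strains x reactions of latent log relative
#'   enzyme levels.
#' @slot sdDraws matrix draws x 3 (protein, metabolite, flux noise sds).
#' @slot elboTrace per-iteration ELBO estimates.
#' @slot seed integer seed the fit and draws were generated from.
#' @slot converged TRUE when the smoothed negative-ELBO stopping rule fired
#'   before the iteration cap.
#' @slot varParams list(mu, omega) of the mean-field solution.
#' @export
setClass("PosteriorSamples", slots = c(
    draws = "integer", epsX = "array", epsY = "array", logE = "array",
    sdDraws = "matrix", elboTrace = "numeric", seed = "integer",
    converged = "logical", varParams = "list"
))

setValidity("PosteriorSamples", function(object) {
    msg <- character()
    if (object@draws < 1L) msg <- c(msg, "draws must be >= 1")
    if (!length(object@elboTrace)) msg <- c(msg, "elboTrace must be non-empty")
    if (length(msg)) msg else TRUE
})

#' FCCPosterior: posterior samples of target-flux control coefficients
#'
#' @slot target id of the target (product export) reaction.
#' @slot samples matrix draws x reactions: the CJ row of the target flux,
#'   one per posterior draw.
#' @slot validMask per-draw flag; draws whose lin-log system was singular
#'   are masked out and excluded from summaries.
#' @export
setClass("FCCPosterior", slots = c(
    target = "character", samples = "matrix", validMask = "logical"
))

#' SyntheticTruth: a generated network with known kinetics
#'
#' @slot model MetabolicModel.
#' @slot ref ReferenceState consistent with the model (N v* = 0).
#' @slot eps true ElasticityMatrices.
#' @slot fcc analytic ControlCoefficients of the truth.
#' @slot designs named list: strain id -> named enzyme fold-change map.
#' @slot preset generator preset name.
#' @slot seed generator seed.
#' @export
setClass("SyntheticTruth", slots = c(
    model = "MetabolicModel", ref = "ReferenceState",
    eps = "ElasticityMatrices", fcc = "ControlCoefficients",
    designs = "list", preset = "character", seed = "integer"
))

#' NoiseSpec: observation model of the synthetic data generator
#'
#' Log-scale noise sds for protein and metabolite log-ratios, a flux noise
#' sd expressed relative to |v*| per reaction, observation fractions,
#' replicate count, clipping bound and seed.
#'
#' @slot sdProtein,sdMetabolite log-scale observation noise sds.
#' @slot sdFlux flux noise sd as a fraction of |v*| per reaction.
#' @slot obsFractionProtein,obsFractionMetabolite fraction of features
#'   observed per sample, in (0, 1].
#' @slot replicates replicates per strain.
#' @slot clipBound clipping bound in natural-log units.
#' @slot seed integer seed.
#' @export
setClass("NoiseSpec", slots = c(
    sdProtein = "numeric", sdMetabolite = "numeric", sdFlux = "numeric",
    obsFractionProtein = "numeric", obsFractionMetabolite = "numeric",
    replicates = "integer", clipBound = "numeric", seed = "integer"
))

setValidity("NoiseSpec", function(object) {
    msg <- character()
    if (object@obsFractionProtein <= 0 || object@obsFractionProtein > 1 ||
        object@obsFractionMetabolite <= 0 || object@obsFractionMetabolite > 1)
        msg <- c(msg, "observation fractions must lie in (0, 1]")
    if (object@replicates < 1L) msg <- c(msg, "replicates must be >= 1")
    if (any(c(object@sdProtein, object@sdMetabolite, object@sdFlux) < 0))
        msg <- c(msg, "noise sds must be non-negative")
    if (length(msg)) msg else TRUE
})
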