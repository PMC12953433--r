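#' Reduce a model to the reactions carried at the reference state
#'
#' Removes reactions whose reference flux magnitude is at or below
#' \code{zeroTol}, then drops metabolites left with no participating
#' reaction, and re-derives the stoichiometric matrix. The target reaction
#' must survive: a zero reference flux on the product export is an error,
#' because the lin-log linearization divides by v*.
#'
#' @param model \linkS4class{MetabolicModel}.
#' @param flux named numeric over the model's reactions (reference flux).
#' @param zeroTol magnitude threshold below which a flux counts as zero
#'   (default 1e-9 mmol gDCW^-1 h^-1).
#' @return The reduced \linkS4class{MetabolicModel}.
#' @export
setMethod("reduceModel", "MetabolicModel", function(model, flux,
                                                    zeroTol = 1e-9) {
    rid <- reactionIds(model)
    if (is.null(names(flux)) && length(flux) == length(rid))
        names(flux) <- rid
    if (!setequal(names(flux), rid))
        stop("flux must be indexed by the model's reaction ids")
    flux <- flux[rid]
    keep <- abs(flux) > zeroTol
    if (!keep[[targetReaction(model)]])
        stop("target reaction '", targetReaction(model),
             "' has zero reference flux; cannot reduce")
    if (all(keep)) return(model)
    S <- stoichiometricMatrix(model, internal = FALSE)[, keep, drop = FALSE]
    metKeep <- rowSums(S != 0) > 0
    MetabolicModel(model@metabolites[metKeep, , drop = FALSE],
                   model@reactions[keep, , drop = FALSE],
                   S[metKeep, , drop = FALSE],
                   model@proteins[rid[keep]],
                   targetReaction(model))
})

#' Remove conserved moieties (dependent stoichiometry rows)
#'
#' Conservation relations (e.g. a closed cofactor pair) make rows of N
#' linearly dependent, so the lin-log steady-state and control-coefficient
#' systems would be singular. This drops dependent internal-metabolite rows
#' until N has full row rank and returns the link matrix L that
#' reconstructs the original internal rows from the kept ones
#' (\code{N_full = L \%*\% N_reduced}). Dropped metabolites are removed from
#' the model (their concentrations are determined by the conservation
#' relations, not by the steady-state solve).
#'
#' Rank and row selection use a pivoted QR decomposition with relative
#' tolerance \code{tol}.
#'
#' @param model \linkS4class{MetabolicModel}.
#' @param tol relative tolerance of the rank decision (default 1e-9).
#' @return list(model = reduced \linkS4class{MetabolicModel},
#'   link = L matrix with rownames = original internal metabolites,
#'   colnames = kept internal metabolites).
#' @export
setMethod("removeConservedMoieties", "MetabolicModel",
          function(model, tol = 1e-9) {
    N <- stoichiometricMatrix(model)
    im <- internalMetabolites(model)
    if (!nrow(N) || max(abs(N)) == 0)
        stop("stoichiometric matrix over internal metabolites is zero; ",
             "the model has no internal structure to solve")
    qrd <- qr(t(N), tol = tol * max(abs(N)))
    r <- qrd$rank
    keptIdx <- sort(qrd$pivot[seq_len(r)])
    kept <- im[keptIdx]
    L <- diag(length(im))[, keptIdx, drop = FALSE]
    dimnames(L) <- list(im, kept)
    if (r < length(im)) {
        dropped <- setdiff(im, kept)
        ## each dropped row is a linear combination of kept rows
        C <- t(qr.solve(t(N[kept, , drop = FALSE]),
                        t(N[dropped, , drop = FALSE])))
        L[dropped, ] <- C
        metKeep <- !(model@metabolites$id %in% dropped)
        S <- stoichiometricMatrix(model, internal = FALSE)
        model <- MetabolicModel(model@metabolites[metKeep, , drop = FALSE],
                                model@reactions,
                                S[metKeep, , drop = FALSE],
                                model@proteins, targetReaction(model))
    }
    list(model = model, link = L)
})

#' Verify that a flux vector is a steady state of a model
#'
#' @param model \linkS4class{MetabolicModel}.
#' @param v named flux vector.
#' @return max |N v| (invisibly errors if above \code{tol}).
#' @param tol steady-state tolerance.
#' @export
checkSteadyState <- function(model, v, tol = 1e-8) {
    res <- max(abs(stoichiometricMatrix(model) %*% v[reactionIds(model)]))
    if (res > tol)
        stop("flux violates steady state: max|N v| = ", format(res))
    invisible(res)
}
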