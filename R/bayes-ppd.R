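#' Posterior predictive check
#'
#' Pushes posterior draws through the generative model: for every draw the
#' per-strain lin-log steady state is solved and replicated observations
#' are simulated with the drawn noise sds; each observed entry is then
#' compared with its predictive central interval. Clipped entries are
#' flagged and excluded from the coverage statistic (their measured value
#' is only a bound, so interval membership is not meaningful).
#'
#' @param problem \linkS4class{BmcaProblem} the posterior was fitted to.
#' @param posterior \linkS4class{PosteriorSamples}.
#' @param data the \linkS4class{OmicsDataset} that was fitted.
#' @param level central predictive interval level, in (0, 1).
#' @param nDraws posterior draws pushed through the model (default up to
#'   400).
#' @return data.frame with one row per observed entry: kind, sample,
#'   strain, feature_id, observed, pred_mean, pred_low, pred_high,
#'   inside_interval, clipped.
#' @export
posteriorPredictive <- function(problem, posterior, data, level = 0.95,
                                nDraws = 400L) {
    if (!(level > 0 && level < 1))
        stop("level must be strictly inside (0, 1)")
    model <- problem@model; ref <- problem@ref
    rid <- reactionIds(model); im <- internalMetabolites(model)
    strainsIds <- problem@strains
    nd <- min(nDraws, posterior@draws)
    sel <- seq_len(nd)
    nS <- length(strainsIds)

    ## per draw/strain model means
    muX <- array(NA_real_, c(nd, nS, length(im)))
    muV <- array(NA_real_, c(nd, nS, length(rid)))
    for (k in sel) {
        eps <- ElasticityMatrices(
            matrix(posterior@epsX[k, , ], length(rid), length(im),
                   dimnames = dimnames(posterior@epsX)[2:3]),
            matrix(posterior@epsY[k, , ], length(rid),
                   dim(posterior@epsY)[3],
                   dimnames = dimnames(posterior@epsY)[2:3]))
        for (s in seq_len(nS)) {
            pert <- PerturbationState(
                model,
                eRel = stats::setNames(exp(posterior@logE[k, s, ]), rid),
                yLog = stats::setNames(problem@yLog[s, ],
                                       colnames(problem@yLog)))
            sol <- tryCatch(
                solveSteadyState(model, ref, eps, pert,
                                 pseudoinverse = TRUE),
                error = function(e) NULL)
            if (!is.null(sol)) {
                muX[k, s, ] <- sol@xLog
                muV[k, s, ] <- sol@v
            }
        }
    }
    lo <- (1 - level) / 2; hi <- 1 - lo
    fluxScale <- problem@stats$fluxScale
    sdD <- posterior@sdDraws[sel, , drop = FALSE]

    ppdBlock <- function(se, kind, rows, meanArr, sdCol, scale = NULL) {
        val <- SummarizedExperiment::assay(se, "value")[rows, , drop = FALSE]
        clp <- SummarizedExperiment::assay(se, "clipped")[rows, , drop = FALSE]
        strain <- as.character(SummarizedExperiment::colData(se)$strain)
        idx <- which(!is.na(val), arr.ind = TRUE)
        if (!nrow(idx)) return(NULL)
        sIdx <- match(strain[idx[, 2]], strainsIds)
        out <- vector("list", nrow(idx))
        noise <- matrix(stats::rnorm(nd * nrow(idx)), nd, nrow(idx))
        for (q in seq_len(nrow(idx))) {
            f <- idx[q, 1]; s <- sIdx[q]
            mu <- meanArr[, s, f]
            sdq <- sdD[, sdCol] * (if (is.null(scale)) 1 else scale[f])
            rep <- mu + sdq * noise[, q]
            rep <- rep[is.finite(rep)]
            qs <- stats::quantile(rep, c(lo, hi), names = FALSE)
            out[[q]] <- data.frame(
                kind = kind, sample = colnames(val)[idx[q, 2]],
                strain = strain[idx[q, 2]], feature_id = rows[f],
                observed = val[idx[q, 1], idx[q, 2]],
                pred_mean = mean(rep), pred_low = qs[1], pred_high = qs[2],
                clipped = clp[idx[q, 1], idx[q, 2]],
                stringsAsFactors = FALSE)
        }
        do.call(rbind, out)
    }
    res <- rbind(
        ppdBlock(data@proteins, "protein", rid,
                 array(posterior@logE[sel, , ], c(nd, nS, length(rid))),
                 "protein"),
        ppdBlock(data@metabolites, "metabolite", im, muX, "metabolite"),
        ppdBlock(data@fluxes, "flux", rid, muV, "flux",
                 scale = fluxScale))
    res$inside_interval <- res$observed >= res$pred_low &
        res$observed <= res$pred_high
    res
}

#' Coverage summary of a posterior predictive check
#'
#' @param ppd output of \code{\link{posteriorPredictive}}.
#' @return data.frame of unclipped empirical coverage by kind plus overall.
#' @export
ppdCoverage <- function(ppd) {
    unc <- ppd[!ppd$clipped, ]
    by <- stats::aggregate(inside_interval ~ kind, unc, mean)
    rbind(by, data.frame(kind = "overall",
                         inside_interval = mean(unc$inside_interval)))
}
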