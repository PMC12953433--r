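#' Posterior of flux control coefficients on the target flux
#'
#' Propagates elasticity uncertainty to the FCCs: for every posterior draw
#' the analytic control coefficients are computed and the CJ row of the
#' target flux extracted. Draws whose lin-log system is singular (or whose
#' condition number exceeds the threshold) are masked rather than
#' regularized, and the masked fraction is reported; more than 50% masked
#' draws aborts.
#'
#' @param posterior \linkS4class{PosteriorSamples}.
#' @param model reduced \linkS4class{MetabolicModel}.
#' @param ref \linkS4class{ReferenceState}.
#' @param target target reaction id (default the model's target).
#' @param condThreshold condition-number mask threshold.
#' @return An \linkS4class{FCCPosterior}.
#' @export
fccPosterior <- function(posterior, model, ref,
                         target = targetReaction(model),
                         condThreshold = 1e10) {
    rid <- reactionIds(model)
    stopifnot(target %in% rid)
    nd <- posterior@draws
    out <- matrix(NA_real_, nd, length(rid), dimnames = list(NULL, rid))
    valid <- logical(nd)
    nM <- dim(posterior@epsX)[3]
    for (k in seq_len(nd)) {
        ex <- matrix(posterior@epsX[k, , ], length(rid), nM,
                     dimnames = dimnames(posterior@epsX)[2:3])
        cc <- tryCatch(
            controlCoefficients(model, ref, ex,
                                condThreshold = condThreshold),
            error = function(e) NULL)
        if (!is.null(cc)) {
            out[k, ] <- cc@CJ[target, ]
            valid[k] <- TRUE
        }
    }
    if (mean(valid) < 0.5)
        stop("more than 50% of posterior draws give a singular lin-log ",
             "system (", sum(!valid), "/", nd, " masked); the fitted ",
             "elasticities are degenerate")
    new("FCCPosterior", target = target, samples = out, validMask = valid)
}

#' Highest posterior density interval
#'
#' The narrowest contiguous interval containing \code{ceiling(level * n)}
#' of the sorted samples.
#'
#' @param samples numeric vector of at least 100 posterior samples.
#' @param level credible level in (0, 1).
#' @return c(low, high).
#' @export
hpdInterval <- function(samples, level = 0.95) {
    samples <- samples[is.finite(samples)]
    n <- length(samples)
    if (n < 100L) stop("need at least 100 samples for an HPD interval")
    if (!(level > 0 && level < 1)) stop("level must be in (0, 1)")
    s <- sort(samples)
    k <- ceiling(level * n)
    if (k >= n) return(c(s[1], s[n]))
    ## window [s[i], s[i+k-1]] holds exactly k samples
    widths <- s[k:n] - s[1:(n - k + 1)]
    i <- which.min(widths)
    c(s[i], s[i + k - 1])
}

#' Call ranked intervention targets from an FCC posterior
#'
#' A reaction is a significant target when its HPD interval at
#' \code{level} excludes zero and the posterior median FCC magnitude is at
#' least \code{magnitudeFloor}. A positive FCC means increasing the enzyme
#' increases the target flux (direction "overexpress"); a negative FCC
#' means decreasing it does (direction "delete"). The target reaction
#' itself is excluded. Calls are ranked by |median FCC| descending; the
#' posterior probability of a positive FCC is reported alongside.
#'
#' @param fcc \linkS4class{FCCPosterior}.
#' @param model \linkS4class{MetabolicModel} (for protein annotations).
#' @param level HPD level (default 0.95).
#' @param magnitudeFloor minimum |median FCC| for a call (default 0.05);
#'   the qualitative selection threshold, reported with the calls.
#' @return A \code{\link[S4Vectors]{DataFrame}} with columns reaction_id,
#'   protein_ids, fcc_median, hpd_low, hpd_high, prob_positive,
#'   significant, direction, ranked by |fcc_median|.
#' @export
callTargets <- function(fcc, model, level = 0.95, magnitudeFloor = 0.05) {
    stopifnot(level > 0, level < 1)
    sm <- fcc@samples[fcc@validMask, , drop = FALSE]
    rxs <- setdiff(colnames(sm), fcc@target)
    rows <- lapply(rxs, function(r) {
        v <- sm[, r]
        hpd <- hpdInterval(v, level)
        med <- stats::median(v)
        sig <- (hpd[1] > 0 || hpd[2] < 0) && abs(med) >= magnitudeFloor
        dir <- if (!sig) "none" else if (med > 0) "overexpress" else "delete"
        prots <- paste(unique(unlist(model@proteins[[r]])), collapse = ";")
        data.frame(reaction_id = r, protein_ids = prots, fcc_median = med,
                   hpd_low = hpd[1], hpd_high = hpd[2],
                   prob_positive = mean(v > 0), significant = sig,
                   direction = dir, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab <- tab[order(-abs(tab$fcc_median)), ]
    rownames(tab) <- NULL
    res <- S4Vectors::DataFrame(tab)
    S4Vectors::metadata(res) <- list(level = level,
                                     magnitudeFloor = magnitudeFloor,
                                     maskedFraction = mean(!fcc@validMask))
    res
}

#' Write a target table as TSV
#'
#' @param targets output of \code{\link{callTargets}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTargetTable <- function(targets, path) {
    utils::write.table(as.data.frame(targets), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}
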