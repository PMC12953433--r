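#' Construct an OmicsDataset from feature x sample matrices
#'
#' @param model \linkS4class{MetabolicModel} the features are indexed
#'   against: protein and flux rows are reaction ids, metabolite rows are
#'   internal metabolite ids. NA marks an unobserved entry.
#' @param proteinLog reactions x samples matrix of reaction-level protein
#'   log-ratios (see \code{\link{reactionLogRatios}}).
#' @param metaboliteLog internal metabolites x samples matrix of metabolite
#'   log-ratios.
#' @param fluxes reactions x samples matrix of flux estimates
#'   (mmol gDCW^-1 h^-1).
#' @param strain character vector, one strain id per sample.
#' @return An \linkS4class{OmicsDataset} (unclipped).
#' @export
OmicsDataset <- function(model, proteinLog, metaboliteLog, fluxes, strain) {
    mkSE <- function(mat, rows) {
        mat <- as.matrix(mat)
        if (is.null(rownames(mat)) && nrow(mat) == length(rows))
            rownames(mat) <- rows
        stopifnot(setequal(rownames(mat), rows))
        mat <- mat[rows, , drop = FALSE]
        SummarizedExperiment::SummarizedExperiment(
            assays = list(value = mat,
                          clipped = matrix(FALSE, nrow(mat), ncol(mat),
                                           dimnames = dimnames(mat))),
            colData = S4Vectors::DataFrame(strain = strain,
                                           row.names = colnames(mat)))
    }
    new("OmicsDataset",
        proteins = mkSE(proteinLog, reactionIds(model)),
        metabolites = mkSE(metaboliteLog, internalMetabolites(model)),
        fluxes = mkSE(fluxes, reactionIds(model)),
        clipBound = NA_real_)
}

#' Clip extreme log-ratio observations
#'
#' Protein and metabolite log-ratio entries with |value| > bound are
#' replaced by the signed bound and flagged in the \code{clipped} assay;
#' the originals are retained in assay \code{raw}. Clipping keeps the data
#' near the reference state, where the lin-log approximation is valid;
#' downstream, clipped entries enter the likelihood as censored
#' observations rather than exact values. Fluxes are absolute-scale and are
#' not clipped. The operation is idempotent at a fixed bound.
#'
#' @param data an \linkS4class{OmicsDataset}.
#' @param bound clipping bound in natural-log units (default 2).
#' @return The clipped \linkS4class{OmicsDataset}.
#' @export
setMethod("clipObservations", "OmicsDataset", function(data, bound = 2) {
    stopifnot(bound > 0)
    clipSE <- function(se) {
        val <- SummarizedExperiment::assay(se, "value")
        raw <- if ("raw" %in% SummarizedExperiment::assayNames(se))
            SummarizedExperiment::assay(se, "raw") else val
        hit <- !is.na(raw) & abs(raw) > bound
        val <- ifelse(hit, sign(raw) * bound, raw)
        SummarizedExperiment::assays(se) <-
            list(value = val, clipped = hit, raw = raw)
        se
    }
    data@proteins <- clipSE(data@proteins)
    data@metabolites <- clipSE(data@metabolites)
    fl <- data@fluxes
    if (!("raw" %in% SummarizedExperiment::assayNames(fl))) {
        SummarizedExperiment::assays(fl) <- c(
            SummarizedExperiment::assays(fl),
            list(raw = SummarizedExperiment::assay(fl, "value")))
        data@fluxes <- fl
    }
    data@clipBound <- bound
    methods::validObject(data)
    data
})

#' Write an OmicsDataset as a long-format TSV
#'
#' Columns: sample, strain, kind (protein/metabolite/flux), feature_id,
#' value. Only observed (non-NA) entries are written; values are the
#' pre-clipping originals when present.
#'
#' @param data \linkS4class{OmicsDataset}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeOmicsTSV <- function(data, path) {
    longOne <- function(se, kind) {
        a <- if ("raw" %in% SummarizedExperiment::assayNames(se))
            SummarizedExperiment::assay(se, "raw")
        else SummarizedExperiment::assay(se, "value")
        idx <- which(!is.na(a), arr.ind = TRUE)
        if (!nrow(idx)) return(NULL)
        data.frame(sample = colnames(a)[idx[, 2]],
                   strain = as.character(
                       SummarizedExperiment::colData(se)$strain)[idx[, 2]],
                   kind = kind, feature_id = rownames(a)[idx[, 1]],
                   value = a[idx], stringsAsFactors = FALSE)
    }
    long <- rbind(longOne(data@proteins, "protein"),
                  longOne(data@metabolites, "metabolite"),
                  longOne(data@fluxes, "flux"))
    long <- long[order(long$kind, long$sample, long$feature_id), ]
    utils::write.table(long, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a long-format omics TSV into an OmicsDataset
#'
#' @param path TSV with columns sample, strain, kind, feature_id, value.
#' @param model \linkS4class{MetabolicModel} the features index into.
#' @return An unclipped \linkS4class{OmicsDataset}.
#' @export
readOmicsTSV <- function(path, model) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("sample", "strain", "kind", "feature_id", "value")
    if (!all(need %in% names(tab)))
        stop("omics table needs columns: ", paste(need, collapse = ", "))
    bad <- setdiff(tab$kind, c("protein", "metabolite", "flux"))
    if (length(bad)) stop("unknown observation kind(s): ",
                          paste(bad, collapse = ", "))
    samples <- unique(tab$sample)
    strain <- tab$strain[match(samples, tab$sample)]
    wide <- function(kind, rows) {
        sub <- tab[tab$kind == kind, ]
        bad <- setdiff(sub$feature_id, rows)
        if (length(bad)) stop(kind, " feature(s) not in model: ",
                              paste(bad, collapse = ", "))
        m <- matrix(NA_real_, length(rows), length(samples),
                    dimnames = list(rows, samples))
        m[cbind(sub$feature_id, sub$sample)] <- sub$value
        m
    }
    OmicsDataset(model,
                 proteinLog = wide("protein", reactionIds(model)),
                 metaboliteLog = wide("metabolite",
                                      internalMetabolites(model)),
                 fluxes = wide("flux", reactionIds(model)),
                 strain = strain)
}
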