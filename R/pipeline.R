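#' Default pipeline configuration
#'
#' Returns the configuration list for a fully synthetic end-to-end run;
#' every key can be overridden (and every value is recorded in the run
#' manifest). Structure: \code{model} (path + dialect + reference flux
#' table, or \code{synthetic} preset), \code{data} (omics/time-series
#' paths or simulation settings), \code{clipBound}, \code{eflux2}
#' (objective, ceiling M, exchange band), \code{fit} (iterations,
#' learningRate, draws, nMC), \code{targets} (level, magnitudeFloor),
#' \code{seed}, \code{outputDir}.
#'
#' @param outputDir run output directory.
#' @param seed master seed of the run.
#' @return nested configuration list.
#' @export
defaultConfig <- function(outputDir = "bmca_run", seed = 1L) {
    list(
        model = list(path = NULL, dialect = "auto", referenceFluxes = NULL,
                     synthetic = list(preset = "branched_3hp", seed = 1L)),
        data = list(omics = NULL, timeseries = NULL,
                    simulate = list(sdProtein = 0.1, sdMetabolite = 0.1,
                                    sdFlux = 0.1, obsFractionProtein = 0.8,
                                    obsFractionMetabolite = 0.8,
                                    replicates = 3L)),
        clipBound = 2,
        eflux2 = list(objective = NULL, M = 100, band = 0.05,
                      enabled = TRUE),
        fit = list(iterations = 20000L, learningRate = 0.2, draws = 1000L,
                   nMC = 1L),
        targets = list(level = 0.95, magnitudeFloor = 0.05),
        seed = as.integer(seed),
        outputDir = outputDir)
}

#' Read and validate a pipeline configuration
#'
#' @param path YAML file; keys as in \code{\link{defaultConfig}} (missing
#'   keys take the defaults).
#' @return validated configuration list.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(defaultConfig(), user)
    validateConfig(cfg)
    cfg
}

#' @rdname readRunConfig
#' @param cfg configuration list.
#' @export
validateConfig <- function(cfg) {
    if (is.null(cfg$model$path) && is.null(cfg$model$synthetic))
        stop("config error: either model$path or model$synthetic required")
    if (!is.null(cfg$model$path) && !file.exists(cfg$model$path))
        stop("config error: model file not found: ", cfg$model$path)
    if (!is.null(cfg$model$path) && is.null(cfg$model$referenceFluxes))
        stop("config error: a loaded model needs model$referenceFluxes")
    if (!is.null(cfg$data$omics) && !file.exists(cfg$data$omics))
        stop("config error: omics file not found: ", cfg$data$omics)
    stopifnot(cfg$clipBound > 0,
              cfg$targets$level > 0, cfg$targets$level < 1,
              cfg$fit$iterations >= 1)
    invisible(cfg)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order -- exchange-rate estimation, E-Flux2 flux
#' estimation, clipping, variational fit, FCC propagation, target calling
#' -- and writes every artifact plus a run manifest (config hash, seed,
#' package version, ELBO summary, masked-draw fraction) to
#' \code{config$outputDir}. Re-running with the same config and seed
#' reproduces the outputs.
#'
#' @param config list from \code{\link{defaultConfig}} /
#'   \code{\link{readRunConfig}}, or a path to a YAML config.
#' @return invisibly, a list with the run objects (model, ref, data,
#'   rates, fluxes, posterior, fcc, targets, ppd, manifest).
#' @export
runPipeline <- function(config = defaultConfig()) {
    if (is.character(config)) config <- readRunConfig(config)
    validateConfig(config)
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(config$outputDir, f)
    yaml::write_yaml(config, out("config.yaml"))
    cfgHash <- unname(tools::md5sum(out("config.yaml")))
    seed <- as.integer(config$seed)
    msg <- function(...) message("[bmca] ", ...)

    ## --- model + data ------------------------------------------------
    truth <- NULL
    if (!is.null(config$model$path)) {
        msg("loading model from ", config$model$path)
        model <- loadModel(config$model$path, config$model$dialect)
        vstar <- readReferenceFluxes(config$model$referenceFluxes)
        model <- reduceModel(model, vstar)
        vstar <- vstar[reactionIds(model)]
        model <- removeConservedMoieties(model)$model
        ref <- ReferenceState(model, vstar)
    } else {
        sy <- config$model$synthetic
        msg("generating synthetic truth (preset ", sy$preset, ", seed ",
            sy$seed, ")")
        truth <- makeToyNetwork(sy$preset, seed = sy$seed)
        model <- truth@model; ref <- truth@ref
    }

    sim <- NULL
    if (!is.null(config$data$omics)) {
        data <- readOmicsTSV(config$data$omics, model)
        series <- if (!is.null(config$data$timeseries))
            readTimeSeries(config$data$timeseries) else NULL
        analyteMap <- NULL
    } else {
        if (is.null(truth))
            stop("config error: no omics data and no synthetic model")
        ns <- config$data$simulate
        noise <- NoiseSpec(sdProtein = ns$sdProtein,
                           sdMetabolite = ns$sdMetabolite,
                           sdFlux = ns$sdFlux,
                           obsFractionProtein = ns$obsFractionProtein,
                           obsFractionMetabolite = ns$obsFractionMetabolite,
                           replicates = ns$replicates,
                           clipBound = config$clipBound, seed = seed)
        msg("simulating ", length(truth@designs), "-strain dataset")
        sim <- simulateDataset(truth, noise)
        data <- sim$data
        series <- sim$series
        analyteMap <- sim$analyteMap
        writeOmicsTSV(data, out("omics.tsv"))
        utils::write.table(series, out("timeseries.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
    }

    ## --- exchange rates ----------------------------------------------
    rates <- NULL
    if (!is.null(series) && !is.null(analyteMap)) {
        msg("estimating exchange rates")
        rates <- estimateExchangeRates(series, analyteMap)
        utils::write.table(rates, out("rates.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
    }

    ## --- E-Flux2 fluxes ----------------------------------------------
    fluxTab <- NULL
    if (isTRUE(config$eflux2$enabled) && !is.null(rates)) {
        objective <- config$eflux2$objective
        if (is.null(objective)) objective <- targetReaction(model)
        msg("estimating intracellular fluxes (E-Flux2, objective ",
            objective, ")")
        pl <- SummarizedExperiment::assay(data@proteins, "value")
        strainOf <- strains(data)
        fmat <- SummarizedExperiment::assay(data@fluxes, "value")
        for (s in unique(strainOf)) {
            cols <- which(strainOf == s)
            expr <- exp(rowMeans(pl[, cols, drop = FALSE], na.rm = TRUE))
            expr[is.nan(expr)] <- NA_real_
            rs <- rates[rates$strain == s, ]
            est <- eflux2(model, expr,
                          stats::setNames(rs$rate, rs$reaction_id),
                          objective, M = config$eflux2$M,
                          band = config$eflux2$band)
            if (est$status == "optimal") {
                fmat[, cols] <- est$v
                fluxTab <- rbind(fluxTab,
                                 data.frame(strain = s,
                                            reaction_id = names(est$v),
                                            flux = unname(est$v)))
            } else {
                warning("E-Flux2 infeasible for strain ", s,
                        "; keeping prior flux observations")
            }
        }
        SummarizedExperiment::assay(data@fluxes, "value") <- fmat
        SummarizedExperiment::assay(data@fluxes, "raw") <- fmat
        if (!is.null(fluxTab))
            utils::write.table(fluxTab, out("fluxes.tsv"), sep = "\t",
                               quote = FALSE, row.names = FALSE)
    }

    ## --- clip + fit ----------------------------------------------------
    data <- clipObservations(data, config$clipBound)
    msg("building inference problem")
    problem <- buildBmcaModel(model, ref, data)
    msg("fitting variational posterior (cap ", config$fit$iterations,
        " iterations)")
    posterior <- fitVariational(problem,
                                iterations = config$fit$iterations,
                                learningRate = config$fit$learningRate,
                                seed = seed, draws = config$fit$draws,
                                nMC = config$fit$nMC)
    msg("ELBO ", format(utils::tail(posterior@elboTrace, 1), digits = 6),
        if (posterior@converged) " (converged)" else " (cap reached)")

    ## --- FCC + targets -------------------------------------------------
    msg("propagating to flux control coefficients")
    fcc <- fccPosterior(posterior, model, ref)
    targets <- callTargets(fcc, model, level = config$targets$level,
                           magnitudeFloor = config$targets$magnitudeFloor)
    writeTargetTable(targets, out("targets.tsv"))
    ppd <- posteriorPredictive(problem, posterior, data,
                               level = config$targets$level)
    utils::write.table(ppd, out("ppd.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)

    manifest <- list(
        config_hash = cfgHash, seed = seed,
        package_version = as.character(utils::packageVersion("BayesMCA")),
        n_strains = length(problem@strains),
        n_samples = ncol(data@proteins),
        elbo_final = utils::tail(posterior@elboTrace, 1),
        elbo_iterations = length(posterior@elboTrace),
        converged = posterior@converged,
        masked_draw_fraction = mean(!fcc@validMask),
        n_significant_targets = sum(targets$significant),
        outputs = list.files(config$outputDir))
    jsonlite::write_json(manifest, out("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    run <- list(config = config, model = model, ref = ref, truth = truth,
                data = data, rates = rates, fluxes = fluxTab,
                problem = problem, posterior = posterior, fcc = fcc,
                targets = targets, ppd = ppd, manifest = manifest)
    makeReport(run, config$outputDir)
    invisible(run)
}

#' Generate the run report (figures + markdown summary)
#'
#' Writes the posterior-predictive scatter (predicted vs. observed, with
#' the unclipped region shaded and clipped points marked), the FCC forest
#' plot with the magnitude-floor threshold lines, and a markdown report
#' embedding the ranked target table. When no target is significant the
#' report says so explicitly.
#'
#' @param run result list of \code{\link{runPipeline}}.
#' @param dir output directory.
#' @return invisibly, the report path.
#' @export
makeReport <- function(run, dir = run$config$outputDir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ppd <- run$ppd
    bound <- run$data@clipBound

    pScatter <- ggplot2::ggplot(
        ppd, ggplot2::aes(x = .data$pred_mean, y = .data$observed,
                          colour = .data$clipped)) +
        ggplot2::geom_abline(slope = 1, intercept = 0,
                             linetype = "dashed", colour = "grey40") +
        ggplot2::geom_point(alpha = 0.5, size = 0.8) +
        ggplot2::facet_wrap(~kind, scales = "free") +
        ggplot2::scale_colour_manual(values = c(`FALSE` = "#2c7fb8",
                                                `TRUE` = "#d95f0e")) +
        ggplot2::labs(x = "posterior predictive mean", y = "observed",
                      colour = "clipped",
                      title = "Posterior predictive check") +
        ggplot2::theme_bw()
    grDevices::pdf(file.path(dir, "ppd_scatter.pdf"), width = 9,
                   height = 3.2)
    print(pScatter)
    grDevices::dev.off()

    tg <- as.data.frame(run$targets)
    tg$reaction_id <- factor(tg$reaction_id,
                             levels = rev(tg$reaction_id))
    floorV <- run$config$targets$magnitudeFloor
    pForest <- ggplot2::ggplot(
        tg, ggplot2::aes(x = .data$fcc_median, y = .data$reaction_id,
                         colour = .data$direction)) +
        ggplot2::geom_vline(xintercept = c(-floorV, floorV),
                            linetype = "dotted") +
        ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
        ggplot2::geom_errorbarh(
            ggplot2::aes(xmin = .data$hpd_low, xmax = .data$hpd_high),
            height = 0.25) +
        ggplot2::geom_point(size = 1.6) +
        ggplot2::scale_colour_manual(values = c(
            overexpress = "#1b9e77", delete = "#d95f02",
            none = "grey55")) +
        ggplot2::labs(x = "flux control coefficient on target flux",
                      y = NULL, title = "FCC posterior (95% HPD)") +
        ggplot2::theme_bw()
    grDevices::pdf(file.path(dir, "fcc_forest.pdf"), width = 6,
                   height = 0.28 * nrow(tg) + 1.5)
    print(pForest)
    grDevices::dev.off()

    rpt <- file.path(dir, "report.md")
    con <- file(rpt, "w"); on.exit(close(con))
    w <- function(...) writeLines(paste0(...), con)
    w("# BMCA run report\n")
    w("- config hash: ", run$manifest$config_hash)
    w("- seed: ", run$manifest$seed)
    w("- samples: ", run$manifest$n_samples, " (",
      run$manifest$n_strains, " strains)")
    w("- ELBO: ", format(run$manifest$elbo_final, digits = 6), " after ",
      run$manifest$elbo_iterations, " iterations (",
      if (run$manifest$converged) "converged" else "cap reached", ")")
    w("- masked FCC draws: ",
      format(100 * run$manifest$masked_draw_fraction, digits = 3), "%\n")
    nsig <- sum(run$targets$significant)
    if (nsig == 0) {
        w("**No significant intervention targets** at HPD level ",
          run$config$targets$level, " with magnitude floor ",
          run$config$targets$magnitudeFloor, ".\n")
    } else {
        w("## Ranked intervention targets (", nsig, " significant)\n")
        w("| reaction | proteins | FCC median | HPD | direction |")
        w("|---|---|---|---|---|")
        for (i in seq_len(nrow(tg))) {
            r <- as.data.frame(run$targets)[i, ]
            w("| ", r$reaction_id, " | ", r$protein_ids, " | ",
              sprintf("%.3f", r$fcc_median), " | [",
              sprintf("%.3f", r$hpd_low), ", ",
              sprintf("%.3f", r$hpd_high), "] | ",
              if (r$significant) r$direction else "-", " |")
        }
        w("")
    }
    w("Figures: `ppd_scatter.pdf`, `fcc_forest.pdf`; tables: ",
      "`targets.tsv`, `ppd.tsv`.")
    invisible(rpt)
}

#' @importFrom ggplot2 .data
NULL
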