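## One replicate of the simulation study: fixed branched ground truth,
## seeded noisy dataset, variational fit, FCC propagation, target calls.
## Computed lazily and cached so several test blocks can share a run.

.studyCache <- new.env(parent = emptyenv())

recoveryRun <- function(seed, truth = NULL, iterations = 20000L,
                        draws = 500L, ppdDraws = 300L) {
    key <- paste0("s", seed)
    if (!is.null(.studyCache[[key]])) return(.studyCache[[key]])
    if (is.null(truth)) truth <- makeToyNetwork("branched_3hp", seed = 1)
    sim <- simulateDataset(truth, NoiseSpec(seed = seed))
    problem <- buildBmcaModel(truth@model, truth@ref, sim$data)
    posterior <- fitVariational(problem, iterations = iterations,
                                seed = seed, draws = draws)
    pm <- posteriorMeanElasticities(posterior)
    nzX <- truth@eps@epsX != 0
    nzY <- truth@eps@epsY != 0
    spearman <- stats::cor(c(pm@epsX[nzX], pm@epsY[nzY]),
                           c(truth@eps@epsX[nzX], truth@eps@epsY[nzY]),
                           method = "spearman")
    fcc <- fccPosterior(posterior, truth@model, truth@ref)
    med <- apply(fcc@samples[fcc@validMask, , drop = FALSE], 2,
                 stats::median)
    truRow <- truth@fcc@CJ[targetReaction(truth@model), ]
    big <- abs(truRow) >= 0.1
    signRecovery <- mean(sign(med[big]) == sign(truRow[big]))
    targets <- callTargets(fcc, truth@model)
    tdf <- as.data.frame(targets)
    dirOf <- function(r) tdf$direction[tdf$reaction_id == r]
    ppd <- posteriorPredictive(problem, posterior, sim$data,
                               level = 0.95, nDraws = ppdDraws)
    cov <- ppdCoverage(ppd)
    res <- list(truth = truth, sim = sim, problem = problem,
                posterior = posterior, fcc = fcc, targets = tdf,
                spearman = spearman, signRecovery = signRecovery,
                ald6 = dirOf("r_ald6"), pyc = dirOf("r_pyc"),
                coverage = cov$inside_interval[cov$kind == "overall"],
                ppd = ppd)
    .studyCache[[key]] <- res
    res
}
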