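test_that("log-joint gradient matches central finite differences", {
    truth <- makeToyNetwork("branched_3hp", seed = 1)
    sim <- simulateDataset(truth, NoiseSpec(seed = 3, replicates = 2,
                                            clipBound = 1.5))
    pb <- buildBmcaModel(truth@model, truth@ref, sim$data)
    set.seed(42)
    th <- rnorm(pb@stats$D, 0, 0.3)
    r <- BayesMCA:::.logpGrad(th, pb)
    h <- 1e-6
    set.seed(9)
    idx <- sample(pb@stats$D, 20)
    fd <- vapply(idx, function(i) {
        tp <- th; tm <- th
        tp[i] <- tp[i] + h; tm[i] <- tm[i] - h
        (BayesMCA:::.logpGrad(tp, pb)$lp -
         BayesMCA:::.logpGrad(tm, pb)$lp) / (2 * h)
    }, 0)
    expect_lt(max(abs(fd - r$grad[idx]) / pmax(abs(fd), 1)), 1e-4)
})

test_that("the ADVI kernel solves the conjugate Gaussian exactly enough", {
    ## prior N(0,1), 10 observations with sd 0.5 and mean 1.2
    n <- 10; sd0 <- 0.5; ybar <- 1.2
    postVar <- 1 / (1 + n / sd0^2)
    postMean <- postVar * n * ybar / sd0^2
    lg <- function(th) list(lp = -th^2 / 2 - n * (th - ybar)^2 / (2 * sd0^2),
                            grad = -th - n * (th - ybar) / sd0^2)
    set.seed(1)
    opt <- BayesMCA:::.adviOptimize(lg, 1L, iterations = 20000L, nMC = 10L)
    expect_lt(abs(opt$mu - postMean) / postMean, 0.02)
    expect_lt(abs(exp(opt$omega) - sqrt(postVar)) / sqrt(postVar), 0.1)
})

test_that("fits are bitwise reproducible under a fixed seed", {
    truth <- twoStepTruth()
    sim <- simulateDataset(truth, NoiseSpec(seed = 5, replicates = 2))
    pb <- buildBmcaModel(truth@model, truth@ref, sim$data)
    p1 <- fitVariational(pb, iterations = 800L, seed = 11, draws = 50L)
    p2 <- fitVariational(pb, iterations = 800L, seed = 11, draws = 50L)
    expect_identical(p1@epsX, p2@epsX)
    expect_identical(p1@logE, p2@logE)
    expect_identical(p1@sdDraws, p2@sdDraws)
    expect_identical(p1@elboTrace, p2@elboTrace)
    ## a different seed gives different draws
    p3 <- fitVariational(pb, iterations = 800L, seed = 12, draws = 50L)
    expect_false(identical(p1@epsX, p3@epsX))
})

test_that("with no data the variational posterior returns the prior", {
    truth <- twoStepTruth()
    pb <- buildBmcaModel(truth@model, truth@ref, data = NULL,
                         prior = priorSpec(fixedSds = c(protein = 0.1,
                                                        metabolite = 0.1,
                                                        flux = 0.1)))
    post <- fitVariational(pb, iterations = 6000L, seed = 2, draws = 200L)
    mu <- post@varParams$mu
    sdv <- exp(post@varParams$omega)
    st <- pb@stats
    ## Gaussian KL(q || prior) per free elasticity below tolerance
    pm <- c(st$fxMean, st$fyMean)
    kl <- 0.5 * ((sdv[st$idxEps]^2 + (mu[st$idxEps] - pm)^2) - 1 -
                 2 * log(sdv[st$idxEps]))
    expect_lt(max(kl), 0.02)
    ## latent enzymes revert to their N(0,1) prior too
    klE <- 0.5 * ((sdv[st$idxLogE]^2 + mu[st$idxLogE]^2) - 1 -
                  2 * log(sdv[st$idxLogE]))
    expect_lt(max(klE), 0.02)
})

test_that("zero-noise observations pin the posterior near the truth", {
    truth <- twoStepTruth()
    sim <- simulateDataset(truth, NoiseSpec(sdProtein = 0, sdMetabolite = 0,
                                            sdFlux = 0, obsFractionProtein = 1,
                                            obsFractionMetabolite = 1,
                                            replicates = 3, seed = 4))
    pb <- buildBmcaModel(truth@model, truth@ref, sim$data,
                         prior = priorSpec(fixedSds = c(protein = 0.02,
                                                        metabolite = 0.02,
                                                        flux = 0.02)))
    post <- fitVariational(pb, iterations = 12000L, seed = 3, draws = 200L)
    pm <- posteriorMeanElasticities(post)
    nz <- truth@eps@epsX != 0
    ## within a tenth of the prior sd of the generating values
    expect_lt(max(abs(pm@epsX[nz] - truth@eps@epsX[nz])), 0.1)
})

test_that("doubling replicates contracts the elasticity posterior", {
    truth <- twoStepTruth()
    meanSd <- function(reps, seed) {
        sim <- simulateDataset(truth, NoiseSpec(replicates = reps,
                                                seed = seed))
        pb <- buildBmcaModel(truth@model, truth@ref, sim$data)
        post <- fitVariational(pb, iterations = 8000L, seed = 1,
                               draws = 100L)
        mean(exp(post@varParams$omega)[pb@stats$idxEps[
            seq_len(pb@stats$Kx)]])
    }
    expect_lt(meanSd(6L, 21), meanSd(2L, 21))
})

test_that("posterior predictive flags clipped entries and checks level", {
    truth <- twoStepTruth()
    sim <- simulateDataset(truth, NoiseSpec(seed = 6, clipBound = 0.5))
    pb <- buildBmcaModel(truth@model, truth@ref, sim$data)
    post <- fitVariational(pb, iterations = 2000L, seed = 1, draws = 150L)
    expect_error(posteriorPredictive(pb, post, sim$data, level = 0),
                 "level")
    ppd <- posteriorPredictive(pb, post, sim$data, nDraws = 100L)
    expect_true(any(ppd$clipped))
    expect_true(all(ppd$pred_low <= ppd$pred_high))
    cov <- ppdCoverage(ppd)
    ## coverage statistic excludes clipped entries by construction
    expect_identical(nrow(ppd[!ppd$clipped, ]) > 0, TRUE)
    expect_true(all(cov$inside_interval >= 0 & cov$inside_interval <= 1))
})

test_that("a divergent model aborts with diagnostics", {
    lg <- function(th) list(lp = NaN, grad = th)
    expect_error(BayesMCA:::.adviOptimize(lg, 1L, iterations = 10L),
                 "divergent ELBO")
})
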