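## Mean-field ADVI kernel. The variational family is a diagonal Gaussian
## q(theta) = N(mu, diag(exp(omega))^2) over the unconstrained parameters;
## the ELBO is maximized by stochastic gradient ascent with the Adagrad
## rule, using reparameterization-gradient estimates
##   theta = mu + exp(omega) z,  z ~ N(0, I)
##   dELBO/dmu = E[dlogp/dtheta],  dELBO/domega = E[dlogp/dtheta * z] sigma + 1.

.adviOptimize <- function(logpGrad, D, muInit = numeric(D),
                          omegaInit = rep(log(0.1), D),
                          iterations = 20000L, learningRate = 0.2,
                          nMC = 1L, window = 500L, convTol = 1e-4,
                          epsAda = 1e-8) {
    mu <- muInit; omega <- omegaInit
    accMu <- numeric(D); accOm <- numeric(D)
    elbo <- numeric(iterations)
    entConst <- D / 2 * log(2 * pi * exp(1))
    converged <- FALSE
    it <- 0L
    while (it < iterations) {
        it <- it + 1L
        sigma <- exp(omega)
        gMu <- numeric(D); gOm <- numeric(D); lpAcc <- 0
        for (m in seq_len(nMC)) {
            z <- stats::rnorm(D)
            theta <- mu + sigma * z
            r <- logpGrad(theta)
            if (!is.finite(r$lp) || any(!is.finite(r$grad)))
                stop("divergent ELBO at iteration ", it,
                     ": non-finite log density or gradient ",
                     "(lp = ", r$lp, "); try a smaller learning rate")
            gMu <- gMu + r$grad / nMC
            gOm <- gOm + (r$grad * z * sigma) / nMC
            lpAcc <- lpAcc + r$lp / nMC
        }
        gOm <- gOm + 1
        accMu <- accMu + gMu^2
        accOm <- accOm + gOm^2
        mu <- mu + learningRate * gMu / (sqrt(accMu) + epsAda)
        omega <- omega + learningRate * gOm / (sqrt(accOm) + epsAda)
        elbo[it] <- lpAcc + sum(omega) + entConst
        ## stopping rule: relative change of the windowed mean of the
        ## smoothed negative ELBO
        if (it %% window == 0L && it >= 2L * window) {
            cur <- mean(-elbo[(it - window + 1L):it])
            prev <- mean(-elbo[(it - 2L * window + 1L):(it - window)])
            if (abs(cur - prev) / max(abs(prev), 1e-12) < convTol) {
                converged <- TRUE
                break
            }
        }
    }
    list(mu = mu, omega = omega, elbo = elbo[seq_len(it)],
         converged = converged, iterations = it)
}

#' Fit the variational posterior
#'
#' Optimizes a mean-field Gaussian approximation to the posterior of the
#' problem built by \code{\link{buildBmcaModel}} using reparameterization
#' gradients and the Adagrad optimizer, stopping when the windowed mean of
#' the negative evidence lower bound changes by less than \code{convTol}
#' relative over a \code{window}-iteration window (or at the iteration
#' cap, flagged in the result). The run is fully reproducible from
#' \code{seed}.
#'
#' @param problem a \linkS4class{BmcaProblem}.
#' @param iterations iteration cap (default 20000).
#' @param learningRate Adagrad learning rate (default 0.2).
#' @param seed integer seed for the stochastic gradients and the returned
#'   draws.
#' @param draws number of posterior draws to return (default 1000).
#' @param nMC Monte Carlo samples per gradient estimate (default 1).
#' @param window,convTol stopping rule parameters.
#' @return A \linkS4class{PosteriorSamples}.
#' @export
fitVariational <- function(problem, iterations = 20000L,
                           learningRate = 0.2, seed = 1L, draws = 1000L,
                           nMC = 1L, window = 500L, convTol = 1e-4) {
    st <- problem@stats
    D <- st$D
    ## initialize latent enzyme means at the observed protein averages
    muInit <- numeric(D)
    muInit[st$idxEps] <- c(st$fxMean, st$fyMean)
    if (!is.null(st$agg)) {
        aP <- st$agg$protein
        mLE <- ifelse(aP$n > 0, aP$sum / pmax(aP$n, 1), 0)
        muInit[st$idxLogE] <- as.vector(mLE)
    }
    if (st$learnSds) muInit[st$idxZeta] <- log(0.2)
    fit <- .withSeed(seed, {
        opt <- .adviOptimize(function(th) .logpGrad(th, problem), D,
                             muInit = muInit, iterations = iterations,
                             learningRate = learningRate, nMC = nMC,
                             window = window, convTol = convTol)
        sigma <- exp(opt$omega)
        Z <- matrix(stats::rnorm(draws * D), draws, D)
        TH <- sweep(Z, 2, sigma, "*") + rep(opt$mu, each = draws)
        list(opt = opt, TH = TH)
    })
    opt <- fit$opt; TH <- fit$TH
    rid <- reactionIds(problem@model)
    im <- internalMetabolites(problem@model)
    ex <- externalMetabolites(problem@model)
    nR <- st$nR; nM <- st$nM; nS <- st$nS
    epsXdraws <- array(0, c(draws, nR, nM),
                       dimnames = list(NULL, rid, im))
    for (k in seq_len(st$Kx))
        epsXdraws[, st$fxIdx[k, 1], st$fxIdx[k, 2]] <- TH[, k]
    epsYdraws <- array(0, c(draws, nR, length(ex)),
                       dimnames = list(NULL, rid, ex))
    for (k in seq_len(st$Ky))
        epsYdraws[, st$fyIdx[k, 1], st$fyIdx[k, 2]] <- TH[, st$Kx + k]
    logEdraws <- array(TH[, st$idxLogE],
                       c(draws, nS, nR),
                       dimnames = list(NULL, problem@strains, rid))
    sdDraws <- if (st$learnSds) exp(TH[, st$idxZeta, drop = FALSE])
               else matrix(rep(unname(
                   st$fixedSds[c("protein", "metabolite", "flux")]),
                   each = draws), draws, 3)
    colnames(sdDraws) <- c("protein", "metabolite", "flux")
    new("PosteriorSamples", draws = as.integer(draws),
        epsX = epsXdraws, epsY = epsYdraws, logE = logEdraws,
        sdDraws = sdDraws, elboTrace = opt$elbo, seed = as.integer(seed),
        converged = opt$converged,
        varParams = list(mu = opt$mu, omega = opt$omega))
}

#' Posterior-mean elasticities
#'
#' @param posterior \linkS4class{PosteriorSamples}.
#' @return An \linkS4class{ElasticityMatrices} of posterior means.
#' @export
posteriorMeanElasticities <- function(posterior) {
    ElasticityMatrices(apply(posterior@epsX, c(2, 3), mean),
                       apply(posterior@epsY, c(2, 3), mean))
}
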