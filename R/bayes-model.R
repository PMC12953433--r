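## Generative model and hand-derived gradients.
##
## Per strain s with latent log enzyme levels logE[s,]:
##   e = exp(logE[s,]), d = v* e
##   x solves   [N diag(d) epsX] x = -N diag(d) (1 + epsY y_s)
##   v = d * (1 + epsX x + epsY y_s)
## Likelihood: protein log-ratios ~ N(logE, sd_p), metabolite log-ratios
## ~ N(x, sd_m), fluxes ~ N(v, sd_f * |v*|); entries clipped at +/-b enter
## as censored terms P(Y > b) / P(Y < -b). Gradients through the
## steady-state solve use the adjoint system t(A) lambda = dL/dx, giving
##   dL/depsX = outer(h, x),  dL/depsY = outer(h, y),
##   dL/dlogE = protein-term + v * (gv - t(N) lambda),
## with h = d * (gv - t(N) lambda) and gv = dL/dv.

#' Prior specification for the elasticity model
#'
#' Elasticities exist only for structurally allowed reaction-metabolite
#' pairs (the stoichiometry, plus an optional regulatory allow-list);
#' substrate elasticities get a Normal(+0.5, sd) prior, product
#' elasticities Normal(-0.5, sd). Latent log enzyme levels are
#' Normal(0, logESd). Observation noise sds get half-Normal(sdScale)
#' hyperpriors unless pinned via \code{fixedSds}.
#'
#' @param elasticitySd prior sd of free elasticities (default 1).
#' @param substrateMean,productMean prior means by stoichiometric role.
#' @param logESd prior sd of latent log enzyme levels (default 1).
#' @param sdScale scale of the half-Normal hyperprior on the three
#'   observation sds (default 0.5).
#' @param fixedSds optional named numeric c(protein=, metabolite=, flux=)
#'   pinning the observation sds instead of learning them.
#' @param allowList optional data.frame(reaction_id, metabolite_id) of
#'   additional (regulatory) elasticity entries to free up.
#' @return list of hyperparameters for \code{\link{buildBmcaModel}}.
#' @export
priorSpec <- function(elasticitySd = 1, substrateMean = 0.5,
                      productMean = -0.5, logESd = 1, sdScale = 0.5,
                      fixedSds = NULL, allowList = NULL) {
    if (!is.null(fixedSds))
        stopifnot(all(c("protein", "metabolite", "flux") %in%
                      names(fixedSds)), all(fixedSds > 0))
    list(elasticitySd = elasticitySd, substrateMean = substrateMean,
         productMean = productMean, logESd = logESd, sdScale = sdScale,
         fixedSds = fixedSds, allowList = allowList)
}

## per-strain sufficient statistics of one observation block
.aggregateBlock <- function(se, strainsIds, rows, bound, scale = NULL) {
    val <- SummarizedExperiment::assay(se, "value")[rows, , drop = FALSE]
    clp <- SummarizedExperiment::assay(se, "clipped")[rows, , drop = FALSE]
    strain <- as.character(SummarizedExperiment::colData(se)$strain)
    S <- length(strainsIds); F <- length(rows)
    zero <- matrix(0, S, F, dimnames = list(strainsIds, rows))
    n <- zero; sm <- zero; cU <- zero; cL <- zero
    ss <- stats::setNames(numeric(S), strainsIds)
    if (!is.null(scale)) val <- val / scale      # standardized fluxes
    for (k in seq_len(ncol(val))) {
        s <- strain[k]
        obs <- !is.na(val[, k])
        isC <- obs & clp[, k]
        unc <- obs & !clp[, k]
        n[s, unc] <- n[s, unc] + 1
        sm[s, unc] <- sm[s, unc] + val[unc, k]
        ss[s] <- ss[s] + sum(val[unc, k]^2)
        if (any(isC) && !is.na(bound)) {
            up <- isC & val[, k] > 0
            lo <- isC & val[, k] < 0
            cU[s, up] <- cU[s, up] + 1
            cL[s, lo] <- cL[s, lo] + 1
        }
    }
    list(n = n, sum = sm, ss = ss, cU = cU, cL = cL, Ntot = sum(n))
}

#' Build the Bayesian inference problem
#'
#' Compiles the reduced model, reference state, priors and observations
#' into the internal structure \code{\link{fitVariational}} optimizes:
#' free-elasticity indexing from the stoichiometric sign structure,
#' per-strain sufficient statistics of unclipped observations, censoring
#' counts for clipped ones, and known external log-deviations per strain.
#'
#' @param model reduced \linkS4class{MetabolicModel} with full-row-rank N.
#' @param ref \linkS4class{ReferenceState}.
#' @param data \linkS4class{OmicsDataset}, or NULL for the no-data limit
#'   (posterior = prior).
#' @param prior a \code{\link{priorSpec}} list.
#' @param yLog optional strains x external metabolites matrix of known
#'   log(y/y*); defaults to 0 (all strains in reference media).
#' @param strainsIds strain ordering; defaults to order of appearance.
#' @return A \linkS4class{BmcaProblem}.
#' @export
buildBmcaModel <- function(model, ref, data, prior = priorSpec(),
                           yLog = NULL, strainsIds = NULL) {
    rid <- reactionIds(model); im <- internalMetabolites(model)
    ex <- externalMetabolites(model)
    N <- stoichiometricMatrix(model)
    Sfull <- stoichiometricMatrix(model, internal = FALSE)
    if (is.null(strainsIds))
        strainsIds <- if (is.null(data)) "strain1" else unique(strains(data))
    nS <- length(strainsIds)

    freeIdx <- function(cols) {
        St <- t(Sfull[cols, rid, drop = FALSE])   # reactions x cols
        idx <- which(St != 0, arr.ind = TRUE)
        mean <- ifelse(St[idx] < 0, prior$substrateMean, prior$productMean)
        list(idx = idx, mean = mean)
    }
    fx <- freeIdx(im); fy <- freeIdx(ex)
    if (!is.null(prior$allowList)) {
        addIdx <- cbind(match(prior$allowList$reaction_id, rid),
                        match(prior$allowList$metabolite_id, im))
        if (any(is.na(addIdx)))
            stop("allowList references unknown reaction/metabolite")
        keep <- !(paste(addIdx[, 1], addIdx[, 2]) %in%
                  paste(fx$idx[, 1], fx$idx[, 2]))
        fx$idx <- rbind(fx$idx, addIdx[keep, , drop = FALSE])
        fx$mean <- c(fx$mean, rep(0, sum(keep)))
    }
    Kx <- nrow(fx$idx); Ky <- nrow(fy$idx)

    bound <- if (is.null(data)) NA_real_ else data@clipBound
    fluxScale <- pmax(abs(vStar(ref)), 1e-6)
    agg <- if (is.null(data)) NULL else list(
        protein = .aggregateBlock(data@proteins, strainsIds, rid, bound),
        metabolite = .aggregateBlock(data@metabolites, strainsIds, im,
                                     bound),
        flux = .aggregateBlock(data@fluxes, strainsIds, rid, NA_real_,
                               scale = fluxScale))
    if (is.null(yLog))
        yLog <- matrix(0, nS, length(ex),
                       dimnames = list(strainsIds, ex))
    yLog <- yLog[strainsIds, ex, drop = FALSE]

    learnSds <- is.null(prior$fixedSds)
    D <- (Kx + Ky) + nS * length(rid) + if (learnSds) 3L else 0L
    stats <- list(N = N, tN = t(N), vstar = vStar(ref),
                  fxIdx = fx$idx, fxMean = fx$mean,
                  fyIdx = fy$idx, fyMean = fy$mean,
                  Kx = Kx, Ky = Ky, nS = nS, nR = length(rid),
                  nM = length(im), agg = agg, bound = bound,
                  fluxScale = fluxScale, learnSds = learnSds,
                  fixedSds = prior$fixedSds, D = D,
                  idxEps = seq_len(Kx + Ky),
                  idxLogE = (Kx + Ky) + seq_len(nS * length(rid)),
                  idxZeta = if (learnSds) D - 2:0 else integer(0))
    new("BmcaProblem", model = model, ref = ref, prior = prior,
        strains = strainsIds, yLog = yLog, stats = stats)
}

## log joint density and its gradient at unconstrained parameters theta
.logpGrad <- function(theta, problem) {
    st <- problem@stats; pr <- problem@prior
    Kx <- st$Kx; Ky <- st$Ky; nS <- st$nS; nR <- st$nR; nM <- st$nM
    epsFree <- theta[st$idxEps]
    logE <- matrix(theta[st$idxLogE], nS, nR)
    sds <- if (st$learnSds) exp(theta[st$idxZeta])
           else unname(st$fixedSds[c("protein", "metabolite", "flux")])
    EX <- matrix(0, nR, nM); EX[st$fxIdx] <- epsFree[seq_len(Kx)]
    EY <- matrix(0, nR, nrow(problem@yLog) * 0 + ncol(problem@yLog))
    if (Ky) EY[st$fyIdx] <- epsFree[Kx + seq_len(Ky)]

    grad <- numeric(length(theta))
    lp <- 0

    ## priors
    em <- c(st$fxMean, st$fyMean)
    lp <- lp - sum((epsFree - em)^2) / (2 * pr$elasticitySd^2)
    grad[st$idxEps] <- -(epsFree - em) / pr$elasticitySd^2
    lp <- lp - sum(logE^2) / (2 * pr$logESd^2)
    grad[st$idxLogE] <- -as.vector(logE) / pr$logESd^2
    if (st$learnSds) {
        zeta <- theta[st$idxZeta]
        lp <- lp - sum((sds / pr$sdScale)^2) / 2 + sum(zeta)
        grad[st$idxZeta] <- -(sds / pr$sdScale)^2 + 1
    }
    if (is.null(st$agg)) return(list(lp = lp, grad = grad))

    sdP <- sds[1]; sdM <- sds[2]; sdF <- sds[3]
    agg <- st$agg
    gZeta <- c(0, 0, 0)
    gEX <- matrix(0, nR, nM)
    gEY <- matrix(0, nR, ncol(EY))
    gLogE <- matrix(0, nS, nR)
    N <- st$N; tN <- st$tN; vstar <- st$vstar

    ## censored-likelihood helper: counts at +/- bound with mean mu, sd s
    censor <- function(mu, cU, cL, s, b) {
        out <- list(lp = 0, gmu = numeric(length(mu)), gz = 0)
        iU <- which(cU > 0); iL <- which(cL > 0)
        if (length(iU)) {
            t1 <- (mu[iU] - b) / s
            lphi <- stats::dnorm(t1, log = TRUE)
            lPhi <- stats::pnorm(t1, log.p = TRUE)
            r <- exp(lphi - lPhi)
            out$lp <- out$lp + sum(cU[iU] * lPhi)
            out$gmu[iU] <- out$gmu[iU] + cU[iU] * r / s
            out$gz <- out$gz - sum(cU[iU] * r * t1)
        }
        if (length(iL)) {
            t2 <- (-b - mu[iL]) / s
            lphi <- stats::dnorm(t2, log = TRUE)
            lPhi <- stats::pnorm(t2, log.p = TRUE)
            r <- exp(lphi - lPhi)
            out$lp <- out$lp + sum(cL[iL] * lPhi)
            out$gmu[iL] <- out$gmu[iL] - cL[iL] * r / s
            out$gz <- out$gz - sum(cL[iL] * r * t2)
        }
        out
    }

    for (s in seq_len(nS)) {
        e <- exp(logE[s, ])
        d <- vstar * e
        ys <- problem@yLog[s, ]
        w <- 1 + if (ncol(EY)) drop(EY %*% ys) else 0
        Nd <- N * rep(d, each = nM)
        A <- Nd %*% EX
        b <- -drop(Nd %*% w)
        x <- tryCatch(solve(A, b), error = function(e)
            drop(pracma::pinv(A) %*% b))
        g <- w + drop(EX %*% x)
        v <- d * g

        ## direct likelihood gradients wrt mu's
        gv <- numeric(nR); gx <- numeric(nM)

        ## protein: mu = logE[s,]
        aP <- agg$protein
        muP <- logE[s, ]
        ssr <- aP$ss[s] - 2 * sum(muP * aP$sum[s, ]) + sum(aP$n[s, ] * muP^2)
        lp <- lp - sum(aP$n[s, ]) * log(sdP) - ssr / (2 * sdP^2)
        gMuP <- (aP$sum[s, ] - aP$n[s, ] * muP) / sdP^2
        gZeta[1] <- gZeta[1] - sum(aP$n[s, ]) + ssr / sdP^2
        if (!is.na(st$bound)) {
            cn <- censor(muP, aP$cU[s, ], aP$cL[s, ], sdP, st$bound)
            lp <- lp + cn$lp; gMuP <- gMuP + cn$gmu
            gZeta[1] <- gZeta[1] + cn$gz
        }

        ## metabolite: mu = x
        aM <- agg$metabolite
        ssr <- aM$ss[s] - 2 * sum(x * aM$sum[s, ]) + sum(aM$n[s, ] * x^2)
        lp <- lp - sum(aM$n[s, ]) * log(sdM) - ssr / (2 * sdM^2)
        gx <- gx + (aM$sum[s, ] - aM$n[s, ] * x) / sdM^2
        gZeta[2] <- gZeta[2] - sum(aM$n[s, ]) + ssr / sdM^2
        if (!is.na(st$bound)) {
            cn <- censor(x, aM$cU[s, ], aM$cL[s, ], sdM, st$bound)
            lp <- lp + cn$lp; gx <- gx + cn$gmu
            gZeta[2] <- gZeta[2] + cn$gz
        }

        ## flux (standardized by |v*|): mu = v / fluxScale
        aF <- agg$flux
        muF <- v / st$fluxScale
        ssr <- aF$ss[s] - 2 * sum(muF * aF$sum[s, ]) + sum(aF$n[s, ] * muF^2)
        lp <- lp - sum(aF$n[s, ]) * log(sdF) - ssr / (2 * sdF^2)
        gv <- gv + (aF$sum[s, ] - aF$n[s, ] * muF) / sdF^2 / st$fluxScale
        gZeta[3] <- gZeta[3] - sum(aF$n[s, ]) + ssr / sdF^2

        ## adjoint through the steady-state solve
        gxTot <- gx + drop(crossprod(EX, d * gv))
        lambda <- tryCatch(solve(t(A), gxTot), error = function(e)
            drop(pracma::pinv(t(A)) %*% gxTot))
        tNl <- drop(tN %*% lambda)
        h <- d * (gv - tNl)
        gEX <- gEX + outer(h, x)
        if (ncol(EY)) gEY <- gEY + outer(h, ys)
        gLogE[s, ] <- gMuP + v * (gv - tNl)
    }

    grad[st$idxEps[seq_len(Kx)]] <- grad[st$idxEps[seq_len(Kx)]] +
        gEX[st$fxIdx]
    if (Ky) grad[st$idxEps[Kx + seq_len(Ky)]] <-
        grad[st$idxEps[Kx + seq_len(Ky)]] + gEY[st$fyIdx]
    grad[st$idxLogE] <- grad[st$idxLogE] + as.vector(gLogE)
    if (st$learnSds) grad[st$idxZeta] <- grad[st$idxZeta] + gZeta
    list(lp = lp, grad = grad)
}
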