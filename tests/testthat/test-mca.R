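## brute-force HPD oracle: scan every contiguous window of k sorted values
bruteHPD <- function(x, level) {
    s <- sort(x)
    n <- length(s)
    k <- ceiling(level * n)
    if (k >= n) return(c(s[1], s[n]))
    best <- c(Inf, NA, NA)
    for (i in 1:(n - k + 1)) {
        w <- s[i + k - 1] - s[i]
        if (w < best[1]) best <- c(w, s[i], s[i + k - 1])
    }
    c(best[2], best[3])
}

## point-mass posterior around given elasticities
pointMassPosterior <- function(truth, draws = 120L) {
    nR <- nrow(truth@eps@epsX); nM <- ncol(truth@eps@epsX)
    nY <- ncol(truth@eps@epsY)
    epsX <- array(rep(truth@eps@epsX, each = draws), c(draws, nR, nM),
                  dimnames = c(list(NULL), dimnames(truth@eps@epsX)))
    epsY <- array(rep(truth@eps@epsY, each = draws), c(draws, nR, nY),
                  dimnames = c(list(NULL), dimnames(truth@eps@epsY)))
    new("PosteriorSamples", draws = draws, epsX = epsX, epsY = epsY,
        logE = array(0, c(draws, 1L, nR)),
        sdDraws = matrix(0.1, draws, 3), elboTrace = 0, seed = 1L,
        converged = TRUE, varParams = list())
}

test_that("narrowest-window HPD matches brute-force enumeration", {
    ## uniform integer ladder: many ties in width; both must agree on width
    x <- 1:100
    got <- hpdInterval(x, 0.95)
    ref <- bruteHPD(x, 0.95)
    expect_equal(got[2] - got[1], ref[2] - ref[1])
    expect_equal(got[2] - got[1], 94)
    for (seed in 1:5) {
        set.seed(seed)
        y <- rgamma(400, shape = 2)          # skewed: HPD != central
        expect_equal(hpdInterval(y, 0.9), bruteHPD(y, 0.9))
        expect_equal(hpdInterval(y, 0.5), bruteHPD(y, 0.5))
    }
    ## degenerate: all samples equal
    expect_equal(hpdInterval(rep(3.3, 200), 0.95), c(3.3, 3.3))
    expect_error(hpdInterval(1:50, 0.95), "100 samples")
    expect_error(hpdInterval(1:200, 1.2), "level")
})

test_that("HPD on standard normal draws brackets the analytic interval", {
    set.seed(7)
    z <- rnorm(10000)
    h <- hpdInterval(z, 0.95)
    expect_lt(abs(h[1] + 1.96), 0.1)
    expect_lt(abs(h[2] - 1.96), 0.1)
    expect_true(h[1] < 0 && h[2] > 0)
})

test_that("a point-mass posterior reproduces the analytic FCC row", {
    truth <- twoStepTruth()
    post <- pointMassPosterior(truth)
    fcc <- fccPosterior(post, truth@model, truth@ref)
    expect_true(all(fcc@validMask))
    expect_equal(unname(fcc@samples[1, ]), c(1 / 3, 2 / 3),
                 tolerance = 1e-10)
    expect_true(all(abs(rowSums(fcc@samples) - 1) < 1e-6))
})

test_that("FCC draws follow the closed form under elasticity uncertainty", {
    ## posterior over eps2 only: C1 = eps2 / (eps2 - eps1) with eps1 = -1
    truth <- twoStepTruth()
    post <- pointMassPosterior(truth, draws = 150L)
    set.seed(3)
    e2 <- runif(150, 0.3, 1.2)
    post@epsX[, "r2", "M_x"] <- e2
    fcc <- fccPosterior(post, truth@model, truth@ref)
    expect_equal(fcc@samples[, "r1"], e2 / (e2 + 1), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(rowSums(fcc@samples), rep(1, 150), tolerance = 1e-10,
                 ignore_attr = TRUE)
})

test_that("target calls obey significance, direction and ranking rules", {
    truth <- twoStepTruth()
    post <- pointMassPosterior(truth, draws = 1000L)
    set.seed(4)
    ## overwrite the target-row FCC samples directly
    fcc <- fccPosterior(post, truth@model, truth@ref)
    fcc@samples[, "r1"] <- rnorm(1000, 0.5, 0.05)
    tg <- as.data.frame(callTargets(fcc, truth@model))
    r1 <- tg[tg$reaction_id == "r1", ]
    expect_true(r1$significant)
    expect_identical(r1$direction, "overexpress")
    fcc@samples[, "r1"] <- rnorm(1000, 0, 1)
    tg2 <- as.data.frame(callTargets(fcc, truth@model))
    expect_false(tg2$significant[tg2$reaction_id == "r1"])
    expect_identical(tg2$direction[tg2$reaction_id == "r1"], "none")
    ## the target reaction itself is never called
    expect_false("r2" %in% tg$reaction_id)
})

test_that("raising the HPD level never adds significant calls", {
    truth <- makeToyNetwork("branched_3hp", seed = 2)
    post <- pointMassPosterior(truth, draws = 400L)
    set.seed(8)
    jit <- array(rnorm(length(post@epsX), 0, 0.08), dim(post@epsX))
    zeroMask <- array(rep(c(post@epsX[1, , ] == 0), each = dim(jit)[1]),
                      dim(jit))
    jit[zeroMask] <- 0
    post@epsX <- post@epsX + jit
    fcc <- fccPosterior(post, truth@model, truth@ref)
    nsig <- vapply(c(0.5, 0.8, 0.95, 0.99), function(lv)
        sum(callTargets(fcc, truth@model, level = lv)$significant), 0L)
    expect_true(all(diff(nsig) <= 0))
})

test_that("called interventions raise the simulated target flux", {
    ## ground-truth FCCs as a point-mass posterior: every called direction
    ## must increase 3-HP export when applied in simulation
    truth <- makeToyNetwork("branched_3hp", seed = 1)
    post <- pointMassPosterior(truth, draws = 120L)
    fcc <- fccPosterior(post, truth@model, truth@ref)
    tg <- as.data.frame(callTargets(fcc, truth@model))
    sig <- tg[tg$significant, ]
    expect_identical(sig$direction[sig$reaction_id == "r_ald6"], "delete")
    expect_identical(sig$direction[sig$reaction_id == "r_pyc"],
                     "overexpress")
    v0 <- vStar(truth@ref)[targetReaction(truth@model)]
    improved <- vapply(seq_len(nrow(sig)), function(i) {
        fold <- if (sig$direction[i] == "overexpress") 5 else 0.05
        st <- simulateStrain(truth@model, truth@ref, truth@eps,
                             stats::setNames(fold, sig$reaction_id[i]))
        st@v[targetReaction(truth@model)] > v0
    }, NA)
    expect_gte(mean(improved), 0.9)
})

test_that("calls are invariant to reaction ordering of the samples", {
    truth <- makeToyNetwork("branched_3hp", seed = 1)
    post <- pointMassPosterior(truth, draws = 150L)
    fcc <- fccPosterior(post, truth@model, truth@ref)
    perm <- sample(ncol(fcc@samples))
    fccP <- fcc
    fccP@samples <- fcc@samples[, perm]
    a <- as.data.frame(callTargets(fcc, truth@model))
    b <- as.data.frame(callTargets(fccP, truth@model))
    b <- b[match(a$reaction_id, b$reaction_id), ]
    rownames(b) <- NULL
    expect_equal(a, b)
})
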