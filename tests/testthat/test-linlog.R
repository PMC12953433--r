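twoStep <- twoStepTruth()

test_that("lin-log rates reproduce the reference state and scale in e", {
    m <- twoStep@model; ref <- twoStep@ref; eps <- twoStep@eps
    v0 <- linlogRates(ref, eps, PerturbationState(m), numeric(1))
    expect_identical(unname(v0), unname(vStar(ref)))
    vHalf <- linlogRates(ref, eps,
                         PerturbationState(m, eRel = c(r1 = 0.5, r2 = 0.5)),
                         numeric(1))
    expect_identical(unname(vHalf), unname(0.5 * vStar(ref)))
})

test_that("scalar lin-log formula evaluates exactly as written", {
    ## v2 = v* e (1 + eps log 2) with v* = 2, e = 3, eps = 0.5
    m <- twoStep@model
    ref <- ReferenceState(m, c(r1 = 2, r2 = 2))
    v <- linlogRates(ref, twoStep@eps,
                     PerturbationState(m, eRel = c(r2 = 3)), log(2))
    expect_equal(unname(v["r2"]), 2 * 3 * (1 + 0.5 * log(2)),
                 tolerance = 1e-12)
})

test_that("two-step steady state matches the hand-solved value", {
    m <- twoStep@model; ref <- twoStep@ref; eps <- twoStep@eps
    ## e = (2, 1): 2(1 - z) = 1(1 + 0.5 z)  =>  z = 0.4, v = 1.2
    sol <- solveSteadyState(m, ref, eps,
                            PerturbationState(m, eRel = c(r1 = 2)))
    expect_equal(unname(sol@xLog), 0.4, tolerance = 1e-12)
    expect_equal(unname(sol@v), c(1.2, 1.2), tolerance = 1e-12)
    expect_false(sol@singular)
    ## reference is the exact fixed point
    s0 <- solveSteadyState(m, ref, eps, PerturbationState(m))
    expect_identical(unname(s0@xLog), 0)
    expect_identical(unname(s0@v), unname(vStar(ref)))
})

test_that("steady-state residual vanishes on random instances", {
    for (seed in 0:19) {
        truth <- makeToyNetwork("random", size = 5 + (seed %% 16),
                                seed = seed)
        sol <- simulateStrain(truth@model, truth@ref, truth@eps,
                              c(r_in = 1.5))
        N <- stoichiometricMatrix(truth@model)
        expect_lte(max(abs(N %*% sol@v)), 1e-10)
    }
})

test_that("control coefficients match the textbook two-step closed form", {
    cc <- controlCoefficients(twoStep@model, twoStep@ref, twoStep@eps)
    ## C1 = eps2/(eps2 - eps1), C2 = -eps1/(eps2 - eps1) with (-1, 0.5)
    expect_equal(unname(cc@CJ["r2", ]), c(1 / 3, 2 / 3),
                 tolerance = 1e-12)
    expect_equal(unname(rowSums(cc@CJ)), c(1, 1), tolerance = 1e-12)
    expect_equal(unname(rowSums(cc@CX)), c(0), tolerance = 1e-12)
})

test_that("summation and connectivity theorems hold on random models", {
    for (seed in c(2, 11, 17)) {
        truth <- makeToyNetwork("random", size = 8 + seed, seed = seed)
        cc <- controlCoefficients(truth@model, truth@ref, truth@eps)
        expect_lte(max(abs(rowSums(cc@CJ) - 1)), 1e-8)
        expect_lte(max(abs(cc@CJ %*% truth@eps@epsX)), 1e-8)
        expect_lte(max(abs(rowSums(cc@CX))), 1e-8)
    }
})

test_that("analytic CJ equals the finite-difference Jacobian", {
    truth <- makeToyNetwork("random", size = 10, seed = 4)
    m <- truth@model; ref <- truth@ref; eps <- truth@eps
    cc <- controlCoefficients(m, ref, eps)
    rid <- reactionIds(m)
    h <- 1e-6
    fd <- matrix(0, length(rid), length(rid), dimnames = list(rid, rid))
    for (k in seq_along(rid)) {
        up <- simulateStrain(m, ref, eps,
                             stats::setNames(exp(h), rid[k]))
        dn <- simulateStrain(m, ref, eps,
                             stats::setNames(exp(-h), rid[k]))
        fd[, k] <- (log(up@v) - log(dn@v)) / (2 * h)
    }
    expect_lte(max(abs(fd - cc@CJ)) / max(abs(fd)), 1e-5)
})

test_that("simulateStrain honours designs and the knockout floor", {
    m <- twoStep@model; ref <- twoStep@ref; eps <- twoStep@eps
    ## empty design reproduces the reference
    s0 <- simulateStrain(m, ref, eps,
                         stats::setNames(numeric(0), character(0)))
    expect_identical(unname(s0@v), unname(vStar(ref)))
    ## doubling the first enzyme matches the hand solve
    s1 <- simulateStrain(m, ref, eps, c(r1 = 2))
    expect_equal(unname(s1@v), c(1.2, 1.2), tolerance = 1e-12)
    ## knockout of the product-forming reaction reduces product flux
    truth <- makeToyNetwork("branched_3hp", seed = 1)
    ko <- simulateStrain(truth@model, truth@ref, truth@eps,
                         c(r_hpdh = 0))
    expect_lt(ko@v["r_ex3hp"],
              vStar(truth@ref)["r_ex3hp"])
    ## unknown reaction ids are rejected
    expect_error(simulateStrain(m, ref, eps, c(nope = 2)), "unknown")
})

test_that("uniform enzyme scaling leaves xLog fixed and scales flux", {
    ## multiplying every e by c cancels in the steady-state system, so
    ## xLog is unchanged and every flux scales by exactly c (d log J =
    ## d log e under the summation theorem)
    truth <- makeToyNetwork("random", size = 9, seed = 7)
    m <- truth@model; ref <- truth@ref; eps <- truth@eps
    rid <- reactionIds(m)
    design <- stats::setNames(rep(1.7, 3), rid[1:3])
    base <- simulateStrain(m, ref, eps, design)
    all2 <- stats::setNames(rep(2, length(rid)), rid)
    all2[rid[1:3]] <- 2 * 1.7
    scaled <- simulateStrain(m, ref, eps, all2)
    expect_equal(scaled@xLog, base@xLog, tolerance = 1e-9)
    expect_equal(scaled@v, 2 * base@v, tolerance = 1e-9)
})

test_that("singular systems error in strict mode and flag in fallback", {
    m <- twoStep@model; ref <- twoStep@ref
    epsSing <- ElasticityMatrices(
        matrix(0, 2, 1, dimnames = dimnames(twoStep@eps@epsX)),
        twoStep@eps@epsY)
    pert <- PerturbationState(m, eRel = c(r1 = 2))
    expect_error(solveSteadyState(m, ref, epsSing, pert), "singular")
    sol <- solveSteadyState(m, ref, epsSing, pert, pseudoinverse = TRUE)
    expect_true(sol@singular)
})
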