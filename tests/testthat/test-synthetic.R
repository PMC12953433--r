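test_that("the two-step preset carries the textbook closed-form FCCs", {
    truth <- makeToyNetwork("two_step", seed = 1)
    expect_equal(unname(truth@fcc@CJ["r2", ]), c(1 / 3, 2 / 3),
                 tolerance = 1e-12)
})

test_that("the branched preset is consistent and has the expected signs", {
    truth <- makeToyNetwork("branched_3hp", seed = 1)
    m <- truth@model
    N <- stoichiometricMatrix(m)
    expect_lte(max(abs(N %*% vStar(truth@ref))), 1e-9)
    expect_true(all(abs(vStar(truth@ref)) > 0))
    expect_identical(targetReaction(m), "r_ex3hp")
    expect_identical(length(truth@designs), 17L)
    ## control-theorem invariants of the stored truth
    expect_lte(max(abs(rowSums(truth@fcc@CJ) - 1)), 1e-8)
    expect_lte(max(abs(truth@fcc@CJ %*% truth@eps@epsX)), 1e-8)
    ## competing drain is a deletion target, the carboxylase a dosage
    ## target, as in the pathway's engineering logic
    row <- truth@fcc@CJ["r_ex3hp", ]
    expect_lt(row[["r_ald6"]], 0)
    expect_gt(row[["r_pyc"]], 0)
    ## elasticities are sign-consistent with the stoichiometry
    Ssub <- t(stoichiometricMatrix(m)[, , drop = FALSE])
    expect_true(all(truth@eps@epsX[Ssub < 0] > 0))
    expect_true(all(truth@eps@epsX[Ssub > 0] < 0))
})

test_that("generation is deterministic in the seed", {
    a <- makeToyNetwork("branched_3hp", seed = 9)
    b <- makeToyNetwork("branched_3hp", seed = 9)
    expect_identical(a@eps@epsX, b@eps@epsX)
    expect_identical(a@fcc@CJ, b@fcc@CJ)
    s1 <- simulateDataset(a, NoiseSpec(seed = 13))
    s2 <- simulateDataset(a, NoiseSpec(seed = 13))
    expect_identical(omicsAssay(s1$data, "proteins"),
                     omicsAssay(s2$data, "proteins"))
    expect_identical(s1$series, s2$series)
    ## generation does not disturb the caller's RNG stream
    set.seed(1); before <- rnorm(1)
    set.seed(1); invisible(makeToyNetwork("branched_3hp", seed = 2))
    expect_identical(rnorm(1), before)
})

test_that("zero noise reproduces the ground-truth log-ratios exactly", {
    truth <- makeToyNetwork("branched_3hp", seed = 1)
    ns <- NoiseSpec(sdProtein = 0, sdMetabolite = 0, sdFlux = 0,
                    obsFractionProtein = 1, obsFractionMetabolite = 1,
                    replicates = 1, clipBound = 100, seed = 1)
    sim <- simulateDataset(truth, ns)
    p <- omicsAssay(sim$data, "proteins")
    hasProt <- vapply(truth@model@proteins, length, 1L) > 0
    for (s in names(truth@designs)) {
        col <- paste0(s, "_rep1")
        expect_equal(p[hasProt, col], sim$eLog[hasProt, s],
                     tolerance = 1e-12, ignore_attr = TRUE)
    }
    f <- omicsAssay(sim$data, "fluxes")
    expect_equal(f[, "S01_ref_rep1"], sim$v[, "S01_ref"],
                 tolerance = 1e-12)
})

test_that("a tight clip bound marks strong-knockout observations", {
    truth <- makeToyNetwork("branched_3hp", seed = 1)
    sim <- simulateDataset(truth, NoiseSpec(clipBound = 0.5, seed = 2))
    cl <- omicsAssay(sim$data, "proteins", "clipped")
    ## the wild-type strain lacks the pathway: log(0.05) is far below -0.5
    wt <- grepl("^S02_wt", colnames(cl))
    expect_true(any(cl["r_pand", wt], na.rm = TRUE) ||
                any(cl["r_bapat", wt], na.rm = TRUE) ||
                any(cl["r_hpdh", wt], na.rm = TRUE))
    expect_equal(sim$data@clipBound, 0.5)
    vals <- omicsAssay(sim$data, "proteins")
    expect_lte(max(abs(vals), na.rm = TRUE), 0.5)
})

test_that("the panel mirrors the 17-strain triplicate design", {
    truth <- makeToyNetwork("branched_3hp", seed = 1)
    sim <- simulateDataset(truth, NoiseSpec(seed = 1))
    expect_identical(ncol(omicsAssay(sim$data, "proteins")), 51L)
    expect_identical(length(unique(strains(sim$data))), 17L)
    ## per-strain series sampled at days 3/5/7
    one <- sim$series[sim$series$strain == "S04_pyc5" &
                      sim$series$analyte == "biomass" &
                      sim$series$replicate == 1, ]
    expect_identical(one$time_h, c(72, 120, 168))
})

test_that("random toys satisfy their own reference steady state", {
    for (seed in c(0, 3, 12)) {
        truth <- makeToyNetwork("random", size = 5 + seed, seed = seed)
        expect_lte(max(abs(stoichiometricMatrix(truth@model) %*%
                           vStar(truth@ref))), 1e-9)
        expect_true(all(vStar(truth@ref) > 0))
    }
})
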