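test_that("JSON toy chain loads with the expected structure", {
    m <- loadModel(extdataPath("toy_chain.json"))
    expect_s4_class(m, "MetabolicModel")
    expect_length(internalMetabolites(m), 2L)
    expect_identical(dim(stoichiometricMatrix(m)), c(2L, 3L))
    expect_identical(targetReaction(m), "r_Bexport")
    expect_setequal(exchangeReactions(m), c("r_Auptake", "r_Bexport"))
    ## deterministic lexicographic ordering
    expect_false(is.unsorted(reactionIds(m)))
    expect_false(is.unsorted(metaboliteIds(m)))
})

test_that("undeclared metabolites and missing targets are rejected", {
    bad <- tempfile(fileext = ".json")
    writeLines('{
      "metabolites": [{"id": "A", "compartment": "c"}],
      "external": [],
      "reactions": [{"id": "r1", "stoichiometry": {"A": -1, "GHOST": 1}}],
      "target_reaction": "r1"
    }', bad)
    expect_error(loadModel(bad), "undeclared")
    noTarget <- tempfile(fileext = ".json")
    writeLines('{
      "metabolites": [{"id": "A", "compartment": "c"},
                      {"id": "B_ext", "compartment": "e"}],
      "external": ["B_ext"],
      "reactions": [{"id": "r1", "stoichiometry": {"A": -1, "B_ext": 1}},
                    {"id": "r0", "stoichiometry": {"A": 1}}]
    }', noTarget)
    expect_error(loadModel(noTarget), "target")
})

test_that("SBML and JSON dialects yield identical models", {
    a <- loadModel(extdataPath("toy_chain.json"))
    b <- loadModel(extdataPath("toy_chain.xml"), target = "r_Bexport")
    expect_identical(stoichiometricMatrix(a, internal = FALSE),
                     stoichiometricMatrix(b, internal = FALSE))
    expect_identical(a@metabolites, b@metabolites)
    expect_identical(a@reactions, b@reactions)
    expect_identical(a@proteins, b@proteins)   # incl. AND/OR structure
})

test_that("serialization round-trips reproduce N bit-identically", {
    truth <- makeToyNetwork("branched_3hp", seed = 3)
    for (writer in list(writeModelJSON, writeModelSBML)) {
        f <- tempfile()
        writer(truth@model, f)
        m2 <- loadModel(f,
                        dialect = if (identical(writer, writeModelSBML))
                            "sbml" else "json",
                        target = targetReaction(truth@model))
        expect_identical(stoichiometricMatrix(m2),
                         stoichiometricMatrix(truth@model))
        expect_identical(m2@proteins, truth@model@proteins)
    }
})

test_that("reduceModel removes zero-flux reactions and orphans", {
    ## chain plus a dead branch B -> C -> C_ext carrying zero flux
    mets <- data.frame(
        id = c("A", "A_ext", "B", "B_ext", "C", "C_ext"),
        name = c("A", "Ae", "B", "Be", "C", "Ce"),
        compartment = c("c", "e", "c", "e", "c", "e"),
        role = c("internal", "external", "internal", "external",
                 "internal", "external"), stringsAsFactors = FALSE)
    rxns <- data.frame(id = c("r1", "r2", "r3", "r4", "r5"),
                       reversible = FALSE,
                       is_exchange = c(TRUE, FALSE, TRUE, FALSE, TRUE),
                       stringsAsFactors = FALSE)
    S <- matrix(0, 6, 5, dimnames = list(mets$id, rxns$id))
    S["A_ext", "r1"] <- -1; S["A", "r1"] <- 1
    S["A", "r2"] <- -1; S["B", "r2"] <- 1
    S["B", "r3"] <- -1; S["B_ext", "r3"] <- 1
    S["B", "r4"] <- -1; S["C", "r4"] <- 1
    S["C", "r5"] <- -1; S["C_ext", "r5"] <- 1
    m <- MetabolicModel(mets, rxns, S,
                        stats::setNames(rep(list(list()), 5), rxns$id),
                        "r3")
    v <- c(r1 = 1, r2 = 1, r3 = 1, r4 = 0, r5 = 0)
    red <- reduceModel(m, v, zeroTol = 1e-9)
    expect_setequal(reactionIds(red), c("r1", "r2", "r3"))
    expect_false("C" %in% metaboliteIds(red))      # orphaned branch dropped
    expect_false("C_ext" %in% metaboliteIds(red))
    ## all fluxes nonzero -> identity
    expect_identical(reduceModel(m, c(r1 = 1, r2 = 1, r3 = 1, r4 = 0.5,
                                      r5 = 0.5)), m)
    ## idempotence on the survivors
    red2 <- reduceModel(red, v[reactionIds(red)])
    expect_identical(red2, red)
    ## zero target flux errors
    expect_error(reduceModel(m, c(r1 = 1, r2 = 1, r3 = 0, r4 = 1,
                                  r5 = 1)), "target")
    ## steady state still holds on survivors
    expect_lte(max(abs(stoichiometricMatrix(red) %*%
                       v[reactionIds(red)])), 1e-9)
})

test_that("conserved moieties are removed and reconstructable", {
    m <- moietyModel()
    N0 <- stoichiometricMatrix(m)
    rank0 <- qr(N0)$rank
    res <- removeConservedMoieties(m)
    N1 <- stoichiometricMatrix(res$model)
    expect_identical(nrow(N1), rank0)        # one dependent row dropped
    expect_identical(qr(N1)$rank, nrow(N1))  # full row rank now
    ## link matrix reconstructs every original internal row
    expect_equal(res$link %*% N1, N0, tolerance = 1e-12,
                 ignore_attr = TRUE)
    ## already full rank -> identity link, model unchanged
    ch <- chainModel()
    res2 <- removeConservedMoieties(ch)
    expect_identical(res2$model, ch)
    expect_equal(unname(res2$link),
                 diag(length(internalMetabolites(ch))))
    ## zero internal matrix errors
    zm <- ch
    expect_error(removeConservedMoieties(
        MetabolicModel(ch@metabolites[ch@metabolites$role == "external", ],
                       ch@reactions[1, ],
                       matrix(c(-1, 1), 2, 1,
                              dimnames = list(c("A_ext", "B_ext"), "r1")),
                       list(r1 = list()), "r1")))
})

test_that("reference state construction enforces the steady state", {
    m <- chainModel()
    expect_error(ReferenceState(m, c(r1 = 1, r2 = 2, r3 = 1)),
                 "steady state")
    ref <- ReferenceState(m, c(r1 = 1.5, r2 = 1.5, r3 = 1.5))
    expect_identical(unname(eStar(ref)), rep(1, 3))
    expect_true(all(xStar(ref) > 0))
})
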