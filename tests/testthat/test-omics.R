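mkDataset <- function() {
    m <- chainModel()
    p <- matrix(c(3.7, -0.5, NA, 0.2, -2.6, 1.1), 3, 2,
                dimnames = list(reactionIds(m), c("s1", "s2")))
    x <- matrix(c(0.5, -1.2, 2.4, NA), 2, 2,
                dimnames = list(internalMetabolites(m), c("s1", "s2")))
    f <- matrix(1.5, 3, 2,
                dimnames = list(reactionIds(m), c("s1", "s2")))
    list(model = m, data = OmicsDataset(m, p, x, f, c("st1", "st2")))
}

test_that("clipping truncates extremes, flags them and keeps originals", {
    d <- mkDataset()$data
    cl <- clipObservations(d, bound = 2)
    pv <- omicsAssay(cl, "proteins", "value")
    pc <- omicsAssay(cl, "proteins", "clipped")
    expect_equal(pv["r1", "s1"], 2)              # 3.7 -> +2
    expect_true(pc["r1", "s1"])
    expect_equal(pv["r2", "s1"], -0.5)           # within bound untouched
    expect_false(pc["r2", "s1"])
    expect_equal(omicsAssay(cl, "proteins", "raw")["r1", "s1"], 3.7)
    ## negative side, metabolites
    expect_equal(omicsAssay(cl, "metabolites", "value")["A", "s2"], 2)
    expect_equal(pv["r2", "s2"], -2)
    ## fluxes are never clipped
    expect_false(any(omicsAssay(cl, "fluxes", "clipped")))
    expect_identical(cl@clipBound, 2)
})

test_that("clipping is idempotent and a loose bound is a no-op", {
    d <- mkDataset()$data
    c1 <- clipObservations(d, 2)
    c2 <- clipObservations(c1, 2)
    expect_identical(omicsAssay(c1, "proteins", "value"),
                     omicsAssay(c2, "proteins", "value"))
    expect_identical(omicsAssay(c1, "proteins", "clipped"),
                     omicsAssay(c2, "proteins", "clipped"))
    wide <- clipObservations(d, 100)
    expect_false(any(omicsAssay(wide, "proteins", "clipped"), na.rm = TRUE))
    expect_identical(omicsAssay(wide, "proteins", "value"),
                     omicsAssay(d, "proteins", "value"))
})

test_that("long-format TSV round-trips the dataset", {
    md <- mkDataset()
    f <- tempfile(fileext = ".tsv")
    writeOmicsTSV(md$data, f)
    back <- readOmicsTSV(f, md$model)
    expect_identical(omicsAssay(back, "proteins"),
                     omicsAssay(md$data, "proteins"))
    expect_identical(omicsAssay(back, "metabolites"),
                     omicsAssay(md$data, "metabolites"))
    expect_identical(strains(back), strains(md$data))
    ## unknown features are rejected
    tab <- utils::read.delim(f)
    tab$feature_id[1] <- "GHOST"
    f2 <- tempfile(fileext = ".tsv")
    utils::write.table(tab, f2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    expect_error(readOmicsTSV(f2, md$model), "not in model")
})
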