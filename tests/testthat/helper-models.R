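## Small networks built in code and reused across test files.

## linear chain A_ext -> A -> B -> B_ext (2 internal metabolites)
chainModel <- function() {
    mets <- data.frame(
        id = c("A", "A_ext", "B", "B_ext"),
        name = c("A", "A medium", "B", "B medium"),
        compartment = c("c", "e", "c", "e"),
        role = c("internal", "external", "internal", "external"),
        stringsAsFactors = FALSE)
    rxns <- data.frame(id = c("r1", "r2", "r3"), reversible = FALSE,
                       is_exchange = c(TRUE, FALSE, TRUE),
                       stringsAsFactors = FALSE)
    S <- matrix(0, 4, 3, dimnames = list(mets$id, rxns$id))
    S["A_ext", "r1"] <- -1; S["A", "r1"] <- 1
    S["A", "r2"] <- -1; S["B", "r2"] <- 1
    S["B", "r3"] <- -1; S["B_ext", "r3"] <- 1
    MetabolicModel(mets, rxns, S,
                   list(r1 = list("p1"), r2 = list("p2"), r3 = list("p3")),
                   "r3")
}

## diamond: A_ext -> A, two parallel A -> B routes, B -> B_ext
diamondModel <- function() {
    mets <- data.frame(
        id = c("A", "A_ext", "B", "B_ext"),
        name = c("A", "A medium", "B", "B medium"),
        compartment = c("c", "e", "c", "e"),
        role = c("internal", "external", "internal", "external"),
        stringsAsFactors = FALSE)
    rxns <- data.frame(id = c("r1", "r2a", "r2b", "r3"),
                       reversible = FALSE,
                       is_exchange = c(TRUE, FALSE, FALSE, TRUE),
                       stringsAsFactors = FALSE)
    S <- matrix(0, 4, 4, dimnames = list(mets$id, rxns$id))
    S["A_ext", "r1"] <- -1; S["A", "r1"] <- 1
    S["A", c("r2a", "r2b")] <- -1; S["B", c("r2a", "r2b")] <- 1
    S["B", "r3"] <- -1; S["B_ext", "r3"] <- 1
    MetabolicModel(mets, rxns, S,
                   stats::setNames(rep(list(list()), 4), rxns$id), "r3")
}

## two-step chain with one internal metabolite and the textbook FCCs
twoStepTruth <- function() makeToyNetwork("two_step", seed = 1)

## closed moiety pair: a loop carrying a conserved cofactor (C + D constant)
moietyModel <- function() {
    mets <- data.frame(
        id = c("A", "A_ext", "B", "B_ext", "C", "D"),
        name = c("A", "A medium", "B", "B medium",
                 "cofactor ox", "cofactor red"),
        compartment = c("c", "e", "c", "e", "c", "c"),
        role = c("internal", "external", "internal", "external",
                 "internal", "internal"),
        stringsAsFactors = FALSE)
    rxns <- data.frame(id = c("r1", "r2", "r3"), reversible = FALSE,
                       is_exchange = c(TRUE, FALSE, TRUE),
                       stringsAsFactors = FALSE)
    S <- matrix(0, 6, 3, dimnames = list(mets$id, rxns$id))
    S["A_ext", "r1"] <- -1; S["A", "r1"] <- 1; S["C", "r1"] <- -1
    S["D", "r1"] <- 1
    S["A", "r2"] <- -1; S["B", "r2"] <- 1; S["D", "r2"] <- -1
    S["C", "r2"] <- 1
    S["B", "r3"] <- -1; S["B_ext", "r3"] <- 1
    MetabolicModel(mets, rxns, S,
                   stats::setNames(rep(list(list()), 3), rxns$id), "r3")
}

extdataPath <- function(f) system.file("extdata", f, package = "BayesMCA")
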