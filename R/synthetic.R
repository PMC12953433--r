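## Synthetic ground-truth networks and multi-omics datasets. The generator
## mirrors the structure of a 17-strain, triplicate, partially observed
## fermentation study of a beta-alanine 3-HP production pathway, with known
## lin-log kinetics so every pipeline stage can be validated.

.withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
    force(expr)
}

## draw sign-consistent elasticities: internal/external substrates get
## U(0.3, 1.2), products U(-1.2, -0.3), zero elsewhere; redraw (bounded
## number of times) if the lin-log system is ill-conditioned
.drawElasticities <- function(model, ref, maxTries = 20L, condMax = 1e6) {
    N <- stoichiometricMatrix(model)
    Sfull <- stoichiometricMatrix(model, internal = FALSE)
    im <- internalMetabolites(model); ex <- externalMetabolites(model)
    rid <- reactionIds(model)
    for (try in seq_len(maxTries)) {
        draw <- function(cols) {
            Ssub <- t(Sfull[cols, rid, drop = FALSE])
            E <- matrix(0, length(rid), length(cols),
                        dimnames = list(rid, cols))
            sub <- Ssub < 0; prd <- Ssub > 0
            E[sub] <- stats::runif(sum(sub), 0.3, 1.2)
            E[prd] <- -stats::runif(sum(prd), 0.3, 1.2)
            E
        }
        ex_ <- draw(im); ey_ <- draw(ex)
        A <- (N * rep(vStar(ref), each = nrow(N))) %*% ex_
        if (is.finite(kappa(A, exact = FALSE)) &&
            kappa(A, exact = FALSE) < condMax)
            return(ElasticityMatrices(ex_, ey_))
    }
    stop("could not draw a well-conditioned elasticity matrix")
}

.branched3hpParts <- function() {
    ## lumped central carbon + beta-alanine pathway: glucose -> pyruvate ->
    ## {pyc -> OAA -> ASP -> BAL -> MSA -> 3-HP export} with an ALD6-like
    ## MSA drain to acetyl-CoA, a TCA-like succinyl-CoA branch (two-subunit
    ## succinyl-CoA ligase), an ethanol drain, and a biomass sink
    internal <- c(G6P = "glucose 6-phosphate", PYR = "pyruvate",
                  OAA = "oxaloacetate", ASP = "aspartate",
                  BAL = "beta-alanine", MSA = "malonic semialdehyde",
                  HP3 = "3-hydroxypropionate", ACCOA = "acetyl-CoA",
                  AKG = "alpha-ketoglutarate", SCOA = "succinyl-CoA",
                  SUC = "succinate", ETOH = "ethanol")
    external <- c(GLC_e = "glucose (medium)", HP3_e = "3-HP (medium)",
                  ETOH_e = "ethanol (medium)", CO2_e = "CO2",
                  BIOM_e = "biomass sink")
    mets <- data.frame(
        id = c(names(internal), names(external)),
        name = c(unname(internal), unname(external)),
        compartment = c(rep("c", length(internal)),
                        rep("e", length(external))),
        role = c(rep("internal", length(internal)),
                 rep("external", length(external))),
        stringsAsFactors = FALSE)
    rx <- list(  # id, stoichiometry, v*
        r_glcup  = list(c(GLC_e = -1, G6P = 1),      2.0),
        r_glyc   = list(c(G6P = -1, PYR = 2),        2.0),
        r_pyc    = list(c(PYR = -1, OAA = 1),        0.8),
        r_aat    = list(c(OAA = -1, ASP = 1),        0.6),
        r_pand   = list(c(ASP = -1, BAL = 1),        0.6),
        r_bapat  = list(c(BAL = -1, MSA = 1),        0.6),
        r_hpdh   = list(c(MSA = -1, HP3 = 1),        0.4),
        r_ex3hp  = list(c(HP3 = -1, HP3_e = 1),      0.4),
        r_ald6   = list(c(MSA = -1, ACCOA = 1),      0.2),
        r_pdh    = list(c(PYR = -1, ACCOA = 1),      2.0),
        r_cs     = list(c(ACCOA = -1, OAA = -1, AKG = 1), 0.2),
        r_kgd    = list(c(AKG = -1, SCOA = 1),       0.2),
        r_scl    = list(c(SCOA = -1, SUC = 1),       0.2),
        r_resp   = list(c(SUC = -1, CO2_e = 1),      0.2),
        r_adh    = list(c(PYR = -1, ETOH = 1),       1.2),
        r_exetoh = list(c(ETOH = -1, ETOH_e = 1),    1.2),
        r_growth = list(c(ACCOA = -1, BIOM_e = 1),   2.0))
    rxns <- data.frame(id = names(rx), reversible = FALSE,
                       is_exchange = FALSE, stringsAsFactors = FALSE)
    S <- matrix(0, nrow(mets), length(rx),
                dimnames = list(mets$id, names(rx)))
    for (j in seq_along(rx)) S[names(rx[[j]][[1]]), j] <- rx[[j]][[1]]
    vstar <- vapply(rx, `[[`, 0, 2)
    proteins <- lapply(names(rx), function(r) list(paste0("prot_", r)))
    names(proteins) <- names(rx)
    proteins$r_scl <- list(c("prot_r_sclA", "prot_r_sclB")) # 2-subunit complex
    proteins$r_glcup <- list()                              # transport, no GPR
    list(mets = mets, rxns = rxns, S = S, vstar = vstar,
         proteins = proteins, target = "r_ex3hp")
}

.branched3hpDesigns <- function(knockoutFloor = 0.05) {
    pw <- c("r_pand", "r_bapat", "r_hpdh")
    d <- function(...) {
        v <- c(...)
        if (!length(v)) stats::setNames(numeric(0), character(0)) else v
    }
    list(
        S01_ref         = d(),
        S02_wt          = stats::setNames(rep(knockoutFloor, 3), pw),
        S03_pw2         = stats::setNames(rep(2, 3), pw),
        S04_pyc5        = d(r_pyc = 5),
        S05_pw2_pyc5    = c(stats::setNames(rep(2, 3), pw), r_pyc = 5),
        S06_ald6ko      = d(r_ald6 = knockoutFloor),
        S07_ald6ko_pyc5 = d(r_ald6 = knockoutFloor, r_pyc = 5),
        S08_aat5        = d(r_aat = 5),
        S09_aat5_pyc5   = d(r_aat = 5, r_pyc = 5),
        S10_sclko       = d(r_scl = knockoutFloor),
        S11_adhko       = d(r_adh = knockoutFloor),
        S12_adh5        = d(r_adh = 5),
        S13_glyc2       = d(r_glyc = 2),
        S14_hpdh5       = d(r_hpdh = 5),
        S15_bapat5      = d(r_bapat = 5),
        S16_pand5_pyc5  = d(r_pand = 5, r_pyc = 5),
        S17_csko        = d(r_cs = knockoutFloor))
}

.randomChainParts <- function(size) {
    size <- max(3L, as.integer(size))
    m <- size - 2L                      # internal chain metabolites
    nExtra <- max(0L, size - (m + 2L))  # filled below by random bypasses
    ids <- sprintf("A%02d", seq_len(m))
    mets <- data.frame(id = c(ids, "SRC_e", "SNK_e"),
                       name = c(ids, "source", "sink"),
                       compartment = c(rep("c", m), "e", "e"),
                       role = c(rep("internal", m), "external", "external"),
                       stringsAsFactors = FALSE)
    edges <- list()
    edges[["r_in"]] <- c(SRC_e = -1)
    edges[["r_in"]][ids[1]] <- 1
    for (k in seq_len(m - 1)) {
        nm <- sprintf("r_c%02d", k)
        edges[[nm]] <- stats::setNames(c(-1, 1), ids[c(k, k + 1)])
    }
    edges[["r_out"]] <- stats::setNames(c(-1, 1), c(ids[m], "SNK_e"))
    ## random forward bypasses to reach the requested size
    nBypass <- size - length(edges)
    u <- numeric(0)
    if (nBypass > 0 && m >= 3) {
        for (k in seq_len(nBypass)) {
            ij <- sort(sample.int(m, 2))
            nm <- sprintf("r_b%02d", k)
            edges[[nm]] <- stats::setNames(c(-1, 1), ids[ij])
            u[nm] <- stats::runif(1, 0.2, 0.5)
        }
    }
    ## balance: entry flux 1 + total bypass, chain carries the remainder
    S <- matrix(0, nrow(mets), length(edges),
                dimnames = list(mets$id, names(edges)))
    for (j in seq_along(edges)) S[names(edges[[j]]), j] <- edges[[j]]
    v <- stats::setNames(numeric(length(edges)), names(edges))
    v["r_in"] <- 1 + sum(u)
    v[names(u)] <- u
    inflow <- stats::setNames(numeric(m), ids)
    inflow[ids[1]] <- v["r_in"]
    for (nm in names(u)) {
        st <- edges[[nm]]
        inflow[names(st)[st > 0]] <- inflow[names(st)[st > 0]] + u[nm]
    }
    for (k in seq_len(m)) {
        outExtra <- sum(vapply(names(u), function(nm)
            if (names(edges[[nm]])[edges[[nm]] < 0] == ids[k]) u[nm] else 0,
            0))
        chainOut <- inflow[ids[k]] - outExtra
        nm <- if (k < m) sprintf("r_c%02d", k) else "r_out"
        v[nm] <- chainOut
        if (k < m) inflow[ids[k + 1]] <- inflow[ids[k + 1]] + chainOut
    }
    rxns <- data.frame(id = names(edges), reversible = FALSE,
                       is_exchange = FALSE, stringsAsFactors = FALSE)
    proteins <- lapply(names(edges), function(r) list(paste0("prot_", r)))
    names(proteins) <- names(edges)
    list(mets = mets, rxns = rxns, S = S, vstar = v, proteins = proteins,
         target = "r_out")
}

#' Generate a toy network with known lin-log kinetics
#'
#' Presets: \code{two_step} is the minimal two-reaction chain whose flux
#' control coefficients have the textbook closed form; \code{branched_3hp}
#' is a ~17-reaction lumped central-carbon network with the heterologous
#' beta-alanine route to 3-HP, a competing malonic-semialdehyde drain
#' (ALD6 analog), a TCA-like succinyl-CoA branch and an ethanol drain,
#' together with a 17-strain design panel (pathway dosage, single
#' overexpressions at 5x, single deletions at the knockout floor, and one
#' wild-type strain without the pathway); \code{random} builds a seeded
#' random forward-flow chain with bypasses, used for property testing.
#'
#' True elasticities are drawn sign-consistently from the stoichiometry
#' (substrates U(0.3, 1.2), products U(-1.2, -0.3)) and redrawn if the
#' lin-log system is ill-conditioned; analytic control coefficients of the
#' truth are stored.
#'
#' @param preset one of "two_step", "branched_3hp", "random".
#' @param size reaction count for the random preset (5-20 sensible).
#' @param seed integer seed; the full truth is reproducible from it.
#' @return A \linkS4class{SyntheticTruth}.
#' @export
makeToyNetwork <- function(preset = c("branched_3hp", "two_step", "random"),
                           size = 12L, seed = 1L) {
    preset <- match.arg(preset)
    .withSeed(seed, {
        if (preset == "two_step") {
            mets <- data.frame(id = c("M_x", "X_ext", "Y_ext"),
                               name = c("intermediate", "source", "sink"),
                               compartment = c("c", "e", "e"),
                               role = c("internal", "external", "external"),
                               stringsAsFactors = FALSE)
            rxns <- data.frame(id = c("r1", "r2"), reversible = FALSE,
                               is_exchange = FALSE, stringsAsFactors = FALSE)
            S <- matrix(c(1, -1, -1, 0, 0, 1), 3, 2, byrow = TRUE,
                        dimnames = list(mets$id, rxns$id))
            model <- MetabolicModel(mets, rxns, S,
                                    list(r1 = list("prot_r1"),
                                         r2 = list("prot_r2")), "r2")
            ref <- ReferenceState(model, c(r1 = 1, r2 = 1))
            eps <- ElasticityMatrices(
                matrix(c(-1, 0.5), 2, 1,
                       dimnames = list(c("r1", "r2"), "M_x")),
                matrix(0, 2, 2,
                       dimnames = list(c("r1", "r2"),
                                       c("X_ext", "Y_ext"))))
            designs <- list(ref = stats::setNames(numeric(0), character(0)),
                            e1x2 = c(r1 = 2), e2x2 = c(r2 = 2),
                            e1ko = c(r1 = 0.05))
        } else {
            parts <- if (preset == "branched_3hp") .branched3hpParts()
                     else .randomChainParts(size)
            model <- MetabolicModel(parts$mets, parts$rxns, parts$S,
                                    parts$proteins, parts$target)
            ref <- ReferenceState(model, parts$vstar)
            eps <- .drawElasticities(model, ref)
            designs <- if (preset == "branched_3hp") .branched3hpDesigns()
                       else list(ref = stats::setNames(numeric(0),
                                                       character(0)))
        }
        fcc <- controlCoefficients(model, ref, eps)
        new("SyntheticTruth", model = model, ref = ref, eps = eps,
            fcc = fcc, designs = designs, preset = preset,
            seed = as.integer(seed))
    })
}

#' Simulate a multi-strain multi-omics dataset from a known truth
#'
#' For every strain design the lin-log steady state is solved; per
#' replicate, a random subset of reaction-level protein log-ratios and
#' internal-metabolite log-ratios is observed with additive Gaussian noise
#' on the log scale, fluxes are observed with noise scaled by |v*|, and
#' extreme log-ratios are clipped. Extracellular time series (biomass,
#' glucose, 3-HP, ethanol at days 3/5/7) are generated from the
#' exponential-growth closed form so the rate-estimation stage can
#' re-derive the simulating exchange rates exactly at zero noise.
#'
#' Log-ratios are taken relative to \code{referenceStrain}; by default the
#' base pathway strain whose design is the identity, i.e. the model's
#' linearization point.
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param noise a \linkS4class{NoiseSpec}.
#' @param referenceStrain strain id used as the log-ratio reference.
#' @param muRef reference specific growth rate (h^-1); strain growth rates
#'   scale with the simulated biomass-sink flux.
#' @param X0 inoculum biomass (gDCW L^-1).
#' @param days sampling days of the fermentation series.
#' @return list(data = clipped \linkS4class{OmicsDataset},
#'   series = long time-series data.frame, rates = true exchange-rate
#'   table, states = per-strain steady states, eLog = true strain log
#'   enzyme levels, analyteMap = analyte -> exchange reaction map).
#' @export
simulateDataset <- function(truth, noise = NoiseSpec(),
                            referenceStrain = names(truth@designs)[1],
                            muRef = 0.025, X0 = 0.05,
                            days = c(3, 5, 7)) {
    model <- truth@model; ref <- truth@ref
    rid <- reactionIds(model); im <- internalMetabolites(model)
    strainsIds <- names(truth@designs)
    stopifnot(referenceStrain %in% strainsIds)
    .withSeed(noise@seed, {
        states <- lapply(truth@designs, function(d)
            simulateStrain(model, ref, truth@eps, d))
        asMat <- function(v, rows)
            matrix(v, nrow = length(rows),
                   dimnames = list(rows, strainsIds))
        eLog <- asMat(vapply(truth@designs, function(d) {
            e <- stats::setNames(rep(1, length(rid)), rid)
            if (length(d)) e[names(d)] <- pmax(d, 0.05)
            log(e)
        }, numeric(length(rid))), rid)
        xLog <- asMat(vapply(states, slot, numeric(length(im)), "xLog"), im)
        vMat <- asMat(vapply(states, slot, numeric(length(rid)), "v"), rid)
        eRef <- eLog[, referenceStrain]
        xRef <- xLog[, referenceStrain]

        nrep <- noise@replicates
        samples <- as.vector(t(outer(strainsIds, seq_len(nrep),
                                     function(s, r) paste0(s, "_rep", r))))
        strainOf <- rep(strainsIds, each = nrep)
        nS <- length(samples)
        pmat <- matrix(NA_real_, length(rid), nS,
                       dimnames = list(rid, samples))
        mmat <- matrix(NA_real_, length(im), nS,
                       dimnames = list(im, samples))
        fmat <- matrix(NA_real_, length(rid), nS,
                       dimnames = list(rid, samples))
        fluxScale <- pmax(abs(vStar(ref)), 1e-6)
        for (k in seq_len(nS)) {
            s <- strainOf[k]
            obsP <- stats::runif(length(rid)) <= noise@obsFractionProtein
            obsM <- stats::runif(length(im)) <= noise@obsFractionMetabolite
            ## reactions without protein association are never measured
            hasProt <- vapply(model@proteins[rid], length, 1L) > 0
            obsP <- obsP & hasProt
            pmat[obsP, k] <- (eLog[obsP, s] - eRef[obsP]) +
                stats::rnorm(sum(obsP), 0, noise@sdProtein)
            mmat[obsM, k] <- (xLog[obsM, s] - xRef[obsM]) +
                stats::rnorm(sum(obsM), 0, noise@sdMetabolite)
            fmat[, k] <- vMat[, s] +
                stats::rnorm(length(rid), 0, noise@sdFlux * fluxScale)
        }
        data <- OmicsDataset(model, pmat, mmat, fmat, strainOf)
        data <- clipObservations(data, noise@clipBound)

        ## fermentation series from the exponential-growth closed form
        analyteMap <- c(glucose = "r_glcup", hp3 = "r_ex3hp",
                        ethanol = "r_exetoh")
        analyteMap <- analyteMap[analyteMap %in% rid]
        S0 <- c(glucose = 555, hp3 = 0, ethanol = 0)
        Sfull <- stoichiometricMatrix(model, internal = FALSE)
        ext <- externalMetabolites(model)
        times <- days * 24
        series <- list(); ratesTab <- list()
        vGrowth <- if ("r_growth" %in% rid) "r_growth" else
            targetReaction(model)
        for (s in strainsIds) {
            mu <- muRef * vMat[vGrowth, s] / vStar(ref)[vGrowth]
            X <- X0 * exp(mu * times)
            zz <- if (abs(mu) > 1e-12) (X0 / mu) * (exp(mu * times) - 1)
                  else X0 * times
            for (r in seq_len(nrep))
                series[[length(series) + 1L]] <- data.frame(
                    strain = s, replicate = r, time_h = times,
                    analyte = "biomass", value = X,
                    stringsAsFactors = FALSE)
            for (a in names(analyteMap)) {
                exr <- analyteMap[[a]]
                sc <- Sfull[ext, exr]; sc <- sc[sc != 0]
                q <- unname(sc) * vMat[exr, s]   # uptake < 0, excretion > 0
                conc <- S0[[a]] + q * zz
                for (r in seq_len(nrep))
                    series[[length(series) + 1L]] <- data.frame(
                        strain = s, replicate = r, time_h = times,
                        analyte = a, value = conc, stringsAsFactors = FALSE)
                ratesTab[[length(ratesTab) + 1L]] <- data.frame(
                    strain = s, reaction_id = exr, rate = q,
                    stringsAsFactors = FALSE)
            }
        }
        list(data = data, series = do.call(rbind, series),
             rates = do.call(rbind, ratesTab),
             states = states, eLog = eLog, xLog = xLog, v = vMat,
             referenceStrain = referenceStrain, analyteMap = analyteMap)
    })
}
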