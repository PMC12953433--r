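#' Map protein abundances to reaction expression (GPR aggregation)
#'
#' Linear-scale aggregation used for E-Flux2 bounds: isozymes (OR groups)
#' sum their expression, enzyme-complex subunits (AND within a group) take
#' the minimum. Proteins without a measurement are ignored inside a group;
#' reactions whose proteins are all unmeasured (or with no association at
#' all) get NA, which \code{\link{eflux2}} treats as an unconstrained
#' (ceiling) bound.
#'
#' @param model \linkS4class{MetabolicModel}.
#' @param proteinValues named non-negative numeric of protein abundances.
#' @return Named numeric over reactions (NA = no expression information).
#' @export
aggregateExpression <- function(model, proteinValues) {
    vapply(reactionIds(model), function(rid) {
        gpr <- model@proteins[[rid]]
        if (!length(gpr)) return(NA_real_)
        iso <- vapply(gpr, function(grp) {
            v <- proteinValues[grp]
            v <- v[!is.na(v)]
            if (!length(v)) return(NA_real_)
            min(v)
        }, 0)
        iso <- iso[!is.na(iso)]
        if (!length(iso)) NA_real_ else sum(iso)
    }, 0)
}

#' Map protein log-ratios to reaction-level log-ratios
#'
#' For the Bayesian observation model, where measurements are log-ratios
#' relative to a reference strain: a reaction's relative enzyme level is
#' summarized as the mean log-ratio over its associated proteins (the log
#' of the geometric-mean fold change).
#'
#' @param model \linkS4class{MetabolicModel}.
#' @param proteinLog named numeric of protein log-ratios (NA = unmeasured).
#' @return Named numeric over reactions (NA = no measured protein).
#' @export
reactionLogRatios <- function(model, proteinLog) {
    vapply(reactionIds(model), function(rid) {
        ids <- unique(unlist(model@proteins[[rid]]))
        if (!length(ids)) return(NA_real_)
        v <- proteinLog[intersect(ids, names(proteinLog))]
        v <- v[!is.na(v)]
        if (!length(v)) NA_real_ else mean(v)
    }, 0)
}

## bounded LP via boot::simplex on shifted variables x = v - lb >= 0
.boundedLP <- function(cvec, Aeq, beq, lb, ub, maximize = TRUE) {
    shift <- lb
    beqS <- beq - drop(Aeq %*% shift)
    n <- length(cvec)
    res <- boot::simplex(a = cvec,
                         A1 = diag(n), b1 = ub - lb,
                         A3 = Aeq, b3 = beqS,
                         maxi = maximize, n.iter = 50 * n,
                         eps = 1e-10)
    if (res$solved < 0) return(list(status = "infeasible"))
    v <- res$soln + shift
    list(status = "optimal", v = v,
         value = sum(cvec * v))
}

#' Expression-constrained flux estimation (E-Flux2)
#'
#' Two-phase solve. Phase 1: maximize the objective flux subject to the
#' steady-state constraint N v = 0, measured exchange fluxes held in a
#' relative band around their values, and per-reaction flux bounds scaled
#' by reaction expression (per-sample expression normalized by its maximum,
#' bound = M x normalized expression; reactions without expression
#' information get the ceiling M). Phase 2: among the optima of phase 1,
#' return the flux vector of minimum squared norm (the E-Flux2 uniqueness
#' criterion). Reversible reactions may carry negative net flux;
#' irreversible reactions are bounded below by 0.
#'
#' @param model \linkS4class{MetabolicModel}.
#' @param expression named numeric over reactions (linear scale,
#'   non-negative; NA = no information), e.g. from
#'   \code{\link{aggregateExpression}}.
#' @param exchangeRates named numeric: exchange reaction id -> measured
#'   specific rate (uptake negative, excretion positive), mapped onto
#'   reaction flux through the stoichiometric sign of the external species.
#' @param objective reaction id whose flux phase 1 maximizes.
#' @param M flux ceiling multiplying the normalized expression (default
#'   100 mmol gDCW^-1 h^-1).
#' @param band relative half-width of the exchange-rate window (default
#'   0.05); 0 pins rates exactly.
#' @param ssTol tolerance for reporting the steady-state residual.
#' @return list(v = named net flux vector, objectiveValue, status
#'   = "optimal" or "infeasible").
#' @export
eflux2 <- function(model, expression, exchangeRates, objective,
                   M = 100, band = 0.05, ssTol = 1e-8) {
    rid <- reactionIds(model)
    stopifnot(objective %in% rid)
    N <- stoichiometricMatrix(model)
    nr <- length(rid)
    expr <- rep(NA_real_, nr); names(expr) <- rid
    expr[names(expression)] <- expression
    if (any(expr < 0, na.rm = TRUE)) stop("expression must be non-negative")
    mx <- suppressWarnings(max(expr, na.rm = TRUE))
    bound <- if (is.finite(mx) && mx > 0) M * expr / mx else expr
    bound[is.na(bound)] <- M
    ub <- pmin(bound, M)
    lb <- ifelse(model@reactions$reversible, -ub, 0)
    names(lb) <- names(ub) <- rid

    ## exchange windows: flux_j such that s_ext * flux_j = measured rate
    Sfull <- stoichiometricMatrix(model, internal = FALSE)
    ext <- externalMetabolites(model)
    for (ex in names(exchangeRates)) {
        if (!(ex %in% rid)) stop("unknown exchange reaction: ", ex)
        s <- Sfull[ext, ex]
        s <- s[s != 0]
        if (length(s) != 1L)
            stop("exchange reaction ", ex,
                 " must touch exactly one external species")
        vj <- exchangeRates[[ex]] / unname(s)
        half <- band * abs(vj)
        lb[ex] <- max(lb[ex], vj - half)
        ub[ex] <- min(ub[ex], vj + half)
        if (lb[ex] > ub[ex] + 1e-12)
            return(list(v = NULL, objectiveValue = NA_real_,
                        status = "infeasible"))
    }

    cvec <- as.numeric(rid == objective)
    p1 <- .boundedLP(cvec, N, rep(0, nrow(N)), lb, ub, maximize = TRUE)
    if (p1$status != "optimal")
        return(list(v = NULL, objectiveValue = NA_real_,
                    status = "infeasible"))
    opt <- p1$value

    ## phase 2: min ||v||^2 with the phase-1 optimum pinned
    Aeq <- rbind(N, cvec)
    beq <- c(rep(0, nrow(N)), opt)
    qp <- tryCatch(
        pracma::quadprog(diag(nr), rep(0, nr), Aeq = Aeq, beq = beq,
                         lb = lb, ub = ub),
        error = function(e) NULL)
    if (is.null(qp) || qp$eflag != 1) {
        v <- p1$v   # fall back to the (feasible) phase-1 vertex
    } else {
        v <- qp$xmin
    }
    names(v) <- rid
    res <- max(abs(N %*% v))
    if (res > ssTol)
        warning("steady-state residual ", format(res), " above tolerance")
    list(v = v, objectiveValue = opt, status = "optimal")
}
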