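#' Lin-log reaction rates
#'
#' Evaluates the lin-log approximate rate law
#' \deqn{v = \mathrm{diag}(v^*)\, (e/e^*) \circ
#'   (1 + \epsilon_x \log(x/x^*) + \epsilon_y \log(y/y^*))}
#' at given relative enzyme levels and log metabolite deviations. The
#' approximation is linear in the log-deviations and proportional to the
#' relative enzyme level, and is valid near the reference state.
#'
#' @param ref \linkS4class{ReferenceState}.
#' @param eps \linkS4class{ElasticityMatrices}.
#' @param pert \linkS4class{PerturbationState} (e/e* and log(y/y*)).
#' @param xLog internal metabolite log-deviations log(x/x*).
#' @return Named numeric vector of fluxes, units of \code{vStar(ref)}.
#' @examples
#' # at the reference state the rate law returns v* exactly
#' @export
linlogRates <- function(ref, eps, pert, xLog) {
    ex <- epsX(eps); ey <- epsY(eps)
    if (length(xLog) != ncol(ex))
        stop("xLog has length ", length(xLog), ", expected ", ncol(ex))
    if (length(pert@eRel) != nrow(ex))
        stop("eRel has length ", length(pert@eRel), ", expected ", nrow(ex))
    if (length(pert@yLog) != ncol(ey))
        stop("yLog has length ", length(pert@yLog), ", expected ", ncol(ey))
    g <- 1 + drop(ex %*% xLog) + drop(ey %*% pert@yLog)
    stats::setNames(vStar(ref) * (pert@eRel / eStar(ref)) * g,
                    names(vStar(ref)))
}

## Shared kernel: assemble and solve the steady-state linear system
##   N diag(v* e) (1 + epsX xLog + epsY yLog) = 0
## => [N diag(v* e) epsX] xLog = -N diag(v* e) (1 + epsY yLog)
.linlogSolve <- function(N, vstar, erel, ex, w, condThreshold, pseudoinverse) {
    d <- vstar * erel
    Nd <- N * rep(d, each = nrow(N))      # N %*% diag(d)
    A <- Nd %*% ex
    b <- -drop(Nd %*% w)
    kappa <- if (nrow(A)) kappa(A, exact = FALSE) else 0
    singular <- !is.finite(kappa) || kappa > condThreshold
    if (singular && !pseudoinverse)
        stop("steady-state system is singular (cond = ", format(kappa),
             "); set pseudoinverse = TRUE to use a Moore-Penrose fallback")
    xLog <- if (singular) drop(pracma::pinv(A) %*% b)
            else drop(solve(A, b))
    list(xLog = xLog, cond = kappa, singular = singular, d = d)
}

#' Solve the lin-log steady state
#'
#' Setting \eqn{N v = 0} in the lin-log rate law reduces the steady-state
#' problem to one linear solve for the internal log-deviations
#' \eqn{x_{\log}}:
#' \deqn{[N\,\mathrm{diag}(v^* e)\,\epsilon_x]\, x_{\log} =
#'   -N\,\mathrm{diag}(v^* e)\,(1 + \epsilon_y y_{\log}).}
#' The model must have full-row-rank N (apply
#' \code{\link{removeConservedMoieties}} first if needed).
#'
#' @param model \linkS4class{MetabolicModel} (reduced, full row rank).
#' @param ref \linkS4class{ReferenceState}.
#' @param eps \linkS4class{ElasticityMatrices}.
#' @param pert \linkS4class{PerturbationState}.
#' @param condThreshold condition number above which the system is flagged
#'   singular (default 1e10).
#' @param pseudoinverse when TRUE, flagged systems are solved with the
#'   Moore-Penrose pseudoinverse instead of erroring.
#' @return A \linkS4class{SteadyStateSolution}.
#' @export
setMethod("solveSteadyState", "MetabolicModel",
          function(model, ref, eps, pert, condThreshold = 1e10,
                   pseudoinverse = FALSE) {
    N <- stoichiometricMatrix(model)
    ex <- epsX(eps); ey <- epsY(eps)
    w <- 1 + drop(ey %*% pert@yLog)
    sol <- .linlogSolve(N, vStar(ref), pert@eRel / eStar(ref), ex, w,
                        condThreshold, pseudoinverse)
    xLog <- stats::setNames(sol$xLog, internalMetabolites(model))
    v <- linlogRates(ref, eps, pert, xLog)
    new("SteadyStateSolution", xLog = xLog, v = v,
        singular = sol$singular, condNumber = sol$cond)
})

#' Flux and concentration control coefficients
#'
#' Applies the implicit function theorem to the lin-log steady state at the
#' reference point: with \eqn{A = N\,\mathrm{diag}(v^*)\,\epsilon_x},
#' \deqn{C^X = -A^{-1} N\,\mathrm{diag}(v^*), \qquad
#'   C^J = I + \epsilon_x C^X,}
#' so that \eqn{C^J_{jk} = \partial \log J_j / \partial \log e_k}. The
#' summation theorem (CJ rows sum to 1) and the connectivity theorem
#' (\eqn{C^J \epsilon_x = 0}) hold identically under these formulas.
#'
#' @param model \linkS4class{MetabolicModel} with full-row-rank N.
#' @param ref \linkS4class{ReferenceState}.
#' @param epsX elasticity matrix (reactions x internal metabolites) or an
#'   \linkS4class{ElasticityMatrices} object.
#' @param condThreshold,pseudoinverse as in \code{\link{solveSteadyState}}.
#' @return A \linkS4class{ControlCoefficients}.
#' @export
setMethod("controlCoefficients", "MetabolicModel",
          function(model, ref, epsX, condThreshold = 1e10,
                   pseudoinverse = FALSE) {
    if (is(epsX, "ElasticityMatrices")) epsX <- epsX(epsX)
    N <- stoichiometricMatrix(model)
    Nv <- N * rep(vStar(ref), each = nrow(N))   # N diag(v*)
    A <- Nv %*% epsX
    kappa <- if (nrow(A)) kappa(A, exact = FALSE) else 0
    singular <- !is.finite(kappa) || kappa > condThreshold
    if (singular && !pseudoinverse)
        stop("control-coefficient system is singular (cond = ",
             format(kappa), ")")
    Ainv <- if (singular) pracma::pinv(A) else solve(A)
    CX <- -Ainv %*% Nv
    CJ <- diag(nrow(epsX)) + epsX %*% CX
    rid <- reactionIds(model)
    dimnames(CJ) <- list(rid, rid)
    dimnames(CX) <- list(internalMetabolites(model), rid)
    new("ControlCoefficients", CJ = CJ, CX = CX, pseudoinverse = singular)
})

#' Simulate a perturbed strain to steady state
#'
#' Builds a \linkS4class{PerturbationState} from an enzyme fold-change
#' design and solves the lin-log steady state. The lin-log law is undefined
#' at e = 0, so deletions (fold-change 0) are represented by a small
#' positive floor that strongly reduces flux while staying in the
#' log-linear regime.
#'
#' @param model,ref,eps as in \code{\link{solveSteadyState}}.
#' @param design named numeric: reaction id -> enzyme fold-change (e/e*).
#'   Reactions not named keep fold-change 1. An empty design reproduces the
#'   reference state exactly.
#' @param knockoutFloor lower floor applied to fold-changes (default 0.05).
#' @param ... passed on to \code{\link{solveSteadyState}}.
#' @return A \linkS4class{SteadyStateSolution}.
#' @export
setMethod("simulateStrain", "MetabolicModel",
          function(model, ref, eps, design, knockoutFloor = 0.05, ...) {
    design <- if (length(design)) pmax(unlist(design), knockoutFloor)
              else stats::setNames(numeric(0), character(0))
    if (length(design) && !all(names(design) %in% reactionIds(model)))
        stop("design names unknown reaction(s): ",
             paste(setdiff(names(design), reactionIds(model)), collapse = ", "))
    pert <- PerturbationState(model, eRel = design)
    solveSteadyState(model, ref, eps, pert, ...)
})
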