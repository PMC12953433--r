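#' Fit an exponential growth model
#'
#' Least-squares fit of \code{log X(t) = log X0 + mu t} to biomass
#' measurements, the standard description of batch growth before substrate
#' limitation.
#'
#' @param times time points (h).
#' @param biomass biomass concentrations (gDCW L^-1), strictly positive.
#' @return list(mu, X0, r_squared): specific growth rate (h^-1), initial
#'   biomass, and the r-squared of the log-linear fit.
#' @export
fitExponentialGrowth <- function(times, biomass) {
    if (length(times) < 2L) stop("need at least 2 time points")
    if (length(times) != length(biomass)) stop("times/biomass length mismatch")
    if (any(biomass <= 0)) stop("biomass must be strictly positive")
    fit <- stats::lm(log(biomass) ~ times)
    tss <- sum((log(biomass) - mean(log(biomass)))^2)
    r2 <- if (tss == 0) 1 else 1 - sum(stats::residuals(fit)^2) / tss
    list(mu = unname(stats::coef(fit)[2]),
         X0 = unname(exp(stats::coef(fit)[1])),
         r_squared = r2)
}

#' Estimate a specific exchange rate from a concentration time series
#'
#' Under exponential growth, a constant specific rate q
#' (mmol gDCW^-1 h^-1) gives the mass balance
#' \deqn{S(t) = S(0) + (q X_0/\mu)(e^{\mu t} - 1),}
#' which is linear in q; q is recovered by least squares on the regressor
#' \eqn{(X_0/\mu)(e^{\mu t}-1)} (or \eqn{X_0 t} in the zero-growth limit).
#' Sign convention: uptake negative, excretion positive.
#'
#' @param times time points (h), same grid as the growth data.
#' @param concentration extracellular concentrations (mmol L^-1).
#' @param growth a fit from \code{\link{fitExponentialGrowth}}.
#' @return q, the specific rate (mmol gDCW^-1 h^-1).
#' @export
estimateExchangeRate <- function(times, concentration, growth) {
    if (length(unique(times)) < 2L) stop("degenerate time grid")
    if (length(times) != length(concentration))
        stop("times/concentration length mismatch")
    z <- if (abs(growth$mu) > 1e-12)
        (growth$X0 / growth$mu) * (exp(growth$mu * times) - 1)
    else growth$X0 * times
    fit <- stats::lm(concentration ~ z)
    unname(stats::coef(fit)[2])
}

#' Estimate all exchange rates for a strain panel
#'
#' Takes a long-format time series table and returns per-strain specific
#' uptake/excretion rates. Replicate series are averaged per strain and
#' time point before fitting (rates are per strain, growth and consumption
#' sharing one grid).
#'
#' @param series data.frame with columns strain, replicate, time_h, analyte,
#'   value. The analyte named by \code{biomassAnalyte} is the biomass
#'   series; every other analyte is an extracellular metabolite whose id
#'   must appear in \code{analyteMap}.
#' @param analyteMap named character: analyte -> exchange reaction id.
#' @param biomassAnalyte analyte name of the biomass series.
#' @return data.frame(strain, reaction_id, rate, mu, X0, r_squared) with
#'   rates in mmol gDCW^-1 h^-1, uptake negative.
#' @export
estimateExchangeRates <- function(series, analyteMap,
                                  biomassAnalyte = "biomass") {
    need <- c("strain", "replicate", "time_h", "analyte", "value")
    stopifnot(all(need %in% names(series)))
    avg <- stats::aggregate(value ~ strain + time_h + analyte, series, mean)
    out <- list()
    for (s in unique(avg$strain)) {
        sub <- avg[avg$strain == s, ]
        bio <- sub[sub$analyte == biomassAnalyte, ]
        if (!nrow(bio)) stop("no biomass series for strain ", s)
        bio <- bio[order(bio$time_h), ]
        g <- fitExponentialGrowth(bio$time_h, bio$value)
        for (a in setdiff(unique(sub$analyte), biomassAnalyte)) {
            if (!(a %in% names(analyteMap)))
                stop("analyte '", a, "' has no exchange-reaction mapping")
            con <- sub[sub$analyte == a, ]
            con <- con[order(con$time_h), ]
            q <- estimateExchangeRate(con$time_h, con$value, g)
            out[[length(out) + 1L]] <- data.frame(
                strain = s, reaction_id = unname(analyteMap[a]), rate = q,
                mu = g$mu, X0 = g$X0, r_squared = g$r_squared,
                stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, out)
}

#' Read a fermentation time-series table
#'
#' @param path TSV with columns strain, replicate, time_h, analyte, value.
#' @return data.frame.
#' @export
readTimeSeries <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("strain", "replicate", "time_h", "analyte", "value")
    if (!all(need %in% names(tab)))
        stop("time-series table needs columns: ", paste(need, collapse = ", "))
    tab
}
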