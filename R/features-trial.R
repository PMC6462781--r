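#' @title Trial-level features: yield, specific rates, biomass normalization
#' @description
#' Features combining several analytes of one trial. When grids differ
#' (HPLC and plate-reader schedules rarely align) the second analyte is
#' linearly interpolated onto the first's time points; no extrapolation is
#' performed, points outside the overlap are dropped with a warning.
#' @name features-trial
NULL

# interpolate course b onto times tt; returns values with NA outside b's span
interp_course <- function(b, tt, what = "course") {
  fp <- finite_points(b)
  if (length(fp$times) < 1L)
    stop(sprintf("%s has no finite values to interpolate", what),
         call. = FALSE)
  inside <- tt >= min(fp$times) & tt <= max(fp$times)
  if (any(!inside))
    warning(sprintf("%d point(s) outside %s span dropped (no extrapolation)",
                    sum(!inside), what), call. = FALSE)
  out <- rep(NA_real_, length(tt))
  if (length(fp$times) == 1L) {
    out[inside & tt == fp$times] <- fp$values
  } else {
    out[inside] <- stats::approx(fp$times, fp$values, xout = tt[inside],
                                 ties = mean)$y
  }
  out
}

#' Product yield on substrate
#'
#' Endpoint yield `(P_end - P_0) / (S_0 - S_end)` and a cumulative yield
#' trajectory `(P_i - P_0) / (S_0 - S_i)`, both in product unit per substrate
#' unit. The substrate is interpolated onto the product's time grid;
#' cumulative values are undefined (NA) where net substrate consumption does
#' not exceed `tol`.
#'
#' @param product product `analyte_course`
#' @param substrate substrate `analyte_course` of the same trial
#' @param tol minimum substrate consumption for a defined cumulative yield
#' @return a `yield_result`: list with `endpoint_yield`, `times`, `cumulative`
#' @export
compute_yield <- function(product, substrate, tol = 1e-9) {
  fp <- finite_points(product)
  tt <- fp$times; P <- fp$values
  if (length(tt) < 2L)
    stop("insufficient data: need >= 2 finite product points", call. = FALSE)
  S <- interp_course(substrate, tt, "substrate")
  keep <- is.finite(S)
  tt <- tt[keep]; P <- P[keep]; S <- S[keep]
  if (length(tt) < 2L)
    stop("insufficient overlap between product and substrate grids",
         call. = FALSE)
  S0 <- S[1]; P0 <- P[1]
  dS_end <- S0 - S[length(S)]
  if (dS_end <= tol)
    stop("no substrate consumed", call. = FALSE)
  cum <- ifelse(S0 - S > tol, (P - P0) / (S0 - S), NA_real_)
  structure(list(endpoint_yield = (P[length(P)] - P0) / dS_end,
                 times = tt, cumulative = cum),
            class = "yield_result")
}

#' @export
print.yield_result <- function(x, ...) {
  cat(sprintf("<yield_result> endpoint yield = %.4g (product/substrate unit)\n",
              x$endpoint_yield))
  invisible(x)
}

#' Biomass-specific rate of an analyte
#'
#' `q_i = gradient(analyte)_i / X_i` with biomass X linearly interpolated
#' onto the analyte's finite time points. With `molar_mass` given and the
#' analyte in g/L, q is converted to mmol/gDW/h via `* 1000 / molar_mass`.
#' Applied to the biomass course itself this yields the instantaneous
#' specific growth rate mu (1/h).
#'
#' @param analyte an `analyte_course`
#' @param biomass the trial's biomass `analyte_course` (gDW/L)
#' @param molar_mass optional molar mass, g/mol, to convert g/L rates to
#'   mmol/gDW/h
#' @return a `rate_series` with `kind = "specific"`
#' @examples
#' id <- parse_identifier("strain:A|media:M9")
#' pid <- id; pid$analyte_name <- "acetate"
#' bid <- id; bid$analyte_name <- "biomass"
#' p <- analyte_course(pid, 0:4, 0.9 * (0:4), unit = "g/L")
#' x <- analyte_course(bid, 0:4, rep(0.5, 5), unit = "gDW/L")
#' specific_rate(p, x, molar_mass = 90)  # 20 mmol/gDW/h
#' @export
specific_rate <- function(analyte, biomass, molar_mass = NULL) {
  g <- gradient(analyte)
  X <- interp_course(biomass, g$times, "biomass")
  keep <- is.finite(X)
  if (any(!keep)) {
    g$times <- g$times[keep]; g$rates <- g$rates[keep]; X <- X[keep]
  }
  if (any(X <= 0))
    stop("biomass must be positive at all evaluation times", call. = FALSE)
  q <- g$rates / X
  if (!is.null(molar_mass)) q <- q * 1000 / molar_mass
  rate_series(g$times, q, "specific")
}

#' Normalize an analyte course to biomass
#'
#' Divides values pointwise by the biomass interpolated at the analyte's
#' times; the unit is annotated `"<unit>/<biomass unit>"`. Missing analyte
#' values stay missing.
#'
#' @param analyte an `analyte_course`
#' @param biomass the trial's biomass `analyte_course`
#' @return a normalized `analyte_course`
#' @export
normalize_to_biomass <- function(analyte, biomass) {
  X <- interp_course(biomass, analyte$times, "biomass")
  eval_at <- is.finite(analyte$values)
  if (any(is.finite(X[eval_at]) & X[eval_at] <= 0) ||
      any(!is.finite(X[eval_at])))
    stop("biomass must be positive at all analyte times", call. = FALSE)
  out <- analyte
  out$values <- analyte$values / X
  out$unit <- paste0(analyte$unit, "/", biomass$unit)
  out
}
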