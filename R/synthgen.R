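#' @title Synthetic fermentation experiments with known ground truth
#' @description
#' Generates batch-fermentation time courses from the generalized logistic
#' growth curve with substrate-coupled product formation, so every derived
#' quantity has a closed-form ground truth: biomass
#' `X(t) = X0 + gen_logistic(t; A, mu_max, lam)`, substrate
#' `S(t) = S0 - (X(t) - X0) / Y_XS`, product `P(t) = Y_PS * (S0 - S(t))`.
#' Optional additive Gaussian noise, missing-completely-at-random dropout and
#' constant-background blank trials emulate the main artifacts of real plate
#' and HPLC data. All randomness flows from a single seed; equal
#' configurations give byte-identical output.
#' @name synthgen
NULL

#' Synthetic experiment configuration
#'
#' @param n_strains number of strains (each gets its own growth parameters)
#' @param n_replicates replicates per strain
#' @param times sampling times, hours
#' @param growth data frame with columns `A`, `mu_max`, `lam`, one row per
#'   strain (recycled); defaults to A = 2 gDW/L, mu_max = 0.5 1/h, lam = 1 h
#' @param X0 initial biomass, gDW/L
#' @param S0 initial substrate, g/L
#' @param Y_XS biomass yield on substrate, g/g
#' @param Y_PS product yield on substrate, g/g
#' @param noise_sd additive Gaussian noise sd (same unit as each analyte)
#' @param missing_frac probability each value is replaced by missing
#' @param blank_level constant background signal; > 0 adds one blank trial
#'   and this offset to every biomass reading
#' @param seed RNG seed
#' @return a `synthetic_config`
#' @export
synthetic_config <- function(n_strains = 1, n_replicates = 3,
                             times = seq(0, 24, by = 2),
                             growth = data.frame(A = 2, mu_max = 0.5, lam = 1),
                             X0 = 0.05, S0 = 20, Y_XS = 0.5, Y_PS = 0.4,
                             noise_sd = 0, missing_frac = 0,
                             blank_level = 0, seed = 1L) {
  stopifnot(n_strains >= 1, n_replicates >= 1, length(times) >= 2,
            all(diff(times) > 0), Y_XS > 0, Y_PS > 0, X0 >= 0, S0 > 0,
            noise_sd >= 0, missing_frac >= 0, missing_frac < 1,
            blank_level >= 0)
  structure(list(n_strains = as.integer(n_strains),
                 n_replicates = as.integer(n_replicates),
                 times = as.numeric(times), growth = growth, X0 = X0, S0 = S0,
                 Y_XS = Y_XS, Y_PS = Y_PS, noise_sd = noise_sd,
                 missing_frac = missing_frac, blank_level = blank_level,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic fermentation experiment
#'
#' @param cfg a [synthetic_config()]
#' @param media media name written into the identifiers
#' @return list with `tidy` (tidy long data frame, the canonical interchange
#'   format), `points` (the same as `time_point`s) and `truth` (the
#'   generating parameters per strain plus the global yields)
#' @examples
#' g <- generate_experiment(synthetic_config(seed = 42))
#' head(g$tidy)
#' @export
generate_experiment <- function(cfg, media = "M9") {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  gr <- cfg$growth[rep(seq_len(nrow(cfg$growth)),
                       length.out = cfg$n_strains), , drop = FALSE]
  tt <- cfg$times
  rows <- list()
  add_row <- function(id_str, an, t, v, unit)
    rows[[length(rows) + 1L]] <<- data.frame(
      trial_identifier = id_str, analyte_name = an, time_h = t, value = v,
      unit = unit, stringsAsFactors = FALSE)
  truth <- list(strains = list(), Y_XS = cfg$Y_XS, Y_PS = cfg$Y_PS,
                X0 = cfg$X0, S0 = cfg$S0, blank_level = cfg$blank_level)
  for (k in seq_len(cfg$n_strains)) {
    A <- gr$A[k]; mu_max <- gr$mu_max[k]; lam <- gr$lam[k]
    X <- cfg$X0 + growth_gen_logistic(tt, A, mu_max, lam)
    S <- cfg$S0 - (X - cfg$X0) / cfg$Y_XS
    if (any(S < 0))
      stop(paste("substrate exhausted before the last sample time;",
                 "reduce A or increase S0"), call. = FALSE)
    P <- cfg$Y_PS * (cfg$S0 - S)
    sname <- sprintf("strain%d", k)
    truth$strains[[sname]] <- list(A = A, mu_max = mu_max, lam = lam)
    for (r in seq_len(cfg$n_replicates)) {
      id_str <- sprintf("strain:%s|media:%s|rep:%d", sname, media, r)
      for (an in c("biomass", "glucose", "product")) {
        v <- switch(an, biomass = X + cfg$blank_level, glucose = S,
                    product = P)
        if (cfg$noise_sd > 0) v <- v + stats::rnorm(length(v), 0, cfg$noise_sd)
        if (cfg$missing_frac > 0) {
          drop <- stats::runif(length(v)) < cfg$missing_frac
          v[drop] <- NA_real_
        }
        unit <- if (an == "biomass") "gDW/L" else "g/L"
        add_row(id_str, an, tt, v, unit)
      }
    }
  }
  if (cfg$blank_level > 0) {
    id_str <- sprintf("strain:blank|media:%s|rep:1", media)
    add_row(id_str, "biomass", tt, rep(cfg$blank_level, length(tt)), "gDW/L")
  }
  tidy <- do.call(rbind, rows)
  list(tidy = tidy, points = tidy_to_points(tidy), truth = truth)
}

#' The worked missing-data example
#'
#' The canonical 3-replicate, 4-time-point OD course with missing values used
#' throughout the documentation and tests: times 0, 2, 4, 6 h; replicate 1 =
#' 0.5, 0.8, 0.9, 1.2; replicate 2 = 0.6, nan, 1.0, nan; replicate 3 = 0.4,
#' 0.7, 1.2, nan. Its replicate statistics are mean 0.5, 0.75, 1.03, 1.2 and
#' sample standard deviation 0.1, 0.07, 0.15, undefined (two-decimal
#' rounding), the t = 6 h deviation being undefined because a single
#' observation remains there.
#'
#' @return list of 12 `time_point`s (9 finite)
#' @export
table1_fixture <- function() {
  vals <- rbind(c(0.5, 0.8, 0.9, 1.2),
                c(0.6, NA, 1.0, NA),
                c(0.4, 0.7, 1.2, NA))
  tt <- c(0, 2, 4, 6)
  points <- list()
  for (r in 1:3) {
    for (j in 1:4) {
      id <- parse_identifier(sprintf("strain:example|media:M9|rep:%d", r))
      id$analyte_name <- "OD600"
      id$sample_time <- tt[j]
      points[[length(points) + 1L]] <- time_point(id, vals[r, j], "OD")
    }
  }
  points
}

#' Toy fermentation network for flux integration
#'
#' Four metabolites (glucose, pyruvate, ethanol, CO2) and five reactions:
#' glucose exchange, glycolysis `glc -> 2 pyr`, fermentation
#' `pyr -> etoh + co2`, ethanol exchange, CO2 exchange. Bounds are
#' +-1000 mmol/gDW/h and the objective maximizes ethanol export. With
#' glucose uptake fixed at 10 the stoichiometric optimum exports 20 ethanol
#' and 20 CO2.
#'
#' @return a `stoichiometric_model`
#' @export
toy_model_fixture <- function() {
  rxns <- c("EX_glc", "GLYC", "FERM", "EX_etoh", "EX_co2")
  mets <- c("glc", "pyr", "etoh", "co2")
  S <- matrix(0, nrow = 4, ncol = 5, dimnames = list(mets, rxns))
  S["glc", "EX_glc"] <- -1          # export convention: EX drains the pool
  S["glc", "GLYC"] <- -1; S["pyr", "GLYC"] <- 2
  S["pyr", "FERM"] <- -1; S["etoh", "FERM"] <- 1; S["co2", "FERM"] <- 1
  S["etoh", "EX_etoh"] <- -1
  S["co2", "EX_co2"] <- -1
  stoichiometric_model(S, lb = rep(-1000, 5), ub = rep(1000, 5),
                       objective = c(0, 0, 0, 1, 0),
                       exchanges = c("EX_glc", "EX_etoh", "EX_co2"))
}
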