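#' @title Flux integration: FBA with measured exchange rates
#' @description
#' Bridges measured physiology and constraint-based modeling: specific rates
#' (mmol/gDW/h) computed from time-course data are applied as exchange-flux
#' constraints on a stoichiometric model, the resulting linear program is
#' solved at steady state (S v = 0), and the optimum is used to estimate
#' unmeasured quantities — most usefully the CO2 evolution rate, which closes
#' the carbon balance without off-gas analysis. Sign convention: exchange
#' flux > 0 is export, < 0 is uptake.
#' @name fluxlink
NULL

#' Construct a stoichiometric model
#'
#' @param S stoichiometric matrix, metabolites x reactions (dimnames used for
#'   metabolite and reaction ids)
#' @param lb,ub flux bound vectors, mmol/gDW/h
#' @param objective objective coefficient vector (maximized)
#' @param exchanges character vector of exchange reaction ids (reactions
#'   crossing the system boundary)
#' @return a `stoichiometric_model`
#' @export
stoichiometric_model <- function(S, lb, ub, objective, exchanges = character()) {
  S <- as.matrix(S)
  n <- ncol(S)
  stopifnot(length(lb) == n, length(ub) == n, length(objective) == n,
            all(lb <= ub))
  if (is.null(colnames(S))) colnames(S) <- paste0("r", seq_len(n))
  if (is.null(rownames(S))) rownames(S) <- paste0("m", seq_len(nrow(S)))
  stopifnot(all(exchanges %in% colnames(S)))
  structure(list(S = S, lb = stats::setNames(as.numeric(lb), colnames(S)),
                 ub = stats::setNames(as.numeric(ub), colnames(S)),
                 objective = stats::setNames(as.numeric(objective), colnames(S)),
                 exchanges = exchanges),
            class = "stoichiometric_model")
}

#' @export
print.stoichiometric_model <- function(x, ...) {
  cat(sprintf("<stoichiometric_model> %d metabolites x %d reactions, %d exchange(s)\n",
              nrow(x$S), ncol(x$S), length(x$exchanges)))
  invisible(x)
}

# Dense two-phase primal simplex for min c'x s.t. Ax = b (b >= 0), x >= 0.
# Bland's anti-cycling rule keeps pivoting deterministic; sized for the
# desk-scale networks this package targets, not genome-scale models.
simplex_standard <- function(A, b, cvec, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(all(b >= -tol))
  b <- pmax(b, 0)
  # phase 1: artificials form the starting basis
  Aw <- cbind(A, diag(m))
  basis <- n + seq_len(m)
  run <- function(Aw, b, cost, basis, allowed) {
    repeat {
      B <- Aw[, basis, drop = FALSE]
      Binv <- tryCatch(solve(B), error = function(e) NULL)
      if (is.null(Binv)) return(list(status = "singular"))
      xB <- as.vector(Binv %*% b)
      y <- as.vector(t(cost[basis]) %*% Binv)
      red <- cost - as.vector(y %*% Aw)
      cand <- which(allowed & red < -tol & !(seq_along(cost) %in% basis))
      if (length(cand) == 0L)
        return(list(status = "optimal", basis = basis, xB = xB, Binv = Binv))
      j <- min(cand)                       # Bland: smallest index enters
      d <- as.vector(Binv %*% Aw[, j])
      pos <- which(d > tol)
      if (length(pos) == 0L) return(list(status = "unbounded"))
      ratio <- xB[pos] / d[pos]
      rmin <- min(ratio)
      leave <- pos[ratio <= rmin + tol]
      i <- leave[which.min(basis[leave])]  # Bland: smallest index leaves
      basis[i] <- j
    }
  }
  cost1 <- c(rep(0, n), rep(1, m))
  r1 <- run(Aw, b, cost1, basis, allowed = rep(TRUE, n + m))
  if (!identical(r1$status, "optimal")) return(list(status = "infeasible"))
  if (sum(cost1[r1$basis] * r1$xB) > 1e-7) return(list(status = "infeasible"))
  basis <- r1$basis
  # drive any residual artificials out of the basis where possible
  art <- which(basis > n)
  for (i in art) {
    row <- as.vector(r1$Binv[i, , drop = FALSE] %*% Aw[, seq_len(n)])
    j <- which(abs(row) > tol & !(seq_len(n) %in% basis))
    if (length(j)) basis[i] <- min(j)
    # else: redundant row; the artificial stays basic at zero
  }
  cost2 <- c(cvec, rep(0, m))
  r2 <- run(Aw, b, cost2, basis,
            allowed = c(rep(TRUE, n), rep(FALSE, m)))
  if (identical(r2$status, "unbounded")) return(list(status = "unbounded"))
  if (!identical(r2$status, "optimal")) return(list(status = "infeasible"))
  x <- numeric(n + m)
  x[r2$basis] <- r2$xB
  list(status = "optimal", x = x[seq_len(n)],
       objective = sum(cvec * x[seq_len(n)]))
}

# Bounded-variable LP: maximize/minimize obj'v s.t. S v = 0, lb <= v <= ub.
# Variables fixed by lb == ub are substituted out; the rest are shifted to
# w = v - lb >= 0 and upper bounds become slack rows, giving standard form.
lp_solve_bounded <- function(obj, S, lb, ub, maximize = TRUE, tol = 1e-9) {
  n <- length(obj)
  fixed <- (ub - lb) < tol
  v <- numeric(n)
  v[fixed] <- lb[fixed]
  free <- !fixed
  if (!any(free)) {
    resid <- as.vector(S %*% v)
    status <- if (max(abs(resid)) <= 1e-6) "optimal" else "infeasible"
    return(list(v = v, objective_value = sum(obj * v), status = status))
  }
  Sf <- S[, free, drop = FALSE]
  lbf <- lb[free]; ubf <- ub[free]
  if (any(!is.finite(lbf)) || any(!is.finite(ubf)))
    stop("LP requires finite bounds on all free fluxes", call. = FALSE)
  nf <- sum(free)
  # S v = 0  ->  Sf w = -(S_fixed v_fixed + Sf lbf), w = v_free - lbf
  beq <- as.vector(-(S[, fixed, drop = FALSE] %*% v[fixed] + Sf %*% lbf))
  Aeq <- Sf
  neg <- beq < 0
  Aeq[neg, ] <- -Aeq[neg, , drop = FALSE]
  beq[neg] <- -beq[neg]
  # w + s = ub - lb (slack s >= 0)
  A <- rbind(cbind(Aeq, matrix(0, nrow(Aeq), nf)),
             cbind(diag(nf), diag(nf)))
  b <- c(beq, ubf - lbf)
  cvec <- c(if (maximize) -obj[free] else obj[free], rep(0, nf))
  res <- simplex_standard(A, b, cvec, tol = tol)
  if (!identical(res$status, "optimal"))
    return(list(v = v, objective_value = NA_real_, status = res$status))
  v[free] <- res$x[seq_len(nf)] + lbf
  list(v = v, objective_value = sum(obj * v), status = "optimal")
}

#' Solve flux balance analysis with measured exchange constraints
#'
#' Measured specific rates are applied to their exchange reactions as
#' equality constraints (or as symmetric bands `rate * (1 -+ slack)` when
#' `slack > 0`); the LP then maximizes the model objective subject to steady
#' state `S v = 0` and the flux bounds. Solver settings are deterministic.
#'
#' @param m a `stoichiometric_model`
#' @param constraints named numeric vector: exchange reaction id -> measured
#'   rate (mmol/gDW/h; negative = uptake)
#' @param slack fractional band half-width around each measured rate,
#'   default 0 (strict equality)
#' @return a `flux_solution`: `v` (named flux vector), `objective_value`,
#'   `status` in `{"optimal","infeasible","unbounded"}`
#' @examples
#' m <- toy_model_fixture()
#' solve_fba(m, c(EX_glc = -10))
#' @export
solve_fba <- function(m, constraints = numeric(), slack = 0) {
  stopifnot(inherits(m, "stoichiometric_model"), slack >= 0)
  unknown <- setdiff(names(constraints), colnames(m$S))
  if (length(unknown))
    stop(sprintf("constrained reaction(s) not in model: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  lb <- m$lb; ub <- m$ub
  for (rid in names(constraints)) {
    rate <- constraints[[rid]]
    half <- abs(rate) * slack
    lb[rid] <- rate - half
    ub[rid] <- rate + half
  }
  sol <- lp_solve_bounded(m$objective, m$S, lb, ub, maximize = TRUE)
  if (sol$status == "infeasible") {
    msg <- paste(sprintf("%s=%g", names(constraints), constraints),
                 collapse = ", ")
    return(structure(list(v = stats::setNames(rep(NA_real_, ncol(m$S)),
                                              colnames(m$S)),
                          objective_value = NA_real_, status = "infeasible",
                          constraints = constraints,
                          message = sprintf("infeasible under constraints: %s",
                                            msg)),
                     class = "flux_solution"))
  }
  structure(list(v = stats::setNames(sol$v, colnames(m$S)),
                 objective_value = sol$objective_value, status = sol$status,
                 constraints = constraints),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution> status=%s, objective=%.6g\n", x$status,
              x$objective_value))
  if (x$status == "optimal") print(round(x$v, 6))
  invisible(x)
}

# minimize total absolute flux subject to fixed measured exchanges;
# split v = p - n (p, n >= 0) after substituting out fixed variables
lp_min_abs_flux <- function(m, lb, ub) {
  S <- m$S; n <- ncol(S)
  fixed <- (ub - lb) < 1e-9
  v <- numeric(n); v[fixed] <- lb[fixed]
  free <- !fixed
  if (!any(free)) {
    resid <- as.vector(S %*% v)
    status <- if (max(abs(resid)) <= 1e-6) "optimal" else "infeasible"
    return(list(v = v, status = status))
  }
  if (any(lb[free] > 0) || any(ub[free] < 0))
    stop("min-|v| fallback requires free flux bounds straddling zero",
         call. = FALSE)
  Sf <- S[, free, drop = FALSE]
  nf <- sum(free)
  beq <- as.vector(-(S[, fixed, drop = FALSE] %*% v[fixed]))
  Aeq <- cbind(Sf, -Sf)                       # v_free = p - q, p, q >= 0
  neg <- beq < 0
  Aeq[neg, ] <- -Aeq[neg, , drop = FALSE]; beq[neg] <- -beq[neg]
  # p + sp = ub (ub >= 0), q + sq = -lb (lb <= 0)
  zero <- matrix(0, nf, nf)
  A <- rbind(cbind(Aeq, matrix(0, nrow(Aeq), 2 * nf)),
             cbind(diag(nf), zero, diag(nf), zero),
             cbind(zero, diag(nf), zero, diag(nf)))
  b <- c(beq, ub[free], -lb[free])
  cvec <- c(rep(1, 2 * nf), rep(0, 2 * nf))
  res <- simplex_standard(A, b, cvec)
  if (!identical(res$status, "optimal"))
    return(list(v = v, status = "infeasible"))
  v[free] <- res$x[seq_len(nf)] - res$x[nf + seq_len(nf)]
  list(v = v, status = "optimal")
}

#' Estimate the CO2 evolution rate from measured exchanges
#'
#' Fixes every measured exchange rate, solves the model and returns the CO2
#' exchange flux at the optimum. When the model carries a nonzero objective
#' (typically biomass, or a product exchange) that objective is maximized;
#' otherwise total absolute flux is minimized (parsimonious fallback). On the
#' bundled toy network the CO2 flux is uniquely determined by stoichiometry,
#' so both objectives agree.
#'
#' @param m a `stoichiometric_model`
#' @param measured named numeric vector exchange id -> measured rate; must
#'   not include `co2_id`
#' @param co2_id the CO2 exchange reaction id
#' @return estimated CO2 exchange rate, mmol/gDW/h (positive = evolution)
#' @examples
#' estimate_co2(toy_model_fixture(), c(EX_glc = -10, EX_etoh = 20), "EX_co2")
#' @export
estimate_co2 <- function(m, measured, co2_id) {
  stopifnot(inherits(m, "stoichiometric_model"))
  if (!co2_id %in% m$exchanges)
    stop(sprintf("'%s' is not an exchange reaction of the model", co2_id),
         call. = FALSE)
  if (co2_id %in% names(measured))
    stop("co2_id must not itself be measured", call. = FALSE)
  use_obj <- any(m$objective != 0)
  if (use_obj) {
    sol <- solve_fba(m, measured)
    if (sol$status != "optimal")
      stop(sprintf("flux estimation %s under constraints: %s", sol$status,
                   paste(sprintf("%s=%g", names(measured), measured),
                         collapse = ", ")), call. = FALSE)
    return(unname(sol$v[co2_id]))
  }
  lb <- m$lb; ub <- m$ub
  for (rid in names(measured)) lb[rid] <- ub[rid] <- measured[[rid]]
  sol <- lp_min_abs_flux(m, lb, ub)
  if (sol$status != "optimal")
    stop(sprintf("flux estimation infeasible under constraints: %s",
                 paste(sprintf("%s=%g", names(measured), measured),
                       collapse = ", ")), call. = FALSE)
  unname(sol$v[match(co2_id, colnames(m$S))])
}

#' Carbon recovery ledger
#'
#' Balances consumed substrate carbon against produced carbon:
#' `recovery = sum_p c_p * dP_p / sum_s c_s * dS_s`, with amounts in mmol and
#' `c` the carbon atom count per molecule. An OD-derived biomass increment in
#' grams can be included via `biomass_grams`; it is converted with the
#' standard elemental composition CH1.8O0.5N0.2 (24.6 g per C-mol,
#' configurable).
#'
#' @param deltas named list: species -> `c(amount, carbon)` with amount in
#'   mmol (consumption and production both entered as positive magnitudes)
#'   and carbon the atoms per molecule
#' @param substrates names within `deltas` counted as consumed substrate
#' @param biomass_grams optional biomass formed, g
#' @param g_per_cmol grams of biomass per C-mol, default 24.6
#' @return a `carbon_ledger`: per-species C-mmol, `consumed_cmmol`,
#'   `produced_cmmol`, `recovery`
#' @examples
#' carbon_recovery(list(glucose = c(10, 6), ethanol = c(20, 2),
#'                      co2 = c(20, 1)), substrates = "glucose")
#' @export
carbon_recovery <- function(deltas, substrates, biomass_grams = NULL,
                            g_per_cmol = 24.6) {
  stopifnot(length(deltas) > 0, all(substrates %in% names(deltas)))
  cmmol <- vapply(deltas, function(d) {
    stopifnot(length(d) == 2, all(d >= 0))
    d[[1]] * d[[2]]
  }, numeric(1))
  consumed <- sum(cmmol[substrates])
  if (consumed <= 0) stop("zero carbon consumed", call. = FALSE)
  produced_by <- cmmol[setdiff(names(cmmol), substrates)]
  if (!is.null(biomass_grams)) {
    stopifnot(biomass_grams >= 0)
    produced_by <- c(produced_by, biomass = 1000 * biomass_grams / g_per_cmol)
  }
  produced <- sum(produced_by)
  structure(list(species_cmmol = cmmol, consumed_cmmol = consumed,
                 produced_cmmol = produced_by,
                 recovery = produced / consumed),
            class = "carbon_ledger")
}

#' @export
print.carbon_ledger <- function(x, ...) {
  cat(sprintf("<carbon_ledger> consumed %.4g C-mmol, recovered %.1f%%\n",
              x$consumed_cmmol, 100 * x$recovery))
  invisible(x)
}

#' Read a stoichiometric model from a reaction-table CSV
#'
#' Columns `reaction_id,equation,lb,ub,objective`; equations use
#' `"glc_e -> 2 pyr_c"` syntax (`<->` also accepted; coefficients optional).
#' A reaction with an empty side is an exchange.
#'
#' @param path CSV file
#' @return a `stoichiometric_model`
#' @export
read_reaction_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("reaction_id", "equation", "lb", "ub", "objective")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("reaction table missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  parse_side <- function(s) {
    s <- trimws(s)
    if (!nzchar(s)) return(list())
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    lapply(terms, function(tm) {
      bits <- strsplit(tm, "\\s+")[[1]]
      if (length(bits) == 2L) list(coef = as.numeric(bits[1]), met = bits[2])
      else list(coef = 1, met = bits[1])
    })
  }
  stoich <- list(); exchanges <- character()
  for (i in seq_len(nrow(df))) {
    eq <- df$equation[i]
    sides <- strsplit(eq, "<->|->")[[1]]
    if (length(sides) > 2L)
      stop(sprintf("reaction '%s': malformed equation '%s'",
                   df$reaction_id[i], eq), call. = FALSE)
    lhs <- parse_side(sides[1])
    rhs <- if (length(sides) == 2L) parse_side(sides[2]) else list()
    col <- numeric()
    addc <- function(met, x) {
      cur <- if (met %in% names(col)) col[[met]] else 0
      col[[met]] <<- cur + x
    }
    for (tm in lhs) addc(tm$met, -tm$coef)
    for (tm in rhs) addc(tm$met, tm$coef)
    stoich[[df$reaction_id[i]]] <- col
    if (length(lhs) == 0L || length(rhs) == 0L)
      exchanges <- c(exchanges, df$reaction_id[i])
  }
  mets <- sort(unique(unlist(lapply(stoich, names))))
  S <- matrix(0, nrow = length(mets), ncol = length(stoich),
              dimnames = list(mets, names(stoich)))
  for (rid in names(stoich)) S[names(stoich[[rid]]), rid] <- stoich[[rid]]
  stoichiometric_model(S, as.numeric(df$lb), as.numeric(df$ub),
                       as.numeric(df$objective), exchanges)
}

#' Read a stoichiometric model from SBML
#'
#' Minimal SBML Level 3 core import: species, reactions with
#' reactant/product stoichiometries, and (when present) fbc flux bounds and
#' objective. Species flagged `boundaryCondition="true"` are excluded from
#' the balance; reactions touching them, or with an empty side, are treated
#' as exchanges. Default bounds are +-1000 mmol/gDW/h.
#'
#' @param path SBML file
#' @return a `stoichiometric_model`
#' @export
read_sbml_model <- function(path) {
  if (!requireNamespace("xml2", quietly = TRUE))
    stop("SBML import requires the xml2 package", call. = FALSE)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  species <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  sp_id <- xml2::xml_attr(species, "id")
  boundary <- xml2::xml_attr(species, "boundaryCondition") %in% "true"
  internal <- sp_id[!boundary]
  rxns <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (length(rxns) == 0L) stop("SBML file has no reactions", call. = FALSE)
  rid <- xml2::xml_attr(rxns, "id")
  S <- matrix(0, nrow = length(internal), ncol = length(rxns),
              dimnames = list(internal, rid))
  exchanges <- character()
  lb <- rep(-1000, length(rxns)); ub <- rep(1000, length(rxns))
  for (j in seq_along(rxns)) {
    rx <- rxns[[j]]
    get_side <- function(which) {
      refs <- xml2::xml_find_all(rx, sprintf("./%s/speciesReference", which))
      data.frame(sp = xml2::xml_attr(refs, "species"),
                 st = as.numeric(ifelse(is.na(xml2::xml_attr(refs, "stoichiometry")),
                                        "1", xml2::xml_attr(refs, "stoichiometry"))),
                 stringsAsFactors = FALSE)
    }
    re <- get_side("listOfReactants"); pr <- get_side("listOfProducts")
    touches_boundary <- any(c(re$sp, pr$sp) %in% sp_id[boundary])
    for (i in seq_len(nrow(re)))
      if (re$sp[i] %in% internal) S[re$sp[i], j] <- S[re$sp[i], j] - re$st[i]
    for (i in seq_len(nrow(pr)))
      if (pr$sp[i] %in% internal) S[pr$sp[i], j] <- S[pr$sp[i], j] + pr$st[i]
    if (touches_boundary || nrow(re) == 0L || nrow(pr) == 0L)
      exchanges <- c(exchanges, rid[j])
    if (!identical(xml2::xml_attr(rx, "reversible"), "true") &&
        !is.na(xml2::xml_attr(rx, "reversible")))
      lb[j] <- 0
  }
  obj <- rep(0, length(rxns))
  fbc <- xml2::xml_find_all(doc, ".//listOfFluxObjectives/fluxObjective")
  if (length(fbc)) {
    orid <- xml2::xml_attr(fbc, "reaction")
    ocf <- as.numeric(xml2::xml_attr(fbc, "coefficient"))
    ocf[is.na(ocf)] <- 1
    obj[match(orid, rid)] <- ocf
  }
  stoichiometric_model(S, lb, ub, obj, exchanges)
}
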