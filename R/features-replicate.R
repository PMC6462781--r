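#' @title Replicate-level features: statistics and outlier screening
#' @description
#' Replicates are combined on the union of their time grids; missing (`nan`)
#' values are simply excluded from each per-time calculation, so replicates
#' sampled on different schedules or with dropped observations are handled
#' without imputation. The standard deviation uses the sample (n-1)
#' denominator and is undefined where fewer than two observations remain.
#' @name features-replicate
NULL

# per-analyte union grid + matrix of replicate values (rows = replicates)
replicate_value_matrix <- function(r, analyte) {
  courses <- lapply(r$singles, function(s) s$courses[[analyte]])
  have <- !vapply(courses, is.null, logical(1))
  courses <- courses[have]
  if (length(courses) == 0L)
    stop(sprintf("analyte '%s' not present in any replicate", analyte),
         call. = FALSE)
  grid <- sort(unique(unlist(lapply(courses, function(co) co$times))))
  m <- matrix(NA_real_, nrow = length(courses), ncol = length(grid))
  for (i in seq_along(courses)) {
    co <- courses[[i]]
    m[i, match(co$times, grid)] <- co$values
  }
  m[!is.finite(m)] <- NA_real_
  rep_idx <- vapply(courses, function(co) {
    ri <- co$identifier$replicate_index
    if (is.na(ri)) 1L else ri
  }, integer(1))
  list(grid = grid, values = m, unit = courses[[1]]$unit,
       analyte_type = courses[[1]]$analyte_type, replicate_index = rep_idx)
}

#' Replicate statistics (missing-value aware)
#'
#' For every analyte of the replicate trial: the union time grid across
#' replicates and, at each time, the mean and sample standard deviation over
#' the finite observations only. The mean is defined wherever at least one
#' observation exists (with a single replicate the mean is that replicate's
#' value); the standard deviation is `NA` where fewer than two observations
#' remain.
#'
#' @param r a `replicate_trial`
#' @param analytes analyte names to summarize (default: all present)
#' @return named list of `replicate_stats`: each has `times`, `mean`, `std`,
#'   `n_obs`, `unit`, `analyte_type`
#' @examples
#' e <- assemble_experiment(table1_fixture())
#' replicate_statistics(e$replicates[[1]])$OD600
#' @export
replicate_statistics <- function(r, analytes = analyte_names(r)) {
  stopifnot(inherits(r, "replicate_trial"))
  out <- list()
  for (an in analytes) {
    vm <- replicate_value_matrix(r, an)
    n_obs <- colSums(!is.na(vm$values))
    mu <- colMeans(vm$values, na.rm = TRUE)
    mu[n_obs == 0L] <- NA_real_
    sd_ <- apply(vm$values, 2, function(col) {
      v <- col[!is.na(col)]
      if (length(v) >= 2L) stats::sd(v) else NA_real_
    })
    out[[an]] <- structure(list(times = vm$grid, mean = mu, std = sd_,
                                n_obs = as.integer(n_obs), unit = vm$unit,
                                analyte_type = vm$analyte_type),
                           class = "replicate_stats")
  }
  out
}

#' @export
print.replicate_stats <- function(x, ...) {
  df <- data.frame(time_h = x$times, mean = x$mean, std = x$std,
                   n_obs = x$n_obs)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Flag outlier replicates by leave-one-out deviation
#'
#' For each replicate r the deviation score is the median, over the time
#' points where both r and the leave-one-out mean of the remaining replicates
#' are defined, of `|y_r(t) - m_(-r)(t)| / max(|m_(-r)(t)|, eps)`. Replicates
#' with score above `tau` are flagged, except that at most `n - 2` replicates
#' are ever flagged (the two best-scoring replicates are always kept). With
#' fewer than three replicates nothing is flagged. `tau` controls the
#' aggressiveness of the screen: smaller values flag smaller relative
#' deviations.
#'
#' @param r a `replicate_trial` (>= 3 singles for any flagging)
#' @param analyte analyte name scored
#' @param tau relative-deviation threshold, default 0.5
#' @param eps floor for the denominator, default 1e-6
#' @return integer vector of flagged replicate indices (possibly empty)
#' @export
detect_outlier_replicates <- function(r, analyte, tau = 0.5, eps = 1e-6) {
  stopifnot(tau > 0)
  vm <- replicate_value_matrix(r, analyte)
  n <- nrow(vm$values)
  if (n < 3L) return(integer())
  rho <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    others <- vm$values[-i, , drop = FALSE]
    n_oth <- colSums(!is.na(others))
    m_loo <- colMeans(others, na.rm = TRUE)
    ok <- n_oth >= 1L & !is.na(vm$values[i, ])
    if (!any(ok)) next
    dev <- abs(vm$values[i, ok] - m_loo[ok]) / pmax(abs(m_loo[ok]), eps)
    rho[i] <- stats::median(dev)
  }
  flagged <- which(!is.na(rho) & rho > tau)
  max_flag <- n - 2L
  if (length(flagged) > max_flag) {
    # keep the two best: flag only the worst max_flag scores
    worst <- order(rho, decreasing = TRUE)
    flagged <- intersect(worst, flagged)[seq_len(max_flag)]
  }
  sort(vm$replicate_index[flagged])
}

#' Drop flagged replicates from a replicate trial
#'
#' @param r a `replicate_trial`
#' @param flagged integer replicate indices to remove
#' @return the pruned `replicate_trial`
#' @export
exclude_replicates <- function(r, flagged) {
  if (length(flagged) == 0L) return(r)
  keep <- vapply(r$singles, function(s) {
    ri <- s$identifier$replicate_index
    is.na(ri) || !(ri %in% flagged)
  }, logical(1))
  if (!any(keep))
    stop("cannot exclude every replicate", call. = FALSE)
  replicate_trial(r$identifier, r$singles[keep])
}
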