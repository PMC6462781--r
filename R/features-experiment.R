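#' @title Experiment-level features: blank correction and stage slicing
#' @description
#' Corrections that involve several trials of one experiment: background
#' (blank) subtraction using cell-free trials, automatic blank assignment by
#' matching media and environment, and slicing a fermentation into stages
#' (e.g. growth vs production phase) so every analyte and trial feature can
#' be recomputed per stage.
#' @name features-experiment
NULL

#' Subtract a blank's mean course from a replicate trial
#'
#' For every analyte present in both trials, the blank's mean course
#' (computed by [replicate_statistics()]) is linearly interpolated at each
#' sample time and subtracted. Values may go negative (no clipping). Sample
#' times outside the blank's time span are left uncorrected with a warning;
#' analytes missing from the blank are left uncorrected with a warning. The
#' result carries attribute `blank_corrected = TRUE`.
#'
#' @param r a `replicate_trial`
#' @param blank the blank `replicate_trial`
#' @return the corrected `replicate_trial`
#' @export
subtract_blank <- function(r, blank) {
  bstats <- replicate_statistics(blank)
  missing_an <- setdiff(analyte_names(r), names(bstats))
  if (length(missing_an))
    warning(sprintf("analyte(s) missing from blank, left uncorrected: %s",
                    paste(missing_an, collapse = ", ")), call. = FALSE)
  out <- r
  for (si in seq_along(out$singles)) {
    s <- out$singles[[si]]
    for (an in names(s$courses)) {
      if (!an %in% names(bstats)) next
      bs <- bstats[[an]]
      ok_b <- !is.na(bs$mean)
      if (!any(ok_b)) next
      bt <- bs$times[ok_b]; bv <- bs$mean[ok_b]
      co <- s$courses[[an]]
      inside <- co$times >= min(bt) & co$times <= max(bt)
      if (any(!inside))
        warning(sprintf(
          "%d sample time(s) of '%s' outside blank span left uncorrected",
          sum(!inside), an), call. = FALSE)
      corr <- rep(0, length(co$times))
      if (length(bt) == 1L) {
        corr[inside] <- bv
      } else {
        corr[inside] <- stats::approx(bt, bv, xout = co$times[inside],
                                      ties = mean)$y
      }
      co$values <- co$values - corr
      out$singles[[si]]$courses[[an]] <- co
    }
  }
  attr(out, "blank_corrected") <- TRUE
  out
}

#' Automatically assign blanks to non-blank replicate trials
#'
#' Each non-blank replicate trial is mapped to the blank replicate trial
#' sharing its media and environment. Trials without a matching blank are
#' left unmapped with a warning; ties between several matching blanks are
#' broken lexicographically on the serialized identifier, with a warning.
#'
#' @param e a `ferm_experiment`
#' @return named character vector: serialized non-blank replicate identifier
#'   -> serialized blank identifier (possibly empty)
#' @export
assign_blanks <- function(e) {
  is_blank <- vapply(e$replicates, function(r) r$identifier$is_blank,
                     logical(1))
  blanks <- e$replicates[is_blank]
  trials <- e$replicates[!is_blank]
  if (length(blanks) == 0L) {
    if (length(trials)) warning("no blank trials in experiment", call. = FALSE)
    return(stats::setNames(character(), character()))
  }
  match_key <- function(r) {
    id <- r$identifier
    paste(serialize_media_env(id), collapse = "|")
  }
  bkeys <- vapply(blanks, match_key, character(1))
  bids <- vapply(blanks, function(b) serialize_identifier(b$identifier),
                 character(1))
  out <- character()
  for (r in trials) {
    hits <- which(bkeys == match_key(r))
    rid <- serialize_identifier(r$identifier)
    if (length(hits) == 0L) {
      warning(sprintf("no matching blank for trial %s", rid), call. = FALSE)
      next
    }
    if (length(hits) > 1L) {
      hits <- hits[order(bids[hits])]
      warning(sprintf("multiple matching blanks for trial %s; using %s",
                      rid, bids[hits[1]]), call. = FALSE)
    }
    out[rid] <- bids[hits[1]]
  }
  out
}

serialize_media_env <- function(id) {
  t <- trial_identifier(media = id$media, environment = id$environment)
  serialize_identifier(t)
}

#' Apply automatic blank correction to a whole experiment
#'
#' Convenience wrapper: [assign_blanks()] then [subtract_blank()] on every
#' mapped trial. Blank trials themselves are dropped from the result.
#'
#' @param e a `ferm_experiment`
#' @return the corrected `ferm_experiment` (blanks removed)
#' @export
apply_blank_correction <- function(e) {
  bmap <- assign_blanks(e)
  by_id <- stats::setNames(
    e$replicates,
    vapply(e$replicates, function(r) serialize_identifier(r$identifier),
           character(1)))
  out <- list()
  for (r in e$replicates) {
    rid <- serialize_identifier(r$identifier)
    if (r$identifier$is_blank) next
    out[[length(out) + 1L]] <-
      if (rid %in% names(bmap)) subtract_blank(r, by_id[[bmap[[rid]]]]) else r
  }
  experiment(e$label, out, e$stage_definitions, as.list(bmap))
}

#' Slice an experiment into fermentation stages
#'
#' Stage k covers the half-open interval `[b_k, b_{k+1})`; the final stage is
#' closed at the last sample time, so every point belongs to exactly one
#' stage. Each course is split by membership of its sample times; empty
#' courses (and trials left without courses) are dropped with a warning. The
#' stage number is recorded in each identifier's `stage` extra key, so every
#' analyte/trial/replicate feature can be computed per stage (e.g. a product
#' yield over the production stage only).
#'
#' @param e a `ferm_experiment`
#' @param boundaries strictly increasing stage boundary times, length >= 2
#' @return a `ferm_experiment` whose replicate trials are per-stage sub-trials
#' @export
slice_stages <- function(e, boundaries) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) < 2L || any(diff(boundaries) <= 0))
    stop("stage boundaries must be strictly increasing, length >= 2",
         call. = FALSE)
  n_stage <- length(boundaries) - 1L
  empty_warned <- FALSE
  reps <- list()
  for (r in e$replicates) {
    for (k in seq_len(n_stage)) {
      lo <- boundaries[k]; hi <- boundaries[k + 1]
      last <- k == n_stage
      singles <- list()
      for (s in r$singles) {
        courses <- list()
        for (an in names(s$courses)) {
          co <- s$courses[[an]]
          keep <- if (last) co$times >= lo & co$times <= hi
                  else co$times >= lo & co$times < hi
          if (!any(keep)) { empty_warned <- TRUE; next }
          cid <- co$identifier
          cid$extras["stage"] <- as.character(k)
          courses[[an]] <- analyte_course(cid, co$times[keep], co$values[keep],
                                          co$unit, co$analyte_type)
        }
        if (length(courses) == 0L) next
        sid <- s$identifier
        sid$extras["stage"] <- as.character(k)
        singles[[length(singles) + 1L]] <- single_trial(sid, courses)
      }
      if (length(singles) == 0L) { empty_warned <- TRUE; next }
      rid <- r$identifier
      rid$extras["stage"] <- as.character(k)
      reps[[length(reps) + 1L]] <- replicate_trial(rid, singles)
    }
  }
  if (empty_warned)
    warning("some stages contained no sample times and were dropped",
            call. = FALSE)
  experiment(e$label, reps,
             stage_definitions = lapply(seq_len(n_stage), function(k)
               c(boundaries[k], boundaries[k + 1])))
}

#' Stage number recorded on an identifier, or NA
#' @param id a `trial_identifier`
#' @return integer stage index or `NA`
#' @export
stage_of <- function(id) {
  if ("stage" %in% names(id$extras)) as.integer(id$extras[["stage"]])
  else NA_integer_
}
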