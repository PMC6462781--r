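#' @title Hierarchical experiment schema
#' @description
#' Analyte data are organized bottom-up: a time point (one quantification
#' event) -> an analyte time course -> a single trial (one independent
#' fermentation volume: flask, well, reactor) -> a replicate trial (single
#' trials equal up to replicate index) -> an experiment. Assembly from a flat
#' stream of time points is driven entirely by the trial-identifier metadata.
#' @name schema
NULL

#' Construct a time point
#'
#' @param identifier a `trial_identifier` with `analyte_name` and
#'   `sample_time` set
#' @param value measured value (concentration, OD, signal); `NA` marks a
#'   missing observation
#' @param unit unit string
#' @return a `time_point`
#' @export
time_point <- function(identifier, value, unit = "") {
  stopifnot(inherits(identifier, "trial_identifier"))
  structure(list(identifier = identifier, value = as.numeric(value),
                 unit = unit), class = "time_point")
}

#' Construct an analyte time course
#'
#' @param identifier trial-level `trial_identifier` with `analyte_name` set
#' @param times strictly increasing time vector, hours
#' @param values value vector, same length; `NA` marks missing observations
#' @param unit unit string
#' @param analyte_type one of `"biomass"`, `"substrate"`, `"product"`,
#'   `"reporter"`; defaults to the registry lookup for the analyte name
#' @return an `analyte_course`
#' @export
analyte_course <- function(identifier, times, values, unit = "",
                           analyte_type = NULL) {
  stopifnot(inherits(identifier, "trial_identifier"),
            !is.na(identifier$analyte_name))
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values) || length(times) < 1L)
    stop("times and values must have equal positive length", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (is.null(analyte_type))
    analyte_type <- analyte_type_for(identifier$analyte_name)
  analyte_type <- match.arg(analyte_type,
                            c("biomass", "substrate", "product", "reporter"))
  structure(list(identifier = identifier, analyte_type = analyte_type,
                 times = times, values = values, unit = unit),
            class = "analyte_course")
}

#' @export
print.analyte_course <- function(x, ...) {
  cat(sprintf("<analyte_course> %s (%s), %d points, t = %g..%g h\n",
              x$identifier$analyte_name, x$analyte_type, length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

# Default analyte-name -> type registry. The schema assumes every analyte has
# a type but raw exports never carry one; names are matched case-insensitively
# against this map, with prefix rules for OD and fluorescence channels.
default_analyte_types <- c(
  od600 = "biomass", od = "biomass", biomass = "biomass", dcw = "biomass",
  glucose = "substrate", xylose = "substrate", glycerol = "substrate"
)

#' Analyte type for an analyte name
#'
#' Lookup order: explicit `registry` entry, package default map
#' (OD600/biomass/DCW -> biomass; glucose/xylose/glycerol -> substrate),
#' prefix rules (`od*` -> biomass, `fluor*`/`gfp*` -> reporter), else
#' `"product"`.
#'
#' @param name analyte name
#' @param registry optional named character vector name -> type overriding the
#'   defaults
#' @return one of `"biomass"`, `"substrate"`, `"product"`, `"reporter"`
#' @export
analyte_type_for <- function(name, registry = getOption("fermentr.analyte_types")) {
  key <- tolower(name)
  if (!is.null(registry) && key %in% tolower(names(registry)))
    return(unname(registry[[which(tolower(names(registry)) == key)[1]]]))
  if (key %in% names(default_analyte_types))
    return(unname(default_analyte_types[[key]]))
  if (startsWith(key, "od")) return("biomass")
  if (startsWith(key, "fluor") || startsWith(key, "gfp")) return("reporter")
  "product"
}

#' Construct a single trial
#' @param identifier trial-level identifier (no analyte/time)
#' @param courses named list of `analyte_course`, names = analyte names
#' @return a `single_trial`
#' @export
single_trial <- function(identifier, courses = list()) {
  stopifnot(inherits(identifier, "trial_identifier"))
  if (length(courses) && is.null(names(courses)))
    names(courses) <- vapply(courses, function(co) co$identifier$analyte_name,
                             character(1))
  structure(list(identifier = identifier, courses = courses),
            class = "single_trial")
}

#' Construct a replicate trial
#' @param identifier identifier shared by the singles, replicate index absent
#' @param singles list of replicate-equivalent `single_trial`s
#' @return a `replicate_trial`
#' @export
replicate_trial <- function(identifier, singles) {
  stopifnot(length(singles) >= 1L)
  idx <- vapply(singles, function(s) s$identifier$replicate_index, integer(1))
  if (anyDuplicated(stats::na.omit(idx)))
    stop("replicate indices must be distinct within a replicate trial",
         call. = FALSE)
  structure(list(identifier = identifier, singles = singles,
                 statistics = NULL), class = "replicate_trial")
}

#' @export
print.replicate_trial <- function(x, ...) {
  cat(sprintf("<replicate_trial> %s: %d replicate(s), analytes: %s\n",
              serialize_identifier(x$identifier), length(x$singles),
              paste(analyte_names(x), collapse = ", ")))
  invisible(x)
}

#' Analyte names present in a trial or replicate trial
#' @param x a `single_trial` or `replicate_trial`
#' @return character vector
#' @export
analyte_names <- function(x) {
  if (inherits(x, "single_trial")) return(names(x$courses))
  sort(unique(unlist(lapply(x$singles, function(s) names(s$courses)))))
}

#' Construct an experiment
#' @param label experiment label
#' @param replicates list of `replicate_trial`
#' @param stage_definitions optional list of half-open time intervals
#' @param blank_map optional named list replicate id string -> blank id string
#' @return an `experiment`
#' @export
experiment <- function(label, replicates = list(), stage_definitions = NULL,
                       blank_map = NULL) {
  ids <- vapply(replicates, function(r) serialize_identifier(r$identifier),
                character(1))
  if (anyDuplicated(ids))
    stop("replicate identifiers must be unique within an experiment",
         call. = FALSE)
  structure(list(label = label, replicates = replicates,
                 stage_definitions = stage_definitions,
                 blank_map = blank_map), class = "ferm_experiment")
}

#' @export
print.ferm_experiment <- function(x, ...) {
  np <- sum(vapply(x$replicates, function(r)
    sum(vapply(r$singles, function(s)
      sum(vapply(s$courses, function(co) length(co$times), integer(1))),
      integer(1))), integer(1)))
  cat(sprintf("<experiment> '%s': %d replicate trial(s), %d time point(s)\n",
              x$label, length(x$replicates), np))
  invisible(x)
}

#' Assemble an experiment from a flat stream of time points
#'
#' Groups points by trial identifier and analyte into time courses (sorted by
#' time), trials into replicate trials by replicate-equivalence, and returns a
#' deterministic experiment: replicate trials, singles and courses are ordered
#' lexicographically on serialized identifiers. Duplicate
#' (identifier, analyte, time) triples are averaged over their finite values
#' with a warning (repeated HPLC injections of one sample are common).
#'
#' @param points list of `time_point`; every point must carry `analyte_name`
#'   and `sample_time`
#' @param label experiment label
#' @return a `ferm_experiment`
#' @export
assemble_experiment <- function(points, label = "experiment") {
  if (length(points) == 0L) return(experiment(label))
  for (i in seq_along(points)) {
    idf <- points[[i]]$identifier
    if (is.na(idf$analyte_name) || is.na(idf$sample_time))
      stop(sprintf("point %d is missing analyte_name or sample_time", i),
           call. = FALSE)
  }
  base_keys <- vapply(points, function(p) base_identifier_string(p$identifier),
                      character(1))
  rep_idx <- vapply(points, function(p) {
    ri <- p$identifier$replicate_index
    if (is.na(ri)) 1L else ri
  }, integer(1))
  analytes <- vapply(points, function(p) p$identifier$analyte_name, character(1))
  trial_keys <- paste(base_keys, rep_idx, sep = "\r")

  dup_warned <- FALSE
  reps <- list()
  for (bk in sort(unique(base_keys))) {
    singles <- list()
    for (tk in sort(unique(trial_keys[base_keys == bk]))) {
      sel <- which(trial_keys == tk)
      ri <- rep_idx[sel[1]]
      tid <- points[[sel[1]]]$identifier
      tid$replicate_index <- ri
      tid$sample_time <- NA_real_
      tid$analyte_name <- NA_character_
      courses <- list()
      for (an in sort(unique(analytes[sel]))) {
        asel <- sel[analytes[sel] == an]
        tt <- vapply(points[asel], function(p) p$identifier$sample_time,
                     numeric(1))
        vv <- vapply(points[asel], function(p) p$value, numeric(1))
        unit <- points[[asel[1]]]$unit
        if (anyDuplicated(tt)) {
          dup_warned <- TRUE
          agg <- tapply(vv, tt, function(v) {
            fin <- v[is.finite(v)]
            if (length(fin)) mean(fin) else NA_real_
          })
          tt2 <- as.numeric(names(agg)); vv2 <- as.numeric(agg)
        } else {
          o <- order(tt); tt2 <- tt[o]; vv2 <- vv[o]
        }
        o <- order(tt2)
        cid <- tid; cid$analyte_name <- an; cid$replicate_index <- ri
        courses[[an]] <- analyte_course(cid, tt2[o], vv2[o], unit)
      }
      singles[[length(singles) + 1L]] <- single_trial(tid, courses)
    }
    rep_id <- singles[[1]]$identifier
    rep_id$replicate_index <- NA_integer_
    reps[[length(reps) + 1L]] <- replicate_trial(rep_id, singles)
  }
  if (dup_warned)
    warning("duplicate (identifier, analyte, time) points averaged",
            call. = FALSE)
  experiment(label, reps)
}

#' Query analyte courses of an experiment
#'
#' Returns all courses matching the given filters, in deterministic
#' (lexicographic identifier) order. All filters are optional and combined
#' with AND.
#'
#' @param e a `ferm_experiment`
#' @param analyte_type filter on analyte type
#' @param analyte_name filter on analyte name
#' @param strain filter on strain name
#' @param media filter on media name
#' @param include_blanks keep blank trials? default `TRUE`
#' @param predicate optional function(`trial_identifier`) -> logical
#' @return list of `analyte_course` (possibly empty)
#' @export
query_courses <- function(e, analyte_type = NULL, analyte_name = NULL,
                          strain = NULL, media = NULL, include_blanks = TRUE,
                          predicate = NULL) {
  out <- list()
  for (r in e$replicates) {
    for (s in r$singles) {
      for (co in s$courses) {
        id <- co$identifier
        if (!is.null(analyte_type) && co$analyte_type != analyte_type) next
        if (!is.null(analyte_name) && id$analyte_name != analyte_name) next
        if (!is.null(strain) &&
            (is.na(id$strain$name) || id$strain$name != strain)) next
        if (!is.null(media) &&
            (is.na(id$media$name) || id$media$name != media)) next
        if (!include_blanks && id$is_blank) next
        if (!is.null(predicate) && !isTRUE(predicate(id))) next
        out[[length(out) + 1L]] <- co
      }
    }
  }
  if (length(out) > 1L) {
    keys <- vapply(out, function(co) serialize_identifier(co$identifier),
                   character(1))
    out <- out[order(keys)]
  }
  out
}

#' Total number of stored time points in an experiment
#' @param e a `ferm_experiment`
#' @return integer
#' @export
n_time_points <- function(e) {
  sum(vapply(e$replicates, function(r)
    sum(vapply(r$singles, function(s)
      sum(vapply(s$courses, function(co) length(co$times), integer(1))),
      integer(1))), integer(1)))
}
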