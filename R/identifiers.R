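#' @title Trial identifier grammar
#' @description
#' Every measurement carries its metadata as a flat, typeable string of
#' `key:value` tokens separated by `|`, e.g.
#' `"strain:MG1655|media:M9|strain__plasmid:pTrc99a"`. Nested keys use a
#' double underscore. The grammar is designed so identifiers can be entered
#' directly in the sample-name field of HPLC or plate-reader software and
#' parsed downstream into structured strain / media / environment records.
#'
#' Reserved keys (case-insensitive; values are case-preserving):
#' \itemize{
#'   \item `strain` - strain name; the sentinel name `blank` marks a cell-free
#'     background trial
#'   \item `strain__knockout`, `strain__plasmid` - list keys, may repeat
#'   \item `media` - media name
#'   \item `media__<component>` - component concentration, value `"<conc> <unit>"`
#'   \item `environment__labware`, `environment__temperature`,
#'     `environment__shaking_speed`
#'   \item `experiment`, `rep`, `time`, `analyte`, `blank`
#' }
#' Unknown keys are retained verbatim in an auxiliary `extras` map with a
#' warning. Values may not contain `|` or `:` (no escaping).
#' @name identifier-grammar
NULL

#' Strain, media and environment records
#'
#' Constructors for the three structured components of a trial identifier:
#' the strain (parent name plus knockouts and plasmids), the media (name plus
#' a component map `name -> list(concentration, unit)`) and the culture
#' environment (labware, temperature in degrees C, shaking speed in rpm).
#' Absent fields are `NA`.
#'
#' @param name strain or media name
#' @param knockouts character vector of knocked-out genes (order-preserving)
#' @param plasmids character vector of plasmid names
#' @return `new_strain`: a `ferm_strain`
#' @export
new_strain <- function(name = NA_character_, knockouts = character(),
                       plasmids = character()) {
  structure(list(name = name, knockouts = knockouts, plasmids = plasmids),
            class = "ferm_strain")
}

#' @rdname new_strain
#' @param components named list of `list(concentration, unit)` entries
#' @return `new_media`: a `ferm_media`
#' @export
new_media <- function(name = NA_character_, components = list()) {
  structure(list(name = name, components = components), class = "ferm_media")
}

#' @rdname new_strain
#' @param labware vessel type, e.g. `"flask"` or `"plate96"`
#' @param temperature culture temperature, degrees C
#' @param shaking_speed shaking speed, rpm (>= 0)
#' @return `new_environment_info`: a `ferm_environment`
#' @export
new_environment_info <- function(labware = NA_character_,
                                 temperature = NA_real_,
                                 shaking_speed = NA_real_) {
  structure(list(labware = labware, temperature = temperature,
                 shaking_speed = shaking_speed), class = "ferm_environment")
}

#' Construct a trial identifier
#'
#' @param strain a `ferm_strain` (name, knockouts, plasmids)
#' @param media a `ferm_media` (name, component map)
#' @param environment a `ferm_environment` (labware, temperature, shaking speed)
#' @param experiment_label experiment grouping label, or `NA`
#' @param replicate_index positive integer replicate number, or `NA`
#' @param sample_time sample time in hours, or `NA`
#' @param analyte_name analyte the datum belongs to, or `NA`
#' @param is_blank `TRUE` for cell-free background trials
#' @param extras named character vector of unrecognized keys carried verbatim
#' @return an object of class `trial_identifier`
#' @export
trial_identifier <- function(strain = new_strain(), media = new_media(),
                             environment = new_environment_info(),
                             experiment_label = NA_character_,
                             replicate_index = NA_integer_,
                             sample_time = NA_real_,
                             analyte_name = NA_character_,
                             is_blank = FALSE,
                             extras = character()) {
  if (!is.na(replicate_index)) {
    replicate_index <- as.integer(replicate_index)
    stopifnot(replicate_index >= 1L)
  }
  if (!is.na(sample_time)) stopifnot(is.finite(sample_time), sample_time >= 0)
  structure(list(strain = strain, media = media, environment = environment,
                 experiment_label = experiment_label,
                 replicate_index = replicate_index,
                 sample_time = sample_time,
                 analyte_name = analyte_name,
                 is_blank = isTRUE(is_blank),
                 extras = extras),
            class = "trial_identifier")
}

#' @export
print.trial_identifier <- function(x, ...) {
  cat("<trial_identifier> ", serialize_identifier(x), "\n", sep = "")
  invisible(x)
}

scalar_id_keys <- c("strain", "media", "experiment", "rep", "time", "analyte",
                    "blank", "environment__labware",
                    "environment__temperature", "environment__shaking_speed")
list_id_keys <- c("strain__knockout", "strain__plasmid")

#' Parse a flat trial-identifier string
#'
#' Splits `s` on `|` into `key:value` tokens (whitespace-trimmed, keys
#' lowercased) and maps the reserved keys into a structured
#' [trial_identifier()]. List keys (`strain__knockout`, `strain__plasmid`)
#' may repeat and append in order; scalar keys repeated with conflicting
#' values are an error. `strain:blank` or `blank:true` marks a blank trial.
#'
#' @param s non-empty identifier string
#' @return a `trial_identifier`
#' @examples
#' parse_identifier("strain:MG1655|media:M9|strain__plasmid:pTrc99a")
#' @export
parse_identifier <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s) || !nzchar(trimws(s)))
    stop("identifier string is empty", call. = FALSE)
  tokens <- trimws(strsplit(s, "|", fixed = TRUE)[[1]])
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) stop("identifier string is empty", call. = FALSE)

  strain <- new_strain(); media <- new_media(); env <- new_environment_info()
  experiment_label <- NA_character_; replicate_index <- NA_integer_
  sample_time <- NA_real_; analyte_name <- NA_character_; is_blank <- FALSE
  extras <- character(); seen <- character()

  for (tok in tokens) {
    parts <- strsplit(tok, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop(sprintf("malformed identifier token '%s' (expected key:value)", tok),
           call. = FALSE)
    key <- tolower(trimws(parts[1])); val <- trimws(parts[2])
    if (!nzchar(key) || !nzchar(val))
      stop(sprintf("malformed identifier token '%s' (expected key:value)", tok),
           call. = FALSE)

    if (key %in% scalar_id_keys || startsWith(key, "media__")) {
      prev <- seen[match(key, names(seen), nomatch = 0L)]
      if (length(prev) == 1L && !identical(unname(prev), val))
        stop(sprintf("duplicate key '%s' with conflicting values ('%s' vs '%s')",
                     key, prev, val), call. = FALSE)
      seen[key] <- val
    }

    if (key == "strain") {
      strain$name <- val
      if (tolower(val) == "blank") is_blank <- TRUE
    } else if (key == "strain__knockout") {
      if (!val %in% strain$knockouts)
        strain$knockouts <- c(strain$knockouts, val)
    } else if (key == "strain__plasmid") {
      if (!val %in% strain$plasmids)
        strain$plasmids <- c(strain$plasmids, val)
    } else if (key == "media") {
      media$name <- val
    } else if (startsWith(key, "media__")) {
      comp <- sub("^media__", "", key)
      cv <- parse_component_value(val, key)
      media$components[[comp]] <- cv
    } else if (key == "environment__labware") {
      env$labware <- val
    } else if (key == "environment__temperature") {
      env$temperature <- parse_num(val, key)
    } else if (key == "environment__shaking_speed") {
      env$shaking_speed <- parse_num(val, key)
      if (env$shaking_speed < 0)
        stop("shaking_speed must be >= 0", call. = FALSE)
    } else if (key == "experiment") {
      experiment_label <- val
    } else if (key == "rep") {
      replicate_index <- as.integer(parse_num(val, key))
      if (is.na(replicate_index) || replicate_index < 1L)
        stop("rep must be a positive integer", call. = FALSE)
    } else if (key == "time") {
      sample_time <- parse_num(val, key)
      if (sample_time < 0) stop("time must be >= 0 hours", call. = FALSE)
    } else if (key == "analyte") {
      analyte_name <- val
    } else if (key == "blank") {
      if (tolower(val) %in% c("true", "1", "yes")) is_blank <- TRUE
    } else {
      warning(sprintf("unknown identifier key '%s' retained verbatim", key),
              call. = FALSE)
      extras[key] <- val
    }
  }
  trial_identifier(strain, media, env, experiment_label, replicate_index,
                   sample_time, analyte_name, is_blank, extras)
}

parse_num <- function(val, key) {
  x <- suppressWarnings(as.numeric(val))
  if (is.na(x))
    stop(sprintf("value '%s' for key '%s' is not numeric", val, key),
         call. = FALSE)
  x
}

parse_component_value <- function(val, key) {
  # "<conc> <unit>", unit optional
  bits <- strsplit(trimws(val), "\\s+")[[1]]
  conc <- suppressWarnings(as.numeric(bits[1]))
  if (is.na(conc) || conc < 0)
    stop(sprintf("component '%s' needs a nonnegative concentration, got '%s'",
                 key, val), call. = FALSE)
  unit <- if (length(bits) > 1L) paste(bits[-1], collapse = " ") else ""
  list(concentration = conc, unit = unit)
}

fmt_num <- function(x) {
  # canonical numeric formatting: no trailing zeros, up to 15 significant digits
  format(x, trim = TRUE, scientific = FALSE, digits = 15)
}

#' Serialize a trial identifier to its canonical flat string
#'
#' Emits tokens in canonical order (strain, knockouts, plasmids, media, media
#' components, environment, experiment, rep, time, analyte, blank, extras);
#' absent fields are omitted. `parse_identifier(serialize_identifier(t))`
#' reproduces `t` for any valid identifier.
#'
#' @param t a `trial_identifier`
#' @return a flat identifier string
#' @export
serialize_identifier <- function(t) {
  stopifnot(inherits(t, "trial_identifier"))
  toks <- character()
  add <- function(key, val) toks[[length(toks) + 1L]] <<- paste0(key, ":", val)
  if (!is.na(t$strain$name)) add("strain", t$strain$name)
  for (k in t$strain$knockouts) add("strain__knockout", k)
  for (p in t$strain$plasmids) add("strain__plasmid", p)
  if (!is.na(t$media$name)) add("media", t$media$name)
  for (comp in sort(names(t$media$components))) {
    cv <- t$media$components[[comp]]
    val <- if (nzchar(cv$unit)) paste(fmt_num(cv$concentration), cv$unit)
           else fmt_num(cv$concentration)
    add(paste0("media__", comp), val)
  }
  if (!is.na(t$environment$labware)) add("environment__labware", t$environment$labware)
  if (!is.na(t$environment$temperature))
    add("environment__temperature", fmt_num(t$environment$temperature))
  if (!is.na(t$environment$shaking_speed))
    add("environment__shaking_speed", fmt_num(t$environment$shaking_speed))
  if (!is.na(t$experiment_label)) add("experiment", t$experiment_label)
  if (!is.na(t$replicate_index)) add("rep", fmt_num(t$replicate_index))
  if (!is.na(t$sample_time)) add("time", fmt_num(t$sample_time))
  if (!is.na(t$analyte_name)) add("analyte", t$analyte_name)
  if (t$is_blank && !identical(tolower(t$strain$name), "blank"))
    add("blank", "true")
  for (k in sort(names(t$extras))) add(k, t$extras[[k]])
  paste(toks, collapse = "|")
}

#' Replicate-equivalence of trial identifiers
#'
#' Two identifiers describe replicates of the same condition iff all fields
#' except `replicate_index`, `sample_time` and `analyte_name` are equal.
#'
#' @param a,b `trial_identifier` objects
#' @return logical
#' @export
replicate_equivalent <- function(a, b) {
  identical(base_identifier_string(a), base_identifier_string(b))
}

#' Serialized identifier with replicate/time/analyte fields stripped
#'
#' The grouping key for replicate-equivalence: the canonical serialization of
#' the identifier after removing `replicate_index`, `sample_time` and
#' `analyte_name`.
#'
#' @param t a `trial_identifier`
#' @return a string
#' @export
base_identifier_string <- function(t) {
  t$replicate_index <- NA_integer_
  t$sample_time <- NA_real_
  t$analyte_name <- NA_character_
  serialize_identifier(t)
}

#' Expand a shorthand identifier via a registry
#'
#' If the first `|`-token of `s` matches a registry key, the registered full
#' identifier string is merged with any extra inline tokens from `s`; inline
#' tokens win on key conflict. Otherwise `s` is returned unchanged.
#'
#' @param s identifier string, possibly starting with a shorthand name
#' @param registry named character vector, shorthand -> full identifier string
#' @return a flat identifier string
#' @examples
#' expand_shorthand("STRAIN7|rep:1", c(STRAIN7 = "strain:MG1655|media:M9"))
#' @export
expand_shorthand <- function(s, registry) {
  stopifnot(is.character(s), length(s) == 1L)
  if (length(registry) == 0L) return(s)
  toks <- trimws(strsplit(s, "|", fixed = TRUE)[[1]])
  key <- toks[1]
  if (!key %in% names(registry)) return(s)
  full <- registry[[key]]
  base <- tryCatch(parse_identifier(full), error = function(e)
    stop(sprintf("shorthand '%s' resolves to unparseable string '%s': %s",
                 key, full, conditionMessage(e)), call. = FALSE))
  inline <- toks[-1]
  if (length(inline) == 0L) return(serialize_identifier(base))
  # merge: parse base tokens and inline tokens, inline wins per key
  base_toks <- trimws(strsplit(full, "|", fixed = TRUE)[[1]])
  key_of <- function(tok) tolower(trimws(strsplit(tok, ":", fixed = TRUE)[[1]][1]))
  inline_keys <- vapply(inline, key_of, character(1))
  keep <- vapply(base_toks, function(tok) {
    k <- key_of(tok)
    !(k %in% scalar_id_keys || startsWith(k, "media__")) || !(k %in% inline_keys)
  }, logical(1))
  merged <- paste(c(base_toks[keep], inline), collapse = "|")
  serialize_identifier(parse_identifier(merged))
}

#' Read a shorthand registry file
#'
#' Two-column UTF-8 CSV `shorthand,identifier` with a header row.
#'
#' @param path CSV file path
#' @return named character vector mapping shorthand -> identifier string
#' @export
read_shorthand_registry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("shorthand", "identifier")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("registry file missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  stats::setNames(as.character(df$identifier), as.character(df$shorthand))
}
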