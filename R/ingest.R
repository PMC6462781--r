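#' @title Raw-data ingest
#' @description
#' Readers for the three tabular dialects that cover most fermentation
#' workflows: the canonical tidy long table, the HPLC-style wide table (one
#' row per injection, identifier string embedding the sample time), and the
#' plate-reader matrix (time x wells) paired with a plate-layout map. All
#' readers emit flat `time_point` streams for [assemble_experiment()];
#' [write_tidy_long()] is the inverse of the tidy reader. CSV is the
#' canonical format; `.xlsx` files are read from their first sheet when the
#' readxl package is available. Missing values are an empty cell or the
#' literal `nan` (case-insensitive).
#' @name ingest
NULL

read_table_auto <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading .xlsx requires the readxl package", call. = FALSE)
    df <- as.data.frame(readxl::read_excel(path, sheet = 1,
                                           col_types = "text"),
                        stringsAsFactors = FALSE)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  }
  df
}

# empty cell or literal nan (any case) -> NA; otherwise numeric or NA+flag
cell_to_value <- function(x) {
  x <- trimws(x)
  if (is.na(x) || !nzchar(x) || tolower(x) %in% c("nan", "na")) return(NA_real_)
  suppressWarnings(as.numeric(x))
}

#' Read a tidy long analyte table
#'
#' The canonical interchange format: columns
#' `trial_identifier,analyte_name,time_h,value,unit`, one row per time point.
#' Empty or `nan` value cells become missing observations.
#'
#' @param path CSV (or XLSX) file
#' @return list of `time_point`
#' @export
read_tidy_long <- function(path) {
  df <- read_table_auto(path)
  need <- c("trial_identifier", "analyte_name", "time_h", "value", "unit")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("tidy long file missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  points <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    tm <- cell_to_value(df$time_h[i])
    if (is.na(tm))
      stop(sprintf("row %d: unparseable time '%s'", i, df$time_h[i]),
           call. = FALSE)
    id <- parse_identifier(df$trial_identifier[i])
    id$analyte_name <- df$analyte_name[i]
    id$sample_time <- tm
    points[[i]] <- time_point(id, cell_to_value(df$value[i]), df$unit[i])
  }
  points
}

#' Read an HPLC-style wide table
#'
#' One row per injection: a `sample` column holding the flat identifier
#' (which must embed a `time:` key) followed by one column per analyte. Each
#' finite cell yields one time point; empty cells are skipped. Repeated
#' injections of the same sample produce duplicate triples that
#' [assemble_experiment()] later averages.
#'
#' @param path CSV (or XLSX) file
#' @param units optional named character vector analyte -> unit (default
#'   `"g/L"` for all)
#' @return list of `time_point`
#' @export
read_hplc_wide <- function(path, units = NULL) {
  df <- read_table_auto(path)
  if (!"sample" %in% names(df))
    stop("HPLC wide file must have a 'sample' column", call. = FALSE)
  analytes <- setdiff(names(df), "sample")
  if (length(analytes) == 0L)
    stop("HPLC wide file has no analyte columns", call. = FALSE)
  points <- list()
  for (i in seq_len(nrow(df))) {
    id <- parse_identifier(df$sample[i])
    if (is.na(id$sample_time))
      stop(sprintf("row %d: sample identifier lacks a time: key", i),
           call. = FALSE)
    for (an in analytes) {
      v <- cell_to_value(df[[an]][i])
      raw <- trimws(df[[an]][i])
      if (is.na(v) && (is.na(raw) || !nzchar(raw))) next  # empty cell: skip
      aid <- id
      aid$analyte_name <- an
      unit <- if (!is.null(units) && an %in% names(units)) units[[an]] else "g/L"
      points[[length(points) + 1L]] <- time_point(aid, v, unit)
    }
  }
  points
}

#' Read a plate-layout map
#'
#' Two-column CSV `well,identifier` mapping well labels (A1..P24) to flat
#' identifier strings.
#'
#' @param path CSV file
#' @return named character vector well -> identifier string
#' @export
read_plate_layout <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(c("well", "identifier"), names(df))
  if (length(miss))
    stop(sprintf("plate layout missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  wells <- trimws(df$well)
  bad <- wells[!grepl("^[A-P][0-9]{1,2}$", wells)]
  if (length(bad))
    stop(sprintf("invalid well label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  for (i in seq_along(wells)) {
    tryCatch(parse_identifier(df$identifier[i]), error = function(e)
      stop(sprintf("layout identifier for well %s unparseable: %s",
                   wells[i], conditionMessage(e)), call. = FALSE))
  }
  stats::setNames(df$identifier, wells)
}

#' Read a plate-reader matrix
#'
#' First column is time, remaining columns are well labels. Each finite cell
#' yields one time point whose identifier comes from the layout; the analyte
#' name is the layout identifier's `analyte` key, defaulting to `"OD600"`.
#' Wells present in the data but absent from the layout are skipped with a
#' warning.
#'
#' @param path CSV (or XLSX) file
#' @param layout named character vector well -> identifier string (see
#'   [read_plate_layout()])
#' @param time_unit `"h"` (default), `"min"` or `"s"`; times are rescaled to
#'   hours
#' @param unit value unit annotation, default `"OD"`
#' @return list of `time_point`
#' @export
read_plate_matrix <- function(path, layout, time_unit = c("h", "min", "s"),
                              unit = "OD") {
  time_unit <- match.arg(time_unit)
  scale <- switch(time_unit, h = 1, min = 1 / 60, s = 1 / 3600)
  df <- read_table_auto(path)
  if (ncol(df) < 1L) stop("plate matrix is empty", call. = FALSE)
  wells <- names(df)[-1]
  unknown <- setdiff(wells, names(layout))
  if (length(unknown))
    warning(sprintf("well(s) absent from layout skipped: %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  ids <- lapply(layout[intersect(wells, names(layout))], parse_identifier)
  points <- list()
  for (i in seq_len(nrow(df))) {
    tm <- cell_to_value(df[[1]][i])
    if (is.na(tm))
      stop(sprintf("row %d: non-numeric time cell '%s'", i, df[[1]][i]),
           call. = FALSE)
    tm <- tm * scale
    for (w in names(ids)) {
      v <- cell_to_value(df[[w]][i])
      raw <- trimws(df[[w]][i])
      if (is.na(v) && (is.na(raw) || !nzchar(raw))) next
      id <- ids[[w]]
      if (is.na(id$analyte_name)) id$analyte_name <- "OD600"
      id$sample_time <- tm
      points[[length(points) + 1L]] <- time_point(id, v, unit)
    }
  }
  points
}

#' Write an experiment as a tidy long CSV
#'
#' One row per stored time point with canonical identifier serialization and
#' missing values written as `nan`, in deterministic row order. Inverse of
#' [read_tidy_long()] + [assemble_experiment()].
#'
#' @param e a `ferm_experiment`
#' @param path output CSV path
#' @return number of data rows written, invisibly
#' @export
write_tidy_long <- function(e, path) {
  rows <- experiment_to_tidy(e)
  utils::write.csv(rows, path, row.names = FALSE, quote = TRUE, na = "nan")
  invisible(nrow(rows))
}

#' Flatten an experiment to a tidy long data frame
#'
#' @param e a `ferm_experiment`
#' @return data frame with columns
#'   `trial_identifier,analyte_name,time_h,value,unit`
#' @export
experiment_to_tidy <- function(e) {
  recs <- list()
  for (r in e$replicates) {
    for (s in r$singles) {
      for (an in sort(names(s$courses))) {
        co <- s$courses[[an]]
        tid <- s$identifier
        recs[[length(recs) + 1L]] <- data.frame(
          trial_identifier = serialize_identifier(tid),
          analyte_name = an,
          time_h = co$times,
          value = co$values,
          unit = co$unit,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(recs) == 0L)
    return(data.frame(trial_identifier = character(), analyte_name = character(),
                      time_h = numeric(), value = numeric(), unit = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, recs)
  out[order(out$trial_identifier, out$analyte_name, out$time_h), , drop = FALSE]
}

#' Convert tidy rows to time points
#'
#' Accepts the data-frame form produced by [experiment_to_tidy()] or the
#' synthetic generator and returns the `time_point` stream the assembler
#' consumes.
#'
#' @param df data frame with columns
#'   `trial_identifier,analyte_name,time_h,value,unit`
#' @return list of `time_point`
#' @export
tidy_to_points <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    id <- parse_identifier(df$trial_identifier[i])
    id$analyte_name <- df$analyte_name[i]
    id$sample_time <- as.numeric(df$time_h[i])
    time_point(id, as.numeric(df$value[i]), df$unit[i])
  })
}
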