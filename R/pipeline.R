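#' @title Analysis pipeline and visualization
#' @description
#' Ties the modules together in the canonical order: read raw data ->
#' assemble the hierarchy -> assign and subtract blanks -> screen outlier
#' replicates -> compute requested features -> plot / export / store. The
#' same entry point backs the command-line interface.
#' @name pipeline
NULL

#' Pipeline run configuration
#'
#' @param input path to the raw data file
#' @param dialect `"tidy"`, `"hplc"` or `"plate"`
#' @param layout plate-layout CSV path (plate dialect only)
#' @param registry shorthand-registry CSV path, optional
#' @param features character vector of registered feature names to compute
#' @param tau outlier aggressiveness threshold (> 0)
#' @param stage_boundaries optional stage boundary times
#' @param blank_correction apply automatic blank assignment/subtraction?
#' @param store optional SQLite store path to save into
#' @param out_dir output directory for plots and exports
#' @param label experiment label
#' @param time_unit plate time unit: `"h"`, `"min"` or `"s"`
#' @return a `run_config`
#' @export
run_config <- function(input, dialect = c("tidy", "hplc", "plate"),
                       layout = NULL, registry = NULL,
                       features = "replicate_statistics", tau = 0.5,
                       stage_boundaries = NULL, blank_correction = FALSE,
                       store = NULL, out_dir = NULL, label = "experiment",
                       time_unit = "h") {
  dialect <- match.arg(dialect)
  stopifnot(tau > 0)
  structure(list(input = input, dialect = dialect, layout = layout,
                 registry = registry, features = features, tau = tau,
                 stage_boundaries = stage_boundaries,
                 blank_correction = blank_correction, store = store,
                 out_dir = out_dir, label = label, time_unit = time_unit),
            class = "run_config")
}

#' Run the analysis pipeline
#'
#' Executes read -> assemble -> blank correction -> outlier screening ->
#' features -> export/store and returns a summary of what happened. Any
#' stage failure aborts before the store is touched.
#'
#' @param cfg a [run_config()]
#' @return a `run_summary`: list with `n_points`, `n_replicate_trials`,
#'   `flagged` (outlier indices per replicate trial), `features` (computed
#'   results), `warnings`, `outputs` (files written), and the final
#'   `experiment`
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  warn_log <- character()
  collect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warn_log <<- c(warn_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  points <- collect(switch(cfg$dialect,
    tidy = read_tidy_long(cfg$input),
    hplc = read_hplc_wide(cfg$input),
    plate = {
      if (is.null(cfg$layout))
        stop("plate dialect requires a layout file", call. = FALSE)
      read_plate_matrix(cfg$input, read_plate_layout(cfg$layout),
                        time_unit = cfg$time_unit)
    }))
  if (length(points) == 0L) stop("no data points", call. = FALSE)

  if (!is.null(cfg$registry)) {
    reg <- read_shorthand_registry(cfg$registry)
    points <- lapply(points, function(p) {
      expanded <- expand_shorthand(serialize_identifier(p$identifier), reg)
      p$identifier <- parse_identifier(expanded)
      p
    })
  }

  e <- collect(assemble_experiment(points, cfg$label))
  n_points <- n_time_points(e)

  if (cfg$blank_correction) e <- collect(apply_blank_correction(e))
  if (!is.null(cfg$stage_boundaries))
    e <- collect(slice_stages(e, cfg$stage_boundaries))

  flagged <- list()
  for (r in e$replicates) {
    for (an in analyte_names(r)) {
      fl <- detect_outlier_replicates(r, an, tau = cfg$tau)
      if (length(fl))
        flagged[[serialize_identifier(r$identifier)]] <-
          sort(unique(c(flagged[[serialize_identifier(r$identifier)]], fl)))
    }
  }
  if (length(flagged)) {
    reps <- lapply(e$replicates, function(r) {
      rid <- serialize_identifier(r$identifier)
      if (rid %in% names(flagged)) exclude_replicates(r, flagged[[rid]]) else r
    })
    e <- experiment(e$label, reps, e$stage_definitions, e$blank_map)
  }

  feats <- list()
  for (fname in cfg$features) {
    reg <- get_feature(fname)
    if (reg$level == "replicate" && fname == "replicate_statistics") {
      feats[[fname]] <- lapply(
        stats::setNames(e$replicates,
                        vapply(e$replicates, function(r)
                          serialize_identifier(r$identifier), character(1))),
        replicate_statistics)
    } else {
      feats[[fname]] <- reg  # non-statistics features need per-call arguments
    }
  }

  outputs <- character()
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    export <- file.path(cfg$out_dir, "experiment_tidy.csv")
    write_tidy_long(e, export)
    outputs <- c(outputs, export)
  }
  if (!is.null(cfg$store)) {
    save_experiment(e, cfg$store)
    outputs <- c(outputs, cfg$store)
  }

  structure(list(n_points = n_points,
                 n_replicate_trials = length(e$replicates),
                 flagged = flagged, features = feats,
                 warnings = warn_log, outputs = outputs, experiment = e),
            class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf("pipeline: %d points read, %d replicate trial(s)\n",
              x$n_points, x$n_replicate_trials))
  if (length(x$flagged))
    cat(sprintf("outlier replicates flagged in %d trial(s)\n",
                length(x$flagged)))
  if (length(x$warnings))
    cat(sprintf("%d warning(s):\n  %s\n", length(x$warnings),
                paste(x$warnings, collapse = "\n  ")))
  if (length(x$outputs))
    cat("outputs:", paste(x$outputs, collapse = ", "), "\n")
  invisible(x)
}

#' Plot replicate-mean time courses per analyte
#'
#' One subplot per analyte; within each subplot one mean line per strain with
#' a +-1 standard deviation band shaded where the deviation is defined (at
#' least two observations). Writes a vector (PDF) and a raster (PNG) file
#' with deterministic names.
#'
#' @param e a `ferm_experiment`
#' @param analytes analyte names to plot (default: all present)
#' @param out_dir output directory
#' @param basename file basename, default `"timecourses"`
#' @return character vector of files written
#' @export
plot_timecourses <- function(e, analytes = NULL, out_dir = ".",
                             basename = "timecourses") {
  all_an <- sort(unique(unlist(lapply(e$replicates, analyte_names))))
  if (is.null(analytes)) analytes <- all_an
  if (length(analytes) == 0L) {
    warning("no analytes to plot", call. = FALSE)
    return(character())
  }
  unknown <- setdiff(analytes, all_an)
  if (length(unknown))
    stop(sprintf("unknown analyte(s): %s; available: %s",
                 paste(unknown, collapse = ", "),
                 paste(all_an, collapse = ", ")), call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(file.path(out_dir, paste0(basename, ".pdf")),
             file.path(out_dir, paste0(basename, ".png")))

  draw <- function() {
    nc <- min(length(analytes), 3L)
    nr <- ceiling(length(analytes) / nc)
    op <- graphics::par(mfrow = c(nr, nc), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(op), add = TRUE)
    for (an in analytes) {
      reps <- Filter(function(r) an %in% analyte_names(r), e$replicates)
      stats_by <- lapply(reps, function(r) replicate_statistics(r, an)[[an]])
      strains <- vapply(reps, function(r) {
        nm <- r$identifier$strain$name
        if (is.na(nm)) "?" else nm
      }, character(1))
      cols <- grDevices::hcl.colors(max(length(reps), 2L), "Dark 2")
      xlim <- range(unlist(lapply(stats_by, `[[`, "times")))
      yy <- unlist(lapply(stats_by, function(s)
        c(s$mean - ifelse(is.na(s$std), 0, s$std),
          s$mean + ifelse(is.na(s$std), 0, s$std))))
      ylim <- range(yy, na.rm = TRUE)
      graphics::plot(NA, xlim = xlim, ylim = ylim, xlab = "time (h)",
                     ylab = stats_by[[1]]$unit, main = an)
      for (i in seq_along(stats_by)) {
        s <- stats_by[[i]]
        band <- !is.na(s$std) & !is.na(s$mean)
        if (sum(band) >= 2) {
          bt <- s$times[band]
          graphics::polygon(c(bt, rev(bt)),
                            c(s$mean[band] - s$std[band],
                              rev(s$mean[band] + s$std[band])),
                            col = grDevices::adjustcolor(cols[i], 0.25),
                            border = NA)
        }
        ok <- !is.na(s$mean)
        graphics::lines(s$times[ok], s$mean[ok], col = cols[i], lwd = 2)
        graphics::points(s$times[ok], s$mean[ok], col = cols[i], pch = 16)
      }
      graphics::legend("topleft", legend = strains, col = cols[seq_along(reps)],
                       lwd = 2, bty = "n", cex = 0.8)
    }
  }
  grDevices::pdf(files[1], width = 4 * min(length(analytes), 3),
                 height = 3.2 * ceiling(length(analytes) / 3))
  draw()
  grDevices::dev.off()
  grDevices::png(files[2], width = 480 * min(length(analytes), 3),
                 height = 380 * ceiling(length(analytes) / 3), res = 110)
  draw()
  grDevices::dev.off()
  files
}
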