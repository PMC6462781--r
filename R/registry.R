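#' @title Feature registry
#' @description
#' Features self-register under a name and a hierarchy level so pipelines
#' (and the command line) can select them by name; new features are added by
#' registering a function, without touching the pipeline code.
#' @name feature-registry
NULL

.feature_registry <- new.env(parent = emptyenv())

#' Register a named feature
#'
#' @param name feature name
#' @param level hierarchy level: `"analyte"`, `"trial"`, `"replicate"` or
#'   `"experiment"`
#' @param fn the feature function
#' @return invisibly, the previous registration (or NULL)
#' @export
register_feature <- function(name, level, fn) {
  level <- match.arg(level, c("analyte", "trial", "replicate", "experiment"))
  prev <- .feature_registry[[name]]
  assign(name, list(name = name, level = level, fn = fn),
         envir = .feature_registry)
  invisible(prev)
}

#' List registered features
#' @param level optional level filter
#' @return data frame with columns `name`, `level`
#' @export
list_features <- function(level = NULL) {
  entries <- mget(ls(.feature_registry), envir = .feature_registry)
  if (!is.null(level)) entries <- Filter(function(e) e$level == level, entries)
  nm <- vapply(entries, `[[`, character(1), "name")
  lv <- vapply(entries, `[[`, character(1), "level")
  df <- data.frame(name = unname(nm), level = unname(lv),
                   stringsAsFactors = FALSE)
  df[order(df$level, df$name), , drop = FALSE]
}

#' Fetch a registered feature
#' @param name feature name
#' @return the registration (name, level, fn)
#' @export
get_feature <- function(name) {
  if (!exists(name, envir = .feature_registry))
    stop(sprintf("unknown feature '%s'; registered: %s", name,
                 paste(ls(.feature_registry), collapse = ", ")),
         call. = FALSE)
  get(name, envir = .feature_registry)
}

register_builtin_features <- function() {
  register_feature("gradient", "analyte", gradient)
  register_feature("fit_growth_model", "analyte", fit_growth_model)
  register_feature("compute_yield", "trial", compute_yield)
  register_feature("specific_rate", "trial", specific_rate)
  register_feature("normalize_to_biomass", "trial", normalize_to_biomass)
  register_feature("replicate_statistics", "replicate", replicate_statistics)
  register_feature("detect_outlier_replicates", "replicate",
                   detect_outlier_replicates)
  register_feature("subtract_blank", "experiment", subtract_blank)
  register_feature("assign_blanks", "experiment", assign_blanks)
  register_feature("slice_stages", "experiment", slice_stages)
}

.onLoad <- function(libname, pkgname) {
  register_builtin_features()
}
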