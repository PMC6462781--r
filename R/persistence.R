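#' @title Relational persistence
#' @description
#' Experiments are stored in a single-file SQLite database so they can be
#' shared and queried without any server setup. The layout normalizes the
#' hierarchy: `experiments`, `replicate_trials` (with normalized `strains`,
#' `media`, `environments` lookups), `single_trials`, `analyte_courses` and
#' `time_points`, plus an `experiment_membership` link table so one
#' replicate trial can belong to several experiments. Saves are idempotent
#' upserts keyed on serialized identifiers; missing observations are stored
#' as SQL NULL and restored as `NA`. Computed features are never persisted;
#' they are cheap to recompute and would go stale.
#' @name persistence
NULL

schema_version <- 1L

store_ddl <- c(
  "CREATE TABLE IF NOT EXISTS schema_version (version INTEGER NOT NULL)",
  "CREATE TABLE IF NOT EXISTS experiments (
     id INTEGER PRIMARY KEY, label TEXT UNIQUE NOT NULL)",
  "CREATE TABLE IF NOT EXISTS strains (
     id INTEGER PRIMARY KEY, name TEXT, knockouts TEXT, plasmids TEXT,
     UNIQUE(name, knockouts, plasmids))",
  "CREATE TABLE IF NOT EXISTS media (
     id INTEGER PRIMARY KEY, name TEXT, components TEXT,
     UNIQUE(name, components))",
  "CREATE TABLE IF NOT EXISTS environments (
     id INTEGER PRIMARY KEY, labware TEXT, temperature REAL,
     shaking_speed REAL, UNIQUE(labware, temperature, shaking_speed))",
  "CREATE TABLE IF NOT EXISTS replicate_trials (
     id INTEGER PRIMARY KEY, identifier TEXT UNIQUE NOT NULL,
     strain_id INTEGER REFERENCES strains(id),
     media_id INTEGER REFERENCES media(id),
     environment_id INTEGER REFERENCES environments(id),
     is_blank INTEGER NOT NULL DEFAULT 0)",
  "CREATE TABLE IF NOT EXISTS experiment_membership (
     experiment_id INTEGER NOT NULL REFERENCES experiments(id),
     replicate_id INTEGER NOT NULL REFERENCES replicate_trials(id),
     UNIQUE(experiment_id, replicate_id))",
  "CREATE TABLE IF NOT EXISTS single_trials (
     id INTEGER PRIMARY KEY, replicate_id INTEGER NOT NULL
       REFERENCES replicate_trials(id),
     replicate_index INTEGER, identifier TEXT NOT NULL,
     UNIQUE(replicate_id, replicate_index))",
  "CREATE TABLE IF NOT EXISTS analyte_courses (
     id INTEGER PRIMARY KEY, trial_id INTEGER NOT NULL
       REFERENCES single_trials(id),
     analyte_name TEXT NOT NULL, analyte_type TEXT NOT NULL, unit TEXT,
     UNIQUE(trial_id, analyte_name))",
  "CREATE TABLE IF NOT EXISTS time_points (
     course_id INTEGER NOT NULL REFERENCES analyte_courses(id),
     time_h REAL NOT NULL, value REAL,
     UNIQUE(course_id, time_h))"
)

open_store <- function(path) {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  for (sql in store_ddl) DBI::dbExecute(con, sql)
  ver <- DBI::dbGetQuery(con, "SELECT version FROM schema_version")$version
  if (length(ver) == 0L) {
    DBI::dbExecute(con, "INSERT INTO schema_version VALUES (:v)",
                   params = list(v = schema_version))
  } else if (ver[1] != schema_version) {
    DBI::dbDisconnect(con)
    stop(sprintf("store schema version %d does not match package version %d",
                 ver[1], schema_version), call. = FALSE)
  }
  con
}

lookup_or_insert <- function(con, table, fields, counts) {
  where <- paste(sprintf("%s IS :%s", names(fields), names(fields)),
                 collapse = " AND ")
  row <- DBI::dbGetQuery(con,
    sprintf("SELECT id FROM %s WHERE %s", table, where), params = fields)
  if (nrow(row)) return(list(id = row$id[1], counts = counts))
  DBI::dbExecute(con, sprintf("INSERT INTO %s (%s) VALUES (%s)", table,
                              paste(names(fields), collapse = ", "),
                              paste0(":", names(fields), collapse = ", ")),
                 params = fields)
  counts[table] <- counts[table] + 1L
  id <- DBI::dbGetQuery(con, "SELECT last_insert_rowid() AS id")$id[1]
  list(id = id, counts = counts)
}

#' Save an experiment to a relational store
#'
#' Idempotent: re-saving the same experiment inserts nothing and reports zero
#' counts. The whole save runs in one transaction; any failure leaves the
#' store untouched.
#'
#' @param e a `ferm_experiment`
#' @param path SQLite file path (created if absent)
#' @return named integer vector of rows inserted per table
#' @export
save_experiment <- function(e, path) {
  con <- open_store(path)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  DBI::dbExecute(con, "BEGIN")
  ok <- FALSE
  on.exit(if (!ok) DBI::dbExecute(con, "ROLLBACK"), add = TRUE)
  counts <- stats::setNames(
    integer(8), c("experiments", "strains", "media", "environments",
                  "replicate_trials", "single_trials", "analyte_courses",
                  "time_points"))

  res <- lookup_or_insert(con, "experiments", list(label = e$label), counts)
  exp_id <- res$id; counts <- res$counts

  for (r in e$replicates) {
    id <- r$identifier
    res <- lookup_or_insert(con, "strains",
      list(name = id$strain$name,
           knockouts = paste(id$strain$knockouts, collapse = "|"),
           plasmids = paste(id$strain$plasmids, collapse = "|")), counts)
    strain_id <- res$id; counts <- res$counts
    res <- lookup_or_insert(con, "media",
      list(name = id$media$name,
           components = jsonlite::toJSON(id$media$components,
                                         auto_unbox = TRUE)), counts)
    media_id <- res$id; counts <- res$counts
    res <- lookup_or_insert(con, "environments",
      list(labware = id$environment$labware,
           temperature = id$environment$temperature,
           shaking_speed = id$environment$shaking_speed), counts)
    env_id <- res$id; counts <- res$counts

    rid_str <- serialize_identifier(id)
    row <- DBI::dbGetQuery(con,
      "SELECT id FROM replicate_trials WHERE identifier = :i",
      params = list(i = rid_str))
    if (nrow(row)) {
      rep_id <- row$id[1]
    } else {
      DBI::dbExecute(con,
        "INSERT INTO replicate_trials
           (identifier, strain_id, media_id, environment_id, is_blank)
         VALUES (:i, :s, :m, :e, :b)",
        params = list(i = rid_str, s = strain_id, m = media_id, e = env_id,
                      b = as.integer(id$is_blank)))
      counts["replicate_trials"] <- counts["replicate_trials"] + 1L
      rep_id <- DBI::dbGetQuery(con, "SELECT last_insert_rowid() AS id")$id[1]
    }
    DBI::dbExecute(con,
      "INSERT OR IGNORE INTO experiment_membership VALUES (:e, :r)",
      params = list(e = exp_id, r = rep_id))

    for (s in r$singles) {
      sid_str <- serialize_identifier(s$identifier)
      ri <- s$identifier$replicate_index
      row <- DBI::dbGetQuery(con,
        "SELECT id FROM single_trials
         WHERE replicate_id = :r AND replicate_index IS :x",
        params = list(r = rep_id, x = ri))
      if (nrow(row)) {
        trial_id <- row$id[1]
      } else {
        DBI::dbExecute(con,
          "INSERT INTO single_trials (replicate_id, replicate_index, identifier)
           VALUES (:r, :x, :i)",
          params = list(r = rep_id, x = ri, i = sid_str))
        counts["single_trials"] <- counts["single_trials"] + 1L
        trial_id <- DBI::dbGetQuery(con,
          "SELECT last_insert_rowid() AS id")$id[1]
      }
      for (an in names(s$courses)) {
        co <- s$courses[[an]]
        row <- DBI::dbGetQuery(con,
          "SELECT id FROM analyte_courses
           WHERE trial_id = :t AND analyte_name = :a",
          params = list(t = trial_id, a = an))
        if (nrow(row)) {
          course_id <- row$id[1]
        } else {
          DBI::dbExecute(con,
            "INSERT INTO analyte_courses (trial_id, analyte_name, analyte_type, unit)
             VALUES (:t, :a, :y, :u)",
            params = list(t = trial_id, a = an, y = co$analyte_type,
                          u = co$unit))
          counts["analyte_courses"] <- counts["analyte_courses"] + 1L
          course_id <- DBI::dbGetQuery(con,
            "SELECT last_insert_rowid() AS id")$id[1]
        }
        existing <- DBI::dbGetQuery(con,
          "SELECT time_h, value FROM time_points WHERE course_id = :c",
          params = list(c = course_id))
        hit <- match(co$times, existing$time_h)
        clash <- !is.na(hit) &
          !(is.na(existing$value[hit]) & !is.finite(co$values)) &
          abs(existing$value[hit] - co$values) > 1e-12
        clash[is.na(clash)] <- TRUE
        if (any(clash, na.rm = TRUE))
          stop(sprintf(
            "stored values for '%s' at t = %s conflict with the data being saved; use a distinct identifier (e.g. an experiment: key)",
            an, paste(co$times[which(clash)], collapse = ", ")),
            call. = FALSE)
        new <- is.na(hit)
        if (any(new)) {
          vals <- co$values[new]
          vals[!is.finite(vals)] <- NA_real_
          DBI::dbExecute(con,
            "INSERT INTO time_points (course_id, time_h, value)
             VALUES (:c, :t, :v)",
            params = list(c = rep(course_id, sum(new)), t = co$times[new],
                          v = vals))
          counts["time_points"] <- counts["time_points"] + sum(new)
        }
      }
    }
  }
  DBI::dbExecute(con, "COMMIT")
  ok <- TRUE
  counts
}

#' Load an experiment from a relational store
#'
#' Reconstructs the full hierarchy; `load_experiment(save_experiment(e))` is
#' structurally equal to `e`, including missing-value positions and all
#' identifier fields.
#'
#' @param path SQLite file path
#' @param label experiment label to load
#' @return a `ferm_experiment`
#' @export
load_experiment <- function(path, label) {
  if (!file.exists(path)) stop("store file does not exist", call. = FALSE)
  con <- open_store(path)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  exp_row <- DBI::dbGetQuery(con,
    "SELECT id FROM experiments WHERE label = :l", params = list(l = label))
  if (nrow(exp_row) == 0L) {
    avail <- DBI::dbGetQuery(con, "SELECT label FROM experiments")$label
    stop(sprintf("unknown experiment '%s'; available: %s", label,
                 if (length(avail)) paste(avail, collapse = ", ") else "(none)"),
         call. = FALSE)
  }
  rows <- DBI::dbGetQuery(con,
    "SELECT st.id AS trial_id, st.identifier AS trial_identifier,
            ac.analyte_name, ac.analyte_type, ac.unit, tp.time_h, tp.value
     FROM experiment_membership em
     JOIN replicate_trials rt ON rt.id = em.replicate_id
     JOIN single_trials st ON st.replicate_id = rt.id
     JOIN analyte_courses ac ON ac.trial_id = st.id
     JOIN time_points tp ON tp.course_id = ac.id
     WHERE em.experiment_id = :e
     ORDER BY st.identifier, ac.analyte_name, tp.time_h",
    params = list(e = exp_row$id[1]))
  points <- lapply(seq_len(nrow(rows)), function(i) {
    id <- parse_identifier(rows$trial_identifier[i])
    id$analyte_name <- rows$analyte_name[i]
    id$sample_time <- rows$time_h[i]
    time_point(id, rows$value[i], rows$unit[i])
  })
  e <- assemble_experiment(points, label)
  # restore stored analyte types (the registry default may differ)
  type_by <- unique(rows[, c("trial_identifier", "analyte_name",
                             "analyte_type")])
  for (ri in seq_along(e$replicates)) {
    for (si in seq_along(e$replicates[[ri]]$singles)) {
      s <- e$replicates[[ri]]$singles[[si]]
      sid <- serialize_identifier(s$identifier)
      for (an in names(s$courses)) {
        hit <- type_by$analyte_type[type_by$trial_identifier == sid &
                                      type_by$analyte_name == an]
        if (length(hit) == 1L)
          e$replicates[[ri]]$singles[[si]]$courses[[an]]$analyte_type <- hit
      }
    }
  }
  e
}

#' List experiment labels in a store
#' @param path SQLite file path
#' @return character vector
#' @export
list_experiments <- function(path) {
  if (!file.exists(path)) stop("store file does not exist", call. = FALSE)
  con <- open_store(path)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  DBI::dbGetQuery(con, "SELECT label FROM experiments ORDER BY label")$label
}
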