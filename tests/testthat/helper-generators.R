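# Random identifier generator for property-style checks. Draws each optional
# field independently so serialization order and absent-field handling both
# get exercised.
random_identifier <- function() {
  strain <- new_strain(
    name = sample(c("MG1655", "BL21", "W3110", "dh5alpha"), 1),
    knockouts = sample(c("adhE", "ldhA", "pflB", "poxB"),
                       sample(0:3, 1)),
    plasmids = sample(c("pTrc99a", "pUC19", "pACYC"), sample(0:2, 1)))
  comps <- list()
  if (stats::runif(1) < 0.5)
    comps[["glucose"]] <- list(concentration = round(stats::runif(1, 1, 30), 3),
                               unit = "g/L")
  if (stats::runif(1) < 0.3)
    comps[["iptg"]] <- list(concentration = round(stats::runif(1, 0, 1), 3),
                            unit = "mM")
  media <- new_media(name = sample(c("M9", "LB", "TB"), 1), components = comps)
  env <- new_environment_info(
    labware = if (stats::runif(1) < 0.5) sample(c("flask", "plate96"), 1)
              else NA_character_,
    temperature = if (stats::runif(1) < 0.5) sample(c(30, 37), 1) else NA_real_,
    shaking_speed = if (stats::runif(1) < 0.5) sample(c(200, 250), 1)
                    else NA_real_)
  trial_identifier(
    strain = strain, media = media, environment = env,
    experiment_label = if (stats::runif(1) < 0.4) "exp1" else NA_character_,
    replicate_index = if (stats::runif(1) < 0.6) sample(1:4, 1) else NA_integer_,
    sample_time = if (stats::runif(1) < 0.5) round(stats::runif(1, 0, 48), 2)
                  else NA_real_,
    analyte_name = if (stats::runif(1) < 0.5)
      sample(c("OD600", "glucose", "acetate"), 1) else NA_character_,
    is_blank = stats::runif(1) < 0.1)
}

# small deterministic course builder
make_course <- function(times, values, analyte = "OD600", rep = 1,
                        strain = "A", unit = "OD") {
  id <- parse_identifier(sprintf("strain:%s|media:M9|rep:%d", strain, rep))
  id$analyte_name <- analyte
  analyte_course(id, times, values, unit)
}

# replicate trial from a list of value vectors on a shared grid
make_replicate_trial <- function(times, value_list, analyte = "OD600") {
  singles <- lapply(seq_along(value_list), function(r) {
    co <- make_course(times, value_list[[r]], analyte = analyte, rep = r)
    id <- co$identifier
    id$analyte_name <- NA_character_
    single_trial(id, stats::setNames(list(co), analyte))
  })
  id <- singles[[1]]$identifier
  id$replicate_index <- NA_integer_
  replicate_trial(id, singles)
}
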