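# ---- analyte features -------------------------------------------------------

test_that("gradient is exact on affine series and at quadratic interiors", {
  co <- make_course(c(0, 1, 2), c(0, 2, 4))
  expect_equal(gradient(co)$rates, c(2, 2, 2))

  # nonuniform quadratic: y = t^2, derivative 2t exact at the interior
  co2 <- make_course(c(0, 1, 3), c(0, 1, 9))
  expect_equal(gradient(co2)$rates, c(1, 2, 4))

  # property: affine exact everywhere on random nonuniform grids
  set.seed(4)
  for (i in 1:20) {
    tt <- sort(stats::runif(6, 0, 10))
    a <- stats::rnorm(1); b <- stats::rnorm(1)
    g <- gradient(make_course(tt, a * tt + b))
    expect_equal(g$rates, rep(a, 6), tolerance = 1e-10)
    # quadratic exact at interior points
    g2 <- gradient(make_course(tt, tt^2))
    expect_equal(g2$rates[2:5], 2 * tt[2:5], tolerance = 1e-9)
  }

  # missing values dropped first; single finite point errors
  com <- make_course(c(0, 1, 2, 3), c(0, NA, 4, 6))
  expect_equal(gradient(com)$times, c(0, 2, 3))
  expect_error(gradient(make_course(c(0, 1), c(1, NA))), "insufficient")
})

test_that("exponential fit recovers mu and X0 exactly from noiseless data", {
  tt <- seq(0, 5, by = 0.5)
  fit <- fit_growth_model(make_course(tt, 0.05 * exp(0.6 * tt)), "exponential")
  expect_equal(unname(coef(fit)[["mu"]]), 0.6, tolerance = 1e-6)
  expect_equal(unname(coef(fit)[["X0"]]), 0.05, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)

  # constant course -> mu = 0
  fit0 <- fit_growth_model(make_course(0:4, rep(1, 5)), "exponential")
  expect_equal(unname(coef(fit0)[["mu"]]), 0, tolerance = 1e-10)

  expect_error(fit_growth_model(make_course(0:3, c(1, -1, 1, 1)),
                                "exponential"), "positive")
  expect_error(fit_growth_model(make_course(0:1, c(1, 2)), "exponential"),
               "insufficient")
})

test_that("sigmoid fits recover their generating parameters", {
  tt <- seq(0, 24, by = 0.5)
  y <- growth_gen_logistic(tt, A = 2, mu_max = 0.5, lam = 1)
  fit <- fit_growth_model(make_course(tt, y), "gen_logistic")
  expect_equal(coef(fit), c(A = 2, mu_max = 0.5, lam = 1), tolerance = 1e-4)

  y5 <- growth_richards5(tt, A = 2, mu_max = 0.5, lam = 1, nu = 1.5, X0 = 0.05)
  fit5 <- fit_growth_model(make_course(tt, y5), "richards5")
  expect_equal(coef(fit5), c(A = 2, mu_max = 0.5, lam = 1, nu = 1.5, X0 = 0.05),
               tolerance = 1e-3)

  # predict/residuals methods are consistent with the stored data
  expect_equal(predict(fit, tt), y, tolerance = 1e-6)
  expect_lt(max(abs(residuals(fit))), 1e-6)

  # a time window restricts the fitted points
  fw <- fit_growth_model(make_course(tt, y), "gen_logistic", window = c(0, 12))
  expect_equal(fw$n_points, sum(tt <= 12))
})

test_that("mu_max survives measurement noise in at least 95 of 100 runs", {
  tt <- seq(0, 24, by = 0.5)
  clean <- growth_gen_logistic(tt, A = 2, mu_max = 0.5, lam = 1)
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    y <- clean + stats::rnorm(length(tt), 0, 0.01)
    mu_hat <- tryCatch(
      coef(fit_growth_model(make_course(tt, y), "gen_logistic"))[["mu_max"]],
      error = function(e) NA_real_)
    if (is.finite(mu_hat) && abs(mu_hat - 0.5) / 0.5 <= 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

# ---- trial features ---------------------------------------------------------

test_that("yield arithmetic matches its defining ratio", {
  s <- make_course(c(0, 4, 8), c(10, 7, 4), analyte = "glucose", unit = "g/L")
  p <- make_course(c(0, 4, 8), c(0, 1.5, 3), analyte = "acetate", unit = "g/L")
  y <- compute_yield(p, s)
  expect_equal(y$endpoint_yield, 0.5)
  expect_equal(y$cumulative, c(NA, 0.5, 0.5))

  # constant product -> zero yield; flat substrate -> error
  p0 <- make_course(c(0, 4, 8), c(1, 1, 1), analyte = "acetate")
  expect_equal(compute_yield(p0, s)$endpoint_yield, 0)
  sflat <- make_course(c(0, 4, 8), c(10, 10, 10), analyte = "glucose")
  expect_error(compute_yield(p, sflat), "no substrate consumed")
})

test_that("noiseless synthetic experiments return their ground-truth yield", {
  for (seed in c(1, 17, 202)) {
    g <- generate_experiment(synthetic_config(Y_PS = 0.4, seed = seed))
    e <- assemble_experiment(g$points)
    s1 <- e$replicates[[1]]$singles[[1]]
    y <- compute_yield(s1$courses$product, s1$courses$glucose)
    expect_equal(y$endpoint_yield, 0.4, tolerance = 1e-12)
  }
})

test_that("specific rates divide gradients by biomass with unit conversion", {
  x <- make_course(0:4, rep(0.5, 5), analyte = "biomass", unit = "gDW/L")
  p <- make_course(0:4, 1.0 * (0:4), analyte = "acetate", unit = "g/L")
  q <- specific_rate(p, x)
  expect_equal(q$rates, rep(2.0, 5))

  # 0.9 g/L/h / 90 g/mol / 0.5 gDW/L = 20 mmol/gDW/h
  p2 <- make_course(0:4, 0.9 * (0:4), analyte = "acetate", unit = "g/L")
  q2 <- specific_rate(p2, x, molar_mass = 90)
  expect_equal(q2$rates, rep(20, 5))

  # applied to biomass itself: instantaneous specific growth rate
  tt <- seq(0, 5, by = 0.25)
  xb <- make_course(tt, 0.05 * exp(0.6 * tt), analyte = "biomass")
  mu <- specific_rate(xb, xb)
  interior <- 2:(length(tt) - 1)
  expect_equal(mu$rates[interior], rep(0.6, length(interior)),
               tolerance = 5e-3)

  xneg <- make_course(0:4, c(0.5, 0, 0.5, 0.5, 0.5), analyte = "biomass")
  expect_error(specific_rate(p, xneg), "positive")
})

test_that("biomass normalization divides pointwise and propagates missing", {
  x <- make_course(c(0, 1), c(0.5, 1.0), analyte = "OD600", unit = "OD")
  sig <- make_course(c(0, 1), c(1, 2), analyte = "fluor1", unit = "AU")
  norm <- normalize_to_biomass(sig, x)
  expect_equal(norm$values, c(2, 2))
  expect_equal(norm$unit, "AU/OD")

  # normalized by itself: all ones
  expect_equal(normalize_to_biomass(x, x)$values, c(1, 1))

  sig2 <- make_course(c(0, 1), c(1, NA), analyte = "fluor1")
  expect_equal(normalize_to_biomass(sig2, x)$values, c(2, NA))
})

# ---- replicate features -----------------------------------------------------

test_that("replicate statistics reproduce the worked missing-data example", {
  e <- assemble_experiment(table1_fixture())
  st <- replicate_statistics(e$replicates[[1]])$OD600
  expect_equal(st$times, c(0, 2, 4, 6))
  expect_equal(round(st$mean, 2), c(0.5, 0.75, 1.03, 1.2))
  expect_equal(round(st$std, 2), c(0.1, 0.07, 0.15, NA))
  expect_equal(st$n_obs, c(3L, 2L, 3L, 1L))
  # t = 6 h: a single observation -> mean defined, std undefined
  expect_true(is.na(st$std[4]) && !is.na(st$mean[4]))
})

test_that("statistics match a brute-force oracle on complete grids", {
  set.seed(31)
  vals <- lapply(1:4, function(i) stats::rnorm(6, mean = i))
  r <- make_replicate_trial(0:5, vals)
  st <- replicate_statistics(r)$OD600
  m <- do.call(rbind, vals)
  expect_equal(st$mean, apply(m, 2, mean))
  expect_equal(st$std, apply(m, 2, stats::sd))
  expect_equal(st$n_obs, rep(4L, 6))
})

test_that("degenerate replicate layouts produce markers, not failures", {
  # three identical replicates -> std 0
  r <- make_replicate_trial(0:3, rep(list(c(1, 2, 3, 4)), 3))
  expect_equal(replicate_statistics(r)$OD600$std, rep(0, 4))
  # one replicate: mean = its values, std all undefined
  r1 <- make_replicate_trial(0:3, list(c(1, 2, 3, 4)))
  st <- replicate_statistics(r1)$OD600
  expect_equal(st$mean, c(1, 2, 3, 4))
  expect_true(all(is.na(st$std)))
  # disjoint grids union cleanly
  co1 <- make_course(c(0, 2), c(1, 2), rep = 1)
  co2 <- make_course(c(1, 3), c(3, 4), rep = 2)
  id <- co1$identifier; id$analyte_name <- NA_character_
  s1 <- single_trial(id, list(OD600 = co1))
  id2 <- co2$identifier; id2$analyte_name <- NA_character_
  s2 <- single_trial(id2, list(OD600 = co2))
  rid <- id; rid$replicate_index <- NA_integer_
  st2 <- replicate_statistics(replicate_trial(rid, list(s1, s2)))$OD600
  expect_equal(st2$times, 0:3)
  expect_equal(st2$n_obs, rep(1L, 4))
})

test_that("a x5-scaled replicate among three is flagged at tau = 0.5", {
  base <- c(0.5, 0.8, 0.9, 1.2)
  r <- make_replicate_trial(c(0, 2, 4, 6), list(base, base, base * 5))
  expect_equal(detect_outlier_replicates(r, "OD600", tau = 0.5), 3L)
  # identical replicates are never flagged
  r0 <- make_replicate_trial(c(0, 2, 4, 6), list(base, base, base))
  expect_length(detect_outlier_replicates(r0, "OD600", tau = 0.5), 0)
  # fewer than three replicates: guard returns empty
  r2 <- make_replicate_trial(c(0, 2, 4, 6), list(base, base * 5))
  expect_length(detect_outlier_replicates(r2, "OD600", tau = 0.5), 0)
  expect_error(detect_outlier_replicates(r, "nope", tau = 0.5), "nope")
})

test_that("outlier screening is permutation-invariant and capped at n - 2", {
  base <- c(0.5, 0.8, 0.9, 1.2)
  sets <- list(base, base * 1.1, base * 5, base * 7)
  perms <- list(1:4, c(3, 1, 4, 2), 4:1)
  flagged <- lapply(perms, function(p) {
    r <- make_replicate_trial(c(0, 2, 4, 6), sets[p])
    # map back: replicate index i in permuted trial holds sets[[p[i]]]
    sort(p[detect_outlier_replicates(r, "OD600", tau = 0.5)])
  })
  expect_equal(flagged[[2]], flagged[[1]])
  expect_equal(flagged[[3]], flagged[[1]])
  # every score exceeds tau here; the cap flags only the two worst and always
  # keeps the two best-agreeing replicates
  expect_length(flagged[[1]], 2)
  expect_true(4L %in% flagged[[1]])
})

# ---- experiment features ----------------------------------------------------

test_that("blank subtraction removes constant and interpolated background", {
  trial <- make_replicate_trial(c(0, 2, 4), rep(list(rep(0.55, 3)), 2))
  blank <- make_replicate_trial(c(0, 2, 4), list(rep(0.05, 3)))
  blank$identifier$is_blank <- TRUE
  corr <- subtract_blank(trial, blank)
  expect_true(attr(corr, "blank_corrected"))
  for (s in corr$singles)
    expect_equal(s$courses$OD600$values, rep(0.50, 3))

  # blank on a coarser grid: linear interpolation at t = 2 subtracts 0.1
  blank2 <- make_replicate_trial(c(0, 4), list(c(0.0, 0.2)))
  trial2 <- make_replicate_trial(2, list(1.0))
  corr2 <- subtract_blank(trial2, blank2)
  expect_equal(corr2$singles[[1]]$courses$OD600$values, 0.9)

  # analyte missing from blank: unchanged + warning
  tr3 <- make_replicate_trial(c(0, 2), list(c(1, 2)), analyte = "acetate")
  expect_warning(corr3 <- subtract_blank(tr3, blank), "acetate")
  expect_equal(corr3$singles[[1]]$courses$acetate$values, c(1, 2))
})

test_that("blank subtraction then statistics equals statistics then mean-blank", {
  set.seed(77)
  vals <- lapply(1:3, function(i) stats::rnorm(5, 1))
  bvals <- lapply(1:2, function(i) stats::rnorm(5, 0.1))
  trial <- make_replicate_trial(0:4, vals)
  blank <- make_replicate_trial(0:4, bvals)
  path1 <- replicate_statistics(subtract_blank(trial, blank))$OD600$mean
  bmean <- replicate_statistics(blank)$OD600$mean
  path2 <- replicate_statistics(trial)$OD600$mean - bmean
  expect_equal(path1, path2)
})

test_that("blanks are auto-assigned by shared media and environment", {
  pts <- c(
    lapply(1:2, function(r) {
      id <- parse_identifier(sprintf("strain:A|media:M9|rep:%d", r))
      id$analyte_name <- "OD600"; id$sample_time <- 0
      time_point(id, 0.5, "OD")
    }),
    lapply(c("M9", "LB"), function(m) {
      id <- parse_identifier(sprintf("strain:blank|media:%s", m))
      id$analyte_name <- "OD600"; id$sample_time <- 0
      time_point(id, 0.05, "OD")
    }),
    list({
      id <- parse_identifier("strain:B|media:LB|rep:1")
      id$analyte_name <- "OD600"; id$sample_time <- 0
      time_point(id, 0.6, "OD")
    }))
  e <- assemble_experiment(pts)
  bmap <- assign_blanks(e)
  expect_length(bmap, 2)
  expect_match(bmap[[grep("strain:A", names(bmap))]], "media:M9")
  expect_match(bmap[[grep("strain:B", names(bmap))]], "media:LB")

  # no blanks -> empty map + warning
  e2 <- assemble_experiment(pts[1:2])
  expect_warning(bmap2 <- assign_blanks(e2), "no blank")
  expect_length(bmap2, 0)

  # two equivalent blanks -> lexicographically first + warning
  id_b2 <- parse_identifier("strain:blank|media:M9|experiment:alt")
  id_b2$analyte_name <- "OD600"; id_b2$sample_time <- 0
  e3 <- assemble_experiment(c(pts[1:3], list(time_point(id_b2, 0.04, "OD"))))
  expect_warning(bmap3 <- assign_blanks(e3), "multiple")
  expect_length(bmap3, 1)
})

test_that("full blank correction recovers the noiseless synthetic signal", {
  g <- generate_experiment(synthetic_config(blank_level = 0.08, seed = 5))
  e <- assemble_experiment(g$points)
  ec <- suppressWarnings(apply_blank_correction(e))
  # corrected biomass equals ground-truth X(t) exactly
  tt <- g$truth$strains$strain1
  co <- ec$replicates[[1]]$singles[[1]]$courses$biomass
  expected <- g$truth$X0 + growth_gen_logistic(co$times, tt$A, tt$mu_max,
                                               tt$lam)
  expect_equal(co$values, expected, tolerance = 1e-12)
  # blanks are dropped from the corrected experiment
  expect_false(any(vapply(ec$replicates, function(r) r$identifier$is_blank,
                          logical(1))))
})

test_that("stage slicing uses half-open intervals and enables per-stage yields", {
  # boundaries [0,4,8]: t = 4 belongs to stage 2
  pts <- table1_fixture()
  e <- assemble_experiment(pts)
  es <- slice_stages(e, c(0, 4, 8))
  stages <- vapply(es$replicates, function(r) stage_of(r$identifier), 1L)
  expect_equal(sort(stages), c(1L, 2L))
  s2 <- es$replicates[[which(stages == 2)]]
  expect_equal(s2$singles[[1]]$courses$OD600$times, c(4, 6))

  expect_error(slice_stages(e, c(4, 4)), "increasing")

  # two-phase synthetic data: production only after the growth stage
  tt <- seq(0, 16, by = 1)
  S <- ifelse(tt < 8, 20, 20 - 1.0 * (tt - 8))
  P <- ifelse(tt < 8, 0, 0.5 * 1.0 * (tt - 8))
  id <- parse_identifier("strain:A|media:M9|rep:1")
  mk <- function(an, vals, unit) {
    i <- id; i$analyte_name <- an
    lapply(seq_along(tt), function(j) {
      i$sample_time <- tt[j]; time_point(i, vals[j], unit)
    })
  }
  e2 <- assemble_experiment(c(mk("glucose", S, "g/L"), mk("acetate", P, "g/L")))
  e2s <- slice_stages(e2, c(0, 8, 16))
  get_stage <- function(k) {
    r <- Filter(function(r) stage_of(r$identifier) == k, e2s$replicates)[[1]]
    r$singles[[1]]
  }
  st2 <- get_stage(2)
  y2 <- compute_yield(st2$courses$acetate, st2$courses$glucose)
  expect_equal(y2$endpoint_yield, 0.5)
  st1 <- get_stage(1)
  expect_error(compute_yield(st1$courses$acetate, st1$courses$glucose),
               "no substrate consumed")

  # empty stage dropped with warning
  expect_warning(slice_stages(e2, c(0, 8, 20, 99)), "no sample times")
})

# ---- feature registry -------------------------------------------------------

test_that("features register and resolve by name and level", {
  df <- list_features()
  expect_true(all(c("gradient", "compute_yield", "replicate_statistics",
                    "slice_stages") %in% df$name))
  expect_equal(get_feature("gradient")$level, "analyte")
  expect_error(get_feature("nonexistent_feature"), "unknown feature")
  register_feature("test_dummy", "analyte", function(co) 42)
  expect_equal(get_feature("test_dummy")$fn(NULL), 42)
})
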