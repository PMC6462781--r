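test_that("toy network FBA reaches the stoichiometric optimum", {
  m <- toy_model_fixture()
  sol <- solve_fba(m, c(EX_glc = -10))
  expect_equal(sol$status, "optimal")
  expect_equal(unname(sol$v[c("EX_etoh", "EX_co2")]), c(20, 20))
  expect_equal(sol$objective_value, 20)
  # steady state within tolerance
  expect_lte(max(abs(m$S %*% sol$v)), 1e-6)
  # original bounds respected and the measured rate held exactly
  expect_true(all(sol$v >= m$lb - 1e-9 & sol$v <= m$ub + 1e-9))
  expect_equal(unname(sol$v["EX_glc"]), -10)
})

test_that("degenerate and infeasible constraint sets are classified", {
  m <- toy_model_fixture()
  z <- solve_fba(m, c(EX_glc = 0, EX_etoh = 0, EX_co2 = 0))
  expect_equal(z$status, "optimal")
  expect_equal(unname(z$v), rep(0, 5))
  expect_equal(z$objective_value, 0)

  # 25 ethanol from 10 glucose exceeds the 2:1 stoichiometric maximum
  inf <- solve_fba(m, c(EX_glc = -10, EX_etoh = 25))
  expect_equal(inf$status, "infeasible")
  expect_match(inf$message, "EX_etoh=25")

  expect_error(solve_fba(m, c(nope = 1)), "not in model")

  # slack bands relax equality: 10% slack admits a slightly higher optimum
  s <- solve_fba(m, c(EX_glc = -10), slack = 0.1)
  expect_equal(s$objective_value, 22, tolerance = 1e-9)
})

test_that("CO2 estimation closes the toy balance under either objective", {
  m <- toy_model_fixture()
  measured <- c(EX_glc = -10, EX_etoh = 20)
  expect_equal(estimate_co2(m, measured, "EX_co2"), 20, tolerance = 1e-9)

  # zero-objective model falls back to minimum total flux, same answer
  # (the CO2 flux is uniquely determined by the constraints)
  m0 <- m; m0$objective[] <- 0
  expect_equal(estimate_co2(m0, measured, "EX_co2"), 20, tolerance = 1e-9)

  expect_equal(estimate_co2(m, c(EX_glc = 0, EX_etoh = 0), "EX_co2"), 0)
  expect_error(estimate_co2(m, c(EX_glc = -10, EX_etoh = 25), "EX_co2"),
               "infeasible")
  expect_error(estimate_co2(m, c(EX_co2 = 5), "EX_co2"), "measured")
  expect_error(estimate_co2(m, c(EX_glc = -10), "GLYC"), "exchange")
})

test_that("carbon recovery balances consumed against produced C-mmol", {
  # 10 mmol glucose (6 C); 10 etoh (2 C) + 10 co2 (1 C) -> 30/60
  led <- carbon_recovery(list(glucose = c(10, 6), ethanol = c(10, 2),
                              co2 = c(10, 1)), substrates = "glucose")
  expect_equal(led$recovery, 0.5)

  # exact toy-network products: full recovery
  full <- carbon_recovery(list(glucose = c(10, 6), ethanol = c(20, 2),
                               co2 = c(20, 1)), substrates = "glucose")
  expect_equal(full$recovery, 1.0)

  # no products -> recovery 0
  none <- carbon_recovery(list(glucose = c(10, 6)), substrates = "glucose")
  expect_equal(none$recovery, 0)

  # homogeneous of degree 0 under uniform scaling
  for (k in c(0.1, 3, 250)) {
    sc <- carbon_recovery(list(glucose = c(10 * k, 6), ethanol = c(10 * k, 2),
                               co2 = c(10 * k, 1)), substrates = "glucose")
    expect_equal(sc$recovery, 0.5)
  }

  # biomass contribution via the standard elemental composition
  bio <- carbon_recovery(list(glucose = c(10, 6)), substrates = "glucose",
                         biomass_grams = 24.6 / 1000 * 60)
  expect_equal(bio$recovery, 1.0)

  expect_error(carbon_recovery(list(glucose = c(0, 6)), "glucose"), "zero")
})

test_that("reaction-table files define working models", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "reaction_id,equation,lb,ub,objective",
    "EX_glc,glc_e ->,-1000,1000,0",
    "GLYC,glc_e -> 2 pyr_c,-1000,1000,0",
    "FERM,pyr_c -> etoh_c + co2_c,-1000,1000,0",
    "EX_etoh,etoh_c ->,-1000,1000,1",
    "EX_co2,co2_c ->,-1000,1000,0"), path)
  m <- read_reaction_table(path)
  expect_s3_class(m, "stoichiometric_model")
  expect_setequal(m$exchanges, c("EX_glc", "EX_etoh", "EX_co2"))
  sol <- solve_fba(m, c(EX_glc = -10))
  expect_equal(unname(sol$v["EX_co2"]), 20)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("reaction_id,equation", bad)
  expect_error(read_reaction_table(bad), "missing column")
})

test_that("minimal SBML models import with species, stoichiometry and bounds", {
  skip_if_not_installed("xml2")
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
 <model id="toy">
  <listOfSpecies>
   <species id="glc" boundaryCondition="false"/>
   <species id="pyr" boundaryCondition="false"/>
   <species id="glc_b" boundaryCondition="true"/>
  </listOfSpecies>
  <listOfReactions>
   <reaction id="EX_glc" reversible="true">
    <listOfReactants><speciesReference species="glc" stoichiometry="1"/></listOfReactants>
    <listOfProducts><speciesReference species="glc_b" stoichiometry="1"/></listOfProducts>
   </reaction>
   <reaction id="GLYC" reversible="false">
    <listOfReactants><speciesReference species="glc" stoichiometry="1"/></listOfReactants>
    <listOfProducts><speciesReference species="pyr" stoichiometry="2"/></listOfProducts>
   </reaction>
   <reaction id="EX_pyr" reversible="true">
    <listOfReactants><speciesReference species="pyr" stoichiometry="1"/></listOfReactants>
   </reaction>
  </listOfReactions>
 </model>
</sbml>', path)
  m <- read_sbml_model(path)
  expect_equal(sort(rownames(m$S)), c("glc", "pyr"))
  expect_true(all(c("EX_glc", "EX_pyr") %in% m$exchanges))
  expect_equal(m$S["pyr", "GLYC"], 2)
  expect_equal(unname(m$lb["GLYC"]), 0)  # irreversible
  # uptake 10 glc (export -10) -> 20 pyr out
  sol <- solve_fba(m, c(EX_glc = -10))
  expect_equal(unname(sol$v["EX_pyr"]), 20, tolerance = 1e-9)
})
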