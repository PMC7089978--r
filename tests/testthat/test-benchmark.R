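# Condition orchestration and reporting

test_that("dye reference table carries the expected physicochemistry", {
  dt <- dyeTable()
  expect_setequal(dt$dye, c("Alexa546", "Alexa647", "Atto550", "Atto647N"))
  # hydrophobic positive dyes adhere; hydrophilic negative ones do not
  expect_true(all(dt$adhesive == (dt$logD > 0)))
  expect_true(all(dt$adhesive == (dt$net_charge > 0)))
  expect_true(all(dt$tau_confocal_ns > dt$tau_zmw_free_ns))
})

test_that("sticking probability mapping follows the benchmark ranking", {
  p0 <- defaultStickingProb("none")
  expect_gt(p0, 0)
  expect_equal(defaultStickingProb("PEG5000"), p0)
  expect_equal(defaultStickingProb("BSA"), p0 / 2)
  expect_equal(defaultStickingProb("PEG500"), p0 / 2)
  expect_equal(defaultStickingProb("PEG1000"), 0)
  expect_equal(defaultStickingProb("PVPA"), 0)
  expect_error(defaultStickingProb("teflon"), "unknown")
  # non-adhesive dyes never stick, whatever the surface
  cfg <- conditionConfig("Alexa647", "none")
  expect_equal(cfg@adsorptionProbPerContact, 0)
})

test_that("an empty photon file fails at the correlate stage, not crash", {
  path <- withr::local_tempfile(fileext = ".txt")
  writePhotonFile(TTTRTrace(numeric(0), numeric(0), duration = 1), path)
  spec <- conditionSpec("Atto647N", "none", path = path)
  row <- runCondition(spec)
  expect_equal(row$status, "failed")
  expect_equal(row$failed_stage, "correlate")
})

test_that("condition spec validity demands exactly one data source", {
  cfg <- quickConfig()
  expect_error(new("ConditionSpec", label = "x", dye = "Atto647N",
                   passivation = "none", concentration = 100,
                   config = cfg, path = "also.txt"), "exactly one")
  expect_error(new("ConditionSpec", label = "x", dye = "Atto647N",
                   passivation = "teflon", concentration = 100,
                   config = cfg, path = NA_character_), "passivation")
})

test_that("pipeline rows are deterministic and rank by slow amplitude", {
  sticky <- conditionSpec("Atto647N", "none",
    config = conditionConfig("Atto647N", "none", duration = 20, seed = 3))
  clean <- conditionSpec("Atto647N", "PVPA",
    config = conditionConfig("Atto647N", "PVPA", duration = 20, seed = 4))
  r1 <- runCondition(sticky)
  r2 <- runCondition(clean)
  expect_equal(r1$status, "ok")
  expect_equal(r2$status, "ok")
  expect_identical(runCondition(sticky), r1)  # determinism at equal seed
  expect_gt(r1$slow_pct, r2$slow_pct)         # sticking condition ranks last
  rep <- compareConditions(list(r1, r2))
  expect_equal(rep@baseline, r2$label)
  expect_equal(rep@table$label, c(r2$label, r1$label))
  expect_equal(rep@table$delta_tau_d_us[1], 0)
  # lifetime is shortened where molecules adsorb on the metal
  expect_lt(r1$avg_lifetime_ns, r2$avg_lifetime_ns)
  expect_gt(r1$fold_change, r2$fold_change)
})

test_that("reports render to CSV + text and round trip", {
  rows <- do.call(rbind, lapply(1:6, function(i) data.frame(
    label = paste0("cond", i), dye = "Atto647N", passivation = "none",
    status = "ok", failed_stage = NA_character_, n_photons = 1e5,
    mean_rate_cps = 1500, n_species = 2L, fast_pct = 100 - i,
    slow_pct = i, tau_d_fast_us = 250, n_molecules = 0.04,
    brightness_cps = 37500, avg_lifetime_ns = 1.5, fold_change = 2.6,
    seed = i, stringsAsFactors = FALSE)))
  rep <- compareConditions(rows)
  expect_equal(nrow(rep@table), 6)
  csv <- withr::local_tempfile(fileext = ".csv")
  paths <- renderReport(rep, csv)
  expect_true(file.exists(paths["csv"]))
  expect_true(file.exists(paths["txt"]))
  expect_equal(length(readLines(csv)), 6 + 2)  # header comment + colnames
  back <- readBenchmarkReport(csv)
  expect_equal(back@baseline, rep@baseline)
  expect_equal(back@table$slow_pct, rep@table$slow_pct)
  expect_equal(back@table$label, rep@table$label)
})

test_that("comparing zero successful rows is an error", {
  row <- data.frame(label = "x", slow_pct = NA_real_, status = "failed")
  expect_error(compareConditions(row), "no successful")
})

test_that("fit results serialize to JSON reports", {
  cv <- modelCurve(fcsParams(N = 5, tauD = 1e-3))
  fit <- fitFCS(cv, nSpecies = 1)
  path <- withr::local_tempfile(fileext = ".json")
  writeFitJson(fit, path)
  obj <- jsonlite::fromJSON(path)
  expect_equal(obj$type, "fcs")
  expect_equal(obj$N, fit@params@N, tolerance = 1e-9)
  expect_equal(obj$kappa, 1)

  irf <- gaussianIRF(110, center = 1000)
  dec <- fitDecay(buildTCSPCHistogram(
    simulateDecayPhotons(2e4, 1, 3.0, irf, seed = 2), 16), irf, nExp = 1)
  writeFitJson(dec, path)
  obj2 <- jsonlite::fromJSON(path)
  expect_equal(obj2$type, "decay")
  expect_equal(obj2$intensity_weighted_lifetime_ns, dec@avgLifetime,
               tolerance = 1e-9)
})
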