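test_that("tetraether cardiolipin fragments reproduce the printed MS2 ions", {
  fs <- predict_fragments(tetraether_cdl64())
  ions <- fs$entries[fs$entries$kind == "ion", ]
  expect_lt(abs(ppm_error(1298.063, fs$precursor_mz)), 5)
  printed <- c(1280.050, 771.529, 743.497, 691.563, 663.531,
               155.010, 234.977, 255.268, 283.299, 297.315)
  for (mz in printed) {
    hits <- explain_peak(mz, fs, tol_ppm = 5)
    expect_gte(nrow(hits), 1)
  }
  # neutral losses of the two dialkylglycerol cores
  losses <- fs$entries[fs$entries$kind == "neutral_loss", ]
  expect_true(any(abs(ppm_error(526.533, losses$mass)) <= 5))
  expect_true(any(abs(ppm_error(554.566, losses$mass)) <= 7))
  expect_identical(sort(losses$formula[grepl("^R2", losses$rule)]),
                   c("C34H70O3", "C36H74O3"))
})

test_that("fragment mass conservation holds to 1e-9 Da for loss/ion pairs", {
  for (lb in c("CDL 64:0;e4 [e17/e16 | e17/e14]",
               "CDL 62:0;e2 [e16/a15 | a17/e14]",
               "MLCDL 45:0;e3 [e17/e14 | e14]",
               "DLCDL 31:0;e2 [e14/e17 | -]",
               "CDL 64:0;e0 [a17/a16 | a17/a14]")) {
    fs <- predict_fragments(parse_species_label(lb))
    for (rule in unique(fs$entries$rule[fs$entries$kind == "neutral_loss"])) {
      pair <- fs$entries[fs$entries$rule == rule, ]
      ion_mass <- pair$mass[pair$kind == "ion"]
      loss_mass <- pair$mass[pair$kind == "neutral_loss"]
      expect_equal(ion_mass + loss_mass, fs$precursor_mz,
                   tolerance = 1e-9)
    }
  }
})

test_that("R5 ether-chain ions follow C(n+3)H(2n+7)O with electron correction", {
  fs <- predict_fragments(tetraether_cdl64())
  r5 <- fs$entries[grepl("^R5", fs$entries$rule), ]
  expect_identical(sort(r5$formula), c("C17H35O", "C19H39O", "C20H41O"))
  expect_equal(sort(r5$mass), c(255.26825, 283.29955, 297.31520),
               tolerance = 1e-4)
  # tetraester: no ether chains, no R5 ions
  fs0 <- predict_fragments(
    parse_species_label("CDL 64:0;e0 [a17/a16 | a17/a14]"))
  expect_identical(sum(grepl("^R5", fs0$entries$rule)), 0L)
})

test_that("symmetric cardiolipins emit each core fragment once", {
  fs <- predict_fragments(
    parse_species_label("CDL 62:0;e4 [e17/e14 | e17/e14]"))
  expect_identical(sum(grepl("^R2", fs$entries$rule) &
                         fs$entries$kind == "ion"), 1L)
  expect_identical(sum(grepl("^R3", fs$entries$rule)), 1L)
  expect_identical(sum(grepl("^R5", fs$entries$rule)), 2L)
})

test_that("monolyso-cardiolipin loses either core as its glyceride", {
  s <- parse_species_label("MLCDL 45:0;e3 [e17/e14 | e14]")
  expect_lt(abs(s$neutral_formula["C"] - 54), 1e-9)
  fs <- predict_fragments(s)
  expect_equal(round(fs$precursor_mz, 1), 1031.8)
  losses <- fs$entries[fs$entries$kind == "neutral_loss" &
                         grepl("^R2", fs$entries$rule), ]
  expect_identical(sort(losses$formula), c("C17H36O3", "C34H70O3"))
})

test_that("mixed ether/ester cardiolipins flag acyl-core losses as low abundance", {
  fs <- predict_fragments(
    parse_species_label("CDL 64:0;e2 [e17/e16 | a17/a14]"))
  r2 <- fs$entries[grepl("^R2", fs$entries$rule) & fs$entries$kind == "ion", ]
  hints <- stats::setNames(r2$abundance_hint, r2$rule)
  expect_identical(unname(hints[grepl("a17/a14", names(hints))]), "low")
  expect_identical(unname(hints[grepl("e17/e16", names(hints))]), "high")
  # all-ester species have no ether core, so nothing is downweighted
  fs0 <- predict_fragments(
    parse_species_label("CDL 64:0;e0 [a17/a16 | a17/a14]"))
  expect_true(all(fs0$entries$abundance_hint == "high"))
})

test_that("glyceride fragments under ammonium adduct match the diether data", {
  # heterologously produced C28:0 diether: protonated monoether fragment
  s <- parse_species_label("FG 28:0;e2 [e14/e14]")
  fs <- predict_fragments(s, "[M+NH4]+", include_r6 = TRUE)
  expect_lt(abs(ppm_error(502.519, fs$precursor_mz)), 5)
  mg <- fs$entries[grepl("^R6mg", fs$entries$rule), ]
  expect_identical(mg$formula, "C17H37O3")
  expect_lt(abs(ppm_error(289.274, mg$mass)), 5)
  expect_error(predict_fragments(s, "[M+H]+"), "unsupported")
  expect_error(predict_fragments(tetraether_cdl64(), "[M+Na]+"),
               "unsupported")
})

test_that("every ion formula is a sub-formula of the precursor ion", {
  for (lb in c("CDL 64:0;e4 [e17/e16 | e17/e14]",
               "MLCDL 45:0;e3 [e17/e14 | e14]",
               "DLCDL 31:0;e2 [e17 | e14]")) {
    fs <- predict_fragments(parse_species_label(lb))
    ions <- fs$entries[fs$entries$kind == "ion", ]
    for (ftxt in ions$formula) {
      expect_no_error(combine(fs$precursor_formula, ftxt, -1))
    }
  }
})

test_that("explain_peak windows are exact and empty off-target", {
  fs <- predict_fragments(tetraether_cdl64())
  expect_identical(nrow(explain_peak(500.0, fs, tol_ppm = 5)), 0L)
  hit <- explain_peak(255.268, fs, tol_ppm = 5)
  expect_identical(hit$rule, "R5[e14]")
  expect_identical(explain_peak(234.977, fs, 5)$formula, "C3H9O8P2")
  expect_error(explain_peak(255.268, fs, tol_ppm = 0))
})
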