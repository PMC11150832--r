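test_that("precursor matching respects the 3 ppm window and sorts by error", {
  index <- default_index()
  hits <- match_precursor(1298.063, index, tol_ppm = 3, adducts = "[M+H]+")
  expect_gt(nrow(hits), 0)
  expect_true(all(hits$head_group == "CDL"))
  sp <- lapply(hits$label, parse_species_label)
  expect_true(all(vapply(sp, `[[`, 0L, "total_carbons") == 64L))
  expect_true(all(vapply(sp, `[[`, 0L, "total_ethers") == 4L))
  # +10 ppm shift leaves the window empty
  expect_identical(nrow(match_precursor(1298.063 * (1 + 10e-6), index,
                                        tol_ppm = 3,
                                        adducts = "[M+H]+")), 0L)
  # dilyso structural variants are both retrieved at their shared mass
  hits2 <- match_precursor(835.546, index, tol_ppm = 3, adducts = "[M+H]+")
  expect_true(all(c("DLCDL 31:0;e2 [e17 | e14]",
                    "DLCDL 31:0;e2 [e17/e14 | -]") %in% hits2$label))
})

test_that("tightening the tolerance never adds candidates", {
  index <- default_index()
  mzs <- c(1298.0630, 1298.0650, 835.5460, 1031.7655)
  for (mz in mzs) {
    wide <- match_precursor(mz, index, tol_ppm = 5)
    narrow <- match_precursor(mz, index, tol_ppm = 2)
    expect_true(all(narrow$label %in% wide$label))
    expect_lte(nrow(narrow), nrow(wide))
  }
})

test_that("the printed tetraether MS2 spectrum annotates to the worked example", {
  spx <- new_spectrum(tetraether_cdl64_peaks(), precursor_mz = 1298.063,
                      id = "worked-example")
  ann <- annotate_spectrum(spx, default_index())
  expect_identical(ann$status, "unambiguous")
  top <- ann$candidates[1, ]
  expect_identical(top$label, "CDL 64:0;e4 [e17/e16 | e17/e14]")
  expect_true(top$complete)
  # chain split pinned: cores C31/C33, ether chains 14/16/17
  s <- parse_species_label(top$label)
  expect_setequal(vapply(s$cores, `[[`, 0L, "n_carbons"), c(31L, 33L))
})

test_that("noiseless predicted spectra round-trip to their own species", {
  set.seed(4)
  species <- default_species()
  for (s in sample(species, 60)) {
    fs <- predict_fragments(s, "[M+H]+", include_r6 = TRUE)
    ions <- fs$entries$mass[fs$entries$kind == "ion"]
    spx <- new_spectrum(
      data.frame(mz = c(fs$precursor_mz, ions), intensity = 100),
      precursor_mz = fs$precursor_mz)
    ann <- annotate_spectrum(spx, default_index(), include_r6 = TRUE)
    top_set <- ann$candidates$label[ann$candidates$top]
    expect_true(s$label %in% top_set, label = s$label)
  }
})

test_that("a precursor-only spectrum yields an unresolved isomer set", {
  spx <- new_spectrum(data.frame(mz = 1312.0417, intensity = 100),
                      precursor_mz = 1312.0417)
  ann <- annotate_spectrum(spx, default_index())
  expect_identical(ann$status, "isomer_set")
  sp <- lapply(ann$candidates$label[ann$candidates$top],
               parse_species_label)
  expect_true(all(vapply(sp, `[[`, 0L, "total_ethers") == 3L))
  expect_true(all(vapply(sp, `[[`, 0L, "total_carbons") == 64L))
  expect_gt(length(sp), 1)
})

test_that("annotation requires a precursor and a non-empty index", {
  spx <- new_spectrum(data.frame(mz = 100, intensity = 1))
  expect_error(annotate_spectrum(spx, default_index()), "no precursor")
  spx2 <- new_spectrum(data.frame(mz = 100, intensity = 1),
                       precursor_mz = 500)
  expect_error(annotate_spectrum(spx2, default_index()[0, ]), "empty")
  # a precursor matching nothing is unassigned, not an error
  ann <- annotate_spectrum(spx2, default_index())
  expect_identical(ann$status, "unassigned")
})

test_that("MS1 feature annotation assigns species and isotope peaks", {
  s <- tetraether_cdl64()
  mh <- adduct_mz(s$neutral_formula, "[M+H]+")
  feats <- data.frame(
    mz = c(mh, mh + 1.0033548, adduct_mz(s$neutral_formula, "[M+Na]+"),
           999.9),
    area = c(100, 80, 10, 5))
  af <- annotate_features(feats, default_index())
  expect_identical(af$adduct[1:3], c("[M+H]+", "M+1", "[M+Na]+"))
  expect_true(is.na(af$label[4]))
  expect_true(all(grepl("^CDL 64:0;e4", af$label[1:3])))
})

test_that("retention ordering flags ether-count inversions only", {
  feats <- data.frame(
    label = c("CDL 64:0;e4 [e17/e16 | e17/e14]",
              "CDL 64:0;e2 [e17/e16 | a17/a14]",
              "CDL 64:0;e0 [a17/a16 | a17/a14]"),
    retention_time = c(19.7, 20.1, 20.6))
  expect_identical(nrow(check_rt_ordering(feats)), 0L)
  feats$retention_time <- c(21.0, 20.0, 20.6)
  v <- check_rt_ordering(feats)
  expect_identical(nrow(v), 2L)  # e4 after e2 and after e0
  expect_true(all(v$rt_more_ethers > v$rt_fewer_ethers))
  # single feature: nothing to compare
  expect_identical(nrow(check_rt_ordering(feats[1, ])), 0L)
  # different carbon totals are never compared
  feats2 <- data.frame(
    label = c("CDL 64:0;e4 [e17/e16 | e17/e14]",
              "CDL 62:0;e0 [a17/a14 | a17/a14]"),
    retention_time = c(21.0, 19.0))
  expect_identical(nrow(check_rt_ordering(feats2)), 0L)
})
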