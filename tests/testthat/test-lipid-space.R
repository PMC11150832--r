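# Build a species from compact chain specs: "e17:1" = 17-carbon ether chain
# with one double bond, "a14" = 14-carbon acyl chain, "-" = PGPG variant.
mk_species <- function(head_group, core_specs) {
  variant <- NULL
  if ("-" %in% core_specs) {
    core_specs <- setdiff(core_specs, "-")
    variant <- "intact-core+PGPG"
  }
  cores <- lapply(core_specs, function(txt) {
    core_lipid(lapply(strsplit(txt, "/", fixed = TRUE)[[1]], function(tok) {
      m <- regmatches(tok, regexec("^([ea])(\\d+)(?::(\\d+))?$", tok))[[1]]
      radyl_chain(as.integer(m[3]),
                  linkage = if (m[2] == "e") "ether" else "ester",
                  n_unsat = if (m[4] == "") 0L else as.integer(m[4]))
    }))
  })
  build_species(head_group, cores, dilyso_variant = variant)
}

# Atom-by-atom bookkeeping oracle: expected neutral formulas for hand-counted
# structures (scaffold atoms plus per-chain contributions tallied manually).
hand_counted <- list(
  list("CDL", c("e17/e16", "e17/e14"), "C73H150O13P2"),
  list("CDL", c("a17/a16", "a17/a14"), "C73H142O17P2"),
  list("CDL", c("e17/e16", "a17/a14"), "C73H146O15P2"),
  list("CDL", c("e17:1/e16", "e17/e14"), "C73H148O13P2"),
  list("CDL", c("e14/e14", "e14/e14"), "C65H134O13P2"),
  list("monolyso-CDL", c("e17/e14", "e14"), "C54H112O13P2"),
  list("monolyso-CDL", c("a16/a14", "a14"), "C53H104O16P2"),
  list("monolyso-CDL", c("e16/a15", "e17"), "C57H116O14P2"),
  list("dilyso-CDL", c("e17", "e14"), "C40H84O13P2"),
  list("dilyso-CDL", c("e14/e17", "-"), "C40H84O13P2"),
  list("dilyso-CDL", c("a15", "a14"), "C38H76O15P2"),
  list("PE", "a17/a14", "C36H72NO8P"),
  list("PE", "e16/a14", "C35H72NO7P"),
  list("PE", "e17/e17", "C39H82NO6P"),
  list("PE", "e16", "C21H46NO6P"),
  list("PG", "e17/e14", "C37H77O8P"),
  list("PG", "a16/a16", "C38H75O10P"),
  list("PG", "a16", "C22H45O9P"),
  list("PG", "e14", "C20H43O8P"),
  list("none", "e14/e14", "C31H64O3"),
  list("none", "e16/e14", "C33H68O3"),
  list("none", "e17:1/e17", "C37H74O3")
)

test_that("formula construction matches atom-by-atom hand counts", {
  for (case in hand_counted) {
    sp <- mk_species(case[[1]], case[[2]])
    expect_identical(formula_string(sp$neutral_formula), case[[3]],
                     label = paste(case[[1]], paste(case[[2]],
                                                    collapse = " | ")))
  }
})

test_that("species labels encode totals and parse/label round-trips", {
  s <- tetraether_cdl64()
  expect_identical(s$label, "CDL 64:0;e4 [e17/e16 | e17/e14]")
  expect_identical(species_label(parse_species_label(s$label)), s$label)
  # determinism: same structure given in any core order
  s2 <- build_species("CDL", list(
    core_lipid(list(radyl_chain(14, "ether"), radyl_chain(17, "ether"))),
    core_lipid(list(radyl_chain(16, "ether"), radyl_chain(17, "ether")))))
  expect_identical(s2$label, s$label)
  expect_error(parse_species_label("CDL 63:0;e4 [e17/e16 | e17/e14]"),
               "disagree")
  expect_error(parse_species_label("XX 64:0;e4 [e17/e16 | e17/e14]"),
               "unknown head-group")
})

test_that("core classes derive from linkages and arity is validated", {
  deg <- core_lipid(list(radyl_chain(17, "ether"), radyl_chain(14, "ether")))
  aeg <- core_lipid(list(radyl_chain(17, "ether"), radyl_chain(14, "ester")))
  dag <- core_lipid(list(radyl_chain(17, "ester"), radyl_chain(14, "ester")))
  meg <- core_lipid(radyl_chain(16, "ether"))
  mag <- core_lipid(radyl_chain(16, "ester"))
  expect_identical(vapply(list(deg, aeg, dag, meg, mag), `[[`, "", "class"),
                   c("DEG", "AEG", "DAG", "MEG", "MAG"))
  expect_identical(vapply(list(deg, aeg, dag, meg, mag), `[[`, 0L,
                          "ether_count"),
                   c(2L, 1L, 0L, 1L, 0L))
  expect_error(build_species("CDL", list(deg, meg)), "two cores of two")
  expect_error(build_species("monolyso-CDL", list(deg, aeg)),
               "1-chain core")
  expect_error(build_species("dilyso-CDL", list(deg, dag)),
               "two chains in total")
  expect_error(build_species("PE", list(deg, deg)), "single core")
})

test_that("branched odd chains are annotated and assigned sn-1", {
  co <- core_lipid(list(radyl_chain(16, "ether"), radyl_chain(15, "ether")))
  sns <- vapply(co$chains, `[[`, 0L, "sn")
  odd <- vapply(co$chains, function(ch) ch$n_carbons %% 2L == 1L, TRUE)
  expect_identical(sns[odd], 1L)
  expect_identical(co$chains[[which(odd)]]$branch_note, "10-Me-C14")
  # mass neutrality of the branch annotation
  co2 <- core_lipid(list(radyl_chain(16, "ether"),
                         radyl_chain(15, "ether", branch_note = "x")))
  expect_identical(
    formula_string(build_species("PG", list(co))$neutral_formula),
    formula_string(build_species("PG", list(co2))$neutral_formula))
})

test_that("ether to ester substitution shifts the formula by -2H +1O", {
  # the C64 cardiolipin ladder: each added ester adds 13.9793 Da
  labels <- c("CDL 64:0;e4 [e17/e16 | e17/e14]",
              "CDL 64:0;e3 [e17/e16 | e17/a14]",
              "CDL 64:0;e2 [e17/e16 | a17/a14]",
              "CDL 64:0;e1 [e17/a16 | a17/a14]",
              "CDL 64:0;e0 [a17/a16 | a17/a14]")
  mzs <- vapply(labels, function(lb)
    adduct_mz(parse_species_label(lb)$neutral_formula, "[M+H]+"), 0)
  expect_equal(unname(diff(mzs)), rep(13.97926, 4), tolerance = 1e-4)
  # the detected-ion mass ladder of the C64 series
  expect_equal(unname(mzs),
               c(1298.0624, 1312.0417, 1326.0210, 1340.0003, 1353.9796),
               tolerance = 1e-3)
})

test_that("enumeration is exhaustive, duplicate-free and matches closed forms", {
  species <- default_species()
  labs <- vapply(species, `[[`, "", "label")
  expect_false(any(duplicated(labs)))
  hg <- vapply(species, `[[`, "", "head_group")
  # 36 distinct two-chain cores over 4 lengths -> closed-form pair counts
  expect_equal(sum(hg == "CDL"), 36 * 37 / 2)
  expect_identical(sum(hg == "monolyso-CDL"), 36L * 8L)
  expect_equal(sum(hg == "dilyso-CDL"), 8 * 9 / 2 + 36)
  expect_identical(sum(hg == "PE"), 44L)  # 36 intact + 8 lyso
  # CDL carbon totals span exactly 56-68
  cdl_c <- vapply(species[hg == "CDL"], `[[`, 0L, "total_carbons")
  expect_identical(range(cdl_c), c(56L, 68L))
  # exactly 5 ether classes for CDLs
  expect_identical(sort(unique(vapply(species[hg == "CDL"], `[[`, 0L,
                                      "total_ethers"))), 0:4)
  # DEG-core combinatorics: 16 ordered = 10 unordered pairs over 4 lengths
  degs <- enumerate_species(head_groups = "none", ether_counts = 2)
  expect_identical(length(degs), 10L)
  expect_identical(range(vapply(degs, `[[`, 0L, "total_carbons")),
                   c(28L, 34L))
})

test_that("mass-degenerate structures are distinct entries sharing a formula", {
  v1 <- parse_species_label("DLCDL 31:0;e2 [e17 | e14]")
  v2 <- parse_species_label("DLCDL 31:0;e2 [e17/e14 | -]")
  expect_false(identical(v1$label, v2$label))
  expect_identical(formula_string(v1$neutral_formula),
                   formula_string(v2$neutral_formula))
  species <- default_species()
  labs <- vapply(species, `[[`, "", "label")
  expect_true(all(c(v1$label, v2$label) %in% labs))
})

test_that("species_table exports one row per species with derived fields", {
  tab <- species_table(list(tetraether_cdl64()))
  expect_identical(tab$formula, "C73H150O13P2")
  expect_identical(tab$core_classes, "DEG/DEG")
  expect_equal(tab$mz_mh, 1298.0624, tolerance = 1e-3)
})
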