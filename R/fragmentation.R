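## Rule-based prediction of diagnostic MS2 ions and neutral losses.
##
## Positive-mode fragmentation of cardiolipin-family species from [M+H]+:
##   R1  water loss (free hydroxyl of the central glycerol; single loss).
##   R2  per core, neutral loss of the diradylglycerol (glycerol + chains),
##       leaving the complementary phosphatidyl-PG ion.
##   R3  each R2 ion further loses HPO3 (79.9663 Da).
##   R4  head-group ions: glycerophosphate C3H8O5P+ and glycerodiphosphate
##       C3H9O8P2+ from the central phosphatidyl-glycero-phosphatidyl moiety.
##   R5  per ether-bound chain of n carbons, an alkyl-related ion
##       C(n+3)H(2n+7)O+.
##   R6  (off by default) generic chain-loss rules for PE/PG and free
##       glycerides: acyl loss as fatty acid / ketene, ether loss as
##       alkylglycerol, protonated monoradylglycerol ions for glycerides
##       under [M+NH4]+. These extrapolate beyond the cardiolipin rules and
##       are therefore configurable.

.HPO3 <- c(H = 1, P = 1, O = 3)
.H2O <- c(H = 2, O = 1)

#' Predict diagnostic MS2 fragments for a species under an adduct
#'
#' Emits the class-specific rule set (see source header) as a fragment set:
#' ion entries carry electron-corrected theoretical m/z, neutral-loss
#' entries carry the neutral mass in Da, and every neutral-loss entry has a
#' companion ion whose formula sums with it to the precursor ion formula.
#' Fragments that require losing an acyl-containing core while an all-ether
#' core is present are tagged `abundance_hint = "low"`, reflecting that
#' mixed ether/ester cardiolipins show mostly the ions representing their
#' acyl cores.
#'
#' @param s A `lipid_species`.
#' @param adduct Precursor adduct. Cardiolipin-family and PE/PG MS2 use
#'   `"[M+H]+"`; free glycerides (`head_group = "none"`) use `"[M+NH4]+"`.
#' @param include_r6 Enable the generic R6 chain rules (default `FALSE`).
#' @return A `fragment_set`: list with `species_label`, `adduct`,
#'   `precursor_formula`, `precursor_mz` and an `entries` data.frame
#'   (`rule`, `kind`, `formula`, `mass`, `abundance_hint`).
#' @export
predict_fragments <- function(s, adduct = "[M+H]+", include_r6 = FALSE) {
  stopifnot(inherits(s, "lipid_species"))
  cdl_family <- s$head_group %in% .CDL_FAMILY
  if (cdl_family || s$head_group %in% c("PE", "PG")) {
    if (adduct != "[M+H]+") {
      stop("unsupported class/adduct pairing: ", s$head_group, " with ",
           adduct)
    }
  } else if (s$head_group == "none") {
    if (adduct != "[M+NH4]+") {
      stop("unsupported class/adduct pairing: free glyceride with ", adduct)
    }
  }

  prec_f <- apply_adduct(s$neutral_formula, adduct)
  prec_mz <- monoisotopic_mz(prec_f, charge = 1L)
  rows <- list()
  add <- function(rule, kind, f, hint, charge) {
    mass <- monoisotopic_mz(f, charge = charge)
    rows[[length(rows) + 1L]] <<- data.frame(
      rule = rule, kind = kind, formula = formula_string(f),
      mass = mass, abundance_hint = hint, stringsAsFactors = FALSE)
  }
  add_pair <- function(rule, neutral_f, hint) {
    ion_f <- combine(prec_f, neutral_f, -1L)
    add(rule, "neutral_loss", neutral_f, hint, 0L)
    add(rule, "ion", ion_f, hint, 1L)
    ion_f
  }

  if (cdl_family) {
    has_pure_ether_core <- any(vapply(s$cores, function(co)
      co$ether_count == length(co$chains), TRUE))
    ## R1: single water loss from the central glycerol hydroxyl
    add_pair("R1", elemental_formula(.H2O), "high")
    ## R2/R3, deduplicated over identical cores
    seen <- character(0)
    for (core in s$cores) {
      tok <- core_token(core)
      if (tok %in% seen) next
      seen <- c(seen, tok)
      neutral <- core_glyceride_formula(core)
      core_has_acyl <- core$ether_count < length(core$chains)
      hint <- if (core_has_acyl && has_pure_ether_core) "low" else "high"
      r2_ion <- add_pair(sprintf("R2[%s]", tok), neutral, hint)
      add(sprintf("R3[%s]", tok), "ion",
          combine(r2_ion, elemental_formula(.HPO3), -1L), hint, 1L)
    }
    ## R4: head-group ions
    add("R4", "ion", parse_formula("C3H8O5P"), "high", 1L)
    add("R4", "ion", parse_formula("C3H9O8P2"), "high", 1L)
    ## R5: per distinct ether chain
    r5_seen <- character(0)
    for (core in s$cores) for (ch in core$chains) {
      if (ch$linkage != "ether") next
      key <- chain_token(ch)
      if (key %in% r5_seen) next
      r5_seen <- c(r5_seen, key)
      n <- ch$n_carbons
      ion <- elemental_formula(c(C = n + 3, H = 2 * n + 7 - 2 * ch$n_unsat,
                                 O = 1))
      add(sprintf("R5[%s]", key), "ion", ion, "high", 1L)
    }
  }

  if (include_r6) {
    if (s$head_group %in% c("PE", "PG")) {
      seen <- character(0)
      for (core in s$cores) for (ch in core$chains) {
        key <- chain_token(ch)
        if (key %in% seen) next
        seen <- c(seen, key)
        n <- ch$n_carbons; u <- ch$n_unsat
        if (ch$linkage == "ester") {
          fa <- elemental_formula(c(C = n, H = 2 * n - 2 * u, O = 2))
          ketene <- elemental_formula(c(C = n, H = 2 * n - 2 - 2 * u, O = 1))
          add_pair(sprintf("R6fa[%s]", key), fa, "high")
          add_pair(sprintf("R6ke[%s]", key), ketene, "low")
        } else {
          akg <- elemental_formula(c(C = n + 3, H = 2 * n + 8 - 2 * u,
                                     O = 3))
          add_pair(sprintf("R6ag[%s]", key), akg, "high")
        }
      }
    } else if (s$head_group == "none") {
      ## protonated monoradylglycerol ions from [M+NH4]+ of a diradylglycerol
      seen <- character(0)
      for (core in s$cores) for (ch in core$chains) {
        key <- chain_token(ch)
        if (key %in% seen) next
        seen <- c(seen, key)
        ion <- combine(combine(elemental_formula(.SCAFFOLD$none),
                               chain_formula_delta(ch), 1L),
                       elemental_formula(c(H = 1)), 1L)
        add(sprintf("R6mg[%s]", key), "ion", ion, "high", 1L)
      }
    }
  }

  entries <- if (length(rows)) do.call(rbind, rows) else
    data.frame(rule = character(0), kind = character(0),
               formula = character(0), mass = numeric(0),
               abundance_hint = character(0), stringsAsFactors = FALSE)
  structure(
    list(species_label = s$label, adduct = adduct,
         precursor_formula = prec_f, precursor_mz = prec_mz,
         entries = entries),
    class = "fragment_set"
  )
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("<fragment_set> %s %s, precursor m/z %.4f, %d entries\n",
              x$species_label, x$adduct, x$precursor_mz, nrow(x$entries)))
  invisible(x)
}

#' Explain an observed peak against a fragment set
#'
#' @param observed_mz Observed m/z (Da).
#' @param fs A `fragment_set` from [predict_fragments()].
#' @param tol_ppm Match tolerance in ppm (default 5, accommodating the
#'   few-ppm accuracy of Orbitrap MS2 spectra).
#' @return The matching ion entries of `fs$entries` (possibly zero rows),
#'   with a `delta_ppm` column appended.
#' @export
explain_peak <- function(observed_mz, fs, tol_ppm = 5) {
  stopifnot(inherits(fs, "fragment_set"), tol_ppm > 0)
  ions <- fs$entries[fs$entries$kind == "ion", , drop = FALSE]
  if (nrow(ions) == 0) return(cbind(ions, delta_ppm = numeric(0)))
  dppm <- ppm_error(observed_mz, ions$mass)
  hit <- abs(dppm) <= tol_ppm
  out <- ions[hit, , drop = FALSE]
  out$delta_ppm <- dppm[hit]
  out
}

#' Export a fragment set as a delimited table
#'
#' @param fs A `fragment_set`.
#' @return A data.frame of entries with precursor metadata columns.
#' @export
fragment_table <- function(fs) {
  stopifnot(inherits(fs, "fragment_set"))
  cbind(
    data.frame(species = fs$species_label, adduct = fs$adduct,
               precursor_mz = fs$precursor_mz, stringsAsFactors = FALSE),
    fs$entries
  )
}

## Memoised fragment prediction, used by annotation over large candidate
## sets (the cache key covers species, adduct and the R6 switch).
.fragment_cache <- new.env(parent = emptyenv())

cached_fragments <- function(s, adduct = "[M+H]+", include_r6 = FALSE) {
  key <- paste(s$label, adduct, include_r6, sep = "\r")
  fs <- .fragment_cache[[key]]
  if (is.null(fs)) {
    fs <- predict_fragments(s, adduct, include_r6 = include_r6)
    assign(key, fs, envir = .fragment_cache)
  }
  fs
}
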