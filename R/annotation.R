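## ppm-tolerance annotation of MS1 features and MS2 spectra against an
## enumerated species x adduct index, with fragment-evidence scoring and a
## retention-order consistency check.

.C13_DELTA <- 1.0033548378  # 13C - 12C, Da

#' Construct a centroided spectrum
#'
#' @param peaks A data.frame (or 2-column matrix) with columns `mz` and
#'   `intensity`. Peaks are sorted by m/z and de-duplicated.
#' @param precursor_mz Precursor m/z; required for MS2 annotation.
#' @param retention_time Retention time in minutes (optional).
#' @param level MS level, 1 or 2.
#' @param id Spectrum identifier.
#' @return A `spectrum` object.
#' @export
new_spectrum <- function(peaks, precursor_mz = NA_real_,
                         retention_time = NA_real_, level = 2L,
                         id = NA_character_) {
  peaks <- as.data.frame(peaks)
  stopifnot(all(c("mz", "intensity") %in% names(peaks)),
            level %in% c(1L, 2L))
  if (nrow(peaks) > 0) {
    stopifnot(all(peaks$mz > 0), all(peaks$intensity >= 0))
    peaks <- peaks[order(peaks$mz), c("mz", "intensity")]
    peaks <- peaks[!duplicated(peaks$mz), , drop = FALSE]
    rownames(peaks) <- NULL
  }
  structure(
    list(peaks = peaks, precursor_mz = precursor_mz,
         retention_time = retention_time, level = as.integer(level),
         id = id),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> MS%d%s, %d peaks%s\n", x$level,
              if (!is.na(x$precursor_mz))
                sprintf(" precursor %.4f", x$precursor_mz) else "",
              nrow(x$peaks),
              if (!is.na(x$retention_time))
                sprintf(", RT %.2f min", x$retention_time) else ""))
  invisible(x)
}

#' Build a species x adduct precursor index
#'
#' One row per (species, adduct) pair with the theoretical ion m/z. For
#' cardiolipin-family species a pseudo-adduct row `"M+1"` (the 13C first
#' isotopologue of `[M+H]+`) is added so that isotope features in MS1 data can
#' be recognised and integrated, as done for CDLs in the quantification
#' policy.
#'
#' @param species List of `lipid_species`.
#' @param adducts Adducts to index; default all of [adduct_names()].
#' @param include_m1 Add the `"M+1"` row for cardiolipin-family species.
#' @return An index data.frame (`label`, `head_group`, `adduct`, `mz`,
#'   `formula`); the species objects are attached as attribute
#'   `"species"` (a named list keyed by label).
#' @export
build_species_index <- function(species, adducts = adduct_names(),
                                include_m1 = TRUE) {
  stopifnot(length(species) > 0)
  rows <- list()
  for (s in species) {
    for (ad in adducts) {
      ion <- tryCatch(apply_adduct(s$neutral_formula, ad),
                      error = function(e) NULL)
      if (is.null(ion)) next
      rows[[length(rows) + 1L]] <- data.frame(
        label = s$label, head_group = s$head_group, adduct = ad,
        mz = monoisotopic_mz(ion, charge = 1L),
        formula = formula_string(ion), stringsAsFactors = FALSE)
    }
    if (include_m1 && s$head_group %in% .CDL_FAMILY &&
        "[M+H]+" %in% adducts) {
      ion <- apply_adduct(s$neutral_formula, "[M+H]+")
      rows[[length(rows) + 1L]] <- data.frame(
        label = s$label, head_group = s$head_group, adduct = "M+1",
        mz = monoisotopic_mz(ion, charge = 1L) + .C13_DELTA,
        formula = formula_string(ion), stringsAsFactors = FALSE)
    }
  }
  idx <- do.call(rbind, rows)
  idx <- idx[order(idx$mz), , drop = FALSE]
  rownames(idx) <- NULL
  sp_list <- species
  names(sp_list) <- vapply(species, `[[`, "", "label")
  attr(idx, "species") <- sp_list
  idx
}

index_species <- function(index, label) {
  sp <- attr(index, "species")[[label]]
  if (is.null(sp)) sp <- parse_species_label(label)
  sp
}

#' Match an observed precursor m/z against the index
#'
#' @param mz Observed m/z.
#' @param index Index from [build_species_index()].
#' @param tol_ppm MS1 mass tolerance in ppm (default 3).
#' @param adducts Optional restriction to a subset of adducts.
#' @return Matching index rows with `delta_ppm`, sorted by |delta_ppm|.
#'   Tightening `tol_ppm` never adds candidates.
#' @export
match_precursor <- function(mz, index, tol_ppm = 3, adducts = NULL) {
  stopifnot(nrow(index) > 0, tol_ppm > 0, length(mz) == 1)
  rows <- index
  if (!is.null(adducts)) rows <- rows[rows$adduct %in% adducts, ,
                                      drop = FALSE]
  dppm <- ppm_error(mz, rows$mz)
  hit <- abs(dppm) <= tol_ppm
  out <- rows[hit, , drop = FALSE]
  out$delta_ppm <- dppm[hit]
  out[order(abs(out$delta_ppm), out$label), , drop = FALSE]
}

#' Annotate one MS2 spectrum
#'
#' Candidates are all species whose `[M+H]+` ion matches the precursor within
#' `tol_ppm_ms1`. Each candidate's predicted fragment set is matched against
#' the peaks at `tol_ppm_ms2`; the score is the number of distinct spectrum
#' peaks explained by predicted diagnostic ions (so mass-coincident
#' predictions are not double-counted). Candidates are ranked by score, then by fewer
#' predicted-but-unmatched entries (so a candidate whose evidence is fully
#' explained outranks a larger species matched only in part), then by fewer
#' violations of the branched-chain-at-sn-1 convention, then by precursor
#' |ppm|. Candidates still tied after these keys are mass-degenerate and
#' indistinguishable on the available evidence; they are reported together
#' with status `"isomer_set"`.
#'
#' @param sp A `spectrum` (level 2, with precursor).
#' @param index Index from [build_species_index()].
#' @param tol_ppm_ms1,tol_ppm_ms2 Mass tolerances in ppm (defaults 3 and 5).
#' @param include_r6 Enable the generic R6 chain rules during candidate
#'   fragment prediction (needed to resolve PE/PG chain splits).
#' @return An `annotation`: list with `spectrum_id`, `precursor_mz`,
#'   `candidates` (ranked data.frame with `label`, `adduct`, `theo_mz`,
#'   `delta_ppm`, `score`, `n_predicted`, `n_unmatched`, `complete`,
#'   `top`), and `status` in `"unambiguous"`, `"isomer_set"`,
#'   `"unassigned"`.
#' @export
annotate_spectrum <- function(sp, index, tol_ppm_ms1 = 3, tol_ppm_ms2 = 5,
                              include_r6 = FALSE) {
  stopifnot(inherits(sp, "spectrum"))
  if (is.na(sp$precursor_mz)) stop("spectrum has no precursor m/z")
  if (nrow(index) == 0) stop("empty species index")

  cand <- match_precursor(sp$precursor_mz, index, tol_ppm = tol_ppm_ms1,
                          adducts = "[M+H]+")
  if (nrow(cand) == 0) {
    return(structure(list(spectrum_id = sp$id,
                          precursor_mz = sp$precursor_mz,
                          candidates = cand, status = "unassigned"),
                     class = "annotation"))
  }

  peaks_mz <- sp$peaks$mz
  scored <- lapply(seq_len(nrow(cand)), function(i) {
    s <- index_species(index, cand$label[i])
    fs <- tryCatch(
      cached_fragments(s, cand$adduct[i], include_r6 = include_r6),
      error = function(e) NULL)
    ions <- if (is.null(fs)) numeric(0) else
      unique(fs$entries$mass[fs$entries$kind == "ion"])
    if (length(ions) == 0 || length(peaks_mz) == 0) {
      score <- 0L
      n_unmatched <- length(ions)
    } else {
      hit <- outer(peaks_mz, ions, function(p, m)
        abs((p - m) / m * 1e6) <= tol_ppm_ms2)
      score <- sum(rowSums(hit) > 0)  # distinct peaks explained
      n_unmatched <- sum(colSums(hit) == 0)
    }
    data.frame(label = cand$label[i], adduct = cand$adduct[i],
               theo_mz = cand$mz[i], delta_ppm = cand$delta_ppm[i],
               score = score, n_predicted = length(ions),
               n_unmatched = n_unmatched,
               sn_violations = sn_violations(s),
               complete = length(ions) > 0 && n_unmatched == 0,
               stringsAsFactors = FALSE)
  })
  cand <- do.call(rbind, scored)
  ## with zero matched fragments there is no evidence to penalise missing
  ## predictions, so the unmatched-entry key applies only to scored hits
  miss_key <- ifelse(cand$score > 0, cand$n_unmatched, 0L)
  ord <- order(-cand$score, miss_key, cand$sn_violations,
               abs(cand$delta_ppm), cand$label)
  cand <- cand[ord, , drop = FALSE]
  miss_key <- miss_key[ord]
  rownames(cand) <- NULL

  tie <- cand$score == cand$score[1] &
    miss_key == miss_key[1] &
    cand$sn_violations == cand$sn_violations[1] &
    abs(abs(cand$delta_ppm) - abs(cand$delta_ppm[1])) < 1e-12
  cand$top <- tie
  status <- if (sum(tie) > 1) "isomer_set" else "unambiguous"

  structure(list(spectrum_id = sp$id, precursor_mz = sp$precursor_mz,
                 candidates = cand, status = status),
            class = "annotation")
}

#' @export
print.annotation <- function(x, ...) {
  cat(sprintf("<annotation> %s: %s\n",
              if (is.na(x$spectrum_id)) "spectrum" else x$spectrum_id,
              x$status))
  if (nrow(x$candidates) > 0) {
    print(utils::head(x$candidates[, c("label", "score", "n_unmatched",
                                       "delta_ppm")], 5))
  }
  invisible(x)
}

#' Annotate a batch of MS2 spectra
#'
#' @param spectra List of `spectrum` objects.
#' @inheritParams annotate_spectrum
#' @return A data.frame with one row per spectrum: `spectrum_id`,
#'   `precursor_mz`, `status`, `top_label` (first ranked candidate),
#'   `top_set` (all tied top candidates, `;`-separated),
#'   `reported_set` (top tie group union fully-matched candidates),
#'   `score`.
#' @export
annotate_spectra <- function(spectra, index, tol_ppm_ms1 = 3,
                             tol_ppm_ms2 = 5, include_r6 = FALSE) {
  rows <- lapply(spectra, function(sp) {
    ann <- annotate_spectrum(sp, index, tol_ppm_ms1, tol_ppm_ms2,
                             include_r6)
    cc <- ann$candidates
    data.frame(
      spectrum_id = sp$id, precursor_mz = sp$precursor_mz,
      status = ann$status,
      top_label = if (nrow(cc)) cc$label[1] else NA_character_,
      top_set = if (nrow(cc)) paste(cc$label[cc$top], collapse = "\t")
                else NA_character_,
      reported_set = if (nrow(cc))
        paste(unique(cc$label[cc$top | cc$complete]), collapse = "\t")
        else NA_character_,
      score = if (nrow(cc)) cc$score[1] else NA_integer_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Annotate an MS1 feature table
#'
#' Assigns each feature the best-matching (species, adduct) identity by
#' exact mass. Features whose m/z matches several mass-degenerate species
#' equally are assigned the isomer set's first label; this is sufficient
#' for class-level quantification because mass-degenerate species share
#' head group, ether count and carbon number.
#'
#' @param features A data.frame with columns `mz` and `area` (and
#'   optionally `feature_id`, `rt`).
#' @param index Index from [build_species_index()].
#' @param tol_ppm MS1 tolerance in ppm (default 3).
#' @return The feature table with `label`, `adduct`, `delta_ppm` and
#'   `n_isomers` columns appended; unmatched features carry `NA`.
#' @export
annotate_features <- function(features, index, tol_ppm = 3) {
  stopifnot(all(c("mz", "area") %in% names(features)))
  res <- lapply(features$mz, function(mz) {
    hits <- match_precursor(mz, index, tol_ppm = tol_ppm)
    if (nrow(hits) == 0) {
      return(data.frame(label = NA_character_, adduct = NA_character_,
                        delta_ppm = NA_real_, n_isomers = 0L,
                        stringsAsFactors = FALSE))
    }
    best <- abs(abs(hits$delta_ppm) - abs(hits$delta_ppm[1])) < 1e-9
    data.frame(label = hits$label[1], adduct = hits$adduct[1],
               delta_ppm = hits$delta_ppm[1], n_isomers = sum(best),
               stringsAsFactors = FALSE)
  })
  cbind(features, do.call(rbind, res))
}

#' Check elution-order consistency of annotated features
#'
#' Within groups sharing head group, chain count and total carbons, a
#' species with more ether-bound chains is expected to elute earlier.
#' Pairs violating this (higher ether count, later retention time) are
#' flagged.
#'
#' @param features A data.frame with columns `label` and `retention_time`.
#' @return A data.frame of violating pairs (possibly zero rows).
#' @export
check_rt_ordering <- function(features) {
  stopifnot(all(c("label", "retention_time") %in% names(features)))
  sp <- lapply(features$label, parse_species_label)
  df <- data.frame(
    label = features$label,
    rt = features$retention_time,
    head_group = vapply(sp, `[[`, "", "head_group"),
    n_chains = vapply(sp, `[[`, 0L, "n_chains"),
    carbons = vapply(sp, `[[`, 0L, "total_carbons"),
    ethers = vapply(sp, `[[`, 0L, "total_ethers"),
    stringsAsFactors = FALSE)
  out <- list()
  key <- paste(df$head_group, df$n_chains, df$carbons)
  for (grp in split(seq_len(nrow(df)), key)) {
    if (length(grp) < 2) next
    for (i in grp) for (j in grp) {
      if (df$ethers[i] > df$ethers[j] && df$rt[i] > df$rt[j]) {
        out[[length(out) + 1L]] <- data.frame(
          label_more_ethers = df$label[i], rt_more_ethers = df$rt[i],
          label_fewer_ethers = df$label[j], rt_fewer_ethers = df$rt[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(label_more_ethers = character(0),
                      rt_more_ethers = numeric(0),
                      label_fewer_ethers = character(0),
                      rt_fewer_ethers = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
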