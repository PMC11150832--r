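## Relative quantification from integrated extracted-ion-chromatogram (XIC)
## areas, following the positive-mode adduct policy: per-class adduct sums,
## with the 13C first-isotopologue (M+1) area of the [M+H]+ ion folded in
## for cardiolipin-family species, whose large carbon number shifts much of
## the ion current into the M+1 peak. No cross-class response-factor
## correction is applied: different phospholipid classes ionise with
## different efficiency and reported values are uncorrected (flagged in the
## output metadata).

#' Default quantification policy
#'
#' @param m1 How to use the cardiolipin M+1 area: `"sum"` (add it to the
#'   adduct sum, recapturing signal lost to the isotope peak; default),
#'   `"scale"` (divide the combined monoisotopic + M+1 area of `[M+H]+` by
#'   `1 + m1_ratio`, the standard isotopologue correction, equivalent to
#'   ignoring the M+1 peak when its area is exactly theoretical), or
#'   `"ignore"`.
#' @param adducts Named list mapping head group to the adducts whose areas
#'   are summed.
#' @return A `quant_policy` list.
#' @export
quant_policy <- function(m1 = c("sum", "scale", "ignore"),
                         adducts = NULL) {
  m1 <- match.arg(m1)
  if (is.null(adducts)) {
    cdl_adducts <- c("[M+H]+", "[M+H-H2O]+", "[M+NH4]+", "[M+Na]+")
    adducts <- list(
      PE = c("[M+H]+", "[M+NH4]+"),
      PG = c("[M+H]+", "[M+NH4]+"),
      CDL = cdl_adducts,
      `monolyso-CDL` = cdl_adducts,
      `dilyso-CDL` = cdl_adducts,
      none = "[M+NH4]+")
  }
  structure(list(m1 = m1, adducts = adducts), class = "quant_policy")
}

#' Relative abundances from an XIC table
#'
#' @param xics A data.frame with columns `label` (species label or isomer
#'   set representative), `adduct` (an adduct name or `"M+1"`), `area`
#'   (integrated area, >= 0).
#' @param policy A [quant_policy()].
#' @return A data.frame (`label`, `head_group`, `abundance`, `percent`)
#'   with percents summing to 100; attribute
#'   `"response_corrected" = FALSE` records that class responses are
#'   uncorrected.
#' @export
quantify <- function(xics, policy = quant_policy()) {
  stopifnot(all(c("label", "adduct", "area") %in% names(xics)),
            all(xics$area >= 0), inherits(policy, "quant_policy"))
  labels <- unique(xics$label)
  rows <- lapply(labels, function(lb) {
    sp <- parse_species_label(lb)
    hg <- sp$head_group
    allowed <- policy$adducts[[hg]]
    if (is.null(allowed)) stop("no adduct policy for head group ", hg)
    sub <- xics[xics$label == lb, , drop = FALSE]
    main <- sum(sub$area[sub$adduct %in% allowed])
    if (!any(sub$adduct %in% allowed)) {
      stop("species '", lb, "' has no area for any configured adduct")
    }
    m1_area <- sum(sub$area[sub$adduct == "M+1"])
    use_m1 <- hg %in% .CDL_FAMILY && policy$m1 != "ignore"
    ab <- if (!use_m1) {
      main
    } else if (policy$m1 == "sum") {
      main + m1_area
    } else { # scale
      r <- m1_ratio(apply_adduct(sp$neutral_formula, "[M+H]+"))
      mh <- sum(sub$area[sub$adduct == "[M+H]+"])
      (main - mh) + (mh + m1_area) / (1 + r)
    }
    data.frame(label = lb, head_group = hg, abundance = ab,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$percent <- out$abundance / sum(out$abundance) * 100
  attr(out, "response_corrected") <- FALSE
  out
}

## Derived class key distinguishing intact from lyso PE/PG (mirrors the
## class panels of membrane-lipidome bar charts).
species_class_key <- function(label) {
  vapply(label, function(lb) {
    sp <- parse_species_label(lb)
    if (sp$head_group %in% c("PE", "PG") && sp$n_chains == 1L) {
      paste0("lyso-", sp$head_group)
    } else {
      sp$head_group
    }
  }, "", USE.NAMES = FALSE)
}

#' Marginal composition report
#'
#' Aggregates species-level percents into marginal distributions over the
#' requested keys (head-group class, ether count, total carbons, core
#' classes), renormalised to 100 within each group declared by `within`.
#'
#' @param abundances Output of [quantify()], or any data.frame with
#'   `label` and `percent` columns.
#' @param group_by Character vector of grouping keys, from `"class"`
#'   (head group with lyso split), `"head_group"`, `"ether_count"`,
#'   `"total_carbons"`, `"core_classes"`.
#' @param within Optional subset of `group_by` defining the normalisation
#'   groups (percent sums to 100 within each); default: the whole table.
#' @return A data.frame with the grouping columns and `percent`.
#' @export
composition_report <- function(abundances,
                               group_by = "ether_count",
                               within = NULL) {
  stopifnot(nrow(abundances) > 0,
            all(c("label", "percent") %in% names(abundances)))
  known <- c("class", "head_group", "ether_count", "total_carbons",
             "core_classes")
  stopifnot(all(group_by %in% known), all(within %in% group_by))
  sp <- lapply(abundances$label, parse_species_label)
  cols <- list(
    class = species_class_key(abundances$label),
    head_group = vapply(sp, `[[`, "", "head_group"),
    ether_count = vapply(sp, `[[`, 0L, "total_ethers"),
    total_carbons = vapply(sp, `[[`, 0L, "total_carbons"),
    core_classes = vapply(sp, function(s)
      paste(sort(vapply(s$cores, `[[`, "", "class")), collapse = "/"), ""))
  df <- as.data.frame(cols[group_by], stringsAsFactors = FALSE)
  agg <- stats::aggregate(list(percent = abundances$percent), by = df, sum)
  if (is.null(within) || length(within) == 0) {
    agg$percent <- agg$percent / sum(agg$percent) * 100
  } else {
    key <- do.call(paste, agg[within])
    agg$percent <- agg$percent / stats::ave(agg$percent, key, FUN = sum) * 100
  }
  ord <- do.call(order, agg[group_by])
  agg <- agg[ord, , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
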