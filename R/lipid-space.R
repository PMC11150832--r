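## Structural model of ether/ester glycerophospholipids and cardiolipins.
##
## A species = head group + 1 or 2 core glycerides, each core carrying 1 or 2
## radyl chains bound by an ether (alkyl) or ester (acyl) linkage. Acyl chain
## length n includes the carbonyl carbon, so an ether<->ester substitution at
## fixed n changes the formula by -2H +1O and leaves total carbons unchanged.

## Head-group scaffolds: the neutral formula of the species with zero chains
## (all chain positions as free hydroxyls). Chains substitute onto these.
.SCAFFOLD <- list(
  none = c(C = 3, H = 8, O = 3),                 # glycerol
  PE   = c(C = 5, H = 14, N = 1, O = 6, P = 1),
  PG   = c(C = 6, H = 15, O = 8, P = 1),
  CDL  = c(C = 9, H = 22, O = 13, P = 2)
)
.CDL_FAMILY <- c("CDL", "monolyso-CDL", "dilyso-CDL")
.HEAD_GROUPS <- c("PE", "PG", .CDL_FAMILY, "none")

.HEAD_TOKEN <- c(PE = "PE", PG = "PG", CDL = "CDL",
                 "monolyso-CDL" = "MLCDL", "dilyso-CDL" = "DLCDL",
                 none = "FG")

#' Construct a radyl chain
#'
#' @param n_carbons Chain length; for acyl chains this includes the carbonyl
#'   carbon (so ether/ester substitution preserves total carbon counts).
#' @param linkage `"ether"` (alkyl, C-O-C) or `"ester"` (acyl).
#' @param n_unsat Number of double bonds (default 0; the modelled lipidome is
#'   fully saturated).
#' @param sn Optional sn position (1 or 2) on the glycerol backbone.
#'   Metadata only: mass spectra cannot distinguish it.
#' @param branch_note Optional free-text branching annotation (e.g.
#'   `"10-Me-C16"`); mass-neutral.
#' @return A `radyl_chain` object.
#' @export
radyl_chain <- function(n_carbons, linkage = c("ether", "ester"),
                        n_unsat = 0L, sn = NA_integer_, branch_note = NULL) {
  linkage <- match.arg(linkage)
  stopifnot(n_carbons >= 1, n_unsat >= 0)
  if (!is.na(sn)) stopifnot(sn %in% c(1L, 2L))
  structure(
    list(n_carbons = as.integer(n_carbons), linkage = linkage,
         n_unsat = as.integer(n_unsat), sn = as.integer(sn),
         branch_note = branch_note),
    class = "radyl_chain"
  )
}

## Formula contribution of one chain substituting a scaffold hydroxyl.
chain_formula_delta <- function(chain) {
  n <- chain$n_carbons
  if (chain$linkage == "ether") {
    f <- c(C = n, H = 2 * n)
  } else {
    f <- c(C = n, H = 2 * n - 2, O = 1)
  }
  f["H"] <- f["H"] - 2L * chain$n_unsat
  if (f["H"] < 0) stop("unsaturation count exceeds chain capacity")
  elemental_formula(f)
}

#' Construct a core glyceride from 1 or 2 radyl chains
#'
#' The core class is derived from chain count and linkages: DEG (dialkyl),
#' AEG (alkyl/acyl), DAG (diacyl), MEG (monoalkyl), MAG (monoacyl). Chains
#' are stored in canonical order (descending carbons, ether before ester on
#' ties) and, unless given, sn positions follow the convention that the
#' methyl-branched (odd-carbon) chain sits at sn-1.
#'
#' @param chains A list of 1 or 2 `radyl_chain` objects.
#' @return A `core_lipid` object with fields `chains`, `class`,
#'   `ether_count`, `n_carbons`.
#' @export
core_lipid <- function(chains) {
  if (inherits(chains, "radyl_chain")) chains <- list(chains)
  stopifnot(length(chains) %in% c(1L, 2L),
            all(vapply(chains, inherits, TRUE, "radyl_chain")))
  ord <- order(-vapply(chains, `[[`, 0L, "n_carbons"),
               vapply(chains, function(ch) ch$linkage != "ether", TRUE))
  chains <- chains[ord]
  chains <- assign_sn(chains)
  linkages <- vapply(chains, `[[`, "", "linkage")
  n_eth <- sum(linkages == "ether")
  cls <- if (length(chains) == 2L) {
    c("DAG", "AEG", "DEG")[n_eth + 1L]
  } else {
    c("MAG", "MEG")[n_eth + 1L]
  }
  structure(
    list(chains = chains, class = cls, ether_count = n_eth,
         n_carbons = sum(vapply(chains, `[[`, 0L, "n_carbons")),
         n_unsat = sum(vapply(chains, `[[`, 0L, "n_unsat"))),
    class = "core_lipid"
  )
}

## sn convention: odd-carbon chains are 10-methyl-branched and sit at sn-1.
## Explicit sn values are honoured; otherwise positions are assigned here.
assign_sn <- function(chains) {
  if (length(chains) == 1L) {
    if (is.na(chains[[1]]$sn)) chains[[1]]$sn <- 1L
  } else if (any(vapply(chains, function(ch) is.na(ch$sn), TRUE))) {
    odd <- vapply(chains, function(ch) ch$n_carbons %% 2L == 1L, TRUE)
    first_sn1 <- !(odd[2] && !odd[1])
    chains[[1]]$sn <- if (first_sn1) 1L else 2L
    chains[[2]]$sn <- if (first_sn1) 2L else 1L
  }
  for (i in seq_along(chains)) {
    ch <- chains[[i]]
    if (is.null(ch$branch_note) && ch$n_carbons %% 2L == 1L) {
      chains[[i]]$branch_note <- sprintf("10-Me-C%d", ch$n_carbons - 1L)
    }
  }
  chains
}

## Count cores where a branched (odd) chain sits at sn-2 while an unbranched
## chain occupies sn-1; used as an annotation tie-break.
sn_violations <- function(species) {
  sum(vapply(species$cores, function(core) {
    if (length(core$chains) < 2L) return(0L)
    odd <- vapply(core$chains, function(ch) ch$n_carbons %% 2L == 1L, TRUE)
    sn <- vapply(core$chains, `[[`, 0L, "sn")
    as.integer(any(odd & sn == 2L) && any(!odd & sn == 1L))
  }, 0L))
}

core_formula_delta <- function(core) {
  out <- elemental_formula(numeric(0))
  for (ch in core$chains) out <- combine(out, chain_formula_delta(ch), 1L)
  out
}

## Neutral formula of the core as a free glyceride (glycerol + chains);
## this is also the R2 neutral-loss composition.
core_glyceride_formula <- function(core) {
  combine(elemental_formula(.SCAFFOLD$none), core_formula_delta(core), 1L)
}

#' Build a lipid species
#'
#' Assembles the neutral elemental formula from the head-group scaffold plus
#' per-chain substitutions and derives totals (carbons, ether bonds).
#'
#' @param head_group One of `"PE"`, `"PG"`, `"CDL"`, `"monolyso-CDL"`,
#'   `"dilyso-CDL"`, `"none"` (free glyceride).
#' @param cores A `core_lipid` or list of cores. Arity is validated: CDL
#'   takes two 2-chain cores; monolyso-CDL one 2-chain and one 1-chain core;
#'   dilyso-CDL either two 1-chain cores or (variant `"intact-core+PGPG"`)
#'   a single 2-chain core; PE/PG and free glycerides take one core.
#' @param dilyso_variant For dilyso-CDL only: `"two-monolyso-cores"` or
#'   `"intact-core+PGPG"`. Inferred from core arity when missing. The two
#'   variants share one neutral formula (they are mass-isomeric) and are
#'   only separable through fragmentation or retention behaviour.
#' @return A `lipid_species` object.
#' @examples
#' s <- build_species("CDL", list(
#'   core_lipid(list(radyl_chain(17, "ether"), radyl_chain(16, "ether"))),
#'   core_lipid(list(radyl_chain(17, "ether"), radyl_chain(14, "ether")))))
#' formula_string(s$neutral_formula)  # "C73H150O13P2"
#' @export
build_species <- function(head_group, cores, dilyso_variant = NULL) {
  head_group <- match.arg(head_group, .HEAD_GROUPS)
  if (inherits(cores, "core_lipid")) cores <- list(cores)
  stopifnot(length(cores) >= 1L,
            all(vapply(cores, inherits, TRUE, "core_lipid")))
  sizes <- vapply(cores, function(co) length(co$chains), 0L)

  if (head_group == "CDL") {
    if (length(cores) != 2L || any(sizes != 2L)) {
      stop("CDL requires two cores of two chains each")
    }
  } else if (head_group == "monolyso-CDL") {
    if (length(cores) != 2L || !setequal(sizes, c(1L, 2L)) ||
        sum(sizes) != 3L) {
      stop("monolyso-CDL requires one 2-chain and one 1-chain core")
    }
  } else if (head_group == "dilyso-CDL") {
    if (length(cores) == 2L && all(sizes == 1L)) {
      if (is.null(dilyso_variant)) dilyso_variant <- "two-monolyso-cores"
      if (dilyso_variant != "two-monolyso-cores") {
        stop("two 1-chain cores imply variant 'two-monolyso-cores'")
      }
    } else if (length(cores) == 1L && sizes == 2L) {
      if (is.null(dilyso_variant)) dilyso_variant <- "intact-core+PGPG"
      if (dilyso_variant != "intact-core+PGPG") {
        stop("a single 2-chain core implies variant 'intact-core+PGPG'")
      }
    } else {
      stop("dilyso-CDL carries exactly two chains in total")
    }
  } else {
    if (length(cores) != 1L) stop(head_group, " takes a single core")
    dilyso_variant <- NULL
  }

  scaffold_name <- if (head_group %in% .CDL_FAMILY) "CDL" else head_group
  f <- elemental_formula(.SCAFFOLD[[scaffold_name]])
  for (core in cores) f <- combine(f, core_formula_delta(core), 1L)

  ## canonical core order: larger core first, more ethers first
  if (length(cores) == 2L) {
    key <- vapply(cores, function(co)
      sprintf("%03d-%d-%s", co$n_carbons, co$ether_count, core_token(co)), "")
    cores <- cores[order(key, decreasing = TRUE)]
  }

  sp <- structure(
    list(head_group = head_group, cores = cores,
         dilyso_variant = dilyso_variant,
         total_carbons = sum(vapply(cores, `[[`, 0L, "n_carbons")),
         total_unsat = sum(vapply(cores, `[[`, 0L, "n_unsat")),
         total_ethers = sum(vapply(cores, `[[`, 0L, "ether_count")),
         n_chains = sum(sizes),
         neutral_formula = f),
    class = "lipid_species"
  )
  sp$label <- species_label(sp)
  sp
}

chain_token <- function(ch) {
  paste0(if (ch$linkage == "ether") "e" else "a", ch$n_carbons,
         if (ch$n_unsat > 0) paste0(":", ch$n_unsat) else "")
}

core_token <- function(core) {
  paste(vapply(core$chains, chain_token, ""), collapse = "/")
}

#' Canonical species label
#'
#' Deterministic text encoding of a species: head group token, total
#' carbons:unsaturations, ether count, and the per-core chain split, e.g.
#' `"CDL 64:0;e4 [e17/e16 | e17/e14]"`. A dilyso-CDL of the intact-core
#' variant shows its empty core position as `-`. `parse_species_label()`
#' inverts it.
#'
#' @param s A `lipid_species`.
#' @return Character scalar.
#' @export
species_label <- function(s) {
  stopifnot(inherits(s, "lipid_species"))
  cores_txt <- vapply(s$cores, core_token, "")
  if (identical(s$dilyso_variant, "intact-core+PGPG")) {
    cores_txt <- c(cores_txt, "-")
  }
  sprintf("%s %d:%d;e%d [%s]", .HEAD_TOKEN[[s$head_group]],
          s$total_carbons, s$total_unsat, s$total_ethers,
          paste(cores_txt, collapse = " | "))
}

#' Parse a canonical species label back into a species
#'
#' @param label A label produced by [species_label()].
#' @return A `lipid_species`; `species_label(parse_species_label(x))`
#'   round-trips.
#' @export
parse_species_label <- function(label) {
  m <- regmatches(label,
    regexec("^(\\S+) (\\d+):(\\d+);e(\\d+) \\[(.*)\\]$", label))[[1]]
  if (length(m) == 0) stop("malformed species label: '", label, "'")
  head_group <- names(.HEAD_TOKEN)[match(m[2], .HEAD_TOKEN)]
  if (is.na(head_group)) stop("unknown head-group token: '", m[2], "'")
  core_txts <- trimws(strsplit(m[6], "|", fixed = TRUE)[[1]])
  variant <- NULL
  if (any(core_txts == "-")) {
    core_txts <- core_txts[core_txts != "-"]
    variant <- "intact-core+PGPG"
  }
  cores <- lapply(core_txts, function(txt) {
    chains <- lapply(strsplit(txt, "/", fixed = TRUE)[[1]], function(tok) {
      cm <- regmatches(tok, regexec("^([ea])(\\d+)(?::(\\d+))?$", tok))[[1]]
      if (length(cm) == 0) stop("malformed chain token: '", tok, "'")
      radyl_chain(as.integer(cm[3]),
                  linkage = if (cm[2] == "e") "ether" else "ester",
                  n_unsat = if (cm[4] == "") 0L else as.integer(cm[4]))
    })
    core_lipid(chains)
  })
  sp <- build_species(head_group, cores, dilyso_variant = variant)
  if (sp$total_carbons != as.integer(m[3]) ||
      sp$total_unsat != as.integer(m[4]) ||
      sp$total_ethers != as.integer(m[5])) {
    stop("label totals disagree with chain split: '", label, "'")
  }
  sp
}

#' @export
print.lipid_species <- function(x, ...) {
  cat("<lipid_species>", x$label, " ",
      formula_string(x$neutral_formula),
      sprintf(" (neutral %.4f Da)\n", monoisotopic_mz(x$neutral_formula)))
  invisible(x)
}

## ---- Enumeration ---------------------------------------------------------

two_chain_cores <- function(chain_lengths, unsat = 0L) {
  out <- list()
  lens <- sort(unique(as.integer(chain_lengths)))
  for (a in lens) for (b in lens[lens <= a]) {
    combos <- list(c("ether", "ether"), c("ester", "ester"),
                   c("ether", "ester"))
    if (a != b) combos <- c(combos, list(c("ester", "ether")))
    for (lk in combos) for (u in unsat) {
      out[[length(out) + 1L]] <- core_lipid(list(
        radyl_chain(a, lk[1], n_unsat = u),
        radyl_chain(b, lk[2])))
    }
  }
  ## deduplicate on canonical token (symmetric combos coincide when a == b)
  out[!duplicated(vapply(out, core_token, ""))]
}

one_chain_cores <- function(chain_lengths, unsat = 0L) {
  out <- list()
  for (n in sort(unique(as.integer(chain_lengths)))) {
    for (lk in c("ether", "ester")) for (u in unsat) {
      out[[length(out) + 1L]] <- core_lipid(list(
        radyl_chain(n, lk, n_unsat = u)))
    }
  }
  out[!duplicated(vapply(out, core_token, ""))]
}

#' Enumerate the lipid species space
#'
#' Exhaustive, duplicate-free enumeration of species over the given chain
#' lengths, head groups and ether counts. Species that are mass-degenerate
#' but structurally distinct (different chain splits; the two dilyso-CDL
#' variants) are separate entries sharing a neutral formula. The defaults
#' reproduce the modelled lipidome: chains of 14-17 carbons, fully
#' saturated, 0-4 ether bonds.
#'
#' @param chain_lengths Integer vector of chain lengths (default `14:17`).
#' @param head_groups Subset of `"PE"`, `"PG"`, `"CDL"`, `"monolyso-CDL"`,
#'   `"dilyso-CDL"`, `"none"`.
#' @param ether_counts Total-ether filter (default `0:4`).
#' @param unsat Per-chain unsaturation values to enumerate (default `0`).
#' @param include_lyso For PE/PG: also emit single-chain (lyso) species.
#' @return A list of `lipid_species`.
#' @export
enumerate_species <- function(chain_lengths = 14:17,
                              head_groups = c("PE", "PG", "CDL",
                                              "monolyso-CDL", "dilyso-CDL"),
                              ether_counts = 0:4,
                              unsat = 0L,
                              include_lyso = TRUE) {
  stopifnot(length(chain_lengths) > 0, length(head_groups) > 0,
            length(ether_counts) > 0)
  head_groups <- match.arg(head_groups, .HEAD_GROUPS, several.ok = TRUE)
  cores2 <- two_chain_cores(chain_lengths, unsat)
  cores1 <- one_chain_cores(chain_lengths, unsat)
  out <- list()
  add <- function(sp) {
    if (sp$total_ethers %in% ether_counts) out[[length(out) + 1L]] <<- sp
  }
  for (hg in head_groups) {
    if (hg == "CDL") {
      for (i in seq_along(cores2)) for (j in i:length(cores2)) {
        add(build_species("CDL", list(cores2[[i]], cores2[[j]])))
      }
    } else if (hg == "monolyso-CDL") {
      for (c2 in cores2) for (c1 in cores1) {
        add(build_species("monolyso-CDL", list(c2, c1)))
      }
    } else if (hg == "dilyso-CDL") {
      for (i in seq_along(cores1)) for (j in i:length(cores1)) {
        add(build_species("dilyso-CDL", list(cores1[[i]], cores1[[j]])))
      }
      for (c2 in cores2) {
        add(build_species("dilyso-CDL", list(c2),
                          dilyso_variant = "intact-core+PGPG"))
      }
    } else {
      for (c2 in cores2) add(build_species(hg, list(c2)))
      if (include_lyso && hg %in% c("PE", "PG")) {
        for (c1 in cores1) add(build_species(hg, list(c1)))
      }
    }
  }
  out[!duplicated(vapply(out, `[[`, "", "label"))]
}

#' Tabulate a species list
#'
#' @param species A list of `lipid_species` (e.g. from
#'   [enumerate_species()]).
#' @return A data.frame with label, class fields, formula, neutral mass and
#'   `[M+H]+` m/z, one row per species.
#' @export
species_table <- function(species) {
  if (inherits(species, "lipid_species")) species <- list(species)
  stopifnot(length(species) > 0)
  data.frame(
    label = vapply(species, `[[`, "", "label"),
    head_group = vapply(species, `[[`, "", "head_group"),
    core_classes = vapply(species, function(s)
      paste(vapply(s$cores, `[[`, "", "class"), collapse = "/"), ""),
    total_carbons = vapply(species, `[[`, 0L, "total_carbons"),
    total_unsat = vapply(species, `[[`, 0L, "total_unsat"),
    total_ethers = vapply(species, `[[`, 0L, "total_ethers"),
    n_chains = vapply(species, `[[`, 0L, "n_chains"),
    formula = vapply(species, function(s)
      formula_string(s$neutral_formula), ""),
    neutral_mass = vapply(species, function(s)
      monoisotopic_mz(s$neutral_formula), 0),
    mz_mh = vapply(species, function(s)
      adduct_mz(s$neutral_formula, "[M+H]+"), 0),
    stringsAsFactors = FALSE
  )
}
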