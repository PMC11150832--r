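#' @keywords internal
"_PACKAGE"

## Monoisotopic atomic masses (NIST/CODATA). ppm-level agreement with printed
## ion masses requires >= 6 decimals, so these are embedded as constants
## rather than taken from a lower-precision table.
.ATOMIC_MASS <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  Na = 22.9897692809
)

.ELECTRON_MASS <- 0.00054857991

## Minor/major abundance ratios for the +1 Da isotopes (13C, 2H, 15N, 17O);
## P and Na are monoisotopic. IUPAC 2021 values.
.M1_RATIO <- c(
  C  = 0.010816,
  H  = 0.000156,
  N  = 0.003676,
  O  = 0.000380,
  P  = 0,
  Na = 0
)

.HILL_ORDER <- c("C", "H", "N", "Na", "O", "P")

#' Construct an elemental formula
#'
#' An elemental formula is a named integer vector mapping element symbols
#' (C, H, N, O, P, Na) to non-negative counts. Elements with count zero are
#' dropped, and elements are stored in Hill order (C, H, then alphabetical).
#'
#' @param counts Named numeric vector of element counts.
#' @return An object of class `elemental_formula`.
#' @examples
#' elemental_formula(c(C = 34, H = 70, O = 3))
#' @export
elemental_formula <- function(counts) {
  if (length(counts) == 0) {
    out <- integer(0)
    names(out) <- character(0)
    class(out) <- "elemental_formula"
    return(out)
  }
  if (is.null(names(counts)) || any(names(counts) == "")) {
    stop("element counts must be named")
  }
  unknown <- setdiff(names(counts), names(.ATOMIC_MASS))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  if (any(counts < 0)) {
    stop("negative element count: formula is not a valid neutral composition")
  }
  if (any(counts != round(counts))) stop("element counts must be integers")
  counts <- tapply(as.integer(round(counts)), names(counts), sum)
  counts <- counts[counts > 0]
  ord <- match(names(counts), .HILL_ORDER)
  out <- as.integer(counts[order(ord)])
  names(out) <- names(counts)[order(ord)]
  class(out) <- "elemental_formula"
  out
}

#' Parse a Hill-notation formula string
#'
#' @param text Formula string such as `"C34H70O3"` or `"H2O"`. Counts may be
#'   multi-digit; an omitted count means 1. Two-letter symbols (Na) are
#'   recognised.
#' @return An `elemental_formula`.
#' @examples
#' parse_formula("C73H151O13P2")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  text <- trimws(text)
  if (text == "" || text == "0") return(elemental_formula(numeric(0)))
  matches <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  pieces <- regmatches(text, gregexpr("([A-Z][a-z]?)([0-9]*)", text))[[1]]
  if (sum(attr(matches, "match.length")) != nchar(text)) {
    stop("malformed formula text: '", text, "'")
  }
  syms <- sub("[0-9]*$", "", pieces)
  nums <- sub("^[A-Z][a-z]?", "", pieces)
  counts <- ifelse(nums == "", 1L, suppressWarnings(as.integer(nums)))
  if (anyNA(counts)) stop("malformed formula text: '", text, "'")
  names(counts) <- syms
  elemental_formula(counts)
}

#' Render a formula in Hill notation
#'
#' @param f An `elemental_formula`.
#' @return Character scalar; `""` for the empty formula.
#' @export
formula_string <- function(f) {
  f <- as_formula(f)
  if (length(f) == 0) return("")
  paste0(names(f), ifelse(unclass(f) == 1, "", unclass(f)), collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<formula>", if (length(x) == 0) "(empty)" else formula_string(x), "\n")
  invisible(x)
}

#' @export
format.elemental_formula <- function(x, ...) formula_string(x)

as_formula <- function(f) {
  if (inherits(f, "elemental_formula")) return(f)
  if (is.character(f)) return(parse_formula(f))
  elemental_formula(f)
}

#' Add or subtract elemental formulas
#'
#' Element-wise sum (`sign = +1`) or difference (`sign = -1`). A negative
#' count on subtraction signals a chemically impossible neutral loss and is
#' an error.
#'
#' @param a,b Elemental formulas (or strings, parsed on the fly).
#' @param sign `+1` or `-1`.
#' @return An `elemental_formula`.
#' @examples
#' combine("C73H151O13P2", "C34H70O3", -1)  # -> C39H81O10P2
#' @export
combine <- function(a, b, sign = 1L) {
  stopifnot(sign %in% c(1L, -1L))
  a <- as_formula(a); b <- as_formula(b)
  elems <- union(names(a), names(b))
  av <- ifelse(elems %in% names(a), unclass(a)[elems], 0L)
  bv <- ifelse(elems %in% names(b), unclass(b)[elems], 0L)
  av[is.na(av)] <- 0L; bv[is.na(bv)] <- 0L
  res <- av + sign * bv
  if (any(res < 0)) {
    bad <- elems[res < 0]
    stop("impossible neutral loss: negative count for ",
         paste(bad, collapse = ", "))
  }
  names(res) <- elems
  elemental_formula(res)
}

#' Monoisotopic mass or m/z of a formula
#'
#' For `charge = 0` the sum of monoisotopic atomic masses is returned. For
#' `charge = +1` one electron mass is subtracted: the convention is that the
#' ionising adduct atoms (the proton or cation) are already part of the
#' formula, matching how ion compositions are printed in positive-mode
#' lipidomics (e.g. the `[M+H]+` ion of a C73H150O13P2 cardiolipin is written
#' C73H151O13P2).
#'
#' @param f An `elemental_formula` (or string).
#' @param charge 0 (neutral mass, Da) or 1 (singly charged cation m/z).
#' @return Numeric scalar, Da.
#' @examples
#' monoisotopic_mz("H2O")                      # 18.0106
#' monoisotopic_mz("C73H151O13P2", charge = 1) # 1298.0624
#' @export
monoisotopic_mz <- function(f, charge = 0L) {
  f <- as_formula(f)
  if (length(f) == 0) stop("empty formula has no mass")
  stopifnot(charge %in% c(0L, 1L))
  mass <- sum(.ATOMIC_MASS[names(f)] * unclass(f))
  if (charge == 1L) mass <- mass - .ELECTRON_MASS
  unname(mass)
}

#' Signed relative mass error in parts per million
#'
#' `(observed - theoretical) / theoretical * 1e6`.
#'
#' @param observed,theoretical Masses in Da; `theoretical` must be > 0.
#' @return Signed ppm error.
#' @export
ppm_error <- function(observed, theoretical) {
  stopifnot(all(theoretical > 0))
  (observed - theoretical) / theoretical * 1e6
}

#' Expected M+1 isotopologue intensity ratio
#'
#' Expected intensity of the first isotopologue peak (one +1 Da isotope
#' substitution: 13C, 2H, 15N or 17O) relative to the monoisotopic peak,
#' computed as the abundance-ratio-weighted atom count. Linear in the element
#' counts; used by the 13C-peak quantification policy for cardiolipins, whose
#' ~70+ carbon atoms put most of the ion current in the M+1 peak.
#'
#' @param f An `elemental_formula` (or string).
#' @return Dimensionless intensity ratio (M+1 / M).
#' @examples
#' m1_ratio("C73H150O13P2") # ~0.82
#' @export
m1_ratio <- function(f) {
  f <- as_formula(f)
  if (length(f) == 0) stop("empty formula has no isotope pattern")
  unname(sum(.M1_RATIO[names(f)] * unclass(f)))
}

## ---- Adducts -------------------------------------------------------------

.ADDUCTS <- list(
  "[M+H]+"      = list(delta = c(H = 1), charge = 1L),
  "[M+H-H2O]+"  = list(delta = c(H = -1, O = -1), charge = 1L),
  "[M+NH4]+"    = list(delta = c(N = 1, H = 4), charge = 1L),
  "[M+Na]+"     = list(delta = c(Na = 1), charge = 1L)
)

#' Supported positive-mode adducts
#'
#' @return Character vector of adduct names.
#' @export
adduct_names <- function() names(.ADDUCTS)

#' Apply an adduct to a neutral formula
#'
#' Returns the ion composition: the neutral formula plus the adduct's signed
#' formula delta. The delta for `[M+H-H2O]+` is negative in H and O, so a
#' neutral that cannot lose water raises an error.
#'
#' @param f Neutral `elemental_formula` (or string).
#' @param adduct One of `adduct_names()`.
#' @return Ion composition as an `elemental_formula`.
#' @export
apply_adduct <- function(f, adduct) {
  spec <- .ADDUCTS[[adduct]]
  if (is.null(spec)) stop("unknown adduct: ", adduct)
  d <- spec$delta
  pos <- d[d > 0]; neg <- -d[d < 0]
  out <- as_formula(f)
  if (length(pos)) out <- combine(out, elemental_formula(pos), 1L)
  if (length(neg)) out <- combine(out, elemental_formula(neg), -1L)
  out
}

#' Theoretical m/z of a neutral under an adduct
#'
#' @inheritParams apply_adduct
#' @return m/z in Da (electron-corrected, charge +1).
#' @export
adduct_mz <- function(f, adduct) {
  monoisotopic_mz(apply_adduct(f, adduct), charge = 1L)
}
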