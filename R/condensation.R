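## Cardiolipin condensation calculus: cardiolipin synthase (Cls) enzymes
## form a CDL by condensing two parent phospholipids (two PGs, or a PE and
## a PG). Assuming ester bonds are not reduced to ethers after CDL
## biosynthesis, the CDL ether-count distribution is the discrete
## convolution of the parents' per-molecule ether-count distributions
## (DEG core -> 2 ethers, AEG -> 1, DAG -> 0).

#' Per-parent ether-count distribution from a composition table
#'
#' Converts measured core-class percentages of a head group into a
#' probability distribution over ether count {0, 1, 2}. Lyso classes
#' (MEG/MAG) are excluded by default -- only intact two-chain cores can
#' contribute a full phosphatidyl moiety to a four-chain CDL -- and the
#' remainder is renormalised.
#'
#' @param comp A data.frame with columns `head_group`, `core_class`
#'   (`DEG`, `AEG`, `DAG`, optionally `MEG`, `MAG`) and `percent`.
#' @param head_group `"PE"` or `"PG"`.
#' @param include_lyso Count MEG as 1 ether and MAG as 0 instead of
#'   excluding them.
#' @return A `parent_distribution`: list with `head_group` and `p`, a
#'   probability vector named `"0" "1" "2"`.
#' @examples
#' comp <- data.frame(
#'   head_group = c("PG", "PG", "PG"),
#'   core_class = c("DEG", "AEG", "DAG"),
#'   percent = c(66.2, 17.0, 9.3))
#' parent_distribution(comp, "PG")$p  # ~ (0.100, 0.184, 0.716)
#' @export
parent_distribution <- function(comp, head_group, include_lyso = FALSE) {
  stopifnot(all(c("head_group", "core_class", "percent") %in% names(comp)))
  sub <- comp[comp$head_group == head_group, , drop = FALSE]
  if (nrow(sub) == 0) stop("composition table lacks head group ",
                           head_group)
  ether_of <- c(DAG = 0, AEG = 1, DEG = 2, MAG = 0, MEG = 1)
  keep <- if (include_lyso) names(ether_of) else c("DAG", "AEG", "DEG")
  sub <- sub[sub$core_class %in% keep, , drop = FALSE]
  if (nrow(sub) == 0 || sum(sub$percent) <= 0) {
    stop("all-zero intact-core composition for ", head_group)
  }
  p <- c(`0` = 0, `1` = 0, `2` = 0)
  for (i in seq_len(nrow(sub))) {
    e <- as.character(ether_of[[sub$core_class[i]]])
    p[e] <- p[e] + sub$percent[i]
  }
  p <- p / sum(p)
  structure(list(head_group = head_group, p = p),
            class = "parent_distribution")
}

parent_p <- function(x) {
  if (inherits(x, "parent_distribution")) return(x$p)
  stopifnot(is.numeric(x), all(x >= 0), abs(sum(x) - 1) < 1e-9)
  x
}

#' Convolve two parent distributions into a CDL ether-count distribution
#'
#' `q[E] = sum over e1 + e2 = E of a[e1] * b[e2]`. Vectors convolve over
#' ether count; matrices (ether count x total carbons) convolve over both
#' coordinates, giving the joint carbon-resolved prediction.
#'
#' @param a,b `parent_distribution` objects, probability vectors over
#'   {0,1,2}, or matrices with rows = ether counts, columns = carbons.
#' @return Probability vector over total ether count {0..4} (or the
#'   convolved joint matrix). Normalisation is preserved and the operation
#'   is commutative.
#' @export
condense <- function(a, b) {
  if (is.matrix(a) || is.matrix(b)) {
    stopifnot(is.matrix(a), is.matrix(b))
    stopifnot(abs(sum(a) - 1) < 1e-9, abs(sum(b) - 1) < 1e-9)
    nr <- nrow(a) + nrow(b) - 1L
    nc <- ncol(a) + ncol(b) - 1L
    q <- matrix(0, nr, nc)
    for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
      if (a[i, j] == 0) next
      q[i:(i + nrow(b) - 1L), j:(j + ncol(b) - 1L)] <-
        q[i:(i + nrow(b) - 1L), j:(j + ncol(b) - 1L)] + a[i, j] * b
    }
    ## carbon labels: index convolution maps to carbon sums when both
    ## parents sit on the same uniform carbon grid
    ca <- suppressWarnings(as.integer(colnames(a)))
    cb <- suppressWarnings(as.integer(colnames(b)))
    if (!anyNA(ca) && !anyNA(cb) && length(ca) && length(cb)) {
      steps <- unique(c(diff(ca), diff(cb)))
      step <- if (length(steps) == 0) 1L else steps[1]
      if (length(steps) > 1) {
        stop("carbon grids must share one uniform spacing")
      }
      colnames(q) <- as.character(seq(ca[1] + cb[1], by = step,
                                      length.out = nc))
    }
    rownames(q) <- as.character(seq(0L, nr - 1L))
    return(q)
  }
  pa <- parent_p(a); pb <- parent_p(b)
  q <- rep(0, length(pa) + length(pb) - 1L)
  for (i in seq_along(pa)) for (j in seq_along(pb)) {
    q[i + j - 1L] <- q[i + j - 1L] + pa[i] * pb[j]
  }
  names(q) <- as.character(seq_along(q) - 1L)
  q
}

#' Predict the CDL ether-class distribution under a condensation scenario
#'
#' @param comp Composition table as in [parent_distribution()], covering
#'   the head groups the scenario requires.
#' @param scenario `"PE+PE"`, `"PE+PG"`, `"PG+PG"` or `"mix"` (a weighted
#'   combination of PE+PG and PG+PG, reflecting both Cls routes operating
#'   simultaneously).
#' @param mix_weights For `"mix"`: weights of (PE+PG, PG+PG), summing
#'   to 1; default 50-50.
#' @param include_lyso Passed to [parent_distribution()].
#' @return A `scenario_result`: list with `scenario`, `mix_weights` and
#'   `q`, the probability vector over CDL ether count {0..4}.
#' @export
run_scenario <- function(comp,
                         scenario = c("PG+PG", "PE+PG", "PE+PE", "mix"),
                         mix_weights = c(0.5, 0.5),
                         include_lyso = FALSE) {
  scenario <- match.arg(scenario)
  pe <- function() parent_distribution(comp, "PE", include_lyso)
  pg <- function() parent_distribution(comp, "PG", include_lyso)
  q <- switch(scenario,
    "PE+PE" = condense(pe(), pe()),
    "PE+PG" = condense(pe(), pg()),
    "PG+PG" = condense(pg(), pg()),
    "mix" = {
      stopifnot(length(mix_weights) == 2, all(mix_weights >= 0),
                abs(sum(mix_weights) - 1) < 1e-9)
      mix_weights[1] * condense(pe(), pg()) +
        mix_weights[2] * condense(pg(), pg())
    })
  structure(list(scenario = scenario,
                 mix_weights = if (scenario == "mix") mix_weights else NULL,
                 q = q),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result>", x$scenario, "\n")
  print(round(100 * x$q, 1))
  invisible(x)
}

#' Compare a predicted and a measured ether-class distribution
#'
#' @param predicted A `scenario_result` or probability vector over {0..4}.
#' @param measured Probability vector over {0..4} (normalised).
#' @return List with `l1` (total variation x 2, the L1 distance) and
#'   `per_class` (signed predicted - measured differences).
#' @export
compare_distributions <- function(predicted, measured) {
  q <- if (inherits(predicted, "scenario_result")) predicted$q else predicted
  stopifnot(length(q) == length(measured),
            abs(sum(q) - 1) < 1e-6, abs(sum(measured) - 1) < 1e-6)
  d <- q - measured
  names(d) <- names(q)
  list(l1 = sum(abs(d)), per_class = d)
}
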