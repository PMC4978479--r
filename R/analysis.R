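#' The five homologous arrangement classes
#'
#' Homologous chromosome territories in a simulated nucleus fall into
#' exactly five arrangement patterns: complete separation, association of
#' the two top arms, of the two bottom arms, along both arms, or between
#' the top arm of one homologue and the bottom arm of the other.
#'
#' @return character vector of the five class labels, in a fixed order.
#' @export
arrangement_classes <- function() {
  c("complete_separation", "top_top", "bottom_bottom", "both_arms",
    "top_bottom")
}

#' Minimum border-to-border distance between two bead sets
#'
#' The distance between two territories is measured between their
#' boundaries: the minimum over all cross pairs of the centre distance
#' minus both bead radii (`2 * r_b`), floored at zero for overlapping
#' beads.
#'
#' @param beads_a,beads_b numeric matrices (n x 3) of bead centres, nm.
#' @param r_b bead radius, nm.
#' @return the border distance in nm (>= 0).
#' @export
border_distance <- function(beads_a, beads_b, r_b) {
  beads_a <- as.matrix(beads_a)
  beads_b <- as.matrix(beads_b)
  if (!nrow(beads_a) || !nrow(beads_b))
    stop("border_distance needs non-empty bead sets", call. = FALSE)
  # all cross-pair squared distances in one shot
  aa <- rowSums(beads_a^2)
  bb <- rowSums(beads_b^2)
  d2 <- outer(aa, bb, "+") - 2 * tcrossprod(beads_a, beads_b)
  max(sqrt(max(min(d2), 0)) - 2 * r_b, 0)
}

bead_xyz <- function(model, chrom, arm = NULL) {
  b <- model$beads
  sel <- b$chrom %in% chrom
  if (!is.null(arm)) sel <- sel & b$arm == arm
  as.matrix(b[sel, c("x", "y", "z")])
}

#' Classify the arrangement of a homologous chromosome pair
#'
#' Computes the border distance ([border_distance()]) for the four arm
#' pairings between the two homologues (top:top, bottom:bottom and the two
#' cross pairings) and calls a pairing associated when its border distance
#' is strictly below `threshold`. The pattern maps onto the five
#' [arrangement_classes()]:
#' no pairing associated — `complete_separation`; both same-arm pairings —
#' `both_arms`; only top:top — `top_top`; only bottom:bottom —
#' `bottom_bottom`; cross pairings only — `top_bottom`. In composite cases
#' same-arm evidence dominates cross-arm evidence
#' (`both_arms` > `top_top`/`bottom_bottom` > `top_bottom`).
#'
#' @param model a `nucleus_model`.
#' @param pair chromosome pair id (1..`chr_pair`).
#' @param threshold association threshold on the border distance, nm;
#'   territories closer than this (strictly) count as associated.
#' @param details logical; also return the raw per-pairing association
#'   booleans as an attribute `"pairings"`.
#' @return one of the five class labels (character).
#' @export
classify_homologue_pair <- function(model, pair, threshold = 500,
                                    details = FALSE) {
  stopifnot(inherits(model, "nucleus_model"))
  if (!(pair >= 1 && pair <= model$cfg$chr_pair))
    stop("no chromosome pair ", pair, " in this model", call. = FALSE)
  c1 <- 2L * as.integer(pair) - 1L
  c2 <- c1 + 1L
  rb <- model$cfg$rad_bead
  arms1 <- list(top = bead_xyz(model, c1, "top"),
                bottom = bead_xyz(model, c1, "bottom"))
  arms2 <- list(top = bead_xyz(model, c2, "top"),
                bottom = bead_xyz(model, c2, "bottom"))
  if (!all(vapply(c(arms1, arms2), nrow, 0L) > 0L))
    stop("pair ", pair, " is missing arm beads", call. = FALSE)
  assoc <- c(
    top_top = border_distance(arms1$top, arms2$top, rb) < threshold,
    bottom_bottom = border_distance(arms1$bottom, arms2$bottom, rb) < threshold,
    top1_bottom2 = border_distance(arms1$top, arms2$bottom, rb) < threshold,
    bottom1_top2 = border_distance(arms1$bottom, arms2$top, rb) < threshold)
  cls <- if (assoc[["top_top"]] && assoc[["bottom_bottom"]]) "both_arms"
    else if (assoc[["top_top"]]) "top_top"
    else if (assoc[["bottom_bottom"]]) "bottom_bottom"
    else if (assoc[["top1_bottom2"]] || assoc[["bottom1_top2"]]) "top_bottom"
    else "complete_separation"
  if (details) attr(cls, "pairings") <- assoc
  cls
}

#' Classify the arrangement of two heterologous chromosome pairs
#'
#' Whole-territory verdict only: the two territories (each the beads of
#' both copies of its pair, centromeres included) are `"associated"` when
#' their border distance is strictly below `threshold`, `"separated"`
#' otherwise. Symmetric in the order of the two pairs.
#'
#' @param model a `nucleus_model`.
#' @param pairs integer vector of two distinct chromosome pair ids.
#' @inheritParams classify_homologue_pair
#' @return `"associated"` or `"separated"`.
#' @export
classify_heterologue_pair <- function(model, pairs, threshold = 500) {
  stopifnot(inherits(model, "nucleus_model"), length(pairs) == 2L)
  pairs <- as.integer(pairs)
  if (pairs[1L] == pairs[2L])
    stop("heterologue classification needs two distinct pairs", call. = FALSE)
  if (any(pairs < 1L | pairs > model$cfg$chr_pair))
    stop("chromosome pair out of range", call. = FALSE)
  a <- bead_xyz(model, c(2L * pairs[1L] - 1L, 2L * pairs[1L]))
  b <- bead_xyz(model, c(2L * pairs[2L] - 1L, 2L * pairs[2L]))
  d <- border_distance(a, b, model$cfg$rad_bead)
  if (d < threshold) "associated" else "separated"
}

#' Tabulate arrangement frequencies over replicate models
#'
#' Classifies every homologous chromosome pair in every model
#' ([classify_homologue_pair()]) and counts how often each of the five
#' arrangement classes occurs per pair, with derived percentages.
#'
#' @param models a list of `nucleus_model`s (or a `ct_batch` from
#'   [simulate_batch()]), all simulated under the same configuration.
#' @inheritParams classify_homologue_pair
#' @return a `ct_freq_table`: data frame with columns `pair`, `class`,
#'   `count`, `percent`; attribute `n_models` carries the replicate count.
#' @export
tabulate_arrangements <- function(models, threshold = 500) {
  if (inherits(models, "ct_batch")) models <- models$models
  stopifnot(length(models) >= 1L)
  ref <- models[[1L]]$cfg
  for (m in models) {
    stopifnot(inherits(m, "nucleus_model"))
    if (m$cfg$chr_pair != ref$chr_pair ||
        !identical(m$cfg$l_arm_d, ref$l_arm_d))
      stop("all models must share one configuration", call. = FALSE)
  }
  n <- length(models)
  classes <- arrangement_classes()
  out <- expand.grid(pair = seq_len(ref$chr_pair),
                     class = factor(classes, levels = classes))
  out$count <- 0L
  for (m in models) {
    for (p in seq_len(ref$chr_pair)) {
      cls <- classify_homologue_pair(m, p, threshold)
      i <- which(out$pair == p & out$class == cls)
      out$count[i] <- out$count[i] + 1L
    }
  }
  out$percent <- 100 * out$count / n
  structure(out, n_models = n, threshold = threshold,
            class = c("ct_freq_table", "data.frame"))
}

#' @export
print.ct_freq_table <- function(x, ...) {
  n <- attr(x, "n_models")
  cat("Homologous territory arrangements over", n, "models",
      sprintf("(association threshold %g nm)\n", attr(x, "threshold")))
  wide <- stats::reshape(as.data.frame(x)[, c("pair", "class", "count")],
                         idvar = "pair", timevar = "class",
                         direction = "wide")
  names(wide) <- sub("^count\\.", "", names(wide))
  print(wide, row.names = FALSE)
  invisible(x)
}

#' Pearson's chi-squared goodness-of-fit test
#'
#' Compares observed category counts against expected counts or
#' proportions with the Pearson statistic `sum((O - E)^2 / E)` on
#' `k - 1` degrees of freedom; the p-value is the upper tail of the
#' chi-squared distribution.
#'
#' @param observed vector of observed counts.
#' @param expected vector of expected counts (same length); mutually
#'   exclusive with `proportions`.
#' @param proportions vector of expected proportions (summing to 1) from
#'   which expected counts are derived as `proportions * sum(observed)`.
#' @return list with `statistic`, `df`, `p_value`, `expected`.
#' @examples
#' chisq_gof(c(10, 0), expected = c(5, 5))  # statistic 10, df 1
#' @export
chisq_gof <- function(observed, expected = NULL, proportions = NULL) {
  if (is.null(expected) == is.null(proportions))
    stop("supply exactly one of expected or proportions", call. = FALSE)
  if (!is.null(proportions)) {
    if (length(proportions) != length(observed))
      stop("proportions must match observed in length", call. = FALSE)
    expected <- proportions * sum(observed)
  }
  if (length(expected) != length(observed))
    stop("expected must match observed in length", call. = FALSE)
  if (any(expected <= 0))
    stop("expected counts must all be positive", call. = FALSE)
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       expected = expected)
}
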