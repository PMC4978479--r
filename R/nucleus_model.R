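#' Validate a simulated nucleus model
#'
#' Re-asserts every structural invariant of a completed `nucleus_model`:
#'
#' * the nucleolus lies entirely inside the nucleus;
#' * every bead lies strictly inside the nucleus
#'   (`|centre| + r_b < R` up to `tol`) and clear of the nucleolus;
#' * per chromosome and arm, the bead count equals the configured
#'   decondensed arm length, with exactly one centromere per chromosome;
#' * all inter-chromosome centre distances are at least `2*r_b + eps_2`
#'   (or the literal threshold under `paper_literal`), all intra-chromosome
#'   distances at least `2*r_b - 2*eps_1`;
#' * chain connectivity: every non-centromere bead sits exactly one step
#'   from its recorded precursory bead.
#'
#' @param model a `nucleus_model`.
#' @param tol numerical slack for the distance checks, nm.
#' @return `model`, invisibly, if all checks pass; otherwise an error
#'   naming the violated invariant.
#' @export
validate_model <- function(model, tol = 1e-6) {
  stopifnot(inherits(model, "nucleus_model"))
  cfg <- model$cfg
  b <- model$beads
  R <- model$nucleus$radius
  rb <- cfg$rad_bead
  fail <- function(...) stop("invalid nucleus_model: ", ..., call. = FALSE)

  if (sqrt(sum(model$nucleolus$centre^2)) + model$nucleolus$radius >= R + tol)
    fail("nucleolus not inside nucleus")

  xyz <- as.matrix(b[, c("x", "y", "z")])
  rad <- sqrt(rowSums(xyz^2))
  if (any(rad + rb >= R + tol)) fail("bead outside the nucleus")
  dno <- sqrt(dist2_to(model$nucleolus$centre, xyz))
  if (any(dno <= model$nucleolus$radius - tol)) fail("bead inside the nucleolus")

  # bead accounting: one centromere per chromosome, arm counts == l_arm_d
  N <- 2L * cfg$chr_pair
  if (!identical(sort(unique(b$chrom)), seq_len(N)))
    fail("expected chromosomes 1..", N)
  cen <- tapply(b$centromere, b$chrom, sum)
  if (any(cen != 1L)) fail("each chromosome needs exactly one centromere bead")
  for (c in seq_len(N)) {
    pair <- (c + 1L) %/% 2L
    for (a in c("top", "bottom")) {
      got <- sum(b$chrom == c & b$arm == a)
      want <- cfg$l_arm_d[pair, a]
      if (got != want)
        fail("chromosome ", c, " ", a, " arm has ", got,
             " beads, expected ", want)
    }
  }

  # resolve precursory references (needed both for connectivity and to
  # exempt precursory links from the intra-chromosome clearance)
  key <- paste(b$chrom, as.character(b$arm), b$index)
  row_of <- match(paste(b$chrom,
                        ifelse(is.na(b$prec_arm), "cen", as.character(b$prec_arm)),
                        ifelse(is.na(b$prec_index), 0L, b$prec_index)), key)
  child <- which(!b$centromere)
  if (anyNA(row_of[child])) fail("missing precursory bead reference")

  # pairwise clearances
  d <- as.matrix(stats::dist(xyz))
  same <- outer(b$chrom, b$chrom, "==")
  off <- upper.tri(d)
  linked <- matrix(FALSE, nrow(b), nrow(b))
  linked[cbind(child, row_of[child])] <- TRUE
  linked <- linked | t(linked)
  thr_for <- if (cfg$paper_literal) 2 * rb - 2 * cfg$eps_2 else 2 * rb + cfg$eps_2
  if (any(d[off & !same] < thr_for - tol))
    fail("inter-chromosome bead distance below ", thr_for, " nm")
  if (any(d[off & same & !linked] < 2 * rb - 2 * cfg$eps_1 - tol))
    fail("intra-chromosome bead distance below ", 2 * rb - 2 * cfg$eps_1, " nm")

  # connectivity to the precursory bead
  step <- if (cfg$step_mode == "tangent") 2 * rb else rb
  dprec <- sqrt(rowSums((xyz[child, , drop = FALSE] -
                         xyz[row_of[child], , drop = FALSE])^2))
  if (any(abs(dprec - step) > tol))
    fail("bead not at step distance from its precursory bead")
  invisible(model)
}

#' @export
print.nucleus_model <- function(x, ...) {
  cat("Simulated interphase nucleus\n")
  cat(sprintf("  nucleus radius: %.0f nm; nucleolus radius %.0f nm (%.1f%% of volume)\n",
              x$nucleus$radius, x$nucleolus$radius,
              100 * (x$nucleolus$radius / x$nucleus$radius)^3))
  cat(sprintf("  %d chromosomes (%d pairs), %d chromatin domains\n",
              2L * x$cfg$chr_pair, x$cfg$chr_pair, nrow(x$beads)))
  cat(sprintf("  restarts consumed: %d%s\n", x$restarts,
              if (is.null(x$seed)) "" else sprintf("; seed %d", x$seed)))
  invisible(x)
}

#' @export
summary.nucleus_model <- function(object, ...) {
  b <- object$beads
  counts <- as.data.frame(table(pair = b$pair, copy = b$copy))
  counts$Freq <- as.integer(counts$Freq)
  names(counts)[3L] <- "domains"
  out <- list(model = object, domains_per_copy = counts)
  class(out) <- "summary.nucleus_model"
  out
}

#' @export
print.summary.nucleus_model <- function(x, ...) {
  print(x$model)
  cat("\nDomains per chromosome copy:\n")
  print(x$domains_per_copy, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.nucleus_model <- function(x, ...) x$beads

#' Plot a simulated nucleus
#'
#' Orthographic projection of the model onto a coordinate plane with
#' painter's-algorithm depth ordering; a thin front-end over
#' [render_scene()].
#'
#' @param x a `nucleus_model`.
#' @param scheme a [colour_scheme()]; default highlights chromosome pair 1.
#' @param ... passed to [render_scene()].
#' @export
plot.nucleus_model <- function(x, scheme = colour_scheme(1L), ...) {
  render_scene(x, scheme, ...)
}
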