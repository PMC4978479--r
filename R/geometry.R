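# squared distances from point p (length-3) to each row of matrix m (n x 3)
dist2_to <- function(p, m) {
  (m[, 1L] - p[1L])^2 + (m[, 2L] - p[2L])^2 + (m[, 3L] - p[3L])^2
}

#' Create a sphere
#'
#' Plain container for the spheres of the model (nucleus, nucleolus,
#' beads): a centre in the nucleus-centred frame (the nucleus centre is the
#' origin) and a radius, both in nanometres.
#'
#' @param centre numeric length-3 (x, y, z), nm.
#' @param radius positive radius, nm.
#' @return a list of class `sphere`.
#' @export
sphere <- function(centre, radius) {
  centre <- as.numeric(centre)
  stopifnot(length(centre) == 3L, all(is.finite(centre)),
            is.finite(radius), radius > 0)
  structure(list(centre = centre, radius = as.numeric(radius)), class = "sphere")
}

#' Random step at a fixed distance
#'
#' Draws one point at Euclidean distance exactly `step` from `origin`. The
#' direction is generated from two angles, theta uniform on (0, pi) and phi
#' uniform on (0, 2*pi), combined as
#' `dx = step*cos(theta)*sin(phi)`, `dy = step*sin(theta)*sin(phi)`,
#' `dz = step*cos(phi)`. This angle convention (phi, not theta, is the
#' polar angle of the z axis) is kept exactly as the growth algorithm
#' defines it; the resulting direction distribution is symmetric about the
#' z axis, which is all the chain growth requires.
#'
#' @param origin numeric length-3, nm.
#' @param step step length, nm (> 0).
#' @return numeric length-3: the new point.
#' @export
random_offset <- function(origin, step) {
  stopifnot(step > 0)
  theta <- stats::runif(1L, 0, pi)
  phi <- stats::runif(1L, 0, 2 * pi)
  origin + step * c(cos(theta) * sin(phi),
                    sin(theta) * sin(phi),
                    cos(phi))
}

#' Nucleolus radius bounds from volume fractions
#'
#' The nucleolus occupies a fraction of the nuclear volume between
#' `vol_min` and `vol_max`; the corresponding radius bounds are
#' `r = (vol * R^3)^(1/3)`.
#'
#' @param R nucleus radius, nm.
#' @param vol_min,vol_max volume fractions, `0 < vol_min <= vol_max < 1`.
#' @return named numeric vector `c(r_min, r_max)`, nm.
#' @examples
#' nucleolus_radius_bounds(1000, 0.064, 0.216)  # 400, 600
#' @export
nucleolus_radius_bounds <- function(R, vol_min, vol_max) {
  if (!(R > 0)) stop("R must be > 0", call. = FALSE)
  if (!(vol_min > 0 && vol_min <= vol_max && vol_max < 1))
    stop("need 0 < vol_min <= vol_max < 1", call. = FALSE)
  c(r_min = (vol_min * R^3)^(1 / 3), r_max = (vol_max * R^3)^(1 / 3))
}

#' Distance windows for candidate acceptance
#'
#' The two admissible centre-distance windows used during chain growth:
#' `d1` for beads of the same chromosome
#' (`2*r_b <= d1 <= R - 2*r_b - eps_1`) and `d2` for beads of foreign
#' chromosomes and the nucleus/nucleolus boundaries
#' (lower bound `2*r_b + eps_2`, upper bound `R - r_b - 5*eps_2`).
#'
#' @param R nucleus radius, nm.
#' @param cfg a [species_config()].
#' @return list with `d1_min`, `d1_max`, `d2_min`, `d2_max` (nm).
#' @export
distance_windows <- function(R, cfg) {
  list(d1_min = 2 * cfg$rad_bead,
       d1_max = R - 2 * cfg$rad_bead - cfg$eps_1,
       d2_min = 2 * cfg$rad_bead + cfg$eps_2,
       d2_max = R - cfg$rad_bead - 5 * cfg$eps_2)
}

ok_verdict <- function(ok, code = NA_character_) list(ok = ok, code = code)

#' Acceptance test for a centromere candidate
#'
#' A candidate centromere position `p` is accepted iff all of:
#' * C1 — it lies inside the nucleus with margin:
#'   `|p - nu| < R - (r_b + 5*eps_2)`;
#' * C2 — it clears the nucleolus: `|p - no| > r + r_b + eps_2`;
#' * C3 — it clears every already placed centromere:
#'   `|p - c| > 2*r_b + eps_2`.
#'
#' All comparisons are strict. On rejection the verdict reports the first
#' failing condition code.
#'
#' @param p numeric length-3 candidate centre, nm.
#' @param nucleus,nucleolus [sphere()]s; the nucleolus must lie inside the
#'   nucleus.
#' @param existing_centromeres numeric matrix (n x 3) of placed centromere
#'   centres (may have zero rows).
#' @param cfg a [species_config()].
#' @return list with logical `ok` and character `code` (`"C1"`, `"C2"`,
#'   `"C3"`, or `NA` when accepted).
#' @export
centromere_candidate_ok <- function(p, nucleus, nucleolus,
                                    existing_centromeres, cfg) {
  R <- nucleus$radius
  rb <- cfg$rad_bead
  e2 <- cfg$eps_2
  if (!(sqrt(sum((p - nucleus$centre)^2)) < R - (rb + 5 * e2)))
    return(ok_verdict(FALSE, "C1"))
  if (!(sqrt(sum((p - nucleolus$centre)^2)) > nucleolus$radius + rb + e2))
    return(ok_verdict(FALSE, "C2"))
  if (NROW(existing_centromeres) > 0L) {
    d2 <- dist2_to(p, existing_centromeres)
    if (!all(d2 > (2 * rb + e2)^2)) return(ok_verdict(FALSE, "C3"))
  }
  ok_verdict(TRUE)
}

#' Acceptance test for a chromatin-domain candidate
#'
#' A candidate bead centre `p` for a chromosome is accepted iff all of:
#' * C1' — inside the nucleus: `|p - nu| < R - r_b`;
#' * C2' — outside the nucleolus: `|p - no| > r + r_b + eps_2`;
#' * C3' — clear of every bead of the *same* chromosome, except the
#'   precursory bead it grows from: centre distance `>= 2*r_b - 2*eps_1`
#'   (a small overlap of up to `2*eps_1` is tolerated within a chromosome);
#' * C4 — close enough to its own chromosome: distance to the nearest own
#'   bead `<= R - 2*r_b - eps_1` (the `d1` upper window);
#' * C5 — far enough from every *foreign* bead: centre distance
#'   `>= 2*r_b + eps_2`. With `paper_literal = TRUE` the foreign threshold
#'   is `2*r_b - 2*eps_2` instead, for comparison runs.
#'
#' @param p numeric length-3 candidate centre, nm.
#' @param nucleus,nucleolus [sphere()]s.
#' @param own_beads matrix (n x 3) of bead centres of the same chromosome
#'   (may have zero rows); `precursory` is a row index into it, or `NULL`.
#' @param foreign_beads matrix (m x 3) of all other chromosomes' bead
#'   centres (may have zero rows).
#' @param cfg a [species_config()].
#' @param precursory index of the precursory bead within `own_beads`,
#'   excluded from the C3' scan.
#' @return list with logical `ok` and character `code` (`"C1"`, `"C2"`,
#'   `"C3"`, `"C4"`, `"C5"`, or `NA` when accepted).
#' @export
domain_candidate_ok <- function(p, nucleus, nucleolus, own_beads,
                                foreign_beads, cfg, precursory = NULL) {
  R <- nucleus$radius
  rb <- cfg$rad_bead
  if (!(sqrt(sum((p - nucleus$centre)^2)) < R - rb))
    return(ok_verdict(FALSE, "C1"))
  if (!(sqrt(sum((p - nucleolus$centre)^2)) >
        nucleolus$radius + rb + cfg$eps_2))
    return(ok_verdict(FALSE, "C2"))
  if (NROW(own_beads) > 0L) {
    d2own <- dist2_to(p, own_beads)
    scan <- d2own
    if (!is.null(precursory)) scan <- scan[-precursory]
    thr_own <- 2 * rb - 2 * cfg$eps_1
    if (length(scan) && any(scan < thr_own^2))
      return(ok_verdict(FALSE, "C3"))
    d1max <- R - 2 * rb - cfg$eps_1
    if (!(min(d2own) <= d1max^2)) return(ok_verdict(FALSE, "C4"))
  }
  if (NROW(foreign_beads) > 0L) {
    thr_for <- if (cfg$paper_literal) 2 * rb - 2 * cfg$eps_2
               else 2 * rb + cfg$eps_2
    if (any(dist2_to(p, foreign_beads) < thr_for^2))
      return(ok_verdict(FALSE, "C5"))
  }
  ok_verdict(TRUE)
}
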