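#' Species configuration for nucleus simulation
#'
#' Builds and validates the full parameter set that drives one simulated
#' interphase nucleus: the karyotype (number of chromosome pairs, per-arm
#' chain lengths in the condensed and decondensed state), the nucleus and
#' nucleolus geometry, the chromatin-domain bead radius and the collision
#' tolerances.
#'
#' All geometry is held in nanometres. Arm-length tables count beads
#' (condensed state) or 1 Mbp chromatin domains (decondensed state) per arm;
#' the centromere bead is index 0 of each chromosome and is *not* included
#' in either arm table, so a chromosome whose DNA content is `M` Mbp has
#' decondensed arm lengths summing to `M - 1`.
#'
#' @param chr_pair number of chromosome pairs (the nucleus holds
#'   `2 * chr_pair` chromosomes).
#' @param l_arm_c integer matrix (or coercible) with `chr_pair` rows and
#'   columns `top`, `bottom`: condensed arm lengths in beads.
#' @param l_arm_d same shape: decondensed arm lengths in 1 Mbp domains.
#' @param min_rad_nu,max_rad_nu nucleus radius bounds, nm.
#' @param min_vol_no,max_vol_no nucleolus volume as a fraction of nucleus
#'   volume (dimensionless, in (0, 1)).
#' @param rad_bead chromatin-domain bead radius, nm. The default 250 nm
#'   corresponds to the usual 500 nm domain diameter.
#' @param eps_1 collision tolerance for beads of the same chromosome, nm.
#' @param eps_2 clearance for beads of different chromosomes and for the
#'   nucleus/nucleolus boundaries, nm; must exceed `eps_1`.
#' @param multi beads per domain; only 1 is supported.
#' @param restart_after number of consecutive failed placement attempts
#'   before the whole model is discarded and regrown.
#' @param max_restarts hard cap on restarts per model (`Inf` = unlimited).
#' @param step_mode `"tangent"` places each new bead at centre distance
#'   `2 * rad_bead` from its precursory bead (tangent spheres); `"radius"`
#'   uses an offset of `rad_bead` instead.
#' @param precursory_pool `"arm"` draws the precursory domain during
#'   decondensation from the arm being extended; `"chromosome"` widens the
#'   pool to the whole chromosome.
#' @param paper_literal logical; if `TRUE` the foreign-bead clearance uses
#'   the literal threshold `2 * rad_bead - 2 * eps_2` instead of the default
#'   `2 * rad_bead + eps_2` (see [domain_candidate_ok()]).
#' @param seed optional integer seed stored with the configuration and used
#'   by [simulate_nucleus()] when no explicit seed is given.
#' @param name optional label for the configuration.
#'
#' @return an object of class `species_config` (a validated list).
#' @seealso [load_config()], [ct_preset()], [simulate_nucleus()]
#' @examples
#' cfg <- species_config(
#'   chr_pair = 1,
#'   l_arm_c = cbind(top = 2, bottom = 2),
#'   l_arm_d = cbind(top = 4, bottom = 4),
#'   min_rad_nu = 3000, max_rad_nu = 3000
#' )
#' cfg$chr_pair
#' @export
species_config <- function(chr_pair,
                           l_arm_c,
                           l_arm_d,
                           min_rad_nu = 3500,
                           max_rad_nu = 4000,
                           min_vol_no = 0.02,
                           max_vol_no = 0.05,
                           rad_bead = 250,
                           eps_1 = 0.1 * rad_bead,
                           eps_2 = 0.2 * rad_bead,
                           multi = 1L,
                           restart_after = 500000L,
                           max_restarts = Inf,
                           step_mode = c("tangent", "radius"),
                           precursory_pool = c("arm", "chromosome"),
                           paper_literal = FALSE,
                           seed = NULL,
                           name = NULL) {
  step_mode <- match.arg(step_mode)
  precursory_pool <- match.arg(precursory_pool)
  l_arm_c <- as_arm_table(l_arm_c, chr_pair, "l_arm_c")
  l_arm_d <- as_arm_table(l_arm_d, chr_pair, "l_arm_d")
  cfg <- structure(
    list(
      chr_pair = as.integer(chr_pair),
      l_arm_c = l_arm_c,
      l_arm_d = l_arm_d,
      min_rad_nu = as.numeric(min_rad_nu),
      max_rad_nu = as.numeric(max_rad_nu),
      min_vol_no = as.numeric(min_vol_no),
      max_vol_no = as.numeric(max_vol_no),
      rad_bead = as.numeric(rad_bead),
      eps_1 = as.numeric(eps_1),
      eps_2 = as.numeric(eps_2),
      multi = as.integer(multi),
      restart_after = as.numeric(restart_after),
      max_restarts = as.numeric(max_restarts),
      step_mode = step_mode,
      precursory_pool = precursory_pool,
      paper_literal = isTRUE(paper_literal),
      seed = if (is.null(seed)) NULL else as.integer(seed),
      name = name
    ),
    class = "species_config"
  )
  validate_config(cfg)
}

as_arm_table <- function(x, chr_pair, what) {
  if (is.list(x) && !is.data.frame(x)) x <- do.call(rbind, x)
  x <- as.matrix(x)
  if (ncol(x) == 1L) x <- t(x)
  if (ncol(x) != 2L) stop(what, " must have two columns (top, bottom)", call. = FALSE)
  if (nrow(x) != chr_pair)
    stop(what, " must have one row per chromosome pair (", chr_pair, ")", call. = FALSE)
  storage.mode(x) <- "integer"
  colnames(x) <- c("top", "bottom")
  rownames(x) <- NULL
  x
}

#' Validate a species configuration
#'
#' Checks every structural invariant of a [species_config()]: positive
#' radii with `min_rad_nu <= max_rad_nu`, nucleolus volume fractions in
#' (0, 1), `eps_2 > eps_1 > 0`, decondensed arm lengths no shorter than the
#' condensed ones, and at least one bead (the centromere) per chromosome.
#'
#' @param cfg object to validate.
#' @return `cfg`, invisibly unchanged, if valid; otherwise an error naming
#'   the offending field.
#' @export
validate_config <- function(cfg) {
  fail <- function(...) stop("invalid species_config: ", ..., call. = FALSE)
  if (!inherits(cfg, "species_config")) fail("not a species_config object")
  if (is.na(cfg$chr_pair) || cfg$chr_pair < 1L) fail("chr_pair must be a positive integer")
  if (!(cfg$min_rad_nu > 0)) fail("min_rad_nu must be > 0")
  if (cfg$min_rad_nu > cfg$max_rad_nu) fail("min_rad_nu must be <= max_rad_nu")
  if (!(cfg$min_vol_no > 0)) fail("min_vol_no must be > 0")
  if (cfg$min_vol_no > cfg$max_vol_no) fail("min_vol_no must be <= max_vol_no")
  if (!(cfg$max_vol_no < 1)) fail("max_vol_no must be < 1")
  if (!(cfg$rad_bead > 0)) fail("rad_bead must be > 0")
  if (!(cfg$eps_1 > 0)) fail("eps_1 must be > 0")
  if (!(cfg$eps_2 > cfg$eps_1)) fail("eps_2 must be greater than eps_1")
  if (cfg$multi != 1L) fail("multi: only one bead per domain (multi = 1) is supported")
  if (!(cfg$restart_after >= 1)) fail("restart_after must be >= 1")
  if (any(cfg$l_arm_c < 0) || any(cfg$l_arm_d < 0)) fail("arm lengths must be non-negative")
  if (any(cfg$l_arm_d < cfg$l_arm_c)) {
    bad <- which(cfg$l_arm_d < cfg$l_arm_c, arr.ind = TRUE)[1L, ]
    fail("l_arm_d: decondensed arm length must be >= condensed length ",
         "(pair ", bad[1L], ", ", c("top", "bottom")[bad[2L]], " arm)")
  }
  invisible(cfg)
}

#' Convert a condensed chromosome length to a bead count
#'
#' A condensed (metaphase) chromosome of physical length `length_um` is
#' represented as a chain of tangent beads of diameter `bead_diameter_um`;
#' the chain length is the rounded ratio, never less than one bead.
#'
#' @param length_um condensed chromosome length, micrometres.
#' @param bead_diameter_um bead diameter, micrometres (default 0.5, i.e.
#'   the 500 nm chromatin-domain diameter).
#' @return integer bead count (vectorised over `length_um`).
#' @examples
#' beads_per_condensed_length(7.0)  # 14
#' beads_per_condensed_length(3.5)  # 7
#' @export
beads_per_condensed_length <- function(length_um, bead_diameter_um = 0.5) {
  if (any(!is.finite(length_um)) || any(length_um <= 0))
    stop("length_um must be positive", call. = FALSE)
  if (!is.finite(bead_diameter_um) || bead_diameter_um <= 0)
    stop("bead_diameter_um must be positive", call. = FALSE)
  pmax(1L, as.integer(round(length_um / bead_diameter_um)))
}

#' Load a species configuration from a YAML file
#'
#' Reads the documented YAML schema (see the packaged presets under
#' `system.file("extdata", package = "ctsim")` for worked examples) and
#' returns a validated [species_config()]. Arm tables are given as
#' `l_arm_c` / `l_arm_d`: lists of two-element `[top, bottom]` integer
#' vectors, one per chromosome pair.
#'
#' @param path path to a YAML configuration file.
#' @return a validated `species_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("cannot parse config ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  known <- names(formals(species_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  do.call(species_config, raw)
}

#' @export
print.species_config <- function(x, ...) {
  nm <- if (is.null(x$name)) "unnamed" else x$name
  cat("Species configuration (", nm, ")\n", sep = "")
  cat("  chromosome pairs: ", x$chr_pair, "\n", sep = "")
  cat("  beads per chromosome (condensed):   ",
      paste(1L + rowSums(x$l_arm_c), collapse = ", "), "\n", sep = "")
  cat("  domains per chromosome (decondensed): ",
      paste(1L + rowSums(x$l_arm_d), collapse = ", "), "\n", sep = "")
  cat("  nucleus radius: ", x$min_rad_nu, "-", x$max_rad_nu, " nm; ",
      "nucleolus ", 100 * x$min_vol_no, "-", 100 * x$max_vol_no,
      "% of nuclear volume\n", sep = "")
  cat("  bead radius ", x$rad_bead, " nm; eps_1 = ", x$eps_1,
      " nm, eps_2 = ", x$eps_2, " nm\n", sep = "")
  invisible(x)
}

# total beads per chromosome (centromere + both arms) for a given phase table
chromosome_totals <- function(cfg, phase = c("decondensed", "condensed")) {
  phase <- match.arg(phase)
  tab <- if (phase == "decondensed") cfg$l_arm_d else cfg$l_arm_c
  1L + rowSums(tab)
}
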