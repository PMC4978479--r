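# Shared fixtures, all built in code at test time.

# a small, roomy two-pair karyotype that simulates in milliseconds
small_config <- function(...) {
  args <- list(
    chr_pair = 2L,
    l_arm_c = rbind(c(2L, 2L), c(1L, 2L)),
    l_arm_d = rbind(c(6L, 6L), c(3L, 5L)),
    min_rad_nu = 3000, max_rad_nu = 3200,
    min_vol_no = 0.02, max_vol_no = 0.04)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(species_config, args)
}

# a configuration that cannot be completed: two centromeres must sit
# > 550 nm apart inside a sphere of radius R - (r_b + 5*eps_2) = 100 nm
infeasible_config <- function(restart_after, max_restarts = 2L) {
  species_config(
    chr_pair = 2L,
    l_arm_c = rbind(c(1L, 1L), c(1L, 1L)),
    l_arm_d = rbind(c(1L, 1L), c(1L, 1L)),
    min_rad_nu = 600, max_rad_nu = 600,
    min_vol_no = 1e-6, max_vol_no = 2e-6,
    restart_after = restart_after, max_restarts = max_restarts)
}

# hand-built single- or two-pair model for classification tests: every arm
# is one bead at a stated position, so border distances are exact by
# construction. `positions` is a list of chromosomes, each a list with
# cen/top/bottom length-3 vectors, in chromosome id order (two consecutive
# ids per pair).
toy_model <- function(positions, rad_bead = 250) {
  n_chrom <- length(positions)
  stopifnot(n_chrom %% 2L == 0L)
  n_pair <- n_chrom %/% 2L
  cfg <- species_config(
    chr_pair = n_pair,
    l_arm_c = matrix(1L, n_pair, 2L),
    l_arm_d = matrix(1L, n_pair, 2L),
    min_rad_nu = 1e6, max_rad_nu = 1e6,
    rad_bead = rad_bead)
  rows <- do.call(rbind, lapply(seq_len(n_chrom), function(c) {
    p <- positions[[c]]
    data.frame(
      chrom = c, pair = (c + 1L) %/% 2L, copy = 2L - c %% 2L,
      arm = factor(c("cen", "top", "bottom"), levels = c("cen", "top", "bottom")),
      index = c(0L, 1L, 1L),
      x = c(p$cen[1], p$top[1], p$bottom[1]),
      y = c(p$cen[2], p$top[2], p$bottom[2]),
      z = c(p$cen[3], p$top[3], p$bottom[3]),
      radius = rad_bead,
      centromere = c(TRUE, FALSE, FALSE),
      phase = factor("condensed", levels = c("condensed", "decondensation")),
      prec_arm = factor(c(NA, "cen", "cen"), levels = c("cen", "top", "bottom")),
      prec_index = c(NA_integer_, 0L, 0L))
  }))
  structure(list(nucleus = sphere(c(0, 0, 0), 1e6),
                 nucleolus = sphere(c(9e5, 9e5, 9e5), 10),
                 beads = rows, cfg = cfg, seed = NULL, restarts = 0L,
                 failures_per_attempt = integer(0)),
            class = "nucleus_model")
}

# replicate batch of B. distachyon models shared by the frequency tests;
# built once per test run
set1_batch <- local({
  cache <- NULL
  function(n = 115L, seed = 1L) {
    if (is.null(cache) || length(cache$models) < n)
      cache <<- simulate_batch(ct_preset("set1"), n, seed = seed)
    cache
  }
})

# independent brute-force re-implementation of the domain acceptance rules,
# used as the oracle for the fast path
brute_force_domain_ok <- function(p, nucleus, nucleolus, own, foreign, cfg,
                                  precursory = NULL) {
  euclid <- function(a, b) sqrt(sum((a - b)^2))
  if (!(euclid(p, nucleus$centre) < nucleus$radius - cfg$rad_bead))
    return(FALSE)
  if (!(euclid(p, nucleolus$centre) >
        nucleolus$radius + cfg$rad_bead + cfg$eps_2)) return(FALSE)
  if (nrow(own)) {
    for (i in seq_len(nrow(own))) {
      if (!is.null(precursory) && i == precursory) next
      if (euclid(p, own[i, ]) < 2 * cfg$rad_bead - 2 * cfg$eps_1)
        return(FALSE)
    }
    dmin <- min(apply(own, 1L, euclid, a = p))
    if (!(dmin <= nucleus$radius - 2 * cfg$rad_bead - cfg$eps_1))
      return(FALSE)
  }
  if (nrow(foreign)) {
    thr <- if (cfg$paper_literal) 2 * cfg$rad_bead - 2 * cfg$eps_2
           else 2 * cfg$rad_bead + cfg$eps_2
    for (i in seq_len(nrow(foreign)))
      if (euclid(p, foreign[i, ]) < thr) return(FALSE)
  }
  TRUE
}
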