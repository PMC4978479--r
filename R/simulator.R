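#' @importFrom stats runif
NULL

# ---- internal growth state -------------------------------------------------
#
# One model attempt mutates an environment holding a pre-allocated coordinate
# matrix plus parallel identity vectors. Arm codes: 0 = centromere, 1 = top,
# 2 = bottom. Chromosome ids run 1..2*chr_pair; pair k owns ids 2k-1, 2k.

ARM_LEVELS <- c("cen", "top", "bottom")

restart_signal <- function(failures) {
  structure(class = c("ctsim_restart", "error", "condition"),
            list(message = "placement failure threshold reached",
                 call = NULL, failures = failures))
}

new_state <- function(cfg, nucleus, nucleolus) {
  st <- new.env(parent = emptyenv())
  N <- 2L * cfg$chr_pair
  totals <- rep(chromosome_totals(cfg, "decondensed"), each = 2L)
  ntot <- sum(totals)
  st$cfg <- cfg
  st$nucleus <- nucleus
  st$nucleolus <- nucleolus
  st$N <- N
  st$xyz <- matrix(NA_real_, ntot, 3L)
  st$chrom <- integer(ntot)
  st$arm <- integer(ntot)
  st$idx <- integer(ntot)
  st$phase <- integer(ntot)        # 1 = condensed, 2 = decondensation
  st$prec_arm <- integer(ntot)     # NA-coded as -1 for centromeres
  st$prec_idx <- integer(ntot)
  st$n <- 0L
  st$fail <- 0L
  st$cen_row <- integer(N)
  # row indices per (chromosome, arm); grown as beads are appended
  st$arm_rows <- lapply(seq_len(N), function(i) list(integer(0), integer(0)))
  st$step <- if (cfg$step_mode == "tangent") 2 * cfg$rad_bead else cfg$rad_bead
  # squared thresholds, hoisted out of the proposal loop
  st$thr_own2 <- (2 * cfg$rad_bead - 2 * cfg$eps_1)^2
  st$thr_for2 <- if (cfg$paper_literal) {
    t <- 2 * cfg$rad_bead - 2 * cfg$eps_2
    if (t > 0) t^2 else 0
  } else (2 * cfg$rad_bead + cfg$eps_2)^2
  st$r_in <- max(nucleus$radius - cfg$rad_bead, 0)
  st$no_clear2 <- (nucleolus$radius + cfg$rad_bead + cfg$eps_2)^2
  st$d1max2 <- max(nucleus$radius - 2 * cfg$rad_bead - cfg$eps_1, 0)^2
  st
}

append_bead <- function(st, p, chrom, arm, idx, prec_arm, prec_idx, phase) {
  i <- st$n + 1L
  st$xyz[i, ] <- p
  st$chrom[i] <- chrom
  st$arm[i] <- arm
  st$idx[i] <- idx
  st$phase[i] <- phase
  st$prec_arm[i] <- prec_arm
  st$prec_idx[i] <- prec_idx
  st$n <- i
  if (arm == 0L) st$cen_row[chrom] <- i
  else st$arm_rows[[chrom]][[arm]] <- c(st$arm_rows[[chrom]][[arm]], i)
  st$fail <- 0L
  i
}

# one chain-growth placement: re-draw a precursory bead from `pool` and a
# candidate one step away from it until the candidate passes C1'-C3', C4,
# C5; appends the bead and returns its row. The rejection loop runs in
# compiled code (src/growth.cpp) on R's RNG.
place_domain <- function(st, chrom, arm, idx, pool, phase) {
  n <- st$n
  own <- st$chrom[seq_len(n)] == chrom
  no <- st$nucleolus$centre
  res <- .place_domain_cpp(st$xyz, n, own, as.integer(pool), st$step,
                           st$r_in^2,
                           no[1L], no[2L], no[3L], st$no_clear2,
                           st$thr_own2, st$thr_for2, st$d1max2,
                           st$fail, st$cfg$restart_after)
  if (!is.null(res$restart)) stop(restart_signal(res$fail))
  org <- res$origin
  append_bead(st, c(res$x, res$y, res$z), chrom, arm, idx,
              st$arm[org], st$idx[org], phase)
}

# ---- block II: nucleus -----------------------------------------------------

#' Create the nucleus sphere
#'
#' The nucleus is centred at the origin with radius drawn uniformly from
#' `[min_rad_nu, max_rad_nu]`.
#'
#' @param cfg a [species_config()].
#' @return a [sphere()].
#' @export
create_nucleus <- function(cfg) {
  sphere(c(0, 0, 0), runif(1L, cfg$min_rad_nu, cfg$max_rad_nu))
}

# ---- block III: nucleolus --------------------------------------------------

#' Create the nucleolus sphere
#'
#' The radius is drawn uniformly between the bounds returned by
#' [nucleolus_radius_bounds()]; the centre is drawn uniformly from the
#' containment box `(-(R - r - 1), R - r - 2)` per axis and redrawn until
#' the whole nucleolus lies strictly inside the nucleus
#' (`|centre| + r < R`).
#'
#' @param nucleus the nucleus [sphere()].
#' @param cfg a [species_config()].
#' @return a [sphere()].
#' @export
create_nucleolus <- function(nucleus, cfg) {
  R <- nucleus$radius
  b <- nucleolus_radius_bounds(R, cfg$min_vol_no, cfg$max_vol_no)
  r <- runif(1L, b[["r_min"]], b[["r_max"]])
  repeat {
    centre <- c(runif(1L, -(R - r - 1), R - r - 2),
                runif(1L, -(R - r - 1), R - r - 2),
                runif(1L, -(R - r - 1), R - r - 2))
    if (sqrt(sum(centre^2)) + r < R) return(sphere(centre, r))
  }
}

# ---- block IV: centromeres -------------------------------------------------

place_centromeres_state <- function(st) {
  cfg <- st$cfg
  R <- st$nucleus$radius
  rmax2 <- max(R - (cfg$rad_bead + 5 * cfg$eps_2), 0)^2
  min_sep2 <- (2 * cfg$rad_bead + cfg$eps_2)^2
  no <- st$nucleolus$centre
  for (i in seq_len(st$N)) {
    prev <- st$xyz[st$cen_row[seq_len(i - 1L)], , drop = FALSE]
    res <- .place_centromere_cpp(prev, i - 1L, R, rmax2,
                                 no[1L], no[2L], no[3L], st$no_clear2,
                                 min_sep2, st$fail, cfg$restart_after)
    if (!is.null(res$restart)) stop(restart_signal(res$fail))
    append_bead(st, c(res$x, res$y, res$z), i, 0L, 0L, -1L, -1L, 1L)
  }
  invisible(st)
}

# ---- block V: condensed growth ---------------------------------------------

grow_condensed_state <- function(st) {
  cfg <- st$cfg
  targets <- cfg$l_arm_c[rep(seq_len(cfg$chr_pair), each = 2L), , drop = FALSE]
  done <- matrix(0L, st$N, 2L)
  next_arm <- rep(1L, st$N)
  repeat {
    progressed <- FALSE
    for (c in seq_len(st$N)) {
      if (all(done[c, ] >= targets[c, ])) next
      a <- next_arm[c]
      if (done[c, a] >= targets[c, a]) a <- 3L - a
      rows <- st$arm_rows[[c]][[a]]
      origin <- if (length(rows)) rows[length(rows)] else st$cen_row[c]
      idx <- done[c, a] + 1L
      place_domain(st, c, a, idx, origin, 1L)
      done[c, a] <- idx
      next_arm[c] <- 3L - a
      progressed <- TRUE
    }
    if (!progressed) break
  }
  invisible(st)
}

# ---- block VI: decondensation ----------------------------------------------

decondense_state <- function(st) {
  cfg <- st$cfg
  targets <- cfg$l_arm_d[rep(seq_len(cfg$chr_pair), each = 2L), , drop = FALSE]
  done <- t(vapply(seq_len(st$N),
                   function(c) lengths(st$arm_rows[[c]]), integer(2L)))
  whole_chrom <- cfg$precursory_pool == "chromosome"
  repeat {
    progressed <- FALSE
    for (c in seq_len(st$N)) {
      deficit <- targets[c, ] - done[c, ]
      if (all(deficit <= 0L)) next
      a <- if (deficit[1L] >= deficit[2L]) 1L else 2L
      pool <- if (whole_chrom) {
        c(st$cen_row[c], st$arm_rows[[c]][[1L]], st$arm_rows[[c]][[2L]])
      } else {
        rows <- st$arm_rows[[c]][[a]]
        if (length(rows)) rows else st$cen_row[c]
      }
      idx <- done[c, a] + 1L
      place_domain(st, c, a, idx, pool, 2L)
      done[c, a] <- idx
      progressed <- TRUE
    }
    if (!progressed) break
  }
  invisible(st)
}

# ---- assembling / converting -----------------------------------------------

finalize_model <- function(st, seed = NULL, restarts = 0L,
                           failures_per_attempt = integer(0)) {
  n <- st$n
  ord <- order(st$chrom[seq_len(n)], st$arm[seq_len(n)], st$idx[seq_len(n)])
  chrom <- st$chrom[ord]
  arm_i <- st$arm[ord]
  pa <- st$prec_arm[ord]
  beads <- data.frame(
    chrom = chrom,
    pair = (chrom + 1L) %/% 2L,
    copy = 2L - chrom %% 2L,
    arm = factor(ARM_LEVELS[arm_i + 1L], levels = ARM_LEVELS),
    index = st$idx[ord],
    x = st$xyz[ord, 1L], y = st$xyz[ord, 2L], z = st$xyz[ord, 3L],
    radius = st$cfg$rad_bead,
    centromere = arm_i == 0L,
    phase = factor(c("condensed", "decondensation")[st$phase[ord]],
                   levels = c("condensed", "decondensation")),
    prec_arm = factor(ARM_LEVELS[ifelse(pa < 0L, NA_integer_, pa + 1L)],
                      levels = ARM_LEVELS),
    prec_index = ifelse(pa < 0L, NA_integer_, st$prec_idx[ord])
  )
  structure(list(nucleus = st$nucleus, nucleolus = st$nucleolus,
                 beads = beads, cfg = st$cfg, seed = seed,
                 restarts = as.integer(restarts),
                 failures_per_attempt = as.integer(failures_per_attempt)),
            class = "nucleus_model")
}

state_from_model <- function(model) {
  st <- new_state(model$cfg, model$nucleus, model$nucleolus)
  b <- model$beads
  arm_i <- as.integer(b$arm) - 1L
  pa <- ifelse(is.na(b$prec_arm), -1L, as.integer(b$prec_arm) - 1L)
  for (i in seq_len(nrow(b))) {
    append_bead(st, c(b$x[i], b$y[i], b$z[i]), b$chrom[i], arm_i[i],
                b$index[i], pa[i],
                ifelse(is.na(b$prec_index[i]), -1L, b$prec_index[i]),
                as.integer(b$phase[i]))
  }
  st
}

# ---- exported step operations ---------------------------------------------

#' Place the centromere beads
#'
#' Draws one centromere bead per chromosome (`2 * chr_pair` in total), each
#' position proposed uniformly in the nucleus bounding cube and accepted by
#' the centromere conditions C1–C3 (see [centromere_candidate_ok()]).
#'
#' @param nucleus,nucleolus [sphere()]s from [create_nucleus()] /
#'   [create_nucleolus()].
#' @param cfg a [species_config()].
#' @return a partial `nucleus_model` containing only centromere beads.
#'   If `restart_after` consecutive rejections accumulate, a restart
#'   condition of class `"ctsim_restart"` is signalled.
#' @export
place_centromeres <- function(nucleus, nucleolus, cfg) {
  st <- new_state(cfg, nucleus, nucleolus)
  place_centromeres_state(st)
  finalize_model(st)
}

#' Grow the condensed chromosome chains
#'
#' Extends every chromosome bidirectionally from its centromere, one bead
#' per chromosome per round (fair interleaving, alternating arms), until
#' each arm holds its condensed bead count `l_arm_c`. Every new bead sits
#' at the step distance from the arm's current terminal bead and passes the
#' domain conditions C1'–C3', C4, C5.
#'
#' @param model partial model from [place_centromeres()].
#' @param cfg a [species_config()] (defaults to the model's own).
#' @return the extended partial model.
#' @export
grow_condensed <- function(model, cfg = model$cfg) {
  st <- state_from_model(model)
  st$cfg <- cfg
  grow_condensed_state(st)
  finalize_model(st)
}

#' Simulate chromatin decondensation
#'
#' Adds beads along the whole length of each chromosome — not only at the
#' chain ends — until every arm reaches its decondensed domain count
#' `l_arm_d`. For each new bead a precursory domain is drawn uniformly at
#' random from the existing beads of the arm being extended (or of the
#' whole chromosome when `precursory_pool = "chromosome"`); the candidate
#' position is one step from the precursory bead and must pass the domain
#' conditions. Chromosomes are advanced round-robin, the arm with the
#' larger remaining deficit first.
#'
#' @inheritParams grow_condensed
#' @return the completed partial model.
#' @export
decondense <- function(model, cfg = model$cfg) {
  st <- state_from_model(model)
  st$cfg <- cfg
  decondense_state(st)
  finalize_model(st)
}

# ---- full simulation with restart logic ------------------------------------

#' Simulate one interphase nucleus
#'
#' Runs the whole modelling pipeline: nucleus, nucleolus, centromeres,
#' condensed chromosome growth, decondensation. Whenever the shared
#' failure counter reaches `cfg$restart_after` consecutive rejected
#' placements, the partly built model is discarded entirely and the run
#' restarts from the nucleus step with fresh randomness; the first fully
#' completed model is returned together with the number of restarts it
#' consumed.
#'
#' @param cfg a [species_config()].
#' @param seed optional integer seed (falls back to `cfg$seed`); when
#'   given, the same `(cfg, seed)` always reproduces the identical model.
#' @return a `nucleus_model`: nucleus and nucleolus [sphere()]s, a bead
#'   data frame (one row per chromatin domain, ordered by chromosome, arm,
#'   index), the configuration snapshot, the seed, the restart count and
#'   the failure count of each discarded attempt.
#' @examples
#' cfg <- species_config(chr_pair = 1,
#'                       l_arm_c = cbind(2, 2), l_arm_d = cbind(5, 5),
#'                       min_rad_nu = 2500, max_rad_nu = 2500)
#' m <- simulate_nucleus(cfg, seed = 1)
#' nrow(m$beads)  # 11 beads: 1 centromere + 2 arms of 5
#' @export
simulate_nucleus <- function(cfg, seed = NULL) {
  validate_config(cfg)
  if (is.null(seed)) seed <- cfg$seed
  if (!is.null(seed)) { seed <- as.integer(seed); set.seed(seed) }
  restarts <- 0L
  attempt_failures <- integer(0)
  repeat {
    res <- tryCatch({
      nucleus <- create_nucleus(cfg)
      nucleolus <- create_nucleolus(nucleus, cfg)
      st <- new_state(cfg, nucleus, nucleolus)
      place_centromeres_state(st)
      grow_condensed_state(st)
      decondense_state(st)
      finalize_model(st, seed = seed, restarts = restarts,
                     failures_per_attempt = attempt_failures)
    }, ctsim_restart = function(cnd) cnd)
    if (inherits(res, "nucleus_model")) return(res)
    restarts <- restarts + 1L
    attempt_failures <- c(attempt_failures, as.integer(res$failures))
    if (restarts > cfg$max_restarts)
      stop(errorCondition(
        sprintf("model did not complete within %d restart(s)",
                as.integer(cfg$max_restarts)),
        restarts = restarts, failures_per_attempt = attempt_failures,
        class = c("ctsim_abort", "error")))
  }
}

#' Simulate a batch of nuclei
#'
#' Runs [simulate_nucleus()] `n_models` times and reports restart
#' bookkeeping. The success rate follows the benchmark definition: the
#' fraction of attempted runs that completed, i.e.
#' `n_models / (n_models + total restarts)` — restarts never reduce the
#' number of delivered models.
#'
#' @param cfg a [species_config()].
#' @param n_models number of completed models required (>= 1).
#' @param seed optional integer seed for the whole batch.
#' @param progress logical; print one line per completed model.
#' @return list of class `ct_batch`: `models` (list of `nucleus_model`),
#'   `restarts` (per model), `total_restarts`, `success_rate`.
#' @export
simulate_batch <- function(cfg, n_models, seed = NULL, progress = FALSE) {
  if (!(is.numeric(n_models) && length(n_models) == 1L && n_models >= 1))
    stop("n_models must be >= 1", call. = FALSE)
  n_models <- as.integer(n_models)
  if (is.null(seed)) seed <- cfg$seed
  if (!is.null(seed)) set.seed(seed)
  models <- vector("list", n_models)
  restarts <- integer(n_models)
  for (i in seq_len(n_models)) {
    m <- simulate_nucleus(cfg, seed = NULL)  # continue the seeded stream
    models[[i]] <- m
    restarts[i] <- m$restarts
    if (progress)
      message(sprintf("model %d/%d: %d beads, %d restart(s)",
                      i, n_models, nrow(m$beads), m$restarts))
  }
  structure(list(models = models, restarts = restarts,
                 total_restarts = sum(restarts),
                 success_rate = success_rate(n_models, sum(restarts)),
                 seed = seed),
            class = "ct_batch")
}

#' Batch success rate
#'
#' Percentage of attempted runs that completed: obtaining `n_models`
#' models at the cost of `n_restarts` discarded attempts means
#' `n_models + n_restarts` runs, of which `n_models` succeeded.
#'
#' @param n_models completed models.
#' @param n_restarts discarded attempts.
#' @return fraction in (0, 1].
#' @examples
#' success_rate(10, 8)  # 10 models from 18 runs: ~0.556
#' @export
success_rate <- function(n_models, n_restarts) {
  n_models / (n_models + n_restarts)
}

#' @export
print.ct_batch <- function(x, ...) {
  cat("Batch of", length(x$models), "simulated nuclei\n")
  cat(sprintf("  restarts: %d total; success rate %.1f%%\n",
              x$total_restarts, 100 * x$success_rate))
  invisible(x)
}
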