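# Text model format, version 1
#
#   # ctsim-model v1
#   # seed <int|NA>
#   # restarts <int>
#   # failures_per_attempt <comma-separated ints, possibly empty>
#   # beads <n>
#   # nucleus <x> <y> <z> <R>
#   # nucleolus <x> <y> <z> <r>
#   # cfg <field> <value ...>          (one line per configuration field)
#   chrom  pair  copy  arm  index  x  y  z  radius  centromere  phase  prec_arm  prec_index
#   ...one tab-separated record per bead, ordered by (chrom, arm, index)...
#
# Coordinates are serialized with 17 significant digits, which round-trips
# IEEE doubles exactly, so read(write(model)) reproduces the model and the
# output is byte-stable for a fixed model.

fmt_num <- function(x) sprintf("%.17g", x)

serialize_cfg <- function(cfg) {
  arm_tab <- function(m) paste(paste0(m[, 1L], "/", m[, 2L]), collapse = " ")
  c(paste("# cfg chr_pair", cfg$chr_pair),
    paste("# cfg l_arm_c", arm_tab(cfg$l_arm_c)),
    paste("# cfg l_arm_d", arm_tab(cfg$l_arm_d)),
    paste("# cfg min_rad_nu", fmt_num(cfg$min_rad_nu)),
    paste("# cfg max_rad_nu", fmt_num(cfg$max_rad_nu)),
    paste("# cfg min_vol_no", fmt_num(cfg$min_vol_no)),
    paste("# cfg max_vol_no", fmt_num(cfg$max_vol_no)),
    paste("# cfg rad_bead", fmt_num(cfg$rad_bead)),
    paste("# cfg eps_1", fmt_num(cfg$eps_1)),
    paste("# cfg eps_2", fmt_num(cfg$eps_2)),
    paste("# cfg multi", cfg$multi),
    paste("# cfg restart_after", fmt_num(cfg$restart_after)),
    paste("# cfg max_restarts", fmt_num(cfg$max_restarts)),
    paste("# cfg step_mode", cfg$step_mode),
    paste("# cfg precursory_pool", cfg$precursory_pool),
    paste("# cfg paper_literal", cfg$paper_literal),
    if (!is.null(cfg$seed)) paste("# cfg seed", cfg$seed),
    if (!is.null(cfg$name)) paste("# cfg name", cfg$name))
}

parse_arm_tab <- function(s) {
  parts <- strsplit(strsplit(s, " ", fixed = TRUE)[[1]], "/", fixed = TRUE)
  do.call(rbind, lapply(parts, as.integer))
}

deserialize_cfg <- function(lines) {
  kv <- sub("^# cfg ", "", lines)
  key <- sub(" .*$", "", kv)
  val <- sub("^[^ ]+ ?", "", kv)
  names(val) <- key
  args <- list(
    chr_pair = as.integer(val[["chr_pair"]]),
    l_arm_c = parse_arm_tab(val[["l_arm_c"]]),
    l_arm_d = parse_arm_tab(val[["l_arm_d"]]),
    min_rad_nu = as.numeric(val[["min_rad_nu"]]),
    max_rad_nu = as.numeric(val[["max_rad_nu"]]),
    min_vol_no = as.numeric(val[["min_vol_no"]]),
    max_vol_no = as.numeric(val[["max_vol_no"]]),
    rad_bead = as.numeric(val[["rad_bead"]]),
    eps_1 = as.numeric(val[["eps_1"]]),
    eps_2 = as.numeric(val[["eps_2"]]),
    multi = as.integer(val[["multi"]]),
    restart_after = as.numeric(val[["restart_after"]]),
    max_restarts = as.numeric(val[["max_restarts"]]),
    step_mode = unname(val[["step_mode"]]),
    precursory_pool = unname(val[["precursory_pool"]]),
    paper_literal = as.logical(val[["paper_literal"]]))
  if ("seed" %in% key) args$seed <- as.integer(val[["seed"]])
  if ("name" %in% key) args$name <- unname(val[["name"]])
  do.call(species_config, args)
}

#' Write a nucleus model to a text file
#'
#' Persists a completed `nucleus_model` in the package's tab-separated
#' dialect: '#'-prefixed header lines (format version, seed, restart
#' bookkeeping, nucleus and nucleolus spheres, configuration snapshot)
#' followed by one record per bead in (chromosome, arm, index) order.
#' Coordinates keep full double precision, so [read_model()] reproduces
#' the model exactly and the bytes are stable for a fixed model.
#'
#' @param model a validated `nucleus_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  validate_model(model)
  b <- model$beads
  header <- c(
    "# ctsim-model v1",
    paste("# seed", if (is.null(model$seed)) "NA" else model$seed),
    paste("# restarts", model$restarts),
    paste("# failures_per_attempt",
          paste(model$failures_per_attempt, collapse = ",")),
    paste("# beads", nrow(b)),
    paste("# nucleus", paste(fmt_num(c(model$nucleus$centre,
                                       model$nucleus$radius)), collapse = " ")),
    paste("# nucleolus", paste(fmt_num(c(model$nucleolus$centre,
                                         model$nucleolus$radius)), collapse = " ")),
    serialize_cfg(model$cfg))
  records <- paste(b$chrom, b$pair, b$copy, as.character(b$arm), b$index,
                   fmt_num(b$x), fmt_num(b$y), fmt_num(b$z), fmt_num(b$radius),
                   as.integer(b$centromere), as.character(b$phase),
                   ifelse(is.na(b$prec_arm), "NA", as.character(b$prec_arm)),
                   ifelse(is.na(b$prec_index), "NA", b$prec_index),
                   sep = "\t")
  con <- tryCatch(suppressWarnings(file(path, "w")),
                  error = function(e) stop("cannot write model file '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  on.exit(close(con))
  writeLines(c(header, records), con)
  invisible(path)
}

#' Read a nucleus model from a text file
#'
#' Parses the dialect written by [write_model()], rebuilds the
#' `nucleus_model` and re-runs the full invariant suite
#' ([validate_model()]), so a tampered file (e.g. a bead outside the
#' nucleus, or a bead count disagreeing with the header) is rejected.
#'
#' @param path path to a model file.
#' @return a validated `nucleus_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (!length(lines) || lines[1L] != "# ctsim-model v1")
    stop("parse error in ", path, " line 1: not a ctsim model file",
         call. = FALSE)
  is_header <- startsWith(lines, "#")
  header <- lines[is_header]
  body <- lines[!is_header]
  hval <- function(key) {
    hit <- header[startsWith(header, paste0("# ", key, " "))]
    if (length(hit) != 1L)
      stop("parse error in ", path, ": missing header '", key, "'",
           call. = FALSE)
    sub(paste0("^# ", key, " "), "", hit)
  }
  seed <- hval("seed")
  seed <- if (seed == "NA") NULL else as.integer(seed)
  restarts <- as.integer(hval("restarts"))
  fpa_raw <- hval("failures_per_attempt")
  fpa <- if (nzchar(fpa_raw)) as.integer(strsplit(fpa_raw, ",")[[1]])
         else integer(0)
  n_declared <- as.integer(hval("beads"))
  nu <- as.numeric(strsplit(hval("nucleus"), " ")[[1]])
  no <- as.numeric(strsplit(hval("nucleolus"), " ")[[1]])
  cfg <- deserialize_cfg(header[startsWith(header, "# cfg ")])

  if (length(body) != n_declared)
    stop("parse error in ", path, ": header declares ", n_declared,
         " beads but body has ", length(body), call. = FALSE)
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 13L)) {
    bad <- which(nf != 13L)[1L]
    stop("parse error in ", path, " line ", sum(is_header) + bad,
         ": expected 13 tab-separated fields, found ", nf[bad], call. = FALSE)
  }
  m <- do.call(rbind, fields)
  suppress_na <- function(x, line_base) {
    out <- suppressWarnings(as.numeric(x))
    if (anyNA(out)) {
      bad <- which(is.na(out))[1L]
      stop("parse error in ", path, " line ", line_base + bad,
           ": non-numeric field", call. = FALSE)
    }
    out
  }
  nb <- sum(is_header)
  beads <- data.frame(
    chrom = as.integer(suppress_na(m[, 1L], nb)),
    pair = as.integer(suppress_na(m[, 2L], nb)),
    copy = as.integer(suppress_na(m[, 3L], nb)),
    arm = factor(m[, 4L], levels = ARM_LEVELS),
    index = as.integer(suppress_na(m[, 5L], nb)),
    x = suppress_na(m[, 6L], nb), y = suppress_na(m[, 7L], nb),
    z = suppress_na(m[, 8L], nb), radius = suppress_na(m[, 9L], nb),
    centromere = suppress_na(m[, 10L], nb) == 1,
    phase = factor(m[, 11L], levels = c("condensed", "decondensation")),
    prec_arm = factor(ifelse(m[, 12L] == "NA", NA_character_, m[, 12L]),
                      levels = ARM_LEVELS),
    prec_index = suppressWarnings(
      ifelse(m[, 13L] == "NA", NA_integer_, as.integer(m[, 13L])))
  )
  if (anyNA(beads$arm) || anyNA(beads$phase))
    stop("parse error in ", path, ": unknown arm or phase tag", call. = FALSE)
  model <- structure(
    list(nucleus = sphere(nu[1:3], nu[4L]),
         nucleolus = sphere(no[1:3], no[4L]),
         beads = beads, cfg = cfg, seed = seed, restarts = restarts,
         failures_per_attempt = fpa),
    class = "nucleus_model")
  tryCatch(validate_model(model),
           error = function(e) stop("integrity error in ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
  model
}

#' Export bead coordinates in XYZ format
#'
#' Flat XYZ-style export loadable by generic 3-D viewers: a count line, a
#' comment line, then one `C<chromosome> x y z` record per bead (the
#' element column carries the chromosome id) and a final `NO x y z` record
#' for the nucleolus centre.
#'
#' @param model a `nucleus_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_xyz <- function(model, path) {
  b <- model$beads
  lines <- c(
    as.character(nrow(b) + 1L),
    "simulated chromosome territories (coordinates in nm)",
    paste(paste0("C", b$chrom), fmt_num(b$x), fmt_num(b$y), fmt_num(b$z)),
    paste("NO", paste(fmt_num(model$nucleolus$centre), collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}
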