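#' Colour scheme for territory rendering
#'
#' Reproduces the two presentation modes used for territory figures:
#'
#' * `mode = "arms"` — highlight one homologous pair, its top arms in one
#'   colour and bottom arms in another (default green/red), matching the
#'   arm-specific labelling of homologue experiments;
#' * `mode = "pairs"` — highlight two heterologous pairs, one colour per
#'   pair, without arm discrimination.
#'
#' All other chromatin is drawn white or, with
#' `background = "transparent"`, not at all. At most two pairs can be
#' highlighted and at most four distinct colours used. The nucleolus is
#' always drawn as a yellow sphere.
#'
#' @param highlight one pair id (`"arms"`) or two pair ids (`"pairs"`).
#' @param mode `"arms"` or `"pairs"`.
#' @param colours character vector of colours: length 2 for `"arms"`
#'   (top, bottom) and for `"pairs"` (first, second pair).
#' @param background `"white"` (non-highlighted beads in white) or
#'   `"transparent"` (hidden).
#' @return an object of class `ct_colour_scheme`.
#' @export
colour_scheme <- function(highlight, mode = c("arms", "pairs"),
                          colours = NULL, background = c("white",
                                                         "transparent")) {
  mode <- match.arg(mode)
  background <- match.arg(background)
  highlight <- as.integer(highlight)
  want <- if (mode == "arms") 1L else 2L
  if (length(highlight) != want)
    stop("mode '", mode, "' highlights exactly ", want, " pair(s)",
         call. = FALSE)
  if (anyDuplicated(highlight))
    stop("highlighted pairs must be distinct", call. = FALSE)
  if (is.null(colours)) colours <- c("green3", "red2")
  if (length(colours) != 2L) stop("need exactly two colours", call. = FALSE)
  structure(list(mode = mode, highlight = highlight, colours = colours,
                 background = background, nucleolus = "gold"),
            class = "ct_colour_scheme")
}

#' Bead colours under a scheme
#'
#' Pure function mapping each bead of a model to a colour (or `NA` for
#' beads hidden by a transparent background) according to a
#' [colour_scheme()].
#'
#' @param model a `nucleus_model`.
#' @param scheme a `ct_colour_scheme`.
#' @return character vector, one colour (or `NA`) per bead row.
#' @export
bead_colours <- function(model, scheme) {
  stopifnot(inherits(scheme, "ct_colour_scheme"))
  if (any(scheme$highlight > model$cfg$chr_pair | scheme$highlight < 1L))
    stop("scheme highlights a chromosome pair absent from the model",
         call. = FALSE)
  b <- model$beads
  col <- rep(if (scheme$background == "white") "white" else NA_character_,
             nrow(b))
  if (scheme$mode == "arms") {
    sel <- b$pair == scheme$highlight
    col[sel & b$arm %in% c("top", "cen")] <- scheme$colours[1L]
    col[sel & b$arm == "bottom"] <- scheme$colours[2L]
  } else {
    col[b$pair == scheme$highlight[1L]] <- scheme$colours[1L]
    col[b$pair == scheme$highlight[2L]] <- scheme$colours[2L]
  }
  col
}

rotation_matrix <- function(theta, phi) {
  ct <- cos(theta); st <- sin(theta)
  cp <- cos(phi); sp <- sin(phi)
  # rotate about z by theta, then about x by phi
  matrix(c(ct, -st, 0, st, ct, 0, 0, 0, 1), 3L, byrow = TRUE) %*%
    matrix(c(1, 0, 0, 0, cp, -sp, 0, sp, cp), 3L, byrow = TRUE)
}

#' Render a static 3-D scene of a simulated nucleus
#'
#' Orthographic projection of the model after rotation by the camera
#' angles, painter's-algorithm depth ordering (far beads drawn first), the
#' nucleolus as a yellow sphere slotted into the depth order, and the
#' nucleus boundary as an enclosing circle. With `file` the scene is
#' written to a PNG or PDF (chosen by extension); otherwise it is drawn on
#' the current graphics device. The model is not modified.
#'
#' @param model a `nucleus_model`.
#' @param scheme a [colour_scheme()].
#' @param file optional output path ending in `.png` or `.pdf`.
#' @param theta,phi camera rotation angles, radians.
#' @param width,height device size in pixels (PNG) or inches (PDF).
#' @return `file` (or `NULL` when drawing on the current device),
#'   invisibly.
#' @export
render_scene <- function(model, scheme = colour_scheme(1L), file = NULL,
                         theta = 0, phi = 0, width = 7, height = 7) {
  cols <- bead_colours(model, scheme)  # validates the scheme
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    switch(ext,
           png = grDevices::png(file, width = width * 100,
                                height = height * 100),
           pdf = grDevices::pdf(file, width = width, height = height),
           stop("unsupported image format: .", ext, call. = FALSE))
    on.exit(grDevices::dev.off())
  }
  rot <- rotation_matrix(theta, phi)
  b <- model$beads
  xyz <- as.matrix(b[, c("x", "y", "z")]) %*% t(rot)
  no <- as.numeric(rot %*% model$nucleolus$centre)
  R <- model$nucleus$radius
  keep <- !is.na(cols)
  px <- c(xyz[keep, 1L], no[1L])
  py <- c(xyz[keep, 2L], no[2L])
  pz <- c(xyz[keep, 3L], no[3L])
  pr <- c(b$radius[keep], model$nucleolus$radius)
  pc <- c(cols[keep], scheme$nucleolus)
  ord <- order(pz)  # far to near
  op <- graphics::par(mar = c(1, 1, 1, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot(NA, xlim = c(-R, R), ylim = c(-R, R), asp = 1,
                 axes = FALSE, xlab = "", ylab = "")
  graphics::symbols(0, 0, circles = R, inches = FALSE, add = TRUE,
                    fg = "grey40", bg = "grey95")
  graphics::symbols(px[ord], py[ord], circles = pr[ord], inches = FALSE,
                    add = TRUE, fg = "grey30", bg = pc[ord])
  invisible(file)
}

#' Export a coloured scene as a flat text file
#'
#' Writes one tab-separated record per visible bead — label, centre
#' coordinates (nm, full precision), radius and colour — plus a final
#' `nucleolus` record, loadable by generic 3-D tools and by
#' [utils::read.delim()].
#'
#' @param model a `nucleus_model`.
#' @param scheme a [colour_scheme()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_scene <- function(model, scheme, path) {
  cols <- bead_colours(model, scheme)
  b <- model$beads
  keep <- !is.na(cols)
  lines <- c(
    paste("label", "x", "y", "z", "radius", "colour", sep = "\t"),
    paste(paste0("chr", b$chrom[keep], "_", as.character(b$arm[keep]), "_",
                 b$index[keep]),
          fmt_num(b$x[keep]), fmt_num(b$y[keep]), fmt_num(b$z[keep]),
          fmt_num(b$radius[keep]), cols[keep], sep = "\t"),
    paste("nucleolus",
          fmt_num(model$nucleolus$centre[1L]),
          fmt_num(model$nucleolus$centre[2L]),
          fmt_num(model$nucleolus$centre[3L]),
          fmt_num(model$nucleolus$radius), scheme$nucleolus, sep = "\t"))
  con <- tryCatch(suppressWarnings(file(path, "w")),
                  error = function(e) stop("cannot write scene file '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
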