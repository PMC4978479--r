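#' Packaged species presets
#'
#' Three ready-made configurations ship with the package as YAML files
#' under `inst/extdata`:
#'
#' * `"set1"` / `"brachypodium"` — the *Brachypodium distachyon* karyotype:
#'   5 chromosome pairs, 28–75 Mbp (so 28–75 decondensed 1 Mbp domains per
#'   chromosome, 540 domains in the whole diploid nucleus), condensed
#'   chains of 7–14 beads for the 3.5–7.0 µm metaphase lengths, Bd1–Bd3
#'   metacentric and Bd4–Bd5 acrocentric.
#' * `"set2"` / `"human"` — a human-like benchmark: 23 pairs, 57–249 Mbp,
#'   condensed lengths 1.5–10.9 µm, sizes interpolated linearly across
#'   chromosomes.
#' * `"set3"` / `"miscanthus"` — a *Miscanthus sinensis*-like benchmark:
#'   19 pairs, 87–244 Mbp, condensed lengths 1.4–3.9 µm.
#'
#' Arm splits for the *B. distachyon* preset are an assumption (the
#' karyotype morphology is published, exact arm ratios are not): the
#' metacentric chromosomes split arm beads 50:50 with any odd bead on the
#' bottom arm, the acrocentric ones 25:75. Edit the YAML files to change
#' this.
#'
#' @param name preset name (see above); case-insensitive.
#' @return a validated [species_config()].
#' @examples
#' cfg <- ct_preset("set1")
#' cfg$chr_pair  # 5
#' @export
ct_preset <- function(name = c("set1", "set2", "set3",
                               "brachypodium", "human", "miscanthus")) {
  name <- match.arg(tolower(name), c("set1", "set2", "set3",
                                     "brachypodium", "human", "miscanthus"))
  file <- switch(name,
    set1 = , brachypodium = "set1_brachypodium.yaml",
    set2 = , human = "set2_human.yaml",
    set3 = , miscanthus = "set3_miscanthus.yaml")
  path <- system.file("extdata", file, package = "ctsim", mustWork = TRUE)
  load_config(path)
}

#' @rdname ct_preset
#' @export
brachypodium_preset <- function() ct_preset("brachypodium")
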