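#' Build a marker map for a simulated genome
#'
#' Lays out evenly spaced biallelic markers along autosomes. Genetic positions
#' are proportional to physical positions at a constant `cm_per_mb` rate, so a
#' chromosome of `chrom_length_bp` base pairs spans
#' `chrom_length_bp / 1e6 * cm_per_mb` centiMorgans.
#'
#' The default desk-scale genome is 10 autosomes of 25 Mb at 1 cM/Mb with
#' 1000 markers each (10,000 markers, 2.5 Morgans total) — a proportionally
#' reduced stand-in for a cattle-like genome typed on a high-density chip.
#' `scale = "full"` configures 10 x 2.5 Morgan chromosomes at HD-chip density.
#'
#' @param n_chrom number of autosomes.
#' @param chrom_length_bp physical length of each chromosome in bp.
#' @param markers_per_chrom evenly spaced markers per chromosome.
#' @param cm_per_mb recombination rate in cM per Mb.
#' @param scale `"desk"` (default) or `"full"`; presets overridden by any
#'   explicitly supplied argument.
#' @return A tibble marker map with columns `chrom`, `marker_id`, `pos_bp`,
#'   `pos_cm`, `ref_allele`, `alt_allele`.
#' @examples
#' map <- sim_genome(n_chrom = 2, markers_per_chrom = 100)
#' @export
sim_genome <- function(n_chrom = NULL, chrom_length_bp = NULL,
                       markers_per_chrom = NULL, cm_per_mb = NULL,
                       scale = c("desk", "full")) {
  scale <- match.arg(scale)
  preset <- switch(scale,
    desk = list(n_chrom = 10, chrom_length_bp = 25e6,
                markers_per_chrom = 1000, cm_per_mb = 1),
    full = list(n_chrom = 10, chrom_length_bp = 100e6,
                markers_per_chrom = 65824, cm_per_mb = 2.5)
  )
  n_chrom <- n_chrom %||% preset$n_chrom
  chrom_length_bp <- chrom_length_bp %||% preset$chrom_length_bp
  markers_per_chrom <- markers_per_chrom %||% preset$markers_per_chrom
  cm_per_mb <- cm_per_mb %||% preset$cm_per_mb
  stopifnot(n_chrom >= 1, markers_per_chrom >= 2,
            chrom_length_bp >= markers_per_chrom, cm_per_mb > 0)

  spacing <- chrom_length_bp / markers_per_chrom
  pos <- as.integer(round(spacing * (seq_len(markers_per_chrom) - 0.5)))
  map <- tidyr::expand_grid(chrom = seq_len(n_chrom), pos_bp = pos)
  map <- dplyr::mutate(map,
    marker_id = sprintf("c%d_%d", .data$chrom, .data$pos_bp),
    pos_cm = .data$pos_bp / 1e6 * cm_per_mb,
    ref_allele = "A",
    alt_allele = "G"
  )
  map <- dplyr::select(map, "chrom", "marker_id", "pos_bp", "pos_cm",
                       "ref_allele", "alt_allele")
  validate_marker_map(map)
  map
}

#' Validate a marker map
#'
#' Checks the invariants every map in the pipeline must satisfy: physical
#' positions strictly increasing within chromosome, genetic positions
#' non-decreasing, biallelic markers with distinct alleles.
#'
#' @param map a marker-map tibble (see [sim_genome()]).
#' @return the map, invisibly, or an error.
#' @export
validate_marker_map <- function(map) {
  need <- c("chrom", "marker_id", "pos_bp", "pos_cm", "ref_allele", "alt_allele")
  missing <- setdiff(need, names(map))
  if (length(missing) > 0) {
    stop_input(paste0("marker map lacks columns: ", paste(missing, collapse = ", ")))
  }
  if (nrow(map) == 0) stop_input("marker map has zero markers")
  by_chr <- split(seq_len(nrow(map)), map$chrom)
  for (idx in by_chr) {
    if (is.unsorted(map$pos_bp[idx], strictly = TRUE)) {
      stop_input("pos_bp must be strictly increasing within each chromosome")
    }
    if (is.unsorted(map$pos_cm[idx])) {
      stop_input("pos_cm must be non-decreasing within each chromosome")
    }
  }
  if (any(map$ref_allele == map$alt_allele)) {
    stop_input("markers must be biallelic with distinct alleles")
  }
  invisible(map)
}
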