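#' Phased haplotype panel
#'
#' A `haplotype_panel` bundles a phased binary haplotype matrix with its
#' marker map. Rows `2i - 1` and `2i` of `haplotypes` are the two gametes of
#' diploid individual `i`; entries count the alternate allele (0/1).
#'
#' @param haplotypes integer matrix, `2H x M`, entries in `{0, 1}`.
#' @param map marker map tibble with `M` rows (see [sim_genome()]).
#' @param breed_id single label for the panel's population.
#' @param sample_ids optional character vector of `H` individual ids.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(haplotypes, map, breed_id = "pop",
                            sample_ids = NULL) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  if (nrow(haplotypes) %% 2 != 0) {
    stop_input("haplotype row count must be even (two gametes per individual)")
  }
  if (ncol(haplotypes) != nrow(map)) {
    stop_input("haplotype column count must equal the number of mapped markers")
  }
  if (!all(haplotypes %in% c(0L, 1L))) {
    stop_input("haplotype entries must be 0 or 1")
  }
  validate_marker_map(map)
  h <- nrow(haplotypes) / 2
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("%s_%03d", breed_id, seq_len(h))
  }
  if (length(sample_ids) != h) stop_input("need one sample id per individual")
  structure(
    list(haplotypes = haplotypes, map = map, breed_id = breed_id,
         sample_ids = as.character(sample_ids)),
    class = "haplotype_panel"
  )
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf(
    "<haplotype_panel> breed '%s': %d individuals (%d haplotypes) x %d markers on %d chromosome(s)\n",
    x$breed_id, n_ind(x), nrow(x$haplotypes), ncol(x$haplotypes),
    length(unique(x$map$chrom))
  ))
  mono <- sum(panel_freq(x) %in% c(0, 1))
  cat(sprintf("  monomorphic markers: %d\n", mono))
  invisible(x)
}

#' Number of diploid individuals in a panel or genotype matrix
#' @param x a `haplotype_panel` or `genotype_matrix`.
#' @return integer count.
#' @export
n_ind <- function(x) UseMethod("n_ind")

#' @export
n_ind.haplotype_panel <- function(x) nrow(x$haplotypes) %/% 2L

#' @export
n_ind.genotype_matrix <- function(x) nrow(x$dosages)

# Alternate-allele frequency per marker, from phased haplotypes.
panel_freq <- function(panel) colMeans(panel$haplotypes)

#' Extract a subset of individuals from a panel
#' @param panel a `haplotype_panel`.
#' @param ind integer indices of individuals to keep (order respected).
#' @return a `haplotype_panel`.
#' @export
subset_panel <- function(panel, ind) {
  stopifnot(all(ind >= 1), all(ind <= n_ind(panel)))
  rows <- as.vector(rbind(2L * ind - 1L, 2L * ind))
  haplotype_panel(panel$haplotypes[rows, , drop = FALSE], panel$map,
                  breed_id = panel$breed_id,
                  sample_ids = panel$sample_ids[ind])
}

#' Convert a phased genotype matrix back to a haplotype panel
#'
#' Requires the genotype matrix to carry its two gamete matrices (as produced
#' by [resample_population()]).
#'
#' @param x a `genotype_matrix` with phase.
#' @param breed_id optional label override.
#' @return a `haplotype_panel`.
#' @export
as_haplotype_panel <- function(x, breed_id = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (is.null(x$gametes)) stop_input("genotype matrix carries no phase")
  n <- nrow(x$dosages)
  h <- matrix(0L, 2L * n, ncol(x$dosages))
  h[seq(1L, 2L * n, by = 2L), ] <- x$gametes[[1]]
  h[seq(2L, 2L * n, by = 2L), ] <- x$gametes[[2]]
  haplotype_panel(h, x$map,
                  breed_id = breed_id %||% x$breed_labels[1],
                  sample_ids = x$sample_ids)
}
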