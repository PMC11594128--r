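#' Genotype matrix container
#'
#' Individuals-by-markers alternate-allele dosages (0/1/2, `NA` = missing),
#' with breed labels, the marker map, and optionally the two phased gamete
#' matrices the dosages were formed from.
#'
#' @param dosages n x M matrix with entries in `{0, 1, 2, NA}`.
#' @param map marker map tibble.
#' @param sample_ids character vector, length n.
#' @param breed_labels character vector, length n (recycled if length 1).
#' @param gametes optional list of two n x M binary matrices whose sum equals
#'   `dosages`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, map, sample_ids = NULL,
                            breed_labels = "pop", gametes = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (ncol(dosages) != nrow(map)) {
    stop_input("dosage column count must equal the number of mapped markers")
  }
  vals <- dosages[!is.na(dosages)]
  if (length(vals) && !all(vals %in% 0:2)) {
    stop_input("dosages must be 0, 1, 2 or NA")
  }
  n <- nrow(dosages)
  if (is.null(sample_ids)) sample_ids <- sprintf("ind_%05d", seq_len(n))
  if (length(sample_ids) != n) stop_input("need one sample id per individual")
  if (length(breed_labels) == 1) breed_labels <- rep(breed_labels, n)
  if (length(breed_labels) != n) stop_input("need one breed label per individual")
  if (!is.null(gametes)) {
    stopifnot(length(gametes) == 2)
    g1 <- gametes[[1]]; g2 <- gametes[[2]]
    storage.mode(g1) <- "integer"; storage.mode(g2) <- "integer"
    if (!identical(dim(g1), dim(dosages)) || !identical(dim(g2), dim(dosages))) {
      stop_input("gamete matrices must match the dosage dimensions")
    }
    ok <- is.na(dosages) | (g1 + g2 == dosages)
    if (!all(ok)) stop_input("dosage must equal the sum of the two gamete rows")
    gametes <- list(g1, g2)
  }
  validate_marker_map(map)
  structure(
    list(dosages = dosages, map = map, sample_ids = as.character(sample_ids),
         breed_labels = as.character(breed_labels), gametes = gametes),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d individuals x %d markers (%s phase), breeds: %s\n",
    nrow(x$dosages), ncol(x$dosages),
    if (is.null(x$gametes)) "no" else "with",
    paste(unique(x$breed_labels), collapse = ", ")
  ))
  invisible(x)
}

#' Subset individuals of a genotype matrix
#' @param x a `genotype_matrix`.
#' @param ind integer indices or sample ids.
#' @return a `genotype_matrix`.
#' @export
subset_individuals <- function(x, ind) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (is.character(ind)) ind <- match(ind, x$sample_ids)
  if (anyNA(ind)) stop_input("unknown sample ids in subset")
  gam <- if (!is.null(x$gametes)) {
    list(x$gametes[[1]][ind, , drop = FALSE], x$gametes[[2]][ind, , drop = FALSE])
  }
  genotype_matrix(x$dosages[ind, , drop = FALSE], x$map,
                  sample_ids = x$sample_ids[ind],
                  breed_labels = x$breed_labels[ind], gametes = gam)
}

#' Combine genotype matrices sharing a map
#' @param ... `genotype_matrix` objects on identical maps.
#' @return a `genotype_matrix` stacking all individuals.
#' @export
bind_genotypes <- function(...) {
  xs <- list(...)
  if (length(xs) == 1 && is.list(xs[[1]]) && !inherits(xs[[1]], "genotype_matrix")) {
    xs <- xs[[1]]
  }
  map <- xs[[1]]$map
  for (x in xs) {
    if (!identical(x$map$marker_id, map$marker_id)) {
      stop_input("genotype matrices must share a marker map")
    }
  }
  phased <- all(vapply(xs, function(x) !is.null(x$gametes), logical(1)))
  gam <- if (phased) {
    list(do.call(rbind, lapply(xs, function(x) x$gametes[[1]])),
         do.call(rbind, lapply(xs, function(x) x$gametes[[2]])))
  }
  genotype_matrix(do.call(rbind, lapply(xs, function(x) x$dosages)), map,
                  sample_ids = unlist(lapply(xs, function(x) x$sample_ids)),
                  breed_labels = unlist(lapply(xs, function(x) x$breed_labels)),
                  gametes = gam)
}

# Tile markers into consecutive blocks of block_len, restarting at every
# chromosome boundary (blocks never span chromosomes; the final block of a
# chromosome may be shorter). Returns an integer block id per marker.
marker_blocks <- function(map, block_len) {
  stopifnot(block_len >= 1)
  offset <- 0L
  ids <- integer(nrow(map))
  for (idx in split(seq_len(nrow(map)), map$chrom)) {
    b <- (seq_along(idx) - 1L) %/% block_len + 1L
    ids[idx] <- b + offset
    offset <- offset + max(b)
  }
  ids
}

#' Expand a breed panel to a large population by haplotype-block resampling
#'
#' Emulates chip data for a large population from a small phased panel: the
#' map is tiled into consecutive blocks of `block_len` adjacent markers
#' (restarting at chromosome boundaries), and every simulated gamete draws,
#' independently per block, one source haplotype uniformly with replacement
#' from the panel and copies its block. Each individual is two independent
#' gametes. Within-block LD and allele frequencies are therefore preserved in
#' expectation, while LD across block boundaries is broken — the boundaries
#' act as strong recombination hotspots.
#'
#' @param panel a [haplotype_panel()].
#' @param n_out simulated individuals (default 1500, the study's population
#'   size per breed).
#' @param block_len markers per block (default 500).
#' @param seed integer seed.
#' @return A phased [genotype_matrix()] with `n_out` individuals labelled
#'   with the panel's breed id.
#' @examples
#' map <- sim_genome(n_chrom = 1, markers_per_chrom = 100)
#' pool <- generate_ancestral_pool(40, map, ancestral_ne = 20, seed = 3)
#' pop <- resample_population(pool, n_out = 50, block_len = 25, seed = 4)
#' @export
resample_population <- function(panel, n_out = 1500, block_len = 500,
                                seed = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (n_out < 1) stop_input("n_out must be at least 1")
  h <- panel$haplotypes
  n_hap <- nrow(h)
  blocks <- marker_blocks(panel$map, block_len)
  block_cols <- split(seq_len(ncol(h)), blocks)
  with_seed(seed, {
    gam <- lapply(1:2, function(g) {
      out <- matrix(0L, n_out, ncol(h))
      for (cols in block_cols) {
        src <- sample.int(n_hap, n_out, replace = TRUE)
        out[, cols] <- h[src, cols, drop = FALSE]
      }
      out
    })
    genotype_matrix(gam[[1]] + gam[[2]], panel$map,
                    sample_ids = sprintf("%s_%05d", panel$breed_id, seq_len(n_out)),
                    breed_labels = panel$breed_id, gametes = gam)
  })
}
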