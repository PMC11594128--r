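# Signed-r linkage disequilibrium, distance-binned decay profiles, and the
# cross-population persistence-of-phase statistic (cor100).

# Enumerate intra-chromosomal marker pairs with pairwise distance in
# (0, max_dist_bp], using the half-open convention applied throughout.
band_pairs <- function(map, max_dist_bp) {
  stopifnot(max_dist_bp > 0)
  chunks <- lapply(split(seq_len(nrow(map)), map$chrom), function(idx) {
    pos <- map$pos_bp[idx]
    n <- length(idx)
    last <- findInterval(pos + max_dist_bp, pos)
    cnt <- pmax(last - seq_len(n), 0L)
    i <- rep(seq_len(n), cnt)
    j <- i + sequence(cnt)
    tibble::tibble(i = idx[i], j = idx[j])
  })
  dplyr::bind_rows(chunks)
}

# Signed LD r for marker pairs from a phased binary haplotype matrix:
# r = (f11 - pA pB) / sqrt(pA qA pB qB), identical to the Pearson correlation
# of the two haplotype indicator columns. Monomorphic markers give NA.
# Chunked so the temporary products stay small.
pair_signed_r <- function(h, i, j) {
  n <- nrow(h)
  p <- colMeans(h)
  r <- numeric(length(i))
  chunk <- max(1L, as.integer(2e7 %/% max(n, 1L)))
  for (s in seq(1L, length(i), by = chunk)) {
    k <- s:min(s + chunk - 1L, length(i))
    ik <- i[k]
    jk <- j[k]
    f11 <- colMeans(h[, ik, drop = FALSE] * h[, jk, drop = FALSE])
    den <- sqrt(p[ik] * (1 - p[ik]) * p[jk] * (1 - p[jk]))
    r[k] <- ifelse(den > 0, (f11 - p[ik] * p[jk]) / den, NA_real_)
  }
  r
}

#' Pairwise signed LD within a distance window
#'
#' Computes signed r (and r^2) from phased haplotype frequencies for every
#' intra-chromosomal marker pair at distance at most `max_dist_bp`. Allele
#' orientation follows the map's alternate alleles, so the sign of r is
#' comparable across panels sharing a map. Pairs involving a monomorphic
#' marker are skipped.
#'
#' @param panel a [haplotype_panel()] (phase is required; the sign of r is
#'   only meaningful on phased data).
#' @param max_dist_bp maximum pair distance in bp.
#' @return A tibble with columns `chrom`, `marker_a`, `marker_b`,
#'   `distance_bp`, `r`, `r2`, carrying class `ld_pair_table`.
#' @export
pairwise_signed_ld <- function(panel, max_dist_bp = 1e6) {
  if (!inherits(panel, "haplotype_panel")) {
    stop_input("pairwise_signed_ld requires a phased haplotype_panel")
  }
  check_ld_sample_size(panel)
  pr <- band_pairs(panel$map, max_dist_bp)
  r <- pair_signed_r(panel$haplotypes, pr$i, pr$j)
  out <- tibble::tibble(
    chrom = panel$map$chrom[pr$i],
    marker_a = panel$map$marker_id[pr$i],
    marker_b = panel$map$marker_id[pr$j],
    distance_bp = panel$map$pos_bp[pr$j] - panel$map$pos_bp[pr$i],
    r = r,
    r2 = r^2
  )
  out <- dplyr::filter(out, !is.na(.data$r))
  class(out) <- c("ld_pair_table", class(out))
  out
}

# Reliable LD-structure estimates need on the order of 70+ individuals; the
# emulated chip panels have 21-26, so this is a warning rather than an error.
check_ld_sample_size <- function(panel, min_ind = 70) {
  if (n_ind(panel) < min_ind) {
    warn(sprintf(
      "panel '%s' has %d individuals; fewer than %d makes LD-consistency estimates unreliable",
      panel$breed_id, n_ind(panel), min_ind),
      class = "crossblup_small_panel")
  }
  invisible(panel)
}

ld_bin_edges_bp <- function() {
  1000 * c(seq(0, 10, by = 2.5), seq(20, 100, by = 10), seq(200, 1000, by = 100))
}

#' Distance-binned LD decay profile
#'
#' Bins marker pairs by distance with 2.5 kb steps on (0, 10\] kb, 10 kb steps
#' on (10, 100\] kb and 100 kb steps on (100, 1000\] kb (22 half-open bins),
#' and averages signed r and r^2 per bin. Pairs beyond 1 Mb are ignored;
#' empty bins are kept with `n_pairs = 0`.
#'
#' @param pairs an `ld_pair_table` from [pairwise_signed_ld()].
#' @return A tibble (`ld_profile`) with `bin_lo_bp`, `bin_hi_bp`, `n_pairs`,
#'   `mean_r`, `mean_r2`.
#' @export
ld_decay_profile <- function(pairs) {
  if (nrow(pairs) == 0) stop_input("empty LD pair table")
  edges <- ld_bin_edges_bp()
  bin <- cut(pairs$distance_bp, breaks = edges, right = TRUE, labels = FALSE)
  keep <- !is.na(bin)
  agg <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(bin = bin[keep], r = pairs$r[keep],
                                   r2 = pairs$r2[keep]), .data$bin),
    n_pairs = dplyr::n(), mean_r = mean(.data$r), mean_r2 = mean(.data$r2),
    .groups = "drop"
  )
  out <- tibble::tibble(
    bin = seq_len(length(edges) - 1),
    bin_lo_bp = edges[-length(edges)],
    bin_hi_bp = edges[-1]
  )
  out <- dplyr::left_join(out, agg, by = "bin")
  out <- dplyr::mutate(out,
    n_pairs = dplyr::coalesce(.data$n_pairs, 0L),
    bin = NULL
  )
  class(out) <- c("ld_profile", class(out))
  out
}

#' Persistence of LD phase between two populations
#'
#' The LD-structure consistency of two panels sharing a marker map: signed r
#' is computed in each panel for every shared polymorphic intra-chromosomal
#' pair within `window_bp`, and the consistency is the Pearson correlation of
#' the two r vectors. With the default 100 kb window this is the `cor100`
#' statistic. `method = "binned"` instead correlates per-distance-bin mean r
#' (the bin-averaged variant of the estimator).
#'
#' @param panel_a,panel_b [haplotype_panel()] objects on the same map.
#' @param window_bp pair-distance window (default 100 kb).
#' @param method `"pairwise"` (default) or `"binned"`.
#' @return A one-row tibble: `breed_a`, `breed_b`, `window_bp`, `n_pairs`,
#'   `consistency`, `method`.
#' @examples
#' map <- sim_genome(n_chrom = 1, markers_per_chrom = 300)
#' pool <- generate_ancestral_pool(160, map, ancestral_ne = 80, seed = 2)
#' phase_consistency(pool, pool)$consistency # exactly 1
#' @export
phase_consistency <- function(panel_a, panel_b, window_bp = 1e5,
                              method = c("pairwise", "binned")) {
  method <- match.arg(method)
  stopifnot(inherits(panel_a, "haplotype_panel"),
            inherits(panel_b, "haplotype_panel"))
  if (!identical(panel_a$map$marker_id, panel_b$map$marker_id)) {
    stop_input("panels must share a marker map")
  }
  check_ld_sample_size(panel_a)
  check_ld_sample_size(panel_b)
  map <- panel_a$map
  pr <- band_pairs(map, window_bp)
  pa <- colMeans(panel_a$haplotypes)
  pb <- colMeans(panel_b$haplotypes)
  poly <- (pa > 0 & pa < 1) & (pb > 0 & pb < 1)
  keep <- poly[pr$i] & poly[pr$j]
  pr <- pr[keep, , drop = FALSE]
  if (nrow(pr) < 2) {
    stop_input("fewer than 2 shared polymorphic marker pairs in the window")
  }
  ra <- pair_signed_r(panel_a$haplotypes, pr$i, pr$j)
  rb <- pair_signed_r(panel_b$haplotypes, pr$i, pr$j)
  if (method == "binned") {
    edges <- ld_bin_edges_bp()
    dist <- map$pos_bp[pr$j] - map$pos_bp[pr$i]
    bin <- cut(dist, breaks = edges, right = TRUE, labels = FALSE)
    ma <- tapply(ra, bin, mean)
    mb <- tapply(rb, bin, mean)
    cons <- stats::cor(ma, mb)
  } else {
    cons <- stats::cor(ra, rb)
  }
  tibble::tibble(
    breed_a = panel_a$breed_id, breed_b = panel_b$breed_id,
    window_bp = window_bp, n_pairs = nrow(pr),
    consistency = cons, method = method
  )
}

#' Select SNP sets with common LD across all populations
#'
#' Marker-pair selection on shared LD: within each panel, |r| is computed for
#' every intra-chromosomal pair inside `window_bp`; a pair becomes a SNP set
#' when `r_low < |r| < r_high` holds in every panel. The default bounds are
#' the 0.80 (or 0.90) lower and 0.999 upper criteria; the upper bound
#' excludes fully redundant pairs.
#'
#' @param panels a list of [haplotype_panel()] objects on one map.
#' @param r_low lower |r| bound (exclusive).
#' @param r_high upper |r| bound (exclusive), default 0.999.
#' @param window_bp pair-distance window.
#' @return A tibble of qualifying pairs (`chrom`, `marker_a`, `marker_b`,
#'   `distance_bp`, one `r_<breed>` column per panel). Zero rows when no pair
#'   qualifies everywhere.
#' @export
ld_marker_select <- function(panels, r_low = 0.80, r_high = 0.999,
                             window_bp = 1e5) {
  stopifnot(length(panels) >= 1, r_low < r_high)
  map <- panels[[1]]$map
  for (p in panels) {
    if (!identical(p$map$marker_id, map$marker_id)) {
      stop_input("all panels must share a marker map")
    }
  }
  pr <- band_pairs(map, window_bp)
  rmat <- vapply(panels, function(p) pair_signed_r(p$haplotypes, pr$i, pr$j),
                 numeric(nrow(pr)))
  rmat <- matrix(rmat, nrow = nrow(pr))
  ok <- !is.na(rmat) & abs(rmat) > r_low & abs(rmat) < r_high
  keep <- rowSums(ok) == length(panels)
  out <- tibble::tibble(
    chrom = map$chrom[pr$i[keep]],
    marker_a = map$marker_id[pr$i[keep]],
    marker_b = map$marker_id[pr$j[keep]],
    distance_bp = map$pos_bp[pr$j[keep]] - map$pos_bp[pr$i[keep]]
  )
  rsel <- as.data.frame(rmat[keep, , drop = FALSE])
  names(rsel) <- make.unique(
    paste0("r_", vapply(panels, function(p) p$breed_id, character(1))))
  out <- dplyr::bind_cols(out, tibble::as_tibble(rsel))
  if (nrow(out) == 0) {
    message("no marker pair satisfies the LD bounds in all panels")
  }
  out
}
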