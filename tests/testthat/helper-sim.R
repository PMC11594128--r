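# Shared fixture builders. Everything is generated in code; heavier shared
# objects are memoised for the session so several test files can reuse them.

h_map <- function(n_chrom = 2, m = 200, len_bp = 5e6, cm_mb = 5) {
  sim_genome(n_chrom = n_chrom, chrom_length_bp = len_bp,
             markers_per_chrom = m, cm_per_mb = cm_mb)
}

h_pool <- function(map = h_map(), n_hap = 120, ne = 60, burn = 30, seed = 1) {
  generate_ancestral_pool(n_hap, map, ancestral_ne = ne, burn_in = burn,
                          seed = seed)
}

# Panel from an explicit haplotype matrix on a minimal map.
h_panel <- function(hmat, breed_id = "t", cm_mb = 1) {
  m <- ncol(hmat)
  map <- sim_genome(n_chrom = 1, chrom_length_bp = m * 1000,
                    markers_per_chrom = m, cm_per_mb = cm_mb)
  haplotype_panel(hmat, map, breed_id = breed_id)
}

# Genotype matrix from an explicit dosage matrix.
h_geno <- function(d, breed = "pop", map = NULL) {
  if (is.null(map)) {
    map <- sim_genome(n_chrom = 1, chrom_length_bp = ncol(d) * 1000,
                      markers_per_chrom = ncol(d))
  }
  genotype_matrix(d, map, breed_labels = breed)
}

# Brute-force signed-r oracle: direct Pearson correlation of haplotype
# indicator columns.
r_oracle <- function(h, i, j) {
  suppressWarnings(stats::cor(h[, i], h[, j]))
}

.sim_cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (is.null(.sim_cache[[name]])) .sim_cache[[name]] <- force(expr)
  .sim_cache[[name]]
}

# Desk-scale calibrated two-breed study shared by the acceptance tests.
desk_pair <- function() cached("desk_pair", make_study_pair(seed = 101))

desk_addedb <- function() {
  cached("desk_addedb", {
    d <- desk_defaults()
    sp <- desk_pair()
    ec <- experiment_config(
      "added_b", panels = sp$panels,
      pairs = tibble::tibble(a = "A", b = "B"),
      h2 = d$h2, strategy = d$strategy, n_sim = d$n_sim,
      block_len = d$block_len, n_b_grid = c(0, d$n_ref_b),
      n_ref_a = d$n_ref_a, n_val = d$n_val,
      replicates = d$replicates, seed = 2024
    )
    suppressWarnings(run_experiment(ec))
  })
}

# The default ten-breed set (equal drift depth, donor-affinity ladder) with
# eleven pairs spanning the study's consistency range, for the trend
# reproductions.
trend_pairs <- function() {
  cached("trend_pairs", {
    map <- cached("trend_map", sim_genome())
    pool <- generate_ancestral_pool(400, map, ancestral_ne = 200, seed = 77)
    cfg <- breed_set_config(breed_ids = paste0("br", 1:10), map = map,
                            seed = 88)
    panels <- make_breed_panels(cfg, ancestral = pool)
    idx <- list(c(1, 2), c(2, 3), c(3, 4), c(2, 5), c(4, 5), c(5, 6),
                c(3, 7), c(6, 7), c(7, 8), c(8, 9), c(9, 10))
    pairs <- dplyr::bind_rows(lapply(idx, function(ij) {
      tibble::tibble(a = paste0("br", ij[1]), b = paste0("br", ij[2]))
    }))
    list(panels = panels, pairs = pairs)
  })
}

trend_cross_results <- function() {
  cached("trend_cross", {
    tp <- trend_pairs()
    ec <- experiment_config(
      "cross_pairs", panels = tp$panels, pairs = tp$pairs,
      h2 = c(0.1, 0.3, 0.6), strategy = "II", n_sim = 1000,
      block_len = desk_defaults()$block_len, replicates = 10, seed = 131
    )
    suppressWarnings(run_experiment(ec))
  })
}
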