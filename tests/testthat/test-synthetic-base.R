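test_that("ancestral pool has the requested shape and is seed-deterministic", {
  map <- h_map(n_chrom = 1, m = 1000, len_bp = 25e6, cm_mb = 1)
  pool <- generate_ancestral_pool(200, map, ancestral_ne = 100, burn_in = 40,
                                  seed = 7)
  expect_equal(dim(pool$haplotypes), c(200L, 1000L))
  expect_true(all(pool$haplotypes %in% 0:1))
  pool2 <- generate_ancestral_pool(200, map, ancestral_ne = 100, burn_in = 40,
                                   seed = 7)
  expect_identical(pool$haplotypes, pool2$haplotypes)
  expect_error(generate_ancestral_pool(201, map, 100), "even")
  expect_error(generate_ancestral_pool(200, map[0, ], 100), "zero markers")
})

test_that("burn-in drift builds LD that decays with genetic distance", {
  map <- h_map(n_chrom = 1, m = 400, len_bp = 4e7, cm_mb = 1)
  pool <- generate_ancestral_pool(160, map, ancestral_ne = 80, burn_in = 40,
                                  seed = 3)
  h <- pool$haplotypes
  p <- colMeans(h)
  poly <- which(p > 0 & p < 1)
  # brute-force signed-r oracle over adjacent pairs vs pairs >= 1 cM apart
  adj <- vapply(head(poly, -1), function(i) {
    j <- poly[which(poly > i)[1]]
    if (map$pos_cm[j] - map$pos_cm[i] < 0.2) r_oracle(h, i, j)^2 else NA_real_
  }, numeric(1))
  far_idx <- expand.grid(i = poly[1:40], j = poly[poly > 200])
  far_idx <- far_idx[map$pos_cm[far_idx$j] - map$pos_cm[far_idx$i] >= 1, ]
  far_idx <- far_idx[sample.int(nrow(far_idx), 500), ]
  far <- mapply(function(i, j) r_oracle(h, i, j)^2, far_idx$i, far_idx$j)
  expect_gt(mean(adj, na.rm = TRUE), mean(far, na.rm = TRUE))
})

test_that("zero-generation derivation is a permutation of the founders", {
  pool <- h_pool(seed = 5)
  br <- derive_breed(pool, n_founders = 20, generations = 0, out_size = 20,
                     breed_id = "b", seed = 9)
  # every output haplotype pair must be one of the ancestral individuals
  anc_pairs <- apply(pool$haplotypes, 1, paste, collapse = "")
  anc_ind <- paste(anc_pairs[seq(1, 120, 2)], anc_pairs[seq(2, 120, 2)])
  out_pairs <- apply(br$haplotypes, 1, paste, collapse = "")
  out_ind <- paste(out_pairs[seq(1, 40, 2)], out_pairs[seq(2, 40, 2)])
  expect_true(all(out_ind %in% anc_ind))
  expect_equal(anyDuplicated(out_ind), 0)
  expect_error(derive_breed(pool, n_founders = 100, 1, 10), "exceeds")
})

test_that("breeds derived without drift share LD phase exactly", {
  pool <- h_pool(seed = 6)
  founders <- subset_panel(pool, 1:30)
  a <- derive_breed(founders, 30, 0, 30, "a", seed = 1)
  b <- derive_breed(founders, 30, 0, 30, "b", seed = 2)
  pc <- suppressWarnings(phase_consistency(a, b, window_bp = 2e5))
  expect_equal(pc$consistency, 1, tolerance = 1e-10)
})

test_that("phase consistency is non-increasing in divergence generations", {
  map <- h_map(n_chrom = 2, m = 250)
  pool <- generate_ancestral_pool(140, map, ancestral_ne = 70, burn_in = 30,
                                  seed = 11)
  gens <- c(0, 8, 25, 60, 120)
  mean_cons <- vapply(gens, function(g) {
    suppressWarnings(
      crossblup:::split_consistency(pool, g, n_founders = 50, panel_size = 50,
                                    window_bp = 2e5, n_mc = 5, seed = 13)
    )
  }, numeric(1))
  expect_lte(cor(gens, mean_cons, method = "spearman"), 0)
  expect_gt(mean_cons[1], mean_cons[5])
})

test_that("drift without migration conserves allele frequency in expectation", {
  map <- h_map(n_chrom = 1, m = 150)
  pool <- generate_ancestral_pool(120, map, ancestral_ne = 60, burn_in = 20,
                                  seed = 21)
  f0 <- colMeans(pool$haplotypes)
  reps <- vapply(1:30, function(r) {
    b <- derive_breed(pool, n_founders = 60, generations = 4, out_size = 60,
                      seed = 100 + r, migration_rate = 0)
    colMeans(b$haplotypes)
  }, numeric(150))
  expect_lt(mean(abs(rowMeans(reps) - f0)), 0.02)
})

test_that("divergence calibration hits targets and respects limits", {
  map <- h_map(n_chrom = 2, m = 300, len_bp = 7.5e6, cm_mb = 2)
  pool <- generate_ancestral_pool(160, map, ancestral_ne = 80, burn_in = 40,
                                  seed = 31)
  cal <- suppressWarnings(
    calibrate_divergence(pool, 0.5, tolerance = 0.07, seed = 3,
                         n_founders = 50, panel_size = 50, n_mc = 2)
  )
  expect_true(abs(cal$consistency - 0.5) <= 0.07)
  expect_gt(cal$generations, 0)
  # identity limit: a target of ~1 is met at zero generations (shared founders)
  cal1 <- suppressWarnings(
    calibrate_divergence(pool, 0.999, tolerance = 0.05, seed = 3,
                         n_founders = 50, panel_size = 50, n_mc = 2)
  )
  expect_equal(cal1$generations, 0)
  expect_error(
    suppressWarnings(
      calibrate_divergence(pool, 0.999999, tolerance = 1e-9, seed = 3,
                           n_founders = 50, panel_size = 40, n_mc = 2)),
    "unreachable")
})

test_that("make_breed_panels returns the configured roster deterministically", {
  map <- h_map(n_chrom = 1, m = 150)
  cfg <- breed_set_config(breed_ids = c("x", "y", "z"),
                          panel_sizes = c(5, 6, 7),
                          split_generations = c(0, 0, 0),
                          n_founders = 20,
                          ancestral_ne = 40, burn_in = 10, map = map, seed = 2)
  panels <- make_breed_panels(cfg)
  expect_named(panels, c("x", "y", "z"))
  expect_equal(vapply(panels, n_ind, integer(1)), c(x = 5L, y = 6L, z = 7L))
  # zero-generation splits with full founder panels: consistency exactly 1
  cfg_full <- breed_set_config(breed_ids = c("x", "y"), panel_sizes = c(20, 20),
                               split_generations = c(0, 0), n_founders = 20,
                               ancestral_ne = 40, burn_in = 10, map = map,
                               seed = 2)
  pf <- make_breed_panels(cfg_full)
  pc <- suppressWarnings(phase_consistency(pf$x, pf$y, 2e5))
  expect_equal(pc$consistency, 1, tolerance = 1e-10)
  panels2 <- make_breed_panels(cfg)
  expect_identical(panels$y$haplotypes, panels2$y$haplotypes)
  expect_error(breed_set_config(breed_ids = c("x", "x"),
                                panel_sizes = c(2, 2),
                                split_generations = c(0, 0)),
               "duplicate")
})

test_that("default configuration matches the emulated breed roster", {
  cfg <- breed_set_config()
  expect_equal(length(cfg$breed_ids), 10)
  expect_equal(cfg$panel_sizes,
               c(21L, 24L, 25L, 26L, 24L, 22L, 23L, 24L, 26L, 25L))
  expect_true(all(cfg$panel_sizes >= 21 & cfg$panel_sizes <= 26))
})
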