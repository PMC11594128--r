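test_that("signed r reproduces the canonical haplotype-frequency cases", {
  # perfect coupling: only 11 and 00 haplotypes
  h <- rbind(matrix(1L, 10, 2), matrix(0L, 10, 2))
  p <- h_panel(h)
  tab <- suppressWarnings(pairwise_signed_ld(p, 5000))
  expect_equal(tab$r, 1)
  # perfect repulsion: only 10 and 01
  h2 <- rbind(matrix(c(1L, 0L), 10, 2, byrow = TRUE),
              matrix(c(0L, 1L), 10, 2, byrow = TRUE))
  expect_equal(suppressWarnings(pairwise_signed_ld(h_panel(h2), 5000))$r, -1)
  # counts 11:40, 10:10, 01:10, 00:40 -> f11 = .4, pA = pB = .5, r = 0.6
  h3 <- rbind(matrix(1L, 40, 2),
              matrix(c(1L, 0L), 10, 2, byrow = TRUE),
              matrix(c(0L, 1L), 10, 2, byrow = TRUE),
              matrix(0L, 40, 2))
  expect_equal(suppressWarnings(pairwise_signed_ld(h_panel(h3), 5000))$r, 0.6,
               tolerance = 1e-12)
})

test_that("signed r equals the brute-force indicator correlation to 1e-12", {
  set.seed(23)
  h <- matrix(rbinom(80 * 50, 1, runif(50, 0.1, 0.9)), 80, 50, byrow = TRUE)
  panel <- h_panel(h)
  tab <- suppressWarnings(pairwise_signed_ld(panel, 60000))
  idx_a <- match(tab$marker_a, panel$map$marker_id)
  idx_b <- match(tab$marker_b, panel$map$marker_id)
  oracle <- mapply(function(i, j) r_oracle(h, i, j), idx_a, idx_b)
  expect_equal(tab$r, oracle, tolerance = 1e-12)
  expect_equal(tab$r2, tab$r^2, tolerance = 1e-15)
  expect_true(all(tab$distance_bp > 0))
})

test_that("r is order-invariant and flips sign under single-locus relabeling", {
  set.seed(24)
  h <- matrix(rbinom(60 * 10, 1, 0.5), 60, 10)
  p1 <- h_panel(h)
  p2 <- h_panel(h[sample.int(60), ])
  t1 <- suppressWarnings(pairwise_signed_ld(p1, 20000))
  t2 <- suppressWarnings(pairwise_signed_ld(p2, 20000))
  expect_equal(t1$r, t2$r, tolerance = 1e-12)
  hf <- h; hf[, 1] <- 1L - hf[, 1]
  tf <- suppressWarnings(pairwise_signed_ld(h_panel(hf), 20000))
  first <- t1$marker_a == p1$map$marker_id[1]
  expect_equal(tf$r[first], -t1$r[first], tolerance = 1e-12)
  hff <- hf; hff[, 2] <- 1L - hff[, 2]
  tff <- suppressWarnings(pairwise_signed_ld(h_panel(hff), 20000))
  pair12 <- first & tff$marker_b == p1$map$marker_id[2]
  expect_equal(tff$r[pair12], t1$r[pair12], tolerance = 1e-12)
})

test_that("decay profile uses the 22-bin half-open scheme", {
  edges <- crossblup:::ld_bin_edges_bp()
  expect_equal(length(edges), 23) # 22 bins
  expect_equal(edges[1:5], c(0, 2500, 5000, 7500, 10000))
  expect_equal(edges[6], 20000)
  expect_equal(edges[23], 1e6)
  pairs <- tibble::tibble(distance_bp = c(2500, 2501, 1e6, 1000001),
                          r = c(0.5, 0.4, 0.1, 0.9), r2 = c(0.25, 0.16, 0.01, 0.81))
  prof <- ld_decay_profile(pairs)
  expect_equal(nrow(prof), 22)
  expect_equal(prof$n_pairs[1], 1L)  # 2500 falls in (0, 2500]
  expect_equal(prof$n_pairs[2], 1L)  # 2501 falls in (2500, 5000]
  expect_equal(prof$n_pairs[22], 1L) # 1 Mb included, 1 Mb + 1 bp excluded
  expect_equal(sum(prof$n_pairs), 3)
})

test_that("mean r2 decays near-monotonically with distance in a drifted pool", {
  map <- h_map(n_chrom = 1, m = 500, len_bp = 1e6, cm_mb = 20)
  pool <- generate_ancestral_pool(160, map, ancestral_ne = 80, burn_in = 40,
                                  seed = 25)
  prof <- ld_decay_profile(pairwise_signed_ld(pool, 1e6))
  obs <- prof$mean_r2[prof$n_pairs > 50]
  iso <- -stats::isoreg(seq_along(obs), -obs)$yf # best non-increasing fit
  expect_lt(mean(abs(obs - iso)), 0.05)
})

test_that("phase consistency is reflexive, symmetric and orientation-invariant", {
  pool <- h_pool(seed = 26)
  a <- derive_breed(pool, 40, 10, 40, "a", seed = 1)
  b <- derive_breed(pool, 40, 10, 40, "b", seed = 2)
  self <- suppressWarnings(phase_consistency(a, a))
  expect_equal(self$consistency, 1, tolerance = 1e-12)
  ab <- suppressWarnings(phase_consistency(a, b))
  ba <- suppressWarnings(phase_consistency(b, a))
  expect_equal(ab$consistency, ba$consistency, tolerance = 1e-12)
  # flipping both alleles at every marker flips every r sign twice
  bf <- b
  bf$haplotypes <- 1L - bf$haplotypes
  abf <- suppressWarnings(phase_consistency(a, bf))
  expect_equal(abf$consistency, ab$consistency, tolerance = 1e-12)
  expect_error(suppressWarnings(phase_consistency(a, b, window_bp = 1)),
               "polymorphic")
})

test_that("cor100 is stable across disjoint half-genomes", {
  sp <- desk_pair()
  a <- derive_breed(sp$pool, 70, sp$generations, 70, "a", seed = 41)
  b <- derive_breed(sp$pool, 70, sp$generations, 70, "b", seed = 42)
  split_panel <- function(p, chroms) {
    keep <- p$map$chrom %in% chroms
    haplotype_panel(p$haplotypes[, keep, drop = FALSE], p$map[keep, ],
                    breed_id = p$breed_id, sample_ids = p$sample_ids)
  }
  c1 <- phase_consistency(split_panel(a, 1:5), split_panel(b, 1:5))
  c2 <- phase_consistency(split_panel(a, 6:10), split_panel(b, 6:10))
  expect_lt(abs(c1$consistency - c2$consistency), 0.1)
})

test_that("SNP-set selection keeps pairs qualifying in every panel", {
  # one pair with |r| = 0.85 in panel 1 and 0.70 in panel 2
  mk <- function(r_target, n = 200) {
    n11 <- round(n * (0.25 + r_target / 4))
    n00 <- n11
    n10 <- n / 2 - n11
    rbind(matrix(1L, n11, 2),
          matrix(c(1L, 0L), n10, 2, byrow = TRUE),
          matrix(c(0L, 1L), n10, 2, byrow = TRUE),
          matrix(0L, n00, 2))
  }
  p85 <- h_panel(mk(0.85), breed_id = "p85")
  p70 <- h_panel(mk(0.70), breed_id = "p70")
  one <- suppressWarnings(ld_marker_select(list(p85), r_low = 0.80))
  expect_equal(nrow(one), 1)
  both <- suppressWarnings(ld_marker_select(list(p85, p70), r_low = 0.80))
  expect_equal(nrow(both), 0)
  # |r| = 1 is excluded by the 0.999 upper bound
  perfect <- h_panel(rbind(matrix(1L, 10, 2), matrix(0L, 10, 2)))
  expect_equal(nrow(suppressWarnings(ld_marker_select(list(perfect), 0.8))), 0)
  loose <- suppressWarnings(ld_marker_select(list(perfect), 0.8, r_high = 1.01))
  expect_equal(nrow(loose), 1)
})
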