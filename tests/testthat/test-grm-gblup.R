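test_that("GRM matches the single-marker hand computation", {
  map1 <- tibble::tibble(chrom = 1L, marker_id = "m1", pos_bp = 100L,
                         pos_cm = 1e-4, ref_allele = "A", alt_allele = "G")
  g <- compute_grm(genotype_matrix(matrix(c(0L, 1L, 2L), 3, 1), map1))
  # p = 0.5, W = (-1, 0, 1), denominator 2 * 0.25 = 0.5 -> diag (2, 0, 2)
  expect_equal(unname(diag(g$mat)), c(2, 0, 2))
  expect_equal(unname(g$mat[1, 3]), -2)
  expect_equal(g$denom, 0.5)
})

test_that("GRM is symmetric, centered, and duplicates are identical rows", {
  set.seed(31)
  d <- matrix(rbinom(30 * 200, 2, runif(200, 0.1, 0.9)), 30, 200, byrow = TRUE)
  d[30, ] <- d[1, ] # duplicated individual
  g <- compute_grm(h_geno(d))
  expect_lt(max(abs(g$mat - t(g$mat))), 1e-10)
  expect_equal(g$mat[30, ], g$mat[1, ], ignore_attr = TRUE)
  expect_equal(unname(g$mat[1, 30]), unname(g$mat[1, 1]))
  # pooled-frequency centering: GRM row sums vanish up to numerical tolerance
  expect_lt(max(abs(rowSums(g$mat))), 1e-8)
  expect_equal(mean(diag(g$mat)), 1, tolerance = 0.2)
})

test_that("within-breed relationships exceed between-breed under pooled frequencies", {
  pool1 <- h_pool(seed = 32)
  pool2 <- h_pool(seed = 33)
  a <- resample_population(derive_breed(pool1, 30, 5, 30, "a", seed = 1),
                           60, 50, seed = 2)
  b <- resample_population(derive_breed(pool2, 30, 5, 30, "b", seed = 3),
                           60, 50, seed = 4)
  g <- compute_grm(bind_genotypes(a, b))$mat
  within <- c(g[1:60, 1:60][lower.tri(diag(60))],
              g[61:120, 61:120][lower.tri(diag(60))])
  between <- g[1:60, 61:120]
  expect_gt(mean(within), mean(between))
})

test_that("GBLUP equals SNP-BLUP ridge regression on the same markers", {
  set.seed(34)
  n <- 50; m <- 200
  d <- matrix(rbinom(n * m, 2, runif(m, 0.1, 0.9)), n, m, byrow = TRUE)
  geno <- h_geno(d)
  grm <- compute_grm(geno)
  p <- colMeans(d) / 2
  keep <- p > 0 & p < 1
  w <- sweep(d, 2, 2 * p)[, keep]
  cc <- 2 * sum(p[keep] * (1 - p[keep]))
  sigma_g2 <- 1.3; sigma_e2 <- 2.1; lambda <- sigma_e2 / sigma_g2
  ridge <- 1e-6
  tbv <- drop(w %*% rnorm(sum(keep), 0, 0.1))
  y <- tbv + rnorm(n)
  pheno <- tibble::tibble(sample_id = geno$sample_ids, y = y)
  train <- geno$sample_ids[1:40]
  fit <- solve_gblup(pheno, grm, train_ids = train, sigma_g2 = sigma_g2,
                     sigma_e2 = sigma_e2, ridge = ridge)
  # independent oracle: ridge regression of y on [W, sqrt(ridge c) I]
  # (the augmented block reproduces the ridge-stabilised GRM exactly)
  wa <- cbind(w, sqrt(ridge * cc) * diag(n))
  wt <- wa[1:40, ]
  k <- ncol(wa)
  cmat <- rbind(cbind(40, t(rep(1, 40)) %*% wt),
                cbind(t(wt) %*% rep(1, 40),
                      crossprod(wt) + lambda * cc * diag(k)))
  rhs <- c(sum(y[1:40]), crossprod(wt, y[1:40]))
  sol <- solve(cmat, rhs)
  gebv_oracle <- drop(wa %*% sol[-1])
  expect_equal(gebv(fit, geno$sample_ids), gebv_oracle,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("GEBVs shrink to zero in the lambda -> infinity limit", {
  set.seed(35)
  d <- matrix(rbinom(20 * 50, 2, 0.5), 20, 50)
  geno <- h_geno(d)
  grm <- compute_grm(geno)
  pheno <- tibble::tibble(sample_id = geno$sample_ids, y = rnorm(20))
  fit <- solve_gblup(pheno, grm, train_ids = geno$sample_ids[1:15],
                     sigma_g2 = 1e-9, sigma_e2 = 1)
  expect_lt(max(abs(fit$gebv$gebv)), 1e-5)
})

test_that("singular fixed-effect designs are rejected", {
  set.seed(36)
  d <- matrix(rbinom(20 * 50, 2, 0.5), 20, 50)
  geno <- h_geno(d)
  grm <- compute_grm(geno)
  pheno <- tibble::tibble(sample_id = geno$sample_ids, y = rnorm(20),
                          breed = "one") # single level + intercept: singular
  expect_error(solve_gblup(pheno, grm, train_ids = geno$sample_ids[1:15],
                           formula = y ~ breed, sigma_g2 = 1, sigma_e2 = 1),
               "singular")
})

test_that("tidiers expose fixed effects, GEBVs and the model summary", {
  set.seed(37)
  d <- matrix(rbinom(24 * 60, 2, 0.5), 24, 60)
  geno <- h_geno(d, breed = rep(c("a", "b"), each = 12))
  grm <- compute_grm(geno)
  pheno <- tibble::tibble(sample_id = geno$sample_ids, y = rnorm(24),
                          breed = geno$breed_labels)
  fit <- solve_gblup(pheno, grm, train_ids = geno$sample_ids[1:20],
                     formula = y ~ breed, sigma_g2 = 1, sigma_e2 = 1)
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "breedb"))
  expect_equal(nrow(tidy(fit, effects = "ran_vals")), 24)
  gl <- glance(fit)
  expect_equal(gl$n_train, 20)
  expect_lt(gl$resid_rel, 1e-8)
  # adjusted phenotype removes the fitted breed means
  ya <- adjusted_phenotype(fit, pheno, geno$sample_ids[21:24])
  expect_equal(unname(ya),
               unname(pheno$y[21:24] -
                        crossblup:::fitted_fixef(fit, pheno[21:24, ])))
})

test_that("REML recovers the simulated heritability and its edge cases", {
  set.seed(38)
  n <- 1000; m <- 300
  d <- matrix(rbinom(n * m, 2, runif(m, 0.1, 0.9)), n, m, byrow = TRUE)
  geno <- h_geno(d)
  grm <- compute_grm(geno)
  p <- colMeans(d) / 2
  w <- sweep(d, 2, 2 * p)
  u <- drop(w %*% rnorm(m, 0, 1)) # genetic values with covariance prop. to G
  u <- u / sd(u) * sqrt(0.3)
  y <- 5 + u + rnorm(n, 0, sqrt(0.7))
  pheno <- tibble::tibble(sample_id = geno$sample_ids, y = y)
  vc <- estimate_varcomp(pheno, grm)
  expect_lt(abs(vc$h2 - 0.30), 0.05)
  expect_false(vc$boundary)
  # shift invariance: the fixed mean absorbs a constant
  vc2 <- estimate_varcomp(dplyr::mutate(pheno, y = y + 100), grm)
  expect_equal(vc$sigma_g2, vc2$sigma_g2, tolerance = 1e-6)
  # pure noise: the genetic fraction collapses towards the lower bound
  vc0 <- estimate_varcomp(dplyr::mutate(pheno, y = rnorm(n)), grm)
  expect_lt(vc0$sigma_g2 / (vc0$sigma_g2 + vc0$sigma_e2), 0.15)
})

test_that("PCA + k-means recovers well-separated lineages deterministically", {
  map <- h_map(n_chrom = 1, m = 200)
  pops <- lapply(1:3, function(k) {
    pool <- generate_ancestral_pool(40, map, ancestral_ne = 20, burn_in = 10,
                                    seed = 40 + k)
    resample_population(pool, 20, 50, seed = 50 + k)
  })
  combined <- bind_genotypes(lapply(seq_along(pops), function(k) {
    p <- pops[[k]]
    genotype_matrix(p$dosages, p$map,
                    sample_ids = paste0("p", k, "_", seq_len(20)),
                    breed_labels = paste0("lineage", k))
  }))
  cl <- cluster_breeds(combined, n_pc = 5, k = 3, seed = 1)
  expect_equal(sort(unname(cl$cluster)), 1:3) # three singleton clusters
  cl2 <- cluster_breeds(combined, n_pc = 5, k = 3, seed = 1)
  expect_identical(cl$cluster, cl2$cluster)
  expect_equal(unique(cluster_breeds(combined, k = 1, seed = 1)$cluster), 1L)
  expect_error(cluster_breeds(combined, k = 5), "exceeds")
})

test_that("accuracy grows with reference size and heritability", {
  pool <- cached("mono_pool", h_pool(h_map(n_chrom = 2, m = 400), seed = 60))
  pop <- cached("mono_pop", {
    suppressWarnings(resample_population(pool, 1400, block_len = 40, seed = 61))
  })
  q <- sample_qtls(pop$map, trait_architecture("custom", n_small = 200,
                                               n_medium = 50, n_large = 10),
                   seed = 62)
  tbv <- compute_tbv(pop, q)
  acc <- function(n_train, h2, r) {
    ph <- simulate_phenotypes(tbv, h2, seed = 70 + r)
    ids <- pop$sample_ids
    with_seed <- crossblup:::with_seed
    sel <- with_seed(80 + r, sample(ids, n_train + 200))
    train <- sel[seq_len(n_train)]
    val <- sel[n_train + 1:200]
    grm <- compute_grm(subset_individuals(pop, c(train, val)))
    pheno <- tibble::tibble(sample_id = ph$sample_id, y = ph$y)
    fit <- solve_gblup(pheno, grm, train_ids = train, predict_ids = val,
                       sigma_g2 = var(tbv), sigma_e2 = attr(ph, "ve"))
    accuracy(tbv[val], gebv(fit, val))
  }
  reps <- 1:5
  by_n <- vapply(c(100, 400, 1200),
                 function(n) mean(vapply(reps, function(r) acc(n, 0.3, r),
                                         numeric(1))), numeric(1))
  expect_true(all(diff(by_n) > 0))
  by_h2 <- vapply(c(0.1, 0.6),
                  function(h2) mean(vapply(reps, function(r) acc(400, h2, r),
                                           numeric(1))), numeric(1))
  expect_gt(by_h2[2], by_h2[1])
})
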