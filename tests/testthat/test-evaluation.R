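test_that("accuracy is the Pearson correlation with its guard rails", {
  x <- c(1, 2, 3, 4)
  expect_equal(accuracy(x, x), 1)
  expect_equal(accuracy(x, -x), -1)
  expect_equal(accuracy(x, c(1, 2, 3, 5)), 0.9827, tolerance = 1e-3)
  expect_error(accuracy(x, x[1:3]), "equal length")
  expect_error(accuracy(rep(1, 4), x), "constant")
})

test_that("bias slope flags deflation and inflation around 1", {
  y <- rnorm(50)
  expect_equal(bias_slope(y, y), 1)
  expect_equal(bias_slope(y, 0.5 * y), 2)   # deflated GEBVs, slope > 1
  expect_equal(bias_slope(y, 2 * y), 0.5)   # inflated GEBVs, slope < 1
  expect_equal(bias_slope(y, 0.5 * y, literal = TRUE),
               cor(y, 0.5 * y) / var(0.5 * y))
  expect_error(bias_slope(y, rep(0, 50)), "zero-variance")
})

samples_10x1500 <- local({
  tibble::tibble(
    sample_id = sprintf("%s_%04d", rep(paste0("b", 1:10), each = 1500),
                        rep(1:1500, 10)),
    breed = rep(paste0("b", 1:10), each = 1500)
  )
})

test_that("scenario builders hit the published reference compositions", {
  w <- build_scenario(scenario_within("b3"), samples_10x1500, seed = 1)
  expect_equal(nrow(w), 1200)
  expect_true(all(w$breed == "b3"))

  p <- build_scenario(scenario_pooled(paste0("b", 1:10)), samples_10x1500,
                      seed = 2)
  expect_equal(nrow(p), 1200)
  expect_equal(unname(table(p$breed)), rep(120L, 10), ignore_attr = TRUE)

  g <- build_scenario(scenario_group(c("b1", "b4", "b7")), samples_10x1500,
                      seed = 3)
  expect_equal(nrow(g), 1200)
  expect_equal(as.vector(table(g$breed)), rep(400L, 3))

  x <- build_scenario(scenario_cross("b1", "b2"), samples_10x1500, seed = 4)
  ref <- x[x$role == "reference", ]
  val <- x[x$role == "validation", ]
  expect_equal(as.vector(table(ref$breed)[c("b1", "b2")]), c(400L, 200L))
  expect_equal(as.vector(table(val$breed)[c("b1", "b2")]), c(200L, 200L))
  expect_equal(length(intersect(ref$sample_id, val$sample_id)), 0)
  expect_equal(anyDuplicated(x$sample_id), 0)
})

test_that("infeasible scenario counts fail loudly and seeds reproduce draws", {
  small <- samples_10x1500[1:300, ]
  expect_error(build_scenario(scenario_within("b1"), small, seed = 1),
               "only 300 available")
  s1 <- build_scenario(scenario_cross("b1", "b2"), samples_10x1500, seed = 9)
  s2 <- build_scenario(scenario_cross("b1", "b2"), samples_10x1500, seed = 9)
  expect_identical(s1, s2)
})

test_that("replicated 5-fold CV produces 25 fold evaluations of 240 each", {
  set.seed(41)
  n <- 1200
  d <- matrix(rbinom(n * 40, 2, 0.5), n, 40)
  geno <- h_geno(d)
  grm <- compute_grm(geno)
  pheno <- tibble::tibble(sample_id = geno$sample_ids,
                          y = rnorm(n) + 0.05 * rowSums(d))
  cv <- cross_validate(pheno, grm, ref_ids = geno$sample_ids,
                       sigma_g2 = 0.5, sigma_e2 = 1, seed = 42)
  expect_equal(nrow(cv), 25)
  expect_true(all(cv$n_val == 240))
  expect_true(all(cv$n_ref == 960))
  cv2 <- cross_validate(pheno, grm, ref_ids = geno$sample_ids,
                        sigma_g2 = 0.5, sigma_e2 = 1, seed = 42)
  expect_identical(cv$accuracy, cv2$accuracy)
  expect_error(cross_validate(pheno, grm, ref_ids = geno$sample_ids[1:10],
                              sigma_g2 = 1, sigma_e2 = 1),
               "fewer than 3")
  gl <- glance(cv)
  expect_equal(gl$n_evals, 25)
})

test_that("top_related_subset picks the most connected individuals", {
  set.seed(43)
  d <- matrix(rbinom(40 * 100, 2, 0.5), 40, 100)
  d[1:5, ] <- d[rep(1, 5), ] # a clique of near-duplicates
  grm <- compute_grm(h_geno(d))
  top <- top_related_subset(grm, n = 5)
  expect_true(all(grm$sample_ids[1:5] %in% top))
})

test_that("accuracy agrees with the deterministic Me approximation", {
  # sqrt(n h2 / (n h2 + Me)) with Me measured from the realized GRM
  res <- desk_addedb()
  sp <- desk_pair()
  d <- desk_defaults()
  popA <- suppressWarnings(resample_population(sp$panels$A, 400,
                                               block_len = d$block_len,
                                               seed = 55))
  me <- effective_segments(compute_grm(popA))
  for (h2v in c(0.3, 0.6)) {
    pred <- sqrt(400 * h2v / (400 * h2v + me))
    obs <- mean(res$accuracy[res$h2 == h2v & res$n_ref_b == 0 &
                               res$val_breed == "A"])
    expect_lt(abs(obs - pred), 0.07)
  }
})
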