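#' Solve the GBLUP mixed-model equations
#'
#' Fits `y = X b + g + e` for the reference individuals, with
#' `g ~ N(0, GRM * sigma_g2)` over *all* individuals in the GRM and
#' `e ~ N(0, I sigma_e2)`, by solving the mixed-model equations
#' \deqn{\begin{bmatrix} X'X & X'Z \\ Z'X & Z'Z + G^{-1}\lambda \end{bmatrix}
#'   \begin{bmatrix} b \\ g \end{bmatrix} =
#'   \begin{bmatrix} X'y \\ Z'y \end{bmatrix}}
#' with \eqn{\lambda = \sigma_e^2 / \sigma_g^2} and `Z` the incidence of
#' phenotype records on individuals. The GRM is ridge-stabilised
#' (`G + ridge * I`) before inversion. GEBVs of unphenotyped individuals are
#' read directly from `g`.
#'
#' Fixed effects follow `formula` (default intercept only; use
#' `y ~ breed` for multi-breed references).
#'
#' @param pheno data frame with a `sample_id` column plus the variables named
#'   in `formula` (at least the response).
#' @param grm a `grm_matrix` covering reference and prediction individuals.
#' @param train_ids sample ids used as phenotyped reference.
#' @param predict_ids ids whose GEBVs are wanted; default all non-reference
#'   individuals in the GRM.
#' @param formula fixed-effect formula, response on the left (default `y ~ 1`).
#' @param sigma_g2,sigma_e2 genetic and residual variances (> 0). Use the
#'   simulation truth or [estimate_varcomp()].
#' @param ridge stabilising ridge added to the GRM diagonal.
#' @return A `gblup_fit` with fixed effects `b`, the full `gebv` tibble,
#'   variances, `lambda`, and a relative residual-norm diagnostic.
#' @seealso [estimate_varcomp()], [tidy.gblup_fit()]
#' @export
solve_gblup <- function(pheno, grm, train_ids, predict_ids = NULL,
                        formula = y ~ 1, sigma_g2, sigma_e2, ridge = 1e-6) {
  stopifnot(inherits(grm, "grm_matrix"))
  if (sigma_g2 <= 0 || sigma_e2 <= 0) stop_input("variance components must be positive")
  ids <- grm$sample_ids
  n_all <- length(ids)
  gi <- match(train_ids, ids)
  if (anyNA(gi)) stop_input("some train_ids are not in the GRM")
  pi_ <- match(train_ids, pheno$sample_id)
  if (anyNA(pi_)) stop_input("some train_ids lack phenotype rows")
  predict_ids <- predict_ids %||% setdiff(ids, train_ids)
  if (anyNA(match(predict_ids, ids))) stop_input("some predict_ids are not in the GRM")

  mf <- stats::model.frame(formula, data = pheno[pi_, , drop = FALSE])
  y <- stats::model.response(mf)
  x <- tryCatch(stats::model.matrix(attr(mf, "terms"), mf),
                error = function(e) stop_input("singular fixed-effect design"))
  if (qr(x)$rank < ncol(x)) stop_input("singular fixed-effect design")
  p <- ncol(x)

  lambda <- sigma_e2 / sigma_g2
  # The GRM inverse is the expensive piece; cache it on the grm object so
  # repeated solves (cross-validation folds) reuse it.
  key <- paste0("ginv_", format(ridge, digits = 12))
  ginv <- if (!is.null(grm$cache) && !is.null(grm$cache[[key]])) {
    grm$cache[[key]]
  } else {
    gmat <- grm$mat + diag(ridge, n_all)
    ch <- tryCatch(chol(gmat),
                   error = function(e) abort("GRM is not positive definite after ridge",
                                             class = "crossblup_numeric_error"))
    gi_ <- chol2inv(ch)
    if (!is.null(grm$cache)) grm$cache[[key]] <- gi_
    gi_
  }

  # MME blocks without forming Z: one record per train individual.
  xtx <- crossprod(x)
  xtz <- matrix(0, p, n_all)
  xtz[, gi] <- t(x)
  ztz <- numeric(n_all)
  ztz[gi] <- 1
  cmat <- rbind(cbind(xtx, xtz),
                cbind(t(xtz), diag(ztz) + ginv * lambda))
  zty <- numeric(n_all)
  zty[gi] <- y
  rhs <- c(crossprod(x, y), zty)
  sol <- drop(solve(cmat, rhs))
  resid_rel <- sqrt(sum((cmat %*% sol - rhs)^2)) / max(sqrt(sum(rhs^2)), 1e-300)

  b <- sol[seq_len(p)]
  names(b) <- colnames(x)
  g <- sol[-seq_len(p)]
  names(g) <- ids
  structure(
    list(b = b, gebv = tibble::tibble(sample_id = ids, gebv = unname(g)),
         sigma_g2 = sigma_g2, sigma_e2 = sigma_e2, lambda = lambda,
         ridge = ridge, formula = formula, terms = attr(mf, "terms"),
         xlevels = stats::.getXlevels(attr(mf, "terms"), mf),
         train_ids = train_ids, predict_ids = predict_ids,
         resid_rel = resid_rel),
    class = "gblup_fit"
  )
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat(sprintf(
    "<gblup_fit> %d reference records, %d GEBVs (lambda = %.4g, residual %.1e)\n",
    length(x$train_ids), nrow(x$gebv), x$lambda, x$resid_rel))
  invisible(x)
}

#' Extract GEBVs for chosen individuals
#' @param fit a `gblup_fit`.
#' @param ids sample ids (default the fit's `predict_ids`).
#' @return named numeric vector of GEBVs.
#' @export
gebv <- function(fit, ids = NULL) {
  ids <- ids %||% fit$predict_ids
  out <- fit$gebv$gebv[match(ids, fit$gebv$sample_id)]
  if (anyNA(out)) stop_input("some requested ids are not in the fit")
  names(out) <- ids
  out
}

# Fixed-effect fitted values for new data, on the training design.
fitted_fixef <- function(fit, newdata) {
  tt <- stats::delete.response(fit$terms)
  mf <- stats::model.frame(tt, newdata, xlev = fit$xlevels)
  x <- stats::model.matrix(tt, mf)
  drop(x %*% fit$b)
}

#' Adjusted phenotypes (phenotype minus fitted fixed effects)
#'
#' The CV accuracy statistic correlates GEBVs with phenotypes adjusted for
#' the training model's fixed effects; in simulation the only fixed effects
#' are the mean and, for multi-breed references, breed.
#'
#' @param fit a `gblup_fit`.
#' @param pheno data frame with `sample_id` and the model variables.
#' @param ids which individuals to adjust (default the fit's predict set).
#' @return named numeric vector `y - X b`.
#' @export
adjusted_phenotype <- function(fit, pheno, ids = NULL) {
  ids <- ids %||% fit$predict_ids
  rows <- match(ids, pheno$sample_id)
  if (anyNA(rows)) stop_input("some ids lack phenotype rows")
  nd <- pheno[rows, , drop = FALSE]
  yv <- stats::model.response(stats::model.frame(fit$formula, nd))
  out <- yv - fitted_fixef(fit, nd)
  names(out) <- ids
  out
}

#' @rdname tidy.gblup_fit
#' @method glance gblup_fit
#' @export
glance.gblup_fit <- function(x, ...) {
  tibble::tibble(
    n_train = length(x$train_ids), n_gebv = nrow(x$gebv),
    sigma_g2 = x$sigma_g2, sigma_e2 = x$sigma_e2, lambda = x$lambda,
    ridge = x$ridge, resid_rel = x$resid_rel
  )
}

#' Tidy a GBLUP fit
#'
#' `tidy()` returns fixed-effect estimates (`effects = "fixed"`) or the GEBV
#' table (`effects = "ran_vals"`); `glance()` returns a one-row model summary.
#'
#' @param x a `gblup_fit`.
#' @param effects `"fixed"` or `"ran_vals"`.
#' @param ... unused.
#' @return a tibble.
#' @method tidy gblup_fit
#' @export
tidy.gblup_fit <- function(x, effects = c("fixed", "ran_vals"), ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") {
    tibble::tibble(term = names(x$b), estimate = unname(x$b))
  } else {
    x$gebv
  }
}

#' REML variance components for the single-GRM animal model
#'
#' Profiles the restricted likelihood of `y = X b + g + e`,
#' `g ~ N(0, G sigma_g2)`, over the variance ratio
#' `gamma = sigma_e2 / sigma_g2` using the eigendecomposition of the
#' (ridge-stabilised) GRM, and maximises it with Brent search on
#' `log(gamma)`. Equivalent to average-information REML for this single
#' random effect, but with a guaranteed global profile.
#'
#' @param pheno data frame with `sample_id` and model variables.
#' @param grm a `grm_matrix`; only phenotyped individuals are used.
#' @param formula fixed-effect formula (default `y ~ 1`).
#' @param ids individuals to use (default: all GRM ids with phenotypes).
#' @param ridge stabilising ridge.
#' @param interval search interval for `log(gamma)`.
#' @return A list: `sigma_g2`, `sigma_e2`, `h2`, `loglik`, `boundary`
#'   (TRUE when the optimum sits at the search edge, e.g. for a trait with
#'   no genetic variance).
#' @export
estimate_varcomp <- function(pheno, grm, formula = y ~ 1, ids = NULL,
                             ridge = 1e-6, interval = c(-12, 12)) {
  stopifnot(inherits(grm, "grm_matrix"))
  ids <- ids %||% intersect(grm$sample_ids, pheno$sample_id)
  if (length(ids) < 30) stop_input("REML needs at least 30 phenotyped individuals")
  gi <- match(ids, grm$sample_ids)
  rows <- match(ids, pheno$sample_id)
  mf <- stats::model.frame(formula, pheno[rows, , drop = FALSE])
  y <- stats::model.response(mf)
  x <- stats::model.matrix(attr(mf, "terms"), mf)
  n <- length(y)
  p <- ncol(x)

  g <- grm$mat[gi, gi] + diag(ridge, n)
  ed <- eigen(g, symmetric = TRUE)
  ys <- drop(crossprod(ed$vectors, y))
  xs <- crossprod(ed$vectors, x)
  ldet_xtx <- determinant(crossprod(x), logarithm = TRUE)$modulus

  reml_ll <- function(lg) {
    w <- ed$values + exp(lg)
    xtwx <- crossprod(xs, xs / w)
    bhat <- solve(xtwx, crossprod(xs, ys / w))
    r <- ys - drop(xs %*% bhat)
    rss <- sum(r^2 / w)
    s2 <- rss / (n - p)
    -0.5 * ((n - p) * log(2 * pi * s2) + sum(log(w)) +
              determinant(xtwx, logarithm = TRUE)$modulus - ldet_xtx + (n - p))
  }
  opt <- stats::optimize(reml_ll, interval = interval, maximum = TRUE,
                         tol = 1e-6)
  lg <- opt$maximum
  gamma <- exp(lg)
  w <- ed$values + gamma
  xtwx <- crossprod(xs, xs / w)
  bhat <- solve(xtwx, crossprod(xs, ys / w))
  rss <- sum((ys - drop(xs %*% bhat))^2 / w)
  sigma_g2 <- rss / (n - p)
  list(
    sigma_g2 = sigma_g2, sigma_e2 = gamma * sigma_g2,
    h2 = sigma_g2 / (sigma_g2 + gamma * sigma_g2),
    loglik = opt$objective,
    boundary = (lg - interval[1] < 0.05) || (interval[2] - lg < 0.05)
  )
}

#' Group breeds by principal components and k-means
#'
#' PCA on the centered pooled dosage matrix, per-breed centroids in the top
#' `n_pc` components, then k-means (multiple restarts) on the centroids.
#'
#' @param geno a [genotype_matrix()] holding individuals of several breeds.
#' @param n_pc principal components retained.
#' @param k number of groups.
#' @param seed integer seed (k-means restarts).
#' @param nstart k-means restarts.
#' @return A `breed_clusters` tibble (`breed`, `cluster`) with the centroid
#'   matrix, `k` and `seed` as attributes.
#' @export
cluster_breeds <- function(geno, n_pc = 10, k = 3, seed = NULL, nstart = 10) {
  stopifnot(inherits(geno, "genotype_matrix"))
  breeds <- unique(geno$breed_labels)
  if (k > length(breeds)) stop_input("k exceeds the number of breeds")
  n_pc <- min(n_pc, nrow(geno$dosages) - 1L)
  pc <- stats::prcomp(geno$dosages, center = TRUE, scale. = FALSE, rank. = n_pc)
  scores <- pc$x
  cent <- rowsum(scores, group = geno$breed_labels)
  cent <- cent / as.vector(table(geno$breed_labels)[rownames(cent)])
  cluster <- if (k == nrow(cent)) {
    # one breed per cluster: the exact (degenerate) k-means solution
    seq_len(k)
  } else {
    with_seed(seed, stats::kmeans(cent, centers = k, nstart = nstart))$cluster
  }
  out <- tibble::tibble(breed = rownames(cent),
                        cluster = as.integer(cluster))
  attr(out, "centroids") <- cent
  attr(out, "k") <- k
  attr(out, "seed") <- seed
  class(out) <- c("breed_clusters", class(out))
  out
}
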