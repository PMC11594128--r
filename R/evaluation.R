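#' Prediction accuracy
#'
#' Pearson correlation between a truth vector and GEBVs. Cross-validation
#' scenarios correlate GEBVs with adjusted phenotypes; pure-simulation
#' scenarios correlate with true breeding values.
#'
#' @param truth numeric vector (adjusted phenotypes or TBVs).
#' @param gebv numeric vector of the same length.
#' @return Pearson correlation.
#' @export
accuracy <- function(truth, gebv) {
  if (length(truth) != length(gebv)) stop_input("vectors must have equal length")
  if (length(truth) < 3) stop_input("need at least 3 observations")
  if (stats::sd(truth) == 0 || stats::sd(gebv) == 0) {
    stop_input("constant vector: accuracy undefined")
  }
  stats::cor(truth, gebv)
}

#' Prediction bias (dispersion) slope
#'
#' Regression coefficient of the (adjusted) phenotype on the GEBV,
#' `cov(y, gebv) / var(gebv)`; approximately 1 for an unbiased model,
#' above 1 for deflated and below 1 for inflated GEBVs. `literal = TRUE`
#' returns `cor(y, gebv) / var(gebv)` instead — a published variant of the
#' statistic that is not scale-free; the regression slope is the default.
#'
#' @param y numeric vector of (adjusted) phenotypes.
#' @param gebv numeric vector of GEBVs (non-constant).
#' @param literal use `cor/var` instead of `cov/var`.
#' @return the slope.
#' @export
bias_slope <- function(y, gebv, literal = FALSE) {
  if (length(y) != length(gebv)) stop_input("vectors must have equal length")
  v <- stats::var(gebv)
  if (!is.finite(v) || v == 0) stop_input("zero-variance gebv: slope undefined")
  if (literal) stats::cor(y, gebv) / v else stats::cov(y, gebv) / v
}

#' Reference/validation scenario specifications
#'
#' Constructors for the evaluation designs:
#' * `scenario_within(breed)` — 1200 individuals of one breed, evaluated by
#'   replicated 5-fold cross-validation.
#' * `scenario_pooled(breeds)` — 120 individuals from each of ten breeds
#'   pooled into a 1200-individual reference, also cross-validated.
#' * `scenario_group(breeds)` — a 1200-individual reference drawn equally
#'   from the breeds of one (k-means) group.
#' * `scenario_cross(a, b)` — reference of `n_a` individuals of breed A plus
#'   `n_b` of breed B; 200 held-out individuals of each breed are predicted
#'   and scored against their TBVs.
#'
#' @param breed,breeds,breed_a,breed_b breed labels.
#' @param n_ref reference size for CV scenarios.
#' @param n_per_breed per-breed draw for the pooled scenario.
#' @param n_a,n_b,n_val cross-design reference and validation sizes.
#' @param folds,repeats cross-validation layout.
#' @return a `scenario_spec` list.
#' @name scenarios
NULL

new_scenario <- function(name, reference, validation, mode, folds = NULL,
                         repeats = NULL) {
  structure(list(name = name, reference = reference, validation = validation,
                 mode = mode, folds = folds, repeats = repeats),
            class = "scenario_spec")
}

#' @rdname scenarios
#' @export
scenario_within <- function(breed, n_ref = 1200, folds = 5, repeats = 5) {
  new_scenario(paste0("within_", breed), setNames(n_ref, breed), NULL,
               "cor_y_gebv", folds, repeats)
}

#' @rdname scenarios
#' @export
scenario_pooled <- function(breeds, n_per_breed = 120, folds = 5, repeats = 5) {
  new_scenario("pooled", setNames(rep(n_per_breed, length(breeds)), breeds),
               NULL, "cor_y_gebv", folds, repeats)
}

#' @rdname scenarios
#' @export
scenario_group <- function(breeds, n_ref = 1200, folds = 5, repeats = 5) {
  n_each <- n_ref %/% length(breeds)
  new_scenario(paste0("group_", paste(breeds, collapse = "+")),
               setNames(rep(n_each, length(breeds)), breeds),
               NULL, "cor_y_gebv", folds, repeats)
}

#' @rdname scenarios
#' @export
scenario_cross <- function(breed_a, breed_b, n_a = 400, n_b = 200,
                           n_val = 200) {
  ref <- c(setNames(n_a, breed_a), setNames(n_b, breed_b))
  ref <- ref[ref > 0]
  new_scenario(paste0("cross_", breed_a, "_", breed_b), ref,
               c(setNames(n_val, breed_a), setNames(n_val, breed_b)),
               "cor_tbv_gebv")
}

#' Materialise a scenario into disjoint reference/validation id sets
#'
#' Draws the configured per-breed counts without replacement; validation
#' individuals are drawn from those not already in the reference, so the two
#' sets are disjoint by construction.
#'
#' @param spec a `scenario_spec`.
#' @param samples tibble with `sample_id` and `breed` for all available
#'   individuals.
#' @param seed integer seed.
#' @return tibble `sample_id`, `breed`, `role` (`"reference"`/`"validation"`).
#' @export
build_scenario <- function(spec, samples, seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  with_seed(seed, {
    take <- function(comp, pool) {
      rows <- lapply(names(comp), function(b) {
        avail <- pool$sample_id[pool$breed == b]
        if (length(avail) < comp[[b]]) {
          stop_input(sprintf("breed %s: need %d individuals, only %d available",
                             b, comp[[b]], length(avail)))
        }
        sample(avail, comp[[b]])
      })
      tibble::tibble(sample_id = unlist(rows),
                     breed = rep(names(comp), comp))
    }
    ref <- take(spec$reference, samples)
    out <- dplyr::mutate(ref, role = "reference")
    if (!is.null(spec$validation)) {
      rest <- samples[!samples$sample_id %in% ref$sample_id, , drop = FALSE]
      val <- take(spec$validation, rest)
      out <- dplyr::bind_rows(out, dplyr::mutate(val, role = "validation"))
    }
    out
  })
}

#' Replicated k-fold cross-validation of GBLUP
#'
#' Partitions the reference individuals into `folds` groups at random, holds
#' each group out in turn, and repeats the random partition `repeats` times.
#' Accuracy is the correlation of the held-out individuals' GEBVs with their
#' adjusted phenotypes (phenotype minus the training model's fixed effects),
#' and bias is the regression of adjusted phenotype on GEBV.
#'
#' @param pheno phenotype data frame (`sample_id` + model variables).
#' @param grm a `grm_matrix` covering the reference individuals.
#' @param ref_ids reference sample ids.
#' @param formula fixed-effect formula.
#' @param folds,repeats CV layout (default 5 x 5).
#' @param sigma_g2,sigma_e2 variance components passed to [solve_gblup()].
#' @param seed integer seed controlling all fold assignments.
#' @return A `cv_result` tibble with one row per repeat x fold:
#'   `rep`, `fold`, `n_ref`, `n_val`, `accuracy`, `bias`.
#' @export
cross_validate <- function(pheno, grm, ref_ids, formula = y ~ 1,
                           folds = 5, repeats = 5, sigma_g2, sigma_e2,
                           seed = NULL) {
  n <- length(ref_ids)
  if (floor(n / folds) < 3) stop_input("folds would contain fewer than 3 individuals")
  with_seed(seed, {
    out <- purrr::map_dfr(seq_len(repeats), function(r) {
      fold_of <- sample(rep(seq_len(folds), length.out = n))
      purrr::map_dfr(seq_len(folds), function(f) {
        val <- ref_ids[fold_of == f]
        trn <- ref_ids[fold_of != f]
        fit <- solve_gblup(pheno, grm, train_ids = trn, predict_ids = val,
                           formula = formula, sigma_g2 = sigma_g2,
                           sigma_e2 = sigma_e2)
        yadj <- adjusted_phenotype(fit, pheno, ids = val)
        gv <- gebv(fit, val)
        tibble::tibble(rep = r, fold = f, n_ref = length(trn),
                       n_val = length(val),
                       accuracy = accuracy(yadj, gv),
                       bias = bias_slope(yadj, gv))
      })
    })
    class(out) <- c("cv_result", class(out))
    out
  })
}

#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(
    n_evals = nrow(x),
    mean_accuracy = mean(x$accuracy), se_accuracy = stats::sd(x$accuracy) / sqrt(nrow(x)),
    mean_bias = mean(x$bias), se_bias = stats::sd(x$bias) / sqrt(nrow(x))
  )
}

#' Subset maximising genetic relationship to a target set
#'
#' Utility for genetic-assessment designs that pick the `n` individuals most
#' related (mean GRM relationship) to the rest of the matrix.
#'
#' @param grm a `grm_matrix`.
#' @param n how many individuals to keep (default 70).
#' @return character vector of sample ids.
#' @export
top_related_subset <- function(grm, n = 70) {
  g <- grm$mat
  diag(g) <- NA
  rel <- rowMeans(g, na.rm = TRUE)
  grm$sample_ids[order(rel, decreasing = TRUE)[seq_len(min(n, length(rel)))]]
}
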