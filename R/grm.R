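#' VanRaden genomic relationship matrix
#'
#' `G = W W' / (2 * sum p_k (1 - p_k))` with `W` the dosage matrix centered
#' by twice the alternate-allele frequency. Monomorphic markers contribute
#' nothing to `W` and are excluded from the denominator. Frequencies are
#' pooled over all individuals by default; `freq_source = "per_breed"`
#' centers each breed by its own frequencies (the scaling denominator stays
#' pooled so relationship scales remain comparable).
#'
#' @param geno a complete (post-QC, no missing dosages) [genotype_matrix()].
#' @param freq_source `"pooled"` or `"per_breed"`.
#' @return A `grm_matrix` object: `mat` (n x n, dimnames = sample ids), the
#'   frequencies `p` used, and the scaling `denom`.
#' @export
compute_grm <- function(geno, freq_source = c("pooled", "per_breed")) {
  freq_source <- match.arg(freq_source)
  stopifnot(inherits(geno, "genotype_matrix"))
  d <- geno$dosages
  if (anyNA(d)) stop_input("GRM requires complete dosages; run qc_filter or impute first")
  p <- colMeans(d) / 2
  poly <- p > 0 & p < 1
  if (sum(poly) < 1) abort("all markers are monomorphic; GRM undefined",
                           class = "crossblup_input_error")
  w <- matrix(as.numeric(d), nrow(d), ncol(d))
  if (freq_source == "pooled") {
    w <- sweep(w, 2, 2 * p)
  } else {
    for (b in unique(geno$breed_labels)) {
      rows <- geno$breed_labels == b
      pb <- colMeans(d[rows, , drop = FALSE]) / 2
      w[rows, ] <- sweep(w[rows, , drop = FALSE], 2, 2 * pb)
    }
  }
  w[, !poly] <- 0
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  g <- tcrossprod(w) / denom
  dimnames(g) <- list(geno$sample_ids, geno$sample_ids)
  structure(
    list(mat = g, sample_ids = geno$sample_ids, p = p, denom = denom,
         freq_source = freq_source, cache = new.env(parent = emptyenv())),
    class = "grm_matrix"
  )
}

#' @export
print.grm_matrix <- function(x, ...) {
  cat(sprintf("<grm_matrix> %d x %d (%s frequencies), mean diagonal %.3f\n",
              nrow(x$mat), ncol(x$mat), x$freq_source, mean(diag(x$mat))))
  invisible(x)
}

#' Effective number of independent chromosome segments
#'
#' Plug-in estimate of Me from the realized relationship matrix: the inverse
#' variance of the off-diagonal relationships, `Me = 1 / var(G_ij)`. This is
#' the quantity entering the deterministic accuracy approximation
#' `sqrt(n h2 / (n h2 + Me))`. An eigenvalue-based alternative,
#' `(sum lambda)^2 / sum(lambda^2)` of the column-centered GRM, is available
#' via `method`.
#'
#' @param grm a `grm_matrix`.
#' @param method `"offdiag_var"` (default) or `"eigen"`.
#' @return A single number.
#' @export
effective_segments <- function(grm, method = c("offdiag_var", "eigen")) {
  method <- match.arg(method)
  g <- grm$mat
  if (method == "offdiag_var") {
    off <- g[lower.tri(g)]
    1 / stats::var(off)
  } else {
    gc <- sweep(g, 2, colMeans(g))
    ev <- eigen(crossprod(gc), symmetric = TRUE, only.values = TRUE)$values
    ev <- sqrt(pmax(ev, 0)) # singular values of the centered GRM
    sum(ev)^2 / sum(ev^2)
  }
}
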