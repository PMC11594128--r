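#' Quality control of a genotype matrix
#'
#' Applies the standard chip QC cascade, in this order: samples by call rate,
#' then markers by call rate, minor allele frequency, and a 1-df chi-square
#' test for deviation from Hardy-Weinberg equilibrium on genotype counts.
#' Only autosomal markers are retained (any marker whose `chrom` is not a
#' plain number is removed first). Each removed sample/marker is reported
#' with exactly one primary reason, the first threshold it failed.
#'
#' @param geno a [genotype_matrix()].
#' @param sample_cr minimum per-sample call rate (default 0.90).
#' @param marker_cr minimum per-marker call rate (default 0.90).
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param hwe_p_min minimum HWE p-value (default 1e-6).
#' @return A list with `genotypes` (the filtered [genotype_matrix()]) and
#'   `report`, a `qc_report` list holding `removed_samples`,
#'   `removed_markers` tibbles and the thresholds used.
#' @export
qc_filter <- function(geno, sample_cr = 0.90, marker_cr = 0.90,
                      maf_min = 0.01, hwe_p_min = 1e-6) {
  stopifnot(inherits(geno, "genotype_matrix"))
  thr <- c(sample_cr = sample_cr, marker_cr = marker_cr,
           maf_min = maf_min, hwe_p_min = hwe_p_min)
  if (any(thr[1:3] < 0) || any(thr[1:3] > 1)) {
    stop_input("QC thresholds must lie in [0, 1]")
  }
  d <- geno$dosages

  scr <- rowMeans(!is.na(d))
  bad_s <- which(scr < sample_cr)
  removed_samples <- tibble::tibble(
    sample_id = geno$sample_ids[bad_s], call_rate = scr[bad_s],
    reason = rep("call_rate", length(bad_s))
  )
  keep_s <- setdiff(seq_len(nrow(d)), bad_s)
  d <- d[keep_s, , drop = FALSE]

  chrom_num <- suppressWarnings(as.numeric(as.character(geno$map$chrom)))
  non_auto <- which(is.na(chrom_num))
  mcr <- colMeans(!is.na(d))
  n0 <- colSums(d == 0L, na.rm = TRUE)
  n1 <- colSums(d == 1L, na.rm = TRUE)
  n2 <- colSums(d == 2L, na.rm = TRUE)
  nn <- n0 + n1 + n2
  p <- ifelse(nn > 0, (2 * n2 + n1) / (2 * nn), NA_real_)
  maf <- pmin(p, 1 - p)
  hwe_p <- hwe_chisq_p(n0, n1, n2)

  reason <- rep(NA_character_, ncol(d))
  reason[mcr < marker_cr] <- "call_rate"
  reason[is.na(reason) & (is.na(maf) | maf < maf_min)] <- "maf"
  reason[is.na(reason) & !is.na(hwe_p) & hwe_p < hwe_p_min] <- "hwe"
  reason[non_auto] <- "non_autosomal"
  bad_m <- which(!is.na(reason))
  removed_markers <- tibble::tibble(
    marker_id = geno$map$marker_id[bad_m],
    call_rate = mcr[bad_m], maf = maf[bad_m], hwe_p = hwe_p[bad_m],
    reason = reason[bad_m]
  )
  keep_m <- which(is.na(reason))
  report <- structure(
    list(removed_samples = removed_samples, removed_markers = removed_markers,
         thresholds = thr, n_samples_kept = length(keep_s),
         n_markers_kept = length(keep_m)),
    class = "qc_report"
  )
  if (length(keep_m) == 0) {
    abort("all markers removed by QC", class = "crossblup_qc_empty",
          report = report)
  }
  gam <- if (!is.null(geno$gametes)) {
    list(geno$gametes[[1]][keep_s, keep_m, drop = FALSE],
         geno$gametes[[2]][keep_s, keep_m, drop = FALSE])
  }
  out <- genotype_matrix(d[, keep_m, drop = FALSE],
                         geno$map[keep_m, , drop = FALSE],
                         sample_ids = geno$sample_ids[keep_s],
                         breed_labels = geno$breed_labels[keep_s],
                         gametes = gam)
  list(genotypes = out, report = report)
}

# Hardy-Weinberg 1-df chi-square p-value from genotype counts, vectorised.
# Expected counts come from the observed allele frequency; monomorphic
# markers return NA (no test possible).
hwe_chisq_p <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  p <- (2 * n2 + n1) / (2 * n)
  q <- 1 - p
  e0 <- n * q^2
  e1 <- 2 * n * p * q
  e2 <- n * p^2
  chisq <- ifelse(
    p > 0 & p < 1 & n > 0,
    (n0 - e0)^2 / e0 + (n1 - e1)^2 / e1 + (n2 - e2)^2 / e2,
    NA_real_
  )
  stats::pchisq(chisq, df = 1, lower.tail = FALSE)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat(sprintf("  samples removed: %d; markers removed: %d\n",
              nrow(x$removed_samples), nrow(x$removed_markers)))
  if (nrow(x$removed_markers) > 0) {
    tab <- table(x$removed_markers$reason)
    cat("  marker reasons:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  cat(sprintf("  kept: %d samples x %d markers\n",
              x$n_samples_kept, x$n_markers_kept))
  invisible(x)
}

#' Inject missingness into a genotype matrix
#'
#' Simulated chip data are complete by default; this utility masks a fraction
#' of calls (and can degrade chosen samples further) so call-rate filters can
#' be exercised. Phase is dropped for masked matrices.
#'
#' @param geno a [genotype_matrix()].
#' @param rate overall fraction of calls set missing.
#' @param sample_rates optional named vector of per-sample missing rates
#'   (names = sample ids), overriding `rate` for those samples.
#' @param seed integer seed.
#' @return a `genotype_matrix` with `NA` dosages and no phase.
#' @export
mask_genotypes <- function(geno, rate = 0.02, sample_rates = NULL, seed = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  d <- geno$dosages
  with_seed(seed, {
    rr <- rep(rate, nrow(d))
    if (!is.null(sample_rates)) {
      idx <- match(names(sample_rates), geno$sample_ids)
      if (anyNA(idx)) stop_input("unknown sample ids in sample_rates")
      rr[idx] <- sample_rates
    }
    mask <- matrix(runif(length(d)) < rr, nrow = nrow(d))
    d[mask] <- NA_integer_
    genotype_matrix(d, geno$map, sample_ids = geno$sample_ids,
                    breed_labels = geno$breed_labels)
  })
}
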