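#' Trait architecture presets
#'
#' The four QTL-architecture strategies used in the simulation study, each
#' splitting `n_qtl` loci into small-, medium- and large-effect classes:
#'
#' | Strategy | nQTL   | nS     | nM  | nL  |
#' |----------|--------|--------|-----|-----|
#' | I        | 100    | 0      | 0   | 100 |
#' | II       | 2000   | 1361   | 614 | 25  |
#' | III      | 5000   | 4595   | 390 | 15  |
#' | IV       | 10000  | 10000  | 0   | 0   |
#'
#' Additive effects are drawn from N(0, c * sigma_g2) with c = 0.0001 (S),
#' 0.001 (M), 0.01 (L). Note the class-to-variance mapping is monotone in
#' effect size: large-effect QTLs carry the 0.01 variance scale (under
#' Strategy I the whole genetic variance rests on 100 large-effect loci).
#'
#' @param strategy `"I"`, `"II"`, `"III"` or `"IV"`, or `"custom"` with
#'   explicit class counts.
#' @param h2 narrow-sense heritability in (0, 1); the study grid is
#'   0.1 / 0.3 / 0.6.
#' @param sigma_g2 nominal additive genetic variance scaling the effect
#'   distributions.
#' @param n_small,n_medium,n_large class counts for `strategy = "custom"`.
#' @return A `trait_architecture` list.
#' @export
trait_architecture <- function(strategy = c("II", "I", "III", "IV", "custom"),
                               h2 = 0.3, sigma_g2 = 1,
                               n_small = NULL, n_medium = NULL, n_large = NULL) {
  strategy <- match.arg(strategy)
  counts <- switch(strategy,
    I = c(0L, 0L, 100L),
    II = c(1361L, 614L, 25L),
    III = c(4595L, 390L, 15L),
    IV = c(10000L, 0L, 0L),
    custom = c(as.integer(n_small), as.integer(n_medium), as.integer(n_large))
  )
  if (length(counts) != 3 || anyNA(counts) || any(counts < 0)) {
    stop_input("custom architectures need non-negative n_small, n_medium, n_large")
  }
  if (h2 <= 0 || h2 >= 1) stop_input("h2 must lie strictly between 0 and 1")
  structure(
    list(strategy = strategy, n_qtl = sum(counts),
         n_small = counts[1], n_medium = counts[2], n_large = counts[3],
         h2 = h2, sigma_g2 = sigma_g2),
    class = "trait_architecture"
  )
}

# Per-class variance scale of QTL effects relative to sigma_g2.
qtl_class_variance <- c(S = 1e-4, M = 1e-3, L = 1e-2)

#' Sample QTL positions and additive effects
#'
#' Draws `n_qtl` marker indices uniformly without replacement from the
#' eligible set, assigns effect classes to match the architecture counts, and
#' samples each additive effect from N(0, c * sigma_g2) with the class
#' variance scale c in (0.0001, 0.001, 0.01) for (S, M, L).
#'
#' @param map marker map of the genotyped panel.
#' @param arch a [trait_architecture()].
#' @param eligible_markers integer indices of markers QTLs may occupy
#'   (typically the QC-passing markers). Default: all mapped markers.
#' @param seed integer seed.
#' @return A `qtl_set` tibble: `marker_index`, `marker_id`, `chrom`,
#'   `pos_bp`, `class`, `effect`.
#' @export
sample_qtls <- function(map, arch, eligible_markers = seq_len(nrow(map)),
                        seed = NULL) {
  stopifnot(inherits(arch, "trait_architecture"))
  if (length(eligible_markers) < arch$n_qtl) {
    stop_input(sprintf("need %d eligible markers, have %d",
                       arch$n_qtl, length(eligible_markers)))
  }
  with_seed(seed, {
    idx <- sample(eligible_markers, arch$n_qtl)
    cls <- rep(c("S", "M", "L"), c(arch$n_small, arch$n_medium, arch$n_large))
    eff <- rnorm(arch$n_qtl, 0, sqrt(qtl_class_variance[cls] * arch$sigma_g2))
    out <- tibble::tibble(
      marker_index = idx,
      marker_id = map$marker_id[idx],
      chrom = map$chrom[idx],
      pos_bp = map$pos_bp[idx],
      class = cls,
      effect = eff
    )
    class(out) <- c("qtl_set", class(out))
    out
  })
}

#' True breeding values from QTL genotypes
#'
#' `TBV_i = sum_j x_ij a_j` over the QTL set, with dosages coded 0/1/2 and no
#' centering. QTLs must be fully observed.
#'
#' @param geno a [genotype_matrix()].
#' @param qtl a `qtl_set` from [sample_qtls()].
#' @return Named numeric vector of TBVs (names = sample ids).
#' @export
compute_tbv <- function(geno, qtl) {
  stopifnot(inherits(geno, "genotype_matrix"))
  idx <- qtl$marker_index
  if (any(idx < 1 | idx > ncol(geno$dosages))) {
    stop_input("QTL indices outside the genotype matrix")
  }
  x <- geno$dosages[, idx, drop = FALSE]
  if (anyNA(x)) stop_input("missing dosage at a QTL; QTLs must be fully observed")
  tbv <- drop(x %*% qtl$effect)
  names(tbv) <- geno$sample_ids
  tbv
}

#' Simulate phenotypes from true breeding values
#'
#' Environmental deviations are N(0, Ve) with
#' `Ve = realized_Vg * (1 - h2) / h2`, where `realized_Vg` is the empirical
#' variance of the TBVs in the simulated population — so the realized
#' heritability matches the target in expectation. Phenotype `y = tbv + e`.
#'
#' @param tbv named numeric vector of true breeding values.
#' @param h2 target heritability in (0, 1).
#' @param seed integer seed.
#' @return A `phenotype_set` tibble with `sample_id`, `tbv`, `e`, `y` and
#'   attributes `realized_vg`, `ve`, `h2`.
#' @export
simulate_phenotypes <- function(tbv, h2, seed = NULL) {
  if (h2 <= 0 || h2 >= 1) stop_input("h2 must lie strictly between 0 and 1")
  vg <- stats::var(tbv)
  if (!is.finite(vg) || vg <= 0) {
    stop_input("TBVs are constant; no genetic variance to scale against")
  }
  ve <- vg * (1 - h2) / h2
  with_seed(seed, {
    e <- rnorm(length(tbv), 0, sqrt(ve))
    out <- tibble::tibble(
      sample_id = names(tbv) %||% as.character(seq_along(tbv)),
      tbv = unname(tbv), e = e, y = unname(tbv) + e
    )
    attr(out, "realized_vg") <- vg
    attr(out, "ve") <- ve
    attr(out, "h2") <- h2
    class(out) <- c("phenotype_set", class(out))
    out
  })
}

#' @method glance phenotype_set
#' @export
glance.phenotype_set <- function(x, ...) {
  tibble::tibble(
    n = nrow(x),
    realized_vg = attr(x, "realized_vg"),
    ve = attr(x, "ve"),
    h2_target = attr(x, "h2"),
    h2_realized = stats::var(x$tbv) / stats::var(x$y)
  )
}
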