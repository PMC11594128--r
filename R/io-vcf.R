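# VCF 4.2 export (GT only) and import. Writing is plain text generation;
# reading delegates parsing to the established vcfR reader.

#' Write genotypes as a (optionally phased) VCF
#'
#' Phased matrices emit `a|b` genotypes from the gamete matrices; unphased
#' dosages emit `0/0`, `0/1`, `1/1`, and missing calls become `./.`.
#'
#' @param geno a [genotype_matrix()].
#' @param path output path (plain text, `.vcf`).
#' @return the path, invisibly.
#' @export
write_phased_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  map <- geno$map
  chroms <- unique(map$chrom)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=crossblup",
    sprintf("##contig=<ID=%s,length=%d>", chroms,
            vapply(chroms, function(cc) max(map$pos_bp[map$chrom == cc]) + 1L,
                   integer(1))),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$sample_ids), collapse = "\t")
  )
  if (!is.null(geno$gametes)) {
    gt <- matrix(paste0(t(geno$gametes[[1]]), "|", t(geno$gametes[[2]])),
                 nrow = ncol(geno$dosages)) # M x n
  } else {
    lut <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    gt <- matrix("./.", ncol(geno$dosages), nrow(geno$dosages))
    ok <- !is.na(t(geno$dosages))
    gt[ok] <- lut[as.character(t(geno$dosages))[ok]]
  }
  body <- paste(map$chrom, map$pos_bp, map$marker_id, map$ref_allele,
                map$alt_allele, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF with GT calls into a genotype matrix
#'
#' `|`-separated genotypes populate the gamete matrices (phase retained);
#' `/`-separated calls yield dosages only. `./.` maps to a missing dosage.
#' The cM position is reconstructed from the physical position at
#' `cm_per_mb` since VCF carries no genetic map.
#'
#' @param path VCF path.
#' @param cm_per_mb genetic map rate used to rebuild `pos_cm`.
#' @param breed_labels optional breed label per sample (defaults to the
#'   label `"pop"`).
#' @return a [genotype_matrix()].
#' @export
read_phased_vcf <- function(path, cm_per_mb = 1, breed_labels = "pop") {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_input("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  map <- tibble::tibble(
    chrom = as.integer(fix[, "CHROM"]),
    marker_id = fix[, "ID"],
    pos_bp = as.integer(fix[, "POS"]),
    ref_allele = fix[, "REF"],
    alt_allele = fix[, "ALT"]
  )
  map$pos_cm <- map$pos_bp / 1e6 * cm_per_mb
  map <- map[, c("chrom", "marker_id", "pos_bp", "pos_cm",
                 "ref_allele", "alt_allele")]
  gt <- vcfR::extract.gt(v) # M x n
  if (any(nchar(gt) != 3, na.rm = TRUE)) stop_input("only diploid GT calls are supported")
  a1 <- substr(gt, 1, 1)
  sep <- substr(gt, 2, 2)
  a2 <- substr(gt, 3, 3)
  miss <- is.na(gt) | a1 == "." | a2 == "."
  d1 <- suppressWarnings(matrix(as.integer(a1), nrow(gt), ncol(gt)))
  d2 <- suppressWarnings(matrix(as.integer(a2), nrow(gt), ncol(gt)))
  dos <- t(d1 + d2)
  dos[t(miss)] <- NA_integer_
  gam <- NULL
  if (all(sep[!miss] == "|") && !any(miss)) {
    gam <- list(t(d1), t(d2))
  }
  genotype_matrix(dos, map, sample_ids = colnames(gt),
                  breed_labels = breed_labels, gametes = gam)
}

#' Read or write genotypes in a standard format
#'
#' Thin dispatchers over [read_plink()]/[write_plink()] and
#' [read_phased_vcf()]/[write_phased_vcf()].
#'
#' @param path file path (VCF) or prefix (PLINK).
#' @param format `"plink_bed"` or `"vcf"`.
#' @param geno a [genotype_matrix()] (write only).
#' @param ... passed to the format-specific function.
#' @return a [genotype_matrix()] (read) or the path (write, invisibly).
#' @export
read_genotypes <- function(path, format = c("plink_bed", "vcf"), ...) {
  format <- match.arg(format)
  switch(format, plink_bed = read_plink(path, ...),
         vcf = read_phased_vcf(path, ...))
}

#' @rdname read_genotypes
#' @export
write_genotypes <- function(geno, path, format = c("plink_bed", "vcf"), ...) {
  format <- match.arg(format)
  switch(format, plink_bed = write_plink(geno, path, ...),
         vcf = write_phased_vcf(geno, path, ...))
}
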