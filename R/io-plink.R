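# PLINK 1 binary triplet (.bed/.bim/.fam) reader and writer. The .bed is
# SNP-major v1.0 (magic 0x6c 0x1b 0x01); two bits per genotype with sample 1
# in the lowest bits: 00 = homozygous A1, 10 = heterozygous, 11 = homozygous
# A2, 01 = missing. A1 is written as the alternate allele, so the stored
# code recovers the alternate-allele dosage. Phase, which PLINK 1 cannot
# carry, goes to a companion tab-separated haplotype table
# (sample_id, hap_index 0/1, one allele column per marker).

#' Write genotypes as a PLINK .bed/.bim/.fam triplet
#'
#' @param geno a [genotype_matrix()].
#' @param prefix path prefix; `.bed`, `.bim`, `.fam` (and `.hap.tsv` when
#'   phase is present and `write_phase = TRUE`) are appended.
#' @param write_phase also write the companion phased haplotype table.
#' @return the prefix, invisibly.
#' @export
write_plink <- function(geno, prefix, write_phase = !is.null(geno$gametes)) {
  stopifnot(inherits(geno, "genotype_matrix"))
  map <- geno$map
  bim <- data.frame(map$chrom, map$marker_id, map$pos_cm, map$pos_bp,
                    map$alt_allele, map$ref_allele)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  fam <- data.frame(geno$breed_labels, geno$sample_ids, 0L, 0L, 0L, -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  d <- geno$dosages
  n <- nrow(d)
  code <- matrix(3L, n, ncol(d)) # dosage 0 -> 11
  code[d == 1L] <- 2L            # het      -> 10
  code[d == 2L] <- 0L            # alt hom  -> 00
  code[is.na(d)] <- 1L           # missing  -> 01
  n_pad <- 4L * ceiling(n / 4L)
  if (n_pad > n) code <- rbind(code, matrix(0L, n_pad - n, ncol(d)))
  q <- matrix(code, nrow = 4L) # columns = byte groups, SNP-major
  bytes <- as.raw(q[1, ] + 4L * q[2, ] + 16L * q[3, ] + 64L * q[4, ])
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(bytes, con)

  if (write_phase) {
    if (is.null(geno$gametes)) stop_input("no phase to write")
    h <- matrix(0L, 2L * n, ncol(d))
    h[seq(1L, 2L * n, 2L), ] <- geno$gametes[[1]]
    h[seq(2L, 2L * n, 2L), ] <- geno$gametes[[2]]
    hap <- cbind(sample_id = rep(geno$sample_ids, each = 2),
                 hap_index = rep(0:1, n), as.data.frame(h))
    utils::write.table(hap, paste0(prefix, ".hap.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(prefix)
}

#' Read a PLINK .bed/.bim/.fam triplet
#'
#' Genetic positions are taken from the .bim cM column; a companion
#' `.hap.tsv` phased haplotype table is picked up automatically when present.
#'
#' @param prefix path prefix of the triplet.
#' @return a [genotype_matrix()].
#' @export
read_plink <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"), sep = "\t",
                           col.names = c("chrom", "marker_id", "pos_cm",
                                         "pos_bp", "a1", "a2"),
                           colClasses = c("integer", "character", "numeric",
                                          "integer", "character", "character"))
  fam <- utils::read.table(paste0(prefix, ".fam"), sep = "\t",
                           colClasses = c("character", "character", "integer",
                                          "integer", "integer", "integer"))
  map <- tibble::tibble(chrom = bim$chrom, marker_id = bim$marker_id,
                        pos_bp = bim$pos_bp, pos_cm = bim$pos_cm,
                        ref_allele = bim$a2, alt_allele = bim$a1)
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3 + ceiling(n / 4) * m)
  if (!identical(as.integer(raw[1:3]), c(0x6cL, 0x1bL, 0x01L))) {
    stop_input("not a SNP-major PLINK v1.0 .bed file")
  }
  b <- as.integer(raw[-(1:3)])
  if (length(b) != ceiling(n / 4) * m) stop_input(".bed size does not match .bim/.fam")
  v <- rbind(b %% 4L, (b %/% 4L) %% 4L, (b %/% 16L) %% 4L, (b %/% 64L) %% 4L)
  v <- matrix(as.vector(v), nrow = 4L * ceiling(n / 4L))[seq_len(n), , drop = FALSE]
  d <- matrix(NA_integer_, n, m)
  d[v == 0L] <- 2L
  d[v == 2L] <- 1L
  d[v == 3L] <- 0L
  gam <- NULL
  hap_path <- paste0(prefix, ".hap.tsv")
  if (file.exists(hap_path)) {
    hp <- utils::read.table(hap_path, sep = "\t")
    hm <- as.matrix(hp[, -(1:2), drop = FALSE])
    storage.mode(hm) <- "integer"
    gam <- list(hm[hp[[2]] == 0, , drop = FALSE], hm[hp[[2]] == 1, , drop = FALSE])
  }
  genotype_matrix(d, map, sample_ids = fam[[2]], breed_labels = fam[[1]],
                  gametes = gam)
}
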