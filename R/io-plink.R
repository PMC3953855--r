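# PLINK 1 binary trio support. The .bed payload is SNP-major v1.00: a
# 3-byte magic header (0x6c 0x1b 0x01) then ceiling(n_samples/4) bytes per
# variant, two bits per sample, least-significant pair first:
#   00 = homozygous A1 (dosage 2), 01 = missing, 10 = het, 11 = homozygous A2.

PLINK_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))
# 2-bit code -> A1 dosage
BED_DECODE <- c(2L, NA_integer_, 1L, 0L)

#' Read a PLINK binary genotype trio
#'
#' Decodes a SNP-major v1.00 `.bed` with its `.bim`/`.fam` sidecars into a
#' [genotype_matrix()]. Dosages count A1 alleles as stored; the missing bed
#' code maps to `NA`. Sample sex is parsed from `.fam` column 5
#' (1 = male, 2 = female, anything else = unknown). Variants with no
#' functional annotation get class `other`; use [read_annotation()] +
#' [set_annotation()] to assign classes.
#'
#' @param bed_path,bim_path,fam_path Paths to the three files. `bim_path`
#'   and `fam_path` default to the `.bed` path with swapped extensions.
#' @return A [genotype_matrix()].
#' @export
read_plink <- function(bed_path,
                       bim_path = sub("\\.bed$", ".bim", bed_path),
                       fam_path = sub("\\.bed$", ".fam", bed_path)) {
  for (p in c(bed_path, bim_path, fam_path)) {
    if (!file.exists(p)) abort(sprintf("file not found: %s", p))
  }
  fam <- utils::read.table(fam_path, header = FALSE,
                           colClasses = "character")
  if (ncol(fam) < 5) abort(sprintf("%s: expected >= 5 .fam columns", fam_path))
  bim <- utils::read.table(bim_path, header = FALSE,
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  n <- nrow(fam)
  m <- nrow(bim)
  bpv <- ceiling(n / 4)

  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3 || !identical(raw[1:3], PLINK_MAGIC)) {
    abort(sprintf("%s: not a SNP-major PLINK v1.00 .bed (bad magic number)",
                  bed_path))
  }
  payload <- raw[-(1:3)]
  if (length(payload) != bpv * m) {
    abort(sprintf(
      "%s: payload is %d bytes but %d variants x %d samples need %d",
      bed_path, length(payload), m, n, bpv * m
    ))
  }
  bytes <- as.integer(payload)
  # unpack 4 two-bit codes per byte, sample order = LSB first
  codes <- matrix(NA_integer_, nrow = 4 * bpv, ncol = m)
  byte_mat <- matrix(bytes, nrow = bpv, ncol = m)
  for (k in 0:3) {
    codes[seq(k + 1, by = 4, length.out = bpv), ] <-
      (byte_mat %/% (4L^k)) %% 4L
  }
  dosage <- matrix(BED_DECODE[codes[seq_len(n), , drop = FALSE] + 1L],
                   nrow = n, ncol = m)

  sex <- dplyr::case_match(fam[[5]], "1" ~ "male", "2" ~ "female",
                           .default = NA_character_)
  genotype_matrix(
    dosage = dosage,
    samples = tibble(sample_id = fam[[2]], sex = sex),
    variants = tibble(
      variant_id = bim[[2]], chrom = bim[[1]], pos = bim[[4]],
      a1 = bim[[5]], a2 = bim[[6]],
      func_class = "other"
    )
  )
}

#' Write a genotype matrix as a PLINK binary trio
#'
#' @param geno A [genotype_matrix()].
#' @param bed_path,bim_path,fam_path Output paths; sidecars default to the
#'   `.bed` path with swapped extensions.
#' @return Invisibly, the `.bed` path.
#' @export
write_plink <- function(geno, bed_path,
                        bim_path = sub("\\.bed$", ".bim", bed_path),
                        fam_path = sub("\\.bed$", ".fam", bed_path)) {
  n <- n_samples(geno)
  m <- n_variants(geno)
  bpv <- ceiling(n / 4)

  # dosage -> 2-bit code (2 -> 00, NA -> 01, 1 -> 10, 0 -> 11)
  d <- geno$dosage
  code <- matrix(1L, nrow = n, ncol = m)
  code[!is.na(d) & d == 2L] <- 0L
  code[!is.na(d) & d == 1L] <- 2L
  code[!is.na(d) & d == 0L] <- 3L
  padded <- matrix(0L, nrow = 4 * bpv, ncol = m)
  padded[seq_len(n), ] <- code
  bytes <- matrix(0L, nrow = bpv, ncol = m)
  for (k in 0:3) {
    bytes <- bytes + padded[seq(k + 1, by = 4, length.out = bpv), ,
                            drop = FALSE] * 4L^k
  }
  con <- file(bed_path, "wb")
  on.exit(close(con))
  writeBin(PLINK_MAGIC, con)
  writeBin(as.raw(bytes), con)

  v <- geno$variants
  utils::write.table(
    data.frame(v$chrom, v$variant_id, 0, v$pos, v$a1, v$a2),
    bim_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  s <- geno$samples
  sex_code <- dplyr::case_match(s$sex, "male" ~ 1L, "female" ~ 2L,
                                .default = 0L)
  utils::write.table(
    data.frame(s$sample_id, s$sample_id, 0, 0, sex_code, -9),
    fam_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(bed_path)
}
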