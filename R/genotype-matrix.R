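#' Construct an in-memory genotype matrix
#'
#' The central data container of the pipeline: a samples-by-variants matrix of
#' A1-allele dosages in \{0, 1, 2, NA\}, with per-sample sex and per-variant
#' metadata (locus, alleles, functional class). `NA` is the missing-call
#' sentinel throughout.
#'
#' @param dosage Integer matrix, samples in rows, variants in columns; values
#'   in \{0, 1, 2, NA\} counting copies of allele A1.
#' @param samples Tibble with columns `sample_id` (character, unique) and
#'   `sex` (`"female"`, `"male"`, or NA when unknown).
#' @param variants Tibble with columns `variant_id` (character, unique),
#'   `chrom` (labels `"1"`–`"22"`, `"X"`), `pos` (1-based integer), `a1`,
#'   `a2` (allele strings), `func_class` (one of `stop_gain_loss`, `splice`,
#'   `missense`, `synonymous`, `other`).
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage`, `samples`, `variants`.
#' @examples
#' geno <- genotype_matrix(
#'   dosage = matrix(c(0L, 1L, 2L, 0L), nrow = 2,
#'                   dimnames = list(c("s1", "s2"), c("v1", "v2"))),
#'   samples = tibble::tibble(sample_id = c("s1", "s2"),
#'                            sex = c("female", "male")),
#'   variants = tibble::tibble(variant_id = c("v1", "v2"),
#'                             chrom = c("1", "2"), pos = c(100L, 200L),
#'                             a1 = c("A", "C"), a2 = c("G", "T"),
#'                             func_class = c("missense", "synonymous"))
#' )
#' n_samples(geno)
#' @export
genotype_matrix <- function(dosage, samples, variants) {
  samples <- as_tibble(samples)
  variants <- as_tibble(variants)
  if (!is.matrix(dosage)) {
    abort("`dosage` must be a matrix (samples x variants).")
  }
  storage.mode(dosage) <- "integer"
  if (nrow(dosage) != nrow(samples) || ncol(dosage) != nrow(variants)) {
    abort(sprintf(
      "dosage dimensions (%d x %d) do not match %d samples x %d variants.",
      nrow(dosage), ncol(dosage), nrow(samples), nrow(variants)
    ))
  }
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && !all(vals %in% 0:2)) {
    abort("dosage values must be 0, 1, 2 or NA.")
  }
  if (anyDuplicated(samples$sample_id)) abort("duplicate sample ids.")
  if (anyDuplicated(variants$variant_id)) abort("duplicate variant ids.")
  bad <- setdiff(unique(variants$func_class), FUNC_CLASSES)
  if (length(bad)) {
    abort(paste0("unknown functional class: ", paste(bad, collapse = ", ")))
  }
  if (any(variants$pos < 1L)) abort("variant positions must be >= 1.")
  dimnames(dosage) <- list(samples$sample_id, variants$variant_id)
  structure(
    list(dosage = dosage, samples = samples, variants = variants),
    class = "genotype_matrix"
  )
}

#' @rdname genotype_matrix
#' @param x A `genotype_matrix`.
#' @export
n_samples <- function(x) nrow(x$dosage)

#' @rdname genotype_matrix
#' @export
n_variants <- function(x) ncol(x$dosage)

#' @export
print.genotype_matrix <- function(x, ...) {
  n_miss <- sum(is.na(x$dosage))
  cat(sprintf(
    "<genotype_matrix> %d samples x %d variants (%.2f%% missing calls)\n",
    n_samples(x), n_variants(x),
    100 * n_miss / max(1, length(x$dosage))
  ))
  cat("functional classes:",
      paste(sprintf("%s=%d", names(table(x$variants$func_class)),
                    table(x$variants$func_class)), collapse = " "), "\n")
  invisible(x)
}

#' Subset a genotype matrix by sample and/or variant
#'
#' @param x A `genotype_matrix`.
#' @param samples,variants Logical, integer, or character index into the
#'   sample / variant axis; `NULL` keeps all.
#' @return A `genotype_matrix` restricted to the selection.
#' @export
subset_genotypes <- function(x, samples = NULL, variants = NULL) {
  si <- if (is.null(samples)) seq_len(n_samples(x)) else samples
  vi <- if (is.null(variants)) seq_len(n_variants(x)) else variants
  if (is.character(si)) si <- match(si, x$samples$sample_id)
  if (is.character(vi)) vi <- match(vi, x$variants$variant_id)
  genotype_matrix(
    dosage = x$dosage[si, vi, drop = FALSE],
    samples = x$samples[si, , drop = FALSE],
    variants = x$variants[vi, , drop = FALSE]
  )
}

# TRUE for male samples (used to adjudicate X-chromosome haploidy).
is_male <- function(x) x$samples$sex %in% "male"

# TRUE for variants on the X chromosome.
is_x_variant <- function(x) x$variants$chrom %in% c("X", "23")
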