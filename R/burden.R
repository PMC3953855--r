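# Per-individual rare-allele burden: the unweighted sum of minor-allele
# copies over a selected variant set (an additive mutation-load model).
# No per-variant weights, no gene-level collapsing.

#' Compute in-sample minor allele frequencies
#'
#' Per variant, the A1 allele frequency over non-missing calls, with
#' X-chromosome males contributing one allele (dosage/2) and females two;
#' MAF = min(f, 1 - f). The minor-allele orientation is recorded so burden
#' scores count minor alleles regardless of file A1/A2 orientation; ties at
#' f = 0.5 orient to A1.
#'
#' @param geno A post-QC [genotype_matrix()].
#' @return A tibble: `variant_id`, `func_class`, `f_a1` (A1 frequency),
#'   `maf`, `minor_is_a1`.
#' @export
compute_maf <- function(geno) {
  d <- geno$dosage
  n_nonmiss <- colSums(!is.na(d))
  if (any(n_nonmiss == 0)) {
    abort(sprintf(
      "%d variant(s) have no non-missing calls; MAF is undefined (QC should have removed them).",
      sum(n_nonmiss == 0)
    ))
  }
  xv <- is_x_variant(geno)
  male <- is_male(geno)
  if (any(xv) && any(is.na(geno$samples$sex))) {
    abort("sample sex is unknown but X-chromosome variants are present.")
  }
  allele_count <- colSums(d, na.rm = TRUE)
  allele_total <- 2 * n_nonmiss
  if (any(xv) && any(male)) {
    dm <- d[male, xv, drop = FALSE]
    # males carry one X allele: count dosage/2 alleles out of 1
    allele_count[xv] <- colSums(d[!male, xv, drop = FALSE], na.rm = TRUE) +
      colSums(dm, na.rm = TRUE) / 2
    allele_total[xv] <- 2 * colSums(!is.na(d[!male, xv, drop = FALSE])) +
      colSums(!is.na(dm))
  }
  f <- unname(allele_count / allele_total)
  tibble(
    variant_id = geno$variants$variant_id,
    func_class = geno$variants$func_class,
    f_a1 = f,
    maf = pmin(f, 1 - f),
    minor_is_a1 = f <= 0.5
  )
}

#' Select rare variants by MAF threshold and functional class
#'
#' Keeps variants with `maf <= maf_threshold` (inclusive, so a variant at
#' exactly the threshold is rare) and functional class in `class_set`.
#' Monomorphic variants (MAF 0) are excluded — they carry no minor alleles
#' and should have been removed by QC anyway.
#'
#' @param maf_table Tibble from [compute_maf()].
#' @param maf_threshold Upper MAF bound, default 0.01 (sensitivity analyses
#'   conventionally use 0.05).
#' @param class_set Character vector of functional classes; default the
#'   protein-altering set `stop_gain_loss`, `splice`, `missense`.
#' @return Character vector of selected variant ids (with a warning when
#'   empty).
#' @export
select_rare_variants <- function(maf_table, maf_threshold = 0.01,
                                 class_set = NONSYN_CLASSES) {
  stopifnot(maf_threshold > 0, maf_threshold <= 0.5)
  sel <- maf_table %>%
    filter(.data$maf <= maf_threshold, .data$maf > 0,
           .data$func_class %in% class_set) %>%
    pull("variant_id")
  if (length(sel) == 0) {
    warn(sprintf("no variants with MAF <= %g in classes {%s}",
                 maf_threshold, paste(class_set, collapse = ", ")))
  }
  sel
}

#' Compute per-individual rare-allele burden
#'
#' `burden_i` is the sum over the selected variants of sample *i*'s
#' minor-allele dosage. A missing call contributes 0 under policy `"zero"`,
#' or the variant's mean observed minor-allele dosage under
#' `"mean_impute"`.
#'
#' @param geno A post-QC [genotype_matrix()].
#' @param variant_ids Selection from [select_rare_variants()].
#' @param maf_table Tibble from [compute_maf()] (supplies minor-allele
#'   orientation); recomputed if omitted.
#' @param missing_policy `"zero"` (default) or `"mean_impute"`.
#' @return A tibble: `sample_id`, `burden`, with attribute
#'   `n_variants_used`.
#' @export
compute_burden <- function(geno, variant_ids, maf_table = compute_maf(geno),
                           missing_policy = c("zero", "mean_impute")) {
  missing_policy <- arg_match(missing_policy)
  idx <- match(variant_ids, geno$variants$variant_id)
  if (anyNA(idx)) abort("some selected variant ids are not in the matrix.")
  d <- geno$dosage[, idx, drop = FALSE]
  flip <- !maf_table$minor_is_a1[match(variant_ids, maf_table$variant_id)]
  if (any(flip)) d[, flip] <- 2L - d[, flip]
  d <- matrix(as.numeric(d), nrow = nrow(d), dimnames = dimnames(d))
  if (missing_policy == "zero") {
    d[is.na(d)] <- 0
  } else {
    means <- colMeans(d, na.rm = TRUE)
    miss <- which(is.na(d), arr.ind = TRUE)
    d[miss] <- means[miss[, 2]]
  }
  out <- tibble(sample_id = geno$samples$sample_id,
                burden = unname(rowSums(d)))
  attr(out, "n_variants_used") <- length(idx)
  attr(out, "missing_policy") <- missing_policy
  out
}

#' Compute the full burden table at one MAF threshold
#'
#' One column per requested class set: the combined protein-altering burden
#' (`burden_total`), each single class, and the all-classes-including-
#' synonymous burden, mirroring the usual report layout.
#'
#' @inheritParams compute_burden
#' @param maf_threshold Upper MAF bound.
#' @return A wide tibble: `sample_id`, `burden_total`,
#'   `burden_stop_gain_loss`, `burden_splice`, `burden_missense`,
#'   `burden_all_incl_synonymous`.
#' @export
burden_table <- function(geno, maf_threshold = 0.01,
                         maf_table = compute_maf(geno),
                         missing_policy = "zero") {
  sets <- list(
    burden_total = NONSYN_CLASSES,
    burden_stop_gain_loss = "stop_gain_loss",
    burden_splice = "splice",
    burden_missense = "missense",
    burden_all_incl_synonymous = c(NONSYN_CLASSES, "synonymous")
  )
  cols <- purrr::imap(sets, function(cls, nm) {
    ids <- withCallingHandlers(
      select_rare_variants(maf_table, maf_threshold, cls),
      warning = function(w) invokeRestart("muffleWarning")
    )
    if (length(ids) == 0) {
      return(setNames(tibble(rep(0, n_samples(geno))), nm))
    }
    b <- compute_burden(geno, ids, maf_table, missing_policy)
    setNames(b["burden"], nm)
  })
  bind_cols(tibble(sample_id = geno$samples$sample_id), cols)
}

#' Flag extreme burden outliers
#'
#' Single-pass rule: samples whose burden deviates from the cohort mean by
#' more than `n_sd` standard deviations (both computed once, on everyone)
#' are flagged for removal before association modelling. With the default
#' 4-s.d. rule a Gaussian burden distribution yields essentially no
#' removals, so only gross outliers are touched.
#'
#' @param burdens Tibble with `sample_id` and `burden` columns.
#' @param n_sd Deviation threshold in standard deviations; `Inf` disables.
#' @return A list: `kept` and `removed` (character vectors of sample ids),
#'   plus `rule` describing the threshold.
#' @export
remove_burden_outliers <- function(burdens, n_sd = 4) {
  if (nrow(burdens) < 10) abort("need at least 10 samples to judge outliers.")
  b <- burdens$burden
  out <- abs(b - mean(b)) > n_sd * sd(b)
  out[is.na(out)] <- FALSE
  n_removed <- sum(out)
  if (n_removed > 0) {
    inform(sprintf("removed %d burden outlier(s) beyond %g s.d.",
                   n_removed, n_sd))
  }
  list(
    kept = burdens$sample_id[!out],
    removed = burdens$sample_id[out],
    rule = sprintf("|burden - mean| > %g * sd, single pass", n_sd)
  )
}

#' Histogram of per-individual burden scores
#'
#' @param burdens Tibble with a `burden` column.
#' @param binwidth Histogram bin width.
#' @return A ggplot.
#' @export
plot_burden_distribution <- function(burdens, binwidth = NULL) {
  ggplot2::ggplot(burdens, ggplot2::aes(x = .data$burden)) +
    ggplot2::geom_histogram(binwidth = binwidth, bins = 40,
                            fill = "grey35", colour = "white") +
    ggplot2::labs(x = "rare-allele burden (minor-allele count)",
                  y = "individuals") +
    ggplot2::theme_minimal()
}
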