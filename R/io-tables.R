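#' Read a variant functional-annotation table
#'
#' Two tab-delimited columns with header: `variant_id`, `class`. Class
#' strings outside the recognised set (`stop_gain_loss`, `splice`,
#' `missense`, `synonymous`, `other`) map to `other` with a warning.
#'
#' @param path Annotation TSV path.
#' @return A tibble `variant_id`, `func_class`.
#' @export
read_annotation <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("variant_id", "class") %in% names(tab))) {
    abort(sprintf("%s: annotation needs columns variant_id, class", path))
  }
  unknown <- setdiff(unique(tab$class), FUNC_CLASSES)
  if (length(unknown)) {
    warn(paste0("unrecognised functional class mapped to 'other': ",
                paste(unknown, collapse = ", ")))
  }
  tab %>%
    mutate(func_class = ifelse(.data$class %in% FUNC_CLASSES,
                               .data$class, "other")) %>%
    select("variant_id", "func_class")
}

#' Attach functional classes to a genotype matrix
#'
#' Variants absent from the annotation keep (or get) class `other`.
#'
#' @param geno A [genotype_matrix()].
#' @param annotation Tibble from [read_annotation()].
#' @return The genotype matrix with `func_class` filled in.
#' @export
set_annotation <- function(geno, annotation) {
  idx <- match(geno$variants$variant_id, annotation$variant_id)
  cls <- annotation$func_class[idx]
  n_unannotated <- sum(is.na(idx))
  if (n_unannotated > 0) {
    inform(sprintf("%d variants without annotation assigned class 'other'",
                   n_unannotated))
  }
  geno$variants$func_class <- ifelse(is.na(cls), "other", cls)
  geno
}

#' Read a cohort phenotype table
#'
#' Requires columns `sample_id`, `sex`, `age_child`, `age_late`,
#' `mht_child`, `mht_late`, plus any number of `battery_*` columns. Moray
#' House Test scores must lie in \[0, 76\] (the instrument's scoring range);
#' out-of-range values are a validation error. When `sample_ids` is given,
#' rows are aligned to that order and samples present on only one side are
#' dropped with a message (cohorts routinely have slightly different n per
#' measure because of missing cognitive data).
#'
#' @param path Phenotype TSV path (tab-delimited, `.` = missing).
#' @param sample_ids Optional genotype sample order to align to.
#' @return A cohort tibble.
#' @export
read_phenotypes <- function(path, sample_ids = NULL) {
  tab <- readr::read_tsv(path, na = c(".", "NA", ""), progress = FALSE,
                         col_types = readr::cols(sample_id = "c", sex = "c",
                                                 .default = "d"))
  required <- c("sample_id", "sex", "age_child", "age_late",
                "mht_child", "mht_late")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    abort(sprintf("%s: missing required column(s): %s", path,
                  paste(missing_cols, collapse = ", ")))
  }
  for (col in c("mht_child", "mht_late")) {
    v <- tab[[col]]
    if (any(v < 0 | v > 76, na.rm = TRUE)) {
      abort(sprintf("%s: %s outside the Moray House Test range [0, 76]",
                    path, col))
    }
  }
  if (!is.null(sample_ids)) {
    n_pheno_only <- sum(!tab$sample_id %in% sample_ids)
    n_geno_only <- sum(!sample_ids %in% tab$sample_id)
    if (n_pheno_only + n_geno_only > 0) {
      inform(sprintf(
        "dropped %d phenotype-only and %d genotype-only samples on join",
        n_pheno_only, n_geno_only
      ))
    }
    tab <- tab[match(intersect(sample_ids, tab$sample_id), tab$sample_id), ]
  }
  tab
}
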