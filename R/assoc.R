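# Covariate-adjusted linear association of cognition on rare-allele burden:
# phenotype ~ mean-centred age + sex(female = 1) + burden, by ordinary
# least squares, with a threshold x class-set x phenotype sensitivity grid
# and Bonferroni correction over the grid's burden tests.

#' Ordinary least-squares fit on an explicit design matrix
#'
#' Thin wrapper around [stats::lm()]: coefficients by QR decomposition,
#' standard errors from sigma-hat^2 (X'X)^-1 with sigma-hat^2 =
#' RSS/(n - k), two-sided p-values from the t distribution on n - k
#' degrees of freedom. Rank deficiency is an error naming the collinear
#' columns rather than a silently dropped coefficient.
#'
#' @param y Response vector.
#' @param design Numeric n x k matrix including any intercept column.
#' @return A tibble: `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`; attributes `n`, `residuals`, `sigma`.
#' @examples
#' x <- rnorm(20)
#' fit_ols(2 * x + rnorm(20), cbind(intercept = 1, x = x))
#' @export
fit_ols <- function(y, design) {
  design <- as.matrix(design)
  if (is.null(colnames(design))) {
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  }
  n <- length(y)
  k <- ncol(design)
  if (nrow(design) != n) abort("`y` and `design` have different lengths.")
  if (n <= k) abort("need more observations than design columns.")
  qrd <- qr(design)
  if (qrd$rank < k) {
    dropped <- colnames(design)[qrd$pivot[(qrd$rank + 1):k]]
    abort(paste0("design matrix is rank deficient; collinear column(s): ",
                 paste(dropped, collapse = ", ")))
  }
  fit <- lm(y ~ 0 + design)
  sfit <- suppressWarnings(summary(fit))  # quiet on zero-residual fits
  sm <- sfit$coefficients
  out <- tibble(
    term = colnames(design),
    estimate = unname(sm[, "Estimate"]),
    std.error = unname(sm[, "Std. Error"]),
    statistic = unname(sm[, "t value"]),
    p.value = unname(sm[, "Pr(>|t|)"])
  )
  attr(out, "n") <- n
  attr(out, "residuals") <- unname(fit$residuals)
  attr(out, "sigma") <- sfit$sigma
  out
}

#' Fit one burden–cognition association model
#'
#' Design: intercept, age mean-centred *on the analysis subset*, sex coded
#' female = 1, and the burden score. Rows with a missing phenotype, age or
#' burden are dropped (complete cases per phenotype, so n can differ across
#' phenotypes).
#'
#' @param cohort Cohort tibble with `sample_id`, `sex`, an age column and
#'   the phenotype column.
#' @param burdens Tibble `sample_id`, `burden` (from [compute_burden()]).
#' @param phenotype Name of the phenotype column (e.g. `"mht_child"`,
#'   `"mht_late"`, `"g"`).
#' @param age_col Name of the age-at-testing column; defaults to
#'   `"age_child"` for childhood phenotypes and `"age_late"` otherwise.
#' @return An `assoc_result`: list with `phenotype`, `n`, `coefficients`
#'   (the [fit_ols()] tibble with terms `intercept`, `age`, `sex_female`,
#'   `burden`), and `diagnostics`.
#' @export
run_burden_model <- function(cohort, burdens, phenotype,
                             age_col = if (grepl("child", phenotype))
                               "age_child" else "age_late") {
  dat <- cohort %>%
    left_join(burdens, by = "sample_id") %>%
    select(all_of(c("sample_id", "sex", age_col, phenotype, "burden"))) %>%
    rename(age = all_of(age_col), y = all_of(phenotype)) %>%
    filter(!is.na(.data$y), !is.na(.data$age), !is.na(.data$burden),
           !is.na(.data$sex))
  if (nrow(dat) < 10) {
    abort(sprintf("only %d complete cases for %s; need at least 10.",
                  nrow(dat), phenotype))
  }
  design <- cbind(
    intercept = 1,
    age = dat$age - mean(dat$age),
    sex_female = as.numeric(dat$sex == "female"),
    burden = dat$burden
  )
  coefs <- fit_ols(dat$y, design)
  structure(
    list(
      phenotype = phenotype,
      n = nrow(dat),
      coefficients = coefs,
      diagnostics = diagnostics(coefs)
    ),
    class = "assoc_result"
  )
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("<assoc_result> %s ~ age + sex + burden (n = %d)\n",
              x$phenotype, x$n))
  print(as.data.frame(x$coefficients), digits = 3)
  invisible(x)
}

#' @rdname run_burden_model
#' @param x An `assoc_result`.
#' @param ... Unused.
#' @method tidy assoc_result
#' @export
tidy.assoc_result <- function(x, ...) x$coefficients

#' @rdname run_burden_model
#' @method glance assoc_result
#' @export
glance.assoc_result <- function(x, ...) {
  b <- x$coefficients %>% filter(.data$term == "burden")
  bind_cols(
    tibble(phenotype = x$phenotype, n = x$n,
           b_burden = b$estimate, se_burden = b$std.error,
           p_burden = b$p.value),
    x$diagnostics
  )
}

#' Numeric residual diagnostics for a fitted model
#'
#' Surrogates for the usual diagnostic plots: residual mean, residual
#' skewness, the maximum absolute standardized residual, and a flag when
#' that maximum exceeds 4.
#'
#' @param fit A [fit_ols()] result (carries residuals as an attribute).
#' @return A one-row tibble: `resid_mean`, `resid_skew`,
#'   `max_abs_std_resid`, `outlier_flag`.
#' @export
diagnostics <- function(fit) {
  r <- attr(fit, "residuals")
  s <- attr(fit, "sigma")
  # a numerically perfect fit has no residual scale, hence no outliers
  std <- if (s > sqrt(.Machine$double.eps)) r / s else r * 0
  skew <- if (sd(r) > 0) mean((r - mean(r))^3) / sd(r)^3 else 0
  tibble(
    resid_mean = mean(r),
    resid_skew = skew,
    max_abs_std_resid = max(abs(std)),
    outlier_flag = max(abs(std)) > 4
  )
}

#' Bonferroni family-wise correction
#'
#' `p_adj = min(1, m * p)`, order preserved; `m` defaults to the number of
#' p-values but is explicit in every report because the appropriate family
#' (one grid, one cohort, all tables) is an analysis choice.
#'
#' @param pvalues Numeric p-values.
#' @param m Family size; must be positive and at least `length(pvalues)`.
#' @return Adjusted p-values.
#' @examples
#' bonferroni(c(0.039, 0.011), m = 30)
#' @export
bonferroni <- function(pvalues, m = length(pvalues)) {
  if (m <= 0) abort("`m` must be positive.")
  if (m < length(pvalues)) {
    abort("`m` must be at least the number of p-values.")
  }
  p.adjust(pvalues, method = "bonferroni", n = m)
}

#' Run the full burden-association sensitivity grid
#'
#' Crosses MAF thresholds (default 0.01 and the less stringent 0.05) with
#' five class sets — the combined protein-altering burden, each of
#' stop-gain/loss, splice and missense alone, and all classes including
#' synonymous — and the three phenotypes (childhood MHT, late-life MHT,
#' late-life fluid g), giving 30 models by default. Burden outliers are
#' flagged once, on the combined-class burden at the primary (smallest)
#' threshold, and excluded from every model. Bonferroni correction over the
#' grid's burden p-values uses m = number of models run unless overridden.
#'
#' @param cohort Cohort tibble (must contain `g`, e.g. merged from
#'   [derive_fluid_g()] scores).
#' @param geno Post-QC [genotype_matrix()].
#' @param maf_thresholds Numeric thresholds; default `c(0.01, 0.05)`.
#' @param class_sets Named list of class vectors; default the five sets
#'   above.
#' @param phenotypes Phenotype columns; default
#'   `c("mht_child", "mht_late", "g")`.
#' @param missing_policy Burden missing-call policy, see [compute_burden()].
#' @param outlier_sd Burden-outlier rule in s.d. units (`Inf` disables).
#' @param m Bonferroni family size override; default the number of models.
#' @return An `assoc_grid`: tibble with one row per model (`phenotype`,
#'   `maf_threshold`, `class_set`, `n`, `n_variants`, per-term `b_*`,
#'   `se_*`, `p_*`, and `p_bonferroni` for the burden term), with
#'   attributes `m` and `outliers_removed`.
#' @export
run_model_grid <- function(cohort, geno,
                           maf_thresholds = c(0.01, 0.05),
                           class_sets = default_class_sets(),
                           phenotypes = c("mht_child", "mht_late", "g"),
                           missing_policy = "zero",
                           outlier_sd = 4,
                           m = NULL) {
  maf_tbl <- compute_maf(geno)

  primary <- compute_burden(
    geno,
    select_rare_variants(maf_tbl, min(maf_thresholds), NONSYN_CLASSES),
    maf_tbl, missing_policy
  )
  outliers <- remove_burden_outliers(primary, n_sd = outlier_sd)
  cohort <- cohort %>% filter(.data$sample_id %in% outliers$kept)

  grid <- tidyr::expand_grid(
    maf_threshold = maf_thresholds,
    class_set = names(class_sets),
    phenotype = phenotypes
  )
  rows <- purrr::pmap(grid, function(maf_threshold, class_set, phenotype) {
    ids <- withCallingHandlers(
      select_rare_variants(maf_tbl, maf_threshold, class_sets[[class_set]]),
      warning = function(w) invokeRestart("muffleWarning")
    )
    if (length(ids) == 0) {
      warn(sprintf("no variants for class set '%s' at MAF <= %g; model skipped",
                   class_set, maf_threshold))
      return(NULL)
    }
    burdens <- compute_burden(geno, ids, maf_tbl, missing_policy)
    res <- run_burden_model(cohort, burdens, phenotype)
    wide <- res$coefficients %>%
      mutate(term = dplyr::recode(.data$term, intercept = "intercept",
                                  sex_female = "sex")) %>%
      select("term", "estimate", "std.error", "p.value") %>%
      tidyr::pivot_wider(
        names_from = "term",
        values_from = c("estimate", "std.error", "p.value"),
        names_glue = "{c(estimate='b', std.error='se', p.value='p')[.value]}_{term}"
      )
    bind_cols(
      tibble(phenotype = phenotype, maf_threshold = maf_threshold,
             class_set = class_set, n = res$n,
             n_variants = length(ids)),
      wide
    )
  })
  out <- bind_rows(rows)
  m_used <- m %||% nrow(out)
  out$p_bonferroni <- bonferroni(out$p_burden, m = m_used)
  structure(out,
            class = c("assoc_grid", class(out)),
            m = m_used,
            outliers_removed = outliers$removed)
}

#' @rdname run_model_grid
#' @export
default_class_sets <- function() {
  list(
    combined = NONSYN_CLASSES,
    stop_gain_loss = "stop_gain_loss",
    splice = "splice",
    missense = "missense",
    all_incl_synonymous = c(NONSYN_CLASSES, "synonymous")
  )
}

#' Forest plot of burden coefficients across the sensitivity grid
#'
#' @param object An `assoc_grid`.
#' @param ... Unused.
#' @return A ggplot of burden estimates with 95% confidence intervals.
#' @method autoplot assoc_grid
#' @export
autoplot.assoc_grid <- function(object, ...) {
  dat <- as_tibble(object) %>%
    mutate(model = paste0(.data$phenotype, " | ", .data$class_set,
                          " | MAF<=", .data$maf_threshold))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$b_burden, y = .data$model)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$b_burden - 1.96 * .data$se_burden,
                   xmax = .data$b_burden + 1.96 * .data$se_burden)
    ) +
    ggplot2::labs(x = "burden coefficient (phenotype points per allele)",
                  y = NULL) +
    ggplot2::theme_minimal()
}
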