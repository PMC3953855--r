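#' Derive a standardized fluid cognitive factor from a test battery
#'
#' Classic first-principal-component composite: complete cases only, each
#' test z-scored (so extraction is on the correlation structure and is
#' invariant to test scaling), first component extracted, sign flipped when
#' the loading sum is negative so that higher scores mean better
#' performance, and the scores z-standardized (n - 1 divisor) to mean 0,
#' variance 1.
#'
#' @param battery A data frame with a `sample_id` column (optional) and at
#'   least 3 numeric test-score columns; rows with any missing test are
#'   dropped (complete-case analysis).
#' @param tests Character vector naming the test columns; default every
#'   numeric column except `sample_id`.
#' @return An object of class `gfactor`: list with `scores` (tibble
#'   `sample_id`, `g`), `loadings` (named numeric), `variance_explained`,
#'   `n_complete`.
#' @examples
#' sim <- simulate_cohort(sim_config(n_samples = 80, n_variants = 200))
#' gf <- derive_fluid_g(sim$cohort)
#' glance(gf)
#' @export
derive_fluid_g <- function(battery, tests = NULL) {
  battery <- as_tibble(battery)
  if (!"sample_id" %in% names(battery)) {
    battery$sample_id <- sprintf("S%05d", seq_len(nrow(battery)))
  }
  if (is.null(tests)) {
    tests <- grep("^battery_", names(battery), value = TRUE)
    if (length(tests) == 0) {
      tests <- names(battery)[vapply(battery, is.numeric, logical(1))]
      tests <- setdiff(tests, "sample_id")
    }
  }
  if (length(tests) < 3) {
    abort("need at least 3 battery tests to extract a factor.")
  }
  x <- as.matrix(battery[tests])
  complete <- complete.cases(x)
  if (sum(complete) < 10) {
    abort("need at least 10 complete cases to extract a factor.")
  }
  x <- x[complete, , drop = FALSE]
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("zero-variance test(s): ",
                 paste(tests[sds == 0], collapse = ", ")))
  }
  z <- scale(x)                           # z-scores with n - 1 divisor
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  loadings <- pc$rotation[, 1]
  scores <- pc$x[, 1]
  if (sum(loadings) < 0) {                # higher g = better performance
    loadings <- -loadings
    scores <- -scores
  }
  g <- as.numeric(scale(scores))          # mean 0, variance 1 (n - 1)
  structure(
    list(
      scores = tibble(sample_id = battery$sample_id[complete], g = g),
      loadings = loadings,
      variance_explained = pc$sdev[1]^2 / sum(pc$sdev^2),
      n_complete = sum(complete)
    ),
    class = "gfactor"
  )
}

#' @export
print.gfactor <- function(x, ...) {
  cat(sprintf(
    "<gfactor> first principal component of %d tests, %d complete cases\n",
    length(x$loadings), x$n_complete
  ))
  cat(sprintf("variance explained: %.1f%%\n", 100 * x$variance_explained))
  invisible(x)
}

#' @rdname derive_fluid_g
#' @param x A `gfactor`.
#' @param ... Unused.
#' @method tidy gfactor
#' @export
tidy.gfactor <- function(x, ...) {
  tibble(test = names(x$loadings), loading = unname(x$loadings))
}

#' @rdname derive_fluid_g
#' @method glance gfactor
#' @export
glance.gfactor <- function(x, ...) {
  tibble(
    n_tests = length(x$loadings),
    n_complete = x$n_complete,
    variance_explained = x$variance_explained
  )
}

#' @rdname derive_fluid_g
#' @param object A `gfactor`.
#' @param ... Unused.
#' @method autoplot gfactor
#' @export
autoplot.gfactor <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$test, y = .data$loading)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = "first-component loading",
                  title = sprintf("fluid g: %.0f%% of battery variance",
                                  100 * object$variance_explained)) +
    ggplot2::theme_minimal()
}

#' Write g-factor scores and loadings as TSV
#'
#' @param gfactor A `gfactor`.
#' @param scores_path,loadings_path Output paths; the loadings sidecar
#'   defaults next to the scores file.
#' @export
write_gfactor <- function(gfactor, scores_path,
                          loadings_path = sub("\\.tsv$", "_loadings.tsv",
                                              scores_path)) {
  readr::write_tsv(gfactor$scores, scores_path)
  readr::write_tsv(tidy(gfactor), loadings_path)
  invisible(scores_path)
}
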