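#' Month-by-year anomaly matrix for a regional series
#'
#' Arranges monthly anomalies into a 12 x n_years matrix (rows January to
#' December, columns years ascending). Only whole calendar years enter:
#' any year missing a month is dropped (and named in a message). Input row
#' order is irrelevant.
#'
#' @param anoms A `region_series` of anomalies, or any data frame with
#'   `year`, `month`, `value` columns for a single series.
#' @return A 12 x n numeric matrix with dimnames (month abbreviations,
#'   years).
#' @export
build_month_year_matrix <- function(anoms) {
  x <- as_tibble(anoms)[c("year", "month", "value")]
  complete_years <- x %>%
    group_by(.data$year) %>%
    summarise(ok = sum(!is.na(.data$value)) == 12, .groups = "drop")
  dropped <- complete_years$year[!complete_years$ok]
  if (length(dropped)) {
    rlang::inform(paste0(
      "dropping incomplete years: ", paste(dropped, collapse = ", ")
    ))
  }
  keep <- sort(complete_years$year[complete_years$ok])
  if (length(keep) < 2) {
    abort("need at least 2 complete calendar years for a month-by-year matrix")
  }
  x <- filter(x, .data$year %in% keep) %>% arrange(.data$year, .data$month)
  m <- matrix(x$value, nrow = 12, ncol = length(keep),
              dimnames = list(month.abb, keep))
  m
}

#' SVD mode decomposition of a month-by-year matrix
#'
#' Thin singular value decomposition of an anomaly matrix, applied directly
#' (no centering or standardization: anomalies are near-zero-mean by
#' construction; set `center = TRUE` to remove row means first). The
#' fraction of overall variance explained by mode *i* is
#' \eqn{R^2_i = s_i^2 / \sum_j s_j^2}. Because SVD sign is undefined, each
#' monthly vector is oriented so its April-June mean is >= 0 (ties broken
#' on the July-September mean), with year loadings flipped to match. Each
#' mode is labelled by its seasonal shape via [classify_mode()].
#'
#' @param m A 12 x n matrix from [build_month_year_matrix()], all entries
#'   finite.
#' @param center Subtract row (month) means before decomposing? Default
#'   `FALSE`.
#' @param theta Shape-classification threshold passed to [classify_mode()].
#' @return An object of class `mode_decomposition`: a list with
#'   `month_vectors` (12 x k, orthonormal columns), `year_loadings`
#'   (n x k, orthonormal columns), `singular_values`,
#'   `variance_fractions`, `shape_labels`, `years`, and `degenerate`
#'   (`TRUE` for an all-zero input, in which case fractions are `NA`).
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @export
svd_modes <- function(m, center = FALSE, theta = 0.05) {
  if (nrow(m) != 12) abort("matrix must have 12 rows (January..December)")
  if (any(!is.finite(m))) abort("matrix entries must be finite (drop incomplete years first)")
  if (center) m <- m - rowMeans(m)
  s <- svd(m)
  degenerate <- all(s$d == 0)
  # fixed orientation: Apr-Jun mean >= 0, ties broken on Jul-Sep mean
  for (j in seq_along(s$d)) {
    a <- mean(s$u[4:6, j])
    flip <- if (a != 0) a < 0 else mean(s$u[7:9, j]) < 0
    if (flip) {
      s$u[, j] <- -s$u[, j]
      s$v[, j] <- -s$v[, j]
    }
  }
  fractions <- if (degenerate) rep(NA_real_, length(s$d)) else s$d^2 / sum(s$d^2)
  structure(
    list(
      month_vectors = s$u,
      year_loadings = s$v,
      singular_values = s$d,
      variance_fractions = fractions,
      shape_labels = vapply(seq_along(s$d), function(j) {
        classify_mode(s$u[, j], theta = theta)
      }, character(1)),
      years = as.integer(colnames(m)),
      degenerate = degenerate
    ),
    class = "mode_decomposition"
  )
}

#' Classify a monthly mode vector as amplification- or compensation-like
#'
#' With `a` the April-June mean and `b` the July-September mean of a
#' unit-norm monthly vector: `"amplification"` when spring and summer agree
#' in sign (`a * b > 0`) and both are substantial
#' (`min(|a|, |b|) > theta`); `"compensation"` when they oppose
#' (`a * b < 0`) with both substantial; `"other"` otherwise.
#'
#' @param month_vector A numeric 12-vector (unit norm).
#' @param theta Magnitude threshold (default 0.05).
#' @return `"amplification"`, `"compensation"` or `"other"`.
#' @export
classify_mode <- function(month_vector, theta = 0.05) {
  a <- mean(month_vector[4:6])
  b <- mean(month_vector[7:9])
  if (a * b > 0 && min(abs(a), abs(b)) > theta) return("amplification")
  if (a * b < 0 && min(abs(a), abs(b)) > theta) return("compensation")
  "other"
}

#' @export
print.mode_decomposition <- function(x, ...) {
  cat(sprintf(
    "<mode_decomposition> %d modes over %d years%s\n",
    length(x$singular_values), length(x$years),
    if (x$degenerate) " (degenerate: zero matrix)" else ""
  ))
  print(glance(x))
  invisible(x)
}

#' Tidy a mode decomposition
#'
#' @param x A `mode_decomposition`.
#' @param ... Unused.
#' @return One row per (mode, month): `mode`, `singular_value`,
#'   `variance_fraction`, `label`, `month`, `weight`.
#' @export
tidy.mode_decomposition <- function(x, ...) {
  k <- length(x$singular_values)
  tidyr::expand_grid(mode = seq_len(k), month = 1:12) %>%
    mutate(
      singular_value = x$singular_values[.data$mode],
      variance_fraction = x$variance_fractions[.data$mode],
      label = x$shape_labels[.data$mode],
      weight = x$month_vectors[cbind(.data$month, .data$mode)]
    ) %>%
    select("mode", "singular_value", "variance_fraction", "label",
           "month", "weight")
}

#' @rdname tidy.mode_decomposition
#' @return `glance()`: one row per mode without the monthly weights.
#' @export
glance.mode_decomposition <- function(x, ...) {
  tibble(
    mode = seq_along(x$singular_values),
    singular_value = x$singular_values,
    variance_fraction = x$variance_fractions,
    label = x$shape_labels
  )
}
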