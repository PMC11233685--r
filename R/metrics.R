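#' Accuracy metrics for measured vs. reference phenotypes
#'
#' The evaluation statistics used throughout: root mean square error, mean
#' absolute percentage error (with the *measured* value in the denominator —
#' the convention of the source field protocol — and an optional conventional
#' truth-denominator variant), the squared Pearson correlation, and the mean
#' absolute error.
#'
#' @param x_m Measured values (meters), one per plant.
#' @param x_a Reference ("actual"/manual) values, same length.
#' @return `rmse`, `mae` in the input units; `mape` in percent; `r_squared`
#'   dimensionless in `[0, 1]`.
#' @name metrics
NULL

check_pair <- function(x_m, x_a) {
  if (length(x_m) != length(x_a))
    stop(sprintf("length mismatch: %d measured vs %d reference values",
                 length(x_m), length(x_a)))
  if (anyNA(x_m) || anyNA(x_a)) stop("metrics require complete (non-NA) pairs")
}

#' @rdname metrics
#' @export
rmse <- function(x_m, x_a) {
  check_pair(x_m, x_a)
  if (!length(x_m)) stop("rmse requires at least one pair")
  sqrt(mean((x_m - x_a)^2))
}

#' @rdname metrics
#' @param denominator `"measured"` (the printed convention) or `"reference"`.
#' @export
mape <- function(x_m, x_a, denominator = c("measured", "reference")) {
  check_pair(x_m, x_a)
  denominator <- match.arg(denominator)
  den <- if (denominator == "measured") x_m else x_a
  zero <- which(den == 0)
  if (length(zero))
    stop("zero ", denominator, " value at position ", zero[1],
         "; MAPE undefined")
  mean(abs(x_m - x_a) / abs(den)) * 100
}

#' @rdname metrics
#' @export
r_squared <- function(x_m, x_a) {
  check_pair(x_m, x_a)
  if (length(x_m) < 2) stop("r_squared requires at least 2 pairs")
  vm <- stats::var(x_m); va <- stats::var(x_a)
  if (vm == 0 || va == 0) return(NA_real_)
  stats::cov(x_m, x_a)^2 / (vm * va)
}

#' @rdname metrics
#' @export
mae <- function(x_m, x_a) {
  check_pair(x_m, x_a)
  if (!length(x_m)) stop("mae requires at least one pair")
  mean(abs(x_m - x_a))
}

#' Summarize measured vs. true phenotypes
#'
#' @param x_m,x_a Paired vectors; NAs in `x_m` (flagged plants) are excluded
#'   and counted.
#' @return One-row data.frame with n, n_excluded, rmse, mae, mape (both
#'   denominators) and r_squared.
#' @export
metric_summary <- function(x_m, x_a) {
  ok <- !is.na(x_m) & !is.na(x_a)
  data.frame(n = sum(ok), n_excluded = sum(!ok),
             rmse = if (any(ok)) rmse(x_m[ok], x_a[ok]) else NA_real_,
             mae = if (any(ok)) mae(x_m[ok], x_a[ok]) else NA_real_,
             mape = if (any(ok)) mape(x_m[ok], x_a[ok]) else NA_real_,
             mape_ref_denom = if (any(ok)) mape(x_m[ok], x_a[ok], "reference") else NA_real_,
             r_squared = if (sum(ok) >= 2) r_squared(x_m[ok], x_a[ok]) else NA_real_)
}
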