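#' Fit an equal-width discretization scheme
#'
#' Each metric's training range `[min, max]` is split into `n_bins`
#' equal-width bins; the representative value of a bin is its midpoint.
#' Bins are half-open `[lo, hi)` with the last bin closed; values outside
#' the training range clip to the extreme bins. A constant-valued metric
#' collapses to a single degenerate bin (with a warning).
#'
#' @param data Tibble or matrix containing the metric columns.
#' @param cols Character vector of metric column names; defaults to columns
#'   named `metric_*`, or all numeric columns when none match.
#' @param n_bins Number of bins per metric.
#' @return A list of class `ir_discretizer` with per-metric `lo`, `width`,
#'   bin edges and representatives.
#' @export
fit_discretizer <- function(data, cols = NULL, n_bins = 20) {
  m <- metric_matrix(data, cols)
  if (nrow(m) < 2) stop("need at least two rows to fit a discretizer")
  n_bins <- as.integer(n_bins)
  stopifnot(n_bins >= 1)
  lo <- apply(m, 2, min)
  hi <- apply(m, 2, max)
  degenerate <- hi <= lo
  if (any(degenerate))
    warning(sprintf("constant-valued metric(s) collapse to one bin: %s",
                    paste(colnames(m)[degenerate], collapse = ", ")))
  width <- ifelse(degenerate, 1, (hi - lo) / n_bins)
  structure(list(metrics = colnames(m), lo = lo, hi = hi, width = width,
                 n_bins = n_bins, degenerate = degenerate),
            class = "ir_discretizer")
}

#' @exportS3Method base::print
print.ir_discretizer <- function(x, ...) {
  cat(sprintf("<ir_discretizer> %d metrics x %d equal-width bins\n",
              length(x$metrics), x$n_bins))
  invisible(x)
}

#' Bin representative values of a fitted discretizer
#' @param scheme An `ir_discretizer`.
#' @param metric Metric name.
#' @return Numeric vector of `n_bins` midpoints.
#' @export
bin_representatives <- function(scheme, metric) {
  i <- match(metric, scheme$metrics)
  if (is.na(i)) stop("unknown metric: ", metric)
  scheme$lo[i] + (seq_len(scheme$n_bins) - 0.5) * scheme$width[i]
}

#' Discretize metric values with a fitted scheme
#'
#' @param data Tibble or matrix with the scheme's metric columns (extra
#'   non-metric columns are carried through unchanged).
#' @param scheme An [fit_discretizer()] result.
#' @return Same shape as `data` with metric columns replaced by integer bin
#'   indices in `0..n_bins-1`.
#' @export
discretize <- function(data, scheme) {
  stopifnot(inherits(scheme, "ir_discretizer"))
  if (is.matrix(data)) {
    if (!all(scheme$metrics %in% colnames(data)))
      stop("data is missing metric columns required by the scheme")
    out <- data
    for (j in seq_along(scheme$metrics)) {
      nm <- scheme$metrics[j]
      out[, nm] <- bin_values(data[, nm], scheme$lo[j], scheme$width[j],
                              scheme$n_bins, scheme$degenerate[j])
    }
    return(out)
  }
  if (!all(scheme$metrics %in% names(data)))
    stop("data is missing metric columns required by the scheme")
  out <- data
  for (j in seq_along(scheme$metrics)) {
    nm <- scheme$metrics[j]
    out[[nm]] <- bin_values(data[[nm]], scheme$lo[j], scheme$width[j],
                            scheme$n_bins, scheme$degenerate[j])
  }
  out
}

bin_values <- function(x, lo, width, n_bins, degenerate = FALSE) {
  if (degenerate) return(rep(0L, length(x)))
  b <- floor((x - lo) / width)
  as.integer(pmin(pmax(b, 0), n_bins - 1))
}

# Extract the metric submatrix from a tibble/matrix; default metric columns
# are those named metric_* (fallback: all numeric columns).
metric_matrix <- function(data, cols = NULL) {
  if (is.matrix(data)) {
    if (is.null(colnames(data)))
      colnames(data) <- sprintf("metric_%d", seq_len(ncol(data)))
    return(data)
  }
  if (is.null(cols)) {
    nms <- grep("^metric_", names(data), value = TRUE)
    if (length(nms) == 0)
      nms <- names(data)[vapply(data, is.numeric, logical(1)) &
                           !names(data) %in% c("x", "y")]
  } else {
    nms <- cols
    missing <- setdiff(nms, names(data))
    if (length(missing))
      stop("unknown metric columns: ", paste(missing, collapse = ", "))
  }
  if (length(nms) == 0) stop("no metric columns found")
  as.matrix(data[, nms, drop = FALSE])
}
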