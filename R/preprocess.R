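#' Filter features by a standard-deviation quantile
#'
#' Keeps the most variable features: columns whose sample standard deviation
#' is at least the q-quantile (linear-interpolation quantile) of all column
#' SDs. Ties at the threshold are kept, so a maximal-variance feature is
#' never silently dropped, and `q = 0` keeps everything. Column order is
#' preserved.
#'
#' @param X numeric matrix with at least 2 rows.
#' @param q quantile cut in [0, 1).
#' @return list with elements `X` (the filtered matrix) and `report`, a
#'   `FilterReport` list carrying `p_in`, `p_out`, `sd_threshold`, `q` and
#'   `kept_ids`.
#' @examples
#' X <- sapply(1:10, function(s) rnorm(20, sd = s))
#' out <- filterBySdQuantile(X, 0.5)
#' out$report$p_out
#' @export
filterBySdQuantile <- function(X, q) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("X must have at least 2 rows")
  if (q < 0 || q >= 1) stop("q must lie in [0, 1)")
  sds <- apply(X, 2L, stats::sd)
  thr <- unname(stats::quantile(sds, probs = q))
  keep <- sds >= thr
  ids <- if (!is.null(colnames(X))) colnames(X) else paste0("V", seq_len(ncol(X)))
  report <- structure(
    list(p_in = ncol(X), p_out = sum(keep), sd_threshold = thr, q = q,
         kept_ids = ids[keep]),
    class = "FilterReport")
  list(X = X[, keep, drop = FALSE], report = report)
}

#' @export
print.FilterReport <- function(x, ...) {
  cat(sprintf("FilterReport: kept %d of %d features (SD >= %.4g at q = %g)\n",
              x$p_out, x$p_in, x$sd_threshold, x$q))
  invisible(x)
}

#' Center and scale the columns of a feature matrix
#'
#' Columns are centered to mean 0 and scaled to sample standard deviation 1
#' (n - 1 denominator). Idempotent. The whole supplied matrix is used; no
#' train/test split is involved.
#'
#' @param X numeric matrix; every column must have positive SD.
#' @return matrix of the same dimensions with standardized columns.
#' @examples
#' standardizeFeatures(cbind(a = c(1, 2, 3)))
#' @export
standardizeFeatures <- function(X) {
  X <- as.matrix(X)
  if (!ncol(X)) return(X)
  sds <- apply(X, 2L, stats::sd)
  if (any(bad <- !(sds > 0))) {
    ids <- if (!is.null(colnames(X))) colnames(X) else paste0("V", seq_len(ncol(X)))
    stop("constant column(s) cannot be standardized: ",
         paste(ids[bad], collapse = ", "))
  }
  out <- scale(X, center = TRUE, scale = sds)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}
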