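## Functional-connectivity feature extraction: Pearson correlation between
## regional time series, vectorized over the upper triangle.

#' Compute a functional-connectivity matrix from ROI time series
#'
#' Pearson correlation between every pair of ROI time series. With the cc200
#' parcellation this yields the classic 200 x 200 connectivity matrix.
#'
#' @param ts numeric matrix, T time points x R regions (T >= 3), or an
#'   object returned by [read_timeseries()].
#' @param on_constant policy for zero-variance columns: `"fail"` (default)
#'   or `"zero"` (off-diagonals of the constant ROI set to 0, with warning).
#' @return R x R symmetric correlation matrix with unit diagonal.
#' @export
compute_fc <- function(ts, on_constant = c("fail", "zero")) {
  on_constant <- match.arg(on_constant)
  ts <- as.matrix(ts)
  storage.mode(ts) <- "double"
  fail_if(nrow(ts) < 3, "need at least 3 time points, got %d", nrow(ts))
  sds <- apply(ts, 2, stats::sd)
  const <- which(sds == 0 | !is.finite(sds))
  if (length(const) && on_constant == "fail") {
    stop(sprintf("constant ROI time series in column(s) %s",
                 paste(const, collapse = ", ")), call. = FALSE)
  }
  fc <- suppressWarnings(stats::cor(ts))
  if (length(const)) {
    warning(sprintf("constant ROI column(s) %s: off-diagonal FC set to 0",
                    paste(const, collapse = ", ")))
    fc[const, ] <- 0
    fc[, const] <- 0
  }
  diag(fc) <- 1
  ## clamp tiny numerical excursions
  fc[fc > 1] <- 1
  fc[fc < -1] <- -1
  fc
}

#' Vectorize the upper triangle of an FC matrix
#'
#' Row-major over 0-based pairs (i, j) with i < j; flat index
#' `i*R - i(i+1)/2 + (j - i - 1)`. For R = 200 the vector has 19,900
#' entries. The ordering is fixed so importance scores map back to ROI
#' pairs unambiguously.
#'
#' @param fcm symmetric R x R matrix.
#' @param tol asymmetry tolerance.
#' @return numeric vector of length R(R-1)/2 with attribute `n_roi`.
#' @export
vectorize_upper <- function(fcm, tol = 1e-8) {
  fcm <- as.matrix(fcm)
  fail_if(nrow(fcm) != ncol(fcm), "FC matrix must be square")
  fail_if(max(abs(fcm - t(fcm))) > tol,
          "FC matrix asymmetric beyond tolerance %g", tol)
  v <- t(fcm)[lower.tri(fcm)] # row-major upper triangle
  structure(as.numeric(v), n_roi = nrow(fcm))
}

#' Rebuild a symmetric unit-diagonal matrix from an upper-triangle vector
#'
#' Inverse of [vectorize_upper()].
#'
#' @param v vector of length R(R-1)/2.
#' @param r region count; inferred from `length(v)` when missing.
#' @param diag_value diagonal fill (1 for correlation matrices).
#' @return R x R symmetric matrix.
#' @export
devectorize_upper <- function(v, r = NULL, diag_value = 1) {
  if (is.null(r)) r <- n_roi_from_length(length(v))
  fail_if(length(v) != r * (r - 1) / 2,
          "vector length %d inconsistent with r = %d", length(v), r)
  m <- matrix(0, r, r)
  m[lower.tri(m)] <- v
  m <- t(m)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- diag_value
  m
}

## Solve R(R-1)/2 = len for integer R.
n_roi_from_length <- function(len) {
  r <- (1 + sqrt(1 + 8 * len)) / 2
  fail_if(abs(r - round(r)) > 1e-9,
          "length %d is not R(R-1)/2 for any integer R", len)
  as.integer(round(r))
}

#' Flat feature index of an ROI pair (and back)
#'
#' 0-based indices; `i < j`. `pair_to_index` implements
#' `i*R - i(i+1)/2 + (j - i - 1)`; `index_to_pair` inverts it.
#'
#' @param i,j 0-based ROI indices, i < j.
#' @param r region count.
#' @param idx 0-based flat feature index.
#' @return `pair_to_index`: 0-based flat index. `index_to_pair`: two-column
#'   matrix of 0-based (i, j).
#' @export
pair_to_index <- function(i, j, r) {
  fail_if(any(i >= j), "require i < j (0-based)")
  fail_if(any(j >= r) || any(i < 0), "ROI index out of range for r = %d", r)
  i * r - i * (i + 1) / 2 + (j - i - 1)
}

#' @rdname pair_to_index
#' @export
index_to_pair <- function(idx, r) {
  fail_if(any(idx < 0) || any(idx >= r * (r - 1) / 2),
          "feature index out of range for r = %d", r)
  ## row i is the largest i with offset(i) <= idx, offset(i) = i*r - i(i+1)/2
  out <- matrix(0L, length(idx), 2, dimnames = list(NULL, c("i", "j")))
  for (k in seq_along(idx)) {
    x <- idx[k]
    i <- 0L
    while (x >= (r - i - 1)) {
      x <- x - (r - i - 1)
      i <- i + 1L
    }
    out[k, ] <- c(i, i + 1L + x)
  }
  out
}

#' Fisher z-transform of a correlation and its inverse
#'
#' `fisher_z` is atanh; `inverse_fisher_z` is tanh. Used by the cohort
#' simulator, which composes class, site, and noise effects in z-space so
#' that back-transformed FC stays strictly inside (-1, 1).
#'
#' @param r correlations with |r| < 1.
#' @param z Fisher-z values.
#' @return transformed numeric vector.
#' @export
fisher_z <- function(r) {
  fail_if(any(abs(r) >= 1), "|r| must be < 1 for the Fisher transform")
  atanh(r)
}

#' @rdname fisher_z
#' @export
inverse_fisher_z <- function(z) tanh(z)

#' Read / write ROI time series (TSV, T rows x R columns)
#'
#' Optional single header row of ROI labels.
#'
#' @param path file path.
#' @param header logical; does the file carry ROI labels?
#' @return numeric matrix with optional `roi_labels` attribute.
#' @export
read_timeseries <- function(path, header = FALSE) {
  fail_if(!file.exists(path), "file not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = header,
                          check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (header) attr(m, "roi_labels") <- colnames(df)
  dimnames(m) <- NULL
  m
}

#' @rdname read_timeseries
#' @param ts matrix to write.
#' @export
write_timeseries <- function(ts, path, header = FALSE) {
  utils::write.table(ts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = isTRUE(header))
  invisible(path)
}

#' Read / write subject-by-feature FC matrices (TSV, subject_id first column)
#'
#' @param path file path.
#' @return numeric matrix with subject ids as rownames.
#' @export
read_fc_matrix <- function(path) {
  fail_if(!file.exists(path), "file not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character")
  fail_if(names(df)[1] != "subject_id",
          "first column must be subject_id, got '%s'", names(df)[1])
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' @rdname read_fc_matrix
#' @param x numeric matrix, rownames are subject ids.
#' @export
write_fc_matrix <- function(x, path) {
  fail_if(is.null(rownames(x)), "feature matrix must carry subject ids")
  df <- data.frame(subject_id = rownames(x), x, check.names = FALSE)
  colnames(df) <- c("subject_id",
                    if (is.null(colnames(x)))
                      paste0("f", seq_len(ncol(x)) - 1L) else colnames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
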