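## Weight-based feature importance from the first encoding layer, a
## retraining permutation null, percent p-values, FDR selection, and the
## mapping of significant features back to ROI pairs.

#' Feature-importance scores from first-layer weight checkpoints
#'
#' For each input feature j, the mean over recorded training checkpoints
#' of the aggregated absolute outgoing weight into the first encoding
#' layer (mean |w| by default, L2 norm by flag).
#'
#' @param checkpoints list of first-layer weight matrices
#'   (input_dim x enc1_dim), e.g. `fit$checkpoints` from
#'   [train_vae_mmd()], or a list of full parameter lists (the `W_e1`
#'   input rows are used).
#' @param input_dim input feature count (required when full parameter
#'   lists are given).
#' @param aggregate `"mean_abs"` (default) or `"l2"` across hidden units.
#' @return non-negative score vector of length input_dim.
#' @export
feature_scores <- function(checkpoints, input_dim = NULL,
                           aggregate = c("mean_abs", "l2")) {
  aggregate <- match.arg(aggregate)
  fail_if(length(checkpoints) == 0, "need >= 1 checkpoint")
  mats <- lapply(checkpoints, function(ck) {
    if (is.list(ck) && !is.null(ck$W_e1)) {
      fail_if(is.null(input_dim),
              "input_dim required with full parameter checkpoints")
      ck$W_e1[seq_len(input_dim), , drop = FALSE]
    } else as.matrix(ck)
  })
  dims <- unique(lapply(mats, dim))
  fail_if(length(dims) != 1, "inconsistent checkpoint shapes")
  per_ck <- sapply(mats, function(w) {
    if (aggregate == "mean_abs") rowMeans(abs(w)) else sqrt(rowSums(w^2))
  })
  if (is.null(dim(per_ck))) per_ck <- matrix(per_ck, nrow = 1)
  rowMeans(per_ck)
}

#' Permutation null distribution of importance scores
#'
#' For each permutation a seeded global shuffle of the input feature order
#' is applied (the same permutation to every subject), the model is
#' retrained under identical settings by `train_fn`, and the resulting
#' score vector recorded. A failed retraining is resampled (at most 3
#' retries) and noted.
#'
#' @param train_fn function(features) returning a score vector of length
#'   `ncol(features)`; it must encapsulate the full training + scoring
#'   pipeline under fixed settings.
#' @param features subjects x features training matrix.
#' @param n_perm number of permutations (the full-scale default in this
#'   line of work is 1,000; use fewer at reduced dimensions).
#' @param seed RNG seed; permutation p is drawn from `seed + p`.
#' @return n_perm x input_dim matrix of null scores, with the permutations
#'   used as attribute `permutations`.
#' @export
permutation_null <- function(train_fn, features, n_perm, seed = 1L) {
  fail_if(n_perm < 1, "n_perm must be >= 1")
  x <- as.matrix(features)
  p <- ncol(x)
  null <- matrix(NA_real_, n_perm, p)
  perms <- matrix(NA_integer_, n_perm, p)
  for (b in seq_len(n_perm)) {
    for (attempt in 1:4) {
      perm <- with_seed(seed + b * 1000L + attempt - 1L, sample.int(p))
      res <- tryCatch(train_fn(x[, perm, drop = FALSE]),
                      error = function(e) e)
      if (!inherits(res, "error")) break
      if (attempt == 4)
        stop(sprintf("permutation %d failed after 3 retries: %s",
                     b, conditionMessage(res)), call. = FALSE)
      message(sprintf("permutation %d attempt %d failed (%s); resampling",
                      b, attempt, conditionMessage(res)))
    }
    null[b, ] <- res
    perms[b, ] <- perm
  }
  structure(null, permutations = perms)
}

#' Percent p-values against a permutation null
#'
#' `p_j = 100 * #(null_j > observed_j) / n_perm` (strictly greater). The
#' smoothed policy `(count + 1) / (n_perm + 1)` avoids exact zeros and is
#' flagged in the result's `policy` attribute.
#'
#' @param observed score vector.
#' @param null n_perm x length(observed) null matrix.
#' @param policy `"strict"` (the plain permutation count) or `"add_one"`.
#' @return percent p-values in [0, 100].
#' @export
p_values <- function(observed, null, policy = c("strict", "add_one")) {
  policy <- match.arg(policy)
  null <- as.matrix(null)
  fail_if(ncol(null) != length(observed),
          "null has %d columns but observed has length %d",
          ncol(null), length(observed))
  greater <- colSums(null > rep(observed, each = nrow(null)))
  p <- if (policy == "strict") 100 * greater / nrow(null)
       else 100 * (greater + 1) / (nrow(null) + 1)
  structure(p, policy = policy)
}

#' FDR feature selection (Benjamini-Hochberg step-up)
#'
#' @param p percent p-values in [0, 100] (as produced by [p_values()]).
#' @param q FDR level (default 0.05).
#' @return logical mask of selected features.
#' @export
fdr_select <- function(p, q = 0.05) {
  fail_if(any(p < 0 | p > 100), "p-values must be percentages in [0, 100]")
  stats::p.adjust(p / 100, method = "BH") <= q
}

#' Map feature scores back to ROI pairs
#'
#' Inverts the flat upper-triangle ordering (0-based row-major, i < j) to
#' an edge list suitable for connectome viewers.
#'
#' @param scores score vector of length r(r-1)/2.
#' @param r region count; inferred when missing.
#' @param p optional percent p-values.
#' @param significant optional logical mask.
#' @return data.frame: roi_i, roi_j (0-based), score, and if given
#'   p_percent and significant.
#' @export
map_to_roi_pairs <- function(scores, r = NULL, p = NULL,
                             significant = NULL) {
  if (is.null(r)) r <- n_roi_from_length(length(scores))
  fail_if(length(scores) != r * (r - 1) / 2,
          "score length %d inconsistent with r = %d", length(scores), r)
  pairs <- index_to_pair(seq_along(scores) - 1L, r)
  out <- data.frame(roi_i = pairs[, "i"], roi_j = pairs[, "j"],
                    score = as.numeric(scores))
  if (!is.null(p)) out$p_percent <- as.numeric(p)
  if (!is.null(significant)) out$significant <- as.logical(significant)
  out
}

#' Write an importance edge list as TSV
#'
#' Header lines document the 0-based flat-index formula so external tools
#' can reproduce the ordering.
#'
#' @param edges data.frame from [map_to_roi_pairs()].
#' @param path output path.
#' @export
write_edge_list <- function(edges, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# fcadapt importance edge list",
               "# 0-based ROI indices; flat index = i*R - i*(i+1)/2 + (j-i-1), i < j"),
             con)
  utils::write.table(edges, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
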