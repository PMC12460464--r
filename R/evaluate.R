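## Evaluation: accuracy, per-class precision/recall/F1 (macro and micro),
## confusion matrix, Gaussian KL divergence between latent sample sets,
## and a deterministic t-SNE embedding export.

#' Classification metrics
#'
#' Accuracy, per-class precision/recall/F1 with
#' `F1 = 2 * Precision * Recall / (Precision + Recall)`, macro F1
#' (unweighted mean over classes, robust to class imbalance), micro F1,
#' and the confusion matrix. Division by zero yields 0 with a
#' `zero_division` flag.
#'
#' @param y_true,y_pred label vectors of equal positive length.
#' @param classes class set fixing row/column order; defaults to the
#'   sorted union of observed labels.
#' @return a `metrics_report` list: `accuracy`, `per_class` (data.frame of
#'   precision/recall/f1/support), `macro_f1`, `micro_f1`, `confusion`,
#'   `zero_division`.
#' @export
score_predictions <- function(y_true, y_pred, classes = NULL) {
  fail_if(length(y_true) == 0, "empty input")
  fail_if(length(y_true) != length(y_pred),
          "y_true and y_pred lengths differ (%d vs %d)",
          length(y_true), length(y_pred))
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (is.null(classes)) classes <- sort(unique(c(y_true, y_pred)))
  conf <- table(factor(y_true, classes), factor(y_pred, classes))
  conf <- matrix(as.integer(conf), nrow(conf),
                 dimnames = list(true = classes, pred = classes))
  tp <- diag(conf)
  support <- rowSums(conf)
  predn <- colSums(conf)
  zero_division <- FALSE
  safe_div <- function(a, b) {
    if (any(b == 0)) zero_division <<- TRUE
    ifelse(b == 0, 0, a / ifelse(b == 0, 1, b))
  }
  precision <- safe_div(tp, predn)
  recall <- safe_div(tp, support)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  per_class <- data.frame(class = classes, precision = precision,
                          recall = recall, f1 = f1,
                          support = as.integer(support),
                          row.names = NULL)
  acc <- sum(tp) / sum(conf)
  structure(list(accuracy = acc, per_class = per_class,
                 macro_f1 = mean(f1), micro_f1 = acc, confusion = conf,
                 zero_division = zero_division),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy: %.4f  macro F1: %.4f\n", x$accuracy, x$macro_f1))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Write a metrics report as JSON
#'
#' Schema: accuracy, macro_f1, micro_f1, per_class (precision/recall/f1/
#' support by label), confusion, seed.
#'
#' @param report a `metrics_report`.
#' @param path output path.
#' @param seed seed recorded alongside the metrics.
#' @export
write_metrics <- function(report, path, seed = NA_integer_) {
  per_class <- stats::setNames(
    lapply(seq_len(nrow(report$per_class)), function(i)
      as.list(report$per_class[i, c("precision", "recall", "f1",
                                    "support")])),
    report$per_class$class)
  jsonlite::write_json(list(accuracy = report$accuracy,
                            macro_f1 = report$macro_f1,
                            micro_f1 = report$micro_f1,
                            per_class = per_class,
                            confusion = report$confusion, seed = seed),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Gaussian KL divergence between two latent sample sets
#'
#' Fits diagonal Gaussians to each set by moments and evaluates the
#' closed-form KL(A || B) summed over dimensions. Asymmetric by
#' construction. Degenerate per-dimension variances are floored at 1e-8
#' with a warning.
#'
#' @param latent_A,latent_B numeric matrices (rows = samples) or vectors;
#'   each needs >= 2 samples.
#' @param var_floor variance floor.
#' @return non-negative scalar.
#' @export
gaussian_kl <- function(latent_A, latent_B, var_floor = 1e-8) {
  if (is.vector(latent_A)) latent_A <- matrix(latent_A, ncol = 1)
  if (is.vector(latent_B)) latent_B <- matrix(latent_B, ncol = 1)
  fail_if(nrow(latent_A) < 2 || nrow(latent_B) < 2,
          "need >= 2 samples per set")
  mu_a <- colMeans(latent_A); mu_b <- colMeans(latent_B)
  va <- apply(latent_A, 2, stats::var)
  vb <- apply(latent_B, 2, stats::var)
  if (any(va < var_floor) || any(vb < var_floor)) {
    warning("degenerate per-dimension variance floored at ", var_floor)
    va <- pmax(va, var_floor); vb <- pmax(vb, var_floor)
  }
  sum(0.5 * log(vb / va) + (va + (mu_a - mu_b)^2) / (2 * vb) - 0.5)
}

#' t-SNE embedding of features or latent representations
#'
#' Exact (quadratic-cost) t-SNE: per-point bandwidths calibrated to the
#' target perplexity by bisection, early exaggeration, momentum gradient
#' descent. Deterministic given `seed`.
#'
#' @param features numeric matrix (rows = subjects).
#' @param seed RNG seed for the initial layout.
#' @param perplexity target perplexity; requires `nrow > 3 * perplexity`.
#' @param n_iter gradient-descent iterations.
#' @param labels optional data.frame (e.g. subject_id, domain, diagnosis)
#'   carried alongside the coordinates.
#' @param path optional TSV export path (subject_id, dim1, dim2 plus label
#'   columns).
#' @return n x 2 coordinate matrix (invisibly writes `path` if given).
#' @export
tsne_embed <- function(features, seed = 1L, perplexity = 30,
                       n_iter = 500L, labels = NULL, path = NULL) {
  x <- as.matrix(features)
  fail_if(nrow(x) <= 3 * perplexity,
          "too few samples (%d) for perplexity %g", nrow(x), perplexity)
  y <- with_seed(seed, tsne_exact(x, perplexity, n_iter))
  colnames(y) <- c("dim1", "dim2")
  if (!is.null(path)) {
    df <- data.frame(subject_id = if (!is.null(rownames(x))) rownames(x)
                     else sprintf("s%04d", seq_len(nrow(x))),
                     dim1 = y[, 1], dim2 = y[, 2])
    if (!is.null(labels)) df <- cbind(df, labels)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  y
}

## Exact t-SNE core. Standard settings: early exaggeration 12 for the
## first quarter of iterations, learning rate 200, momentum 0.5 -> 0.8.
tsne_exact <- function(x, perplexity, n_iter) {
  n <- nrow(x)
  P <- tsne_input_probs(x, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  gain <- matrix(1, n, 2); inc <- matrix(0, n, 2)
  eta <- 200; exag_until <- max(50L, n_iter %/% 4L)
  for (it in seq_len(n_iter)) {
    Pe <- if (it <= exag_until) P * 12 else P
    d2 <- sq_dists(y, y)
    num <- 1 / (1 + d2); diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% y
    mom <- if (it < 250) 0.5 else 0.8
    gain <- ifelse(sign(grad) != sign(inc), gain + 0.2, gain * 0.8)
    gain[gain < 0.01] <- 0.01
    inc <- mom * inc - eta * gain * grad
    y <- y + inc
    y <- sweep(y, 2, colMeans(y))
  }
  y
}

## Row-conditional probabilities at the target perplexity (bisection on
## the Gaussian precision).
tsne_input_probs <- function(x, perplexity, tol = 1e-5, max_iter = 50L) {
  n <- nrow(x)
  d2 <- sq_dists(x, x)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    beta <- 1; beta_lo <- -Inf; beta_hi <- Inf
    for (it in seq_len(max_iter)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw <= 0) { h <- 0 } else {
        h <- log(sw) + beta * sum(di * w) / sw
      }
      if (abs(h - target) < tol) break
      if (h > target) {
        beta_lo <- beta
        beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2
      } else {
        beta_hi <- beta
        beta <- if (is.finite(beta_lo)) (beta + beta_lo) / 2 else beta / 2
      }
    }
    P[i, -i] <- w / sum(w)
  }
  P
}
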