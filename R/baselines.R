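## Comparison classifiers: a polynomial-kernel SVM (C = 100) wrapped
## one-vs-rest for the three classes, and a plain two-hidden-layer MLP
## (200 then 500 units) trained with Adam cross-entropy.

#' Configure a baseline classifier
#'
#' @param kind `"svm"` (polynomial kernel, `C = 100`) or `"mlp"`
#'   (hidden widths 200 and 500).
#' @param svm_C SVM cost parameter.
#' @param svm_degree polynomial degree (the common default, 3).
#' @param mlp_layers hidden-layer widths for the MLP. A
#'   `c(2000, 1000)`-wide preset mirroring the VAE encoder is also valid.
#' @param learning_rate,epochs MLP Adam settings (matched to the VAE
#'   training defaults for comparability).
#' @param batch_size MLP minibatch size.
#' @param seed RNG seed (MLP init and shuffling).
#' @return a `baseline_config` list.
#' @export
baseline_config <- function(kind = c("svm", "mlp"), svm_C = 100,
                            svm_degree = 3L, mlp_layers = c(200L, 500L),
                            learning_rate = 1e-4, epochs = 50L,
                            batch_size = 32L, seed = 1L) {
  kind <- match.arg(kind)
  fail_if(svm_C <= 0, "svm_C must be positive")
  fail_if(any(mlp_layers < 1), "mlp layer widths must be positive")
  structure(list(kind = kind, svm_C = svm_C,
                 svm_degree = as.integer(svm_degree),
                 mlp_layers = as.integer(mlp_layers),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "baseline_config")
}

#' Train a baseline classifier
#'
#' @param features subjects x features matrix.
#' @param labels class label per subject (>= 2 classes present).
#' @param config a [baseline_config()].
#' @return a `baseline_fit` usable with [predict_baseline()].
#' @export
train_baseline <- function(features, labels, config) {
  x <- as.matrix(features)
  labels <- canonical_diagnosis(labels)
  classes <- CLASS_LEVELS[CLASS_LEVELS %in% unique(labels)]
  fail_if(length(classes) < 2, "need >= 2 classes in the training set")
  fit <- if (config$kind == "svm") {
    ## one-vs-rest over binary e1071 SVMs, argmax of decision values
    models <- with_seed(config$seed, lapply(classes, function(cl) {
      yb <- factor(ifelse(labels == cl, cl, "rest"),
                   levels = c(cl, "rest"))
      e1071::svm(x, yb, type = "C-classification",
                 kernel = "polynomial", degree = config$svm_degree,
                 cost = config$svm_C, scale = FALSE)
    }))
    list(models = models)
  } else {
    y <- match(labels, classes)
    n_hidden <- length(config$mlp_layers)
    with_seed(config$seed, {
      params <- mlp_init(ncol(x), config$mlp_layers, length(classes))
      adam <- adam_init(params)
      n <- nrow(x)
      for (epoch in seq_len(config$epochs)) {
        ord <- sample(n)
        batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
        for (idx in batches) {
          fw <- mlp_forward(params, x[idx, , drop = FALSE], n_hidden)
          bw <- mlp_backward(params, fw, y[idx], n_hidden)
          upd <- adam_step(params, bw$grads, adam, config$learning_rate)
          params <- upd$params; adam <- upd$state
        }
      }
      list(params = params, n_hidden = n_hidden)
    })
  }
  structure(c(fit, list(kind = config$kind, classes = classes,
                        input_dim = ncol(x), config = config)),
            class = "baseline_fit")
}

#' Predict with a baseline classifier
#'
#' @param fit a `baseline_fit`.
#' @param features matrix with the training feature dimension.
#' @return character vector of class labels (one per row; empty input
#'   gives an empty output).
#' @export
predict_baseline <- function(fit, features) {
  stopifnot(inherits(fit, "baseline_fit"))
  x <- as.matrix(features)
  if (nrow(x) == 0) return(character(0))
  fail_if(ncol(x) != fit$input_dim,
          "feature dimension %d does not match training (%d)",
          ncol(x), fit$input_dim)
  if (fit$kind == "svm") {
    scores <- sapply(seq_along(fit$models), function(i) {
      dv <- attr(stats::predict(fit$models[[i]], x,
                                decision.values = TRUE),
                 "decision.values")
      ## positive decision values side with the class named first in the
      ## "a/b" column label, which depends on training-data order
      sgn <- if (startsWith(colnames(dv)[1], paste0(fit$classes[i], "/")))
        1 else -1
      sgn * dv[, 1]
    })
    if (nrow(x) == 1) scores <- matrix(scores, 1)
    fit$classes[max.col(scores, ties.method = "first")]
  } else {
    fw <- mlp_forward(fit$params, x, fit$n_hidden)
    fit$classes[max.col(fw$logits, ties.method = "first")]
  }
}
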