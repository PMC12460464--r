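## Parametric empirical-Bayes ComBat harmonization with an explicit
## fit/apply split, so the model can be estimated on training subjects only
## and applied to held-out data.
##
## Model per feature f and batch (site) b:
##   y[s, f] = alpha[f] + x[s, ] %*% beta[, f] + gamma[b, f]
##             + delta[b, f] * eps[s, f]
## gamma has a normal prior, delta^2 an inverse-gamma prior; the EB
## posterior estimates (gamma*, delta*) are found by the standard
## conditional iteration.

#' Describe batches and preserved covariates
#'
#' @param batch batch (site) identifier per subject.
#' @param covariates optional numeric design matrix of effects to preserve
#'   (e.g. diagnosis one-hot without intercept, age); `NULL` for none.
#' @return a `batch_design` list.
#' @export
batch_design <- function(batch, covariates = NULL) {
  batch <- as.character(batch)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    fail_if(nrow(covariates) != length(batch),
            "covariates rows must match batch length")
  }
  structure(list(batch = batch, covariates = covariates),
            class = "batch_design")
}

## Diagnosis one-hot (reference level dropped) for covariate preservation.
#' Diagnosis covariate matrix for ComBat
#'
#' One-hot encoding of the labeled classes with "control" as the reference
#' level; rows with diagnosis "unknown" get all zeros (treated as the
#' reference, which keeps them usable while not informing class effects).
#'
#' @param diagnosis character vector of diagnosis tokens.
#' @return numeric matrix with one column per non-reference class.
#' @export
diagnosis_covariates <- function(diagnosis) {
  diagnosis <- canonical_diagnosis(diagnosis)
  lev <- setdiff(CLASS_LEVELS, "control")
  m <- sapply(lev, function(l) as.numeric(diagnosis == l))
  matrix(m, ncol = length(lev), dimnames = list(NULL, lev))
}

#' Fit the ComBat harmonization model
#'
#' @param features subjects x features numeric matrix.
#' @param design a [batch_design()].
#' @param parametric use parametric EB shrinkage (default); `FALSE` uses
#'   the raw per-batch location/scale estimates (no shrinkage).
#' @param tol,max_iter convergence controls of the EB iteration.
#' @return a `combat_model`.
#' @export
fit_combat <- function(features, design, parametric = TRUE,
                       tol = 1e-6, max_iter = 100L) {
  x <- as.matrix(features)
  stopifnot(inherits(design, "batch_design"))
  batch <- factor(design$batch)
  fail_if(nlevels(batch) < 2,
          "single batch: harmonization needs >= 2 batches")
  tab <- table(batch)
  fail_if(any(tab < 2), "batch(es) with < 2 subjects: %s",
          paste(names(tab)[tab < 2], collapse = ", "))
  n <- nrow(x); p <- ncol(x)
  ## zero-variance features are passed through unchanged
  keep <- apply(x, 2, stats::sd) > 0
  if (any(!keep))
    message(sprintf("%d zero-variance feature(s) excluded from fitting and passed through",
                    sum(!keep)))
  xf <- x[, keep, drop = FALSE]

  B <- stats::model.matrix(~ 0 + batch)           # n x n_batch
  M <- cbind(B, design$covariates)
  fail_if(qr(M)$rank < ncol(M),
          "design matrix is rank-deficient (confounded batch/covariates)")
  beta <- solve(crossprod(M), crossprod(M, xf))   # (n_batch + q) x p
  nb <- nlevels(batch)
  batch_means <- beta[seq_len(nb), , drop = FALSE]
  beta_cov <- beta[-seq_len(nb), , drop = FALSE]  # may be 0-row
  w <- as.numeric(tab) / n
  grand <- drop(crossprod(w, batch_means))        # weighted grand location
  fitted <- M %*% beta
  var_pooled <- colMeans((xf - fitted)^2)         # n denominator, as in EB ComBat
  fail_if(any(var_pooled <= 0), "zero pooled variance after regression")

  ## standardize: remove grand location, covariate effects, pooled scale
  stand_mean <- matrix(grand, n, ncol(xf), byrow = TRUE)
  if (ncol(M) > nb)
    stand_mean <- stand_mean + design$covariates %*% beta_cov
  z <- (xf - stand_mean) / matrix(sqrt(var_pooled), n, ncol(xf), byrow = TRUE)

  gamma_hat <- t(sapply(levels(batch),
                        function(b) colMeans(z[batch == b, , drop = FALSE])))
  delta2_hat <- t(sapply(levels(batch), function(b) {
    zb <- z[batch == b, , drop = FALSE]
    colSums(sweep(zb, 2, colMeans(zb))^2) / (nrow(zb) - 1)
  }))

  if (parametric) {
    gamma_star <- gamma_hat * 0
    delta2_star <- delta2_hat * 0
    for (bi in seq_len(nb)) {
      zb <- z[batch == levels(batch)[bi], , drop = FALSE]
      eb <- eb_iterate(zb, gamma_hat[bi, ], delta2_hat[bi, ], tol, max_iter)
      gamma_star[bi, ] <- eb$gamma
      delta2_star[bi, ] <- eb$delta2
    }
  } else {
    gamma_star <- gamma_hat
    delta2_star <- delta2_hat
  }

  structure(list(batches = levels(batch), grand = grand,
                 var_pooled = var_pooled, beta_cov = beta_cov,
                 gamma_star = gamma_star, delta2_star = delta2_star,
                 gamma_hat = gamma_hat, delta2_hat = delta2_hat,
                 keep = keep, n_features = p, parametric = parametric),
            class = "combat_model")
}

## Parametric EB conditional iteration for one batch.
## Normal prior on gamma (moments gamma_bar, tau2 across features),
## inverse-gamma prior on delta^2 (moment-matched a, b across features).
eb_iterate <- function(zb, g_hat, d2_hat, tol, max_iter) {
  nb <- nrow(zb)
  gamma_bar <- mean(g_hat)
  tau2 <- stats::var(g_hat)
  m <- mean(d2_hat); v <- stats::var(d2_hat)
  a_prior <- (2 * v + m^2) / v
  b_prior <- (m * v + m^3) / v
  g <- g_hat; d2 <- d2_hat
  for (it in seq_len(max_iter)) {
    g_new <- (nb * tau2 * g_hat + d2 * gamma_bar) / (nb * tau2 + d2)
    ss <- colSums(sweep(zb, 2, g_new)^2)
    d2_new <- (0.5 * ss + b_prior) / (nb / 2 + a_prior - 1)
    change <- max(abs(g_new - g), abs(d2_new - d2))
    g <- g_new; d2 <- d2_new
    if (change < tol) break
  }
  list(gamma = g, delta2 = d2)
}

#' Apply a fitted ComBat model
#'
#' Standardizes, removes the batch location/scale effects, and
#' back-transforms restoring preserved covariate effects. Batches unseen at
#' fit time are refused (no extrapolation).
#'
#' @param model a `combat_model`.
#' @param features subjects x features matrix (same feature set as fit).
#' @param design a [batch_design()] for these subjects.
#' @return harmonized matrix, same shape as `features`.
#' @export
apply_combat <- function(model, features, design) {
  x <- as.matrix(features)
  stopifnot(inherits(model, "combat_model"), inherits(design, "batch_design"))
  fail_if(ncol(x) != model$n_features,
          "feature count %d does not match fitted model (%d)",
          ncol(x), model$n_features)
  unseen <- setdiff(unique(design$batch), model$batches)
  fail_if(length(unseen) > 0, "batch(es) not seen at fit time: %s",
          paste(unseen, collapse = ", "))
  n <- nrow(x)
  xf <- x[, model$keep, drop = FALSE]
  stand_mean <- matrix(model$grand, n, ncol(xf), byrow = TRUE)
  if (nrow(model$beta_cov) > 0) {
    fail_if(is.null(design$covariates) ||
              ncol(design$covariates) != nrow(model$beta_cov),
            "covariates must match those used at fit time")
    stand_mean <- stand_mean + design$covariates %*% model$beta_cov
  }
  sdv <- matrix(sqrt(model$var_pooled), n, ncol(xf), byrow = TRUE)
  z <- (xf - stand_mean) / sdv
  bi <- match(design$batch, model$batches)
  adj <- (z - model$gamma_star[bi, , drop = FALSE]) /
    sqrt(model$delta2_star[bi, , drop = FALSE])
  out <- x
  out[, model$keep] <- adj * sdv + stand_mean
  out
}

#' Fit-and-apply convenience wrapper
#'
#' @inheritParams fit_combat
#' @return harmonized matrix.
#' @export
combat_harmonize <- function(features, design, parametric = TRUE) {
  model <- fit_combat(features, design, parametric = parametric)
  apply_combat(model, features, design)
}
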