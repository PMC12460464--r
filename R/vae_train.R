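## Forward/backward passes and the joint training loop of the VAE-MMD
## model. Gradients are hand-derived; a finite-difference check in the test
## suite guards every term.

## Forward pass for one batch. y: integer classes (1-based) for labeled
## batches, NULL for unlabeled (the class is marginalized under q(y|z1)).
## eps1/eps2 are the reparameterization draws (shared across the class
## branches of an unlabeled batch).
vae_forward <- function(params, X, dOH, y, eps1, eps2, cfg) {
  B <- nrow(X); D <- cfg$input_dim; K <- cfg$n_classes
  A1 <- cbind(X, dOH)
  H1p <- sweep(A1 %*% params$W_e1, 2, params$b_e1, "+")
  H1 <- relu(H1p)
  mu1 <- sweep(H1 %*% params$W_mu1, 2, params$b_mu1, "+")
  lv1 <- sweep(H1 %*% params$W_lv1, 2, params$b_lv1, "+")
  sd1 <- exp(lv1 / 2)
  z1 <- mu1 + sd1 * eps1
  cls_in <- if (identical(cfg$classify_on, "sample")) z1 else mu1
  logits <- sweep(cls_in %*% params$W_c, 2, params$b_c, "+")
  logp <- log_softmax_rows(logits)
  p <- exp(logp)
  ## decoder p(x | z1, d)
  A4 <- cbind(z1, dOH)
  H4p <- sweep(A4 %*% params$W_d1, 2, params$b_d1, "+")
  H4 <- relu(H4p)
  xhat <- sweep(H4 %*% params$W_x, 2, params$b_x, "+")
  rx <- 0.5 * (D * (LOG2PI + params$lv_x) +
                 rowSums((X - xhat)^2) * exp(-params$lv_x))
  h1q <- 0.5 * (cfg$z1_dim * (1 + LOG2PI) + rowSums(lv1))

  branch <- function(yOH) {
    A2 <- cbind(z1, yOH)
    H2p <- sweep(A2 %*% params$W_e2, 2, params$b_e2, "+")
    H2 <- relu(H2p)
    mu2 <- sweep(H2 %*% params$W_mu2, 2, params$b_mu2, "+")
    lv2 <- sweep(H2 %*% params$W_lv2, 2, params$b_lv2, "+")
    sd2 <- exp(lv2 / 2)
    z2 <- mu2 + sd2 * eps2
    A3 <- cbind(z2, yOH)
    H3p <- sweep(A3 %*% params$W_d2, 2, params$b_d2, "+")
    H3 <- relu(H3p)
    m1p <- sweep(H3 %*% params$W_m1p, 2, params$b_m1p, "+")
    lvp <- sweep(H3 %*% params$W_lvp, 2, params$b_lvp, "+")
    rz1 <- 0.5 * rowSums(LOG2PI + lvp + (z1 - m1p)^2 * exp(-lvp))
    pz2 <- 0.5 * (cfg$z2_dim * LOG2PI + rowSums(z2^2))
    h2q <- 0.5 * (cfg$z2_dim * (1 + LOG2PI) + rowSums(lv2))
    list(A2 = A2, H2p = H2p, H2 = H2, mu2 = mu2, lv2 = lv2, sd2 = sd2,
         z2 = z2, A3 = A3, H3p = H3p, H3 = H3, m1p = m1p, lvp = lvp,
         f = rz1 + pz2 + log(K) - h2q)
  }

  fw <- list(X = X, dOH = dOH, y = y, A1 = A1, H1p = H1p, H1 = H1,
             mu1 = mu1, lv1 = lv1, sd1 = sd1, z1 = z1, eps1 = eps1,
             eps2 = eps2, logits = logits, logp = logp, p = p,
             A4 = A4, H4p = H4p, H4 = H4, xhat = xhat, rx = rx, h1q = h1q)
  if (!is.null(y)) {
    yOH <- matrix(0, B, K)
    yOH[cbind(seq_len(B), y)] <- 1
    fw$yOH <- yOH
    fw$br <- branch(yOH)
    fw$ls <- rx - h1q + fw$br$f             # per-sample negative ELBO
    fw$ce <- -logp[cbind(seq_len(B), y)]    # per-sample cross-entropy
  } else {
    fw$brs <- lapply(seq_len(K), function(k) {
      yOH <- matrix(0, B, K)
      yOH[, k] <- 1
      c(branch(yOH), list(yOH = yOH))
    })
    fw$Fmat <- sapply(fw$brs, `[[`, "f")
    if (B == 1) fw$Fmat <- matrix(fw$Fmat, 1)
    fw$lt <- rx - h1q + rowSums(p * fw$Fmat) + rowSums(p * logp)
  }
  fw
}

## Backward pass; returns the gradient list. dmu1_extra carries the MMD
## gradient on the posterior means.
vae_backward <- function(params, fw, cfg, dmu1_extra = NULL) {
  g <- zero_like(params)
  z1d <- cfg$z1_dim; z2d <- cfg$z2_dim
  B <- nrow(fw$X)

  ## y-branch backward with per-sample weights w; returns dz1 contribution
  branch_back <- function(br, w) {
    dlvp <- 0.5 * w * (1 - (fw$z1 - br$m1p)^2 * exp(-br$lvp))
    dm1p <- w * ((br$m1p - fw$z1) * exp(-br$lvp))
    dz1 <- w * ((fw$z1 - br$m1p) * exp(-br$lvp))
    g$W_m1p <<- g$W_m1p + crossprod(br$H3, dm1p)
    g$b_m1p <<- g$b_m1p + colSums(dm1p)
    g$W_lvp <<- g$W_lvp + crossprod(br$H3, dlvp)
    g$b_lvp <<- g$b_lvp + colSums(dlvp)
    dH3 <- dm1p %*% t(params$W_m1p) + dlvp %*% t(params$W_lvp)
    dH3p <- dH3 * (br$H3p > 0)
    g$W_d2 <<- g$W_d2 + crossprod(br$A3, dH3p)
    g$b_d2 <<- g$b_d2 + colSums(dH3p)
    dA3 <- dH3p %*% t(params$W_d2)
    dz2 <- dA3[, seq_len(z2d), drop = FALSE] + w * br$z2
    dmu2 <- dz2
    dlv2 <- dz2 * fw$eps2 * br$sd2 * 0.5 - 0.5 * w
    g$W_mu2 <<- g$W_mu2 + crossprod(br$H2, dmu2)
    g$b_mu2 <<- g$b_mu2 + colSums(dmu2)
    g$W_lv2 <<- g$W_lv2 + crossprod(br$H2, dlv2)
    g$b_lv2 <<- g$b_lv2 + colSums(dlv2)
    dH2 <- dmu2 %*% t(params$W_mu2) + dlv2 %*% t(params$W_lv2)
    dH2p <- dH2 * (br$H2p > 0)
    g$W_e2 <<- g$W_e2 + crossprod(br$A2, dH2p)
    g$b_e2 <<- g$b_e2 + colSums(dH2p)
    dA2 <- dH2p %*% t(params$W_e2)
    dz1 + dA2[, seq_len(z1d), drop = FALSE]
  }

  if (!is.null(fw$y)) {
    dz1 <- branch_back(fw$br, rep(1, B))
    dlogits <- cfg$alpha * (fw$p - fw$yOH)
  } else {
    dz1 <- matrix(0, B, z1d)
    for (k in seq_along(fw$brs))
      dz1 <- dz1 + branch_back(fw$brs[[k]], fw$p[, k])
    pf <- rowSums(fw$p * fw$Fmat)
    plogp <- rowSums(fw$p * fw$logp)
    dlogits <- fw$p * (fw$Fmat - pf) + fw$p * (fw$logp - plogp)
  }

  ## decoder p(x | z1, d)
  dxhat <- (fw$xhat - fw$X) * exp(-params$lv_x)
  g$lv_x <- g$lv_x +
    sum(0.5 * (1 - (fw$X - fw$xhat)^2 * exp(-params$lv_x)))
  g$W_x <- g$W_x + crossprod(fw$H4, dxhat)
  g$b_x <- g$b_x + colSums(dxhat)
  dH4 <- dxhat %*% t(params$W_x)
  dH4p <- dH4 * (fw$H4p > 0)
  g$W_d1 <- g$W_d1 + crossprod(fw$A4, dH4p)
  g$b_d1 <- g$b_d1 + colSums(dH4p)
  dz1 <- dz1 + (dH4p %*% t(params$W_d1))[, seq_len(z1d), drop = FALSE]

  ## classifier head (reads the posterior mean unless configured to read
  ## the sample)
  on_sample <- identical(cfg$classify_on, "sample")
  g$W_c <- g$W_c + crossprod(if (on_sample) fw$z1 else fw$mu1, dlogits)
  g$b_c <- g$b_c + colSums(dlogits)
  dmu1_cls <- dlogits %*% t(params$W_c)
  if (on_sample) dz1 <- dz1 + dmu1_cls

  ## reparameterization into the z1 posterior
  dmu1 <- dz1
  if (!on_sample) dmu1 <- dmu1 + dmu1_cls
  if (!is.null(dmu1_extra)) dmu1 <- dmu1 + dmu1_extra
  dlv1 <- dz1 * fw$eps1 * fw$sd1 * 0.5 - 0.5
  g$W_mu1 <- g$W_mu1 + crossprod(fw$H1, dmu1)
  g$b_mu1 <- g$b_mu1 + colSums(dmu1)
  g$W_lv1 <- g$W_lv1 + crossprod(fw$H1, dlv1)
  g$b_lv1 <- g$b_lv1 + colSums(dlv1)
  dH1 <- dmu1 %*% t(params$W_mu1) + dlv1 %*% t(params$W_lv1)
  dH1p <- dH1 * (fw$H1p > 0)
  g$W_e1 <- g$W_e1 + crossprod(fw$A1, dH1p)
  g$b_e1 <- g$b_e1 + colSums(dH1p)
  g
}

## M1-only pass: unsupervised VAE on x with standard-normal prior on z1,
## used for optional pretraining. Returns loss sum and gradients for the
## M1 parameter subset.
M1_PARAMS <- c("W_e1", "b_e1", "W_mu1", "b_mu1", "W_lv1", "b_lv1",
               "W_d1", "b_d1", "W_x", "b_x", "lv_x")

m1_pass <- function(params, X, dOH, eps1, cfg) {
  D <- cfg$input_dim
  A1 <- cbind(X, dOH)
  H1p <- sweep(A1 %*% params$W_e1, 2, params$b_e1, "+")
  H1 <- relu(H1p)
  mu1 <- sweep(H1 %*% params$W_mu1, 2, params$b_mu1, "+")
  lv1 <- sweep(H1 %*% params$W_lv1, 2, params$b_lv1, "+")
  sd1 <- exp(lv1 / 2)
  z1 <- mu1 + sd1 * eps1
  A4 <- cbind(z1, dOH)
  H4p <- sweep(A4 %*% params$W_d1, 2, params$b_d1, "+")
  H4 <- relu(H4p)
  xhat <- sweep(H4 %*% params$W_x, 2, params$b_x, "+")
  recon <- 0.5 * sum(D * (LOG2PI + params$lv_x) +
                       rowSums((X - xhat)^2) * exp(-params$lv_x))
  kl <- 0.5 * sum(mu1^2 + exp(lv1) - 1 - lv1)
  g <- stats::setNames(lapply(M1_PARAMS, function(nm) params[[nm]] * 0),
                       M1_PARAMS)
  dxhat <- (xhat - X) * exp(-params$lv_x)
  g$lv_x <- sum(0.5 * (1 - (X - xhat)^2 * exp(-params$lv_x)))
  g$W_x <- crossprod(H4, dxhat)
  g$b_x <- colSums(dxhat)
  dH4p <- (dxhat %*% t(params$W_x)) * (H4p > 0)
  g$W_d1 <- crossprod(A4, dH4p)
  g$b_d1 <- colSums(dH4p)
  dz1 <- (dH4p %*% t(params$W_d1))[, seq_len(cfg$z1_dim), drop = FALSE]
  dmu1 <- dz1 + mu1
  dlv1 <- dz1 * eps1 * sd1 * 0.5 + 0.5 * (exp(lv1) - 1)
  g$W_mu1 <- crossprod(H1, dmu1)
  g$b_mu1 <- colSums(dmu1)
  g$W_lv1 <- crossprod(H1, dlv1)
  g$b_lv1 <- colSums(dlv1)
  dH1p <- (dmu1 %*% t(params$W_mu1) + dlv1 %*% t(params$W_lv1)) *
    (H1p > 0)
  g$W_e1 <- crossprod(A1, dH1p)
  g$b_e1 <- colSums(dH1p)
  list(loss = recon + kl, grads = g)
}

add_grads <- function(a, b) {
  for (nm in names(a)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

## Reparameterization draws for a batch.
draw_eps <- function(B, cfg) {
  list(eps1 = matrix(stats::rnorm(B * cfg$z1_dim), B),
       eps2 = matrix(stats::rnorm(B * cfg$z2_dim), B))
}

class_index <- function(y, cfg) {
  idx <- match(canonical_diagnosis(y), CLASS_LEVELS[seq_len(cfg$n_classes)])
  fail_if(anyNA(idx), "unlabeled or unknown label passed where labels are required")
  idx
}

#' Loss contribution of a labeled batch
#'
#' Per-point negative ELBO of the stacked generative model plus the
#' alpha-weighted classification cross-entropy. Sums over the batch.
#'
#' @inheritParams encode_z1
#' @param y class labels (control/autism/asperger).
#' @param eps1,eps2 optional reparameterization draws (matrices n x z1_dim
#'   and n x z2_dim); drawn from the current RNG stream when missing.
#' @return list with `labeled_elbo_sum`, `classification_term`, `total`,
#'   per-sample vectors `per_sample` and `ce`, and the sampled `z1`.
#' @export
loss_labeled <- function(params, x, d, y, cfg, eps1 = NULL, eps2 = NULL) {
  x <- as.matrix(x); B <- nrow(x)
  dOH <- if (is.matrix(d)) d else domain_onehot(d, cfg)
  if (is.null(eps1)) eps1 <- matrix(stats::rnorm(B * cfg$z1_dim), B)
  if (is.null(eps2)) eps2 <- matrix(stats::rnorm(B * cfg$z2_dim), B)
  fw <- vae_forward(params, x, dOH, class_index(y, cfg), eps1, eps2, cfg)
  list(labeled_elbo_sum = sum(fw$ls),
       classification_term = cfg$alpha * sum(fw$ce),
       total = sum(fw$ls) + cfg$alpha * sum(fw$ce),
       per_sample = fw$ls, ce = fw$ce, z1 = fw$z1)
}

#' Loss contribution of an unlabeled batch
#'
#' The class is marginalized under q(y | z1):
#' `sum_y q(y|z1) L(x, d, y) - H[q(y|z1)]`, summed over the batch.
#'
#' @inheritParams loss_labeled
#' @return list with `unlabeled_elbo_sum`, per-sample vector `per_sample`,
#'   the class-responsibility matrix `probs`, the per-class per-sample
#'   negative-ELBO matrix `elbo_by_class`, and the sampled `z1`.
#' @export
loss_unlabeled <- function(params, x, d, cfg, eps1 = NULL, eps2 = NULL) {
  x <- as.matrix(x); B <- nrow(x)
  dOH <- if (is.matrix(d)) d else domain_onehot(d, cfg)
  if (is.null(eps1)) eps1 <- matrix(stats::rnorm(B * cfg$z1_dim), B)
  if (is.null(eps2)) eps2 <- matrix(stats::rnorm(B * cfg$z2_dim), B)
  fw <- vae_forward(params, x, dOH, NULL, eps1, eps2, cfg)
  list(unlabeled_elbo_sum = sum(fw$lt), total = sum(fw$lt),
       per_sample = fw$lt, probs = fw$p,
       elbo_by_class = fw$Fmat + (fw$rx - fw$h1q), z1 = fw$z1)
}

#' Total minimized loss over source, target and auxiliary batches
#'
#' `labeled + unlabeled + alpha-term + beta * sum_s MMD^2(z1 means of s,
#' z1 means of target)` with one MMD pair per non-target domain. With
#' `beta = 0` the MMD term is skipped entirely.
#'
#' @param params model parameters.
#' @param source list(x, y, d) labeled source batch.
#' @param target list(x, d) unlabeled target batch.
#' @param aux optional list of labeled control-only batches, each
#'   list(x, d).
#' @param cfg the `vae_mmd_config`.
#' @return a loss-breakdown list: `labeled_elbo_sum`,
#'   `unlabeled_elbo_sum`, `classification_term`, `mmd_term`, `total`.
#' @export
total_loss <- function(params, source, target, aux = list(), cfg) {
  fail_if(is.null(target$x) || nrow(as.matrix(target$x)) == 0,
          "no target-domain data")
  ls <- loss_labeled(params, source$x, source$d, source$y, cfg)
  lt <- loss_unlabeled(params, target$x, target$d, cfg)
  labeled <- ls$labeled_elbo_sum
  cls <- ls$classification_term
  mu_sets <- list(encode_z1(params, source$x, source$d, cfg)$mean)
  for (a in aux) {
    la <- loss_labeled(params, a$x, a$d,
                       rep("control", nrow(as.matrix(a$x))), cfg)
    labeled <- labeled + la$labeled_elbo_sum
    cls <- cls + la$classification_term
    mu_sets <- c(mu_sets, list(encode_z1(params, a$x, a$d, cfg)$mean))
  }
  mmd <- 0
  if (cfg$beta > 0) {
    mu_t <- encode_z1(params, target$x, target$d, cfg)$mean
    for (mu_s in mu_sets)
      mmd <- mmd + mmd_squared(mu_s, mu_t, cfg$kernel)
  }
  breakdown(labeled, lt$unlabeled_elbo_sum, cls, cfg$beta * mmd)
}

breakdown <- function(labeled, unlabeled, cls, mmd) {
  list(labeled_elbo_sum = labeled, unlabeled_elbo_sum = unlabeled,
       classification_term = cls, mmd_term = mmd,
       total = labeled + unlabeled + cls + mmd)
}

#' Train the VAE-MMD model
#'
#' Joint Adam training on labeled source data, unlabeled target data, and
#' optional control-only auxiliary cohorts (transfer learning). Every
#' domain is cut into the same number of batches per epoch so all domains
#' are trained simultaneously; each non-target domain contributes one MMD
#' pair to the target per step. Deterministic given `cfg$seed`.
#'
#' @param x_source,y_source labeled source features and class labels.
#' @param x_target unlabeled target features (labels are never seen).
#' @param aux named list of auxiliary feature matrices; every auxiliary
#'   subject carries the control label. Names must match `cfg$domain_ids`.
#' @param cfg a [vae_config()]; `cfg$domain_ids` must be
#'   `c("source", "target", names(aux))`.
#' @param eval_data optional list(x, d, y) scored each epoch (e.g. a
#'   validation set); never used for fitting.
#' @return a `vae_mmd_fit`: `params`, `cfg`, per-epoch `history`
#'   (loss-breakdown fields and accuracies), and `checkpoints` (per-epoch
#'   input rows of the first encoding layer, when enabled).
#' @export
train_vae_mmd <- function(x_source, y_source, x_target, aux = list(),
                          cfg, eval_data = NULL) {
  x_source <- as.matrix(x_source); x_target <- as.matrix(x_target)
  fail_if(nrow(x_source) == 0 || nrow(x_target) == 0,
          "source and target must be non-empty")
  fail_if(!setequal(cfg$domain_ids, c("source", "target", names(aux))),
          "cfg$domain_ids must be source, target and the aux names")
  y_idx <- class_index(y_source, cfg)
  aux <- lapply(aux, as.matrix)
  domains <- c(list(source = x_source, target = x_target), aux)
  n_dom <- length(domains)
  labeled <- names(domains) != "target"
  dOH_full <- lapply(names(domains), function(nm)
    domain_onehot(rep(nm, nrow(domains[[nm]])), cfg))
  names(dOH_full) <- names(domains)

  nb <- if (!is.null(cfg$batch_size))
    max(1L, ceiling(nrow(x_source) / cfg$batch_size)) else cfg$n_batches
  set.seed(cfg$seed)
  params <- vae_init_params(cfg)

  ## optional unsupervised M1 pretraining on all domains pooled
  if (cfg$pretrain_epochs > 0) {
    m1 <- params[M1_PARAMS]
    adam1 <- adam_init(m1)
    for (epoch in seq_len(cfg$pretrain_epochs)) {
      for (di in seq_len(n_dom)) {
        ord <- sample(nrow(domains[[di]]))
        for (idx in split(ord, cut(seq_along(ord), nb, labels = FALSE))) {
          if (length(idx) == 0) next
          eps1 <- matrix(stats::rnorm(length(idx) * cfg$z1_dim),
                         length(idx))
          ps <- m1_pass(c(m1, params[setdiff(names(params), M1_PARAMS)]),
                        domains[[di]][idx, , drop = FALSE],
                        dOH_full[[di]][idx, , drop = FALSE], eps1, cfg)
          fail_if(!is.finite(ps$loss),
                  "M1 pretraining diverged at epoch %d", epoch)
          upd <- adam_step(m1, ps$grads, adam1, cfg$learning_rate)
          m1 <- upd$params; adam1 <- upd$state
        }
      }
    }
    params[M1_PARAMS] <- m1
  }

  adam <- adam_init(params)
  history <- vector("list", cfg$epochs)
  checkpoints <- if (cfg$checkpoint_first_layer) vector("list", cfg$epochs)

  for (epoch in seq_len(cfg$epochs)) {
    chunks <- lapply(domains, function(xd) {
      ord <- sample(nrow(xd))
      split(ord, cut(seq_along(ord), nb, labels = FALSE))
    })
    ep <- c(labeled_elbo_sum = 0, unlabeled_elbo_sum = 0,
            classification_term = 0, mmd_term = 0)
    for (b in seq_len(nb)) {
      fws <- vector("list", n_dom)
      for (di in seq_len(n_dom)) {
        nm <- names(domains)[di]
        idx <- chunks[[di]][[b]]
        if (is.null(idx) || length(idx) == 0) next
        X <- domains[[di]][idx, , drop = FALSE]
        eps <- draw_eps(length(idx), cfg)
        yb <- if (nm == "source") y_idx[idx]
              else if (labeled[di]) rep(1L, length(idx))  # aux: control
              else NULL
        fws[[di]] <- vae_forward(params, X,
                                 dOH_full[[nm]][idx, , drop = FALSE],
                                 yb, eps$eps1, eps$eps2, cfg)
      }
      present <- !vapply(fws, is.null, logical(1))
      ti <- which(names(domains) == "target")
      dmu1 <- vector("list", n_dom)
      mmd_sum <- 0
      if (cfg$beta > 0 && present[ti]) {
        mu_t <- fws[[ti]]$mu1
        for (di in which(present & labeled)) {
          mg <- mmd_squared_grad(fws[[di]]$mu1, mu_t, cfg$kernel)
          mmd_sum <- mmd_sum + mg$value
          dmu1[[di]] <- if (is.null(dmu1[[di]])) cfg$beta * mg$dA
                        else dmu1[[di]] + cfg$beta * mg$dA
          dmu1[[ti]] <- if (is.null(dmu1[[ti]])) cfg$beta * mg$dB
                        else dmu1[[ti]] + cfg$beta * mg$dB
        }
      }
      grads <- zero_like(params)
      step <- c(labeled_elbo_sum = 0, unlabeled_elbo_sum = 0,
                classification_term = 0, mmd_term = cfg$beta * mmd_sum)
      for (di in which(present)) {
        fw <- fws[[di]]
        grads <- add_grads(grads,
                           vae_backward(params, fw, cfg, dmu1[[di]]))
        if (labeled[di]) {
          step["labeled_elbo_sum"] <- step["labeled_elbo_sum"] + sum(fw$ls)
          step["classification_term"] <- step["classification_term"] +
            cfg$alpha * sum(fw$ce)
        } else {
          step["unlabeled_elbo_sum"] <- step["unlabeled_elbo_sum"] +
            sum(fw$lt)
        }
      }
      total <- sum(step)
      if (!is.finite(total)) {
        stop(sprintf(paste0("training diverged at epoch %d, batch %d ",
                            "(loss terms: %s)"), epoch, b,
                     paste(sprintf("%s=%g", names(step), step),
                           collapse = ", ")), call. = FALSE)
      }
      upd <- adam_step(params, grads, adam, cfg$learning_rate)
      params <- upd$params
      adam <- upd$state
      if (cfg$weight_decay > 0) {
        shrink <- 1 - cfg$learning_rate * cfg$weight_decay
        for (nm in grep("^W_", names(params), value = TRUE))
          params[[nm]] <- params[[nm]] * shrink
      }
      ep <- ep + step
    }
    acc_src <- mean(vae_predict(params, x_source,
                                rep("source", nrow(x_source)), cfg) ==
                      CLASS_LEVELS[y_idx])
    acc_eval <- if (!is.null(eval_data))
      mean(vae_predict(params, eval_data$x, eval_data$d, cfg) ==
             canonical_diagnosis(eval_data$y)) else NA_real_
    history[[epoch]] <- data.frame(
      epoch = epoch, labeled_elbo_sum = ep[["labeled_elbo_sum"]],
      unlabeled_elbo_sum = ep[["unlabeled_elbo_sum"]],
      classification_term = ep[["classification_term"]],
      mmd_term = ep[["mmd_term"]], total = sum(ep),
      source_accuracy = acc_src, eval_accuracy = acc_eval)
    if (cfg$checkpoint_first_layer)
      checkpoints[[epoch]] <-
        params$W_e1[seq_len(cfg$input_dim), , drop = FALSE]
  }
  structure(list(params = params, cfg = cfg,
                 history = do.call(rbind, history),
                 checkpoints = checkpoints),
            class = "vae_mmd_fit")
}

#' Save / load a trained model checkpoint
#'
#' A directory holding `config.json` and `params.json` (all parameter
#' tensors, full precision) plus a format version marker.
#'
#' @param fit a `vae_mmd_fit`.
#' @param dir checkpoint directory.
#' @return `save_checkpoint` the directory, `load_checkpoint` the fit.
#' @export
save_checkpoint <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- fit$cfg
  cfg$batch_size <- if (is.null(cfg$batch_size)) NA_integer_ else
    cfg$batch_size
  jsonlite::write_json(list(format = "fcadapt-checkpoint-1",
                            config = unclass(cfg)),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  ser <- lapply(fit$params, function(p)
    list(dim = if (is.matrix(p)) dim(p) else length(p),
         data = as.numeric(p)))
  jsonlite::write_json(ser, file.path(dir, "params.json"), digits = NA)
  jsonlite::write_json(fit$history, file.path(dir, "history.json"),
                       digits = NA, dataframe = "rows", na = "null")
  if (!is.null(fit$checkpoints)) {
    ck <- lapply(fit$checkpoints, function(p)
      list(dim = dim(p), data = as.numeric(p)))
    jsonlite::write_json(ck, file.path(dir, "first_layer_checkpoints.json"),
                         digits = NA)
  }
  invisible(dir)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  fail_if(!identical(meta$format, "fcadapt-checkpoint-1"),
          "not an fcadapt checkpoint: %s", dir)
  cfg <- meta$config
  if (is.na(cfg$batch_size)) cfg$batch_size <- NULL
  cfg$kernel <- as.list(cfg$kernel)
  class(cfg) <- "vae_mmd_config"
  deser <- function(p) {
    d <- unlist(p$dim)
    v <- as.numeric(unlist(p$data))
    if (length(d) == 2) matrix(v, d[1], d[2]) else v
  }
  params <- lapply(jsonlite::read_json(file.path(dir, "params.json")),
                   deser)
  hist_path <- file.path(dir, "history.json")
  history <- if (file.exists(hist_path))
    jsonlite::read_json(hist_path, simplifyVector = TRUE)
  ckpt_path <- file.path(dir, "first_layer_checkpoints.json")
  checkpoints <- if (file.exists(ckpt_path))
    lapply(jsonlite::read_json(ckpt_path), deser)
  structure(list(params = params, cfg = cfg, history = history,
                 checkpoints = checkpoints), class = "vae_mmd_fit")
}
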