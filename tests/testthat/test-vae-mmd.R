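fa <- asNamespace("fcadapt")

small_cfg <- function(...) {
  args <- utils::modifyList(
    list(input_dim = 6, enc1_dim = 5, enc2_dim = 4, z1_dim = 3,
         z2_dim = 2, alpha = 2.5, beta = 1.7,
         kernel = list(family = "rbf", bandwidth = 0.9)), list(...))
  do.call(vae_config, args)
}

test_that("encode_z1 honors its shape and determinism contracts", {
  cfg <- small_cfg()
  params <- with_seed_local(1, fa$vae_init_params(cfg))
  x <- with_seed_local(2, matrix(rnorm(5 * 6), 5))
  post <- encode_z1(params, x, rep("source", 5), cfg)
  expect_equal(dim(post$mean), c(5, 3))
  expect_equal(dim(post$logvar), c(5, 3))
  ## identical inputs give identical posteriors
  x2 <- x[c(1, 1, 3, 4, 5), ]
  post2 <- encode_z1(params, x2, rep("source", 5), cfg)
  expect_equal(post2$mean[1, ], post2$mean[2, ])

  ## zero parameters: mean 0, logvar 0
  zp <- zero_params(cfg)
  post0 <- encode_z1(zp, x, rep("target", 5), cfg)
  expect_equal(post0$mean, matrix(0, 5, 3))
  expect_equal(post0$logvar, matrix(0, 5, 3))

  expect_error(encode_z1(params, x[, 1:4], rep("source", 5), cfg),
               "columns")
})

test_that("classification probabilities normalize and are equivariant", {
  cfg <- small_cfg()
  params <- with_seed_local(3, fa$vae_init_params(cfg))
  x <- with_seed_local(4, matrix(rnorm(7 * 6), 7))
  p <- vae_classify(params, x, rep("source", 7), cfg)
  expect_equal(rowSums(p), rep(1, 7), tolerance = 1e-6)
  expect_true(all(p >= 0))
  ## permuting the batch permutes outputs identically
  ord <- c(3, 1, 2, 7, 6, 5, 4)
  expect_equal(vae_classify(params, x[ord, ], rep("source", 7), cfg),
               p[ord, ])
})

test_that("prediction takes the argmax with lowest-index tie-breaking", {
  cfg <- small_cfg()
  params <- zero_params(cfg)
  x <- matrix(0, 1, 6)
  params$b_c <- log(c(0.2, 0.5, 0.3))
  expect_equal(vae_predict(params, x, "source", cfg), "autism")
  params$b_c <- c(1, 1, 0)  # exact tie between the first two classes
  expect_equal(vae_predict(params, x, "source", cfg), "control")
  ## batch predict equals row-wise predict
  params2 <- with_seed_local(5, fa$vae_init_params(cfg))
  xb <- with_seed_local(6, matrix(rnorm(4 * 6), 4))
  batch <- vae_predict(params2, xb, rep("target", 4), cfg)
  rowwise <- vapply(1:4, function(i)
    vae_predict(params2, xb[i, , drop = FALSE], "target", cfg),
    character(1))
  expect_equal(batch, rowwise)
  params$b_c <- c(NaN, 0, 0)
  expect_error(vae_predict(params, x, "source", cfg), "non-finite")
})

test_that("the MMD estimator matches brute-force kernel sums", {
  kern <- list(family = "rbf", bandwidth = 1)
  ## identical multisets
  A <- matrix(c(0.3, -1, 0.3, 2), 4)
  expect_lt(mmd_squared(A, A, kern), 1e-12)
  ## hand-computable 1-D case: A = {0}, B = {10}
  expect_equal(mmd_squared(0, 10, kern), 1 + 1 - 2 * exp(-50))
  ## brute-force double loop over random sets of every size <= 20
  brute <- function(a, b, s) {
    k <- function(u, v) exp(-sum((u - v)^2) / (2 * s^2))
    ka <- kb <- kab <- 0
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(a)))
      ka <- ka + k(a[i, ], a[j, ])
    for (i in seq_len(nrow(b))) for (j in seq_len(nrow(b)))
      kb <- kb + k(b[i, ], b[j, ])
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b)))
      kab <- kab + k(a[i, ], b[j, ])
    ka / nrow(a)^2 + kb / nrow(b)^2 - 2 * kab / (nrow(a) * nrow(b))
  }
  for (n in c(1, 2, 5, 13, 20)) {
    a <- with_seed_local(n, matrix(rnorm(n * 2), n))
    b <- with_seed_local(n + 50, matrix(rnorm((21 - n) * 2, 1), 21 - n))
    expect_equal(mmd_squared(a, b, kern), max(brute(a, b, 1), 0),
                 tolerance = 1e-10)
    expect_equal(mmd_squared(a, b, kern), mmd_squared(b, a, kern))
    expect_gte(mmd_squared(a, b, kern), 0)
  }
  expect_error(mmd_squared(matrix(0, 0, 2), matrix(0, 1, 2), kern),
               "non-empty")
})

test_that("the MMD gradient matches finite differences", {
  kern <- list(family = "rbf", bandwidth = 0.8)
  A <- with_seed_local(7, matrix(rnorm(8), 4))
  B <- with_seed_local(8, matrix(rnorm(6, 0.5), 3))
  mg <- fa$mmd_squared_grad(A, B, kern)
  h <- 1e-6
  for (i in seq_along(A)) {
    Ap <- A; Ap[i] <- Ap[i] + h
    Am <- A; Am[i] <- Am[i] - h
    num <- (mmd_squared(Ap, B, kern) - mmd_squared(Am, B, kern)) / (2 * h)
    expect_equal(mg$dA[i], num, tolerance = 1e-5)
  }
})

test_that("the labeled loss is linear in alpha with fixed noise draws", {
  cfg0 <- small_cfg(alpha = 0)
  cfg1 <- small_cfg(alpha = 3)
  cfg2 <- small_cfg(alpha = 6)
  params <- with_seed_local(9, fa$vae_init_params(cfg0))
  x <- with_seed_local(10, matrix(rnorm(4 * 6), 4))
  y <- c("control", "autism", "asperger", "control")
  e1 <- with_seed_local(11, matrix(rnorm(12), 4))
  e2 <- with_seed_local(12, matrix(rnorm(8), 4))
  d <- rep("source", 4)
  l0 <- loss_labeled(params, x, d, y, cfg0, e1, e2)
  l1 <- loss_labeled(params, x, d, y, cfg1, e1, e2)
  l2 <- loss_labeled(params, x, d, y, cfg2, e1, e2)
  expect_identical(l0$classification_term, 0)
  expect_equal(l2$classification_term, 2 * l1$classification_term)
  expect_equal(l0$labeled_elbo_sum, l1$labeled_elbo_sum)
  expect_equal(l1$labeled_elbo_sum, l2$labeled_elbo_sum)
})

test_that("losses stay finite across random initializations", {
  cfg <- small_cfg()
  x <- with_seed_local(13, matrix(rnorm(3 * 6), 3))
  for (s in 1:100) {
    params <- with_seed_local(s, fa$vae_init_params(cfg))
    l <- with_seed_local(s + 1000,
                         loss_labeled(params, x, rep("source", 3),
                                      c("control", "autism", "asperger"),
                                      cfg))
    u <- with_seed_local(s + 2000,
                         loss_unlabeled(params, x, rep("target", 3), cfg))
    expect_true(is.finite(l$total))
    expect_true(is.finite(u$total))
  }
})

test_that("the unlabeled loss marginalizes exactly over the classes", {
  cfg <- small_cfg()
  params <- with_seed_local(14, fa$vae_init_params(cfg))
  x <- with_seed_local(15, matrix(rnorm(5 * 6), 5))
  d <- rep("target", 5)
  e1 <- with_seed_local(16, matrix(rnorm(15), 5))
  e2 <- with_seed_local(17, matrix(rnorm(10), 5))
  u <- loss_unlabeled(params, x, d, cfg, e1, e2)
  ## oracle: explicit enumeration over the three classes with the same
  ## noise draws, weighted by q(y | z1), minus the classifier entropy
  per_class <- sapply(c("control", "autism", "asperger"), function(cl)
    loss_labeled(params, x, d, rep(cl, 5), cfg, e1, e2)$per_sample)
  probs <- u$probs
  oracle <- rowSums(probs * per_class) + rowSums(probs * log(probs))
  expect_equal(u$per_sample, oracle, tolerance = 1e-10)
  expect_equal(u$unlabeled_elbo_sum, sum(oracle), tolerance = 1e-10)
  expect_equal(unname(u$elbo_by_class), unname(per_class),
               tolerance = 1e-10)
})

test_that("degenerate classifiers reduce the unlabeled loss as expected", {
  cfg <- small_cfg()
  params <- with_seed_local(18, fa$vae_init_params(cfg))
  x <- with_seed_local(19, matrix(rnorm(3 * 6), 3))
  d <- rep("target", 3)
  e1 <- with_seed_local(20, matrix(rnorm(9), 3))
  e2 <- with_seed_local(21, matrix(rnorm(6), 3))
  ## near point mass on class 2 (autism)
  params$W_c[] <- 0
  params$b_c <- c(-60, 0, -60)
  u <- loss_unlabeled(params, x, d, cfg, e1, e2)
  ls2 <- loss_labeled(params, x, d, rep("autism", 3), cfg, e1, e2)
  expect_equal(u$unlabeled_elbo_sum, ls2$labeled_elbo_sum,
               tolerance = 1e-6)
  ## uniform classifier: the entropy term is exactly log 3 per point
  params$b_c <- c(0, 0, 0)
  u2 <- loss_unlabeled(params, x, d, cfg, e1, e2)
  per_class <- u2$elbo_by_class
  expect_equal(u2$per_sample, rowMeans(per_class) - log(3),
               tolerance = 1e-10)
})

test_that("total loss composes its terms and honors beta", {
  cfg <- small_cfg(beta = 0)
  params <- with_seed_local(22, fa$vae_init_params(cfg))
  xs <- with_seed_local(23, matrix(rnorm(4 * 6), 4))
  xt <- with_seed_local(24, matrix(rnorm(3 * 6), 3))
  src <- list(x = xs, d = rep("source", 4),
              y = c("control", "autism", "asperger", "control"))
  tgt <- list(x = xt, d = rep("target", 3))
  tl0 <- with_seed_local(25, total_loss(params, src, tgt, cfg = cfg))
  expect_identical(tl0$mmd_term, 0)
  expect_equal(tl0$total, tl0$labeled_elbo_sum + tl0$unlabeled_elbo_sum +
                 tl0$classification_term)

  cfgb <- small_cfg(beta = 4)
  tlb <- with_seed_local(25, total_loss(params, src, tgt, cfg = cfgb))
  expect_gte(tlb$mmd_term, 0)
  mu_s <- encode_z1(params, xs, src$d, cfgb)$mean
  mu_t <- encode_z1(params, xt, tgt$d, cfgb)$mean
  expect_equal(tlb$mmd_term, 4 * mmd_squared(mu_s, mu_t, cfgb$kernel))

  ## an auxiliary cohort adds exactly one more MMD pair
  cfg3 <- vae_config(input_dim = 6, enc1_dim = 5, enc2_dim = 4,
                     z1_dim = 3, z2_dim = 2, alpha = 2.5, beta = 4,
                     kernel = list(family = "rbf", bandwidth = 0.9),
                     domain_ids = c("source", "target", "aux1"))
  xa <- with_seed_local(26, matrix(rnorm(2 * 6), 2))
  fa <- asNamespace("fcadapt")
  params3 <- with_seed_local(27, fa$vae_init_params(cfg3))
  tla <- with_seed_local(25, total_loss(params3, src, tgt,
                                        aux = list(list(x = xa,
                                                        d = rep("aux1", 2))),
                                        cfg = cfg3))
  mu_s3 <- encode_z1(params3, xs, src$d, cfg3)$mean
  mu_t3 <- encode_z1(params3, xt, tgt$d, cfg3)$mean
  mu_a3 <- encode_z1(params3, xa, rep("aux1", 2), cfg3)$mean
  expect_equal(tla$mmd_term,
               4 * (mmd_squared(mu_s3, mu_t3, cfg3$kernel) +
                      mmd_squared(mu_a3, mu_t3, cfg3$kernel)))
  expect_error(total_loss(params, src, list(x = xs[0, ], d = character(0)),
                          cfg = cfg), "no target")
})

test_that("hand-derived gradients match finite differences everywhere", {
  cfg <- small_cfg()
  params <- with_seed_local(42, fa$vae_init_params(cfg))
  xs <- with_seed_local(43, matrix(rnorm(4 * 6), 4))
  xt <- with_seed_local(44, matrix(rnorm(3 * 6), 3))
  dS <- fa$domain_onehot(rep("source", 4), cfg)
  dT <- fa$domain_onehot(rep("target", 3), cfg)
  ys <- c(1L, 2L, 3L, 2L)
  e1s <- with_seed_local(45, matrix(rnorm(12), 4))
  e2s <- with_seed_local(46, matrix(rnorm(8), 4))
  e1t <- with_seed_local(47, matrix(rnorm(9), 3))
  e2t <- with_seed_local(48, matrix(rnorm(6), 3))

  loss_fn <- function(p) {
    fs <- fa$vae_forward(p, xs, dS, ys, e1s, e2s, cfg)
    ft <- fa$vae_forward(p, xt, dT, NULL, e1t, e2t, cfg)
    mmd <- mmd_squared(fs$mu1, ft$mu1, cfg$kernel)
    sum(fs$ls) + cfg$alpha * sum(fs$ce) + sum(ft$lt) + cfg$beta * mmd
  }
  fs <- fa$vae_forward(params, xs, dS, ys, e1s, e2s, cfg)
  ft <- fa$vae_forward(params, xt, dT, NULL, e1t, e2t, cfg)
  mg <- fa$mmd_squared_grad(fs$mu1, ft$mu1, cfg$kernel)
  g <- fa$add_grads(
    fa$vae_backward(params, fs, cfg, cfg$beta * mg$dA),
    fa$vae_backward(params, ft, cfg, cfg$beta * mg$dB))
  h <- 1e-5
  for (nm in names(params)) {
    idx <- if (length(params[[nm]]) > 8)
      with_seed_local(match(nm, names(params)),
                      sample(length(params[[nm]]), 8))
    else seq_along(params[[nm]])
    for (i in idx) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - h
      num <- (loss_fn(pp) - loss_fn(pm)) / (2 * h)
      expect_equal(g[[nm]][i], num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("training is deterministic and records a full history", {
  cohort <- tiny_cohort()
  m <- as.data.frame(cohort$manifest)
  src <- m$domain == "source"
  cfg <- tiny_vae_config(epochs = 5)
  fit1 <- train_vae_mmd(cohort$features[src, ], m$diagnosis[src],
                        cohort$features[!src, ], cfg = cfg)
  fit2 <- train_vae_mmd(cohort$features[src, ], m$diagnosis[src],
                        cohort$features[!src, ], cfg = cfg)
  expect_identical(fit1$params, fit2$params)
  expect_identical(fit1$history, fit2$history)
  expect_equal(nrow(fit1$history), 5)
  expect_true(all(c("labeled_elbo_sum", "unlabeled_elbo_sum",
                    "classification_term", "mmd_term", "total",
                    "source_accuracy") %in% names(fit1$history)))
  expect_true(all(fit1$history$mmd_term >= 0))
  expect_length(fit1$checkpoints, 5)

  ## beta = 0 zeroes the MMD history
  cfg0 <- tiny_vae_config(epochs = 3, beta = 0)
  fit0 <- train_vae_mmd(cohort$features[src, ], m$diagnosis[src],
                        cohort$features[!src, ], cfg = cfg0)
  expect_identical(fit0$history$mmd_term, rep(0, 3))
})

test_that("training aborts with diagnostics when the loss diverges", {
  cohort <- tiny_cohort()
  m <- as.data.frame(cohort$manifest)
  src <- m$domain == "source"
  cfg <- tiny_vae_config(epochs = 30, learning_rate = 30)
  expect_error(train_vae_mmd(cohort$features[src, ], m$diagnosis[src],
                             cohort$features[!src, ], cfg = cfg),
               "diverged")
})

test_that("unlabeled data cannot smuggle labels into training", {
  cohort <- tiny_cohort()
  m <- as.data.frame(cohort$manifest)
  src <- m$domain == "source"
  masked <- mask_labels(cohort$manifest)
  expect_true(all(masked$diagnosis == "unknown"))
  ## labeled-loss entry points refuse unknown labels outright
  cfg <- tiny_vae_config()
  params <- with_seed_local(1, fa$vae_init_params(cfg))
  expect_error(loss_labeled(params, cohort$features[1:3, ],
                            rep("source", 3), rep("unknown", 3), cfg),
               "unlabeled")
})

test_that("checkpoints round-trip through save/load", {
  tf <- tiny_fit()
  dir <- withr::local_tempdir()
  save_checkpoint(tf$fit, dir)
  back <- load_checkpoint(dir)
  expect_equal(back$params, lapply(tf$fit$params, unname))
  expect_equal(back$cfg$alpha, tf$cfg$alpha)
  x <- tiny_cohort()$features[1:5, ]
  expect_equal(vae_predict(back$params, x, rep("source", 5), back$cfg),
               vae_predict(tf$fit$params, x, rep("source", 5), tf$cfg))
})
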