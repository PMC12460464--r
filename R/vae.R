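## Stacked semi-supervised VAE (latent-feature model M1 feeding a generative
## classifier model M2) with an alpha-weighted classification term and a
## beta-weighted MMD domain-confusion penalty, trained jointly on labeled
## source data, unlabeled target data, and optional control-only auxiliary
## cohorts.
##
## Generative model:   p(x | z1, d)  p(z1 | z2, y)  p(z2) = N(0, I)
##                     p(y) uniform over the classes
## Inference model:    q(z1 | x, d)  q(z2 | z1, y)  q(y | z1)
##
## Everything is minimized:   (-ELBO) + alpha * CE + beta * MMD
## Per labeled point the negative ELBO (single-sample reparameterized) is
##   -log p(x|z1,d) - log p(z1|z2,y) - log p(z2) - log p(y)
##   - H[q(z1|x,d)] - H[q(z2|z1,y)]
## and per unlabeled point the classifier marginalizes the class:
##   sum_y q(y|z1) L(x, d, y) - H[q(y|z1)].

LOG2PI <- log(2 * pi)

#' Configure the VAE-MMD model
#'
#' @param input_dim feature count (19,900 for 200-ROI FC vectors).
#' @param domain_ids finite set of domain identifiers; order fixes the
#'   domain one-hot encoding.
#' @param target_domain the one domain whose labels are never used and
#'   toward which every other domain's latent MMD is minimized.
#' @param enc1_dim,enc2_dim widths of the first/second encoding layers
#'   (defaults 2,000 and 1,000).
#' @param z1_dim,z2_dim latent dimensions (defaults `enc1_dim/4`,
#'   `enc2_dim/4`).
#' @param n_classes number of diagnostic classes (3).
#' @param alpha classification weight (>= 0); larger values push the model
#'   toward purely discriminative learning.
#' @param beta MMD weight (>= 0); larger values enforce more domain
#'   confusion.
#' @param kernel list: `family = "rbf"`, `bandwidth` a positive number or
#'   `"median"` for the median heuristic.
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param weight_decay decoupled L2 weight decay applied to weight
#'   matrices (not biases) each optimizer step, as a per-step shrink of
#'   `learning_rate * weight_decay`; combats overfitting at the small
#'   labeled sample sizes typical of neuroimaging cohorts.
#' @param epochs training epochs (default 50).
#' @param n_batches batches per epoch (default 20); every domain is cut
#'   into this many batches so all domains are trained simultaneously.
#' @param batch_size alternative to `n_batches`: fixes the source batch
#'   size and derives the batch count.
#' @param pretrain_epochs epochs of unsupervised M1 pretraining (encoder
#'   q(z1|x,d) and decoder p(x|z1,d) only, standard-normal prior on z1,
#'   all domains pooled) before the joint semi-supervised phase; 0
#'   disables pretraining.
#' @param classify_on feed the classifier the z1 posterior `"mean"`
#'   (default; matches prediction, which always uses the mean) or the
#'   reparameterized `"sample"`.
#' @param checkpoint_first_layer record the input rows of the first
#'   encoding layer each epoch (needed for feature importance).
#' @param seed RNG seed controlling init, shuffling and the reparameterized
#'   noise draws.
#' @return a `vae_mmd_config` list.
#' @export
vae_config <- function(input_dim,
                       domain_ids = c("source", "target"),
                       target_domain = "target",
                       enc1_dim = 2000, enc2_dim = 1000,
                       z1_dim = max(2L, enc1_dim %/% 4L),
                       z2_dim = max(2L, enc2_dim %/% 4L),
                       n_classes = 3L,
                       alpha = 50, beta = 1,
                       kernel = list(family = "rbf", bandwidth = "median"),
                       learning_rate = 1e-4, weight_decay = 0,
                       pretrain_epochs = 0L,
                       classify_on = c("mean", "sample"),
                       epochs = 50L, n_batches = 20L, batch_size = NULL,
                       checkpoint_first_layer = TRUE,
                       seed = 1L) {
  fail_if(alpha < 0 || beta < 0, "alpha and beta must be >= 0")
  fail_if(!(target_domain %in% domain_ids),
          "target_domain must be one of domain_ids")
  fail_if(sum(domain_ids == target_domain) != 1,
          "exactly one target domain required")
  fail_if(any(c(input_dim, enc1_dim, enc2_dim, z1_dim, z2_dim) < 1),
          "all dimensions must be positive")
  fail_if(!identical(kernel$family, "rbf"), "only the rbf kernel is supported")
  if (is.numeric(kernel$bandwidth))
    fail_if(kernel$bandwidth <= 0, "numeric bandwidth must be positive")
  structure(list(input_dim = as.integer(input_dim),
                 domain_ids = domain_ids, target_domain = target_domain,
                 n_domains = length(domain_ids),
                 enc1_dim = as.integer(enc1_dim),
                 enc2_dim = as.integer(enc2_dim),
                 z1_dim = as.integer(z1_dim), z2_dim = as.integer(z2_dim),
                 n_classes = as.integer(n_classes),
                 alpha = alpha, beta = beta, kernel = kernel,
                 learning_rate = learning_rate,
                 weight_decay = weight_decay,
                 pretrain_epochs = as.integer(pretrain_epochs),
                 classify_on = match.arg(classify_on),
                 epochs = as.integer(epochs),
                 n_batches = as.integer(n_batches),
                 batch_size = if (is.null(batch_size)) NULL
                              else as.integer(batch_size),
                 checkpoint_first_layer = isTRUE(checkpoint_first_layer),
                 seed = as.integer(seed)),
            class = "vae_mmd_config")
}

## Parameter initialization. Log-variance heads start at zero weights with
## a negative bias so initial posterior scales are moderate (~0.37).
vae_init_params <- function(cfg) {
  D <- cfg$input_dim; nd <- cfg$n_domains; K <- cfg$n_classes
  H1 <- cfg$enc1_dim; H2 <- cfg$enc2_dim
  z1 <- cfg$z1_dim; z2 <- cfg$z2_dim
  lv_bias <- -2
  list(
    W_e1 = init_weight(D + nd, H1), b_e1 = numeric(H1),
    W_mu1 = init_weight(H1, z1, 0.5), b_mu1 = numeric(z1),
    W_lv1 = matrix(0, H1, z1), b_lv1 = rep(lv_bias, z1),
    W_c = init_weight(z1, K, 0.5), b_c = numeric(K),
    W_e2 = init_weight(z1 + K, H2), b_e2 = numeric(H2),
    W_mu2 = init_weight(H2, z2, 0.5), b_mu2 = numeric(z2),
    W_lv2 = matrix(0, H2, z2), b_lv2 = rep(lv_bias, z2),
    W_d2 = init_weight(z2 + K, H2), b_d2 = numeric(H2),
    W_m1p = init_weight(H2, z1, 0.5), b_m1p = numeric(z1),
    W_lvp = matrix(0, H2, z1), b_lvp = rep(lv_bias, z1),
    W_d1 = init_weight(z1 + nd, H1), b_d1 = numeric(H1),
    W_x = init_weight(H1, D, 0.5), b_x = numeric(D),
    lv_x = 0)
}

zero_like <- function(params) lapply(params, function(p) p * 0)

## Domain one-hot for a vector of domain ids under a config.
domain_onehot <- function(d, cfg) one_hot(as.character(d), cfg$domain_ids)

#' Encode inputs to the z1 latent posterior
#'
#' Deterministic given parameters and inputs; the optional sample is
#' `mean + exp(logvar/2) * eps` with the drawn `eps` recorded.
#'
#' @param params model parameters from [train_vae_mmd()] (or
#'   `vae_init_params` internally).
#' @param x batch matrix (rows = subjects).
#' @param d domain id per row (character) or a precomputed one-hot matrix.
#' @param cfg the `vae_mmd_config`.
#' @param sample draw a reparameterized sample?
#' @return list with `mean`, `logvar` (rows = subjects) and, if requested,
#'   `sample` and `eps`.
#' @export
encode_z1 <- function(params, x, d, cfg, sample = FALSE) {
  x <- as.matrix(x)
  fail_if(ncol(x) != cfg$input_dim, "x has %d columns, config expects %d",
          ncol(x), cfg$input_dim)
  dOH <- if (is.matrix(d)) d else domain_onehot(d, cfg)
  A1 <- cbind(x, dOH)
  H1 <- relu(sweep(A1 %*% params$W_e1, 2, params$b_e1, "+"))
  mean <- sweep(H1 %*% params$W_mu1, 2, params$b_mu1, "+")
  logvar <- sweep(H1 %*% params$W_lv1, 2, params$b_lv1, "+")
  out <- list(mean = mean, logvar = logvar)
  if (sample) {
    eps <- matrix(stats::rnorm(length(mean)), nrow(mean))
    out$eps <- eps
    out$sample <- mean + exp(logvar / 2) * eps
  }
  out
}

#' Class probabilities q(y | z1)
#'
#' Uses the posterior mean of z1, so the output is deterministic given
#' parameters and inputs. Rows sum to 1.
#'
#' @inheritParams encode_z1
#' @return n x n_classes probability matrix with class-name columns.
#' @export
vae_classify <- function(params, x, d, cfg) {
  z1 <- encode_z1(params, x, d, cfg)$mean
  p <- softmax_rows(sweep(z1 %*% params$W_c, 2, params$b_c, "+"))
  colnames(p) <- CLASS_LEVELS[seq_len(cfg$n_classes)]
  p
}

#' Predict class labels
#'
#' Argmax of [vae_classify()]; exact ties go to the lowest class index.
#'
#' @inheritParams encode_z1
#' @return character vector of class labels.
#' @export
vae_predict <- function(params, x, d, cfg) {
  p <- vae_classify(params, x, d, cfg)
  fail_if(any(!is.finite(p)), "non-finite class probabilities (untrained or diverged parameters)")
  colnames(p)[max.col(p, ties.method = "first")]
}

#' Squared maximum mean discrepancy between two sample sets
#'
#' Biased V-statistic with an RBF kernel:
#' `mean k(a,a') + mean k(b,b') - 2 mean k(a,b)`; symmetric and >= 0.
#'
#' @param A,B numeric matrices (rows = samples) or vectors (1-D samples).
#' @param kernel list with `family = "rbf"` and `bandwidth` (positive
#'   number, the sigma of `exp(-||u-v||^2 / (2 sigma^2))`, or `"median"`
#'   for the median heuristic over pooled pairwise distances).
#' @return non-negative scalar.
#' @export
mmd_squared <- function(A, B, kernel = list(family = "rbf",
                                            bandwidth = "median")) {
  if (is.vector(A)) A <- matrix(A, ncol = 1)
  if (is.vector(B)) B <- matrix(B, ncol = 1)
  fail_if(nrow(A) == 0 || nrow(B) == 0, "sample sets must be non-empty")
  s2 <- rbf_bandwidth2(A, B, kernel)
  max(mean(rbf_gram(A, A, s2)) + mean(rbf_gram(B, B, s2)) -
        2 * mean(rbf_gram(A, B, s2)), 0)
}

## sigma^2 for the RBF kernel; median heuristic over pooled pairwise
## distances, floored to keep the kernel defined on degenerate sets.
rbf_bandwidth2 <- function(A, B, kernel) {
  if (is.numeric(kernel$bandwidth)) return(kernel$bandwidth^2)
  X <- rbind(A, B)
  d2 <- sq_dists(X, X)
  med <- stats::median(sqrt(d2[upper.tri(d2)]))
  max(med^2, 1e-12)
}

sq_dists <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

rbf_gram <- function(A, B, s2) exp(-sq_dists(A, B) / (2 * s2))

## MMD^2 with gradients w.r.t. both sample sets (sigma treated constant).
mmd_squared_grad <- function(A, B, kernel) {
  n <- nrow(A); m <- nrow(B)
  s2 <- rbf_bandwidth2(A, B, kernel)
  Kaa <- rbf_gram(A, A, s2); Kbb <- rbf_gram(B, B, s2)
  Kab <- rbf_gram(A, B, s2)
  value <- mean(Kaa) + mean(Kbb) - 2 * mean(Kab)
  ## d/dA_i of mean Kaa: (2/n^2) sum_j -K(a_i,a_j)(a_i-a_j)/s2
  dA <- (-2 / (n^2 * s2)) * (rowSums(Kaa) * A - Kaa %*% A) +
    (2 / (n * m * s2)) * (rowSums(Kab) * A - Kab %*% B)
  dB <- (-2 / (m^2 * s2)) * (rowSums(Kbb) * B - Kbb %*% B) +
    (2 / (n * m * s2)) * (colSums(Kab) * B - t(Kab) %*% A)
  list(value = value, dA = dA, dB = dB)
}
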