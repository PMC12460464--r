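## Minimal dense-network numerics shared by the VAE-MMD model and the MLP
## baseline: ReLU, row softmax, weight init, and a vectorized Adam
## optimizer over named parameter lists.

relu <- function(x) pmax(x, 0)

## Row-wise log-softmax / softmax, numerically stable.
log_softmax_rows <- function(z) {
  m <- apply(z, 1, max)
  zs <- z - m
  zs - log(rowSums(exp(zs)))
}

softmax_rows <- function(z) exp(log_softmax_rows(z))

## He-scaled Gaussian init for a fan_in x fan_out weight matrix.
init_weight <- function(fan_in, fan_out, scale = 1) {
  matrix(stats::rnorm(fan_in * fan_out, 0, scale * sqrt(2 / fan_in)),
         fan_in, fan_out)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

## Generic feed-forward classifier (hidden ReLU layers + softmax head),
## used by the MLP baseline. params: W1,b1,...,Wk,bk,Wo,bo.
mlp_init <- function(input_dim, hidden, n_classes) {
  dims <- c(input_dim, hidden)
  params <- list()
  for (i in seq_along(hidden)) {
    params[[paste0("W", i)]] <- init_weight(dims[i], dims[i + 1])
    params[[paste0("b", i)]] <- numeric(dims[i + 1])
  }
  params$Wo <- init_weight(dims[length(dims)], n_classes, scale = 0.5)
  params$bo <- numeric(n_classes)
  params
}

mlp_forward <- function(params, x, n_hidden) {
  h <- list(x)
  pre <- list()
  for (i in seq_len(n_hidden)) {
    pre[[i]] <- sweep(h[[i]] %*% params[[paste0("W", i)]], 2,
                      params[[paste0("b", i)]], "+")
    h[[i + 1]] <- relu(pre[[i]])
  }
  logits <- sweep(h[[n_hidden + 1]] %*% params$Wo, 2, params$bo, "+")
  list(h = h, pre = pre, logits = logits)
}

## Cross-entropy loss + gradients for mlp_forward. y: integer class (1-based).
mlp_backward <- function(params, fw, y, n_hidden) {
  n <- nrow(fw$logits)
  logp <- log_softmax_rows(fw$logits)
  p <- exp(logp)
  loss <- -sum(logp[cbind(seq_len(n), y)]) / n
  dlogits <- p
  dlogits[cbind(seq_len(n), y)] <- dlogits[cbind(seq_len(n), y)] - 1
  dlogits <- dlogits / n
  grads <- list()
  grads$Wo <- crossprod(fw$h[[n_hidden + 1]], dlogits)
  grads$bo <- colSums(dlogits)
  dh <- dlogits %*% t(params$Wo)
  for (i in rev(seq_len(n_hidden))) {
    dpre <- dh * (fw$pre[[i]] > 0)
    grads[[paste0("W", i)]] <- crossprod(fw$h[[i]], dpre)
    grads[[paste0("b", i)]] <- colSums(dpre)
    dh <- dpre %*% t(params[[paste0("W", i)]])
  }
  list(loss = loss, grads = grads[names(params)])
}
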