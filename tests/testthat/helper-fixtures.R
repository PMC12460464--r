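## Shared fixtures, memoized so expensive simulations and fits are built
## once per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

## Strong-signal, no-site-effect cohort (the default study conditions with
## site effects switched off).
strong_cohort <- function() memo("strong", {
  simulate_cohort(sim_config(n_rois = 30, class_effect = 0.6,
                             site_additive_sd = 0, domain_additive_sd = 0,
                             site_scale_range = c(1, 1), seed = 0))
})

## Site-shifted cohort at the default simulator settings.
shifted_cohort <- function() memo("shifted", {
  simulate_cohort(sim_config(n_rois = 30, seed = 0))
})

## Tiny two-domain cohort for fast end-to-end runs (10 ROIs, 45 features).
tiny_cohort <- function() memo("tiny", {
  sites <- data.frame(site = c("s1", "t1"), domain = c("source", "target"),
                      control = 30, autism = 30, asperger = 30)
  simulate_cohort(sim_config(n_rois = 10, sites = sites, n_affected = 10,
                             class_effect = 0.6, site_additive_sd = 0,
                             domain_additive_sd = 0,
                             site_scale_range = c(1, 1), seed = 0))
})

## Canonical toy VAE-MMD configuration used throughout the suite.
toy_vae_config <- function(...) {
  args <- utils::modifyList(
    list(input_dim = 435, enc1_dim = 64, enc2_dim = 32,
         z1_dim = 16, z2_dim = 8, alpha = 1000, beta = 1,
         epochs = 50, n_batches = 20, seed = 0), list(...))
  do.call(vae_config, args)
}

tiny_vae_config <- function(...) {
  args <- utils::modifyList(
    list(input_dim = 45, enc1_dim = 32, enc2_dim = 16,
         z1_dim = 8, z2_dim = 4, alpha = 1000, beta = 1,
         learning_rate = 1e-3, epochs = 80, n_batches = 10,
         seed = 0), list(...))
  do.call(vae_config, args)
}

## Importance-recovery fit on the tiny cohort (reused by several tests).
tiny_fit <- function() memo("tiny_fit", {
  cohort <- tiny_cohort()
  m <- as.data.frame(cohort$manifest)
  src <- m$domain == "source"
  cfg <- tiny_vae_config()
  fit <- train_vae_mmd(cohort$features[src, ], m$diagnosis[src],
                       cohort$features[!src, ], cfg = cfg)
  list(fit = fit, cfg = cfg, src = src, m = m)
})

## Zeroed parameters of a config (all weights and biases 0).
zero_params <- function(cfg) {
  p <- with_seed_local(1L, fcadapt:::vae_init_params(cfg))
  lapply(p, function(x) x * 0)
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

## Mean silhouette of a 2-cluster labeling (internal test statistic only).
mini_silhouette <- function(xy, lab) {
  d <- as.matrix(stats::dist(xy))
  mean(vapply(seq_len(nrow(xy)), function(i) {
    same <- which(lab == lab[i] & seq_along(lab) != i)
    a <- mean(d[i, same])
    b <- min(vapply(setdiff(unique(lab), lab[i]),
                    function(l) mean(d[i, lab == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1)))
}
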