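test_that("simulated cohorts have the declared shape and bounds", {
  cohort <- tiny_cohort()
  expect_equal(ncol(cohort$features), 45)
  expect_equal(nrow(cohort$features), 180)
  expect_true(all(abs(cohort$features) < 1))
  expect_equal(rownames(cohort$features), cohort$manifest$subject_id)
  expect_s3_class(cohort$manifest, "cohort_manifest")
  expect_equal(anyDuplicated(cohort$manifest$subject_id), 0)

  ## a 200-ROI configuration yields 19,900 features per subject
  sites <- data.frame(site = "s", domain = "source", control = 2,
                      autism = 0, asperger = 0)
  big <- simulate_cohort(sim_config(n_rois = 200, sites = sites,
                                    n_affected = 100, seed = 1))
  expect_equal(ncol(big$features), 19900)
})

test_that("simulation is reproducible and validates its config", {
  cfg <- sim_config(n_rois = 8, seed = 9)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$features, b$features)
  expect_identical(a$truth, b$truth)

  empty <- data.frame(site = "s", domain = "source", control = 0,
                      autism = 0, asperger = 0)
  expect_error(sim_config(sites = empty), "zero total subjects")
  expect_error(sim_config(n_rois = 5, n_affected = 99), "exceeds")
  expect_error(sim_config(site_scale_range = c(2, 1)), "interval")
})

test_that("the Asperger mean lies between control and autism", {
  truth <- strong_cohort()$truth
  aff <- truth$affected_features
  cm <- truth$class_means
  expect_true(all(cm[aff, "asperger"] > cm[aff, "control"]))
  expect_true(all(cm[aff, "asperger"] < cm[aff, "autism"]))
  ## and closer to autism than to control
  expect_true(all(cm[aff, "autism"] - cm[aff, "asperger"] <
                    cm[aff, "asperger"] - cm[aff, "control"]))
  ## unaffected features identical across classes
  expect_equal(cm[-aff, "control"], cm[-aff, "autism"])
})

test_that("site-effect injection is the stated affine map", {
  x <- with_seed_local(5, matrix(rnorm(20 * 6), 20))
  sites <- rep(c("A", "B"), each = 10)
  id <- list(A = list(gamma = rep(0, 6), delta = rep(1, 6)),
             B = list(gamma = rep(0, 6), delta = rep(1, 6)))
  expect_equal(inject_site_effects(x, id, sites), x)

  shift <- list(A = list(gamma = rep(0.5, 6), delta = rep(1, 6)),
                B = list(gamma = rep(0, 6), delta = rep(1, 6)))
  out <- inject_site_effects(x, shift, sites)
  expect_equal(colMeans(out[1:10, ]) - colMeans(x[1:10, ]), rep(0.5, 6))
  expect_equal(out[11:20, ], x[11:20, ])

  scale2 <- list(A = list(gamma = rep(0, 6), delta = rep(2, 6)),
                 B = list(gamma = rep(0, 6), delta = rep(1, 6)))
  out2 <- inject_site_effects(x, scale2, sites)
  expect_equal(apply(out2[1:10, ], 2, sd), 2 * apply(x[1:10, ], 2, sd))

  expect_error(inject_site_effects(x, id, rep("C", 20)), "unknown site")
})

test_that("under the null, across-site KS tests reject at the nominal rate", {
  ## class_effect = 0 and no site effects: any feature has the same
  ## distribution at every site, so a 5% KS test should reject ~5% of
  ## the time across repeated simulations
  sites <- data.frame(site = c("A", "B"), domain = "source",
                      control = 20, autism = 0, asperger = 0)
  rejections <- vapply(1:100, function(s) {
    cohort <- simulate_cohort(sim_config(
      n_rois = 6, sites = sites, class_effect = 0, n_affected = 0,
      site_additive_sd = 0, site_scale_range = c(1, 1), seed = 5000 + s))
    f <- cohort$features[, 1]
    site <- cohort$manifest$site
    suppressWarnings(
      stats::ks.test(f[site == "A"], f[site == "B"])$p.value) < 0.05
  }, logical(1))
  expect_gte(sum(rejections), 1)
  expect_lte(sum(rejections), 12)
})

test_that("simulated time series reproduce the target correlations", {
  sites <- data.frame(site = "s", domain = "source", control = 2,
                      autism = 0, asperger = 0)
  cfg0 <- sim_config(n_rois = 5, sites = sites, class_effect = 0,
                     n_affected = 0, site_additive_sd = 0,
                     site_scale_range = c(1, 1),
                     mode = "timeseries", t_points = 4000, seed = 2)
  sim0 <- suppressMessages(simulate_timeseries(cfg0))
  ## per-subject sample FC within Pearson sampling error of the target
  for (i in 1:2) {
    target <- fcadapt:::nearest_pd_correlation(devectorize_upper(
      inverse_fisher_z(sim0$truth$features_z[i, ]), 5))
    got <- compute_fc(sim0$series[[i]])
    expect_lt(max(abs(got - target)), 3 / sqrt(4000))
  }

  ## reproducibility
  sim0b <- suppressMessages(simulate_timeseries(cfg0))
  expect_identical(sim0$series, sim0b$series)
})

test_that("a strong pairwise correlation survives the sampling step", {
  ## build one subject whose target FC has r = 0.8 on a single pair
  v <- rep(0, 10)
  v[pair_to_index(0, 1, 5) + 1] <- 0.8
  target <- devectorize_upper(v, 5)
  L <- chol(target)
  ts <- with_seed_local(11,
                        matrix(rnorm(5000 * 5), 5000) %*% L)
  got <- compute_fc(ts)
  expect_lt(abs(got[1, 2] - 0.8), 0.02)
})

test_that("FC -> time series -> FC round trip closes at large T", {
  sites <- data.frame(site = "s", domain = "source", control = 3,
                      autism = 3, asperger = 0)
  cfg <- sim_config(n_rois = 6, sites = sites, mode = "timeseries",
                    t_points = 6000, n_affected = 5, seed = 13)
  sim <- suppressMessages(simulate_timeseries(cfg))
  for (i in seq_along(sim$series)) {
    truth_fc <- devectorize_upper(
      inverse_fisher_z(sim$truth$features_z[i, ]), 6)
    truth_fc <- fcadapt:::nearest_pd_correlation(truth_fc)
    got <- vectorize_upper(compute_fc(sim$series[[i]]))
    expect_lt(max(abs(got - vectorize_upper(truth_fc))), 4 / sqrt(6000))
  }
})

test_that("separability increases monotonically with class effect", {
  sites <- data.frame(site = "s", domain = "source", control = 40,
                      autism = 40, asperger = 0)
  accs <- vapply(c(0.1, 0.3, 0.6), function(eff) {
    cohort <- simulate_cohort(sim_config(
      n_rois = 12, sites = sites, class_effect = eff, n_affected = 15,
      site_additive_sd = 0, site_scale_range = c(1, 1), seed = 21))
    x <- cohort$features
    y <- factor(cohort$manifest$diagnosis)
    folds <- with_seed_local(1, sample(rep(1:4, length.out = nrow(x))))
    mean(vapply(1:4, function(f) {
      fit <- e1071::svm(x[folds != f, ], y[folds != f],
                        kernel = "linear", scale = FALSE)
      mean(predict(fit, x[folds == f, ]) == y[folds == f])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(accs) > 0))
})

test_that("cohorts write to disk in the documented formats", {
  dir <- withr::local_tempdir()
  cohort <- tiny_cohort()
  write_cohort(cohort, dir)
  x <- read_fc_matrix(file.path(dir, "features.tsv"))
  expect_equal(unname(x), unname(cohort$features))
  m <- read_manifest(file.path(dir, "manifest.tsv"))
  expect_equal(m$subject_id, cohort$manifest$subject_id)
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$affected_features, cohort$truth$affected_features)
})
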