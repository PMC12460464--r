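## Synthetic multi-site FC cohort generator with known ground truth.
##
## All effects are composed in Fisher-z space and mapped through tanh, so
## simulated FC stays strictly inside (-1, 1) and the additive/multiplicative
## site-effect model that ComBat assumes is exactly correct in z-space:
##
##   z[s, f] = mu[f] + class_shift[y(s), f] + gamma[site(s), f]
##             + delta[site(s), f] * eps[s, f],   eps ~ N(0, noise_sd^2)

#' Configure a synthetic multi-site cohort
#'
#' @param n_rois region count; features number n_rois(n_rois-1)/2.
#' @param sites data.frame with columns `site`, `domain`, `control`,
#'   `autism`, `asperger` (per-class subject counts). Default: three sites
#'   per domain for domains "source" and "target", 20 subjects per class
#'   per site.
#' @param class_effect mean z-shift of the autism class on affected
#'   features; the Asperger shift is `asperger_frac * class_effect`,
#'   placing Asperger between control and autism but closer to autism.
#' @param asperger_frac fraction of the autism shift given to Asperger.
#' @param n_affected number of affected features.
#' @param site_additive_sd SD of per-site per-feature additive offsets
#'   (gamma, z units).
#' @param domain_additive_sd SD of a per-domain per-feature additive
#'   offset shared by every site of the domain (z units). This is the
#'   systematic release-level shift (different scanners, protocols and
#'   recruitment between data releases) that domain adaptation targets;
#'   site offsets alone average out across sites and produce little
#'   cross-domain degradation.
#' @param site_scale_range range of per-site per-feature multiplicative
#'   factors (delta) on the subject noise; `c(1, 1)` disables them.
#' @param subject_noise_sd per-subject feature noise SD (z units).
#' @param mode `"fc"` (feature matrix) or `"timeseries"` (per-subject T x R
#'   series whose population correlation equals the subject's FC matrix).
#' @param t_points time points per subject in timeseries mode.
#' @param seed RNG seed; identical seeds give identical cohorts.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_rois = 30,
                       sites = default_sites(),
                       class_effect = 0.6,
                       asperger_frac = 2 / 3,
                       n_affected = min(40, floor(n_rois * (n_rois - 1) / 4)),
                       site_additive_sd = 0.15,
                       domain_additive_sd = 0.25,
                       site_scale_range = c(0.8, 1.3),
                       subject_noise_sd = 0.3,
                       mode = c("fc", "timeseries"),
                       t_points = 200,
                       seed = 1L) {
  mode <- match.arg(mode)
  n_feat <- n_rois * (n_rois - 1) / 2
  fail_if(n_rois < 3, "n_rois must be >= 3")
  fail_if(n_affected > n_feat,
          "n_affected (%d) exceeds feature count (%d)", n_affected, n_feat)
  fail_if(length(site_scale_range) != 2 || any(site_scale_range <= 0) ||
            site_scale_range[2] < site_scale_range[1],
          "site_scale_range must be a positive increasing interval")
  fail_if(!all(c("site", "domain", "control", "autism", "asperger") %in%
                 names(sites)), "sites must have site/domain/class columns")
  fail_if(sum(sites$control + sites$autism + sites$asperger) == 0,
          "zero total subjects")
  fail_if(mode == "timeseries" && t_points < 2, "t_points must be >= 2")
  structure(list(n_rois = n_rois, n_features = n_feat, sites = sites,
                 class_effect = class_effect, asperger_frac = asperger_frac,
                 n_affected = n_affected,
                 site_additive_sd = site_additive_sd,
                 domain_additive_sd = domain_additive_sd,
                 site_scale_range = site_scale_range,
                 subject_noise_sd = subject_noise_sd,
                 mode = mode, t_points = t_points, seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @param n_per_class subjects per class per site.
#' @param domains domain identifiers.
#' @param n_sites sites per domain.
#' @export
default_sites <- function(n_per_class = 20, domains = c("source", "target"),
                          n_sites = 3) {
  do.call(rbind, lapply(domains, function(d) {
    data.frame(site = sprintf("%s_s%d", d, seq_len(n_sites)), domain = d,
               control = n_per_class, autism = n_per_class,
               asperger = n_per_class, stringsAsFactors = FALSE)
  }))
}

#' Apply per-site affine effects in z-space
#'
#' `out[s, f] = delta[site(s), f] * x[s, f] + gamma[site(s), f]`.
#'
#' @param features_z subjects x features matrix (Fisher-z space).
#' @param site_params named list per site, each with numeric vectors
#'   `gamma` and `delta` of length `ncol(features_z)`.
#' @param site_assignment site id per row.
#' @return shifted matrix, same shape.
#' @export
inject_site_effects <- function(features_z, site_params, site_assignment) {
  fail_if(length(site_assignment) != nrow(features_z),
          "site_assignment length mismatch")
  unknown <- setdiff(unique(site_assignment), names(site_params))
  fail_if(length(unknown) > 0, "unknown site id(s): %s",
          paste(unknown, collapse = ", "))
  out <- features_z
  for (s in unique(site_assignment)) {
    rows <- site_assignment == s
    p <- site_params[[s]]
    out[rows, ] <- sweep(sweep(features_z[rows, , drop = FALSE], 2,
                               p$delta, "*"), 2, p$gamma, "+")
  }
  out
}

#' Simulate a multi-site FC cohort with known ground truth
#'
#' @param config a [sim_config()].
#' @return list with `features` (subjects x features, strictly in (-1, 1),
#'   subject ids as rownames), `manifest` (a `cohort_manifest` carrying the
#'   true diagnoses), and `truth` (class mean vectors in z units, affected
#'   feature indices (1-based), per-site gamma/delta, noise SD, and the
#'   pre-tanh z matrix `features_z`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    F <- config$n_features
    sites <- config$sites
    ## subject roster
    roster <- do.call(rbind, lapply(seq_len(nrow(sites)), function(i) {
      counts <- c(control = sites$control[i], autism = sites$autism[i],
                  asperger = sites$asperger[i])
      if (sum(counts) == 0) return(NULL)
      data.frame(site = sites$site[i], domain = sites$domain[i],
                 diagnosis = rep(names(counts), counts),
                 stringsAsFactors = FALSE)
    }))
    n <- nrow(roster)
    roster$subject_id <- sprintf("sim_%s_%04d", roster$site,
                                 stats::ave(seq_len(n), roster$site,
                                            FUN = seq_along))
    ## ground truth in z-space
    mu <- stats::rnorm(F, mean = 0.2, sd = 0.2)
    affected <- sort(sample.int(F, config$n_affected))
    shift <- c(control = 0, asperger = config$asperger_frac, autism = 1) *
      config$class_effect
    class_means <- sapply(c("control", "autism", "asperger"), function(cl) {
      m <- mu
      m[affected] <- m[affected] + shift[[cl]]
      m
    })
    domain_ids <- unique(sites$domain)
    domain_gamma <- lapply(domain_ids, function(d)
      stats::rnorm(F, 0, config$domain_additive_sd))
    names(domain_gamma) <- domain_ids
    ## each site's additive effect is its domain's shared offset plus a
    ## site-specific offset
    site_params <- lapply(seq_len(nrow(sites)), function(i) {
      list(gamma = domain_gamma[[sites$domain[i]]] +
             stats::rnorm(F, 0, config$site_additive_sd),
           delta = stats::runif(F, config$site_scale_range[1],
                                config$site_scale_range[2]))
    })
    names(site_params) <- sites$site
    ## compose: mean + site-affine(noise)
    mean_part <- t(class_means[, roster$diagnosis])
    noise <- matrix(stats::rnorm(n * F, 0, config$subject_noise_sd), n, F)
    z <- mean_part + inject_site_effects(noise, site_params, roster$site)
    features <- inverse_fisher_z(z)
    rownames(features) <- roster$subject_id
    rownames(z) <- roster$subject_id
    manifest <- cohort_manifest(roster$subject_id, roster$site,
                                roster$domain, roster$diagnosis,
                                provenance = "simulate_cohort")
    truth <- list(class_means = class_means, affected_features = affected,
                  site_params = site_params,
                  noise_sd = config$subject_noise_sd,
                  features_z = z)
    list(features = features, manifest = manifest, truth = truth)
  })
}

#' Simulate per-subject ROI time series
#'
#' Each subject's series is drawn from a zero-mean multivariate normal whose
#' population correlation matrix equals the subject's ground-truth FC
#' matrix; non-positive-definite targets are repaired by eigenvalue
#' clipping (at 1e-8) with a message.
#'
#' @param config a [sim_config()] with `mode = "timeseries"`.
#' @return list with `series` (named list of T x R matrices), `manifest`,
#'   and `truth` (as in [simulate_cohort()]).
#' @export
simulate_timeseries <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fail_if(config$mode != "timeseries", "config mode must be 'timeseries'")
  cohort <- simulate_cohort(config)
  n_repaired <- 0L
  series <- with_seed(config$seed + 1L, {
    lapply(seq_len(nrow(cohort$features)), function(i) {
      cmat <- devectorize_upper(cohort$features[i, ], config$n_rois)
      pd <- nearest_pd_correlation(cmat)
      if (attr(pd, "repaired")) n_repaired <<- n_repaired + 1L
      L <- chol(pd)
      matrix(stats::rnorm(config$t_points * config$n_rois),
             config$t_points) %*% L
    })
  })
  if (n_repaired > 0)
    message(sprintf("nearest-PD repair applied to %d target correlation matrices",
                    n_repaired))
  names(series) <- rownames(cohort$features)
  list(series = series, manifest = cohort$manifest, truth = cohort$truth)
}

## Eigenvalue-clipped nearest positive-definite correlation matrix.
nearest_pd_correlation <- function(m, eps = 1e-8) {
  e <- eigen(m, symmetric = TRUE)
  repaired <- any(e$values < eps)
  if (repaired) {
    v <- pmax(e$values, eps)
    m <- e$vectors %*% (v * t(e$vectors))
    d <- sqrt(diag(m))
    m <- m / outer(d, d)   # restore unit diagonal
    m <- (m + t(m)) / 2
  }
  structure(m, repaired = repaired)
}

#' Hide diagnosis labels (mark records unlabeled)
#'
#' Semi-supervised training must never read target-domain labels; records
#' passed as unlabeled carry diagnosis `"unknown"` by construction.
#'
#' @param manifest a `cohort_manifest`.
#' @return the manifest with every diagnosis set to `"unknown"`.
#' @export
mask_labels <- function(manifest) {
  manifest$diagnosis <- "unknown"
  manifest
}

#' Write a simulated cohort to disk
#'
#' Feature matrix as TSV (subject_id first column), manifest TSV, ground
#' truth as JSON (class means, affected indices, site params, noise SD).
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fc_matrix(cohort$features, file.path(dir, "features.tsv"))
  write_manifest(cohort$manifest, file.path(dir, "manifest.tsv"))
  truth <- cohort$truth
  truth$features_z <- NULL  # derivable; keep the JSON small
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
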