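## End-to-end experiment harness: split -> (optional ComBat) -> train ->
## evaluate, with a runtime leakage guard keeping held-out subjects out of
## every fitting call and target-domain labels out of training.

#' Assert that no held-out subject reaches a fitting routine
#'
#' @param fit_ids subject ids entering a fit.
#' @param test_ids held-out subject ids.
#' @param what label for the error message.
#' @export
assert_no_leakage <- function(fit_ids, test_ids, what = "fit") {
  leaked <- intersect(fit_ids, test_ids)
  fail_if(length(leaked) > 0,
          "leakage: %d held-out subject(s) reached %s (e.g. %s)",
          length(leaked), what, leaked[1])
  invisible(TRUE)
}

#' Run a full domain-adaptation experiment
#'
#' Splits the source and target domains into train/validation/test,
#' optionally ComBat-harmonizes (fit on training subjects only, applied to
#' the rest), trains the VAE-MMD model on labeled source training data,
#' label-masked target training data and any auxiliary control-only
#' domains, and scores source/target test sets. Target labels are used
#' only for evaluation, never for fitting.
#'
#' @param features subjects x features matrix (rownames = subject ids
#'   covering every manifest record).
#' @param manifest a `cohort_manifest` with domains matching
#'   `cfg$domain_ids`; auxiliary domains are used in full as control-only
#'   training data.
#' @param cfg a [vae_config()].
#' @param split_fractions train/validation/test fractions per domain.
#' @param split_seed seed of the split shuffle.
#' @param harmonize apply ComBat (site as batch, diagnosis preserved where
#'   labeled) before training?
#' @param combat_fit_on `"train"` (default; honors strict dataset
#'   separation) or `"all"` (harmonize before splitting).
#' @return list: `fit`, `metrics` (source/target test reports), `kl`
#'   (latent source-target Gaussian KL on training data), `splits`,
#'   `predictions` (target test data.frame).
#' @export
run_experiment <- function(features, manifest, cfg,
                           split_fractions = c(0.7, 0.15, 0.15),
                           split_seed = cfg$seed,
                           harmonize = FALSE,
                           combat_fit_on = c("train", "all")) {
  combat_fit_on <- match.arg(combat_fit_on)
  features <- as.matrix(features)
  fail_if(!all(manifest$subject_id %in% rownames(features)),
          "feature matrix is missing manifest subjects")
  df <- as.data.frame(manifest)
  fail_if(!all(unique(df$domain) %in% cfg$domain_ids),
          "manifest domains not declared in cfg$domain_ids")

  part_of <- function(dom) {
    sub <- df[df$domain == dom, , drop = FALSE]
    m <- cohort_manifest(sub$subject_id, sub$site, sub$domain,
                         sub$diagnosis, sub$age, sub$sex)
    split_cohort(m, split_spec("fractions", split_fractions,
                               stratify_by = "diagnosis",
                               seed = split_seed))
  }
  splits <- list(source = part_of("source"), target = part_of("target"))
  test_ids <- c(splits$source$test$subject_id,
                splits$target$test$subject_id)
  val_ids <- c(splits$source$validation$subject_id,
               splits$target$validation$subject_id)

  aux_names <- setdiff(cfg$domain_ids, c("source", "target"))
  aux_ids <- lapply(aux_names, function(a) df$subject_id[df$domain == a])
  names(aux_ids) <- aux_names

  fit_ids <- c(splits$source$train$subject_id,
               splits$target$train$subject_id, unlist(aux_ids))
  assert_no_leakage(fit_ids, test_ids, "model training")

  x <- features
  if (harmonize) {
    combat_ids <- if (combat_fit_on == "train") fit_ids else df$subject_id
    assert_no_leakage(combat_ids,
                      if (combat_fit_on == "train") test_ids else character(0),
                      "ComBat fitting")
    sub <- df[match(combat_ids, df$subject_id), ]
    design_fit <- batch_design(sub$site, diagnosis_covariates(sub$diagnosis))
    model <- fit_combat(x[combat_ids, , drop = FALSE], design_fit)
    design_all <- batch_design(df$site, diagnosis_covariates(df$diagnosis))
    x[df$subject_id, ] <- apply_combat(model,
                                       x[df$subject_id, , drop = FALSE],
                                       design_all)
  }

  src_tr <- splits$source$train
  tgt_tr <- mask_labels(splits$target$train)
  fail_if(!all(tgt_tr$diagnosis == "unknown"),
          "target training labels must be masked")
  aux <- lapply(aux_ids, function(ids) x[ids, , drop = FALSE])
  val_src <- splits$source$validation
  fit <- train_vae_mmd(x[src_tr$subject_id, , drop = FALSE],
                       src_tr$diagnosis,
                       x[tgt_tr$subject_id, , drop = FALSE],
                       aux = aux, cfg = cfg,
                       eval_data = if (!is.null(val_src))
                         list(x = x[val_src$subject_id, , drop = FALSE],
                              d = rep("source", nrow(val_src)),
                              y = val_src$diagnosis))

  score_part <- function(part, dom) {
    if (is.null(part)) return(NULL)
    pred <- vae_predict(fit$params, x[part$subject_id, , drop = FALSE],
                        rep(dom, nrow(part)), cfg)
    list(report = score_predictions(part$diagnosis, pred,
                                    CLASS_LEVELS[seq_len(cfg$n_classes)]),
         pred = pred)
  }
  src_test <- score_part(splits$source$test, "source")
  tgt_test <- score_part(splits$target$test, "target")
  src_train_acc <- score_part(splits$source$train, "source")

  z_src <- encode_z1(fit$params, x[src_tr$subject_id, , drop = FALSE],
                     rep("source", nrow(src_tr)), cfg)$mean
  z_tgt <- encode_z1(fit$params, x[tgt_tr$subject_id, , drop = FALSE],
                     rep("target", nrow(tgt_tr)), cfg)$mean
  kl <- gaussian_kl(z_src, z_tgt)

  predictions <- if (!is.null(tgt_test))
    data.frame(subject_id = splits$target$test$subject_id,
               diagnosis = splits$target$test$diagnosis,
               predicted = tgt_test$pred)
  list(fit = fit,
       metrics = list(source_train = src_train_acc$report,
                      source_test = src_test$report,
                      target_test = tgt_test$report),
       kl = kl, splits = splits, predictions = predictions,
       harmonized = harmonize)
}

#' Five-fold cross-validated accuracy of the VAE-MMD model
#'
#' Splits the labeled source training data into k folds (stratified by
#' diagnosis), trains on k-1 folds plus the unlabeled target data, and
#' scores the held-out fold; reported as mean and sd over folds.
#'
#' @param x_source,y_source labeled source data.
#' @param x_target unlabeled target features.
#' @param cfg a [vae_config()].
#' @param k fold count.
#' @return list: `fold_accuracy`, `mean`, `sd`.
#' @export
cross_validate_vae <- function(x_source, y_source, x_target, cfg, k = 5L) {
  x_source <- as.matrix(x_source)
  n <- nrow(x_source)
  folds <- with_seed(cfg$seed, {
    f <- integer(n)
    for (cl in unique(y_source)) {
      idx <- sample(which(y_source == cl))
      f[idx] <- rep_len(seq_len(k), length(idx))
    }
    f
  })
  accs <- vapply(seq_len(k), function(fold) {
    tr <- folds != fold
    fit <- train_vae_mmd(x_source[tr, , drop = FALSE], y_source[tr],
                         x_target, cfg = cfg)
    pred <- vae_predict(fit$params, x_source[!tr, , drop = FALSE],
                        rep("source", sum(!tr)), cfg)
    mean(pred == canonical_diagnosis(y_source[!tr]))
  }, numeric(1))
  list(fold_accuracy = accs, mean = mean(accs), sd = stats::sd(accs))
}
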