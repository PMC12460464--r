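## Cohort manifests: subject-level metadata (site, domain, diagnosis) for
## multi-site cohorts, plus leakage-free train/validation/test splits.

MANIFEST_COLS <- c("subject_id", "site", "domain", "diagnosis", "age", "sex")

#' Construct a cohort manifest
#'
#' A manifest is a data.frame of subject records: `subject_id`, `site`,
#' `domain` (e.g. "source", "target", "aux1"), `diagnosis` (control /
#' autism / asperger / unknown; "unknown" marks unlabeled records), and
#' optional `age` and `sex`.
#'
#' @param subject_id,site,domain,diagnosis character vectors (recycled
#'   scalars allowed for all but `subject_id`).
#' @param age,sex optional per-subject covariates (NA allowed).
#' @param provenance free-text provenance note.
#' @return a `cohort_manifest` (data.frame subclass).
#' @export
cohort_manifest <- function(subject_id, site, domain, diagnosis,
                            age = NA_real_, sex = NA_character_,
                            provenance = "") {
  n <- length(subject_id)
  fail_if(n == 0L, "manifest must be non-empty")
  df <- data.frame(subject_id = as.character(subject_id),
                   site = as.character(rep_len(site, n)),
                   domain = as.character(rep_len(domain, n)),
                   diagnosis = canonical_diagnosis(rep_len(diagnosis, n)),
                   age = as.numeric(rep_len(age, n)),
                   sex = as.character(rep_len(sex, n)),
                   stringsAsFactors = FALSE)
  dup <- df$subject_id[duplicated(df$subject_id)]
  fail_if(length(dup) > 0, "duplicate subject_id: %s",
          paste(unique(dup), collapse = ", "))
  structure(df, provenance = provenance,
            class = c("cohort_manifest", "data.frame"))
}

#' Read a cohort manifest TSV
#'
#' Tab-separated, UTF-8, header `subject_id site domain diagnosis age sex`;
#' empty age/sex fields mean missing. Diagnosis tokens are matched
#' case-insensitively and canonicalized to lower case.
#'
#' @param path manifest file path.
#' @return a `cohort_manifest`.
#' @export
read_manifest <- function(path) {
  fail_if(!file.exists(path), "file not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = "",
                          quote = "", comment.char = "",
                          fileEncoding = "UTF-8")
  missing_cols <- setdiff(MANIFEST_COLS[1:4], names(df))
  fail_if(length(missing_cols) > 0, "missing required column(s): %s",
          paste(missing_cols, collapse = ", "))
  dup <- df$subject_id[duplicated(df$subject_id)]
  if (length(dup)) {
    rows <- which(df$subject_id %in% dup)
    stop(sprintf("duplicate subject_id '%s' (row(s) %s)",
                 paste(unique(dup), collapse = ", "),
                 paste(rows, collapse = ", ")), call. = FALSE)
  }
  cohort_manifest(df$subject_id, df$site, df$domain, df$diagnosis,
                  age = if ("age" %in% names(df))
                    suppressWarnings(as.numeric(df$age)) else NA_real_,
                  sex = if ("sex" %in% names(df)) df$sex else NA_character_,
                  provenance = path)
}

#' @rdname read_manifest
#' @param manifest manifest to write.
#' @export
write_manifest <- function(manifest, path) {
  df <- as.data.frame(manifest)[, MANIFEST_COLS]
  df$age <- ifelse(is.na(df$age), "", format(df$age, trim = TRUE))
  df$sex <- ifelse(is.na(df$sex), "", df$sex)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Per-site cohort summary
#'
#' Counts subjects per site (and per diagnosis within site) with a grand
#' total row; sites are ordered lexicographically.
#'
#' @param manifest a `cohort_manifest`.
#' @return data.frame: site, n, one column per diagnosis present.
#' @export
summarize_by_site <- function(manifest) {
  df <- as.data.frame(manifest)
  sites <- sort(unique(df$site))
  diags <- DIAGNOSIS_LEVELS[DIAGNOSIS_LEVELS %in% unique(df$diagnosis)]
  tab <- table(factor(df$site, sites), factor(df$diagnosis, diags))
  out <- data.frame(site = sites, n = as.integer(rowSums(tab)),
                    stringsAsFactors = FALSE)
  for (d in diags) out[[d]] <- as.integer(tab[, d])
  total <- data.frame(site = "TOTAL", n = nrow(df), stringsAsFactors = FALSE)
  for (d in diags) total[[d]] <- as.integer(sum(tab[, d]))
  rbind(out, total)
}

#' Expand a per-cohort count table into a subject-level manifest
#'
#' Takes rows of (site, n[, per-diagnosis counts...]) and emits n subjects
#' per row with generated ids `<prefix><site>_<k>`. Used to turn packaged
#' cohort-count fixtures into full manifests.
#'
#' @param counts data.frame with columns `site`, `n`, and optionally
#'   diagnosis-level count columns (control/autism/asperger/unknown).
#' @param domain domain identifier for every subject.
#' @param prefix id prefix.
#' @return a `cohort_manifest`.
#' @export
expand_cohort_counts <- function(counts, domain = "source", prefix = "sub_") {
  fail_if(!all(c("site", "n") %in% names(counts)),
          "counts must have columns 'site' and 'n'")
  diag_cols <- intersect(DIAGNOSIS_LEVELS, names(counts))
  recs <- lapply(seq_len(nrow(counts)), function(i) {
    n <- as.integer(counts$n[i])
    if (length(diag_cols)) {
      per <- as.integer(counts[i, diag_cols])
      fail_if(sum(per) != n, "diagnosis counts do not sum to n in row %d", i)
      diagnosis <- rep(diag_cols, per)
    } else diagnosis <- rep("unknown", n)
    data.frame(subject_id = sprintf("%s%s_%04d", prefix, counts$site[i],
                                    seq_len(n)),
               site = counts$site[i], diagnosis = diagnosis,
               stringsAsFactors = FALSE)
  })
  recs <- do.call(rbind, recs)
  cohort_manifest(recs$subject_id, recs$site, domain, recs$diagnosis)
}

#' Specify a train/validation/test split
#'
#' @param mode `"counts"` (three subset sizes) or `"fractions"` (three
#'   non-negative fractions summing to 1).
#' @param values three non-negative numbers.
#' @param stratify_by subset of `c("diagnosis", "site")`; default
#'   stratifies on diagnosis.
#' @param seed RNG seed controlling the shuffle.
#' @return a `split_spec` list.
#' @export
split_spec <- function(mode = c("counts", "fractions"), values,
                       stratify_by = "diagnosis", seed = 1L) {
  mode <- match.arg(mode)
  fail_if(length(values) != 3 || any(values < 0),
          "values must be three non-negative numbers")
  if (mode == "fractions")
    fail_if(abs(sum(values) - 1) > 1e-8, "fractions must sum to 1")
  fail_if(!all(stratify_by %in% c("diagnosis", "site")),
          "stratify_by must be a subset of {diagnosis, site}")
  structure(list(mode = mode, values = values, stratify_by = stratify_by,
                 seed = as.integer(seed)), class = "split_spec")
}

#' Split a cohort into train / validation / test
#'
#' Deterministic, stratified partition. Within each stratum subjects are
#' shuffled (seeded) and allocated by largest-remainder rounding of the
#' requested proportions; a fix-up pass then moves single subjects between
#' parts so the three totals are met exactly, never moving a stratum more
#' than one subject from its rounded share.
#'
#' @param manifest a `cohort_manifest`.
#' @param spec a [split_spec()].
#' @return named list of three `cohort_manifest`s (`train`, `validation`,
#'   `test`) with a `split_report` attribute (sizes, seed, stratification).
#' @export
split_cohort <- function(manifest, spec) {
  df <- as.data.frame(manifest)
  n <- nrow(df)
  counts <- if (spec$mode == "counts") {
    fail_if(sum(spec$values) != n,
            "split counts sum to %d but manifest has %d records",
            sum(spec$values), n)
    as.integer(spec$values)
  } else {
    largest_remainder(spec$values * n, n)
  }
  strat <- if (length(spec$stratify_by))
    interaction(df[spec$stratify_by], drop = TRUE) else factor(rep(1L, n))
  assign_part <- integer(n)
  with_seed(spec$seed, {
    alloc <- matrix(0L, nlevels(strat), 3) # per-stratum allocation
    for (s in seq_len(nlevels(strat))) {
      idx <- which(as.integer(strat) == s)
      alloc[s, ] <- largest_remainder(counts / n * length(idx), length(idx))
    }
    ## fix-up: move single subjects from surplus to deficit parts until the
    ## three column sums match `counts` exactly (each move cuts the total
    ## discrepancy by 2, so this terminates)
    repeat {
      gap <- colSums(alloc) - counts
      if (all(gap == 0)) break
      p <- which.max(gap)                       # surplus part
      q <- which.min(gap)                       # deficit part
      s <- which.max(alloc[, p])                # stratum with most to spare
      alloc[s, p] <- alloc[s, p] - 1L
      alloc[s, q] <- alloc[s, q] + 1L
    }
    for (s in seq_len(nlevels(strat))) {
      idx <- sample(which(as.integer(strat) == s))
      assign_part[idx] <- rep(1:3, alloc[s, ])
    }
  })
  parts <- lapply(1:3, function(p) {
    sub <- df[assign_part == p, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    cohort_manifest(sub$subject_id, sub$site, sub$domain, sub$diagnosis,
                    sub$age, sub$sex,
                    provenance = attr(manifest, "provenance"))
  })
  names(parts) <- c("train", "validation", "test")
  attr(parts, "split_report") <- list(
    sizes = counts, seed = spec$seed, mode = spec$mode,
    stratify_by = spec$stratify_by)
  parts
}

## Integer allocation by largest remainder, forced to sum to `total`.
largest_remainder <- function(ideal, total) {
  base <- floor(ideal)
  rem <- ideal - base
  short <- as.integer(round(total - sum(base)))
  if (short > 0) {
    give <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[give] <- base[give] + 1
  }
  as.integer(base)
}

#' Write split outputs: three manifest TSVs plus a JSON report
#'
#' @param parts result of [split_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the report path.
#' @export
write_split <- function(parts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(parts)) {
    if (!is.null(parts[[nm]]))
      write_manifest(parts[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  report <- attr(parts, "split_report")
  report$n <- lapply(parts, function(p) if (is.null(p)) 0L else nrow(p))
  path <- file.path(dir, "split_report.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
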