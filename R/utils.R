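#' @keywords internal
"_PACKAGE"

## Run an expression under a fixed RNG seed without disturbing the caller's
## RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## stopifnot() with a formatted message.
fail_if <- function(cond, fmt, ...) {
  if (isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(NULL)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x == floor(x)
}

## Canonical diagnosis tokens; "unknown" marks unlabeled records.
DIAGNOSIS_LEVELS <- c("control", "autism", "asperger", "unknown")
CLASS_LEVELS <- c("control", "autism", "asperger")

canonical_diagnosis <- function(x) {
  out <- tolower(trimws(as.character(x)))
  bad <- !(out %in% DIAGNOSIS_LEVELS)
  if (any(bad)) {
    stop(sprintf("unknown diagnosis token(s) at row(s) %s: %s",
                 paste(which(bad), collapse = ", "),
                 paste(unique(out[bad]), collapse = ", ")), call. = FALSE)
  }
  out
}

## One-hot encode a factor-like vector against a fixed level set.
one_hot <- function(x, levels) {
  m <- matrix(0, length(x), length(levels),
              dimnames = list(NULL, levels))
  idx <- match(x, levels)
  fail_if(anyNA(idx), "value(s) outside declared levels: %s",
          paste(unique(x[is.na(idx)]), collapse = ", "))
  m[cbind(seq_along(x), idx)] <- 1
  m
}
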