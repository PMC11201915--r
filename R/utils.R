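# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards so generators never
#' perturb user-level random streams.
#' @noRd
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Small deterministic string hash, used only to decorrelate per-stage
# substreams derived from the one user-facing seed.
string_hash <- function(x) {
  v <- utf8ToInt(paste(x, collapse = "\r"))
  if (length(v) == 0L) return(0L)
  as.integer(sum((v %% 97) * (seq_along(v) %% 89)) %% 30011L)
}

# Derive a per-stage seed below 2^31 from the master seed, a stage offset
# and a free-text key (agent/cell line/condition names).
stage_seed <- function(seed, offset, key = "") {
  s <- (abs(as.numeric(seed)) %% 65011) * 31013 + offset * 101 + string_hash(key)
  as.integer(s %% 2147483629)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

assert_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stopf("`%s` must be a single number", name)
  }
  if (finite && !is.finite(x)) stopf("`%s` must be finite", name)
  if (positive && x <= 0) stopf("`%s` must be > 0", name)
  invisible(x)
}

assert_columns <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stopf("`%s` is missing column(s): %s", name, paste(missing, collapse = ", "))
  }
  invisible(df)
}

# MD5 fingerprint of an arbitrary R object (configs, tables) through its
# deparsed form; used to stamp pipeline outputs.
object_fingerprint <- function(x) {
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf), add = TRUE)
  writeLines(deparse(x, control = c("exact", "showAttributes")), tf)
  unname(tools::md5sum(tf))
}

# r-squared that tolerates degenerate (zero-variance) responses: a model
# that reproduces a constant series exactly is a perfect fit.
safe_r2 <- function(observed, fitted, tol = 1e-12) {
  ss_tot <- sum((observed - mean(observed))^2)
  ss_res <- sum((observed - fitted)^2)
  if (ss_tot < tol) {
    return(if (ss_res < tol) 1 else 0)
  }
  max(0, min(1, 1 - ss_res / ss_tot))
}
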