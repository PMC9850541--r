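# Internal helpers shared across stages.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Structured log line to stderr
#'
#' Emits `[stage] key=value ...` lines; silenced unless
#' `options(scvuln.verbose = TRUE)`.
#' @param stage character scalar naming the pipeline stage
#' @param ... named values to report
#' @return invisibly, the formatted line
#' @keywords internal
log_stage <- function(stage, ...) {
  vals <- list(...)
  msg <- paste0("[", stage, "]")
  if (length(vals)) {
    kv <- vapply(seq_along(vals), function(i) {
      paste0(names(vals)[i], "=", paste(format(vals[[i]]), collapse = ","))
    }, character(1))
    msg <- paste(msg, paste(kv, collapse = " "))
  }
  if (isTRUE(getOption("scvuln.verbose", FALSE))) message(msg)
  invisible(msg)
}

# Row-wise variance of a dense matrix without matrixStats.
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(NA_real_, nrow(x)))
  mu <- rowMeans(x)
  (rowSums(x^2) - n * mu^2) / (n - 1)
}

# Center rows and scale to unit variance; zero-variance rows are dropped
# (with attribute "dropped" listing them) because they carry no signal.
standardize_rows <- function(x) {
  mu <- rowMeans(x)
  sdv <- sqrt(row_vars(x))
  keep <- is.finite(sdv) & sdv > 0
  z <- (x[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  attr(z, "dropped") <- rownames(x)[!keep]
  z
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same cells;
#' 1 means identical partitions (up to label renaming), 0 is the expected
#' value for independent labelings.
#'
#' @param a,b vectors of equal length with cluster labels
#' @return numeric scalar in \[-1, 1\]
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b"))
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  max_idx <- (sum_i + sum_j) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

# FNV-1a 32-bit hash of a character scalar; used for config/manifest
# fingerprints only (not cryptographic).
fnv1a_hash <- function(x) {
  # 32-bit xor in 16-bit halves: bitwXor() only takes values < 2^31
  xor32 <- function(a, b) {
    bitwXor(a %% 65536, b %% 65536) + bitwXor(a %/% 65536, b %/% 65536) * 65536
  }
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- xor32(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Deterministic seed derivation: keeps derived seeds in 32-bit range.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}
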