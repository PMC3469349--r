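#' Derive a reproducible child seed from a parent seed and labels
#'
#' A single global seed deterministically fans out into per-stage,
#' per-condition and per-network seeds via a small integer hash chain, so any
#' sub-computation can be reproduced in isolation without sharing RNG state.
#'
#' @param seed Parent integer seed.
#' @param ... Character or numeric labels identifying the sub-computation
#'   (e.g. stage name, condition id, network name).
#' @return An integer in `[0, 2^31 - 1)` suitable for [set.seed()].
#' @export
#' @examples
#' derive_seed(1, "discover", "prochloraz.ovary")
derive_seed <- function(seed, ...) {
  labels <- paste(c(seed, ...), collapse = "/")
  bytes <- utf8ToInt(labels)
  h <- 0
  m <- 2147483647  # 2^31 - 1, keeps the result a valid 32-bit R integer
  for (b in bytes) h <- (h * 31 + b) %% m
  as.integer(h)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
condition_id <- function(chemical, tissue) paste(chemical, tissue, sep = ".")

# Stratified train/test split indices for one condition slice.
# Returns a list of `n_splits` lists with vectors $train and $test. Each class
# contributes round(train_fraction * n_class) samples to training, at least
# one sample to each side. With seed = NULL the splits are drawn from the
# caller's current RNG stream.
make_splits <- function(treated_idx, control_idx, n_splits, train_fraction,
                        seed = NULL) {
  draw <- function(idx) {
    n_tr <- max(1L, min(length(idx) - 1L, round(train_fraction * length(idx))))
    tr <- sample(idx, n_tr)
    list(train = tr, test = setdiff(idx, tr))
  }
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_splits), function(i) {
    a <- draw(treated_idx)
    b <- draw(control_idx)
    list(train = c(a$train, b$train), test = c(a$test, b$test))
  })
}
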