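#' Derive a reproducible sub-seed from a master seed and a component key
#'
#' All stochastic components of the session generator draw from their own
#' RNG substream so that, e.g., adding a channel never perturbs the spike
#' trains of existing clusters. The substream seed is a deterministic hash
#' of the master seed and a string key, kept below 2^31.
#'
#' @param seed master integer seed
#' @param key character key naming the component (e.g. "cluster:u01")
#' @return an integer seed in [0, 2^31 - 2]
#' @keywords internal
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key))
  codes <- utf8ToInt(key)
  h <- as.double(seed) %% 2147483647
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded helpers do not
#' interfere with user-level randomness.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Runs of TRUE in a logical mask, as half-open index intervals
#'
#' @param mask logical vector
#' @return data.frame with columns `start`, `end` (1-based indices,
#'   half-open: the run covers `start .. end - 1`)
#' @keywords internal
mask_runs <- function(mask) {
  mask <- as.logical(mask)
  mask[is.na(mask)] <- FALSE
  if (!any(mask)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep] + 1L)
}

#' Rebuild a logical mask from half-open index runs
#' @keywords internal
runs_to_mask <- function(runs, n) {
  mask <- logical(n)
  if (nrow(runs)) {
    for (i in seq_len(nrow(runs))) {
      mask[runs$start[i]:(runs$end[i] - 1L)] <- TRUE
    }
  }
  mask
}

#' Linear-interpolation percentile (type 7), the package-wide convention
#' @keywords internal
pctl <- function(x, p) stats::quantile(x, probs = p, type = 7, names = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
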