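# Internal helpers: seeded evaluation and stable string hashing for
# per-farm RNG substreams.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `code`, and restores the previous RNG
#' state so callers' random streams are not disturbed.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Stable 31-bit hash of a character string
#'
#' Polynomial rolling hash (base 31, modulus 2^31 - 1). Used to derive a
#' reproducible RNG substream per farm, so adding farms to a simulated
#' cohort never perturbs the records of existing farms.
#'
#' @param x character scalar.
#' @return non-negative integer < 2^31 - 1.
#' @keywords internal
#' @noRd
hash_string <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- 2147483647  # 2^31 - 1, keeps arithmetic exact in doubles
  h <- 0
  for (v in utf8ToInt(x)) h <- (h * 31 + v) %% m
  as.integer(h)
}

# Substream seed for one farm under a root seed.
farm_seed <- function(root_seed, farm_id) {
  hash_string(paste0("farm:", farm_id, ":", as.integer(root_seed)))
}

# Stop with a consistent message when a required scalar is invalid.
check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != as.integer(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  as.integer(x)
}
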