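# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. A NULL seed leaves the RNG stream untouched, so repeated
# unseeded calls keep advancing the global stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L) # initialize RNG state so it can be saved
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Error class used for degenerate-data conditions so the CLI can map them to
# a distinct exit code.
stop_degenerate <- function(msg) {
  stop(errorCondition(msg, class = c("heavytail_degenerate", "error")))
}

is_whole <- function(x, tol = 1e-8) {
  all(abs(x - round(x)) <= tol)
}

check_positive_values <- function(values) {
  if (length(values) == 0L) stop("`values` must be nonempty", call. = FALSE)
  if (!is.numeric(values)) stop("`values` must be numeric", call. = FALSE)
  if (anyNA(values)) stop("`values` must not contain NA", call. = FALSE)
  if (any(values <= 0)) stop("all values must be positive", call. = FALSE)
  invisible(values)
}
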