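#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards so callers do not perturb each other. With
#' `seed = NULL` the expression runs against the current RNG stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # materialise a RNG state so it can be restored
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Polynomial rolling hash (mod 2^31) of a serialised R object, as 8 hex
# digits. Stamps run manifests so outputs trace back to an exact config;
# not cryptographic.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, connection = NULL, version = 2))
  h <- 17
  for (b in bytes) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

stop_larvagg <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "larvagg_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}
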