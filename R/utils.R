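#' @keywords internal
"_PACKAGE"

abort_if <- function(cond, msg) {
  if (isTRUE(cond)) stop(msg, call. = FALSE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0 && x == round(x)
}

#' Derive a stream-specific seed from a master seed
#'
#' Deterministically maps a master seed and a stream label to a 31-bit
#' integer seed so that independent pipeline stages draw from decorrelated
#' but reproducible streams.
#'
#' @param seed master integer seed.
#' @param stream character label of the consuming stage.
#' @return a single integer in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, stream) {
  abort_if(!is.numeric(seed) || length(seed) != 1L, "seed must be a single number")
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((abs(seed) * 2654435.0 + h * 97 + 17) %% 2147483629)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state,
#' so seeded computations do not perturb surrounding randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483629))
  force(expr)
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

read_json_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
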