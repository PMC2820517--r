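#' Derive a reproducible sub-stream seed from a master seed
#'
#' Every stochastic step of a multi-stage pipeline draws its own seed from a
#' single master seed plus a named stream label, so that re-running any stage
#' in isolation reproduces exactly the draws it saw inside the full pipeline.
#'
#' @param master integer master seed.
#' @param stream character label of the sub-stream (e.g. `"bootstrap"`), or an
#'   integer offset.
#' @return A single integer in `[0, 2^31 - 2]`, suitable for [set.seed()].
#' @export
#' @examples
#' derive_seed(1L, "scan")
derive_seed <- function(master, stream = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  m <- 2147483647 # 2^31 - 1, keeps results inside R's integer range
  h <- as.numeric(master) %% m
  if (is.character(stream)) {
    for (code in utf8ToInt(stream)) h <- (h * 131 + code) %% m
  } else {
    h <- (h * 131 + as.numeric(stream)) %% m
  }
  as.integer(h)
}

#' Evaluate an expression with a locally set RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded package functions do
#' not perturb user-level random sequences.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# stop() with a classed condition so callers can distinguish argument misuse
# from data problems
abort_tn <- function(msg, class) {
  stop(structure(
    class = c(class, "temponet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

arg_error  <- function(msg) abort_tn(msg, "temponet_argument_error")
data_error <- function(msg) abort_tn(msg, "temponet_data_error")
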