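# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed, restorable RNG state
#'
#' The generator kind is pinned (Mersenne-Twister / Inversion / Rejection) so
#' that seeds are portable across R releases; the caller's RNG state is
#' restored on exit.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
local_rng <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  code
}

# Deterministic sub-stream seed from (seed, operation tag); stays below 2^31.
derive_seed <- function(seed, tag) {
  ints <- utf8ToInt(tag)
  h <- sum(ints * seq_along(ints)) %% 1000003
  as.integer((as.numeric(seed) %% 2146483647) + h %% 1000000)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

is_prob <- function(x, open = TRUE) {
  is.numeric(x) && length(x) == 1L && is.finite(x) &&
    if (open) (x > 0 && x < 1) else (x >= 0 && x <= 1)
}

stop_cellnp <- function(class, message, call. = FALSE) {
  stop(structure(class = c(class, "cellnp_error", "error", "condition"),
                 list(message = message, call = NULL)))
}

# symmetric part, guarding tiny asymmetries from floating point
symmetrize <- function(x) (x + t(x)) / 2
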