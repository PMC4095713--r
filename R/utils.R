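#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the generator seeded by `seed`, then restores the caller's
#' RNG state, so seeded helpers do not perturb the session stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Derive k child seeds (< 2^31) from one master seed, reproducibly.
derive_seeds <- function(master_seed, k) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, k))
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}

#' @keywords internal
p_tier <- function(p) {
  if (!is.finite(p)) return("n.s.")
  if (p <= 0.001) "p <= 0.001 (very highly significant)"
  else if (p <= 0.01) "p <= 0.01 (highly significant)"
  else if (p <= 0.05) "p <= 0.05 (significant)"
  else "n.s."
}
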