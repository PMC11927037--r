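#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded at `seed`, then
#' restores the previous RNG state so that surrounding code is unaffected.
#' All stochastic internals of the package (HEIDI null draws, bootstrap
#' standard errors, Monte Carlo confidence intervals, the study simulator)
#' route their randomness through this helper, which is what makes identical
#' config + seed runs byte-identical.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two-sided normal p-value, never exactly 0 (p must lie in (0, 1])
z_to_p <- function(z) {
  pmax(2 * stats::pnorm(abs(z), lower.tail = FALSE), .Machine$double.xmin)
}

# two-sided t p-value with the same floor
t_to_p <- function(t, df) {
  pmax(2 * stats::pt(abs(t), df = df, lower.tail = FALSE), .Machine$double.xmin)
}

stop_mrtriage <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "mrtriage_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}
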