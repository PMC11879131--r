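# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a nucleotide string to the uppercase DNA alphabet
#'
#' RNA input (U) is converted to T; case is folded. All sequence handling in
#' the package is done on DNA-alphabet strings.
#'
#' @param x character vector of sequences.
#' @return character vector, uppercase, U replaced by T.
#' @export
norm_seq <- function(x) {
  chartr("U", "T", toupper(x))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the given seed and restores the caller's RNG state
#' afterwards, so simulators are pure functions of (inputs, seed) with no
#' hidden global random state.
#'
#' @param seed integer seed (mandatory).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) stop("a seed is mandatory")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# 0-based half-open interval validation
check_interval <- function(x, len = NULL, what = "interval") {
  if (length(x) != 2L || any(is.na(x)) || x[1] > x[2])
    stop(sprintf("invalid %s", what))
  if (!is.null(len) && (x[1] < 0L || x[2] > len))
    stop(sprintf("%s out of bounds", what))
  invisible(as.integer(x))
}

substr0 <- function(s, start, end) {
  # substring by 0-based half-open coordinates
  if (end <= start) return("")
  substr(s, start + 1L, end)
}
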