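# Shared small helpers: stage codes, local RNG scoping, validation.

#' Sleep stage codes
#'
#' The five AASM stage labels used throughout the package, in canonical order:
#' Wake, N1, N2, N3, REM.
#'
#' @return Character vector of length 5: `c("W", "N1", "N2", "N3", "R")`.
#' @export
stage_levels <- function() c("W", "N1", "N2", "N3", "R")

#' @keywords internal
as_stage_factor <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x)) x <- stage_levels()[x]
  bad <- !(x %in% stage_levels())
  if (any(bad)) {
    stop("unknown stage codes: ", paste(unique(x[bad]), collapse = ", "),
         " (allowed: ", paste(stage_levels(), collapse = ", "), ")")
  }
  factor(x, levels = stage_levels())
}

# Evaluate `expr` under a temporary RNG seed, restoring global RNG state.
# All stochastic package internals funnel through this so no global state leaks.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

#' @keywords internal
stopifnot_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stop(what, " contains non-finite values")
  invisible(TRUE)
}
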