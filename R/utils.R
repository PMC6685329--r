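#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fluorophore vocabulary of the Brainbow2.1 reporter
#'
#' The four heritable Confetti labels plus `"NONE"` for unlabelled cells.
#' @export
CONFETTI_COLOURS <- c("YFP", "RFP", "nGFP", "mCFP")

#' @keywords internal
COLOUR_VOCAB <- c(CONFETTI_COLOURS, "NONE")

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

stop_clonevasc <- function(...) stop(..., call. = FALSE)

check_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_clonevasc(sprintf("`%s` must be a single probability in [0, 1]", name))
  }
  invisible(x)
}

check_colour_probs <- function(p) {
  if (!is.numeric(p) || length(p) != 4L || anyNA(p) || any(p < 0)) {
    stop_clonevasc("`colour_probs` must be 4 non-negative numbers (YFP, RFP, nGFP, mCFP)")
  }
  if (abs(sum(p) - 1) > 1e-12) {
    stop_clonevasc("`colour_probs` must sum to 1 (within 1e-12); got sum = ", format(sum(p), digits = 15))
  }
  if (is.null(names(p))) names(p) <- CONFETTI_COLOURS
  if (!identical(names(p), CONFETTI_COLOURS)) {
    stop_clonevasc("`colour_probs` must be named YFP, RFP, nGFP, mCFP in that order")
  }
  p
}
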