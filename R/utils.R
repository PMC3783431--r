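## Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG state
#'
#' Saves and restores `.Random.seed` so that seeded simulation helpers do
#' not disturb the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

## sprintf-style stop/warning without call noise
stop2 <- function(...) stop(sprintf(...), call. = FALSE)
warn2 <- function(...) warning(sprintf(...), call. = FALSE)

## full-precision formatting for deterministic, lossless TSV output
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    s <- sprintf("%.17g", v)
    # shortest round-trip representation
    for (d in 1:16) {
      cand <- sprintf(paste0("%.", d, "g"), v)
      if (as.numeric(cand) == v) return(cand)
    }
    s
  }, character(1))
  out
}
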