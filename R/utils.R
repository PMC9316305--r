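# internal helpers: classed error conditions and local RNG scoping

cs_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "capturesim_error")))
}

check_number <- function(x, name, positive = FALSE, nonneg = FALSE,
                         len1 = TRUE, finite = TRUE) {
  if (len1 && length(x) != 1L) {
    cs_abort(sprintf("`%s` must be a single number.", name), "invalid_parameter")
  }
  if (!is.numeric(x) || anyNA(x) || (finite && any(!is.finite(x)))) {
    cs_abort(sprintf("`%s` must be a finite numeric value.", name), "invalid_parameter")
  }
  if (positive && any(x <= 0)) {
    cs_abort(sprintf("`%s` must be > 0.", name), "invalid_parameter")
  }
  if (nonneg && any(x < 0)) {
    cs_abort(sprintf("`%s` must be >= 0.", name), "invalid_parameter")
  }
  invisible(x)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream; seed = NULL leaves the global stream untouched.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  check_number(seed, "seed")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
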