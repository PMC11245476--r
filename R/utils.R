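# Internal helpers shared across modules.

# Run `code` under `seed` without disturbing the caller's RNG stream.
# seed = NULL means "use whatever stream is active".
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Round half away from zero, the convention used for reported fold changes
# (base round() rounds half to even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

check_columns <- function(data, cols, what = "input table") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ), class = "nitrisphere_validation_error")
  }
  invisible(data)
}

validation_error <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "nitrisphere_validation_error")
}
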