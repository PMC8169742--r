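# RNG bookkeeping: functions that take an explicit seed must not disturb the
# caller's RNG stream.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# elu activation and its derivative (branch via subsetting: much faster than
# ifelse on the hot training path)
elu <- function(z) {
  neg <- z < 0
  if (any(neg)) z[neg] <- exp(z[neg]) - 1
  z
}
elu_grad_z <- function(z) {
  g <- array(1, dim(z))
  neg <- z < 0
  if (any(neg)) g[neg] <- exp(z[neg])
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a
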