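# Seeded RNG streams: every stochastic routine draws from a named stream
# derived from one master seed, so (for example) movement draws in the
# simulation can never perturb the probability-drift sequence.

# Deterministic 32-bit sub-seed for a named stream.
stream_seed <- function(master_seed, stream) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1)
  bytes <- utils::head(c(utf8ToInt(stream), 7L, 11L), 8)
  h <- as.double(master_seed) %% 2147483647
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a private RNG state seeded from (master_seed, stream),
# leaving the caller's .Random.seed untouched.
with_stream <- function(master_seed, stream, expr) {
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
  set.seed(stream_seed(master_seed, stream))
  expr
}

# A resumable stream: returns an environment whose $draw(expr) evaluates expr
# continuing the stream's own RNG state.
make_stream <- function(master_seed, stream) {
  env <- new.env(parent = emptyenv())
  local({
    set.seed(stream_seed(master_seed, stream))
    env$state <- get(".Random.seed", envir = globalenv())
  })
  env$draw <- function(expr) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <<- get(".Random.seed", envir = globalenv())
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    expr
  }
  env
}

check_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1].", name))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}
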