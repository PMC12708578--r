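# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`; restore the
# caller's RNG afterwards. With seed = NULL the code runs on the ambient RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream of child seeds from one parent seed, below 2^31.
child_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_invalid <- function(kind, msg) {
  cond <- structure(
    class = c(paste0("fedlsh_", kind), "fedlsh_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

as_num_matrix <- function(x, arg = "x") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop_invalid("config", sprintf("`%s` must be a numeric matrix", arg))
  if (!all(is.finite(x)))
    stop_invalid("config", sprintf("`%s` must have finite entries", arg))
  x
}
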