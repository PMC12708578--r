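#' Scalar-multiplication cost accounting
#'
#' The protocol's cost model counts scalar multiplications (SM) and ignores
#' additions. Every blinding, cloud, verification and recovery operation in
#' this package tallies the number of real-number multiplications the
#' algorithm performs into a per-phase counter: one Givens rotation applied to
#' a matrix touches two rows (or columns) and costs 4 multiplications per
#' touched element, a scalar-matrix product costs one multiplication per
#' element, and the naive cloud product of a t x d by a d x m matrix costs
#' t*d*m. `sm_reset()` zeroes the counter, `sm_counts()` reads it.
#'
#' @return `sm_counts()` returns a named numeric vector of SM counts per phase
#'   (phases: `encryption`, `cloud`, `verification`, `recovery`, `other`).
#'   `sm_reset()` invisibly returns the counts at the time of reset.
#' @examples
#' sm_reset()
#' k <- keygen(4, 6, l = 2, seed = 1)
#' Xp <- encrypt_data(matrix(rnorm(24), 4), k)
#' sm_counts()["encryption"]  # 4*6 + 4*6*2 + 4*4*2 = 104
#' @export
sm_counts <- function() {
  unlist(as.list(.sm_env$counts))[c("encryption", "cloud", "verification",
                                    "recovery", "other")]
}

#' @rdname sm_counts
#' @export
sm_reset <- function() {
  old <- sm_counts()
  .sm_env$counts <- new_sm_counts()
  invisible(old)
}

.sm_env <- new.env(parent = emptyenv())

new_sm_counts <- function() {
  e <- new.env(parent = emptyenv())
  for (ph in c("encryption", "cloud", "verification", "recovery", "other"))
    assign(ph, 0, envir = e)
  e
}
.sm_env$counts <- new_sm_counts()
.sm_env$phase <- "other"

sm_tally <- function(n, phase = .sm_env$phase) {
  assign(phase, get(phase, envir = .sm_env$counts) + n, envir = .sm_env$counts)
  invisible(NULL)
}

# run `code` with the counter phase set to `phase`, restoring the old phase
sm_phase <- function(phase, code) {
  old <- .sm_env$phase
  .sm_env$phase <- phase
  on.exit(.sm_env$phase <- old)
  force(code)
}
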