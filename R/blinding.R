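#' Sample a random Givens rotation
#'
#' Draws an elementary (Givens) rotation acting on a space of dimension `dim`:
#' an index pair `i < j` chosen uniformly among all pairs and an angle `theta`
#' uniform on (0, 2*pi). Products of such rotations are the orthogonal
#' blinding factors of the outsourcing scheme; because each factor touches
#' only two rows or columns, applying a product of `l` of them is far cheaper
#' than a dense orthogonal multiply.
#'
#' @param dim Dimension of the space the rotation acts on (>= 2).
#' @return An object of class `givens_rotation`: a list with 1-based indices
#'   `i`, `j` (`i < j`) and angle `theta` in radians.
#' @seealso [rotation_as_dense()], [keygen()]
#' @export
sample_givens <- function(dim) {
  if (!is.numeric(dim) || length(dim) != 1L || dim < 2)
    stop_invalid("dimension", "`dim` must be a single integer >= 2")
  ij <- sort(sample.int(dim, 2L))
  new_givens(ij[1L], ij[2L], stats::runif(1, 0, 2 * pi))
}

new_givens <- function(i, j, theta) {
  structure(list(i = as.integer(i), j = as.integer(j), theta = theta),
            class = "givens_rotation")
}

#' @export
print.givens_rotation <- function(x, ...) {
  cat(sprintf("Givens rotation (i=%d, j=%d, theta=%.6f)\n", x$i, x$j, x$theta))
  invisible(x)
}

#' Dense matrix form of a Givens rotation
#'
#' Materializes the `dim` x `dim` rotation matrix: identity except for entries
#' (i,i) = (j,j) = cos(theta), (i,j) = sin(theta), (j,i) = -sin(theta).
#' Used for oracles and inspection only; the protocol itself never forms
#' dense rotation matrices.
#'
#' @param rot A `givens_rotation`.
#' @param dim Matrix dimension (>= `rot$j`).
#' @return A `dim` x `dim` orthogonal matrix.
#' @export
rotation_as_dense <- function(rot, dim) {
  stopifnot(inherits(rot, "givens_rotation"))
  if (dim < rot$j)
    stop_invalid("dimension", "`dim` smaller than rotation index `j`")
  G <- diag(dim)
  cs <- cos(rot$theta); sn <- sin(rot$theta)
  G[rot$i, rot$i] <- cs
  G[rot$j, rot$j] <- cs
  G[rot$i, rot$j] <- sn
  G[rot$j, rot$i] <- -sn
  G
}

#' Apply an ordered product of Givens rotations to a matrix
#'
#' `apply_left_rotations(M, rots)` computes `P1 P2 ... Pl %*% M` (the
#' rightmost factor `Pl` acts first); `apply_right_rotations(M, rots)`
#' computes `M %*% Q1 Q2 ... Ql` (the leftmost factor `Q1` acts first).
#' Neither forms a dense rotation: each factor updates only the two affected
#' rows (or columns), at 4 scalar multiplications per touched element, which
#' is what makes the blinding cheap relative to the projection it protects.
#'
#' @param M Numeric matrix.
#' @param rotations List of `givens_rotation` objects; indices must be valid
#'   for the row (left) or column (right) dimension of `M`.
#' @return The rotated matrix, same shape as `M`.
#' @export
apply_left_rotations <- function(M, rotations) {
  M <- as_num_matrix(M, "M")
  check_rotations(rotations, nrow(M), "row")
  nc <- ncol(M)
  for (k in rev(seq_along(rotations))) {
    r <- rotations[[k]]
    cs <- cos(r$theta); sn <- sin(r$theta)
    ri <- M[r$i, ]; rj <- M[r$j, ]
    M[r$i, ] <- cs * ri + sn * rj
    M[r$j, ] <- -sn * ri + cs * rj
    sm_tally(4 * nc)
  }
  M
}

#' @rdname apply_left_rotations
#' @export
apply_right_rotations <- function(M, rotations) {
  M <- as_num_matrix(M, "M")
  check_rotations(rotations, ncol(M), "column")
  nr <- nrow(M)
  for (k in seq_along(rotations)) {
    r <- rotations[[k]]
    cs <- cos(r$theta); sn <- sin(r$theta)
    ci <- M[, r$i]; cj <- M[, r$j]
    M[, r$i] <- cs * ci - sn * cj
    M[, r$j] <- sn * ci + cs * cj
    sm_tally(4 * nr)
  }
  M
}

check_rotations <- function(rotations, dim, what) {
  ok <- vapply(rotations, function(r)
    inherits(r, "givens_rotation") && r$i >= 1L && r$i < r$j && r$j <= dim,
    logical(1))
  if (!all(ok))
    stop_invalid("key", sprintf(
      "rotation indices out of range for %s dimension %d", what, dim))
  invisible(NULL)
}

#' Generate a client blinding key
#'
#' The secret key held by one client consists of a nonzero scalar `alpha`
#' (log-uniform on \[0.5, 2\], bounded away from 0 so the 1/alpha^2 recovery
#' is well conditioned), `l` left rotations acting on the item dimension `m`,
#' and `l` right rotations acting on the feature dimension `d`. The key is
#' stored as rotation parameter triples, never as dense matrices, and is only
#' ever used locally: it appears in no protocol message.
#'
#' @param m Number of items (rows of the client's data matrix), >= 2.
#' @param d Feature dimension (columns), >= 2.
#' @param l Number of rotations per side, >= 1. Default 8.
#' @param seed Optional integer seed; the key is fully determined by it.
#' @return An object of class `blinding_key`.
#' @seealso [encrypt_data()], [recover_table()], [write_blinding_key()]
#' @export
keygen <- function(m, d, l = 8L, seed = NULL) {
  if (m < 2 || d < 2)
    stop_invalid("dimension", "`m` and `d` must both be >= 2")
  if (l < 1) stop_invalid("config", "`l` must be >= 1")
  with_seed(seed, {
    key <- structure(list(
      alpha = exp(stats::runif(1, log(0.5), log(2))),
      left_rotations = replicate(l, sample_givens(m), simplify = FALSE),
      right_rotations = replicate(l, sample_givens(d), simplify = FALSE),
      m = as.integer(m), d = as.integer(d), l = as.integer(l),
      seed = seed
    ), class = "blinding_key")
    key
  })
}

#' @export
print.blinding_key <- function(x, ...) {
  cat(sprintf(
    "Blinding key: alpha=%.4f, l=%d rotations/side, data shape %d x %d\n",
    x$alpha, x$l, x$m, x$d))
  invisible(x)
}

#' Blind a client data matrix for outsourcing
#'
#' Encrypts the m x d data matrix as
#' `X' = P1 P2 ... Pl (alpha * X) Q1 Q2 ... Ql`. The orthogonal factors and
#' the scalar hide `X` from the cloud while preserving the algebra the cloud
#' needs: the recovered projection table equals the plaintext one exactly.
#' Blinding preserves the Frobenius norm up to `|alpha|`.
#'
#' @param X Numeric m x d matrix (rownames, if any, are item identifiers and
#'   are dropped from the encrypted payload).
#' @param key A `blinding_key` with matching `m` and `d`.
#' @return The encrypted matrix `X'` (class `encrypted_matrix`, kind "data").
#' @export
encrypt_data <- function(X, key) {
  X <- as_num_matrix(X, "X")
  stopifnot(inherits(key, "blinding_key"))
  if (nrow(X) != key$m || ncol(X) != key$d)
    stop_invalid("key", sprintf(
      "data is %d x %d but key expects %d x %d", nrow(X), ncol(X), key$m, key$d))
  sm_phase("encryption", {
    sm_tally(length(X))  # alpha * X
    Xp <- key$alpha * X
    dimnames(Xp) <- NULL
    Xp <- apply_left_rotations(Xp, key$left_rotations)
    Xp <- apply_right_rotations(Xp, key$right_rotations)
    structure(Xp, kind = "data", class = c("encrypted_matrix", class(Xp)))
  })
}

#' Blind a projection matrix for outsourcing
#'
#' Encrypts the t x d projection matrix as `W' = (alpha * W) Q1 Q2 ... Ql`.
#' Only the right (feature-side) rotations act on `W`, so the cloud product
#' `W' X'^T` carries `Q Q^T = I` in its interior.
#'
#' @param W Numeric t x d matrix.
#' @param key A `blinding_key` whose `d` matches `ncol(W)`.
#' @return The encrypted matrix `W'` (class `encrypted_matrix`, kind
#'   "projection").
#' @export
encrypt_projection <- function(W, key) {
  W <- as_num_matrix(W, "W")
  stopifnot(inherits(key, "blinding_key"))
  if (ncol(W) != key$d)
    stop_invalid("key", sprintf(
      "projection has %d columns but key expects %d", ncol(W), key$d))
  sm_phase("encryption", {
    sm_tally(length(W))  # alpha * W
    Wp <- key$alpha * W
    dimnames(Wp) <- NULL
    Wp <- apply_right_rotations(Wp, key$right_rotations)
    structure(Wp, kind = "projection", class = c("encrypted_matrix", class(Wp)))
  })
}

#' Cloud-side encrypted projection product
#'
#' The untrusted cloud computes the encrypted hash table
#' `HashTable' = W' %*% t(X')`. This is a pure function of its two encrypted
#' inputs: the cloud holds no key and learns only blinded values. Cost:
#' t*d*m scalar multiplications (the full projection work the client is
#' offloading).
#'
#' @param Wp Encrypted projection, t x d.
#' @param Xp Encrypted data, m x d.
#' @return The t x m encrypted table (class `encrypted_hashtable`).
#' @export
encrypted_product <- function(Wp, Xp) {
  if (ncol(Wp) != ncol(Xp))
    stop_invalid("protocol", sprintf(
      "inner dimensions disagree: %d vs %d columns", ncol(Wp), ncol(Xp)))
  sm_tally(nrow(Wp) * ncol(Wp) * nrow(Xp), phase = "cloud")
  H <- unclass(Wp) %*% t(unclass(Xp))
  structure(H, class = c("encrypted_hashtable", class(H)))
}

#' Verify a claimed encrypted product by random contraction
#'
#' Freivalds-style check of the cloud's work: draw a random row vector
#' `r` (i.i.d. standard normal, length t) and compare
#' `V1 = (r W') X'^T` against `V2 = r HashTable'`. An honest table satisfies
#' V1 = V2 identically; a tampered one fails for almost every `r`, so a
#' single continuous draw rejects perturbations with probability 1 up to the
#' floating-point tolerance. Cost: t*d + d*m + t*m scalar multiplications —
#' linear in the matrix sizes, versus t*d*m to redo the product.
#'
#' @param Hp Claimed t x m encrypted table.
#' @param Wp,Xp The encrypted matrices that were outsourced.
#' @param rel_tol Relative tolerance on the max-norm discrepancy. Exact
#'   equality is not meaningful in floating point; the default 1e-10 sits
#'   orders of magnitude above honest rounding error yet low enough that a
#'   single-entry perturbation of 1e-3 escapes it for all but a vanishing
#'   fraction of contraction vectors.
#' @param seed Optional seed for the random contraction vector.
#' @return `TRUE` if the table is consistent, `FALSE` otherwise.
#' @export
verify_product <- function(Hp, Wp, Xp, rel_tol = 1e-10, seed = NULL) {
  t_ <- nrow(Wp); d_ <- ncol(Wp); m_ <- nrow(Xp)
  if (nrow(Hp) != t_ || ncol(Hp) != m_) return(FALSE)
  with_seed(seed, {
    r <- matrix(stats::rnorm(t_), nrow = 1L)
    sm_tally(t_ * d_ + d_ * m_ + t_ * m_, phase = "verification")
    V1 <- (r %*% unclass(Wp)) %*% t(unclass(Xp))
    V2 <- r %*% unclass(Hp)
    max(abs(V1 - V2)) <= rel_tol * (1 + max(abs(V1)))
  })
}

#' Recover the plaintext projection table
#'
#' The key holder undoes the blinding of a verified encrypted table:
#' `HashTable = (1/alpha^2) * (HashTable' %*% P1 P2 ... Pl)`. The left
#' rotations cancel (`P^T P = I`) because `HashTable'` carries `P` through
#' the transposed data factor; the result equals the plaintext `W %*% t(X)`
#' exactly (up to floating-point rounding).
#'
#' @param Hp Encrypted t x m table.
#' @param key The `blinding_key` used for encryption (`m` must match).
#' @param column_ids Optional item identifiers for the m columns.
#' @return The t x m plaintext projection table.
#' @seealso [encrypt_data()], [verify_product()]
#' @export
recover_table <- function(Hp, key, column_ids = NULL) {
  stopifnot(inherits(key, "blinding_key"))
  if (ncol(Hp) != key$m)
    stop_invalid("key", sprintf(
      "table has %d columns but key expects m=%d", ncol(Hp), key$m))
  sm_phase("recovery", {
    H <- apply_right_rotations(unclass(Hp), key$left_rotations)
    sm_tally(length(H))  # 1/alpha^2 scaling
    H <- H / key$alpha^2
    if (!is.null(column_ids)) colnames(H) <- column_ids
    H
  })
}

#' Read and write blinding keys as JSON
#'
#' Keys are serialized as rotation parameter triples (i, j, theta) plus the
#' scalar and shape metadata — never as dense matrices. Key files are local
#' secrets: the orchestrated protocol never transmits them.
#'
#' @param key A `blinding_key`.
#' @param path File path.
#' @return `read_blinding_key()` returns the `blinding_key`;
#'   `write_blinding_key()` invisibly returns `path`.
#' @export
write_blinding_key <- function(key, path) {
  stopifnot(inherits(key, "blinding_key"))
  enc <- function(rots) lapply(rots, function(r)
    list(i = r$i, j = r$j, theta = r$theta))
  jsonlite::write_json(list(
    alpha = key$alpha, m = key$m, d = key$d, l = key$l,
    seed = if (is.null(key$seed)) NA else key$seed,
    left_rotations = enc(key$left_rotations),
    right_rotations = enc(key$right_rotations)
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_blinding_key
#' @export
read_blinding_key <- function(path) {
  x <- jsonlite::read_json(path)
  dec <- function(rots) lapply(rots, function(r)
    new_givens(r$i, r$j, r$theta))
  structure(list(
    alpha = x$alpha,
    left_rotations = dec(x$left_rotations),
    right_rotations = dec(x$right_rotations),
    m = as.integer(x$m), d = as.integer(x$d), l = as.integer(x$l),
    seed = if (is.null(x$seed) || is.na(x$seed)) NULL else x$seed
  ), class = "blinding_key")
}
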