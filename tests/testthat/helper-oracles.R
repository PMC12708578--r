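# Independent oracles used across the suite. These deliberately take the
# slow, obviously-correct route (dense matrices, explicit loops) and never
# call the fast-path code they check.

# dense product P1 P2 ... Pl as an explicit matrix
dense_rotation_product <- function(rotations, dim) {
  Reduce(`%*%`, lapply(rotations, rotation_as_dense, dim = dim), diag(dim))
}

# dense-oracle encryption: P (alpha X) Q
oracle_encrypt_data <- function(X, key) {
  P <- dense_rotation_product(key$left_rotations, nrow(X))
  Q <- dense_rotation_product(key$right_rotations, ncol(X))
  P %*% (key$alpha * X) %*% Q
}

oracle_encrypt_projection <- function(W, key) {
  Q <- dense_rotation_product(key$right_rotations, ncol(W))
  (key$alpha * W) %*% Q
}

# brute-force window enumeration: list of windows by explicit index walk
oracle_slices <- function(vec, sl, ov) {
  step <- sl - ov
  out <- list()
  start <- 1L
  repeat {
    w <- integer(sl)
    for (p in seq_len(sl)) {
      q <- start + p - 1L
      w[p] <- if (q <= length(vec)) vec[q] else -1L
    }
    out[[length(out) + 1L]] <- w
    if (start + sl - 1L >= length(vec)) break
    start <- start + step
  }
  out
}

# brute-force top-k by metric with id tie-break
oracle_topk <- function(q, C, metric, k) {
  d <- apply(C, 1L, function(v) switch(metric,
    euclidean = sqrt(sum((v - q)^2)),
    l1 = sum(abs(v - q)),
    cosine = 1 - sum(v * q) / (sqrt(sum(v^2)) * sqrt(sum(q^2)))))
  ord <- order(d, rownames(C))
  rownames(C)[ord[seq_len(min(k, nrow(C)))]]
}

random_rotations <- function(n, dim) replicate(n, sample_givens(dim), simplify = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

rot <- function(i, j, theta)
  structure(list(i = as.integer(i), j = as.integer(j), theta = theta),
            class = "givens_rotation")

# strip encryption marker attributes for plain-matrix comparison
plain <- function(x) { x <- unclass(x); attr(x, "kind") <- NULL; x }
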