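#' Sample a random-projection LSH ensemble
#'
#' Draws `L` independent hash tables, each defined by a t x d projection
#' matrix with i.i.d. standard normal entries (2-stable, so per-row collision
#' probability is a decreasing function of Euclidean distance) and `t` random
#' offsets uniform on \[0, bucket_width). All tables share the hash size `t`,
#' the feature dimension `d` and the bucket width. In the federated protocol
#' the cloud server samples one ensemble and broadcasts it to every client,
#' which keeps the global hash space consistent across institutions.
#'
#' @param t Hash size: number of projection rows per table.
#' @param d Feature dimension of the data.
#' @param L Number of independent hash tables. Default 3.
#' @param bucket_width Quantization width `r` of the bucket grid (positive;
#'   default 4, a common choice for roughly unit-variance features). The
#'   protocol also accepts this under its historical alias `num_hash`.
#' @param seed Optional integer seed; the ensemble is fully determined by it.
#' @return An object of class `lsh_ensemble`: list of `L` tables
#'   (`$W`, `$offsets`) plus `t`, `d`, `L`, `bucket_width`, `seed`.
#' @export
sample_ensemble <- function(t, d, L = 3L, bucket_width = 4, seed = NULL) {
  if (t < 1 || d < 1 || L < 1 || bucket_width <= 0)
    stop_invalid("config",
      "`t`, `d`, `L` must be positive integers and `bucket_width` > 0")
  with_seed(seed, {
    tables <- lapply(seq_len(L), function(i) list(
      W = matrix(stats::rnorm(t * d), nrow = t, ncol = d),
      offsets = stats::runif(t, 0, bucket_width)
    ))
    structure(list(tables = tables, t = as.integer(t), d = as.integer(d),
                   L = as.integer(L), bucket_width = bucket_width,
                   seed = seed),
              class = "lsh_ensemble")
  })
}

#' @export
print.lsh_ensemble <- function(x, ...) {
  cat(sprintf("LSH ensemble: %d table(s) of hash size %d on %d-dimensional data, bucket width %g\n",
              x$L, x$t, x$d, x$bucket_width))
  invisible(x)
}

#' Project a data matrix onto LSH hash rows
#'
#' Computes the real-valued projection table `W %*% t(X)` (t x m): column j
#' holds the `t` hash projections of item j. This is the quantity a client
#' either computes locally or outsources to the cloud in blinded form.
#'
#' @param W t x d projection matrix (or an `lsh_ensemble`, in which case a
#'   list of `L` tables is returned).
#' @param X m x d data matrix; rownames are item identifiers.
#' @return A t x m matrix with `colnames` the item ids (or a list of them).
#' @export
project <- function(W, X) {
  X <- as_num_matrix(X, "X")
  if (inherits(W, "lsh_ensemble")) {
    if (ncol(X) != W$d)
      stop_invalid("config", "feature dimension mismatch with ensemble")
    return(lapply(W$tables, function(tb) project(tb$W, X)))
  }
  W <- as_num_matrix(W, "W")
  if (ncol(W) != ncol(X))
    stop_invalid("config", sprintf(
      "W has %d columns but X has %d", ncol(W), ncol(X)))
  H <- W %*% t(X)
  colnames(H) <- rownames(X)
  H
}

#' Quantize a projection table into integer buckets
#'
#' Applies the p-stable LSH quantizer elementwise:
#' `bucket = floor((H + offset) / bucket_width)`, with the offset added
#' per hash row and floor taken toward minus infinity. Two items collide on a
#' row exactly when their offset projections fall in the same length-`r`
#' cell, which happens with probability decreasing in their Euclidean
#' distance.
#'
#' @param H t x m real projection table.
#' @param offsets Length-t offsets in \[0, bucket_width).
#' @param bucket_width Positive bucket width.
#' @return A t x m integer matrix (storage mode double to avoid overflow on
#'   large-magnitude projections; values are exact integers).
#' @export
bucketize <- function(H, offsets, bucket_width) {
  H <- as_num_matrix(H, "H")
  if (bucket_width <= 0) stop_invalid("config", "`bucket_width` must be > 0")
  if (length(offsets) != nrow(H))
    stop_invalid("config", "`offsets` must have one entry per hash row")
  B <- floor((H + offsets) / bucket_width)
  colnames(B) <- colnames(H)
  B
}

# t x m bucket tables for every ensemble table; returns list of L matrices
bucketize_ensemble <- function(ensemble, H_list) {
  stopifnot(inherits(ensemble, "lsh_ensemble"),
            length(H_list) == ensemble$L)
  lapply(seq_len(ensemble$L), function(i)
    bucketize(H_list[[i]], ensemble$tables[[i]]$offsets,
              ensemble$bucket_width))
}

bucket_key <- function(v) paste(v, collapse = ",")

#' Build the data server's federated index
#'
#' Aggregates per-table integer bucket tables from all clients into a single
#' index: for each of the `L` tables, a map from the full t-integer bucket
#' key to the set of item ids in that bucket, plus the stored t*L bucket
#' vector per item used for distance ranking. Items whose id (typically a
#' content UUID) has already been indexed are skipped, so the index holds
#' each unique item once even when several clients submit it.
#'
#' @param submissions A list with one element per client; each element is a
#'   list with `buckets` (list of `L` t x m integer matrices, columns in item
#'   order) and `ids` (length-m item identifiers). A single client's
#'   submission may be passed directly.
#' @return An object of class `federated_index`.
#' @export
build_index <- function(submissions) {
  if (!is.null(submissions$buckets)) submissions <- list(submissions)
  if (length(submissions) == 0L ||
      all(vapply(submissions, function(s) length(s$ids) == 0L, logical(1))))
    return(empty_index())
  L <- length(submissions[[1L]]$buckets)
  t_ <- nrow(submissions[[1L]]$buckets[[1L]])
  for (s in submissions) {
    if (length(s$buckets) != L ||
        any(vapply(s$buckets, nrow, 0L) != t_) ||
        any(vapply(s$buckets, ncol, 0L) != length(s$ids)))
      stop_invalid("protocol", "inconsistent bucket-table shapes across clients")
  }
  ids <- unlist(lapply(submissions, `[[`, "ids"), use.names = FALSE)
  client <- rep(seq_along(submissions),
                vapply(submissions, function(s) length(s$ids), 0L))
  # m x (t*L) matrix of concatenated bucket vectors
  vecs <- do.call(rbind, lapply(submissions, function(s)
    do.call(cbind, lapply(s$buckets, t))))
  keep <- !duplicated(ids)
  ids <- ids[keep]; client <- client[keep]
  vecs <- vecs[keep, , drop = FALSE]
  rownames(vecs) <- ids
  buckets <- lapply(seq_len(L), function(tb) {
    keys <- apply(vecs[, (tb - 1L) * t_ + seq_len(t_), drop = FALSE],
                  1L, bucket_key)
    split(ids, keys)
  })
  structure(list(t = t_, L = L, buckets = buckets, vectors = vecs,
                 ids = ids, client = stats::setNames(client, ids)),
            class = "federated_index")
}

empty_index <- function() {
  structure(list(t = 0L, L = 0L, buckets = list(),
                 vectors = matrix(0, 0, 0), ids = character(0),
                 client = integer(0)),
            class = "federated_index")
}

#' @export
print.federated_index <- function(x, ...) {
  cat(sprintf("Federated LSH index: %d items from %d client(s), %d table(s) of hash size %d\n",
              length(x$ids), length(unique(x$client)), x$L, x$t))
  invisible(x)
}

#' Candidate generation from a federated index
#'
#' Returns the union, over the `L` tables, of items whose full t-integer
#' bucket key equals the query's. Exact key collisions are rare for large
#' `t`, so when the union holds fewer than `num_results` ids the lookup falls
#' back to ranking all indexed items by the L1 distance between integer
#' bucket vectors (averaged over tables) and adds nearest ids until
#' `num_results` is reached. Fewer than `num_results` ids are returned only
#' when the index itself is smaller.
#'
#' @param index A `federated_index`.
#' @param query_buckets List of `L` integer t-vectors (the query's bucket
#'   vector per table), or a single concatenated t*L vector.
#' @param num_results Number of candidates wanted.
#' @return Character vector of candidate item ids (unordered set).
#' @export
lookup_candidates <- function(index, query_buckets, num_results) {
  stopifnot(inherits(index, "federated_index"))
  if (length(index$ids) == 0L) return(character(0))
  qv <- query_bucket_vector(index, query_buckets)
  cands <- character(0)
  for (tb in seq_len(index$L)) {
    key <- bucket_key(qv[(tb - 1L) * index$t + seq_len(index$t)])
    hit <- index$buckets[[tb]][[key]]
    if (!is.null(hit)) cands <- union(cands, hit)
  }
  if (length(cands) < num_results) {
    d1 <- colSums(abs(t(index$vectors) - qv)) / index$L
    ranked <- index$ids[order(d1, index$ids)]
    ranked <- setdiff(ranked, cands)
    need <- min(num_results - length(cands), length(ranked))
    cands <- c(cands, ranked[seq_len(need)])
  }
  cands
}

query_bucket_vector <- function(index, query_buckets) {
  qv <- if (is.list(query_buckets)) unlist(query_buckets) else query_buckets
  if (length(qv) != index$t * index$L)
    stop_invalid("config", sprintf(
      "query bucket vector has length %d; index expects %d",
      length(qv), index$t * index$L))
  as.numeric(qv)
}

#' Rank candidates by distance to a query vector
#'
#' Orders candidate items by ascending distance between their stored vectors
#' (by default the t*L integer bucket vectors held by the data server) and
#' the query's, under one of three metrics: `euclidean`, `cosine` (ranked by
#' 1 - cosine similarity) or `l1`. Ties are broken by item id in lexicographic
#' order so results are reproducible.
#'
#' @param query_vector Numeric vector of length t*L.
#' @param cand_vectors Matrix of candidate vectors (rows named by item id).
#' @param metric One of `"euclidean"`, `"cosine"`, `"l1"`.
#' @param num_results Maximum number of ranked results to return.
#' @return An object of class `query_result`: a data.frame with columns
#'   `id` and `distance`, ordered by rank, with attributes `metric` and
#'   `num_results`.
#' @export
rank_candidates <- function(query_vector, cand_vectors,
                            metric = c("euclidean", "cosine", "l1"),
                            num_results = 4L) {
  metric <- tryCatch(match.arg(metric),
                     error = function(e) stop_invalid("config",
                       sprintf("unknown metric '%s'", metric[1L])))
  C <- as_num_matrix(cand_vectors, "cand_vectors")
  q <- as.numeric(query_vector)
  if (ncol(C) != length(q))
    stop_invalid("config", "candidate vectors and query length disagree")
  dist <- switch(metric,
    euclidean = sqrt(rowSums(sweep(C, 2L, q)^2)),
    l1 = rowSums(abs(sweep(C, 2L, q))),
    cosine = {
      qn <- sqrt(sum(q^2)); cn <- sqrt(rowSums(C^2))
      sim <- as.numeric(C %*% q) / (cn * qn)
      # zero-norm vectors have undefined direction: maximal distance, except
      # a zero query against a zero candidate (distance 0)
      bad <- !is.finite(sim)
      sim[bad] <- ifelse(qn == 0 & cn[bad] == 0, 1, 0)
      1 - sim
    })
  ord <- order(dist, rownames(C))
  keep <- ord[seq_len(min(num_results, length(ord)))]
  structure(data.frame(id = rownames(C)[keep], distance = dist[keep],
                       row.names = NULL),
            metric = metric, num_results = as.integer(num_results),
            class = c("query_result", "data.frame"))
}
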