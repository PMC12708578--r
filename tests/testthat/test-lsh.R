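test_that("ensembles are seed-deterministic with the right shapes and moments", {
  e1 <- sample_ensemble(5, 8, L = 2, bucket_width = 3, seed = 10)
  e2 <- sample_ensemble(5, 8, L = 2, bucket_width = 3, seed = 10)
  expect_identical(e1, e2)
  expect_length(e1$tables, 2L)
  expect_identical(dim(e1$tables[[1]]$W), c(5L, 8L))
  expect_true(all(e1$tables[[1]]$offsets >= 0 & e1$tables[[1]]$offsets < 3))
  expect_error(sample_ensemble(0, 8), class = "fedlsh_config")
  expect_error(sample_ensemble(5, 8, bucket_width = -1), class = "fedlsh_config")

  big <- sample_ensemble(40, 3072, L = 3, seed = 1)
  expect_length(big$tables, 3L)
  expect_identical(dim(big$tables[[2]]$W), c(40L, 3072L))
  expect_lt(abs(mean(big$tables[[1]]$W)), 0.02)
})

test_that("projection equals row-by-row dot products", {
  set.seed(2)
  X <- matrix(rnorm(6 * 4), 6, dimnames = list(paste0("i", 1:6), NULL))
  W <- matrix(rnorm(3 * 4), 3)
  H <- project(W, X)
  expect_identical(colnames(H), rownames(X))
  for (r in 1:3) for (j in 1:6)
    expect_equal(H[r, j], sum(W[r, ] * X[j, ]), tolerance = 1e-10,
                 ignore_attr = TRUE)
  expect_equal(project(diag(4), X), t(X), ignore_attr = TRUE)
  expect_equal(project(W, matrix(0, 2, 4)), matrix(0, 3, 2))
  expect_error(project(W, matrix(0, 2, 5)), class = "fedlsh_config")
})

test_that("bucketize floors offset projections toward minus infinity", {
  expect_equal(bucketize(matrix(5.0), 0.3, 1), matrix(5))
  expect_equal(bucketize(matrix(-0.5), 0.0, 1), matrix(-1))
  expect_error(bucketize(matrix(1), 0, 0), class = "fedlsh_config")

  # monotone: raising an entry never lowers its bucket
  set.seed(3)
  H <- matrix(rnorm(50), 5)
  off <- runif(5, 0, 2)
  B1 <- bucketize(H, off, 2)
  B2 <- bucketize(H + abs(matrix(rnorm(50), 5)), off, 2)
  expect_true(all(B2 >= B1))
})

test_that("doubling the bucket width never splits a colliding pair", {
  set.seed(4)
  X <- matrix(rnorm(30 * 8), 30)
  W <- matrix(rnorm(6 * 8), 6)
  H <- project(W, X)
  off <- runif(6, 0, 1)
  B1 <- bucketize(H, off, 1)
  B2 <- bucketize(H, off, 2)
  coll <- function(B) {
    n <- ncol(B)
    sum(vapply(seq_len(n - 1), function(i)
      sum(B[, i] == B[, (i + 1):n, drop = FALSE]), 0))
  }
  expect_gte(coll(B2), coll(B1))
})

test_that("the federated index aggregates clients and skips duplicate ids", {
  set.seed(5)
  e <- sample_ensemble(4, 6, L = 2, bucket_width = 2, seed = 1)
  mk <- function(ids) {
    X <- matrix(rnorm(length(ids) * 6), length(ids),
                dimnames = list(ids, NULL))
    list(buckets = bucketize_ensemble(e, project(e, X)), ids = ids)
  }
  idx <- build_index(list(mk(c("a", "b")), mk(c("c", "d", "e"))))
  expect_identical(sort(idx$ids), c("a", "b", "c", "d", "e"))

  sub <- mk(c("x", "y"))
  idx2 <- build_index(list(sub, sub))  # same UUIDs submitted twice
  expect_identical(sort(idx2$ids), c("x", "y"))
  expect_identical(nrow(idx2$vectors), 2L)

  expect_length(build_index(list())$ids, 0L)
  res <- query_index(list(index = build_index(list()), ensemble = e,
                          config = fed_config(1, 6, t = 4, L = 2)),
                     matrix(rnorm(6), 1))
  expect_identical(nrow(res[[1]]), 0L)

  bad <- mk("z"); bad$buckets[[2]] <- bad$buckets[[2]][1:3, , drop = FALSE]
  expect_error(build_index(list(bad)), class = "fedlsh_protocol")
})

test_that("candidate lookup matches a brute-force nearest-bucket scan", {
  set.seed(6)
  e <- sample_ensemble(8, 10, L = 2, bucket_width = 4, seed = 2)
  ids <- sprintf("it%02d", 1:50)
  X <- matrix(rnorm(50 * 10), 50, dimnames = list(ids, NULL))
  B <- bucketize_ensemble(e, project(e, X))
  idx <- build_index(list(list(buckets = B, ids = ids)))

  # an indexed item's own buckets must return it
  qv <- idx$vectors["it07", ]
  expect_true("it07" %in% lookup_candidates(idx, qv, 4))

  # fallback path equals brute-force L1 ranking over bucket vectors
  q <- rnorm(10)
  qb <- unlist(lapply(seq_len(e$L), function(i)
    bucketize(project(e$tables[[i]]$W, matrix(q, 1)),
              e$tables[[i]]$offsets, e$bucket_width)))
  got <- lookup_candidates(idx, qb, 7)
  d1 <- apply(idx$vectors, 1, function(v) sum(abs(v - qb)))
  exact <- idx$ids[vapply(seq_len(e$L), function(tb) {
    key <- paste(qb[(tb - 1) * 8 + 1:8], collapse = ",")
    idx$ids %in% (idx$buckets[[tb]][[key]] %||% character(0))
  }, logical(50)) |> apply(1, any)]
  brute <- union(exact, idx$ids[order(d1, idx$ids)])
  expect_setequal(got, brute[seq_len(7)])

  # small index exhausted: all items returned
  small <- build_index(list(list(buckets = lapply(B, function(b) b[, 1:3]),
                                 ids = ids[1:3])))
  expect_setequal(lookup_candidates(small, qb, 4), ids[1:3])
})

test_that("candidate ranking agrees with a brute-force sort for all metrics", {
  set.seed(7)
  C <- matrix(rnorm(5 * 6), 5, dimnames = list(paste0("c", 1:5), NULL))
  q <- rnorm(6)
  for (metric in c("euclidean", "cosine", "l1")) {
    r <- rank_candidates(q, C, metric, num_results = 5)
    expect_identical(r$id, oracle_topk(q, C, metric, 5))
    expect_true(all(diff(r$distance) >= -1e-12))
  }
  # identical candidate ranks first at distance 0; cosine is scale-free
  C2 <- rbind(C, q = q, q2 = 2 * q)
  expect_identical(rank_candidates(q, C2, "euclidean", 1)$id, "q")
  rc <- rank_candidates(q, C2, "cosine", 2)
  expect_setequal(rc$id, c("q", "q2"))
  expect_equal(rc$distance, c(0, 0), tolerance = 1e-9)
  expect_identical(nrow(rank_candidates(q, rbind(C2, C2 + 1), "l1", 4)), 4L)
  expect_error(rank_candidates(q, C, "mahalanobis"), class = "fedlsh_config")
})

test_that("per-row collisions grow less frequent with distance", {
  pairs <- gen_distance_pairs(800, 32, max_dist = 16, seed = 8)
  e <- sample_ensemble(20, 32, L = 2, bucket_width = 4, seed = 9)
  prof <- collision_profile(pairs$X1, pairs$X2, e, n_bins = 8)
  expect_true(all(prof$collision >= 0 & prof$collision <= 1))
  expect_lte(sum(diff(prof$collision) > 0), 1)  # at most one inversion
  expect_lt(attr(prof, "spearman"), -0.9)
})
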