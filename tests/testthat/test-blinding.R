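test_that("sampled rotations have valid uniform index pairs and angles", {
  expect_error(sample_givens(1), class = "fedlsh_dimension")

  set.seed(42)
  r2 <- sample_givens(2)
  expect_identical(c(r2$i, r2$j), c(1L, 2L))
  expect_gt(r2$theta, 0); expect_lt(r2$theta, 2 * pi)

  set.seed(7); a <- sample_givens(5)
  set.seed(7); b <- sample_givens(5)
  expect_identical(a, b)

  # Monte-Carlo over the uniform pair distribution: dim=4 has 6 pairs
  set.seed(1)
  draws <- replicate(10000, { r <- sample_givens(4); paste(r$i, r$j) })
  freq <- table(draws) / 10000
  expect_length(freq, 6L)
  expect_true(all(abs(freq - 1 / 6) < 0.02))
})

test_that("dense rotation form follows the sign convention and is orthogonal", {
  G <- rotation_as_dense(rot(1, 2, pi / 2), 2)
  expect_equal(G, matrix(c(0, -1, 1, 0), 2), tolerance = 1e-12)

  G3 <- rotation_as_dense(rot(1, 3, pi), 3)
  expect_equal(diag(G3), c(-1, 1, -1), tolerance = 1e-12)
  expect_lt(max(abs(G3[row(G3) != col(G3)])), 1e-12)

  set.seed(3)
  for (dim in c(2, 5, 17)) {
    G <- rotation_as_dense(sample_givens(dim), dim)
    expect_lt(max(abs(crossprod(G) - diag(dim))), 1e-12)
  }
})

test_that("sparse rotation application matches the dense-product oracle", {
  M <- diag(2)
  r90 <- list(rot(1, 2, pi / 2))
  expect_equal(apply_left_rotations(M, r90), matrix(c(0, -1, 1, 0), 2),
               tolerance = 1e-12)
  expect_equal(apply_right_rotations(M, r90), matrix(c(0, -1, 1, 0), 2),
               tolerance = 1e-12)
  expect_identical(apply_left_rotations(M, list()), M)
  expect_identical(apply_right_rotations(M, list()), M)

  set.seed(11)
  for (rep in 1:5) {
    M <- matrix(rnorm(8 * 5), 8)
    rl <- random_rotations(6, 8)
    rr <- random_rotations(6, 5)
    expect_equal(apply_left_rotations(M, rl),
                 dense_rotation_product(rl, 8) %*% M, tolerance = 1e-10)
    expect_equal(apply_right_rotations(M, rr),
                 M %*% dense_rotation_product(rr, 5), tolerance = 1e-10)
  }
  bad <- random_rotations(1, 10)
  expect_error(apply_left_rotations(matrix(0, 3, 3), bad),
               class = "fedlsh_key")
})

test_that("products of many rotations stay orthogonal at scale", {
  set.seed(5)
  for (case in list(c(16, 8), c(128, 32), c(256, 64))) {
    G <- dense_rotation_product(random_rotations(case[2], case[1]), case[1])
    expect_lt(max(abs(crossprod(G) - diag(case[1]))), 1e-10)
  }
})

test_that("keygen is seed-deterministic with bounded alpha and valid indices", {
  expect_error(keygen(1, 4), class = "fedlsh_dimension")
  expect_identical(keygen(4, 4, 2, seed = 9), keygen(4, 4, 2, seed = 9))

  set.seed(2)
  alphas <- replicate(1000, keygen(3, 3, 1)$alpha)
  expect_true(all(alphas >= 0.5 & alphas <= 2))

  k <- keygen(2, 3, 1, seed = 4)
  expect_identical(c(k$left_rotations[[1]]$i, k$left_rotations[[1]]$j),
                   c(1L, 2L))
  rr <- k$right_rotations[[1]]
  expect_true(rr$i < rr$j && rr$j <= 3)
})

test_that("encryption matches the dense oracle and conserves the norm", {
  rot90 <- list(rot(1, 2, pi / 2))
  key <- structure(list(alpha = 2, left_rotations = rot90,
                        right_rotations = rot90, m = 2L, d = 2L, l = 1L,
                        seed = NULL), class = "blinding_key")
  expect_equal(plain(encrypt_data(diag(2), key)), diag(c(-2, -2)),
               tolerance = 1e-12)
  expect_equal(plain(encrypt_projection(matrix(c(1, 0), 1), key)),
               matrix(c(0, 1), 1) * 2, tolerance = 1e-12)

  set.seed(8)
  for (rep in 1:5) {
    k <- keygen(7, 9, 5)
    X <- matrix(rnorm(7 * 9), 7)
    W <- matrix(rnorm(4 * 9), 4)
    Xp <- encrypt_data(X, k); Wp <- encrypt_projection(W, k)
    expect_equal(plain(Xp), oracle_encrypt_data(X, k), tolerance = 1e-10)
    expect_equal(plain(Wp), oracle_encrypt_projection(W, k), tolerance = 1e-10)
    expect_equal(norm(plain(Xp), "F"), abs(k$alpha) * norm(X, "F"),
                 tolerance = 1e-9)
    expect_equal(norm(plain(Wp), "F"), abs(k$alpha) * norm(W, "F"),
                 tolerance = 1e-9)
  }
  expect_error(encrypt_data(matrix(0, 3, 3), keygen(4, 3, 1, seed = 1)),
               class = "fedlsh_key")
  expect_equal(plain(encrypt_projection(matrix(0, 2, 9), keygen(5, 9, 2, seed = 1))),
               matrix(0, 2, 9))
})

test_that("the encrypted product is the plain matrix product of its inputs", {
  expect_equal(plain(encrypted_product(matrix(c(0, 1), 1), matrix(c(3, 4), 1))),
               matrix(4), tolerance = 1e-12)
  expect_equal(plain(encrypted_product(matrix(0, 2, 3), matrix(rnorm(12), 4))),
               matrix(0, 2, 4))
  set.seed(12)
  Wp <- matrix(rnorm(6 * 5), 6); Xp <- matrix(rnorm(9 * 5), 9)
  expect_equal(plain(encrypted_product(Wp, Xp)), Wp %*% t(Xp),
               tolerance = 1e-10)
  expect_error(encrypted_product(matrix(0, 2, 3), matrix(0, 2, 4)),
               class = "fedlsh_protocol")
})

test_that("verification accepts honest tables and rejects perturbed ones", {
  set.seed(21)
  k <- keygen(12, 10, 4)
  Xp <- encrypt_data(matrix(rnorm(120), 12), k)
  Wp <- encrypt_projection(matrix(rnorm(50), 5), k)
  Hp <- encrypted_product(Wp, Xp)
  expect_true(all(replicate(200, verify_product(Hp, Wp, Xp))))
  expect_true(verify_product(matrix(0, 2, 2), matrix(0, 2, 3), matrix(0, 2, 3)))

  rejected <- sum(replicate(200, {
    Hbad <- plain(Hp)
    i <- sample(5, 1); j <- sample(12, 1)
    Hbad[i, j] <- Hbad[i, j] + 1
    !verify_product(Hbad, Wp, Xp)
  }))
  expect_gte(rejected, 199)
  expect_false(verify_product(matrix(0, 3, 3), Wp, Xp))  # wrong shape
})

test_that("recovery inverts the full outsourcing round trip", {
  set.seed(31)
  for (rep in 1:10) {
    k <- keygen(10, 6, 4)
    W <- matrix(rnorm(8 * 6), 8); X <- matrix(rnorm(10 * 6), 10)
    H <- recover_table(encrypted_product(encrypt_projection(W, k),
                                         encrypt_data(X, k)), k)
    truth <- W %*% t(X)
    expect_lt(max(abs(H - truth)) / max(abs(truth)), 1e-9)
  }
  k <- keygen(4, 4, 1, seed = 1)
  expect_equal(recover_table(matrix(0, 3, 4), k), matrix(0, 3, 4))
  expect_error(recover_table(matrix(0, 3, 5), k), class = "fedlsh_key")
})

test_that("rotation application honors the sparsity cost contract", {
  set.seed(6)
  M <- matrix(rnorm(20 * 30), 20)
  for (l in c(1, 5, 12)) {
    sm_reset()
    apply_left_rotations(M, random_rotations(l, 20))
    expect_identical(unname(sm_counts()["other"]), 4 * 30 * l)
    sm_reset()
    apply_right_rotations(M, random_rotations(l, 30))
    expect_identical(unname(sm_counts()["other"]), 4 * 20 * l)
  }
  sm_reset()
})

test_that("encrypted tables conserve the scaled Frobenius norm", {
  set.seed(41)
  k <- keygen(9, 7, 3)
  W <- matrix(rnorm(5 * 7), 5); X <- matrix(rnorm(9 * 7), 9)
  Hp <- encrypted_product(encrypt_projection(W, k), encrypt_data(X, k))
  expect_equal(norm(plain(Hp), "F"), k$alpha^2 * norm(W %*% t(X), "F"),
               tolerance = 1e-9)
})

test_that("blinding keys survive a JSON round trip", {
  k <- keygen(6, 11, 3, seed = 99)
  path <- tempfile(fileext = ".json")
  write_blinding_key(k, path)
  k2 <- read_blinding_key(path)
  expect_equal(k2$alpha, k$alpha, tolerance = 1e-12)
  expect_identical(k2$m, k$m); expect_identical(k2$d, k$d)
  X <- matrix(rnorm(6 * 11), 6)
  expect_equal(plain(encrypt_data(X, k2)), plain(encrypt_data(X, k)),
               tolerance = 1e-12)
})
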