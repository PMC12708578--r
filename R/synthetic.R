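#' Labeled Gaussian cluster benchmark generator
#'
#' Generates the package's stand-in for a labeled image benchmark: `K` class
#' centers drawn i.i.d. N(0, center_scale^2 I_d), and points as
#' center + N(0, noise_sd^2 I_d). The default spec (10 classes x 500 points,
#' d = 64, center_scale 0.55, noise_sd 1) is calibrated so a plain
#' leave-one-out 1-nearest-neighbour classifier attains about 0.90 accuracy
#' — enough class structure that a working LSH pipeline must clearly beat
#' the chance level, without being trivially separable.
#'
#' @param n_classes Number of classes. Default 10.
#' @param points_per_class Points per class. Default 500.
#' @param d Feature dimension. Default 64.
#' @param center_scale Standard deviation of the class centers. Default 0.55.
#' @param noise_sd Within-class standard deviation. Default 1.
#' @param seed Optional integer seed; data fully determined by it.
#' @return List with `X` (n x d matrix, rownames `item1..n`), `labels`
#'   (named integer vector) and the spec fields.
#' @export
gen_clusters <- function(n_classes = 10L, points_per_class = 500L, d = 64L,
                         center_scale = 0.55, noise_sd = 1, seed = NULL) {
  stopifnot(n_classes >= 1, points_per_class >= 1, d >= 1,
            center_scale >= 0, noise_sd >= 0)
  with_seed(seed, {
    centers <- matrix(stats::rnorm(n_classes * d, 0, center_scale), n_classes)
    labels <- rep(seq_len(n_classes), each = points_per_class)
    n <- length(labels)
    X <- centers[labels, , drop = FALSE] +
      matrix(stats::rnorm(n * d, 0, noise_sd), n)
    ids <- paste0("item", seq_len(n))
    rownames(X) <- ids
    names(labels) <- ids
    list(X = X, labels = labels, n_classes = as.integer(n_classes),
         points_per_class = as.integer(points_per_class), d = as.integer(d),
         center_scale = center_scale, noise_sd = noise_sd, seed = seed)
  })
}

#' Synthetic genomes with planted near-duplicates
#'
#' Generates variable-length random ACGT sequences and, for each, a number
#' of "variant" copies with i.i.d. per-base substitutions at a fixed rate.
#' Variants emulate the near-duplicate gene fragments a federated index is
#' meant to retrieve; provenance (which base sequence a variant descends
#' from) is returned as ground truth so hit-rate evaluation needs no
#' external labels. Substitution-only (no indels): an indel would shift
#' every downstream slicing frame and sever the planted-pair ground truth.
#'
#' @param n_base Number of base sequences. Default 20.
#' @param length_range Integer range `c(min, max)` of sequence lengths.
#' @param mutation_rate Per-base substitution probability in \[0, 1).
#' @param variants_per_base Variant copies per base sequence. Default 1.
#' @param seed Optional integer seed.
#' @return List with `sequences` (named character vector; variants named
#'   `<base>_v<k>`) and `truth` (named character vector mapping every
#'   record id to its base-sequence id).
#' @export
gen_genomes <- function(n_base = 20L, length_range = c(3000L, 12000L),
                        mutation_rate = 0.01, variants_per_base = 1L,
                        seed = NULL) {
  stopifnot(n_base >= 1, length_range[1L] >= 1,
            length_range[2L] >= length_range[1L],
            mutation_rate >= 0, mutation_rate < 1, variants_per_base >= 0)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    lens <- length_range[1L] - 1L +
      sample.int(length_range[2L] - length_range[1L] + 1L, n_base,
                 replace = TRUE)
    seqs <- character(0); truth <- character(0)
    for (i in seq_len(n_base)) {
      id <- sprintf("base%03d", i)
      s <- sample(bases, lens[i], replace = TRUE)
      seqs[id] <- paste(s, collapse = "")
      truth[id] <- id
      for (k in seq_len(variants_per_base)) {
        hit <- which(stats::runif(lens[i]) < mutation_rate)
        v <- s
        if (length(hit))  # substitute with one of the 3 other bases
          v[hit] <- bases[(match(s[hit], bases) - 1L +
                             sample.int(3L, length(hit), replace = TRUE)) %% 4L + 1L]
        vid <- sprintf("%s_v%d", id, k)
        seqs[vid] <- paste(v, collapse = "")
        truth[vid] <- id
      }
    }
    list(sequences = seqs, truth = truth, mutation_rate = mutation_rate,
         seed = seed)
  })
}

#' Shard items across federation clients
#'
#' Seed-shuffled balanced partition: shard sizes differ by at most one,
#' shards are disjoint and exhaustive.
#'
#' @param items Vector of items (or a single count, in which case indices
#'   are sharded).
#' @param n_clients Number of shards.
#' @param seed Optional seed for the shuffle.
#' @return List of `n_clients` vectors.
#' @export
shard_clients <- function(items, n_clients, seed = NULL) {
  stopifnot(n_clients >= 1)
  if (length(items) == 1L && is.numeric(items)) items <- seq_len(items)
  with_seed(seed, {
    perm <- sample(length(items))
    shard_of <- rep(seq_len(n_clients), length.out = length(items))
    lapply(seq_len(n_clients), function(k) items[perm[shard_of == k]])
  })
}

#' Point pairs at controlled Euclidean distances
#'
#' Diagnostic generator for collision profiling: each pair is a Gaussian
#' point and a partner displaced along a random direction by a distance
#' drawn uniformly on (0, max_dist\]. This spreads true distances evenly
#' across the profiling range instead of letting them concentrate at
#' sqrt(2d), which is what i.i.d. Gaussian pairs would do.
#'
#' @param n_pairs Number of pairs.
#' @param d Dimension.
#' @param max_dist Largest pair distance.
#' @param seed Optional seed.
#' @return List of matrices `X1`, `X2` (n_pairs x d) and `dist` (true
#'   pairwise distances).
#' @export
gen_distance_pairs <- function(n_pairs, d, max_dist, seed = NULL) {
  stopifnot(n_pairs >= 1, d >= 1, max_dist > 0)
  with_seed(seed, {
    X1 <- matrix(stats::rnorm(n_pairs * d), n_pairs)
    U <- matrix(stats::rnorm(n_pairs * d), n_pairs)
    U <- U / sqrt(rowSums(U^2))
    dist <- stats::runif(n_pairs, 0, max_dist)
    list(X1 = X1, X2 = X1 + dist * U, dist = dist)
  })
}
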