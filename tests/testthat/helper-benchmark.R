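# Default 10-class cluster benchmark (500 points/class, d = 64) indexed by
# a 10-client federation at t = 40, L = 3, with 300 held-in queries.
# Built once per session and cached: several tests interrogate the same run.
.bench_cache <- new.env(parent = emptyenv())

benchmark_run <- function(seed = 20260101) {
  key <- as.character(seed)
  if (!is.null(.bench_cache[[key]])) return(.bench_cache[[key]])
  cd <- gen_clusters(seed = seed)
  shards <- shard_clients(rownames(cd$X), 10, seed = seed + 1)
  cfg <- fed_config(10, cd$d, t = 40, L = 3, bucket_width = 4, l = 8,
                    mode = "cloud-assisted", seed = seed + 2)
  run <- orchestrate(cfg, lapply(shards, function(s) cd$X[s, , drop = FALSE]))
  qids <- with_preserved_seed(seed + 3, sample(rownames(cd$X), 300))
  # fetch k+1 so each indexed query still yields k candidates besides itself
  results <- query_index(run, cd$X[qids, , drop = FALSE], mode = "local-hash",
                         num_results = cfg$num_results + 1L)
  out <- list(run = run, clusters = cd, results = results, qids = qids)
  .bench_cache[[key]] <- out
  out
}

with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
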