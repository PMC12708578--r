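#' Federated run configuration
#'
#' Bundles the topology and algorithm parameters of one federated indexing
#' run: number of clients, hash size `t`, table count `L`, bucket width,
#' rotations per key side `l`, feature dimension `d`, ranking metric, number
#' of candidates returned per query, query mode and master seed. All
#' randomness in a run (ensemble, keys, verification vectors) is derived
#' from the master seed, so runs are fully reproducible.
#'
#' @param n_clients Number of participating clients.
#' @param d Feature dimension.
#' @param t Hash size per table. Default 40.
#' @param L Number of hash tables. Default 3.
#' @param bucket_width LSH bucket width. Default 4.
#' @param l Givens rotations per key side. Default 8.
#' @param num_results Candidates returned per query. Default 4.
#' @param metric Ranking metric: euclidean, cosine or l1.
#' @param mode Query mode: `"local-hash"` (client projects, sends hashes),
#'   `"cloud-assisted"` (client outsources the projection in blinded form),
#'   or `"raw"` (no privacy: data server projects raw query data).
#' @param seed Master seed (integer) or NULL.
#' @return An object of class `fed_config`.
#' @export
fed_config <- function(n_clients, d, t = 40L, L = 3L, bucket_width = 4,
                       l = 8L, num_results = 4L,
                       metric = c("euclidean", "cosine", "l1"),
                       mode = c("local-hash", "cloud-assisted", "raw"),
                       seed = NULL) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  vals <- c(n_clients = n_clients, d = d, t = t, L = L,
            bucket_width = bucket_width, l = l, num_results = num_results)
  if (any(vals <= 0))
    stop_invalid("config", sprintf(
      "all numeric settings must be positive (offending: %s)",
      paste(names(vals)[vals <= 0], collapse = ", ")))
  structure(list(n_clients = as.integer(n_clients), d = as.integer(d),
                 t = as.integer(t), L = as.integer(L),
                 bucket_width = bucket_width, l = as.integer(l),
                 num_results = as.integer(num_results), metric = metric,
                 mode = mode, seed = seed),
            class = "fed_config")
}

new_message <- function(sender, receiver, kind, payload, round = 0L) {
  structure(list(sender = sender, receiver = receiver, kind = kind,
                 payload = payload, round = round),
            class = "protocol_message")
}

#' Broadcast the global projection ensemble to all clients
#'
#' The cloud server's first duty is consistency of the global hash space:
#' every client must hash with the identical projection ensemble or their
#' bucket keys would be incomparable at the data server. In-process this is
#' modelled by handing every client state the same ensemble object.
#'
#' @param ensemble An `lsh_ensemble` sampled by the cloud.
#' @param clients List of client states (see [orchestrate()]).
#' @return The client list, each with `$ensemble` set.
#' @export
broadcast_ensemble <- function(ensemble, clients) {
  stopifnot(inherits(ensemble, "lsh_ensemble"))
  lapply(clients, function(cl) { cl$ensemble <- ensemble; cl })
}

#' Client-side outsourcing message
#'
#' Encrypts the client's data once (`X'`) and each of the `L` projection
#' matrices (`W'`) under the client's own key, and packs them into a
#' cloud-bound protocol message. Only blinded matrices and their shapes leave
#' the client; neither the raw data nor the key is ever serialized into a
#' message (the privacy audit in [orchestrate()] records every outbound
#' payload so this can be checked after the fact).
#'
#' @param client A client state holding `$X`, `$key` and `$ensemble`.
#' @return A `protocol_message` of kind `"encrypted-pair"` whose payload has
#'   `Xp` (one encrypted data matrix) and `Wp` (list of `L` encrypted
#'   projections).
#' @export
client_outsource <- function(client) {
  if (is.null(client$key) || is.null(client$ensemble))
    stop_invalid("protocol", "client is missing its key or the broadcast ensemble")
  Xp <- encrypt_data(client$X, client$key)
  Wp <- lapply(client$ensemble$tables, function(tb)
    encrypt_projection(tb$W, client$key))
  new_message(client$id, "cloud", "encrypted-pair",
              list(Xp = Xp, Wp = Wp, m = nrow(client$X), d = ncol(client$X)))
}

#' Cloud server: compute encrypted hash tables
#'
#' Applies the encrypted product `W' X'^T` for every table in the incoming
#' encrypted pair and returns the tables to the sender. The cloud is
#' stateless with respect to clients and holds no key material.
#'
#' @param msg A `protocol_message` of kind `"encrypted-pair"`.
#' @return A `protocol_message` of kind `"encrypted-hashtable"`.
#' @export
cloud_serve <- function(msg) {
  if (!inherits(msg, "protocol_message") || msg$kind != "encrypted-pair")
    stop_invalid("protocol", "cloud expects an encrypted-pair message")
  Hp <- lapply(msg$payload$Wp, function(Wp)
    encrypted_product(Wp, msg$payload$Xp))
  new_message("cloud", msg$sender, "encrypted-hashtable", list(Hp = Hp))
}

#' Client-side verification and recovery
#'
#' On receipt of the cloud's encrypted hash tables the client first runs the
#' random-contraction check against the encrypted pair it sent; only tables
#' that pass are unblinded. A failed check raises a `fedlsh_verification`
#' error and the tables are discarded — a tampering cloud can deny service
#' but cannot plant a wrong table.
#'
#' @param client Client state (holding the encrypted pair it outsourced).
#' @param msg The cloud's `"encrypted-hashtable"` message.
#' @param rel_tol Verification tolerance, see [verify_product()].
#' @param seed Optional seed for the verification draws.
#' @return List of `L` recovered t x m projection tables (columns named by
#'   the client's item ids).
#' @export
client_finalize <- function(client, msg, rel_tol = 1e-10, seed = NULL) {
  if (!inherits(msg, "protocol_message") || msg$kind != "encrypted-hashtable")
    stop_invalid("protocol", "expected an encrypted-hashtable message")
  seeds <- child_seeds(seed, length(msg$payload$Hp))
  lapply(seq_along(msg$payload$Hp), function(i) {
    Hp <- msg$payload$Hp[[i]]
    ok <- verify_product(Hp, client$outbox$payload$Wp[[i]],
                         client$outbox$payload$Xp,
                         rel_tol = rel_tol, seed = seeds[[i]])
    if (!ok)
      stop_invalid("verification", sprintf(
        "client %s: cloud table %d failed verification; table discarded",
        client$id, i))
    recover_table(Hp, client$key, column_ids = rownames(client$X))
  })
}

#' Client submission to the data server
#'
#' Quantizes the client's recovered (or locally computed) projection tables
#' into integer buckets and packs them with the item ids. By default the
#' quantization happens client-side so the data server only ever sees
#' integer hash values; `at_server = TRUE` instead ships the real-valued
#' tables and lets the data server quantize (a weaker-privacy variant kept
#' as an explicit option).
#'
#' @param client Client state with `$ensemble`.
#' @param tables List of `L` recovered t x m projection tables.
#' @param at_server If TRUE, submit real-valued tables for server-side
#'   quantization. Default FALSE.
#' @return A `protocol_message` of kind `"bucket-table"` (or `"hashtable"`).
#' @export
submit_hashtables <- function(client, tables, at_server = FALSE) {
  ids <- rownames(client$X)
  if (is.null(ids)) ids <- paste0(client$id, ":", seq_len(nrow(client$X)))
  if (at_server)
    return(new_message(client$id, "dataserver", "hashtable",
                       list(tables = tables, ids = ids)))
  buckets <- bucketize_ensemble(client$ensemble, tables)
  new_message(client$id, "dataserver", "bucket-table",
              list(buckets = buckets, ids = ids))
}

#' Orchestrate a full federated indexing run
#'
#' Runs the complete protocol in process: the cloud samples and broadcasts
#' the global ensemble; each client draws its own blinding key, either
#' projects locally (`mode = "local-hash"` / `"raw"`) or outsources the
#' blinded projection to the cloud and verifies + recovers the result
#' (`mode = "cloud-assisted"`); clients quantize and submit their bucket
#' tables; the data server aggregates them into a [build_index()] federated
#' index. Every outbound client message is recorded in a privacy audit.
#'
#' @param config A [fed_config()].
#' @param client_data List of `n_clients` numeric matrices (rows = items,
#'   rownames = item ids, `d` columns).
#' @param verbose Print per-phase progress. Default FALSE.
#' @return An object of class `fed_run`: list with `index`
#'   (`federated_index`), `ensemble`, `config`, `clients` (states with key
#'   material, local only), `audit` (all outbound client messages) and
#'   `report` (per-phase SM counts and timings).
#' @export
orchestrate <- function(config, client_data, verbose = FALSE) {
  stopifnot(inherits(config, "fed_config"))
  if (length(client_data) != config$n_clients)
    stop_invalid("config", sprintf(
      "expected data for %d clients, got %d",
      config$n_clients, length(client_data)))
  say <- function(...) if (verbose) message(sprintf(...))
  seeds <- child_seeds(config$seed, 2L * config$n_clients + 1L)
  sm_reset()
  t0 <- proc.time()[["elapsed"]]

  ensemble <- sample_ensemble(config$t, config$d, config$L,
                              config$bucket_width, seed = seeds[[1L]])
  clients <- lapply(seq_len(config$n_clients), function(i) {
    X <- as_num_matrix(client_data[[i]], sprintf("client_data[[%d]]", i))
    if (ncol(X) != config$d)
      stop_invalid("config", sprintf(
        "client %d data has %d columns, config says d=%d", i, ncol(X), config$d))
    list(id = paste0("client", i), X = X)
  })
  clients <- broadcast_ensemble(ensemble, clients)
  say("broadcast: ensemble (t=%d, L=%d) to %d clients",
      config$t, config$L, config$n_clients)
  t_bcast <- proc.time()[["elapsed"]]

  audit <- list()
  submissions <- vector("list", config$n_clients)
  for (i in seq_len(config$n_clients)) {
    cl <- clients[[i]]
    cl$key <- keygen(nrow(cl$X), config$d, config$l, seed = seeds[[2L * i]])
    if (config$mode == "cloud-assisted") {
      out <- client_outsource(cl)
      cl$outbox <- out
      audit[[length(audit) + 1L]] <- out
      reply <- cloud_serve(out)
      tables <- client_finalize(cl, reply, seed = seeds[[2L * i + 1L]])
    } else {
      # local-hash (and raw indexing, which hashes identically): the client
      # computes W X^T itself with the broadcast ensemble
      tables <- project(ensemble, cl$X)
    }
    sub <- submit_hashtables(cl, tables)
    audit[[length(audit) + 1L]] <- sub
    submissions[[i]] <- sub$payload
    clients[[i]] <- cl
    say("client %d: %d items indexed (%s mode)", i, nrow(cl$X), config$mode)
  }
  t_clients <- proc.time()[["elapsed"]]

  index <- build_index(submissions)
  t_index <- proc.time()[["elapsed"]]
  say("data server: index of %d unique items", length(index$ids))

  report <- list(
    sm = as.list(sm_counts()),
    timings = list(broadcast = t_bcast - t0,
                   clients = t_clients - t_bcast,
                   index = t_index - t_clients,
                   total = t_index - t0),
    n_items = length(index$ids),
    config = unclass(config))
  structure(list(index = index, ensemble = ensemble, config = config,
                 clients = clients, audit = audit, report = report),
            class = "fed_run")
}

#' @export
print.fed_run <- function(x, ...) {
  cat(sprintf("Federated LSH run: %d clients, %d items, mode '%s' (%.2fs)\n",
              x$config$n_clients, length(x$index$ids), x$config$mode,
              x$report$timings$total))
  invisible(x)
}

#' Query a federated index
#'
#' Answers similarity queries through one of the three protocol paths, which
#' differ only in where the projection `W %*% t(Xq)` is computed:
#' `"raw"` ships the raw query vectors to the data server (no privacy),
#' `"local-hash"` projects on the querying client and ships hash values,
#' and `"cloud-assisted"` outsources the blinded projection to the cloud,
#' then verifies and recovers it before shipping hash values. All three
#' produce the same projections (up to floating-point recovery error far
#' below the bucket width), so ranked results agree across modes.
#'
#' @param run A `fed_run` from [orchestrate()] (or a list with `index` and
#'   `ensemble`).
#' @param Xq Query matrix (rows = query items, rownames = query ids).
#' @param mode Query mode; defaults to the run's configured mode.
#' @param num_results,metric Override the run config.
#' @param seed Optional seed for the query-side key and verification.
#' @return Named list of [rank_candidates()] `query_result` objects, one per
#'   query row.
#' @export
query_index <- function(run, Xq, mode = NULL, num_results = NULL,
                        metric = NULL, seed = NULL) {
  config <- run$config
  mode <- if (is.null(mode)) config$mode else
    match.arg(mode, c("local-hash", "cloud-assisted", "raw"))
  num_results <- if (is.null(num_results)) config$num_results else
    as.integer(num_results)
  metric <- if (is.null(metric)) config$metric else
    match.arg(metric, c("euclidean", "cosine", "l1"))
  Xq <- as_num_matrix(Xq, "Xq")
  if (is.null(rownames(Xq))) rownames(Xq) <- paste0("q", seq_len(nrow(Xq)))
  ensemble <- run$ensemble

  tables <- switch(mode,
    raw = ,            # data server computes W Xq^T on the raw payload
    `local-hash` = project(ensemble, Xq),
    `cloud-assisted` = {
      if (nrow(Xq) < 2)  # blinding needs >= 2 rows to rotate; pad with zeros
        Xq2 <- rbind(Xq, `..pad..` = 0) else Xq2 <- Xq
      seeds <- child_seeds(seed, 2L)
      cl <- list(id = "query-client", X = Xq2, ensemble = ensemble,
                 key = keygen(nrow(Xq2), ncol(Xq2), config$l,
                              seed = seeds[[1L]]))
      cl$outbox <- client_outsource(cl)
      reply <- cloud_serve(cl$outbox)
      tabs <- client_finalize(cl, reply, seed = seeds[[2L]])
      lapply(tabs, function(H) H[, rownames(Xq), drop = FALSE])
    })

  qbuckets <- bucketize_ensemble(ensemble, tables)
  index <- run$index
  results <- lapply(seq_len(nrow(Xq)), function(qi) {
    qv <- unlist(lapply(qbuckets, function(B) B[, qi]))
    cands <- lookup_candidates(index, qv, num_results)
    if (length(cands) == 0L)
      return(structure(data.frame(id = character(0), distance = numeric(0)),
                       metric = metric, num_results = num_results,
                       class = c("query_result", "data.frame")))
    rank_candidates(qv, index$vectors[cands, , drop = FALSE],
                    metric = metric, num_results = num_results)
  })
  names(results) <- rownames(Xq)
  results
}
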