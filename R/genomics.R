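#' Read a FASTA file of nucleotide records
#'
#' Thin wrapper around `seqinr::read.fasta()` that upper-cases sequences,
#' preserves record order and validates ids. Multi-line (wrapped) sequences
#' and lower-case bases are handled; any symbol is accepted at this stage
#' (ambiguity codes are dealt with by [numericize()]).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector: names are the header tokens (first word),
#'   values the upper-cased sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_invalid("parse", paste("no such file:", path))
  recs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                       seqonly = FALSE, forceDNAtolower = FALSE),
    error = function(e) stop_invalid("parse", sprintf(
      "malformed FASTA '%s': %s", path, conditionMessage(e))))
  if (length(recs) == 0L)
    stop_invalid("parse", paste("no records in", path))
  out <- toupper(vapply(recs, function(r) as.character(r)[1L], ""))
  names(out) <- vapply(recs, function(r) attr(r, "name"), "")
  if (anyDuplicated(names(out)))
    stop_invalid("parse", "duplicate record ids in FASTA")
  if (any(nchar(out) == 0L))
    stop_invalid("parse", "empty sequence in FASTA")
  out
}

#' Write records to FASTA
#'
#' @param sequences Named character vector of sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(sequences, path) {
  seqinr::write.fasta(as.list(unname(sequences)), names = names(sequences),
                      file.out = path, nbchar = 70)
  invisible(path)
}

#' Numericize a nucleotide sequence
#'
#' Maps bases to integer codes A=0, T=1, C=2, G=3; every other symbol
#' (N, IUPAC ambiguity codes, gaps) maps to the same -1 sentinel used for
#' window padding, so downstream code has a single "no information" value.
#' Case-insensitive, total (never errors on content).
#'
#' @param sequence A single character string.
#' @return Integer vector of the same length with values in
#'   \{-1, 0, 1, 2, 3\}.
#' @export
numericize <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nchar(sequence) > 0L)
  lut <- .numericize_lut
  unname(lut[utf8ToInt(sequence) + 1L])
}

.numericize_lut <- local({
  lut <- rep(-1L, 256L)
  lut[utf8ToInt("A") + 1L] <- 0L; lut[utf8ToInt("a") + 1L] <- 0L
  lut[utf8ToInt("T") + 1L] <- 1L; lut[utf8ToInt("t") + 1L] <- 1L
  lut[utf8ToInt("C") + 1L] <- 2L; lut[utf8ToInt("c") + 1L] <- 2L
  lut[utf8ToInt("G") + 1L] <- 3L; lut[utf8ToInt("g") + 1L] <- 3L
  lut
})

#' Slicing configuration
#'
#' Fixed-length windowing of numericized sequences: consecutive windows
#' share `overlap` positions, i.e. the stride is
#' `sequence_length - overlap`. The defaults (window 3072, overlap 100)
#' give the slice dimensionality used throughout the genomic benchmarks.
#'
#' @param sequence_length Window size in bases (> overlap).
#' @param overlap Bases shared by consecutive windows (>= 0).
#' @return An object of class `slicing_config`.
#' @export
slicing_config <- function(sequence_length = 3072L, overlap = 100L) {
  if (overlap < 0 || overlap >= sequence_length)
    stop_invalid("config", "need 0 <= overlap < sequence_length")
  structure(list(sequence_length = as.integer(sequence_length),
                 overlap = as.integer(overlap)),
            class = "slicing_config")
}

#' Slice a numericized sequence into fixed-length overlapping windows
#'
#' Windows start at positions 0, s, 2s, ... (s = sequence_length - overlap),
#' covering every input position at least once; the number of chunks is
#' `max(1, ceiling((len - overlap) / s))` and the final window is
#' right-padded with -1 up to `sequence_length`. Concatenating the chunks
#' while dropping each later chunk's first `overlap` positions reproduces
#' the input exactly (up to the final padding).
#'
#' @param vec Integer vector (output of [numericize()]).
#' @param cfg A [slicing_config()].
#' @return An n_chunks x sequence_length integer matrix, one chunk per row.
#' @export
slice_sequence <- function(vec, cfg) {
  stopifnot(inherits(cfg, "slicing_config"), length(vec) >= 1L)
  sl <- cfg$sequence_length; ov <- cfg$overlap
  step <- sl - ov
  n <- length(vec)
  n_chunks <- max(1L, as.integer(ceiling((n - ov) / step)))
  starts <- (seq_len(n_chunks) - 1L) * step + 1L
  need <- starts[n_chunks] + sl - 1L
  if (need > n) vec <- c(vec, rep(-1L, need - n))
  idx <- outer(starts, 0L:(sl - 1L), `+`)
  matrix(vec[idx], nrow = n_chunks, ncol = sl)
}

#' Slice a set of genome records into content-addressed fragments
#'
#' Numericizes each record, slices it with [slice_sequence()], and attaches
#' provenance: `source_index` (ordinal of the source record — the "count" of
#' a (k-mer, count) pair), `chunk_index` (ordinal within the record) and a
#' deterministic content UUID (hash of the slice vector), so identical
#' fragments get identical ids on any client without coordination.
#'
#' @param records Named character vector of sequences (see [read_fasta()]).
#' @param cfg A [slicing_config()].
#' @return An object of class `slice_set`: list with `meta` (data.frame:
#'   `uuid`, `source_id`, `source_index`, `chunk_index`) and `vectors`
#'   (n x sequence_length integer matrix, rownames = uuid).
#' @export
make_slice_records <- function(records, cfg = slicing_config()) {
  stopifnot(length(records) >= 1L)
  if (is.null(names(records))) names(records) <- paste0("seq", seq_along(records))
  per <- lapply(seq_along(records), function(i) {
    M <- slice_sequence(numericize(records[[i]]), cfg)
    list(M = M, src = i)
  })
  vectors <- do.call(rbind, lapply(per, `[[`, "M"))
  n_per <- vapply(per, function(p) nrow(p$M), 0L)
  meta <- data.frame(
    uuid = apply(vectors, 1L, slice_uuid),
    source_id = rep(names(records), n_per),
    source_index = rep(seq_along(records), n_per),
    chunk_index = unlist(lapply(n_per, seq_len)),
    stringsAsFactors = FALSE)
  rownames(vectors) <- meta$uuid
  structure(list(meta = meta, vectors = vectors, config = cfg),
            class = "slice_set")
}

slice_uuid <- function(v) digest::digest(as.integer(v), algo = "xxhash64")

#' @export
print.slice_set <- function(x, ...) {
  cat(sprintf("Slice set: %d fragments of length %d from %d record(s)\n",
              nrow(x$vectors), ncol(x$vectors), length(unique(x$meta$source_index))))
  invisible(x)
}

#' Deduplicate slices by content UUID
#'
#' Keeps the first occurrence of each UUID, preserving order. Idempotent.
#' Mirrors the data server's skip rule: the federated index only ever holds
#' one copy of a fragment, however many clients submit it.
#'
#' @param slices A `slice_set`.
#' @return A `slice_set` with unique UUIDs.
#' @export
dedup_slices <- function(slices) {
  stopifnot(inherits(slices, "slice_set"))
  keep <- !duplicated(slices$meta$uuid)
  structure(list(meta = slices$meta[keep, , drop = FALSE],
                 vectors = slices$vectors[keep, , drop = FALSE],
                 config = slices$config),
            class = "slice_set")
}

#' Slice-table serialization (TSV)
#'
#' Writes a `slice_set` as a TSV with columns `uuid`, `source_id`,
#' `source_index`, `chunk_index`, then one integer column per position;
#' `read_slice_table()` inverts it exactly.
#'
#' @param slices A `slice_set`.
#' @param path TSV path.
#' @return `read_slice_table()` returns the `slice_set`;
#'   `write_slice_table()` invisibly returns `path`.
#' @export
write_slice_table <- function(slices, path) {
  stopifnot(inherits(slices, "slice_set"))
  V <- as.data.frame(slices$vectors, row.names = FALSE)
  names(V) <- paste0("v", seq_len(ncol(V)))
  data.table::fwrite(cbind(slices$meta, V), path, sep = "\t")
  invisible(path)
}

#' @rdname write_slice_table
#' @param overlap The overlap recorded in the restored `slicing_config`
#'   (the TSV stores window content, not the stride). Default 100.
#' @export
read_slice_table <- function(path, overlap = 100L) {
  dt <- data.table::fread(path, sep = "\t")
  need <- c("uuid", "source_id", "source_index", "chunk_index")
  if (!all(need %in% names(dt)))
    stop_invalid("parse", "slice table missing metadata columns")
  vcols <- setdiff(names(dt), need)
  if (length(vcols) == 0L)
    stop_invalid("parse", "slice table has no vector columns")
  vectors <- as.matrix(dt[, vcols, with = FALSE])
  if (!is.numeric(vectors))
    stop_invalid("parse", "non-numeric vector columns in slice table")
  meta <- as.data.frame(dt[, need, with = FALSE])
  rownames(vectors) <- meta$uuid
  colnames(vectors) <- NULL
  storage.mode(vectors) <- "integer"
  cfg <- slicing_config(ncol(vectors), min(overlap, ncol(vectors) - 1L))
  structure(list(meta = meta, vectors = vectors, config = cfg),
            class = "slice_set")
}
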