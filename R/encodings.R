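# Sequence encoders.
#
# Two schemes behind one interface:
#  * embed-OneHot: a frozen 5 x 4 lookup table (A,C,G,T -> basis vectors,
#    N -> zero row) indexed by integer-encoded sequences. The table is a
#    constant, never a trainable parameter, so the expanded one-hot matrix
#    never needs to be stored on disk.
#  * DNA2Vec mode: overlapping k-mers (default k = 6, stride 1) looked up in
#    a table of pretrained vectors (default width 100, word2vec text format),
#    with a deterministic random-frozen fallback when no file is available.

ALPHABET <- c("A", "C", "G", "T", "N")

# byte -> index lookup (1..5 internally; exported API is 0-based)
.char_lut <- local({
  lut <- integer(256)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("a")] <- 1L
  lut[utf8ToInt("C")] <- 2L; lut[utf8ToInt("c")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("g")] <- 3L
  lut[utf8ToInt("T")] <- 4L; lut[utf8ToInt("t")] <- 4L
  lut[utf8ToInt("N")] <- 5L; lut[utf8ToInt("n")] <- 5L
  lut
})

#' Integer-encode a DNA sequence
#'
#' Maps `A -> 0, C -> 1, G -> 2, T -> 3, N -> 4` after folding lower case to
#' upper case. Any other character is an error reporting the (1-based)
#' offending position.
#'
#' @param seq a character scalar over `{A,C,G,T,N}` (any case).
#' @return an integer vector of the same length as the sequence.
#' @examples
#' seq_to_indices("ACGTN") # 0 1 2 3 4
#' @export
seq_to_indices <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) return(integer())
  code <- utf8ToInt(seq)
  idx <- .char_lut[code]
  if (any(idx == 0L)) {
    pos <- which(idx == 0L)[1L]
    stop("invalid character '", substr(seq, pos, pos), "' at position ", pos)
  }
  idx - 1L
}

#' The frozen nucleotide one-hot lookup table
#'
#' Rows (in order A, C, G, T, N) are the four standard basis vectors plus an
#' all-zero row for N, so an undetermined base contributes nothing to
#' downstream convolution sums. The table is a constant: it is stored on the
#' model but excluded from every optimiser update.
#'
#' @return a 5 x 4 numeric matrix with rownames `A,C,G,T,N`.
#' @export
nucleotide_lookup <- function() {
  m <- rbind(diag(4), rep(0, 4))
  dimnames(m) <- list(ALPHABET, c("A", "C", "G", "T"))
  m
}

#' Expand integer indices through the one-hot lookup
#'
#' Row `i` of the result is the lookup row of `indices[i]`; for N-free input
#' this is bit-identical to constructing the one-hot matrix directly from the
#' string.
#'
#' @param indices integer vector as produced by [seq_to_indices()] (0-based,
#'   values in `0..4`).
#' @param lookup the lookup table, by default [nucleotide_lookup()].
#' @return a `length(indices)` x 4 numeric matrix.
#' @export
embed_onehot <- function(indices, lookup = nucleotide_lookup()) {
  indices <- as.integer(indices)
  if (length(indices) && (min(indices) < 0L || max(indices) > 4L))
    stop("indices must be in 0..4")
  lookup[indices + 1L, , drop = FALSE]
}

#' Tokenize a sequence into overlapping k-mers
#'
#' Stride-1 windows; a sequence of length L yields `L - k + 1` tokens. Any
#' token containing N is replaced by the unknown token `"<UNK>"`, which maps
#' to the zero vector in a k-mer table.
#'
#' @param seq character scalar over `{A,C,G,T,N}` (any case).
#' @param k k-mer length.
#' @return a character vector of tokens.
#' @export
kmer_tokenize <- function(seq, k = 6L) {
  k <- as.integer(k)
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L < k) stop("sequence length ", L, " shorter than k = ", k)
  seq_to_indices(seq) # validates the alphabet
  starts <- seq_len(L - k + 1L)
  toks <- substring(seq, starts, starts + k - 1L)
  toks[grepl("N", toks, fixed = TRUE)] <- "<UNK>"
  toks
}

new_kmer_table <- function(vectors, k, source) {
  structure(list(vectors = vectors, k = as.integer(k),
                 dim = ncol(vectors), source = source),
            class = "epi_kmer_table")
}

#' Load pretrained k-mer vectors (word2vec text format)
#'
#' Expects a header line `"<n_tokens> <dim>"` followed by one line per token:
#' the token then `dim` floats. Unknown tokens later map to the zero vector.
#'
#' @param path vector file.
#' @param expected_dim required vector width (default 100); a file with a
#'   different width is rejected.
#' @return an object of class `epi_kmer_table`.
#' @export
load_kmer_vectors <- function(path, expected_dim = 100L) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("empty k-mer vector file: ", path)
  hdr <- scan(text = lines[1L], quiet = TRUE)
  if (length(hdr) != 2L) stop("malformed word2vec header: '", lines[1L], "'")
  n <- as.integer(hdr[1L]); d <- as.integer(hdr[2L])
  if (d != expected_dim)
    stop("vector width ", d, " does not match expected_dim ", expected_dim)
  body <- lines[-1L][nzchar(lines[-1L])]
  if (length(body) != n)
    stop("header declares ", n, " tokens but file has ", length(body))
  toks <- character(n)
  mat <- matrix(NA_real_, n, d)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(body[i]), "\\s+")[[1L]]
    if (length(parts) != d + 1L)
      stop("line ", i + 1L, ": expected token + ", d, " floats, got ",
           length(parts) - 1L)
    toks[i] <- parts[1L]
    mat[i, ] <- as.numeric(parts[-1L])
  }
  if (anyNA(mat)) stop("non-numeric vector entries in ", path)
  rownames(mat) <- toks
  new_kmer_table(mat, k = nchar(toks[1L]), source = "file")
}

#' Deterministic random-frozen k-mer table
#'
#' Fallback when no pretrained vector file is available: every k-mer over
#' `{A,C,G,T}` gets a fixed random vector (standard normal scaled by
#' `1/sqrt(dim)`) drawn once from `seed`. Frozen, like every encoder table.
#'
#' @param k k-mer length (table has `4^k` rows; keep k small).
#' @param dim vector width.
#' @param seed integer seed.
#' @return an object of class `epi_kmer_table`.
#' @export
random_kmer_table <- function(k = 6L, dim = 100L, seed = 1L) {
  k <- as.integer(k)
  if (k > 8L) stop("random-frozen table supports k <= 8 (4^k rows)")
  toks <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k),
                                      stringsAsFactors = FALSE)[, k:1, drop = FALSE])
  set.seed(seed)
  mat <- matrix(rnorm(length(toks) * dim) / sqrt(dim), nrow = length(toks))
  rownames(mat) <- toks
  new_kmer_table(mat, k = k, source = "random-frozen")
}

#' Encode a sequence with a k-mer table
#'
#' @param seq character scalar.
#' @param table an `epi_kmer_table`.
#' @return a `(L - k + 1)` x `dim` matrix; unknown tokens (including any
#'   containing N) are zero rows.
#' @export
encode_kmers <- function(seq, table) {
  stopifnot(inherits(table, "epi_kmer_table"))
  toks <- kmer_tokenize(seq, table$k)
  idx <- match(toks, rownames(table$vectors))
  out <- matrix(0, length(toks), table$dim)
  hit <- !is.na(idx)
  out[hit, ] <- table$vectors[idx[hit], , drop = FALSE]
  out
}

# Batch integer encoding: records column -> B x L integer matrix (1..5).
encode_index_matrix <- function(seqs, L) {
  B <- length(seqs)
  out <- matrix(0L, B, L)
  for (b in seq_len(B)) {
    v <- seq_to_indices(seqs[b]) + 1L
    if (length(v) != L)
      stop("sequence ", b, " has length ", length(v), ", expected ", L)
    out[b, ] <- v
  }
  out
}
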