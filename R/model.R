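# The EPI classifier: per-branch conv + maxpool feature extraction, a
# positional-axis merge (enhancer rows first), one transformer block
# (multi-head self-attention + feed-forward, post-layer-norm residuals),
# hierarchical attention pooling and a sigmoid output neuron.

#' Build an untrained EPI classifier
#'
#' Initialises all trainable weights (Glorot-uniform) for the configured
#' architecture. The one-hot lookup table is attached as a frozen constant:
#' it is consulted during every forward pass but excluded from every
#' optimiser update. In `"dna2vec"` mode a frozen k-mer vector table is
#' attached instead (loaded from file via [load_kmer_vectors()] or a
#' deterministic [random_kmer_table()] fallback).
#'
#' @param cfg an [model_config()] object.
#' @param seed integer seed for weight initialisation.
#' @param kmer_table optional `epi_kmer_table` for `"dna2vec"` mode.
#' @return an object of class `epi_model`.
#' @export
build_model <- function(cfg, seed = 1L, kmer_table = NULL) {
  stopifnot(inherits(cfg, "epi_model_config"))
  set.seed(seed)
  in_dim <- if (cfg$encoding == "dna2vec") cfg$embed_dim else 4L
  if (cfg$encoding == "dna2vec" && is.null(kmer_table))
    kmer_table <- random_kmer_table(cfg$kmer_k, cfg$embed_dim, seed)
  if (!is.null(kmer_table) && kmer_table$dim != cfg$embed_dim)
    stop("kmer table width ", kmer_table$dim, " != embed_dim ", cfg$embed_dim)
  structure(list(cfg = cfg,
                 params = init_model_params(cfg, in_dim),
                 lookup = nucleotide_lookup(),
                 kmer_table = kmer_table,
                 trained = FALSE, history = NULL),
            class = "epi_model")
}

#' @export
print.epi_model <- function(x, ...) {
  cat("EPI classifier (", if (x$trained) "trained" else "untrained", ")\n", sep = "")
  print(x$cfg)
  invisible(x)
}

# Build the branch input structure for a batch of sequences.
branch_input <- function(seqs, model, which = c("enhancer", "promoter")) {
  which <- match.arg(which)
  cfg <- model$cfg
  raw_len <- if (which == "enhancer") cfg$enh_len else cfg$prom_len
  Lin <- if (which == "enhancer") cfg$in_len_e else cfg$in_len_p
  B <- length(seqs)
  if (cfg$encoding == "onehot") {
    idx <- encode_index_matrix(toupper(seqs), raw_len)
    list(kind = "index", iv = as.vector(t(idx)), B = B, Lin = Lin)
  } else {
    X <- matrix(0, B * Lin, cfg$embed_dim)
    for (b in seq_len(B)) {
      enc <- encode_kmers(seqs[b], model$kmer_table)
      if (nrow(enc) != Lin)
        stop("sequence ", b, ": ", nrow(enc), " k-mers, expected ", Lin)
      X[(b - 1L) * Lin + seq_len(Lin), ] <- enc
    }
    list(kind = "dense", X = X, B = B, Lin = Lin)
  }
}

forward_records <- function(model, records, train = FALSE, keep_attn = FALSE) {
  records <- validate_pairs(records)
  in_e <- branch_input(records$enhancer, model, "enhancer")
  in_p <- branch_input(records$promoter, model, "promoter")
  nn_forward(model$params, model$cfg, in_e, in_p, model$lookup,
             train = train, keep_attn = keep_attn)
}

#' Predict interaction probabilities
#'
#' Runs the model in inference mode (dropout disabled); output is one
#' probability in `[0, 1]` per record, deterministic for fixed weights.
#'
#' @param object a trained (or untrained) `epi_model`.
#' @param records an [epi_pairs()] data.frame.
#' @param batch_size batch size for memory-bounded evaluation; defaults to
#'   the configured training batch size.
#' @param ... unused.
#' @return a numeric vector of probabilities, one per record.
#' @export
predict.epi_model <- function(object, records, batch_size = NULL, ...) {
  records <- validate_pairs(records)
  if (nrow(records) == 0L) return(numeric())
  bs <- if (is.null(batch_size)) object$cfg$batch_size else as.integer(batch_size)
  out <- numeric(nrow(records))
  starts <- seq.int(1L, nrow(records), by = bs)
  for (s in starts) {
    e <- min(s + bs - 1L, nrow(records))
    out[s:e] <- forward_records(object, records[s:e, , drop = FALSE])$probs
  }
  out
}

#' Apply the transformer block to a merged feature matrix
#'
#' Functional view of the core block: given a merged representation `M`
#' (`L_merged` rows, `conv_filters` columns, enhancer rows first), computes
#' `H = LayerNorm(FFN(A) + A)` with `A = LayerNorm(MHA(M) + M)`, and returns
#' the per-head attention maps (query = row, key = column; each row is a
#' probability vector).
#'
#' @param M a `L_merged x conv_filters` matrix.
#' @param model an `epi_model` whose parameters are used.
#' @return a list with `H` (same shape as `M`) and `attention`
#'   (`n_heads x L_merged x L_merged` array).
#' @export
transformer_block <- function(M, model) {
  cfg <- model$cfg
  stopifnot(is.matrix(M), ncol(M) == cfg$conv_filters)
  Lm <- nrow(M)
  p <- model$params
  mh <- mha_forward(M, p, 1L, Lm, cfg$n_heads, cfg$head_dim, keep_attn = TRUE)
  ln1 <- layernorm_forward(M + mh$O, p$ln1_g, p$ln1_b)
  Z1 <- pmax(add_rowvec(ln1$y %*% p$f1_W, p$f1_b), 0)
  Z2 <- add_rowvec(Z1 %*% p$f2_W, p$f2_b)
  ln2 <- layernorm_forward(ln1$y + Z2, p$ln2_g, p$ln2_b)
  list(H = ln2$y, attention = as_head_array(mh$A, 1L, cfg$n_heads, Lm))
}

#' Hierarchical attention pooling
#'
#' Computes, per position `i` of `H`, the score
#' `tanh(Wh h_i + bh) . uc`, softmax-normalises the scores into weights
#' `alpha_i` and returns the weighted sum `S = sum_i alpha_i h_i`.
#'
#' @param H a `L x conv_filters` matrix (e.g. a transformer output).
#' @param model an `epi_model` supplying `Wh`, `bh` and `uc`.
#' @return a list with `S` (length-`conv_filters` vector) and `weights`
#'   (length-`L`, non-negative, summing to 1).
#' @export
hier_attention <- function(H, model) {
  stopifnot(is.matrix(H), ncol(H) == model$cfg$conv_filters)
  hi <- hier_forward(H, model$params, 1L, nrow(H))
  list(S = as.vector(hi$S), weights = hi$w)
}

#' Save / load a model checkpoint
#'
#' @param model an `epi_model`.
#' @param path checkpoint file path.
#' @return `save_model` the path invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "epi_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "epi_model")) stop("not an epi_model checkpoint: ", path)
  m
}
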