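# Shared fixtures and independent oracles.

# Small architecture used across unit tests (fast, non-trivial geometry).
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(enh_len = 60L, prom_len = 45L, conv_filters = 8L,
         conv_kernel = 5L, pool_size = 3L, pool_stride = 3L,
         n_heads = 2L, ffn_dense1 = 10L, attn_hidden = 6L,
         dropout = 0.2, batch_size = 8L),
    list(...))
  do.call(model_config, args)
}

tiny_motifs <- function(rate = 0) {
  list(enh = planted_motif("enh8", "TGACGTCA", rate),
       prom = planted_motif("prom8", "CACGTGAC", rate))
}

tiny_dataset <- function(n_pos = 8L, neg_per_pos = 2L, seed = 1L, rate = 0,
                         negative_mode = "clean", enh_len = 60L, prom_len = 45L) {
  mo <- tiny_motifs(rate)
  generate_dataset(n_pos, neg_per_pos, enh_len = enh_len, prom_len = prom_len,
                   enh_motif = mo$enh, prom_motif = mo$prom, seed = seed,
                   negative_mode = negative_mode)
}

# Brute-force pooled length: enumerate conv windows, then pool windows.
bf_pooled_length <- function(L, kernel, pool, stride) {
  conv_positions <- seq_len(L - kernel + 1L)    # stride-1 valid conv
  n <- 0L
  start <- 1L
  while (start + pool - 1L <= length(conv_positions)) {
    n <- n + 1L
    start <- start + stride
  }
  n
}

# Brute-force receptive field of pooled position r (0-based): union of the
# base windows of every conv position inside the pool window.
bf_receptive_field <- function(r, L, kernel, pool, stride) {
  Lc <- L - kernel + 1L
  cpos <- (r * stride):min(r * stride + pool - 1L, Lc - 1L)
  c(start = min(cpos), end = max(cpos) + kernel)
}

# Direct one-hot construction, character by character (independent of the
# lookup-table path).
bf_onehot <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1L]]
  rows <- list(A = c(1, 0, 0, 0), C = c(0, 1, 0, 0), G = c(0, 0, 1, 0),
               T = c(0, 0, 0, 1), N = c(0, 0, 0, 0))
  do.call(rbind, lapply(chars, function(ch) rows[[ch]]))
}

# Elementwise re-evaluation of the hierarchical attention equation.
bf_hier_attention <- function(H, Wh, bh, uc) {
  L <- nrow(H)
  scores <- numeric(L)
  for (i in seq_len(L))
    scores[i] <- sum(tanh(as.vector(Wh %*% H[i, ]) + bh) * uc)
  w <- exp(scores - max(scores))
  w <- w / sum(w)
  S <- colSums(H * w)
  list(S = S, weights = w)
}

# A planted window [pos, pos + width) overlaps a region window [start, end)?
windows_overlap <- function(start, end, pos, width) {
  start < pos + width && pos < end
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
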