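#' Length of a feature map after valid convolution and max pooling
#'
#' One branch of the network applies a 1-D convolution (valid padding,
#' stride 1) followed by max pooling. For an input of length `L`, the
#' convolution yields `L - kernel + 1` positions and pooling keeps
#' `floor((L - kernel + 1 - pool) / stride) + 1` windows. Under the default
#' geometry (kernel 40, pool 20/20) a 3000-bp enhancer maps to 148 pooled
#' positions and a 2000-bp promoter to 98, so the merged representation has
#' 246 positions.
#'
#' @param L integer, input sequence length.
#' @param kernel integer, convolution kernel width.
#' @param pool integer, max-pooling window size.
#' @param stride integer, max-pooling stride.
#' @return integer, number of pooled positions.
#' @examples
#' pooled_length(3000, 40, 20, 20) # 148
#' pooled_length(2000, 40, 20, 20) # 98
#' @export
pooled_length <- function(L, kernel, pool, stride) {
  L <- as.integer(L); kernel <- as.integer(kernel)
  pool <- as.integer(pool); stride <- as.integer(stride)
  if (length(L) != 1L || is.na(L) || L < kernel)
    stop("input length L (", L, ") must be >= kernel (", kernel, ")")
  if (pool < 1L || stride < 1L) stop("pool and stride must be >= 1")
  Lc <- L - kernel + 1L
  if (Lc < pool) stop("convolved length ", Lc, " shorter than pool window ", pool)
  as.integer((Lc - pool) %/% stride + 1L)
}

#' Model configuration
#'
#' Collects every architecture and optimisation hyperparameter of the
#' EPI classifier together with the derived feature-map geometry. The
#' defaults are the published operating point of the model: 128 convolution
#' filters of width 40, 20/20 max pooling, 16 attention heads, transformer
#' feed-forward widths 255 and 128, a 246-dimensional hierarchical-attention
#' hidden layer, dropout 0.5 and batch size 64, on 3000-bp enhancers and
#' 2000-bp promoters. All fields can be overridden, e.g. for scaled-down
#' experiments.
#'
#' @param enh_len,prom_len input sequence lengths in bp.
#' @param conv_filters number of convolution filters per branch.
#' @param conv_kernel convolution kernel width (bp).
#' @param pool_size,pool_stride max-pooling window and stride.
#' @param dropout dropout probability applied after the merge layer and after
#'   the attention and feed-forward sublayers.
#' @param n_heads number of attention heads; must divide `conv_filters`.
#' @param ffn_dense1 width of the first transformer feed-forward layer.
#' @param ffn_dense2 width of the second feed-forward layer; must equal
#'   `conv_filters` so the residual connection type-checks.
#' @param attn_hidden hidden width of the hierarchical attention layer;
#'   `NULL` means "use the merged length" (246 under defaults).
#' @param batch_size minibatch size for training and batched inference.
#' @param encoding `"onehot"` (frozen-lookup one-hot) or `"dna2vec"`
#'   (k-mer vectors, see [load_kmer_vectors()]).
#' @param kmer_k k-mer length for `"dna2vec"` encoding.
#' @param embed_dim k-mer vector width for `"dna2vec"` encoding.
#' @param learning_rate Adam learning rate.
#' @return an object of class `epi_model_config` (a list) with derived fields
#'   `L_enh`, `L_prom`, `L_merged` and `head_dim`.
#' @examples
#' cfg <- model_config()
#' cfg$L_enh   # 148
#' cfg$L_merged # 246
#' @export
model_config <- function(enh_len = 3000L, prom_len = 2000L,
                         conv_filters = 128L, conv_kernel = 40L,
                         pool_size = 20L, pool_stride = 20L,
                         dropout = 0.5, n_heads = 16L,
                         ffn_dense1 = 255L, ffn_dense2 = conv_filters,
                         attn_hidden = NULL, batch_size = 64L,
                         encoding = c("onehot", "dna2vec"),
                         kmer_k = 6L, embed_dim = 100L,
                         learning_rate = 1e-3) {
  encoding <- match.arg(encoding)
  cfg <- list(
    enh_len = as.integer(enh_len), prom_len = as.integer(prom_len),
    conv_filters = as.integer(conv_filters), conv_kernel = as.integer(conv_kernel),
    pool_size = as.integer(pool_size), pool_stride = as.integer(pool_stride),
    dropout = dropout, n_heads = as.integer(n_heads),
    ffn_dense1 = as.integer(ffn_dense1), ffn_dense2 = as.integer(ffn_dense2),
    batch_size = as.integer(batch_size), encoding = encoding,
    kmer_k = as.integer(kmer_k), embed_dim = as.integer(embed_dim),
    learning_rate = learning_rate, output_units = 1L
  )
  # dna2vec mode shortens the conv input to the k-mer count (L - k + 1)
  cfg$in_len_e <- if (encoding == "dna2vec") cfg$enh_len - cfg$kmer_k + 1L else cfg$enh_len
  cfg$in_len_p <- if (encoding == "dna2vec") cfg$prom_len - cfg$kmer_k + 1L else cfg$prom_len
  cfg$L_enh <- pooled_length(cfg$in_len_e, cfg$conv_kernel, cfg$pool_size, cfg$pool_stride)
  cfg$L_prom <- pooled_length(cfg$in_len_p, cfg$conv_kernel, cfg$pool_size, cfg$pool_stride)
  cfg$L_merged <- cfg$L_enh + cfg$L_prom
  cfg$attn_hidden <- if (is.null(attn_hidden)) cfg$L_merged else as.integer(attn_hidden)
  if (cfg$dropout < 0 || cfg$dropout >= 1) stop("dropout must be in [0, 1)")
  if (cfg$conv_filters %% cfg$n_heads != 0L)
    stop("conv_filters (", cfg$conv_filters, ") must be divisible by n_heads (",
         cfg$n_heads, ")")
  if (cfg$ffn_dense2 != cfg$conv_filters)
    stop("ffn_dense2 (", cfg$ffn_dense2, ") must equal conv_filters (",
         cfg$conv_filters, ") for the residual connection")
  cfg$head_dim <- cfg$conv_filters %/% cfg$n_heads
  class(cfg) <- "epi_model_config"
  cfg
}

#' @export
print.epi_model_config <- function(x, ...) {
  cat("EPI model configuration\n")
  cat(sprintf("  branches: enhancer %d bp -> %d pooled, promoter %d bp -> %d pooled\n",
              x$enh_len, x$L_enh, x$prom_len, x$L_prom))
  cat(sprintf("  conv: %d filters x %d bp, pool %d/%d; merged length %d\n",
              x$conv_filters, x$conv_kernel, x$pool_size, x$pool_stride, x$L_merged))
  cat(sprintf("  transformer: %d heads (dim %d), ffn %d -> %d; attn hidden %d\n",
              x$n_heads, x$head_dim, x$ffn_dense1, x$ffn_dense2, x$attn_hidden))
  cat(sprintf("  dropout %.2f, batch %d, encoding %s, lr %g\n",
              x$dropout, x$batch_size, x$encoding, x$learning_rate))
  invisible(x)
}
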