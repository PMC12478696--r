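# Attention interpretability pipeline.
#
# The transformer block sees a merged sequence of L_enh + L_prom pooled
# positions (enhancer first). Each position is a "region" with a receptive
# field on the raw sequence: pool window r covers conv positions
# [r*stride, r*stride + pool) (clipped to the valid conv range), each conv
# window spans `kernel` bases, so under the default geometry every region
# maps to a 59-bp window, [20r, 20r + 59). The pipeline captures per-head
# attention on positive samples, averages heads, ranks enhancer x promoter
# region pairs by cross-attention, and summarises each region's sequence
# content as a PWM built from the maximally-activating conv windows.
# Interpretation assumes the one-hot encoding (positions map 1:1 to bases).

role_prefix <- c(enhancer = "enh", promoter = "prom")

#' Map a merged region index to its raw-sequence window
#'
#' @param r merged region index, 0-based, in `[0, L_merged)`; indices below
#'   `L_enh` are enhancer regions, the rest promoter regions.
#' @param cfg a [model_config()].
#' @return a list with `region` (merged index), `role`, `role_index`
#'   (0-based index within the branch), `start`, `end` (0-based half-open
#'   window on the raw sequence) and `name` (e.g. `"enh_r12"`).
#' @examples
#' region_window(0, model_config())   # enhancer [0, 59)
#' region_window(245, model_config()) # promoter [1940, 1999)
#' @export
region_window <- function(r, cfg) {
  stopifnot(inherits(cfg, "epi_model_config"))
  r <- as.integer(r)
  if (is.na(r) || r < 0L || r >= cfg$L_merged)
    stop("region index ", r, " out of range [0, ", cfg$L_merged, ")")
  if (r < cfg$L_enh) {
    role <- "enhancer"; ri <- r; Lin <- cfg$in_len_e
  } else {
    role <- "promoter"; ri <- r - cfg$L_enh; Lin <- cfg$in_len_p
  }
  Lc <- Lin - cfg$conv_kernel + 1L
  cstart <- ri * cfg$pool_stride
  cend <- min(cstart + cfg$pool_size - 1L, Lc - 1L)
  list(region = r, role = role, role_index = ri,
       start = cstart, end = cend + cfg$conv_kernel,
       name = sprintf("%s_r%d", role_prefix[[role]], ri))
}

#' Capture per-head attention maps on positive samples
#'
#' Runs the model in inference mode and records, for every record, the
#' `n_heads` row-normalised `L_merged x L_merged` attention matrices
#' (query = row, key = column) of the transformer block.
#'
#' @param model a trained `epi_model`.
#' @param records positive records (`label == 1`); negatives are an error.
#' @return a named list (by record id) of `n_heads x L_merged x L_merged`
#'   arrays.
#' @export
capture_attention <- function(model, records) {
  records <- validate_pairs(records)
  if (nrow(records) == 0L) stop("no positive records supplied")
  if (any(records$label != 1L))
    stop("attention is captured on positive samples only; negative record id: ",
         records$id[which(records$label != 1L)[1L]])
  out <- vector("list", nrow(records))
  bs <- model$cfg$batch_size
  starts <- seq.int(1L, nrow(records), by = bs)
  for (s in starts) {
    e <- min(s + bs - 1L, nrow(records))
    fw <- forward_records(model, records[s:e, , drop = FALSE], keep_attn = TRUE)
    out[s:e] <- fw$attn
  }
  names(out) <- records$id
  out
}

#' Average attention maps over heads and samples
#'
#' Elementwise mean, preserving the query -> key direction (no
#' symmetrisation). Rows of the result still sum to 1 (a convex combination
#' of probability rows).
#'
#' @param maps a list of `n_heads x L x L` arrays (as from
#'   [capture_attention()]), or a single such array.
#' @return an `L x L` matrix.
#' @export
average_heads <- function(maps) {
  if (is.array(maps) && length(dim(maps)) == 3L) maps <- list(maps)
  if (!length(maps)) stop("no attention maps supplied")
  d <- dim(maps[[1L]])
  acc <- matrix(0, d[2L], d[3L])
  for (a in maps) {
    stopifnot(identical(dim(a), d))
    acc <- acc + matrix(colMeans(matrix(a, d[1L])), d[2L], d[3L])
  }
  acc / length(maps)
}

#' Rank enhancer x promoter region pairs by cross-attention
#'
#' Candidates are restricted to the two cross blocks of the averaged map
#' (enhancer rows x promoter columns, and the transposed promoter-query
#' block); each candidate's score is the mean of its two directional
#' entries, since attention is not symmetric. Ranking is by descending
#' score, ties broken by ascending (enhancer index, promoter index). The
#' published analysis reads off the top 5 to 8 pairs; pass `k_max = Inf`
#' (and a large `k`) for an exhaustive ranked scan of all
#' `L_enh * L_prom` candidates.
#'
#' @param avg an `L_merged x L_merged` averaged attention matrix.
#' @param cfg the [model_config()] that defines the block geometry.
#' @param k number of pairs to return.
#' @param k_min,k_max admissible bounds on `k` (defaults 5 and 8).
#' @return a data.frame with 0-based `enh_region`, `prom_region` (indices
#'   within their branch), `merged_enh`, `merged_prom` and `score`.
#' @export
top_region_pairs <- function(avg, cfg, k = 8L, k_min = 5L, k_max = 8L) {
  stopifnot(inherits(cfg, "epi_model_config"), is.matrix(avg))
  if (!all(dim(avg) == cfg$L_merged))
    stop("attention matrix must be ", cfg$L_merged, " x ", cfg$L_merged)
  k <- as.integer(k)
  if (k < k_min || k > k_max)
    stop("k = ", k, " outside the configured bounds [", k_min, ", ", k_max, "]")
  Le <- cfg$L_enh; Lp <- cfg$L_prom
  if (k > Le * Lp) stop("k = ", k, " exceeds the ", Le * Lp, " candidate pairs")
  e2p <- avg[seq_len(Le), Le + seq_len(Lp), drop = FALSE]
  p2e <- t(avg[Le + seq_len(Lp), seq_len(Le), drop = FALSE])
  score <- (e2p + p2e) / 2
  ei <- as.vector(row(score)) - 1L
  pi <- as.vector(col(score)) - 1L
  sc <- as.vector(score)
  ord <- order(-sc, ei, pi)[seq_len(k)]
  data.frame(enh_region = ei[ord], prom_region = pi[ord],
             merged_enh = ei[ord], merged_prom = Le + pi[ord],
             score = sc[ord])
}

# Per-sample conv activations of one branch (inference mode).
branch_activations <- function(model, seqs, which) {
  inp <- branch_input(seqs, model, which)
  W <- if (which == "enhancer") model$params$conv_e_W else model$params$conv_p_W
  b <- if (which == "enhancer") model$params$conv_e_b else model$params$conv_p_b
  cv <- conv_forward(inp, W, b, model$lookup)
  list(act = cv$act, Lc = cv$Lc, B = inp$B)
}

#' Build a region PWM from maximally-activating conv windows
#'
#' For every record, within the pool window of region `r`, finds the conv
#' position whose strongest filter activation (per-position max over
#' filters) is largest, extracts the `kernel`-wide sequence window at that
#' position, and accumulates per-offset base counts. Frequencies use
#' pseudocounts: `(count + pc) / (n + 4 pc)`.
#'
#' @param model a trained `epi_model` with one-hot encoding.
#' @param records positive records to aggregate over.
#' @param r merged region index (0-based).
#' @param pseudocount per-base pseudocount (default 0.25).
#' @return an object of class `epi_region_pwm`: list with `region`, `role`,
#'   `name`, `counts` (4 x kernel integer), `freq` (4 x kernel, columns sum
#'   to 1), `n_sequences` and `width`.
#' @export
extract_region_pwm <- function(model, records, r, pseudocount = 0.25) {
  stopifnot(inherits(model, "epi_model"))
  if (model$cfg$encoding != "onehot")
    stop("PWM extraction maps conv positions to bases and requires one-hot encoding")
  records <- validate_pairs(records)
  if (nrow(records) == 0L) stop("no records supplied")
  cfg <- model$cfg
  rw <- region_window(r, cfg)
  seqs <- if (rw$role == "enhancer") records$enhancer else records$promoter
  K <- cfg$conv_kernel
  ba <- branch_activations(model, seqs, rw$role)
  cpos <- seq.int(rw$start, rw$end - K)          # 0-based conv positions in window
  counts <- matrix(0L, 4L, K, dimnames = list(BASES, NULL))
  for (b in seq_len(ba$B)) {
    rows <- (b - 1L) * ba$Lc + cpos + 1L
    act <- ba$act[rows, , drop = FALSE]
    peak <- apply(act, 1L, max)
    jstar <- cpos[which.max(peak)]               # first max wins ties
    win <- substr(seqs[b], jstar + 1L, jstar + K)
    ci <- match(strsplit(win, "")[[1L]], BASES)  # N (no match) is skipped
    ok <- !is.na(ci)
    counts[cbind(ci[ok], which(ok))] <- counts[cbind(ci[ok], which(ok))] + 1L
  }
  freq <- (counts + pseudocount) / (ba$B + 4 * pseudocount)
  structure(list(region = rw$region, role = rw$role, name = rw$name,
                 counts = counts, freq = freq,
                 n_sequences = ba$B, width = K),
            class = "epi_region_pwm")
}

#' @export
print.epi_region_pwm <- function(x, ...) {
  cat(sprintf("Region PWM %s (merged index %d, %s): %d bp from %d sequences\n",
              x$name, x$region, x$role, x$width, x$n_sequences))
  consensus <- paste(BASES[apply(x$freq, 2L, which.max)], collapse = "")
  cat("  consensus of frequencies:", consensus, "\n")
  invisible(x)
}

#' Best-alignment column-wise correlation between two PWMs
#'
#' Slides one matrix along the other and returns the maximum over offsets
#' of the mean per-column Pearson correlation of the aligned base-frequency
#' columns. By default only full-containment alignments are considered;
#' `min_overlap` admits partial overlaps of at least that many columns —
#' useful because windows extracted through max pooling carry a phase
#' uncertainty of up to `pool_stride - 1` bases relative to the true motif
#' start. Columns with zero variance on either side are skipped; if every
#' column is skipped the alignment scores 0.
#'
#' @param a,b 4-row frequency matrices (rows A, C, G, T).
#' @param min_overlap minimum number of aligned columns; default
#'   `min(ncol(a), ncol(b))` (full containment of the narrower matrix).
#' @return a list with `correlation` and the best `offset` of `b` relative
#'   to `a` (0-based; negative = `b` starts before `a`).
#' @export
pwm_correlation <- function(a, b, min_overlap = NULL) {
  stopifnot(nrow(a) == 4L, nrow(b) == 4L)
  wa <- ncol(a); wb <- ncol(b)
  if (is.null(min_overlap)) min_overlap <- min(wa, wb)
  min_overlap <- as.integer(min_overlap)
  if (min_overlap < 1L || min_overlap > min(wa, wb))
    stop("min_overlap must be in [1, ", min(wa, wb), "]")
  best <- list(correlation = -Inf, offset = 0L)
  for (off in (min_overlap - wb):(wa - min_overlap)) {
    js <- which(seq_len(wb) + off >= 1L & seq_len(wb) + off <= wa)
    cors <- vapply(js, function(j) {
      x <- a[, off + j]; y <- b[, j]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else stats::cor(x, y)
    }, 0)
    m <- if (all(is.na(cors))) 0 else mean(cors, na.rm = TRUE)
    if (m > best$correlation) best <- list(correlation = m, offset = off)
  }
  best
}
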