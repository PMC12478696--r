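# Synthetic planted-motif dataset generator.
#
# Emulates the shape of the TargetFinder-style EPI benchmark: fixed-length
# enhancer/promoter pairs at a 1:20 positive:negative imbalance. Positive
# pairs carry one planted enhancer motif and one planted promoter motif at
# uniformly random admissible positions, so that both the classifier and the
# attention-based interpretability pipeline have a known ground truth.
# All coordinates are 0-based, half-open.

BASES <- c("A", "C", "G", "T")

#' Define a planted motif
#'
#' @param name short identifier used in ground-truth manifests.
#' @param consensus consensus sequence over `{A,C,G,T}`, length 6-40.
#' @param mutation_rate per-position probability that a planted instance
#'   deviates from the consensus (the substituted base is drawn uniformly
#'   from the other three).
#' @return an object of class `planted_motif`.
#' @examples
#' planted_motif("enh8", "TGACGTCA", mutation_rate = 0.05)
#' @export
planted_motif <- function(name, consensus, mutation_rate = 0) {
  consensus <- toupper(consensus)
  if (!nzchar(consensus)) stop("consensus must be non-empty")
  if (grepl("[^ACGT]", consensus)) stop("consensus must be over {A,C,G,T}")
  if (mutation_rate < 0 || mutation_rate > 1) stop("mutation_rate must be in [0, 1]")
  structure(list(name = as.character(name), consensus = consensus,
                 mutation_rate = mutation_rate),
            class = "planted_motif")
}

#' Theoretical PWM of a planted motif
#'
#' Per-column base probabilities implied by the consensus and mutation rate:
#' the consensus base has probability `1 - mutation_rate`, each of the other
#' three `mutation_rate / 3`.
#'
#' @param motif a [planted_motif()].
#' @return a 4 x width matrix with rownames `A,C,G,T`, columns summing to 1.
#' @export
motif_pwm <- function(motif) {
  stopifnot(inherits(motif, "planted_motif"))
  w <- nchar(motif$consensus)
  m <- matrix(motif$mutation_rate / 3, nrow = 4L, ncol = w,
              dimnames = list(BASES, NULL))
  cons <- strsplit(motif$consensus, "")[[1L]]
  m[cbind(match(cons, BASES), seq_len(w))] <- 1 - motif$mutation_rate
  m
}

#' Sample a background DNA sequence
#'
#' Bases are drawn i.i.d. with a configurable GC content (default 50%,
#' i.e. uniform over `{A,C,G,T}`).
#'
#' @param length non-negative sequence length.
#' @param seed optional integer seed; the same seed yields the same sequence.
#' @param gc GC content in `[0, 1]`.
#' @return a character scalar of exactly `length` bases.
#' @export
sample_background <- function(length, seed = NULL, gc = 0.5) {
  length <- as.integer(length)
  if (is.na(length) || length < 0L) stop("length must be a non-negative integer")
  if (!is.null(seed)) set.seed(seed)
  if (length == 0L) return("")
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, length, replace = TRUE, prob = prob), collapse = "")
}

#' Plant a motif instance into a sequence
#'
#' Replaces the window `[position, position + width)` (0-based, half-open)
#' with an instance of the motif: the consensus, with each position
#' independently mutated to one of the other three bases with probability
#' `mutation_rate`. The rest of the sequence is untouched.
#'
#' @param seq a character scalar.
#' @param motif a [planted_motif()].
#' @param position 0-based start offset.
#' @param seed optional integer seed for the mutation draws.
#' @return the modified sequence, same length as the input.
#' @examples
#' plant_motif("AAAA", planted_motif("m", "GG"), position = 1) # "AGGA"
#' @export
plant_motif <- function(seq, motif, position, seed = NULL) {
  stopifnot(inherits(motif, "planted_motif"))
  w <- nchar(motif$consensus)
  L <- nchar(seq)
  position <- as.integer(position)
  if (is.na(position) || position < 0L || position + w > L)
    stop("position ", position, " out of range for motif width ", w,
         " in sequence of length ", L)
  if (!is.null(seed)) set.seed(seed)
  inst <- strsplit(motif$consensus, "")[[1L]]
  if (motif$mutation_rate > 0) {
    mut <- runif(w) < motif$mutation_rate
    if (any(mut)) {
      inst[mut] <- vapply(inst[mut], function(b) sample(setdiff(BASES, b), 1L), "")
    }
  }
  paste0(substr(seq, 1L, position), paste(inst, collapse = ""),
         substr(seq, position + w + 1L, L))
}

contains_motif <- function(seq, motif) {
  grepl(motif$consensus, seq, fixed = TRUE)
}

#' Generate a planted-motif EPI dataset with ground truth
#'
#' Produces `n_pos` positive pairs, each carrying one instance of the
#' enhancer motif and one instance of the promoter motif at uniformly random
#' admissible positions, and `n_pos * neg_per_pos` negative pairs. Negative
#' composition is controlled by `negative_mode`:
#' \describe{
#'   \item{`"clean"`}{negatives are pure background (resampled until they do
#'     not contain both consensus strings).}
#'   \item{`"decoy"`}{a random half of the negatives carries exactly one of
#'     the two motifs (chosen at random), so single-motif presence cannot
#'     separate the classes and a classifier must learn the pairing.}
#' }
#' Records are shuffled deterministically by `seed`. The returned manifest
#' records every plant (motif name and 0-based offset) per record plus the
#' generator settings.
#'
#' @param n_pos number of positive pairs (>= 1).
#' @param neg_per_pos negatives per positive (the benchmark convention is 20).
#' @param enh_len,prom_len sequence lengths in bp (defaults 3000/2000).
#' @param enh_motif,prom_motif [planted_motif()] objects.
#' @param seed integer seed controlling the whole dataset.
#' @param negative_mode `"clean"` or `"decoy"`, see above.
#' @param gc background GC content.
#' @param cell_line cell-line tag stamped on every record.
#' @return a list with elements `records` (an [epi_pairs()] data.frame) and
#'   `manifest` (a list; see [write_manifest()]).
#' @export
generate_dataset <- function(n_pos, neg_per_pos,
                             enh_len = 3000L, prom_len = 2000L,
                             enh_motif, prom_motif, seed = 1L,
                             negative_mode = c("clean", "decoy"),
                             gc = 0.5, cell_line = "synthetic") {
  negative_mode <- match.arg(negative_mode)
  n_pos <- as.integer(n_pos); neg_per_pos <- as.integer(neg_per_pos)
  enh_len <- as.integer(enh_len); prom_len <- as.integer(prom_len)
  if (n_pos < 1L) stop("n_pos must be >= 1")
  if (neg_per_pos < 0L) stop("neg_per_pos must be >= 0")
  stopifnot(inherits(enh_motif, "planted_motif"), inherits(prom_motif, "planted_motif"))
  we <- nchar(enh_motif$consensus); wp <- nchar(prom_motif$consensus)
  if (we > enh_len) stop("enhancer motif (", we, " bp) longer than enh_len ", enh_len)
  if (wp > prom_len) stop("promoter motif (", wp, " bp) longer than prom_len ", prom_len)

  set.seed(seed)
  n_neg <- n_pos * neg_per_pos
  n <- n_pos + n_neg
  ids <- c(sprintf("pos%05d", seq_len(n_pos)),
           if (n_neg) sprintf("neg%06d", seq_len(n_neg)))
  enh <- character(n); prom <- character(n)
  man <- data.frame(id = ids, label = c(rep(1L, n_pos), rep(0L, n_neg)),
                    enh_motif = NA_character_, enh_pos = NA_integer_,
                    prom_motif = NA_character_, prom_pos = NA_integer_,
                    stringsAsFactors = FALSE)

  for (i in seq_len(n_pos)) {
    pe <- sample.int(enh_len - we + 1L, 1L) - 1L
    pp <- sample.int(prom_len - wp + 1L, 1L) - 1L
    enh[i] <- plant_motif(sample_background(enh_len, gc = gc), enh_motif, pe)
    prom[i] <- plant_motif(sample_background(prom_len, gc = gc), prom_motif, pp)
    man$enh_motif[i] <- enh_motif$name; man$enh_pos[i] <- pe
    man$prom_motif[i] <- prom_motif$name; man$prom_pos[i] <- pp
  }

  if (n_neg) {
    decoy <- rep(FALSE, n_neg)
    if (negative_mode == "decoy")
      decoy[sample.int(n_neg, n_neg %/% 2L)] <- TRUE
    cap_hit <- FALSE
    for (j in seq_len(n_neg)) {
      i <- n_pos + j
      # resample any negative that looks like a positive (enhancer carries
      # the enhancer consensus AND promoter carries the promoter consensus);
      # short motifs in long windows occur by chance, so attempts are capped
      for (attempt in seq_len(100L)) {
        e <- sample_background(enh_len, gc = gc)
        p <- sample_background(prom_len, gc = gc)
        de <- dp <- NA_integer_
        if (decoy[j]) {
          if (runif(1) < 0.5) {
            de <- sample.int(enh_len - we + 1L, 1L) - 1L
            e <- plant_motif(e, enh_motif, de)
          } else {
            dp <- sample.int(prom_len - wp + 1L, 1L) - 1L
            p <- plant_motif(p, prom_motif, dp)
          }
        }
        if (!(contains_motif(e, enh_motif) && contains_motif(p, prom_motif)))
          break
        if (attempt == 100L) cap_hit <- TRUE
      }
      if (!is.na(de)) { man$enh_motif[i] <- enh_motif$name; man$enh_pos[i] <- de }
      if (!is.na(dp)) { man$prom_motif[i] <- prom_motif$name; man$prom_pos[i] <- dp }
      enh[i] <- e; prom[i] <- p
    }
    if (cap_hit)
      warning("some negatives contain both consensus strings by chance: ",
              "the motifs are too short relative to the sequence lengths ",
              "for negative purity to be attainable")
  }

  ord <- sample.int(n)
  records <- epi_pairs(ids[ord], enh[ord], prom[ord],
                       c(rep(1L, n_pos), rep(0L, n_neg))[ord], cell_line)
  man <- man[ord, , drop = FALSE]
  rownames(man) <- NULL
  manifest <- list(
    generator = "epiattn planted-motif generator",
    seed = seed, n_pos = n_pos, neg_per_pos = neg_per_pos,
    enh_len = enh_len, prom_len = prom_len, gc = gc,
    negative_mode = negative_mode, cell_line = cell_line,
    motifs = list(
      enhancer = unclass(enh_motif),
      promoter = unclass(prom_motif)
    ),
    records = man
  )
  list(records = records, manifest = manifest)
}
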