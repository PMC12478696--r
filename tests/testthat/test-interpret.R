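test_that("region windows follow the 20r + 59 rule under defaults", {
  cfg <- model_config()
  r0 <- region_window(0, cfg)
  expect_equal(r0[c("role", "start", "end")],
               list(role = "enhancer", start = 0, end = 59))
  r148 <- region_window(148, cfg)
  expect_equal(r148[c("role", "role_index", "start", "end")],
               list(role = "promoter", role_index = 0, start = 0, end = 59))
  r245 <- region_window(245, cfg)
  expect_equal(r245[c("role", "start", "end")],
               list(role = "promoter", start = 1940, end = 1999))
  expect_equal(region_window(147, cfg)$role, "enhancer")
  expect_error(region_window(246, cfg), "out of range")
  expect_error(region_window(-1, cfg), "out of range")
})

test_that("region windows agree with brute-force receptive-field enumeration", {
  set.seed(91)
  for (i in 1:20) {
    kernel <- sample(4:12, 1); pool <- sample(2:6, 1); stride <- sample(2:6, 1)
    enh_len <- kernel + pool + sample(50:200, 1)
    prom_len <- kernel + pool + sample(40:150, 1)
    cfg <- model_config(enh_len = enh_len, prom_len = prom_len,
                        conv_filters = 8, conv_kernel = kernel,
                        pool_size = pool, pool_stride = stride,
                        n_heads = 2, ffn_dense1 = 8, attn_hidden = 5)
    for (r in unique(c(0L, cfg$L_enh - 1L, cfg$L_enh, cfg$L_merged - 1L,
                       sample(0:(cfg$L_merged - 1L), 4)))) {
      rw <- region_window(r, cfg)
      L <- if (rw$role == "enhancer") enh_len else prom_len
      bf <- bf_receptive_field(rw$role_index, L, kernel, pool, stride)
      expect_equal(rw$start, unname(bf["start"]))
      expect_equal(rw$end, unname(bf["end"]))
      expect_lte(rw$end, L)
    }
  }
})

test_that("attention capture returns one row-normalised map per head and sample", {
  cfg <- tiny_config()
  m <- build_model(cfg, seed = 92)
  ds <- tiny_dataset(n_pos = 3, neg_per_pos = 1, seed = 92)
  pos <- ds$records[ds$records$label == 1, ]
  maps <- capture_attention(m, pos)
  expect_length(maps, 3)
  expect_named(maps, pos$id)
  for (a in maps) {
    expect_equal(dim(a), c(cfg$n_heads, cfg$L_merged, cfg$L_merged))
    expect_true(all(abs(apply(a, c(1, 2), sum) - 1) < 1e-5))
  }
  expect_error(capture_attention(m, ds$records),
               ds$records$id[ds$records$label == 0][1])
  expect_error(capture_attention(m, ds$records[0, ]), "no positive")
})

test_that("head averaging is the elementwise mean and keeps rows normalised", {
  a1 <- array(0, c(2, 3, 3)); a2 <- array(0, c(2, 3, 3))
  r1 <- matrix(c(.2, .3, .5, .1, .8, .1, .6, .2, .2), 3, byrow = TRUE)
  r2 <- matrix(c(.4, .4, .2, .3, .3, .4, .1, .1, .8), 3, byrow = TRUE)
  a1[1, , ] <- r1; a1[2, , ] <- r2
  a2[1, , ] <- r2; a2[2, , ] <- r1
  expect_equal(average_heads(list(a1, a2)), (r1 + r2) / 2)
  # all heads identical -> average equals any head
  a3 <- array(0, c(2, 3, 3)); a3[1, , ] <- r1; a3[2, , ] <- r1
  expect_equal(average_heads(a3), r1)
  expect_equal(rowSums(average_heads(list(a1, a2))), rep(1, 3))
  expect_error(average_heads(list()), "no attention")
})

test_that("top pairs are drawn from the cross blocks with the documented tie rule", {
  cfg <- tiny_config()   # L_enh 18, L_prom 13, merged 31
  Lm <- cfg$L_merged
  avg <- matrix(0.001, Lm, Lm)
  avg[5, cfg$L_enh + 8] <- 0.9     # enhancer 4 -> promoter 7 (0-based)
  tp <- top_region_pairs(avg, cfg, k = 5)
  expect_equal(tp$enh_region[1], 4)
  expect_equal(tp$prom_region[1], 7)
  expect_equal(tp$merged_prom[1], cfg$L_enh + 7)
  # all-equal matrix: ties broken by ascending (enh, prom)
  tie <- top_region_pairs(matrix(1, Lm, Lm), cfg, k = 5)
  expect_equal(tie$enh_region, rep(0, 5))
  expect_equal(tie$prom_region, 0:4)
})

test_that("ranking matches an exhaustive sort over all candidate pairs", {
  cfg <- tiny_config()
  Lm <- cfg$L_merged; Le <- cfg$L_enh; Lp <- cfg$L_prom
  set.seed(93)
  avg <- matrix(runif(Lm * Lm), Lm, Lm)
  tp <- top_region_pairs(avg, cfg, k = 8)
  # brute force over every (e, p) candidate
  cand <- expand.grid(e = 0:(Le - 1), p = 0:(Lp - 1))
  cand$score <- mapply(function(e, p)
    (avg[e + 1, Le + p + 1] + avg[Le + p + 1, e + 1]) / 2, cand$e, cand$p)
  cand <- cand[order(-cand$score, cand$e, cand$p), ]
  expect_equal(tp$enh_region, cand$e[1:8])
  expect_equal(tp$prom_region, cand$p[1:8])
  expect_equal(tp$score, cand$score[1:8], tolerance = 1e-12)
  # exhaustive mode returns every candidate, ranked
  full <- top_region_pairs(avg, cfg, k = Le * Lp, k_max = Inf)
  expect_equal(nrow(full), Le * Lp)
  expect_equal(full$score, sort(full$score, decreasing = TRUE))
})

test_that("k outside the configured bounds is rejected", {
  cfg <- tiny_config()
  avg <- matrix(1, cfg$L_merged, cfg$L_merged)
  expect_error(top_region_pairs(avg, cfg, k = 4), "bounds")
  expect_error(top_region_pairs(avg, cfg, k = 9), "bounds")
  expect_error(top_region_pairs(avg, cfg, k = 10^6, k_max = Inf), "candidate")
})

test_that("a consensus-matched filter recovers the planted window in the PWM", {
  cfg <- tiny_config(dropout = 0)
  m <- build_model(cfg, seed = 94)
  consensus <- "TGACG"
  # hand-set conv filter 1 to be a perfect detector of the consensus;
  # all other filters silent
  m$params$conv_e_W[] <- 0
  m$params$conv_e_b[] <- 0
  for (o in seq_len(nchar(consensus))) {
    base <- match(substr(consensus, o, o), c("A", "C", "G", "T"))
    m$params$conv_e_W[base, o, 1] <- 1
  }
  r <- 3L                                    # enhancer region [9, 16) under 3/3 pooling
  rw <- region_window(r, cfg)
  pos <- rw$start + 1L                       # plant inside the region window
  mo <- planted_motif("m", consensus, 0)
  seqs <- vapply(1:6, function(i)
    plant_motif(sample_background(cfg$enh_len, seed = 940 + i), mo, pos), "")
  recs <- epi_pairs(sprintf("s%d", 1:6), seqs,
                    vapply(1:6, function(i) sample_background(cfg$prom_len, seed = i), ""),
                    1L)
  pwm <- extract_region_pwm(m, recs, r, pseudocount = 0)
  expect_s3_class(pwm, "epi_region_pwm")
  expect_equal(pwm$n_sequences, 6)
  expect_equal(colSums(pwm$counts), rep(6, cfg$conv_kernel))
  # the detector filter peaks exactly at the planted position, so every
  # extracted window is the consensus itself (kernel width == motif width)
  expect_equal(paste(rownames(pwm$freq)[apply(pwm$freq, 2, which.max)],
                     collapse = ""), consensus)
  expect_true(all(pwm$freq[cbind(match(strsplit(consensus, "")[[1]],
                                       rownames(pwm$freq)),
                                 seq_len(nchar(consensus)))] == 1))
})

test_that("single-sequence PWMs with zero pseudocount are basis vectors", {
  cfg <- tiny_config()
  m <- build_model(cfg, seed = 95)
  rec <- tiny_dataset(n_pos = 1, neg_per_pos = 0, seed = 95)$records
  pwm <- extract_region_pwm(m, rec, 0L, pseudocount = 0)
  expect_equal(colSums(pwm$counts), rep(1, cfg$conv_kernel))
  expect_true(all(apply(pwm$freq, 2, max) == 1))
  # pseudocounts keep columns normalised
  pwm2 <- extract_region_pwm(m, rec, 0L, pseudocount = 0.25)
  expect_equal(colSums(pwm2$freq), rep(1, cfg$conv_kernel))
})

test_that("pwm correlation finds the aligned offset", {
  mo <- planted_motif("m", "TGACGTCA", 0.05)
  target <- motif_pwm(mo)
  expect_equal(pwm_correlation(target, target)$correlation, 1)
  # embed the motif PWM inside a wider uniform matrix at offset 3
  wide <- matrix(0.25, 4, 14, dimnames = list(c("A","C","G","T"), NULL))
  wide[, 3 + seq_len(8)] <- target
  al <- pwm_correlation(wide, target)
  expect_equal(al$offset, 3)
  expect_gt(al$correlation, 0.99)
})

test_that("partial-overlap alignment recovers phase-shifted extractions", {
  target <- motif_pwm(planted_motif("m", "TGACGTCA", 0.05))
  # an extraction window shifted 3 bases downstream of the true start:
  # columns 1..5 hold motif columns 4..8, the rest is background
  shifted <- matrix(0.25, 4, 8, dimnames = list(c("A","C","G","T"), NULL))
  shifted[, 1:5] <- target[, 4:8]
  full_only <- pwm_correlation(shifted, target)       # forced offset 0
  part <- pwm_correlation(shifted, target, min_overlap = 5)
  expect_equal(part$offset, -3)
  expect_gt(part$correlation, 0.99)
  expect_lt(full_only$correlation, part$correlation)
  expect_error(pwm_correlation(shifted, target, min_overlap = 9), "min_overlap")
})

test_that("interpretation requires the one-hot encoding", {
  cfg <- tiny_config(encoding = "dna2vec", kmer_k = 4L, embed_dim = 8L)
  m <- build_model(cfg, seed = 96)
  rec <- tiny_dataset(n_pos = 1, neg_per_pos = 0, seed = 96)$records
  expect_error(extract_region_pwm(m, rec, 0L), "one-hot")
})
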