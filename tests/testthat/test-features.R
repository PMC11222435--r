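test_that("move-table steps map to basecalled bases like a brute-force scan", {
  expect_equal(signal_to_base_index(c(1L, 0L, 1L, 1L)), c(0L, 0L, 1L, 2L))
  expect_equal(signal_to_base_index(rep(1L, 6)), 0:5)
  expect_error(signal_to_base_index(c(0L, 1L)), "start with 1")

  # Oracle: assign each step to the most recent move = 1.
  with_seed_local(8, {
    for (rep in 1:10) {
      moves <- c(1L, sample(0:1, 30, replace = TRUE))
      oracle <- integer(length(moves))
      cur <- -1L
      for (t in seq_along(moves)) {
        if (moves[t] == 1L) cur <- cur + 1L
        oracle[t] <- cur
      }
      expect_equal(signal_to_base_index(moves), oracle)
    }
  })
})

test_that("CIGAR mapping matches a per-operation walk, flagging insertions and clips", {
  m <- reference_query_mapping("4M", 100L)
  expect_equal(m$query, 0:3)
  expect_equal(m$ref, 100:103)
  expect_false(any(m$insertion))

  m <- reference_query_mapping("2M1I2M", 0L)
  expect_equal(m$ref[m$query == 2], 1L)     # insertion carries previous ref
  expect_true(m$insertion[m$query == 2])
  expect_equal(m$ref[m$query == 3], 2L)

  m <- reference_query_mapping("2S3M", 10L)
  expect_true(all(m$clipped[1:2]))
  expect_equal(m$ref[3:5], 10:12)

  expect_error(reference_query_mapping("3Z"), "CIGAR")

  # Oracle walk over random CIGARs.
  with_seed_local(4, {
    for (rep in 1:20) {
      n_ops <- sample(1:6, 1)
      ops <- c("M", sample(c("M", "I", "D"), n_ops, TRUE), "M")
      lens <- sample(1:4, length(ops), TRUE)
      cigar <- paste0(lens, ops, collapse = "")
      qi <- 0L; ri <- 7L; last <- NA_integer_
      oq <- integer(0); orf <- integer(0); oins <- logical(0)
      for (j in seq_along(ops)) {
        for (step in seq_len(lens[j])) {
          if (ops[j] == "M") {
            oq <- c(oq, qi); orf <- c(orf, ri); oins <- c(oins, FALSE)
            qi <- qi + 1L; ri <- ri + 1L; last <- ri - 1L
          } else if (ops[j] == "I") {
            oq <- c(oq, qi); orf <- c(orf, last); oins <- c(oins, TRUE)
            qi <- qi + 1L
          } else {
            ri <- ri + 1L; last <- ri - 1L
          }
        }
      }
      m <- reference_query_mapping(cigar, 7L)
      expect_equal(m$query, oq)
      expect_equal(m$ref, orf)
      expect_equal(m$insertion, oins)
    }
  })
})

test_that("CpG sites are reported on both strands, matching a regex scan", {
  s <- find_cpg_sites("ACGTCG")
  expect_equal(s$pos[s$strand == "+"], c(1L, 4L))
  expect_equal(s$pos[s$strand == "-"], c(2L, 5L))
  expect_equal(nrow(find_cpg_sites("AAAA")), 0)
  expect_equal(nrow(find_cpg_sites("ANGCNG")), 0)  # ambiguity never matches

  with_seed_local(10, {
    seq <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
    hits <- gregexpr("(?=CG)", seq, perl = TRUE)[[1]]
    s <- find_cpg_sites(seq)
    expect_equal(s$pos[s$strand == "+"], as.integer(hits) - 1L)
    expect_equal(s$pos[s$strand == "-"], as.integer(hits))
  })
})

test_that("signal normalization is affine-invariant median/MAD with sd fallback", {
  expect_equal(normalize_signal(rep(3, 10)), rep(0, 10))
  with_seed_local(2, {
    x <- rnorm(500, 3, 2)
    expect_equal(normalize_signal(x), normalize_signal(2 * x + 7))
    y <- normalize_signal(rnorm(10000, 3, 2))
    expect_lt(abs(median(y)), 0.05)
    expect_lt(abs(mad(y) - 1), 0.05)
  })
  expect_error(normalize_signal(numeric(0)), "non-empty")
})

test_that("extracted examples reproduce the signal slice and enforce the block filter", {
  # Deterministic-dwell read: force exactly 2 strides per base by using a
  # pore model whose geometric dwell is truncated at its minimum... the
  # simulator draws dwell >= 1 stride, so instead reconstruct the expected
  # slice from the read's own move table (dwell bookkeeping oracle).
  pore <- build_pore_model(k = 2, mod_shift = 1, seed = 3, dwell_mean = 10,
                           stride = 5)
  cfg <- sim_config(ref_length = 3000, sub_rate = 0, ins_rate = 0,
                    del_rate = 0, seed = 12)
  ref <- simulate_reference(cfg)
  fc <- feature_config(l = 9, b = 5, mode = "reference")
  n_checked <- 0
  for (i in 1:50) {
    rb <- simulate_read(ref$sequence, ref$truth, pore, cfg, seed = 400 + i,
                        interval = c(40 * i %% 1000, 40 * i %% 1000 + 500))
    norm <- normalize_signal(rb$signal)
    base_idx <- cumsum(rb$moves) - 1L
    ex <- extract_examples(rb, ref$sequence, fc)
    for (j in seq_len(nrow(ex))) {
      # Dwell bookkeeping oracle: on an error-free read the window's
      # blocks are the steps of 9 consecutive basecalled bases.
      tk <- ex$tokens[[j]]
      expect_equal(tk[5], 2L)  # central C
      expect_equal(tk[6], 3L)  # following G
      expect_true(all(diff(ex$r[[j]]) >= 0))
      expect_true(all(diff(ex$q[[j]]) >= 0))
      expect_true(ex$s[j] >= ceiling(0.5 * 9) && ex$s[j] <= 5 * 9)
      if (ex$strand[j] == "+") {
        c_read <- ex$pos[j] - rb$alignment$start  # 0-based read coordinate
        win_steps <- which(base_idx >= c_read - 4 & base_idx <= c_read + 4)
        slice <- norm[((min(win_steps) - 1) * 5 + 1):(max(win_steps) * 5)]
        expect_equal(as.numeric(t(ex$blocks[[j]])), slice)
        n_checked <- n_checked + 1
      }
    }
  }
  expect_gt(n_checked, 100)
})

test_that("windows overflowing the read are dropped and minus-strand tokens flip", {
  pore <- build_pore_model(k = 2, mod_shift = 1, seed = 3)
  cfg <- sim_config(ref_length = 3000, sub_rate = 0, ins_rate = 0,
                    del_rate = 0, seed = 12)
  ref <- simulate_reference(cfg)
  fc <- feature_config(l = 9, b = 5, mode = "reference")
  rb <- simulate_read(ref$sequence, ref$truth, pore, cfg, seed = 2,
                      interval = c(500, 800), strand = "+")
  ex <- extract_examples(rb, ref$sequence, fc)
  # No window may start before the read or end past it.
  expect_true(all(ex$pos - rb$alignment$start >= 4))
  expect_true(all(ex$pos - rb$alignment$start <= 300 - 5))

  # Minus-strand read: tokens are the reverse complement of the forward
  # genomic window, so the assayed C still sits at the center.
  rbm <- simulate_read(ref$sequence, ref$truth, pore, cfg, seed = 2,
                       interval = c(500, 800), strand = "-")
  exm <- extract_examples(rbm, ref$sequence, fc)
  expect_true(all(exm$strand == "-"))
  for (j in seq_len(min(nrow(exm), 20))) {
    fwd_window <- substr(ref$sequence, exm$pos[j] + 1 - 4, exm$pos[j] + 1 + 4)
    expect_equal(paste(tokens_to_bases(exm$tokens[[j]]), collapse = ""),
                 revcomp(fwd_window))
  }
})

test_that("reference- and basecall-anchored extraction agree on error-free reads", {
  pore <- build_pore_model(k = 2, mod_shift = 1, seed = 5)
  cfg <- sim_config(ref_length = 3000, sub_rate = 0, ins_rate = 0,
                    del_rate = 0, seed = 21)
  ref <- simulate_reference(cfg)
  fc_ref <- feature_config(l = 9, b = 5, mode = "reference")
  fc_bc <- feature_config(l = 9, b = 5, mode = "basecall")
  for (i in 1:5) {
    rb <- simulate_read(ref$sequence, ref$truth, pore, cfg, seed = 30 + i)
    e1 <- extract_examples(rb, ref$sequence, fc_ref)
    e2 <- extract_examples(rb, ref$sequence, fc_bc)
    expect_equal(nrow(e1), nrow(e2))
    expect_equal(e1$pos, e2$pos)
    for (j in seq_len(nrow(e1))) {
      expect_identical(e1$tokens[[j]], e2$tokens[[j]])
      expect_equal(e1$blocks[[j]], e2$blocks[[j]])
      expect_equal(e1$q[[j]], e2$q[[j]])
    }
  }
})

test_that("block-count filter bookkeeping partitions the candidate sites", {
  pore <- build_pore_model(k = 2, mod_shift = 1, seed = 5, dwell_mean = 25,
                           stride = 5)  # long dwells force some s > 5l
  cfg <- sim_config(ref_length = 3000, seed = 21)
  ref <- simulate_reference(cfg)
  fc <- feature_config(l = 5, b = 5, mode = "reference")
  rb <- simulate_read(ref$sequence, ref$truth, pore, cfg, seed = 77,
                      interval = c(0, 2000), strand = "+")
  ex <- extract_examples(rb, ref$sequence, fc)
  # A plus-strand read assays only plus-strand cytosines.
  cand <- find_cpg_sites(substr(ref$sequence, 1, 2000))
  n_cand <- sum(cand$strand == "+")
  n_window_fit <- n_cand - attr(ex, "n_boundary")
  expect_equal(nrow(ex) + attr(ex, "n_filtered"), n_window_fit)
  expect_gt(attr(ex, "n_filtered"), 0)
})

test_that("reference mode without an alignment or with low mapq skips the read", {
  b <- local({
    x <- list(read_id = "u", signal = rnorm(20), stride = 5L,
              moves = c(1L, 1L, 1L, 1L), basecalls = "ACGT",
              alignment = NULL, meth = NULL)
    class(x) <- "read_bundle"
    x
  })
  fc <- feature_config(l = 3, b = 5, mode = "reference")
  expect_warning(ex <- extract_examples(b, "ACGT", fc), "alignment")
  expect_equal(nrow(ex), 0)
  b$alignment <- list(contig = "c", start = 0L, strand = "+", cigar = "4M",
                      mapq = 10L)
  expect_warning(ex <- extract_examples(b, "ACGT", fc), "quality")
  expect_equal(nrow(ex), 0)
})
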