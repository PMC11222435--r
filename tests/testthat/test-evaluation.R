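test_that("truth filtering applies the coverage floor and partial-methylation band", {
  # Coverage distribution with P5 = 3: the effective lower bound is 5.
  wgbs <- tibble::tibble(
    contig = "c", pos = 1:100, strand = "+",
    meth = c(rep(0, 50), rep(10, 50)),
    unmeth = c(rep(3, 5), rep(10, 45), rep(0, 50)))
  wgbs$freq <- ifelse(wgbs$meth + wgbs$unmeth > 0,
                      wgbs$meth / (wgbs$meth + wgbs$unmeth), NA)
  out <- filter_truth(wgbs, eval_config(), "classification")
  expect_true(all(out$coverage >= 5))
  expect_false(any(out$pos %in% 1:5))

  # A half-methylated site is dropped for classification, kept for
  # correlation.
  wgbs2 <- tibble::tibble(contig = "c", pos = 1:200, strand = "+",
                          meth = 10L, unmeth = 10L, freq = 0.5)
  wgbs2$meth[1:100] <- 20L; wgbs2$unmeth[1:100] <- 0L
  wgbs2$freq[1:100] <- 1
  cls <- filter_truth(wgbs2, eval_config(), "classification")
  expect_true(all(cls$freq %in% c(0, 1) | cls$freq >= 0.99 | cls$freq <= 0.01))
  expect_false(any(cls$freq == 0.5))
  cor_t <- filter_truth(wgbs2, eval_config(), "correlation")
  expect_true(any(cor_t$freq == 0.5))

  # Brute-force oracle on a random table.
  with_seed_local(33, {
    n <- 10000
    w <- tibble::tibble(contig = "c", pos = seq_len(n), strand = "+",
                        meth = rpois(n, 8), unmeth = rpois(n, 8))
    w$freq <- ifelse(w$meth + w$unmeth > 0,
                     w$meth / (w$meth + w$unmeth), NA)
    cov <- w$meth + w$unmeth
    p5 <- sort(cov)[ceiling(0.05 * n)]
    lower <- max(p5, 5)
    keep <- cov >= lower & !is.na(w$freq) & (w$freq <= 0.01 | w$freq >= 0.99)
    out <- filter_truth(w, eval_config(), "classification")
    expect_equal(nrow(out), sum(keep))
    p95 <- sort(cov)[ceiling(0.95 * n)]
    keep_cor <- cov >= lower & cov <= p95 & !is.na(w$freq)
    expect_equal(nrow(filter_truth(w, eval_config(), "correlation")),
                 sum(keep_cor))
  })
  expect_warning(filter_truth(tibble::tibble(contig = character(0),
                                             pos = integer(0),
                                             meth = integer(0),
                                             unmeth = integer(0),
                                             freq = numeric(0))), "empty")
})

test_that("confusion metrics match their closed forms and the AP ranked sweep", {
  # TP=2 FP=1 TN=1 FN=0.
  scores <- c(0.9, 0.8, 0.7, 0.2)
  truth <- c(TRUE, TRUE, FALSE, FALSE)
  m <- confusion_metrics(scores, truth, threshold = 0.5)
  expect_equal(m$TP, 2); expect_equal(m$FP, 1)
  expect_equal(m$TN, 1); expect_equal(m$FN, 0)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 1)
  expect_equal(m$accuracy, 3 / 4)
  expect_equal(m$fpr, 1 / 2)
  expect_equal(m$f1, 4 / 5)
  # F1 is the harmonic-mean identity.
  expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))

  # Perfect ranking gives AP = 1.
  expect_equal(average_precision(c(0.9, 0.8, 0.1), c(TRUE, TRUE, FALSE)), 1)

  # Brute-force ranked sweep on random scores (with ties).
  with_seed_local(21, {
    scores <- round(runif(200), 2)
    truth <- runif(200) < 0.4
    ord <- order(scores, decreasing = TRUE)
    st <- scores[ord]; tt <- truth[ord]
    prev_rec <- 0; ap <- 0
    for (thr in unique(st)) {
      sel <- scores >= thr
      prec <- sum(truth & sel) / sum(sel)
      rec <- sum(truth & sel) / sum(truth)
      ap <- ap + (rec - prev_rec) * prec
      prev_rec <- rec
    }
    expect_equal(average_precision(scores, truth), ap, tolerance = 1e-12)
  })
  expect_error(confusion_metrics(numeric(0), logical(0)), "pairs")
})

test_that("Pearson correlation of sites against truth hits the closed form", {
  sites <- tibble::tibble(contig = "c", pos = 1:100, strand = "+",
                          coverage = 10L, n_mod = 0L,
                          frequency = seq(0, 1, length.out = 100))
  wgbs <- tibble::tibble(contig = "c", pos = 1:100, strand = "+",
                         meth = round(20 * seq(0, 1, length.out = 100)))
  wgbs$unmeth <- 20L - wgbs$meth
  wgbs$freq <- wgbs$meth / 20
  r <- correlate_sites(sites, wgbs, eval_config())
  expect_equal(r$r, cor(sites$frequency, wgbs$freq))
  expect_gt(r$r, 0.99)

  anti <- dplyr::mutate(sites, frequency = 1 - frequency)
  expect_equal(correlate_sites(anti, wgbs)$r,
               cor(1 - sites$frequency, wgbs$freq))
  expect_lt(correlate_sites(anti, wgbs)$r, -0.99)

  # Exact closed-form agreement under added noise.
  with_seed_local(5, {
    noisy <- dplyr::mutate(sites,
                           frequency = pmin(1, pmax(0, frequency +
                                                      rnorm(100, 0, 0.1))))
    paired_cov <- wgbs$meth + wgbs$unmeth
    keep <- paired_cov >= max(sort(paired_cov)[ceiling(0.05 * 100)], 5) &
      paired_cov <= sort(paired_cov)[ceiling(0.95 * 100)]
    expect_equal(correlate_sites(noisy, wgbs)$r,
                 cor(noisy$frequency[keep], wgbs$freq[keep]))
  })
})

test_that("TSS binning floors signed offsets with strand-aware orientation", {
  ec <- eval_config(tss_bin_size = 50L)
  mk_sites <- function(pos) {
    tibble::tibble(contig = "c", pos = pos, strand = "+", coverage = 10L,
                   n_mod = 5L, frequency = 0.5)
  }
  anchors <- tibble::tibble(contig = "c", pos = 1000L, strand = "+")
  expect_equal(tss_profile(mk_sites(1000L), anchors, config = ec)$bin, 0)
  expect_equal(tss_profile(mk_sites(1025L), anchors, config = ec)$bin, 1)
  # Negative offsets floor downward: -26 + 25 = -1 -> bin -1.
  expect_equal(tss_profile(mk_sites(974L), anchors, config = ec)$bin, -1)
  # Minus-strand anchors negate the offset before binning.
  anchors_m <- tibble::tibble(contig = "c", pos = 1000L, strand = "-")
  expect_equal(tss_profile(mk_sites(1025L), anchors_m, config = ec)$bin, 0)
  expect_equal(tss_profile(mk_sites(1045L), anchors_m, config = ec)$bin, -1)

  # Per-tool coverage filters: low-coverage ONT sites and low-coverage
  # WGBS positions are excluded.
  lo <- mk_sites(1000L); lo$coverage <- 2L
  expect_equal(nrow(tss_profile(lo, anchors, config = ec)), 0)
  wg <- tibble::tibble(contig = "c", pos = 1000L, strand = "+", meth = 2L,
                       unmeth = 1L, freq = 2 / 3)
  expect_equal(nrow(tss_profile(mk_sites(1000L), anchors, wgbs = wg,
                                config = ec)), 0)
  expect_error(tss_profile(mk_sites(1L), anchors,
                           config = eval_config(tss_bin_size = 0L)), "bin")
})

test_that("coverage CCDF is a nonincreasing step function starting at 1", {
  tbl <- coverage_ccdf(c(0, 5, 10, 10))
  expect_equal(tbl$ccdf[tbl$coverage == 0], 1)
  expect_equal(tbl$ccdf[tbl$coverage == 5], 3 / 4)
  expect_equal(tbl$ccdf[tbl$coverage == 10], 2 / 4)
  with_seed_local(2, {
    cov <- rpois(500, 7)
    tbl <- coverage_ccdf(cov)
    expect_equal(tbl$ccdf[1], 1)
    expect_true(all(diff(tbl$ccdf) <= 0))
    for (cv in sample(0:max(cov), 10)) {
      expect_equal(tbl$ccdf[tbl$coverage == cv], mean(cov >= cv))
    }
  })
  expect_equal(strand_specific_coverage(2 * 3.117e9, 3.117e9), 1)
  expect_error(coverage_ccdf(integer(0), n_sites = 0), "zero")
})

test_that("confident-site comparison follows the coverage-5 and 50% rules", {
  mk <- function(pos, cov, freq) {
    tibble::tibble(contig = "c", pos = pos, strand = "+",
                   coverage = cov, n_mod = round(freq * cov),
                   frequency = freq)
  }
  a <- mk(1:6, c(5, 5, 4, 10, 5, 8), c(0.6, 0.4, 0.9, 0.8, 0.5, 0.2))
  b <- mk(1:6, c(7, 5, 9, 10, 5, 3), c(0.7, 0.3, 0.6, 0.2, 0.6, 0.9))
  sup <- mk(1:6, 10, c(1, 0, 1, 0.9, 1, 0))
  cmp <- confident_site_comparison(a, b, support = list(sup))
  pos <- cmp[cmp$class == "positive", ]
  neg <- cmp[cmp$class == "negative", ]
  # Site 1 concordant positive; site 2 concordant negative.
  expect_equal(pos$concordant, 1)
  expect_equal(neg$concordant, 1)
  # Site 3: a uncalled (coverage 4), b positive -> unique to b.
  expect_equal(pos$unique_b, 1)
  # Site 4: a positive, b negative, support positive -> a supported.
  expect_equal(pos$discordant_a_supported, 1)
  # Site 5: frequency exactly 0.5 is negative for a, 0.6 positive for b;
  # support positive -> b supported.
  expect_equal(pos$discordant_b_supported, 1)
  # Site 6: a negative, b uncalled -> unique to a in the negative class.
  expect_equal(neg$unique_a, 1)
  # Categories partition the evaluated universe.
  expect_equal(attr(cmp, "n_universe"), 6)
  expect_equal(pos$concordant + neg$concordant + attr(cmp, "n_discordant") +
                 pos$unique_a + pos$unique_b + neg$unique_a + neg$unique_b +
                 attr(cmp, "n_uncalled_both"), 6)
})

test_that("high-filtering classes follow the missing/HFP definitions", {
  cls <- high_filtering_analysis(
    overall = c(10, 4, 20, 20, 10),
    valid = c(4, 4, 17, 19, 10))
  expect_equal(cls, c("missing-due-to-filtering", "missing-low-overall",
                      "high-filtering", "ok", "ok"))
  expect_error(high_filtering_analysis(5, 6), "exceeds")
})

test_that("annotation contexts apply precedence, flanks, GC buckets and singletons", {
  tracks <- list(
    tss = tibble::tibble(contig = "c", pos = 5000L, strand = "+"),
    genes = load_bed_local("c\t4000\t9000"),
    exons = load_bed_local("c\t4500\t4800"),
    islands = load_bed_local("c\t10000\t10800"),
    sine = load_bed_local("c\t1\t100"),
    line = load_bed_local("c\t50\t200"))
  sites <- tibble::tibble(
    contig = "c",
    pos = c(4600L, 8000L, 8500L, 500L, 10100L, 9000L, 13000L, 60L),
    strand = "+")
  ref <- paste(c(rep("A", 30), "C", "G", rep("A", 28), "C", "G",
                 rep(c("A", "C", "G", "T"), 5000)), collapse = "")
  ann <- annotate_contexts(sites, tracks, ref)
  # Promoter halo beats the exon at 4600 (TSS 5000 +- 2000).
  expect_equal(ann$genic[1], "promoter")
  # 8000 is within gene, outside exons and promoter halo -> intron.
  expect_equal(ann$genic[2], "intron")
  # 8500 also intron; 500 intergenic.
  expect_equal(ann$genic[4], "intergenic")
  # Island zone: 10100 inside the island; 9000 within the 2000 bp flank
  # -> shore (shores span [8000,10000) and [10800,12800)); 13000 within
  # the next 2000 -> shelf.
  expect_equal(ann$island_zone[5], "island")
  expect_equal(ann$island_zone[6], "shore")
  expect_equal(ann$island_zone[7], "shelf")
  # Repeat priority: position 60 overlaps SINE and LINE -> SINE.
  expect_equal(ann$repeat_class[8], "SINE")
  # GC bucket from the 5-base window: "ACGTA"-type window -> 40%.
  site_gc <- annotate_contexts(tibble::tibble(contig = "c", pos = 62L,
                                              strand = "+"),
                               tracks, ref)
  expect_true(site_gc$gc_bucket %in% c(20, 40, 60, 80, 100))
  win <- substr(ref, 61, 65)
  g <- mean(strsplit(win, "")[[1]] %in% c("C", "G"))
  expect_equal(site_gc$gc_bucket, c(20, 40, 60, 80, 100)[
    which(c(20, 40, 60, 80, 100) >= 100 * g)[1]])
  # Singletons: the CpG at 30 (0-based) has no neighbor within 10 bp; the
  # paired CpGs at 60/62 are non-singletons.
  s_single <- annotate_contexts(tibble::tibble(contig = "c", pos = 30L,
                                               strand = "+"), tracks, ref)
  expect_true(s_single$singleton)
  expect_false(all(annotate_contexts(
    tibble::tibble(contig = "c", pos = c(60L, 62L), strand = "+"),
    tracks, ref)$singleton))
  # Missing tracks yield NA, not fabricated labels.
  bare <- annotate_contexts(sites[1, ], list(), NULL)
  expect_true(is.na(bare$genic) && is.na(bare$repeat_class) &&
                is.na(bare$island_zone) && is.na(bare$gc_bucket))
})

test_that("a perfect caller recovers unit metrics and correlation", {
  # Evaluating calls that equal the truth yields accuracy, precision,
  # recall, F1 = 1 and r = 1 on any simulation.
  cfg <- sim_config(ref_length = 4000, wgbs_mean_coverage = 40,
                    bs_epsilon = 0, truth_mix = c(0.5, 0.5, 0), seed = 3)
  ref <- simulate_reference(cfg)
  wgbs <- simulate_wgbs(ref$truth, cfg, seed = 4)
  sites <- tibble::tibble(contig = ref$truth$contig, pos = ref$truth$pos,
                          strand = ref$truth$strand, coverage = 20L,
                          n_mod = as.integer(round(20 * ref$truth$freq)),
                          frequency = ref$truth$freq)
  truth_cls <- filter_truth(wgbs, eval_config(), "classification")
  paired <- dplyr::inner_join(sites, truth_cls,
                              by = c("contig", "pos", "strand"))
  m <- confusion_metrics(paired$frequency, paired$positive, threshold = 0.5)
  expect_equal(m$accuracy, 1)
  expect_equal(m$f1, 1)
  expect_equal(m$average_precision, 1)
  r <- correlate_sites(sites, wgbs)
  expect_equal(r$r, 1, tolerance = 1e-12)
})
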