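# Synthetic nanopore squiggle simulator: k-mer current model, reference with
# CpG-island structure, per-read signal/move-table/alignment generation and
# matched bisulfite (Bismark-coverage style) ground truth.

#' Build a k-mer pore current model
#'
#' Draws one current level and noise scale per k-mer, reproducibly from a
#' seed. Methylation of the assayed cytosine adds `mod_shift` to the level of
#' every k-mer whose window overlaps that cytosine, so modification
#' perturbs the signal over a multi-base context. All levels are in
#' arbitrary normalized units; no picoampere calibration is attempted.
#'
#' @param k K-mer length (>= 1).
#' @param mod_shift Additive current-level delta for k-mers overlapping a
#'   methylated cytosine, in units of the (unit-variance) level scale.
#' @param seed Integer seed; identical seeds give bitwise-identical tables.
#' @param level_sd Baseline per-sample noise scale; per-k-mer scales are
#'   jittered around this value and are strictly positive.
#' @param dwell_mean Mean number of raw samples per base (>= `stride`).
#' @param stride Samples per move-table step (5 for 4 kHz super-accurate
#'   basecalling, 6 for 5 kHz).
#' @return An object of class `pore_model`.
#' @export
build_pore_model <- function(k = 6L, mod_shift = 0.5, seed = 1L,
                             level_sd = 0.25, dwell_mean = 9, stride = 5L) {
  if (!is.numeric(k) || length(k) != 1L || k < 1) {
    stop_invalid("`k` must be a single integer >= 1 (got %s)", format(k))
  }
  k <- as.integer(k)
  if (dwell_mean < stride) {
    stop_invalid("`dwell_mean` (%s) must be >= `stride` (%s)", dwell_mean, stride)
  }
  n <- 4L^k
  kmers <- do.call(paste0, expand.grid(rep(list(DNA_BASES), k),
                                       stringsAsFactors = FALSE)[, k:1, drop = FALSE])
  with_rng_seed(seed, {
    level_mean <- stats::rnorm(n, 0, 1)
    sd_jitter <- stats::runif(n, 0.8, 1.2)
  })
  structure(list(
    k = k,
    kmers = kmers,
    level_mean = stats::setNames(level_mean, kmers),
    level_sd = stats::setNames(level_sd * sd_jitter, kmers),
    mod_shift = mod_shift,
    dwell_mean = dwell_mean,
    stride = as.integer(stride)
  ), class = "pore_model")
}

#' @export
print.pore_model <- function(x, ...) {
  cat(sprintf("<pore_model> k=%d (%d k-mers), mod_shift=%.3f, dwell_mean=%.1f, stride=%d\n",
              x$k, length(x$level_mean), x$mod_shift, x$dwell_mean, x$stride))
  invisible(x)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic data generator. All rates are
#' probabilities in \[0, 1\] and a single `seed` fixes every random draw.
#'
#' @param ref_length Reference length in bases.
#' @param island_count,island_length Number and length of planted CpG islands.
#' @param island_oe,background_oe Observed/expected CpG ratio targets inside
#'   islands and in the background.
#' @param island_gc,background_gc G+C fraction inside islands and background.
#' @param n_reads Number of reads to simulate.
#' @param read_length_mean,read_length_sd Gaussian read-length distribution
#'   (truncated below at `2 * 31` bases).
#' @param sub_rate,ins_rate,del_rate Basecall substitution and single-base
#'   indel error rates.
#' @param wgbs_mean_coverage Mean (Poisson) bisulfite coverage per site.
#' @param bs_epsilon Bisulfite conversion error rate.
#' @param truth_mix Length-3 mixture weights for per-site methylation
#'   frequency classes (fully unmethylated 0, fully methylated 1, partial).
#' @param contig Contig name used for all simulated records.
#' @param seed Integer master seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(ref_length = 20000L,
                       island_count = 4L, island_length = 600L,
                       island_oe = 0.7, background_oe = 0.2,
                       island_gc = 0.6, background_gc = 0.4,
                       n_reads = 200L,
                       read_length_mean = 2000, read_length_sd = 400,
                       sub_rate = 0.005, ins_rate = 0.0025, del_rate = 0.0025,
                       wgbs_mean_coverage = 30,
                       bs_epsilon = 0.005,
                       truth_mix = c(0.45, 0.45, 0.10),
                       contig = "sim1",
                       seed = 1L) {
  rates <- c(sub_rate, ins_rate, del_rate, bs_epsilon,
             island_oe, background_oe, island_gc, background_gc)
  if (any(rates < 0 | rates > 1)) {
    stop_invalid("all rates must lie in [0, 1]")
  }
  if (length(truth_mix) != 3L || any(truth_mix < 0) || sum(truth_mix) <= 0) {
    stop_invalid("`truth_mix` must be 3 nonnegative weights with positive sum")
  }
  structure(list(
    ref_length = as.integer(ref_length),
    island_count = as.integer(island_count),
    island_length = as.integer(island_length),
    island_oe = island_oe, background_oe = background_oe,
    island_gc = island_gc, background_gc = background_gc,
    n_reads = as.integer(n_reads),
    read_length_mean = read_length_mean, read_length_sd = read_length_sd,
    sub_rate = sub_rate, ins_rate = ins_rate, del_rate = del_rate,
    wgbs_mean_coverage = wgbs_mean_coverage,
    bs_epsilon = bs_epsilon,
    truth_mix = truth_mix / sum(truth_mix),
    contig = contig,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Sample one base given the previous base under a CpG-aware first-order model.
# gc: target G+C fraction; oe: observed/expected CpG ratio target. After a C,
# the probability of G is oe * p(G); remaining mass is spread over A/C/T
# proportionally to their stationary frequencies.
sample_bases_markov <- function(n, prev, gc, oe) {
  pA <- (1 - gc) / 2; pC <- gc / 2; pG <- gc / 2; pT <- (1 - gc) / 2
  base_p <- c(A = pA, C = pC, G = pG, T = pT)
  after_c <- base_p
  after_c["G"] <- oe * pG
  rest <- 1 - after_c["G"]
  after_c[c("A", "C", "T")] <- base_p[c("A", "C", "T")] /
    sum(base_p[c("A", "C", "T")]) * rest
  out <- character(n)
  for (i in seq_len(n)) {
    p <- if (identical(prev, "C")) after_c else base_p
    prev <- sample(DNA_BASES, 1L, prob = p)
    out[i] <- prev
  }
  out
}

#' Simulate a reference sequence with CpG islands and methylation truth
#'
#' Generates a background sequence with suppressed CpG dinucleotides, plants
#' CpG-dense GC-rich islands at evenly spaced positions, and assigns every
#' CpG site a ground-truth methylation frequency drawn from a three-class
#' mixture (fully unmethylated, fully methylated, partial). The two strand
#' sites of one CpG dinucleotide share a frequency, mirroring the symmetric
#' maintenance methylation of CpG context.
#'
#' @param config A [sim_config()].
#' @return A list with `sequence` (a single DNA string), `truth` (a tibble
#'   with columns `contig`, `pos` (0-based position of the C on its strand,
#'   forward coordinates), `strand`, `freq`), and `islands` (a tibble of the
#'   planted island intervals, 0-based half-open).
#' @export
simulate_reference <- function(config = sim_config()) {
  n <- config$ref_length
  if (n < 62L) stop_invalid("reference length must be at least twice the window length")
  with_rng_seed(child_seed(config$seed, 1L), {
    in_island <- rep(FALSE, n)
    islands <- tibble::tibble(start = integer(0), end = integer(0))
    if (config$island_count > 0L && config$island_length > 0L) {
      gap <- n %/% (config$island_count + 1L)
      starts <- pmin(pmax(0L, gap * seq_len(config$island_count) -
                            config$island_length %/% 2L),
                     n - config$island_length)
      islands <- tibble::tibble(start = as.integer(starts),
                                end = as.integer(starts + config$island_length))
      for (j in seq_len(nrow(islands))) {
        in_island[(islands$start[j] + 1L):islands$end[j]] <- TRUE
      }
    }
    # Generate sequence segment-wise so each region uses its own composition.
    runs <- rle(in_island)
    chars <- character(0)
    prev <- "A"
    for (j in seq_along(runs$lengths)) {
      gc <- if (runs$values[j]) config$island_gc else config$background_gc
      oe <- if (runs$values[j]) config$island_oe else config$background_oe
      seg <- sample_bases_markov(runs$lengths[j], prev, gc, oe)
      chars <- c(chars, seg)
      prev <- seg[length(seg)]
    }
    sequence <- paste(chars, collapse = "")

    # CpG truth: one frequency per dinucleotide, shared by both strand sites.
    cg_pos <- which(chars[-n] == "C" & chars[-1] == "G") - 1L  # 0-based C pos
    cls <- sample.int(3L, length(cg_pos), replace = TRUE, prob = config$truth_mix)
    freq <- numeric(length(cg_pos))
    freq[cls == 2L] <- 1
    freq[cls == 3L] <- stats::runif(sum(cls == 3L), 0.1, 0.9)
    truth <- tibble::tibble(
      contig = config$contig,
      pos = c(cg_pos, cg_pos + 1L),
      strand = rep(c("+", "-"), each = length(cg_pos)),
      freq = c(freq, freq)
    )
    truth <- dplyr::arrange(truth, .data$pos, .data$strand)
    list(sequence = sequence, truth = truth, islands = islands)
  })
}

# Current level and noise per base of a read-orientation sequence.
# meth: logical per base, TRUE where that base is a methylated C.
# The k-mer window anchored at base i starts at i - floor((k-1)/2); edges are
# clamped by repeating the terminal base.
kmer_levels <- function(chars, meth, pore) {
  n <- length(chars)
  k <- pore$k
  off <- -((k - 1L) %/% 2L) + 0:(k - 1L)
  idx <- outer(seq_len(n), off, `+`)
  idx[idx < 1L] <- 1L
  idx[idx > n] <- n
  km <- matrix(chars[idx], nrow = n)
  kmer_str <- do.call(paste0, as.data.frame(km, stringsAsFactors = FALSE))
  level <- unname(pore$level_mean[kmer_str])
  sdv <- unname(pore$level_sd[kmer_str])
  # A methylated C at position m shifts every base whose k-mer window
  # covers m, i.e. positions m - max(off) .. m - min(off).
  shifted <- rep(FALSE, n)
  for (m in which(meth)) {
    lo <- max(1L, m - max(off)); hi <- min(n, m - min(off))
    shifted[lo:hi] <- TRUE
  }
  level[shifted] <- level[shifted] + pore$mod_shift
  list(level = level, sd = sdv)
}

# Inject basecall errors into a true read sequence. Returns the basecalled
# characters, the CIGAR op per emitted/deleted true base (in read
# orientation), and for each basecalled base the index of the true base whose
# signal it is attributed to.
inject_errors <- function(true_chars, sub_rate, ins_rate, del_rate) {
  n <- length(true_chars)
  u <- stats::runif(n)
  deleted <- u < del_rate
  subbed <- !deleted & u < del_rate + sub_rate
  emitted <- true_chars
  if (any(subbed)) {
    # Substitute with one of the three other bases, uniformly.
    shift <- sample.int(3L, sum(subbed), replace = TRUE)
    cur <- match(true_chars[subbed], DNA_BASES)
    emitted[subbed] <- DNA_BASES[((cur - 1L + shift) %% 4L) + 1L]
  }
  has_ins <- stats::runif(n) < ins_rate
  if (!any(deleted) && !any(has_ins)) {
    return(list(basecalls = emitted, ops = rep("M", n), src = seq_len(n)))
  }
  ins_base <- character(n)
  ins_base[has_ins] <- DNA_BASES[sample.int(4L, sum(has_ins), replace = TRUE)]
  # Interleave: per true position, an optional emitted base then an
  # optional inserted base.
  n_out <- (!deleted) + has_ins
  bc <- character(sum(n_out)); ops <- character(n + sum(has_ins))
  src <- integer(sum(n_out))
  bi <- 1L; oi <- 1L
  for (i in seq_len(n)) {
    if (deleted[i]) {
      ops[oi] <- "D"; oi <- oi + 1L
    } else {
      bc[bi] <- emitted[i]; src[bi] <- i; bi <- bi + 1L
      ops[oi] <- "M"; oi <- oi + 1L
    }
    if (has_ins[i]) {
      bc[bi] <- ins_base[i]; src[bi] <- i; bi <- bi + 1L
      ops[oi] <- "I"; oi <- oi + 1L
    }
  }
  list(basecalls = bc, ops = ops, src = src)
}

collapse_cigar <- function(ops) {
  r <- rle(ops)
  paste0(r$lengths, r$values, collapse = "")
}

#' Simulate one nanopore read
#'
#' Samples a read interval and strand, draws each CpG cytosine's methylation
#' state from the truth frequency, generates per-base dwells (shifted
#' geometric, minimum one stride step), Gaussian signal around the k-mer
#' levels (shifted where methylated), a stride-based move table, basecalls
#' with injected substitution/indel errors, and an alignment record whose
#' CIGAR reflects the injected indels.
#'
#' @param reference Reference DNA string.
#' @param truth Methylation truth tibble from [simulate_reference()].
#' @param pore A [build_pore_model()] object.
#' @param config A [sim_config()].
#' @param seed Integer seed for this read.
#' @param read_id Identifier; defaults to a seed-derived name.
#' @param interval Optional c(start, end) 0-based half-open forward-strand
#'   interval; drawn from the configured length distribution when `NULL`.
#' @param strand Optional "+" or "-"; random when `NULL`.
#' @return A `read_bundle`: list with `read_id`, `signal`, `stride`, `moves`,
#'   `basecalls`, `alignment` (contig, start, strand, cigar, mapq) and `meth`
#'   (tibble of this molecule's sampled per-CpG states, forward coordinates).
#' @export
simulate_read <- function(reference, truth, pore, config = sim_config(),
                          seed = 1L, read_id = NULL,
                          interval = NULL, strand = NULL) {
  n_ref <- nchar(reference)
  with_rng_seed(seed, {
    if (is.null(interval)) {
      len <- max(62L, min(n_ref, round(stats::rnorm(1, config$read_length_mean,
                                                    config$read_length_sd))))
      start <- sample.int(n_ref - len + 1L, 1L) - 1L
      interval <- c(start, start + len)
    }
    start <- as.integer(interval[1]); end <- as.integer(interval[2])
    if (end <= start || start < 0L || end > n_ref) {
      stop_invalid("read interval [%d, %d) is empty or outside the reference", start, end)
    }
    if (is.null(strand)) strand <- sample(c("+", "-"), 1L)
    if (is.null(read_id)) read_id <- sprintf("read_%d", seed)

    fwd <- substr(reference, start + 1L, end)
    read_seq <- if (strand == "+") fwd else revcomp(fwd)
    chars <- seq_chars(read_seq)
    L <- length(chars)

    # CpG cytosines in read orientation and their forward-strand coordinates.
    cg <- which(chars[-L] == "C" & chars[-1] == "G")  # 1-based read pos of C
    gpos <- if (strand == "+") start + cg - 1L else start + (L - cg)
    tt <- truth[truth$strand == strand, , drop = FALSE]
    freq <- tt$freq[match(gpos, tt$pos)]
    freq[is.na(freq)] <- 0
    state <- as.integer(stats::runif(length(cg)) < freq)
    meth <- rep(FALSE, L)
    meth[cg[state == 1L]] <- TRUE

    lv <- kmer_levels(chars, meth, pore)

    err <- inject_errors(chars, config$sub_rate, config$ins_rate, config$del_rate)
    nb <- length(err$basecalls)
    if (nb == 0L) stop_invalid("read reduced to zero basecalls")

    p_extra <- pore$stride / pore$dwell_mean
    dwell <- 1L + stats::rgeom(nb, p_extra)  # strides per basecalled base
    moves <- integer(sum(dwell))
    moves[cumsum(c(1L, dwell[-nb]))] <- 1L
    per_samp <- dwell * pore$stride
    mu <- rep(lv$level[err$src], per_samp)
    sdv <- rep(lv$sd[err$src], per_samp)
    signal <- stats::rnorm(length(mu), mu, sdv)

    alignment <- list(contig = config$contig, start = start, strand = strand,
                      cigar = collapse_cigar(err$ops), mapq = 60L)
    meth_tbl <- tibble::tibble(contig = config$contig, pos = gpos,
                               strand = strand, state = state)
    structure(list(
      read_id = read_id, signal = signal, stride = pore$stride,
      moves = moves, basecalls = paste(err$basecalls, collapse = ""),
      alignment = alignment, meth = meth_tbl
    ), class = "read_bundle")
  })
}

#' @export
print.read_bundle <- function(x, ...) {
  cat(sprintf("<read_bundle> %s: %d basecalls, %d signal samples (stride %d)%s\n",
              x$read_id, nchar(x$basecalls), length(x$signal), x$stride,
              if (is.null(x$alignment)) ", unaligned"
              else sprintf(", %s:%d%s", x$alignment$contig, x$alignment$start,
                           x$alignment$strand)))
  invisible(x)
}

#' Simulate bisulfite (WGBS-style) coverage records
#'
#' Per truth site, coverage is Poisson with the configured mean and the
#' methylated count is binomial with success probability
#' `freq * (1 - eps) + (1 - freq) * eps`, where `eps` is the bisulfite
#' conversion error rate.
#'
#' @param truth Truth tibble from [simulate_reference()].
#' @param config A [sim_config()] (uses `wgbs_mean_coverage`, `bs_epsilon`).
#' @param seed Integer seed.
#' @return A tibble of WGBS records: `contig`, `pos` (0-based), `strand`,
#'   `meth`, `unmeth`, `freq` (NA when coverage is zero).
#' @export
simulate_wgbs <- function(truth, config = sim_config(), seed = 1L) {
  if (config$wgbs_mean_coverage <= 0) stop_invalid("mean coverage must be > 0")
  with_rng_seed(seed, {
    n <- nrow(truth)
    cov <- stats::rpois(n, config$wgbs_mean_coverage)
    eps <- config$bs_epsilon
    p <- pmin(1, pmax(0, truth$freq * (1 - eps) + (1 - truth$freq) * eps))
    meth <- stats::rbinom(n, cov, p)
    tibble::tibble(
      contig = truth$contig, pos = truth$pos, strand = truth$strand,
      meth = meth, unmeth = cov - meth,
      freq = ifelse(cov > 0, meth / cov, NA_real_)
    )
  })
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: reference + truth, `n_reads` reads, and matched WGBS
#' coverage, all derived from the single seed in `config`.
#'
#' @param config A [sim_config()].
#' @param pore A [build_pore_model()]; a default model is built from the
#'   config seed when `NULL`.
#' @return List with `reference`, `truth`, `islands`, `reads` (list of
#'   `read_bundle`), `wgbs`, `pore`, `config`.
#' @export
simulate_dataset <- function(config = sim_config(), pore = NULL) {
  if (is.null(pore)) pore <- build_pore_model(seed = child_seed(config$seed, 2L))
  ref <- simulate_reference(config)
  reads <- lapply(seq_len(config$n_reads), function(i) {
    simulate_read(ref$sequence, ref$truth, pore, config,
                  seed = child_seed(config$seed, 100L + i),
                  read_id = sprintf("read_%04d", i))
  })
  wgbs <- simulate_wgbs(ref$truth, config, seed = child_seed(config$seed, 3L))
  list(reference = ref$sequence, truth = ref$truth, islands = ref$islands,
       reads = reads, wgbs = wgbs, pore = pore, config = config)
}
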