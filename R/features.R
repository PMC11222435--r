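# Feature extraction: convert a read bundle into per-CpG windowed examples
# (token window, signal-block matrix, window-relative reference/query
# indices) using the move table and, in reference-anchored mode, the CIGAR
# alignment.

#' Feature extraction configuration
#'
#' @param l Window length in bases (odd, >= 3; default 31).
#' @param b Samples per signal block (equal to the basecaller stride: 5 for
#'   4 kHz super-accurate models, 6 for 5 kHz).
#' @param mode "reference" anchors windows on the reference via the
#'   alignment (R9-style); "basecall" anchors on the basecalled sequence
#'   (R10-style).
#' @param min_mapq Minimum mapping quality in reference mode (default 60).
#' @param min_blocks_per_base,max_blocks_per_base Acceptable block count per
#'   window base: examples with fewer than `ceiling(0.5 * l)` or more than
#'   `5 * l` blocks are discarded.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(l = 31L, b = 5L,
                           mode = c("reference", "basecall"),
                           min_mapq = 60L,
                           min_blocks_per_base = 0.5,
                           max_blocks_per_base = 5) {
  l <- as.integer(l)
  if (l < 3L || l %% 2L == 0L) stop_invalid("`l` must be odd and >= 3")
  if (b < 1L) stop_invalid("`b` must be >= 1")
  structure(list(l = l, b = as.integer(b), mode = match.arg(mode),
                 min_mapq = as.integer(min_mapq),
                 min_blocks_per_base = min_blocks_per_base,
                 max_blocks_per_base = max_blocks_per_base),
            class = "feature_config")
}

#' Map move-table steps to basecalled-base indices
#'
#' Each move-table step covers `stride` raw samples; a 1 marks the start of
#' a new base. Returns, per step, the 0-based index of the basecalled base
#' the step's samples belong to (the cumulative sum of the moves minus one).
#'
#' @param moves Integer 0/1 vector with `moves[1] == 1`.
#' @param stride Samples per step (unused by the index arithmetic; kept for
#'   interface symmetry).
#' @return Integer vector of 0-based base indices, one per step.
#' @export
signal_to_base_index <- function(moves, stride = NULL) {
  if (length(moves) == 0L || moves[1] != 1L) {
    stop_invalid("move table must start with 1")
  }
  cumsum(moves) - 1L
}

#' Expand a CIGAR string into a reference coordinate per query base
#'
#' Walks the CIGAR (operations M, =, X, I, D, S, H) from `ref_start`,
#' producing for every query base its 0-based reference coordinate.
#' Inserted bases carry the previous reference coordinate and are flagged;
#' deletions advance the reference only; soft-clipped bases are emitted with
#' `NA` coordinates and flagged as clipped; hard clips consume nothing.
#'
#' @param cigar CIGAR string.
#' @param ref_start 0-based reference start of the alignment.
#' @return Tibble with `query` (0-based), `ref` (0-based or NA),
#'   `insertion`, `clipped`.
#' @export
reference_query_mapping <- function(cigar, ref_start = 0L) {
  m <- gregexpr("([0-9]+)([MIDNSHP=X])", cigar)[[1]]
  toks <- regmatches(cigar, list(m))[[1]]
  if (length(toks) == 0L || sum(attr(m, "match.length")) != nchar(cigar)) {
    stop_invalid("invalid CIGAR string: %s", cigar)
  }
  lens <- as.integer(sub("[MIDNSHP=X]$", "", toks))
  ops <- sub("^[0-9]+", "", toks)
  if (any(!ops %in% c("M", "=", "X", "I", "D", "S", "H"))) {
    stop_invalid("unsupported CIGAR operation in %s", cigar)
  }
  q <- integer(0); r <- integer(0); ins <- logical(0); clip <- logical(0)
  qi <- 0L; ri <- as.integer(ref_start)
  last_ref <- NA_integer_
  for (j in seq_along(ops)) {
    n <- lens[j]
    op <- ops[j]
    if (op %in% c("M", "=", "X")) {
      q <- c(q, qi + 0:(n - 1L)); r <- c(r, ri + 0:(n - 1L))
      ins <- c(ins, rep(FALSE, n)); clip <- c(clip, rep(FALSE, n))
      qi <- qi + n; ri <- ri + n; last_ref <- ri - 1L
    } else if (op == "I") {
      q <- c(q, qi + 0:(n - 1L)); r <- c(r, rep(last_ref, n))
      ins <- c(ins, rep(TRUE, n)); clip <- c(clip, rep(FALSE, n))
      qi <- qi + n
    } else if (op == "D" || op == "N") {
      ri <- ri + n; last_ref <- ri - 1L
    } else if (op == "S") {
      q <- c(q, qi + 0:(n - 1L)); r <- c(r, rep(NA_integer_, n))
      ins <- c(ins, rep(FALSE, n)); clip <- c(clip, rep(TRUE, n))
      qi <- qi + n
    }  # H consumes nothing
  }
  tibble::tibble(query = q, ref = r, insertion = ins, clipped = clip)
}

#' Find CpG sites on both strands of a sequence
#'
#' Forward-strand hits are reported at the 0-based index of the C of each
#' "CG" dinucleotide; reverse-strand hits at the following index (the C on
#' the minus strand). IUPAC ambiguity codes never match.
#'
#' @param sequence DNA string.
#' @return Tibble with `pos` (0-based C position on the reported strand,
#'   forward coordinates) and `strand`.
#' @export
find_cpg_sites <- function(sequence) {
  chars <- seq_chars(sequence)
  n <- length(chars)
  if (n < 2L) return(tibble::tibble(pos = integer(0), strand = character(0)))
  c_pos <- which(chars[-n] == "C" & chars[-1] == "G") - 1L
  tibble::tibble(
    pos = c(c_pos, c_pos + 1L),
    strand = rep(c("+", "-"), each = length(c_pos))
  )
}

#' Normalize a raw signal per read
#'
#' Median/MAD normalization: `(x - median(x)) / (1.4826 * mad)`. When the
#' MAD is zero the standard deviation is used instead; a constant signal
#' maps to all zeros.
#'
#' @param signal Non-empty numeric vector.
#' @return Normalized numeric vector.
#' @export
normalize_signal <- function(signal) {
  if (length(signal) == 0L) stop_invalid("signal must be non-empty")
  med <- stats::median(signal)
  scale <- stats::mad(signal, center = med)  # already scaled by 1.4826
  if (scale == 0) scale <- stats::sd(signal)
  if (is.na(scale) || scale == 0) return(rep(0, length(signal)))
  (signal - med) / scale
}

# Forward coordinate of read-orientation reference offset o (0-based within
# the aligned span).
ref_offset_to_forward <- function(o, start, ref_span, strand) {
  if (strand == "+") start + o else start + ref_span - 1L - o
}

#' Extract per-CpG site examples from a read bundle
#'
#' For every CpG site of the anchoring sequence (the aligned reference
#' subsequence in reference mode, the basecalls in basecall mode) whose
#' `l`-base window fits inside that sequence, emits one example: the token
#' window (in read orientation, so the assayed C always sits at the central
#' index followed by G), the matrix of all signal blocks whose anchoring
#' base falls in the window (each block contributing `b` normalized
#' samples), and window-relative reference (`r`, reference mode only) and
#' query (`q`) indices per block. Examples whose block count `s` falls
#' outside `[ceiling(0.5 l), 5 l]` are discarded and counted in the
#' `n_filtered` attribute; windows overlapping the sequence ends are
#' dropped (counted in `n_boundary`).
#'
#' @param bundle A `read_bundle`.
#' @param reference Reference DNA string (required in reference mode; used
#'   in basecall mode only to attach genomic coordinates when an alignment
#'   is present).
#' @param config A [feature_config()].
#' @return Tibble with one row per example: `read_id`, `contig`, `pos`,
#'   `strand`, `s`, list-columns `tokens` (integer vector over the 6-token
#'   vocabulary), `blocks` (s x b matrix), `r`, `q`, and `label` (this
#'   molecule's simulated state where known, else NA). Attributes
#'   `n_filtered` and `n_boundary` count discarded candidates.
#' @export
extract_examples <- function(bundle, reference = NULL,
                             config = feature_config()) {
  err <- validate_bundle(bundle)
  if (!is.null(err)) stop_invalid("invalid read bundle %s: %s", bundle$read_id, err)
  l <- config$l
  h <- (l - 1L) %/% 2L
  s_min <- ceiling(config$min_blocks_per_base * l)
  s_max <- config$max_blocks_per_base * l

  norm <- normalize_signal(bundle$signal)
  n_steps <- length(bundle$moves)
  block_q <- signal_to_base_index(bundle$moves)  # 0-based basecall index/step
  blocks_all <- matrix(norm[seq_len(n_steps * bundle$stride)],
                       nrow = n_steps, ncol = bundle$stride, byrow = TRUE)

  aln <- bundle$alignment
  if (config$mode == "reference") {
    if (is.null(aln)) {
      warning(sprintf("read %s skipped: reference mode requires an alignment",
                      bundle$read_id), call. = FALSE)
      return(empty_examples())
    }
    if (aln$mapq < config$min_mapq) {
      warning(sprintf("read %s skipped: mapping quality %d < %d",
                      bundle$read_id, aln$mapq, config$min_mapq), call. = FALSE)
      return(empty_examples())
    }
    if (is.null(reference)) stop_invalid("reference mode requires a reference sequence")
    map <- reference_query_mapping(aln$cigar, 0L)  # read-orientation offsets
    ref_span <- max(map$ref, na.rm = TRUE) + 1L
    fwd_sub <- substr(reference, aln$start + 1L, aln$start + ref_span)
    anchor_seq <- if (aln$strand == "+") fwd_sub else revcomp(fwd_sub)
    # Per move step: read-orientation reference offset of its base.
    qmap <- rep(NA_integer_, sum(bundle$moves))
    ok <- !map$clipped
    qmap[map$query[ok] + 1L] <- map$ref[ok]
    block_anchor <- qmap[block_q + 1L]
  } else {
    anchor_seq <- bundle$basecalls
    block_anchor <- block_q
    map <- NULL
    ref_span <- NA_integer_
  }

  anchor_chars <- seq_chars(anchor_seq)
  n_anchor <- length(anchor_chars)
  # CpG sites in read orientation of the anchoring sequence.
  cands <- which(anchor_chars[-n_anchor] == "C" & anchor_chars[-1] == "G") - 1L

  n_boundary <- 0L; n_filtered <- 0L
  nc <- length(cands)
  o_pos <- integer(nc); o_strand <- character(nc); o_s <- integer(nc)
  o_contig <- character(nc); o_label <- numeric(nc)
  o_tokens <- vector("list", nc); o_blocks <- vector("list", nc)
  o_r <- vector("list", nc); o_q <- vector("list", nc)
  keep <- logical(nc)
  meth <- bundle$meth
  for (ci in seq_along(cands)) {
    c0 <- cands[ci]
    w0 <- c0 - h
    if (w0 < 0L || w0 + l > n_anchor) { n_boundary <- n_boundary + 1L; next }
    in_win <- !is.na(block_anchor) & block_anchor >= w0 & block_anchor < w0 + l
    s <- sum(in_win)
    if (s < s_min || s > s_max) { n_filtered <- n_filtered + 1L; next }
    tokens <- bases_to_tokens(anchor_chars[(w0 + 1L):(w0 + l)])
    blocks <- blocks_all[in_win, , drop = FALSE]
    q_abs <- block_q[in_win]
    q_rel <- pmin(pmax(q_abs - q_abs[1], 0L), l - 1L)
    if (config$mode == "reference") {
      r_rel <- block_anchor[in_win] - w0
      strand <- aln$strand
      # Forward-strand coordinate of the assayed C.
      pos <- ref_offset_to_forward(c0, aln$start, ref_span, strand)
      contig <- aln$contig
    } else {
      r_rel <- NULL
      if (!is.null(aln)) {
        strand <- aln$strand
        rq <- reference_query_mapping(aln$cigar, 0L)
        ro <- rq$ref[match(c0, rq$query)]
        if (is.na(ro)) { n_boundary <- n_boundary + 1L; next }
        rsp <- max(rq$ref, na.rm = TRUE) + 1L
        pos <- ref_offset_to_forward(ro, aln$start, rsp, strand)
        contig <- aln$contig
      } else {
        strand <- "+"; pos <- c0; contig <- NA_character_
      }
    }
    label <- NA_real_
    if (!is.null(meth) && nrow(meth) > 0L) {
      hit <- which(meth$pos == pos & meth$strand == strand)
      if (length(hit) == 1L) label <- as.numeric(meth$state[hit])
    }
    keep[ci] <- TRUE
    o_pos[ci] <- as.integer(pos); o_strand[ci] <- strand; o_s[ci] <- s
    o_contig[ci] <- if (is.na(contig)) NA_character_ else contig
    o_label[ci] <- label
    o_tokens[[ci]] <- tokens; o_blocks[[ci]] <- blocks
    o_r[[ci]] <- r_rel; o_q[[ci]] <- q_rel
  }
  out <- if (!any(keep)) empty_examples() else tibble::tibble(
    read_id = bundle$read_id, contig = o_contig[keep], pos = o_pos[keep],
    strand = o_strand[keep], s = o_s[keep],
    tokens = o_tokens[keep], blocks = o_blocks[keep],
    r = o_r[keep], q = o_q[keep], label = o_label[keep]
  )
  attr(out, "n_boundary") <- n_boundary
  attr(out, "n_filtered") <- n_filtered
  out
}

empty_examples <- function() {
  tibble::tibble(read_id = character(0), contig = character(0),
                 pos = integer(0), strand = character(0), s = integer(0),
                 tokens = list(), blocks = list(), r = list(), q = list(),
                 label = numeric(0))
}

#' Extract examples from many bundles
#'
#' @param bundles List of `read_bundle` objects.
#' @param reference Reference DNA string.
#' @param config A [feature_config()].
#' @return Row-bound example tibble; attributes `n_boundary`/`n_filtered`
#'   are summed over reads.
#' @export
extract_examples_many <- function(bundles, reference = NULL,
                                  config = feature_config()) {
  parts <- lapply(bundles, extract_examples, reference = reference,
                  config = config)
  out <- dplyr::bind_rows(parts)
  attr(out, "n_boundary") <- sum(vapply(parts, attr, 0L, "n_boundary"))
  attr(out, "n_filtered") <- sum(vapply(parts, attr, 0L, "n_filtered"))
  out
}
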