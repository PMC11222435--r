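# Read-bundle ingestion and serialization. Two dialects are supported:
# a JSON-lines fixture format (one read per line) and a SAM text dialect
# carrying the move table in an `mv:B:c` tag with the raw signal in a
# tab-separated side file. FAST5/POD5 binary parsing is out of scope.

validate_bundle <- function(b) {
  if (is.null(b$moves) || length(b$moves) == 0L || b$moves[1] != 1L) {
    return("move table must start with 1")
  }
  if (sum(b$moves) != nchar(b$basecalls)) {
    return(sprintf("sum(moves) = %d but basecall length = %d",
                   sum(b$moves), nchar(b$basecalls)))
  }
  if (length(b$signal) != b$stride * length(b$moves)) {
    return(sprintf("signal length %d != stride %d x %d move steps",
                   length(b$signal), b$stride, length(b$moves)))
  }
  NULL
}

bundle_to_json <- function(b) {
  x <- list(
    read_id = b$read_id,
    stride = b$stride,
    moves = paste(b$moves, collapse = ""),
    basecalls = b$basecalls,
    signal = round(b$signal, 5)
  )
  if (!is.null(b$alignment)) {
    x$contig <- b$alignment$contig
    x$start <- b$alignment$start
    x$strand <- b$alignment$strand
    x$cigar <- b$alignment$cigar
    x$mapq <- b$alignment$mapq
  }
  if (!is.null(b$meth) && nrow(b$meth) > 0L) {
    x$meth <- list(pos = b$meth$pos, strand = b$meth$strand,
                   state = b$meth$state)
  }
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
}

json_to_bundle <- function(line) {
  x <- jsonlite::fromJSON(line, simplifyVector = TRUE)
  alignment <- NULL
  if (!is.null(x$contig)) {
    alignment <- list(contig = x$contig, start = as.integer(x$start),
                      strand = x$strand, cigar = x$cigar,
                      mapq = as.integer(x$mapq))
  }
  meth <- NULL
  if (!is.null(x$meth)) {
    meth <- tibble::tibble(contig = if (is.null(x$contig)) NA_character_ else x$contig,
                           pos = as.integer(x$meth$pos),
                           strand = as.character(x$meth$strand),
                           state = as.integer(x$meth$state))
  }
  structure(list(
    read_id = x$read_id,
    signal = as.numeric(x$signal),
    stride = as.integer(x$stride),
    moves = as.integer(strsplit(x$moves, "", fixed = TRUE)[[1]]),
    basecalls = x$basecalls,
    alignment = alignment,
    meth = meth
  ), class = "read_bundle")
}

#' Write read bundles as JSON lines
#'
#' @param bundles List of `read_bundle` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_read_bundles <- function(bundles, path) {
  lines <- vapply(bundles, bundle_to_json, character(1))
  writeLines(lines, path)
  invisible(path)
}

reverse_cigar <- function(cigar) {
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, list(m))[[1]]
  paste(rev(toks), collapse = "")
}

#' Write read bundles as SAM text with an `mv` tag and a signal side file
#'
#' Follows the SAM convention: minus-strand reads store the reverse
#' complement of the basecalls and a reference-orientation CIGAR (flag 16);
#' the move table and signal stay in signal (read) orientation in the
#' `mv:B:c` tag (stride first, as emitted by production basecallers) and in
#' the side file.
#'
#' @param bundles List of `read_bundle` objects.
#' @param sam_path Output SAM path.
#' @param signal_path Output signal side file (TSV: read_id, space-separated
#'   samples); defaults to `sam_path` with a `.signal.tsv` suffix.
#' @return `sam_path`, invisibly.
#' @export
write_sam_bundles <- function(bundles, sam_path,
                              signal_path = paste0(sam_path, ".signal.tsv")) {
  contigs <- unique(stats::na.omit(vapply(bundles, function(b) {
    if (is.null(b$alignment)) NA_character_ else b$alignment$contig
  }, character(1))))
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", contigs, 536870911L))
  recs <- vapply(bundles, function(b) {
    mv <- paste0("mv:B:c,", b$stride, ",", paste(b$moves, collapse = ","))
    if (is.null(b$alignment)) {
      flag <- 4L; rname <- "*"; pos <- 0L; mapq <- 0L; cigar <- "*"
      seq <- b$basecalls
    } else {
      a <- b$alignment
      minus <- identical(a$strand, "-")
      flag <- if (minus) 16L else 0L
      rname <- a$contig; pos <- a$start + 1L; mapq <- a$mapq
      cigar <- if (minus) reverse_cigar(a$cigar) else a$cigar
      seq <- if (minus) revcomp(b$basecalls) else b$basecalls
    }
    paste(b$read_id, flag, rname, pos, mapq, cigar, "*", 0L, 0L,
          seq, "*", mv, sep = "\t")
  }, character(1))
  writeLines(c(header, recs), sam_path)
  sig <- vapply(bundles, function(b) {
    paste(b$read_id, paste(round(b$signal, 5), collapse = " "), sep = "\t")
  }, character(1))
  writeLines(sig, signal_path)
  invisible(sam_path)
}

parse_sam_bundle <- function(fields, signal_map) {
  tags <- fields[-(1:11)]
  mv <- tags[startsWith(tags, "mv:B:c,")]
  if (length(mv) != 1L) return(list(err = "missing mv:B:c tag"))
  vals <- as.integer(strsplit(sub("^mv:B:c,", "", mv), ",", fixed = TRUE)[[1]])
  stride <- vals[1]; moves <- vals[-1]
  flag <- as.integer(fields[2])
  minus <- bitwAnd(flag, 16L) > 0L
  unmapped <- bitwAnd(flag, 4L) > 0L
  seq <- fields[10]
  basecalls <- if (minus) revcomp(seq) else seq
  alignment <- NULL
  if (!unmapped) {
    cigar <- fields[6]
    alignment <- list(contig = fields[3], start = as.integer(fields[4]) - 1L,
                      strand = if (minus) "-" else "+",
                      cigar = if (minus) reverse_cigar(cigar) else cigar,
                      mapq = as.integer(fields[5]))
  }
  signal <- signal_map[[fields[1]]]
  if (is.null(signal)) return(list(err = "no signal record for read"))
  list(bundle = structure(list(
    read_id = fields[1], signal = signal, stride = stride, moves = moves,
    basecalls = basecalls, alignment = alignment, meth = NULL
  ), class = "read_bundle"))
}

#' Load read bundles
#'
#' Reads either the JSON-lines dialect or the SAM + signal-side-file dialect
#' (sniffed from the extension unless `dialect` is given). Bundles violating
#' the move-table invariants (`sum(moves)` equal to the basecall length,
#' signal length equal to `stride * length(moves)`, leading move 1) are
#' skipped with a warning unless `strict = TRUE`, in which case loading
#' aborts. The number of skipped records is attached as attribute
#' `n_skipped`.
#'
#' @param path Input path (`.jsonl` or `.sam`).
#' @param dialect One of "auto", "jsonl", "sam".
#' @param signal_path Side file for the SAM dialect; defaults to
#'   `path` + `.signal.tsv`.
#' @param strict Abort on the first malformed record instead of skipping.
#' @return List of `read_bundle` objects with attribute `n_skipped`.
#' @export
load_read_bundles <- function(path, dialect = c("auto", "jsonl", "sam"),
                              signal_path = paste0(path, ".signal.tsv"),
                              strict = FALSE) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.sam$", path)) "sam" else "jsonl"
  }
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  n_skipped <- 0L
  out <- list()
  if (dialect == "jsonl") {
    lines <- readLines(path)
    for (i in seq_along(lines)) {
      if (!nzchar(lines[i])) next
      b <- tryCatch(json_to_bundle(lines[i]), error = function(e) NULL)
      msg <- if (is.null(b)) "unparseable JSON record" else validate_bundle(b)
      if (!is.null(msg)) {
        if (strict) stop_invalid("%s line %d: %s", path, i, msg)
        warning(sprintf("%s line %d skipped: %s", path, i, msg), call. = FALSE)
        n_skipped <- n_skipped + 1L
        next
      }
      out[[length(out) + 1L]] <- b
    }
  } else {
    if (!file.exists(signal_path)) stop_invalid("signal side file not found: %s", signal_path)
    sig_lines <- readLines(signal_path)
    signal_map <- list()
    for (sl in sig_lines) {
      parts <- strsplit(sl, "\t", fixed = TRUE)[[1]]
      signal_map[[parts[1]]] <- as.numeric(strsplit(parts[2], " ", fixed = TRUE)[[1]])
    }
    lines <- readLines(path)
    for (i in seq_along(lines)) {
      if (startsWith(lines[i], "@") || !nzchar(lines[i])) next
      fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      if (length(fields) < 12L) {
        if (strict) stop_invalid("%s line %d: too few SAM fields", path, i)
        warning(sprintf("%s line %d skipped: too few SAM fields", path, i),
                call. = FALSE)
        n_skipped <- n_skipped + 1L
        next
      }
      res <- parse_sam_bundle(fields, signal_map)
      msg <- if (!is.null(res$err)) res$err else validate_bundle(res$bundle)
      if (!is.null(msg)) {
        if (strict) stop_invalid("%s line %d: %s", path, i, msg)
        warning(sprintf("%s line %d skipped: %s", path, i, msg), call. = FALSE)
        n_skipped <- n_skipped + 1L
        next
      }
      out[[length(out) + 1L]] <- res$bundle
    }
  }
  attr(out, "n_skipped") <- n_skipped
  out
}
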