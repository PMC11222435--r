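# Tabular formats: Bismark coverage, BED tracks, read-call and site-record
# TSVs. Internal coordinates are 0-based half-open everywhere; the Bismark
# reader/writer is the sole 1-based boundary.

#' Load a Bismark coverage file
#'
#' Expects the 6-column coverage dialect: contig, 1-based start, 1-based end,
#' methylation percentage, methylated count, unmethylated count. Positions
#' are converted to 0-based and the frequency is recomputed from the counts
#' (the percentage column is ignored for arithmetic). Records with zero
#' total count are retained with `freq = NA` so downstream filters can drop
#' them explicitly.
#'
#' @param path Input TSV path.
#' @return Tibble with `contig`, `pos` (0-based), `meth`, `unmeth`, `freq`.
#' @export
load_bismark_coverage <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = c("character", "integer", "integer",
                                         "numeric", "integer", "integer"),
                          col.names = c("contig", "start", "end", "pct",
                                        "meth", "unmeth"))
  if (ncol(df) != 6L) stop_invalid("%s: expected 6 columns, got %d", path, ncol(df))
  total <- df$meth + df$unmeth
  tibble::tibble(
    contig = df$contig,
    pos = df$start - 1L,
    meth = df$meth,
    unmeth = df$unmeth,
    freq = ifelse(total > 0, df$meth / total, NA_real_)
  )
}

#' Write WGBS records in Bismark coverage format
#'
#' @param wgbs Tibble with `contig`, `pos` (0-based), `meth`, `unmeth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bismark_coverage <- function(wgbs, path) {
  total <- wgbs$meth + wgbs$unmeth
  pct <- ifelse(total > 0, 100 * wgbs$meth / total, 0)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d",
                   wgbs$contig, wgbs$pos + 1L, wgbs$pos + 1L,
                   format(pct, trim = TRUE, digits = 7),
                   wgbs$meth, wgbs$unmeth)
  writeLines(lines, path)
  invisible(path)
}

#' Load a BED interval track
#'
#' Accepts BED3+ input; intervals are 0-based half-open and returned sorted
#' per contig. A BED6 strand column is preserved when present.
#'
#' @param path Input BED path.
#' @param label Class label attached to every interval of this track.
#' @return Tibble with `contig`, `start`, `end`, `label`, `strand`.
#' @export
load_bed_track <- function(path, label = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 3L)) {
    stop_invalid("%s line %d: fewer than 3 BED columns", path, which(nfield < 3L)[1])
  }
  start <- as.integer(vapply(parts, `[`, character(1), 2L))
  end <- as.integer(vapply(parts, `[`, character(1), 3L))
  bad <- which(start >= end)
  if (length(bad) > 0L) {
    stop_invalid("%s line %d: start (%d) >= end (%d)", path, bad[1],
                 start[bad[1]], end[bad[1]])
  }
  strand <- rep(NA_character_, length(lines))
  has6 <- nfield >= 6L
  strand[has6] <- vapply(parts[has6], `[`, character(1), 6L)
  out <- tibble::tibble(
    contig = vapply(parts, `[`, character(1), 1L),
    start = start, end = end, label = label, strand = strand
  )
  dplyr::arrange(out, .data$contig, .data$start, .data$end)
}

#' Write per-read modification calls
#'
#' Fixed headered TSV (`read_id`, `contig`, `pos`, `strand`, `prob`) with
#' probabilities serialized to 6 decimals and deterministic
#' (contig, pos, strand, read_id) ordering.
#'
#' @param calls Read-call tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_read_calls <- function(calls, path) {
  calls <- dplyr::arrange(calls, .data$contig, .data$pos, .data$strand,
                          .data$read_id)
  lines <- c("read_id\tcontig\tpos\tstrand\tprob",
             sprintf("%s\t%s\t%d\t%s\t%.6f", calls$read_id, calls$contig,
                     calls$pos, calls$strand, calls$prob))
  writeLines(lines, path)
  invisible(path)
}

#' Load per-read modification calls
#' @param path Input TSV written by [write_read_calls()].
#' @return Read-call tibble.
#' @export
load_read_calls <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "integer",
                                         "character", "numeric"))
  tibble::as_tibble(df)
}

#' Write site-level methylation records
#'
#' Fixed headered TSV (`contig`, `pos`, `strand`, `coverage`, `n_mod`,
#' `frequency`) in deterministic (contig, pos, strand) order.
#'
#' @param sites Site-record tibble from [aggregate_sites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_records <- function(sites, path) {
  sites <- dplyr::arrange(sites, .data$contig, .data$pos, .data$strand)
  lines <- c("contig\tpos\tstrand\tcoverage\tn_mod\tfrequency",
             sprintf("%s\t%d\t%s\t%d\t%d\t%.6f", sites$contig, sites$pos,
                     sites$strand, sites$coverage, sites$n_mod,
                     sites$frequency))
  writeLines(lines, path)
  invisible(path)
}

#' Load site-level methylation records
#' @param path Input TSV written by [write_site_records()].
#' @return Site-record tibble.
#' @export
load_site_records <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "integer", "character",
                                         "integer", "integer", "numeric"))
  tibble::as_tibble(df)
}
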