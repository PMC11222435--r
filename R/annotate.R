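# Genomic-context annotation of CpG sites: genic precedence, repeat
# classes, CpG island/shore/shelf zones, GC-content buckets and singleton
# status. Interval overlap is delegated to IRanges.

overlaps_any <- function(pos, contig, track) {
  if (is.null(track) || nrow(track) == 0L) return(rep(FALSE, length(pos)))
  hit <- rep(FALSE, length(pos))
  for (ctg in unique(contig)) {
    sel <- contig == ctg
    tr <- track[track$contig == ctg, , drop = FALSE]
    if (nrow(tr) == 0L) next
    ir <- IRanges::IRanges(start = tr$start + 1L, end = tr$end)  # 1-based closed
    qr <- IRanges::IRanges(start = pos[sel] + 1L, width = 1L)
    hit[sel] <- IRanges::overlapsAny(qr, ir)
  }
  hit
}

# Expand a track by `w` bp on both sides (clamped at 0).
flank_track <- function(track, w) {
  dplyr::mutate(track, start = pmax(0L, .data$start - as.integer(w)),
                end = .data$end + as.integer(w))
}

#' Annotate sites with genomic contexts
#'
#' Adds, per site: a genic label with precedence promoter > exon > intron >
#' intergenic (promoters are TSS plus/minus the configured halo; introns
#' are genes minus exons); a repeat class with priority SINE > LINE > LTR >
#' DNA > Other; a CpG island zone (island from the track, shores the 2 kb
#' flanks, shelves the next 2 kb, island over shore over shelf); a GC
#' bucket (G+C fraction of the 5-base window centered on the site, mapped
#' to the smallest bucket of 20/40/60/80/100 percent at or above it); and
#' singleton status (no other CpG within 10 bp of the central C on either
#' strand). Missing tracks yield `NA` labels for their context rather than
#' fabricated values.
#'
#' @param sites Site tibble with `contig`, `pos`, `strand`.
#' @param tracks Named list of BED-track tibbles from [load_bed_track()]:
#'   `tss` (anchors; may carry strand), `genes`, `exons`, `islands`, and
#'   repeat tracks `sine`, `line`, `ltr`, `dna`, `other_repeat`. Any may be
#'   absent.
#' @param reference Reference DNA string (for GC content and singleton
#'   status); `NA` labels when NULL.
#' @param config An [eval_config()].
#' @return `sites` with added `genic`, `repeat_class`, `island_zone`,
#'   `gc_bucket`, `singleton` columns.
#' @export
annotate_contexts <- function(sites, tracks = list(), reference = NULL,
                              config = eval_config()) {
  n <- nrow(sites)
  pos <- sites$pos; contig <- sites$contig

  # Genic: promoter > exon > intron > intergenic.
  if (!is.null(tracks$tss) || !is.null(tracks$genes) || !is.null(tracks$exons)) {
    genic <- rep("intergenic", n)
    if (!is.null(tracks$genes) && !is.null(tracks$exons)) {
      in_gene <- overlaps_any(pos, contig, tracks$genes)
      in_exon <- overlaps_any(pos, contig, tracks$exons)
      genic[in_gene & !in_exon] <- "intron"
      genic[in_exon] <- "exon"
    } else if (!is.null(tracks$exons)) {
      genic[overlaps_any(pos, contig, tracks$exons)] <- "exon"
    }
    if (!is.null(tracks$tss)) {
      prom <- tibble::tibble(contig = tracks$tss$contig,
                             start = pmax(0L, tracks$tss$pos - config$promoter_halo),
                             end = tracks$tss$pos + config$promoter_halo + 1L)
      genic[overlaps_any(pos, contig, prom)] <- "promoter"
    }
  } else {
    genic <- rep(NA_character_, n)
  }

  # Repeats: first matching class in priority order.
  rep_tracks <- list(SINE = tracks$sine, LINE = tracks$line, LTR = tracks$ltr,
                     DNA = tracks$dna, Other = tracks$other_repeat)
  if (any(!vapply(rep_tracks, is.null, logical(1)))) {
    repeat_class <- rep("none", n)
    for (cl in rev(names(rep_tracks))) {  # assign low priority first
      if (is.null(rep_tracks[[cl]])) next
      repeat_class[overlaps_any(pos, contig, rep_tracks[[cl]])] <- cl
    }
  } else {
    repeat_class <- rep(NA_character_, n)
  }

  # CpG island zones: island beats shore beats shelf.
  if (!is.null(tracks$islands)) {
    zone <- rep("open_sea", n)
    shores <- flank_track(tracks$islands, config$shore_width)
    shelves <- flank_track(tracks$islands, config$shore_width + config$shelf_width)
    zone[overlaps_any(pos, contig, shelves)] <- "shelf"
    zone[overlaps_any(pos, contig, shores)] <- "shore"
    zone[overlaps_any(pos, contig, tracks$islands)] <- "island"
  } else {
    zone <- rep(NA_character_, n)
  }

  # GC bucket and singleton status need the reference sequence.
  if (!is.null(reference)) {
    chars <- seq_chars(reference)
    nref <- length(chars)
    hw <- config$gc_window %/% 2L
    gc_bucket <- vapply(pos, function(p) {
      lo <- max(1L, p + 1L - hw); hi <- min(nref, p + 1L + hw)
      g <- mean(chars[lo:hi] %in% c("C", "G"))
      buckets <- c(20, 40, 60, 80, 100)
      buckets[which(buckets >= 100 * g)[1]]
    }, numeric(1))

    cpg_c <- find_cpg_sites(reference)
    singleton <- vapply(seq_len(n), function(i) {
      others <- cpg_c$pos[cpg_c$pos != pos[i] &
                            abs(cpg_c$pos - pos[i]) <= config$singleton_halo]
      # The partner C of the same CpG dinucleotide does not break
      # singleton status; any other CpG within the halo does.
      partner <- if (sites$strand[i] == "+") pos[i] + 1L else pos[i] - 1L
      length(setdiff(others, partner)) == 0L
    }, logical(1))
  } else {
    gc_bucket <- rep(NA_real_, n)
    singleton <- rep(NA, n)
  }

  dplyr::mutate(sites, genic = genic, repeat_class = repeat_class,
                island_zone = zone, gc_bucket = gc_bucket,
                singleton = singleton)
}
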