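# Benchmarking framework: bisulfite truth filtering, confusion metrics and
# average precision, correlation, TSS profiles, coverage CCDF,
# confident-site comparison and filtering-bias analysis.

#' Evaluation configuration
#'
#' @param min_ont_coverage Minimum ONT site coverage for site-level and
#'   correlation evaluation (sites with coverage strictly above this value
#'   are kept, matching the "higher than 5x" rule).
#' @param wgbs_min_floor Floor of the WGBS lower coverage bound; the bound
#'   is `max(P5, wgbs_min_floor)` with `P5` the 5th coverage percentile.
#' @param partial_band Open frequency interval defining partially
#'   methylated sites, excluded from classification truth.
#' @param read_threshold Read-level probability threshold.
#' @param tss_bin_size Bin width for TSS profiles (125 for CTCF-style
#'   anchors).
#' @param promoter_halo Promoter half-width around a TSS.
#' @param shore_width,shelf_width CpG shore and shelf widths.
#' @param gc_window Window size for GC-content buckets.
#' @param singleton_halo Half-width of the singleton exclusion zone.
#' @param site_min_coverage Coverage below which a site is uncalled in the
#'   confident-site comparison.
#' @param expected_filter_rate Expected fraction of filtered calls in the
#'   high-filtering analysis.
#' @return A list of class `eval_config`.
#' @export
eval_config <- function(min_ont_coverage = 5L,
                        wgbs_min_floor = 5L,
                        partial_band = c(0.01, 0.99),
                        read_threshold = 0.5,
                        tss_bin_size = 50L,
                        promoter_halo = 2000L,
                        shore_width = 2000L, shelf_width = 2000L,
                        gc_window = 5L, singleton_halo = 10L,
                        site_min_coverage = 5L,
                        expected_filter_rate = 0.10) {
  structure(list(min_ont_coverage = as.integer(min_ont_coverage),
                 wgbs_min_floor = as.integer(wgbs_min_floor),
                 partial_band = partial_band,
                 read_threshold = read_threshold,
                 tss_bin_size = as.integer(tss_bin_size),
                 promoter_halo = as.integer(promoter_halo),
                 shore_width = as.integer(shore_width),
                 shelf_width = as.integer(shelf_width),
                 gc_window = as.integer(gc_window),
                 singleton_halo = as.integer(singleton_halo),
                 site_min_coverage = as.integer(site_min_coverage),
                 expected_filter_rate = expected_filter_rate),
            class = "eval_config")
}

#' Filter WGBS records into a truth site set
#'
#' For classification, drops sites with coverage below `max(P5, 5)` (P5 is
#' the nearest-rank 5th percentile of the coverage distribution) and sites
#' with frequency strictly inside the partial-methylation band, then labels
#' the survivors positive (frequency at or above the band's upper edge) or
#' negative. For correlation, applies the lower bound, additionally drops
#' coverage above the 95th percentile, and keeps partially methylated
#' sites.
#'
#' @param wgbs WGBS tibble (`contig`, `pos`, optional `strand`, `meth`,
#'   `unmeth`, `freq`).
#' @param config An [eval_config()].
#' @param purpose "classification" or "correlation".
#' @return Filtered tibble with `coverage` and, for classification, a
#'   logical `positive` column.
#' @export
filter_truth <- function(wgbs, config = eval_config(),
                         purpose = c("classification", "correlation")) {
  purpose <- match.arg(purpose)
  if (nrow(wgbs) == 0L) {
    warning("empty WGBS input; empty truth set", call. = FALSE)
    return(dplyr::mutate(wgbs, coverage = integer(0)))
  }
  wgbs <- dplyr::mutate(wgbs, coverage = .data$meth + .data$unmeth)
  p5 <- nearest_rank(wgbs$coverage, 0.05)
  lower <- max(p5, config$wgbs_min_floor)
  out <- dplyr::filter(wgbs, .data$coverage >= lower, !is.na(.data$freq))
  if (purpose == "classification") {
    band <- config$partial_band
    out <- dplyr::filter(out, .data$freq <= band[1] | .data$freq >= band[2])
    out <- dplyr::mutate(out, positive = .data$freq >= band[2])
  } else {
    p95 <- nearest_rank(wgbs$coverage, 0.95)
    out <- dplyr::filter(out, .data$coverage <= p95)
  }
  out
}

#' Confusion-matrix metrics with average precision
#'
#' Standard definitions with methylated as the positive class: accuracy,
#' precision, recall, false-positive rate, F1, and average precision
#' computed as `sum((R_k - R_{k-1}) * P_k)` over the ranked score sweep.
#'
#' @param scores Numeric prediction scores (read probabilities or site
#'   frequencies).
#' @param truth Logical (or 0/1) ground-truth labels.
#' @param threshold Score threshold for the binary metrics.
#' @return Tibble of class `metrics_report` with one row: TP, FP, TN, FN,
#'   accuracy, precision, recall, fpr, f1, average_precision, n.
#' @export
confusion_metrics <- function(scores, truth, threshold = 0.5) {
  if (length(scores) == 0L) stop_invalid("no prediction/truth pairs to evaluate")
  truth <- as.logical(truth)
  pred <- scores > threshold
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  tn <- sum(!pred & !truth); fn <- sum(!pred & truth)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  fpr <- if (fp + tn > 0) fp / (fp + tn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) {
    2 * prec * rec / (prec + rec)
  } else NA_real_
  out <- tibble::tibble(
    TP = tp, FP = fp, TN = tn, FN = fn,
    accuracy = (tp + tn) / length(truth),
    precision = prec, recall = rec, fpr = fpr, f1 = f1,
    average_precision = average_precision(scores, truth),
    n = length(truth)
  )
  class(out) <- c("metrics_report", class(out))
  out
}

#' Average precision over the ranked score sweep
#'
#' @param scores Numeric scores.
#' @param truth Logical labels.
#' @return `sum((R_k - R_{k-1}) * P_k)` with precision/recall evaluated at
#'   each distinct score threshold, descending.
#' @export
average_precision <- function(scores, truth) {
  truth <- as.logical(truth)
  n_pos <- sum(truth)
  if (n_pos == 0L) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  t_sorted <- truth[ord]
  s_sorted <- scores[ord]
  tp <- cumsum(t_sorted)
  k <- seq_along(t_sorted)
  # Evaluate only at the last index of each tied-score run.
  last <- c(s_sorted[-1] != s_sorted[-length(s_sorted)], TRUE)
  prec <- tp[last] / k[last]
  rec <- tp[last] / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Pearson correlation between ONT and WGBS site frequencies
#'
#' Intersects site records (ONT coverage strictly greater than the
#' configured minimum) with correlation-filtered WGBS truth and computes
#' Pearson's r on the paired frequencies.
#'
#' @param sites Site-record tibble from [aggregate_sites()].
#' @param wgbs WGBS tibble.
#' @param config An [eval_config()].
#' @return List with `r`, `n`.
#' @export
correlate_sites <- function(sites, wgbs, config = eval_config()) {
  truth <- filter_truth(wgbs, config, "correlation")
  sites <- dplyr::filter(sites, .data$coverage > config$min_ont_coverage)
  by_cols <- intersect(c("contig", "pos", "strand"), names(truth))
  paired <- dplyr::inner_join(sites, truth, by = by_cols,
                              suffix = c("_ont", "_wgbs"))
  if (nrow(paired) < 2L) {
    warning("fewer than 2 paired sites; correlation undefined", call. = FALSE)
    return(list(r = NA_real_, n = nrow(paired)))
  }
  list(r = stats::cor(paired$frequency, paired$freq, method = "pearson"),
       n = nrow(paired))
}

#' Methylation profile in binned distance from anchors
#'
#' Assigns each site to `bin = floor((pos - P + floor(B/2)) / B)` relative
#' to its nearest anchor `P`; minus-strand anchors have their offsets
#' negated first so upstream is consistently negative. Sites with ONT
#' coverage below 3 or WGBS coverage below 5 at the same position are
#' excluded (per-tool filtering; no cross-tool intersection). Reports the
#' per-bin mean frequency.
#'
#' @param sites Site-record tibble.
#' @param anchors Tibble with `contig`, `pos`, `strand` (TSS or similar).
#' @param wgbs Optional WGBS tibble enforcing the 5x truth-coverage filter.
#' @param config An [eval_config()] (uses `tss_bin_size`).
#' @param max_offset Maximum absolute signed distance retained.
#' @param min_ont_cov,min_wgbs_cov Per-tool coverage filters.
#' @return Tibble with `bin`, `offset` (bin center in bp), `mean_freq`, `n`.
#' @export
tss_profile <- function(sites, anchors, wgbs = NULL, config = eval_config(),
                        max_offset = 2000L, min_ont_cov = 3L,
                        min_wgbs_cov = 5L) {
  B <- config$tss_bin_size
  if (B <= 0L) stop_invalid("bin size must be positive")
  sites <- dplyr::filter(sites, .data$coverage >= min_ont_cov)
  if (!is.null(wgbs)) {
    keep <- dplyr::filter(wgbs, .data$meth + .data$unmeth >= min_wgbs_cov)
    by_cols <- intersect(c("contig", "pos", "strand"), names(keep))
    sites <- dplyr::semi_join(sites, keep, by = by_cols)
  }
  rows <- list()
  for (a in seq_len(nrow(anchors))) {
    anc <- anchors[a, ]
    near <- dplyr::filter(sites, .data$contig == anc$contig,
                          abs(.data$pos - anc$pos) <= max_offset)
    if (nrow(near) == 0L) next
    off <- near$pos - anc$pos
    if (identical(anc$strand, "-")) off <- -off
    rows[[length(rows) + 1L]] <- tibble::tibble(
      bin = floor((off + B %/% 2L) / B), frequency = near$frequency)
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(bin = integer(0), offset = numeric(0),
                          mean_freq = numeric(0), n = integer(0)))
  }
  dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean_freq = mean(.data$frequency), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(offset = .data$bin * B) |>
    dplyr::select("bin", "offset", "mean_freq", "n") |>
    dplyr::arrange(.data$bin)
}

#' Complementary CDF of per-site calling coverage
#'
#' `ccdf(cov) = N_{>= cov} / N_sites` for every integer coverage from 0 to
#' the maximum observed.
#'
#' @param coverages Nonnegative integer per-site coverages.
#' @param n_sites Total number of sites in the universe (defaults to
#'   `length(coverages)`).
#' @return Tibble with `coverage`, `ccdf` (nonincreasing; `ccdf(0) = 1`
#'   when `n_sites == length(coverages)`).
#' @export
coverage_ccdf <- function(coverages, n_sites = length(coverages)) {
  if (n_sites == 0L) stop_invalid("CCDF undefined for zero sites")
  if (any(coverages < 0)) stop_invalid("coverages must be nonnegative")
  cov <- 0:max(coverages, 0L)
  n_ge <- vapply(cov, function(cv) sum(coverages >= cv), numeric(1))
  tibble::tibble(coverage = cov, ccdf = n_ge / n_sites)
}

#' Strand-specific sequencing coverage
#'
#' Total sequenced bases divided by twice the genome size (one factor of
#' two for the two strands).
#'
#' @param n_bases Total sequenced bases.
#' @param genome_size Genome size in bases.
#' @return Scalar coverage.
#' @export
strand_specific_coverage <- function(n_bases, genome_size) {
  n_bases / (2 * genome_size)
}

# Classify one tool's site set into positive / negative / uncalled.
site_class <- function(sites, universe, min_cov) {
  cls <- rep("uncalled", nrow(universe))
  by_cols <- intersect(c("contig", "pos", "strand"), names(sites))
  m <- dplyr::left_join(universe, sites, by = by_cols)
  called <- !is.na(m$coverage) & m$coverage >= min_cov
  cls[called & m$frequency > 0.5] <- "positive"
  cls[called & m$frequency <= 0.5] <- "negative"
  cls
}

#' Compare confident site calls between two methods
#'
#' A site is positive for a method if its coverage is at least 5 with a
#' methylation frequency strictly above 50%, negative if coverage is at
#' least 5 with frequency at or below 50%, and uncalled below 5x coverage.
#' Evaluated sites fall into three categories per class: concordant calls,
#' discordant calls where the target method is supported by at least one
#' support set, and unique calls where the other method is uncalled.
#'
#' @param sites_a,sites_b Site-record tibbles for the two methods (e.g.
#'   nanopore calls and WGBS restated as site records).
#' @param support Optional list of site-record tibbles from additional
#'   methods used as support for discordant calls.
#' @param config An [eval_config()] (uses `site_min_coverage`).
#' @return Tibble with `class` (positive/negative) and counts `concordant`,
#'   `discordant_a_supported`, `discordant_b_supported`,
#'   `discordant_unsupported`, `unique_a`, `unique_b`; attributes
#'   `n_universe`, `n_uncalled_both`, `n_discordant` let callers verify
#'   that the categories partition the evaluated site set.
#' @export
confident_site_comparison <- function(sites_a, sites_b, support = list(),
                                      config = eval_config()) {
  mc <- config$site_min_coverage
  key_cols <- c("contig", "pos", "strand")
  universe <- dplyr::distinct(dplyr::bind_rows(
    dplyr::select(sites_a, dplyr::all_of(key_cols)),
    dplyr::select(sites_b, dplyr::all_of(key_cols))))
  a <- site_class(sites_a, universe, mc)
  b <- site_class(sites_b, universe, mc)
  sup <- lapply(support, site_class, universe = universe, min_cov = mc)
  sup_has <- function(cls) {
    if (length(sup) == 0L) rep(FALSE, nrow(universe))
    else Reduce(`|`, lapply(sup, function(sc) sc == cls))
  }
  out <- lapply(c("positive", "negative"), function(cl) {
    tibble::tibble(
      class = cl,
      concordant = sum(a == cl & b == cl),
      discordant_a_supported = sum(a == cl & b != cl & b != "uncalled" & sup_has(cl)[seq_len(nrow(universe))]),
      discordant_b_supported = sum(b == cl & a != cl & a != "uncalled" & sup_has(cl)),
      discordant_unsupported = sum(((a == cl & b != cl & b != "uncalled") |
                                      (b == cl & a != cl & a != "uncalled")) &
                                     !sup_has(cl)),
      unique_a = sum(a == cl & b == "uncalled"),
      unique_b = sum(b == cl & a == "uncalled")
    )
  })
  out <- dplyr::bind_rows(out)
  attr(out, "n_universe") <- nrow(universe)
  attr(out, "n_uncalled_both") <- sum(a == "uncalled" & b == "uncalled")
  attr(out, "n_discordant") <- sum(a != b & a != "uncalled" & b != "uncalled")
  out
}

#' Classify sites by the effect of read-level filtering
#'
#' A position is `missing-low-overall` if its overall coverage (valid plus
#' filtered calls) is below 5, `missing-due-to-filtering` if its valid
#' coverage is below 5 but overall coverage is at least 5,
#' `high-filtering` if valid coverage is at least 5 but the number of
#' filtered calls exceeds the expected fraction (10%) of the overall
#' coverage, and `ok` otherwise.
#'
#' @param overall Integer overall coverage per site.
#' @param valid Integer valid (unfiltered) coverage per site.
#' @param config An [eval_config()] (uses `expected_filter_rate`,
#'   `site_min_coverage`).
#' @return Character vector of classes.
#' @export
high_filtering_analysis <- function(overall, valid, config = eval_config()) {
  if (any(valid > overall)) stop_invalid("valid coverage exceeds overall coverage")
  if (any(valid < 0)) stop_invalid("coverages must be nonnegative")
  mc <- config$site_min_coverage
  rate <- config$expected_filter_rate
  cls <- rep("ok", length(overall))
  cls[overall < mc] <- "missing-low-overall"
  cls[overall >= mc & valid < mc] <- "missing-due-to-filtering"
  hf <- valid >= mc & (overall - valid) > rate * overall
  cls[hf] <- "high-filtering"
  cls
}
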