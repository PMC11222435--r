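# Inference over reads and unfiltered site-level aggregation.

#' Call per-read CpG modification probabilities
#'
#' Extracts site examples from each bundle and applies the model; every
#' emitted example yields one call (no confidence filtering). Probabilities
#' are `sigmoid(z)` of the modification logit.
#'
#' @param model A trained `sigmeth_model`.
#' @param bundles List of `read_bundle` objects.
#' @param reference Reference DNA string (required for reference-anchored
#'   feature extraction).
#' @param config A [feature_config()]; its window length and block width
#'   must match the model configuration.
#' @return Read-call tibble: `read_id`, `contig`, `pos` (0-based
#'   forward-strand position of the assayed C), `strand`, `prob`, `label`
#'   (simulated molecule state where known).
#' @export
call_reads <- function(model, bundles, reference = NULL,
                       config = feature_config()) {
  if (config$l != model$config$l || config$b != model$config$b) {
    stop_invalid("feature config (l=%d, b=%d) does not match model (l=%d, b=%d)",
                 config$l, config$b, model$config$l, model$config$b)
  }
  ex <- extract_examples_many(bundles, reference, config)
  if (nrow(ex) == 0L) {
    return(tibble::tibble(read_id = character(0), contig = character(0),
                          pos = integer(0), strand = character(0),
                          prob = numeric(0), label = numeric(0)))
  }
  ex$prob <- predict_examples(model, ex)
  dplyr::select(ex, "read_id", "contig", "pos", "strand", "prob", "label")
}

#' Aggregate read calls into site records
#'
#' Groups calls by (contig, position, strand) — plus and minus strand sites
#' are kept separate — and reports coverage, the number of calls with
#' probability strictly above the threshold, and their ratio. Every covered
#' site is emitted; no minimum-coverage filter is applied here. A call at
#' exactly the threshold counts as unmethylated.
#'
#' @param calls Read-call tibble from [call_reads()].
#' @param threshold Methylation probability threshold in (0, 1).
#' @return Site-record tibble: `contig`, `pos`, `strand`, `coverage`,
#'   `n_mod`, `frequency`.
#' @export
aggregate_sites <- function(calls, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) {
    stop_invalid("`threshold` must lie strictly inside (0, 1)")
  }
  calls |>
    dplyr::group_by(.data$contig, .data$pos, .data$strand) |>
    dplyr::summarise(coverage = dplyr::n(),
                     n_mod = sum(.data$prob > threshold),
                     .groups = "drop") |>
    dplyr::mutate(frequency = .data$n_mod / .data$coverage) |>
    dplyr::arrange(.data$contig, .data$pos, .data$strand)
}
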