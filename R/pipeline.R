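# End-to-end convenience: simulate -> extract -> train -> call ->
# aggregate -> evaluate from one seeded configuration.

#' Run the full pipeline on simulated data
#'
#' Simulates a dataset, extracts labeled examples, splits reads into
#' training and held-out sets, trains a model, calls the held-out reads,
#' aggregates sites and evaluates against the simulated bisulfite truth.
#' Every stage derives its randomness from `sim$seed`.
#'
#' @param sim A [sim_config()].
#' @param pore A [build_pore_model()]; defaults from the sim seed.
#' @param fcfg A [feature_config()].
#' @param mcfg A [model_config()] (window and block width must match `fcfg`).
#' @param tcfg A [train_config()].
#' @param ecfg An [eval_config()].
#' @param holdout_frac Fraction of reads held out for calling/evaluation.
#' @return List with `model`, `examples_train`, `calls`, `sites`,
#'   `read_metrics`, `site_metrics`, `correlation`, `dataset`.
#' @export
run_pipeline <- function(sim = sim_config(), pore = NULL,
                         fcfg = feature_config(),
                         mcfg = model_config(l = fcfg$l, b = fcfg$b),
                         tcfg = train_config(seed = sim$seed),
                         ecfg = eval_config(),
                         holdout_frac = 0.25) {
  ds <- simulate_dataset(sim, pore)
  n_hold <- max(1L, round(holdout_frac * length(ds$reads)))
  hold_idx <- with_rng_seed(child_seed(sim$seed, 9L),
                            sample.int(length(ds$reads), n_hold))
  train_reads <- ds$reads[-hold_idx]
  hold_reads <- ds$reads[hold_idx]

  ex_train <- extract_examples_many(train_reads, ds$reference, fcfg)
  model <- new_model(mcfg, seed = child_seed(sim$seed, 10L))
  model <- train(model, ex_train, tcfg)

  calls <- call_reads(model, hold_reads, ds$reference, fcfg)
  sites <- aggregate_sites(calls, threshold = 0.5)

  read_metrics <- NULL
  labeled <- calls[!is.na(calls$label), , drop = FALSE]
  if (nrow(labeled) > 0L) {
    read_metrics <- confusion_metrics(labeled$prob, labeled$label == 1,
                                      threshold = ecfg$read_threshold)
  }

  truth_cls <- filter_truth(ds$wgbs, ecfg, "classification")
  paired <- dplyr::inner_join(
    dplyr::filter(sites, .data$coverage > ecfg$min_ont_coverage),
    truth_cls, by = c("contig", "pos", "strand"))
  site_metrics <- NULL
  if (nrow(paired) > 0L && length(unique(paired$positive)) > 0L) {
    site_metrics <- confusion_metrics(paired$frequency, paired$positive,
                                      threshold = 0.5)
  }
  correlation <- correlate_sites(sites, ds$wgbs, ecfg)

  list(model = model, examples_train = ex_train, calls = calls,
       sites = sites, read_metrics = read_metrics,
       site_metrics = site_metrics, correlation = correlation,
       dataset = ds)
}
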