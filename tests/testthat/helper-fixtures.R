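# Shared fixtures. Heavy artifacts (the trained tiny model and its data)
# are built once per test run and memoised here.

.fixture_cache <- new.env(parent = emptyenv())

# Frozen desk-scale study conditions: a 2-mer pore model whose methylation
# shift equals twice the per-sample noise sd, ~9 samples per base at stride
# 5, and a 9-base window.
recovery_pore <- function(mod_shift = 0.5) {
  build_pore_model(k = 2, mod_shift = mod_shift, seed = 21,
                   level_sd = 0.25, dwell_mean = 9, stride = 5)
}

recovery_sim_config <- function(seed = 5) {
  sim_config(ref_length = 20000, n_reads = 700, read_length_mean = 2000,
             read_length_sd = 300, seed = seed)
}

recovery_feature_config <- function() feature_config(l = 9, b = 5, mode = "reference")

tiny_model_config <- function(f = 64L, H = 4L, L_enc = 2L, L_dec = 2L) {
  model_config(f = f, H = H, L_enc = L_enc, L_dec = L_dec, d_ff = 2L * f,
               b = 5L, l = 9L, K = 16L, dropout = 0)
}

# Simulate + extract + split for a given pore model.
recovery_dataset <- function(pore, seed = 5) {
  ds <- simulate_dataset(recovery_sim_config(seed), pore)
  ex <- extract_examples_many(ds$reads, ds$reference, recovery_feature_config())
  idx <- with_seed_local(99, sample(nrow(ex)))
  n_test <- 2000L
  list(ds = ds,
       train = ex[idx[seq_len(min(20000L, nrow(ex) - n_test))], ],
       test = ex[idx[(nrow(ex) - n_test + 1L):nrow(ex)], ])
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# The trained tiny model (2+2 layers, f=64, H=4) on separable simulation:
# the single expensive fixture, shared by the recovery, auxiliary-task and
# distillation checks.
get_recovery_fit <- function() {
  hit <- .fixture_cache$recovery_fit
  if (!is.null(hit)) return(hit)
  data <- recovery_dataset(recovery_pore(0.5))
  model <- new_model(tiny_model_config(), seed = 7)
  tc <- train_config(epochs = 7, batch_size = 64, lr = 2e-3, alpha = 1,
                     seed = 3)
  model <- train(model, data$train, tc)
  fit <- list(model = model, train = data$train, test = data$test,
              ds = data$ds)
  .fixture_cache$recovery_fit <- fit
  fit
}

# A small random example for model-level tests.
random_example <- function(seed, l = 7L, b = 3L, s_range = 5:9) {
  with_seed_local(seed, {
    s <- if (length(s_range) == 1L) s_range else sample(s_range, 1)
    list(tokens = {
      tk <- sample(1:4, l, replace = TRUE)
      tk[l %/% 2 + 1] <- 2L; tk[l %/% 2 + 2] <- 3L
      tk
    },
    blocks = matrix(rnorm(s * b), s, b),
    r = sort(sample(0:(l - 1), s, replace = TRUE)),
    q = sort(sample(0:(l - 1), s, replace = TRUE)))
  })
}

# Build a BED track tibble from literal lines.
load_bed_local <- function(..., label = "trk") {
  path <- tempfile(fileext = ".bed")
  writeLines(c(...), path)
  on.exit(unlink(path))
  load_bed_track(path, label = label)
}
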