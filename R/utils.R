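# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# Token vocabulary: 4 canonical bases + unknown + mask.
TOKEN_LEVELS <- c("A", "C", "G", "T", "[UNK]", "[MASK]")
TOK_A <- 1L; TOK_C <- 2L; TOK_G <- 3L; TOK_T <- 4L
TOK_UNK <- 5L; TOK_MASK <- 6L

#' Reverse complement of a DNA string
#'
#' Ambiguity codes other than A/C/G/T are preserved through `chartr` where a
#' complement is defined and left untouched otherwise.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTacgtNn", "TGCAtgcaNn", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""),
         character(1))
}

# Split a DNA string into a character vector of single bases.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Map base characters to token ids; anything non-ACGT becomes [UNK].
bases_to_tokens <- function(chars) {
  idx <- match(chars, DNA_BASES)
  idx[is.na(idx)] <- TOK_UNK
  idx
}

tokens_to_bases <- function(tokens) TOKEN_LEVELS[tokens]

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_rng_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Derive a child seed from a base seed and an index, kept inside 32-bit range.
child_seed <- function(seed, index) {
  (as.numeric(seed) * 1000003 + as.numeric(index) * 7919) %% 2147483629
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

# Nearest-rank percentile (deterministic, used by the evaluation filters).
nearest_rank <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  if (n == 0L) return(NA_real_)
  x[max(1L, ceiling(p * n))]
}
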