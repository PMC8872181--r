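# Small internal helpers.

# Reverse complement of a plain character DNA string (keeps N).
.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Sample `n` iid bases with the given A/C/G/T frequencies.
.draw_bases <- function(n, freqs) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = freqs)
}

.stopifnot_scalar_int <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x)) {
    stop(sprintf("'%s' must be a single integer", name))
  }
  as.integer(x)
}
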