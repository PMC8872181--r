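# Small in-code fixtures shared across test files.

# sample() from a vector without the scalar-x pitfall
pick <- function(v) v[sample.int(length(v), 1L)]

# A minimal annotated record: one H-strand PCG, one L-strand tRNA, a CR.
tiny_record <- function(pcg_seq = "ATGAAATAA") {
  n_pcg <- nchar(pcg_seq)
  trna <- paste(rep("ACGT", 18L), collapse = "")          # 72 bp
  cr <- paste(rep("TTAC", 60L), collapse = "")            # 240 bp
  genome <- paste0(pcg_seq, trna, cr)
  feats <- rbind(
    gene_feature("ND1", 0L, n_pcg, 1L),
    gene_feature("tRNA-Gln", n_pcg, n_pcg + 72L, -1L),
    gene_feature("CR", n_pcg + 72L, nchar(genome), 1L)
  )
  mitogenome_record("TINY", genome, feats)
}

# Hotspot token vectors of the shipped arrangement types.
hotspots <- list(
  typical = c("tRNA-Pro", "CR", "tRNA-Phe"),
  V = c("CR", "tRNA-Pro", "tRNA-Phe", "CR"),
  IX = c("CR", "tRNA-Phe", "tRNA-Pro", "CR", "tRNA-Phe", "CR")
)

# Random DNA string.
random_dna <- function(n, freqs = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = freqs),
        collapse = "")
}

# A random valid 1- or 2-event TDRL scenario starting from the
# ancestral P-CR-F hotspot (suitable for generate_record()).
random_hotspot_scenario <- function(max_len = 8L) {
  start <- c("tRNA-Pro", "CR", "tRNA-Phe")
  n_events <- sample(1:2, 1L)
  events <- list()
  cur <- start
  for (e in seq_len(n_events)) {
    repeat {
      n <- length(cur)
      i <- pick(seq_len(n)); j <- pick(i:n)
      d <- n + (j - i + 1L)
      min_loss <- max(0L, d - max_len)
      k <- pick(min_loss:(d - 1L))
      losses <- if (k > 0L) sort(sample(d, k)) else integer()
      ev <- tdrl_event(c(i, j), losses)
      res <- tryCatch(apply_tdrl_event(cur, ev), error = function(err) NULL)
      if (!is.null(res)) { cur <- res; events[[e]] <- ev; break }
    }
  }
  tdrl_scenario(start, events)
}

# A random valid 1- or 2-event TDRL scenario from a random segment,
# keeping every intermediate segment small enough to search.
random_tdrl_instance <- function(max_len = 8L) {
  pool <- c("tRNA-Pro", "CR", "tRNA-Phe", "tRNA-Thr", "CR")
  seg <- sample(pool, sample(3:5, 1L), replace = TRUE)
  n_events <- sample(1:2, 1L)
  events <- list()
  cur <- seg
  for (e in seq_len(n_events)) {
    repeat {
      n <- length(cur)
      i <- pick(seq_len(n)); j <- pick(i:n)
      d <- n + (j - i + 1L)
      min_loss <- max(0L, d - max_len)
      k <- pick(min_loss:(d - 1L))
      losses <- if (k > 0L) sort(sample(d, k)) else integer()
      ev <- tdrl_event(c(i, j), losses)
      res <- tryCatch(apply_tdrl_event(cur, ev), error = function(err) NULL)
      if (!is.null(res)) { cur <- res; events[[e]] <- ev; break }
    }
  }
  list(scenario = tdrl_scenario(seg, events), end = cur,
       n_events = n_events)
}
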