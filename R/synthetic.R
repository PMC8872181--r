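# Seeded synthetic mitogenome generator with ground-truth manifests.
#
# The generator lays the canonical vertebrate gene order out on a
# circle starting at rrnS, replaces the tRNA-Thr..rrnS hotspot with the
# segment produced by a TDRL scenario (or a named arrangement), fills
# the sequence with iid draws from the requested base frequencies, and
# then enforces the biological constraints the statistics modules care
# about: start and stop codons per gene (complete or polyadenylation-
# completed), the CSB1 motif in every control region, light-strand
# genes reverse-complemented in place, and a 13 bp ND5/ND6 overlap.

.CSB1 <- "CTTTTCATGCTCAGTAGACATA"

# default per-PCG lengths (bp); lengths with remainder 1 mod 3 carry an
# incomplete T-- stop, the rest a complete stop
.PCG_LENGTHS <- c(ND1 = 957, ND2 = 1035, COX1 = 1551, COX2 = 688,
                  ATP8 = 165, ATP6 = 679, COX3 = 784, ND3 = 346,
                  ND4L = 294, ND4 = 1377, ND5 = 1812, ND6 = 519,
                  CYTB = 1141)

.PCG_STARTS <- c(ND1 = "ATG", ND2 = "ATG", COX1 = "ATG", COX2 = "ATG",
                 ATP8 = "GTG", ATP6 = "ATG", COX3 = "ATG", ND3 = "ATG",
                 ND4L = "GTG", ND4 = "ATG", ND5 = "ATG", ND6 = "GTG",
                 CYTB = "ATG")

.PCG_STOPS <- c(ND1 = "TAA", ND2 = "AGA", COX1 = "AGA", COX2 = "T",
                ATP8 = "TAA", ATP6 = "T", COX3 = "T", ND3 = "T",
                ND4L = "TAA", ND4 = "TAA", ND5 = "TAA", ND6 = "AGG",
                CYTB = "T")

# canonical vertebrate order from rrnS to tRNA-Thr (hotspot appended
# separately); short tokens
.CORE_ORDER <- c("12S", "V", "16S", "L2", "ND1", "I", "Q", "M", "ND2",
                 "W", "A", "N", "C", "Y", "COX1", "S2", "D", "COX2",
                 "K", "ATP8", "ATP6", "COX3", "G", "ND3", "R", "ND4L",
                 "ND4", "H", "S1", "L1", "ND5", "ND6", "E", "CYTB", "T")

#' Canonical vertebrate mitogenome gene order
#'
#' @param include_ol Include the light-strand replication origin (OL)
#'   between tRNA-Asn and tRNA-Cys.
#' @return Character vector of canonical labels from rrnS around the
#'   circle (37 genes + 1 CR; 39 tokens with OL).
#' @export
canonical_gene_order <- function(include_ol = FALSE) {
  core <- .CORE_ORDER
  if (include_ol) core <- append(core, "OL", after = match("N", core))
  .from_short(c(core, "P", "CR", "F"))
}

# Built-in arrangements: the TDRL history producing each hotspot from
# the ancestral P-CR-F segment, and the IQM/QIM cluster state.
.builtin_arrangements <- function() {
  list(
    typical = list(qim = FALSE, scenario = tdrl_scenario(c("P", "CR", "F"))),
    V = list(qim = TRUE, scenario = tdrl_scenario(
      c("P", "CR", "F"),
      list(tdrl_event(c(1L, 3L), losses = 1L),          # dup P-CR-F, lose P(a)
           tdrl_event(c(4L, 5L), losses = c(2L, 4L, 7L))))), # dup CR(b)-F(b); lose F(a), CR(b), F(c)
    IX = list(qim = TRUE, scenario = tdrl_scenario(
      c("P", "CR", "F"),
      list(tdrl_event(c(1L, 3L), losses = 1L),          # dup P-CR-F, lose P(a)
           tdrl_event(c(4L, 5L), losses = 7L))))        # dup CR(b)-F(b), lose F(c)
  )
}

#' Specification for a synthetic mitogenome
#'
#' Defaults emulate the composition and layout reported for toad-headed
#' agama mitogenomes: A+T near 62.5% with positive AT-skew and negative
#' GC-skew, ~11.3 kb of PCGs with the usual ATG/GTG starts and
#' TAA/AGA/AGG or incomplete `T--` stops, 70 bp tRNA placeholders
#' (22 x 70 = 1540 bp, the scale of reported tRNA totals), ~890 bp
#' control regions carrying the CSB1 motif, and a 13 bp ND5/ND6
#' overlap.
#'
#' @param arrangement `"typical"`, `"V"`, `"IX"`, or a [tdrl_scenario()]
#'   starting from the ancestral `P, CR, F` hotspot.
#' @param base_freqs Named A/C/G/T frequencies summing to 1.
#' @param trna_length tRNA placeholder length (bp).
#' @param rrna_lengths Named lengths for `rrnS` and `rrnL` (bp).
#' @param cr_length Control-region length (bp); must exceed the CSB1
#'   motif offset + length.
#' @param pcg_lengths Named per-PCG lengths (bp).
#' @param ol_length Light-strand origin length (bp).
#' @param include_ol Include an OL feature.
#' @param nd5_nd6_overlap Overlap (bp) between ND5 and ND6.
#' @param max_spacer Maximum random intergenic spacer (bp).
#' @param seed Integer seed; the whole record derives from one stream.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(arrangement = "typical",
                           base_freqs = c(A = 0.34, C = 0.245, G = 0.13, T = 0.285),
                           trna_length = 70L,
                           rrna_lengths = c(rrnS = 950L, rrnL = 1600L),
                           cr_length = 890L,
                           pcg_lengths = .PCG_LENGTHS,
                           ol_length = 35L,
                           include_ol = FALSE,
                           nd5_nd6_overlap = 13L,
                           max_spacer = 5L,
                           seed = 1L) {
  if (abs(sum(base_freqs) - 1) > 1e-9) stop("base_freqs must sum to 1")
  stopifnot(all(base_freqs >= 0),
            all(c("A", "C", "G", "T") %in% names(base_freqs)))
  if (any(c(trna_length, rrna_lengths, cr_length, pcg_lengths, ol_length) <= 0)) {
    stop("all feature lengths must be positive")
  }
  if (cr_length < nchar(.CSB1) + 30L) {
    stop("cr_length too small to carry the CSB1 motif")
  }
  if (!inherits(arrangement, "tdrl_scenario") &&
      !arrangement %in% names(.builtin_arrangements())) {
    stop("arrangement must be one of ",
         paste(names(.builtin_arrangements()), collapse = ", "),
         " or a tdrl_scenario")
  }
  structure(list(arrangement = arrangement,
                 base_freqs = base_freqs[c("A", "C", "G", "T")],
                 trna_length = as.integer(trna_length),
                 rrna_lengths = rrna_lengths, cr_length = as.integer(cr_length),
                 pcg_lengths = pcg_lengths, ol_length = as.integer(ol_length),
                 include_ol = isTRUE(include_ol),
                 nd5_nd6_overlap = as.integer(nd5_nd6_overlap),
                 max_spacer = as.integer(max_spacer),
                 seed = .stopifnot_scalar_int(seed, "seed")),
            class = "synthetic_spec")
}

.feature_lengths_for <- function(spec, tokens) {
  cls <- feature_class(tokens)
  len <- integer(length(tokens))
  len[cls == "PCG"] <- spec$pcg_lengths[tokens[cls == "PCG"]]
  len[cls == "tRNA"] <- spec$trna_length
  len[cls == "rRNA"] <- spec$rrna_lengths[tokens[cls == "rRNA"]]
  len[cls == "CR"] <- spec$cr_length
  len[cls == "OL"] <- spec$ol_length
  len
}

#' Generate a synthetic annotated mitogenome
#'
#' Builds the canonical vertebrate order, applies the arrangement's
#' TDRL history to the hotspot segment (named arrangements `V` and `IX`
#' also carry the derived QIM state of the Ile/Gln/Met cluster), lays
#' features out contiguously with small random spacers and a fixed
#' ND5/ND6 overlap, and fills the sequence from the base frequencies.
#' Every PCG begins with its configured ATG/GTG start and ends with a
#' complete (TAA/TAG/AGA/AGG) or incomplete (`T--`) stop; every control
#' region contains the CSB1 motif verbatim; light-strand genes are
#' reverse-complemented in place. Two calls with the same spec produce
#' byte-identical records.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `record` (a [mitogenome_record()]) and `manifest`:
#'   the ground truth (intended token order, per-feature coordinates,
#'   intended base frequencies, arrangement, seed) for round-trip
#'   tests.
#' @export
generate_record <- function(spec) {
  arr <- if (inherits(spec$arrangement, "tdrl_scenario")) {
    list(qim = TRUE, scenario = spec$arrangement, label = "custom")
  } else {
    c(.builtin_arrangements()[[spec$arrangement]],
      list(label = spec$arrangement))
  }
  if (!identical(arr$scenario$start, .from_short(c("P", "CR", "F")))) {
    stop("arrangement scenario must start from the ancestral P, CR, F hotspot")
  }
  hotspot <- as.character(apply_tdrl_scenario(arr$scenario))
  core <- .CORE_ORDER
  if (arr$qim) {
    core[match(c("I", "Q"), core)] <- c("Q", "I")
  }
  if (spec$include_ol) core <- append(core, "OL", after = match("N", core))
  tokens <- .from_short(c(core, short_token(hotspot)))

  .with_seed(spec$seed, {
    n <- length(tokens)
    lens <- .feature_lengths_for(spec, tokens)
    gaps <- sample(0:spec$max_spacer, n, replace = TRUE)
    gaps[1L] <- 0L
    nd6_at <- match("ND6", tokens)
    if (!is.na(nd6_at) && tokens[nd6_at - 1L] == "ND5") {
      gaps[nd6_at] <- -spec$nd5_nd6_overlap
    }
    starts <- integer(n); pos <- 0L
    for (i in seq_len(n)) {
      pos <- pos + gaps[i]
      starts[i] <- pos
      pos <- pos + lens[i]
    }
    genome_len <- pos + sample(0:spec$max_spacer, 1L)
    strands <- default_strand(tokens)

    seq_vec <- .draw_bases(genome_len, spec$base_freqs)
    # feature content, then a constraint pass so overlaps cannot clobber
    # a start/stop codon or the CSB1 motif
    for (i in seq_len(n)) {
      body <- .draw_bases(lens[i], spec$base_freqs)
      if (strands[i] == -1L) {
        body <- rev(chartr("ACGT", "TGCA", body))
      }
      seq_vec <- .write_region(seq_vec, starts[i], starts[i] + lens[i], body)
    }
    for (i in seq_len(n)) {
      cls <- feature_class(tokens[i])
      if (cls == "PCG") {
        stop_bases <- strsplit(.PCG_STOPS[[tokens[i]]], "")[[1L]]
        if (lens[i] %% 3L != length(stop_bases) %% 3L) {
          stop("length of ", tokens[i], " inconsistent with its stop codon")
        }
        seq_vec <- .write_coding(seq_vec, starts[i], lens[i], strands[i],
                                 0L, strsplit(.PCG_STARTS[[tokens[i]]], "")[[1L]])
        seq_vec <- .write_coding(seq_vec, starts[i], lens[i], strands[i],
                                 lens[i] - length(stop_bases), stop_bases)
      } else if (cls == "CR") {
        seq_vec <- .write_region(seq_vec, starts[i] + 20L,
                                 starts[i] + 20L + nchar(.CSB1),
                                 strsplit(.CSB1, "")[[1L]])
      }
    }

    feats <- do.call(rbind, lapply(seq_len(n), function(i) {
      gene_feature(tokens[i], starts[i], starts[i] + lens[i], strands[i])
    }))
    record <- mitogenome_record(
      id = sprintf("SYN_%s_%d",
                   if (is.character(spec$arrangement)) spec$arrangement else "custom",
                   spec$seed),
      sequence = paste(seq_vec, collapse = ""),
      features = feats)
    manifest <- list(order = tokens,
                     coordinates = data.frame(name = tokens, start = starts,
                                              end = starts + lens,
                                              strand = strands,
                                              stringsAsFactors = FALSE),
                     base_freqs = spec$base_freqs,
                     arrangement = arr$label,
                     scenario = arr$scenario,
                     genome_length = genome_len,
                     seed = spec$seed)
    list(record = record, manifest = manifest)
  })
}

# Write `bases` (coding-strand) at coding offset `offset` of a feature
# located at [start, start+len) with the given strand.
.write_coding <- function(seq_vec, start, len, strand, offset, bases) {
  k <- length(bases)
  if (strand == 1L) {
    .write_region(seq_vec, start + offset, start + offset + k, bases)
  } else {
    rc <- rev(chartr("ACGT", "TGCA", bases))
    .write_region(seq_vec, start + len - offset - k, start + len - offset, rc)
  }
}

#' Mutate a copy of a record at a fixed per-site substitution rate
#'
#' Substitutes bases independently at the given rate, uniformly among
#' the three alternative bases, preserving the annotation. The expected
#' pairwise p-distance to the original is approximately the rate (no
#' back-substitution at a single application).
#'
#' @param record A `mitogenome_record`.
#' @param per_site_rate Substitution probability per site, in \[0, 1).
#' @param seed Integer seed.
#' @return A new `mitogenome_record` with id suffix `"_mut"`.
#' @export
mutate_copy <- function(record, per_site_rate, seed = 1L) {
  if (per_site_rate < 0 || per_site_rate >= 1) {
    stop("per_site_rate must be in [0, 1)")
  }
  .with_seed(seed, {
    bases <- strsplit(record$sequence, "")[[1L]]
    hit <- which(stats::runif(length(bases)) < per_site_rate &
                   bases %in% c("A", "C", "G", "T"))
    for (i in hit) {
      bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1L)
    }
    mitogenome_record(paste0(record$id, "_mut"),
                      paste(bases, collapse = ""),
                      record$features, is_complete = record$is_complete)
  })
}
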