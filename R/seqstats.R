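# Composition, skew, codon usage / RSCU, start/stop codons, spacer and
# overlap reports, and uncorrected p-distance.

.STOP_CODONS <- c("TAA", "TAG", "AGA", "AGG")  # vertebrate mitochondrial code

#' Base composition and strand skews of a DNA sequence
#'
#' Computes A/C/G/T counts (N and other symbols excluded from every
#' denominator), A+T and G+C content, and the strand-asymmetry skews
#' AT-skew = (A - T) / (A + T) and GC-skew = (G - C) / (G + C).
#'
#' @param seq DNA string.
#' @return An object of class `base_composition`: a list with `counts`
#'   (named A/C/G/T), `at_content` and `gc_content` (percent), `at_skew`
#'   and `gc_skew` (dimensionless, in \[-1, 1\]; `NA` when the
#'   denominator is zero).
#' @examples
#' base_composition("AAAT")$at_skew  # (3 - 1) / (3 + 1) = 0.5
#' @export
base_composition <- function(seq) {
  seq <- toupper(seq)
  counts <- vapply(c("A", "C", "G", "T"), function(b) {
    sum(charToRaw(seq) == charToRaw(b))
  }, integer(1L))
  n <- sum(counts)
  if (n == 0L) stop("sequence empty after removing non-ACGT symbols")
  at <- counts[["A"]] + counts[["T"]]
  gc <- counts[["G"]] + counts[["C"]]
  structure(list(
    counts = counts,
    at_content = 100 * at / n,
    gc_content = 100 * gc / n,
    at_skew = if (at > 0L) (counts[["A"]] - counts[["T"]]) / at else NA_real_,
    gc_skew = if (gc > 0L) (counts[["G"]] - counts[["C"]]) / gc else NA_real_
  ), class = "base_composition")
}

#' @export
print.base_composition <- function(x, ...) {
  cat(sprintf("A+T %.1f%%  G+C %.1f%%  AT-skew %s  GC-skew %s\n",
              x$at_content, x$gc_content,
              ifelse(is.na(x$at_skew), "NA", sprintf("%.3f", x$at_skew)),
              ifelse(is.na(x$gc_skew), "NA", sprintf("%.3f", x$gc_skew))))
  invisible(x)
}

#' Per-region composition statistics
#'
#' Concatenates the features of each class (each on its own coding
#' strand, so light-strand genes contribute their reverse complement)
#' and computes [base_composition()] per class plus a whole-genome row
#' (heavy strand). Classes absent from the record are omitted with a
#' warning.
#'
#' @param record A `mitogenome_record`.
#' @return A data frame with columns `region` (`whole`, `PCG`, `tRNA`,
#'   `rRNA`, `CR`), `total_length`, `A`, `C`, `G`, `T`, `at_content`,
#'   `gc_content`, `at_skew`, `gc_skew`.
#' @export
region_stats <- function(record) {
  rows <- list(.region_row("whole", record$sequence))
  for (cls in c("PCG", "tRNA", "rRNA", "CR")) {
    feats <- record$features[record$features$class == cls, , drop = FALSE]
    if (nrow(feats) == 0L) {
      warning("no features of class ", cls, " in record ", record$id)
      next
    }
    seqs <- vapply(seq_len(nrow(feats)),
                   function(i) feature_sequence(record, feats[i, ]),
                   character(1L))
    rows[[length(rows) + 1L]] <- .region_row(cls, paste(seqs, collapse = ""))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.region_row <- function(region, seq) {
  bc <- base_composition(seq)
  data.frame(region = region, total_length = nchar(seq),
             A = bc$counts[["A"]], C = bc$counts[["C"]],
             G = bc$counts[["G"]], T = bc$counts[["T"]],
             at_content = bc$at_content, gc_content = bc$gc_content,
             at_skew = bc$at_skew, gc_skew = bc$gc_skew,
             stringsAsFactors = FALSE)
}

#' Codon usage and RSCU of the protein-coding genes
#'
#' Reads every annotated PCG on its coding strand, in frame from the
#' start codon, and counts complete triplets. A complete termination
#' codon (TAA, TAG, AGA or AGG under the vertebrate mitochondrial code)
#' at the end of a gene, and any trailing incomplete codon (`T--` /
#' `TA-`, completed by polyadenylation in vivo), are tabulated
#' separately and excluded from the codon and amino-acid totals. RSCU
#' (relative synonymous codon usage) of a codon is its observed count
#' times the degeneracy of its synonymous family, divided by the family
#' total; families follow the vertebrate mitochondrial genetic code
#' (translation table 2), and the stop family is excluded.
#'
#' @param record A `mitogenome_record` with annotated PCGs; genes
#'   shorter than 6 bp are skipped with a warning.
#' @return An object of class `codon_usage_table`: list with `codons`
#'   (data frame: `codon`, `codon_rna`, `aa`, `count`, `rscu`),
#'   `aa_totals` (named counts of sense codons per amino acid),
#'   `stop_codons` (named counts of complete terminal stops),
#'   `incomplete_stops` (count of genes ending in a truncated stop) and
#'   `total_codons`.
#' @export
codon_usage <- function(record) {
  pcgs <- record$features[record$features$class == "PCG", , drop = FALSE]
  if (nrow(pcgs) == 0L) stop("record has no annotated PCGs")
  code <- Biostrings::getGeneticCode("2")
  counts <- stats::setNames(integer(length(code)), names(code))
  stop_counts <- stats::setNames(integer(length(.STOP_CODONS)), .STOP_CODONS)
  incomplete <- 0L
  for (i in seq_len(nrow(pcgs))) {
    f <- pcgs[i, ]
    seq <- feature_sequence(record, f)
    if (nchar(seq) < 6L) {
      warning("PCG ", f$name, " shorter than 6 bp; skipped")
      next
    }
    n_full <- nchar(seq) %/% 3L
    cods <- substring(seq, 3L * seq_len(n_full) - 2L, 3L * seq_len(n_full))
    rem <- nchar(seq) %% 3L
    if (rem == 0L && cods[n_full] %in% .STOP_CODONS) {
      stop_counts[cods[n_full]] <- stop_counts[cods[n_full]] + 1L
      cods <- cods[-n_full]
    } else if (rem > 0L) {
      incomplete <- incomplete + 1L
    }
    cods <- cods[cods %in% names(counts)]   # triplets with N are dropped
    tab <- table(cods)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  aa <- unname(code)
  sense <- aa != "*"
  fam_deg <- table(aa[sense])
  fam_tot <- tapply(counts[sense], aa[sense], sum)
  rscu <- rep(NA_real_, length(counts))
  rscu[sense] <- ifelse(fam_tot[aa[sense]] > 0,
                        counts[sense] * as.integer(fam_deg[aa[sense]]) /
                          fam_tot[aa[sense]],
                        NA_real_)
  codons <- data.frame(codon = names(counts),
                       codon_rna = chartr("T", "U", names(counts)),
                       aa = aa, count = unname(counts), rscu = rscu,
                       stringsAsFactors = FALSE)
  structure(list(codons = codons,
                 aa_totals = fam_tot,
                 stop_codons = stop_counts,
                 incomplete_stops = incomplete,
                 total_codons = sum(counts[sense])),
            class = "codon_usage_table")
}

#' @export
print.codon_usage_table <- function(x, ...) {
  cat(sprintf("<codon_usage_table> %d sense codons, %d complete stops, %d incomplete stops\n",
              x$total_codons, sum(x$stop_codons), x$incomplete_stops))
  top <- x$codons[order(-x$codons$count), ][1:5, c("codon_rna", "aa", "count", "rscu")]
  cat("most used codons:\n")
  print(top, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Start and stop codons of every protein-coding gene
#'
#' The start is the first in-frame triplet of the coding-strand
#' sequence. The stop is classified as complete when the gene length is
#' a multiple of 3 and the final triplet is TAA/TAG/AGA/AGG, or as an
#' incomplete `T--` / `TA-` stop when 1 or 2 trailing bases remain.
#'
#' @param record A `mitogenome_record` with annotated PCGs.
#' @return Data frame with one row per PCG: `gene`, `copy_label`,
#'   `start_codon`, `stop_codon`, `stop_complete`.
#' @export
start_stop_table <- function(record) {
  pcgs <- record$features[record$features$class == "PCG", , drop = FALSE]
  if (nrow(pcgs) == 0L) stop("record has no annotated PCGs")
  rows <- lapply(seq_len(nrow(pcgs)), function(i) {
    f <- pcgs[i, ]
    seq <- feature_sequence(record, f)
    n <- nchar(seq)
    rem <- n %% 3L
    if (rem == 0L) {
      stop_codon <- substr(seq, n - 2L, n)
      complete <- stop_codon %in% .STOP_CODONS
    } else if (rem == 1L) {
      stop_codon <- paste0(substr(seq, n, n), "--")
      complete <- FALSE
    } else {
      stop_codon <- paste0(substr(seq, n - 1L, n), "-")
      complete <- FALSE
    }
    data.frame(gene = f$name, copy_label = f$copy_label,
               start_codon = substr(seq, 1L, 3L),
               stop_codon = stop_codon, stop_complete = complete,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Intergenic spacers and gene overlaps on the circular order
#'
#' For every circularly adjacent pair of features (in genome order) the
#' signed gap is `next start - previous end`: negative values are
#' overlaps, positive values intergenic spacers, zero means abutting
#' genes. The pair closing the circle (last feature back to the first)
#' is included, so the number of pairs equals the number of features.
#'
#' @param record A `mitogenome_record` with at least 2 features.
#' @return Data frame with columns `from`, `to`, `gap`, plus attribute
#'   `"summary"`: list with `n_overlaps`, `n_spacers`, `max_overlap`
#'   (bp, positive), `max_spacer` (bp).
#' @export
spacers_and_overlaps <- function(record) {
  feats <- record$features
  if (nrow(feats) < 2L) stop("need at least 2 features")
  len <- nchar(record$sequence)
  n <- nrow(feats)
  nxt <- c(2:n, 1L)
  gap <- feats$start[nxt] - feats$end
  gap[n] <- feats$start[1L] + len - feats$end[n]
  lab <- ifelse(is.na(feats$copy_label), feats$name,
                paste0(feats$name, "(", feats$copy_label, ")"))
  out <- data.frame(from = lab, to = lab[nxt], gap = gap,
                    stringsAsFactors = FALSE)
  attr(out, "summary") <- list(
    n_overlaps = sum(gap < 0L),
    n_spacers = sum(gap > 0L),
    max_overlap = if (any(gap < 0L)) -min(gap) else 0L,
    max_spacer = if (any(gap > 0L)) max(gap) else 0L)
  out
}

#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of differing columns among the columns where both
#' sequences carry a comparable base (A/C/G/T); columns with a gap or N
#' in either sequence are excluded. Symmetric by construction.
#'
#' @param aligned_a,aligned_b Aligned DNA strings of equal length (gaps
#'   as `-`).
#' @return Proportion in \[0, 1\], or `NA` if no comparable columns
#'   remain.
#' @examples
#' p_distance("ACGT", "ACGA")  # 0.25
#' @export
p_distance <- function(aligned_a, aligned_b) {
  if (nchar(aligned_a) != nchar(aligned_b)) {
    stop("aligned sequences must have equal length")
  }
  a <- strsplit(toupper(aligned_a), "")[[1L]]
  b <- strsplit(toupper(aligned_b), "")[[1L]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(ok)) return(NA_real_)
  mean(a[ok] != b[ok])
}

#' Pairwise p-distances of an alignment
#'
#' @param aln Named character vector of aligned sequences, or a
#'   `Biostrings::DNAStringSet` (e.g. from
#'   `Biostrings::readDNAStringSet`).
#' @return Symmetric matrix of uncorrected p-distances.
#' @export
p_distance_matrix <- function(aln) {
  if (methods::is(aln, "XStringSet")) {
    aln <- stats::setNames(as.character(aln), names(aln))
  }
  n <- length(aln)
  m <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) m[i, j] <- m[j, i] <- p_distance(aln[[i]], aln[[j]])
    }
  }
  m
}

#' Write the per-region composition table as TSV
#'
#' Percentages are reported to 1 decimal and skews to 3 decimals,
#' mirroring the usual supplementary-table precision.
#'
#' @param stats Data frame from [region_stats()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_composition_tsv <- function(stats, path) {
  out <- stats
  for (col in c("at_content", "gc_content")) out[[col]] <- round(out[[col]], 1)
  for (col in c("at_skew", "gc_skew")) out[[col]] <- round(out[[col]], 3)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
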