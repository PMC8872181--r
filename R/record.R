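# MitogenomeRecord: a circular annotated mitochondrial genome.
#
# Coordinates are 0-based half-open on the forward (heavy) strand.
# A feature that spans the replication origin is stored unwrapped, with
# end > genome length; all positions are interpreted modulo the length,
# so length arithmetic (end - start) needs no special cases.

#' Construct a gene feature
#'
#' @param name Canonical label from [mito_vocabulary()] (raw names can be
#'   mapped with [normalize_gene_name()]).
#' @param start,end 0-based half-open coordinates on the forward strand.
#'   `end` may exceed the genome length to represent an origin-spanning
#'   feature (interpreted modulo the length).
#' @param strand `+1` (heavy/H strand) or `-1` (light/L strand).
#' @param copy_label Optional lowercase letter (`"a"`, `"b"`, ...)
#'   distinguishing duplicated genes in genome order; assigned
#'   automatically by [mitogenome_record()].
#' @return A one-row data frame with columns `name`, `class`, `start`,
#'   `end`, `strand`, `copy_label`.
#' @export
gene_feature <- function(name, start, end, strand = 1L, copy_label = NA_character_) {
  cls <- feature_class(name)
  start <- .stopifnot_scalar_int(start, "start")
  end <- .stopifnot_scalar_int(end, "end")
  if (start < 0L) stop("feature start must be >= 0")
  if (end <= start) stop("feature end must be > start")
  if (!strand %in% c(1L, -1L)) stop("strand must be +1 or -1")
  data.frame(name = name, class = cls, start = start, end = end,
             strand = as.integer(strand), copy_label = copy_label,
             stringsAsFactors = FALSE)
}

#' Construct an annotated mitogenome record
#'
#' Features are sorted by start (stable; longer feature first on ties)
#' and copy labels `a`, `b`, `c`, ... are assigned in genome order from
#' position 0 to every gene name that occurs more than once — the same
#' convention as the CR I/II/III numbering used for multi-copy control
#' regions.
#'
#' @param id Record identifier (e.g. an accession).
#' @param sequence Circular DNA sequence as a single string over
#'   `A`, `C`, `G`, `T`, `N`.
#' @param features Data frame of features as built by [gene_feature()]
#'   (rows are rbind-ed one-row feature frames).
#' @param is_complete Logical; `FALSE` marks a nearly complete genome.
#' @return An object of class `mitogenome_record`.
#' @export
mitogenome_record <- function(id, sequence, features, is_complete = TRUE) {
  sequence <- toupper(sequence)
  if (!grepl("^[ACGTN]*$", sequence)) {
    stop("sequence may only contain A, C, G, T, N")
  }
  len <- nchar(sequence)
  if (len == 0L) stop("sequence must be nonempty")
  if (nrow(features) > 0L) {
    bad <- features$start < 0L | features$start >= len |
      features$end <= features$start | (features$end - features$start) > len
    if (any(bad)) {
      stop("invalid feature coordinates for: ",
           paste(features$name[bad], collapse = ", "))
    }
    # stable sort: by start, then longer feature first
    o <- order(features$start, -(features$end - features$start))
    features <- features[o, , drop = FALSE]
    features$copy_label <- NA_character_
    for (nm in unique(features$name)) {
      idx <- which(features$name == nm)
      if (length(idx) >= 2L) {
        features$copy_label[idx] <- letters[seq_along(idx)]
      }
    }
    rownames(features) <- NULL
  }
  structure(list(id = id, sequence = sequence, features = features,
                 is_complete = isTRUE(is_complete)),
            class = "mitogenome_record")
}

#' @export
print.mitogenome_record <- function(x, ...) {
  cat(sprintf("<mitogenome_record> %s: %s bp circular DNA, %d features%s\n",
              x$id, format(nchar(x$sequence), big.mark = ","),
              nrow(x$features),
              if (x$is_complete) "" else " (nearly complete)"))
  if (nrow(x$features) > 0L) {
    tab <- table(x$features$class)
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.mitogenome_record <- function(x) nchar(x$sequence)

#' Length of a feature in base pairs
#'
#' Origin-spanning features are stored unwrapped (`end` beyond the genome
#' length), so the length is always `end - start`.
#'
#' @param f One-row feature data frame (or a row of `record$features`).
#' @param genome_length Genome length in bp (used only for validation).
#' @return Length in bp.
#' @export
feature_length <- function(f, genome_length) {
  len <- f$end - f$start
  if (any(len <= 0L) || any(len > genome_length)) {
    stop("invalid feature length")
  }
  len
}

#' Extract the sequence of a feature
#'
#' Returns the feature's sequence on its own coding strand: light-strand
#' features are reverse-complemented. Origin-spanning features wrap
#' around position 0.
#'
#' @param record A `mitogenome_record`.
#' @param feature One-row feature data frame.
#' @return DNA string.
#' @export
feature_sequence <- function(record, feature) {
  len <- nchar(record$sequence)
  s <- feature$start
  e <- feature$end
  seq <- if (e <= len) {
    substr(record$sequence, s + 1L, e)
  } else {
    paste0(substr(record$sequence, s + 1L, len),
           substr(record$sequence, 1L, e - len))
  }
  if (feature$strand == -1L) .revcomp(seq) else seq
}

# Replace the bases of [start, end) (unwrapped coords) with `bases`
# given on the forward strand. Internal, used by the generator.
.write_region <- function(seq_vec, start, end, bases) {
  len <- length(seq_vec)
  pos <- ((start:(end - 1L)) %% len) + 1L
  seq_vec[pos] <- bases
  seq_vec
}
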