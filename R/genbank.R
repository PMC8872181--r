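# GenBank flat-file input/output.
#
# GenBank locations are 1-based inclusive; internally the package uses
# 0-based half-open coordinates. A feature that spans the replication
# origin is written as join(a..LEN,1..b) and read back as one unwrapped
# feature with end > LEN, so the conversion is an involution.

.KEY_BY_CLASS <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                   CR = "D-loop", OL = "rep_origin")

#' Read annotated mitogenome records from a GenBank flat file
#'
#' Parses one or more GenBank records, normalizing feature names through
#' [normalize_gene_name()] and converting coordinates to the internal
#' 0-based half-open convention. `join()` locations that span the
#' replication origin become a single wrapping feature. Features whose
#' names cannot be mapped to the vocabulary (or whose locations are not
#' representable) are not kept in the record; they are collected in a
#' "skipped" log attached as `attr(result, "skipped")`, because deposited
#' annotations are often inconsistent and one bad feature should not
#' discard a whole record.
#'
#' Only annotation keys `CDS`, `tRNA`, `rRNA`, `D-loop`, `rep_origin`
#' and `misc_feature` are considered; `gene` and `source` entries (which
#' duplicate them) are ignored.
#'
#' @param path Path to a GenBank flat file.
#' @param patch Optional annotation patch (path to a TSV or a data
#'   frame), applied with [apply_annotation_patch()] after parsing.
#' @return A list of [mitogenome_record()] objects with attribute
#'   `"skipped"`: a data frame with columns `record_id`, `raw_name`,
#'   `location`, `reason`.
#' @seealso [write_genbank()], [write_skipped_log()]
#' @export
read_genbank <- function(path, patch = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || all(!nzchar(trimws(lines)))) {
    stop("empty GenBank file: ", path)
  }
  locus_at <- grep("^LOCUS ", lines)
  if (length(locus_at) == 0L) {
    stop(sprintf("not a GenBank flat file (no LOCUS line): %s, line 1: '%s'",
                 path, lines[1L]))
  }
  ends <- grep("^//\\s*$", lines)
  if (length(ends) != length(locus_at)) {
    stop(sprintf("unterminated GenBank record in %s (LOCUS at line %d)",
                 path, locus_at[length(locus_at)]))
  }
  records <- vector("list", length(locus_at))
  skipped <- list()
  for (k in seq_along(locus_at)) {
    chunk <- lines[locus_at[k]:ends[k]]
    parsed <- .parse_genbank_record(chunk, locus_at[k], path)
    records[[k]] <- parsed$record
    if (nrow(parsed$skipped) > 0L) skipped[[length(skipped) + 1L]] <- parsed$skipped
  }
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(record_id = character(), raw_name = character(),
               location = character(), reason = character(),
               stringsAsFactors = FALSE)
  if (!is.null(patch)) {
    records <- lapply(records, apply_annotation_patch, patch = patch)
  }
  attr(records, "skipped") <- skipped
  records
}

.parse_genbank_record <- function(chunk, offset, path) {
  locus <- strsplit(trimws(chunk[1L]), "\\s+")[[1L]]
  id <- locus[2L]
  def_at <- grep("^DEFINITION", chunk)
  definition <- if (length(def_at)) sub("^DEFINITION\\s+", "", chunk[def_at[1L]]) else ""
  is_complete <- !grepl("nearly complete|partial", definition, ignore.case = TRUE)

  feat_at <- grep("^FEATURES", chunk)
  origin_at <- grep("^ORIGIN", chunk)
  if (length(origin_at) == 0L) {
    stop(sprintf("GenBank record '%s' has no ORIGIN section (line %d of %s)",
                 id, offset, path))
  }
  seq_lines <- chunk[(origin_at[1L] + 1L):(length(chunk) - 1L)]
  sequence <- toupper(gsub("[0-9 /]", "", paste(seq_lines, collapse = "")))
  if (!grepl("^[ACGTN]*$", sequence)) {
    stop(sprintf("non-DNA characters in ORIGIN of record '%s' (%s)", id, path))
  }
  len <- nchar(sequence)

  feats <- list(); skip <- list()
  if (length(feat_at)) {
    flines <- chunk[(feat_at[1L] + 1L):(origin_at[1L] - 1L)]
    entries <- .split_feature_entries(flines)
    for (en in entries) {
      if (en$key %in% c("source", "gene")) next
      raw_name <- en$qualifiers[["gene"]] %||% en$qualifiers[["product"]] %||%
        switch(en$key, "D-loop" = "CR", "rep_origin" = "OL", NULL)
      loc <- .parse_location(en$location, len)
      if (is.null(loc)) {
        skip[[length(skip) + 1L]] <- data.frame(
          record_id = id, raw_name = raw_name %||% en$key,
          location = en$location, reason = "unsupported location",
          stringsAsFactors = FALSE)
        next
      }
      label <- if (is.null(raw_name)) NULL else
        tryCatch(normalize_gene_name(raw_name), error = function(e) NULL)
      if (is.null(label)) {
        skip[[length(skip) + 1L]] <- data.frame(
          record_id = id, raw_name = raw_name %||% en$key,
          location = en$location, reason = "unmappable name",
          stringsAsFactors = FALSE)
        next
      }
      feats[[length(feats) + 1L]] <-
        gene_feature(label, loc$start, loc$end, loc$strand)
    }
  }
  features <- if (length(feats)) do.call(rbind, feats) else
    gene_feature("CR", 0L, 1L)[0L, ]
  rec <- mitogenome_record(id, sequence, features, is_complete = is_complete)
  skipped <- if (length(skip)) do.call(rbind, skip) else
    data.frame(record_id = character(), raw_name = character(),
               location = character(), reason = character(),
               stringsAsFactors = FALSE)
  list(record = rec, skipped = skipped)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Group the FEATURES block into (key, location, qualifiers) entries.
.split_feature_entries <- function(flines) {
  entries <- list(); cur <- NULL; cur_qual <- NULL
  for (ln in flines) {
    if (grepl("^ {5}\\S", ln)) {                       # new feature
      if (!is.null(cur)) entries[[length(entries) + 1L]] <- cur
      parts <- strsplit(trimws(ln), "\\s+")[[1L]]
      cur <- list(key = parts[1L],
                  location = paste(parts[-1L], collapse = ""),
                  qualifiers = list())
      cur_qual <- NULL
    } else if (!is.null(cur)) {
      txt <- trimws(ln)
      if (startsWith(txt, "/")) {                      # qualifier
        eq <- regexpr("=", txt, fixed = TRUE)
        if (eq > 0L) {
          nm <- substr(txt, 2L, eq - 1L)
          val <- gsub('^"|"$', "", substr(txt, eq + 1L, nchar(txt)))
        } else {
          nm <- substr(txt, 2L, nchar(txt)); val <- TRUE
        }
        cur$qualifiers[[nm]] <- val
        cur_qual <- nm
      } else if (is.null(cur_qual)) {                  # location continuation
        cur$location <- paste0(cur$location, txt)
      } else {                                         # qualifier continuation
        cur$qualifiers[[cur_qual]] <-
          paste(cur$qualifiers[[cur_qual]], gsub('"$', "", txt))
      }
    }
  }
  if (!is.null(cur)) entries[[length(entries) + 1L]] <- cur
  entries
}

# 1-based inclusive GenBank location -> internal 0-based half-open.
# Returns NULL for locations this package does not represent.
.parse_location <- function(loc, len) {
  strand <- 1L
  if (grepl("^complement\\(", loc)) {
    strand <- -1L
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  joined <- grepl("^join\\(", loc)
  if (joined) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  loc <- gsub("[<>]", "", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1L]]
  rng <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^([0-9]+)\\.\\.([0-9]+)$", p))[[1L]]
    if (length(m) != 3L) return(NULL)
    as.integer(m[2:3])
  })
  if (any(vapply(rng, is.null, logical(1L)))) return(NULL)
  if (length(rng) == 1L) {
    a <- rng[[1L]][1L]; b <- rng[[1L]][2L]
    if (a > b) return(NULL)
    return(list(start = a - 1L, end = b, strand = strand))
  }
  if (length(rng) == 2L && rng[[1L]][2L] == len && rng[[2L]][1L] == 1L) {
    # origin-spanning join(a..LEN,1..b) -> unwrapped end beyond LEN
    return(list(start = rng[[1L]][1L] - 1L, end = len + rng[[2L]][2L],
                strand = strand))
  }
  NULL
}

# internal coords -> GenBank location string
.format_location <- function(start, end, strand, len) {
  loc <- if (end <= len) {
    sprintf("%d..%d", start + 1L, end)
  } else {
    sprintf("join(%d..%d,1..%d)", start + 1L, len, end - len)
  }
  if (strand == -1L) loc <- sprintf("complement(%s)", loc)
  loc
}

#' Write mitogenome records as a GenBank flat file
#'
#' Emits files that [read_genbank()] parses back to identical records
#' (names, strands and coordinates, modulo the wrapping representation
#' of origin-spanning features). Protein-coding genes are written as
#' `CDS`, tRNAs as `tRNA`, rRNAs as `rRNA`, control regions as `D-loop`
#' and the light-strand origin as `rep_origin`; light-strand features
#' get `complement()` locations.
#'
#' @param records List of [mitogenome_record()] objects (nonempty).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(records, path) {
  if (length(records) == 0L) stop("no records to write")
  if (inherits(records, "mitogenome_record")) records <- list(records)
  out <- character()
  for (rec in records) {
    len <- nchar(rec$sequence)
    defn <- sprintf("%s mitochondrion, %s genome.", rec$id,
                    if (rec$is_complete) "complete" else "nearly complete")
    out <- c(out,
             sprintf("LOCUS       %-16s %6d bp    DNA     circular VRT 01-JAN-2026",
                     rec$id, len),
             paste0("DEFINITION  ", defn),
             sprintf("ACCESSION   %s", rec$id),
             "FEATURES             Location/Qualifiers",
             sprintf("     source          1..%d", len),
             "                     /organism=\"mitochondrion\"")
    if (nrow(rec$features) > 0L) {
      for (i in seq_len(nrow(rec$features))) {
        f <- rec$features[i, ]
        key <- .KEY_BY_CLASS[[f$class]]
        loc <- .format_location(f$start, f$end, f$strand, len)
        out <- c(out, sprintf("     %-15s %s", key, loc),
                 sprintf("                     /gene=\"%s\"", f$name))
        if (f$class == "CR") {
          out <- c(out, "                     /note=\"control region\"")
        }
      }
    }
    out <- c(out, "ORIGIN", .format_origin(rec$sequence), "//")
  }
  writeLines(out, path)
  invisible(path)
}

.format_origin <- function(sequence) {
  len <- nchar(sequence)
  starts <- seq(1L, len, by = 60L)
  vapply(starts, function(s) {
    line <- substr(sequence, s, min(s + 59L, len))
    blocks <- substring(line, seq(1L, nchar(line), by = 10L),
                        pmin(seq(10L, nchar(line) + 9L, by = 10L), nchar(line)))
    sprintf("%9d %s", s, tolower(paste(blocks, collapse = " ")))
  }, character(1L))
}

#' Write the skipped-features log as TSV
#'
#' @param records Result of [read_genbank()] (carries the `"skipped"`
#'   attribute).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_skipped_log <- function(records, path) {
  skipped <- attr(records, "skipped")
  if (is.null(skipped)) {
    skipped <- data.frame(record_id = character(), raw_name = character(),
                          location = character(), reason = character())
  }
  utils::write.table(skipped, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Apply an annotation patch to a record
#'
#' Deposited annotations sometimes need curation (e.g. re-annotating a
#' feature that actually belongs to the control region). Rather than
#' second-guessing annotations automatically, the package applies an
#' explicit user-supplied patch: a TSV (or data frame) with columns
#' `record_id`, `action` (`add`, `remove` or `rename`), `name`, `start`,
#' `end` (0-based half-open), `strand`, and `new_name` (for `rename`).
#' Rows whose `record_id` differs from `record$id` are ignored.
#'
#' @param record A `mitogenome_record`.
#' @param patch Path to a TSV file or a data frame.
#' @return The patched `mitogenome_record`.
#' @export
apply_annotation_patch <- function(record, patch) {
  if (is.character(patch)) {
    patch <- utils::read.delim(patch, stringsAsFactors = FALSE)
  }
  patch <- patch[patch$record_id == record$id, , drop = FALSE]
  feats <- record$features
  for (i in seq_len(nrow(patch))) {
    p <- patch[i, ]
    if (p$action == "add") {
      feats <- rbind(feats, gene_feature(normalize_gene_name(p$name),
                                         p$start, p$end, p$strand))
    } else if (p$action == "remove") {
      hit <- feats$name == normalize_gene_name(p$name) &
        feats$start == p$start
      feats <- feats[!hit, , drop = FALSE]
    } else if (p$action == "rename") {
      hit <- feats$name == normalize_gene_name(p$name) &
        feats$start == p$start
      feats$name[hit] <- normalize_gene_name(p$new_name)
      feats$class[hit] <- feature_class(feats$name[hit])
    } else {
      stop("unknown patch action: ", p$action)
    }
  }
  mitogenome_record(record$id, record$sequence, feats,
                    is_complete = record$is_complete)
}

#' Export feature sequences as FASTA
#'
#' @param record A `mitogenome_record`.
#' @param path Output FASTA path.
#' @param labels Optional character vector restricting the export to
#'   these canonical labels.
#' @return `path`, invisibly.
#' @export
write_feature_fasta <- function(record, path, labels = NULL) {
  feats <- record$features
  if (!is.null(labels)) feats <- feats[feats$name %in% labels, , drop = FALSE]
  if (nrow(feats) == 0L) stop("no features to export")
  seqs <- vapply(seq_len(nrow(feats)),
                 function(i) feature_sequence(record, feats[i, ]),
                 character(1L))
  ids <- ifelse(is.na(feats$copy_label), feats$name,
                paste0(feats$name, "(", feats$copy_label, ")"))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- paste(record$id, ids)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
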