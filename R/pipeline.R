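# Orchestration: run every per-record statistic, classify arrangements,
# compare records, and emit machine-readable reports.

.SCHEMA_VERSION <- "1.0"

#' Run the full comparative analysis over a set of records
#'
#' For every record: per-region composition, codon usage/RSCU,
#' start/stop codons, spacer/overlap report and arrangement
#' classification. Across records: the count of distinct arrangement
#' types, the minimal TDRL event count from the ancestral hotspot
#' (Pro–CR–Phe) to each record's hotspot, optionally record-to-record
#' minimal counts, and pairwise p-distances when an alignment is
#' supplied. A record that fails any stage is excluded with a logged
#' reason rather than aborting the run; the pipeline fails only if all
#' records fail.
#'
#' @param records List of [mitogenome_record()] objects.
#' @param registry Arrangement registry ([default_registry()] or
#'   [read_registry()]).
#' @param alignments Optional named character vector (or
#'   `DNAStringSet`) of aligned sequences, one per record id, for
#'   p-distance computation.
#' @param search_config A [tdrl_search_config()].
#' @param pairwise_records Also compute record-to-record minimal TDRL
#'   counts (default `FALSE`; the default comparison is against the
#'   ancestral order).
#' @return An object of class `analysis_report`: list with
#'   `schema_version`, `per_record` (named list of per-record
#'   sections), `cross` (distinct types, TDRL counts, p-distance
#'   matrix) and `exclusions` (data frame id/reason).
#' @export
analyze <- function(records, registry = default_registry(),
                    alignments = NULL,
                    search_config = tdrl_search_config(),
                    pairwise_records = FALSE) {
  if (length(records) == 0L) stop("need at least one record")
  per_record <- list()
  exclusions <- data.frame(id = character(), reason = character(),
                           stringsAsFactors = FALSE)
  orders <- list()
  for (rec in records) {
    sec <- tryCatch({
      order <- extract_gene_order(rec)
      list(id = rec$id,
           genome_length = nchar(rec$sequence),
           region_stats = region_stats(rec),
           codon_usage = codon_usage(rec),
           start_stop = start_stop_table(rec),
           spacer_overlap = spacers_and_overlaps(rec),
           arrangement = classify_order(order, registry),
           order = order)
    }, error = function(e) e)
    if (inherits(sec, "error")) {
      exclusions <- rbind(exclusions,
                          data.frame(id = rec$id,
                                     reason = conditionMessage(sec),
                                     stringsAsFactors = FALSE))
    } else {
      per_record[[rec$id]] <- sec
      orders[[rec$id]] <- sec$order
    }
  }
  if (length(per_record) == 0L) {
    stop("all records failed analysis; first reason: ",
         exclusions$reason[1L])
  }
  types <- count_distinct_types(orders, registry)
  ancestral <- c("tRNA-Pro", "CR", "tRNA-Phe")
  tdrl_from_ancestral <- vapply(names(orders), function(id) {
    hs <- hotspot_segment(orders[[id]])$name
    res <- tryCatch(search_min_scenarios(ancestral, hs, search_config),
                    error = function(e) list(min_events = NA_integer_))
    as.integer(res$min_events)
  }, integer(1L))
  cross <- list(n_types = types$n_types, type_labels = types$labels,
                tdrl_events_from_ancestral = tdrl_from_ancestral)
  if (isTRUE(pairwise_records) && length(orders) > 1L) {
    ids <- names(orders)
    m <- matrix(NA_integer_, length(ids), length(ids),
                dimnames = list(ids, ids))
    for (a in ids) for (b in ids) {
      if (a == b) { m[a, b] <- 0L; next }
      res <- tryCatch(
        search_min_scenarios(hotspot_segment(orders[[a]])$name,
                             hotspot_segment(orders[[b]])$name,
                             search_config),
        error = function(e) list(min_events = NA_integer_))
      m[a, b] <- as.integer(res$min_events)
    }
    cross$tdrl_events_pairwise <- m
  }
  if (!is.null(alignments)) {
    cross$p_distances <- p_distance_matrix(alignments)
  }
  structure(list(schema_version = .SCHEMA_VERSION,
                 per_record = per_record, cross = cross,
                 exclusions = exclusions),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> %d record(s), %d distinct arrangement type(s)\n",
              length(x$per_record), x$cross$n_types))
  for (id in names(x$per_record)) {
    sec <- x$per_record[[id]]
    cat(sprintf("  %s: %s bp, type %s, %d TDRL event(s) from ancestral hotspot\n",
                id, format(sec$genome_length, big.mark = ","),
                sec$arrangement$label,
                x$cross$tdrl_events_from_ancestral[[id]]))
  }
  if (nrow(x$exclusions)) {
    cat("  excluded:", paste(x$exclusions$id, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write an analysis report to a directory
#'
#' Emits `report.json` (the machine-readable report) plus human-facing
#' TSVs: `composition.tsv` (per record and region),
#' `arrangements.tsv`, `start_stop.tsv` and `spacer_overlap.tsv`.
#'
#' @param report An `analysis_report` from [analyze()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_analysis_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json <- list(schema_version = report$schema_version,
               records = lapply(report$per_record, function(sec) {
                 list(id = sec$id,
                      genome_length = sec$genome_length,
                      arrangement = sec$arrangement$label,
                      diagnostics = sec$arrangement$diagnostics,
                      hotspot = short_token(sec$arrangement$hotspot),
                      total_codons = sec$codon_usage$total_codons,
                      region_stats = sec$region_stats,
                      start_stop = sec$start_stop,
                      spacer_overlap_summary = attr(sec$spacer_overlap, "summary"))
               }),
               cross = report$cross,
               exclusions = report$exclusions)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
  comp <- do.call(rbind, lapply(report$per_record, function(sec) {
    cbind(id = sec$id, sec$region_stats)
  }))
  write_composition_tsv(comp, file.path(dir, "composition.tsv"))
  arr <- do.call(rbind, lapply(report$per_record, function(sec) {
    d <- sec$arrangement$diagnostics
    data.frame(id = sec$id, label = sec$arrangement$label,
               hotspot = paste(short_token(sec$arrangement$hotspot),
                               collapse = "-"),
               iqm_or_qim = d$iqm_or_qim, trnP_position = d$trnP_position,
               trnF_copies = d$trnF_copies, cr_copies = d$cr_copies,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(arr, file.path(dir, "arrangements.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ss <- do.call(rbind, lapply(report$per_record, function(sec) {
    cbind(id = sec$id, sec$start_stop)
  }))
  utils::write.table(ss, file.path(dir, "start_stop.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  so <- do.call(rbind, lapply(report$per_record, function(sec) {
    cbind(id = sec$id, sec$spacer_overlap)
  }))
  utils::write.table(so, file.path(dir, "spacer_overlap.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

# ---- command-line entry point ------------------------------------------

.cli_usage <- "usage:
  mitorearr analyze <genbank>... [--registry FILE] [--out DIR] [--alignments FASTA]
  mitorearr order classify <genbank> [--registry FILE]
  mitorearr tdrl search --from TOKENS --to TOKENS [--max-events N]
  mitorearr tdrl validate --scenario FILE [--to TOKENS]
  mitorearr simulate --arrangement LABEL --seed N --out DIR
TOKENS are comma-separated gene tokens, e.g. P,CR,F"

.cli_log <- function(fmt, ..., t0 = NULL) {
  elapsed <- if (is.null(t0)) "" else
    sprintf(" [%.2fs]", as.numeric(proc.time()[["elapsed"]]) - t0)
  message(sprintf("[mitorearr] %s%s", sprintf(fmt, ...), elapsed))
}

.cli_opt <- function(argv, name, default = NULL) {
  at <- which(argv == name)
  if (length(at) == 0L) return(default)
  if (at[1L] == length(argv)) stop("missing value for ", name)
  argv[at[1L] + 1L]
}

.cli_positional <- function(argv) {
  drop <- integer()
  at <- grep("^--", argv)
  drop <- c(at, at + 1L)
  argv[setdiff(seq_along(argv), drop)]
}

#' Command-line interface
#'
#' Thin dispatcher over the package's functions; see the wrapper script
#' in `inst/cli/`. Exit status 0 on success, 1 on a validation failure
#' (e.g. a scenario that does not reproduce its target), 2 on a usage
#' error. Stage timings are logged to standard error.
#'
#' @param argv Character vector of arguments (default:
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly.
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch(.cli_dispatch(argv),
                     usage_error = function(e) {
                       message(conditionMessage(e)); message(.cli_usage); 2L
                     },
                     error = function(e) {
                       message("[mitorearr] error: ", conditionMessage(e)); 1L
                     })
  invisible(status)
}

.usage_stop <- function(msg) {
  stop(structure(class = c("usage_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

.cli_tokens <- function(x) trimws(strsplit(x, ",")[[1L]])

.cli_dispatch <- function(argv) {
  if (length(argv) == 0L) .usage_stop("no subcommand given")
  cmd <- argv[1L]
  rest <- argv[-1L]
  t0 <- as.numeric(proc.time()[["elapsed"]])
  if (cmd == "analyze") {
    files <- .cli_positional(rest)
    if (length(files) == 0L) .usage_stop("analyze: no GenBank files given")
    registry <- .cli_opt(rest, "--registry")
    registry <- if (is.null(registry)) default_registry() else read_registry(registry)
    records <- unlist(lapply(files, read_genbank), recursive = FALSE)
    .cli_log("read %d record(s) from %d file(s)", length(records),
             length(files), t0 = t0)
    aln <- .cli_opt(rest, "--alignments")
    aln <- if (is.null(aln)) NULL else Biostrings::readDNAStringSet(aln)
    report <- analyze(records, registry, alignments = aln)
    .cli_log("analysis complete: %d type(s)", report$cross$n_types, t0 = t0)
    out <- .cli_opt(rest, "--out", "mitorearr_report")
    write_analysis_report(report, out)
    .cli_log("report written to %s", out, t0 = t0)
    print(report)
    return(0L)
  }
  if (cmd == "order") {
    if (length(rest) < 2L || rest[1L] != "classify") {
      .usage_stop("unknown 'order' subcommand")
    }
    registry <- .cli_opt(rest, "--registry")
    registry <- if (is.null(registry)) default_registry() else read_registry(registry)
    files <- .cli_positional(rest[-1L])
    if (length(files) == 0L) .usage_stop("order classify: no GenBank file given")
    for (rec in unlist(lapply(files, read_genbank), recursive = FALSE)) {
      call <- classify_order(extract_gene_order(rec), registry)
      cat(sprintf("%s\t%s\t%s\n", rec$id, call$label,
                  paste(short_token(call$hotspot), collapse = "-")))
    }
    .cli_log("classification done", t0 = t0)
    return(0L)
  }
  if (cmd == "tdrl") {
    if (length(rest) < 1L) .usage_stop("missing 'tdrl' subcommand")
    sub <- rest[1L]
    if (sub == "search") {
      from <- .cli_opt(rest, "--from"); to <- .cli_opt(rest, "--to")
      if (is.null(from) || is.null(to)) {
        .usage_stop("tdrl search needs --from and --to")
      }
      cfg <- tdrl_search_config(
        max_events = as.integer(.cli_opt(rest, "--max-events", "3")))
      res <- search_min_scenarios(.cli_tokens(from), .cli_tokens(to), cfg)
      if (!res$reachable) {
        cat(sprintf("unreachable within %d events\n", cfg$max_events))
        .cli_log("search done", t0 = t0)
        return(1L)
      }
      cat(sprintf("minimal events: %d (%d scenario(s))\n", res$min_events,
                  length(res$scenarios)))
      for (sc in res$scenarios) {
        cat(render_trace(attr(apply_tdrl_scenario(sc), "trace")), "\n")
      }
      .cli_log("search done", t0 = t0)
      return(0L)
    }
    if (sub == "validate") {
      path <- .cli_opt(rest, "--scenario")
      if (is.null(path)) .usage_stop("tdrl validate needs --scenario")
      sc <- read_tdrl_scenario(path)
      to <- .cli_opt(rest, "--to")
      to <- if (is.null(to)) sc$end else .from_short(.cli_tokens(to))
      if (is.null(to)) .usage_stop("scenario has no end order; pass --to")
      res <- validate_tdrl_scenario(sc$start, to, sc)
      cat(render_trace(res$trace), "\n")
      .cli_log("validation %s", if (res$valid) "passed" else "FAILED", t0 = t0)
      return(if (res$valid) 0L else 1L)
    }
    .usage_stop("unknown 'tdrl' subcommand")
  }
  if (cmd == "simulate") {
    arrangement <- .cli_opt(rest, "--arrangement", "typical")
    seed <- as.integer(.cli_opt(rest, "--seed", "1"))
    out <- .cli_opt(rest, "--out")
    if (is.null(out)) .usage_stop("simulate needs --out DIR")
    gen <- generate_record(synthetic_spec(arrangement = arrangement,
                                          seed = seed))
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write_genbank(list(gen$record), file.path(out, paste0(gen$record$id, ".gb")))
    manifest <- gen$manifest
    manifest$scenario <- list(
      start = short_token(manifest$scenario$start),
      events = lapply(manifest$scenario$events, unclass))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    .cli_log("simulated %s into %s", gen$record$id, out, t0 = t0)
    return(0L)
  }
  .usage_stop(paste0("unknown subcommand '", cmd, "'"))
}
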