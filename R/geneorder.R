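# Circular gene orders: extraction, canonical rotation, the
# tRNA-Thr .. rrnS hotspot segment, rearrangement diagnostics and
# classification against a registry of named arrangement types.

#' Construct a circular gene order
#'
#' @param names Character vector of gene tokens in genome order
#'   (canonical labels or short tokens, see [mito_vocabulary()]).
#' @param strands Optional integer vector of +1/-1; defaults to
#'   [default_strand()] of each gene.
#' @param anchor Single-copy gene used for rotation (default `rrnS`, the
#'   12S rRNA, which is single-copy in all arrangements handled here;
#'   tRNA-Phe cannot anchor because some arrangements duplicate it).
#' @return An object of class `gene_order`: list with `tokens` (data
#'   frame: `name`, `strand`, `copy_label`) rotated so the anchor is
#'   first, and `anchor`.
#' @export
gene_order <- function(names, strands = NULL, anchor = "rrnS") {
  names <- .from_short(names)
  if (is.null(strands)) strands <- default_strand(names)
  stopifnot(length(strands) == length(names))
  tokens <- data.frame(name = names, strand = as.integer(strands),
                       copy_label = NA_character_, stringsAsFactors = FALSE)
  .canonical_order(tokens, anchor)
}

.canonical_order <- function(tokens, anchor) {
  at <- which(tokens$name == anchor)
  if (length(at) == 0L) {
    singles <- names(which(table(tokens$name) == 1L))
    stop(sprintf("anchor '%s' absent from the order; single-copy candidates: %s",
                 anchor, paste(utils::head(singles, 5L), collapse = ", ")))
  }
  if (length(at) > 1L) {
    singles <- names(which(table(tokens$name) == 1L))
    stop(sprintf("anchor '%s' occurs %d times; single-copy candidates: %s",
                 anchor, length(at),
                 paste(utils::head(singles, 5L), collapse = ", ")))
  }
  n <- nrow(tokens)
  rot <- ((at - 1L + seq_len(n) - 1L) %% n) + 1L
  tokens <- tokens[rot, , drop = FALSE]
  tokens$copy_label <- NA_character_
  for (nm in unique(tokens$name)) {
    idx <- which(tokens$name == nm)
    if (length(idx) >= 2L) tokens$copy_label[idx] <- letters[seq_along(idx)]
  }
  rownames(tokens) <- NULL
  structure(list(tokens = tokens, anchor = anchor), class = "gene_order")
}

#' @export
print.gene_order <- function(x, ...) {
  lab <- short_token(x$tokens$name)
  lab <- ifelse(is.na(x$tokens$copy_label), lab,
                paste0(lab, "(", x$tokens$copy_label, ")"))
  lab <- ifelse(x$tokens$strand == -1L, paste0("-", lab), lab)
  cat(sprintf("<gene_order> %d tokens (anchor %s):\n  %s\n",
              nrow(x$tokens), x$anchor, paste(lab, collapse = " ")))
  invisible(x)
}

#' Extract the gene order of an annotated record
#'
#' Tokens are taken in genome order (feature start coordinate) and the
#' order is rotated so the anchor gene comes first; copy labels are
#' re-assigned `a`, `b`, `c` in genome order.
#'
#' @param record A `mitogenome_record`.
#' @inheritParams gene_order
#' @return A `gene_order`.
#' @export
extract_gene_order <- function(record, anchor = "rrnS") {
  feats <- record$features
  if (nrow(feats) == 0L) stop("record has no features")
  tokens <- data.frame(name = feats$name, strand = feats$strand,
                       copy_label = NA_character_, stringsAsFactors = FALSE)
  .canonical_order(tokens, anchor)
}

#' Hotspot segment between tRNA-Thr and the 12S rRNA
#'
#' Returns the linear run of tokens strictly between tRNA-Thr and rrnS
#' (both exclusive), walking forward around the circle. In the
#' arrangements handled here this segment — tRNA-Pro, control region(s),
#' tRNA-Phe copies — is where all of the described gene-order variation
#' occurs.
#'
#' @param order A `gene_order` containing tRNA-Thr and rrnS exactly
#'   once each.
#' @return Data frame of tokens (columns `name`, `strand`,
#'   `copy_label`), possibly zero-row.
#' @export
hotspot_segment <- function(order) {
  tokens <- order$tokens
  n <- nrow(tokens)
  thr <- which(tokens$name == "tRNA-Thr")
  rrs <- which(tokens$name == "rrnS")
  if (length(thr) != 1L || length(rrs) != 1L) {
    stop("hotspot bounds require exactly one tRNA-Thr and one rrnS")
  }
  idx <- integer()
  i <- thr %% n + 1L
  while (i != rrs) {
    idx <- c(idx, i)
    i <- i %% n + 1L
  }
  out <- tokens[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rearrangement diagnostics of a gene order
#'
#' Reports the three kinds of tRNA position variation seen among
#' toad-headed agama mitogenomes: the state of the Ile/Gln/Met tRNA
#' cluster (ancestral `IQM` vs derived `QIM`), the position class of
#' tRNA-Pro relative to tRNA-Phe within the hotspot segment, and the
#' copy numbers of tRNA-Phe and the control region.
#'
#' `trnP_position` is `"before-F"` when tRNA-Phe occurs only downstream
#' of tRNA-Pro in the hotspot, `"after-F"` when only upstream,
#' `"between-CRs"` when tRNA-Phe flanks tRNA-Pro on both sides (the
#' state where Pro sits between two duplicated CR/Phe blocks), and
#' `"absent"` when tRNA-Pro is missing.
#'
#' @param order A `gene_order`.
#' @return List with `iqm_or_qim` (`"IQM"`, `"QIM"`, `"other"` or
#'   `"absent"`), `trnP_position`, `trnF_copies`, `cr_copies`.
#' @export
order_diagnostics <- function(order) {
  tokens <- order$tokens
  iqm_genes <- c("tRNA-Ile", "tRNA-Gln", "tRNA-Met")
  present <- iqm_genes %in% tokens$name
  iqm <- if (!all(present)) {
    "absent"
  } else {
    pat <- paste(short_token(tokens$name[tokens$name %in% iqm_genes]),
                 collapse = "")
    if (pat == "IQM") "IQM" else if (pat == "QIM") "QIM" else "other"
  }
  trnp <- "absent"
  hs <- tryCatch(hotspot_segment(order), error = function(e) NULL)
  if (!is.null(hs)) {
    p <- which(hs$name == "tRNA-Pro")
    f <- which(hs$name == "tRNA-Phe")
    if (length(p) >= 1L) {
      p <- p[1L]
      before <- any(f < p); after <- any(f > p)
      trnp <- if (before && after) "between-CRs"
              else if (after) "before-F"
              else if (before) "after-F"
              else "absent"
    }
  }
  list(iqm_or_qim = iqm,
       trnP_position = trnp,
       trnF_copies = sum(tokens$name == "tRNA-Phe"),
       cr_copies = sum(tokens$name == "CR"))
}

#' Built-in registry of named arrangement types
#'
#' Ships the three arrangements fully recoverable from the comparative
#' literature on *Phrynocephalus* mitogenomes: the typical vertebrate
#' arrangement (ancestral IQM cluster; hotspot Pro–CR–Phe), type V
#' (derived QIM; hotspot CR–Pro–Phe–CR) and type IX (derived QIM;
#' hotspot CR–Phe–Pro–CR–Phe–CR with a duplicated tRNA-Phe and three
#' CRs). Additional types can be supplied as a registry TSV via
#' [read_registry()].
#'
#' @return Data frame with columns `label`, `iqm_or_qim`, `hotspot`
#'   (comma-separated canonical labels).
#' @export
default_registry <- function() {
  data.frame(
    label = c("typical", "V", "IX"),
    iqm_or_qim = c("IQM", "QIM", "QIM"),
    hotspot = c("tRNA-Pro,CR,tRNA-Phe",
                "CR,tRNA-Pro,tRNA-Phe,CR",
                "CR,tRNA-Phe,tRNA-Pro,CR,tRNA-Phe,CR"),
    stringsAsFactors = FALSE
  )
}

#' Read an arrangement-type registry from TSV
#'
#' The file must have columns `label`, `iqm_or_qim` and `hotspot`
#' (comma-separated gene tokens, canonical labels or short tokens);
#' labels must be unique and the file order is the classification
#' tie-break order.
#'
#' @param path TSV path.
#' @return Registry data frame as in [default_registry()].
#' @export
read_registry <- function(path) {
  reg <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("label", "iqm_or_qim", "hotspot")
  if (!all(need %in% names(reg))) {
    stop("registry must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(reg$label)) stop("registry labels must be unique")
  reg$hotspot <- vapply(strsplit(reg$hotspot, ","), function(tok) {
    paste(.from_short(trimws(tok)), collapse = ",")
  }, character(1L))
  reg
}

#' Classify a gene order against an arrangement-type registry
#'
#' The hotspot segment (token names, ignoring copy labels and strand)
#' together with the IQM/QIM cluster state is matched exactly against
#' each registry entry; the first match wins (registry order is the
#' deterministic tie-break). With no match the call is `"novel"` and
#' the diagnostics still describe the order.
#'
#' @param order A `gene_order`.
#' @param registry Registry data frame ([default_registry()] or
#'   [read_registry()]).
#' @return An object of class `arrangement_call`: list with `label`
#'   (registry label or `"novel"`), `hotspot` (character vector of
#'   names) and `diagnostics` (see [order_diagnostics()]).
#' @export
classify_order <- function(order, registry = default_registry()) {
  if (nrow(registry) == 0L) stop("registry is empty")
  hs <- hotspot_segment(order)
  key <- paste(hs$name, collapse = ",")
  diag <- order_diagnostics(order)
  label <- "novel"
  for (i in seq_len(nrow(registry))) {
    if (registry$hotspot[i] == key &&
        registry$iqm_or_qim[i] == diag$iqm_or_qim) {
      label <- registry$label[i]
      break
    }
  }
  structure(list(label = label, hotspot = hs$name, diagnostics = diag),
            class = "arrangement_call")
}

#' @export
print.arrangement_call <- function(x, ...) {
  cat(sprintf("<arrangement_call> %s; hotspot %s; %s cluster; trnP %s; %d trnF, %d CR\n",
              x$label, paste(short_token(x$hotspot), collapse = "-"),
              x$diagnostics$iqm_or_qim, x$diagnostics$trnP_position,
              x$diagnostics$trnF_copies, x$diagnostics$cr_copies))
  invisible(x)
}

#' Count distinct arrangement types in a set of orders
#'
#' Orders are grouped by their classification label; novel orders are
#' grouped by their exact hotspot token sequence plus cluster state, so
#' two identical unrecognized orders still count as one type.
#'
#' @param orders List of `gene_order` objects.
#' @param registry Registry data frame.
#' @return List with `n_types` (count of distinct types), `labels`
#'   (per-order call label) and `partition` (named list of order
#'   indices per type).
#' @export
count_distinct_types <- function(orders, registry = default_registry()) {
  if (length(orders) == 0L) stop("need at least one order")
  keys <- vapply(orders, function(o) {
    call <- classify_order(o, registry)
    if (call$label != "novel") call$label else
      paste0("novel:", call$diagnostics$iqm_or_qim, ":",
             paste(call$hotspot, collapse = ","))
  }, character(1L))
  partition <- split(seq_along(orders), keys)
  list(n_types = length(partition), labels = keys, partition = partition)
}
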