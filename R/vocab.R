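# Controlled vocabulary of mitochondrial feature names.
#
# Canonical labels follow the usual vertebrate mitogenome convention:
# 13 protein-coding genes, 22 tRNAs (Leu1 = CUN, Leu2 = UUR, Ser1 = AGY,
# Ser2 = UCN), the two rRNAs as rrnS/rrnL, the control region as CR and
# the light-strand replication origin as OL.

.PCG_LABELS <- c("ND1", "ND2", "COX1", "COX2", "ATP8", "ATP6", "COX3",
                 "ND3", "ND4L", "ND4", "ND5", "ND6", "CYTB")

.TRNA_AA <- c(Phe = "F", Val = "V", Leu1 = "L1", Leu2 = "L2", Ile = "I",
              Gln = "Q", Met = "M", Trp = "W", Ala = "A", Asn = "N",
              Cys = "C", Tyr = "Y", Ser1 = "S1", Ser2 = "S2", Asp = "D",
              Lys = "K", Gly = "G", Arg = "R", His = "H", Glu = "E",
              Thr = "T", Pro = "P")

.TRNA_LABELS <- paste0("tRNA-", names(.TRNA_AA))

.RRNA_LABELS <- c("rrnS", "rrnL")

# Genes encoded on the light (L) strand; everything else is heavy (H) strand.
.L_STRAND_GENES <- c("ND6", "tRNA-Gln", "tRNA-Ala", "tRNA-Asn", "tRNA-Cys",
                     "tRNA-Tyr", "tRNA-Ser2", "tRNA-Glu", "tRNA-Pro")

#' Controlled vocabulary of mitogenome feature labels
#'
#' Returns the closed vocabulary used throughout the package: the 13
#' protein-coding genes (PCGs), 22 tRNAs with Leu1(CUN)/Leu2(UUR) and
#' Ser1(AGY)/Ser2(UCN) disambiguation, the two rRNAs (`rrnS` = 12S,
#' `rrnL` = 16S), the control region (`CR`) and the light-strand
#' replication origin (`OL`).
#'
#' @return A data frame with columns `label` (canonical label), `class`
#'   (one of `"PCG"`, `"tRNA"`, `"rRNA"`, `"CR"`, `"OL"`) and `short`
#'   (compact token used in gene-order traces, e.g. `"P"` for tRNA-Pro,
#'   `"12S"` for rrnS).
#' @examples
#' head(mito_vocabulary())
#' @export
mito_vocabulary <- function() {
  data.frame(
    label = c(.PCG_LABELS, .TRNA_LABELS, .RRNA_LABELS, "CR", "OL"),
    class = c(rep("PCG", length(.PCG_LABELS)),
              rep("tRNA", length(.TRNA_LABELS)),
              rep("rRNA", 2), "CR", "OL"),
    short = c(.PCG_LABELS, unname(.TRNA_AA), "12S", "16S", "CR", "OL"),
    stringsAsFactors = FALSE
  )
}

#' Feature class of a canonical label
#'
#' @param label Character vector of canonical labels.
#' @return Character vector of classes (`"PCG"`, `"tRNA"`, `"rRNA"`,
#'   `"CR"`, `"OL"`).
#' @export
feature_class <- function(label) {
  voc <- mito_vocabulary()
  idx <- match(label, voc$label)
  if (anyNA(idx)) {
    stop("not in the feature vocabulary: ",
         paste(label[is.na(idx)], collapse = ", "))
  }
  voc$class[idx]
}

# Normalisation key: case-folded, spaces/hyphens/underscores/dots removed.
.name_key <- function(x) {
  gsub("[ \t._-]", "", tolower(x))
}

.synonym_table <- local({
  syn <- list()
  add <- function(label, ...) {
    for (s in c(...)) syn[[.name_key(s)]] <<- label
  }
  # protein-coding genes
  add("ND1", "ND1", "nad1", "NADH1", "NADH dehydrogenase subunit 1")
  add("ND2", "ND2", "nad2", "NADH2", "NADH dehydrogenase subunit 2")
  add("ND3", "ND3", "nad3", "NADH3", "NADH dehydrogenase subunit 3")
  add("ND4", "ND4", "nad4", "NADH4", "NADH dehydrogenase subunit 4")
  add("ND4L", "ND4L", "nad4l", "NADH4L", "NADH dehydrogenase subunit 4L")
  add("ND5", "ND5", "nad5", "NADH5", "NADH dehydrogenase subunit 5")
  add("ND6", "ND6", "nad6", "NADH6", "NADH dehydrogenase subunit 6")
  add("COX1", "COX1", "COI", "CO1", "COXI",
      "cytochrome c oxidase subunit 1", "cytochrome c oxidase subunit I")
  add("COX2", "COX2", "COII", "CO2", "COXII",
      "cytochrome c oxidase subunit 2", "cytochrome c oxidase subunit II")
  add("COX3", "COX3", "COIII", "CO3", "COXIII",
      "cytochrome c oxidase subunit 3", "cytochrome c oxidase subunit III")
  add("ATP6", "ATP6", "ATPase6", "ATP synthase F0 subunit 6")
  add("ATP8", "ATP8", "ATPase8", "ATP synthase F0 subunit 8")
  add("CYTB", "CYTB", "cob", "cytb", "cyt b", "cytochrome b")
  # rRNAs
  add("rrnS", "rrnS", "12S", "12S rRNA", "12S ribosomal RNA", "s-rRNA",
      "small subunit ribosomal RNA", "rrn12")
  add("rrnL", "rrnL", "16S", "16S rRNA", "16S ribosomal RNA", "l-rRNA",
      "large subunit ribosomal RNA", "rrn16")
  # control region and replication origin
  add("CR", "CR", "D-loop", "control region", "putative control region")
  add("OL", "OL", "L-strand origin", "origin of L-strand replication",
      "light strand replication origin", "rep_origin")
  # tRNAs: trnX single-letter form and tRNA-Xyz three-letter form
  aa1 <- c(Phe = "F", Val = "V", Ile = "I", Gln = "Q", Met = "M",
           Trp = "W", Ala = "A", Asn = "N", Cys = "C", Tyr = "Y",
           Asp = "D", Lys = "K", Gly = "G", Arg = "R", His = "H",
           Glu = "E", Thr = "T", Pro = "P")
  for (aa in names(aa1)) {
    add(paste0("tRNA-", aa), paste0("trn", aa1[[aa]]), paste0("tRNA-", aa),
        paste0("tRNA ", aa))
  }
  # Leu and Ser need anticodon or index disambiguation
  add("tRNA-Leu1", "trnL1", "tRNA-Leu1", "tRNA-Leu(CUN)", "tRNA-Leu (CUN)",
      "trnL(CUN)", "trnL-cun")
  add("tRNA-Leu2", "trnL2", "tRNA-Leu2", "tRNA-Leu(UUR)", "tRNA-Leu (UUR)",
      "trnL(UUR)", "trnL-uur")
  add("tRNA-Ser1", "trnS1", "tRNA-Ser1", "tRNA-Ser(AGY)", "tRNA-Ser (AGY)",
      "trnS(AGY)", "trnS-agy")
  add("tRNA-Ser2", "trnS2", "tRNA-Ser2", "tRNA-Ser(UCN)", "tRNA-Ser (UCN)",
      "trnS(UCN)", "trnS-ucn")
  syn
})

#' Normalize a raw feature name to a canonical label
#'
#' Maps the name dialects found in deposited annotations ("COI",
#' "D-loop", "tRNA-Ser (UCN)", "nad5", ...) onto the package's closed
#' vocabulary. Matching is case-insensitive and ignores spaces, hyphens,
#' underscores and dots. Bare "tRNA-Leu"/"tRNA-Ser" without an anticodon
#' or index are ambiguous and rejected.
#'
#' @param raw Character scalar, the name as it appears in an annotation.
#' @return The canonical label (see [mito_vocabulary()]).
#' @examples
#' normalize_gene_name("COI")            # "COX1"
#' normalize_gene_name("D-loop")         # "CR"
#' normalize_gene_name("tRNA-Ser (UCN)") # "tRNA-Ser2"
#' @export
normalize_gene_name <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || !nzchar(trimws(raw))) {
    stop("'raw' must be a single nonempty character string")
  }
  key <- .name_key(raw)
  hit <- .synonym_table[[key]]
  if (!is.null(hit)) {
    return(hit)
  }
  # idempotence on canonical labels is guaranteed by the table itself,
  # so reaching this point means an unknown name: suggest near matches.
  keys <- names(.synonym_table)
  d <- utils::adist(key, keys)
  near <- unique(unlist(.synonym_table[keys[order(d)[seq_len(min(3L, length(keys)))]]],
                        use.names = FALSE))
  stop(sprintf("unknown feature name '%s'; nearest vocabulary entries: %s",
               raw, paste(near, collapse = ", ")))
}

#' Compact display token for a canonical label
#'
#' @param label Character vector of canonical labels.
#' @return Character vector of short tokens (e.g. `"P"`, `"CR"`, `"12S"`).
#' @export
short_token <- function(label) {
  voc <- mito_vocabulary()
  idx <- match(label, voc$label)
  if (anyNA(idx)) {
    stop("not in the feature vocabulary: ",
         paste(label[is.na(idx)], collapse = ", "))
  }
  voc$short[idx]
}

# Inverse of short_token (also accepts canonical labels unchanged).
.from_short <- function(tok) {
  voc <- mito_vocabulary()
  idx <- match(tok, voc$short)
  miss <- is.na(idx)
  idx[miss] <- match(tok[miss], voc$label)
  if (anyNA(idx)) {
    stop("unknown gene token: ", paste(tok[is.na(idx)], collapse = ", "))
  }
  voc$label[idx]
}

#' Default strand of a gene in the vertebrate mitogenome
#'
#' ND6 and eight tRNAs (Gln, Ala, Asn, Cys, Tyr, Ser2/UCN, Glu, Pro) are
#' encoded on the light strand; all other features sit on the heavy
#' strand.
#'
#' @param label Character vector of canonical labels.
#' @return Integer vector of +1 (heavy/H) or -1 (light/L).
#' @export
default_strand <- function(label) {
  ifelse(label %in% .L_STRAND_GENES, -1L, 1L)
}
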