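test_that("feature construction enforces the coordinate invariants", {
  expect_error(gene_feature("ND1", -1L, 10L), "start")
  expect_error(gene_feature("ND1", 10L, 10L), "end")
  expect_error(gene_feature("ND1", 0L, 10L, strand = 2L), "strand")
  f <- gene_feature("ND1", 0L, 70L)
  expect_identical(feature_length(f, 1000L), 70L)
})

test_that("origin-spanning features have modular length arithmetic", {
  f <- gene_feature("CR", 17240L, 17353L)  # wraps on a 17,253 bp genome
  expect_identical(feature_length(f, 17253L), 113L)
})

test_that("copy labels are assigned in genome order iff a name is duplicated", {
  feats <- rbind(gene_feature("CR", 200L, 400L),
                 gene_feature("tRNA-Phe", 0L, 70L),
                 gene_feature("CR", 500L, 700L),
                 gene_feature("CR", 100L, 150L))
  rec <- mitogenome_record("X", strrep("ACGT", 200L), feats)
  cr <- rec$features[rec$features$name == "CR", ]
  expect_identical(cr$copy_label, c("a", "b", "c"))
  expect_identical(cr$start, c(100L, 200L, 500L))  # genome order from 0
  expect_true(is.na(rec$features$copy_label[rec$features$name == "tRNA-Phe"]))
})

test_that("GenBank write/read round trip is the identity on records", {
  for (lab in c("typical", "IX")) {
    gen <- generate_record(synthetic_spec(arrangement = lab, seed = 3L))
    path <- withr::local_tempfile(fileext = ".gb")
    write_genbank(list(gen$record), path)
    back <- read_genbank(path)
    expect_length(back, 1L)
    expect_identical(back[[1L]]$id, gen$record$id)
    expect_identical(back[[1L]]$sequence, gen$record$sequence)
    expect_identical(back[[1L]]$features, gen$record$features)
    expect_identical(back[[1L]]$is_complete, gen$record$is_complete)
    expect_identical(nrow(attr(back, "skipped")), 0L)
  }
})

test_that("origin-spanning join() locations survive the round trip", {
  len <- 1000L
  feats <- rbind(gene_feature("rrnS", 100L, 300L),
                 gene_feature("tRNA-Thr", 400L, 470L),
                 gene_feature("CR", 900L, 1100L))  # wraps: join(901..1000,1..100)
  rec <- mitogenome_record("WRAP", strrep("ACGTT", 200L), feats)
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(list(rec), path)
  txt <- readLines(path)
  expect_true(any(grepl("join(901..1000,1..100)", txt, fixed = TRUE)))
  back <- read_genbank(path)[[1L]]
  cr <- back$features[back$features$name == "CR", ]
  expect_identical(cr$start, 900L)
  expect_identical(cr$end, 1100L)
})

test_that("L-strand features are written with complement() locations", {
  rec <- tiny_record()
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(list(rec), path)
  txt <- readLines(path)
  expect_true(any(grepl("complement(10..81)", txt, fixed = TRUE)))
  back <- read_genbank(path)[[1L]]
  expect_identical(back$features$strand[back$features$name == "tRNA-Gln"], -1L)
})

test_that("internal->GenBank->internal coordinate conversion is an involution", {
  set.seed(41)
  len <- 5000L
  for (i in 1:25) {
    start <- sample(0:(len - 1L), 1L)
    flen <- sample(50:900, 1L)
    strand <- sample(c(1L, -1L), 1L)
    loc <- mitorearr:::.format_location(start, start + flen, strand, len)
    parsed <- mitorearr:::.parse_location(loc, len)
    expect_identical(parsed$start, start)
    expect_identical(parsed$end, start + flen)
    expect_identical(parsed$strand, strand)
  }
})

test_that("unmappable feature names land in the skipped log, not the record", {
  gb <- c(
    "LOCUS       SKIP                 120 bp    DNA     circular VRT 01-JAN-2026",
    "DEFINITION  SKIP mitochondrion, complete genome.",
    "FEATURES             Location/Qualifiers",
    "     source          1..120",
    "     tRNA            1..70",
    "                     /product=\"tRNA-Phe\"",
    "     misc_feature    71..100",
    "                     /gene=\"mystery_orf\"",
    "ORIGIN",
    paste0("        1 ", tolower(strrep("acgtacgtac", 6L))),
    paste0("       61 ", tolower(strrep("acgtacgtac", 6L))),
    "//")
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, path)
  recs <- read_genbank(path)
  expect_identical(recs[[1L]]$features$name, "tRNA-Phe")
  skipped <- attr(recs, "skipped")
  expect_identical(nrow(skipped), 1L)
  expect_identical(skipped$raw_name, "mystery_orf")
  expect_identical(skipped$reason, "unmappable name")
  log <- withr::local_tempfile(fileext = ".tsv")
  write_skipped_log(recs, log)
  expect_identical(utils::read.delim(log)$raw_name, "mystery_orf")
})

test_that("degenerate inputs raise the documented errors", {
  empty <- withr::local_tempfile(fileext = ".gb")
  writeLines(character(), empty)
  expect_error(read_genbank(empty), "empty")
  junk <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("this is", "not genbank"), junk)
  expect_error(read_genbank(junk), "LOCUS")
  expect_error(write_genbank(list(), withr::local_tempfile()), "no records")
})

test_that("an annotation patch can re-annotate a feature", {
  rec <- tiny_record()
  patch <- data.frame(record_id = "TINY", action = "rename",
                      name = "tRNA-Gln", start = 9L, end = NA, strand = NA,
                      new_name = "tRNA-Met", stringsAsFactors = FALSE)
  patched <- apply_annotation_patch(rec, patch)
  expect_true("tRNA-Met" %in% patched$features$name)
  expect_false("tRNA-Gln" %in% patched$features$name)
})

test_that("a reference GenBank parser reads our files identically", {
  # Biopython as an independent parser oracle for the writer
  gen <- generate_record(synthetic_spec(arrangement = "V", seed = 5L))
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(list(gen$record), path)
  py <- paste(
    "from Bio import SeqIO",
    sprintf("r = SeqIO.read('%s', 'genbank')", path),
    "print(len(r.seq))",
    "for f in sorted(r.features, key=lambda f: int(f.location.start)):",
    "    if f.type == 'source': continue",
    "    print(int(f.location.start), int(f.location.end), f.location.strand)",
    sep = "\n")
  out <- system2("python", "-", stdout = TRUE, input = py)
  expect_identical(out[1L], as.character(nchar(gen$record$sequence)))
  got <- do.call(rbind, strsplit(out[-1L], " "))
  feats <- gen$record$features[order(gen$record$features$start), ]
  expect_identical(as.integer(got[, 1L]), feats$start)
  expect_identical(as.integer(got[, 2L]), feats$end)
  expect_identical(as.integer(got[, 3L]), feats$strand)
})
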