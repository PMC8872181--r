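test_that("base composition and skews follow the defining formulas", {
  bc <- base_composition("AATT")
  expect_equal(bc$at_skew, 0)
  expect_equal(bc$at_content, 100)
  expect_equal(base_composition("AAAT")$at_skew, 0.5)   # (3 - 1) / 4
  # N excluded from every denominator
  bc <- base_composition("AANNT")
  expect_equal(bc$at_content, 100)
  expect_equal(bc$at_skew, (2 - 1) / 3)
  # undefined skew is NA, not 0
  expect_true(is.na(base_composition("GGCC")$at_skew))
  expect_true(is.na(base_composition("AATT")$gc_skew))
  expect_error(base_composition("NNN"), "empty")
})

test_that("skews are bounded and antisymmetric under reverse complement", {
  set.seed(11)
  for (i in 1:30) {
    s <- random_dna(sample(50:400, 1L), freqs = c(0.4, 0.25, 0.1, 0.25))
    bc <- base_composition(s)
    rc <- base_composition(
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))))
    expect_true(abs(bc$at_skew) <= 1 && abs(bc$gc_skew) <= 1)
    expect_equal(rc$at_skew, -bc$at_skew)
    expect_equal(rc$gc_skew, -bc$gc_skew)
    expect_equal(bc$at_content + bc$gc_content, 100)
  }
})

test_that("region stats concatenate features per class on the coding strand", {
  rec <- tiny_record("ATGAAATAA")
  expect_warning(stats <- region_stats(rec), "rRNA")
  pcg <- stats[stats$region == "PCG", ]
  expect_identical(pcg$total_length, 9L)
  expect_identical(stats$region[1L], "whole")
  expect_identical(stats$total_length[1L], nchar(rec$sequence))
  # uniform base frequencies: skews ~ 0 within sampling error
  set.seed(7)
  long <- mitogenome_record("U", random_dna(40000L),
                            gene_feature("CR", 0L, 100L))
  bc <- base_composition(long$sequence)
  expect_lt(abs(bc$at_skew), 0.02)
  expect_lt(abs(bc$gc_skew), 0.02)
})

test_that("codon counts exclude terminal stops and RSCU follows its formula", {
  rec <- tiny_record("ATGCTACTATAA")
  cu <- codon_usage(rec)
  expect_identical(cu$total_codons, 3L)         # ATG, CTA, CTA
  expect_identical(unname(cu$stop_codons[["TAA"]]), 1L)
  # CTA is the only Leu codon used: RSCU = 2 * 6 / 2 = 6
  expect_equal(cu$codons$rscu[cu$codons$codon == "CTA"], 6)
  # Met family is {ATA, ATG}; only ATG used: RSCU = 1 * 2 / 1 = 2
  expect_equal(cu$codons$rscu[cu$codons$codon == "ATG"], 2)
  # equal use of a whole family gives RSCU 1 for each member
  leu <- c("CTA", "CTC", "CTG", "CTT", "TTA", "TTG")
  rec2 <- tiny_record(paste0("ATG", paste(leu, collapse = ""), "TAA"))
  cu2 <- codon_usage(rec2)
  expect_equal(cu2$codons$rscu[cu2$codons$codon %in% leu], rep(1, 6L))
})

test_that("RSCU family sums equal the family degeneracy on random records", {
  set.seed(23)
  for (i in 1:5) {
    gen <- generate_record(synthetic_spec(seed = 100L + i))
    cu <- codon_usage(gen$record)
    sense <- cu$codons[cu$codons$aa != "*", ]
    for (fam in split(sense, sense$aa)) {
      if (sum(fam$count) > 0L) {
        expect_equal(sum(fam$rscu), nrow(fam))
      }
    }
    # family counts sum to the amino-acid totals
    expect_equal(unname(tapply(sense$count, sense$aa, sum)[names(cu$aa_totals)]),
                 unname(cu$aa_totals))
  }
})

test_that("start/stop table classifies complete and incomplete stops", {
  rec <- tiny_record("GTGAAATAA")
  ss <- start_stop_table(rec)
  expect_identical(ss$start_codon, "GTG")
  expect_identical(ss$stop_codon, "TAA")
  expect_true(ss$stop_complete)
  # length = 1 (mod 3), ends in T: polyadenylation-completed stop
  ss <- start_stop_table(tiny_record("ATGAAAAAAT"))
  expect_identical(ss$stop_codon, "T--")
  expect_false(ss$stop_complete)
  ss <- start_stop_table(tiny_record("ATGAAAAGA"))
  expect_identical(ss$stop_codon, "AGA")
  expect_true(ss$stop_complete)
})

test_that("spacer/overlap report covers every circular adjacency", {
  feats <- rbind(gene_feature("ND5", 0L, 100L),
                 gene_feature("ND6", 87L, 150L),
                 gene_feature("CYTB", 150L, 200L))
  rec <- mitogenome_record("G", strrep("ACGT", 50L), feats)
  so <- spacers_and_overlaps(rec)
  expect_identical(nrow(so), 3L)                       # pairs == features
  expect_identical(so$gap[so$from == "ND5"], -13L)     # overlap
  expect_identical(so$gap[so$from == "ND6"], 0L)       # abutting
  expect_identical(so$gap[so$from == "CYTB"], 0L)      # circular closure
  expect_identical(attr(so, "summary")$max_overlap, 13L)
})

test_that("p-distance matches its definition and is symmetric", {
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_equal(p_distance("ACGT", "ACGA"), 0.25)
  expect_equal(p_distance("AC-T", "ACGT"), 0)          # gap column excluded
  expect_true(is.na(p_distance("----", "AAAA")))
  expect_error(p_distance("ACG", "ACGT"), "equal length")
  set.seed(31)
  for (i in 1:10) {
    a <- random_dna(300L); b <- random_dna(300L)
    expect_equal(p_distance(a, b), p_distance(b, a))
    d <- p_distance(a, b)
    expect_true(d >= 0 && d <= 1)
    # appending all-gap columns changes nothing
    expect_equal(p_distance(paste0(a, "----"), paste0(b, "----")), d)
  }
})

test_that("p-distance agrees with an independent implementation", {
  set.seed(13)
  a <- strsplit(random_dna(600L), "")[[1L]]
  b <- a
  flip <- sample(600L, 60L)
  for (i in flip) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1L)
  b[sample(600L, 20L)] <- "-"   # some gap columns
  m <- rbind(a = a, b = b)
  ours <- p_distance(paste(a, collapse = ""), paste(b, collapse = ""))
  ref <- as.numeric(ape::dist.dna(ape::as.DNAbin(m), model = "raw",
                                  pairwise.deletion = TRUE))
  expect_equal(ours, ref)
})

test_that("composition converges to generator frequencies with length", {
  freqs <- c(A = 0.34, C = 0.245, G = 0.13, T = 0.285)
  gen <- generate_record(synthetic_spec(seed = 77L, base_freqs = freqs))
  bc <- base_composition(gen$record$sequence)
  n <- sum(bc$counts)
  for (b in names(freqs)) {
    p <- freqs[[b]]
    # constrained motifs (start/stop codons, CSB1) shift a few hundred
    # of ~17k positions; 4 sigma plus that margin
    tol <- 4 * sqrt(p * (1 - p) / n) + 0.01
    expect_lt(abs(bc$counts[[b]] / n - p), tol)
  }
})
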