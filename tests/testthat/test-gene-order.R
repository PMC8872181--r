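test_that("extracted orders have the expected token census", {
  typical <- extract_gene_order(
    generate_record(synthetic_spec(arrangement = "typical", seed = 1L))$record)
  expect_identical(nrow(typical$tokens), 38L)   # 37 genes + 1 CR
  expect_identical(typical$tokens$name[1L], "rrnS")
  ix <- extract_gene_order(
    generate_record(synthetic_spec(arrangement = "IX", seed = 1L))$record)
  expect_identical(sum(feature_class(ix$tokens$name) == "tRNA"), 23L)
  expect_identical(sum(ix$tokens$name == "CR"), 3L)
})

test_that("anchoring requires a unique anchor and suggests alternatives", {
  expect_error(gene_order(c("tRNA-Phe", "CR", "tRNA-Phe"), anchor = "rrnS"),
               "absent")
  expect_error(gene_order(c("rrnS", "CR", "rrnS"), anchor = "rrnS"),
               "occurs 2 times")
})

test_that("hotspot segments match the named arrangements", {
  for (lab in names(hotspots)) {
    rec <- generate_record(synthetic_spec(arrangement = lab, seed = 2L))$record
    hs <- hotspot_segment(extract_gene_order(rec))
    expect_identical(hs$name, hotspots[[lab]])
  }
})

test_that("diagnostics report cluster state, trnP position and copy numbers", {
  canonical <- gene_order(canonical_gene_order())
  d <- order_diagnostics(canonical)
  expect_identical(d, list(iqm_or_qim = "IQM", trnP_position = "before-F",
                           trnF_copies = 1L, cr_copies = 1L))
  ix <- extract_gene_order(
    generate_record(synthetic_spec(arrangement = "IX", seed = 1L))$record)
  d <- order_diagnostics(ix)
  expect_identical(d, list(iqm_or_qim = "QIM", trnP_position = "between-CRs",
                           trnF_copies = 2L, cr_copies = 3L))
  v <- extract_gene_order(
    generate_record(synthetic_spec(arrangement = "V", seed = 1L))$record)
  d <- order_diagnostics(v)
  expect_identical(d, list(iqm_or_qim = "QIM", trnP_position = "before-F",
                           trnF_copies = 1L, cr_copies = 2L))
})

test_that("classification matches hotspot plus cluster state, else novel", {
  expect_identical(classify_order(gene_order(canonical_gene_order()))$label,
                   "typical")
  # same hotspot as typical but derived QIM cluster: no longer typical
  ord <- canonical_gene_order()
  iq <- match(c("tRNA-Ile", "tRNA-Gln"), ord)
  ord[iq] <- ord[rev(iq)]
  expect_identical(classify_order(gene_order(ord))$label, "novel")
  for (lab in c("V", "IX")) {
    rec <- generate_record(synthetic_spec(arrangement = lab, seed = 4L))$record
    expect_identical(classify_order(extract_gene_order(rec))$label, lab)
  }
})

test_that("classification is invariant to rotation of the token list", {
  tokens <- canonical_gene_order()
  set.seed(5)
  for (r in sample(length(tokens), 5L)) {
    rotated <- c(tokens[r:length(tokens)], tokens[seq_len(r - 1L)])
    expect_identical(classify_order(gene_order(rotated))$label, "typical")
  }
})

test_that("classify(generate(L)) = L for every shipped registry label", {
  for (lab in default_registry()$label) {
    for (seed in 1:3) {
      gen <- generate_record(synthetic_spec(arrangement = lab, seed = seed))
      expect_identical(classify_order(extract_gene_order(gen$record))$label,
                       lab)
    }
  }
})

test_that("distinct-type counting groups by call and is permutation-invariant", {
  orders <- lapply(c("V", "IX", "IX"), function(lab) {
    extract_gene_order(
      generate_record(synthetic_spec(arrangement = lab, seed = 6L))$record)
  })
  res <- count_distinct_types(orders)
  expect_identical(res$n_types, 2L)
  expect_identical(sort(unique(res$labels)), c("IX", "V"))
  expect_identical(count_distinct_types(orders[c(2, 3, 1)])$n_types, 2L)
  expect_identical(count_distinct_types(orders[c(2, 2, 2)])$n_types, 1L)
  all3 <- lapply(c("typical", "V", "IX"), function(lab) {
    extract_gene_order(
      generate_record(synthetic_spec(arrangement = lab, seed = 6L))$record)
  })
  expect_identical(count_distinct_types(all3)$n_types, 3L)
  expect_lte(count_distinct_types(all3)$n_types, length(all3))
})

test_that("the shipped registry file parses to the built-in registry", {
  path <- system.file("extdata", "arrangement_registry.tsv",
                      package = "mitorearr")
  expect_identical(read_registry(path), default_registry())
  # short tokens in a user registry are normalized to canonical labels
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("label\tiqm_or_qim\thotspot", "typ2\tIQM\tP,CR,F"), tmp)
  expect_identical(read_registry(tmp)$hotspot, "tRNA-Pro,CR,tRNA-Phe")
})
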