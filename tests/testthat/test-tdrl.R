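PCF <- c("tRNA-Pro", "CR", "tRNA-Phe")

test_that("a tandem duplication doubles exactly the block", {
  out <- apply_tdrl_event(c("P", "CR", "F"), tdrl_event(c(1, 3)))
  expect_identical(out, rep(PCF, 2L))
  # losing the entire duplicate copy is the identity
  out <- apply_tdrl_event(c("P", "CR", "F"), tdrl_event(c(2, 3), losses = 4:5))
  expect_identical(out, PCF)
  # losing P(a) after a whole-segment duplication
  out <- apply_tdrl_event(c("P", "CR", "F"), tdrl_event(c(1, 3), losses = 1L))
  expect_identical(out, c("CR", "tRNA-Phe", "tRNA-Pro", "CR", "tRNA-Phe"))
})

test_that("events never change the gene multiset except by losses", {
  set.seed(19)
  for (i in 1:25) {
    inst <- random_tdrl_instance()
    seg <- inst$scenario$start
    ev <- inst$scenario$events[[1L]]
    dup_only <- apply_tdrl_event(seg, tdrl_event(ev$block))
    tab0 <- table(seg); tab1 <- table(dup_only)
    blk <- seg[ev$block[1L]:ev$block[2L]]
    for (nm in names(tab1)) {
      expect_identical(as.integer(tab1[[nm]]),
                       as.integer(tab0[nm]) + sum(blk == nm))
    }
  }
})

test_that("extinguishing an essential gene is rejected by name", {
  # only one F; duplicating CR and deleting both F copies is impossible,
  # deleting the single F is an invalid event
  expect_error(
    apply_tdrl_event(c("P", "CR", "F"), tdrl_event(c(2, 2), losses = 4L)),
    "essential.*F")
  # CR is not essential: all CR copies may be lost
  out <- apply_tdrl_event(c("P", "CR", "F"), tdrl_event(c(2, 2), losses = c(2L, 3L)))
  expect_identical(out, c("tRNA-Pro", "tRNA-Phe"))
})

test_that("the shipped duplication pathways reproduce both derived hotspots", {
  branchB <- read_tdrl_scenario(
    system.file("extdata", "fig_branchB_typeIX.json", package = "mitorearr"))
  resB <- validate_tdrl_scenario(PCF, hotspots$IX, branchB)
  expect_true(resB$valid)
  expect_length(resB$trace, 3L)
  branchA <- read_tdrl_scenario(
    system.file("extdata", "fig_branchA_typeV.json", package = "mitorearr"))
  resA <- validate_tdrl_scenario(PCF, hotspots$V, branchA)
  expect_true(resA$valid)
  expect_length(resA$trace, 3L)
  # both branches share the same first duplication step
  expect_identical(resA$trace[[2L]], resB$trace[[2L]])
  # cross-validation: branch B does not produce the type V hotspot
  expect_false(validate_tdrl_scenario(PCF, hotspots$V, branchB)$valid)
  # zero-event scenario is the identity
  expect_true(validate_tdrl_scenario(PCF, PCF, tdrl_scenario(PCF))$valid)
  expect_error(validate_tdrl_scenario(hotspots$V, PCF, branchA),
               "does not match")
})

test_that("scenario JSON round-trips", {
  sc <- read_tdrl_scenario(
    system.file("extdata", "fig_branchA_typeV.json", package = "mitorearr"))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_tdrl_scenario(sc, tmp)
  back <- read_tdrl_scenario(tmp)
  expect_identical(back$start, sc$start)
  expect_identical(back$end, sc$end)
  expect_identical(lapply(back$events, unclass), lapply(sc$events, unclass))
})

test_that("minimal-scenario search finds the expected counts", {
  expect_identical(search_min_scenarios(PCF, PCF)$min_events, 0L)
  resV <- search_min_scenarios(PCF, hotspots$V)
  expect_identical(resV$min_events, 2L)
  resIX <- search_min_scenarios(PCF, hotspots$IX)
  expect_identical(resIX$min_events, 2L)
  # every returned scenario replays to the target through the
  # independently written applier
  for (sc in resIX$scenarios) {
    seg <- sc$start
    for (ev in sc$events) {
      seg <- oracle_apply(seg, ev$block[1L], ev$block[2L], ev$losses)
    }
    expect_identical(seg, hotspots$IX)
  }
  # unreachable within the event budget is a result, not an error
  res <- search_min_scenarios(PCF, c(rep("CR", 7L), "tRNA-Pro", "tRNA-Phe"),
                              tdrl_search_config(max_events = 1L))
  expect_false(res$reachable)
  expect_true(is.na(res$min_events))
})

test_that("search errors on out-of-bounds or unsatisfiable inputs", {
  expect_error(search_min_scenarios(PCF, c("CR", "tRNA-Thr"),
                                    tdrl_search_config()),
               "absent from 'from'")
  expect_error(search_min_scenarios(rep(PCF, 5L), PCF,
                                    tdrl_search_config(max_segment_length = 12L)),
               "max_segment_length")
})

test_that("search agrees with the brute-force enumerator on all hotspot pairs", {
  for (a in names(hotspots)) {
    for (b in names(hotspots)) {
      res <- search_min_scenarios(hotspots[[a]], hotspots[[b]],
                                  tdrl_search_config(max_events = 2L))
      orc <- oracle_min_scenarios(hotspots[[a]], hotspots[[b]], max_events = 2L)
      expect_identical(res$min_events, orc$min_events,
                       info = paste(a, "->", b))
      got <- sequence_keys(lapply(res$scenarios, function(sc) {
        attr(apply_tdrl_scenario(sc), "trace")
      }))
      expect_identical(got, sequence_keys(orc$sequences),
                       info = paste(a, "->", b))
    }
  }
})

test_that("search never needs more events than a generating scenario", {
  set.seed(101)
  for (i in 1:40) {
    inst <- random_tdrl_instance()
    res <- search_min_scenarios(inst$scenario$start, inst$end,
                                tdrl_search_config(max_events = 2L))
    expect_true(res$reachable)
    expect_lte(res$min_events, inst$n_events)
  }
})

test_that("results are invariant to copy-label decoration of inputs", {
  # copy labels are display bookkeeping: segments are token-name lists,
  # and label_copies assigns letters left-to-right deterministically
  expect_identical(label_copies(hotspots$IX),
                   c("CR(a)", "F(a)", "P", "CR(b)", "F(b)", "CR(c)"))
  expect_identical(
    search_min_scenarios(c("P", "CR", "F"), hotspots$IX)$min_events,
    search_min_scenarios(PCF, hotspots$IX)$min_events)
  expect_match(render_trace(list(c("tRNA-Thr", "CR", "tRNA-Phe"))),
               "T-CR-F", fixed = TRUE)
})
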