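test_that("each self-target rule rejects its designed violation", {
  rules <- self_target_rules()
  m20 <- "TGCATCGAGCTACGATCGAT"
  st_of <- function(site, mi = m20) {
    a <- align_site(mi, site)
    a$states[a$offset == 1]
  }
  # perfect site passes rules 1-5
  expect_true(all(check_self_rules(st_of(design_site(m20)), rules)))
  # rule 1: four mismatches plus a wobble = 4.5 equivalents
  r1 <- check_self_rules(st_of(design_site(m20,
                                           mismatch_pos = c(2, 5, 14, 17),
                                           wobble_pos = 18)), rules)
  expect_false(r1[["rule1"]])
  # rule 2: three consecutive mismatches (outside the seed band)
  r2 <- check_self_rules(st_of(design_site(m20, mismatch_pos = 14:16)), rules)
  expect_false(r2[["rule2"]])
  expect_true(r2[["rule3"]])
  # rule 3: two adjacent mismatches inside positions 2-12
  r3 <- check_self_rules(st_of(design_site(m20, mismatch_pos = 5:6)), rules)
  expect_false(r3[["rule3"]])
  expect_true(r3[["rule2"]])
  # rule 4: a mismatch at position 10 (plus one at 14)
  r4 <- check_self_rules(st_of(design_site(m20, mismatch_pos = c(10, 14))),
                         rules)
  expect_false(r4[["rule4"]])
  # rule 5: three spread mismatches within positions 1-12
  r5 <- check_self_rules(st_of(design_site(m20, mismatch_pos = c(2, 5, 8))),
                         rules)
  expect_false(r5[["rule5"]])
  expect_true(r5[["rule1"]])
})

test_that("rule 6 rejects sites whose duplex energy falls below 60%", {
  # damage confined to the 3' half passes rules 1-5 but guts the duplex
  m <- "TGCGGCCAGCTCGGCAGCGC"
  good <- paste0("GGGG", design_site(m), "AAAA")
  bad <- paste0("GGGG", design_site(m, mismatch_pos = c(13, 15, 17, 19)),
                "AAAA")
  tx <- Biostrings::DNAStringSet(c(good_tx = good, bad_tx = bad))
  hits <- verify_self_targets(data.frame(id = "m", sequence = m), tx,
                              engine = engine)
  expect_true("good_tx" %in% hits$transcript)
  expect_false("bad_tx" %in% hits$transcript)
})

test_that("milRNAs absent from the host are eligible; stable loci are not", {
  study <- get_study()
  res <- get_result()
  screen <- res$transboundary
  host_enc <- screen$milrna[screen$is_host_encoded]
  expect_equal(host_enc, study$expected$host_encoded)
  expect_true(all(screen$eligible[screen$n_matches == 0]))
  # the stable locus folds far below the -85 kcal/mol bar
  expect_lte(screen$min_flank_mfe[screen$milrna == host_enc], -85)
})

test_that("transboundary eligibility at infinite thresholds is degenerate", {
  study <- get_study()
  milrnas <- data.frame(id = "known-mir-1",
                        sequence = study$mature_reference[[1]] |>
                          as.character())
  lax <- screen_transboundary(milrnas, study$host$host_genome,
                              stability_mfe = -Inf, engine = engine)
  expect_true(all(lax$eligible))
  strict <- screen_transboundary(milrnas, study$host$host_genome,
                                 stability_mfe = Inf, engine = engine)
  expect_true(all(!strict$eligible[strict$n_matches > 0]))
})

test_that("host rulesets disagree exactly where their constraints differ", {
  m <- "TGCATCGAGCTACGATCGAT"
  sites <- c(perfect = design_site(m),
             pos10 = design_site(m, mismatch_pos = 10),
             seed3 = design_site(m, mismatch_pos = c(3, 5, 7)))
  tx <- Biostrings::DNAStringSet(vapply(sites, function(s)
    paste0("CCCC", s, "GGGG"), character(1)))
  ml <- data.frame(id = "m", sequence = m)
  acc <- lapply(c("expectation", "seed17", "allen"), function(rs)
    unique(predict_host_targets(ml, tx, rs)$transcript))
  names(acc) <- c("expectation", "seed17", "allen")
  for (rs in names(acc)) expect_true("perfect" %in% acc[[rs]])
  # position-10 mismatch: rejected by the expectation ruleset only
  expect_false("pos10" %in% acc$expectation)
  expect_true("pos10" %in% acc$seed17)
  expect_true("pos10" %in% acc$allen)
  # three seed mismatches overwhelm every ruleset's 4.0 cutoff
  for (rs in names(acc)) expect_false("seed3" %in% acc[[rs]])
  expect_error(predict_host_targets(ml, tx, "bogus"), "arg")
})

test_that("tightening the threshold never grows the accepted set", {
  set.seed(23)
  m <- rand_seq(21)
  tx <- Biostrings::DNAStringSet(setNames(
    c(paste0(rand_seq(10), design_site(m, wobble_pos =
               which(strsplit(m, "")[[1]] %in% c("G", "T"))[1]), rand_seq(10)),
      rand_seq(80)), c("t1", "t2")))
  ml <- data.frame(id = "m", sequence = m)
  loose <- predict_host_targets(ml, tx, host_ruleset("allen", threshold = 4))
  tight <- predict_host_targets(ml, tx, host_ruleset("allen", threshold = 1))
  key <- function(h) paste(h$transcript, h$site_start, h$states)
  expect_true(all(key(tight) %in% key(loose)))
})

test_that("consensus is the triple intersection, with faithful Venn counts", {
  mk <- function(pairs) data.frame(milrna = pairs, transcript = pairs,
                                   site_start = rep(1L, length(pairs)),
                                   site_end = rep(20L, length(pairs)),
                                   states = rep("", length(pairs)),
                                   score = rep(0, length(pairs)),
                                   ruleset = rep("x", length(pairs)))
  ten <- sprintf("p%02d", 1:10)
  hits <- list(a = mk(c(ten, "only_a")), b = mk(c(ten, "only_b")),
               c = mk(c(ten, "only_c1", "only_c2", "only_c3")))
  out <- consensus_targets(hits)
  expect_equal(nrow(out$consensus), 10L)
  expect_equal(unname(out$venn[["111"]]), 10L)
  expect_equal(unname(out$venn[["100"]]), 1L)
  expect_equal(unname(out$venn[["001"]]), 3L)
  # a pair accepted by two rulesets is not consensus
  expect_false("only_a" %in% out$consensus$transcript)
  two <- list(a = mk(c("x", "y")), b = mk(c("x", "y")), c = mk("z"))
  expect_equal(nrow(consensus_targets(two)$consensus), 0L)
  # empty inputs give an empty consensus and an all-zero Venn
  none <- consensus_targets(list(a = mk(character()), b = mk(character()),
                                 c = mk(character())))
  expect_equal(nrow(none$consensus), 0L)
  expect_true(all(none$venn == 0L))
  # consensus is contained in every ruleset's accepted set
  for (h in hits) {
    expect_true(all(out$consensus$transcript %in% h$transcript))
  }
})

test_that("gene mapping collapses transcripts in the Venn", {
  mk <- function(tx) data.frame(milrna = "m", transcript = tx,
                                site_start = 1L, site_end = 20L,
                                states = "", score = 0, ruleset = "x")
  gm <- c(t1 = "geneA", t2 = "geneA", t3 = "geneB")
  out <- consensus_targets(list(a = mk("t1"), b = mk("t2"), c = mk("t2")),
                           gene_map = gm)
  # t1 and t2 are the same gene, so geneA is seen by all three rulesets
  expect_equal(unname(out$venn[["111"]]), 1L)
})
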