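test_that("known-milRNA matching honours the mismatch and slack budget", {
  ref <- Biostrings::DNAStringSet(c(mir1 = "TGAAACCGCGAACAAACTTGCC",
                                    mir2 = "ACGGTCAAGCTCATGCATGACT"))
  exact <- data.frame(sequence = "TGAAACCGCGAACAAACTTGCC", count = 5L)
  hit <- match_known(exact, ref)
  expect_equal(hit$reference, "mir1")
  expect_equal(hit$mismatches, 0L)
  # two substitutions pass, three do not
  two <- data.frame(sequence = "TGTAACCGCGAACAAACTAGCC", count = 1L)
  expect_equal(match_known(two, ref)$mismatches, 2L)
  three <- data.frame(sequence = "TGTAACCGCGTACAAACTAGCC", count = 1L)
  expect_equal(nrow(match_known(three, ref)), 0L)
  # a tag overhanging the reference by 2 nt still matches (slack positions
  # count as mismatches)
  slack <- data.frame(sequence = "CCTGAAACCGCGAACAAACTTG", count = 1L)
  expect_equal(nrow(match_known(slack, ref)), 1L)
})

test_that("a synthetic reference with 21 planted matures yields 21 matches", {
  set.seed(17)
  seqs <- vapply(1:21, function(i) rand_seq(21), character(1))
  ref <- Biostrings::DNAStringSet(setNames(seqs, sprintf("mir%02d", 1:21)))
  tags <- data.frame(sequence = c(seqs, vapply(1:5, function(i) rand_seq(21),
                                               character(1))),
                     count = 1L)
  hits <- match_known(tags, ref)
  expect_equal(sum(tags$sequence[1:21] %in% hits$sequence), 21L)
})

test_that("TPM follows count/total x 1e6 and sums to one million", {
  expect_equal(tpm(0, 100), 0)
  expect_equal(tpm(100, 100), 1e6)
  expect_equal(round(tpm(24796, 13464142), 2), 1841.63)
  counts <- c(5, 120, 33, 900, 1)
  expect_equal(sum(tpm(counts, sum(counts))), 1e6)
  expect_error(tpm(1, 0), "positive")
})

test_that("the milRNA table renders locations, lengths and arm suffixes", {
  cands <- data.frame(
    mature = c("TGAAACCGCGAACAAACTTG", "ACGGTCAAGCTCATGCATGA",
               "TTGCCGGCTCTCCAACTCTC"),
    count = c(24796L, 100L, 90L), arm = c("5p", "3p", "5p"),
    contig = c("scaffold_3", "scaffold_8", "scaffold_8"),
    pre_start = c(1682263L, 1880833L, 1880833L),
    pre_end = c(1682370L, 1880914L, 1880914L),
    strand = c("+", "+", "+"),
    precursor = "", structure = "", mfe = c(-49.4, -23.9, -23.9),
    star = "", space = 20L, bulge = 0L, asymmetry = 0L, truncated = FALSE)
  tab <- milrna_table(cands)
  expect_equal(tab$precursor_location[1], "scaffold_3:1682263:1682370:+")
  expect_equal(tab$precursor_length[1], 108L)
  expect_true(all(tab$precursor_length ==
                    cands$pre_end[match(tab$precursor_location,
                                        paste(cands$contig, cands$pre_start,
                                              cands$pre_end, cands$strand,
                                              sep = ":"))] -
                    cands$pre_start[match(tab$precursor_location,
                                          paste(cands$contig, cands$pre_start,
                                                cands$pre_end, cands$strand,
                                                sep = ":"))] + 1L))
  # two matures from one precursor share the number with arm suffixes
  shared <- tab$novel_milRNA[tab$precursor_location ==
                               "scaffold_8:1880833:1880914:+"]
  expect_setequal(shared, c("milR002-3p", "milR002-5p"))
  # ranking follows read counts
  expect_equal(tab$novel_milRNA[1], "milR001-5p")
  expect_equal(nrow(milrna_table(cands[0, ])), 0L)
})

test_that("the hairpin assessor reads duplex geometry from the structure", {
  # handcrafted fold-backs: 18 nt mature paired to an 18 nt star
  ok_struct <- paste0(strrep("(", 18), strrep(".", 20), strrep(")", 18))
  a <- assess_hairpin(ok_struct, -30, 1, 18)
  expect_true(a$ok)
  expect_equal(a$arm, "5p")
  expect_equal(a$space, 20L)
  expect_equal(a$bulge, 0L)
  # the same duplex seen from the star side is a 3p arm
  b <- assess_hairpin(ok_struct, -30, 39, 56)
  expect_equal(b$arm, "3p")
})

test_that("planted hairpins are recovered with their planted geometry", {
  res <- get_result()
  study <- get_study()
  truth <- study$genome$truth$milrnas
  found <- c(res$discovery$table$sequence, res$discovery$known$sequence)
  expect_gte(mean(truth$mature %in% found), 0.95)
  # recovered arms match the planted arms
  cand <- res$discovery$candidates
  m <- match(cand$mature, truth$mature)
  expect_equal(cand$arm[!is.na(m)], truth$arm[m[!is.na(m)]])
  # reported precursor span contains the planted mature locus
  for (i in which(!is.na(m))) {
    expect_lte(cand$pre_start[i], truth$mature_start[m[i]])
    expect_gte(cand$pre_end[i], truth$mature_end[m[i]])
  }
})
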