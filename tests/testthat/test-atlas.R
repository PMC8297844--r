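test_that("collapsing preserves total counts and aggregates duplicates", {
  ins <- c(rep("AAACCCGGGTTTAAACCCGG", 3), "GGGTTTAAACCCGGGTTTAA")
  tags <- collapse_tags(ins)
  expect_equal(nrow(tags), 2L)
  expect_equal(tags$count, c(3L, 1L))
  expect_equal(sum(tags$count), length(ins))
  expect_equal(nrow(collapse_tags(character())), 0L)
})

test_that("mapping agrees with a naive substring-scan oracle", {
  set.seed(21)
  genome_seq <- rand_seq(5000)
  genome <- Biostrings::DNAStringSet(c(chr1 = genome_seq))
  # tags: several genuine windows plus one absent sequence
  starts <- c(11, 500, 1200, 4000)
  tags <- collapse_tags(c(
    substring(genome_seq, starts, starts + 19),
    naive_rc(substring(genome_seq, 2000, 2021)),
    "TTTTTTTTTTTTTTTTTTGG"))
  hits <- map_tags(tags, genome)
  for (i in seq_len(nrow(tags))) {
    seq <- tags$sequence[i]
    fwd <- gregexpr(seq, genome_seq, fixed = TRUE)[[1]]
    rev <- gregexpr(naive_rc(seq), genome_seq, fixed = TRUE)[[1]]
    n_expected <- sum(fwd > 0) + sum(rev > 0)
    expect_equal(sum(hits$sequence == seq), n_expected)
  }
  # the reverse-complement tag is reported on the minus strand
  rc_hit <- hits[hits$sequence == naive_rc(substring(genome_seq, 2000, 2021)), ]
  expect_equal(rc_hit$strand, "-")
  expect_equal(rc_hit$start, 2000L)
  expect_equal(rc_hit$end, 2021L)
})

test_that("a tag inside a tandem repeat maps to both copies", {
  unit <- "ACGGTCAAGCTCATGCATGA"
  genome <- Biostrings::DNAStringSet(c(
    chr1 = paste0(strrep("T", 30), unit, unit, strrep("C", 30))))
  hits <- map_tags(collapse_tags(unit), genome)
  expect_equal(nrow(hits[hits$strand == "+", ]), 2L)
  expect_error(map_tags(collapse_tags(unit), Biostrings::DNAStringSet()),
               "empty genome")
})

test_that("classification follows the precedence order and truth decoys", {
  study <- get_study()
  g <- study$genome
  decoys <- g$truth$decoys
  # one tag sampled from inside each decoy locus
  tag_seqs <- substring(decoys$seq, 5, 26)
  tags <- collapse_tags(tag_seqs)
  loci <- map_tags(tags, g$genome)
  cls <- classify_tags(tags, loci, g$tracks, g$ncrna)
  got <- cls$categories$category[match(tag_seqs, cls$categories$sequence)]
  want <- ifelse(decoys$class %in% c("exon", "intron"),
                 paste0(decoys$class, "_sense"), decoys$class)
  expect_equal(got, want)
  # summary conservation: totals sum to the clean totals
  expect_equal(sum(cls$summary$total), sum(tags$count))
  expect_equal(sum(cls$summary$unique), nrow(tags))
})

test_that("a tag matching both a tRNA reference and an exon takes tRNA", {
  seq <- "TGCACTGACGGTCAAGCTCA"
  genome <- Biostrings::DNAStringSet(c(
    chr1 = paste0(strrep("A", 50), seq, strrep("C", 50))))
  tags <- collapse_tags(seq)
  loci <- map_tags(tags, genome)
  tracks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(40, 80),
                                   strand = "+", type = "exon")
  ncrna <- list(tRNA = Biostrings::DNAStringSet(paste0("GG", seq, "CC")))
  cls <- classify_tags(tags, loci, tracks, ncrna)
  expect_equal(cls$categories$category, "tRNA")
  # reversed precedence puts the exon first
  cls2 <- classify_tags(tags, loci, tracks, ncrna,
                        precedence = c("exon_sense", "tRNA", "unannotated",
                                       "unmapped"))
  expect_equal(cls2$categories$category, "exon_sense")
})

test_that("category percentages reproduce the published summary values", {
  counts <- data.frame(category = c("rRNA", "unannotated"),
                       total = c(1312667, 11725692),
                       unique = c(86509, 1694925))
  out <- category_percentages(counts, total_reads = 13464142,
                              total_unique = 1858454)
  expect_equal(out$total_percent[out$category == "rRNA"], 9.75)
  expect_equal(out$unique_percent[out$category == "unannotated"], 91.2)
})

test_that("length histogram and first-base fractions behave", {
  tags <- collapse_tags(c("TGAAACCGCGAACAAACTTG", "TGCACTGACGGTCAAGCTCA",
                          "AGCACTGACGGTCAAGCTCAT"))
  prof <- length_first_base_profile(tags)
  expect_equal(prof$lengths$n_unique[prof$lengths$length == 20], 2L)
  expect_equal(prof$lengths$n_unique[prof$lengths$length == 21], 1L)
  # fractions sum to 1 within each populated length class
  sums <- tapply(prof$first_base$fraction, prof$first_base$length, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # forced 5'-T tags give T fraction 1 at every length
  t20 <- prof$first_base[prof$first_base$length == 20, ]
  expect_equal(t20$fraction[t20$base == "T"], 1)
  empty <- length_first_base_profile(collapse_tags(character()))
  expect_equal(nrow(empty$lengths), 0L)
})
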