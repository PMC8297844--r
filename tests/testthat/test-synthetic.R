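test_that("empty genome build yields empty truth", {
  g <- build_genome(0, 0, 10000, rng_seed = 1)
  expect_equal(nrow(g$truth$milrnas), 0L)
  expect_equal(nrow(g$truth$decoys), 0L)
  expect_equal(sum(Biostrings::width(g$genome)), 10000L)
})

test_that("genome building is reproducible and truth lists have the right sizes", {
  g1 <- build_genome(5, 2, 50000, rng_seed = 7, engine = engine)
  g2 <- build_genome(5, 2, 50000, rng_seed = 7, engine = engine)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$truth$milrnas, g2$truth$milrnas)
  expect_equal(nrow(g1$truth$milrnas), 5L)
  expect_equal(nrow(g1$truth$decoys), 14L)  # 2 per class x 7 classes
})

test_that("planted precursors satisfy the hairpin criteria when refolded", {
  g <- build_genome(1, 0, 10000, rng_seed = 3, engine = engine)
  tr <- g$truth$milrnas
  pre <- as.character(Biostrings::subseq(g$genome[[1]], tr$pre_start, tr$pre_end))
  if (tr$strand == "-") {
    pre <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(pre)))
  }
  # mature is an exact substring of its precursor
  expect_true(grepl(tr$mature, pre, fixed = TRUE))
  fold <- engine$fold(pre)
  expect_lte(fold$mfe, -18)
  off <- regexpr(tr$mature, pre, fixed = TRUE)
  a <- assess_hairpin(fold$structure, fold$mfe, off,
                      off + nchar(tr$mature) - 1L)
  expect_true(a$ok)
})

test_that("a clean library survives all six filters", {
  g <- build_genome(2, 0, 20000, rng_seed = 5, engine = engine)
  reads <- simulate_reads(g$truth, n_reads = 500, rng_seed = 2)
  cl <- cleanse(reads)
  expect_equal(cl$report$clean_tags, 500L)
  expect_equal(length(cl$inserts), 500L)
})

test_that("an all-adapter-dimer library is fully attributed to insert_null", {
  g <- build_genome(1, 0, 10000, rng_seed = 5, engine = engine)
  reads <- simulate_reads(g$truth, n_reads = 200,
                          contamination_rates = c(insert_null = 1),
                          rng_seed = 2)
  cl <- cleanse(reads)
  expect_equal(cl$report$clean_tags, 0L)
  expect_equal(cl$report$insert_null, 200L)
  pct <- report_percentages(cl$report)
  expect_equal(pct$percent[pct$category == "insert_null"], 100)
})

test_that("per-class contamination counts stay within 3-sigma binomial bounds", {
  g <- build_genome(2, 0, 20000, rng_seed = 5, engine = engine)
  rates <- c(low_quality = 0.05, adapter3_null = 0.05, insert_null = 0.02,
             adapter5 = 0.01, polyA = 0.01, short = 0.05)
  n <- 10000L
  reads <- simulate_reads(g$truth, n_reads = n, contamination_rates = rates,
                          rng_seed = 11)
  obs <- table(factor(reads$class, levels = names(rates)))
  for (cls in names(rates)) {
    expected <- n * rates[[cls]]
    sigma <- sqrt(n * rates[[cls]] * (1 - rates[[cls]]))
    expect_lt(abs(obs[[cls]] - expected), 3 * sigma)
  }
})

test_that("same seed gives byte-identical FASTQ output", {
  g <- build_genome(1, 0, 10000, rng_seed = 5, engine = engine)
  r1 <- simulate_reads(g$truth, n_reads = 50, rng_seed = 9)
  r2 <- simulate_reads(g$truth, n_reads = 50, rng_seed = 9)
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq(r1, f1); write_fastq(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(simulate_reads(g$truth, contamination_rates = c(bogus = 0.1)),
               "unknown contamination class")
})

test_that("designed sites reverse-complement-match except at designed positions", {
  m <- "TGAAACCGCGAACAAACTTG"
  expect_identical(design_site(m), naive_rc(m))
  s <- design_site(m, mismatch_pos = 10, wobble_pos = 8)
  st <- align_site(m, s)
  st <- st[st$offset == 1, ]
  expect_identical(substr(st$states, 10, 10), "X")
  expect_identical(substr(st$states, 8, 8), "W")
  expect_equal(st$n_mismatch, 1L)
  expect_equal(st$n_wobble, 1L)
  expect_error(design_site(m, mismatch_pos = 25), "inconsistent")
  expect_error(design_site(m, wobble_pos = 5), "requires G or T")
})

test_that("host building records planted sites and validates milRNA ids", {
  study <- get_study()
  sites <- study$host$truth$target_sites
  expect_equal(nrow(sites), 6L)
  # each designed site really sits at its recorded offset
  for (r in seq_len(nrow(sites))) {
    tx <- as.character(study$host$transcripts[[sites$transcript[r]]])
    mi <- match(sites$milrna[r], study$genome$truth$milrnas$id)
    mseq <- study$genome$truth$milrnas$mature[mi]
    win <- substr(tx, sites$site_start[r], sites$site_end[r])
    mm_designed <- sites$n_mismatch[r] + sites$n_wobble[r]
    aln <- align_site(mseq, win)
    expect_equal(aln$n_mismatch[1] + aln$n_wobble[1], mm_designed)
  }
  expect_error(build_host(study$genome$truth, 2,
                          site_design = data.frame(milrna = "nope")),
               "unknown milRNA")
})
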