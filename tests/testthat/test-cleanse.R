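adapter3 <- cleanse_params()$adapter3
adapter5 <- cleanse_params()$adapter5

make_reads <- function(seqs, quals = NULL) {
  if (is.null(quals)) quals <- strrep("G", nchar(seqs))
  structure(list(id = sprintf("r%03d", seq_along(seqs)), sequence = seqs,
                 quality = quals, class = NULL),
            class = "fastq_reads")
}

test_that("reads with two low-quality bases or Ns are removed first", {
  insert <- "TGAAACCGCGAACAAACTTG"
  read <- paste0(insert, adapter3)
  qual_bad <- paste0("++", strrep("G", nchar(read) - 2))   # two Q10 bases
  qual_one <- paste0("+", strrep("G", nchar(read) - 1))    # one Q10 base
  cl <- cleanse(make_reads(c(read, read, sub("G", "N", read)),
                           c(qual_bad, qual_one, strrep("G", nchar(read)))))
  expect_equal(cl$report$low_quality_removed, 2L)  # bad quality + N
  expect_equal(cl$report$clean_tags, 1L)
  expect_identical(cl$inserts, insert)
})

test_that("adapter-dimer and adapterless reads hit their own categories", {
  insert <- "TGAAACCGCGAACAAACTTG"
  cl <- cleanse(make_reads(c(adapter3,                     # empty insert
                             insert,                       # no 3' adapter
                             paste0(adapter5, "CA", adapter3),  # 5' adapter
                             paste0(strrep("A", 20), adapter3), # poly-A
                             paste0("TGCAATCGCATGCCT", adapter3)))) # 15 nt
  expect_equal(cl$report$insert_null, 1L)
  expect_equal(cl$report$adapter3_null, 1L)
  expect_equal(cl$report$adapter5_contaminant, 1L)
  expect_equal(cl$report$polyA, 1L)
  expect_equal(cl$report$shorter_than_18nt, 1L)
  expect_equal(cl$report$clean_tags, 0L)
})

test_that("filter categories agree exactly with simulated truth labels", {
  g <- build_genome(3, 0, 30000, rng_seed = 5, engine = engine)
  reads <- simulate_reads(g$truth, n_reads = 4000,
                          contamination_rates = c(low_quality = 0.05,
                                                  adapter3_null = 0.05,
                                                  insert_null = 0.02,
                                                  adapter5 = 0.01,
                                                  polyA = 0.01, short = 0.05),
                          rng_seed = 11)
  cl <- cleanse(reads)
  truth <- table(reads$class)
  expect_equal(cl$report$low_quality_removed, unname(truth["low_quality"]))
  expect_equal(cl$report$adapter3_null, unname(truth["adapter3_null"]))
  expect_equal(cl$report$insert_null, unname(truth["insert_null"]))
  expect_equal(cl$report$adapter5_contaminant, unname(truth["adapter5"]))
  expect_equal(cl$report$polyA, unname(truth["polyA"]))
  expect_equal(cl$report$shorter_than_18nt, unname(truth["short"]))
  expect_equal(cl$report$clean_tags, unname(truth["clean"]))
  # conservation: every read lands in exactly one terminal category
  r <- cl$report
  expect_equal(r$low_quality_removed + r$adapter3_null + r$insert_null +
                 r$adapter5_contaminant + r$polyA + r$shorter_than_18nt +
                 r$longer_than_max + r$clean_tags,
               r$clean_reads)
  expect_equal(r$high_quality, r$clean_reads - r$low_quality_removed)
})

test_that("raising the quality threshold never increases high_quality", {
  g <- build_genome(2, 0, 20000, rng_seed = 5, engine = engine)
  reads <- simulate_reads(g$truth, n_reads = 500,
                          contamination_rates = c(low_quality = 0.2),
                          rng_seed = 3)
  hq <- vapply(c(5L, 10L, 20L, 37L, 40L), function(q) {
    cleanse(reads, cleanse_params(quality_threshold = q))$report$high_quality
  }, integer(1))
  expect_true(all(diff(hq) <= 0))
})

test_that("cleansing already-clean inserts removes nothing", {
  g <- build_genome(2, 0, 20000, rng_seed = 5, engine = engine)
  reads <- simulate_reads(g$truth, n_reads = 300, rng_seed = 4)
  first <- cleanse(reads)
  rewrapped <- make_reads(paste0(first$inserts, adapter3))
  second <- cleanse(rewrapped)
  expect_identical(sort(second$inserts), sort(first$inserts))
  expect_equal(second$report$clean_tags, length(first$inserts))
})

test_that("malformed records are reported with their index", {
  bad <- make_reads("ACGTACGTACGTACGTACGTA", "GGG")
  expect_error(cleanse(bad), "record 1")
})

test_that("percentage conventions match the published accounting table", {
  # counts as printed in the study's read-accounting table
  rep <- filter_report(clean_reads = 15049834,
                       low_quality_removed = 15049834 - 14851368,
                       adapter3_null = 27899, insert_null = 98745,
                       adapter5_contaminant = 9355, polyA = 193,
                       shorter_than_18nt = 1251034)
  expect_equal(rep$high_quality, 14851368L)
  expect_equal(rep$clean_tags, 13464142L)
  pct <- report_percentages(rep)
  val <- function(cat) pct$percent[pct$category == cat]
  expect_equal(val("high_quality"), 98.68)
  expect_equal(val("3'adapter_null"), 0.19)
  expect_equal(val("insert_null"), 0.66)
  expect_equal(val("5'adapter_contaminants"), 0.06)
  expect_equal(val("smaller_than_18nt"), 8.42)
  expect_equal(val("clean_tags"), 90.66)
})

test_that("zero counts yield NA percentages, not division errors", {
  pct <- report_percentages(filter_report(clean_reads = 0))
  expect_true(all(is.na(pct$percent)))
})
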