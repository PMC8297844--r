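#!/usr/bin/env Rscript

# Stage 5 -- transboundary screen, host target prediction and consensus.
#
# Screens every discovered milRNA against the host genome (full-length
# exact matches whose +/-100 bp flanks fold at or below -85 kcal/mol mark a
# milRNA as host-encoded and ineligible), predicts target sites in the host
# transcripts for the eligible milRNAs under the three rulesets
# (expectation / seed17 / allen, all with cutoff 4.0), and reports the
# pairs accepted by all three together with the Venn decomposition.
# Also demonstrates the six-rule fungal self-target verification on a small
# designed fungal transcript set.

suppressPackageStartupMessages(library(milkit))

if (!file.exists("results/milrna_set.tsv")) {
  stop("run analysis/04_discovery.R first")
}
milrnas <- read.delim("results/milrna_set.tsv")
host_genome <- Biostrings::readDNAStringSet(
  "results/data/host_genome.synthetic.fasta")
transcripts <- Biostrings::readDNAStringSet(
  "results/data/host_transcripts.fasta")
engine <- vienna_engine()

screen <- screen_transboundary(milrnas, host_genome, engine = engine)
write.table(screen, "results/transboundary_screen.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(screen, row.names = FALSE)
eligible <- milrnas[milrnas$id %in% screen$milrna[screen$eligible], ]
message(nrow(eligible), " of ", nrow(milrnas),
        " milRNAs eligible for transboundary target prediction")

hits <- lapply(c("expectation", "seed17", "allen"), function(rs) {
  h <- predict_host_targets(eligible, transcripts, rs)
  message(rs, ": ", length(unique(paste(h$milrna, h$transcript))),
          " (milRNA, transcript) pairs")
  h
})
names(hits) <- c("expectation", "seed17", "allen")
all_hits <- do.call(rbind, hits)
write.table(all_hits, "results/host_target_hits.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cons <- consensus_targets(hits)
write.table(cons$consensus, "results/consensus_targets.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(region = names(cons$venn), genes = cons$venn),
            "results/venn_counts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("consensus (all three rulesets): ", nrow(cons$consensus),
        " pairs; Venn centre ", cons$venn[["111"]])

# self-target verification demo: the fungal exon decoys plus one designed
# perfect-complement transcript for the top milRNA
decoy_exons <- local({
  tr <- read.delim("results/data/truth_decoys.tsv")
  gen <- Biostrings::readDNAStringSet("results/data/fungal_genome.fasta")
  ex <- tr[tr$class == "exon", ]
  s <- Biostrings::DNAStringSet(vapply(seq_len(nrow(ex)), function(i)
    as.character(Biostrings::subseq(gen[[1]], ex$start[i], ex$end[i])),
    character(1)))
  names(s) <- sprintf("fungal_tx_%02d", seq_len(nrow(ex)))
  s
})
designed <- Biostrings::DNAStringSet(c(fungal_tx_designed = paste0(
  "GCGC", design_site(milrnas$sequence[1]), "ATAT")))
self_hits <- verify_self_targets(milrnas,
                                 c(decoy_exons, designed),
                                 engine = engine)
write.table(self_hits, "results/self_targets.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(nrow(self_hits), " verified self-target site(s) (designed: 1)")
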