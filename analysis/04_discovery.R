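#!/usr/bin/env Rscript

# Stage 4 -- milRNA discovery.
#
# Splits unannotated tags into known milRNAs (matched against the mature
# reference with at most two substitutions) and novel candidates (called
# from hairpin precursors under the eleven structural criteria, folding
# candidate windows with ViennaRNA), computes TPM over the clean-tag total
# and writes the novel-milRNA table.

suppressPackageStartupMessages(library(milkit))

if (!file.exists("results/tags_classified.tsv")) {
  stop("run analysis/03_atlas.R first")
}
tags <- read.delim("results/tags_classified.tsv")
genome <- Biostrings::readDNAStringSet("results/data/fungal_genome.fasta")
reference <- Biostrings::readDNAStringSet("results/data/known_mature.fasta")
engine <- vienna_engine()

loci <- map_tags(tags, genome)
unann <- tags[tags$category == "unannotated", ]
known <- match_known(unann, reference)
novel_pool <- unann[!unann$sequence %in% known$sequence, ]

message("folding candidate precursor windows for ", nrow(novel_pool),
        " unannotated tags ...")
cands <- call_hairpins(novel_pool, loci, genome, engine = engine)
tab <- milrna_table(cands)
tab$TPM <- round(tpm(tab$total_reads, sum(tags$count)), 2)

write.table(known, "results/known_milrnas.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(tab, "results/table3_novel_milrnas.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(id = c(tab$novel_milRNA, known$reference),
                       sequence = c(tab$sequence, known$sequence)),
            "results/milrna_set.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
writeLines(paste0(">", tab$novel_milRNA, "\n", cands$structure[
  match(tab$sequence, cands$mature)]), "results/precursor_structures.txt")

message(nrow(known), " known milRNA(s), ", nrow(tab),
        " novel milRNA(s); precursor MFE range ",
        if (nrow(tab)) paste(min(tab$mfe), "..", max(tab$mfe)) else "-",
        " kcal/mol")
print(tab, row.names = FALSE)

truth <- read.delim("results/data/truth_milrnas.tsv")
rec <- mean(truth$mature %in% c(tab$sequence, known$sequence))
message("planted-truth recovery: ", round(100 * rec, 1), "%")
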