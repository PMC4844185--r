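#!/usr/bin/env Rscript

# Stage 2: resolve read placements.
#
# Reads the stage-1 FASTQ libraries, enumerates all candidate loci per pair
# (up to 2 mismatches per mate), randomly assigns each multi-mapping pair to
# one of its equally best loci, and removes PCR duplicates at the fragment
# level. Placement TSVs go to scratch/placements/; a mapping summary goes to
# results/.

suppressMessages(library(neocenscan))

seed <- 20160405L
data_dir <- "scratch/data"
out_dir <- "scratch/placements"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

genome_fa <- Biostrings::readDNAStringSet(file.path(data_dir, "genome.fa"))
index <- build_genome_index(genome_fa)

stats <- list()
for (lib in c("chip_4ds", "control_cs")) {
  reads <- read_fastq_pairs(file.path(data_dir, paste0(lib, "_1.fastq")),
                            file.path(data_dir, paste0(lib, "_2.fastq")))
  pl <- map_reads(reads, genome_fa, seed = derive_seed(seed, lib), index = index)
  write_placements(pl, file.path(out_dir, paste0(lib, ".placements.tsv")))
  stats[[lib]] <- data.frame(
    library = lib,
    pairs = attr(pl, "n_pairs"),
    mapped = attr(pl, "n_mapped"),
    unmapped = attr(pl, "n_unmapped"),
    duplicates_removed = attr(pl, "n_duplicates_removed"),
    surviving_fragments = nrow(pl),
    multimapped = sum(pl$n_equal_best > 1))
  cat(sprintf("%s: %d pairs, %d mapped (%.2f%%), %d duplicates removed, %d surviving, %d surviving multi-mappers\n",
              lib, attr(pl, "n_pairs"), attr(pl, "n_mapped"),
              100 * attr(pl, "n_mapped") / attr(pl, "n_pairs"),
              attr(pl, "n_duplicates_removed"), nrow(pl),
              sum(pl$n_equal_best > 1)))
}
write.table(do.call(rbind, stats), "results/02_mapping_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
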