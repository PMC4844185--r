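#!/usr/bin/env Rscript

# Stage 1: simulate the study inputs.
#
# Builds a fragmented genome assembly (200 scaffolds, 1.6-32 kb) carrying a
# planted 5-scaffold neocentromere with elevated GC and transposable-element
# content, then draws a CENH3 ChIP (treatment, 50-fold enrichment over the
# planted block) and a deeper control library. FASTA/GFF3/FASTQ and the
# truth table go to scratch/data/ (large, regenerable); a genome summary
# table goes to results/.

suppressMessages(library(neocenscan))

seed <- 20160405L
dir.create("results", showWarnings = FALSE)
data_dir <- "scratch/data"

gspec <- genome_spec(seed = seed)
genome <- simulate_genome(gspec)
paths <- write_genome(genome, data_dir)

rspec_t <- read_sim_spec(n_fragments = 250000L, seed = seed)
rspec_c <- read_sim_spec(n_fragments = 1000000L, seed = seed)
treat <- simulate_reads(genome, rspec_t, "treatment")
ctrl <- simulate_reads(genome, rspec_c, "control")
write_fastq(treat, file.path(data_dir, "chip_4ds"))
write_fastq(ctrl, file.path(data_dir, "control_cs"))
jsonlite::write_json(list(treatment = unclass(rspec_t),
                          control = unclass(rspec_c)),
                     file.path(data_dir, "read_specs.json"),
                     auto_unbox = TRUE, digits = NA)

truth <- genome$truth$table
summary_tab <- data.frame(
  what = c("scaffolds", "genome_bp", "planted_scaffolds", "planted_bp",
           "planted_fraction_pct", "genes", "repeat_families",
           "chip_pairs", "control_pairs"),
  value = c(nrow(truth), sum(truth$length), sum(truth$is_neocen),
            sum(truth$length[truth$is_neocen]),
            round(100 * sum(truth$length[truth$is_neocen]) / sum(truth$length), 2),
            sum(truth$gene_count), length(genome$repeat_library),
            length(treat$id), length(ctrl$id)))
write.table(summary_tab, "results/01_genome_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Simulated genome:", nrow(truth), "scaffolds,",
    round(sum(truth$length) / 1e6, 2), "Mb;",
    sum(truth$is_neocen), "planted scaffolds totalling",
    sum(truth$length[truth$is_neocen]), "bp (",
    summary_tab$value[5], "% of the genome).\n")
cat("Planted block:", paste(genome$truth$neocen_ids, collapse = ", "), "\n")
cat("Libraries: ChIP", length(treat$id), "pairs; control", length(ctrl$id),
    "pairs. Files under", data_dir, "\n")
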