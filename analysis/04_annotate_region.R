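#!/usr/bin/env Rscript

# Stage 4: annotate the candidate region and run the intensity comparison.
#
# Computes pooled and per-scaffold GC of the candidate region, counts
# overlapping gene models, scores repeat composition against the repeat
# library by seed-and-extend homology, confirms the top candidate scaffold
# against a second "relative" genome, and runs the two-tailed Student's
# t-test on a synthetic per-cell fluorescence-intensity table (the ImageJ
# export workflow). Everything is folded into the final run report.

suppressMessages(library(neocenscan))

seed <- 20160405L
data_dir <- "scratch/data"
genome_fa <- Biostrings::readDNAStringSet(file.path(data_dir, "genome.fa"))
repeats <- Biostrings::readDNAStringSet(file.path(data_dir, "repeat_library.fa"))
truth <- read.table(file.path(data_dir, "truth.tsv"), header = TRUE, sep = "\t")

selection <- read.table("results/03_scaffold_enrichment.tsv", header = TRUE,
                        sep = "\t", stringsAsFactors = FALSE)
region <- assemble_region(selection, genome_fa)
stopifnot(!is.null(region))
member_seqs <- genome_fa[region$scaffold_ids]

gc <- gc_content(member_seqs)
genes <- count_genes_in_region(region, file.path(data_dir, "genes.gff3"),
                               genome_fa)
rc <- repeat_composition(member_seqs, repeats)
write.table(rc$coverage, "results/04_repeat_coverage.bed.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("Region annotation: GC %.2f%%, %d genes, repeat fraction %.1f%%\n",
            100 * as.numeric(gc), genes$gene_count, 100 * rc$repeat_fraction))

# cross-genome confirmation: scan the top-ratio scaffold against a relative
# genome emulated by mutating the true member sequences to ~95% identity
top <- selection$scaffold_id[selection$selected][1]
set.seed(derive_seed(seed, "relative-genome"))
mutate <- function(s, rate = 0.05) {
  ch <- strsplit(as.character(s), "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  ch[hit] <- vapply(ch[hit], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  paste(ch, collapse = "")
}
relative <- Biostrings::DNAStringSet(
  setNames(vapply(as.character(member_seqs), mutate, ""),
           paste0("rel_", names(member_seqs))))
hits <- homology_scan(genome_fa[[top]], relative, min_identity = 0.85,
                      min_length = 200, query_id = top)
write.table(hits, "results/04_homology_hits.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Homology confirmation:", nrow(hits), "hits for", top,
    "against the synthetic relative genome; best:",
    if (nrow(hits)) sprintf("%s %d-%d (%.1f%% identity, %d bp)",
                            hits$target_id[1], hits$t_start[1], hits$t_end[1],
                            100 * hits$identity[1], hits$aligned_length[1])
    else "none", "\n")

# per-cell relative fluorescence intensities, target arm vs wild type
set.seed(derive_seed(seed, "intensity"))
intensity <- data.frame(
  cell_id = sprintf("cell_%02d", 1:40),
  group = rep(c("target", "control"), each = 20),
  relative_intensity = c(abs(rnorm(20, 0.25, 0.1)), abs(rnorm(20, 1.0, 0.1))))
write.table(intensity, "results/04_intensity_synthetic.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
it <- compare_intensity(intensity$relative_intensity[intensity$group == "target"],
                        intensity$relative_intensity[intensity$group == "control"])
cat(sprintf("Intensity comparison (synthetic): mean ratio %.3f, t = %.2f, two-tailed p = %.3g\n",
            it$mean_ratio, it$t, it$p_value))

report <- emit_report(
  enrichment = selection,
  config = list(selection = unclass(selection_config())),
  libraries = as.list(read.table("results/02_mapping_summary.tsv",
                                 header = TRUE, sep = "\t")),
  region = region,
  annotation = list(gc = as.numeric(gc), gene_count = genes$gene_count,
                    gene_ids = genes$gene_ids,
                    repeat_fraction = rc$repeat_fraction,
                    per_family_bp = as.list(rc$per_family_bp)),
  intensity = it,
  truth_ids = truth$scaffold_id[truth$is_neocen],
  seed = seed)
validate_report(report)
write_report(report, "results/04_run_report.json")
cat("Run report written to results/04_run_report.json\n")
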