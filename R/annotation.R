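#' Pooled GC content
#'
#' `(G + C) / (A + C + G + T)` pooled over all supplied sequences.
#' Ambiguity codes are excluded from numerator and denominator; their count
#' is reported in the `"n_ambiguous"` attribute.
#'
#' @param sequences Character vector, `DNAString` or `DNAStringSet`.
#' @return GC fraction in `[0, 1]`, with attribute `"n_ambiguous"`.
#' @export
gc_content <- function(sequences) {
  ss <- if (is(sequences, "DNAStringSet")) sequences
        else Biostrings::DNAStringSet(as.character(sequences))
  if (sum(Biostrings::width(ss)) == 0) stop("empty input")
  freq <- colSums(Biostrings::letterFrequency(ss, c("A", "C", "G", "T")))
  n_amb <- sum(Biostrings::width(ss)) - sum(freq)
  if (sum(freq) == 0) stop("input contains only ambiguous bases")
  structure(unname((freq["G"] + freq["C"]) / sum(freq)),
            n_ambiguous = as.integer(n_amb))
}

#' Count genes overlapping a candidate region
#'
#' A gene counts if any part of it overlaps a member scaffold (unanchored
#' mode: the gene lies on one of the region's scaffolds) or any anchored
#' chromosome interval (anchored mode). Each gene is counted once.
#'
#' @param region An `ncs_region` from [assemble_region()].
#' @param genes Gene models: a `GRanges`, or a path to a GFF3 file (records
#'   with type `gene` are used; 1-based closed coordinates per the GFF3
#'   convention).
#' @param genome Optional genome for validating gene sequence ids; unknown
#'   ids produce a warning and are skipped (error if all are skipped).
#' @return List with `gene_count` and `gene_ids`.
#' @export
count_genes_in_region <- function(region, genes, genome = NULL) {
  stopifnot(inherits(region, "ncs_region"))
  if (is.character(genes))
    genes <- rtracklayer::import(genes, format = "gff3")
  if ("type" %in% names(S4Vectors::mcols(genes)) &&
      any(S4Vectors::mcols(genes)$type == "gene"))
    genes <- genes[S4Vectors::mcols(genes)$type == "gene"]
  known <- unique(c(
    if (!is.null(genome)) names(genome_seqs(genome)),
    region$scaffold_ids,
    if (!is.null(region$anchored_intervals)) region$anchored_intervals$chrom))
  if (!is.null(genome)) {
    seqn <- as.character(GenomicRanges::seqnames(genes))
    bad <- !(seqn %in% known)
    if (all(bad) && length(genes) > 0)
      stop("all gene records reference unknown sequence ids")
    if (any(bad)) {
      warning(sum(bad), " gene record(s) on unknown sequence ids skipped")
      genes <- genes[!bad]
    }
  }
  ids <- gene_ids_of(genes)
  on_scaffold <- as.character(GenomicRanges::seqnames(genes)) %in% region$scaffold_ids
  hit <- on_scaffold
  if (!is.null(region$anchored_intervals) && nrow(region$anchored_intervals)) {
    ai <- region$anchored_intervals
    agr <- GenomicRanges::GRanges(ai$chrom, IRanges::IRanges(ai$start + 1L, ai$end))
    ov <- GenomicRanges::findOverlaps(genes, agr, ignore.strand = TRUE)
    hit[S4Vectors::queryHits(ov)] <- TRUE
  }
  list(gene_count = length(unique(ids[hit])), gene_ids = unique(ids[hit]))
}

gene_ids_of <- function(genes) {
  mc <- S4Vectors::mcols(genes)
  if ("ID" %in% names(mc) && !all(is.na(mc$ID))) as.character(mc$ID)
  else if ("Name" %in% names(mc)) as.character(mc$Name)
  else sprintf("gene_%d", seq_along(genes))
}

#' Repeat composition of a region
#'
#' Scans every region sequence against every repeat-library monomer with
#' [homology_scan()], merges overlapping hits (no double counting) and
#' reports the fraction of region bp covered by repeats plus per-family
#' coverage.
#'
#' @param region_seqs Named `DNAStringSet` (or character vector) of region
#'   member sequences.
#' @param repeat_library Named `DNAStringSet` of family monomers.
#' @param min_identity,seed_k Passed to [homology_scan()].
#' @param min_length Minimum hit length in bp.
#' @return List with `repeat_fraction`, `per_family_bp` (named numeric),
#'   `covered_bp`, `total_bp`, and `coverage` (a data.frame of merged
#'   covered intervals, 0-based half-open).
#' @export
repeat_composition <- function(region_seqs, repeat_library, min_identity = 0.8,
                               seed_k = 11L, min_length = 50L) {
  if (length(repeat_library) == 0L) stop("repeat library is empty")
  ss <- if (is(region_seqs, "DNAStringSet")) region_seqs
        else Biostrings::DNAStringSet(region_seqs)
  if (is.null(names(ss))) names(ss) <- sprintf("seq_%d", seq_along(ss))
  lib <- if (is(repeat_library, "DNAStringSet")) repeat_library
         else Biostrings::DNAStringSet(repeat_library)
  if (is.null(names(lib))) names(lib) <- sprintf("family_%d", seq_along(lib))
  all_hits <- list()
  for (f in names(lib)) {
    h <- homology_scan(lib[[f]], ss, min_identity = min_identity,
                       min_length = min_length, seed_k = seed_k, query_id = f)
    if (nrow(h)) all_hits[[f]] <- h
  }
  total_bp <- sum(Biostrings::width(ss))
  if (!length(all_hits))
    return(list(repeat_fraction = 0, per_family_bp = setNames(numeric(length(lib)), names(lib)),
                covered_bp = 0L, total_bp = total_bp,
                coverage = data.frame(scaffold_id = character(0), start = integer(0),
                                      end = integer(0), stringsAsFactors = FALSE)))
  hits <- do.call(rbind, all_hits)
  gr <- GenomicRanges::GRanges(hits$target_id,
                               IRanges::IRanges(hits$t_start + 1L, hits$t_end))
  merged <- GenomicRanges::reduce(gr)
  covered <- sum(GenomicRanges::width(merged))
  per_family <- vapply(names(lib), function(f) {
    h <- all_hits[[f]]
    if (is.null(h)) return(0)
    g <- GenomicRanges::GRanges(h$target_id, IRanges::IRanges(h$t_start + 1L, h$t_end))
    sum(GenomicRanges::width(GenomicRanges::reduce(g)))
  }, numeric(1))
  list(repeat_fraction = covered / total_bp,
       per_family_bp = per_family,
       covered_bp = covered, total_bp = total_bp,
       coverage = data.frame(scaffold_id = as.character(GenomicRanges::seqnames(merged)),
                             start = GenomicRanges::start(merged) - 1L,
                             end = GenomicRanges::end(merged),
                             stringsAsFactors = FALSE))
}

#' Two-sample comparison of fluorescence intensities
#'
#' Classical equal-variance (Student's) two-sample t-test with a two-tailed
#' p value, as used for relative centromeric-repeat fluorescence intensities
#' quantified per cell. Welch's unequal-variance test is available behind
#' `var_equal = FALSE`. Degenerate inputs with zero pooled variance return
#' `p = 1` when the group means are equal (no evidence of difference by
#' convention) and raise an error when they differ.
#'
#' @param a,b Numeric vectors of relative intensities (each of length >= 2,
#'   values >= 0).
#' @param var_equal Use the pooled-variance Student's test (default).
#' @return List: `mean_a`, `mean_b`, `mean_ratio` (a/b), `t`, `df`,
#'   `p_value`, `method`.
#' @export
compare_intensity <- function(a, b, var_equal = TRUE) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) >= 2, length(b) >= 2)
  if (any(c(a, b) < 0)) stop("relative intensities must be >= 0")
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(mean_a = mean(a), mean_b = mean(b),
                  mean_ratio = mean(a) / mean(b), t = 0,
                  df = length(a) + length(b) - 2, p_value = 1,
                  method = "Student's t (degenerate: zero variance, equal means)"))
    stop("zero variance in both groups with unequal means: t is undefined")
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  list(mean_a = mean(a), mean_b = mean(b), mean_ratio = mean(a) / mean(b),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value,
       method = if (var_equal) "Student's two-sample t (two-tailed)"
                else "Welch's two-sample t (two-tailed)")
}

#' Read an intensity measurement table
#' @param path TSV with columns `cell_id`, `group`, `relative_intensity`.
#' @return data.frame.
#' @export
read_intensity <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("cell_id", "group", "relative_intensity") %in% names(d)))
  if (any(d$relative_intensity < 0)) stop("relative_intensity must be >= 0")
  d
}
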