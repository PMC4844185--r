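#' Count deduplicated fragments per scaffold
#'
#' @param placements Deduplicated placement data.frame.
#' @param genome `ncs_genome` or named `DNAStringSet`; defines the scaffold
#'   universe (every scaffold appears in the result, zeros allowed).
#' @return Named integer vector over all scaffolds, summing to the number of
#'   placements.
#' @export
count_fragments <- function(placements, genome) {
  ids <- names(genome_seqs(genome))
  bad <- setdiff(unique(placements$scaffold_id), ids)
  if (length(bad))
    stop("placement references unknown scaffold(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  tab <- table(factor(placements$scaffold_id, levels = ids))
  setNames(as.integer(tab), ids)
}

#' Reads-per-million normalization
#'
#' `rpm(s) = count(s) / sum(counts) * 1e6`: each scaffold's deduplicated
#' fragment count normalized by library size, so that libraries of different
#' depth are comparable. The values always sum to 1e6.
#'
#' @param counts Named count vector (from [count_fragments()]).
#' @return Named numeric RPM vector.
#' @export
compute_rpm <- function(counts) {
  stopifnot(is.numeric(counts), all(counts >= 0))
  tot <- sum(as.numeric(counts))
  if (tot == 0) stop("no mapped fragments: all counts are zero")
  counts / tot * 1e6
}

#' Selection rule configuration
#'
#' Defaults are the published thresholds for wheat 4DS neocentromere
#' discovery: scaffolds with reads in both samples need an RPM ratio of at
#' least 20, and scaffolds with reads only in the treatment need at least 20
#' deduplicated fragments.
#'
#' @param ratio_threshold Minimum treatment/control RPM ratio (ratio branch).
#' @param count_threshold Minimum treatment fragment count (treatment-only
#'   branch).
#' @param min_enriched_count Minimum count in *both* samples for a scaffold
#'   to be considered as "having enriched reads" in the ratio branch.
#' @param pseudocount Optional fragment pseudocount added to both samples'
#'   counts when forming the ratio. The default 0 keeps the published rule:
#'   scaffolds with zero control counts are routed exclusively to the
#'   treatment-only branch, where the ratio is undefined. A positive value
#'   gives such scaffolds a finite ratio and makes them eligible for the
#'   ratio branch as well.
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(ratio_threshold = 20,
                             count_threshold = 20L,
                             min_enriched_count = 1L,
                             pseudocount = 0) {
  cfg <- list(ratio_threshold = ratio_threshold,
              count_threshold = as.integer(count_threshold),
              min_enriched_count = as.integer(min_enriched_count),
              pseudocount = pseudocount)
  stopifnot(cfg$ratio_threshold > 0, cfg$count_threshold > 0,
            cfg$min_enriched_count > 0, cfg$pseudocount >= 0)
  class(cfg) <- "selection_config"
  cfg
}

#' Two-branch differential scaffold selection
#'
#' Applies the published CENH3 ChIP-seq rule for fragmented assemblies: a
#' scaffold is selected when it has reads in both treatment and control and
#' its treatment/control RPM ratio is at least `ratio_threshold` (branch
#' `"ratio"`), or when it has reads only in the treatment sample and at
#' least `count_threshold` of them (branch `"treat_only"`). The ratio
#' direction is treatment over control (the direction that detects sequences
#' gained by the neocentromere-bearing line); the reverse ratio is also
#' emitted for audit.
#'
#' @param treat,control Named fragment-count vectors over the identical
#'   scaffold universe (from [count_fragments()]).
#' @param cfg A [selection_config()].
#' @return A data.frame sorted by descending ratio then scaffold id, one row
#'   per scaffold: `scaffold_id`, `count_treat`, `count_control`,
#'   `rpm_treat`, `rpm_control`, `ratio`, `ratio_rev`, `branch`
#'   (`"ratio"`, `"treat_only"` or `"none"`) and `selected`.
#' @export
select_scaffolds <- function(treat, control, cfg = selection_config()) {
  stopifnot(inherits(cfg, "selection_config"))
  if (is.null(names(treat)) || is.null(names(control)))
    stop("count vectors must be named by scaffold id")
  if (!setequal(names(treat), names(control))) {
    d <- c(setdiff(names(treat), names(control)),
           setdiff(names(control), names(treat)))
    stop("treatment and control cover different scaffold universes; ",
         "symmetric difference: ", paste(utils::head(d, 10), collapse = ", "))
  }
  control <- control[names(treat)]
  rpm_t <- compute_rpm(treat)
  rpm_c <- compute_rpm(control)
  p <- cfg$pseudocount
  # pseudocount enters on the count scale, then each sample is renormalized
  rpm_tp <- (treat + p) / sum(treat + p) * 1e6
  rpm_cp <- (control + p) / sum(control + p) * 1e6
  ratio <- ifelse(rpm_cp > 0, rpm_tp / rpm_cp,
                  ifelse(rpm_tp > 0, Inf, NaN))
  ratio_rev <- ifelse(rpm_tp > 0, rpm_cp / rpm_tp,
                      ifelse(rpm_cp > 0, Inf, NaN))
  eligible <- if (p > 0) {
    # pseudocount policy: zero-control scaffolds get a finite ratio and
    # become eligible for the ratio branch
    treat >= cfg$min_enriched_count
  } else {
    treat >= cfg$min_enriched_count & control >= cfg$min_enriched_count
  }
  ratio_ok <- eligible & is.finite(ratio) & ratio >= cfg$ratio_threshold
  treat_only <- control == 0 & treat >= cfg$count_threshold & !ratio_ok
  branch <- ifelse(ratio_ok, "ratio", ifelse(treat_only, "treat_only", "none"))
  out <- data.frame(scaffold_id = names(treat),
                    count_treat = as.integer(treat),
                    count_control = as.integer(control),
                    rpm_treat = unname(rpm_t), rpm_control = unname(rpm_c),
                    ratio = unname(ratio), ratio_rev = unname(ratio_rev),
                    branch = branch, selected = branch != "none",
                    stringsAsFactors = FALSE)
  ord <- order(-ifelse(is.nan(out$ratio), -Inf, out$ratio), out$scaffold_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Combine selected scaffolds into a candidate region
#'
#' Without anchoring information the region is an unordered bag of selected
#' scaffolds with their summed length -- exactly how a ~1-Mb candidate
#' neocentromere arises from ~100 unplaced scaffolds in a fragmented
#' assembly. When an anchor table maps scaffolds to chromosome coordinates,
#' the anchored members additionally contribute merged intervals
#' (overlapping or adjacent intervals are merged; 0-based half-open).
#'
#' @param selection Selection table from [select_scaffolds()] (or any
#'   data.frame with `scaffold_id` and `selected` columns).
#' @param genome `ncs_genome` or named `DNAStringSet` (for member lengths).
#' @param anchors Optional data.frame `scaffold_id`, `chrom`, `start`, `end`
#'   (0-based half-open), e.g. from [read_anchors()].
#' @return `NULL` (with a message) when nothing is selected; otherwise an
#'   object of class `ncs_region`: list with `scaffold_ids` (in selection
#'   order), `lengths`, `total_length`, `anchored_intervals` (data.frame or
#'   `NULL`) and `unanchored_ids`.
#' @export
assemble_region <- function(selection, genome, anchors = NULL) {
  seqs <- genome_seqs(genome)
  sel <- selection$scaffold_id[selection$selected]
  if (length(sel) == 0L) {
    message("no candidates: no scaffold passed the selection rule")
    return(NULL)
  }
  missing <- setdiff(sel, names(seqs))
  if (length(missing))
    stop("selected scaffold(s) absent from genome: ",
         paste(missing, collapse = ", "))
  lens <- setNames(Biostrings::width(seqs)[match(sel, names(seqs))], sel)
  anchored <- NULL
  unanchored <- sel
  if (!is.null(anchors)) {
    stopifnot(all(c("scaffold_id", "chrom", "start", "end") %in% names(anchors)))
    bad <- setdiff(anchors$scaffold_id, names(seqs))
    if (length(bad))
      stop("anchor table references unknown scaffold(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    a <- anchors[anchors$scaffold_id %in% sel, , drop = FALSE]
    unanchored <- setdiff(sel, a$scaffold_id)
    if (nrow(a)) {
      gr <- GenomicRanges::GRanges(a$chrom,
                                   IRanges::IRanges(start = a$start + 1L, end = a$end))
      merged <- GenomicRanges::reduce(gr, min.gapwidth = 1L)
      anchored <- data.frame(chrom = as.character(GenomicRanges::seqnames(merged)),
                             start = GenomicRanges::start(merged) - 1L,
                             end = GenomicRanges::end(merged),
                             stringsAsFactors = FALSE)
    }
  }
  structure(list(scaffold_ids = sel, lengths = lens,
                 total_length = sum(lens),
                 anchored_intervals = anchored,
                 unanchored_ids = unanchored),
            class = "ncs_region")
}

#' Read a scaffold anchor table
#' @param path TSV with columns `scaffold_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return data.frame.
#' @export
read_anchors <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
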