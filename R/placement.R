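#' Enumerate candidate placements for read pairs
#'
#' A desk-scale paired-end placer with a testable contract: for every pair it
#' returns *all* loci where both mates match with at most `max_mismatches`
#' substitutions each, in proper forward/reverse orientation, with a fragment
#' span no longer than `max_insert`. Seeding uses `max_mismatches + 1`
#' disjoint exact k-mers per mate, which by pigeonhole cannot all be hit by
#' `max_mismatches` substitutions, so no qualifying locus is missed as long
#' as `(max_mismatches + 1) * seed_k <= read_len`. Candidate enumeration is
#' fully deterministic; randomness enters only in
#' [resolve_multimappers()].
#'
#' @param reads An `ncs_reads` (see [simulate_reads()], [read_fastq_pairs()]).
#' @param genome An `ncs_genome`, or a named [Biostrings::DNAStringSet].
#' @param max_mismatches Maximum substitutions allowed per mate.
#' @param seed_k Exact seed length in bp.
#' @param max_insert Maximum fragment span in bp.
#' @param index Optional prebuilt genome index from [build_genome_index()]
#'   (must have been built with the same `seed_k`); avoids re-indexing when
#'   placing several libraries against one genome.
#' @return A data.frame of candidate placements: `read_id`, `scaffold_id`,
#'   `start`, `end` (0-based half-open fragment span), `strand` (of mate 1),
#'   `mismatches` (summed over mates), plus internal integer columns
#'   `read_idx`/`scaffold_idx` and an `"unmapped"` attribute listing read
#'   ids with no candidate.
#' @export
place_reads <- function(reads, genome, max_mismatches = 2L, seed_k = 31L,
                        max_insert = 1000L, index = NULL) {
  seqs <- genome_seqs(genome)
  stopifnot(inherits(reads, "ncs_reads"), max_mismatches >= 0L)
  if (length(reads$lens1) &&
      (max_mismatches + 1L) * seed_k > min(reads$lens1[1], reads$lens2[1]))
    warning("(max_mismatches + 1) * seed_k exceeds the read length; ",
            "placements with many mismatches may be missed")
  res <- cpp_place_pairs(genome_seqs_chr(genome),
                         reads$blob1, as.integer(reads$lens1),
                         reads$blob2, as.integer(reads$lens2),
                         as.integer(seed_k), as.integer(max_mismatches),
                         as.integer(max_insert), index)
  read_id <- if (is.null(reads$id)) res$read else reads$id[res$read]
  out <- data.frame(read_id = read_id,
                    scaffold_id = names(seqs)[res$scaffold],
                    start = res$start, end = res$end,
                    strand = res$strand, mismatches = res$mismatches,
                    read_idx = res$read, scaffold_idx = res$scaffold,
                    stringsAsFactors = FALSE)
  n <- length(reads$lens1)
  unm <- which(!(seq_len(n) %in% res$read))
  attr(out, "unmapped") <- if (is.null(reads$id)) unm else reads$id[unm]
  out
}

#' Build a reusable placement index for a genome
#'
#' @param genome `ncs_genome` or named `DNAStringSet`.
#' @param seed_k Seed k-mer length (must match the `seed_k` used at
#'   placement time).
#' @return An external pointer usable as the `index` argument of
#'   [place_reads()] and [map_reads()]. Not serializable; rebuild per
#'   session.
#' @export
build_genome_index <- function(genome, seed_k = 31L) {
  cpp_build_index(genome_seqs_chr(genome), as.integer(seed_k))
}

genome_seqs <- function(genome) {
  if (inherits(genome, "ncs_genome")) genome$seqs
  else if (is(genome, "DNAStringSet")) genome
  else stop("genome must be an ncs_genome or a DNAStringSet")
}

# character form of the scaffold sequences, reusing the cached copy when the
# genome object carries one
genome_seqs_chr <- function(genome) {
  if (inherits(genome, "ncs_genome") && !is.null(genome$seqs_chr))
    genome$seqs_chr
  else as.character(genome_seqs(genome))
}

#' Randomly assign each multi-mapping pair to one locus
#'
#' Among each pair's candidates with the minimal total mismatch count (the
#' "equally best" loci), exactly one is chosen uniformly at random from a
#' seeded stream -- the random-assignment rule used for CENH3 ChIP reads in
#' repeat-rich genomes, where discarding multi-mappers would blank out the
#' very sequences of interest. `n_equal_best` records the tie size. The
#' choice is reproducible for identical seed and input order; different
#' seeds change only the assignment of tied pairs.
#'
#' @param candidates Candidate data.frame from [place_reads()].
#' @param seed Integer seed.
#' @return A placement data.frame with one row per mapped pair: `read_id`,
#'   `scaffold_id`, `start`, `end`, `strand`, `n_equal_best`, `duplicate`
#'   (all `FALSE` here; see [deduplicate()]).
#' @export
resolve_multimappers <- function(candidates, seed = 1L) {
  cols <- c("read_id", "scaffold_id", "start", "end", "strand", "mismatches")
  stopifnot(all(cols %in% names(candidates)))
  if (nrow(candidates) == 0L)
    return(empty_placements())
  idx <- candidates$read_idx
  if (is.null(idx)) idx <- match(candidates$read_id, unique(candidates$read_id))
  tie <- with_stream(seed, "resolve", stats::runif(nrow(candidates)))
  # per read: rows ordered by (mismatches, tie); the first is a uniform
  # draw among the equally-best candidates
  ord <- order(idx, candidates$mismatches, tie)
  first <- !duplicated(idx[ord])
  pick <- ord[first]
  # tie size among the minimal-mismatch candidates of each read
  pick_of <- match(idx, idx[pick])
  is_best <- candidates$mismatches == candidates$mismatches[pick][pick_of]
  n_eq <- as.integer(rowsum(as.integer(is_best), idx)[, 1])
  # rowsum sorts by group value; map back to each picked read
  n_eq <- n_eq[match(idx[pick], sort(unique(idx)))]
  out <- data.frame(read_id = candidates$read_id[pick],
                    scaffold_id = candidates$scaffold_id[pick],
                    start = candidates$start[pick], end = candidates$end[pick],
                    strand = candidates$strand[pick],
                    n_equal_best = n_eq,
                    duplicate = FALSE, stringsAsFactors = FALSE)
  if (!is.null(candidates$scaffold_idx))
    out$scaffold_idx <- candidates$scaffold_idx[pick]
  if (!is.null(candidates$read_idx)) out$read_idx <- candidates$read_idx[pick]
  out
}

empty_placements <- function() {
  data.frame(read_id = character(0), scaffold_id = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             n_equal_best = integer(0), duplicate = logical(0),
             stringsAsFactors = FALSE)
}

#' Remove PCR duplicates at the fragment level
#'
#' Placements sharing (scaffold, fragment start, fragment end, strand) --
#' the exact-span convention -- are duplicates; the first record in input
#' order survives. The number removed is reported via the `"n_removed"`
#' attribute and a message.
#'
#' @param placements Placement data.frame from [resolve_multimappers()] or
#'   [import_placements()].
#' @param quiet Suppress the removal message.
#' @return The surviving placements (with `duplicate = FALSE`); attribute
#'   `"n_removed"` holds the removed count.
#' @export
deduplicate <- function(placements, quiet = FALSE) {
  sidx <- placements$scaffold_idx
  if (is.null(sidx)) sidx <- match(placements$scaffold_id,
                                   unique(placements$scaffold_id))
  M <- max(placements$end, 1L) + 1
  S <- max(sidx, 1L)
  if (S * M * M * 2 < 2^53) {
    # exact numeric key (scaffold, start, end, strand)
    key <- (((sidx - 1) * M + placements$start) * M + placements$end) * 2 +
      (placements$strand == "+")
  } else {
    key <- paste(placements$scaffold_id, placements$start, placements$end,
                 placements$strand, sep = "\r")
  }
  dup <- duplicated(key)
  out <- placements[!dup, , drop = FALSE]
  rownames(out) <- NULL
  out$duplicate <- FALSE
  attr(out, "n_removed") <- sum(dup)
  if (!quiet) message(sum(dup), " duplicate fragment(s) removed, ",
                      nrow(out), " surviving")
  out
}

#' Place, resolve and deduplicate in one call
#'
#' Convenience wrapper running [place_reads()], [resolve_multimappers()] and
#' [deduplicate()]; returns the surviving placements with mapping statistics
#' attached as attributes (`n_pairs`, `n_mapped`, `n_unmapped`,
#' `n_duplicates_removed`).
#'
#' @inheritParams place_reads
#' @param seed Seed for the multi-mapper assignment.
#' @param index Optional prebuilt index from [build_genome_index()].
#' @param dedup Deduplicate after assignment (the default order; set
#'   `FALSE` to keep duplicates).
#' @return Placement data.frame.
#' @export
map_reads <- function(reads, genome, max_mismatches = 2L, seed_k = 31L,
                      max_insert = 1000L, seed = 1L, dedup = TRUE,
                      index = NULL) {
  cand <- place_reads(reads, genome, max_mismatches, seed_k, max_insert, index)
  unmapped <- attr(cand, "unmapped")
  pl <- resolve_multimappers(cand, seed = seed)
  n_assigned <- nrow(pl)
  if (dedup) pl <- deduplicate(pl, quiet = TRUE)
  attr(pl, "n_pairs") <- length(reads$id)
  attr(pl, "n_mapped") <- n_assigned
  attr(pl, "n_unmapped") <- length(unmapped)
  attr(pl, "unmapped") <- unmapped
  attr(pl, "n_duplicates_removed") <- n_assigned - nrow(pl)
  pl
}

#' Write placements to the internal TSV format
#' @param placements Placement data.frame.
#' @param path Output file; unmapped read ids (if recorded) go to a sidecar
#'   `<path>.unmapped.tsv` rather than being silently dropped.
#' @return Invisibly `path`.
#' @export
write_placements <- function(placements, path) {
  write.table(placements, path, sep = "\t", quote = FALSE, row.names = FALSE)
  unm <- attr(placements, "unmapped")
  if (!is.null(unm) && length(unm))
    write.table(data.frame(read_id = unm), paste0(path, ".unmapped.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read placements from the internal TSV format
#' @param path TSV written by [write_placements()].
#' @return Placement data.frame.
#' @export
read_placements <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Export placements as SAM
#'
#' Each fragment is written as a properly-paired primary alignment pair with
#' ungapped CIGARs reconstructed from the fragment span (1-based SAM
#' coordinates). Sequence and quality are omitted (`*`): the placement
#' record keeps span information only.
#'
#' @param placements Placement data.frame.
#' @param genome `ncs_genome` or named `DNAStringSet` (for `@SQ` headers).
#' @param path Output SAM path.
#' @param read_len Mate length used to reconstruct per-mate intervals.
#' @return Invisibly `path`.
#' @export
export_sam <- function(placements, genome, path, read_len = 100L) {
  seqs <- genome_seqs(genome)
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqs), Biostrings::width(seqs)))
  p <- placements
  span <- p$end - p$start
  rl <- pmin(read_len, span)
  left_pos <- p$start + 1L            # SAM is 1-based
  right_pos <- p$end - rl + 1L
  # strand '+': mate 1 is the left (forward) mate
  m1_first <- p$strand == "+"
  cigar <- sprintf("%dM", rl)
  lines <- character(2L * nrow(p))
  if (nrow(p)) {
    flag_left <- ifelse(m1_first, 99L, 163L)   # paired, proper, mate rev, first/second
    flag_right <- ifelse(m1_first, 147L, 83L)
    lines[seq(1, by = 2, length.out = nrow(p))] <- sprintf(
      "%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t%d\t*\t*",
      p$read_id, flag_left, p$scaffold_id, left_pos, cigar, right_pos, span)
    lines[seq(2, by = 2, length.out = nrow(p))] <- sprintf(
      "%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t%d\t*\t*",
      p$read_id, flag_right, p$scaffold_id, right_pos, cigar, left_pos, -span)
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Import placements from a SAM/BAM alignment file
#'
#' Properly-paired primary alignments become fragment-level placement
#' records (span from the outermost mate coordinates, converted from SAM's
#' 1-based to the internal 0-based half-open convention). Records flagged
#' secondary, supplementary, duplicate or unmapped are skipped and counted.
#'
#' @param path SAM or BAM file.
#' @param genome Optional `ncs_genome`/`DNAStringSet`; if given, alignments
#'   referencing scaffolds absent from it raise an error.
#' @return Placement data.frame; attribute `"skipped"` is a named count
#'   vector of skipped record classes.
#' @export
import_placements <- function(path, genome = NULL) {
  bam <- if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  } else path
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "qwidth", "isize", "cigar")))[[1]]
  fl <- res$flag
  secondary <- bitwAnd(fl, 256L) > 0L
  supplementary <- bitwAnd(fl, 2048L) > 0L
  dupflag <- bitwAnd(fl, 1024L) > 0L
  unmapped <- bitwAnd(fl, 4L) > 0L | bitwAnd(fl, 8L) > 0L
  proper <- bitwAnd(fl, 2L) > 0L
  keep <- !secondary & !supplementary & !dupflag & !unmapped & proper &
    res$isize > 0L # leftmost mate of each pair carries the positive TLEN
  skipped <- c(secondary = sum(secondary), supplementary = sum(supplementary),
               duplicate = sum(dupflag), unmapped = sum(unmapped),
               improper = sum(!proper & !secondary & !supplementary &
                                !dupflag & !unmapped))
  scaf <- as.character(res$rname[keep])
  if (!is.null(genome)) {
    known <- names(genome_seqs(genome))
    bad <- setdiff(unique(scaf), known)
    if (length(bad))
      stop("alignment references scaffold(s) absent from the genome: ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  if (!any(keep)) {
    out <- empty_placements()
    attr(out, "skipped") <- skipped
    return(out)
  }
  # strand of mate 1: this record is forward; if it is first-in-pair the
  # pair strand is '+', otherwise mate 1 is the reverse (right) mate
  first_in_pair <- bitwAnd(res$flag[keep], 64L) > 0L
  out <- data.frame(
    read_id = res$qname[keep],
    scaffold_id = scaf,
    start = res$pos[keep] - 1L,
    end = res$pos[keep] - 1L + res$isize[keep],
    strand = ifelse(first_in_pair, "+", "-"),
    n_equal_best = 1L,
    duplicate = FALSE,
    stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}
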