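#' Specification of a paired-end ChIP read library
#'
#' @param read_len Read length in bp (the wheat CENH3 ChIP-seq libraries were
#'   paired-end 100 bp). Must be at least 20 and at most half the mean
#'   fragment length.
#' @param fragment_len_mean,fragment_len_sd Fragment length distribution
#'   (normal, truncated to `[2 * read_len, scaffold length]`).
#' @param n_fragments Number of fragment pairs to emit (including PCR
#'   duplicates).
#' @param enrichment_fold Per-bp sampling weight multiplier applied to
#'   planted neocentromere scaffolds in a *treatment* library; `1` yields a
#'   null (no-enrichment) library. Control libraries always ignore it.
#' @param duplicate_rate Fraction of emitted pairs that are exact
#'   re-emissions of earlier pairs (PCR duplicates).
#' @param error_rate Per-base uniform substitution error rate.
#' @param seed Integer seed; identical (genome, spec, role) give identical
#'   libraries.
#' @return An object of class `read_sim_spec`.
#' @export
read_sim_spec <- function(read_len = 100L,
                          fragment_len_mean = 300,
                          fragment_len_sd = 50,
                          n_fragments = 50000L,
                          enrichment_fold = 50,
                          duplicate_rate = 0.1,
                          error_rate = 0.002,
                          seed = 1L) {
  spec <- list(read_len = as.integer(read_len),
               fragment_len_mean = fragment_len_mean,
               fragment_len_sd = fragment_len_sd,
               n_fragments = as.integer(n_fragments),
               enrichment_fold = enrichment_fold,
               duplicate_rate = duplicate_rate,
               error_rate = error_rate,
               seed = as.integer(seed))
  stopifnot(spec$read_len >= 20L,
            2 * spec$read_len <= spec$fragment_len_mean,
            spec$fragment_len_sd >= 0,
            spec$n_fragments >= 1L,
            spec$enrichment_fold >= 1,
            spec$duplicate_rate >= 0, spec$duplicate_rate < 1,
            spec$error_rate >= 0, spec$error_rate <= 1)
  class(spec) <- "read_sim_spec"
  spec
}

#' Expected relative per-bp coverage per scaffold
#'
#' The expected-coverage map of the truth set: for a treatment library every
#' planted scaffold is sampled `enrichment_fold` times more densely per bp
#' than background; a control library is uniform. Scaffolds too short for the
#' fragment model (shorter than `fragment_len_mean + 4 * fragment_len_sd`)
#' have weight zero.
#'
#' @param genome An `ncs_genome`.
#' @param spec A [read_sim_spec()].
#' @param sample_role `"treatment"` or `"control"`.
#' @return Named numeric vector over all scaffold ids.
#' @export
expected_coverage_fold <- function(genome, spec, sample_role = c("treatment", "control")) {
  sample_role <- match.arg(sample_role)
  ids <- names(genome$seqs)
  w <- rep(1, length(ids))
  if (sample_role == "treatment")
    w[ids %in% genome$truth$neocen_ids] <- spec$enrichment_fold
  minlen <- spec$fragment_len_mean + 4 * spec$fragment_len_sd
  w[Biostrings::width(genome$seqs) < minlen] <- 0
  setNames(w, ids)
}

#' Simulate a paired-end ChIP or control library
#'
#' Fragments are drawn uniformly per bp across scaffolds, except that in a
#' treatment library the planted neocentromere scaffolds are over-sampled by
#' `enrichment_fold`. Each fragment yields one forward/reverse read pair of
#' length `read_len`; a `duplicate_rate` fraction of pairs are exact
#' re-emissions of earlier pairs. Read names encode the true origin in the
#' token format `frag<index>|<scaffold>|<start>|<end>|<strand>|<dup_source>`
#' with 0-based half-open coordinates and `dup_source = 0` for original
#' fragments, so that placement and deduplication can be scored without any
#' alignment.
#'
#' @param genome An `ncs_genome` (or any named `DNAStringSet`-bearing list
#'   with a `truth$neocen_ids` element).
#' @param spec A [read_sim_spec()].
#' @param sample_role `"treatment"` applies `enrichment_fold` to planted
#'   scaffolds; `"control"` ignores it.
#' @param make_ids Materialize per-read origin-encoding names. Setting
#'   `FALSE` skips name generation for large throughput runs (the origin
#'   ledger still records every pair's origin by index); such libraries
#'   cannot be written as FASTQ.
#' @return An object of class `ncs_reads`: list with `id` (character), the
#'   mate sequences stored as two concatenated blobs (`blob1`, `blob2`,
#'   raw or single-string) with
#'   per-read lengths (`lens1`, `lens2`) -- use [reads_seqs()] for a
#'   `DNAStringSet` view -- plus `sample_role`, `spec`, and `ledger` (origin
#'   bookkeeping: per-pair origin columns, per-scaffold pair and
#'   distinct-span counts, `n_distinct_spans`, `n_duplicates`, and any
#'   `excluded` scaffolds).
#' @export
simulate_reads <- function(genome, spec, sample_role = c("treatment", "control"),
                           make_ids = TRUE) {
  sample_role <- match.arg(sample_role)
  stopifnot(inherits(spec, "read_sim_spec"))
  seqs <- genome$seqs
  if (length(seqs) == 0L) stop("genome is empty")
  ids <- names(seqs)
  w <- expected_coverage_fold(genome, spec, sample_role)
  excluded <- ids[w == 0 & Biostrings::width(seqs) <
                    spec$fragment_len_mean + 4 * spec$fragment_len_sd]
  if (length(excluded))
    warning(length(excluded), " scaffold(s) shorter than fragment_len_mean + 4*sd ",
            "excluded from sampling: ", paste(utils::head(excluded, 5), collapse = ", "))
  if (all(w == 0)) stop("all scaffolds excluded by the fragment length model")

  seqs_chr <- if (!is.null(genome$seqs_chr)) genome$seqs_chr else as.character(seqs)
  res <- cpp_simulate_fragments(
    seqs_chr, ids, unname(w),
    spec$n_fragments, spec$read_len,
    spec$fragment_len_mean, spec$fragment_len_sd,
    spec$error_rate, spec$duplicate_rate,
    derive_seed(spec$seed, paste0("reads:", sample_role)), make_ids)

  origin <- data.frame(scaffold_id = ids[res$origin_scaffold],
                       start = res$origin_start, end = res$origin_end,
                       strand = as.character(res$origin_strand),
                       dup_of = res$dup_of, stringsAsFactors = FALSE)
  if (make_ids) origin <- cbind(id = as.character(res$id), origin,
                                stringsAsFactors = FALSE)
  ledger <- list(
    origin = origin,
    per_scaffold_pairs = setNames(res$per_scaffold_pairs, ids),
    per_scaffold_distinct = setNames(res$per_scaffold_distinct, ids),
    n_pairs = res$n_pairs, n_original = res$n_original,
    n_duplicates = res$n_duplicates,
    n_distinct_spans = res$n_distinct_spans,
    excluded = excluded)

  n <- res$n_pairs
  structure(list(id = if (make_ids) as.character(res$id),
                 blob1 = res$blob1, blob2 = res$blob2,
                 lens1 = rep.int(spec$read_len, n),
                 lens2 = rep.int(spec$read_len, n),
                 sample_role = sample_role, spec = spec, ledger = ledger),
            class = "ncs_reads")
}

#' View a read library's mate sequences as a `DNAStringSet`
#'
#' The sequences share the underlying blob storage, so this is cheap even
#' for millions of reads.
#'
#' @param reads An `ncs_reads`.
#' @param mate 1 or 2.
#' @return A [Biostrings::DNAStringSet] named by read id.
#' @export
reads_seqs <- function(reads, mate = 1L) {
  stopifnot(inherits(reads, "ncs_reads"), mate %in% 1:2)
  lens <- reads[[paste0("lens", mate)]]
  ends <- cumsum(lens)
  blob <- reads[[paste0("blob", mate)]]
  if (is.raw(blob)) blob <- rawToChar(blob)
  ss <- Biostrings::DNAStringSet(Biostrings::DNAString(blob),
                                 start = ends - lens + 1L, end = ends)
  if (!is.null(reads$id)) names(ss) <- reads$id
  ss
}

#' Write a read library as a FASTQ file pair
#'
#' Mate 1 and mate 2 go to `<prefix>_1.fastq` and `<prefix>_2.fastq` with
#' `/1` and `/2` name suffixes and constant Phred quality (the error model is
#' uniform substitution, so qualities carry no information).
#'
#' @param reads An `ncs_reads`.
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_fastq <- function(reads, prefix) {
  stopifnot(inherits(reads, "ncs_reads"))
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  if (is.null(reads$id))
    stop("library was simulated with make_ids = FALSE; no read names to write")
  for (m in 1:2) {
    ss <- reads_seqs(reads, m)
    writeLines(as.character(rbind(paste0("@", reads$id, "/", m),
                                  as.character(ss), "+",
                                  strrep("I", Biostrings::width(ss)))),
               paths[m])
  }
  invisible(paths)
}

#' Read a FASTQ mate pair into an `ncs_reads`-style object
#'
#' @param path1,path2 FASTQ files for mate 1 and mate 2 (gzip accepted).
#' @return An object of class `ncs_reads` (without a simulation ledger).
#' @export
read_fastq_pairs <- function(path1, path2) {
  r1 <- Biostrings::readDNAStringSet(path1, format = "fastq", with.qualities = FALSE)
  r2 <- Biostrings::readDNAStringSet(path2, format = "fastq", with.qualities = FALSE)
  id1 <- sub("/1$", "", names(r1))
  id2 <- sub("/2$", "", names(r2))
  if (length(r1) != length(r2)) {
    n <- min(length(r1), length(r2))
    bad <- if (length(r1) > length(r2)) id1[n + 1L] else id2[n + 1L]
    stop("mate files have unequal record counts (", length(r1), " vs ",
         length(r2), "); first unpaired read: ", bad)
  }
  if (!all(id1 == id2))
    stop("mate files disagree on read ids; first mismatch: ",
         id1[which(id1 != id2)[1]])
  structure(list(id = id1,
                 blob1 = paste(as.character(r1), collapse = ""),
                 blob2 = paste(as.character(r2), collapse = ""),
                 lens1 = Biostrings::width(r1), lens2 = Biostrings::width(r2),
                 sample_role = NA_character_, spec = NULL, ledger = NULL),
            class = "ncs_reads")
}
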