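#' Ungapped seed-and-extend homology search
#'
#' A desk-scale nucleotide homology scanner in the BLASTN mould: exact
#' k-mer seeds shared between query and target define diagonals; each seed
#' is extended in both directions without gaps under an X-drop rule
#' (extension stops once the running score falls `x_drop` below the best
#' score seen), then trimmed back to the maximal-scoring segment. Both
#' strands are searched; reverse-strand hits report the target interval on
#' forward coordinates with `strand = "-"`. Suited to confirming candidate
#' neocentromere scaffolds against a second genome assembly and to scoring
#' repeat composition, where homologs differ by substitutions rather than
#' large indels. For gapped, genome-scale search import external BLASTN
#' tabular output with [read_blast_hits()] instead.
#'
#' @param query A single sequence (character or `DNAString`).
#' @param target Named [Biostrings::DNAStringSet] (or character vector).
#' @param min_identity Minimum hit identity in `[0, 1]`.
#' @param min_length Minimum aligned length in bp.
#' @param seed_k Exact seed length (word size).
#' @param x_drop Raw-score X-drop for extension termination.
#' @param match,mismatch Match/mismatch scores.
#' @param query_id Label for the query in the output.
#' @return A data.frame of hits sorted by descending aligned length:
#'   `query_id`, `target_id`, `q_start`, `q_end`, `t_start`, `t_end`
#'   (0-based half-open), `strand`, `identity`, `aligned_length`, `score`.
#'   Empty (zero rows) when nothing passes the filters.
#' @export
homology_scan <- function(query, target, min_identity = 0.8, min_length = 50L,
                          seed_k = 11L, x_drop = 20, match = 1, mismatch = -2,
                          query_id = "query") {
  q <- toupper(as.character(query))
  stopifnot(length(q) == 1L, nchar(q) >= seed_k)
  tg <- if (is(target, "DNAStringSet")) as.character(target) else as.character(target)
  if (is.null(names(tg))) names(tg) <- sprintf("target_%d", seq_along(tg))
  hits <- list()
  qc <- strsplit(q, "", fixed = TRUE)[[1]]
  for (ti in seq_along(tg)) {
    for (strand in c("+", "-")) {
      tseq <- if (strand == "+") tg[[ti]] else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(tg[[ti]])))
      h <- scan_one(qc, q, tseq, min_identity, min_length, seed_k,
                    x_drop, match, mismatch)
      if (!is.null(h) && nrow(h)) {
        tl <- nchar(tg[[ti]])
        if (strand == "-") {
          # map intervals from the reverse-complemented target back to
          # forward coordinates
          new_start <- tl - h$t_end
          h$t_end <- tl - h$t_start
          h$t_start <- new_start
        }
        h$target_id <- names(tg)[ti]
        h$strand <- strand
        hits[[length(hits) + 1L]] <- h
      }
    }
  }
  if (!length(hits)) return(empty_hits(query_id))
  out <- do.call(rbind, hits)
  out$query_id <- query_id
  out <- out[order(-out$aligned_length, out$target_id, out$t_start),
             c("query_id", "target_id", "q_start", "q_end", "t_start",
               "t_end", "strand", "identity", "aligned_length", "score")]
  rownames(out) <- NULL
  out
}

empty_hits <- function(query_id = character(0)) {
  data.frame(query_id = character(0), target_id = character(0),
             q_start = integer(0), q_end = integer(0),
             t_start = integer(0), t_end = integer(0),
             strand = character(0), identity = numeric(0),
             aligned_length = integer(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

# seed-and-extend on one (query, oriented target) pair; coordinates are
# 0-based half-open on the oriented target
scan_one <- function(qc, q, tseq, min_identity, min_length, seed_k,
                     x_drop, match, mismatch) {
  nq <- length(qc)
  nt <- nchar(tseq)
  if (nt < seed_k) return(NULL)
  tc <- strsplit(tseq, "", fixed = TRUE)[[1]]
  tk <- substring(tseq, 1:(nt - seed_k + 1L), seed_k:nt)
  qk <- substring(q, 1:(nq - seed_k + 1L), seed_k:nq)
  shared <- which(qk %in% tk)
  if (!length(shared)) return(NULL)
  tpos <- split(seq_len(nt - seed_k + 1L), tk)
  rows <- list()
  done_diag <- list() # per-diagonal covered query intervals, to skip re-extension
  for (qi in shared) {
    for (tj in tpos[[qk[qi]]]) {
      d <- tj - qi # diagonal offset (t index - q index), 1-based indices
      dkey <- as.character(d)
      covered <- done_diag[[dkey]]
      if (!is.null(covered) &&
          any(qi >= covered[, 1] & qi + seed_k - 1L <= covered[, 2])) next
      # overlap of query and target along this diagonal
      i0 <- max(1L, 1L - d); i1 <- min(nq, nt - d)
      seg_q <- i0:i1
      mv <- qc[seg_q] == tc[seg_q + d]
      sc <- ifelse(mv, match, mismatch)
      s_rel <- qi - i0 + 1L # seed start within segment
      e_rel <- s_rel + seed_k - 1L
      # X-drop extension right of the seed, then trim to the best score
      right <- xdrop_end(sc, e_rel, x_drop)
      left <- length(sc) + 1L - xdrop_end(rev(sc), length(sc) + 1L - s_rel, x_drop)
      a <- left; b <- right
      seg_m <- mv[a:b]
      len <- b - a + 1L
      idy <- sum(seg_m) / len
      score <- sum(sc[a:b])
      done_diag[[dkey]] <- rbind(covered, c(i0 + a - 1L, i0 + b - 1L))
      if (len >= min_length && idy >= min_identity) {
        rows[[length(rows) + 1L]] <- data.frame(
          q_start = i0 + a - 2L, q_end = i0 + b - 1L,          # 0-based half-open
          t_start = i0 + d + a - 2L, t_end = i0 + d + b - 1L,
          identity = idy, aligned_length = len, score = score,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  unique(out)
}

# furthest index reached (and trimmed to max cumulative score) when
# extending rightwards from position `from` under an X-drop rule; ties in
# score are broken in favour of the longer extension
xdrop_end <- function(sc, from, x_drop) {
  n <- length(sc)
  if (from > n) return(n)
  cs <- cumsum(sc[from:n])
  peak <- cummax(cs)
  dropped <- which(cs < peak - x_drop)
  lim <- if (length(dropped)) dropped[1] else length(cs)
  best <- max(cs[seq_len(lim)])
  from + max(which(cs[seq_len(lim)] == best)) - 1L
}

#' Import BLASTN tabular hits
#'
#' Reads `-outfmt 6` style tables (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore) into the same hit format
#' as [homology_scan()], converting 1-based closed BLAST coordinates to
#' 0-based half-open and expressing minus-strand hits on forward target
#' coordinates.
#'
#' @param path BLAST tabular file.
#' @return Hit data.frame (see [homology_scan()]).
#' @export
read_blast_hits <- function(path) {
  cols <- c("query_id", "target_id", "pident", "length", "mismatch",
            "gapopen", "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  b <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  names(b) <- cols[seq_len(ncol(b))]
  minus <- b$sstart > b$send
  t_start <- ifelse(minus, b$send, b$sstart) - 1L
  t_end <- ifelse(minus, b$sstart, b$send)
  data.frame(query_id = b$query_id, target_id = b$target_id,
             q_start = b$qstart - 1L, q_end = b$qend,
             t_start = t_start, t_end = t_end,
             strand = ifelse(minus, "-", "+"),
             identity = b$pident / 100,
             aligned_length = b$length,
             score = b$bitscore,
             stringsAsFactors = FALSE)
}
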