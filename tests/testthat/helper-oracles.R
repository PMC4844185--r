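# Shared fixtures and independent oracles for the test suite.

revcomp_str <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# build an ncs_reads object from explicit mate sequences
make_reads <- function(m1, m2, ids = sprintf("read_%03d", seq_along(m1))) {
  stopifnot(length(m1) == length(m2))
  structure(list(id = ids,
                 blob1 = charToRaw(paste(m1, collapse = "")),
                 blob2 = charToRaw(paste(m2, collapse = "")),
                 lens1 = nchar(m1), lens2 = nchar(m2),
                 sample_role = NA_character_, spec = NULL, ledger = NULL),
            class = "ncs_reads")
}

# deterministic random DNA (independent of the package's generators)
rand_dna <- function(n, seed, gc = 0.5) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# small hand-made genome: unique scaffolds plus one exact repeat shared by
# three scaffolds
toy_genome <- function(seed = 42, n_unique = 5, len = 4000, repeat_len = 600) {
  seqs <- vapply(seq_len(n_unique), function(i) rand_dna(len, seed + i), "")
  rep_unit <- rand_dna(repeat_len, seed + 100)
  host <- vapply(1:3, function(i) rand_dna(len, seed + 200 + i), "")
  for (i in 1:3) # identical copy at position 1000 of three scaffolds
    substr(host[i], 1001, 1000 + repeat_len) <- rep_unit
  ss <- Biostrings::DNAStringSet(c(seqs, host))
  names(ss) <- sprintf("toy_%02d", seq_along(ss))
  list(seqs = ss, repeat_unit = rep_unit, repeat_hosts = sprintf("toy_%02d", n_unique + 1:3))
}

# Brute-force paired-end placement oracle built on Biostrings exact
# dictionary matching: enumerates every locus where both mates match
# exactly (max_mismatch = 0) in proper orientation within the insert bound.
brute_place <- function(reads, seqs, max_insert = 1000) {
  s1 <- reads_seqs(reads, 1)
  s2 <- reads_seqs(reads, 2)
  w1 <- Biostrings::width(s1)
  w2 <- Biostrings::width(s2)
  all_hits <- function(patterns) { # data.frame(read, scaffold, pos0)
    pd <- Biostrings::PDict(patterns)
    out <- list()
    for (sc in names(seqs)) {
      m <- Biostrings::matchPDict(pd, seqs[[sc]])
      st <- Biostrings::startIndex(m)
      n_per <- lengths(st)
      if (sum(n_per) == 0) next
      out[[sc]] <- data.frame(read = rep(seq_along(st), n_per),
                              scaffold = sc,
                              pos0 = unlist(st) - 1L,
                              stringsAsFactors = FALSE)
    }
    if (!length(out)) return(NULL)
    do.call(rbind, out)
  }
  combine <- function(left, right, rlen, strand) {
    if (is.null(left) || is.null(right)) return(NULL)
    j <- merge(left, right, by = c("read", "scaffold"),
               suffixes = c("_a", "_b"))
    if (!nrow(j)) return(NULL)
    lmax <- pmax(w1[j$read], w2[j$read])
    span <- j$pos0_b + rlen - j$pos0_a
    keep <- j$pos0_b >= j$pos0_a & span >= lmax & span <= max_insert
    j <- j[keep, , drop = FALSE]; span <- span[keep]
    if (!nrow(j)) return(NULL)
    data.frame(read_id = reads$id[j$read], scaffold_id = j$scaffold,
               start = j$pos0_a, end = j$pos0_a + span, strand = strand,
               mismatches = 0L, stringsAsFactors = FALSE)
  }
  res <- rbind(
    combine(all_hits(s1), all_hits(Biostrings::reverseComplement(s2)),
            w2[1], "+"),
    combine(all_hits(s2), all_hits(Biostrings::reverseComplement(s1)),
            w1[1], "-"))
  res
}

canon_placements <- function(df) {
  df <- df[c("read_id", "scaffold_id", "start", "end", "strand", "mismatches")]
  df <- df[do.call(order, df), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# direct single-pass base-counting GC oracle
gc_oracle <- function(x) {
  ch <- unlist(strsplit(as.character(x), "", fixed = TRUE))
  n_gc <- sum(ch %in% c("G", "C"))
  n_at <- sum(ch %in% c("A", "T"))
  n_gc / (n_gc + n_at)
}

# exhaustive best ungapped local alignment over all diagonals and both
# strands; scores +1 match / -2 mismatch (Kadane per diagonal)
brute_ungapped <- function(q, t, match = 1, mismatch = -2) {
  qc <- strsplit(toupper(q), "", fixed = TRUE)[[1]]
  best <- list(score = -Inf)
  for (strand in c("+", "-")) {
    tt <- if (strand == "+") t else revcomp_str(t)
    tc <- strsplit(toupper(tt), "", fixed = TRUE)[[1]]
    nq <- length(qc); nt <- length(tc)
    for (d in (1 - nq):(nt - 1)) { # t_index - q_index
      i0 <- max(1L, 1L - d); i1 <- min(nq, nt - d)
      if (i1 - i0 + 1L < 1L) next
      sc <- ifelse(qc[i0:i1] == tc[(i0:i1) + d], match, mismatch)
      cs <- cumsum(sc)
      prev_min <- cummin(c(0, cs[-length(cs)]))
      gains <- cs - prev_min
      if (max(gains) > best$score) {
        # among equal-score segments prefer the longest: last argmax on the
        # right, first compatible index on the left
        b <- max(which(gains == max(gains)))
        a <- which(c(0, cs)[1:b] == cs[b] - gains[b])[1]
        qs <- i0 + a - 1L; qe <- i0 + b - 1L
        ts <- qs + d; te <- qe + d
        if (strand == "-") { tmp <- ts; ts <- nt - te + 1L; te <- nt - tmp + 1L }
        best <- list(score = gains[b], strand = strand,
                     q_start = qs - 1L, q_end = qe,      # 0-based half-open
                     t_start = ts - 1L, t_end = te)
      }
    }
  }
  best
}

# textbook pooled-variance two-sample t statistic and two-tailed p
student_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * pt(-abs(t), df = na + nb - 2)
  list(t = t, p = p, df = na + nb - 2)
}

# small default-shaped genome for quick pipeline tests
quick_gspec <- function(seed = 1, n_scaffolds = 40L, n_neocen = 3L)
  genome_spec(n_scaffolds = n_scaffolds, scaffold_len_range = c(1594L, 8000L),
              n_neocen_scaffolds = n_neocen, n_genes = n_scaffolds, seed = seed)

blob_chr <- function(b) if (is.raw(b)) rawToChar(b) else b
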