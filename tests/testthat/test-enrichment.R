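test_that("fragment counting covers the scaffold universe and conserves totals", {
  tg <- toy_genome()
  pl <- data.frame(read_id = c("a", "b", "c"),
                   scaffold_id = c("toy_01", "toy_01", "toy_01"),
                   start = c(0L, 5L, 9L), end = c(300L, 310L, 320L),
                   strand = "+", stringsAsFactors = FALSE)
  counts <- count_fragments(pl, tg$seqs)
  expect_equal(unname(counts[c("toy_01", "toy_02")]), c(3L, 0L))
  expect_setequal(names(counts), names(tg$seqs))
  expect_equal(sum(counts), nrow(pl))
  expect_equal(sum(count_fragments(pl[0, ], tg$seqs)), 0L)
  bad <- within(pl, scaffold_id <- "nonexistent")
  expect_error(count_fragments(bad, tg$seqs), "unknown scaffold")
})

test_that("counts agree with the origin tally for an error-free library", {
  g <- simulate_genome(quick_gspec(seed = 41))
  rs <- read_sim_spec(n_fragments = 5000L, error_rate = 0, duplicate_rate = 0,
                      seed = 41)
  reads <- simulate_reads(g, rs, "treatment")
  pl <- map_reads(reads, g, seed = 41, dedup = FALSE)
  counts <- count_fragments(pl, g)
  org <- do.call(rbind, strsplit(reads$id, "|", fixed = TRUE))
  tally <- table(factor(org[, 2], levels = names(g$seqs)))
  # random assignment can relocate tied repeat pairs between scaffolds, so
  # compare where ties cannot occur and totals overall
  expect_equal(sum(counts), sum(tally))
  unique_reads <- pl$n_equal_best == 1
  by_unique <- table(factor(pl$scaffold_id[unique_reads], levels = names(g$seqs)))
  org_unique <- table(factor(org[pl$read_idx[unique_reads], 2], levels = names(g$seqs)))
  expect_equal(as.integer(by_unique), as.integer(org_unique))
})

test_that("RPM normalization matches the direct formula and always sums to 1e6", {
  expect_equal(compute_rpm(c(s1 = 20, s2 = 80)),
               c(s1 = 200000, s2 = 800000))
  expect_equal(unname(compute_rpm(c(only = 7))), 1e6)
  expect_error(compute_rpm(c(a = 0, b = 0)), "no mapped fragments")
  set.seed(99)
  for (i in 1:20) {
    n <- sample(1:500, 1)
    counts <- rpois(n, lambda = sample(c(0.01, 1, 1000), 1))
    if (sum(counts) == 0) counts[1] <- 1
    names(counts) <- paste0("s", seq_len(n))
    expect_lt(abs(sum(compute_rpm(counts)) - 1e6) / 1e6, 1e-6)
  }
})

test_that("the two-branch selection rule reproduces its published thresholds", {
  # ratio branch: rpm 500 vs 20 -> ratio 25 >= 20, both samples covered
  treat <- c(hit = 500, bg = 19500)
  ctrl <- c(hit = 20, bg = 19980)
  sel <- select_scaffolds(treat * 10, ctrl * 10) # counts scale, rpm invariant
  row <- sel[sel$scaffold_id == "hit", ]
  expect_true(row$selected)
  expect_equal(row$branch, "ratio")
  expect_equal(row$ratio, 25, tolerance = 1e-12)
  # treatment-only branch: zero control, counts >= 20
  treat2 <- c(solo = 25, bg = 10000)
  ctrl2 <- c(solo = 0, bg = 10000)
  sel2 <- select_scaffolds(treat2, ctrl2)
  row2 <- sel2[sel2$scaffold_id == "solo", ]
  expect_true(row2$selected)
  expect_equal(row2$branch, "treat_only")
  # boundary: ratio 19.9 just below threshold -> not selected
  treat3 <- c(near = 19900, bg = 980100)
  ctrl3 <- c(near = 1000, bg = 999000)
  sel3 <- select_scaffolds(treat3, ctrl3)
  row3 <- sel3[sel3$scaffold_id == "near", ]
  expect_false(row3$selected)
  expect_equal(row3$branch, "none")
  expect_lt(row3$ratio, 20)
  # treat_only needs the count threshold
  sel4 <- select_scaffolds(c(solo = 19, bg = 10000), c(solo = 0, bg = 10000))
  expect_false(sel4$selected[sel4$scaffold_id == "solo"])
  # the audit reverse ratio is the reciprocal
  expect_equal(row$ratio_rev, 1 / row$ratio, tolerance = 1e-12)
})

test_that("selection output is sorted and branches satisfy their invariants", {
  set.seed(7)
  n <- 50
  treat <- rpois(n, 100); ctrl <- rpois(n, 100)
  treat[1:3] <- c(5000, 4000, 3000); ctrl[4] <- 0; treat[4] <- 50
  names(treat) <- names(ctrl) <- paste0("s", 1:n)
  sel <- select_scaffolds(treat, ctrl)
  finite <- is.finite(sel$ratio)
  expect_true(!is.unsorted(rev(sel$ratio[finite])))
  expect_true(all(sel$count_control[sel$branch == "treat_only"] == 0))
  expect_true(all(sel$count_treat[sel$branch == "treat_only"] >= 20))
  rb <- sel$branch == "ratio"
  expect_true(all(sel$count_treat[rb] > 0 & sel$count_control[rb] > 0))
  expect_true(all(sel$ratio[rb] >= 20))
})

test_that("mismatched scaffold universes are rejected with the difference", {
  expect_error(select_scaffolds(c(a = 1, b = 2), c(a = 1, c = 2)),
               "different scaffold universes")
  expect_error(select_scaffolds(c(a = 1, b = 2), c(a = 1, c = 2)), "c")
})

test_that("a positive pseudocount reroutes zero-control scaffolds to the ratio branch", {
  treat <- c(solo = 25, bg = 10000)
  ctrl <- c(solo = 0, bg = 10000)
  base <- select_scaffolds(treat, ctrl)
  expect_equal(base$branch[base$scaffold_id == "solo"], "treat_only")
  ps <- select_scaffolds(treat, ctrl, selection_config(pseudocount = 1))
  expect_equal(ps$branch[ps$scaffold_id == "solo"], "ratio")
})

test_that("raising either threshold never adds a selected scaffold", {
  set.seed(13)
  n <- 80
  treat <- rpois(n, 50); ctrl <- rpois(n, 50)
  treat[1:8] <- rpois(8, 2000); ctrl[9:12] <- 0; treat[9:12] <- c(10, 25, 40, 100)
  names(treat) <- names(ctrl) <- paste0("s", 1:n)
  prev_r <- NULL
  for (rt in seq(2, 40, length.out = 10)) {
    cur <- select_scaffolds(treat, ctrl, selection_config(ratio_threshold = rt))
    cur <- cur$scaffold_id[cur$selected]
    if (!is.null(prev_r)) expect_true(all(cur %in% prev_r))
    prev_r <- cur
  }
  prev_c <- NULL
  for (ct in seq(2, 150, length.out = 10)) {
    cur <- select_scaffolds(treat, ctrl, selection_config(count_threshold = ct))
    cur <- cur$scaffold_id[cur$selected]
    if (!is.null(prev_c)) expect_true(all(cur %in% prev_c))
    prev_c <- cur
  }
})

test_that("region assembly sums member lengths and merges anchored intervals", {
  seqs <- Biostrings::DNAStringSet(c(a = strrep("A", 3000),
                                     b = strrep("C", 5000),
                                     c = strrep("G", 2000)))
  sel <- data.frame(scaffold_id = c("a", "b", "c"),
                    selected = c(TRUE, TRUE, TRUE), stringsAsFactors = FALSE)
  region <- assemble_region(sel, seqs)
  expect_equal(region$total_length, 10000L)
  expect_setequal(region$scaffold_ids, c("a", "b", "c"))
  anchors <- data.frame(scaffold_id = c("a", "b"), chrom = "chr4D",
                        start = c(100L, 150L), end = c(200L, 300L),
                        stringsAsFactors = FALSE)
  region2 <- assemble_region(sel, seqs, anchors)
  expect_equal(region2$anchored_intervals,
               data.frame(chrom = "chr4D", start = 100L, end = 300L,
                          stringsAsFactors = FALSE))
  expect_equal(region2$unanchored_ids, "c")
  # nothing selected -> explicit no-candidates result
  none <- within(sel, selected <- FALSE)
  expect_message(res <- assemble_region(none, seqs), "no candidates")
  expect_null(res)
  # unknown scaffold in anchors -> error
  bad <- data.frame(scaffold_id = "zz", chrom = "chr1", start = 0L, end = 5L)
  expect_error(assemble_region(sel, seqs, bad), "unknown scaffold")
})

test_that("swapping null treatment and control labels leaves selection empty", {
  g <- simulate_genome(quick_gspec(seed = 53))
  rs <- read_sim_spec(n_fragments = 20000L, enrichment_fold = 1, seed = 53)
  a <- map_reads(simulate_reads(g, rs, "treatment", make_ids = FALSE), g, seed = 1)
  b <- map_reads(simulate_reads(g, rs, "control", make_ids = FALSE), g, seed = 2)
  ca <- count_fragments(a, g); cb <- count_fragments(b, g)
  expect_equal(sum(select_scaffolds(ca, cb)$selected), 0L)
  expect_equal(sum(select_scaffolds(cb, ca)$selected), 0L)
})

test_that("homology scan finds identical and reverse-complement matches", {
  target <- Biostrings::DNAStringSet(c(t1 = rand_dna(3000, 61)))
  q <- substr(as.character(target[[1]]), 501, 1000)
  hits <- homology_scan(q, target)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$identity, 1.0)
  expect_equal(hits$aligned_length, 500L)
  expect_equal(hits$t_start, 500L) # 0-based
  expect_equal(hits$t_end, 1000L)
  expect_equal(hits$strand, "+")
  # reverse complement of a target segment reports a minus-strand hit on
  # forward coordinates
  qrc <- revcomp_str(substr(as.character(target[[1]]), 1201, 1700))
  hrc <- homology_scan(qrc, target)
  expect_equal(hrc$strand[1], "-")
  expect_equal(hrc$t_start[1], 1200L)
  expect_equal(hrc$t_end[1], 1700L)
  # no shared k-mers -> empty result
  none <- homology_scan(strrep("AT", 40), Biostrings::DNAStringSet(c(x = strrep("G", 500))))
  expect_equal(nrow(none), 0L)
})

test_that("homology hits agree with the exhaustive ungapped oracle", {
  set.seed(71)
  target <- rand_dna(10000, 71)
  for (i in 1:5) {
    q <- rand_dna(500, 710 + i)
    # plant a 300-bp ~95%-identity copy of query positions 101-400
    seg <- strsplit(substr(q, 101, 400), "")[[1]]
    flips <- sample(300, 15)
    seg[flips] <- vapply(seg[flips], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    pos <- sample(9000, 1)
    planted <- target
    substr(planted, pos, pos + 299) <- paste(seg, collapse = "")
    hits <- homology_scan(q, Biostrings::DNAStringSet(c(t = planted)),
                          min_identity = 0.9, min_length = 100)
    expect_gte(nrow(hits), 1L)
    oracle <- brute_ungapped(q, planted)
    expect_lte(abs(hits$t_start[1] - oracle$t_start), 5L)
    expect_lte(abs(hits$t_end[1] - oracle$t_end), 5L)
    expect_lte(abs(hits$q_start[1] - oracle$q_start), 5L)
    expect_lte(abs(hits$q_end[1] - oracle$q_end), 5L)
  }
})

test_that("BLAST tabular import converts coordinates and strand", {
  tab <- file.path(tempdir(), "hits.tsv")
  writeLines(c("q1\tt1\t98.5\t200\t3\t0\t1\t200\t501\t700\t1e-50\t350",
               "q1\tt2\t95.0\t150\t7\t0\t11\t160\t900\t751\t1e-30\t200"), tab)
  hits <- read_blast_hits(tab)
  expect_equal(hits$t_start, c(500L, 750L))
  expect_equal(hits$t_end, c(700L, 900L))
  expect_equal(hits$strand, c("+", "-"))
  expect_equal(hits$identity, c(0.985, 0.95))
  expect_equal(hits$q_start, c(0L, 10L))
})
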