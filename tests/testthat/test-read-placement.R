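test_that("an error-free pair from a unique locus yields exactly its true candidate", {
  tg <- toy_genome()
  s1 <- as.character(tg$seqs[["toy_01"]])
  m1 <- substr(s1, 101, 200)
  m2 <- revcomp_str(substr(s1, 301, 400))
  reads <- make_reads(m1, m2)
  cand <- place_reads(reads, tg$seqs)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$scaffold_id, "toy_01")
  expect_equal(cand$start, 100L)  # 0-based
  expect_equal(cand$end, 400L)
  expect_equal(cand$strand, "+")
  expect_equal(cand$mismatches, 0L)
  # swapped mates place on the minus strand at the same span
  cand2 <- place_reads(make_reads(m2, m1), tg$seqs)
  expect_equal(cand2$strand, "-")
  expect_equal(cand2$start, 100L)
  expect_equal(cand2$end, 400L)
})

test_that("a pair from a repeat copied to three scaffolds yields three exact candidates", {
  tg <- toy_genome()
  m1 <- substr(tg$repeat_unit, 51, 150)
  m2 <- revcomp_str(substr(tg$repeat_unit, 301, 400))
  cand <- place_reads(make_reads(m1, m2), tg$seqs)
  expect_equal(nrow(cand), 3L)
  expect_setequal(cand$scaffold_id, tg$repeat_hosts)
  expect_true(all(cand$mismatches == 0L))
  expect_true(all(cand$start == 1050L)) # copies all sit at offset 1000
})

test_that("mismatched loci are found up to the per-mate limit", {
  tg <- toy_genome()
  s1 <- as.character(tg$seqs[["toy_02"]])
  m1 <- substr(s1, 501, 600)
  substr(m1, 10, 10) <- "N" # never matches: one mismatch
  substr(m1, 90, 90) <- "N"
  m2 <- revcomp_str(substr(s1, 701, 800))
  expect_equal(nrow(place_reads(make_reads(m1, m2), tg$seqs, max_mismatches = 2L)), 1L)
  expect_equal(nrow(place_reads(make_reads(m1, m2), tg$seqs, max_mismatches = 1L)), 0L)
})

test_that("candidate enumeration equals the brute-force oracle on a toy genome", {
  tg <- toy_genome()
  g <- simulate_genome(genome_spec(n_scaffolds = 8L,
                                   scaffold_len_range = c(1594L, 5000L),
                                   n_neocen_scaffolds = 2L, n_genes = 10L,
                                   repeat_density = 0.2, seed = 17))
  rs <- read_sim_spec(n_fragments = 200L, error_rate = 0, duplicate_rate = 0,
                      seed = 17)
  reads <- simulate_reads(g, rs, "treatment")
  mine <- place_reads(reads, g, max_mismatches = 0L)
  oracle <- brute_place(reads, g$seqs)
  expect_identical(canon_placements(mine), canon_placements(oracle))
})

test_that("resolution keeps the unique best and breaks ties reproducibly", {
  cand <- data.frame(read_id = "r1", scaffold_id = c("a", "b", "c"),
                     start = c(0L, 5L, 9L), end = c(300L, 305L, 309L),
                     strand = "+", mismatches = c(0L, 2L, 2L),
                     stringsAsFactors = FALSE)
  pl <- resolve_multimappers(cand, seed = 1)
  expect_equal(nrow(pl), 1L)
  expect_equal(pl$scaffold_id, "a")
  expect_equal(pl$n_equal_best, 1L)
  # four-way tie: same choice on every rerun with the same seed
  tie <- data.frame(read_id = "r1", scaffold_id = letters[1:4],
                    start = 0L, end = 300L, strand = "+", mismatches = 1L,
                    stringsAsFactors = FALSE)
  picks <- replicate(5, resolve_multimappers(tie, seed = 99)$scaffold_id)
  expect_length(unique(picks), 1L)
  expect_equal(resolve_multimappers(tie, seed = 99)$n_equal_best, 4L)
  # different seeds redistribute only tied reads
  both <- rbind(cand, within(tie, read_id <- "r2"))
  a <- resolve_multimappers(both, seed = 1)
  b <- resolve_multimappers(both, seed = 2)
  expect_equal(a$scaffold_id[a$read_id == "r1"], b$scaffold_id[b$read_id == "r1"])
})

test_that("tie-breaking is uniform across equally best loci", {
  n <- 3000L
  cand <- data.frame(read_id = rep(sprintf("r%04d", 1:n), each = 3),
                     scaffold_id = rep(c("a", "b", "c"), n),
                     start = 0L, end = 300L, strand = "+", mismatches = 0L,
                     stringsAsFactors = FALSE)
  pl <- resolve_multimappers(cand, seed = 11)
  tab <- table(pl$scaffold_id)
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("deduplication keys on scaffold, span and strand and is idempotent", {
  pl <- data.frame(
    read_id = sprintf("r%d", 1:4),
    scaffold_id = c("s1", "s1", "s2", "s1"),
    start = c(10L, 10L, 10L, 10L),
    end = c(310L, 310L, 310L, 310L),
    strand = c("+", "+", "+", "-"),
    n_equal_best = 1L, duplicate = FALSE, stringsAsFactors = FALSE)
  out <- deduplicate(pl, quiet = TRUE)
  # same span on another scaffold or strand survives; exact duplicate does not
  expect_equal(nrow(out), 3L)
  expect_equal(attr(out, "n_removed"), 1L)
  expect_equal(out$read_id, c("r1", "r3", "r4")) # first in input order survives
  again <- deduplicate(out, quiet = TRUE)
  expect_equal(attr(again, "n_removed"), 0L)
  expect_identical(out[names(out) != "duplicate"], again[names(again) != "duplicate"])
})

test_that("survivor counts track the simulator's distinct-fragment ledger", {
  g <- simulate_genome(quick_gspec(seed = 23))
  rs <- read_sim_spec(n_fragments = 10000L, duplicate_rate = 0.2,
                      error_rate = 0, seed = 23)
  reads <- simulate_reads(g, rs, "treatment", make_ids = FALSE)
  pl <- map_reads(reads, g, seed = 23)
  expect_lt(abs(nrow(pl) - reads$ledger$n_distinct_spans) /
              reads$ledger$n_distinct_spans, 0.03)
  # count conservation: mapped = assigned = survivors + removed
  expect_equal(attr(pl, "n_mapped") + attr(pl, "n_unmapped"), 10000L)
  expect_equal(attr(pl, "n_mapped"), nrow(pl) + attr(pl, "n_duplicates_removed"))
})

test_that("SAM export/import round-trips the placement multiset", {
  g <- simulate_genome(quick_gspec(seed = 31, n_scaffolds = 10L, n_neocen = 2L))
  rs <- read_sim_spec(n_fragments = 500L, seed = 31)
  pl <- map_reads(simulate_reads(g, rs, "treatment"), g, seed = 31)
  sam <- file.path(tempdir(), "roundtrip.sam")
  export_sam(pl, g, sam, read_len = 100L)
  back <- import_placements(sam, g)
  cols <- c("read_id", "scaffold_id", "start", "end", "strand")
  expect_identical(canon_placements(cbind(pl[cols], mismatches = 0L)),
                   canon_placements(cbind(back[cols], mismatches = 0L)))
})

test_that("SAM import consumes primary proper pairs only", {
  hdr <- c("@HD\tVN:1.6", "@SQ\tSN:chrA\tLN:10000")
  rec <- function(id, flag, pos, mpos, tlen)
    sprintf("%s\t%d\tchrA\t%d\t60\t100M\t=\t%d\t%d\t*\t*", id, flag, pos, mpos, tlen)
  lines <- c(hdr,
             rec("p1", 99, 101, 401, 400), rec("p1", 147, 401, 101, -400),
             rec("p2", 99, 501, 801, 400), rec("p2", 147, 801, 501, -400),
             rec("p2", 355, 901, 1201, 400),  # secondary
             rec("p3", 1123, 601, 901, 400), rec("p3", 1171, 901, 601, -400)) # duplicates
  sam <- file.path(tempdir(), "mixed.sam")
  writeLines(lines, sam)
  out <- import_placements(sam)
  expect_equal(sort(out$read_id), c("p1", "p2"))
  expect_equal(out$start[out$read_id == "p1"], 100L)
  expect_equal(out$end[out$read_id == "p1"], 500L)
  sk <- attr(out, "skipped")
  expect_equal(unname(sk["secondary"]), 1L)
  expect_equal(unname(sk["duplicate"]), 2L)
  # unknown scaffold against a genome -> error
  g <- toy_genome()
  expect_error(import_placements(sam, g$seqs), "absent from the genome")
  # empty alignment with a valid header imports cleanly
  empty <- file.path(tempdir(), "empty.sam")
  writeLines(hdr, empty)
  expect_equal(nrow(import_placements(empty)), 0L)
})

test_that("unequal FASTQ mate files raise an error naming the offender", {
  g <- simulate_genome(quick_gspec(seed = 37, n_scaffolds = 6L, n_neocen = 1L))
  reads <- simulate_reads(g, read_sim_spec(n_fragments = 5L, seed = 37), "control")
  paths <- write_fastq(reads, file.path(tempdir(), "uneq"))
  l1 <- readLines(paths[1])
  writeLines(l1[1:(4 * 3)], paths[1]) # truncate mate-1 file to 3 records
  expect_error(read_fastq_pairs(paths[1], paths[2]),
               "unequal record counts")
  expect_error(read_fastq_pairs(paths[1], paths[2]), reads$id[4], fixed = TRUE)
})
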