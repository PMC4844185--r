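test_that("GC content follows the pooled exclusion rule", {
  expect_equal(as.numeric(gc_content("GCGC")), 1.0)
  expect_equal(as.numeric(gc_content("ATATAT")), 0.0)
  # ambiguity codes leave numerator and denominator and are counted
  x <- gc_content("GCNNAT")
  expect_equal(as.numeric(x), 0.5)
  expect_equal(attr(x, "n_ambiguous"), 2L)
  expect_error(gc_content("NNNN"), "ambiguous")
  expect_error(gc_content(""), "empty")
  # pooled across sequences, not averaged
  expect_equal(as.numeric(gc_content(c("GGGG", "AT"))), 4 / 6)
})

test_that("GC content is invariant under reversal and complementation and matches counting", {
  for (i in 1:10) {
    s <- rand_dna(1000, 800 + i, gc = 0.3 + 0.04 * i)
    g <- as.numeric(gc_content(s))
    expect_identical(g, gc_oracle(s))
    rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    comp_s <- chartr("ACGT", "TGCA", s)
    expect_identical(as.numeric(gc_content(rev_s)), g)
    expect_identical(as.numeric(gc_content(comp_s)), g)
  }
})

test_that("gene counting respects region membership and anchoring", {
  genes <- GenomicRanges::GRanges(
    c("s1", "s1", "s2", "s2", "s2", "chr4D", "chr4D"),
    IRanges::IRanges(start = c(10, 500, 10, 300, 700, 1000, 5000),
                     width = 100),
    type = "gene",
    ID = paste0("g", 1:7))
  region <- structure(list(scaffold_ids = "s1", lengths = c(s1 = 1000L),
                           total_length = 1000L, anchored_intervals = NULL,
                           unanchored_ids = "s1"), class = "ncs_region")
  res <- count_genes_in_region(region, genes)
  expect_equal(res$gene_count, 2L)
  expect_setequal(res$gene_ids, c("g1", "g2"))
  # anchored mode adds genes overlapping chromosome intervals, counted once
  region$anchored_intervals <- data.frame(chrom = "chr4D", start = 900L,
                                          end = 1500L, stringsAsFactors = FALSE)
  res2 <- count_genes_in_region(region, genes)
  expect_equal(res2$gene_count, 3L)
  expect_true("g6" %in% res2$gene_ids)
  # empty gene set counts zero
  empty <- GenomicRanges::GRanges()
  expect_equal(count_genes_in_region(region, empty)$gene_count, 0L)
})

test_that("gene counts over a synthetic region equal the simulator's ledger", {
  g <- simulate_genome(quick_gspec(seed = 47, n_scaffolds = 25L, n_neocen = 4L))
  dir <- file.path(tempdir(), "genes47")
  paths <- write_genome(g, dir)
  region <- structure(list(scaffold_ids = g$truth$neocen_ids,
                           total_length = NA, anchored_intervals = NULL,
                           unanchored_ids = g$truth$neocen_ids),
                      class = "ncs_region")
  res <- count_genes_in_region(region, paths$genes, g)
  truth <- g$truth$table
  expect_equal(res$gene_count, sum(truth$gene_count[truth$is_neocen]))
})

test_that("unknown gene sequence ids are skipped with a warning, all-skipped errors", {
  genes <- GenomicRanges::GRanges(c("s1", "weird"), IRanges::IRanges(c(1, 1), width = 50),
                                  type = "gene", ID = c("g1", "g2"))
  region <- structure(list(scaffold_ids = "s1", lengths = c(s1 = 1000L),
                           total_length = 1000L, anchored_intervals = NULL,
                           unanchored_ids = "s1"), class = "ncs_region")
  seqs <- Biostrings::DNAStringSet(c(s1 = strrep("A", 1000)))
  expect_warning(res <- count_genes_in_region(region, genes, seqs), "skipped")
  expect_equal(res$gene_count, 1L)
  allbad <- GenomicRanges::GRanges("weird", IRanges::IRanges(1, 50),
                                   type = "gene", ID = "g2")
  expect_error(suppressWarnings(count_genes_in_region(region, allbad, seqs)),
               "unknown sequence ids")
})

test_that("repeat composition saturates, vanishes and tracks planted truth", {
  unit <- rand_dna(400, 901)
  lib <- Biostrings::DNAStringSet(c(fam1 = unit))
  triple <- Biostrings::DNAStringSet(c(r = strrep(unit, 3)))
  full <- repeat_composition(triple, lib)
  expect_equal(full$repeat_fraction, 1.0)
  none <- repeat_composition(Biostrings::DNAStringSet(c(x = rand_dna(2000, 902))),
                             lib, min_identity = 0.95)
  expect_equal(none$repeat_fraction, 0.0)
  # simulated scaffolds carry a known repeat fraction (2% copy divergence)
  g <- simulate_genome(genome_spec(n_scaffolds = 6L,
                                   scaffold_len_range = c(4000L, 9000L),
                                   repeat_density = 0.4, neocen_repeat_boost = 1,
                                   n_neocen_scaffolds = 1L, n_genes = 10L,
                                   seed = 59))
  rc <- repeat_composition(g$seqs, g$repeat_library)
  truth_frac <- sum(g$truth$table$repeat_bp) / sum(scaffold_lengths(g))
  expect_lt(abs(rc$repeat_fraction - truth_frac), 0.05)
  expect_lte(rc$repeat_fraction, 1)
  # per-family coverage sums to at least the merged total
  expect_gte(sum(rc$per_family_bp), rc$covered_bp)
})

test_that("repeat fraction is monotone as identity threshold is lowered", {
  g <- simulate_genome(genome_spec(n_scaffolds = 4L,
                                   scaffold_len_range = c(3000L, 6000L),
                                   repeat_density = 0.3, neocen_repeat_boost = 1,
                                   n_neocen_scaffolds = 1L, n_genes = 5L,
                                   seed = 67))
  fr <- vapply(c(0.98, 0.9, 0.8, 0.7), function(mi)
    repeat_composition(g$seqs, g$repeat_library, min_identity = mi)$repeat_fraction,
    numeric(1))
  expect_true(!is.unsorted(fr))
  expect_true(all(fr <= 1))
})

test_that("intensity comparison implements the two-tailed Student's t-test", {
  same <- compare_intensity(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  # degenerate zero-variance equal groups use the stated convention
  deg <- compare_intensity(c(1, 1, 1), c(1, 1, 1))
  expect_equal(deg$p_value, 1)
  expect_error(compare_intensity(c(1, 1, 1), c(2, 2, 2)), "zero variance")
  expect_error(compare_intensity(c(1, -2, 3), c(1, 2, 3)), ">= 0")
  # textbook-formula oracle to 1e-10 on seeded normal samples
  set.seed(73)
  a <- abs(rnorm(20, 1.0, 0.1)); b <- abs(rnorm(20, 0.3, 0.1))
  res <- compare_intensity(a, b)
  oracle <- student_t_oracle(a, b)
  expect_equal(res$t, oracle$t, tolerance = 1e-10)
  expect_equal(res$p_value, oracle$p, tolerance = 1e-10)
  expect_equal(res$df, oracle$df)
  expect_equal(res$mean_ratio, mean(a) / mean(b))
  # antisymmetry under group swap
  swap <- compare_intensity(b, a)
  expect_equal(swap$t, -res$t, tolerance = 1e-12)
  expect_equal(swap$p_value, res$p_value, tolerance = 1e-12)
  # Welch's variant is available behind the flag
  w <- compare_intensity(a, c(b, 5, 6), var_equal = FALSE)
  expect_match(w$method, "Welch")
})

test_that("intensity tables read from TSV with validation", {
  tsv <- file.path(tempdir(), "intensity.tsv")
  writeLines(c("cell_id\tgroup\trelative_intensity",
               "c1\ttarget\t0.21", "c2\ttarget\t0.25", "c3\tcontrol\t1.02",
               "c4\tcontrol\t0.98"), tsv)
  d <- read_intensity(tsv)
  expect_equal(nrow(d), 4L)
  res <- compare_intensity(d$relative_intensity[d$group == "target"],
                           d$relative_intensity[d$group == "control"])
  expect_lt(res$p_value, 0.01)
})

test_that("run reports validate, bound their recovery metrics and round-trip", {
  g <- simulate_genome(quick_gspec(seed = 79))
  rs <- read_sim_spec(n_fragments = 20000L, seed = 79)
  res <- run_chip_experiment(gspec = quick_gspec(seed = 79), rspec = rs,
                             seed = 79, timestamp = TRUE)
  expect_silent(validate_report(res$report))
  rec <- res$report$recovery
  expect_gte(rec$sensitivity, 0); expect_lte(rec$sensitivity, 1)
  expect_gte(rec$precision, 0); expect_lte(rec$precision, 1)
  # JSON round-trip preserves the numeric tables bit-exactly
  path <- file.path(tempdir(), "report.json")
  write_report(res$report, path)
  back <- read_report(path)
  expect_identical(back$enrichment$rpm_treat, res$report$enrichment$rpm_treat)
  expect_identical(back$enrichment$ratio[is.finite(res$report$enrichment$ratio)],
                   res$report$enrichment$ratio[is.finite(res$report$enrichment$ratio)])
  expect_identical(back$annotation$gc, res$report$annotation$gc)
  expect_silent(validate_report(back))
  # structural violations are caught
  broken <- res$report
  broken$enrichment$ratio <- NULL
  expect_error(validate_report(broken), "missing column")
})
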