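#' Recovery metrics against a truth set
#'
#' @param selection Selection table from [select_scaffolds()].
#' @param truth_ids Character vector of planted (true) scaffold ids.
#' @return List: `sensitivity`, `precision`, `tp`, `fp`, `fn`,
#'   `selected_ids`. Precision is 1 by convention when nothing is selected
#'   (no false positives).
#' @export
recovery_metrics <- function(selection, truth_ids) {
  sel <- selection$scaffold_id[selection$selected]
  tp <- length(intersect(sel, truth_ids))
  fp <- length(setdiff(sel, truth_ids))
  fn <- length(setdiff(truth_ids, sel))
  list(sensitivity = if (length(truth_ids)) tp / length(truth_ids) else NA_real_,
       precision = if (length(sel)) tp / length(sel) else 1,
       tp = tp, fp = fp, fn = fn, selected_ids = sel)
}

#' Assemble the run report
#'
#' Collects configuration, seeds, library and mapping statistics, the
#' selection table, region annotation and (when a truth set is supplied)
#' recovery metrics into a single report object that can be written as JSON
#' and validated with [validate_report()]. Reports from identical seeds are
#' identical apart from the `generated_at` stamp.
#'
#' @param enrichment Selection table from [select_scaffolds()] (required).
#' @param config Named list of configuration objects (specs, thresholds).
#' @param libraries Named list of per-library mapping statistics.
#' @param region `ncs_region` or `NULL`.
#' @param annotation Named list (GC, gene count, repeat composition) or `NULL`.
#' @param intensity Intensity comparison from [compare_intensity()] or `NULL`.
#' @param truth_ids Planted scaffold ids, or `NULL` to omit recovery metrics.
#' @param seed The run's global seed.
#' @param timestamp Include a `generated_at` stamp.
#' @return A list of class `ncs_report`.
#' @export
emit_report <- function(enrichment, config = list(), libraries = list(),
                        region = NULL, annotation = NULL, intensity = NULL,
                        truth_ids = NULL, seed = NA_integer_, timestamp = TRUE) {
  stopifnot(is.data.frame(enrichment))
  rep <- list(
    meta = list(tool = "neocenscan",
                version = as.character(packageVersion("neocenscan")),
                seed = seed,
                generated_at = if (timestamp) format(Sys.time(), tz = "UTC") else NULL),
    config = config,
    libraries = libraries,
    enrichment = enrichment,
    n_selected = sum(enrichment$selected),
    region = if (!is.null(region)) list(
      scaffold_ids = region$scaffold_ids,
      n_scaffolds = length(region$scaffold_ids),
      total_length = unname(region$total_length),
      anchored_intervals = region$anchored_intervals,
      unanchored_ids = region$unanchored_ids),
    annotation = annotation,
    intensity = intensity,
    recovery = if (!is.null(truth_ids)) recovery_metrics(enrichment, truth_ids))
  class(rep) <- c("ncs_report", "list")
  rep
}

#' Validate a run report's structure
#'
#' Structural schema check: required sections, required enrichment columns,
#' and bounds on recovery metrics. Returns `TRUE` invisibly or stops with
#' the first violation.
#'
#' @param report An `ncs_report` (or a list parsed back from report JSON).
#' @return `TRUE`, invisibly.
#' @export
validate_report <- function(report) {
  need <- c("meta", "config", "libraries", "enrichment", "n_selected")
  miss <- setdiff(need, names(report))
  if (length(miss)) stop("report is missing section(s): ", paste(miss, collapse = ", "))
  for (f in c("tool", "version", "seed"))
    if (is.null(report$meta[[f]])) stop("report meta is missing field: ", f)
  enr <- as.data.frame(report$enrichment)
  cols <- c("scaffold_id", "count_treat", "count_control", "rpm_treat",
            "rpm_control", "ratio", "branch", "selected")
  miss <- setdiff(cols, names(enr))
  if (length(miss)) stop("enrichment table is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!is.null(report$recovery)) {
    s <- report$recovery$sensitivity; p <- report$recovery$precision
    if (!is.na(s) && (s < 0 || s > 1)) stop("sensitivity out of [0, 1]")
    if (!is.na(p) && (p < 0 || p > 1)) stop("precision out of [0, 1]")
  }
  invisible(TRUE)
}

#' Write a report as JSON (full numeric precision)
#' @param report An `ncs_report`.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_report <- function(report, path) {
  # undefined ratios (zero-control scaffolds) serialize as null
  for (col in c("ratio", "ratio_rev")) {
    v <- report$enrichment[[col]]
    if (!is.null(v)) report$enrichment[[col]][!is.finite(v)] <- NA_real_
  }
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a report back from JSON
#' @param path JSON written by [write_report()].
#' @return A list.
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
}

#' Run the full neocentromere-discovery pipeline on a synthetic genome
#'
#' Simulates a genome with a planted neocentromere, draws a CENH3 ChIP
#' (treatment) and a control library, places and deduplicates both, applies
#' RPM normalization and the two-branch selection rule, assembles and
#' annotates the candidate region, and emits a report scored against the
#' planted truth.
#'
#' @param gspec A [genome_spec()].
#' @param rspec A [read_sim_spec()] for the treatment (ChIP) library.
#' @param rspec_control Optional [read_sim_spec()] for the control library;
#'   defaults to `rspec`. Because the RPM-ratio variance is dominated by the
#'   shallower-counted control, sequencing the control deeper than the ChIP
#'   is the efficient design.
#' @param cfg A [selection_config()].
#' @param seed Global seed; overrides the seeds inside `gspec`/`rspec` so a
#'   single integer reproduces the whole run.
#' @param max_mismatches,seed_k,max_insert Placement parameters
#'   (see [place_reads()]).
#' @param annotate Compute region GC, gene counts and repeat composition.
#' @param timestamp Passed to [emit_report()].
#' @return List: `genome`, `selection`, `region`, `annotation`, `report`.
#' @export
run_chip_experiment <- function(gspec = genome_spec(), rspec = read_sim_spec(),
                                rspec_control = NULL,
                                cfg = selection_config(), seed = 1L,
                                max_mismatches = 2L, seed_k = 31L,
                                max_insert = 1000L, annotate = TRUE,
                                timestamp = TRUE) {
  gspec$seed <- as.integer(seed)
  rspec$seed <- as.integer(seed)
  if (is.null(rspec_control)) rspec_control <- rspec
  rspec_control$seed <- as.integer(seed)
  genome <- simulate_genome(gspec)
  index <- build_genome_index(genome, seed_k)

  stats_of <- function(pl) list(
    n_pairs = attr(pl, "n_pairs"), n_mapped = attr(pl, "n_mapped"),
    n_unmapped = attr(pl, "n_unmapped"),
    n_duplicates_removed = attr(pl, "n_duplicates_removed"),
    n_surviving = nrow(pl))

  reads_t <- simulate_reads(genome, rspec, "treatment", make_ids = FALSE)
  pl_t <- map_reads(reads_t, genome, max_mismatches, seed_k, max_insert,
                    seed = derive_seed(seed, "assign:treatment"), index = index)
  lib_t <- stats_of(pl_t)
  rm(reads_t)

  reads_c <- simulate_reads(genome, rspec_control, "control", make_ids = FALSE)
  pl_c <- map_reads(reads_c, genome, max_mismatches, seed_k, max_insert,
                    seed = derive_seed(seed, "assign:control"), index = index)
  lib_c <- stats_of(pl_c)
  rm(reads_c)
  gc(verbose = FALSE)

  counts_t <- count_fragments(pl_t, genome)
  counts_c <- count_fragments(pl_c, genome)
  rm(pl_t, pl_c)
  selection <- select_scaffolds(counts_t, counts_c, cfg)
  region <- assemble_region(selection, genome)

  annotation <- NULL
  if (annotate && !is.null(region)) {
    member_seqs <- genome$seqs[region$scaffold_ids]
    genes <- count_genes_in_region(region, genome$genes, genome)
    rc <- if (length(genome$repeat_library))
      repeat_composition(member_seqs, genome$repeat_library) else NULL
    annotation <- list(
      gc = as.numeric(gc_content(member_seqs)),
      per_scaffold_gc = setNames(
        vapply(seq_along(member_seqs),
               function(i) as.numeric(gc_content(member_seqs[i])), numeric(1)),
        names(member_seqs)),
      gene_count = genes$gene_count, gene_ids = genes$gene_ids,
      repeat_fraction = if (!is.null(rc)) rc$repeat_fraction else NA_real_,
      per_family_bp = if (!is.null(rc)) as.list(rc$per_family_bp) else NULL)
  }

  report <- emit_report(
    enrichment = selection,
    config = list(genome_spec = unclass(gspec), read_sim_spec = unclass(rspec),
                  read_sim_spec_control = unclass(rspec_control),
                  selection = unclass(cfg),
                  placement = list(max_mismatches = max_mismatches,
                                   seed_k = seed_k, max_insert = max_insert)),
    libraries = list(treatment = lib_t, control = lib_c),
    region = region, annotation = annotation,
    truth_ids = genome$truth$neocen_ids, seed = seed, timestamp = timestamp)
  list(genome = genome, selection = selection, region = region,
       annotation = annotation, report = report)
}
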