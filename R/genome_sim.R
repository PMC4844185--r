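#' Specification of a synthetic fragmented genome
#'
#' Describes a scaffold-level assembly of the kind produced for large
#' repeat-rich plant genomes: hundreds of short scaffolds, interspersed
#' retrotransposon-like repeat families shared across scaffolds (so that
#' short-read multi-mapping is common), and a contiguous block of scaffolds
#' designated as a planted neocentromere with elevated GC and repeat content.
#'
#' @param n_scaffolds Number of scaffolds.
#' @param scaffold_len_range Length range in bp, `c(min, max)`; lengths are
#'   drawn uniformly. Must lie within `[1000, 40000]`. The default matches
#'   the scaffold size range observed for neocentromeric scaffolds in wheat
#'   (1,594-32,269 bp).
#' @param repeat_families Number of repeat families in the library.
#' @param repeat_unit_len Length in bp of each family's monomer. Truncated
#'   copies are allowed, as for fragmented transposable elements.
#' @param repeat_density Fraction of background-scaffold bp covered by repeat
#'   copies, in `[0, 1]`.
#' @param gc_background GC fraction of background scaffolds.
#' @param gc_neocentromere GC fraction of planted neocentromere scaffolds
#'   (the wheat neocentromere region is GC-rich, 48-53%).
#' @param n_neocen_scaffolds Number of planted scaffolds (a contiguous block
#'   by scaffold index); must be `< n_scaffolds`.
#' @param n_genes Number of genes placed outside repeat copies.
#' @param neocen_repeat_boost Multiplier on `repeat_density` for planted
#'   scaffolds (the neocentromere scaffold observed in wheat is enriched for
#'   transposable elements); set to 1 to disable.
#' @param repeat_divergence Per-copy substitution divergence from the family
#'   monomer, so that multi-mapping is common but not degenerate.
#' @param seed Integer seed; identical specs give byte-identical output.
#' @return An object of class `genome_spec` (a validated list).
#' @export
genome_spec <- function(n_scaffolds = 200L,
                        scaffold_len_range = c(1594L, 32269L),
                        repeat_families = 4L,
                        repeat_unit_len = 2000L,
                        repeat_density = 0.25,
                        gc_background = 0.46,
                        gc_neocentromere = 0.52,
                        n_neocen_scaffolds = 5L,
                        n_genes = 300L,
                        neocen_repeat_boost = 2,
                        repeat_divergence = 0.02,
                        seed = 1L) {
  spec <- list(n_scaffolds = as.integer(n_scaffolds),
               scaffold_len_range = as.integer(scaffold_len_range),
               repeat_families = as.integer(repeat_families),
               repeat_unit_len = as.integer(repeat_unit_len),
               repeat_density = repeat_density,
               gc_background = gc_background,
               gc_neocentromere = gc_neocentromere,
               n_neocen_scaffolds = as.integer(n_neocen_scaffolds),
               n_genes = as.integer(n_genes),
               neocen_repeat_boost = neocen_repeat_boost,
               repeat_divergence = repeat_divergence,
               seed = as.integer(seed))
  stopifnot(spec$n_scaffolds >= 1L,
            length(spec$scaffold_len_range) == 2L,
            spec$scaffold_len_range[1] >= 1000L,
            spec$scaffold_len_range[2] <= 40000L,
            spec$scaffold_len_range[1] <= spec$scaffold_len_range[2],
            spec$n_neocen_scaffolds < spec$n_scaffolds,
            spec$n_neocen_scaffolds >= 0L,
            spec$repeat_density >= 0, spec$repeat_density <= 1,
            spec$gc_background >= 0, spec$gc_background <= 1,
            spec$gc_neocentromere >= 0, spec$gc_neocentromere <= 1,
            spec$repeat_divergence >= 0, spec$repeat_divergence <= 1,
            spec$neocen_repeat_boost >= 0,
            spec$repeat_families >= 0L, spec$n_genes >= 0L)
  if (spec$repeat_density * spec$neocen_repeat_boost > 0.9)
    stop("infeasible: repeat_density * neocen_repeat_boost exceeds 0.9; ",
         "no room left for unique sequence and genes")
  class(spec) <- "genome_spec"
  spec
}

BASES <- c("A", "C", "G", "T")

# vector of base characters with expected GC `gc`
random_bases <- function(n, gc) {
  BASES[sample.int(4L, n, replace = TRUE,
                   prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))]
}

mutate_bases <- function(x, rate) {
  if (rate <= 0) return(x)
  hit <- which(runif(length(x)) < rate)
  if (length(hit)) {
    # substitute with one of the three other bases
    cur <- match(x[hit], BASES)
    x[hit] <- BASES[((cur - 1L + sample.int(3L, length(hit), replace = TRUE)) %% 4L) + 1L]
  }
  x
}

revcomp_chars <- function(x) rev(chartr("ACGT", "TGCA", x))

#' Simulate a fragmented genome with a planted neocentromere
#'
#' Generates scaffold sequences, a repeat library whose monomers are copied
#' (with per-copy divergence and random orientation) onto many scaffolds,
#' gene models placed outside repeat copies, and a truth set recording which
#' scaffolds form the planted neocentromere. Background base composition is
#' compensated for the realized GC of embedded repeat copies so that each
#' scaffold's overall GC matches its target (`gc_background` or
#' `gc_neocentromere`).
#'
#' @param spec A [genome_spec()].
#' @return An object of class `ncs_genome`: a list with elements
#'   \describe{
#'     \item{seqs}{named [Biostrings::DNAStringSet] of scaffolds.}
#'     \item{genes}{[GenomicRanges::GRanges] of gene models (1-based closed,
#'       GFF3 convention) with an `ID` metadata column.}
#'     \item{repeat_library}{[Biostrings::DNAStringSet] of family monomers.}
#'     \item{truth}{list: `neocen_ids`, per-scaffold `table`
#'       (scaffold_id, length, is_neocen, repeat_bp, gene_count), and
#'       `repeats`, a GRanges of placed repeat copies with family labels.}
#'     \item{spec}{the input spec.}
#'   }
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_stream(spec$seed, "genome", {
    n <- spec$n_scaffolds
    lens <- sample.int(spec$scaffold_len_range[2] - spec$scaffold_len_range[1] + 1L,
                       n, replace = TRUE) + spec$scaffold_len_range[1] - 1L
    ids <- sprintf("scaffold_%03d", seq_len(n))
    is_neo <- rep(FALSE, n)
    if (spec$n_neocen_scaffolds > 0L) {
      run_start <- sample.int(n - spec$n_neocen_scaffolds + 1L, 1L)
      is_neo[run_start:(run_start + spec$n_neocen_scaffolds - 1L)] <- TRUE
    }

    # repeat family monomers (genome-wide background composition)
    fam <- character(spec$repeat_families)
    if (spec$repeat_families > 0L && spec$repeat_density > 0) {
      for (f in seq_len(spec$repeat_families))
        fam[f] <- paste0(random_bases(spec$repeat_unit_len, spec$gc_background),
                         collapse = "")
    }
    has_repeats <- spec$repeat_density > 0 && spec$repeat_families > 0L

    seqs <- character(n)
    rep_scaf <- character(0); rep_start <- integer(0); rep_end <- integer(0)
    rep_fam <- character(0); rep_strand <- character(0)
    repeat_bp <- integer(n)
    min_copy <- 200L

    for (i in seq_len(n)) {
      L <- lens[i]
      dens <- spec$repeat_density * if (is_neo[i]) spec$neocen_repeat_boost else 1
      target <- floor(dens * L)
      copies <- list(); starts <- integer(0); ends <- integer(0)
      fams <- character(0); strands <- character(0)
      placed <- 0L
      while (has_repeats && target - placed >= min_copy) {
        clen <- min(spec$repeat_unit_len, target - placed, L)
        ok <- FALSE
        for (try in 1:200) {
          s0 <- sample.int(L - clen + 1L, 1L) - 1L # 0-based
          if (!any(s0 < ends & s0 + clen > starts)) { ok <- TRUE; break }
        }
        if (!ok) break
        f <- sample.int(spec$repeat_families, 1L)
        off <- if (clen < spec$repeat_unit_len)
          sample.int(spec$repeat_unit_len - clen + 1L, 1L) else 1L
        cp <- strsplit(substr(fam[f], off, off + clen - 1L), "", fixed = TRUE)[[1]]
        cp <- mutate_bases(cp, spec$repeat_divergence)
        strand <- if (runif(1) < 0.5) "+" else "-"
        if (strand == "-") cp <- revcomp_chars(cp)
        copies[[length(copies) + 1L]] <- cp
        starts <- c(starts, s0); ends <- c(ends, s0 + clen)
        fams <- c(fams, names(fam)[f] %||% sprintf("family_%d", f))
        strands <- c(strands, strand)
        placed <- placed + clen
      }
      if (has_repeats && target > 0L && placed < 0.5 * target && target >= min_copy)
        stop("infeasible: could not place repeat copies to reach the ",
             "requested repeat_density on ", ids[i])

      gc_target <- if (is_neo[i]) spec$gc_neocentromere else spec$gc_background
      rho <- placed / L
      gc_rep <- if (placed > 0) {
        allrep <- unlist(copies)
        sum(allrep %in% c("G", "C")) / length(allrep)
      } else 0
      gc_bg <- if (rho >= 1) gc_target else (gc_target - rho * gc_rep) / (1 - rho)
      if (gc_bg < 0 || gc_bg > 1)
        stop("infeasible: cannot reach target GC ", gc_target, " on ", ids[i],
             " given embedded repeat composition")
      chars <- random_bases(L, gc_bg)
      for (j in seq_along(copies))
        chars[(starts[j] + 1L):ends[j]] <- copies[[j]]
      seqs[i] <- paste0(chars, collapse = "")

      if (length(starts)) {
        ord <- order(starts)
        rep_scaf <- c(rep_scaf, rep(ids[i], length(starts)))
        rep_start <- c(rep_start, starts[ord]); rep_end <- c(rep_end, ends[ord])
        rep_fam <- c(rep_fam, fams[ord]); rep_strand <- c(rep_strand, strands[ord])
      }
      repeat_bp[i] <- placed
    }

    # genes: placed outside repeat copies and outside each other
    gene_scaf <- character(0); gene_start <- integer(0); gene_end <- integer(0)
    occupied <- split(
      data.frame(start = rep_start, end = rep_end),
      factor(rep_scaf, levels = ids))
    if (spec$n_genes > 0L) {
      for (g in seq_len(spec$n_genes)) {
        done <- FALSE
        for (try in 1:500) {
          i <- sample.int(n, 1L, prob = lens)
          # gene length 300-1500 bp, capped by the host scaffold
          gl <- sample(300:max(301L, min(1500L, lens[i] - 100L)), 1L)
          if (gl >= lens[i]) next
          s0 <- sample.int(lens[i] - gl + 1L, 1L) - 1L
          occ <- occupied[[ids[i]]]
          if (nrow(occ) && any(s0 < occ$end & s0 + gl > occ$start)) next
          own <- gene_scaf == ids[i]
          if (any(own) && any(s0 < gene_end[own] & s0 + gl > gene_start[own])) next
          gene_scaf <- c(gene_scaf, ids[i])
          gene_start <- c(gene_start, s0); gene_end <- c(gene_end, s0 + gl)
          done <- TRUE
          break
        }
        if (!done)
          stop("infeasible: could not place gene ", g,
               " outside repeats; lower repeat_density or n_genes")
      }
    }

    seqs <- Biostrings::DNAStringSet(setNames(seqs, ids))
    ord <- order(match(gene_scaf, ids), gene_start)
    genes <- GenomicRanges::GRanges(
      seqnames = factor(gene_scaf[ord], levels = ids),
      ranges = IRanges::IRanges(start = gene_start[ord] + 1L, end = gene_end[ord]),
      strand = "+",
      type = "gene",
      ID = sprintf("gene_%04d", seq_along(gene_scaf)))
    GenomeInfoDb::seqlengths(genes) <- setNames(as.integer(lens), ids)
    repeats <- GenomicRanges::GRanges(
      seqnames = factor(rep_scaf, levels = ids),
      ranges = IRanges::IRanges(start = rep_start + 1L, end = rep_end),
      strand = rep_strand,
      family = rep_fam)
    GenomeInfoDb::seqlengths(repeats) <- setNames(as.integer(lens), ids)

    truth_tab <- data.frame(
      scaffold_id = ids,
      length = as.integer(lens),
      is_neocen = is_neo,
      repeat_bp = repeat_bp,
      gene_count = as.integer(table(factor(gene_scaf, levels = ids))),
      stringsAsFactors = FALSE)

    lib <- if (has_repeats)
      Biostrings::DNAStringSet(setNames(fam, sprintf("family_%d", seq_along(fam))))
    else Biostrings::DNAStringSet()

    structure(list(seqs = seqs, seqs_chr = as.character(seqs),
                   genes = genes, repeat_library = lib,
                   truth = list(neocen_ids = ids[is_neo], table = truth_tab,
                                repeats = repeats),
                   spec = spec),
              class = "ncs_genome")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scaffold lengths of a simulated genome
#' @param genome An `ncs_genome`.
#' @return Named integer vector of scaffold lengths.
#' @export
scaffold_lengths <- function(genome) {
  stopifnot(inherits(genome, "ncs_genome"))
  setNames(Biostrings::width(genome$seqs), names(genome$seqs))
}

#' Write a simulated genome to disk
#'
#' Emits the scaffold FASTA, repeat-library FASTA, gene GFF3 (1-based closed
#' coordinates, the GFF3 convention), a truth TSV (scaffold_id, length,
#' is_neocen, repeat_bp, gene_count) and a JSON copy of the generating spec.
#'
#' @param genome An `ncs_genome`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named list of the written paths.
#' @export
write_genome <- function(genome, dir) {
  stopifnot(inherits(genome, "ncs_genome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    fasta = file.path(dir, "genome.fa"),
    repeats = file.path(dir, "repeat_library.fa"),
    genes = file.path(dir, "genes.gff3"),
    truth = file.path(dir, "truth.tsv"),
    spec = file.path(dir, "genome_spec.json"))
  Biostrings::writeXStringSet(genome$seqs, paths$fasta)
  Biostrings::writeXStringSet(genome$repeat_library, paths$repeats)
  rtracklayer::export(genome$genes, paths$genes, format = "gff3")
  write.table(genome$truth$table, paths$truth, sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(genome$spec), paths$spec,
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
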