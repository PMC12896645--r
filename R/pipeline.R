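pkg_version <- function() {
  as.character(utils::packageVersion("retrovis"))
}

write_manifest <- function(path, stage_counts, config, seeds = NULL,
                           inputs = NULL) {
  digests <- NULL
  if (!is.null(inputs)) {
    inputs <- inputs[file.exists(inputs)]
    digests <- as.list(tools::md5sum(inputs))
  }
  manifest <- list(tool = "retrovis", version = pkg_version(),
                   config = config, seeds = seeds,
                   input_digests = digests, stage_counts = stage_counts)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Simulate a screen to disk
#'
#' Generates a genome, clone table and full screen from a configuration and
#' writes the file set a real screen would provide: per-sample SAM
#' alignments (and optional FASTQ reads), a TSV sample sheet, the
#' ground-truth clone and abundance tables, a BED gene annotation, and a
#' JSON run manifest.
#'
#' @param config either a list or a YAML/JSON file path with (all optional)
#'   blocks `genome` (`n_chromosomes`, `chrom_length`, `n_genes`,
#'   `gene_width`), `clones` (`n_clones`, `concentration`, `fitness`: list
#'   of `treatment`/`n`/`weight`), and `design` (`treatments`: list of
#'   `name`/`n_pLN1`/`n_pLN2`, plus [screen_design()] scalars).
#' @param out_dir output directory (created).
#' @param rng_seed integer seed.
#' @param emit_reads also write per-sample FASTQ files.
#' @return invisibly, the [simulate_screen()] result plus file paths.
#' @export
run_simulate <- function(config = list(), out_dir, rng_seed = 1L,
                         emit_reads = FALSE) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  gcfg <- config$genome %||% list()
  ccfg <- config$clones %||% list()
  dcfg <- config$design %||% list()

  genome <- make_genome(gcfg$n_chromosomes %||% 4L,
                        gcfg$chrom_length %||% 4e7,
                        gcfg$n_genes %||% 800L,
                        gcfg$gene_width %||% 10000L,
                        rng_seed = rng_seed)
  fitness_spec <- NULL
  if (!is.null(ccfg$fitness))
    fitness_spec <- do.call(rbind, lapply(ccfg$fitness, as.data.frame))
  clones <- plant_integrations(genome, ccfg$n_clones %||% 300L, fitness_spec,
                               concentration = ccfg$concentration %||% 1,
                               rng_seed = rng_seed + 1L)
  if (!is.null(dcfg$treatments)) {
    tdf <- do.call(rbind, lapply(dcfg$treatments, as.data.frame))
    design <- screen_design(tdf,
                            reads_per_sample = dcfg$reads_per_sample %||% 5e4,
                            population_size = dcfg$population_size %||% 2e4,
                            n_passages = dcfg$n_passages %||% 8L,
                            read_length = dcfg$read_length %||% 150L,
                            offset_spread = dcfg$offset_spread %||% 500L)
  } else {
    design <- default_screen_design(
      reads_per_sample = dcfg$reads_per_sample %||% 5e4,
      population_size = dcfg$population_size %||% 2e4,
      n_passages = dcfg$n_passages %||% 8L)
  }

  scr <- simulate_screen(design, clones, genome, emit_reads = emit_reads,
                         rng_seed = rng_seed + 2L)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sam_dir <- file.path(out_dir, "sam")
  dir.create(sam_dir, showWarnings = FALSE)
  write_tsv(scr$samples, file.path(out_dir, "sample_sheet.tsv"))
  write_tsv(scr$clones$clones, file.path(out_dir, "truth_clones.tsv"))
  write_matrix_tsv(scr$truth$abundances,
                   file.path(out_dir, "truth_abundances.tsv"), "clone_id")
  write_tsv(scr$truth$directions, file.path(out_dir, "truth_directions.tsv"))
  write_genes_bed(genome, file.path(out_dir, "genes.bed"))
  for (s in scr$samples$sample_id) {
    aln <- scr$alignments[scr$alignments$sample_id == s, , drop = FALSE]
    write_sam(aln, genome, file.path(sam_dir, paste0(s, ".sam")),
              read_length = design$read_length)
  }
  if (emit_reads) {
    fq_dir <- file.path(out_dir, "fastq")
    dir.create(fq_dir, showWarnings = FALSE)
    for (s in names(scr$reads))
      write_fastq(scr$reads[[s]], file.path(fq_dir, paste0(s, ".fastq")))
  }
  write_manifest(file.path(out_dir, "manifest.json"),
                 stage_counts = list(samples = nrow(scr$samples),
                                     clones = nrow(clones$clones),
                                     genes = nrow(genome$genes),
                                     alignments = nrow(scr$alignments)),
                 config = config, seeds = rng_seed)
  invisible(c(scr, list(genome = genome, out_dir = out_dir)))
}

check_sheet_schema <- function(samples) {
  need <- c("sample_id", "treatment", "biological_replicate")
  missing <- setdiff(need, names(samples))
  if (length(missing))
    stopf("sample sheet schema error: missing column(s) %s",
          paste(missing, collapse = ", "))
  bad <- which(is.na(samples$biological_replicate) |
                 !nzchar(samples$biological_replicate))
  if (length(bad))
    stopf("sample sheet schema error: empty biological_replicate in row(s) %s",
          paste(head(bad, 5L), collapse = ", "))
  invisible(samples)
}

#' Run the screen analysis from alignments to candidates
#'
#' The complete post-alignment pipeline: MAPQ filtering, pooled VIS
#' calling, quantification, optional nearest-gene annotation, the
#' singleton / replicate-concordance / treatment-concordance cascade,
#' frequency and coverage tests per discovery treatment, candidate
#' selection over the candidate treatments, verification-cohort
#' categorisation (when verification samples exist), and TSV/JSON outputs.
#'
#' @param alignments data.frame of alignment records, or a named character
#'   vector of SAM paths (names = sample ids).
#' @param samples sample sheet data.frame or TSV path.
#' @param annotation a `GenomeModel`, BED path, or `NULL` (no annotation).
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param config a [screen_config()].
#' @param window_bp,mapq_min,min_reads_detect pipeline thresholds.
#' @param directions candidate-direction rule, see [select_candidates()].
#' @return invisibly, a list with every stage: `matrix_raw`, `matrix`
#'   (filtered), `results`, `candidates`, `partitions`, `loci`.
#' @export
run_screen <- function(alignments, samples, annotation = NULL,
                       out_dir = NULL, config = screen_config(),
                       window_bp = 1000L, mapq_min = 20L,
                       min_reads_detect = 1L,
                       directions = c("enriched", "exclusive_treated")) {
  if (is.character(samples)) samples <- read_tsv(samples)
  check_sheet_schema(samples)
  if (is.character(alignments)) {
    ids <- names(alignments) %||%
      sub("\\.sam$", "", basename(alignments))
    alignments <- do.call(rbind, Map(read_sam, alignments, ids))
  }
  genome <- NULL
  if (is.character(annotation)) genome <- read_genes_bed(annotation)
  else if (inherits(annotation, "GenomeModel")) genome <- annotation

  aln <- filter_alignments(alignments, mapq_min)
  loci <- call_vis(aln, window_bp)
  if (!is.null(genome)) loci <- annotate_loci(loci, genome)
  m0 <- quantify(loci, aln, samples, min_reads_detect)
  m <- filter_singletons(m0)
  m <- filter_replicate_concordance(m)
  m <- filter_treatment_concordance(m, config)

  treats <- intersect(config$discovery_treatments, unique(samples$treatment))
  results <- do.call(rbind, lapply(treats, function(t)
    screen_results(m, t, config)))
  gene_map <- if (!is.null(genome)) m$loci else NULL
  if (is.null(results)) {  # e.g. control-only input: nothing to test
    candidates <- select_candidates(
      data.frame(locus_id = character(), treatment = character(),
                 freq_flag = character(), cov_flag = character(),
                 freq_direction = character(), cov_direction = character(),
                 stringsAsFactors = FALSE),
      gene_map, config, directions)
  } else {
    cand_res <- results[results$treatment %in% config$candidate_treatments, ,
                        drop = FALSE]
    candidates <- select_candidates(cand_res, gene_map, config, directions)
  }
  have_verif <- all(config$verification_treatments %in% samples$treatment)
  if (have_verif && nrow(candidates))
    candidates <- verify_candidates(candidates, m0, config)

  partitions <- list(
    cascade = summarize_partitions(
      total = nrow(m0$loci),
      exclusions = c(
        singletons = m$filter_log$removed[m$filter_log$stage == "filter_singletons"],
        replicate_discordant = m$filter_log$removed[
          m$filter_log$stage == "filter_replicate_concordance"],
        treatment_discordant = m$filter_log$removed[
          m$filter_log$stage == "filter_treatment_concordance"])),
    candidates = attr(candidates, "partition"))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_loci_bed(m0$loci, file.path(out_dir, "loci.bed"))
    write_tsv(m0$loci, file.path(out_dir, "loci.tsv"))
    write_matrix_tsv(m0$counts, file.path(out_dir, "read_counts.tsv"))
    write_matrix_tsv(m0$rpm, file.path(out_dir, "rpm.tsv"))
    write_matrix_tsv(m0$detected * 1L, file.path(out_dir, "detected.tsv"))
    if (!is.null(results)) {
      write_tsv(results, file.path(out_dir, "screen_results.tsv"))
      write_tsv(volcano_table(results), file.path(out_dir, "volcano.tsv"))
    }
    write_tsv(candidates, file.path(out_dir, "candidate_genes.tsv"))
    write_tsv(m$filter_log, file.path(out_dir, "filter_log.tsv"))
    write_manifest(file.path(out_dir, "manifest.json"),
                   stage_counts = list(
                     alignments_in = nrow(alignments),
                     alignments_mapq = nrow(aln),
                     loci_called = nrow(m0$loci),
                     loci_retained = nrow(m$loci),
                     results_rows = if (is.null(results)) 0L else nrow(results),
                     candidate_genes = nrow(candidates)),
                   config = unclass(config))
  }
  invisible(list(matrix_raw = m0, matrix = m, results = results,
                 candidates = candidates, partitions = partitions,
                 loci = m0$loci))
}

#' Run the single-cell fraction-positive validation
#'
#' @param counts genes x cells matrix, an MTX triplet directory (see
#'   [read_mtx()]), or a dense TSV path (first column gene names).
#' @param labels per-cell labels, or a TSV path with columns `cell`,
#'   `population`.
#' @param genes genes to test (e.g. candidate genes); `NULL` tests all.
#' @param out_dir output directory, or `NULL`.
#' @param threshold CPM positivity threshold.
#' @param alias_map named character vector of symbol aliases.
#' @return invisibly, the [validate_expression()] table.
#' @export
run_validate <- function(counts, labels, genes = NULL, out_dir = NULL,
                         threshold = 1, alias_map = NULL) {
  if (is.character(counts) && length(counts) == 1L) {
    counts <- if (dir.exists(counts)) read_mtx(counts) else {
      df <- read_tsv(counts)
      mm <- as.matrix(df[, -1L, drop = FALSE])
      rownames(mm) <- df[[1L]]
      mm
    }
  }
  if (is.character(labels) && length(labels) == 1L && file.exists(labels)) {
    ldf <- read_tsv(labels)
    labels <- setNames(ldf$population, ldf$cell)
  }
  if (!is.null(genes) && !length(genes)) {
    warning("empty candidate gene list; nothing to validate")
    return(invisible(data.frame()))
  }
  res <- validate_expression(counts, labels, genes, threshold, alias_map)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(res, file.path(out_dir, "validation_results.tsv"))
    write_manifest(file.path(out_dir, "manifest.json"),
                   stage_counts = list(genes_tested = nrow(res),
                                       cells = ncol(counts)),
                   config = list(threshold = threshold))
  }
  invisible(res)
}
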