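# Default adapter sequences used by the simulator (invented, MLV-like LTR
# terminus and a ligation linker); real screens supply their own.
LTR_ADAPTER_DEFAULT <- "TGAAAGACCCCACCTGTAGG"
LINKER_ADAPTER_DEFAULT <- "GTCCCTTAAGCGGAGCCCTA"

#' Describe a screen design (treatments, replicates, depth)
#'
#' @param treatments data.frame with columns `name`, `n_pLN1`, `n_pLN2`
#'   (samples per biological replicate) and optionally `n_passages`
#'   (defaults to `n_passages` argument).  Use name `"NC"` for untreated
#'   controls.
#' @param reads_per_sample sequencing reads simulated per sample.
#' @param population_size cells per passage bottleneck.
#' @param n_passages default passages for treatments lacking their own;
#'   two passages per month of treatment (biweekly splitting), so the
#'   default 8 corresponds to four months of selection.
#' @param read_length read length in bp.
#' @param offset_spread maximum shear-site offset between an alignment's
#'   leftmost position and the true integration point (bp).
#' @param low_mapq_frac fraction of reads assigned a low (< 20) mapping
#'   quality, to exercise the MAPQ filter.
#' @param ltr_adapter,linker_adapter adapter sequences placed on simulated
#'   reads.
#' @return A `ScreenDesign` list.
#' @seealso [default_screen_design()] for the 60-sample layout.
#' @export
screen_design <- function(treatments, reads_per_sample = 5e4,
                          population_size = 2e4, n_passages = 8L,
                          read_length = 150L, offset_spread = 500L,
                          low_mapq_frac = 0.05,
                          ltr_adapter = LTR_ADAPTER_DEFAULT,
                          linker_adapter = LINKER_ADAPTER_DEFAULT) {
  need <- c("name", "n_pLN1", "n_pLN2")
  if (!is.data.frame(treatments) || !all(need %in% names(treatments)))
    stopf("treatments must be a data.frame with columns name, n_pLN1, n_pLN2")
  if (anyDuplicated(treatments$name)) stopf("treatment names must be unique")
  if (any(treatments$n_pLN1 < 0 | treatments$n_pLN2 < 0))
    stopf("sample counts must be non-negative")
  if (is.null(treatments$n_passages)) treatments$n_passages <- n_passages
  if (any(treatments$n_passages < 0)) stopf("n_passages must be >= 0")
  unbalanced <- treatments$name[treatments$n_pLN1 == 0 | treatments$n_pLN2 == 0]
  unbalanced <- setdiff(unbalanced,
                        treatments$name[treatments$n_pLN1 + treatments$n_pLN2 == 0])
  structure(list(
    treatments = treatments,
    reads_per_sample = reads_per_sample,
    population_size = population_size,
    read_length = as.integer(read_length),
    offset_spread = as.integer(offset_spread),
    low_mapq_frac = low_mapq_frac,
    ltr_adapter = ltr_adapter,
    linker_adapter = linker_adapter,
    unbalanced = unbalanced
  ), class = "ScreenDesign")
}

#' The 60-sample discovery + verification screen layout
#'
#' Nineteen untreated controls and 41 treated samples split across the two
#' biological replicates (pLN1/pLN2): 4-OH-tamoxifen 8, fulvestrant 15,
#' ribociclib 7, palbociclib 4, abemaciclib 4, and fulvestrant+ribociclib
#' combination 3.
#'
#' @inheritParams screen_design
#' @return A `ScreenDesign` with 60 samples.
#' @export
default_screen_design <- function(reads_per_sample = 5e4,
                                  population_size = 2e4, n_passages = 8L, ...) {
  tr <- data.frame(
    name = c("NC", "tamoxifen", "fulvestrant", "ribociclib",
             "palbociclib", "abemaciclib", "fulvestrant+ribociclib"),
    n_pLN1 = c(10L, 4L, 8L, 4L, 2L, 2L, 2L),
    n_pLN2 = c(9L, 4L, 7L, 3L, 2L, 2L, 1L),
    stringsAsFactors = FALSE
  )
  screen_design(tr, reads_per_sample = reads_per_sample,
                population_size = population_size, n_passages = n_passages, ...)
}

#' @export
print.ScreenDesign <- function(x, ...) {
  n <- sum(x$treatments$n_pLN1 + x$treatments$n_pLN2)
  cat(sprintf("ScreenDesign: %d samples, %d treatment group(s), %g reads/sample\n",
              n, nrow(x$treatments), x$reads_per_sample))
  if (length(x$unbalanced))
    cat("  unbalanced (single-replicate) groups:",
        paste(x$unbalanced, collapse = ", "), "\n")
  invisible(x)
}

rand_dna <- function(n_chars) {
  paste(sample(c("A", "C", "G", "T"), n_chars, replace = TRUE), collapse = "")
}

#' Simulate one sample's junction reads and alignments
#'
#' Each read is drawn from a clone proportionally to its abundance.  The
#' alignment's leftmost position equals the clone's integration point plus a
#' shear-site offset bounded by `offset_spread` (downstream of the junction
#' for `+` clones, upstream for `-` clones), so all reads of one clone fall
#' within `offset_spread` of the true site.  Read sequences are LTR adapter
#' + genomic flank + linker adapter, truncated to the read length; the flank
#' is random sequence (reads are not re-aligned, the alignment records carry
#' the positional truth).  MAPQ is drawn from a mixture with a configurable
#' low-quality fraction so that the MAPQ < 20 filter has work to do.
#'
#' @param clones a `CloneTable`.
#' @param abundances abundance vector over clones (sums to 1), e.g. from
#'   [evolve_population()].
#' @param reads_per_sample number of reads (0 gives empty outputs).
#' @param genome the `GenomeModel`.
#' @param sample_id sample identifier stamped on reads/alignments.
#' @param read_length,offset_spread,low_mapq_frac,ltr_adapter,linker_adapter
#'   see [screen_design()].
#' @param emit_reads if `FALSE`, skip sequence generation (alignments only).
#' @param rng_seed integer seed or `NULL`.
#' @return list with `reads` (data.frame `read_id`, `sequence`, `qualities`,
#'   or `NULL`) and `alignments` (data.frame `read_id`, `sample_id`,
#'   `chrom`, `position`, `orientation`, `mapq`; 0-based positions).
#' @export
simulate_sample <- function(clones, abundances, reads_per_sample, genome,
                            sample_id = "S1", read_length = 150L,
                            offset_spread = 500L, low_mapq_frac = 0.05,
                            ltr_adapter = LTR_ADAPTER_DEFAULT,
                            linker_adapter = LINKER_ADAPTER_DEFAULT,
                            emit_reads = TRUE, rng_seed = NULL) {
  if (!inherits(clones, "CloneTable")) stopf("expected a CloneTable")
  cl <- clones$clones
  if (length(abundances) != nrow(cl))
    stopf("abundances (%d) must match clone count (%d)",
          length(abundances), nrow(cl))
  if (!is_count(reads_per_sample)) stopf("reads_per_sample must be >= 0")
  empty_aln <- data.frame(read_id = character(), sample_id = character(),
                          chrom = character(), position = numeric(),
                          orientation = character(), mapq = integer(),
                          stringsAsFactors = FALSE)
  if (reads_per_sample == 0L)
    return(list(reads = if (emit_reads) data.frame(read_id = character(),
                                                   sequence = character(),
                                                   qualities = character(),
                                                   stringsAsFactors = FALSE) else NULL,
                alignments = empty_aln))

  with_seed(rng_seed, {
    n <- as.integer(reads_per_sample)
    idx <- sample.int(nrow(cl), n, replace = TRUE, prob = abundances)
    offset <- if (offset_spread > 0)
      sample.int(offset_spread + 1L, n, replace = TRUE) - 1L else integer(n)
    sgn <- ifelse(cl$orientation[idx] == "+", 1, -1)
    pos <- cl$position[idx] + sgn * offset
    lim <- genome$chromosomes[cl$chrom[idx]]
    pos <- pmax(0, pmin(pos, lim - 1))
    mapq <- ifelse(runif(n) < low_mapq_frac,
                   sample.int(20L, n, replace = TRUE) - 1L, 60L)
    ids <- sprintf("%s_r%06d", sample_id, seq_len(n))
    aln <- data.frame(read_id = ids, sample_id = sample_id,
                      chrom = cl$chrom[idx], position = as.numeric(pos),
                      orientation = cl$orientation[idx],
                      mapq = as.integer(mapq), stringsAsFactors = FALSE)
    reads <- NULL
    if (emit_reads) {
      flank_len <- sample(30:max(30L, read_length), n, replace = TRUE)
      seqs <- vapply(flank_len, rand_dna, character(1))
      full <- paste0(ltr_adapter, seqs, linker_adapter)
      full <- substr(full, 1L, read_length)
      reads <- data.frame(read_id = ids, sequence = full,
                          qualities = strrep("I", nchar(full)),
                          stringsAsFactors = FALSE)
    }
    list(reads = reads, alignments = aln)
  })
}

#' Simulate a complete screen with ground truth
#'
#' Runs one [evolve_population()] plus one [simulate_sample()] per sample of
#' the design (independent selection trajectories per sample, hierarchically
#' seeded), attaches treatment/replicate/timepoint metadata, and records the
#' truth: each clone's expected enrichment direction per treatment and its
#' realised final abundance in every sample.
#'
#' @param design a [screen_design()].
#' @param clones a `CloneTable`.
#' @param genome the `GenomeModel`.
#' @param emit_reads generate read sequences as well as alignments.
#' @param rng_seed integer seed or `NULL`.
#' @return list with `samples` (sample sheet: `sample_id`, `treatment`,
#'   `biological_replicate`, `timepoint_months`), `alignments` (all samples,
#'   row-bound), `reads` (list per sample or `NULL`), and `truth` (list:
#'   `directions` clone x treatment data.frame, `abundances` clone x sample
#'   matrix).
#' @examples
#' gm <- make_genome(2, 1e6, 0, rng_seed = 1)
#' ct <- plant_integrations(gm, 10, rng_seed = 1)
#' des <- screen_design(data.frame(name = c("NC", "fulvestrant"),
#'                                 n_pLN1 = c(2, 2), n_pLN2 = c(2, 2)),
#'                      reads_per_sample = 500)
#' scr <- simulate_screen(des, ct, gm, rng_seed = 42)
#' scr$samples
#' @export
simulate_screen <- function(design, clones, genome, emit_reads = FALSE,
                            rng_seed = NULL) {
  if (!inherits(design, "ScreenDesign")) stopf("expected a ScreenDesign")
  if (!inherits(clones, "CloneTable")) stopf("expected a CloneTable")
  tr <- design$treatments

  sheet <- do.call(rbind, lapply(seq_len(nrow(tr)), function(r) {
    reps <- c(rep("pLN1", tr$n_pLN1[r]), rep("pLN2", tr$n_pLN2[r]))
    if (!length(reps)) return(NULL)
    safe <- gsub("[^A-Za-z0-9]+", "", tr$name[r])
    data.frame(
      sample_id = sprintf("%s_%s_%02d", safe, reps,
                          c(seq_len(tr$n_pLN1[r]), seq_len(tr$n_pLN2[r]))),
      treatment = tr$name[r],
      biological_replicate = reps,
      timepoint_months = tr$n_passages[r] / 2,
      n_passages = tr$n_passages[r],
      stringsAsFactors = FALSE
    )
  }))
  rownames(sheet) <- NULL
  n_samples <- nrow(sheet)

  with_seed(rng_seed, {
    seeds <- split_seeds(2L * n_samples)
    ab_mat <- matrix(NA_real_, nrow(clones$clones), n_samples,
                     dimnames = list(clones$clones$clone_id, sheet$sample_id))
    aln <- vector("list", n_samples)
    reads <- if (emit_reads) vector("list", n_samples) else NULL
    for (s in seq_len(n_samples)) {
      ab <- evolve_population(clones, sheet$treatment[s], sheet$n_passages[s],
                              design$population_size, rng_seed = seeds[s])
      ab_mat[, s] <- ab
      sim <- simulate_sample(
        clones, ab, design$reads_per_sample, genome,
        sample_id = sheet$sample_id[s], read_length = design$read_length,
        offset_spread = design$offset_spread,
        low_mapq_frac = design$low_mapq_frac,
        ltr_adapter = design$ltr_adapter,
        linker_adapter = design$linker_adapter,
        emit_reads = emit_reads, rng_seed = seeds[n_samples + s])
      aln[[s]] <- sim$alignments
      if (emit_reads) reads[[s]] <- sim$reads
    }
    if (emit_reads) names(reads) <- sheet$sample_id

    fit <- clones$fitness
    dir_mat <- ifelse(fit > 1, "enriched", ifelse(fit < 1, "depleted", "neutral"))
    directions <- data.frame(clone_id = rownames(fit),
                             as.data.frame(dir_mat, stringsAsFactors = FALSE),
                             check.names = FALSE, stringsAsFactors = FALSE)
    rownames(directions) <- NULL

    list(samples = sheet[, c("sample_id", "treatment", "biological_replicate",
                             "timepoint_months")],
         alignments = do.call(rbind, aln),
         reads = reads,
         truth = list(directions = directions, abundances = ab_mat),
         clones = clones)
  })
}
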