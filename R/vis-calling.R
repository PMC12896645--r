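#' Remove alignments below a mapping-quality threshold
#'
#' @param alignments data.frame with at least a `mapq` column.
#' @param mapq_min minimum retained MAPQ (default 20; records with
#'   `mapq < mapq_min` are removed, record order preserved).
#' @return the filtered data.frame.
#' @export
filter_alignments <- function(alignments, mapq_min = 20L) {
  if (mapq_min < 0) stopf("mapq_min must be >= 0")
  if (!"mapq" %in% names(alignments)) stopf("alignments must have a mapq column")
  alignments[alignments$mapq >= mapq_min, , drop = FALSE]
}

#' Collapse alignment positions into viral integration-site loci
#'
#' Pools alignments across all samples and, per chromosome, chains sorted
#' positions by single linkage: consecutive positions at most `window_bp`
#' apart join the same locus (the boundary is inclusive: a gap of exactly
#' `window_bp` merges).  The resulting partition equals the transitive
#' closure of the pairwise <= `window_bp` relation and is independent of
#' input record order.
#'
#' @param alignments data.frame with columns `chrom`, `position` and
#'   optionally `orientation` (for per-locus strand tallies).
#' @param window_bp merge window in bp (default 1000).
#' @return data.frame of loci ordered by (chromosome, start) with columns
#'   `locus_id`, `chrom`, `start`, `end` (0-based half-open span of member
#'   positions), `representative_position` (read-count-weighted median of
#'   member positions, rounded down), `n_reads`, `n_plus`, `n_minus`.
#' @examples
#' aln <- data.frame(chrom = "chr1", position = c(100, 1100, 2101),
#'                   orientation = "+")
#' call_vis(aln)  # gap 1000 merges, gap 1001 does not
#' @export
call_vis <- function(alignments, window_bp = 1000L) {
  if (window_bp < 0) stopf("window_bp must be >= 0")
  need <- c("chrom", "position")
  if (!all(need %in% names(alignments)))
    stopf("alignments must have chrom and position columns")
  if (nrow(alignments) == 0L)
    return(data.frame(locus_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      representative_position = numeric(),
                      n_reads = integer(), n_plus = integer(),
                      n_minus = integer(), stringsAsFactors = FALSE))
  ori <- if ("orientation" %in% names(alignments)) alignments$orientation
         else rep(NA_character_, nrow(alignments))
  o <- order(alignments$chrom, alignments$position)
  ch <- alignments$chrom[o]
  pos <- alignments$position[o]
  ori <- ori[o]
  new_cluster <- c(TRUE, ch[-1L] != ch[-length(ch)] |
                     diff(pos) > window_bp)
  cid <- cumsum(new_cluster)
  start <- tapply(pos, cid, min)
  endp <- tapply(pos, cid, max)
  repp <- floor(tapply(pos, cid, median))
  nr <- tabulate(cid)
  npl <- as.integer(tapply(ori == "+", cid, sum))
  nmi <- as.integer(tapply(ori == "-", cid, sum))
  loci <- data.frame(
    chrom = tapply(ch, cid, `[`, 1L),
    start = as.numeric(start),
    end = as.numeric(endp) + 1,
    representative_position = as.numeric(repp),
    n_reads = nr,
    n_plus = ifelse(is.na(npl), 0L, npl),
    n_minus = ifelse(is.na(nmi), 0L, nmi),
    stringsAsFactors = FALSE
  )
  loci <- loci[order(loci$chrom, loci$start), , drop = FALSE]
  loci <- data.frame(locus_id = sprintf("VIS_%05d", seq_len(nrow(loci))),
                     loci, stringsAsFactors = FALSE)
  rownames(loci) <- NULL
  loci
}

#' Build the locus x sample detection/read-count/RPM matrix
#'
#' Assigns each alignment to the locus whose span contains its position
#' (loci must come from [call_vis()] on the same pooled alignments, which
#' guarantees a unique home for every record), tallies read counts per
#' locus and sample, normalises per sample to reads per million of
#' VIS-assigned reads, and flags detection at `min_reads_detect` reads.
#'
#' @param loci data.frame from [call_vis()].
#' @param alignments the same pooled alignments (needs `sample_id`).
#' @param samples sample sheet: data.frame with `sample_id`, `treatment`,
#'   `biological_replicate` and optionally `timepoint_months`.
#' @param min_reads_detect reads required to call a locus detected in a
#'   sample (default 1).
#' @return A `LocusSampleMatrix`: list with `loci`, `samples`, `counts`,
#'   `rpm`, `detected` (loci x samples matrices) and `min_reads_detect`.
#'   Samples without any assigned read get RPM 0 (with a warning).
#' @export
quantify <- function(loci, alignments, samples, min_reads_detect = 1L) {
  need <- c("sample_id", "treatment", "biological_replicate")
  if (!is.data.frame(samples) || !all(need %in% names(samples)))
    stopf("samples must be a data.frame with columns %s",
          paste(need, collapse = ", "))
  if (!"sample_id" %in% names(alignments))
    stopf("alignments must carry sample_id")
  extra <- setdiff(unique(alignments$sample_id), samples$sample_id)
  if (length(extra))
    stopf("alignments reference samples missing from the sheet: %s",
          paste(head(extra, 5L), collapse = ", "))

  lix <- rep(NA_integer_, nrow(alignments))
  for (ch in unique(loci$chrom)) {
    li <- which(loci$chrom == ch)
    ai <- which(alignments$chrom == ch)
    if (!length(ai)) next
    pos <- alignments$position[ai]
    j <- findInterval(pos, loci$start[li])
    bad <- j == 0L | pos > loci$end[li[pmax(j, 1L)]] - 1
    if (any(bad))
      stopf("%d alignment(s) fall outside all loci (pipeline misuse: quantify must see the same pooled alignments as call_vis)",
            sum(bad))
    lix[ai] <- li[j]
  }
  if (anyNA(lix) && nrow(alignments))
    stopf("alignments on chromosomes without loci (pipeline misuse)")

  counts <- table(factor(lix, levels = seq_len(nrow(loci))),
                  factor(alignments$sample_id, levels = samples$sample_id))
  counts <- matrix(as.integer(counts), nrow(loci), nrow(samples),
                   dimnames = list(loci$locus_id, samples$sample_id))
  tot <- colSums(counts)
  zero <- tot == 0
  if (any(zero))
    warning(sprintf("%d sample(s) have no VIS-assigned reads; their RPM is 0: %s",
                    sum(zero), paste(head(names(tot)[zero], 5L), collapse = ", ")))
  denom <- ifelse(zero, 1, tot)
  rpm <- sweep(counts, 2L, denom, "/") * 1e6
  detected <- counts >= min_reads_detect
  structure(list(loci = loci, samples = samples, counts = counts, rpm = rpm,
                 detected = detected,
                 min_reads_detect = as.integer(min_reads_detect),
                 filter_log = data.frame(stage = "quantify",
                                         input = nrow(loci), removed = 0L,
                                         retained = nrow(loci),
                                         stringsAsFactors = FALSE)),
            class = "LocusSampleMatrix")
}

#' @export
print.LocusSampleMatrix <- function(x, ...) {
  cat(sprintf("LocusSampleMatrix: %d loci x %d samples (%d detections, min reads %d)\n",
              nrow(x$counts), ncol(x$counts), sum(x$detected),
              x$min_reads_detect))
  invisible(x)
}

# Keep a subset of loci, recording the stage in the filter log.
lsm_subset <- function(m, keep, stage) {
  keep <- which(keep)
  out <- m
  out$loci <- m$loci[keep, , drop = FALSE]
  out$counts <- m$counts[keep, , drop = FALSE]
  out$rpm <- m$rpm[keep, , drop = FALSE]
  out$detected <- m$detected[keep, , drop = FALSE]
  out$filter_log <- rbind(m$filter_log, data.frame(
    stage = stage, input = nrow(m$loci),
    removed = nrow(m$loci) - length(keep), retained = length(keep),
    stringsAsFactors = FALSE))
  out
}

#' Annotate loci with their nearest gene
#'
#' Distance is 0 when the representative position lies within a gene
#' interval, otherwise the gap to the nearest interval boundary on the same
#' chromosome (`start - p` upstream, `p - end` downstream, with the
#' half-open end coordinate).  Ties go to the gene with the smaller start,
#' then to the lexicographically smaller name; chromosomes without genes
#' yield `NA`.
#'
#' @param loci data.frame from [call_vis()].
#' @param genome a `GenomeModel` (genes sorted per chromosome).
#' @return `loci` with added `nearest_gene` and `gene_distance` columns.
#' @export
annotate_loci <- function(loci, genome) {
  validate_genome(genome)
  g <- genome$genes
  loci$nearest_gene <- NA_character_
  loci$gene_distance <- NA_real_
  if (!nrow(loci) || !nrow(g)) return(loci)
  for (ch in unique(loci$chrom)) {
    gi <- g[g$chrom == ch, , drop = FALSE]
    if (!nrow(gi)) next
    gi <- gi[order(gi$start, gi$name), , drop = FALSE]
    li <- which(loci$chrom == ch)
    for (i in li) {
      p <- loci$representative_position[i]
      d <- pmax(0, gi$start - p, p - gi$end)
      best <- which(d == min(d))  # already ordered by (start, name)
      loci$nearest_gene[i] <- gi$name[best[1L]]
      loci$gene_distance[i] <- d[best[1L]]
    }
  }
  loci
}
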