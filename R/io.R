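#' Read and write FASTQ files
#'
#' Thin wrappers around Biostrings keeping the package's plain data.frame
#' read representation (`read_id`, `sequence`, `qualities`).
#'
#' @param reads data.frame with `read_id`, `sequence`, `qualities`.
#' @param path file path.
#' @return `read_fastq` returns the data.frame; `write_fastq` returns the
#'   path invisibly.
#' @export
write_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- reads$read_id
  quals <- Biostrings::BStringSet(reads$qualities)
  qs <- suppressWarnings(Biostrings::QualityScaledDNAStringSet(
    seqs, Biostrings::PhredQuality(quals)))  # harmless mcols-dropped chatter
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  # harmless mcols-dropped chatter from the Biostrings constructor
  qs <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(read_id = names(qs),
             sequence = as.character(qs),
             qualities = as.character(Biostrings::quality(qs)),
             stringsAsFactors = FALSE)
}

#' Write alignment records as a headered SAM file
#'
#' Emits minimal single-end records: 0-based internal positions become
#' 1-based SAM `POS`, orientation becomes the 0x10 flag, the CIGAR is a
#' single match run of `read_length`, and SEQ/QUAL are omitted (`*`).
#'
#' @param alignments data.frame with `read_id`, `chrom`, `position`
#'   (0-based), `orientation`, `mapq`.
#' @param genome a `GenomeModel` (for the `@SQ` header lines).
#' @param path output path.
#' @param read_length match-run length written in the CIGAR.
#' @return the path, invisibly.
#' @export
write_sam <- function(alignments, genome, path, read_length = 150L) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(genome$chromosomes),
                      as.integer(genome$chromosomes)))
  flag <- ifelse(alignments$orientation == "-", 16L, 0L)
  recs <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*",
                  alignments$read_id, flag, alignments$chrom,
                  as.integer(alignments$position) + 1L,
                  as.integer(alignments$mapq), as.integer(read_length))
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Read a SAM file into the package's alignment table
#'
#' Converts via Rsamtools (SAM -> BAM -> records); positions come back
#' 0-based, orientation from the strand flag.
#'
#' @param path SAM file path (headered).
#' @param sample_id sample identifier stamped on the records.
#' @return data.frame with `read_id`, `sample_id`, `chrom`, `position`,
#'   `orientation`, `mapq`.
#' @export
read_sam <- function(path, sample_id = NA_character_) {
  dest <- tempfile(fileext = "")
  bam <- Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai")), force = TRUE))
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "strand"))
  b <- Rsamtools::scanBam(bam, param = p)[[1L]]
  keep <- !is.na(b$pos)
  data.frame(read_id = b$qname[keep], sample_id = sample_id,
             chrom = as.character(b$rname)[keep],
             position = as.numeric(b$pos[keep]) - 1,
             orientation = as.character(b$strand)[keep],
             mapq = as.integer(b$mapq)[keep],
             stringsAsFactors = FALSE)
}

#' Write a gene annotation (or loci) as BED
#'
#' @param genome a `GenomeModel`.
#' @param path output path (BED, 0-based half-open, native).
#' @return the path, invisibly.
#' @export
write_genes_bed <- function(genome, path) {
  g <- genome$genes
  if (!nrow(g)) { writeLines(character(), path); return(invisible(path)) }
  gr <- GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
    strand = g$strand, name = g$name)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED gene annotation into a `GenomeModel`
#'
#' @param path BED file path.
#' @param chromosomes named chromosome lengths; when `NULL`, lengths are
#'   taken as the furthest annotated end per chromosome.
#' @return a `GenomeModel`.
#' @export
read_genes_bed <- function(path, chromosomes = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  g <- data.frame(
    name = if (!is.null(gr$name)) gr$name else
      sprintf("G%04d", seq_along(gr)),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  g$strand[g$strand == "*"] <- "+"
  if (is.null(chromosomes)) {
    chromosomes <- tapply(g$end, g$chrom, max)
    chromosomes <- setNames(as.numeric(chromosomes), names(chromosomes))
  }
  g <- g[order(g$chrom, g$start), , drop = FALSE]
  rownames(g) <- NULL
  structure(list(chromosomes = chromosomes, genes = g), class = "GenomeModel")
}

#' Write the BED track of called VIS loci
#'
#' Locus id becomes the BED name and total read count the score.
#'
#' @param loci data.frame from [call_vis()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_loci_bed <- function(loci, path) {
  if (!nrow(loci)) { writeLines(character(), path); return(invisible(path)) }
  gr <- GenomicRanges::GRanges(
    seqnames = loci$chrom,
    ranges = IRanges::IRanges(start = loci$start + 1L, end = loci$end),
    name = loci$locus_id, score = pmin(loci$n_reads, 1000L))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

write_matrix_tsv <- function(m, path, id_col = "locus_id") {
  df <- data.frame(rownames(m), as.data.frame(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  write_tsv(df, path)
}

#' Read or write a sparse count matrix in Matrix Market form
#'
#' The triplet of files standard in single-cell work: `matrix.mtx` plus
#' `genes.tsv` and `barcodes.tsv` (one name per line).
#'
#' @param counts genes x cells matrix.
#' @param dir directory holding/receiving the triplet.
#' @return `read_mtx` returns a dense genes x cells matrix.
#' @export
write_mtx <- function(counts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' @rdname write_mtx
#' @export
read_mtx <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  rownames(m) <- readLines(file.path(dir, "genes.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  storage.mode(m) <- "integer"
  m
}
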