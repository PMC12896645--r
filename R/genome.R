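#' Build a toy genome model with a non-overlapping gene annotation
#'
#' Generates a small stand-in for a reference genome: named chromosomes of
#' fixed length and a set of non-overlapping gene intervals placed uniformly
#' at random.  Coordinates are 0-based half-open throughout the package;
#' they only become 1-based in SAM output.
#'
#' Genes are assigned to chromosomes proportionally to chromosome length and
#' placed uniformly among all non-overlapping configurations (touching
#' intervals are allowed; half-open intervals that touch do not overlap).
#'
#' @param n_chromosomes number of chromosomes (named `chr1`, `chr2`, ...).
#' @param chrom_length chromosome length in bp; a scalar (all equal) or a
#'   vector of length `n_chromosomes`.
#' @param n_genes number of gene intervals to place.
#' @param gene_width gene width in bp (scalar).
#' @param rng_seed integer seed for reproducible placement, or `NULL`.
#' @return A `GenomeModel`: list with `chromosomes` (named lengths) and
#'   `genes` (data.frame with `name`, `chrom`, `start`, `end`, `strand`).
#' @examples
#' gm <- make_genome(2, 5e5, 50, rng_seed = 7)
#' head(gm$genes)
#' @export
make_genome <- function(n_chromosomes, chrom_length, n_genes,
                        gene_width = 2000L, rng_seed = NULL) {
  if (!is_count(n_chromosomes, 1L)) stopf("n_chromosomes must be a positive integer")
  if (!is_count(n_genes)) stopf("n_genes must be a non-negative integer")
  if (!is_count(gene_width, 1L)) stopf("gene_width must be a positive integer")
  len <- rep_len(as.numeric(chrom_length), n_chromosomes)
  if (any(len < 1)) stopf("chromosome lengths must be positive")
  chroms <- setNames(len, paste0("chr", seq_len(n_chromosomes)))

  if (n_genes * gene_width > sum(len))
    stopf("cannot place %d non-overlapping genes of width %d in %g bp of genome",
          n_genes, gene_width, sum(len))

  genes <- with_seed(rng_seed, {
    placed <- NULL
    if (n_genes > 0L) {
      # retry chromosome assignment until each chromosome can hold its share
      for (attempt in seq_len(100L)) {
        idx <- sample.int(n_chromosomes, n_genes, replace = TRUE, prob = len)
        k <- tabulate(idx, n_chromosomes)
        if (all(k * gene_width <= len)) { placed <- idx; break }
      }
      if (is.null(placed))
        stopf("cannot place %d non-overlapping genes of width %d (per-chromosome capacity exceeded)",
              n_genes, gene_width)
    }
    out <- vector("list", n_chromosomes)
    for (ci in seq_len(n_chromosomes)) {
      k <- sum(placed == ci)
      if (k == 0L) next
      # uniform non-overlapping placement: sorted draws plus width offsets
      slack <- len[ci] - k * gene_width
      x <- sort(sample.int(slack + 1, k, replace = TRUE) - 1)
      out[[ci]] <- data.frame(
        chrom = names(chroms)[ci],
        start = x + (seq_len(k) - 1) * gene_width,
        stringsAsFactors = FALSE
      )
    }
    g <- do.call(rbind, out)
    if (is.null(g)) {
      g <- data.frame(name = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      strand = character(), stringsAsFactors = FALSE)
    } else {
      g$end <- g$start + gene_width
      g$strand <- sample(c("+", "-"), nrow(g), replace = TRUE)
      g <- g[order(g$chrom, g$start), , drop = FALSE]
      g <- data.frame(name = sprintf("G%04d", seq_len(nrow(g))), g,
                      stringsAsFactors = FALSE)
      rownames(g) <- NULL
    }
    g
  })

  structure(list(chromosomes = chroms, genes = genes), class = "GenomeModel")
}

#' @export
print.GenomeModel <- function(x, ...) {
  cat(sprintf("GenomeModel: %d chromosome(s), %g bp total, %d gene(s)\n",
              length(x$chromosomes), sum(x$chromosomes), nrow(x$genes)))
  invisible(x)
}

validate_genome <- function(genome) {
  if (!inherits(genome, "GenomeModel")) stopf("expected a GenomeModel")
  g <- genome$genes
  if (nrow(g)) {
    if (anyDuplicated(g$name)) stopf("gene names must be unique")
    if (any(g$start >= g$end)) stopf("gene intervals must satisfy start < end")
    if (any(g$end > genome$chromosomes[g$chrom]))
      stopf("gene intervals must lie within their chromosome")
  }
  invisible(genome)
}
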