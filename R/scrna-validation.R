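#' Counts-per-million normalisation of a cell expression matrix
#'
#' `cpm(g, c) = 1e6 * count(g, c) / total counts of cell c`.  Cells with a
#' zero total are excluded with a warning (their names are kept in
#' `attr(, "excluded_cells")`).
#'
#' @param counts genes x cells non-negative count matrix with dimnames.
#' @return the CPM matrix over retained cells.
#' @export
cpm_normalize <- function(counts) {
  if (any(counts < 0)) stopf("counts must be non-negative")
  tot <- colSums(counts)
  zero <- tot == 0
  if (any(zero))
    warning(sprintf("excluding %d zero-count cell(s)", sum(zero)))
  cpm <- sweep(counts[, !zero, drop = FALSE], 2L, tot[!zero], "/") * 1e6
  attr(cpm, "excluded_cells") <- colnames(counts)[zero]
  cpm
}

#' Fraction of expression-positive cells per gene and population
#'
#' A cell is positive for a gene iff its CPM is at least `threshold`
#' (inclusive boundary).
#'
#' @param cpm CPM matrix (genes x cells) from [cpm_normalize()].
#' @param labels population label per cell (`"parental"`/`"resistant"`),
#'   in column order or named by cell.
#' @param threshold minimum CPM to call a cell positive (default 1).
#' @return data.frame with per-gene positive counts and fractions for both
#'   populations.
#' @export
positive_fractions <- function(cpm, labels, threshold = 1) {
  if (threshold <= 0) stopf("threshold must be > 0")
  if (!is.null(names(labels))) labels <- labels[colnames(cpm)]
  if (length(labels) != ncol(cpm))
    stopf("labels must cover every cell")
  pops <- c("parental", "resistant")
  bad <- setdiff(unique(labels), pops)
  if (length(bad)) stopf("unknown population label(s): %s",
                         paste(bad, collapse = ", "))
  n_par <- sum(labels == "parental"); n_res <- sum(labels == "resistant")
  if (n_par == 0L || n_res == 0L)
    stopf("both populations must be non-empty")
  pos <- cpm >= threshold
  pp <- rowSums(pos[, labels == "parental", drop = FALSE])
  pr <- rowSums(pos[, labels == "resistant", drop = FALSE])
  data.frame(gene = rownames(cpm),
             n_parental = n_par, n_resistant = n_res,
             pos_parental = as.integer(pp), pos_resistant = as.integer(pr),
             frac_parental = pp / n_par, frac_resistant = pr / n_res,
             stringsAsFactors = FALSE)
}

#' Pearson chi-squared test for a 2x2 table
#'
#' Statistic `sum((O - E)^2 / E)` on 1 degree of freedom, without
#' continuity correction by default (Yates available); equals the shortcut
#' `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`.  Any zero margin gives
#' statistic 0 and p = 1.
#'
#' @param pos_a,neg_a,pos_b,neg_b cell counts: positive/negative cells in
#'   populations a and b.
#' @param yates apply the continuity correction.
#' @return list with `statistic` and `p`.
#' @export
chi_squared_2x2 <- function(pos_a, neg_a, pos_b, neg_b, yates = FALSE) {
  cells <- c(pos_a, neg_a, pos_b, neg_b)
  if (any(cells < 0)) stopf("counts must be non-negative")
  cells <- as.numeric(cells)  # doubles: margin products overflow integers
  a <- cells[1L]; b <- cells[2L]; c <- cells[3L]; d <- cells[4L]
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0)
    return(list(statistic = 0, p = 1))
  delta <- abs(a * d - b * c)
  if (yates) delta <- max(0, delta - n / 2)
  stat <- n * delta^2 / (r1 * r2 * c1 * c2)
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Bonferroni correction
#'
#' `p_adj = min(1, m * p)`, order-preserving.  `m` defaults to the number
#' of p-values and must be at least that many.
#'
#' @param p_values numeric p-values.
#' @param m number of tests in the family.
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (!is_count(m, 1L)) stopf("m must be a positive integer")
  if (m < length(p_values))
    stopf("m (%d) must be at least the number of tests (%d)",
          m, length(p_values))
  pmin(1, m * p_values)
}

#' Fraction-positive validation of candidate genes in single-cell data
#'
#' CPM-normalises the counts, computes per-gene positive fractions in the
#' parental and resistant populations, tests each gene with the 2x2
#' chi-squared test, and Bonferroni-corrects over the genes actually
#' tested.
#'
#' @param counts genes x cells count matrix.
#' @param labels per-cell population labels (`"parental"`/`"resistant"`).
#' @param genes genes to test (default: all rows); an alias map
#'   (named character vector, `names` = external symbol, value = matrix
#'   rowname) is applied first.
#' @param threshold CPM positivity threshold (default 1).
#' @param alias_map optional named character vector mapping requested gene
#'   symbols to matrix rownames.
#' @param yates continuity correction for the chi-squared test.
#' @return data.frame of `ValidationResult`s: `gene`,
#'   `frac_positive_parental`, `frac_positive_resistant`, `chi2_stat`, `p`,
#'   `p_bonferroni`, `direction` (resistant vs parental).  Unmatched genes
#'   are reported in `attr(, "unmatched")`.
#' @export
validate_expression <- function(counts, labels, genes = NULL, threshold = 1,
                                alias_map = NULL, yates = FALSE) {
  genes <- genes %||% rownames(counts)
  requested <- genes
  if (!is.null(alias_map)) {
    hit <- requested %in% names(alias_map)
    genes[hit] <- alias_map[requested[hit]]
  }
  found <- genes %in% rownames(counts)
  if (!any(found))
    stopf("none of the requested genes are present in the matrix: %s",
          paste(head(requested, 10L), collapse = ", "))
  cpm <- cpm_normalize(counts)
  if (!is.null(names(labels))) labels <- labels[colnames(cpm)]
  else labels <- labels[colnames(counts) %in% colnames(cpm)]
  fr <- positive_fractions(cpm[genes[found], , drop = FALSE], labels,
                           threshold)
  tests <- mapply(function(pa, na, pb, nb) {
    unlist(chi_squared_2x2(pa, na, pb, nb, yates = yates))
  }, fr$pos_parental, fr$n_parental - fr$pos_parental,
     fr$pos_resistant, fr$n_resistant - fr$pos_resistant)
  out <- data.frame(
    gene = requested[found],
    frac_positive_parental = fr$frac_parental,
    frac_positive_resistant = fr$frac_resistant,
    chi2_stat = tests["statistic", ],
    p = tests["p", ],
    stringsAsFactors = FALSE)
  out$p_bonferroni <- bonferroni_adjust(out$p, m = nrow(out))
  out$direction <- ifelse(out$frac_positive_resistant >
                            out$frac_positive_parental, "up",
                   ifelse(out$frac_positive_resistant <
                            out$frac_positive_parental, "down", "none"))
  attr(out, "unmatched") <- requested[!found]
  out
}

#' Concordance between single-cell validation and the screen
#'
#' A gene is `consistent` when its RNA direction (resistant vs parental
#' positive fraction) matches its screen direction (treated vs control
#' detection fraction, pooled over the gene's supporting loci) for the
#' designated treatment, `opposite` when the directions disagree, and
#' `not_in_screen` when the gene has no screen detection in that treatment.
#'
#' @param validation a [validate_expression()] table.
#' @param results a [screen_results()] (or [frequency_tests()]) table for
#'   the designated treatment.
#' @param locus_gene_map data.frame with `locus_id`, `nearest_gene`
#'   (e.g. from [annotate_loci()]); `NULL` treats locus ids as genes.
#' @param alias_map optional named character vector mapping validation gene
#'   symbols to screen gene symbols (matching is case-sensitive).
#' @return `validation` with added `screen_direction` and `concordance`.
#' @export
concordance <- function(validation, results, locus_gene_map = NULL,
                        alias_map = NULL) {
  gene_of <- results$locus_id
  if (!is.null(locus_gene_map)) {
    g <- locus_gene_map$nearest_gene[match(results$locus_id,
                                           locus_gene_map$locus_id)]
    gene_of <- ifelse(is.na(g), results$locus_id, g)
  }
  screen_dir <- vapply(split(seq_len(nrow(results)), gene_of), function(i) {
    ft <- sum(results$a[i]) / results$n_t[i][1L]
    fc <- sum(results$b[i]) / results$n_c[i][1L]
    if (sum(results$a[i]) == 0) return(NA_character_)  # no treated detection
    if (ft > fc) "up" else if (ft < fc) "down" else "none"
  }, character(1))

  query <- validation$gene
  if (!is.null(alias_map)) {
    hit <- query %in% names(alias_map)
    query[hit] <- alias_map[query[hit]]
  }
  sd <- screen_dir[query]
  validation$screen_direction <- unname(sd)
  validation$concordance <- ifelse(
    is.na(sd), "not_in_screen",
    ifelse(sd == validation$direction, "consistent", "opposite"))
  validation
}
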