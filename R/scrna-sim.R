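#' Simulate a parental-vs-resistant single-cell expression matrix
#'
#' A zero-inflated count model for fraction-positive validation: for each
#' gene and population, a cell expresses the gene with that population's
#' probability; expressed cells draw a strictly positive count from a
#' negative-binomial component whose mean scales with a per-cell log-normal
#' library-size factor, non-expressed cells contribute 0.  The planted truth
#' records both probabilities per gene.
#'
#' @param gene_names character vector of gene names (unique).
#' @param n_parental,n_resistant cells per population (>= 1 each).
#' @param effect_spec data.frame with columns `gene`, `p_parental`,
#'   `p_resistant` (probabilities in \[0, 1\]); genes not listed default to
#'   0.5 / 0.5 (no true difference).
#' @param nb_mu,nb_size negative-binomial mean and dispersion of the
#'   positive component (counts are the NB draw plus 1).
#' @param lib_sdlog sd(log) of the per-cell library-size factor.
#' @param rng_seed integer seed or `NULL`.
#' @return list with `counts` (genes x cells integer matrix), `labels`
#'   (named character vector, `"parental"`/`"resistant"`), and `truth`
#'   (data.frame `gene`, `p_parental`, `p_resistant`, `direction`).
#' @examples
#' sim <- simulate_scrna(paste0("g", 1:4), 100, 100,
#'   effect_spec = data.frame(gene = "g1", p_parental = 0.2, p_resistant = 0.8),
#'   rng_seed = 1)
#' dim(sim$counts)
#' @export
simulate_scrna <- function(gene_names, n_parental, n_resistant,
                           effect_spec = NULL, nb_mu = 5, nb_size = 2,
                           lib_sdlog = 0.3, rng_seed = NULL) {
  if (anyDuplicated(gene_names)) stopf("gene names must be unique")
  if (!is_count(n_parental, 1L) || !is_count(n_resistant, 1L))
    stopf("both populations must contain at least one cell")
  p_par <- setNames(rep(0.5, length(gene_names)), gene_names)
  p_res <- p_par
  if (!is.null(effect_spec)) {
    need <- c("gene", "p_parental", "p_resistant")
    if (!is.data.frame(effect_spec) || !all(need %in% names(effect_spec)))
      stopf("effect_spec must have columns gene, p_parental, p_resistant")
    if (any(effect_spec$p_parental < 0 | effect_spec$p_parental > 1 |
            effect_spec$p_resistant < 0 | effect_spec$p_resistant > 1))
      stopf("positive-cell probabilities must lie in [0, 1]")
    bad <- setdiff(effect_spec$gene, gene_names)
    if (length(bad)) stopf("effect_spec names unknown genes: %s",
                           paste(bad, collapse = ", "))
    p_par[effect_spec$gene] <- effect_spec$p_parental
    p_res[effect_spec$gene] <- effect_spec$p_resistant
  }

  with_seed(rng_seed, {
    n_cells <- n_parental + n_resistant
    labels <- setNames(
      rep(c("parental", "resistant"), c(n_parental, n_resistant)),
      sprintf("cell_%05d", seq_len(n_cells)))
    libf <- rlnorm(n_cells, meanlog = 0, sdlog = lib_sdlog)
    p_cell <- matrix(NA_real_, length(gene_names), n_cells)
    p_cell[, labels == "parental"] <- p_par
    p_cell[, labels == "resistant"] <- p_res
    expressed <- matrix(runif(length(p_cell)) < p_cell, nrow(p_cell))
    counts <- matrix(0L, length(gene_names), n_cells,
                     dimnames = list(gene_names, names(labels)))
    n_pos <- sum(expressed)
    mu <- nb_mu * rep(libf, each = length(gene_names))[as.vector(expressed)]
    counts[expressed] <- rnbinom(n_pos, size = nb_size, mu = mu) + 1L
    truth <- data.frame(
      gene = gene_names, p_parental = unname(p_par), p_resistant = unname(p_res),
      direction = ifelse(p_res > p_par, "up",
                         ifelse(p_res < p_par, "down", "none")),
      stringsAsFactors = FALSE)
    list(counts = counts, labels = labels, truth = truth)
  })
}
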