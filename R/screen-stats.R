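#' Screen analysis configuration
#'
#' Defaults mirror the discovery screen: an exploratory p threshold of 0.1
#' for both the detection-frequency and read-depth tests, with 0.05 marking
#' conventional significance; discovery treatments tamoxifen, fulvestrant
#' and ribociclib; candidate selection over fulvestrant and ribociclib; and
#' verification against abemaciclib, palbociclib and the
#' fulvestrant+ribociclib combination.
#'
#' @param p_exploratory exploratory threshold (default 0.10).
#' @param p_significant significance threshold (default 0.05).
#' @param discovery_treatments treatments entering the frequency/coverage
#'   discovery analysis.
#' @param candidate_treatments treatments whose evidence defines candidate
#'   genes.
#' @param verification_treatments independent treatment groups used to
#'   categorise candidates.
#' @param control_label untreated control group label.
#' @return A `ScreenConfig` list.
#' @export
screen_config <- function(p_exploratory = 0.10, p_significant = 0.05,
                          discovery_treatments = c("tamoxifen", "fulvestrant",
                                                   "ribociclib"),
                          candidate_treatments = c("fulvestrant", "ribociclib"),
                          verification_treatments = c("abemaciclib",
                                                      "palbociclib",
                                                      "fulvestrant+ribociclib"),
                          control_label = "NC") {
  if (!(p_significant > 0 && p_significant <= p_exploratory &&
        p_exploratory < 1))
    stopf("need 0 < p_significant <= p_exploratory < 1")
  structure(list(p_exploratory = p_exploratory, p_significant = p_significant,
                 discovery_treatments = discovery_treatments,
                 candidate_treatments = candidate_treatments,
                 verification_treatments = verification_treatments,
                 control_label = control_label),
            class = "ScreenConfig")
}

#' Remove loci detected in exactly one sample
#'
#' Singleton loci (one detected sample across the whole screen) are treated
#' as random integration events and excluded.
#'
#' @param m a `LocusSampleMatrix`.
#' @return the filtered `LocusSampleMatrix` (removal logged in
#'   `$filter_log`).
#' @export
filter_singletons <- function(m) {
  stopifnot(inherits(m, "LocusSampleMatrix"))
  keep <- rowSums(m$detected) != 1L
  lsm_subset(m, keep, "filter_singletons")
}

#' Keep loci detected in both biological replicates
#'
#' A locus must be detected in at least one pLN1 sample and at least one
#' pLN2 sample (under any condition) to survive; loci private to one
#' replicate culture are treated as random integrations.
#'
#' @param m a `LocusSampleMatrix`.
#' @return the filtered `LocusSampleMatrix`.
#' @export
filter_replicate_concordance <- function(m) {
  stopifnot(inherits(m, "LocusSampleMatrix"))
  rep_lab <- m$samples$biological_replicate
  if (anyNA(rep_lab) || any(!nzchar(rep_lab)))
    stopf("every sample must carry a biological replicate label")
  in1 <- rowSums(m$detected[, rep_lab == "pLN1", drop = FALSE]) > 0
  in2 <- rowSums(m$detected[, rep_lab == "pLN2", drop = FALSE]) > 0
  lsm_subset(m, in1 & in2, "filter_replicate_concordance")
}

#' Keep loci replicate-concordant within some treatment
#'
#' A locus survives when at least one non-control treatment has a detected
#' sample in both biological replicates.  Cross-treatment mixing (pLN1 under
#' one drug, pLN2 under another) does not qualify, nor does control-only
#' detection.
#'
#' @param m a `LocusSampleMatrix`.
#' @param config a [screen_config()] (for the control label).
#' @return the filtered `LocusSampleMatrix`.
#' @export
filter_treatment_concordance <- function(m, config = screen_config()) {
  stopifnot(inherits(m, "LocusSampleMatrix"))
  treats <- setdiff(unique(m$samples$treatment), config$control_label)
  keep <- rep(FALSE, nrow(m$loci))
  for (t in treats) {
    s1 <- m$samples$treatment == t & m$samples$biological_replicate == "pLN1"
    s2 <- m$samples$treatment == t & m$samples$biological_replicate == "pLN2"
    keep <- keep |
      (rowSums(m$detected[, s1, drop = FALSE]) > 0 &
       rowSums(m$detected[, s2, drop = FALSE]) > 0)
  }
  lsm_subset(m, keep, "filter_treatment_concordance")
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p by the probability-mass rule: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed the observed table's (within a 1e-7
#' relative tie tolerance).  A zero row or column margin gives p = 1.
#'
#' The table is `rbind(c(a, b), c(c, d))`.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return the two-sided p-value.
#' @examples
#' fisher_exact_2x2(5, 0, 0, 5)   # 2 / choose(10, 5)
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != floor(cells)))
    stopf("cells must be non-negative integers")
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  k <- max(0, r1 - c2):min(r1, c1)
  probs <- dhyper(k, c1, c2, r1)
  p_obs <- dhyper(a, c1, c2, r1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Pooled-variance two-sample Student t-test
#'
#' Two-sided, equal-variance t with `n_a + n_b - 2` degrees of freedom
#' (Welch's unequal-variance form available via `var_equal = FALSE`).
#' Degenerate inputs follow the screen's conventions: zero pooled variance
#' with equal means gives t = 0, p = 1; zero pooled variance with unequal
#' means gives p = 0 and is flagged degenerate; a group with fewer than two
#' values makes the test not computable.
#'
#' @param x,y numeric value vectors for the two groups.
#' @param var_equal pooled (TRUE, default) or Welch (FALSE).
#' @return list with `t_stat`, `df`, `p`, `computable`, `degenerate`.
#' @export
student_t_test <- function(x, y, var_equal = TRUE) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L)
    return(list(t_stat = NA_real_, df = NA_real_, p = NA_real_,
                computable = FALSE, degenerate = FALSE))
  m1 <- mean(x); m2 <- mean(y)
  v1 <- var(x); v2 <- var(y)
  if (var_equal) {
    df <- n1 + n2 - 2
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se <- sqrt(s2 * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- if (se > 0)
      (v1 / n1 + v2 / n2)^2 /
        ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)) else NA_real_
  }
  if (se == 0) {
    if (m1 == m2)
      return(list(t_stat = 0, df = df, p = 1, computable = TRUE,
                  degenerate = FALSE))
    return(list(t_stat = sign(m1 - m2) * Inf, df = df, p = 0,
                computable = TRUE, degenerate = TRUE))
  }
  t <- (m1 - m2) / se
  list(t_stat = t, df = df, p = 2 * pt(-abs(t), df), computable = TRUE,
       degenerate = FALSE)
}

flag_from_p <- function(p, config) {
  ifelse(is.na(p), "ns",
         ifelse(p < config$p_significant, "significant",
                ifelse(p < config$p_exploratory, "exploratory", "ns")))
}

#' Detection-frequency enrichment tests for one treatment
#'
#' For every locus, compares the number of detected treated samples against
#' detected controls (timepoints pooled within groups) in a 2x2 Fisher
#' exact test.  Direction comes from the detection proportions;
#' `exclusive_treated` / `exclusive_control` mark loci absent from one
#' group entirely.
#'
#' @param m a `LocusSampleMatrix`.
#' @param treatment treatment group name.
#' @param config a [screen_config()].
#' @return data.frame with `locus_id`, `treatment`, `a` (detected treated),
#'   `n_t`, `b` (detected control), `n_c`, `fisher_p`, `direction`,
#'   `freq_flag`.
#' @export
frequency_tests <- function(m, treatment, config = screen_config()) {
  stopifnot(inherits(m, "LocusSampleMatrix"))
  ts <- m$samples$treatment == treatment
  cs <- m$samples$treatment == config$control_label
  if (!any(ts) || !any(cs))
    stopf("need both treated ('%s') and control ('%s') samples",
          treatment, config$control_label)
  n_t <- sum(ts); n_c <- sum(cs)
  a <- rowSums(m$detected[, ts, drop = FALSE])
  b <- rowSums(m$detected[, cs, drop = FALSE])
  p <- mapply(fisher_exact_2x2, a, n_t - a, b, n_c - b)
  pt_ <- a / n_t; pc_ <- b / n_c
  direction <- ifelse(a > 0 & b == 0, "exclusive_treated",
               ifelse(b > 0 & a == 0, "exclusive_control",
               ifelse(pt_ > pc_, "enriched",
               ifelse(pt_ < pc_, "depleted", "none"))))
  data.frame(locus_id = m$loci$locus_id, treatment = treatment,
             a = as.integer(a), n_t = n_t, b = as.integer(b), n_c = n_c,
             fisher_p = p, direction = direction,
             freq_flag = flag_from_p(p, config),
             stringsAsFactors = FALSE)
}

#' Read-depth (RPM) coverage tests for one treatment
#'
#' Per locus, a two-sample Student t-test of RPM in treated versus control
#' samples.  By default non-detected samples contribute RPM 0, keeping the
#' group sizes fixed and coupling the coverage test to the frequency test;
#' `include_undetected = FALSE` restricts to detected samples only.
#'
#' @inheritParams frequency_tests
#' @param include_undetected include non-detected samples as RPM 0.
#' @param var_equal pooled-variance t (default) or Welch.
#' @return data.frame with `locus_id`, `treatment`, `mean_rpm_treated`,
#'   `mean_rpm_control`, `t_stat`, `t_p`, `cov_direction`, `cov_flag`.
#' @export
coverage_tests <- function(m, treatment, config = screen_config(),
                           include_undetected = TRUE, var_equal = TRUE) {
  stopifnot(inherits(m, "LocusSampleMatrix"))
  ts <- which(m$samples$treatment == treatment)
  cs <- which(m$samples$treatment == config$control_label)
  if (!length(ts) || !length(cs))
    stopf("need both treated ('%s') and control ('%s') samples",
          treatment, config$control_label)
  n <- nrow(m$loci)
  out <- data.frame(locus_id = m$loci$locus_id, treatment = treatment,
                    mean_rpm_treated = NA_real_, mean_rpm_control = NA_real_,
                    t_stat = NA_real_, t_p = NA_real_,
                    cov_direction = "none", cov_flag = "ns",
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    x <- m$rpm[i, ts]; y <- m$rpm[i, cs]
    if (!include_undetected) {
      x <- x[m$detected[i, ts]]; y <- y[m$detected[i, cs]]
    }
    mt <- if (length(x)) mean(x) else 0
    mc <- if (length(y)) mean(y) else 0
    tt <- student_t_test(x, y, var_equal = var_equal)
    out$mean_rpm_treated[i] <- mt
    out$mean_rpm_control[i] <- mc
    out$t_stat[i] <- tt$t_stat
    out$t_p[i] <- tt$p
    out$cov_direction[i] <- if (mt > mc) "enriched"
                            else if (mt < mc) "depleted" else "none"
    out$cov_flag[i] <- if (!tt$computable) "ns" else flag_from_p(tt$p, config)
  }
  out
}

#' Combined frequency + coverage results for one treatment
#'
#' Merges [frequency_tests()] and [coverage_tests()]; the headline
#' `direction` is the frequency direction, falling back to the coverage
#' direction when the detection proportions are equal.
#'
#' @inheritParams coverage_tests
#' @return one data.frame per locus x treatment with all test fields.
#' @export
screen_results <- function(m, treatment, config = screen_config(),
                           include_undetected = TRUE, var_equal = TRUE) {
  fr <- frequency_tests(m, treatment, config)
  cv <- coverage_tests(m, treatment, config, include_undetected, var_equal)
  out <- cbind(fr, cv[, c("mean_rpm_treated", "mean_rpm_control",
                          "t_stat", "t_p", "cov_direction", "cov_flag")])
  names(out)[names(out) == "direction"] <- "freq_direction"
  out$direction <- ifelse(out$freq_direction == "none", out$cov_direction,
                          out$freq_direction)
  out
}

#' Select candidate resistance genes from screen results
#'
#' A locus qualifies when either test reaches at least exploratory evidence
#' (p < 0.1 by default) in any of the supplied treatments with an
#' enrichment-direction signal (direction `enriched` or `exclusive_treated`
#' by default; pass `directions = NULL` for direction-blind selection).
#' Qualifying loci are collapsed to genes via the locus-to-gene map; loci
#' without an annotated gene keep their locus id as gene surrogate.
#'
#' @param results row-bound [screen_results()] tables over the candidate
#'   treatments (e.g. fulvestrant and ribociclib).
#' @param locus_gene_map data.frame with `locus_id` and `nearest_gene`
#'   (e.g. annotated loci from [annotate_loci()]); `NULL` uses locus ids.
#' @param config a [screen_config()].
#' @param directions directions that count as candidate evidence, or `NULL`
#'   for any direction.
#' @return data.frame of `CandidateGene`s: `gene`, `loci`, `treatments`,
#'   `n_loci`, `freq_evidence`, `cov_evidence`; the per-treatment partition
#'   (unique/shared gene counts) is in `attr(, "partition")`.
#' @export
select_candidates <- function(results, locus_gene_map = NULL,
                              config = screen_config(),
                              directions = c("enriched", "exclusive_treated")) {
  stopifnot(is.data.frame(results))
  freq_ok <- results$freq_flag %in% c("significant", "exploratory")
  cov_ok <- results$cov_flag %in% c("significant", "exploratory")
  if (!is.null(directions)) {
    freq_ok <- freq_ok & results$freq_direction %in% directions
    cov_ok <- cov_ok & results$cov_direction %in% directions
  }
  hit <- results[freq_ok | cov_ok, , drop = FALSE]
  hit$freq_hit <- freq_ok[freq_ok | cov_ok]
  hit$cov_hit <- cov_ok[freq_ok | cov_ok]
  empty <- data.frame(gene = character(), loci = character(),
                      treatments = character(), n_loci = integer(),
                      freq_evidence = character(), cov_evidence = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(hit)) {
    attr(empty, "partition") <- summarize_partitions(categories = integer())
    return(empty)
  }
  gene_of <- hit$locus_id
  if (!is.null(locus_gene_map)) {
    idx <- match(hit$locus_id, locus_gene_map$locus_id)
    g <- locus_gene_map$nearest_gene[idx]
    gene_of <- ifelse(is.na(g), hit$locus_id, g)
  }
  hit$gene <- gene_of
  by_gene <- split(hit, hit$gene)
  out <- do.call(rbind, lapply(by_gene, function(h) data.frame(
    gene = h$gene[1L],
    loci = paste(sort(unique(h$locus_id)), collapse = ","),
    treatments = paste(sort(unique(h$treatment)), collapse = ","),
    n_loci = length(unique(h$locus_id)),
    freq_evidence = paste(sort(unique(h$treatment[h$freq_hit])), collapse = ","),
    cov_evidence = paste(sort(unique(h$treatment[h$cov_hit])), collapse = ","),
    stringsAsFactors = FALSE)))
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL

  treats <- sort(unique(results$treatment))
  sets <- lapply(by_gene, function(h) sort(unique(h$treatment)))
  cat_counts <- integer()
  for (t in treats)
    cat_counts[paste0("unique_", t)] <-
      sum(vapply(sets, function(s) identical(s, t), logical(1)))
  cat_counts["shared"] <- sum(lengths(sets) > 1L)
  attr(out, "partition") <- summarize_partitions(categories = cat_counts)
  out
}

#' Categorise candidates by verification-cohort detection
#'
#' Counts, per candidate gene, how many verification treatment groups
#' contain at least one detected sample at any supporting locus:
#' all groups -> `all_groups`, some but not all -> `one_or_two_groups`,
#' none -> `none`.
#'
#' @param candidates data.frame from [select_candidates()].
#' @param m the `LocusSampleMatrix` (pre-filter matrix, so verification
#'   treatments are present).
#' @param config a [screen_config()] naming `verification_treatments`.
#' @return `candidates` with added `n_verification_groups` and
#'   `verification_category`.
#' @export
verify_candidates <- function(candidates, m, config = screen_config()) {
  stopifnot(inherits(m, "LocusSampleMatrix"))
  vt <- config$verification_treatments
  missing_t <- setdiff(vt, unique(m$samples$treatment))
  if (length(missing_t))
    stopf("verification treatments absent from the matrix: %s",
          paste(missing_t, collapse = ", "))
  ngroups <- integer(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    loci <- strsplit(candidates$loci[i], ",", fixed = TRUE)[[1L]]
    li <- match(loci, m$loci$locus_id)
    li <- li[!is.na(li)]
    ngroups[i] <- sum(vapply(vt, function(t) {
      sc <- m$samples$treatment == t
      length(li) > 0 && any(m$detected[li, sc, drop = FALSE])
    }, logical(1)))
  }
  candidates$n_verification_groups <- ngroups
  candidates$verification_category <-
    ifelse(ngroups == length(vt), "all_groups",
           ifelse(ngroups >= 1L, "one_or_two_groups", "none"))
  candidates
}

#' Partition bookkeeping with consistency checks
#'
#' Tracks the filtering cascade's arithmetic: a stage total, named
#' exclusion counts, and named category tallies.  The total may be given or
#' derived as the sum of categories; when both are supplied they must
#' agree, and the retained count is total minus exclusions.  Inconsistent
#' tallies raise an error naming the failing identity.
#'
#' @param total stage total (or `NULL` to derive from `categories`).
#' @param exclusions named non-negative counts removed from `total`.
#' @param categories named non-negative counts partitioning `total`.
#' @return A `PartitionSummary`: list with `total`, `exclusions`,
#'   `categories`, `retained`.
#' @examples
#' summarize_partitions(3902, exclusions = c(singletons = 3171,
#'                                           replicate_discordant = 305))
#' summarize_partitions(categories = c(unique_tamoxifen = 61,
#'   unique_fulvestrant = 9, unique_ribociclib = 14, shared = 5))
#' @export
summarize_partitions <- function(total = NULL, exclusions = NULL,
                                 categories = NULL) {
  exclusions <- exclusions %||% numeric()
  categories <- categories %||% numeric()
  if (any(exclusions < 0) || any(categories < 0))
    stopf("tallies must be non-negative")
  cat_total <- sum(categories)
  if (is.null(total)) {
    total <- cat_total
  } else if (length(categories) && cat_total != total) {
    stopf("inconsistent tallies: sum(categories) = %g but total = %g",
          cat_total, total)
  }
  retained <- total - sum(exclusions)
  if (retained < 0)
    stopf("inconsistent tallies: exclusions (%g) exceed total (%g)",
          sum(exclusions), total)
  structure(list(total = total, exclusions = exclusions,
                 categories = categories, retained = retained),
            class = "PartitionSummary")
}

#' @export
print.PartitionSummary <- function(x, ...) {
  cat(sprintf("PartitionSummary: total %g, retained %g\n", x$total, x$retained))
  if (length(x$exclusions))
    cat("  exclusions:",
        paste(sprintf("%s=%g", names(x$exclusions), x$exclusions),
              collapse = ", "), "\n")
  if (length(x$categories))
    cat("  categories:",
        paste(sprintf("%s=%g", names(x$categories), x$categories),
              collapse = ", "), "\n")
  invisible(x)
}

#' Scatter/volcano source table for screen results
#'
#' Plot-ready data: detection fractions per group, log2 fold change of mean
#' RPM with a pseudocount for zero handling, and -log10 p for both tests.
#'
#' @param results a [screen_results()] table.
#' @param pseudocount RPM pseudocount (default 0.5).
#' @return data.frame with plotting columns.
#' @export
volcano_table <- function(results, pseudocount = 0.5) {
  data.frame(
    locus_id = results$locus_id,
    treatment = results$treatment,
    frac_treated = results$a / results$n_t,
    frac_control = results$b / results$n_c,
    log2_fc_rpm = log2((results$mean_rpm_treated + pseudocount) /
                       (results$mean_rpm_control + pseudocount)),
    neg_log10_fisher_p = -log10(results$fisher_p),
    neg_log10_t_p = -log10(results$t_p),
    direction = results$direction,
    stringsAsFactors = FALSE
  )
}
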