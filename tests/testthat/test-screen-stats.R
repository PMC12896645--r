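# A 10-sample fixture: 4 NC, 4 fulvestrant, 2 ribociclib across pLN1/pLN2.
fixture_lsm <- function() {
  counts <- rbind(
    singleton    = c(0, 0, 0, 0, 5, 0, 0, 0, 0, 0),
    one_rep_only = c(5, 5, 0, 0, 6, 0, 0, 0, 5, 0),   # pLN1 columns only
    control_only = c(4, 0, 5, 0, 0, 0, 0, 0, 0, 0),   # NC both reps
    cross_treat  = c(0, 0, 0, 0, 7, 0, 0, 0, 0, 4),   # fulv pLN1 + ribo pLN2
    concordant   = c(0, 0, 0, 0, 9, 8, 9, 8, 0, 0),   # fulv both reps
    everywhere   = c(3, 3, 3, 3, 3, 3, 3, 3, 3, 3))
  make_lsm(counts,
           treatment = c("NC", "NC", "NC", "NC", "fulvestrant", "fulvestrant",
                         "fulvestrant", "fulvestrant", "ribociclib", "ribociclib"),
           replicate = c("pLN1", "pLN1", "pLN2", "pLN2", "pLN1", "pLN1",
                         "pLN2", "pLN2", "pLN1", "pLN2"))
}

test_that("the filtering cascade removes singletons and discordant loci", {
  m <- fixture_lsm()
  m1 <- filter_singletons(m)
  expect_setequal(m1$loci$locus_id,
                  c("one_rep_only", "control_only", "cross_treat",
                    "concordant", "everywhere"))
  m2 <- filter_replicate_concordance(m1)
  expect_setequal(m2$loci$locus_id,
                  c("control_only", "cross_treat", "concordant", "everywhere"))
  m3 <- filter_treatment_concordance(m2)
  expect_setequal(m3$loci$locus_id, c("concordant", "everywhere"))

  # contraction identities logged at every stage
  lg <- m3$filter_log
  expect_true(all(lg$input - lg$removed == lg$retained))
  expect_true(all(m3$loci$locus_id %in% m$loci$locus_id))

  # boundary: two detected samples survive the singleton filter
  two <- make_lsm(rbind(x = c(1, 1, 0, 0)), treatment = c("NC", "NC", "d", "d"),
                  replicate = c("pLN1", "pLN2", "pLN1", "pLN2"))
  expect_equal(nrow(filter_singletons(two)$loci), 1L)

  # empty matrix passes through
  em <- make_lsm(matrix(0L, 0, 4), treatment = c("NC", "NC", "d", "d"),
                 replicate = c("pLN1", "pLN2", "pLN1", "pLN2"))
  expect_equal(nrow(filter_singletons(em)$loci), 0L)

  # missing replicate labels are an error
  bad <- fixture_lsm()
  bad$samples$biological_replicate[1] <- NA
  expect_error(filter_replicate_concordance(bad), "replicate label")
})

test_that("fisher_exact_2x2 reproduces hand-enumerated values", {
  expect_equal(fisher_exact_2x2(2, 2, 2, 2), 1)
  expect_equal(fisher_exact_2x2(5, 0, 0, 5), 2 / choose(10, 5))
  expect_equal(fisher_exact_2x2(15, 0, 0, 19), 1 / choose(34, 15))
  # zero margins
  expect_equal(fisher_exact_2x2(0, 0, 3, 4), 1)
  expect_equal(fisher_exact_2x2(0, 5, 0, 3), 1)
  expect_error(fisher_exact_2x2(-1, 0, 0, 1), "non-negative")

  # symmetry under simultaneous row and column swap
  set.seed(3)
  for (i in 1:25) {
    t <- sample(0:8, 4, replace = TRUE)
    expect_equal(fisher_exact_2x2(t[1], t[2], t[3], t[4]),
                 fisher_exact_2x2(t[4], t[3], t[2], t[1]))
  }
})

test_that("fisher_exact_2x2 agrees with stats::fisher.test", {
  set.seed(5)
  for (i in 1:40) {
    t <- sample(0:12, 4, replace = TRUE)
    if (sum(t) == 0) next
    ref <- stats::fisher.test(matrix(t, 2, byrow = TRUE))$p.value
    expect_equal(fisher_exact_2x2(t[1], t[2], t[3], t[4]), ref,
                 tolerance = 1e-9,
                 info = paste(t, collapse = ","))
  }
})

test_that("student_t_test matches the closed-form pooled formula", {
  eq <- student_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$t_stat, 0)
  expect_equal(eq$p, 1)

  r <- student_t_test(c(1, 2, 3), c(4, 5, 6))
  # pooled s2 = 1, SE = sqrt(2/3), t = -3 / sqrt(2/3)
  expect_equal(r$t_stat, -3 / sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(r$df, 4)
  expect_equal(r$p, 2 * pt(-abs(r$t_stat), 4), tolerance = 1e-12)
  expect_equal(r$p, 0.02131164, tolerance = 1e-6)

  # all-zero groups: t = 0, p = 1
  z <- student_t_test(c(0, 0, 0), c(0, 0, 0))
  expect_equal(z$t_stat, 0)
  expect_equal(z$p, 1)

  # zero pooled variance, unequal means: degenerate, p = 0
  d <- student_t_test(c(1, 1), c(2, 2))
  expect_equal(d$p, 0)
  expect_true(d$degenerate)

  # too-small groups are not computable
  expect_false(student_t_test(1, c(1, 2))$computable)

  # random fixtures against stats::t.test (pooled and Welch)
  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1), mean = 0.5)
    ref <- stats::t.test(x, y, var.equal = TRUE)
    got <- student_t_test(x, y)
    expect_equal(got$t_stat, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(got$p, ref$p.value, tolerance = 1e-9)
    refw <- stats::t.test(x, y)
    gotw <- student_t_test(x, y, var_equal = FALSE)
    expect_equal(gotw$t_stat, unname(refw$statistic), tolerance = 1e-9)
    expect_equal(gotw$p, refw$p.value, tolerance = 1e-9)
  }
})

test_that("frequency_tests classifies detection patterns", {
  counts <- rbind(absent = rep(0L, 34),
                  excl = c(rep(1L, 15), rep(0L, 19)),
                  flat = rep(1L, 34))
  m <- make_lsm(counts,
                treatment = c(rep("fulvestrant", 15), rep("NC", 19)),
                replicate = rep(c("pLN1", "pLN2"), 17))
  fr <- frequency_tests(m, "fulvestrant")
  expect_equal(fr$fisher_p[fr$locus_id == "absent"], 1)
  expect_equal(fr$direction[fr$locus_id == "absent"], "none")
  expect_equal(fr$direction[fr$locus_id == "excl"], "exclusive_treated")
  expect_equal(fr$fisher_p[fr$locus_id == "excl"], 1 / choose(34, 15))
  expect_equal(fr$freq_flag[fr$locus_id == "excl"], "significant")
  expect_equal(fr$freq_flag[fr$locus_id == "flat"], "ns")
  expect_error(frequency_tests(m, "nonexistent"), "treated")
})

test_that("coverage_tests follows planted RPM differences", {
  rpm <- rbind(flat = rep(100, 10),
               up   = c(rep(10, 4), rep(500, 6)),
               down = c(rep(800, 4), rep(0, 6)))
  counts <- (rpm > 0) * 5L
  m <- make_lsm(counts, treatment = c(rep("NC", 4), rep("drug", 6)),
                replicate = rep(c("pLN1", "pLN2"), 5), rpm = rpm)
  cv <- coverage_tests(m, "drug", screen_config(
    discovery_treatments = "drug", candidate_treatments = "drug"))
  expect_equal(cv$cov_flag[cv$locus_id == "flat"], "ns")
  expect_equal(cv$cov_direction[cv$locus_id == "up"], "enriched")
  expect_equal(cv$cov_direction[cv$locus_id == "down"], "depleted")
  # degenerate zero-variance difference is flagged (p = 0 < threshold)
  expect_equal(cv$cov_flag[cv$locus_id == "up"], "significant")
})

test_that("significant results are nested inside exploratory results", {
  fx <- small_planted_screen(seed = 77, reads = 1500)
  aln <- filter_alignments(fx$screen$alignments)
  m <- quantify(call_vis(aln), aln, fx$screen$samples)
  cfg <- screen_config()
  res <- rbind(screen_results(m, "fulvestrant", cfg),
               screen_results(m, "ribociclib", cfg))
  sig_f <- res$freq_flag == "significant"
  expl_f <- res$freq_flag %in% c("significant", "exploratory")
  expect_true(all(res$fisher_p[sig_f] < 0.05))
  expect_true(all(res$fisher_p[expl_f] < 0.1))
  sig_c <- res$cov_flag == "significant"
  expect_true(all(res$t_p[sig_c] < 0.05))
  # flags at 0.05 are a subset of flags at 0.1 by construction of the tiers
  expect_true(all(sig_f <= expl_f))
})

test_that("select_candidates collapses qualifying loci to genes", {
  base <- data.frame(
    locus_id = c("L1", "L2", "L3", "L4"),
    treatment = "fulvestrant",
    a = c(5, 5, 0, 4), n_t = 5, b = c(0, 0, 3, 4), n_c = 4,
    fisher_p = c(0.01, 0.08, 0.01, 1),
    freq_direction = c("exclusive_treated", "exclusive_treated",
                       "exclusive_control", "none"),
    freq_flag = c("significant", "exploratory", "significant", "ns"),
    mean_rpm_treated = c(10, 10, 0, 5), mean_rpm_control = c(0, 0, 9, 5),
    t_stat = 1, t_p = c(0.2, 0.2, 0.2, 0.9),
    cov_direction = c("enriched", "enriched", "depleted", "none"),
    cov_flag = "ns", stringsAsFactors = FALSE)
  base$direction <- base$freq_direction
  map <- data.frame(locus_id = c("L1", "L2", "L3", "L4"),
                    nearest_gene = c("GENE1", "GENE1", "GENE2", NA))

  cand <- select_candidates(base, map)
  expect_equal(cand$gene, "GENE1")          # L3 is control-exclusive: excluded
  expect_equal(cand$loci, "L1,L2")
  expect_equal(cand$n_loci, 2L)

  # direction-blind selection also admits the depleted locus
  blind <- select_candidates(base, map, directions = NULL)
  expect_setequal(blind$gene, c("GENE1", "GENE2"))

  # no qualifying loci -> empty
  none <- base; none$freq_flag <- "ns"; none$cov_flag <- "ns"
  expect_equal(nrow(select_candidates(none, map)), 0L)

  # a gene hit by both treatments lands once, in the shared partition
  both <- rbind(base[1, ], transform(base[1, ], treatment = "ribociclib"))
  cb <- select_candidates(both, map)
  expect_equal(nrow(cb), 1L)
  expect_equal(cb$treatments, "fulvestrant,ribociclib")
  part <- attr(cb, "partition")
  expect_equal(unname(part$categories["shared"]), 1L)
  expect_equal(part$total, 1)
})

test_that("verify_candidates counts verification-group detections", {
  counts <- rbind(gA = c(1, 1, 1, 1, 1, 1), gB = c(1, 0, 0, 0, 0, 0),
                  gC = c(0, 0, 1, 0, 0, 0))
  m <- make_lsm(counts,
                treatment = c("fulvestrant", "abemaciclib", "abemaciclib",
                              "palbociclib", "fulvestrant+ribociclib",
                              "fulvestrant+ribociclib"),
                replicate = rep(c("pLN1", "pLN2"), 3))
  cand <- data.frame(gene = c("gA", "gB", "gC"),
                     loci = c("gA", "gB", "gC"),
                     treatments = "fulvestrant", n_loci = 1L,
                     freq_evidence = "fulvestrant", cov_evidence = "",
                     stringsAsFactors = FALSE)
  v <- verify_candidates(cand, m)
  expect_equal(v$verification_category,
               c("all_groups", "none", "one_or_two_groups"))
  expect_equal(v$n_verification_groups, c(3L, 0L, 1L))
  expect_error(verify_candidates(cand, fixture_lsm()), "absent")
})

test_that("summarize_partitions enforces the cascade identities", {
  s <- summarize_partitions(3902, exclusions = c(singleton = 3171,
                                                 replicate = 305))
  expect_equal(s$retained, 426)
  s2 <- summarize_partitions(categories = c(u_tam = 61, u_fulv = 9,
                                            u_ribo = 14, shared = 5))
  expect_equal(s2$total, 89)
  empty <- summarize_partitions()
  expect_equal(empty$total, 0)
  expect_equal(empty$retained, 0)
  expect_error(summarize_partitions(100, categories = c(a = 60, b = 50)),
               "inconsistent")
  expect_error(summarize_partitions(10, exclusions = c(a = 11)),
               "inconsistent")
  expect_error(summarize_partitions(categories = c(a = -1)), "non-negative")
})

test_that("volcano_table exposes fold changes and -log10 p", {
  res <- data.frame(locus_id = "L", treatment = "d", a = 3, n_t = 4, b = 1,
                    n_c = 4, fisher_p = 0.25, freq_direction = "enriched",
                    freq_flag = "ns", mean_rpm_treated = 99.5,
                    mean_rpm_control = 0, t_stat = 2, t_p = 0.1,
                    cov_direction = "enriched", cov_flag = "ns",
                    direction = "enriched")
  v <- volcano_table(res)
  expect_equal(v$log2_fc_rpm, log2(100 / 0.5))
  expect_equal(v$neg_log10_fisher_p, -log10(0.25))
  expect_equal(v$frac_treated, 0.75)
})
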