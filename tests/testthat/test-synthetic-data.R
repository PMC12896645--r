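test_that("make_genome handles degenerate, deterministic and impossible cases", {
  gm <- make_genome(1, 1e6, 0, rng_seed = 1)
  expect_equal(nrow(gm$genes), 0L)
  expect_equal(unname(gm$chromosomes), 1e6)

  g1 <- make_genome(2, 5e5, 50, rng_seed = 7)
  g2 <- make_genome(2, 5e5, 50, rng_seed = 7)
  expect_identical(g1, g2)
  expect_equal(nrow(g1$genes), 50L)
  # non-overlap within each chromosome
  for (ch in unique(g1$genes$chrom)) {
    g <- g1$genes[g1$genes$chrom == ch, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1) expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
  expect_false(anyDuplicated(g1$genes$name) > 0)
  expect_true(all(g1$genes$end <= g1$chromosomes[g1$genes$chrom]))

  # pigeonhole: 50 genes x 300 bp = 15000 bp cannot fit in 10000 bp
  expect_error(make_genome(1, 1e4, 50, gene_width = 300, rng_seed = 1),
               "cannot place")
})

test_that("plant_integrations distributes abundance and fitness as specified", {
  gm <- make_genome(1, 1e6, 0, rng_seed = 1)
  one <- plant_integrations(gm, 1, rng_seed = 3)
  expect_equal(one$clones$baseline_abundance, 1)

  spec <- data.frame(treatment = "fulvestrant", n = 12, weight = 1.6)
  ct <- plant_integrations(gm, 300, spec, rng_seed = 5)
  expect_equal(sum(ct$fitness[, "fulvestrant"] == 1.6), 12L)
  expect_equal(sum(ct$fitness[, "NC"] != 1), 0L)
  expect_equal(sum(ct$clones$baseline_abundance), 1, tolerance = 1e-9)
  expect_true(all(ct$clones$position >= 0 &
                    ct$clones$position < gm$chromosomes[ct$clones$chrom]))

  ct2 <- plant_integrations(gm, 300, spec, rng_seed = 5)
  expect_identical(ct, ct2)

  expect_error(plant_integrations(gm, 5,
    data.frame(treatment = "x", n = 6, weight = 2), rng_seed = 1),
    "more clones")
  expect_error(plant_integrations(gm, 5,
    data.frame(treatment = "x", n = 2, weight = 0), rng_seed = 1),
    "> 0")
  expect_error(plant_integrations(gm, 5,
    data.frame(treatment = "NC", n = 2, weight = 2), rng_seed = 1),
    "neutral by convention")
})

test_that("evolve_population conserves abundance and respects n_passages = 0", {
  gm <- make_genome(1, 1e6, 0, rng_seed = 1)
  ct <- plant_integrations(gm, 8, rng_seed = 2)
  base <- setNames(ct$clones$baseline_abundance, ct$clones$clone_id)
  expect_identical(evolve_population(ct, "NC", 0, 1000), base)
  for (s in 1:5) {
    ab <- evolve_population(ct, "NC", 3, 500, rng_seed = s)
    expect_equal(sum(ab), 1, tolerance = 1e-9)
    expect_true(all(ab >= 0))
  }
  expect_message(evolve_population(ct, "no-such-drug", 1, 100, rng_seed = 1),
                 "neutral")
})

test_that("neutral selection leaves expected abundances at baseline", {
  gm <- make_genome(1, 1e6, 0, rng_seed = 1)
  ct <- plant_integrations(gm, 5, rng_seed = 9)
  base <- ct$clones$baseline_abundance
  n_rep <- 1000
  pop <- 1000
  finals <- vapply(seq_len(n_rep), function(s)
    evolve_population(ct, "NC", 2, pop, rng_seed = s), numeric(5))
  means <- rowMeans(finals)
  se <- apply(finals, 1, stats::sd) / sqrt(n_rep)
  expect_true(all(abs(means - base) <= 3 * se + 1e-12))
})

test_that("one passage of 2:1 selection converges to the 2/3 closed form", {
  gm <- make_genome(1, 1e6, 0, rng_seed = 1)
  ct <- plant_integrations(gm, 2,
    data.frame(treatment = "drugA", n = 1, weight = 2), rng_seed = 4)
  # force equal baselines so the closed form w = (2, 1)/3 applies exactly
  ct$clones$baseline_abundance <- c(0.5, 0.5)
  fav <- which(ct$fitness[, "drugA"] == 2)
  finals <- vapply(1:2000, function(s)
    evolve_population(ct, "drugA", 1, 2e5, rng_seed = s)[fav], numeric(1))
  expect_equal(mean(finals), 2 / 3, tolerance = 0.01)
})

test_that("expected final abundance is monotone in the fitness weight", {
  gm <- make_genome(1, 1e6, 0, rng_seed = 1)
  grid <- c(1, 1.25, 1.6, 2)
  means <- vapply(grid, function(w) {
    ct <- plant_integrations(gm, 4, rng_seed = 7)
    ct$fitness <- cbind(ct$fitness, drugA = c(w, 1, 1, 1))
    mean(vapply(1:200, function(s)
      evolve_population(ct, "drugA", 4, 2000, rng_seed = s)[1], numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
})

test_that("simulate_sample anchors reads at the junction and samples clones by abundance", {
  gm <- make_genome(1, 1e6, 0, rng_seed = 1)
  ct <- plant_integrations(gm, 2, rng_seed = 2)

  # spread 0: every alignment sits exactly on the integration point
  sim0 <- simulate_sample(ct, c(0.5, 0.5), 200, gm, offset_spread = 0,
                          low_mapq_frac = 0, rng_seed = 3)
  pos_by_clone <- split(sim0$alignments$position, sim0$alignments$chrom)
  expect_true(all(sim0$alignments$position %in% ct$clones$position))

  # one clone: all reads on its chromosome
  one <- plant_integrations(gm, 1, rng_seed = 5)
  sim1 <- simulate_sample(one, 1, 100, gm, rng_seed = 6)
  expect_equal(nrow(sim1$alignments), 100L)
  expect_true(all(sim1$alignments$chrom == one$clones$chrom))
  expect_equal(nchar(sim1$reads$sequence), nchar(sim1$reads$qualities))

  # abundance split within the binomial 99% interval
  sim2 <- simulate_sample(ct, c(0.9, 0.1), 10000, gm, emit_reads = FALSE,
                          rng_seed = 7)
  offs <- abs(sim2$alignments$position - ct$clones$position[1]) <= 500 &
    sim2$alignments$chrom == ct$clones$chrom[1]
  k <- sum(vapply(seq_len(nrow(sim2$alignments)), function(i) {
    d1 <- if (sim2$alignments$chrom[i] == ct$clones$chrom[1])
      abs(sim2$alignments$position[i] - ct$clones$position[1]) else Inf
    d2 <- if (sim2$alignments$chrom[i] == ct$clones$chrom[2])
      abs(sim2$alignments$position[i] - ct$clones$position[2]) else Inf
    d1 < d2
  }, logical(1)))
  bounds <- stats::qbinom(c(0.005, 0.995), 10000, 0.9)
  expect_true(k >= bounds[1] && k <= bounds[2])

  # zero reads
  sim3 <- simulate_sample(ct, c(0.5, 0.5), 0, gm)
  expect_equal(nrow(sim3$alignments), 0L)
})

test_that("simulate_screen emits the designed samples with recorded truth", {
  fx <- small_planted_screen(seed = 42, reads = 500)
  scr <- fx$screen
  expect_equal(nrow(scr$samples), 16L)
  expect_equal(sum(scr$samples$treatment == "NC"), 6L)
  expect_setequal(unique(scr$samples$biological_replicate), c("pLN1", "pLN2"))
  expect_equal(colSums(scr$truth$abundances), rep(1, 16),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(sum(scr$truth$directions$fulvestrant == "enriched"), 4L)
  expect_equal(sum(scr$truth$directions$ribociclib == "enriched"), 2L)

  # determinism
  scr2 <- simulate_screen(fx$design, fx$clones, fx$genome, rng_seed = 44)
  expect_identical(scr$samples, scr2$samples)
  expect_identical(scr$alignments, scr2$alignments)
  expect_identical(scr$truth, scr2$truth)

  # paper-shaped default: 60 samples, 19 untreated
  des60 <- default_screen_design()
  sheet <- simulate_screen(des60,
    plant_integrations(fx$genome, 5, rng_seed = 1), fx$genome,
    rng_seed = 1)$samples
  expect_equal(nrow(sheet), 60L)
  expect_equal(sum(sheet$treatment == "NC"), 19L)

  # control-only screen: truth all neutral
  desNC <- screen_design(data.frame(name = "NC", n_pLN1 = 2, n_pLN2 = 2),
                         reads_per_sample = 100)
  scrNC <- simulate_screen(desNC, plant_integrations(fx$genome, 5, rng_seed = 1),
                           fx$genome, rng_seed = 1)
  expect_true(all(scrNC$truth$directions$NC == "neutral"))
})

test_that("simulate_scrna plants fraction-positive differences faithfully", {
  genes <- paste0("g", 1:5)
  eff <- data.frame(gene = "g1", p_parental = 0.2, p_resistant = 0.8)
  sim <- simulate_scrna(genes, 2000, 2000, eff, rng_seed = 11)
  expect_equal(dim(sim$counts), c(5L, 4000L))
  expect_true(all(sim$counts >= 0))
  # empirical positive fractions within 3 binomial SEs of truth
  pos <- sim$counts > 0
  for (g in genes) {
    for (popn in c("parental", "resistant")) {
      truth_p <- sim$truth[sim$truth$gene == g,
                           paste0("p_", popn)]
      obs <- mean(pos[g, sim$labels == popn])
      se <- sqrt(truth_p * (1 - truth_p) / 2000)
      expect_lt(abs(obs - truth_p), 3 * se + 1e-9)
    }
  }
  expect_true(all(sim$truth$direction[sim$truth$gene != "g1"] == "none"))
  expect_equal(sim$truth$direction[sim$truth$gene == "g1"], "up")

  expect_error(simulate_scrna(genes, 0, 100, rng_seed = 1), "at least one")
  expect_error(simulate_scrna(genes, 10, 10,
    data.frame(gene = "g1", p_parental = -0.1, p_resistant = 0.5)),
    "\\[0, 1\\]")
})
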