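# Construct a LocusSampleMatrix directly from a count matrix, bypassing
# call_vis/quantify, for filter and test fixtures.
make_lsm <- function(counts, treatment, replicate,
                     min_reads_detect = 1L, rpm = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("VIS_%05d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("S%02d", seq_len(ncol(counts)))
  samples <- data.frame(sample_id = colnames(counts),
                        treatment = treatment,
                        biological_replicate = replicate,
                        stringsAsFactors = FALSE)
  loci <- data.frame(locus_id = rownames(counts),
                     chrom = rep("chr1", nrow(counts)),
                     start = seq_len(nrow(counts)) * 1e5,
                     end = seq_len(nrow(counts)) * 1e5 + 100,
                     representative_position = seq_len(nrow(counts)) * 1e5 + 50,
                     n_reads = rowSums(counts),
                     stringsAsFactors = FALSE)
  if (is.null(rpm)) {
    tot <- colSums(counts)
    rpm <- sweep(counts, 2L, ifelse(tot == 0, 1, tot), "/") * 1e6
  }
  structure(list(loci = loci, samples = samples, counts = counts, rpm = rpm,
                 detected = counts >= min_reads_detect,
                 min_reads_detect = as.integer(min_reads_detect),
                 filter_log = data.frame(stage = "quantify",
                                         input = nrow(loci), removed = 0L,
                                         retained = nrow(loci),
                                         stringsAsFactors = FALSE)),
            class = "LocusSampleMatrix")
}

# Small planted screen reused by several tests: returns the simulation and
# its clone table.  6 clones with effects out of 50, two treatments.
small_planted_screen <- function(seed = 42, reads = 2000) {
  gm <- make_genome(3, 2e7, 200, 5000, rng_seed = seed)
  ct <- plant_integrations(gm, 50,
    data.frame(treatment = c("fulvestrant", "ribociclib"),
               n = c(4, 2), weight = 1.6),
    rng_seed = seed + 1)
  des <- screen_design(data.frame(
    name = c("NC", "fulvestrant", "ribociclib"),
    n_pLN1 = c(3, 3, 2), n_pLN2 = c(3, 3, 2)), reads_per_sample = reads)
  scr <- simulate_screen(des, ct, gm, rng_seed = seed + 2)
  list(genome = gm, clones = ct, design = des, screen = scr)
}
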