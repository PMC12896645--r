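#' Plant integration clones with baseline abundances and fitness effects
#'
#' Creates the ground truth of a simulated screen: `n_clones` uniquely
#' integrated cell clones with uniform random integration points, symmetric
#' Dirichlet baseline abundances, and per-treatment multiplicative fitness
#' weights.  Clones not named by `fitness_spec` are neutral (weight 1) under
#' every treatment; the untreated control (`"NC"`) is neutral by convention.
#'
#' @param genome a [make_genome()] `GenomeModel`.
#' @param n_clones number of clones (>= 1).
#' @param fitness_spec `NULL` (all neutral) or a data.frame with columns
#'   `treatment`, `n`, `weight`: for each row, `n` distinct clones (sampled
#'   without replacement, disjoint across rows) receive per-passage
#'   multiplicative weight `weight` (> 0) under that treatment.
#' @param concentration symmetric Dirichlet concentration for baseline
#'   abundances (1 = flat).
#' @param rng_seed integer seed or `NULL`.
#' @return A `CloneTable`: list with `clones` (data.frame: `clone_id`,
#'   `chrom`, `position`, `orientation`, `baseline_abundance`,
#'   `treatment_effect`, `effect_weight`) and `fitness` (clones x treatments
#'   matrix, including an `NC` column of ones).
#' @examples
#' gm <- make_genome(2, 1e6, 0, rng_seed = 1)
#' ct <- plant_integrations(gm, 20,
#'   fitness_spec = data.frame(treatment = "fulvestrant", n = 3, weight = 1.6),
#'   rng_seed = 1)
#' table(ct$clones$treatment_effect, useNA = "ifany")
#' @export
plant_integrations <- function(genome, n_clones, fitness_spec = NULL,
                               concentration = 1, rng_seed = NULL) {
  validate_genome(genome)
  if (!is_count(n_clones, 1L)) stopf("n_clones must be >= 1")
  if (!is.null(fitness_spec)) {
    need <- c("treatment", "n", "weight")
    if (!is.data.frame(fitness_spec) || !all(need %in% names(fitness_spec)))
      stopf("fitness_spec must be a data.frame with columns treatment, n, weight")
    if (any(fitness_spec$weight <= 0)) stopf("fitness weights must be > 0")
    if (any(fitness_spec$n < 0)) stopf("fitness_spec$n must be non-negative")
    if (sum(fitness_spec$n) > n_clones)
      stopf("fitness_spec assigns more clones (%d) than exist (%d)",
            sum(fitness_spec$n), n_clones)
    if ("NC" %in% fitness_spec$treatment)
      stopf("the control (NC) is neutral by convention and cannot carry fitness effects")
  }

  with_seed(rng_seed, {
    len <- genome$chromosomes
    ci <- sample.int(length(len), n_clones, replace = TRUE, prob = len)
    pos <- floor(runif(n_clones) * len[ci])
    ori <- sample(c("+", "-"), n_clones, replace = TRUE)
    ab <- rgamma(n_clones, shape = concentration)
    ab <- ab / sum(ab)

    clones <- data.frame(
      clone_id = sprintf("clone_%04d", seq_len(n_clones)),
      chrom = names(len)[ci],
      position = as.numeric(pos),
      orientation = ori,
      baseline_abundance = ab,
      treatment_effect = NA_character_,
      effect_weight = 1,
      stringsAsFactors = FALSE
    )

    treatments <- "NC"
    if (!is.null(fitness_spec)) treatments <- union(treatments, fitness_spec$treatment)
    fit <- matrix(1, nrow = n_clones, ncol = length(treatments),
                  dimnames = list(clones$clone_id, treatments))
    if (!is.null(fitness_spec) && nrow(fitness_spec)) {
      pool <- sample.int(n_clones)  # disjoint random assignment across rows
      taken <- 0L
      for (r in seq_len(nrow(fitness_spec))) {
        nr <- fitness_spec$n[r]
        if (nr == 0L) next
        who <- pool[taken + seq_len(nr)]
        taken <- taken + nr
        fit[who, fitness_spec$treatment[r]] <- fitness_spec$weight[r]
        clones$treatment_effect[who] <- fitness_spec$treatment[r]
        clones$effect_weight[who] <- fitness_spec$weight[r]
      }
    }
    stopifnot(abs(sum(clones$baseline_abundance) - 1) < 1e-9)
    structure(list(clones = clones, fitness = fit), class = "CloneTable")
  })
}

#' @export
print.CloneTable <- function(x, ...) {
  eff <- sum(!is.na(x$clones$treatment_effect))
  cat(sprintf("CloneTable: %d clones (%d with fitness effects), treatments: %s\n",
              nrow(x$clones), eff, paste(colnames(x$fitness), collapse = ", ")))
  invisible(x)
}

#' Evolve clone abundances under fitness-weighted multinomial passaging
#'
#' Models serial passaging under drug selection as discrete generations:
#' at each passage the expected share of clone i is proportional to
#' `abundance_i * fitness_i(treatment)` and the realised population of
#' `population_size` cells is drawn from a multinomial, capturing genetic
#' drift at the passage bottleneck.  `n_passages = 0` returns the baseline
#' abundances unchanged.
#'
#' A treatment absent from the fitness matrix is treated as all-neutral
#' (a message is emitted), matching the convention that untreated controls
#' carry no selection.
#'
#' @param clones a `CloneTable`.
#' @param treatment treatment name (column of `clones$fitness`, or `"NC"`).
#' @param n_passages number of passages (>= 0).
#' @param population_size cells per passage (>= 1).
#' @param rng_seed integer seed or `NULL`.
#' @return Named numeric vector of final abundances (sums to 1).
#' @examples
#' gm <- make_genome(1, 1e6, 0, rng_seed = 1)
#' ct <- plant_integrations(gm, 5, rng_seed = 1)
#' evolve_population(ct, "NC", 4, 1000, rng_seed = 2)
#' @export
evolve_population <- function(clones, treatment, n_passages, population_size,
                              rng_seed = NULL) {
  if (!inherits(clones, "CloneTable")) stopf("expected a CloneTable")
  if (!is_count(n_passages)) stopf("n_passages must be >= 0")
  if (!is_count(population_size, 1L)) stopf("population_size must be >= 1")
  a <- setNames(clones$clones$baseline_abundance, clones$clones$clone_id)
  if (treatment %in% colnames(clones$fitness)) {
    f <- clones$fitness[, treatment]
  } else {
    message(sprintf("treatment '%s' has no fitness entry; treating as neutral",
                    treatment))
    f <- rep(1, length(a))
  }
  if (n_passages == 0L) return(a)
  with_seed(rng_seed, {
    for (p in seq_len(n_passages)) {
      w <- a * f
      w <- w / sum(w)
      cnt <- rmultinom(1, population_size, w)[, 1]
      a <- cnt / sum(cnt)
    }
    setNames(a, clones$clones$clone_id)
  })
}
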