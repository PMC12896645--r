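# Independent oracles used to cross-check the implementation.

# Brute-force adapter search: enumerate every candidate (span, adapter part)
# in the documented match space, score with utils::adist (generalised
# Levenshtein), apply the acceptance threshold and tie-break order.
# N is made unmatchable by recoding to characters that differ everywhere.
oracle_find_adapter <- function(sequence, adapter, error_rate = 0.25,
                                end = "5prime", min_overlap = 3L) {
  n <- nchar(sequence)
  if (n == 0L) return(NULL)
  seqx <- chartr("N", "!", toupper(sequence))
  adax <- chartr("N", "?", toupper(adapter))
  m <- nchar(adax)
  cand <- list()
  add <- function(start, span_end, alen, part) {
    d <- as.integer(utils::adist(substr(seqx, start, span_end), part))
    if (d <= floor(error_rate * alen))
      cand[[length(cand) + 1L]] <<- c(d, start, alen, span_end)
  }
  for (s in seq_len(n)) for (j in s:n) add(s, j, m, adax)
  if (m > 1L && min_overlap <= m - 1L) {
    for (l in min_overlap:(m - 1L)) {
      if (end == "5prime") {
        part <- substr(adax, m - l + 1L, m)       # adapter suffix, read prefix
        for (j in seq_len(n)) add(1L, j, l, part)
      } else {
        part <- substr(adax, 1L, l)               # adapter prefix, read suffix
        for (s in seq_len(n)) add(s, n, l, part)
      }
    }
  }
  if (!length(cand)) return(NULL)
  better <- function(a, b) {
    if (a[1L] != b[1L]) return(a[1L] < b[1L])
    if (a[2L] != b[2L])
      return(if (end == "5prime") a[2L] < b[2L] else a[2L] > b[2L])
    if (a[3L] != b[3L]) return(a[3L] > b[3L])
    if (end == "5prime") a[4L] < b[4L] else a[4L] > b[4L]
  }
  best <- cand[[1L]]
  for (x in cand[-1L]) if (better(x, best)) best <- x
  list(start = as.integer(best[2L]), end = as.integer(best[4L]),
       distance = as.integer(best[1L]), adapter_len = as.integer(best[3L]))
}

# Exhaustive two-sided Fisher p for a 2x2 table from first principles
# (binomial coefficients; probability-mass rule).
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; c2 <- b + d; n <- a + b + c + d
  if (r1 == 0 || c + d == 0 || c1 == 0 || c2 == 0) return(1)
  ks <- max(0, r1 - c2):min(r1, c1)
  pr <- vapply(ks, function(k)
    choose(c1, k) * choose(c2, r1 - k) / choose(n, r1), numeric(1))
  p_obs <- pr[ks == a]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

# Transitive closure of the pairwise <= window relation via union-find.
oracle_cluster <- function(positions, window) {
  n <- length(positions)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (abs(positions[i] - positions[j]) <= window) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, integer(1))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

mutate_seq <- function(s, k) {
  v <- strsplit(s, "")[[1L]]
  i <- sample(seq_along(v), k)
  v[i] <- vapply(v[i], function(ch)
    sample(setdiff(c("A", "C", "G", "T"), ch), 1L), character(1))
  paste(v, collapse = "")
}
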