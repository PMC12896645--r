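#' Adapter trimming configuration
#'
#' @param ltr_adapter 5' LTR adapter sequence (removed through its end).
#' @param linker_adapter 3' linker adapter sequence (removed from its start).
#' @param error_rate allowed edit-distance fraction of the matched adapter
#'   length: a match is accepted iff distance <= floor(error_rate * length).
#' @param min_read_len reads shorter than this after trimming are discarded.
#' @param discard_untrimmed drop reads in which neither adapter is found.
#' @param min_overlap minimum adapter bases for a partial match at a read
#'   end (adapter running off the read).
#' @return A `TrimConfig` list.
#' @export
trim_config <- function(ltr_adapter, linker_adapter, error_rate = 0.25,
                        min_read_len = 36L, discard_untrimmed = TRUE,
                        min_overlap = 3L) {
  if (!nzchar(ltr_adapter) || !nzchar(linker_adapter))
    stopf("adapters must be non-empty")
  if (error_rate < 0 || error_rate >= 1) stopf("error_rate must be in [0, 1)")
  if (!is_count(min_read_len, 1L)) stopf("min_read_len must be >= 1")
  structure(list(ltr_adapter = toupper(ltr_adapter),
                 linker_adapter = toupper(linker_adapter),
                 error_rate = error_rate,
                 min_read_len = as.integer(min_read_len),
                 discard_untrimmed = isTRUE(discard_untrimmed),
                 min_overlap = as.integer(min_overlap)),
            class = "TrimConfig")
}

# Full edit-distance DP between adapter (rows) and a read segment (cols).
# Returns the (m+1) x (k+1) matrix D with D[i+1, j+1] = edit distance of
# adapter[1..i] vs segment[1..j].  N matches nothing (always cost 1).
# Rows are filled with a prefix-min recurrence so each row is one
# vectorised pass.
edit_dp <- function(segv, adapv) {
  k <- length(segv)
  m <- length(adapv)
  D <- matrix(0L, m + 1L, k + 1L)
  row <- 0:k
  D[1L, ] <- row
  idx <- 0:k
  for (i in seq_len(m)) {
    a <- adapv[i]
    sub <- as.integer(segv != a | segv == "N" | a == "N")
    cand <- pmin(row[seq_len(k)] + sub, row[-1L] + 1L)
    vals <- c(i, cand)
    row <- cummin(vals - idx) + idx
    D[i + 1L, ] <- row
  }
  D
}

#' Find the best error-tolerant adapter match in a read
#'
#' Semiglobal edit-distance search (substitutions and indels) of an adapter
#' inside a read.  A candidate match aligns either the full adapter against
#' any read span, or -- for partial matches at read ends -- an adapter
#' suffix against a read prefix (5' adapters) or an adapter prefix against a
#' read suffix (3' adapters), with at least `min_overlap` adapter bases.
#' A candidate is accepted iff its edit distance is at most
#' `floor(error_rate * matched adapter length)`; `N` never matches.
#'
#' Among accepted candidates the winner minimises edit distance; remaining
#' ties are broken by span start (leftmost for 5' adapters, rightmost for
#' 3'), then by longer matched adapter, then by span end (smaller for 5',
#' larger for 3').
#'
#' @param sequence read sequence (A/C/G/T/N).
#' @param adapter adapter sequence.
#' @param error_rate allowed error fraction (default 0.25).
#' @param end `"5prime"` (LTR-style) or `"3prime"` (linker-style).
#' @param min_overlap minimum adapter overlap for partial end matches.
#' @return `NULL` if no acceptable match, else a list with `start`, `end`
#'   (1-based inclusive span in the read), `distance`, and `adapter_len`
#'   (matched adapter bases).
#' @examples
#' find_adapter("ACGTACGTTGCA", "ACGTT", error_rate = 0.25, end = "5prime")
#' @export
find_adapter <- function(sequence, adapter, error_rate = 0.25,
                         end = c("5prime", "3prime"), min_overlap = 3L) {
  end <- match.arg(end)
  n <- nchar(sequence)
  if (n == 0L) return(NULL)
  readv <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  adapv <- strsplit(toupper(adapter), "", fixed = TRUE)[[1L]]
  m <- length(adapv)
  if (m == 0L) stopf("adapter must be non-empty")
  max_err_full <- floor(error_rate * m)

  # quick rejection: a free-start DP (row 0 all zero) lower-bounds every
  # full-adapter match; when partial end matches are impossible too, stop.
  if (min_overlap > m - 1L) {
    row <- integer(n + 1L)
    idx <- 0:n
    for (i in seq_len(m)) {
      a <- adapv[i]
      sub <- as.integer(readv != a | readv == "N" | a == "N")
      cand <- pmin(row[seq_len(n)] + sub, row[-1L] + 1L)
      row <- cummin(c(i, cand) - idx) + idx
    }
    if (min(row) > max_err_full) return(NULL)
  }

  better <- function(a, b) {
    # is candidate a strictly preferred over b?  candidates are
    # c(distance, start, adapter_len, end)
    if (a[1L] != b[1L]) return(a[1L] < b[1L])
    if (a[2L] != b[2L])
      return(if (end == "5prime") a[2L] < b[2L] else a[2L] > b[2L])
    if (a[3L] != b[3L]) return(a[3L] > b[3L])
    if (end == "5prime") a[4L] < b[4L] else a[4L] > b[4L]
  }
  best <- NULL
  consider <- function(dist, start, alen, span_end) {
    cand <- c(dist, start, alen, span_end)
    if (is.null(best) || better(cand, best)) best <<- cand
  }

  for (s in 0:(n - 1L)) {
    segv <- readv[(s + 1L):n]
    D <- edit_dp(segv, adapv)
    k <- length(segv)
    # full-adapter matches: span (s+1)..(s+j), j >= 1
    dists <- D[m + 1L, -1L]
    ok <- which(dists <= max_err_full)
    for (j in ok) consider(dists[j], s + 1L, m, s + j)
    if (end == "3prime" && m > 1L) {
      # adapter prefix running off the 3' read end: span (s+1)..n
      ls <- min_overlap:(m - 1L)
      ls <- ls[ls >= 1L]
      for (l in ls) {
        d <- D[l + 1L, k + 1L]
        if (d <= floor(error_rate * l)) consider(d, s + 1L, l, n)
      }
    }
  }
  if (end == "5prime" && m > 1L && min_overlap <= m - 1L) {
    # adapter suffix running off the 5' read end: span 1..j
    for (l in min_overlap:(m - 1L)) {
      sufv <- adapv[(m - l + 1L):m]
      D <- edit_dp(readv, sufv)
      dists <- D[l + 1L, -1L]
      ok <- which(dists <= floor(error_rate * l))
      for (j in ok) consider(dists[j], 1L, l, j)
    }
  }
  if (is.null(best)) return(NULL)
  list(start = as.integer(best[2L]), end = as.integer(best[4L]),
       distance = as.integer(best[1L]), adapter_len = as.integer(best[3L]))
}

#' Trim LTR and linker adapters from reads
#'
#' Reproduces the screen's trimming contract: the 5' LTR adapter match is
#' removed through its end, the 3' linker match (searched in the remainder)
#' is removed from its start onwards, reads in which neither adapter is
#' found are discarded when `discard_untrimmed`, and surviving reads shorter
#' than `min_read_len` are discarded.  Qualities are trimmed in register
#' with the sequence.
#'
#' @param reads data.frame with columns `read_id`, `sequence`, `qualities`
#'   (e.g. from [read_fastq()]).
#' @param config a [trim_config()].
#' @return list with `reads` (surviving trimmed reads) and `log`
#'   (data.frame `read_id`, `action`, `trimmed_length`; actions are
#'   `trimmed`, `kept_untrimmed`, `discarded_untrimmed`, `discarded_short`).
#' @export
trim_reads <- function(reads, config) {
  if (!inherits(config, "TrimConfig")) stopf("expected a TrimConfig")
  need <- c("read_id", "sequence", "qualities")
  if (!is.data.frame(reads) || !all(need %in% names(reads)))
    stopf("reads must be a data.frame with columns read_id, sequence, qualities")
  n <- nrow(reads)
  out_seq <- character(n); out_qual <- character(n)
  action <- character(n); tlen <- integer(n)
  for (i in seq_len(n)) {
    sq <- reads$sequence[i]
    m5 <- find_adapter(sq, config$ltr_adapter, config$error_rate,
                       end = "5prime", min_overlap = config$min_overlap)
    cut5 <- if (is.null(m5)) 0L else m5$end
    rest <- substring(sq, cut5 + 1L)
    m3 <- if (nchar(rest))
      find_adapter(rest, config$linker_adapter, config$error_rate,
                   end = "3prime", min_overlap = config$min_overlap) else NULL
    keep_len <- if (is.null(m3)) nchar(rest) else m3$start - 1L
    found <- !is.null(m5) || !is.null(m3)
    if (!found && config$discard_untrimmed) {
      action[i] <- "discarded_untrimmed"; tlen[i] <- NA_integer_
      next
    }
    if (keep_len < config$min_read_len) {
      action[i] <- "discarded_short"; tlen[i] <- keep_len
      next
    }
    action[i] <- if (found) "trimmed" else "kept_untrimmed"
    tlen[i] <- keep_len
    out_seq[i] <- substr(sq, cut5 + 1L, cut5 + keep_len)
    out_qual[i] <- substr(reads$qualities[i], cut5 + 1L, cut5 + keep_len)
  }
  keep <- action %in% c("trimmed", "kept_untrimmed")
  list(
    reads = data.frame(read_id = reads$read_id[keep],
                       sequence = out_seq[keep],
                       qualities = out_qual[keep],
                       stringsAsFactors = FALSE),
    log = data.frame(read_id = reads$read_id, action = action,
                     trimmed_length = tlen, stringsAsFactors = FALSE)
  )
}
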