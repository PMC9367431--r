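# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately re-derive results by enumeration rather
# than calling the package's scanning/statistic code paths.

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Exhaustive SSR enumerator: every start, every period 2-6, extend
# maximally, filter minimal-period and thresholds, then resolve
# cross-period overlaps (longer span wins, ties to smaller period, then
# smaller start).
oracle_ssrs <- function(sequence,
                        min_repeats = c(`2` = 6L, `3` = 5L, `4` = 5L,
                                        `5` = 5L, `6` = 5L)) {
  ch <- strsplit(toupper(sequence), "")[[1]]
  n <- length(ch)
  ok <- ch %in% c("A", "C", "G", "T")
  min_per <- function(m) {
    p <- nchar(m)
    for (d in seq_len(p - 1))
      if (p %% d == 0 && m == strrep(substr(m, 1, d), p %/% d)) return(d)
    p
  }
  cand <- list()
  for (p in 2:6) {
    minrep <- min_repeats[[as.character(p)]]
    for (i in seq_len(max(0L, n - p))) {
      # left-maximal starts only, so each maximal run is counted once
      if (i > 1L && ok[i - 1L] && ok[i - 1L + p] && ch[i - 1L] == ch[i - 1L + p])
        next
      j <- i
      while (j + p <= n && ok[j] && ok[j + p] && ch[j] == ch[j + p])
        j <- j + 1L
      run <- j - i  # matched comparisons
      copies <- (run + p) %/% p
      if (copies < minrep) next
      if (!all(ok[i:(i + p - 1L)])) next
      motif <- paste(ch[i:(i + p - 1L)], collapse = "")
      if (min_per(motif) != p) next
      cand[[length(cand) + 1]] <- data.frame(
        period = p, motif = motif, repeats = copies,
        start = i, end = i + copies * p - 1L)
    }
  }
  if (!length(cand)) return(NULL)
  cand <- do.call(rbind, cand)
  ord <- order(-(cand$end - cand$start + 1L), cand$period, cand$start)
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ov <- keep & cand$start <= cand$end[i] & cand$end >= cand$start[i]
    keep[i] <- !any(ov)
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Brute-force Nxx: the largest sequence length L whose at-least-L
# sequences cover >= x% of the assembly.
oracle_nxx <- function(lengths, x) {
  for (L in sort(unique(lengths), decreasing = TRUE))
    if (sum(lengths[lengths >= L]) >= x / 100 * sum(lengths)) return(L)
  min(lengths)
}

# A 101-bp interruption verified to contain no SSR at default thresholds,
# so merge boundary tests are not confounded by chance tandem structure.
tandem_free_filler <- function(len, seed = 99) {
  set.seed(seed)
  repeat {
    s <- random_dna(len)
    if (nrow(find_ssrs(c(f = s),
                       min_repeats = c(`2` = 3, `3` = 3, `4` = 3,
                                       `5` = 3, `6` = 3))) == 0)
      return(s)
  }
}

# Tandem-free filler wrapped in CC guards so adjacent planted runs can
# neither extend into it nor shift phase across the boundary.
gap_seq <- function(len, seed = 99) {
  paste0("CC", tandem_free_filler(len - 4, seed), "CC")
}

# Build a kmer_histogram directly from depth/species pairs.
load_hist_df <- function(depth, species) {
  gsurvey:::new_kmer_histogram(depth, species, 19L)
}

ssr_key <- function(df) {
  paste(df$motif, df$repeats, df$start, df$end, sep = ":")
}
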