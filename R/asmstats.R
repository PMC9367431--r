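#' Nxx assembly statistic
#'
#' The smallest length L such that sequences of length >= L together cover
#' at least x% of the total assembly length (descending sort + cumulative
#' sum). N50 is `nxx(lengths, 50)`, N90 is `nxx(lengths, 90)`.
#'
#' @param lengths sequence lengths in bp (non-empty).
#' @param x percentage in (0, 100].
#' @return length in bp.
#' @export
nxx <- function(lengths, x) {
  if (!length(lengths)) stop("empty length list", call. = FALSE)
  if (x <= 0 || x > 100) stop("x must be in (0, 100]", call. = FALSE)
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  cs <- cumsum(s)
  s[which(cs >= x / 100 * cs[length(cs)])[1]]
}

# G+C percentage over unambiguous bases of a DNAStringSet.
gc_percent_of <- function(ss) {
  f <- Biostrings::letterFrequency(ss, c("G", "C", "A", "T"))
  totals <- colSums(f)
  denom <- sum(totals)
  if (denom == 0) return(NA_real_)
  100 * (totals[["G"]] + totals[["C"]]) / denom
}

#' Assembly metrics table
#'
#' Total length, sequence count, maximum length, N50, N90 and GC content
#' of an assembly. GC% is `(G + C) / (A + C + G + T) * 100`; ambiguous
#' bases contribute length but are excluded from the GC denominator.
#'
#' @param x assembly: FASTA path, `DNAStringSet`, or named character
#'   vector (non-empty).
#' @return object of class `assembly_metrics`: `total_length`,
#'   `total_number`, `max_length`, `n50`, `n90`, `gc_percent`.
#' @export
assembly_metrics <- function(x) {
  seqs <- as_sequences(x)
  if (!length(seqs)) stop("empty assembly", call. = FALSE)
  ss <- Biostrings::DNAStringSet(seqs)
  len <- Biostrings::width(ss)
  structure(list(total_length = sum(as.numeric(len)),
                 total_number = length(len),
                 max_length = max(len),
                 n50 = nxx(len, 50), n90 = nxx(len, 90),
                 gc_percent = gc_percent_of(ss)),
            class = "assembly_metrics")
}

#' @export
print.assembly_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "assembly metrics\n",
    "  total length: %.0f bp\n  sequences:    %d\n  max length:   %d bp\n",
    "  N50:          %d bp\n  N90:          %d bp\n  GC content:   %.2f%%\n"),
    x$total_length, x$total_number, x$max_length, x$n50, x$n90,
    x$gc_percent))
  invisible(x)
}

#' Split scaffolds into contigs at N gaps
#'
#' Splits each scaffold on runs of one or more N and emits the non-empty
#' pieces with `_1`, `_2`, ... suffixed ids, preserving order. Non-N bases
#' are conserved exactly.
#'
#' @param x assembly (FASTA path, `DNAStringSet`, or named character
#'   vector).
#' @return named character vector of contigs.
#' @export
scaffold_to_contigs <- function(x) {
  seqs <- as_sequences(x)
  out <- lapply(names(seqs), function(id) {
    pieces <- strsplit(toupper(seqs[[id]]), "N+")[[1]]
    pieces <- pieces[nzchar(pieces)]
    if (!length(pieces)) return(NULL)
    setNames(pieces, paste0(id, "_", seq_along(pieces)))
  })
  unlist(out)
}

#' GC content versus k-mer depth per window
#'
#' For each non-overlapping window of an assembly, the GC percentage and
#' the mean multiplicity (in a k-mer index built from the reads) of the
#' canonical k-mers starting in the window. Multiplicity stands proxy for
#' sequencing depth, so no read aligner is needed. Windows with more than
#' 50% N are skipped.
#'
#' @param x assembly (FASTA path, `DNAStringSet`, or named character
#'   vector).
#' @param index a [kmer_index()] built from the read set.
#' @param window window size in bp (>= the index k).
#' @return data.frame with `seq_id`, `window_start`, `gc_percent`,
#'   `mean_depth`.
#' @export
gc_depth_table <- function(x, index, window = 500L) {
  k <- attr(index, "k")
  if (window < k)
    stop("window must be at least k (", k, ")", call. = FALSE)
  seqs <- as_sequences(x)
  mult <- .cpp_kmer_lookup(index, unname(seqs))
  res <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    n <- nchar(s)
    starts <- seq(1L, n, by = window)
    rows <- lapply(starts, function(w0) {
      w1 <- min(w0 + window - 1L, n)
      win <- substr(s, w0, w1)
      ss <- Biostrings::DNAStringSet(win)
      nN <- Biostrings::letterFrequency(ss, "N")[1, 1]
      if (nN > 0.5 * (w1 - w0 + 1L)) return(NULL)
      m <- mult[[i]]
      hi <- min(w1, length(m))
      vals <- if (w0 <= hi) m[w0:hi] else integer(0)
      vals <- vals[vals >= 0]  # windows containing N have multiplicity -1
      data.frame(seq_id = names(seqs)[i], window_start = w0,
                 gc_percent = gc_percent_of(ss),
                 mean_depth = if (length(vals)) mean(vals) else NA_real_)
    })
    do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  })
  out <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(seq_id = character(0), window_start = integer(0),
                      gc_percent = numeric(0), mean_depth = numeric(0))
  rownames(out) <- NULL
  out
}
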