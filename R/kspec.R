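#' Count canonical k-mers in a read collection
#'
#' Every window of k consecutive non-N bases contributes one count to its
#' canonical k-mer (the lexicographic minimum of the k-mer and its reverse
#' complement); windows containing N are skipped. Counting is in-memory and
#' intended for desk-scale inputs (tens of Mb of reads). Multiplicities
#' above `cap` accumulate in the cap bin so histograms stay bounded.
#'
#' @param reads a `read_set`, named character vector, `DNAStringSet`, or
#'   FASTA/FASTQ path.
#' @param k odd k-mer size (<= 31; odd k avoids self-reverse-complement
#'   palindromes, for which the canonical form is ill-defined).
#' @param cap depth cap (default 10000).
#' @return a `kmer_histogram`: data.frame with columns `depth` and
#'   `species` (number of distinct canonical k-mers at that depth), with
#'   attribute `k`.
#' @seealso [kmer_index()] for a reusable multiplicity lookup.
#' @export
count_kmers <- function(reads, k, cap = 10000L) {
  idx <- kmer_index(reads, k)
  kmer_histogram_from_index(idx, cap)
}

#' Build a canonical k-mer multiplicity index
#'
#' @inheritParams count_kmers
#' @return an opaque index object (class `kmer_index`) usable with
#'   [kmer_histogram_from_index()] and [gc_depth_table()].
#' @export
kmer_index <- function(reads, k) {
  k <- as.integer(k)
  if (k %% 2L == 0L)
    stop("k must be odd: canonical form is ill-defined for palindromes",
         call. = FALSE)
  if (k < 1L || k > 31L) stop("k must be between 1 and 31", call. = FALSE)
  seqs <- as_sequences(reads)
  idx <- .cpp_kmer_index(unname(seqs), k)
  class(idx) <- "kmer_index"
  idx
}

#' Histogram of a k-mer index
#'
#' @param index a [kmer_index()].
#' @param cap depth cap.
#' @return a `kmer_histogram`.
#' @export
kmer_histogram_from_index <- function(index, cap = 10000L) {
  h <- .cpp_kmer_histogram(index, as.integer(cap))
  new_kmer_histogram(h$depth, h$species, attr(index, "k"))
}

new_kmer_histogram <- function(depth, species, k) {
  ord <- order(depth)
  out <- data.frame(depth = as.integer(depth)[ord],
                    species = as.numeric(species)[ord])
  if (any(out$depth < 1)) stop("depths must be >= 1", call. = FALSE)
  if (any(out$species < 0)) stop("species counts must be >= 0", call. = FALSE)
  attr(out, "k") <- as.integer(k)
  class(out) <- c("kmer_histogram", "data.frame")
  out
}

#' @export
print.kmer_histogram <- function(x, ...) {
  cat(sprintf("k-mer histogram (k = %s): %d depth bins, N_kmer = %.0f\n",
              attr(x, "k"), nrow(x), n_kmer(x)))
  invisible(x)
}

#' Total k-mer volume of a histogram
#'
#' `N_kmer`: the total number of counted k-mer windows,
#' `sum(depth * species)`.
#'
#' @param hist a `kmer_histogram`.
#' @return numeric scalar.
#' @export
n_kmer <- function(hist) sum(as.numeric(hist$depth) * hist$species)

#' k-mer volume at one depth
#'
#' @param hist a `kmer_histogram`.
#' @param d depth.
#' @return `d * species(d)` (0 if the depth is absent).
#' @export
kmer_volume <- function(hist, d) {
  i <- match(d, hist$depth)
  if (is.na(i)) 0 else as.numeric(d) * hist$species[i]
}

#' Read / write two-column k-mer histograms
#'
#' The common counter dialect: one `depth species` pair per line,
#' whitespace-separated, ascending depth.
#'
#' @param path file path.
#' @param k the k the histogram was counted at (stored as an attribute;
#'   optional on load).
#' @return `load_histogram()` returns a `kmer_histogram`;
#'   `save_histogram()` returns `path` invisibly.
#' @export
load_histogram <- function(path, k = NA_integer_) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(parts, length, 0L) != 2L |
                 vapply(parts, function(p) anyNA(suppressWarnings(as.numeric(p))), TRUE))
  if (length(bad))
    stop(sprintf("malformed histogram line %d: '%s'", bad[1], lines[bad[1]]),
         call. = FALSE)
  m <- matrix(as.numeric(unlist(parts)), ncol = 2, byrow = TRUE)
  new_kmer_histogram(m[, 1], m[, 2], k)
}

#' @rdname load_histogram
#' @param hist a `kmer_histogram`.
#' @export
save_histogram <- function(hist, path) {
  writeLines(sprintf("%d %.0f", hist$depth, hist$species), path)
  invisible(path)
}

# Species counts on the full 1..max depth grid (zeros filled in).
dense_species <- function(hist) {
  dmax <- max(hist$depth)
  s <- numeric(dmax)
  s[hist$depth] <- hist$species
  s
}

#' Locate the main peak of a k-mer spectrum
#'
#' Returns the depth of the main (homozygous-coverage) mode of the
#' spectrum. The error peak at low depth is excluded by finding the first
#' local minimum of the window-3 moving-average of species counts; the mode
#' is first located as the argmax of species counts at depths strictly
#' beyond that minimum (ties toward the smaller depth), then refined to
#' the rounded species-weighted mean depth within a window of one third of
#' the mode on either side. The refinement makes the returned depth stable
#' against bin-level sampling noise, to which the raw argmax of a nearly
#' flat Poisson top is sensitive.
#'
#' @param hist a `kmer_histogram`.
#' @return integer depth of the peak (`C_kmer`).
#' @export
find_peak <- function(hist) {
  if (nrow(hist) == 0) stop("empty histogram", call. = FALSE)
  s <- dense_species(hist)
  n <- length(s)
  if (n < 2) stop("no post-error peak in histogram", call. = FALSE)
  sm <- vapply(seq_len(n), function(i)
    mean(s[max(1, i - 1):min(n, i + 1)]), 0)
  rising <- which(sm[-1] > sm[-n])
  if (!length(rising))
    stop("no post-error peak: histogram is monotone decreasing", call. = FALSE)
  lo <- rising[1]  # first local minimum of the smoothed curve
  cand <- (lo + 1):n
  mode <- cand[which.max(s[cand])]  # which.max ties toward smaller depth
  w <- max(2L, as.integer(round(mode / 3)))
  win <- max(lo + 1L, mode - w):min(n, mode + w)
  mhat <- sum(win * s[win]) / sum(s[win])
  as.integer(round(mhat))
}

#' Sequencing error rate from the depth-1 bin
#'
#' Depth-1 k-mers are taken as the error case: the estimate is
#' `volume(1) / N_kmer`, the fraction of k-mer windows observed exactly
#' once.
#'
#' @param hist a `kmer_histogram`.
#' @return fraction in \[0, 1\].
#' @export
estimate_error_rate <- function(hist) {
  if (nrow(hist) == 0) stop("empty histogram", call. = FALSE)
  kmer_volume(hist, 1L) / n_kmer(hist)
}

#' Genome size from the k-mer spectrum
#'
#' `G_size = N_kmer / C_kmer`, with the error-corrected value
#' `revised_G_size = G_size * (1 - error_rate)`, equivalently
#' `(N_kmer - volume(1)) / C_kmer` exactly.
#'
#' @param hist a `kmer_histogram`.
#' @param peak the peak depth `C_kmer` (>= 2), e.g. from [find_peak()].
#' @return list with `g_size` and `revised_g_size` (bp).
#' @export
estimate_genome_size <- function(hist, peak) {
  if (peak < 2) stop("peak depth must be >= 2", call. = FALSE)
  if (peak < min(hist$depth) || peak > max(hist$depth))
    stop("peak outside the histogram depth range", call. = FALSE)
  N <- n_kmer(hist)
  g <- N / peak
  list(g_size = g, revised_g_size = (N - kmer_volume(hist, 1L)) / peak)
}

#' Heterozygosity from the half-depth spectrum component
#'
#' Fits a two-component Poisson mixture with means `m/2` (heterozygous
#' k-mers, present on one haplotype) and `m` (homozygous k-mers) to the
#' species counts over depths `[peak/4, 1.5*peak]` by least squares, where
#' the coverage mean `m` is refined continuously within 20% of the integer
#' histogram peak (the mode only locates coverage to one depth unit). Each
#' heterozygous site yields two distinct half-depth k-mer species per
#' overlapping window, so the heterozygous weight alpha is taken as the
#' half-depth component's share of k-mer occurrences,
#' `A1 / (A1 + 2*A2)` for species amplitudes `A1`, `A2`. The per-base rate
#' is then `r = 1 - (1 - alpha)^(1/k)`, the standard transform from the
#' probability that a k-base window covers a heterozygous site.
#'
#' @param hist a `kmer_histogram`.
#' @param peak the peak depth (>= 4).
#' @param k k-mer size (defaults to the histogram's `k` attribute).
#' @return per-base heterozygosity estimate in \[0, 1\].
#' @export
estimate_heterozygosity <- function(hist, peak, k = attr(hist, "k")) {
  if (is.na(k)) stop("k is required", call. = FALSE)
  if (peak < 4) stop("peak depth must be >= 4", call. = FALSE)
  d <- seq(max(1L, ceiling(peak / 4)), floor(1.5 * peak))
  s <- dense_species(hist)
  y <- ifelse(d <= length(s), s[d], 0)
  # closed-form non-negative amplitudes for a given coverage mean m;
  # m itself is refined continuously around the integer peak, since the
  # histogram mode only locates the coverage to +/- 1 depth unit
  fit_at <- function(m) {
    X <- cbind(dpois(d, m / 2), dpois(d, m))
    a <- tryCatch(pmax(qr.solve(crossprod(X), crossprod(X, y)), 0),
                  error = function(e)
                    stop("heterozygosity fit failed: ",
                         conditionMessage(e), call. = FALSE))
    list(a = a, rss = sum((y - X %*% a)^2))
  }
  m <- stats::optimize(function(m) fit_at(m)$rss,
                       c(0.8 * peak, 1.2 * peak))$minimum
  a <- fit_at(m)$a
  if (anyNA(a) || sum(a) == 0)
    stop("heterozygosity fit degenerate: amplitudes ",
         paste(signif(a, 4), collapse = ", "), call. = FALSE)
  alpha <- a[1] / (a[1] + 2 * a[2])
  unname(1 - (1 - alpha)^(1 / k))
}

#' Repeat ratio from the high-depth spectrum tail
#'
#' Repetitive sequence appears at multiples of the coverage peak; the
#' estimate is the error-free k-mer volume at depths at or beyond
#' `round(1.5 * peak)`:
#' `sum(volume(d >= 1.5*peak)) / (N_kmer - volume(1))`. The 1.5x threshold
#' splits the homozygous peak from the 2x repeat peak and is a documented
#' heuristic.
#'
#' @param hist a `kmer_histogram`.
#' @param peak the peak depth (>= 2).
#' @return fraction in \[0, 1\].
#' @export
estimate_repeat_ratio <- function(hist, peak) {
  if (peak < 2) stop("peak depth must be >= 2", call. = FALSE)
  cut <- round(1.5 * peak)
  high <- hist$depth >= cut
  num <- sum(as.numeric(hist$depth[high]) * hist$species[high])
  num / (n_kmer(hist) - kmer_volume(hist, 1L))
}

#' Full spectrum-based survey estimates
#'
#' Convenience wrapper running peak detection, error-rate, genome-size,
#' heterozygosity and repeat-ratio estimation on one histogram.
#'
#' @param hist a `kmer_histogram`.
#' @param k k-mer size (defaults to the histogram attribute).
#' @return object of class `spectrum_estimates`: `c_kmer`, `error_rate`,
#'   `g_size`, `revised_g_size`, `het_rate`, `repeat_ratio`.
#' @export
spectrum_estimates <- function(hist, k = attr(hist, "k")) {
  peak <- find_peak(hist)
  err <- estimate_error_rate(hist)
  gs <- estimate_genome_size(hist, peak)
  het <- if (peak >= 4) estimate_heterozygosity(hist, peak, k) else NA_real_
  rep_ratio <- estimate_repeat_ratio(hist, peak)
  structure(list(c_kmer = peak, error_rate = err, g_size = gs$g_size,
                 revised_g_size = gs$revised_g_size, het_rate = het,
                 repeat_ratio = rep_ratio, k = k),
            class = "spectrum_estimates")
}

#' @export
print.spectrum_estimates <- function(x, ...) {
  cat(sprintf(paste0(
    "k-mer spectrum estimates (k = %s)\n",
    "  peak depth (C_kmer):  %d\n",
    "  error rate:           %.4f%%\n",
    "  genome size:          %.2f bp\n",
    "  revised genome size:  %.2f bp\n",
    "  heterozygosity:       %s\n",
    "  repeat ratio:         %.2f%%\n"),
    x$k, x$c_kmer, 100 * x$error_rate, x$g_size, x$revised_g_size,
    if (is.na(x$het_rate)) "NA" else sprintf("%.4f%%", 100 * x$het_rate),
    100 * x$repeat_ratio))
  invisible(x)
}
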