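#' Simulation parameters for a synthetic diploid genome
#'
#' Bundles and validates the truth parameters behind a simulated survey
#' dataset. The defaults mirror a small diploid fish genome with moderate
#' heterozygosity (0.47% per base) and repeat content (32.6% of the genome
#' covered by exact duplications).
#'
#' @param genome_length haploid genome length in bp (> 0).
#' @param het_rate per-base heterozygosity probability, in \[0, 0.05\].
#' @param repeat_fraction fraction of the genome covered by exact duplicated
#'   sequence (sources plus copies), in \[0, 0.9\].
#' @param repeat_unit_length length in bp of each duplicated block.
#' @param seed integer RNG seed; identical parameters and seed give
#'   byte-identical simulations.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(genome_length, het_rate = 0.0047,
                       repeat_fraction = 0.326, repeat_unit_length = 500,
                       seed = 1L) {
  stopifnot(is.numeric(genome_length), length(genome_length) == 1)
  genome_length <- as.integer(genome_length)
  if (genome_length <= 0)
    stop("genome_length must be positive", call. = FALSE)
  if (het_rate < 0 || het_rate > 0.05)
    stop("het_rate must lie in [0, 0.05]", call. = FALSE)
  if (repeat_fraction < 0 || repeat_fraction > 0.9)
    stop("repeat_fraction must lie in [0, 0.9]", call. = FALSE)
  if (genome_length < repeat_unit_length)
    stop("genome_length must be at least repeat_unit_length", call. = FALSE)
  structure(list(genome_length = genome_length, het_rate = het_rate,
                 repeat_fraction = repeat_fraction,
                 repeat_unit_length = as.integer(repeat_unit_length),
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Simulate a diploid genome with known heterozygosity and repeat content
#'
#' Builds haplotype 1 as random sequence into which exact copies of earlier
#' blocks are inserted until `repeat_fraction` of the genome is covered by
#' duplicated sequence (each duplication event covers two blocks: source and
#' copy). Haplotype 2 is then derived by independent per-base substitution
#' at `het_rate`, so the recorded heterozygous sites exactly enumerate the
#' positions where the haplotypes differ.
#'
#' @param params a [sim_params()] object.
#' @return an object of class `diploid_genome`: `hap1`, `hap2` (DNA strings
#'   of equal length), `het_sites` (1-based positions where they differ),
#'   `ssr_truth` (empty; see [plant_ssrs()]), and `params`.
#' @export
simulate_diploid_genome <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  L <- params$genome_length
  u <- params$repeat_unit_length
  n_copies <- round(L * params$repeat_fraction / 2 / u)
  base_len <- L - n_copies * u
  if (base_len < u)
    stop("genome too short for the requested repeat content", call. = FALSE)
  g <- sample(DNA_BASES, base_len, replace = TRUE)
  for (i in seq_len(n_copies)) {
    n <- length(g)
    src <- sample.int(n - u + 1L, 1L)
    block <- g[src:(src + u - 1L)]
    # insertion point strictly after the source block keeps copies "later"
    at <- sample((src + u):(n + 1L), 1L)
    g <- append(g, block, after = at - 1L)
  }
  hap1 <- paste(g, collapse = "")
  hap2 <- hap1
  het_sites <- integer(0)
  if (params$het_rate > 0) {
    het_sites <- which(runif(L) < params$het_rate)
    if (length(het_sites)) {
      ch <- g
      cur <- match(ch[het_sites], DNA_BASES)
      new <- ((cur - 1L + sample.int(3L, length(het_sites), replace = TRUE)) %% 4L) + 1L
      ch[het_sites] <- DNA_BASES[new]
      hap2 <- paste(ch, collapse = "")
    }
  }
  structure(list(hap1 = hap1, hap2 = hap2, het_sites = het_sites,
                 ssr_truth = data.frame(start = integer(0), end = integer(0),
                                        motif = character(0), repeats = integer(0)),
                 params = params),
            class = "diploid_genome")
}

#' @export
print.diploid_genome <- function(x, ...) {
  cat(sprintf("diploid genome: %d bp, %d heterozygous sites (%.4f%%)\n",
              nchar(x$hap1), length(x$het_sites),
              100 * length(x$het_sites) / nchar(x$hap1)))
  invisible(x)
}

#' Simulate uniform-coverage single-end reads with substitution errors
#'
#' Read start positions are uniform over both haplotypes and both strands;
#' substitution errors are i.i.d. per base. Indels and base-quality profiles
#' are deliberately absent: depth-1 k-mer error estimation assumes a
#' substitution-only model.
#'
#' @param genome a [simulate_diploid_genome()] result.
#' @param coverage expected pooled depth per genome position (> 0), both
#'   haplotypes together.
#' @param read_length read length in bp (<= genome length).
#' @param error_rate per-base substitution probability.
#' @param seed integer RNG seed.
#' @return an object of class `read_set`: `reads` (data.frame with `id`,
#'   `seq`, `qual`), `read_length`, `coverage`, `error_rate`. The read count
#'   is `round(coverage * genome_length / read_length)`.
#' @export
simulate_reads <- function(genome, coverage, read_length = 150L,
                           error_rate = 0.001, seed = 1L) {
  stopifnot(inherits(genome, "diploid_genome"))
  if (coverage <= 0) stop("coverage must be positive", call. = FALSE)
  L <- nchar(genome$hap1)
  if (read_length > L)
    stop("read_length exceeds genome length", call. = FALSE)
  set.seed(seed)
  n <- round(coverage * L / read_length)
  hap <- sample.int(2L, n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  starts <- sample.int(L - read_length + 1L, n, replace = TRUE)
  seqs <- character(n)
  i1 <- hap == 1L
  seqs[i1] <- substring(genome$hap1, starts[i1], starts[i1] + read_length - 1L)
  seqs[!i1] <- substring(genome$hap2, starts[!i1], starts[!i1] + read_length - 1L)
  neg <- strand == "-"
  if (any(neg)) seqs[neg] <- revcomp(seqs[neg])
  if (error_rate > 0) {
    total <- n * read_length
    n_err <- rbinom(1L, total, error_rate)
    if (n_err > 0) {
      idx <- sample.int(total, n_err)
      rd <- (idx - 1L) %/% read_length + 1L
      pos <- (idx - 1L) %% read_length + 1L
      cur <- match(substring(seqs[rd], pos, pos), DNA_BASES)
      new <- DNA_BASES[((cur - 1L + sample.int(3L, n_err, replace = TRUE)) %% 4L) + 1L]
      for (j in seq_len(n_err))
        substr(seqs[rd[j]], pos[j], pos[j]) <- new[j]
    }
  }
  reads <- data.frame(id = sprintf("read_%07d", seq_len(n)), seq = seqs,
                      qual = strrep("I", read_length))
  structure(list(reads = reads, read_length = as.integer(read_length),
                 coverage = coverage, error_rate = error_rate),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read set: %d reads x %d bp (coverage %.1f, error rate %g)\n",
              nrow(x$reads), x$read_length, x$coverage, x$error_rate))
  invisible(x)
}

# TRUE if `window` (character scalar) contains any tandem run of period 1-6
# with >= min_copies full copies. Used to vet SSR insertion flanks.
has_tandem <- function(window, min_copies = 3L) {
  ch <- seq_chars(window)
  n <- length(ch)
  for (p in 1:6) {
    if (n < p * min_copies) next
    a <- ch[seq_len(n - p)]
    b <- ch[(p + 1):n]
    m <- a == b & a %in% DNA_BASES & b %in% DNA_BASES
    r <- rle(m)
    len <- r$lengths[r$values]
    if (length(len) && any((len + p) %/% p >= min_copies)) return(TRUE)
  }
  FALSE
}

#' Plant perfect SSR arrays into a sequence with recoverable truth
#'
#' Inserts `copies` tandem arrays of each motif at non-overlapping random
#' positions. Each array is wrapped in single guard bases chosen so that the
#' flanking sequence can neither extend the run nor shift its phase, and
#' insertion sites whose neighbourhoods already contain tandem structure are
#' rejected, so a scanner recovers every planted array at exactly the
#' recorded coordinates.
#'
#' @param sequence DNA string to plant into.
#' @param spec data.frame with columns `motif` (period 2-6, not a repetition
#'   of a shorter unit), `repeats` (full copies per array), `copies` (number
#'   of arrays to plant).
#' @param seed integer RNG seed.
#' @return list with `sequence` (the augmented string) and `truth`
#'   (data.frame `start`, `end`, `motif`, `repeats`, 1-based inclusive).
#' @export
plant_ssrs <- function(sequence, spec, seed = 1L) {
  if (is.null(spec) || nrow(as.data.frame(spec)) == 0)
    return(list(sequence = sequence,
                truth = data.frame(start = integer(0), end = integer(0),
                                   motif = character(0), repeats = integer(0))))
  spec <- as.data.frame(spec)
  stopifnot(all(c("motif", "repeats", "copies") %in% names(spec)))
  spec$motif <- toupper(spec$motif)
  for (m in spec$motif) {
    p <- nchar(m)
    if (p < 2 || p > 6 || !all(seq_chars(m) %in% DNA_BASES))
      stop("motifs must be DNA of period 2-6: ", m, call. = FALSE)
    if (minimal_period(m) < p)
      stop("motif is a repetition of a shorter unit: ", m, call. = FALSE)
  }
  set.seed(seed)
  rows <- spec[rep(seq_len(nrow(spec)), spec$copies), c("motif", "repeats")]
  n_ins <- nrow(rows)
  L <- nchar(sequence)
  margin <- 40L
  if (L < 2 * margin + 20L * n_ins)
    stop("sequence too short for the requested number of planted arrays",
         call. = FALSE)
  # pick insertion points (original coordinates) with clean flanks
  pts <- integer(0)
  attempts <- 0L
  while (length(pts) < n_ins) {
    if ((attempts <- attempts + 1L) > 200L * n_ins)
      stop("could not place all arrays: no non-repetitive flanks available",
           call. = FALSE)
    cand <- sample((margin + 1L):(L - margin), 1L)
    if (length(pts) && min(abs(pts - cand)) < 2L * margin) next
    win <- substr(sequence, cand - margin + 1L, cand + margin)
    if (has_tandem(win)) next
    pts <- c(pts, cand)
  }
  ord <- order(pts)
  pts <- pts[ord]
  rows <- rows[ord, , drop = FALSE]
  array_seq <- strrep(rows$motif, rows$repeats)
  first <- substr(rows$motif, 1L, 1L)
  last <- substr(rows$motif, nchar(rows$motif), nchar(rows$motif))
  pick_other <- function(b) vapply(b, function(x) setdiff(DNA_BASES, x)[1L], "")
  g1 <- pick_other(last)   # left guard: cannot complete a preceding copy
  g2 <- pick_other(first)  # right guard: cannot start a trailing copy
  ins_text <- paste0(g1, array_seq, g2)
  ins_len <- nchar(ins_text)
  shift <- c(0, cumsum(ins_len))[seq_len(n_ins)]
  start <- pts + shift + 2L  # +1 past insertion point, +1 past guard
  end <- start + nchar(array_seq) - 1L
  ch <- seq_chars(sequence)
  pieces <- character(2L * n_ins + 1L)
  prev <- 0L
  for (i in seq_len(n_ins)) {
    pieces[2L * i - 1L] <- paste(ch[(prev + 1L):pts[i]], collapse = "")
    pieces[2L * i] <- ins_text[i]
    prev <- pts[i]
  }
  pieces[2L * n_ins + 1L] <- if (prev < L)
    paste(ch[(prev + 1L):L], collapse = "") else ""
  list(sequence = paste(pieces, collapse = ""),
       truth = data.frame(start = start, end = end, motif = rows$motif,
                          repeats = as.integer(rows$repeats),
                          row.names = NULL))
}
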