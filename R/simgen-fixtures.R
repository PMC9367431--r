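# Gene layout for the synthetic mitochondrial fixture: standard teleost
# order, 13 PCGs / 22 tRNAs / 2 rRNAs / 1 control region. ND6 and eight
# tRNAs (Gln, Ala, Asn, Cys, Tyr, Ser2, Glu, Pro) sit on the light strand.
# PCG lengths are chosen mod 3 to realize the planted stop classes:
# multiples of 3 carry a full stop codon, len %% 3 == 1 ends in "T" and
# len %% 3 == 2 ends in "TA" (incomplete stops completed by polyadenylation).
mito_layout <- function() {
  f <- function(name, type, strand, len, start = NA, stop = NA)
    data.frame(name = name, type = type, strand = strand, len = len,
               start_codon = start, stop = stop)
  rbind(
    f("trnF",  "tRNA", "H", 68),
    f("rrnS",  "rRNA", "H", 950),
    f("trnV",  "tRNA", "H", 72),
    f("rrnL",  "rRNA", "H", 1700),
    f("trnL2", "tRNA", "H", 74),
    f("ND1",   "PCG",  "H", 975,  "ATG", "TAG"),
    f("trnI",  "tRNA", "H", 71),
    f("trnQ",  "tRNA", "L", 72),
    f("trnM",  "tRNA", "H", 69),
    f("ND2",   "PCG",  "H", 1046, "ATG", "TA"),
    f("trnW",  "tRNA", "H", 71),
    f("trnA",  "tRNA", "L", 69),
    f("trnN",  "tRNA", "L", 73),
    f("trnC",  "tRNA", "L", 67),
    f("trnY",  "tRNA", "L", 70),
    f("COI",   "PCG",  "H", 1549, "GTG", "T"),
    f("trnS2", "tRNA", "L", 72),
    f("trnD",  "tRNA", "H", 71),
    f("COII",  "PCG",  "H", 690,  "ATG", "AGA"),
    f("trnK",  "tRNA", "H", 73),
    f("ATP8",  "PCG",  "H", 168,  "ATG", "TAA"),
    f("ATP6",  "PCG",  "H", 684,  "ATA", "TAA"),
    f("COIII", "PCG",  "H", 785,  "ATG", "TA"),
    f("trnG",  "tRNA", "H", 70),
    f("ND3",   "PCG",  "H", 351,  "ATG", "TAG"),
    f("trnR",  "tRNA", "H", 69),
    f("ND4L",  "PCG",  "H", 298,  "ATG", "T"),
    f("ND4",   "PCG",  "H", 1380, "ATG", "AGA"),
    f("trnH",  "tRNA", "H", 69),
    f("trnS1", "tRNA", "H", 67),
    f("trnL1", "tRNA", "H", 73),
    f("ND5",   "PCG",  "H", 1838, "ATG", "TA"),
    f("ND6",   "PCG",  "L", 522,  "ATG", "TAG"),
    f("trnE",  "tRNA", "L", 69),
    f("CYTB",  "PCG",  "H", 1141, "ATG", "T"),
    f("trnT",  "tRNA", "H", 72),
    f("trnP",  "tRNA", "L", 70),
    f("CR",    "CR",   "H", 860)
  )
}

# Random CDS of the requested length under the vertebrate mitochondrial
# code: fixed start codon, non-stop body codons, planted stop suffix.
random_cds <- function(len, start_codon, stop) {
  stops <- c("TAA", "TAG", "AGA", "AGG")
  codons <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1, paste,
                  collapse = "")
  codons <- setdiff(codons, stops)
  stop_len <- nchar(stop)
  n_body <- (len - 3L - stop_len) / 3L
  stopifnot(n_body == floor(n_body), n_body >= 1)
  paste0(start_codon,
         paste(sample(codons, n_body, replace = TRUE), collapse = ""),
         stop)
}

#' Build a synthetic circular mitochondrial genome fixture
#'
#' Generates a ~16.5 kb circular genome in the canonical teleost layout:
#' 13 protein-coding genes, 22 tRNAs, 2 rRNAs and one control region, with
#' ND6 plus eight tRNAs on the light strand. The COI analog starts with
#' GTG, the ATP6 analog with ATA, the remaining 11 PCGs with ATG; seven
#' PCGs carry conventional stops (TAA/TAG/AGA) and six carry incomplete
#' stops (T or TA). The genome is rotated so the origin falls inside the
#' control region, which therefore wraps — exercising circular coordinate
#' handling downstream.
#'
#' @param seed integer RNG seed.
#' @return list of class `mito_fixture`: `sequence` (heavy-strand DNA
#'   string), `annotation` (a `mito_annotation`, see [read_annotation()]),
#'   and `code_table` (2, vertebrate mitochondrial).
#' @export
make_mito_fixture <- function(seed = 1L) {
  set.seed(seed)
  lay <- mito_layout()
  n <- nrow(lay)
  spacers <- sample(0:3, n, replace = TRUE)
  spacers[n] <- 0L
  pieces <- character(2L * n)
  start <- end <- integer(n)
  pos <- 0L
  for (i in seq_len(n)) {
    len <- lay$len[i]
    gene <- if (lay$type[i] == "PCG")
      random_cds(len, lay$start_codon[i], lay$stop[i])
    else
      paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
    placed <- if (lay$strand[i] == "L") revcomp(gene) else gene
    start[i] <- pos + 1L
    end[i] <- pos + len
    pieces[2L * i - 1L] <- placed
    pieces[2L * i] <- paste(sample(DNA_BASES, spacers[i], replace = TRUE),
                            collapse = "")
    pos <- pos + len + spacers[i]
  }
  genome <- paste(pieces, collapse = "")
  L <- nchar(genome)
  # rotate so the origin lands 400 bp into the control region
  rot <- start[n] + 399L
  genome <- paste0(substr(genome, rot + 1L, L), substr(genome, 1L, rot))
  new_pos <- function(x) ifelse(x > rot, x - rot, x - rot + L)
  ns <- new_pos(start); ne <- new_pos(end)
  ann <- mito_annotation(
    data.frame(name = lay$name, type = lay$type, strand = lay$strand,
               start = ns, end = ne, wraps = ns > ne),
    genome_length = L)
  structure(list(sequence = genome, annotation = ann, code_table = 2L),
            class = "mito_fixture")
}

#' PSMC truth trajectory
#'
#' Holds the scaled coalescent parameters from which [make_psmc_output()]
#' writes PSMC-dialect text, together with the constants used to convert
#' back to (years, Ne): per-site per-generation substitution rate `u`,
#' consensus bin size `s` (bp), and generation time `g` (years).
#'
#' @param theta0 scaled mutation parameter (4 N0 u s).
#' @param t time interval boundaries in units of 2 N0 generations; must
#'   start at 0 and increase strictly.
#' @param lambda relative population sizes per interval (> 0).
#' @param u per-site per-generation substitution rate.
#' @param s consensus bin size in bp.
#' @param g generation time in years.
#' @return object of class `psmc_truth`.
#' @export
psmc_truth <- function(theta0, t, lambda, u = 2.5e-8, s = 100, g = 1) {
  if (length(t) != length(lambda))
    stop("t and lambda must have equal length", call. = FALSE)
  if (t[1] != 0 || any(diff(t) <= 0))
    stop("t must start at 0 and be strictly increasing", call. = FALSE)
  if (any(lambda <= 0)) stop("lambda must be positive", call. = FALSE)
  structure(list(theta0 = theta0, t = as.numeric(t),
                 lambda = as.numeric(lambda), u = u, s = s, g = g),
            class = "psmc_truth")
}

#' Ne trajectory implied by a PSMC truth object
#'
#' @param truth a [psmc_truth()] object.
#' @return data.frame with `years` and `Ne`, the exact trajectory that
#'   parsing and scaling [make_psmc_output()] text must reproduce.
#' @export
truth_trajectory <- function(truth) {
  N0 <- truth$theta0 / (4 * truth$u * truth$s)
  data.frame(years = 2 * N0 * truth$t * truth$g, Ne = N0 * truth$lambda)
}

#' Write PSMC-dialect text for a known trajectory
#'
#' Emits the RD/TR/RS/PA round blocks of PSMC output such that
#' [parse_psmc_output()] followed by [scale_trajectory()] reproduces the
#' generating trajectory. Rounds before the last are written with a flat
#' `lambda = 1` history so that last-round selection is observable.
#'
#' @param truth a [psmc_truth()] object.
#' @param n_rounds number of EM rounds to emit (blocks `RD 0 .. RD n_rounds`).
#' @param path optional file to write to.
#' @return the text as a single string (invisibly if `path` is given).
#' @export
make_psmc_output <- function(truth, n_rounds = 25L, path = NULL) {
  stopifnot(inherits(truth, "psmc_truth"))
  rho0 <- truth$theta0 / 5
  k <- seq_along(truth$t) - 1L
  block <- function(round, lambda) {
    c(sprintf("RD\t%d", round),
      sprintf("TR\t%.12g\t%.12g", truth$theta0, rho0),
      sprintf("RS\t%d\t%.12g\t%.12g", k, truth$t, lambda),
      "PA\t4+25*2+4+6 simulated", "//")
  }
  lines <- c("CC\tsimulated PSMC output",
             sprintf("MM\tn_intervals: %d", length(k)))
  for (r in seq_len(n_rounds) - 1L)
    lines <- c(lines, block(r, rep(1, length(k))))
  lines <- c(lines, block(n_rounds, truth$lambda))
  text <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(text))
  }
  text
}
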