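#' Mitochondrial annotation table
#'
#' A validated feature table for a circular genome: feature `name`, `type`
#' (PCG, tRNA, rRNA or CR), `strand` (H heavy / L light), 1-based inclusive
#' `start` and `end`, and a `wraps` flag for features crossing the origin
#' (whose `end` is recorded modulo the genome length).
#'
#' @param features data.frame with columns `name`, `type`, `strand`,
#'   `start`, `end` and optionally `wraps`.
#' @param genome_length genome length in bp.
#' @return object of class `mito_annotation` (a data.frame with a
#'   `genome_length` attribute).
#' @export
mito_annotation <- function(features, genome_length) {
  features <- as.data.frame(features)
  need <- c("name", "type", "strand", "start", "end")
  stopifnot(all(need %in% names(features)))
  if (is.null(features$wraps))
    features$wraps <- features$start > features$end
  if (anyDuplicated(features$name))
    stop("duplicate feature names: ",
         paste(unique(features$name[duplicated(features$name)]), collapse = ", "),
         call. = FALSE)
  if (!all(features$type %in% c("PCG", "tRNA", "rRNA", "CR")))
    stop("feature types must be PCG, tRNA, rRNA or CR", call. = FALSE)
  if (!all(features$strand %in% c("H", "L")))
    stop("strand must be H or L", call. = FALSE)
  bad <- features$start < 1 | features$start > genome_length |
    features$end < 1 | features$end > genome_length
  if (any(bad))
    stop("coordinates out of range for: ",
         paste(features$name[bad], collapse = ", "), call. = FALSE)
  if (any(!features$wraps & features$start > features$end))
    stop("non-wrapping features must have start <= end", call. = FALSE)
  rownames(features) <- NULL
  attr(features, "genome_length") <- as.integer(genome_length)
  class(features) <- c("mito_annotation", "data.frame")
  features
}

# Map common flat-file labels to the four census types.
normalize_feature_type <- function(type) {
  t <- tolower(type)
  ifelse(t %in% c("cds", "pcg", "gene"), "PCG",
         ifelse(t %in% c("trna"), "tRNA",
                ifelse(t %in% c("rrna"), "rRNA",
                       ifelse(t %in% c("d-loop", "dloop", "cr",
                                       "control_region", "misc_feature"),
                              "CR", type))))
}

read_annotation_tsv <- function(path, genome_length) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  df$type <- normalize_feature_type(df$type)
  df$strand <- ifelse(df$strand %in% c("-", "L", "l"), "L", "H")
  if (is.null(df$wraps)) df$wraps <- df$start > df$end
  if (is.null(genome_length)) genome_length <- max(df$start, df$end)
  mito_annotation(df[c("name", "type", "strand", "start", "end", "wraps")],
                  genome_length)
}

# Minimal GenBank flat-file feature reader: LOCUS length plus
# CDS/tRNA/rRNA/D-loop feature lines with complement() and join() for
# origin wrap, and /gene or /product qualifiers for names. No installed R
# package parses GenBank feature tables, so this dialect is read directly.
read_annotation_genbank <- function(path) {
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  genome_length <- as.integer(sub(".*?(\\d+)\\s+bp.*", "\\1", locus[1]))
  f0 <- grep("^FEATURES", lines)
  if (!length(f0)) stop("no FEATURES block in ", path, call. = FALSE)
  end_block <- grep("^(ORIGIN|//)", lines)
  end_block <- if (length(end_block)) min(end_block[end_block > f0]) else length(lines) + 1L
  block <- lines[(f0 + 1):(end_block - 1)]
  is_feat <- grepl("^\\s{5}\\S", block)
  idx <- which(is_feat)
  feats <- list()
  for (j in seq_along(idx)) {
    i <- idx[j]
    key <- sub("^\\s+(\\S+).*", "\\1", block[i])
    if (!tolower(key) %in% c("cds", "trna", "rrna", "d-loop", "misc_feature"))
      next
    loc <- sub("^\\s+\\S+\\s+", "", block[i])
    last <- if (j < length(idx)) idx[j + 1] - 1L else length(block)
    quals <- block[(i + 1):last]
    name <- grep("/(gene|product)=", quals, value = TRUE)
    name <- if (length(name))
      gsub('.*="?([^"]*)"?.*', "\\1", name[1]) else paste0(key, "_", j)
    strand <- if (grepl("complement", loc)) "L" else "H"
    nums <- as.integer(regmatches(loc, gregexpr("\\d+", loc))[[1]])
    wraps <- grepl("join", loc) && length(nums) >= 4
    feats[[length(feats) + 1]] <- data.frame(
      name = name, type = normalize_feature_type(key), strand = strand,
      start = nums[1], end = nums[length(nums)], wraps = wraps)
  }
  mito_annotation(do.call(rbind, feats), genome_length)
}

#' Read a mitochondrial annotation
#'
#' Reads either the 6-column TSV dialect (`name`, `type`, `strand`,
#' `start`, `end`, `wraps`) or a GenBank-style flat file (CDS / tRNA /
#' rRNA / D-loop features; `complement()` maps to the light strand,
#' `join()` across the origin sets the wrap flag). Coordinates are
#' normalized to 1-based inclusive.
#'
#' @param path annotation file.
#' @param genome_length genome length in bp; required for TSV files whose
#'   features do not reach the genome end.
#' @return a [mito_annotation()].
#' @export
read_annotation <- function(path, genome_length = NULL) {
  first <- readLines(path, n = 1)
  if (grepl("^LOCUS", first)) read_annotation_genbank(path)
  else read_annotation_tsv(path, genome_length)
}

#' Write a mitochondrial annotation as TSV
#'
#' @param ann a [mito_annotation()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(ann, path) {
  utils::write.table(as.data.frame(ann), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Feature census by type and strand
#'
#' @param ann a [mito_annotation()].
#' @return list with `by_type` (named counts over PCG, tRNA, rRNA, CR) and
#'   `by_strand` (named counts over H, L).
#' @export
feature_census <- function(ann) {
  types <- c("PCG", "tRNA", "rRNA", "CR")
  by_type <- setNames(integer(4), types)
  tt <- table(factor(ann$type, levels = types))
  by_type[names(tt)] <- as.integer(tt)
  by_strand <- setNames(integer(2), c("H", "L"))
  st <- table(factor(ann$strand, levels = c("H", "L")))
  by_strand[names(st)] <- as.integer(st)
  list(by_type = by_type, by_strand = by_strand)
}

# Extract a feature's sequence from the circular genome, honouring origin
# wrap and strand (light-strand features are reverse complemented).
extract_feature_seq <- function(sequence, start, end, strand = "H",
                                wraps = FALSE) {
  L <- nchar(sequence)
  s <- if (wraps)
    paste0(substr(sequence, start, L), substr(sequence, 1, end))
  else
    substr(sequence, start, end)
  if (strand == "L") revcomp(s) else s
}

CONVENTIONAL_STOPS <- c("TAA", "TAG", "AGA", "AGG")

#' Start / stop codon report for protein-coding genes
#'
#' Extracts each PCG's CDS from the circular genome (reverse complementing
#' light-strand genes and joining across the origin for wrapped features),
#' and reports the start codon, the stop codon (the trailing 1-3 nt after
#' whole codons) and its class: `conventional` for a full 3-nt stop,
#' `incomplete` for a 1-2 nt stop (T or TA, completed to TAA by
#' polyadenylation). AGA/AGG count as conventional stops under the
#' vertebrate mitochondrial code.
#'
#' @param sequence circular genome as a DNA string (heavy strand).
#' @param ann a [mito_annotation()] containing PCG features.
#' @return data.frame with `gene`, `start_codon`, `stop_codon`,
#'   `stop_class`.
#' @export
codon_report <- function(sequence, ann) {
  pcg <- ann[ann$type == "PCG", , drop = FALSE]
  if (nrow(pcg) == 0) stop("annotation contains no PCG features", call. = FALSE)
  rows <- lapply(seq_len(nrow(pcg)), function(i) {
    cds <- extract_feature_seq(sequence, pcg$start[i], pcg$end[i],
                               pcg$strand[i], pcg$wraps[i])
    n <- nchar(cds)
    if (n < 6)
      stop("CDS of ", pcg$name[i], " shorter than 6 nt", call. = FALSE)
    rem <- n %% 3L
    stop_len <- if (rem == 0L) 3L else rem
    data.frame(gene = pcg$name[i],
               start_codon = substr(cds, 1, 3),
               stop_codon = substr(cds, n - stop_len + 1L, n),
               stop_class = if (stop_len == 3L) "conventional" else "incomplete")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Base composition of a sequence
#'
#' @param sequence DNA string (non-empty).
#' @return list with `length`, `gc_percent`, `at_percent`; the two
#'   percentages sum to 100 over unambiguous bases.
#' @export
composition <- function(sequence) {
  if (!nzchar(sequence)) stop("empty sequence", call. = FALSE)
  ss <- Biostrings::DNAStringSet(sequence)
  gc <- gc_percent_of(ss)
  list(length = nchar(sequence), gc_percent = gc, at_percent = 100 - gc)
}
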