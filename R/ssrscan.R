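# Smallest q such that `motif` is q/|motif| copies of its first q bases;
# equals nchar(motif) when the motif is not a repetition of a shorter unit.
minimal_period <- function(motif) {
  p <- nchar(motif)
  for (d in seq_len(p - 1)) {
    if (p %% d == 0 && motif == strrep(substr(motif, 1, d), p %/% d))
      return(d)
  }
  p
}

DEFAULT_MIN_REPEATS <- c(`2` = 6L, `3` = 5L, `4` = 5L, `5` = 5L, `6` = 5L)

# All maximal perfect tandem candidates in one sequence (character vector
# of bases), before cross-period overlap resolution.
ssr_candidates <- function(ch, min_repeats) {
  n <- length(ch)
  valid <- ch %in% DNA_BASES
  out <- vector("list", 5)
  for (p in 2:6) {
    minrep <- min_repeats[[as.character(p)]]
    if (n < p * minrep) next
    a <- seq_len(n - p)
    m <- ch[a] == ch[a + p] & valid[a] & valid[a + p]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & (r$lengths + p) %/% p >= minrep
    if (!any(keep)) next
    st <- starts[keep]
    copies <- (r$lengths[keep] + p) %/% p
    motif <- vapply(st, function(i) paste(ch[i:(i + p - 1L)], collapse = ""), "")
    ok <- vapply(motif, minimal_period, 0L) == p
    if (!any(ok)) next
    out[[p - 1]] <- data.frame(period = p, motif = motif[ok],
                               repeats = copies[ok], start = st[ok],
                               end = st[ok] + copies[ok] * p - 1L)
  }
  do.call(rbind, out[!vapply(out, is.null, TRUE)])
}

# Cross-period overlap resolution: longer total span wins, ties to the
# smaller period, then the smaller start; losers overlapping a kept record
# are dropped. Prevents double-reporting the same locus at two periods.
resolve_overlaps <- function(cand) {
  if (is.null(cand) || nrow(cand) < 2) return(cand)
  ord <- order(-(cand$end - cand$start + 1L), cand$period, cand$start)
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ov <- keep & cand$start <= cand$end[i] & cand$end >= cand$start[i]
    keep[i] <- !any(ov)
  }
  cand[keep, , drop = FALSE]
}

#' Find perfect microsatellites (SSRs)
#'
#' Scans for maximal perfect tandem runs of motifs with period 2-6, with
#' MISA-style minimum repeat thresholds (default 6 copies for
#' dinucleotides, 5 for periods 3-6). Motifs that are repetitions of a
#' shorter unit are classified at the shorter period and mononucleotide
#' runs are never reported; partial trailing motif copies are excluded from
#' the repeat count and coordinates; any N breaks a run. Motif phase is
#' preserved (AC and CA are distinct motifs). Overlapping candidates of
#' different periods are resolved in favour of the longer span (ties: the
#' smaller period).
#'
#' @param x sequences: named character vector, `DNAStringSet`, or FASTA
#'   path. Characters other than A/C/G/T/N are an error.
#' @param min_repeats named map period -> minimum full copies, default
#'   `c("2" = 6, "3" = 5, "4" = 5, "5" = 5, "6" = 5)`.
#' @return data.frame with columns `seq_id`, `index` (1-based per
#'   sequence), `type` (`p2`..`p6`), `motif` (as it occurs), `repeats`,
#'   `start`, `end` (1-based inclusive), `size`, `ssr` (standardized form
#'   like `"(AC)6"`).
#' @export
find_ssrs <- function(x, min_repeats = DEFAULT_MIN_REPEATS) {
  seqs <- as_sequences(x)
  mr <- DEFAULT_MIN_REPEATS
  mr[names(min_repeats)] <- as.integer(min_repeats)
  res <- lapply(names(seqs), function(id) {
    ch <- seq_chars(seqs[[id]])
    if (!all(ch %in% c(DNA_BASES, "N")))
      stop("sequence '", id, "' contains non-DNA characters", call. = FALSE)
    cand <- resolve_overlaps(ssr_candidates(ch, mr))
    if (is.null(cand) || nrow(cand) == 0) return(NULL)
    cand <- cand[order(cand$start), , drop = FALSE]
    data.frame(seq_id = id, index = seq_len(nrow(cand)),
               type = paste0("p", cand$period), motif = cand$motif,
               repeats = cand$repeats, start = cand$start, end = cand$end,
               size = cand$end - cand$start + 1L,
               ssr = sprintf("(%s)%d", cand$motif, cand$repeats),
               row.names = NULL)
  })
  res <- res[!vapply(res, is.null, TRUE)]
  if (!length(res))
    return(data.frame(seq_id = character(0), index = integer(0),
                      type = character(0), motif = character(0),
                      repeats = integer(0), start = integer(0),
                      end = integer(0), size = integer(0), ssr = character(0)))
  do.call(rbind, res)
}

#' Merge neighbouring SSRs into compound records
#'
#' Consecutive perfect SSRs on the same sequence separated by at most
#' `max_interruption` bp are merged into one type-`c` record spanning all
#' constituents, with interruption sequence rendered in lowercase in the
#' standardized form (e.g. `"(AC)6tt(GA)5"`). Records not involved in a
#' merge pass through unchanged. The merged perfect constituents are kept
#' in the `"constituents"` attribute of the result for census statistics.
#'
#' @param records output of [find_ssrs()] (sorted by start within each
#'   sequence).
#' @param sequences the scanned sequences (same form as for [find_ssrs()]);
#'   if omitted, interruptions are rendered as lowercase `n`s.
#' @param max_interruption maximum interruption length in bp (default 100,
#'   the de facto standard).
#' @return data.frame in the [find_ssrs()] layout plus `n_constituents`;
#'   compound rows have `type = "c"` and `repeats = NA`.
#' @export
merge_compound <- function(records, sequences = NULL, max_interruption = 100L) {
  if (nrow(records) == 0) {
    records$n_constituents <- integer(0)
    attr(records, "constituents") <- records
    return(records)
  }
  seqs <- if (!is.null(sequences)) as_sequences(sequences)
  parts <- split(records, records$seq_id)
  merged <- lapply(parts, function(df) {
    df <- df[order(df$start), , drop = FALSE]
    gap <- c(Inf, df$start[-1] - df$end[-nrow(df)] - 1L)
    grp <- cumsum(gap > max_interruption)
    res <- lapply(split(df, grp), function(g) {
      g$n_constituents <- 1L
      if (nrow(g) == 1) return(g)
      inter <- character(nrow(g) - 1)
      for (i in seq_along(inter)) {
        len <- g$start[i + 1] - g$end[i] - 1L
        inter[i] <- if (len == 0) "" else if (is.null(seqs))
          strrep("n", len)
        else
          tolower(substr(seqs[[g$seq_id[1]]], g$end[i] + 1L, g$start[i + 1] - 1L))
      }
      form <- paste0(paste0(g$ssr[-nrow(g)], inter, collapse = ""),
                     g$ssr[nrow(g)])
      out <- g[1, , drop = FALSE]
      out$type <- "c"
      out$motif <- NA_character_
      out$repeats <- NA_integer_
      out$end <- g$end[nrow(g)]
      out$size <- out$end - out$start + 1L
      out$ssr <- form
      out$n_constituents <- nrow(g)
      attr(out, "members") <- g
      out
    })
    members <- do.call(rbind, lapply(res, function(r) attr(r, "members")))
    out <- do.call(rbind, lapply(res, function(r) { attr(r, "members") <- NULL; r }))
    attr(out, "members") <- members
    out
  })
  constituents <- do.call(rbind, lapply(merged, function(m) attr(m, "members")))
  out <- do.call(rbind, lapply(merged, function(m) { attr(m, "members") <- NULL; m }))
  out <- out[order(out$seq_id, out$start), , drop = FALSE]
  out$index <- stats::ave(out$start, out$seq_id, FUN = seq_along)
  rownames(out) <- NULL
  if (!is.null(constituents)) rownames(constituents) <- NULL
  attr(out, "constituents") <- constituents
  out
}

#' SSR census statistics
#'
#' Mirrors the standard microsatellite summary table: totals, sequence
#' counts, compound membership, density per Mb, and per-period / per-motif
#' percentage tables with motif phase preserved.
#'
#' @param records [find_ssrs()] output, or [merge_compound()] output (in
#'   which case compound membership is taken from its constituents).
#' @param sequences_examined number of sequences scanned.
#' @param total_length total scanned length in bp (> 0).
#' @return object of class `ssr_summary` with fields `sequences_examined`,
#'   `total_ssrs`, `sequences_with_ssr`,
#'   `sequences_with_more_than_one_ssr`, `compound_ssrs`, `density_per_mb`,
#'   `type_percentages` (p2..p6), `motif_percentages` (list per period).
#' @export
summarize_ssrs <- function(records, sequences_examined, total_length) {
  if (total_length <= 0) stop("total_length must be positive", call. = FALSE)
  cons <- attr(records, "constituents")
  plain <- records[records$type != "c", , drop = FALSE]
  # merged input: the full perfect set is the pass-through records plus
  # the constituents absorbed into compounds
  perfect <- if (!is.null(cons) && nrow(cons))
    rbind(plain, cons[names(plain)]) else plain
  compound_ssrs <- if (!is.null(cons) && nrow(records))
    sum(records$n_constituents[records$type == "c"]) else 0L
  per_seq <- table(perfect$seq_id)
  types <- paste0("p", 2:6)
  type_counts <- setNames(integer(5), types)
  tc <- table(perfect$type)
  type_counts[names(tc)] <- as.integer(tc)
  total <- nrow(perfect)
  type_pct <- if (total > 0) 100 * type_counts / total else type_counts * 0
  motif_pct <- lapply(setNames(types, types), function(tp) {
    sub <- perfect$motif[perfect$type == tp]
    if (!length(sub)) return(numeric(0))
    sort(100 * table(sub) / length(sub), decreasing = TRUE)
  })
  structure(list(
    sequences_examined = as.integer(sequences_examined),
    total_ssrs = total,
    sequences_with_ssr = length(per_seq),
    sequences_with_more_than_one_ssr = sum(per_seq > 1),
    compound_ssrs = as.integer(compound_ssrs),
    density_per_mb = total / (total_length / 1e6),
    type_percentages = type_pct,
    motif_percentages = motif_pct), class = "ssr_summary")
}

#' @export
print.ssr_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "SSR census\n",
    "  sequences examined:        %d\n",
    "  total SSRs:                %d\n",
    "  sequences with SSRs:       %d\n",
    "  sequences with >1 SSR:     %d\n",
    "  SSRs in compound form:     %d\n",
    "  density:                   %.2f per Mb\n"),
    x$sequences_examined, x$total_ssrs, x$sequences_with_ssr,
    x$sequences_with_more_than_one_ssr, x$compound_ssrs, x$density_per_mb))
  pct <- paste(sprintf("%s %.2f%%", names(x$type_percentages),
                       x$type_percentages), collapse = ", ")
  cat("  by period:", pct, "\n")
  invisible(x)
}

#' Write SSR records as MISA-style TSV
#'
#' @param records [find_ssrs()] or [merge_compound()] output.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ssr_tsv <- function(records, path) {
  out <- data.frame(ID = records$seq_id, `SSR nr.` = records$index,
                    `SSR type` = records$type, SSR = records$ssr,
                    size = records$size, start = records$start,
                    end = records$end, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
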