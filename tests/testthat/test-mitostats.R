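toy_annotation <- function() {
  mito_annotation(data.frame(
    name = c("geneA", "geneB", "trnX", "CR"),
    type = c("PCG", "PCG", "tRNA", "CR"),
    strand = c("H", "L", "H", "H"),
    start = c(1, 25, 50, 90),
    end = c(18, 42, 60, 10),
    wraps = c(FALSE, FALSE, FALSE, TRUE)), genome_length = 100)
}

test_that("annotation validation catches malformed tables", {
  expect_error(mito_annotation(data.frame(
    name = c("a", "a"), type = c("PCG", "PCG"), strand = c("H", "H"),
    start = c(1, 10), end = c(5, 20)), 100), "duplicate")
  expect_error(mito_annotation(data.frame(
    name = "a", type = "PCG", strand = "H", start = 5, end = 300), 100),
    "out of range")
  expect_error(mito_annotation(data.frame(
    name = "a", type = "XXX", strand = "H", start = 1, end = 9), 100),
    "types")
})

test_that("TSV annotations round-trip exactly", {
  fx <- make_mito_fixture(seed = 61)
  f <- tempfile(fileext = ".tsv")
  write_annotation_tsv(fx$annotation, f)
  back <- read_annotation(f, genome_length = nchar(fx$sequence))
  expect_equal(as.data.frame(back), as.data.frame(fx$annotation))
  expect_equal(nrow(back), 38)  # 13 + 22 + 2 + 1
})

test_that("GenBank-style flat files parse to the same census", {
  gb <- c(
    "LOCUS       synth_mt    120 bp    DNA     circular",
    "FEATURES             Location/Qualifiers",
    "     CDS             1..18",
    '                     /gene="geneA"',
    "     CDS             complement(25..42)",
    '                     /gene="geneB"',
    "     tRNA            50..60",
    '                     /product="trnX"',
    "     D-loop          join(90..120,1..10)",
    "ORIGIN",
    "//")
  f <- tempfile(fileext = ".gb")
  writeLines(gb, f)
  ann <- read_annotation(f)
  expect_equal(nrow(ann), 4)
  expect_equal(ann$strand, c("H", "L", "H", "H"))
  expect_equal(ann$type, c("PCG", "PCG", "tRNA", "CR"))
  expect_true(ann$wraps[4])
  expect_equal(attr(ann, "genome_length"), 120L)
})

test_that("feature census counts by type and strand, order-invariantly", {
  ann <- toy_annotation()
  cs <- feature_census(ann)
  expect_equal(cs$by_type, c(PCG = 2L, tRNA = 1L, rRNA = 0L, CR = 1L))
  expect_equal(cs$by_strand, c(H = 3L, L = 1L))
  expect_equal(sum(cs$by_type), nrow(ann))
  shuffled <- mito_annotation(as.data.frame(ann)[c(3, 1, 4, 2), ], 100)
  expect_equal(feature_census(shuffled), cs)
  empty <- mito_annotation(data.frame(name = character(0), type = character(0),
                                      strand = character(0), start = integer(0),
                                      end = integer(0)), 100)
  expect_equal(sum(feature_census(empty)$by_type), 0)
})

test_that("codon extraction honours strand on an 18-nt toy CDS", {
  # hand-built: geneA forward ATGAAACCCGGGTTTTAG at 1..18;
  # geneB is ATGTCTCGAATCGGCTAA placed as its reverse complement at 25..42
  cdsB <- "ATGTCTCGAATCGGCTAA"
  rcB <- "TTAGCCGATTCGAGACAT"  # manual reverse complement
  genome <- paste0("ATGAAACCCGGGTTTTAG", "AGCTGA", rcB,
                   paste(rep("C", 48), collapse = ""),
                   "GGGGGGGGGG")
  rep <- codon_report(genome, toy_annotation())
  expect_equal(rep$start_codon[rep$gene == "geneA"], "ATG")
  expect_equal(rep$stop_codon[rep$gene == "geneA"], "TAG")
  expect_equal(rep$start_codon[rep$gene == "geneB"], "ATG")
  expect_equal(rep$stop_codon[rep$gene == "geneB"], "TAA")
  expect_equal(rep$stop_class[1:2], c("conventional", "conventional"))
})

test_that("incomplete stops are classified by trailing length", {
  # CDS length 19 = 6 codons + 1: bare T stop
  ann <- mito_annotation(data.frame(name = "g", type = "PCG", strand = "H",
                                    start = 1, end = 19), 40)
  genome <- paste0("ATG", strrep("AAA", 5), "T", strrep("G", 21))
  rep <- codon_report(genome, ann)
  expect_equal(rep$stop_codon, "T")
  expect_equal(rep$stop_class, "incomplete")
  ann2 <- mito_annotation(data.frame(name = "g", type = "PCG", strand = "H",
                                     start = 1, end = 20), 40)
  genome2 <- paste0("ATG", strrep("AAA", 5), "TA", strrep("G", 20))
  expect_equal(codon_report(genome2, ann2)$stop_codon, "TA")
  short <- mito_annotation(data.frame(name = "g", type = "PCG", strand = "H",
                                      start = 1, end = 4), 40)
  expect_error(codon_report(genome, short), "shorter than 6")
})

test_that("wrapped features extract the same sequence as a rotated genome", {
  fx <- make_mito_fixture(seed = 62)
  ann <- fx$annotation
  L <- attr(ann, "genome_length")
  wrapped <- ann[ann$wraps, , drop = FALSE]
  expect_equal(nrow(wrapped), 1)  # the control region spans the origin
  got <- gsurvey:::extract_feature_seq(fx$sequence, wrapped$start,
                                       wrapped$end, wrapped$strand, TRUE)
  # rotate the genome so the feature is contiguous, then extract plainly
  rot <- paste0(substr(fx$sequence, wrapped$start, L),
                substr(fx$sequence, 1, wrapped$start - 1))
  expect_equal(got, substr(rot, 1, wrapped$end + L - wrapped$start + 1))
})

test_that("start codons agree with independent Biostrings extraction", {
  fx <- make_mito_fixture(seed = 63)
  rep <- codon_report(fx$sequence, fx$annotation)
  pcg <- fx$annotation[fx$annotation$type == "PCG", ]
  dna <- Biostrings::DNAString(fx$sequence)
  for (i in seq_len(nrow(pcg))) {
    expect_false(pcg$wraps[i])
    cds <- Biostrings::subseq(dna, pcg$start[i], pcg$end[i])
    if (pcg$strand[i] == "L") cds <- Biostrings::reverseComplement(cds)
    expect_identical(as.character(Biostrings::subseq(cds, 1, 3)),
                     rep$start_codon[rep$gene == pcg$name[i]])
    # first codon of the translated CDS corresponds to the reported start
    aa <- Biostrings::translate(
      Biostrings::subseq(cds, 1, 3 * (length(cds) %/% 3)),
      genetic.code = Biostrings::getGeneticCode("2"))
    expect_identical(as.character(Biostrings::subseq(aa, 1, 1)), "M")
  }
})

test_that("base composition splits GC and AT over unambiguous bases", {
  expect_equal(composition(strrep("A", 10))$gc_percent, 0)
  expect_equal(composition(strrep("A", 10))$at_percent, 100)
  expect_equal(composition("ATGC")$gc_percent, 50)
  cmp <- composition(random_dna(5000, seed = 64))
  expect_equal(cmp$gc_percent + cmp$at_percent, 100)
  expect_error(composition(""), "empty")
})
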