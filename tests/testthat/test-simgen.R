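test_that("parameter validation rejects out-of-range simulation settings", {
  expect_error(sim_params(0), "positive")
  expect_error(sim_params(1000, het_rate = 0.2), "het_rate")
  expect_error(sim_params(1000, repeat_fraction = 0.95), "repeat_fraction")
  expect_error(sim_params(100, repeat_unit_length = 500), "repeat_unit_length")
})

test_that("zero heterozygosity gives identical haplotypes", {
  g <- simulate_diploid_genome(sim_params(5000, het_rate = 0,
                                          repeat_fraction = 0, seed = 3))
  expect_identical(g$hap1, g$hap2)
  expect_length(g$het_sites, 0)
})

test_that("het_sites exactly enumerate haplotype mismatches", {
  g <- simulate_diploid_genome(sim_params(20000, het_rate = 0.01,
                                          repeat_fraction = 0.2, seed = 5))
  a <- strsplit(g$hap1, "")[[1]]
  b <- strsplit(g$hap2, "")[[1]]
  expect_identical(which(a != b), g$het_sites)
  expect_equal(nchar(g$hap1), nchar(g$hap2))
})

test_that("heterozygous site count behaves binomially", {
  # spec example at the study scale
  g <- simulate_diploid_genome(sim_params(500000, het_rate = 0.005,
                                          repeat_fraction = 0, seed = 11))
  sd3 <- 3 * sqrt(500000 * 0.005 * 0.995)
  expect_lt(abs(length(g$het_sites) - 500000 * 0.005), sd3)
  # 4-SD property over 20 seeds at a smaller size
  L <- 20000; h <- 0.005
  sd4 <- 4 * sqrt(L * h * (1 - h))
  for (s in 1:20) {
    g <- simulate_diploid_genome(sim_params(L, het_rate = h,
                                            repeat_fraction = 0, seed = s))
    expect_lt(abs(length(g$het_sites) - L * h), sd4)
  }
})

test_that("identical parameters and seed give byte-identical output", {
  p <- sim_params(15000, het_rate = 0.005, repeat_fraction = 0.3, seed = 8)
  g1 <- simulate_diploid_genome(p)
  g2 <- simulate_diploid_genome(p)
  expect_identical(g1, g2)
  r1 <- simulate_reads(g1, coverage = 5, read_length = 100,
                       error_rate = 0.002, seed = 9)
  r2 <- simulate_reads(g2, coverage = 5, read_length = 100,
                       error_rate = 0.002, seed = 9)
  expect_identical(r1, r2)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(r1, f1); write_fastq(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
  a1 <- tempfile(fileext = ".fa")
  write_fasta(g1, a1)
  expect_identical(unname(gsurvey:::as_sequences(a1)),
                   c(g1$hap1, g1$hap2))
})

test_that("read count follows the coverage formula and lengths are uniform", {
  g <- simulate_diploid_genome(sim_params(9000, het_rate = 0,
                                          repeat_fraction = 0, seed = 2))
  rs <- simulate_reads(g, coverage = 30, read_length = 150, error_rate = 0,
                       seed = 2)
  expect_equal(nrow(rs$reads), round(30 * 9000 / 150))
  expect_true(all(nchar(rs$reads$seq) == 150))
  expect_error(simulate_reads(g, coverage = 0), "coverage")
  expect_error(simulate_reads(g, coverage = 1, read_length = 10000),
               "read_length")
})

test_that("error-free reads are exact substrings of a haplotype or its revcomp", {
  g <- simulate_diploid_genome(sim_params(8000, het_rate = 0,
                                          repeat_fraction = 0, seed = 4))
  rs <- simulate_reads(g, coverage = 2, read_length = 120, error_rate = 0,
                       seed = 4)
  for (s in head(rs$reads$seq, 40)) {
    expect_true(grepl(s, g$hap1, fixed = TRUE) ||
                  grepl(revcomp(s), g$hap1, fixed = TRUE))
  }
})

test_that("repeat construction doubles k-mer depth over the duplicated fraction", {
  g <- simulate_diploid_genome(sim_params(60000, het_rate = 0,
                                          repeat_fraction = 0.4,
                                          repeat_unit_length = 400, seed = 6))
  h <- count_kmers(c(g = g$hap1), 19)
  # genomic k-mer multiplicities: ~40% of volume at depth >= 2
  high <- sum(as.numeric(h$depth[h$depth >= 2]) * h$species[h$depth >= 2])
  # overlapping source blocks shave a little off the covered fraction
  expect_lt(abs(high / n_kmer(h) - 0.4), 0.08)
})

test_that("planted SSR truth is recovered by the scanner", {
  base <- random_dna(50000, seed = 21)
  spec <- data.frame(motif = c("AC", "AAT", "AAAT"),
                     repeats = c(8, 6, 5), copies = c(10, 5, 5))
  pl <- plant_ssrs(base, spec, seed = 22)
  found <- find_ssrs(c(chr = pl$sequence))
  expect_true(all(ssr_key(pl$truth) %in% ssr_key(found)))
})

test_that("plant_ssrs validates motifs and handles empty and overfull specs", {
  out <- plant_ssrs("ACGTACGTAC", NULL)
  expect_identical(out$sequence, "ACGTACGTAC")
  expect_equal(nrow(out$truth), 0)
  expect_error(plant_ssrs(random_dna(1000, 1),
                          data.frame(motif = "ATAT", repeats = 5, copies = 1)),
               "shorter unit")
  expect_error(plant_ssrs(random_dna(200, 1),
                          data.frame(motif = "AC", repeats = 8, copies = 50)),
               "too short")
})

test_that("mito fixture has the canonical gene complement and planted codons", {
  fx <- make_mito_fixture(seed = 14)
  cs <- feature_census(fx$annotation)
  expect_equal(cs$by_type, c(PCG = 13L, tRNA = 22L, rRNA = 2L, CR = 1L))
  expect_equal(cs$by_strand[["L"]], 9L)
  rep <- codon_report(fx$sequence, fx$annotation)
  expect_equal(rep$start_codon[rep$gene == "COI"], "GTG")
  expect_equal(rep$start_codon[rep$gene == "ATP6"], "ATA")
  expect_equal(sum(rep$start_codon == "ATG"), 11)
  expect_equal(sum(rep$stop_class == "conventional"), 7)
  # at least one CDS of length = 1 mod 3 ending in a bare T
  lens <- with(as.data.frame(fx$annotation)[fx$annotation$type == "PCG", ],
               ifelse(wraps, end + attr(fx$annotation, "genome_length") - start + 1,
                      end - start + 1))
  expect_true(any(lens %% 3 == 1 & rep$stop_codon == "T"))
  expect_gt(composition(fx$sequence)$length, 16000)
  expect_lt(composition(fx$sequence)$length, 17000)
})

test_that("PSMC text generator writes flat histories as lambda 1", {
  tr <- psmc_truth(0.02, t = c(0, 0.5, 1), lambda = c(1, 1, 1))
  txt <- make_psmc_output(tr, n_rounds = 2)
  last <- sub(".*RD\t2\n", "", txt)
  rs <- grep("^RS", strsplit(last, "\n")[[1]], value = TRUE)
  lam <- vapply(strsplit(rs, "\t"), function(p) as.numeric(p[4]), 0)
  expect_equal(lam, c(1, 1, 1))
  expect_error(psmc_truth(0.02, t = c(0, 1, 1), lambda = c(1, 1, 1)),
               "strictly increasing")
  expect_error(psmc_truth(0.02, t = c(0, 1, 2), lambda = c(1, -1, 1)),
               "positive")
})
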