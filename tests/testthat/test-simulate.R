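# Toy genomes, paired-end read simulation with ground truth, pulldown
# libraries with planted enrichment.

test_that("toy genomes are deterministic under a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  spec <- toy_genome_spec(seed = 21, chrom_length = 60000L,
                          catalog = default_repeat_catalog()[c(1, 7), ])
  write_toy_genome(build_toy_genome(spec), d1)
  write_toy_genome(build_toy_genome(spec), d2)
  for (f in c("genome.fa", "repeats.bed", "grouping.tsv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # different seed, different genome
  spec2 <- spec; spec2$seed <- 22L
  d3 <- withr::local_tempdir()
  write_toy_genome(build_toy_genome(spec2), d3)
  expect_false(identical(readLines(file.path(d1, "genome.fa")),
                         readLines(file.path(d3, "genome.fa"))))
})

test_that("planted annotation matches the placements exactly", {
  cat1 <- data.frame(name = "L1HS", family = "L1", cls = "LINE",
                     length = 300L, copies = 1L, divergence = 0)
  tg <- build_toy_genome(toy_genome_spec(n_chroms = 1L,
                                         chrom_length = 5000L,
                                         catalog = cat1, seed = 5))
  expect_length(tg$annotation, 1L)
  expect_equal(width(tg$annotation), 300L)
  # zero-divergence copy is the consensus (up to strand)
  seq <- renrich:::.extract_windows(tg$genome,
                                    as.character(seqnames(tg$annotation)),
                                    start(tg$annotation),
                                    end(tg$annotation))
  if (as.character(strand(tg$annotation)) == "-")
    seq <- reverseComplement(seq)
  expect_equal(as.character(seq), unname(tg$consensus["L1HS"]))

  # empty catalog -> background-only genome, empty annotation
  cat0 <- cat1[0, ]
  tg0 <- build_toy_genome(toy_genome_spec(n_chroms = 1L,
                                          chrom_length = 2000L,
                                          catalog = cat0, seed = 5))
  expect_length(tg0$annotation, 0L)
  expect_equal(sum(width(tg0$genome)), 2000L)

  # BED12 round trip: one single-block row per planted copy
  d <- withr::local_tempdir()
  fx <- write_toy_genome(tg, d)
  parsed <- parse_bed12(fx["bed"])
  expect_equal(start(parsed$models), start(tg$annotation))
  expect_equal(end(parsed$models), end(tg$annotation))

  # an oversized catalog fails placement
  big <- data.frame(name = "X", family = "X", cls = "X",
                    length = 1000L, copies = 10L, divergence = 0)
  expect_error(build_toy_genome(toy_genome_spec(
    n_chroms = 1L, chrom_length = 4000L, catalog = big, seed = 1)),
    "placement")
})

test_that("zero-error reads match the genome at their truth coordinates", {
  tg <- shared_toy_genome()
  sim <- simulate_reads(tg, sim_spec(n_pairs = 300L, error_rate = 0,
                                     seed = 8))
  reads <- renrich:::.truth_to_reads(tg$genome, sim$truth, sim$spec)
  ref <- renrich:::.extract_windows(tg$genome, sim$truth$chrom,
                                    sim$truth$start, sim$truth$end)
  minus <- sim$truth$strand == "-"
  ref[minus] <- reverseComplement(ref[minus])
  expect_identical(as.character(reads), as.character(ref))
  # every read has exactly one truth record, both mates present
  expect_equal(nrow(sim$truth), 2L * sim$n_pairs)
  expect_equal(as.integer(table(sim$truth$mate)), c(300L, 300L))
})

test_that("fragment counts and lengths follow the stated model", {
  tg <- shared_toy_genome()
  g <- sum(width(tg$genome))
  sim <- simulate_reads(tg, sim_spec(coverage = 1, error_rate = 0,
                                     seed = 13))
  expected_pairs <- g / (2 * 150)
  expect_equal(sim$n_pairs, round(expected_pairs))
  fl <- abs(sim$truth$tlen[sim$truth$mate == 1L])
  # CLT check on the Normal(450, 30) fragment model
  expect_lt(abs(mean(fl) - 450), 3 * 30 / sqrt(length(fl)))
  expect_true(all(fl >= 150))
  # substitution errors appear at roughly the requested rate
  sim_e <- simulate_reads(tg, sim_spec(n_pairs = 500L, error_rate = 0.01,
                                       seed = 14))
  reads <- renrich:::.truth_to_reads(tg$genome, sim_e$truth, sim_e$spec)
  ref <- renrich:::.extract_windows(tg$genome, sim_e$truth$chrom,
                                    sim_e$truth$start, sim_e$truth$end)
  minus <- sim_e$truth$strand == "-"
  ref[minus] <- reverseComplement(ref[minus])
  mism <- sum(mapply(function(a, b) sum(strsplit(a, "")[[1]] !=
                                          strsplit(b, "")[[1]]),
                     as.character(reads[1:200]), as.character(ref[1:200])))
  rate <- mism / (200 * 150)
  expect_gt(rate, 0.005); expect_lt(rate, 0.02)
})

test_that("FASTQ and truth-SAM outputs are valid and seed-stable", {
  tg <- shared_toy_genome()
  d <- withr::local_tempdir()
  run <- function(dir) {
    simulate_reads(tg, sim_spec(n_pairs = 200L, error_rate = 0.001,
                                seed = 17),
                   fastq_prefix = file.path(dir, "sim"),
                   sam = file.path(dir, "truth.sam"), gz = FALSE)
  }
  dir.create(file.path(d, "a")); dir.create(file.path(d, "b"))
  s1 <- run(file.path(d, "a"))
  s2 <- run(file.path(d, "b"))
  expect_identical(readLines(s1$fastq[1]), readLines(s2$fastq[1]))
  expect_identical(readLines(s1$sam), readLines(s2$sam))
  fq <- readLines(s1$fastq[1])
  expect_equal(length(fq), 4L * 200L)
  expect_true(all(nchar(fq[seq(2, length(fq), by = 4)]) == 150L))
  # the truth SAM is a valid alignment file for the counting module and
  # reproduces the direct truth assignment
  aln <- stream_primary(s1$sam)
  expect_length(aln, 400L)
  ct <- count_reads(aln, tg$annotation)
  ref <- assign_truth(s1, tg$annotation)
  expect_identical(ct$counts, ref$counts)
})

test_that("pulldown sampling realises the renormalized enrichment algebra", {
  tg <- shared_toy_genome()
  emap <- c(ERV1 = 4)
  pd <- simulate_pulldown(tg, enrichment_map = emap,
                          spec = sim_spec(n_pairs = 30000L, seed = 19))
  # fragment-level share of the enriched family
  frag_share <- function(sim) {
    m1 <- sim$truth[sim$truth$mate == 1L, ]
    frags <- GRanges(m1$chrom, IRanges(m1$start, m1$start + m1$tlen - 1L))
    sel <- tg$annotation[tg$annotation$family == "ERV1"]
    mean(countOverlaps(frags, sel, ignore.strand = TRUE) > 0)
  }
  q <- frag_share(pd$input)
  p_chip <- frag_share(pd$chip)
  expected <- 4 * q / (1 + 3 * q)
  # binomial sampling tolerance at n = 30000
  expect_lt(abs(p_chip - expected), 4 * sqrt(expected * (1 - expected) /
                                               30000))
  # factor 1 everywhere is plain uniform sampling
  pd_null <- simulate_pulldown(tg, enrichment_map = c(ERV1 = 1),
                               spec = sim_spec(n_pairs = 5000L, seed = 23))
  expect_lt(abs(frag_share(pd_null$chip) - frag_share(pd_null$input)),
            4 * sqrt(q * (1 - q) / 5000) + 0.01)
  expect_error(simulate_pulldown(tg, enrichment_map = c(NotAFamily = 2),
                                 spec = sim_spec(n_pairs = 10L, seed = 1)),
               "unknown family")
  expect_error(simulate_pulldown(tg, enrichment_map = c(ERV1 = -1),
                                 spec = sim_spec(n_pairs = 10L, seed = 1)),
               "> 0")
})

test_that("planted depletion is recovered end to end", {
  tg <- shared_toy_genome()
  counts <- list()
  for (rep in 1:2) {
    pd <- simulate_pulldown(tg, enrichment_map = c(ERV1 = 0.25),
                            spec = sim_spec(n_pairs = 20000L,
                                            seed = 30L + rep))
    counts[[paste0("chip", rep)]] <- assign_truth(pd$chip, tg$annotation)
    counts[[paste0("input", rep)]] <- assign_truth(pd$input, tg$annotation)
  }
  norm <- lapply(counts, normalize_counts)
  fam <- summarize_families(norm$chip1, norm$input1, norm$chip2,
                            norm$input2, tg$grouping)
  erv <- fam[fam$family == "ERV1", ]
  expect_lt(erv$mean, 0.5)
  expect_gt(erv$mean, 0.1)
})
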