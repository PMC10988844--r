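# Normalization, ratios, two-replicate statistic, FDR adjustment, family
# summaries.

mk_counts <- function(counts, lib) {
  structure(list(counts = counts, library_size = lib,
                 total_assigned = sum(counts)), class = "re_counts")
}

test_that("pseudocounted densities follow the 0.1 / library-size rule", {
  ct <- mk_counts(c(A = 0L, B = 100L), 1e6)
  nt <- normalize_counts(ct)
  expect_equal(unname(nt$density["A"]), 1e-7)
  expect_equal(unname(nt$density["B"]), 1e-4)
  expect_true(all(nt$density > 0))
  expect_error(normalize_counts(mk_counts(c(A = 0L), 0)), "empty library")

  # algebraic identity on a non-overlapping toy annotation:
  # sum(density) == total_assigned/lib + n_zero * 0.1 / lib
  set.seed(3)
  cn <- c(A = 17L, B = 0L, C = 5L, D = 0L)
  nt2 <- normalize_counts(mk_counts(cn, 1000))
  expect_equal(sum(nt2$density), sum(cn) / 1000 + 2 * 0.1 / 1000)
})

test_that("enrichment ratios are finite and validate name sets", {
  lib <- 1e6
  chip <- normalize_counts(mk_counts(c(A = 100L, B = 0L), lib))
  inp <- normalize_counts(mk_counts(c(A = 100L, B = 10L), lib))
  r <- enrichment_ratio(chip, inp)
  expect_equal(unname(r["A"]), 1.0)
  expect_equal(unname(r["B"]), 0.01)  # 0.1 / 10 at equal library sizes
  chip2 <- normalize_counts(mk_counts(c(A = 200L, B = 10L), lib))
  expect_equal(unname(enrichment_ratio(chip2, inp)["A"]), 2.0)

  bad <- normalize_counts(mk_counts(c(A = 1L, C = 2L), lib))
  expect_error(enrichment_ratio(chip, bad), "C")
})

test_that("two-replicate statistic reproduces hand-derived cases", {
  st <- replicate_stats(c(x = 2), c(x = 4))
  expect_equal(st$mean, 3)
  expect_equal(st$sd, 1)  # population SD of {2, 4}
  expect_equal(st$z, 2)
  # upper-tail standard normal via the erfc identity as oracle
  expect_equal(st$p, pracma::erfc(2 / sqrt(2)) / 2, tolerance = 1e-12)

  # no deviation from 1: flagged, p reported as 0.5
  st2 <- replicate_stats(c(x = 1), c(x = 1))
  expect_equal(st2$p, 0.5)
  expect_true(st2$degenerate_sd)
  # identical ratios away from 1: z infinite, p zero, flagged
  st3 <- replicate_stats(c(x = 0.5), c(x = 0.5))
  expect_equal(st3$p, 0)
  expect_true(is.infinite(st3$z))
  expect_true(st3$degenerate_sd)
  # limit behaviour: shrinking spread drives p to 0
  eps <- 10^-(1:6)
  ps <- vapply(eps, function(e)
    replicate_stats(c(x = 0.5), c(x = 0.5 + e))$p, numeric(1))
  expect_true(all(diff(ps) <= 0))  # pnorm underflows to exactly 0 eventually
  expect_lt(ps[length(ps)], 1e-10)
})

test_that("FDR adjustment applies floor, stable ranking and cap", {
  # floor applies before ranking
  adj <- fdr_adjust(c(1e-20, 0.5), N = 2)
  expect_equal(adj[1], 1e-16 * 2 / 1)
  # worked example: (0.01, 0.02, 0.03, 0.04) with N = 4 -> all 0.04
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # single value, k = N = 1
  expect_equal(fdr_adjust(0.5), 0.5)
  expect_error(fdr_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  # opt-in monotone BH equals stats::p.adjust
  p <- c(0.04, 0.01, 0.3, 0.9)
  expect_equal(fdr_adjust(p, method = "bh"), p.adjust(p, "BH"))
})

test_that("FDR adjustment matches the independent oracle on random vectors", {
  set.seed(77)
  for (i in 1:1000) {
    n <- sample(1:100, 1L)
    p <- runif(n)^sample(1:3, 1L)
    if (i %% 7 == 0) p[sample(n, 1L)] <- 10^-runif(1, 16, 30)  # floor hits
    if (i %% 5 == 0 && n > 3) p[1:3] <- p[4 %% n + 1]          # ties
    nm <- paste0("re", seq_len(n))
    expect_equal(fdr_adjust(p, names = nm), oracle_fdr(p, names = nm))
  }
})

test_that("ratios and statistics are invariant to library rescaling", {
  set.seed(12)
  cn <- setNames(rpois(50, 40) + 1L, paste0("re", 1:50))
  ci <- setNames(rpois(50, 40) + 1L, paste0("re", 1:50))
  st <- function(k) {
    chip <- normalize_counts(mk_counts(cn * k, 1e5 * k))
    inp <- normalize_counts(mk_counts(ci, 1e5))
    chip2 <- normalize_counts(mk_counts(ci * 2L, 2e5))
    replicate_stats(enrichment_ratio(chip, inp),
                    enrichment_ratio(chip2, normalize_counts(
                      mk_counts(ci, 1e5))))
  }
  expect_equal(st(1L)[c("mean", "sd", "z", "p")],
               st(10L)[c("mean", "sd", "z", "p")])
})

test_that("family summaries pool member densities over the group size", {
  lib <- 1e5
  side <- data.frame(name = c("A1", "A2", "B1"),
                     family = c("FamA", "FamA", "FamB"),
                     class = "X")
  g <- build_grouping(sidecar = side)
  mkn <- function(a1, a2, b1)
    normalize_counts(mk_counts(c(A1 = a1, A2 = a2, B1 = b1), lib))
  c1 <- mkn(200L, 100L, 50L); i1 <- mkn(100L, 100L, 50L)
  c2 <- mkn(220L, 90L, 50L); i2 <- mkn(110L, 95L, 50L)
  fam <- summarize_families(c1, i1, c2, i2, g)
  a <- fam[fam$family == "FamA", ]
  # family density is (d1 + d2) / group size
  expect_equal(a$dens_chip1, (200 + 100) / lib / 2)
  expect_equal(a$enr1, (200 + 100) / (100 + 100))
  # a singleton family equals its member's row
  b <- fam[fam$family == "FamB", ]
  expect_equal(b$enr1, 1)
  expect_equal(b$dens_chip1, 50 / lib)
  # member order does not matter
  g_perm <- build_grouping(sidecar = side[c(3, 1, 2), ])
  fam_perm <- summarize_families(c1, i1, c2, i2, g_perm)
  expect_equal(fam, fam_perm)
})

test_that("statistic calibration agrees with a Monte-Carlo oracle under its own null", {
  # chip == input sampling, 300 names with ample counts: the fraction of
  # names with p <= 0.05 must match an independent resampling of the same
  # formula (the statistic's null is heavy-tailed, so this fraction is far
  # from 0.05 by construction; what we check is implementation agreement).
  set.seed(31)
  n_names <- 300L
  lam <- runif(n_names, 50, 500)
  draw_frac <- function() {
    e1 <- rpois(n_names, lam) / rpois(n_names, lam)
    e2 <- rpois(n_names, lam) / rpois(n_names, lam)
    ok <- is.finite(e1) & is.finite(e2) & e1 > 0 & e2 > 0
    st <- replicate_stats(setNames(e1[ok], paste0("r", which(ok))),
                          setNames(e2[ok], paste0("r", which(ok))))
    mean(st$p <= 0.05)
  }
  frac_impl <- mean(replicate(20, draw_frac()))
  # oracle: direct transcription of the formula in a loop
  oracle_frac <- function() {
    hits <- 0L; tot <- 0L
    e1 <- rpois(n_names, lam) / rpois(n_names, lam)
    e2 <- rpois(n_names, lam) / rpois(n_names, lam)
    for (j in seq_len(n_names)) {
      if (!is.finite(e1[j]) || !is.finite(e2[j])) next
      m <- (e1[j] + e2[j]) / 2
      s <- sqrt(((e1[j] - m)^2 + (e2[j] - m)^2) / 2)
      if (s == 0) next
      z <- abs(m - 1) / s
      p <- 1 - pnorm(z)
      tot <- tot + 1L
      if (p <= 0.05) hits <- hits + 1L
    }
    hits / tot
  }
  frac_orc <- mean(replicate(20, oracle_frac()))
  expect_equal(frac_impl, frac_orc, tolerance = 0.05)
})

test_that("enrichment tables assemble, adjust and round-trip deterministically", {
  side <- data.frame(name = c("A1", "A2", "B1"),
                     family = c("FamA", "FamA", "FamB"), class = "X")
  g <- build_grouping(sidecar = side)
  mk <- function(a1, a2, b1) mk_counts(c(A1 = a1, A2 = a2, B1 = b1), 1e4)
  tab <- enrichment_table(mk(40L, 10L, 5L), mk(10L, 10L, 5L),
                          mk(44L, 11L, 5L), mk(11L, 10L, 5L), g)
  expect_s3_class(tab, "re_enrichment")
  expect_equal(tab$name, sort(tab$name))
  expect_equal(tab$log2_mean, log2(tab$mean))
  expect_true(all(tab$p_fdr >= pmax(tab$p, 1e-16) - 1e-18))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_enrichment_table(tab, f1)
  write_enrichment_table(tab, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read.table(f1, header = TRUE, sep = "\t")
  expect_equal(back$mean, tab$mean)
  expect_equal(nrow(back), 3L)
})
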