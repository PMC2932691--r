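test_that("window sizes follow the sqrt(2) ladder capped at the chromosome", {
  expect_equal(window_sizes(8), c(3, 4, 6, 8))
  expect_equal(window_sizes(3), 3)
  s100 <- window_sizes(100)
  expect_equal(s100[length(s100)], 100)
  expect_equal(s100, c(3, 4, 6, 8, 12, 17, 24, 34, 48, 68, 96, 100))
  expect_true(all(diff(window_sizes(1000)) > 0))
  expect_error(window_sizes(2))
})

test_that("window t-tests agree with the reference t-test", {
  # hand-checked example: t = mean/(sd/sqrt(n)) = 3.4641, df 2
  w <- c(0.5, 1.0, 1.5)
  sc <- scan_chromosome(w, sizes = 3)
  expect_equal(sc$mean, 1.0)
  expect_equal(sc$median, 1.0)
  tt <- t.test(w, mu = 0)
  expect_equal(sc$p_value, tt$p.value, tolerance = 1e-10)
  expect_equal(unname(tt$statistic), 3.4641, tolerance = 1e-4)
  expect_equal(sc$p_value, 0.0742, tolerance = 1e-3)

  # every window of every size matches stats::t.test on random data
  set.seed(11)
  x <- rnorm(40)
  sc <- scan_chromosome(x, sizes = window_sizes(40))
  for (i in sample(nrow(sc), 25)) {
    win <- x[(sc$start_index[i] + 1):sc$end_index[i]]
    expect_equal(sc$p_value[i], t.test(win, mu = 0)$p.value,
                 tolerance = 1e-10)
    expect_equal(sc$median[i], median(win), tolerance = 1e-12)
  }
})

test_that("zero-variance windows use the documented p-value conventions", {
  sc0 <- scan_chromosome(c(0, 0, 0), sizes = 3)
  expect_equal(sc0$p_value, 1)
  sc1 <- scan_chromosome(c(1, 1, 1), sizes = 3)
  expect_equal(sc1$p_value, .Machine$double.xmin)
})

test_that("genome randomization permutes values without changing the multiset", {
  set.seed(12)
  x <- rnorm(500)
  xp <- randomize_genome(x, seed = 13)
  expect_equal(sort(xp), sort(x))
  expect_equal(mean(xp), mean(x))
  expect_equal(var(xp), var(x))
  expect_identical(randomize_genome(x, seed = 13), xp)
  expect_false(identical(xp, x))
})

test_that("PEP is the null-to-observed density ratio, capped and monotone", {
  # a stratum where observed duplicates the null exactly -> pep 1
  obs <- data.frame(size = 10, p_value = seq(0.05, 0.95, by = 0.01))
  null_p <- list(obs$p_value, obs$p_value)
  pep <- pep_transform(obs, null_p, n_bins = 10)
  expect_true(all(pep$pep_obs == 1))

  # observed density 10x the null in the low-p bins -> pep ~0.1 there
  obs2 <- data.frame(size = 10,
                     p_value = c(rep(1e-4, 200), runif(200, 0.5, 1)))
  nul2 <- replicate(4, c(rep(1e-4, 20), runif(380, 0.5, 1)),
                    simplify = FALSE)
  pep2 <- pep_transform(obs2, nul2, n_bins = 5)
  lowp <- pep2$pep_obs[obs2$p_value == 1e-4]
  expect_equal(unique(lowp), 0.1, tolerance = 0.02)

  # monotone: pep never increases as p decreases, within a size stratum
  set.seed(14)
  obs3 <- data.frame(size = 10, p_value = runif(400)^2)
  nul3 <- replicate(5, runif(400), simplify = FALSE)
  pep3 <- pep_transform(obs3, nul3)
  o <- order(obs3$p_value)
  expect_true(all(diff(pep3$pep_obs[o]) >= -1e-12))

  # on pure-null data the average pep is near 1
  set.seed(15)
  obs4 <- data.frame(size = 10, p_value = runif(2000))
  nul4 <- replicate(10, runif(2000), simplify = FALSE)
  pep4 <- pep_transform(obs4, nul4)
  expect_gt(mean(pep4$pep_obs), 0.85)
})

test_that("the permutation FDR threshold behaves at the extremes", {
  set.seed(16)
  pep_obs <- runif(500)
  pep_null <- matrix(runif(5000), ncol = 10)
  # fdr 0 yields an empty significant set
  thr0 <- significance_threshold(pep_obs, pep_null, fdr = 0)
  expect_false(any(thr0$significant))
  # observed indistinguishable from null: at most a trace passes at 2%
  thr <- significance_threshold(pep_obs, pep_null, fdr = 0.02)
  expect_lte(sum(thr$significant), 0.02 * 500 + 1)
  # clear signal: low observed peps against a flat null are accepted
  pep_obs2 <- c(rep(0.001, 100), runif(400, 0.5, 1))
  thr2 <- significance_threshold(pep_obs2, pep_null, fdr = 0.02)
  expect_true(all(thr2$significant[1:100]))
  expect_lte(thr2$fdr_at_cutoff, 0.02)
})

test_that("profile construction applies the max-deviation and tie-break rules", {
  gene_order <- data.frame(gene = sprintf("g%02d", 1:50),
                           chromosome = "chr1")
  one <- data.frame(chromosome = "chr1", start_index = 10L,
                    end_index = 30L, size = 20L, median = 0.9)
  v <- build_profile(one, gene_order)
  expect_equal(as.numeric(v), c(rep(0, 10), rep(0.9, 20), rep(0, 20)))

  # overlapping windows: larger |median| wins where they intersect
  two <- rbind(one, data.frame(chromosome = "chr1", start_index = 20L,
                               end_index = 45L, size = 25L, median = -0.2))
  v2 <- as.numeric(build_profile(two, gene_order))
  expect_equal(v2[21:30], rep(0.9, 10))   # |0.9| beats |-0.2|
  expect_equal(v2[31:45], rep(-0.2, 15))
  # tie on |median|: the shorter window wins
  tie <- data.frame(chromosome = "chr1",
                    start_index = c(0L, 5L), end_index = c(40L, 15L),
                    size = c(40L, 10L), median = c(0.5, -0.5))
  v3 <- as.numeric(build_profile(tie, gene_order))
  expect_equal(v3[6:15], rep(-0.5, 10))
  expect_equal(v3[1:5], rep(0.5, 5))

  # idempotence and monotonicity
  expect_equal(build_profile(two, gene_order), build_profile(two, gene_order))
  more <- rbind(two, data.frame(chromosome = "chr1", start_index = 46L,
                                end_index = 50L, size = 4L, median = 0.1))
  v4 <- as.numeric(build_profile(more, gene_order))
  expect_true(all(v4[v2 != 0] != 0))

  # empty significant set: all-zero profile
  expect_equal(as.numeric(build_profile(one[0, ], gene_order)), rep(0, 50))
})

test_that("profile values convert to copy numbers by exponentiation times two", {
  expect_identical(profile_to_copy_number(c(-1, 0, 1)), c(1, 2, 4))
  expect_equal(profile_to_copy_number(log2(3 / 2)), 3)
})

test_that("profiled correlation handles exact and degenerate tracks", {
  set.seed(17)
  x <- rnorm(100)
  expect_equal(profiled_correlation(x, x), 1)
  expect_warning(out <- profiled_correlation(rep(0, 100), x), "undefined")
  expect_true(is.na(out))
})

test_that("window p-values are uniform under a Gaussian null", {
  # disjoint windows of one fixed size, so the KS test sees independent
  # p-values (overlapping windows share genes and correlate)
  set.seed(18)
  sc <- scan_chromosome(rnorm(20000), sizes = 10, medians = FALSE)
  p_disjoint <- sc$p_value[seq(1, nrow(sc), by = 10)]
  expect_gt(ks.test(p_disjoint, "punif")$p.value, 0.01)
})

test_that("planted regional signals are detected with the right sign", {
  res <- recovery_run(601)
  rec <- segment_recovery(res$segs, res$ap)
  expect_equal(mean(rec[, "sign_ok"]), 1)
  # significant windows concentrate on the planted segments
  sig <- res$ap$windows[res$ap$windows$significant, ]
  expect_gt(nrow(sig), 0)
  for (i in seq_len(nrow(res$segs))) {
    s <- sig[sig$chromosome == res$segs$chromosome[i], ]
    overlaps <- s$start_index < res$segs$end[i] &
      s$end_index >= res$segs$start[i]
    expect_true(any(overlaps))
  }
  # the profile inside each segment carries the planted sign and scale
  p <- res$ap$profile
  for (i in seq_len(nrow(res$segs))) {
    inside <- which(p$chromosome == res$segs$chromosome[i])[
      res$segs$start[i]:res$segs$end[i]]
    med <- median(p$profile_value[inside])
    expect_equal(sign(med), sign(res$segs$mean[i]))
    expect_gt(abs(med), 0.5 * abs(res$segs$mean[i]))
  }
})

test_that("short chromosomes are skipped with a warning, not an error", {
  tr <- data.frame(gene = sprintf("g%d", 1:12),
                   chromosome = c(rep("chr1", 10), rep("chr2", 2)),
                   position = c(1:10, 1:2) * 10,
                   log2_ratio = rnorm(12))
  expect_warning(ap <- genome_profile(tr, n_permutations = 3, seed = 1),
                 "fewer than 3")
  expect_equal(nrow(ap$profile), 10)
})

test_that("segment merging and BED export round-trip the profile runs", {
  gene_order <- data.frame(gene = sprintf("g%02d", 1:30),
                           chromosome = "chr1")
  sig <- data.frame(chromosome = "chr1", start_index = c(2L, 20L),
                    end_index = c(10L, 26L), size = c(8L, 6L),
                    median = c(0.8, -0.6))
  prof <- data.frame(gene_order, position = seq(1, by = 10, length.out = 30),
                     profile_value = as.numeric(build_profile(sig, gene_order)))
  segs <- profile_segments(prof)
  expect_equal(segs$call, c("amp", "del"))
  expect_equal(segs$start_index, c(2L, 20L))
  expect_equal(segs$end_index, c(10L, 26L))
  expect_equal(segs$n_genes, c(8L, 6L))
  bed <- withr::local_tempfile(fileext = ".bed")
  write_segments_bed(segs, bed)
  lines <- read.delim(bed, header = FALSE)
  expect_equal(nrow(lines), 2)
  expect_equal(lines$V4, c("amp", "del"))
  expect_equal(lines$V5, c(800L, 600L))
})
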