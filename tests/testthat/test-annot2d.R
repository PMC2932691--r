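test_that("rank conventions: ascending, average ties, conserved sum", {
  m <- data.frame(gene = c("a", "b", "c"),
                  copy_log2 = c(0.1, 0.3, 0.2),
                  protein_log2 = c(1, 1, 1))
  r <- rank_dimensions(m)
  expect_equal(r$genome, c(1, 3, 2))
  expect_equal(r$proteome, rep(2, 3))  # all equal -> (n+1)/2
  expect_equal(sum(r$genome), 3 * 4 / 2)
  set.seed(21)
  m2 <- make_matched(100, seed = 21)
  r2 <- rank_dimensions(m2)
  expect_equal(sum(r2$proteome), 100 * 101 / 2)
})

test_that("the per-dimension statistic matches the reference Mann-Whitney test", {
  set.seed(22)
  n <- 60
  m <- make_matched(n, seed = 22)
  ranks <- rank_dimensions(m)
  mem <- rep(FALSE, n); mem[sample.int(n, 15)] <- TRUE
  res <- mannwhitney_2d(mem, ranks)
  # reconstruct U from z and compare with wilcox.test's W statistic
  wt <- wilcox.test(m$copy_log2[mem], m$copy_log2[!mem],
                    exact = FALSE, correct = FALSE)
  mu <- 15 * (n - 15) / 2
  v <- 15 * (n - 15) * (n + 1) / 12
  expect_equal(res$z_genome, (unname(wt$statistic) - mu) / sqrt(v),
               tolerance = 1e-10)
  expect_equal(2 * pnorm(-abs(res$z_genome)), wt$p.value, tolerance = 1e-10)
})

test_that("2D test extremes: maximal one-dimensional shift and perfect symmetry", {
  n <- 1000; m <- 20
  set.seed(23)
  tab <- make_matched(n, seed = 23)
  # members occupy the top m protein ranks, random in the copy dimension
  ranks <- rank_dimensions(tab)
  mem <- ranks$proteome > n - m
  res <- mannwhitney_2d(mem, ranks)
  expect_lt(res$p_value, 1e-3)
  expect_gt(res$z_proteome, 3)

  # m = n/2 with member ranks {1,4,5,8} exactly mirroring the complement
  # {2,3,6,7} in both dimensions: z1 = z2 = 0, p = 1
  tab3 <- data.frame(gene = sprintf("g%02d", 1:8),
                     copy_log2 = c(1, 4, 5, 8, 2, 3, 6, 7),
                     protein_log2 = c(1, 4, 5, 8, 2, 3, 6, 7))
  ranks3 <- rank_dimensions(tab3)
  mem3 <- c(rep(TRUE, 4), rep(FALSE, 4))
  res3 <- mannwhitney_2d(mem3, ranks3)
  expect_equal(res3$z_genome, 0, tolerance = 1e-12)
  expect_equal(res3$z_proteome, 0, tolerance = 1e-12)
  expect_equal(res3$p_value, 1)
})

test_that("null p-values are uniform and the permutation p agrees with the analytic one", {
  n <- 500
  tab <- make_matched(n, seed = 24)
  ranks <- rank_dimensions(tab)
  set.seed(25)
  p <- vapply(1:500, function(i) {
    mem <- rep(FALSE, n); mem[sample.int(n, 25)] <- TRUE
    mannwhitney_2d(mem, ranks)$p_value
  }, numeric(1))
  # ties are expected: U is discrete, so KS ties are benign here
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)

  set.seed(26)
  mem <- rep(FALSE, n); mem[sample.int(n, 30)] <- TRUE
  mem[ranks$proteome > n - 10] <- TRUE
  p_an <- mannwhitney_2d(mem, ranks)$p_value
  p_pm <- mannwhitney_2d(mem, ranks, n_perm = 4000)$p_value
  expect_lt(abs(p_an - p_pm), 0.02 + 2 * p_an)
})

test_that("rescaled mean-rank scores hit the defining endpoints exactly", {
  n <- 200; m <- 17
  set.seed(27)
  ranks_1d <- sample(n)  # a permutation: untied ranks
  top <- ranks_1d > n - m
  bottom <- ranks_1d <= m
  expect_equal(score_2d(top, ranks_1d), 1)
  expect_equal(score_2d(bottom, ranks_1d), -1)
  # background-distributed members: mean rank (n+1)/2 -> score 0
  sym <- ranks_1d %in% c(1:5, n:(n - 4))
  expect_equal(score_2d(sym, ranks_1d), 0)

  # antisymmetry: negating the dimension negates the score
  set.seed(28)
  x <- rnorm(n)
  memb <- rep(FALSE, n); memb[sample.int(n, 20)] <- TRUE
  expect_equal(score_2d(memb, rank(x)), -score_2d(memb, rank(-x)),
               tolerance = 1e-12)

  # rank-sum conservation forces member and complement scores to
  # opposite signs
  s_m <- score_2d(memb, rank(x))
  s_c <- score_2d(!memb, rank(x))
  expect_lte(s_m * s_c, 0)
  expect_equal(s_m * 20 * (n - 20) / 2, -s_c * (n - 20) * 20 / 2,
               tolerance = 1e-9)
})

test_that("Benjamini-Hochberg adjustment matches the hand-computed oracle", {
  # step-up on {0.01, 0.02, 0.03, 0.04} with k = 4: max p_i * k / i = 0.04,
  # so all four are significant at 0.05
  adj <- bh_adjust(c(0.01, 0.02, 0.03, 0.04), fdr = 0.05)
  expect_equal(adj$q_values, c(0.04, 0.04, 0.04, 0.04))
  expect_true(all(adj$significant))
  expect_false(any(bh_adjust(rep(1, 6))$significant))
  set.seed(29)
  p <- runif(50)
  q <- bh_adjust(p)$q_values
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("planted proteome-shifted terms are detected with one-sided scores", {
  cfg <- sim_config(n_chromosomes = 10, genes_per_chromosome = 300,
                    n_terms = 40, term_size_range = c(30L, 30L),
                    n_planted_terms = 1,
                    planted_term_shift = c(copy = 0, protein = 1),
                    single_event_fraction = 0, seed = 30)
  d <- simulate_dataset(cfg)
  m <- suppressWarnings(suppressMessages(
    integrate_datasets(d$proteins, d$tumor_probes, d$control_probes)))
  res <- run_annotation_analysis(m, d$terms)
  planted <- res[res$term_id == names(d$truth$planted_terms)[1], ]
  expect_lte(planted$q_value, 0.05)
  expect_gt(planted$score_proteome, 0.3)
  expect_lt(abs(planted$score_genome), 0.15)
  expect_true(all(abs(res$score_genome) <= 1) &&
                all(abs(res$score_proteome) <= 1))
})

test_that("chromosome pseudo-terms expose arm-level dosage in the genome dimension", {
  # one chromosome amplified everywhere: its pseudo-term must shift right
  set.seed(31)
  m <- make_matched(400, seed = 31, sd_copy = 0.1)
  amp <- m$chromosome == "chr2"
  m$copy_log2[amp] <- m$copy_log2[amp] + 1
  m$protein_log2[amp] <- m$protein_log2[amp] + 0.3
  res <- run_annotation_analysis(m, structure(list(), source = character(0)))
  chr2 <- res[res$term_id == "chr2", ]
  expect_equal(chr2$source, "chromosome")
  expect_gt(chr2$score_genome, 0.5)
  expect_lte(chr2$q_value, 0.05)
})

test_that("results are invariant to gene order and monotone transforms", {
  m <- make_matched(300, seed = 32)
  terms <- list(T1 = m$gene[5:40], T2 = m$gene[100:160])
  attr(terms, "source") <- c("SIM", "SIM")
  r1 <- run_annotation_analysis(m, terms, add_chromosome_terms = FALSE)
  mshuf <- m[sample(nrow(m)), ]
  r2 <- run_annotation_analysis(mshuf, terms, add_chromosome_terms = FALSE)
  expect_equal(r1[order(r1$term_id), -1], r2[order(r2$term_id), -1],
               tolerance = 1e-12, ignore_attr = TRUE)
  mtr <- m
  mtr$protein_log2 <- exp(mtr$protein_log2)     # strictly monotone
  mtr$copy_log2 <- mtr$copy_log2^3              # strictly monotone
  r3 <- run_annotation_analysis(mtr, terms, add_chromosome_terms = FALSE)
  expect_equal(r1[order(r1$term_id), -1], r3[order(r3$term_id), -1],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("terms outside the size bounds are skipped and empty input warns", {
  m <- make_matched(50, seed = 33)
  terms <- list(tiny = m$gene[1:2], big = m$gene[1:48],
                ok = m$gene[1:10])
  attr(terms, "source") <- rep("SIM", 3)
  res <- run_annotation_analysis(m, terms, min_category_size = 5,
                                 add_chromosome_terms = FALSE)
  expect_equal(res$term_id, "ok")
  expect_warning(
    empty <- run_annotation_analysis(m, structure(list(),
                                                  source = character(0)),
                                     add_chromosome_terms = FALSE),
    "no annotation terms")
  expect_equal(nrow(empty), 0)
})
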