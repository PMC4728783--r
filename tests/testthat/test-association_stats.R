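test_that("CpG classification uses strict 0.33 / 0.66 thresholds", {
  expect_equal(classify_cpg(c(0.10, 0.90, 0.50, 0.33, 0.66)),
               c("hypo", "hyper", "intermediate", "intermediate",
                 "intermediate"))
})

test_that("fisher_exact matches enumeration and base R on fixtures", {
  f <- fisher_exact(matrix(c(10, 10, 10, 10), 2))
  expect_equal(f$odds_ratio, 1)
  expect_equal(f$p, 1)
  f2 <- fisher_exact(c(8, 2, 2, 8))
  expect_equal(f2$odds_ratio, 16)
  expect_equal(f2$p, oracle_fisher_p(8, 2, 2, 8), tolerance = 1e-12)
  expect_equal(f2$p, fisher.test(matrix(c(8, 2, 2, 8), 2))$p.value,
               tolerance = 1e-9)
  # Haldane correction only when a zero cell is present
  f3 <- fisher_exact(c(5, 0, 5, 5))
  expect_equal(f3$odds_ratio, (5.5 * 5.5) / (0.5 * 5.5))
  # zero margin
  f4 <- fisher_exact(c(0, 0, 5, 5))
  expect_true(is.na(f4$odds_ratio))
  expect_equal(f4$p, 1)
  # invariances: row+column swap keeps p; single row swap inverts OR
  set.seed(6)
  for (i in 1:10) {
    t0 <- matrix(rpois(4, 8) + 1, 2)
    swapped <- t0[2:1, 2:1]
    expect_equal(fisher_exact(t0)$p, fisher_exact(swapped)$p,
                 tolerance = 1e-12)
    expect_equal(fisher_exact(t0[2:1, ])$odds_ratio,
                 1 / fisher_exact(t0)$odds_ratio, tolerance = 1e-12)
  }
})

test_that("window_stats tiles regions and averages tracks", {
  region <- list(chrom = "chr1", start = 0L, end = 230L)
  sig <- data.frame(chrom = "chr1", start = seq(0L, 220L, 10L),
                    end = seq(10L, 230L, 10L), value = 2)
  sm <- structure(data.frame(chrom = "chr1", pos = c(10L, 60L, 70L),
                             meth = 1L, unmeth = 1L, raw = .5,
                             smooth = c(0.1, 0.9, 0.7)),
                  class = c("smoothed_methylome", "methylome",
                            "data.frame"))
  w <- window_stats(sig, sm, region, 50)
  expect_equal(nrow(w), 5)
  expect_equal(w$full, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(w$mean_signal, rep(2, 5))
  expect_equal(w$mean_meth[1:2], c(0.1, 0.8))
  expect_true(all(is.na(w$mean_meth[3:5])))
  expect_equal(w$cpg_density[1:2], c(1 / 50, 2 / 50))
  expect_equal(w$meth_class[1:2], c("hypo", "hyper"))
  # a 200-bp region gives exactly 4 windows
  expect_equal(nrow(window_stats(sig, sm,
                                 list(chrom = "chr1", start = 0L,
                                      end = 200L), 50)), 4)
})

test_that("rank-sum test: exact enumeration, symmetry, degenerate input", {
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p, 0.1)  # 2 of the 20 assignments are as extreme
  expect_equal(r$method, "exact")
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_equal(rank_sum_test(rep(2, 4), rep(2, 5))$p, 1)
  x <- rnorm(4); y <- rnorm(5)
  expect_equal(rank_sum_test(x, y)$p, rank_sum_test(y, x)$p)
  # large-sample normal path against base R (no continuity correction there)
  set.seed(7)
  x <- rnorm(30); y <- rnorm(25, 0.5)
  mine <- rank_sum_test(x, y)
  ref <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
})

test_that("linear_model_signal recovers noiseless coefficients and matches
           the normal-equation oracle", {
  w <- data.frame(mean_signal = NA, meth_class = rep(c("hypo", "hyper"), 10),
                  cpg_density = runif(20))
  w$mean_signal <- 3 - 2 * (w$meth_class == "hyper")
  fit <- suppressWarnings(linear_model_signal(w))  # perfect-fit lm warning
  expect_equal(fit$status_coef, -2, tolerance = 1e-10)
  set.seed(13)
  w$mean_signal <- 3 - 2 * (w$meth_class == "hyper") +
    0.5 * w$cpg_density + rnorm(20, 0, 0.3)
  fit2 <- linear_model_signal(w)
  beta <- oracle_ols(cbind(1, as.integer(w$meth_class == "hyper"),
                           w$cpg_density), w$mean_signal)
  expect_equal(unname(fit2$coef), unname(beta), tolerance = 1e-8)
  w$meth_class <- "hypo"
  expect_error(linear_model_signal(w), "both")
})

test_that("spearman: monotone data, ties fixture vs full enumeration,
           monotone-transform invariance", {
  expect_equal(spearman_test(1:5, c(2, 4, 6, 8, 10))$rho, 1)
  expect_equal(spearman_test(1:5, 5:1)$rho, -1)
  x <- c(1, 2, 2, 3, 4); y <- c(5, 3, 4, 4, 1)
  s <- spearman_test(x, y)
  rx <- rank(x); ry <- rank(y)
  expect_equal(s$rho, cor(rx, ry), tolerance = 1e-12)
  perms <- semethyl:::.permutations(5)
  rhos <- apply(perms, 1, function(pm) cor(rx, ry[pm]))
  expect_equal(s$p, mean(abs(rhos) >= abs(s$rho) - 1e-9), tolerance = 1e-12)
  # invariance under strictly monotone transforms
  set.seed(19)
  a <- rnorm(12); b <- rnorm(12)
  expect_equal(spearman_test(exp(a), b)$rho, spearman_test(a, b)$rho)
  expect_equal(spearman_test(a, b^3 + b)$p, spearman_test(a, b)$p)
  expect_true(is.na(spearman_test(rep(1, 5), 1:5)$rho))
})

test_that("assign_target picks the closest TSS within 1 Mb", {
  se <- list(chrom = "chr1", start = 1000L, end = 2000L)
  tss <- data.frame(gene = c("in", "near", "far"), chrom = "chr1",
                    pos = c(1500L, 10000L, 5e6))
  expect_equal(assign_target(se, tss)$gene, "in")
  expect_equal(assign_target(se, tss)$distance, 0)
  expect_equal(assign_target(se, tss[-1, ])$gene, "near")
  # strict 1 Mb rule: 1,000,001 bp away -> none
  only_far <- data.frame(gene = "g", chrom = "chr1", pos = 2000L + 1000000L)
  expect_equal(assign_target(se, only_far)$distance, 1e6 + 1)
  expect_true(is.na(assign_target(se, only_far)$gene))
  at_limit <- data.frame(gene = "g", chrom = "chr1", pos = 1999L + 1000000L)
  expect_equal(assign_target(se, at_limit)$gene, "g")
  # deterministic tie-break: smaller coordinate wins
  ties <- data.frame(gene = c("left", "right"), chrom = "chr1",
                     pos = c(1000L - 5000L, 1999L + 5000L))
  expect_equal(assign_target(se, ties)$gene, "left")
})

test_that("loglinear_expression: noiseless slope and oracle agreement", {
  meth <- seq(0.05, 0.65, length.out = 12)  # keeps expr non-negative
  expr <- exp(2 - 3 * meth) - 1
  expect_equal(suppressWarnings(loglinear_expression(expr, meth))$slope,
               -3, tolerance = 1e-10)
  expect_error(loglinear_expression(expr, rep(0.5, 12)), "degenerate")
  set.seed(23)
  expr2 <- exp(2 - 3 * meth + rnorm(12, 0, 0.2))
  beta <- oracle_ols(cbind(1, meth), log(expr2 + 1))
  expect_equal(loglinear_expression(expr2, meth)$slope, unname(beta[2]),
               tolerance = 1e-8)
})

test_that("bh_fdr reproduces the hand-computed step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(31)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(q >= p & q <= 1))
  expect_equal(q, p.adjust(p, "BH"))  # independent reference
})
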