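mk_sm <- function(pos, smooth, chrom = "chr1") {
  structure(data.frame(chrom = chrom, pos = pos, meth = 1L, unmeth = 1L,
                       raw = 0.5, smooth = smooth),
            class = c("smoothed_methylome", "methylome", "data.frame"))
}

test_that("flank extension and the scaled map obey the stated geometry", {
  se <- data.frame(chrom = "chr1", start = 1000L, end = 2000L,
                   se_id = "SE_1")
  e <- extend_and_scale(se)
  expect_equal(c(e$ext_start, e$ext_end), c(500, 2500))
  expect_equal(se_scaled_position(e[1, ], c(1500, 1000, 2000, 1750, 500,
                                            2500)),
               c(0, -1, 1, 0.5, -2, 2))
  # odd length: floor left, ceil right; length-1 SE doubles
  e1 <- extend_and_scale(data.frame(chrom = "chr1", start = 10L, end = 11L))
  expect_equal(c(e1$ext_start, e1$ext_end), c(10, 12))
  # clipping at 0 warns but keeps map anchored
  expect_warning(ec <- extend_and_scale(
    data.frame(chrom = "chr1", start = 100L, end = 1100L)), "clip")
  expect_equal(ec$ext_start, 0)
  expect_equal(se_scaled_position(ec[1, ], 100), -1)
  # property: edges map to exactly +/-1 for random intervals
  set.seed(2)
  ses <- data.frame(chrom = "chr1",
                    start = as.integer(sample(1e5:2e5, 25)))
  ses$end <- ses$start + as.integer(sample(101:9999, 25))
  ee <- extend_and_scale(ses)
  for (i in seq_len(25)) {
    expect_equal(se_scaled_position(ee[i, ], ee$start[i]), -1)
    expect_equal(se_scaled_position(ee[i, ], ee$end[i]), 1)
  }
})

test_that("profiles cover exactly the CpGs in the extended interval", {
  e <- extend_and_scale(data.frame(chrom = "chr1", start = 1000L,
                                   end = 2000L, se_id = "a"))
  sm <- mk_sm(c(400L, 500L, 1500L, 2499L, 2500L), c(.1, .2, .3, .4, .5))
  pr <- se_profile(e[1, ], sm)
  expect_equal(nrow(pr), 3)  # 500, 1500, 2499
  expect_equal(pr$scaled_pos[2], 0)
  expect_true(all(pr$scaled_pos >= -2 & pr$scaled_pos < 2))
  expect_true(attr(pr, "covered"))
  empty <- se_profile(e[1, ], mk_sm(10L, 0.5))
  expect_false(attr(empty, "covered"))
})

test_that("average methylation and categories bin correctly", {
  expect_equal(as.character(se_categorize(c(0.10, 0.30, 0.60, 0.90))),
               c("Q1", "Q2", "Q3", "Q4"))
  # left-closed boundaries
  expect_equal(as.character(se_categorize(c(0.25, 0.50, 0.75))),
               c("Q2", "Q3", "Q4"))
  e <- extend_and_scale(data.frame(chrom = "chr1", start = 1000L,
                                   end = 2000L))
  sm <- mk_sm(c(1200L, 1800L, 2100L), c(0.4, 0.4, 0.9))
  expect_equal(se_average_methylation(e, sm), 0.4)  # flank CpG excluded
  expect_true(is.na(se_average_methylation(e, mk_sm(10L, .5))))
})

test_that("coverage filter is a strict majority rule", {
  ses <- data.frame(chrom = "chr1", start = 0L, end = 100L, se_id = "s")
  mk_cov <- function(ncov, ntot) {
    mk_methylome(seq(0L, length.out = ntot, by = 5L),
                 c(rep(1L, ncov), rep(0L, ntot - ncov)),
                 rep(0L, ntot))
  }
  expect_true(se_coverage_filter(ses, mk_cov(6, 10))$pass)
  expect_false(se_coverage_filter(ses, mk_cov(5, 10))$pass)  # exactly 0.5
  none <- se_coverage_filter(ses, mk_methylome(500L, 1L, 0L))
  expect_false(none$pass)
  expect_true(is.na(none$frac))
})

test_that("occupancy is the base-pair fraction of the HMR union", {
  ses <- data.frame(chrom = "chr1", start = 100L, end = 200L, se_id = "s")
  hmrs <- data.frame(chrom = "chr1", start = c(90L, 180L),
                     end = c(150L, 190L))
  expect_equal(se_occupancy(ses, hmrs)$occupancy, 0.6)
  expect_equal(se_occupancy(ses, hmrs[0, ])$occupancy, 0)
  expect_equal(se_occupancy(ses, data.frame(chrom = "chr1", start = 0L,
                                            end = 500L))$occupancy, 1)
  # overlapping HMRs are unioned, never double counted
  twice <- data.frame(chrom = "chr1", start = c(100L, 120L),
                      end = c(160L, 160L))
  expect_equal(se_occupancy(ses, twice)$occupancy, 0.6)
})

test_that("delta occupancy labels follow the strict 0.25 threshold", {
  occ <- function(o) data.frame(se_id = "s", sample_id = "x", occupancy = o)
  expect_equal(delta_occupancy(occ(0.80), occ(0.50))$label, "hypomethylated")
  expect_equal(delta_occupancy(occ(0.10), occ(0.50))$label, "hypermethylated")
  expect_equal(delta_occupancy(occ(0.50), occ(0.50))$label, "unchanged")
  expect_equal(delta_occupancy(occ(0.75), occ(0.50))$label, "unchanged")
  expect_equal(delta_occupancy(occ(0.5), occ(0.5))$delta, 0)
  bad <- data.frame(se_id = "other", sample_id = "x", occupancy = 1)
  expect_error(delta_occupancy(occ(1), bad), "mismatch")
})

test_that("tissue-specific calls need both thresholds and are
           label-equivariant", {
  occ <- rbind(c(0.5, 0.1, 0.1), c(0.15, 0.0, 0.0), c(0.5, 0.45, 0.45))
  colnames(occ) <- c("A", "B", "C")
  rownames(occ) <- paste0("SE", 1:3)
  ts <- call_tissue_specific(occ)
  expect_equal(unname(ts[, "A"]), c(TRUE, FALSE, FALSE))
  expect_false(any(ts[, c("B", "C")]))
  perm <- c("C", "A", "B")
  expect_equal(call_tissue_specific(occ[, perm]), ts[, perm])
})

test_that("flank-inside reduction test separates focal from global shifts", {
  set.seed(14)
  n_se <- 200
  se_len <- 1000L
  starts <- seq(2000L, by = 4000L, length.out = n_se)
  ses <- extend_and_scale(data.frame(chrom = "chr1", start = starts,
                                     end = starts + se_len,
                                     se_id = sprintf("s%03d", 1:n_se)))
  pos <- seq(0L, max(ses$ext_end) + 1000L, by = 200L)
  base <- pmin(pmax(rnorm(length(pos), 0.75, 0.05), 0), 1)
  inside <- rep(FALSE, length(pos))
  for (i in seq_len(n_se))
    inside <- inside | (pos >= ses$start[i] & pos < ses$end[i])
  sm_n <- mk_sm(pos, base)
  # identical samples -> t = 0, p = 1
  same <- flank_inside_reduction(sm_n, sm_n, ses)
  expect_equal(c(same$t, same$p), c(0, 1))
  # global shift: everything drops equally -> not significant
  glob <- mk_sm(pos, pmax(base - 0.08 +
                            rnorm(length(pos), 0, 0.01), 0))
  expect_gt(flank_inside_reduction(sm_n, glob, ses)$p, 0.05)
  # focal shift: only SE interiors drop 0.3 -> highly significant
  foc <- base - ifelse(inside, 0.3, 0) + rnorm(length(pos), 0, 0.01)
  expect_lt(flank_inside_reduction(sm_n, mk_sm(pos, pmax(foc, 0)), ses)$p,
            1e-3)
})

test_that("array validation applies probe, beta and FDR rules", {
  se_ids <- c("se1", "se2", "se3")
  probes <- data.frame(probe_id = c(paste0("p", 1:3), paste0("q", 1:2),
                                    paste0("r", 1:3)),
                       se_id = rep(se_ids, c(3, 2, 3)))
  beta <- rbind(matrix(0.1, 3, 10), matrix(0.5, 2, 10), matrix(0.5, 3, 10))
  rownames(beta) <- probes$probe_id
  beta[1:3, 6:10] <- 0.9
  groups <- rep(c("target", "other"), each = 5)
  v <- array_validate(beta, probes, groups, "target")
  expect_equal(v$verdict[v$se_id == "se1"], "validated")
  expect_equal(v$verdict[v$se_id == "se2"], "not_testable")  # 2 probes
  expect_equal(v$verdict[v$se_id == "se3"], "not_validated") # identical
})
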