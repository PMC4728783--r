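#' Simulation configuration
#'
#' Defaults describe a WGBS-like world at the scale of the study design this
#' package targets: CpGs every ~100 bp (geometric gaps), read coverage
#' Poisson with mean 14 (matching typical WGBS CpG coverage), a highly
#' methylated background (beta-binomial mean 0.75, in line with normal-tissue
#' global methylation near 70 percent) dotted with hypomethylated regions
#' (mean 0.10), and a cancer shift combining a small global methylation loss
#' (default 0.075) with focal super-enhancer-targeted changes of magnitude
#' 0.4 in HMR occupancy.
#'
#' @param seed mandatory RNG seed; each generator derives its own stream as
#'   seed + a small op-specific offset.
#' @param n_chroms number of simulated chromosomes.
#' @param chrom_len chromosome length (bp).
#' @param cpg_gap_mean mean CpG gap (bp, geometric).
#' @param coverage_mean mean read coverage per CpG (Poisson).
#' @param bg_mean,hmr_mean beta-binomial means of the high (background) and
#'   low (HMR) methylation states.
#' @param precision beta-binomial precision alpha + beta (controls
#'   overdispersion; per-site level sd ~ 0.12 at coverage 14).
#' @param hmr_spacing_mean mean spacing between background true HMRs (bp).
#' @param hmr_len_mean mean true-HMR length (bp, lognormal, sdlog 0.3).
#' @param n_ses number of super-enhancers to implant.
#' @param se_len SE length (bp).
#' @param global_drop global background methylation loss in cancer.
#' @param focal_delta magnitude of focal occupancy change in cancer.
#' @param fraction_focal fraction of SEs receiving a focal change.
#' @param histone_s0 histone signal scale (signal = s0 (1 - meth) + noise).
#' @param histone_noise sd of the Gaussian histone noise.
#' @param expr_e0,expr_e1 expression model: expr = exp(e0 - e1 meth) x noise.
#' @param expr_noise sdlog of the lognormal expression noise.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(seed, n_chroms = 2, chrom_len = 1e6,
                       cpg_gap_mean = 100, coverage_mean = 14,
                       bg_mean = 0.75, hmr_mean = 0.10, precision = 30,
                       hmr_spacing_mean = 3e4, hmr_len_mean = 1500,
                       n_ses = 20, se_len = 10000,
                       global_drop = 0.075, focal_delta = 0.4,
                       fraction_focal = 0.3,
                       histone_s0 = 5, histone_noise = 0.5,
                       expr_e0 = 2, expr_e1 = 3, expr_noise = 0.3) {
  stopifnot(!missing(seed), bg_mean > 0, bg_mean < 1, hmr_mean > 0,
            hmr_mean < 1, precision > 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate CpG positions
#'
#' Per chromosome, positions are cumulative geometric gaps (mean
#' \code{cpg_gap_mean}), strictly increasing, truncated at \code{chrom_len}.
#' Deterministic per seed.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return data.frame(chrom, pos).
#' @export
simulate_positions <- function(cfg) {
  set.seed(cfg$seed + 0L)
  out <- lapply(seq_len(cfg$n_chroms), function(ci) {
    n_guess <- ceiling(cfg$chrom_len / cfg$cpg_gap_mean * 1.3) + 50
    gaps <- stats::rgeom(n_guess, 1 / cfg$cpg_gap_mean) + 1
    pos <- cumsum(gaps)
    pos <- pos[pos < cfg$chrom_len]
    data.frame(chrom = rep(sprintf("chrS%d", ci), length(pos)),
               pos = as.integer(pos))
  })
  do.call(rbind, out)
}

#' Simulate background true-HMR segmentation
#'
#' Places true hypomethylated intervals along each chromosome with
#' exponential spacing (mean \code{hmr_spacing_mean}) and lognormal lengths
#' (mean \code{hmr_len_mean}), then labels each CpG position low/high.
#'
#' @param positions data.frame(chrom, pos) from
#'   \code{\link{simulate_positions}}.
#' @param cfg a \code{\link{sim_config}}.
#' @return list: \code{intervals} (chrom, start, end), \code{state}
#'   (per-position "low"/"high"), \code{mu} (per-position emission mean).
#' @export
simulate_segmentation <- function(positions, cfg) {
  set.seed(cfg$seed + 1L)
  ivs <- lapply(unique(positions$chrom), function(chr) {
    xs <- integer(0); xe <- integer(0)
    cur <- 0
    repeat {
      cur <- cur + stats::rexp(1, 1 / cfg$hmr_spacing_mean)
      len <- stats::rlnorm(1, log(cfg$hmr_len_mean) - 0.045, 0.3)
      if (cur + len >= cfg$chrom_len) break
      xs <- c(xs, round(cur)); xe <- c(xe, round(cur + len))
      cur <- cur + len
    }
    data.frame(chrom = chr, start = xs, end = xe)
  })
  intervals <- do.call(rbind, ivs)
  state <- .label_positions(positions, intervals)
  mu <- ifelse(state == "low", cfg$hmr_mean, cfg$bg_mean)
  list(intervals = .snap_to_cpgs(intervals, positions), state = state,
       mu = mu)
}

# recorded truth intervals are snapped to the extent of the CpGs they
# contain (first low CpG .. last low CpG + 1): count data carry no signal
# between CpGs, so this is the recoverable ground truth and matches the
# extract_hmrs convention. Intervals with no CpG are dropped.
.snap_to_cpgs <- function(intervals, positions) {
  out <- lapply(seq_len(nrow(intervals)), function(i) {
    p <- positions$pos[positions$chrom == intervals$chrom[i] &
                         positions$pos >= intervals$start[i] &
                         positions$pos < intervals$end[i]]
    if (length(p) == 0) return(NULL)
    data.frame(chrom = intervals$chrom[i], start = min(p),
               end = max(p) + 1L)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

.label_positions <- function(positions, intervals) {
  state <- rep("high", nrow(positions))
  for (chr in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == chr, , drop = FALSE]
    px <- which(positions$chrom == chr)
    if (length(px) == 0 || nrow(iv) == 0) next
    iv <- iv[order(iv$start), , drop = FALSE]
    j <- findInterval(positions$pos[px], iv$start)
    inside <- j >= 1 & positions$pos[px] < iv$end[pmax(j, 1)]
    state[px[inside]] <- "low"
  }
  state
}

#' Simulate a two-state Markov segmentation (for parameter recovery)
#'
#' Generates a hidden state sequence along the CpG positions from a 2-state
#' Markov chain with the given self-transition probabilities (low first).
#'
#' @param positions data.frame(chrom, pos).
#' @param cfg a \code{\link{sim_config}} (seed).
#' @param p_stay_low,p_stay_high self-transition probabilities.
#' @param p_init_low initial probability of the low state.
#' @return character vector of states along positions.
#' @export
simulate_markov_states <- function(positions, cfg, p_stay_low = 0.99,
                                   p_stay_high = 0.995, p_init_low = 0.5) {
  set.seed(cfg$seed + 2L)
  n <- nrow(positions)
  u <- stats::runif(n)
  st <- integer(n)
  newchrom <- c(TRUE, positions$chrom[-1] != positions$chrom[-n])
  for (i in seq_len(n)) {
    if (newchrom[i]) {
      st[i] <- if (u[i] < p_init_low) 1L else 2L
    } else {
      stay <- if (st[i - 1] == 1L) p_stay_low else p_stay_high
      st[i] <- if (u[i] < stay) st[i - 1] else 3L - st[i - 1]
    }
  }
  c("low", "high")[st]
}

#' Simulate a methylome from a truth segmentation
#'
#' Coverage is Poisson(\code{coverage_mean}); the methylated count is
#' beta-binomial: per-site success probability drawn from
#' Beta(mu s, (1 - mu) s) with s = \code{precision} and mu the site's state
#' mean (or an explicit per-site \code{mu} vector), then binomial thinning of
#' the coverage.
#'
#' @param positions data.frame(chrom, pos).
#' @param state per-position "low"/"high" labels (ignored when \code{mu}
#'   given).
#' @param cfg a \code{\link{sim_config}}.
#' @param mu optional explicit per-position emission means.
#' @param sample_id,tissue,condition methylome metadata.
#' @param seed_offset RNG stream offset (default 3; use distinct offsets for
#'   multiple samples from one config).
#' @return a \code{\link{methylome}}.
#' @export
simulate_methylome <- function(positions, state = NULL, cfg, mu = NULL,
                               sample_id = "sim", tissue = "simTissue",
                               condition = "normal", seed_offset = 3L) {
  set.seed(cfg$seed + seed_offset)
  n <- nrow(positions)
  if (is.null(mu)) {
    stopifnot(!is.null(state), length(state) == n)
    mu <- ifelse(state == "low", cfg$hmr_mean, cfg$bg_mean)
  }
  cov <- stats::rpois(n, cfg$coverage_mean)
  p <- stats::rbeta(n, mu * cfg$precision, (1 - mu) * cfg$precision)
  meth <- stats::rbinom(n, cov, p)
  methylome(data.frame(chrom = positions$chrom, pos = positions$pos,
                       meth = meth, unmeth = cov - meth),
            sample_id, tissue, condition)
}

# category targets: intended inside-SE HMR occupancy per category
.se_cat_plan <- function() {
  data.frame(category = c("Q1", "Q2", "Q3", "Q4"),
             occupancy = c(1.0, 0.5, 0.2, 0.0))
}

#' Implant super-enhancers into a truth segmentation
#'
#' Places non-overlapping SEs (length \code{se_len}) clear of chromosome
#' ends, cycling through the four methylation categories. Low-state segments
#' are implanted anchored at the SE edges (extending inward, plus a small
#' 5 percent-of-L outward lip so the profile minimum sits at the scaled
#' edges): Q1 is fully hypomethylated (occupancy 1), Q2 edge implants give
#' occupancy 0.5, Q3 occupancy 0.2, Q4 none (occupancy 0) with the SE-local
#' background raised to mean 0.85 so its average stays in the top bin.
#'
#' @param truth output of \code{\link{simulate_segmentation}} (modified in the
#'   returned value; background HMRs overlapping an SE footprint are dropped
#'   first so realized occupancy matches the plan).
#' @param positions data.frame(chrom, pos).
#' @param cfg a \code{\link{sim_config}}.
#' @param tissue tissue label recorded on the SEs.
#' @return list: \code{ses} (chrom, start, end, se_id, tissue, category,
#'   true_occupancy), \code{truth} (updated intervals/state/mu).
#' @export
implant_superenhancers <- function(truth, positions, cfg,
                                   tissue = "simTissue") {
  set.seed(cfg$seed + 4L)
  plan <- .se_cat_plan()
  L <- cfg$se_len
  margin <- L  # keep SE + flanks inside the chromosome
  slots_per_chrom <- floor((cfg$chrom_len - 2 * margin) / (2.5 * L))
  ses <- list()
  k <- 0
  for (chr in sprintf("chrS%d", seq_len(cfg$n_chroms))) {
    n_here <- min(slots_per_chrom, cfg$n_ses - k)
    if (n_here <= 0) break
    anchors <- margin + (seq_len(n_here) - 1) * 2.5 * L +
      round(stats::runif(n_here, 0, 0.4 * L))
    for (a in anchors) {
      k <- k + 1
      ses[[k]] <- data.frame(chrom = chr, start = as.integer(a),
                             end = as.integer(a + L),
                             se_id = sprintf("SE_%03d", k),
                             tissue = tissue,
                             category = plan$category[(k - 1) %% 4 + 1])
    }
  }
  if (k < cfg$n_ses)
    message("insufficient space: implanted ", k, " of ", cfg$n_ses, " SEs")
  ses <- do.call(rbind, ses)
  ses$true_occupancy <- plan$occupancy[match(ses$category, plan$category)]

  # clear background HMRs from SE footprints (incl. flanks)
  fp_start <- ses$start - ceiling(0.55 * L)
  fp_end <- ses$end + ceiling(0.55 * L)
  bg <- truth$intervals
  drop <- rep(FALSE, nrow(bg))
  for (i in seq_len(nrow(ses))) {
    drop <- drop | (bg$chrom == ses$chrom[i] & bg$end > fp_start[i] &
                      bg$start < fp_end[i])
  }
  bg <- bg[!drop, , drop = FALSE]

  lip <- round(0.05 * L)
  imp <- list()
  for (i in seq_len(nrow(ses))) {
    occ <- ses$true_occupancy[i]
    if (occ >= 1) {
      imp[[length(imp) + 1]] <- data.frame(
        chrom = ses$chrom[i], start = ses$start[i] - lip,
        end = ses$end[i] + lip)
    } else if (occ > 0) {
      half_in <- round(occ / 2 * L)
      imp[[length(imp) + 1]] <- data.frame(
        chrom = ses$chrom[i],
        start = c(ses$start[i] - lip, ses$end[i] - half_in),
        end = c(ses$start[i] + half_in, ses$end[i] + lip))
    }
  }
  intervals <- rbind(bg, do.call(rbind, imp))
  intervals <- intervals[order(intervals$chrom, intervals$start), ,
                         drop = FALSE]
  state <- .label_positions(positions, intervals)
  mu <- ifelse(state == "low", cfg$hmr_mean, cfg$bg_mean)
  # Q4: elevated local background so the SE mean sits in the top bin
  for (i in which(ses$category == "Q4")) {
    ix <- positions$chrom == ses$chrom[i] & positions$pos >= ses$start[i] &
      positions$pos < ses$end[i]
    mu[ix & state == "high"] <- 0.85
  }
  list(ses = ses,
       truth = list(intervals = .snap_to_cpgs(intervals, positions),
                    state = state, mu = mu))
}

#' Apply a cancer shift to a truth segmentation
#'
#' The background (high-state) emission mean drops by \code{global_drop}
#' everywhere. A fraction \code{fraction_focal} of the SEs additionally get a
#' focal change of magnitude \code{focal_delta} in HMR occupancy: half gain
#' an implanted low segment in uncovered SE sequence (hypomethylated,
#' delta > 0), half lose implanted low segments (hypermethylated, delta < 0);
#' only SEs with enough uncovered/covered room are eligible for each
#' direction. Remaining SEs are labeled unchanged.
#'
#' @param se_truth output of \code{\link{implant_superenhancers}}.
#' @param positions data.frame(chrom, pos).
#' @param cfg a \code{\link{sim_config}}.
#' @return list: \code{truth} (cancer intervals/state/mu), \code{labels}
#'   data.frame(se_id, true_label, true_delta).
#' @export
apply_cancer_shift <- function(se_truth, positions, cfg) {
  set.seed(cfg$seed + 5L)
  ses <- se_truth$ses
  dl <- cfg$focal_delta
  can_hypo <- ses$true_occupancy <= 1 - dl - 0.05
  can_hyper <- ses$true_occupancy >= dl + 0.05
  n_focal <- round(cfg$fraction_focal * nrow(ses))
  n_hypo <- ceiling(n_focal / 2); n_hyper <- floor(n_focal / 2)
  hypo_ix <- sample(which(can_hypo), min(n_hypo, sum(can_hypo)))
  hyper_ix <- sample(setdiff(which(can_hyper), hypo_ix),
                     min(n_hyper, sum(can_hyper)))
  labels <- data.frame(se_id = ses$se_id, true_label = "unchanged",
                       true_delta = 0)
  labels$true_label[hypo_ix] <- "hypomethylated"
  labels$true_delta[hypo_ix] <- dl
  labels$true_label[hyper_ix] <- "hypermethylated"
  labels$true_delta[hyper_ix] <- -dl

  intervals <- se_truth$truth$intervals
  L <- cfg$se_len
  for (i in hypo_ix) {
    # add a low segment in the uncovered central/right part of the SE
    occ <- ses$true_occupancy[i]
    half_in <- round(occ / 2 * L)
    free_lo <- ses$start[i] + half_in
    free_hi <- ses$end[i] - half_in
    seg_len <- round(dl * L)
    s0 <- round((free_lo + free_hi - seg_len) / 2)
    intervals <- rbind(intervals,
                       data.frame(chrom = ses$chrom[i], start = s0,
                                  end = s0 + seg_len))
  }
  for (i in hyper_ix) {
    # shrink the edge implants by dl * L of inside coverage in total
    occ <- ses$true_occupancy[i]
    target_in <- round((occ - dl) / 2 * L)  # remaining inward reach per edge
    target_in <- max(target_in, 0)
    hit <- intervals$chrom == ses$chrom[i] &
      intervals$end > ses$start[i] & intervals$start < ses$end[i]
    intervals <- intervals[!hit, , drop = FALSE]
    if (occ >= 1) {
      # full implant: keep a single left-edge implant reaching 2*target_in
      keep_in <- round((occ - dl) * L)
      intervals <- rbind(intervals,
                         data.frame(chrom = ses$chrom[i],
                                    start = ses$start[i],
                                    end = ses$start[i] + keep_in))
    } else if (target_in > 0) {
      intervals <- rbind(intervals,
                         data.frame(chrom = ses$chrom[i],
                                    start = c(ses$start[i],
                                              ses$end[i] - target_in),
                                    end = c(ses$start[i] + target_in,
                                            ses$end[i])))
    }
  }
  intervals <- intervals[order(intervals$chrom, intervals$start), ,
                         drop = FALSE]
  state <- .label_positions(positions, intervals)
  mu <- ifelse(state == "low", cfg$hmr_mean,
               pmax(cfg$bg_mean - cfg$global_drop, 0.02))
  for (i in which(ses$category == "Q4")) {
    ix <- positions$chrom == ses$chrom[i] & positions$pos >= ses$start[i] &
      positions$pos < ses$end[i]
    mu[ix & state == "high"] <- max(0.85 - cfg$global_drop, 0.02)
  }
  list(truth = list(intervals = .snap_to_cpgs(intervals, positions),
                    state = state, mu = mu),
       labels = labels)
}

#' Simulate a histone signal track from truth methylation
#'
#' 50-bp windows per chromosome; signal = s0 (1 - local mean truth
#' methylation) + Gaussian noise. Windows without CpGs inherit the background
#' mean.
#'
#' @param truth a truth list (state/mu along positions).
#' @param positions data.frame(chrom, pos).
#' @param cfg a \code{\link{sim_config}}.
#' @param width window width (default 50).
#' @return data.frame(chrom, start, end, value).
#' @export
simulate_histone_track <- function(truth, positions, cfg, width = 50) {
  set.seed(cfg$seed + 6L)
  out <- lapply(unique(positions$chrom), function(chr) {
    starts <- seq(0, cfg$chrom_len - 1, by = width)
    px <- which(positions$chrom == chr)
    bin <- findInterval(positions$pos[px], starts)
    mu_w <- rep(cfg$bg_mean, length(starts))
    tb <- tapply(truth$mu[px], bin, mean)
    mu_w[as.integer(names(tb))] <- as.numeric(tb)
    data.frame(chrom = chr, start = starts,
               end = pmin(starts + width, cfg$chrom_len),
               value = cfg$histone_s0 * (1 - mu_w) +
                 stats::rnorm(length(starts), 0, cfg$histone_noise))
  })
  do.call(rbind, out)
}

#' Simulate target-gene expression from SE truth methylation
#'
#' expr = exp(e0 - e1 x SE mean truth methylation) x lognormal noise, one
#' gene per SE; the generating parameters are recorded as attributes.
#'
#' @param se_truth output of \code{\link{implant_superenhancers}}.
#' @param positions data.frame(chrom, pos).
#' @param cfg a \code{\link{sim_config}}.
#' @return data.frame(gene, se_id, true_meth, expr).
#' @export
simulate_expression <- function(se_truth, positions, cfg) {
  set.seed(cfg$seed + 7L)
  ses <- se_truth$ses
  true_meth <- vapply(seq_len(nrow(ses)), function(i) {
    ix <- positions$chrom == ses$chrom[i] & positions$pos >= ses$start[i] &
      positions$pos < ses$end[i]
    if (!any(ix)) return(NA_real_)
    mean(se_truth$truth$mu[ix])
  }, numeric(1))
  out <- data.frame(gene = sprintf("gene_%03d", seq_len(nrow(ses))),
                    se_id = ses$se_id, true_meth = true_meth,
                    expr = exp(cfg$expr_e0 - cfg$expr_e1 * true_meth) *
                      stats::rlnorm(nrow(ses), 0, cfg$expr_noise))
  attr(out, "params") <- c(e0 = cfg$expr_e0, e1 = cfg$expr_e1,
                           noise = cfg$expr_noise)
  out
}

#' Simulate a complete paired normal/cancer dataset with ground truth
#'
#' Convenience wrapper running positions, segmentation, SE implantation,
#' cancer shift, methylome emission for both conditions, histone track and
#' expression table.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return list: positions, normal, cancer (methylomes), ses, labels,
#'   truth_normal, truth_cancer, histone, expression.
#' @export
simulate_dataset <- function(cfg) {
  positions <- simulate_positions(cfg)
  seg <- simulate_segmentation(positions, cfg)
  st <- implant_superenhancers(seg, positions, cfg)
  cs <- apply_cancer_shift(st, positions, cfg)
  normal <- simulate_methylome(positions, cfg = cfg, mu = st$truth$mu,
                               sample_id = "sim_normal",
                               condition = "normal", seed_offset = 3L)
  cancer <- simulate_methylome(positions, cfg = cfg, mu = cs$truth$mu,
                               sample_id = "sim_cancer",
                               condition = "cancer", seed_offset = 8L)
  list(positions = positions, normal = normal, cancer = cancer,
       ses = st$ses, labels = cs$labels,
       truth_normal = st$truth, truth_cancer = cs$truth,
       histone = simulate_histone_track(st$truth, positions, cfg),
       expression = simulate_expression(st, positions, cfg))
}
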