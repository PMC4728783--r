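#' Extend super-enhancers by 50 percent flanks and build the scaled map
#'
#' Each super-enhancer of length L gains flanks of L/2 on either side, so the
#' extended region is twice the original length. Positions map linearly to a
#' scaled coordinate with the SE center at 0, the original edges at -1/+1 and
#' the extended edges at -2/+2. Fractional bp from odd L are resolved by
#' floor on the left flank and ceiling on the right. If the left extension
#' would go below position 0 it is clipped (with a warning) but the scaled
#' map stays anchored to the unclipped geometry.
#'
#' @param ses data.frame of super-enhancers: chrom, start, end, se_id and
#'   optionally tissue, target_gene.
#' @return the input with added columns ext_start, ext_end, center, half
#'   (L/2, real-valued); class \code{extended_se}.
#' @export
extend_and_scale <- function(ses) {
  stopifnot(all(c("chrom", "start", "end") %in% names(ses)))
  if (any(ses$end <= ses$start)) stop("super-enhancer with length <= 0")
  if (!"se_id" %in% names(ses))
    ses$se_id <- sprintf("SE_%d", seq_len(nrow(ses)))
  L <- ses$end - ses$start
  ses$ext_start <- ses$start - floor(L / 2)
  ses$ext_end <- ses$end + ceiling(L / 2)
  ses$center <- (ses$start + ses$end) / 2
  ses$half <- L / 2
  if (any(ses$ext_start < 0)) {
    warning("extension clipped at position 0 for ",
            sum(ses$ext_start < 0), " super-enhancer(s)")
    ses$ext_start <- pmax(ses$ext_start, 0)
  }
  class(ses) <- c("extended_se", "data.frame")
  ses
}

#' Scaled coordinate of positions relative to one extended SE
#' @param ese one row of an \code{extended_se}.
#' @param pos genomic positions (bp).
#' @return (pos - center) / (L/2): -1/+1 at the SE edges, -2/+2 at the
#'   extended edges.
#' @export
se_scaled_position <- function(ese, pos) {
  (pos - ese$center) / ese$half
}

#' Scaled methylation profile of a super-enhancer
#'
#' One point per CpG inside the extended interval: scaled position in
#' \[-2, 2\] and smoothed methylation level.
#'
#' @param ese one row of an \code{extended_se}.
#' @param sm a \code{smoothed_methylome}.
#' @return data.frame(se_id, scaled_pos, smooth); attribute \code{covered}
#'   FALSE when no CpG falls in the extended interval.
#' @export
se_profile <- function(ese, sm) {
  ix <- which(sm$chrom == ese$chrom & sm$pos >= ese$ext_start &
                sm$pos < ese$ext_end)
  out <- data.frame(se_id = rep(ese$se_id, length(ix)),
                    scaled_pos = se_scaled_position(ese, sm$pos[ix]),
                    smooth = sm$smooth[ix])
  attr(out, "covered") <- length(ix) > 0
  out
}

#' Average smoothed methylation strictly inside a super-enhancer
#'
#' Unweighted mean of smoothed levels over CpGs in \[start, end). NA when no
#' CpG lies inside (the SE is then excluded from category analyses).
#'
#' @param ses an \code{extended_se} (or any data.frame with chrom/start/end).
#' @param sm a \code{smoothed_methylome}.
#' @return numeric vector of means along the rows of \code{ses}.
#' @export
se_average_methylation <- function(ses, sm) {
  vapply(seq_len(nrow(ses)), function(i) {
    ix <- sm$chrom == ses$chrom[i] & sm$pos >= ses$start[i] &
      sm$pos < ses$end[i]
    if (!any(ix)) return(NA_real_)
    mean(sm$smooth[ix])
  }, numeric(1))
}

#' Methylation category of a super-enhancer
#'
#' Four bins on the average methylation level, left-closed on the lower
#' edge: Q1 mean < 0.25, Q2 in \[0.25, 0.50), Q3 in \[0.50, 0.75),
#' Q4 >= 0.75.
#'
#' @param mean_meth average methylation in \[0, 1\] (NA allowed).
#' @return factor with levels Q1..Q4.
#' @export
se_categorize <- function(mean_meth) {
  cut(mean_meth, breaks = c(-Inf, 0.25, 0.50, 0.75, Inf),
      labels = c("Q1", "Q2", "Q3", "Q4"), right = FALSE)
}

#' WGBS coverage filter for super-enhancers
#'
#' Pass iff the fraction of the SE's CpG sites with coverage >= 1 read is
#' strictly greater than \code{min_frac}. The site registry is the observed
#' CpG records of the methylome (which may include zero-coverage sites); an
#' SE with no known CpG fails with an NA fraction.
#'
#' @param ses SE data.frame (chrom, start, end).
#' @param m a methylome.
#' @param min_frac coverage fraction threshold (default 0.5, strict >).
#' @return data.frame(se_id if present, n_cpgs, n_covered, frac, pass).
#' @export
se_coverage_filter <- function(ses, m, min_frac = 0.5) {
  cov <- m$meth + m$unmeth
  res <- lapply(seq_len(nrow(ses)), function(i) {
    ix <- m$chrom == ses$chrom[i] & m$pos >= ses$start[i] &
      m$pos < ses$end[i]
    n <- sum(ix)
    nc <- sum(cov[ix] >= 1)
    data.frame(n_cpgs = n, n_covered = nc,
               frac = if (n > 0) nc / n else NA_real_,
               pass = n > 0 && nc / n > min_frac)
  })
  out <- do.call(rbind, res)
  if ("se_id" %in% names(ses)) out <- cbind(se_id = ses$se_id, out)
  out
}

# union length of intervals (start, end) clipped to [lo, hi)
.union_overlap <- function(start, end, lo, hi) {
  s <- pmax(start, lo); e <- pmin(end, hi)
  keep <- s < e
  if (!any(keep)) return(0)
  s <- s[keep]; e <- e[keep]
  o <- order(s)
  s <- s[o]; e <- e[o]
  tot <- 0; cs <- s[1]; ce <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] > ce) { tot <- tot + (ce - cs); cs <- s[i]; ce <- e[i] }
    else ce <- max(ce, e[i])
  }
  tot + (ce - cs)
}

#' HMR occupancy of super-enhancers
#'
#' Base-pair fraction of each SE interval covered by the union of the HMRs
#' (overlapping HMRs are unioned first, so occupancy never exceeds 1).
#'
#' @param ses SE data.frame (chrom, start, end, se_id).
#' @param hmrs HMR data.frame (chrom, start, end).
#' @param sample_id label recorded in the output.
#' @return data.frame(se_id, sample_id, occupancy).
#' @export
se_occupancy <- function(ses, hmrs, sample_id = "sample") {
  occ <- vapply(seq_len(nrow(ses)), function(i) {
    hx <- hmrs$chrom == ses$chrom[i] & hmrs$end > ses$start[i] &
      hmrs$start < ses$end[i]
    if (!any(hx)) return(0)
    .union_overlap(hmrs$start[hx], hmrs$end[hx], ses$start[i], ses$end[i]) /
      (ses$end[i] - ses$start[i])
  }, numeric(1))
  ids <- if ("se_id" %in% names(ses)) ses$se_id
         else sprintf("SE_%d", seq_len(nrow(ses)))
  data.frame(se_id = ids, sample_id = sample_id, occupancy = occ)
}

#' Differential HMR occupancy (delta) and its class label
#'
#' delta = occupancy(cancer) - occupancy(normal) per SE; positive delta means
#' methylation loss in cancer. Label: "hypomethylated" if delta >
#' threshold, "hypermethylated" if delta < -threshold, else "unchanged"
#' (strict inequalities).
#'
#' @param occ_cancer,occ_normal outputs of \code{\link{se_occupancy}} for the
#'   same SE set (matched by se_id; mismatched sets are an error).
#' @param threshold magnitude threshold (default 0.25).
#' @return data.frame(se_id, occ_normal, occ_cancer, delta, label).
#' @export
delta_occupancy <- function(occ_cancer, occ_normal, threshold = 0.25) {
  j <- match(occ_cancer$se_id, occ_normal$se_id)
  if (anyNA(j) || nrow(occ_cancer) != nrow(occ_normal))
    stop("mismatched se_id sets between samples")
  delta <- occ_cancer$occupancy - occ_normal$occupancy[j]
  label <- ifelse(delta > threshold, "hypomethylated",
                  ifelse(delta < -threshold, "hypermethylated", "unchanged"))
  data.frame(se_id = occ_cancer$se_id,
             occ_normal = occ_normal$occupancy[j],
             occ_cancer = occ_cancer$occupancy,
             delta = delta, label = label)
}

#' Tissue-specific super-enhancer calls from an occupancy matrix
#'
#' An SE is specific to tissue t iff its HMR occupancy in t exceeds
#' \code{abs_thr} and exceeds the summary (mean or max) of its occupancy in
#' the remaining tissues by more than \code{diff_thr} (both strict).
#'
#' @param occ_matrix numeric matrix, rows = SEs (rownames se_id),
#'   columns = tissues.
#' @param abs_thr absolute occupancy threshold (default 0.20).
#' @param diff_thr difference threshold versus the other tissues
#'   (default 0.10).
#' @param other how to summarize the remaining tissues ("mean" or "max").
#' @return logical matrix of the same shape: TRUE = specific to that tissue.
#' @export
call_tissue_specific <- function(occ_matrix, abs_thr = 0.20, diff_thr = 0.10,
                                 other = c("mean", "max")) {
  other <- match.arg(other)
  if (ncol(occ_matrix) < 2) stop("need at least 2 tissues")
  fun <- if (other == "mean") rowMeans else function(x) apply(x, 1, max)
  res <- matrix(FALSE, nrow(occ_matrix), ncol(occ_matrix),
                dimnames = dimnames(occ_matrix))
  for (t in seq_len(ncol(occ_matrix))) {
    rest <- fun(occ_matrix[, -t, drop = FALSE])
    ok <- !is.na(occ_matrix[, t]) & !is.na(rest)
    res[ok, t] <- occ_matrix[ok, t] > abs_thr &
      (occ_matrix[ok, t] - rest[ok]) > diff_thr
  }
  res
}

# per-SE flank-minus-inside smoothed methylation difference
.se_reduction <- function(ses, sm) {
  vapply(seq_len(nrow(ses)), function(i) {
    on_chr <- sm$chrom == ses$chrom[i]
    inside <- on_chr & sm$pos >= ses$start[i] & sm$pos < ses$end[i]
    flank <- on_chr & sm$pos >= ses$ext_start[i] & sm$pos < ses$ext_end[i] &
      !inside
    if (!any(inside) || !any(flank)) return(NA_real_)
    mean(sm$smooth[flank]) - mean(sm$smooth[inside])
  }, numeric(1))
}

#' Paired flank-versus-inside methylation reduction test
#'
#' For each SE and sample, r = mean smoothed methylation in the flanks minus
#' mean inside the SE (the focal "reduction"). A paired two-sided t-test
#' compares the per-SE reductions between the cancer and the normal sample:
#' a global methylation shift leaves r unchanged, a focal SE-specific shift
#' increases it.
#'
#' @param sm_normal,sm_cancer smoothed methylomes of the paired samples.
#' @param ses an \code{extended_se}.
#' @return list: n (SEs used), mean_r_normal, mean_r_cancer, t, p.
#' @export
flank_inside_reduction <- function(sm_normal, sm_cancer, ses) {
  stopifnot(inherits(ses, "extended_se"))
  rn <- .se_reduction(ses, sm_normal)
  rc <- .se_reduction(ses, sm_cancer)
  ok <- !is.na(rn) & !is.na(rc)
  if (sum(ok) < 2) stop("fewer than 2 SEs with paired observations")
  d <- rc[ok] - rn[ok]
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(list(n = sum(ok), mean_r_normal = mean(rn[ok]),
                  mean_r_cancer = mean(rc[ok]), t = 0, p = 1))
    stop("zero variance of paired differences; t statistic undefined")
  }
  tt <- stats::t.test(rc[ok], rn[ok], paired = TRUE)
  list(n = sum(ok), mean_r_normal = mean(rn[ok]),
       mean_r_cancer = mean(rc[ok]),
       t = unname(tt$statistic), p = tt$p.value)
}

#' Array-based validation of differential SE methylation
#'
#' For SEs represented by at least \code{min_probes} array probes: the
#' per-sample mean beta value over the SE's probes is compared between the
#' target group and the remaining samples by a two-sided t-test;
#' Benjamini-Hochberg adjustment across testable SEs. Validated iff the
#' target-group mean beta is < \code{beta_thr} and FDR < \code{fdr_thr}.
#'
#' @param beta_table numeric matrix probes x samples, values in \[0, 1\].
#' @param probe_map data.frame(probe_id, se_id) joining probes (rownames of
#'   beta_table) to SEs.
#' @param group_labels factor/character per sample column.
#' @param target_group the group whose methylation must be low.
#' @param min_probes minimum probes per SE (default 3).
#' @param beta_thr target-group mean beta threshold (default 0.33).
#' @param fdr_thr FDR threshold (default 0.05).
#' @return data.frame(se_id, n_probes, mean_target, mean_other, p, fdr,
#'   verdict in {validated, not_validated, not_testable}).
#' @export
array_validate <- function(beta_table, probe_map, group_labels, target_group,
                           min_probes = 3, beta_thr = 0.33, fdr_thr = 0.05) {
  stopifnot(target_group %in% group_labels)
  tgt <- group_labels == target_group
  ses <- unique(probe_map$se_id)
  rows <- lapply(ses, function(id) {
    probes <- probe_map$probe_id[probe_map$se_id == id]
    probes <- intersect(probes, rownames(beta_table))
    if (length(probes) < min_probes)
      return(data.frame(se_id = id, n_probes = length(probes),
                        mean_target = NA_real_, mean_other = NA_real_,
                        p = NA_real_))
    means <- colMeans(beta_table[probes, , drop = FALSE])
    # degenerate (constant) groups: p = 1 when equal, 0 when perfectly split
    p <- tryCatch(stats::t.test(means[tgt], means[!tgt])$p.value,
                  error = function(e)
                    if (mean(means[tgt]) == mean(means[!tgt])) 1 else 0)
    data.frame(se_id = id, n_probes = length(probes),
               mean_target = mean(means[tgt]),
               mean_other = mean(means[!tgt]), p = p)
  })
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  testable <- !is.na(out$p)
  out$fdr[testable] <- bh_fdr(out$p[testable])
  out$verdict <- ifelse(!testable, "not_testable",
                        ifelse(out$mean_target < beta_thr &
                                 out$fdr < fdr_thr,
                               "validated", "not_validated"))
  out
}
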