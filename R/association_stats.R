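#' Classify a methylation level as hypo-, hyper- or intermediate
#'
#' hypo if m < 0.33, hyper if m > 0.66, intermediate otherwise (strict
#' inequalities: the boundaries themselves are intermediate). Vectorized.
#'
#' @param m smoothed methylation levels in \[0, 1\] (NA passes through).
#' @return character vector.
#' @export
classify_cpg <- function(m) {
  ifelse(is.na(m), NA_character_,
         ifelse(m < 0.33, "hypo", ifelse(m > 0.66, "hyper", "intermediate")))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p: with all margins fixed, the hypergeometric probabilities of
#' every table whose probability is at most that of the observed table are
#' summed. The odds ratio is the cross-product (a d)/(b c), with the Haldane
#' correction (+0.5 to every cell) applied iff any cell is zero. A zero
#' margin gives p = 1 and an undefined (NA) odds ratio.
#'
#' @param tab 2x2 matrix of non-negative counts, or a length-4 vector
#'   (a, b, c, d) filled by row.
#' @return list(odds_ratio, p).
#' @export
fisher_exact <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(tab, 2, 2, byrow = TRUE)
  stopifnot(all(dim(tab) == 2), all(tab >= 0))
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  if (a + b + c + d == 0) stop("empty table")
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  if (r1 == 0 || c1 == 0 || r1 == N || c1 == N)
    return(list(odds_ratio = NA_real_, p = 1))
  or <- if (any(tab == 0)) ((a + .5) * (d + .5)) / ((b + .5) * (c + .5))
        else (a * d) / (b * c)
  support <- max(0, r1 + c1 - N):min(r1, c1)
  pr <- stats::dhyper(support, c1, N - c1, r1)
  p_obs <- stats::dhyper(a, c1, N - c1, r1)
  p <- sum(pr[pr <= p_obs * (1 + 1e-7)])
  list(odds_ratio = or, p = min(p, 1))
}

#' Per-window histone signal, methylation and CpG density
#'
#' Tiles a region with non-overlapping windows of \code{width} bp from the
#' region start (a shorter terminal remainder window is kept but flagged
#' \code{full = FALSE}). Per window: base-pair-weighted mean of the signal
#' track, unweighted mean of the smoothed methylation of member CpGs (NA and
#' excluded from class-based tests when the window has no CpG), CpG density
#' (CpGs per bp) and the methylation class of the window mean.
#'
#' @param signal data.frame(chrom, start, end, value) signal track
#'   (ChIP vs input).
#' @param sm a \code{smoothed_methylome}.
#' @param region list or one-row data.frame with chrom, start, end.
#' @param width window width in bp (default 50).
#' @return data.frame(chrom, start, end, full, mean_signal, mean_meth,
#'   cpg_density, meth_class).
#' @export
window_stats <- function(signal, sm, region, width = 50) {
  starts <- seq(region$start, region$end - 1, by = width)
  ends <- pmin(starts + width, region$end)
  sg <- signal[signal$chrom == region$chrom, , drop = FALSE]
  cp <- sm[sm$chrom == region$chrom, , drop = FALSE]
  out <- data.frame(chrom = region$chrom, start = starts, end = ends,
                    full = (ends - starts) == width)
  out$mean_signal <- vapply(seq_along(starts), function(i) {
    ov <- pmin(sg$end, ends[i]) - pmax(sg$start, starts[i])
    keep <- ov > 0
    if (!any(keep)) return(NA_real_)
    sum(sg$value[keep] * ov[keep]) / sum(ov[keep])
  }, numeric(1))
  cnt <- numeric(length(starts)); msum <- numeric(length(starts))
  bin <- findInterval(cp$pos, starts)
  inwin <- bin >= 1 & cp$pos < ends[pmax(bin, 1)]
  tb <- tapply(cp$smooth[inwin], bin[inwin], mean)
  nb <- table(bin[inwin])
  out$mean_meth <- NA_real_
  out$mean_meth[as.integer(names(tb))] <- as.numeric(tb)
  out$cpg_density <- 0
  out$cpg_density[as.integer(names(nb))] <-
    as.integer(nb) / (ends[as.integer(names(nb))] -
                        starts[as.integer(names(nb))])
  out$meth_class <- classify_cpg(out$mean_meth)
  out
}

#' Wilcoxon rank-sum test with midrank ties
#'
#' Statistic W = sum of the pooled-sample midranks of group x. Two-sided p:
#' exact by enumeration of all rank assignments when n1 + n2 <= 12
#' (probability of |W' - E\[W\]| >= |W - E\[W\]|), otherwise the normal
#' approximation with tie correction. All values identical gives p = 1.
#'
#' @param x,y numeric vectors (both non-empty).
#' @return list(W, p, method).
#' @export
rank_sum_test <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L)
    return(list(W = n1 * (N + 1) / 2, p = 1, method = "degenerate"))
  r <- rank(pooled)
  W <- sum(r[seq_len(n1)])
  EW <- n1 * (N + 1) / 2
  if (N <= 12) {
    combs <- utils::combn(N, n1)
    Ws <- colSums(matrix(r[combs], nrow = n1))
    p <- mean(abs(Ws - EW) >= abs(W - EW) - 1e-9)
    return(list(W = W, p = p, method = "exact"))
  }
  ties <- table(r)
  V <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- (W - EW) / sqrt(V)
  list(W = W, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
}

#' Linear model of histone signal on methylation status and CpG density
#'
#' OLS with the window signal as response and methylation status (hyper = 1,
#' hypo = 0; intermediate windows dropped) plus CpG density as predictors.
#' Reports the status coefficient and its t-based p-value.
#'
#' @param windows output of \code{\link{window_stats}} (or any data.frame
#'   with mean_signal, meth_class, cpg_density).
#' @return list(coef (named vector), status_coef, status_p, n).
#' @export
linear_model_signal <- function(windows) {
  w <- windows[windows$meth_class %in% c("hypo", "hyper") &
                 !is.na(windows$mean_signal), , drop = FALSE]
  if (nrow(w) < 3) stop("need at least 3 hypo/hyper windows")
  w$status <- as.integer(w$meth_class == "hyper")
  if (length(unique(w$status)) < 2)
    stop("both methylation statuses must be present")
  X <- cbind(1, w$status, w$cpg_density)
  if (qr(X)$rank < 3) stop("collinear design")
  fit <- stats::lm(mean_signal ~ status + cpg_density, data = w)
  sm <- summary(fit)$coefficients
  list(coef = stats::coef(fit), status_coef = unname(stats::coef(fit)["status"]),
       status_p = sm["status", 4], n = nrow(w))
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of midranks. p two-sided: exact by full
#' permutation enumeration when n <= 8, otherwise the t approximation
#' \eqn{t = rho \sqrt{(n-2)/(1-rho^2)}}. Zero variance in either rank vector
#' gives an NA (undefined) result.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return list(rho, p, n, method).
#' @export
spearman_test <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "degenerate"))
  rho <- stats::cor(rx, ry)
  if (n <= 8) {
    perms <- .permutations(n)
    rhos <- apply(perms, 1, function(pm) stats::cor(rx, ry[pm]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-9)
    return(list(rho = rho, p = p, n = n, method = "exact"))
  }
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = min(1, 2 * stats::pt(-abs(tt), n - 2)), n = n,
       method = "t")
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- .permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Assign a super-enhancer to its closest TSS
#'
#' Distance from the SE boundary (0 if the TSS lies inside the SE) to each
#' TSS; the gene minimizing the distance wins if that distance is at most
#' \code{max_dist} (1 Mb); otherwise no target. Ties are broken by the
#' smaller TSS coordinate (logged via attribute \code{tie}).
#'
#' @param se one-row data.frame or list with chrom, start, end.
#' @param tss data.frame(gene, chrom, pos) where pos is the most upstream
#'   annotated base of the gene.
#' @param max_dist maximum distance in bp (default 1e6, inclusive).
#' @return list(gene, distance) with gene = NA when no TSS qualifies.
#' @export
assign_target <- function(se, tss, max_dist = 1e6) {
  tt <- tss[tss$chrom == se$chrom, , drop = FALSE]
  if (nrow(tt) == 0) return(list(gene = NA_character_, distance = NA_real_))
  d <- pmax(se$start - tt$pos, tt$pos - (se$end - 1), 0)
  dmin <- min(d)
  if (dmin > max_dist) return(list(gene = NA_character_, distance = dmin))
  hits <- which(d == dmin)
  tie <- length(hits) > 1
  pick <- hits[which.min(tt$pos[hits])]
  out <- list(gene = tt$gene[pick], distance = dmin)
  attr(out, "tie") <- tie
  out
}

#' Log-linear model of expression on SE methylation
#'
#' OLS of log(expr + 1) on the average SE methylation (the +1 offset guards
#' zero expression values). Reports slope and t-based p.
#'
#' @param expr non-negative normalized expression values.
#' @param meth average SE methylation per gene.
#' @return list(slope, intercept, p, n).
#' @export
loglinear_expression <- function(expr, meth) {
  n <- length(expr)
  stopifnot(length(meth) == n, n >= 3, all(expr >= 0))
  if (stats::sd(meth) == 0) stop("degenerate predictor: constant methylation")
  fit <- stats::lm(log(expr + 1) ~ meth)
  sm <- summary(fit)$coefficients
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       p = sm[2, 4], n = n)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up: sort p ascending, q_i = min_{j >= i} (n p_j / j), capped at 1;
#' returned in the original order. Output is pointwise >= the input.
#'
#' @param p p-values in \[0, 1\].
#' @return adjusted values.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  n <- length(p)
  if (n == 0) return(numeric(0))
  o <- order(p)
  q <- pmin(1, rev(cummin(rev(p[o] * n / seq_len(n)))))
  out <- numeric(n)
  out[o] <- q
  out
}
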