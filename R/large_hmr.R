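#' Candidate selection for large-HMR detection
#'
#' Keeps HMRs whose mean smoothed methylation level is strictly below 0.2.
#'
#' @param hmrs HMR data.frame (chrom, start, end, ...).
#' @param sm a \code{smoothed_methylome} covering the HMRs.
#' @param max_level threshold on the mean smoothed level (default 0.2,
#'   strict <).
#' @return the subset of \code{hmrs}, with a \code{mean_smooth} column.
#' @export
select_candidates <- function(hmrs, sm, max_level = 0.2) {
  if (nrow(hmrs) == 0) {
    hmrs$mean_smooth <- numeric(0)
    return(hmrs)
  }
  hmrs$mean_smooth <- vapply(seq_len(nrow(hmrs)), function(i) {
    ix <- sm$chrom == hmrs$chrom[i] & sm$pos >= hmrs$start[i] &
      sm$pos < hmrs$end[i]
    if (!any(ix)) return(NA_real_)
    mean(sm$smooth[ix])
  }, numeric(1))
  out <- hmrs[!is.na(hmrs$mean_smooth) & hmrs$mean_smooth < max_level, ,
              drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank-scale HMR sizes to the unit square
#'
#' Sorts regions by genomic size ascending (ties broken by chrom, start) and
#' maps rank i of n to \eqn{x_i = (i - 0.5)/n} and size to
#' \eqn{y_i = size_i / size_n} (largest size = 1). The half-offset keeps the
#' logit of x finite at both ends.
#'
#' @param hmrs HMR data.frame with at least chrom, start, end.
#' @return data.frame: the input columns plus size, x, y, sorted ascending by
#'   size.
#' @export
scale_rank <- function(hmrs) {
  n <- nrow(hmrs)
  if (n < 2) stop("need at least 2 regions to rank-scale")
  hmrs$size <- hmrs$end - hmrs$start
  o <- order(hmrs$size, hmrs$chrom, hmrs$start)
  out <- hmrs[o, , drop = FALSE]
  out$x <- (seq_len(n) - 0.5) / n
  out$y <- out$size / out$size[n]
  rownames(out) <- NULL
  out
}

.logit <- function(p) log(p / (1 - p))

#' Fit the log-size versus logit-index line on the upper tail
#'
#' Ordinary least squares of \code{log(y)} on \code{logit(x)} over the
#' regions whose size exceeds the \code{size_quantile} quantile of sizes (the
#' high-index upper tail; on size-sorted data the size and index criteria
#' coincide).
#'
#' @param ranked output of \code{\link{scale_rank}}.
#' @param size_quantile quantile defining the fit subset (default 0.90).
#' @return list of class \code{elbow_fit}: a (intercept), b (slope),
#'   n_fit, size_quantile.
#' @export
fit_log_logit <- function(ranked, size_quantile = 0.90) {
  qs <- stats::quantile(ranked$size, size_quantile, type = 7)
  sub <- ranked[ranked$size > qs, , drop = FALSE]
  if (nrow(sub) < 3) stop("fit subset has fewer than 3 points")
  if (length(unique(sub$y)) == 1L) stop("degenerate fit: all sizes equal")
  X <- .logit(sub$x)
  Y <- log(sub$y)
  b <- stats::cov(X, Y) / stats::var(X)
  a <- mean(Y) - b * mean(X)
  structure(list(a = a, b = b, n_fit = nrow(sub),
                 size_quantile = size_quantile),
            class = "elbow_fit")
}

#' Tangent-slope-1 cutoff on the fitted rank-size curve
#'
#' On the original scale the fitted curve is
#' \eqn{y(x) = exp(a + b\,logit(x))} with derivative
#' \eqn{g(x) = y(x)\, b / (x(1-x))}. The cutoff \code{x_star} solves
#' \eqn{g(x) = 1} on (0.5, 1): a sign scan over a fine grid locates the sign
#' changes of \eqn{g - 1} and bisection refines the largest root to 1e-8.
#' If g > 1 everywhere the cutoff collapses to the 0.5 boundary (warning);
#' if g < 1 everywhere no region is large (x_star = 1).
#'
#' @param fit an \code{elbow_fit} with b > 0.
#' @return x_star in (0.5, 1\].
#' @export
tangent_cutoff <- function(fit) {
  if (fit$b <= 0) stop("tangent cutoff requires a positive slope b")
  g1 <- function(x) exp(fit$a + fit$b * .logit(x)) * fit$b / (x * (1 - x)) - 1
  lo <- 0.5; hi <- 1 - 1e-9
  xs <- seq(lo, hi, length.out = 4096)
  v <- g1(xs)
  sgn <- sign(v)
  ch <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (length(ch) == 0) {
    if (all(v > 0)) {
      warning("curve slope exceeds 1 on the whole interval; x_star = 0.5")
      return(0.5)
    }
    return(1)
  }
  i <- ch[length(ch)]  # largest root: the upper tangent
  stats::uniroot(g1, c(xs[i], xs[i + 1]), tol = 1e-10)$root
}

#' Classify large HMRs
#'
#' Regions with scaled index x strictly above \code{x_star} are large. The
#' large set is an upper set in the size ordering.
#'
#' @param ranked output of \code{\link{scale_rank}}.
#' @param x_star tangent cutoff.
#' @return logical vector along \code{ranked} rows (TRUE = large).
#' @export
classify_large <- function(ranked, x_star) {
  ranked$x > x_star
}

#' Detect large HMRs (full per-sample procedure)
#'
#' Candidate selection (mean smoothed level < 0.2), rank scaling, log-logit
#' fit on the upper size tail, tangent-slope-1 cutoff, classification.
#'
#' @param hmrs called HMRs for one sample.
#' @param sm the sample's smoothed methylome.
#' @param size_quantile fit-subset quantile (default 0.90).
#' @param max_level candidate smoothed-level threshold (default 0.2).
#' @return list: \code{large} (data.frame of large HMRs), \code{ranked},
#'   \code{fit} (with x_star and size_cutoff in bp).
#' @export
find_large_hmrs <- function(hmrs, sm, size_quantile = 0.90, max_level = 0.2) {
  cand <- select_candidates(hmrs, sm, max_level)
  ranked <- scale_rank(cand)
  fit <- fit_log_logit(ranked, size_quantile)
  x_star <- tangent_cutoff(fit)
  is_large <- classify_large(ranked, x_star)
  fit$x_star <- x_star
  fit$size_cutoff <- if (any(is_large)) min(ranked$size[is_large]) else Inf
  list(large = ranked[is_large, , drop = FALSE], ranked = ranked, fit = fit)
}
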