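#' Local-likelihood smoothing of CpG methylation levels
#'
#' Produces a smoothed methylation level per CpG by a degree-0 local
#' likelihood fit: at each site the estimate is the kernel- and
#' coverage-weighted binomial mean over neighbouring CpGs,
#' \deqn{\hat m_i = \sum_j w_{ij} \, meth_j \; / \; \sum_j w_{ij} (meth_j + unmeth_j),}
#' with tricube weights \eqn{w_{ij} = (1 - (d_{ij}/h_i)^3)^3} on genomic
#' distance. The base kernel half-width is \code{half_window}; if fewer than
#' \code{min_cpgs} sites fall inside the window it expands symmetrically (one
#' site on each side per step, clamped at chromosome ends) and the kernel
#' radius grows to the furthest included site plus 1 bp so every included
#' site keeps positive weight. Chromosomes are never mixed.
#'
#' Zero-coverage sites contribute weight 0 to the fit but still receive a
#' fitted value from their neighbours. A single-site chromosome gets its raw
#' level (0.5 if undefined, with a warning). Degree 0 guarantees the estimate
#' stays in \[0, 1\] without clipping and that constant input is reproduced
#' exactly.
#'
#' @param m a \code{\link{methylome}}.
#' @param half_window kernel half-width in bp (default 500).
#' @param min_cpgs minimum number of CpGs per fitting window (default 10).
#' @return the methylome with added columns \code{raw} (per-site level, NA at
#'   zero coverage) and \code{smooth}; class \code{smoothed_methylome}.
#' @export
smooth_methylome <- function(m, half_window = 500, min_cpgs = 10) {
  stopifnot(inherits(m, "methylome"), half_window > 0, min_cpgs >= 1)
  out <- as.data.frame(m)
  out$raw <- methylation_level(m$meth, m$unmeth)
  out$smooth <- NA_real_
  for (chr in unique(out$chrom)) {
    idx <- which(out$chrom == chr)
    out$smooth[idx] <- .smooth_chrom(out$pos[idx], out$meth[idx],
                                     out$unmeth[idx], out$raw[idx],
                                     half_window, min_cpgs)
  }
  structure(out, class = c("smoothed_methylome", "methylome", "data.frame"),
            sample_id = attr(m, "sample_id"), tissue = attr(m, "tissue"),
            condition = attr(m, "condition"),
            half_window = half_window, min_cpgs = min_cpgs)
}

.tricube <- function(u) {
  w <- (1 - pmin(abs(u), 1)^3)^3
  w
}

.smooth_chrom <- function(pos, meth, unmeth, raw, half_window, min_cpgs) {
  n <- length(pos)
  if (n == 0) return(numeric(0))
  if (n == 1) {
    if (is.na(raw)) {
      warning("single zero-coverage CpG on chromosome; smoothed level 0.5")
      return(0.5)
    }
    return(raw)
  }
  cov <- meth + unmeth
  lo0 <- findInterval(pos - half_window - 0.5, pos) + 1L
  hi0 <- findInterval(pos + half_window + 0.5, pos)
  sm <- numeric(n)
  for (i in seq_len(n)) {
    lo <- lo0[i]; hi <- hi0[i]
    repeat {
      while (hi - lo + 1L < min_cpgs && (lo > 1L || hi < n)) {
        if (lo > 1L) lo <- lo - 1L
        if (hi < n) hi <- hi + 1L
      }
      d <- abs(pos[lo:hi] - pos[i])
      h <- max(half_window, max(d) + 1)
      w <- .tricube(d / h)
      den <- sum(w * cov[lo:hi])
      if (den > 0 || (lo == 1L && hi == n)) break
      # all included sites uncovered: widen until data appear
      if (lo > 1L) lo <- lo - 1L
      if (hi < n) hi <- hi + 1L
    }
    if (den > 0) {
      sm[i] <- sum(w * meth[lo:hi]) / den
    } else {
      warning("no covered CpGs on chromosome; smoothed level 0.5")
      sm[i] <- 0.5
    }
  }
  sm
}

#' Write smoothed levels as a bedGraph (one 1-bp record per CpG)
#' @param sm a smoothed_methylome.
#' @param path output path.
#' @export
write_smoothed_bedgraph <- function(sm, path) {
  stopifnot(inherits(sm, "smoothed_methylome"))
  write_bedgraph(sm$chrom, sm$pos, sm$pos + 1L, sm$smooth, path = path)
}

#' Read smoothed levels back from a bedGraph into a smoothed_methylome
#'
#' Joins a bedGraph of smoothed levels (as written by
#' \code{\link{write_smoothed_bedgraph}}) onto a methylome's sites.
#' @param m a methylome.
#' @param path bedGraph path.
#' @export
read_smoothed_bedgraph <- function(m, path) {
  bg <- read_bedgraph(path)
  key_m <- paste(m$chrom, m$pos)
  key_b <- paste(bg$chrom, bg$start)
  out <- as.data.frame(m)
  out$raw <- methylation_level(m$meth, m$unmeth)
  out$smooth <- bg$value[match(key_m, key_b)]
  if (anyNA(out$smooth)) stop("bedGraph does not cover all CpG sites")
  structure(out, class = c("smoothed_methylome", "methylome", "data.frame"),
            sample_id = attr(m, "sample_id"), tissue = attr(m, "tissue"),
            condition = attr(m, "condition"))
}
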