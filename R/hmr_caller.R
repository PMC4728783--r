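#' Configuration for HMR calling
#'
#' @param n_permutations permutations for the null score distribution
#'   (default 20).
#' @param seed RNG seed used by the permutation filter.
#' @param max_iter maximum Baum-Welch iterations (default 100).
#' @param tol relative log-likelihood convergence tolerance (default 1e-4).
#' @param gap_bp CpG gap (bp) beyond which the observation chain is broken and
#'   restarted from the initial distribution; chromosome ends always break
#'   (default 5000).
#' @param decode "posterior" (per-site argmax, default) or "viterbi".
#' @return list of class \code{hmr_call_config}.
#' @export
hmr_call_config <- function(n_permutations = 20, seed = 1, max_iter = 100,
                            tol = 1e-4, gap_bp = 5000,
                            decode = c("posterior", "viterbi")) {
  stopifnot(n_permutations >= 1, max_iter >= 1, tol > 0, gap_bp > 0)
  structure(list(n_permutations = n_permutations, seed = seed,
                 max_iter = max_iter, tol = tol, gap_bp = gap_bp,
                 decode = match.arg(decode)),
            class = "hmr_call_config")
}

#' Beta-binomial log-pmf
#'
#' log P(k | n, alpha, beta) for the beta-binomial emission model; vectorized
#' over sites.
#' @param k methylated counts.
#' @param n total coverage.
#' @param alpha,beta beta shape parameters (> 0).
#' @export
dbetabinom_log <- function(k, n, alpha, beta) {
  lchoose(n, k) + lbeta(k + alpha, n - k + beta) - lbeta(alpha, beta)
}

# covered-site indices split into chains at chromosome ends and gaps > gap_bp
.hmm_chains <- function(chrom, pos, gap_bp) {
  n <- length(pos)
  if (n == 0) return(integer(0))
  brk <- c(TRUE, chrom[-1] != chrom[-n] | (pos[-1] - pos[-n]) > gap_bp)
  cumsum(brk)
}

# scaled forward-backward for one chain.
# ll: n x 2 matrix of emission log-likelihoods.
# Returns gamma (n x 2 posteriors), xi (2 x 2 summed transition counts),
# loglik, gamma at t = 1.
.fb_chain <- function(ll, initial, transition) {
  n <- nrow(ll)
  mx <- pmax(ll[, 1], ll[, 2])
  e <- exp(ll - mx)
  alpha <- matrix(0, n, 2)
  cvec <- numeric(n)
  a <- initial * e[1, ]
  cvec[1] <- sum(a)
  alpha[1, ] <- a / cvec[1]
  for (t in 2:n) {
    a <- (alpha[t - 1, ] %*% transition) * e[t, ]
    cvec[t] <- sum(a)
    alpha[t, ] <- a / cvec[t]
  }
  beta <- matrix(0, n, 2)
  beta[n, ] <- 1
  xi <- matrix(0, 2, 2)
  for (t in (n - 1):1) {
    eb <- e[t + 1, ] * beta[t + 1, ]
    beta[t, ] <- (transition %*% eb) / cvec[t + 1]
    xi <- xi + (outer(alpha[t, ], eb) * transition) / cvec[t + 1]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  list(gamma = gamma, xi = xi, loglik = sum(log(cvec)) + sum(mx),
       gamma1 = gamma[1, ])
}

# E-step over all chains; ll is n x 2 for covered sites, chains the chain ids
.fb_all <- function(ll, chains, initial, transition) {
  gamma <- matrix(0, nrow(ll), 2)
  xi <- matrix(0, 2, 2)
  g1 <- c(0, 0)
  loglik <- 0
  nchain <- 0L
  for (cid in unique(chains)) {
    idx <- which(chains == cid)
    if (length(idx) == 1) {
      # single-site chain: posterior from initial and emission only
      p <- initial * exp(ll[idx, ] - max(ll[idx, ]))
      p <- p / sum(p)
      gamma[idx, ] <- p
      g1 <- g1 + p
      loglik <- loglik + log(sum(initial * exp(ll[idx, ] - max(ll[idx, ])))) +
        max(ll[idx, ])
    } else {
      fb <- .fb_chain(ll[idx, , drop = FALSE], initial, transition)
      gamma[idx, ] <- fb$gamma
      xi <- xi + fb$xi
      g1 <- g1 + fb$gamma1
      loglik <- loglik + fb$loglik
    }
    nchain <- nchain + 1L
  }
  list(gamma = gamma, xi = xi, g1 = g1 / nchain, loglik = loglik)
}

# weighted beta-binomial M-step: maximize sum_i w_i log BB(k_i | n_i, a, b).
# Bounded in log space: shapes confined to [1e-3, 1e4]. Unbounded search is
# numerically unsafe (lgamma differences of huge shapes lose all precision
# and fake a likelihood of ~0).
.bb_mstep <- function(k, n, w, init_ab) {
  nll <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    -sum(w * dbetabinom_log(k, n, a, b))
  }
  fit <- stats::optim(log(pmin(pmax(init_ab, 1e-3), 1e4)), nll,
                      method = "L-BFGS-B",
                      lower = log(1e-3), upper = log(1e4),
                      control = list(maxit = 200, factr = 1e4))
  exp(fit$par)
}

#' Fit the two-state beta-binomial HMM
#'
#' Baum-Welch EM on the covered CpG sites of a methylome. Emissions are
#' beta-binomial on raw (meth, coverage) counts; the observation sequence is
#' broken (restarting from the initial distribution) at chromosome ends and
#' at CpG gaps larger than \code{cfg$gap_bp}. The M-step for the emission
#' shapes is a bounded numerical maximization of the expected beta-binomial
#' log-likelihood, warm-started from the previous iterate; EM is initialized
#' at state means 0.2 / 0.8 (precision 10). Iteration stops when the relative
#' log-likelihood change drops below \code{cfg$tol} or after
#' \code{cfg$max_iter} iterations. States are returned ordered so that
#' mean(low) < mean(high).
#'
#' @param m a methylome with at least 100 covered CpGs.
#' @param cfg an \code{\link{hmr_call_config}}.
#' @return list of class \code{hmm_params}: \code{initial} (2-vector),
#'   \code{transition} (2x2 row-stochastic, order low/high),
#'   \code{emissions} (list low/high with alpha, beta, mean),
#'   \code{loglik_trace}, \code{n_iter}, \code{converged}.
#' @export
fit_hmm <- function(m, cfg = hmr_call_config()) {
  cov <- m$meth + m$unmeth
  keep <- which(cov > 0)
  if (length(keep) < 100)
    stop("need at least 100 covered CpGs to fit the HMM")
  k <- m$meth[keep]; n <- cov[keep]
  lev <- k / n
  if (length(unique(lev)) == 1L)
    stop("two states unidentifiable: all methylation levels identical")
  chains <- .hmm_chains(m$chrom[keep], m$pos[keep], cfg$gap_bp)

  initial <- c(0.5, 0.5)
  transition <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE)
  prec <- 10
  ab <- list(c(0.2, 0.8) * prec, c(0.8, 0.2) * prec)  # state 1 low, 2 high

  trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(cfg$max_iter)) {
    ll <- cbind(dbetabinom_log(k, n, ab[[1]][1], ab[[1]][2]),
                dbetabinom_log(k, n, ab[[2]][1], ab[[2]][2]))
    es <- .fb_all(ll, chains, initial, transition)
    trace <- c(trace, es$loglik)
    if (iter > 1) {
      rel <- abs(trace[iter] - trace[iter - 1]) /
        (abs(trace[iter - 1]) + .Machine$double.eps)
      if (rel < cfg$tol) { converged <- TRUE; break }
    }
    initial <- es$g1
    initial <- initial / sum(initial)
    transition <- es$xi / rowSums(es$xi)
    for (s in 1:2) ab[[s]] <- .bb_mstep(k, n, es$gamma[, s], ab[[s]])
  }

  means <- vapply(ab, function(p) p[1] / sum(p), numeric(1))
  ord <- order(means)
  params <- list(
    initial = initial[ord],
    transition = transition[ord, ord, drop = FALSE],
    emissions = list(
      low = list(alpha = ab[[ord[1]]][1], beta = ab[[ord[1]]][2],
                 mean = means[ord[1]]),
      high = list(alpha = ab[[ord[2]]][1], beta = ab[[ord[2]]][2],
                  mean = means[ord[2]])),
    loglik_trace = trace, n_iter = length(trace), converged = converged)
  class(params) <- "hmm_params"
  params
}

#' @export
print.hmm_params <- function(x, ...) {
  cat(sprintf(
    "two-state beta-binomial HMM: mean(low)=%.3f mean(high)=%.3f\n",
    x$emissions$low$mean, x$emissions$high$mean))
  cat(sprintf("self-transitions: low %.4f, high %.4f; %d EM iterations%s\n",
              x$transition[1, 1], x$transition[2, 2], x$n_iter,
              if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' Posterior decoding of a methylome
#'
#' Forward-backward posteriors per covered CpG under fitted parameters;
#' the label is the argmax state ("low"/"high"). Posteriors at each site sum
#' to 1. With \code{cfg$decode = "viterbi"} the joint-MAP path is used for
#' the labels instead (posteriors still reported).
#'
#' @param m a methylome.
#' @param params an \code{hmm_params}.
#' @param cfg an \code{\link{hmr_call_config}} (chain-break distance, decoder).
#' @return data.frame: chrom, pos, meth, unmeth, chain, post_low, post_high,
#'   state; attribute \code{loglik}.
#' @export
posterior_decode <- function(m, params, cfg = hmr_call_config()) {
  cov <- m$meth + m$unmeth
  keep <- which(cov > 0)
  k <- m$meth[keep]; n <- cov[keep]
  chains <- .hmm_chains(m$chrom[keep], m$pos[keep], cfg$gap_bp)
  ll <- cbind(dbetabinom_log(k, n, params$emissions$low$alpha,
                             params$emissions$low$beta),
              dbetabinom_log(k, n, params$emissions$high$alpha,
                             params$emissions$high$beta))
  es <- .fb_all(ll, chains, params$initial, params$transition)
  out <- data.frame(chrom = m$chrom[keep], pos = m$pos[keep],
                    meth = k, unmeth = n - k, chain = chains,
                    post_low = es$gamma[, 1], post_high = es$gamma[, 2])
  if (cfg$decode == "viterbi") {
    out$state <- .viterbi_all(ll, chains, params$initial, params$transition)
  } else {
    out$state <- ifelse(out$post_low >= out$post_high, "low", "high")
  }
  attr(out, "loglik") <- es$loglik
  out
}

.viterbi_all <- function(ll, chains, initial, transition) {
  state <- character(nrow(ll))
  lA <- log(transition)
  for (cid in unique(chains)) {
    idx <- which(chains == cid)
    nT <- length(idx)
    d <- log(initial) + ll[idx[1], ]
    bp <- matrix(0L, nT, 2)
    if (nT > 1) for (t in 2:nT) {
      cand <- d + lA  # cand[i, j] = d[i] + log A[i, j]
      bp[t, ] <- max.col(t(cand))
      d <- apply(cand, 2, max) + ll[idx[t], ]
    }
    s <- integer(nT)
    s[nT] <- which.max(d)
    if (nT > 1) for (t in (nT - 1):1) s[t] <- bp[t + 1, s[t + 1]]
    state[idx] <- c("low", "high")[s]
  }
  state
}

#' Extract hypomethylated regions from a decoded methylome
#'
#' Maximal runs of low-state CpGs, never crossing chain breaks, become HMRs.
#' The interval spans first CpG position to last CpG position + 1 (0-based
#' half-open). Each HMR carries its CpG count, mean raw methylation level and
#' score \eqn{S = n - \sum_i m_i} (CpG count minus the sum of the raw
#' per-site levels).
#'
#' @param decoded output of \code{\link{posterior_decode}}.
#' @return data.frame: chrom, start, end, n_cpgs, mean_meth, score.
#' @export
extract_hmrs <- function(decoded) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_cpgs = integer(),
                      mean_meth = numeric(), score = numeric())
  if (nrow(decoded) == 0) return(empty)
  low <- decoded$state == "low"
  if (!any(low)) return(empty)
  grp <- cumsum(c(TRUE, diff(decoded$chain) != 0))  # runs within chains
  run <- cumsum(c(TRUE, low[-1] != low[-length(low)] |
                    grp[-1] != grp[-length(grp)]))
  keep <- which(low)
  runs <- split(keep, run[keep])
  lev <- decoded$meth / (decoded$meth + decoded$unmeth)
  do.call(rbind, lapply(runs, function(ix) {
    data.frame(chrom = decoded$chrom[ix[1]],
               start = decoded$pos[ix[1]],
               end = decoded$pos[ix[length(ix)]] + 1L,
               n_cpgs = length(ix),
               mean_meth = mean(lev[ix]),
               score = score_hmr(lev[ix]))
  })) -> out
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' HMR score
#'
#' \eqn{S = n - \sum_i m_i}: the number of CpG sites minus the sum of their
#' methylation values. Bounded in \[0, n\].
#'
#' @param levels per-CpG methylation values in \[0, 1\].
#' @return the score.
#' @export
score_hmr <- function(levels) {
  if (length(levels) == 0) stop("score is undefined for an empty region")
  stopifnot(all(levels >= 0 & levels <= 1))
  length(levels) - sum(levels)
}

#' Permutation null score threshold
#'
#' For each of \code{cfg$n_permutations} permutations, the (meth, unmeth)
#' count pairs are shuffled across site positions genome-wide (positions stay
#' fixed), the methylome is re-decoded under the fitted parameters, HMRs are
#' re-extracted and their scores pooled. The cutoff is the empirical 99th
#' percentile of the pooled null scores, using the linear-interpolation
#' quantile definition (R type 7). Deterministic given \code{cfg$seed}.
#'
#' @param m a methylome.
#' @param params fitted \code{hmm_params}.
#' @param cfg an \code{\link{hmr_call_config}}.
#' @param probs percentile for the cutoff (default 0.99).
#' @return the score cutoff (0 with a warning if no null HMRs arise).
#' @export
permutation_threshold <- function(m, params, cfg = hmr_call_config(),
                                  probs = 0.99) {
  set.seed(cfg$seed)
  scores <- numeric(0)
  for (i in seq_len(cfg$n_permutations)) {
    perm <- sample.int(nrow(m))
    mp <- methylome(data.frame(chrom = m$chrom, pos = m$pos,
                               meth = m$meth[perm], unmeth = m$unmeth[perm]),
                    attr(m, "sample_id"), attr(m, "tissue"),
                    attr(m, "condition"))
    hm <- extract_hmrs(posterior_decode(mp, params, cfg))
    scores <- c(scores, hm$score)
  }
  if (length(scores) == 0) {
    warning("no null HMRs in any permutation; score cutoff 0")
    return(0)
  }
  unname(stats::quantile(scores, probs, type = 7))
}

#' Call hypomethylated regions
#'
#' Full procedure: fit the two-state beta-binomial HMM, decode, extract
#' low-state runs as HMRs, and keep regions whose score exceeds the 99th
#' percentile of the permutation null.
#'
#' @param m a methylome.
#' @param cfg an \code{\link{hmr_call_config}}.
#' @param params optional pre-fitted \code{hmm_params} (skips fitting).
#' @return sorted HMR data.frame (see \code{\link{extract_hmrs}}) with
#'   attributes \code{cutoff}, \code{params} and \code{n_prefilter}.
#' @export
call_hmrs <- function(m, cfg = hmr_call_config(), params = NULL) {
  if (is.null(params)) params <- fit_hmm(m, cfg)
  decoded <- posterior_decode(m, params, cfg)
  hmrs <- extract_hmrs(decoded)
  cutoff <- permutation_threshold(m, params, cfg)
  out <- hmrs[hmrs$score > cutoff, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  attr(out, "params") <- params
  attr(out, "n_prefilter") <- nrow(hmrs)
  out
}

#' Write HMRs as BED4+ (name, score, n_cpgs, mean_meth)
#' @param hmrs HMR data.frame.
#' @param path output path.
#' @export
write_hmr_bed <- function(hmrs, path) {
  out <- data.frame(chrom = hmrs$chrom, start = hmrs$start, end = hmrs$end,
                    name = sprintf("HMR_%d", seq_len(nrow(hmrs))),
                    score = round(hmrs$score, 6), n_cpgs = hmrs$n_cpgs,
                    mean_meth = round(hmrs$mean_meth, 6))
  write_bed(out, path)
}
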