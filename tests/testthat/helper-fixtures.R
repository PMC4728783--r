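# shared fixture builders and independent oracles

# quick methylome from parallel vectors
mk_methylome <- function(pos, meth, unmeth, chrom = "chr1", ...) {
  methylome(data.frame(chrom = chrom, pos = pos, meth = meth,
                       unmeth = unmeth), ...)
}

# base-level Jaccard of two interval sets over [0, len) on a single genome
interval_jaccard <- function(a, b, chrom_lens) {
  cov <- function(iv) {
    unlist(lapply(names(chrom_lens), function(chr) {
      v <- logical(chrom_lens[[chr]])
      sub <- iv[iv$chrom == chr, , drop = FALSE]
      for (i in seq_len(nrow(sub))) v[(sub$start[i] + 1):sub$end[i]] <- TRUE
      v
    }))
  }
  ca <- cov(a); cb <- cov(b)
  sum(ca & cb) / sum(ca | cb)
}

# independent brute-force tricube smoother implementing the documented
# window/radius rules (loop-based, no shared code with the package internals)
oracle_smooth <- function(pos, meth, unmeth, half_window, min_cpgs) {
  n <- length(pos)
  cov <- meth + unmeth
  sapply(seq_len(n), function(i) {
    inwin <- which(abs(pos - pos[i]) <= half_window)
    lo <- min(inwin); hi <- max(inwin)
    while (hi - lo + 1 < min_cpgs && (lo > 1 || hi < n)) {
      if (lo > 1) lo <- lo - 1
      if (hi < n) hi <- hi + 1
    }
    idx <- lo:hi
    d <- abs(pos[idx] - pos[i])
    h <- max(half_window, max(d) + 1)
    w <- (1 - pmin(d / h, 1)^3)^3
    sum(w * meth[idx]) / sum(w * cov[idx])
  })
}

# exhaustive-path HMM oracle: total log-likelihood and posteriors of a single
# chain by summing over all 2^n state paths
oracle_hmm_enum <- function(k, n, init, A, em) {
  nT <- length(k)
  states <- as.matrix(expand.grid(rep(list(1:2), nT)))
  emis <- cbind(
    exp(dbetabinom_log(k, n, em$low$alpha, em$low$beta)),
    exp(dbetabinom_log(k, n, em$high$alpha, em$high$beta)))
  pp <- apply(states, 1, function(s) {
    p <- init[s[1]] * emis[1, s[1]]
    for (t in seq_len(nT)[-1]) p <- p * A[s[t - 1], s[t]] * emis[t, s[t]]
    p
  })
  tot <- sum(pp)
  gamma <- sapply(seq_len(nT), function(t)
    sum(pp[states[, t] == 1]) / tot)
  list(loglik = log(tot), post_low = gamma)
}

# OLS by explicit normal equations
oracle_ols <- function(X, y) solve(t(X) %*% X, t(X) %*% y)[, 1]

# two-sided Fisher p by direct enumeration with choose()
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  supp <- max(0, r1 + c1 - N):min(r1, c1)
  pr <- choose(c1, supp) * choose(N - c1, r1 - supp) / choose(N, r1)
  obs <- choose(c1, a) * choose(N - c1, r1 - a) / choose(N, r1)
  sum(pr[pr <= obs * (1 + 1e-7)])
}
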