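# Independent brute-force / closed-form oracles. These deliberately avoid
# the code paths (and the stats:: routines) they are used to check.

# Mann-Whitney: enumerate every assignment of the pooled values into the
# two groups; two-sided p = 2 * min(tail masses), capped at 1.
oracle_mw <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - nx * (nx + 1) / 2
  u_obs <- u_of(seq_len(nx))
  u_all <- apply(utils::combn(n, nx), 2, u_of)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  list(statistic = u_obs, p_value = min(1, p))
}

# Wilcoxon signed rank: enumerate all 2^m sign patterns of the absolute
# differences; two-sided p = 2 * min(tail masses), capped at 1.
oracle_wsr <- function(d) {
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  v_all <- drop(signs %*% r)
  p <- 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs))
  list(statistic = v_obs, p_value = min(1, p))
}

# Fisher 2x2: full hypergeometric enumeration at fixed margins; two-sided
# p sums the probabilities of tables no more probable than the observed.
oracle_fisher <- function(n1, n2, n3, n4) {
  row1 <- n1 + n2; row2 <- n3 + n4
  col_high <- n2 + n4
  if (row1 == 0 || row2 == 0 || col_high == 0 || n1 + n3 == 0)
    return(NA_real_)
  a_range <- max(0, col_high - row1):min(row2, col_high)
  probs <- vapply(a_range, function(a)
    exp(lchoose(row2, a) + lchoose(row1, col_high - a) -
          lchoose(row1 + row2, col_high)), numeric(1))
  p_obs <- probs[match(n4, a_range)]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Bernoulli-logit likelihood maximised by a generic numerical optimiser.
oracle_logit <- function(X, z) {
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(z * eta - log1p(exp(eta)))
  }
  opt <- stats::optim(rep(0, ncol(X)), nll, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  opt$par
}

# OLS by the normal equations.
oracle_ols <- function(X, y) {
  drop(solve(crossprod(X), crossprod(X, y)))
}

# Exhaustive per-read, per-exon overlap count.
oracle_count <- function(alignments, exons) {
  counts <- stats::setNames(integer(nrow(exons)), exons$exon_id)
  bl <- alignments$blocks
  read_of <- alignments$records$read_id[match(bl$aln_id,
                                              alignments$records$aln_id)]
  for (j in seq_len(nrow(exons))) {
    ov <- bl$chrom == exons$chrom[j] &
      bl$start < exons$end[j] & bl$end > exons$start[j]
    counts[j] <- length(unique(read_of[ov]))
  }
  counts
}
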