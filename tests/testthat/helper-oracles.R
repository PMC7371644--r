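# Independent brute-force oracles used against the package implementations.

# Mann-Whitney U by direct pair counting (ties count 1/2).
mw_u_oracle <- function(x, y) {
  sum(outer(x, y, `>`)) + 0.5 * sum(outer(x, y, `==`))
}

# Exact p-value by full enumeration of rank assignments (no ties).
mw_p_oracle <- function(x, y, alternative) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_obs <- mw_u_oracle(x, y)
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(idx) {
    mw_u_oracle(pooled[idx], pooled[-idx])
  })
  switch(alternative,
         greater = mean(u_all >= u_obs),
         less = mean(u_all <= u_obs),
         two.sided = {
           mn <- n1 * length(y)
           p <- if (u_obs > mn / 2) 2 * mean(u_all >= u_obs) else
             2 * mean(u_all <= u_obs)
           min(1, p)
         })
}

# Benjamini-Hochberg step-up rejection set straight from its definition.
bh_reject_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- suppressWarnings(max(which(ps <= seq_len(m) * q / m)))
  rejected <- rep(FALSE, m)
  if (is.finite(k)) rejected[p <= ps[k]] <- TRUE
  rejected
}

expect_all_true <- function(x, info = NULL) {
  testthat::expect_true(all(x), info = info)
}
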