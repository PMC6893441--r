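# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except through the package's own writers.

# small two-cohort scenario for fast end-to-end tests
small_cfg <- function(seed = 1, ...) {
  defaults <- list(n_A = 20, n_B = 30, n_targets = 12, n_decoys = 120,
                   n_canonical = 3, seed = seed)
  override <- list(...)
  defaults[names(override)] <- override
  do.call(synthetic_config, defaults)
}

toy_expr <- function(genes, n_samples, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rnorm(length(genes) * n_samples),
              nrow = length(genes),
              dimnames = list(genes, sprintf("S%02d", seq_len(n_samples))))
  m
}

# independent brute-force step-up q-values (deliberately naive double loop)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# classic BH step-up rejection set at level alpha
bh_reject_oracle <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= alpha * seq_len(m) / m)
  rej <- logical(m)
  if (length(k) > 0) rej[o[seq_len(max(k))]] <- TRUE
  rej
}

# two-sided Fisher p by direct binomial-coefficient arithmetic
fisher_oracle <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  supp <- max(0, k - n):min(k, m)
  pr <- choose(m, supp) * choose(n, k - supp) / choose(m + n, k)
  pobs <- choose(m, a) * choose(n, k - a) / choose(m + n, k)
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
}

# Mann-Whitney U with midranks, plus exact two-sided p by enumerating
# every relabelling of the pooled observations
mwu_u_stat <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}
mwu_oracle_p <- function(x, y) {
  pool <- c(x, y)
  nx <- length(x)
  combs <- utils::combn(length(pool), nx)
  us <- apply(combs, 2, function(idx) mwu_u_stat(pool[idx], pool[-idx]))
  u_obs <- mwu_u_stat(x, y)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}
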