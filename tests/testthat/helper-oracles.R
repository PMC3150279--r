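# independent oracles used across the suite; deliberately written from first
# principles, not by calling package internals

# exact parsimony length by exhaustive enumeration of internal-node states
brute_force_parsimony <- function(gt, state_idx) {
  n <- gt$n_tip
  k <- max(state_idx)
  n_int <- n - 1L
  combos <- as.matrix(expand.grid(rep(list(seq_len(k)), n_int)))
  st <- cbind(matrix(state_idx, nrow(combos), n, byrow = TRUE), combos)
  cost <- numeric(nrow(combos))
  for (m in seq_len(n_int)) {
    par <- n + m
    cost <- cost + (st[, gt$merges[m, 1]] != st[, par]) +
      (st[, gt$merges[m, 2]] != st[, par])
  }
  min(cost)
}

rand_coal_tree <- function(n, seed = NULL) {
  simulate_growth_tree(n, 100, 0, seed = seed)
}

# two-sided Fisher exact P by full hypergeometric enumeration over all
# 2x2 tables with the observed margins (probability-ordering convention)
fisher_enum_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  lp <- function(a) {
    b <- r1 - a; cc <- c1 - a; d <- r2 - cc
    if (b < 0 || cc < 0 || d < 0) return(-Inf)
    lchoose(r1, a) + lchoose(r2, cc) - lchoose(r1 + r2, c1)
  }
  as_range <- 0:min(r1, c1)
  probs <- exp(vapply(as_range, lp, 0))
  p_obs <- exp(lp(tab[1, 1]))
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# mean TMRCA from an independent coalescent simulator (msprime), in
# generations on the E[T2] = Ne scale (haploid populations)
msprime_mean_tmrca <- function(py_demography, sample_spec, n_rep, seed) {
  code <- c(
    "import msprime",
    py_demography,
    sprintf("reps = msprime.sim_ancestry(samples=%s, demography=demography, ploidy=1, num_replicates=%d, random_seed=%d)",
            sample_spec, n_rep, seed),
    "tot = 0.0",
    "for ts in reps:",
    "    tot += max(ts.tables.nodes.time)",
    sprintf("print(tot / %d)", n_rep))
  f <- tempfile(fileext = ".py")
  writeLines(code, f)
  out <- system2("python", f, stdout = TRUE, stderr = TRUE)
  val <- suppressWarnings(as.numeric(out[length(out)]))
  if (is.na(val)) stop("msprime oracle failed: ", paste(out, collapse = "\n"))
  val
}

# mean and standard error helper for 3-SE comparisons
mean_se <- function(x) c(mean = mean(x), se = stats::sd(x) / sqrt(length(x)))
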