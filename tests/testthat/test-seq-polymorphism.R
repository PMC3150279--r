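toy_aln <- function() {
  haplotype_alignment(
    c(s1 = "ACGTACGT", s2 = "ACGTACGA", s3 = "ACGTACGT", s4 = "TCGTACGT"),
    demes = c("X", "X", "Y", "Y"))
}

test_that("polymorphism summaries match hand-computed values", {
  # monomorphic sample
  mono <- haplotype_alignment(rep("ACGT", 5), demes = rep("Z", 5))
  sm <- polymorphism_summary(mono, "all")
  expect_equal(sm[, c("S", "Nhap", "Hd", "pi")],
               data.frame(S = 0L, Nhap = 1L, Hd = 0, pi = 0),
               ignore_attr = TRUE)

  # two sequences differing at 4 of 4029 sites
  base <- paste(rep("A", 4029), collapse = "")
  alt <- base
  substr(alt, 1, 4) <- "CCCC"
  two <- haplotype_alignment(c(a = base, b = alt), demes = c("P", "P"))
  s2 <- polymorphism_summary(two, "all")
  expect_identical(s2$S, 4L)
  expect_identical(s2$Nhap, 2L)
  expect_equal(s2$Hd, 1)
  expect_equal(s2$pi, 4 / 4029)

  # four sequences with haplotype counts {2, 1, 1}:
  # Hd = n (1 - sum p^2) / (n - 1)
  s4 <- polymorphism_summary(toy_aln(), "all")
  expect_equal(s4$Hd, 4 * (1 - (0.5^2 + 0.25^2 + 0.25^2)) / 3)
  # per-deme scope errors on singleton demes
  one <- haplotype_alignment(c(a = "AC", b = "AC", c = "AG"),
                             demes = c("X", "X", "Y"))
  expect_error(polymorphism_summary(one, "per_deme"), "at least two")
})

test_that("summaries are invariant to sequence and column permutation", {
  aln <- toy_aln()
  set.seed(5)
  ro <- sample(4); co <- sample(8)
  perm <- haplotype_alignment(aln$seq[ro, co], demes = aln$deme[ro])
  a <- polymorphism_summary(aln, "all")
  b <- polymorphism_summary(perm, "all")
  expect_equal(a[, -1], b[, -1])
})

test_that("gap/ambiguity columns are removed before any statistic", {
  aln <- haplotype_alignment(c(a = "A-GT", b = "ANGA", c = "ACGT"),
                             demes = rep("X", 3))
  sm <- polymorphism_summary(aln, "all")
  expect_identical(sm$S, 1L)   # column 2 dropped, three columns retained
  expect_equal(sm$pi, (2 / 3) / 3)
})

test_that("segregating sites match the Watterson expectation", {
  # theta per locus = 2 Ne mu L = 10; infinite sites keeps E[S] = theta a_{n-1}
  m <- build_model("single", total_ne = 1000, deme_sizes = c(A = 20))
  set.seed(41)
  S <- replicate(300, {
    a <- mutate_on_tree(simulate_gene_tree(m, c(A = 20)), 2000, 2.5e-6,
                        sites = "infinite")
    polymorphism_summary(a, "all")$S
  })
  ms <- mean_se(S)
  expect_lt(abs(ms["mean"] - 10 * sum(1 / (1:19))), 3 * ms["se"])
})

test_that("pairwise diversity matches theta and the Watterson estimator", {
  # E[pi per site] = theta = 2 Ne mu; theta_w agrees in expectation
  m <- build_model("single", total_ne = 1000, deme_sizes = c(A = 20))
  set.seed(43)
  res <- replicate(300, {
    a <- mutate_on_tree(simulate_gene_tree(m, c(A = 20)), 1000, 2e-6)
    s <- polymorphism_summary(a, "all")
    c(s$pi, s$theta_w / 1000)
  })
  ms_pi <- mean_se(res[1, ])
  expect_lt(abs(ms_pi["mean"] - 0.004), 3 * ms_pi["se"])
  dd <- res[1, ] - res[2, ]
  ms_d <- mean_se(dd)
  expect_lt(abs(ms_d["mean"]), 3 * ms_d["se"])
})

test_that("Fu's Fs reduces to ln(theta) for two sequences", {
  b <- haplotype_alignment(c(x = "AAAAA", y = "AATTA"), demes = c("X", "X"))
  f <- fu_fs(b)
  # n = 2: S' = theta/(1+theta) so Fs = ln(theta)
  expect_equal(f$fs, log(f$theta_pi), tolerance = 1e-12)
  expect_equal(f$theta_pi, 2)
  mono <- haplotype_alignment(rep("ACGT", 4), demes = rep("X", 4))
  expect_error(fu_fs(mono), "monomorphic")
})

test_that("the Ewens probabilities behind Fs are exact for small n", {
  # n = 3: P(K=1) = 2/((1+theta)(2+theta)), P(K=2) = 3 theta/(...),
  # P(K=3) = theta^2/(...) from |s(3,k)| = (2, 3, 1)
  th <- 0.7
  lp <- skyrefugia:::log_ewens_pmf(3, th)
  denom <- (1 + th) * (2 + th)
  expect_equal(exp(lp), c(2, 3 * th, th^2) / denom, tolerance = 1e-12)
  expect_equal(sum(exp(skyrefugia:::log_ewens_pmf(25, 3.3))), 1,
               tolerance = 1e-9)
})

test_that("Fu and Li's D orients singletons with the outgroup", {
  # every derived mutation a singleton: D must be negative
  n <- 10
  mat <- matrix("A", n, 40)
  for (i in 1:8) mat[i, i] <- "T"   # 8 singleton derived mutations
  rownames(mat) <- paste0("s", 1:n)
  og <- matrix("A", 1, 40, dimnames = list("out", NULL))
  aln <- haplotype_alignment(mat, demes = rep("X", n), outgroup = og)
  d <- fu_li_d(aln, "D")
  expect_identical(d$eta, 8L)
  expect_identical(d$singletons, 8L)
  expect_lt(d$d, 0)
  # without an outgroup the D variant refuses, D* still works
  no_og <- haplotype_alignment(mat, demes = rep("X", n))
  expect_error(fu_li_d(no_og, "D"), "outgroup")
  expect_lt(fu_li_d(no_og, "D_star")$d, 0)
  expect_error(fu_li_d(haplotype_alignment(rep("AC", 4), rep("X", 4)),
                       "D_star"), "no polymorphism")
})

test_that("Fu and Li's statistics are centred under neutral equilibrium", {
  set.seed(47)
  d_vals <- replicate(150, {
    gt <- simulate_growth_tree(30, 1000, 0)
    a <- mutate_on_tree(gt, 1000, 5e-6)
    og <- matrix(sample(c("A", "C", "G", "T"), 1000, TRUE), 1,
                 dimnames = list("out", NULL))
    a2 <- haplotype_alignment(a$seq, a$deme, outgroup = NULL)
    tryCatch(fu_li_d(a2, "D_star")$d, error = function(e) NA_real_)
  })
  d_vals <- d_vals[!is.na(d_vals)]
  ms <- mean_se(d_vals)
  expect_lt(abs(ms["mean"]), 3 * ms["se"])
})

test_that("the McDonald-Kreitman table and P match a constructed case", {
  # 4 ingroup sequences, 4 codons; third positions of codon 1 vary
  # synonymously, first position of codon 2 varies nonsynonymously, codon 3
  # carries a synonymous fixed difference, codon 4 a nonsynonymous one.
  # Standard code: CTT/CTC = Leu (syn poly); ATG -> GTG Met/Val (nonsyn
  # poly); GGA vs GGC = Gly (syn fixed); AAA vs GAA Lys/Glu (nonsyn fixed).
  ing <- rbind(c("C","T","T", "A","T","G", "G","G","A", "A","A","A"),
               c("C","T","C", "A","T","G", "G","G","A", "A","A","A"),
               c("C","T","T", "G","T","G", "G","G","A", "A","A","A"),
               c("C","T","T", "A","T","G", "G","G","A", "A","A","A"))
  rownames(ing) <- paste0("s", 1:4)
  og <- matrix(c("C","T","T", "A","T","G", "G","G","C", "G","A","A"), 1,
               dimnames = list("out", NULL))
  aln <- haplotype_alignment(ing, demes = rep("X", 4), outgroup = og)
  mk <- mk_test(aln, code = "standard")
  expect_identical(as.vector(mk$table), c(1L, 1L, 1L, 1L))
  expect_equal(mk$p_value, fisher_enum_p(mk$table), tolerance = 1e-9)
  expect_equal(mk$p_value, 1)  # this margin pattern carries no signal
  # Fisher path against the brute-force hypergeometric oracle
  expect_equal(stats::fisher.test(matrix(c(10, 3, 2, 9), 2))$p.value,
               fisher_enum_p(matrix(c(10, 3, 2, 9), 2)), tolerance = 1e-9)
  # no fixed differences: degenerate margin convention
  aln0 <- haplotype_alignment(ing, demes = rep("X", 4),
                              outgroup = matrix(ing[1, ], 1))
  expect_equal(mk_test(aln0, code = "standard")$p_value, 1)
  bad <- haplotype_alignment(ing[, 1:4], demes = rep("X", 4),
                             outgroup = og[, 1:4, drop = FALSE])
  expect_error(mk_test(bad, code = "standard"), "divisible")
})

test_that("the mitochondrial genetic code changes the classification", {
  # AGA: Arg under the standard code, a stop under vertebrate mtDNA;
  # AGA -> AGG is synonymous in both, but TGA (mito Trp) vs TGG differs
  ing <- rbind(c("T","G","A"), c("T","G","A"))
  rownames(ing) <- c("a", "b")
  og <- matrix(c("T","G","G"), 1)
  aln <- haplotype_alignment(ing, demes = c("X", "X"), outgroup = og)
  # mito: TGA = TGG = Trp (synonymous fixed); standard: stop vs Trp
  expect_identical(mk_test(aln)$table["synonymous", "fixed"], 1L)
  expect_identical(mk_test(aln, code = "standard")$table[
    "nonsynonymous", "fixed"], 1L)
})

test_that("Phi_ST matches a first-principles AMOVA on three demes", {
  set.seed(53)
  seqs <- matrix(sample(c("A", "T"), 9 * 20, TRUE, prob = c(0.7, 0.3)), 9)
  rownames(seqs) <- paste0("s", 1:9)
  demes <- rep(c("P", "Q"), c(4, 5))
  aln <- haplotype_alignment(seqs, demes = demes)
  got <- distance_matrices(aln, "phi_st")["P", "Q"]
  # oracle: variance components from the sums of squared differences
  dd <- outer(1:9, 1:9, Vectorize(function(i, j) sum(seqs[i, ] != seqs[j, ])))
  idx <- list(P = 1:4, Q = 5:9)
  ssd_w <- sum(dd[idx$P, idx$P]) / (2 * 4) + sum(dd[idx$Q, idx$Q]) / (2 * 5)
  ssd_t <- sum(dd) / (2 * 9)
  sig_w <- ssd_w / (9 - 2)
  n_pr <- 9 - (16 + 25) / 9
  sig_a <- ((ssd_t - ssd_w) - sig_w) / n_pr
  expect_equal(got, max(0, sig_a / (sig_a + sig_w)), tolerance = 1e-9)

  # two demes fixed for different haplotypes
  fix <- haplotype_alignment(c(a = "AAAA", b = "AAAA", c = "TTTT",
                               d = "TTTT"), demes = c("P", "P", "Q", "Q"))
  expect_equal(distance_matrices(fix, "phi_st")["P", "Q"], 1)
  # p-distance variant
  expect_equal(distance_matrices(fix, "p_distance")["P", "Q"], 1)
  # singleton demes are dropped with a warning
  s1 <- haplotype_alignment(c(a = "AA", b = "AT", c = "TT", d = "TA",
                              e = "AT"), demes = c("P", "P", "Q", "Q", "R"))
  expect_warning(distance_matrices(s1, "phi_st"), "R")
})

test_that("Phi_ST is near zero for demes drawn from one panmictic pool", {
  m <- build_model("single", total_ne = 1000, deme_sizes = c(A = 20))
  set.seed(59)
  ph <- replicate(60, {
    a <- mutate_on_tree(simulate_gene_tree(m, c(A = 20)), 400, 2e-6)
    a2 <- haplotype_alignment(a$seq, rep(c("X", "Y"), each = 10))
    distance_matrices(a2, "phi_st")[1, 2]
  })
  # truncation at zero leaves a small positive residue
  expect_lt(mean(ph), 0.08)
})
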