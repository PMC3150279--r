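test_that("theta/Ne conversions and the clock rate modulation are exact", {
  # mitochondrial theta = 2 Ne mu
  expect_equal(theta_to_ne(0.0467, 0.78e-8), 0.0467 / (2 * 0.78e-8))
  expect_equal(ne_to_theta(theta_to_ne(0.3, 1e-6), 1e-6), 0.3,
               tolerance = 1e-12)
  expect_error(theta_to_ne(-1, 1e-8), "positive")
  expect_error(theta_to_ne(0.1, 0), "positive")

  expect_equal(modulate_rate(1e-8, 0.0036, 0.0046), 1e-8 * 36 / 46)
  expect_equal(modulate_rate(1e-8, 0.004, 0.004), 1e-8)
  expect_equal(modulate_rate(1e-8, 0.0072, 0.0092),
               modulate_rate(1e-8, 0.0036, 0.0046))
})

test_that("scaled divergence times convert to calendar years per marker", {
  rs <- rate_set()
  # sequence time is scaled by mutations per locus
  expect_equal(scaled_time_to_years(3.415, rs, "mtdna"),
               3.415 / (0.78e-8 * 4029))
  expect_equal(scaled_time_to_years(0, rs, "mtdna"), 0)
  # microsatellite time is scaled per generation
  expect_equal(scaled_time_to_years(0.15, rs, "msat"), 15000)
  expect_error(scaled_time_to_years(-1, rs, "mtdna"), "non-negative")
  expect_error(rate_set(mu_site_cytb = 0), "positive")
})

test_that("build_model produces the hypothesized population trees", {
  ne <- 3e6
  m1 <- build_model("single", total_ne = ne)
  expect_identical(nrow(m1$branches), 1L)
  expect_true(is.infinite(m1$branches$t1))

  m2 <- build_model("two_refugia", total_ne = ne,
                    divergence_times_years = 1e5)
  expect_equal(sort(m2$branches$t0), c(0, 0, 1e5))
  # leaf Ne defaults to the sample-share of total
  expect_equal(m2$branches$ne[m2$branches$label == "S"], 25 / 80 * ne)

  m3 <- build_model("three_refugia", total_ne = ne,
                    divergence_times_years = c(1e5, 1.5e4))
  expect_equal(sort(unique(m3$branches$t0)), c(0, 1.5e4, 1e5))
  expect_equal(m3$branches$ne[m3$branches$label == "E"], 32 / 80 * ne)
  # refugial-branch constraint override
  m3b <- build_model("three_refugia", total_ne = ne,
                     divergence_times_years = c(1e5, 1.5e4),
                     refugial_proportions = c(NE = 22 / 80))
  expect_equal(m3b$branches$ne[m3b$branches$label == "EN"], 22 / 80 * ne)

  expect_error(build_model("three_refugia", total_ne = ne,
                           divergence_times_years = c(1e4, 5e4)),
               "nested split")
  expect_error(build_model("two_refugia", total_ne = ne,
                           proportions = c(S = 0.6, NE = 0.6),
                           divergence_times_years = 1e5),
               "sum to 1")
  expect_equal(build_model("two_refugia", total_ne = 3e6,
                           proportions = c(S = 1 / 3, NE = 2 / 3),
                           divergence_times_years = 1e5)$branches$ne[1:2],
               c(1e6, 2e6))
})

test_that("simulated gene trees are ultrametric with the configured tips", {
  m <- build_model("three_refugia", total_ne = 2000,
                   divergence_times_years = c(500, 100))
  g <- simulate_gene_tree(m, seed = 11)
  expect_s3_class(g, "gene_tree")
  expect_identical(g$n_tip, 80L)
  expect_equal(as.vector(table(g$tip_deme)), as.vector(study_demes()))
  phy <- as.phylo(g)
  expect_true(ape::is.ultrametric(phy, option = 2))
  expect_true(ape::is.binary(phy))
  # round-trip through the merge representation preserves the genealogy
  g2 <- skyrefugia:::gene_tree_from_phylo(phy)
  expect_equal(max(g2$times), max(g$times), tolerance = 1e-9)
  expect_identical(fitch_steps(g2), fitch_steps(g))

  # same seed, same tree
  g3 <- simulate_gene_tree(m, seed = 11)
  expect_identical(g3$merges, g$merges)
  expect_identical(g3$times, g$times)
})

test_that("coalescence times follow the Kingman law within a branch", {
  m <- build_model("single", total_ne = 1000, deme_sizes = c(A = 2))
  set.seed(42)
  t2 <- replicate(2000, max(simulate_gene_tree(m, c(A = 2))$times))
  # E[T2] = Ne on the maternal-locus scale
  ms <- mean_se(t2)
  expect_lt(abs(ms["mean"] - 1000), 3 * ms["se"])
  # full distribution: exponential with rate 1/Ne
  ks <- stats::ks.test(t2, "pexp", rate = 1 / 1000)
  expect_gt(ks$p.value, 0.01)

  # n-tip tree height: 2 Ne (1 - 1/n)
  mbig <- build_model("single", total_ne = 1000, deme_sizes = c(A = 40))
  h <- replicate(400, max(simulate_gene_tree(mbig, c(A = 40))$times))
  ms2 <- mean_se(h)
  expect_lt(abs(ms2["mean"] - 2 * 1000 * (1 - 1 / 40)), 3 * ms2["se"])
})

test_that("deep splits drive refugia to reciprocal monophyly", {
  # divergence >> Ne: every within-refugium coalescence precedes the root
  m <- build_model("two_refugia", total_ne = 100,
                   deme_sizes = c(A = 8, B = 8),
                   refugia = list(S = "A", NE = "B"),
                   divergence_times_years = 1e4)
  set.seed(7)
  s <- replicate(200, fitch_steps(simulate_gene_tree(m, c(A = 8, B = 8))))
  expect_gte(mean(s == 1L), 0.99)
})

test_that("mean tree height agrees with an independent coalescent simulator", {
  n_rep <- 300L
  # one panmictic and two structured benchmark models
  m1 <- build_model("single", total_ne = 1000, deme_sizes = c(A = 10))
  m2 <- build_model("two_refugia", total_ne = 1000,
                    deme_sizes = c(A = 5, B = 5),
                    refugia = list(S = "A", NE = "B"),
                    proportions = c(S = 0.4, NE = 0.6),
                    divergence_times_years = 800)
  set.seed(99)
  h1 <- replicate(n_rep, max(simulate_gene_tree(m1, c(A = 10))$times))
  h2 <- replicate(n_rep, max(simulate_gene_tree(m2, c(A = 5, B = 5))$times))

  o1 <- msprime_mean_tmrca(
    "demography = msprime.Demography.isolated_model([1000])",
    "{0: 10}", n_rep, 1)
  dem2 <- paste(
    "demography = msprime.Demography()",
    "demography.add_population(name='S', initial_size=400)",
    "demography.add_population(name='NE', initial_size=600)",
    "demography.add_population(name='anc', initial_size=1000)",
    "demography.add_population_split(time=800, derived=['S','NE'], ancestral='anc')",
    sep = "\n")
  o2 <- msprime_mean_tmrca(dem2, "{'S': 5, 'NE': 5}", n_rep, 2)

  expect_lt(abs(mean(h1) - o1),
            3 * stats::sd(h1) / sqrt(n_rep) * sqrt(2))
  expect_lt(abs(mean(h2) - o2),
            3 * stats::sd(h2) / sqrt(n_rep) * sqrt(2))
})
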