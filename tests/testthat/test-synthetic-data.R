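test_that("the generator configuration enforces its invariants", {
  cfg <- synthetic_study_config()
  expect_identical(sum(cfg$deme_sizes), 80L)
  expect_identical(cfg$seq_length, 4029L)
  expect_error(synthetic_study_config(deme_sizes = c(3, 2)), "named")
  expect_error(synthetic_study_config(theta_target = 0), "positive")
  expect_error(synthetic_study_config(msat_range = c(9, 9)), "increasing")
})

test_that("zero mutation rates yield invariant data", {
  m <- build_model("single", total_ne = 200, deme_sizes = c(A = 6))
  cfg <- synthetic_study_config(deme_sizes = c(A = 6), seq_length = 50,
                                mu_site = 0, msat_mu = 0,
                                missing_rate = 0, rng_seed = 5)
  aln <- simulate_sequences(m, cfg)
  expect_identical(polymorphism_summary(aln, "all")$S, 0L)
  expect_identical(length(unique(apply(aln$seq, 1, paste, collapse = ""))),
                   1L)
  geno <- simulate_microsats(m, cfg)
  expect_identical(length(unique(c(geno$a, geno$b))), 1L)
})

test_that("identical seeds reproduce identical outputs", {
  m <- build_model("single", total_ne = 300, deme_sizes = c(A = 5, B = 5))
  cfg <- synthetic_study_config(deme_sizes = c(A = 5, B = 5),
                                seq_length = 100, theta_target = 0.01,
                                n_loci_msat = 4, msat_mu = 1e-3,
                                rng_seed = 99)
  expect_identical(simulate_sequences(m, cfg)$seq,
                   simulate_sequences(m, cfg)$seq)
  g1 <- simulate_microsats(m, cfg); g2 <- simulate_microsats(m, cfg)
  expect_identical(g1$a, g2$a)
  expect_identical(g1$b, g2$b)
  e1 <- simulate_env_table(letters[1:6], 0.5, seed = 3)
  e2 <- simulate_env_table(letters[1:6], 0.5, seed = 3)
  expect_identical(e1, e2)
})

test_that("stepwise alleles respect the reflecting range", {
  m <- build_model("single", total_ne = 2000, deme_sizes = c(A = 12))
  cfg <- synthetic_study_config(deme_sizes = c(A = 12), n_loci_msat = 6,
                                msat_mu = 5e-3, msat_range = c(16, 24),
                                missing_rate = 0, rng_seed = 13)
  g <- simulate_microsats(m, cfg)
  expect_true(all(g$a >= 16 & g$a <= 24))
  # allele count per locus bounded by the range width
  expect_true(all(apply(g$a, 2, function(x) length(unique(x))) <= 9))
  # the reflected endpoint law preserves the walk's support
  expect_identical(skyrefugia:::fold_reflect(c(15L, 16L, 25L, 27L), 16L, 24L),
                   c(17L, 16L, 23L, 21L))
})

test_that("the environmental table has coherent one-hot sets", {
  env <- simulate_env_table(paste0("L", 1:15), effect = 0.5, seed = 21)
  expect_identical(nrow(env), 15L)
  sub_cols <- grep("^subregion_", colnames(env))
  veg_cols <- grep("^veg_", colnames(env))
  expect_identical(length(sub_cols), 3L)
  expect_identical(length(veg_cols), 5L)
  expect_true(all(rowSums(env[, sub_cols]) == 1))
  expect_true(all(rowSums(env[, veg_cols]) == 1))
  expect_identical(length(attr(env, "latent")), 15L)
  expect_error(simulate_env_table(c("a", "b")), "three")
})

test_that("a zero effect leaves subregions independent of the gradient", {
  set.seed(23)
  sig <- replicate(150, {
    env <- simulate_env_table(paste0("L", 1:12), effect = 0)
    D <- as.matrix(dist(attr(env, "latent")))
    marginal_test(gower_center(D), predictor_sets(env)$subregion,
                  n_perm = 99)$p_value <= 0.05
  })
  expect_gte(mean(!sig), 0.9)
})

test_that("a maximal effect plants the signal in the subregion set", {
  set.seed(29)
  win <- replicate(60, {
    env <- simulate_env_table(paste0("L", 1:12), effect = 1)
    G <- gower_center(as.matrix(dist(attr(env, "latent"))))
    ps <- predictor_sets(env)
    marginal_test(G, ps$subregion, n_perm = 99)$pct_var >
      marginal_test(G, ps$rainfall, n_perm = 99)$pct_var
  })
  expect_gte(mean(win), 0.95)
})

test_that("long isolation inflates microsatellite F_ST", {
  m <- build_model("two_refugia", total_ne = 500,
                   deme_sizes = c(A = 10, B = 10),
                   refugia = list(S = "A", NE = "B"),
                   divergence_times_years = 5000)  # 10 Ne generations
  set.seed(31)
  fst <- replicate(25, {
    cfg <- synthetic_study_config(deme_sizes = c(A = 10, B = 10),
                                  n_loci_msat = 5, msat_mu = 2e-4,
                                  missing_rate = 0,
                                  rng_seed = sample.int(1e6, 1))
    genetic_distances(simulate_microsats(m, cfg), "fst")["A", "B"]
  })
  expect_gt(mean(fst), 0.2)
})

test_that("fixtures round-trip losslessly through their text formats", {
  m <- build_model("single", total_ne = 300, deme_sizes = c(A = 4, B = 4))
  cfg <- synthetic_study_config(deme_sizes = c(A = 4, B = 4),
                                seq_length = 60, theta_target = 0.01,
                                n_loci_msat = 3, msat_mu = 1e-3,
                                missing_rate = 0.2, rng_seed = 37)
  aln <- simulate_sequences(m, cfg)
  gt <- attr(aln, "gene_tree")
  geno <- simulate_microsats(m, cfg)
  env <- simulate_env_table(paste0("L", 1:5), 0.5, seed = 37)
  dir <- file.path(tempdir(), "fixtures-test")
  paths <- write_fixtures(dir, alignment = aln, gene_tree = gt,
                          genotypes = geno, predictors = env, config = cfg)
  # alignment: sequences, names and demes identical
  back <- read_alignment(paths[["fasta"]], paths[["metadata"]])
  expect_identical(back$seq, aln$seq)
  expect_identical(as.character(back$deme), as.character(aln$deme))
  # tree: same topology and branch lengths to 1e-9
  tr <- ape::read.tree(paths[["tree"]])
  orig <- as.phylo(gt)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr),
                                         ape::unroot(orig))), 0)
  d1 <- ape::cophenetic.phylo(tr); d2 <- ape::cophenetic.phylo(orig)
  expect_equal(d1[rownames(d2), colnames(d2)], d2, tolerance = 1e-9)
  # genotypes: identical values and missing mask
  gback <- read_genotypes(paths[["genotypes"]])
  expect_identical(gback$a, geno$a)
  expect_identical(gback$b, geno$b)
  expect_identical(is.na(gback$a), is.na(geno$a))
  # predictors
  eback <- read_predictors(paths[["predictors"]])
  expect_equal(as.data.frame(env), eback, tolerance = 1e-12,
               ignore_attr = TRUE)
  # config file documents every generator parameter
  cfg_back <- yaml::read_yaml(paths[["config"]])
  expect_setequal(names(cfg_back), names(unclass(cfg)))
  expect_identical(cfg_back$rng_seed, 37L)
})
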