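#' Default pipeline configuration
#'
#' Returns the configuration list used by [run_pipeline()], documenting
#' every setting: either a `synthetic` generation block or a set of input
#' paths must be present. The defaults generate a synthetic dataset under
#' the single-refugium (panmictic) truth with the ten-population study
#' design, then run every analysis stage against the three refugium
#' hypotheses.
#'
#' @param seed integer master seed recorded in the run manifest.
#' @return A nested configuration list (serializable as YAML).
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    synthetic = list(truth = "single", theta_site = 0.004,
                     n_loci_msat = 10, msat_mu = 1e-5, env_effect = 0.8),
    inputs = NULL,  # alternatively: list(fasta=, metadata=, genotypes=,
                    #   predictors=, observed_tree=)
    rates = list(mu_site_cytb = 1e-8, mu_site_combined = 0.78e-8,
                 locus_length = 4029, msat_mu = 1e-5, generation_time = 1),
    models = list(theta_total = 0.0467,
                  hypotheses = c("single", "two_refugia", "three_refugia"),
                  divergence_times_years = list(two_refugia = 1e5,
                                                three_refugia = c(1e5, 1.5e4))),
    n_sims = 1000L,
    n_perm = 499L,
    skyline_groups = 10L)
}

#' Run the full refugium-test pipeline
#'
#' Orchestrates every stage from one configuration: data generation (or
#' loading), sequence polymorphism and neutrality statistics,
#' microsatellite summaries, the sorting test of each refugium hypothesis,
#' distance-based redundancy analysis of the environmental predictor sets,
#' and skyline/growth demography. All tables are written as TSV under
#' `output_dir` together with a machine-readable JSON manifest recording
#' the seed and settings; identical configuration and seed reproduce
#' byte-identical outputs.
#'
#' @param config a list as from [default_pipeline_config()], or the path to
#'   a YAML file with the same structure.
#' @param output_dir directory for the report bundle.
#' @param quiet suppress per-stage progress messages.
#' @return Invisibly, a list with every stage result and the manifest.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         output_dir, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$synthetic) == is.null(config$inputs))
    stop_domain("exactly one of 'synthetic' or 'inputs' must be configured")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[skyrefugia] ", ...)
  rates <- do.call(rate_set, config$rates)
  total_ne <- if (!is.null(config$models$total_ne)) config$models$total_ne
    else theta_to_ne(config$models$theta_total,
                     rates$mu_site_combined * rates$generation_time)

  # ---- stage 1: data ----
  if (!is.null(config$synthetic)) {
    say("generating synthetic data (truth: ", config$synthetic$truth, ")")
    truth <- build_refugium_hypothesis(config$synthetic$truth, total_ne,
                                       config, rates)
    gen_cfg <- synthetic_study_config(
      theta_target = config$synthetic$theta_site,
      n_loci_msat = config$synthetic$n_loci_msat,
      msat_mu = config$synthetic$msat_mu,
      rng_seed = config$seed)
    aln <- simulate_sequences(truth, gen_cfg)
    genealogy <- attr(aln, "gene_tree")
    geno <- simulate_microsats(truth, gen_cfg, seed = config$seed + 1L)
    env <- simulate_env_table(names(gen_cfg$deme_sizes),
                              effect = config$synthetic$env_effect,
                              seed = config$seed + 2L)
    deme_sizes <- gen_cfg$deme_sizes
    write_fixtures(file.path(output_dir, "data"), alignment = aln,
                   gene_tree = genealogy, genotypes = geno,
                   predictors = env, config = gen_cfg)
  } else {
    say("loading inputs")
    inp <- config$inputs
    aln <- read_alignment(inp$fasta, inp$metadata,
                          outgroup = inp$outgroup %||% NULL)
    genealogy <- ape::read.tree(inp$observed_tree)
    geno <- if (!is.null(inp$genotypes)) read_genotypes(inp$genotypes)
    env <- if (!is.null(inp$predictors)) read_predictors(inp$predictors)
    deme_sizes <- table_to_sizes(aln$deme)
  }

  # ---- stage 2: sequence statistics ----
  say("sequence polymorphism")
  poly <- polymorphism_summary(aln)
  fs <- tryCatch(fu_fs(aln), error = function(e) NULL)
  dstar <- tryCatch(fu_li_d(aln, "D_star"), error = function(e) NULL)
  neut <- data.frame(
    statistic = c("fu_fs", "fu_li_d_star"),
    value = c(if (is.null(fs)) NA_real_ else fs$fs,
              if (is.null(dstar)) NA_real_ else dstar$d))
  write_tsv(poly, file.path(output_dir, "sequence_polymorphism.tsv"))
  write_tsv(neut, file.path(output_dir, "neutrality_tests.tsv"))

  # ---- stage 3: microsatellite statistics ----
  msat <- NULL
  if (!is.null(geno)) {
    say("microsatellite summaries")
    msat <- locus_summaries(geno)
    write_tsv(msat, file.path(output_dir, "microsat_summaries.tsv"))
  }

  # ---- stage 4: sorting test ----
  say("sorting test (", config$n_sims, " simulations per model)")
  s_obs <- if (inherits(genealogy, "gene_tree")) fitch_steps(genealogy)
    else observed_s(genealogy,
                    stats::setNames(as.character(aln$deme),
                                    rownames(aln$seq)))
  sorting <- do.call(rbind, lapply(
    seq_along(config$models$hypotheses), function(i) {
      h <- config$models$hypotheses[i]
      m <- build_refugium_hypothesis(h, total_ne, config, rates)
      nd <- null_distribution(m, deme_sizes, n_sims = config$n_sims,
                              seed = config$seed + 10L + i)
      tm <- test_model(s_obs, nd)
      data.frame(model = h, null_mean = tm$null_mean, null_sd = tm$null_sd,
                 observed_s = s_obs, p_value = tm$p_value,
                 rejected = tm$rejected)
    }))
  write_tsv(sorting, file.path(output_dir, "sorting_test.tsv"))

  # ---- stage 5: landscape genetics ----
  dbrda <- NULL
  if (!is.null(env)) {
    say("distance-based redundancy analysis")
    D <- suppressWarnings(distance_matrices(aln, "phi_st"))
    env_rows <- match(rownames(D), env$location %||% env[[1L]])
    sets <- predictor_sets(env[env_rows, , drop = FALSE])
    seed_rng(config$seed + 20L)
    dbrda <- forward_selection(gower_center(D), sets,
                               n_perm = config$n_perm)
    write_tsv(dbrda$marginal, file.path(output_dir, "dbrda_marginal.tsv"))
    write_tsv(dbrda$selection, file.path(output_dir, "dbrda_selection.tsv"))
  }

  # ---- stage 6: demography ----
  say("demography")
  sky <- classic_skyline(genealogy, n_groups = config$skyline_groups)
  growth <- exp_growth_ml(genealogy)
  write_tsv(as.data.frame(sky), file.path(output_dir, "skyline.tsv"))
  write_tsv(data.frame(n0 = growth$n0, g = growth$g,
                       loglik = growth$loglik),
            file.path(output_dir, "growth.tsv"))

  manifest <- list(package = "skyrefugia",
                   version = as.character(utils::packageVersion("skyrefugia")),
                   seed = config$seed, total_ne = total_ne,
                   n_sims = config$n_sims, n_perm = config$n_perm,
                   hypotheses = config$models$hypotheses,
                   observed_s = s_obs,
                   outputs = list.files(output_dir, recursive = TRUE))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done: ", output_dir)
  invisible(list(polymorphism = poly, neutrality = neut, microsat = msat,
                 sorting = sorting, dbrda = dbrda, skyline = sky,
                 growth = growth, manifest = manifest))
}

build_refugium_hypothesis <- function(h, total_ne, config, rates) {
  tim <- config$models$divergence_times_years
  build_model(h, total_ne = total_ne,
              divergence_times_years = if (h == "single") NULL
                else unlist(tim[[h]]),
              generation_time = rates$generation_time)
}

table_to_sizes <- function(demes) {
  tb <- table(demes)
  stats::setNames(as.integer(tb), names(tb))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
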