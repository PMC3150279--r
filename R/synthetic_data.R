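#' Configuration for the synthetic study generator
#'
#' Collects every parameter of the synthetic data generator in one place.
#' Defaults emulate the ten-population montane study design: Table-1 sample
#' sizes over three subregions, a 4029-bp mitochondrial alignment with
#' per-site diversity of order 0.004, and ten stepwise-mutating
#' microsatellite loci whose reflecting allele-size range caps the allele
#' count per locus at nine.
#'
#' @param deme_sizes named samples per deme.
#' @param seq_length aligned sites of the mitochondrial locus.
#' @param theta_target per-site scaled diversity 2 Ne mu used to derive the
#'   sequence mutation rate when `mu_site` is `NULL`.
#' @param mu_site per-site per-generation mutation rate; overrides
#'   `theta_target` when given.
#' @param n_loci_msat number of microsatellite loci.
#' @param msat_mu stepwise mutation rate per generation.
#' @param msat_range reflecting lower/upper allele sizes of the stepwise
#'   walk (bounds the allele count per locus).
#' @param missing_rate fraction of microsatellite genotypes set missing.
#' @param rng_seed integer seed making all generator output reproducible.
#' @return An object of class `synthetic_study_config`.
#' @export
synthetic_study_config <- function(deme_sizes = study_demes(),
                                   seq_length = 4029,
                                   theta_target = 0.004,
                                   mu_site = NULL,
                                   n_loci_msat = 10,
                                   msat_mu = 1e-5,
                                   msat_range = c(16, 24),
                                   missing_rate = 0.02,
                                   rng_seed = 1L) {
  if (is.null(names(deme_sizes)) || any(deme_sizes < 1))
    stop_domain("deme_sizes must be named and >= 1")
  if (seq_length < 1) stop_domain("seq_length must be >= 1")
  if (!is.null(mu_site) && mu_site < 0)
    stop_domain("mu_site must be non-negative")
  if (is.null(mu_site) && theta_target <= 0)
    stop_domain("theta_target must be positive when mu_site is not given")
  if (msat_range[1] >= msat_range[2])
    stop_domain("msat_range must be an increasing pair")
  storage.mode(deme_sizes) <- "integer"
  structure(list(deme_sizes = deme_sizes, seq_length = as.integer(seq_length),
                 theta_target = theta_target, mu_site = mu_site,
                 n_loci_msat = as.integer(n_loci_msat), msat_mu = msat_mu,
                 msat_range = as.integer(msat_range),
                 missing_rate = missing_rate,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_study_config")
}

config_mu_site <- function(model, config) {
  config$mu_site %||% (config$theta_target / (2 * model$total_ne))
}

#' Simulate a coalescent gene tree under exponential growth
#'
#' Single panmictic population with N(t) = n0 exp(-g t), t in generations
#' before present. Simulated by inverting the cumulative coalescence rate
#' of the Kingman process, so each waiting time is drawn exactly. Used to
#' generate the growth genealogies against which the neutrality statistics
#' and [exp_growth_ml()] are calibrated.
#'
#' @param n number of tips.
#' @param n0 present-day effective size.
#' @param g exponential growth rate per generation (>= 0; 0 gives the
#'   constant-size coalescent).
#' @param deme tip deme label.
#' @param seed optional integer seed.
#' @return A `gene_tree`.
#' @export
simulate_growth_tree <- function(n, n0, g = 0, deme = "A", seed = NULL) {
  n <- as.integer(n)
  if (n < 2L) stop_domain("need at least two tips")
  if (n0 <= 0 || g < 0) stop_domain("n0 must be positive and g >= 0")
  seed_rng(seed)
  merges <- matrix(0L, n - 1L, 2L)
  times <- numeric(n - 1L)
  lin <- seq_len(n)
  t <- 0
  for (k in seq_len(n - 1L)) {
    kk <- length(lin)
    cr <- kk * (kk - 1L) / (2 * n0)
    e <- stats::rexp(1L)
    t <- if (g == 0) t + e / cr
      else log(exp(g * t) + e * g / cr) / g
    pr <- sample.int(kk, 2L)
    merges[k, ] <- lin[pr]
    times[k] <- t
    lin <- c(lin[-pr], n + k)
  }
  structure(list(n_tip = n, merges = merges, times = times,
                 tip_deme = factor(rep(deme, n)),
                 tip_label = paste0(deme, "_", seq_len(n))),
            class = "gene_tree")
}

#' Drop finite-sites mutations on a gene tree
#'
#' Evolves a random root sequence down the genealogy under the Jukes-Cantor
#' model (Poisson mutation events per branch, uniform site choice, uniform
#' alternative base), returning the tip sequences as an alignment.
#'
#' @param gt a `gene_tree`.
#' @param seq_length number of sites.
#' @param mu_site per-site per-generation mutation rate (0 gives identical
#'   sequences).
#' @param sites `"finite"` (Jukes-Cantor, sites can be hit repeatedly) or
#'   `"infinite"` (every mutation claims a fresh site; errors if more
#'   mutations arise than `seq_length`).
#' @param seed optional integer seed.
#' @return A [haplotype_alignment()].
#' @export
mutate_on_tree <- function(gt, seq_length, mu_site,
                           sites = c("finite", "infinite"), seed = NULL) {
  stopifnot(inherits(gt, "gene_tree"))
  sites <- match.arg(sites)
  if (mu_site < 0) stop_domain("mu_site must be non-negative")
  seed_rng(seed)
  L <- as.integer(seq_length)
  n <- gt$n_tip
  node_time <- c(numeric(n), gt$times)
  seqs <- vector("list", 2L * n - 1L)
  seqs[[2L * n - 1L]] <- sample.int(4L, L, replace = TRUE)
  used <- 0L  # infinite-sites: next fresh column is used + 1
  for (k in (n - 1L):1L) {
    par <- n + k
    for (ch in gt$merges[k, ]) {
      s <- seqs[[par]]
      n_mut <- stats::rpois(1L, mu_site * L * (node_time[par] - node_time[ch]))
      if (n_mut > 0L) {
        if (sites == "finite") {
          pos <- sample.int(L, n_mut, replace = TRUE)
        } else {
          if (used + n_mut > L)
            stop_domain("more mutations than sites; increase seq_length")
          pos <- used + seq_len(n_mut)
          used <- used + n_mut
        }
        for (p in pos) s[p] <- sample((1:4)[-s[p]], 1L)
      }
      seqs[[ch]] <- s
    }
  }
  bases <- c("A", "C", "G", "T")
  mat <- t(vapply(seqs[seq_len(n)], function(s) bases[s], character(L)))
  rownames(mat) <- gt$tip_label
  haplotype_alignment(mat, gt$tip_deme)
}

#' Simulate a mitochondrial alignment under a refugium model
#'
#' Draws a gene tree with [simulate_gene_tree()] and drops mutations on it
#' under a finite-sites Jukes-Cantor model: the number of mutation events
#' on each branch is Poisson with mean mu_site * L * length, each event
#' hits a uniform site and substitutes one of the three alternative bases.
#' With `mu_site = 0` all sequences are identical. Under panmixia the
#' expected per-site pairwise diversity equals 2 Ne mu (the configured
#' `theta_target`).
#'
#' @param model a [build_model()] object.
#' @param config a [synthetic_study_config()].
#' @param seed optional seed overriding `config$rng_seed`.
#' @return A [haplotype_alignment()]; the simulated `gene_tree` is attached
#'   as attribute `"gene_tree"`.
#' @export
simulate_sequences <- function(model, config, seed = NULL) {
  stopifnot(inherits(model, "refugium_model"),
            inherits(config, "synthetic_study_config"))
  seed_rng(seed %||% config$rng_seed)
  gt <- sim_gene_tree_raw(model, config$deme_sizes)
  aln <- mutate_on_tree(gt, config$seq_length, config_mu_site(model, config))
  attr(aln, "gene_tree") <- gt
  aln
}

# reflect x into [lo, hi]; exact endpoint law for a +/-1 walk with
# reflecting barriers
fold_reflect <- function(x, lo, hi) {
  p <- 2L * (hi - lo)
  y <- (x - lo) %% p
  ifelse(y > hi - lo, p - y, y) + lo
}

#' Simulate diploid microsatellite genotypes under a refugium model
#'
#' For each locus, simulates an independent gene tree of 2n gene copies
#' (two per individual) and evolves an integer allele size down the tree
#' under the strict stepwise mutation model: mutation events are Poisson
#' along branches and each moves the allele by one repeat, reflecting at
#' the configured minimum/maximum size. Gene copies are paired per
#' individual into genotypes; a fraction `missing_rate` of genotypes is
#' masked at random.
#'
#' @inheritParams simulate_sequences
#' @return A [genotype_table()].
#' @export
simulate_microsats <- function(model, config, seed = NULL) {
  stopifnot(inherits(model, "refugium_model"),
            inherits(config, "synthetic_study_config"))
  seed_rng(seed %||% config$rng_seed)
  sizes2 <- config$deme_sizes * 2L
  n_ind <- sum(config$deme_sizes)
  lo <- config$msat_range[1]; hi <- config$msat_range[2]
  root_allele <- as.integer(round((lo + hi) / 2))
  A <- B <- matrix(NA_integer_, n_ind, config$n_loci_msat)
  for (lc in seq_len(config$n_loci_msat)) {
    gt <- sim_gene_tree_raw(model, sizes2)
    n <- gt$n_tip
    node_time <- c(numeric(n), gt$times)
    al <- integer(2L * n - 1L)
    al[2L * n - 1L] <- root_allele
    for (k in (n - 1L):1L) {
      par <- n + k
      for (ch in gt$merges[k, ]) {
        len <- node_time[par] - node_time[ch]
        n_mut <- stats::rpois(1L, config$msat_mu * len)
        step <- if (n_mut > 0L)
          sum(sample(c(-1L, 1L), n_mut, replace = TRUE)) else 0L
        al[ch] <- fold_reflect(al[par] + step, lo, hi)
      }
    }
    A[, lc] <- al[seq(1L, n, by = 2L)]
    B[, lc] <- al[seq(2L, n, by = 2L)]
  }
  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(length(A)) < config$missing_rate, nrow(A))
    # keep every locus typed somewhere
    for (lc in which(colSums(!mask) == 0L)) mask[1L, lc] <- FALSE
    A[mask] <- NA_integer_; B[mask] <- NA_integer_
  }
  demes <- rep(names(config$deme_sizes), config$deme_sizes)
  samples <- paste0(demes, "_", stats::ave(seq_along(demes), demes,
                                           FUN = seq_along))
  genotype_table(A, B, demes, samples = samples,
                 loci = paste0("locus_", seq_len(config$n_loci_msat)))
}

#' Simulate an environmental predictor table
#'
#' Generates, per sampling location: coordinates (longitude, latitude),
#' elevation (m), three temperatures (mean annual, January, July; degrees
#' C), mean annual rainfall (mm), a five-class vegetation one-hot set and a
#' three-class subregion one-hot set. A single latent geographic gradient
#' (attached as attribute `"latent"`) stands in for the genetic structure;
#' `effect` in [0, 1] tunes how strongly the subregion classes (and
#' latitude) follow that gradient: at 0 they are independent of it, at 1
#' the subregions are its exact tertiles.
#'
#' @param locations character vector of location labels (>= 3).
#' @param effect association strength between subregion and the latent
#'   gradient, in [0, 1].
#' @param seed optional integer seed.
#' @return A data frame, one row per location, with attribute `"latent"`.
#' @export
simulate_env_table <- function(locations, effect = 0.8, seed = NULL) {
  if (length(locations) < 3L) stop_domain("at least three locations required")
  if (effect < 0 || effect > 1) stop_domain("effect must lie in [0, 1]")
  seed_rng(seed)
  n <- length(locations)
  z <- stats::rnorm(n)
  score <- effect * z + (1 - effect) * stats::rnorm(n)
  subregion <- cut(rank(score, ties.method = "first"), 3L,
                   labels = c("southern", "eastern", "northern"))
  lat <- 27 + 2 * as.integer(subregion) + 0.8 * stats::rnorm(n)
  lon <- 98 + 4 * stats::runif(n)
  elev <- 3000 + 400 * stats::rnorm(n)
  t_ann <- 20 - 0.004 * elev - 0.6 * (lat - 27) + 0.5 * stats::rnorm(n)
  t_jan <- t_ann - 8 + 0.5 * stats::rnorm(n)
  t_jul <- t_ann + 8 + 0.5 * stats::rnorm(n)
  rain <- exp(stats::rnorm(n, log(800), 0.25))
  veg <- cut(rank(elev + 200 * stats::rnorm(n), ties.method = "first"), 5L,
             labels = c("subtropical_shrub", "temperate_shrub",
                        "subalpine_shrub", "alpine_meadow", "alpine_steppe"))
  onehot <- function(f, prefix) {
    m <- stats::model.matrix(~ f - 1)
    colnames(m) <- paste0(prefix, "_", levels(f))
    m
  }
  out <- data.frame(location = locations, longitude = lon, latitude = lat,
                    elevation = elev, temp_annual = t_ann, temp_jan = t_jan,
                    temp_jul = t_jul, rainfall = rain,
                    onehot(veg, "veg"), onehot(subregion, "subregion"),
                    check.names = FALSE)
  attr(out, "latent") <- z
  out
}

#' Split an environmental table into its dbRDA predictor sets
#'
#' @param env a table from [simulate_env_table()] (or one read back from
#'   disk with the same columns).
#' @return Named list of predictor matrices: coordinate, vegetation,
#'   subregion, elevation, temperature, rainfall.
#' @export
predictor_sets <- function(env) {
  cols <- colnames(env)
  list(coordinate = as.matrix(env[, c("longitude", "latitude")]),
       vegetation = as.matrix(env[, grep("^veg_", cols), drop = FALSE]),
       subregion = as.matrix(env[, grep("^subregion_", cols), drop = FALSE]),
       elevation = as.matrix(env[, "elevation", drop = FALSE]),
       temperature = as.matrix(env[, c("temp_annual", "temp_jan",
                                       "temp_jul")]),
       rainfall = as.matrix(env[, "rainfall", drop = FALSE]))
}

#' Write synthetic outputs as plain-text fixtures
#'
#' Writes whichever pieces are supplied: alignment as FASTA plus a
#' sample-to-deme metadata TSV, gene tree as newick, genotypes as a TSV
#' with two allele columns per locus (missing = `NA`), predictors as TSV,
#' and the generator configuration as a YAML file. All formats round-trip
#' losslessly through the matching `read_*` functions.
#'
#' @param dir output directory (created if needed).
#' @param alignment optional [haplotype_alignment()].
#' @param gene_tree optional `gene_tree` or `phylo`.
#' @param genotypes optional [genotype_table()].
#' @param predictors optional predictor data frame.
#' @param config optional [synthetic_study_config()].
#' @return Invisibly, the named vector of file paths written.
#' @export
write_fixtures <- function(dir, alignment = NULL, gene_tree = NULL,
                           genotypes = NULL, predictors = NULL,
                           config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (!is.null(alignment)) {
    fa <- file.path(dir, "sequences.fasta")
    writeLines(paste0(">", rownames(alignment$seq), "\n",
                      apply(alignment$seq, 1L, paste, collapse = "")), fa)
    md <- file.path(dir, "samples.tsv")
    utils::write.table(
      data.frame(sample = rownames(alignment$seq),
                 deme = as.character(alignment$deme)),
      md, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, fasta = fa, metadata = md)
    if (!is.null(alignment$outgroup)) {
      og <- file.path(dir, "outgroup.fasta")
      writeLines(paste0(">", rownames(alignment$outgroup), "\n",
                        apply(alignment$outgroup, 1L, paste, collapse = "")),
                 og)
      paths <- c(paths, outgroup = og)
    }
  }
  if (!is.null(gene_tree)) {
    if (inherits(gene_tree, "gene_tree")) gene_tree <- as.phylo(gene_tree)
    nw <- file.path(dir, "gene_tree.nwk")
    ape::write.tree(gene_tree, nw, digits = 12)
    paths <- c(paths, tree = nw)
  }
  if (!is.null(genotypes)) {
    gp <- file.path(dir, "genotypes.tsv")
    df <- data.frame(sample = genotypes$samples,
                     deme = as.character(genotypes$deme))
    for (l in seq_along(genotypes$loci)) {
      df[[paste0(genotypes$loci[l], "_a")]] <- genotypes$a[, l]
      df[[paste0(genotypes$loci[l], "_b")]] <- genotypes$b[, l]
    }
    utils::write.table(df, gp, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, genotypes = gp)
  }
  if (!is.null(predictors)) {
    pp <- file.path(dir, "predictors.tsv")
    utils::write.table(predictors, pp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, predictors = pp)
  }
  if (!is.null(config)) {
    cp <- file.path(dir, "generator_config.yaml")
    yaml::write_yaml(unclass(config), cp)
    paths <- c(paths, config = cp)
  }
  invisible(paths)
}

#' Read a FASTA alignment and its metadata back
#'
#' @param fasta path to a FASTA file written by [write_fixtures()].
#' @param metadata path to the sample-to-deme TSV; when `NULL`, deme labels
#'   are recovered from the `"<deme>_<i>"` tip-name convention.
#' @param outgroup optional path to an outgroup FASTA.
#' @return A [haplotype_alignment()].
#' @export
read_alignment <- function(fasta, metadata = NULL, outgroup = NULL) {
  seqs <- read_fasta_strings(fasta)
  demes <- if (!is.null(metadata)) {
    md <- utils::read.table(metadata, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    stats::setNames(md$deme, md$sample)[names(seqs)]
  } else sub("_[0-9]+$", "", names(seqs))
  og <- if (!is.null(outgroup)) read_fasta_strings(outgroup) else NULL
  haplotype_alignment(seqs, demes, outgroup = og)
}

read_fasta_strings <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  stopifnot(length(hdr) > 0L)
  ends <- c(hdr[-1L] - 1L, length(lines))
  out <- vapply(seq_along(hdr), function(i)
    paste(lines[(hdr[i] + 1L):ends[i]], collapse = ""), "")
  names(out) <- sub("^>", "", lines[hdr])
  out
}

#' Read a genotype TSV back into a genotype table
#'
#' @param path file written by [write_fixtures()].
#' @return A [genotype_table()].
#' @export
read_genotypes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  acols <- grep("_a$", colnames(df), value = TRUE)
  loci <- sub("_a$", "", acols)
  A <- as.matrix(df[, paste0(loci, "_a"), drop = FALSE])
  B <- as.matrix(df[, paste0(loci, "_b"), drop = FALSE])
  genotype_table(A, B, df$deme, samples = df$sample, loci = loci)
}

#' Read a predictor TSV back
#'
#' @param path file written by [write_fixtures()].
#' @return A data frame, one row per location.
#' @export
read_predictors <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}
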