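#' Mutation-rate and generation-time settings
#'
#' Bundles the per-site mitochondrial mutation rate, the modulated rate for a
#' multi-fragment concatenation, the locus length, the microsatellite
#' per-generation rate and the generation time. These are the constants used
#' in every conversion between scaled coalescent quantities and calendar
#' time. Defaults follow the conventional avian cytochrome-b clock
#' (1e-8 substitutions/site/year), a combined-fragment rate of 0.78e-8
#' (see [modulate_rate()]), a 4029-bp mitochondrial concatenation, a 1e-5
#' per-generation microsatellite rate and a one-year generation time.
#'
#' @param mu_site_cytb per-site per-year mutation rate of cytochrome b.
#' @param mu_site_combined per-site per-year rate for the combined fragments.
#' @param locus_length number of aligned sites in the combined locus.
#' @param msat_mu microsatellite mutation rate per generation.
#' @param generation_time generation time in years.
#' @return An object of class `rate_set`.
#' @export
rate_set <- function(mu_site_cytb = 1e-8, mu_site_combined = 0.78e-8,
                     locus_length = 4029, msat_mu = 1e-5,
                     generation_time = 1) {
  vals <- c(mu_site_cytb, mu_site_combined, locus_length, msat_mu,
            generation_time)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_domain("all rate-set values must be positive and finite")
  structure(list(mu_site_cytb = mu_site_cytb,
                 mu_site_combined = mu_site_combined,
                 locus_length = locus_length,
                 msat_mu = msat_mu,
                 generation_time = generation_time),
            class = "rate_set")
}

#' Convert a maternal-locus theta to an effective population size
#'
#' For a maternally inherited (haploid, uniparental) locus the scaled
#' diversity is theta = 2 Ne mu, so Ne = theta / (2 mu). `mu` must be the
#' mutation rate per generation on the same per-site or per-locus scale as
#' `theta`.
#'
#' @param theta scaled diversity (positive).
#' @param mu mutation rate per generation (positive).
#' @return Effective population size.
#' @seealso [ne_to_theta()]
#' @export
theta_to_ne <- function(theta, mu) {
  if (!is.numeric(theta) || !is.numeric(mu) || any(theta <= 0) || any(mu <= 0))
    stop_domain("theta and mu must be positive")
  theta / (2 * mu)
}

#' @rdname theta_to_ne
#' @param ne effective population size (positive).
#' @export
ne_to_theta <- function(ne, mu) {
  if (!is.numeric(ne) || !is.numeric(mu) || any(ne <= 0) || any(mu <= 0))
    stop_domain("ne and mu must be positive")
  2 * ne * mu
}

#' Modulate a single-gene clock rate to a multi-fragment concatenation
#'
#' Rescales a reference per-site rate (e.g. the cytochrome-b clock) by the
#' ratio of mean pairwise distance in the combined sequences to that in the
#' reference gene alone, giving the per-site rate appropriate for the
#' concatenated alignment.
#'
#' @param mu_cytb reference per-site rate.
#' @param mean_dist_combined mean pairwise distance of the combined sequences.
#' @param mean_dist_cytb mean pairwise distance of the reference gene.
#' @return Modulated per-site rate `mu_cytb * mean_dist_combined / mean_dist_cytb`.
#' @export
modulate_rate <- function(mu_cytb, mean_dist_combined, mean_dist_cytb) {
  if (any(c(mu_cytb, mean_dist_combined, mean_dist_cytb) <= 0))
    stop_domain("rates and distances must be positive")
  mu_cytb * mean_dist_combined / mean_dist_cytb
}

#' Convert a model-scaled divergence time to calendar years
#'
#' Isolation-with-migration programs report divergence time scaled by the
#' mutation rate. For sequence data the scaled time t is in units of
#' mutations per locus, so years = t / (mu_site * L). For microsatellites t
#' is in mutations per locus per generation, so years =
#' (t / msat_mu) * generation_time.
#'
#' @param t scaled divergence time (>= 0).
#' @param rates a [rate_set()].
#' @param marker `"mtdna"` or `"msat"`.
#' @return Time in calendar years.
#' @export
scaled_time_to_years <- function(t, rates, marker = c("mtdna", "msat")) {
  marker <- match.arg(marker)
  stopifnot(inherits(rates, "rate_set"))
  if (any(t < 0)) stop_domain("scaled time must be non-negative")
  if (marker == "mtdna") {
    t / (rates$mu_site_combined * rates$locus_length)
  } else {
    (t / rates$msat_mu) * rates$generation_time
  }
}

#' The ten-population study design
#'
#' `study_demes()` returns the individual sample sizes of the ten sampling
#' populations (80 birds in three subregions: southern DL, ZD; eastern WX,
#' QL, HB, BC, YA; northern MK, CD, RT). `study_haplotype_counts()` returns
#' the distinct mitochondrial haplotypes per population (67 in total) — the
#' tip configuration of the haplotype-level genealogy. The observed
#' genealogy in this kind of study is a tree of distinct haplotypes, not of
#' individuals, so coalescent null distributions that are compared with it
#' must carry the same tips: under panmixia the sorting statistic depends
#' only on the tip configuration, which makes the choice consequential.
#' Haplotypes shared between neighbouring populations are counted once, in
#' one member of the admixture-zone populations (BC, YA, MK).
#'
#' @return Named integer vector of per-deme counts.
#' @export
study_demes <- function() {
  c(DL = 11L, ZD = 14L, WX = 7L, QL = 5L, HB = 5L, BC = 7L, YA = 8L,
    MK = 14L, CD = 7L, RT = 2L)
}

#' @rdname study_demes
#' @export
study_haplotype_counts <- function() {
  c(DL = 10L, ZD = 13L, WX = 5L, QL = 5L, HB = 5L, BC = 6L, YA = 6L,
    MK = 9L, CD = 6L, RT = 2L)
}

study_refugia <- function(hypothesis) {
  switch(hypothesis,
    single = list(ALL = names(study_demes())),
    two_refugia = list(S = c("DL", "ZD"),
                       NE = c("WX", "QL", "HB", "BC", "YA", "MK", "CD", "RT")),
    three_refugia = list(S = c("DL", "ZD"),
                         E = c("WX", "QL", "HB", "BC", "YA"),
                         N = c("MK", "CD", "RT")))
}

#' Build an Ne-scaled refugium population model
#'
#' Constructs the population tree for one of three diversification
#' hypotheses: a single refugium (panmixia, divergence time zero), two
#' refugia (a southern and a north-eastern unit splitting at
#' `divergence_times_years[1]`), or three refugia (southern versus a
#' north-eastern ancestor that subsequently splits into northern and eastern
#' units at `divergence_times_years[2]`). Each contemporary branch carries an
#' absolute effective size equal to its refugium's share of `total_ne`;
#' shares default to the refugium's fraction of the sampled individuals.
#' Ancestral ("refugial") branch sizes default to the sum of the descendant
#' shares but can be constrained explicitly through `refugial_proportions`,
#' e.g. to the share of the populations sampled at the putative refugium
#' sites.
#'
#' @param hypothesis `"single"`, `"two_refugia"` or `"three_refugia"`.
#' @param total_ne total effective population size summed over demes.
#' @param deme_sizes named integer vector of samples per deme; defaults to
#'   the ten-population study design.
#' @param refugia named list mapping refugium labels to deme names; defaults
#'   to the subregional grouping for the chosen hypothesis.
#' @param proportions optional named share of `total_ne` per refugium
#'   (must sum to 1).
#' @param divergence_times_years divergence times in years: none for
#'   `"single"`, one value for `"two_refugia"`, `c(root, nested)` for
#'   `"three_refugia"`.
#' @param generation_time years per generation.
#' @param refugial_proportions optional named numeric giving the share of
#'   `total_ne` carried by ancestral branches (names among `"NE"`, `"root"`).
#' @return An object of class `refugium_model`: a table of branches with
#'   start/end times in generations and absolute Ne, plus the deme-to-branch
#'   map.
#' @examples
#' m <- build_model("three_refugia", total_ne = 3e6,
#'                  divergence_times_years = c(1e5, 1.5e4))
#' m
#' @export
build_model <- function(hypothesis = c("single", "two_refugia",
                                       "three_refugia"),
                        total_ne,
                        deme_sizes = study_demes(),
                        refugia = NULL,
                        proportions = NULL,
                        divergence_times_years = NULL,
                        generation_time = 1,
                        refugial_proportions = NULL) {
  hypothesis <- match.arg(hypothesis)
  if (!is.numeric(total_ne) || total_ne <= 0)
    stop_domain("total_ne must be positive")
  if (is.null(names(deme_sizes)) || any(deme_sizes < 1))
    stop_domain("deme_sizes must be a named vector of sizes >= 1")
  if (is.null(refugia)) {
    refugia <- if (hypothesis == "single") list(ALL = names(deme_sizes))
      else study_refugia(hypothesis)
    if (!setequal(unlist(refugia), names(deme_sizes)))
      stop_domain("non-default demes: supply 'refugia' grouping them")
  }
  if (!setequal(unlist(refugia), names(deme_sizes)))
    stop_domain("refugia must partition the deme names")
  if (anyDuplicated(unlist(refugia)))
    stop_domain("each deme must belong to exactly one refugium")

  if (is.null(proportions)) {
    proportions <- vapply(refugia, function(d) sum(deme_sizes[d]), 0) /
      sum(deme_sizes)
  }
  if (abs(sum(proportions) - 1) > 1e-9)
    stop_domain("refugium proportions must sum to 1")
  if (!setequal(names(proportions), names(refugia)))
    stop_domain("proportions must be named by refugium")
  proportions <- proportions[names(refugia)]

  tgen <- function(y) y / generation_time
  n_ref <- length(refugia)
  if (hypothesis == "single") {
    if (!is.null(divergence_times_years) && any(divergence_times_years != 0))
      stop_domain("the single-refugium model has divergence time 0")
    branches <- data.frame(label = "root", parent = NA_integer_,
                           t0 = 0, t1 = Inf, ne = total_ne)
    leaf_of_refugium <- stats::setNames(rep(1L, n_ref), names(refugia))
  } else if (hypothesis == "two_refugia") {
    if (length(divergence_times_years) != 1L)
      stop_domain("two_refugia needs one divergence time")
    t_root <- tgen(divergence_times_years[1])
    if (t_root <= 0) stop_domain("divergence time must be positive")
    branches <- data.frame(
      label = c(names(refugia), "root"),
      parent = c(3L, 3L, NA_integer_),
      t0 = c(0, 0, t_root),
      t1 = c(t_root, t_root, Inf),
      ne = c(proportions * total_ne, total_ne))
    leaf_of_refugium <- stats::setNames(1:2, names(refugia))
  } else {
    if (length(divergence_times_years) != 2L)
      stop_domain("three_refugia needs c(root, nested) divergence times")
    t_root <- tgen(divergence_times_years[1])
    t_nest <- tgen(divergence_times_years[2])
    if (t_nest <= 0 || t_nest >= t_root)
      stop_domain("nested split must fall between 0 and the root time")
    if (n_ref != 3L) stop_domain("three_refugia needs three refugia")
    # topology (S, (E, N)): refugia 2 and 3 share the nested ancestor
    ne_anc <- sum(proportions[2:3]) * total_ne
    ne_root <- total_ne
    if (!is.null(refugial_proportions)) {
      if ("NE" %in% names(refugial_proportions))
        ne_anc <- refugial_proportions[["NE"]] * total_ne
      if ("root" %in% names(refugial_proportions))
        ne_root <- refugial_proportions[["root"]] * total_ne
    }
    branches <- data.frame(
      label = c(names(refugia), paste0(names(refugia)[2], names(refugia)[3]),
                "root"),
      parent = c(5L, 4L, 4L, 5L, NA_integer_),
      t0 = c(0, 0, 0, t_nest, t_root),
      t1 = c(t_root, t_nest, t_nest, t_root, Inf),
      ne = c(proportions * total_ne, ne_anc, ne_root))
    leaf_of_refugium <- stats::setNames(1:3, names(refugia))
  }
  if (any(branches$ne <= 0)) stop_domain("all branch Ne must be positive")

  deme_to_branch <- integer(length(deme_sizes))
  names(deme_to_branch) <- names(deme_sizes)
  for (r in names(refugia)) deme_to_branch[refugia[[r]]] <- leaf_of_refugium[[r]]

  structure(list(hypothesis = hypothesis, branches = branches,
                 refugia = refugia, deme_to_branch = deme_to_branch,
                 total_ne = total_ne, generation_time = generation_time),
            class = "refugium_model")
}

#' @export
print.refugium_model <- function(x, ...) {
  cat("Refugium model:", x$hypothesis, "\n")
  cat("Total Ne:", format(x$total_ne, big.mark = ","), "\n")
  b <- x$branches
  b$t1 <- ifelse(is.infinite(b$t1), Inf, b$t1)
  print(b, row.names = FALSE)
  invisible(x)
}

#' Simulate a gene tree under a refugium model
#'
#' Runs a neutral structured coalescent constrained by the population tree:
#' within each branch lineages coalesce as a Kingman process with pair rate
#' 1/Ne per generation (so the expected coalescence time of two lineages in
#' a population of size Ne is Ne generations, the scale implied by
#' theta = 2 Ne mu for a maternal locus); lineages surviving to an ancestral
#' node are pooled and continue in the parent branch. There is no migration
#' between contemporaneous branches, and the root branch extends until all
#' lineages have coalesced.
#'
#' @param model a [build_model()] object.
#' @param deme_sizes named vector of sampled tip counts per deme; every name
#'   must map to a model leaf. Defaults to the ten-population study design.
#' @param seed optional integer seed.
#' @return A `gene_tree`: a binary ultrametric genealogy with branch lengths
#'   in generations and deme-labelled tips. Convert with
#'   [as.phylo.gene_tree()].
#' @examples
#' m <- build_model("single", total_ne = 1000)
#' g <- simulate_gene_tree(m, c(A = 3, B = 2), seed = 1)
#' ape::is.ultrametric(as.phylo(g))
#' @export
simulate_gene_tree <- function(model, deme_sizes = study_demes(),
                               seed = NULL) {
  stopifnot(inherits(model, "refugium_model"))
  if (is.null(names(deme_sizes)) || any(deme_sizes < 1))
    stop_domain("deme_sizes must be named and >= 1")
  if (!all(names(deme_sizes) %in% names(model$deme_to_branch)))
    stop_domain("unknown demes: ",
                paste(setdiff(names(deme_sizes),
                              names(model$deme_to_branch)), collapse = ", "))
  seed_rng(seed)
  sim_gene_tree_raw(model, deme_sizes)
}

# simulation core; assumes RNG already seeded and inputs validated
sim_gene_tree_raw <- function(model, deme_sizes) {
  n <- as.integer(sum(deme_sizes))
  demes <- names(deme_sizes)
  deme_idx <- rep(seq_along(deme_sizes), deme_sizes)
  br <- model$branches
  nb <- nrow(br)
  pool <- vector("list", nb)
  for (d in seq_along(deme_sizes)) {
    b <- model$deme_to_branch[[demes[d]]]
    pool[[b]] <- c(pool[[b]], which(deme_idx == d))
  }
  merges <- matrix(0L, n - 1L, 2L)
  times <- numeric(n - 1L)
  nxt <- n  # id of the most recently created node
  ord <- order(br$t0)
  for (bi in ord) {
    lin <- pool[[bi]]
    k <- length(lin)
    t <- br$t0[bi]
    t1 <- br$t1[bi]
    ne <- br$ne[bi]
    while (k >= 2L) {
      t <- t + stats::rexp(1L, k * (k - 1L) / (2 * ne))
      if (t > t1) break
      pr <- sample.int(k, 2L)
      nxt <- nxt + 1L
      merges[nxt - n, ] <- lin[pr]
      times[nxt - n] <- t
      lin <- c(lin[-pr], nxt)
      k <- k - 1L
    }
    if (!is.infinite(t1)) {
      p <- br$parent[bi]
      pool[[p]] <- c(pool[[p]], lin)
    }
  }
  tip_label <- paste0(demes[deme_idx], "_", stats::ave(deme_idx, deme_idx,
                                                       FUN = seq_along))
  structure(list(n_tip = n, merges = merges, times = times,
                 tip_deme = factor(demes[deme_idx], levels = demes),
                 tip_label = tip_label),
            class = "gene_tree")
}

#' @export
print.gene_tree <- function(x, ...) {
  cat("Gene tree with", x$n_tip, "tips in",
      nlevels(x$tip_deme), "demes; height",
      format(max(x$times), digits = 4), "generations\n")
  invisible(x)
}

#' Convert a simulated gene tree to an ape phylo object
#'
#' @param x a `gene_tree` from [simulate_gene_tree()].
#' @param ... unused.
#' @return An ultrametric `phylo` with branch lengths in generations and tip
#'   labels `"<deme>_<i>"`.
#' @exportS3Method ape::as.phylo
as.phylo.gene_tree <- function(x, ...) {
  n <- x$n_tip
  # ape numbering: tips 1..n, root n+1, other internals n+2..2n-1.
  # internal node n+k in our scheme (k-th merge) maps to an ape id.
  node_time <- c(numeric(n), x$times)
  n_int <- n - 1L
  # our internal ids n+1..2n-1 in merge order; root is the last merge
  ape_id <- integer(2L * n - 1L)
  ape_id[seq_len(n)] <- seq_len(n)
  ape_id[2L * n - 1L] <- n + 1L
  if (n_int > 1L)
    ape_id[(n + 1L):(2L * n - 2L)] <- (n + 2L):(2L * n - 1L)
  edge <- matrix(0L, 2L * (n - 1L), 2L)
  elen <- numeric(2L * (n - 1L))
  for (k in seq_len(n_int)) {
    par <- n + k
    ch <- x$merges[k, ]
    i <- 2L * k - 1L
    edge[i, ] <- c(ape_id[par], ape_id[ch[1L]])
    edge[i + 1L, ] <- c(ape_id[par], ape_id[ch[2L]])
    elen[i] <- node_time[par] - node_time[ch[1L]]
    elen[i + 1L] <- node_time[par] - node_time[ch[2L]]
  }
  phy <- structure(list(edge = edge, edge.length = elen,
                        tip.label = x$tip_label, Nnode = n_int),
                   class = "phylo", order = "none")
  ape::reorder.phylo(phy, "cladewise")
}

# coalescent (merge-order) representation of an ultrametric binary phylo;
# used so statistics written for gene_tree objects accept external trees
gene_tree_from_phylo <- function(phy, demes = NULL) {
  stopifnot(inherits(phy, "phylo"))
  if (!ape::is.binary(phy)) phy <- ape::multi2di(phy)
  n <- ape::Ntip(phy)
  depth <- ape::node.depth.edgelength(phy)
  height <- max(depth)
  age <- height - depth  # time before present of each node
  int_ids <- (n + 1L):(n + phy$Nnode)
  ord <- int_ids[order(age[int_ids])]
  remap <- integer(n + phy$Nnode)
  remap[seq_len(n)] <- seq_len(n)
  remap[ord] <- n + seq_along(ord)
  merges <- matrix(0L, n - 1L, 2L)
  times <- numeric(n - 1L)
  kids <- split(phy$edge[, 2L], phy$edge[, 1L])
  for (k in seq_along(ord)) {
    ch <- kids[[as.character(ord[k])]]
    merges[k, ] <- remap[ch]
    times[k] <- age[ord[k]]
  }
  if (is.null(demes)) demes <- sub("_[0-9]+$", "", phy$tip.label)
  if (length(demes) != n) stop_domain("one deme label per tip required")
  structure(list(n_tip = n, merges = merges, times = times,
                 tip_deme = factor(demes), tip_label = phy$tip.label),
            class = "gene_tree")
}
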