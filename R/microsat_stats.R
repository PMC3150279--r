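#' Construct a diploid microsatellite genotype table
#'
#' Stores two allele sizes (integer repeat counts) per sample and locus,
#' with missing genotypes as `NA` in both allele slots.
#'
#' @param allele_a,allele_b integer matrices (samples x loci) holding the
#'   two allele sizes of each genotype; `NA` marks a missing genotype.
#' @param demes deme label per sample.
#' @param samples optional sample ids (default: rownames of `allele_a`).
#' @param loci optional locus names (default: colnames of `allele_a`).
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(allele_a, allele_b, demes, samples = NULL,
                           loci = NULL) {
  allele_a <- as.matrix(allele_a); allele_b <- as.matrix(allele_b)
  if (!all(dim(allele_a) == dim(allele_b)))
    stop_domain("allele matrices must have identical dimensions")
  if (length(demes) != nrow(allele_a))
    stop_domain("one deme label per sample required")
  if (any(stats::na.omit(c(allele_a, allele_b)) <= 0))
    stop_domain("allele sizes must be positive integers")
  miss_a <- is.na(allele_a); miss_b <- is.na(allele_b)
  if (!identical(unname(miss_a), unname(miss_b)))
    stop_domain("missing genotypes must have NA in both allele slots")
  samples <- samples %||% rownames(allele_a) %||%
    paste0("ind", seq_len(nrow(allele_a)))
  loci <- loci %||% colnames(allele_a) %||%
    paste0("locus_", seq_len(ncol(allele_a)))
  if (any(colSums(!miss_a) == 0L))
    stop_domain("each locus must be typed in at least one individual")
  dimnames(allele_a) <- dimnames(allele_b) <- list(samples, loci)
  structure(list(a = allele_a, b = allele_b, deme = factor(demes),
                 samples = samples, loci = loci),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("Genotype table:", length(x$samples), "samples x", length(x$loci),
      "loci;", nlevels(x$deme), "demes;",
      sum(is.na(x$a)), "missing genotypes\n")
  invisible(x)
}

allele_freqs <- function(tab, deme, locus) {
  sel <- tab$deme == deme & !is.na(tab$a[, locus])
  al <- c(tab$a[sel, locus], tab$b[sel, locus])
  if (!length(al)) return(numeric(0))
  table(al) / length(al)
}

#' Per-deme, per-locus microsatellite summaries
#'
#' For each deme x locus cell with at least one typed individual: the number
#' of alleles N_A, allelic richness A_R rarefied to the smallest per-deme
#' gene count at that locus (so cells are comparable across unequal sample
#' sizes), observed heterozygosity H_O, unbiased expected heterozygosity
#' H_E = (2n/(2n-1)) (1 - sum p^2), and the inbreeding coefficient
#' F_IS = 1 - H_O/H_E (undefined where H_E = 0). Cells with no typed
#' individual are reported as `NA`.
#'
#' @param tab a [genotype_table()].
#' @return A data frame keyed by deme and locus.
#' @export
locus_summaries <- function(tab) {
  stopifnot(inherits(tab, "genotype_table"))
  demes <- levels(tab$deme)
  out <- expand.grid(deme = demes, locus = tab$loci, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  for (col in c("n", "n_alleles", "allelic_richness", "h_obs", "h_exp",
                "f_is"))
    out[[col]] <- NA_real_
  for (lc in tab$loci) {
    # rarefaction depth: smallest nonzero gene count across demes
    gene_counts <- vapply(demes, function(d)
      2L * sum(tab$deme == d & !is.na(tab$a[, lc])), 0L)
    g <- min(gene_counts[gene_counts > 0L])
    for (d in demes) {
      i <- which(out$deme == d & out$locus == lc)
      sel <- tab$deme == d & !is.na(tab$a[, lc])
      n <- sum(sel)
      if (n == 0L) next
      al <- c(tab$a[sel, lc], tab$b[sel, lc])
      cnt <- table(al)
      p <- as.numeric(cnt) / (2 * n)
      he <- (2 * n) / (2 * n - 1) * (1 - sum(p^2))
      ho <- mean(tab$a[sel, lc] != tab$b[sel, lc])
      out$n[i] <- n
      out$n_alleles[i] <- length(cnt)
      out$allelic_richness[i] <- rarefied_richness(as.integer(cnt), g)
      out$h_obs[i] <- ho
      out$h_exp[i] <- he
      out$f_is[i] <- if (he > 0) 1 - ho / he else NA_real_
    }
  }
  out
}

# expected number of alleles in a subsample of g gene copies:
# sum_a [1 - choose(N - N_a, g) / choose(N, g)]
rarefied_richness <- function(counts, g) {
  N <- sum(counts)
  if (g > N) g <- N
  sum(1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
}

#' Monte-Carlo exact test of Hardy-Weinberg equilibrium
#'
#' Computes the conditional probability of the observed genotype array
#' given its allele counts and estimates the exact-test P by repeatedly
#' shuffling the 2n gene copies into random genotypes: P is the fraction of
#' shuffles whose array probability does not exceed the observed one (with
#' the add-one correction). Monomorphic data return P = 1.
#'
#' @param tab a [genotype_table()].
#' @param deme,locus the cell to test.
#' @param n_mc number of Monte-Carlo shuffles.
#' @param seed optional integer seed.
#' @return The estimated exact P value.
#' @seealso [stats::p.adjust()] with `method = "bonferroni"` for the
#'   multiple-test correction across deme x locus combinations.
#' @export
hwe_exact <- function(tab, deme, locus, n_mc = 2000, seed = NULL) {
  stopifnot(inherits(tab, "genotype_table"))
  sel <- tab$deme == deme & !is.na(tab$a[, locus])
  n <- sum(sel)
  if (n < 3L) stop_domain("at least three genotyped individuals required")
  a <- tab$a[sel, locus]; b <- tab$b[sel, locus]
  copies <- c(a, b)
  if (length(unique(copies)) == 1L) return(1)
  seed_rng(seed)
  obs <- log_array_prob(a, b)
  hits <- 0L
  for (r in seq_len(n_mc)) {
    perm <- sample(copies)
    pa <- perm[seq_len(n)]; pb <- perm[n + seq_len(n)]
    if (log_array_prob(pa, pb) <= obs + 1e-9) hits <- hits + 1L
  }
  (1 + hits) / (n_mc + 1)
}

# log conditional probability of a genotype array given allele counts:
# P = n! prod_a(n_a!) 2^het / ((2n)! prod_{a<=b} n_ab!)
log_array_prob <- function(a, b) {
  n <- length(a)
  het <- sum(a != b)
  geno <- paste(pmin(a, b), pmax(a, b))
  n_ab <- table(geno)
  n_a <- table(c(a, b))
  lfactorial(n) + sum(lfactorial(n_a)) + het * log(2) -
    lfactorial(2 * n) - sum(lfactorial(n_ab))
}

#' Between-deme microsatellite genetic distances
#'
#' `"nei_standard"` computes Nei's (1972) standard genetic distance
#' D = -ln( Jxy / sqrt(Jx Jy) ) with the gene identities averaged
#' arithmetically across loci. `"fst"` computes the pairwise
#' variance-component (Weir-Cockerham theta) estimator summed over loci and
#' alleles, truncated below at zero.
#'
#' @param tab a [genotype_table()].
#' @param kind `"nei_standard"` or `"fst"`.
#' @return A symmetric deme x deme matrix with zero diagonal.
#' @export
genetic_distances <- function(tab, kind = c("nei_standard", "fst")) {
  stopifnot(inherits(tab, "genotype_table"))
  kind <- match.arg(kind)
  demes <- levels(tab$deme)
  out <- matrix(0, length(demes), length(demes),
                dimnames = list(demes, demes))
  for (i in seq_along(demes)[-1]) for (j in seq_len(i - 1L)) {
    v <- if (kind == "nei_standard")
      nei_standard_pair(tab, demes[i], demes[j])
    else fst_pair(tab, demes[i], demes[j])
    out[i, j] <- out[j, i] <- v
  }
  out
}

nei_standard_pair <- function(tab, dx, dy) {
  jx <- jy <- jxy <- numeric(0)
  for (lc in tab$loci) {
    px <- allele_freqs(tab, dx, lc)
    py <- allele_freqs(tab, dy, lc)
    if (!length(px) || !length(py)) next
    alleles <- union(names(px), names(py))
    vx <- stats::setNames(rep(0, length(alleles)), alleles); vx[names(px)] <- px
    vy <- stats::setNames(rep(0, length(alleles)), alleles); vy[names(py)] <- py
    jx <- c(jx, sum(vx^2)); jy <- c(jy, sum(vy^2)); jxy <- c(jxy, sum(vx * vy))
  }
  if (!length(jx)) stop_domain("no locus typed in both demes")
  val <- mean(jxy) / sqrt(mean(jx) * mean(jy))
  max(0, -log(val))
}

# Weir & Cockerham (1984) theta for two demes, summed over loci and alleles
fst_pair <- function(tab, dx, dy) {
  num <- den <- 0
  for (lc in tab$loci) {
    sel_x <- tab$deme == dx & !is.na(tab$a[, lc])
    sel_y <- tab$deme == dy & !is.na(tab$a[, lc])
    nx <- sum(sel_x); ny <- sum(sel_y)
    if (nx < 1L || ny < 1L) next
    ax <- c(tab$a[sel_x, lc], tab$b[sel_x, lc])
    ay <- c(tab$a[sel_y, lc], tab$b[sel_y, lc])
    alleles <- unique(c(ax, ay))
    if (length(alleles) < 2L) next
    r <- 2
    n_bar <- (nx + ny) / r
    nc <- (nx + ny - (nx^2 + ny^2) / (nx + ny)) / (r - 1)
    for (al in alleles) {
      px <- mean(ax == al); py <- mean(ay == al)
      p_bar <- (nx * px + ny * py) / (nx + ny)
      s2 <- (nx * (px - p_bar)^2 + ny * (py - p_bar)^2) / ((r - 1) * n_bar)
      hx <- mean((tab$a[sel_x, lc] == al) != (tab$b[sel_x, lc] == al))
      hy <- mean((tab$a[sel_y, lc] == al) != (tab$b[sel_y, lc] == al))
      h_bar <- (nx * hx + ny * hy) / (nx + ny)
      a_comp <- n_bar / nc * (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
                                      h_bar / 4) / (n_bar - 1))
      b_comp <- n_bar / (n_bar - 1) *
        (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
           (2 * n_bar - 1) / (4 * n_bar) * h_bar)
      c_comp <- h_bar / 2
      num <- num + a_comp
      den <- den + a_comp + b_comp + c_comp
    }
  }
  if (den == 0) return(0)
  max(0, num / den)
}

#' Frequency-based assignment and exclusion test
#'
#' Assigns each individual to the deme whose allele frequencies give its
#' multilocus genotype the highest likelihood (Hardy-Weinberg genotype
#' probabilities; alleles unobserved in a deme receive a frequency floor,
#' by default 1/(2n+1)). The exclusion test simulates `n_sim` genotypes per
#' deme by resampling gametes from the deme's frequencies; an individual is
#' excluded from its sampling deme when the likelihood of its genotype
#' falls below the `alpha` quantile of the simulated likelihoods (computed
#' over the loci the individual was typed at).
#'
#' @param tab a [genotype_table()].
#' @param n_sim simulated individuals per deme (>= 100).
#' @param alpha exclusion threshold (default 0.01).
#' @param freq_floor frequency assigned to unobserved alleles; default
#'   1/(2n+1) with n the deme's typed sample size at the locus.
#' @param seed optional integer seed.
#' @return A data frame: individual, sampling deme, assigned deme,
#'   log-likelihood in the sampling deme, exclusion P and flag.
#' @export
assignment_exclusion <- function(tab, n_sim = 1000, alpha = 0.01,
                                 freq_floor = NULL, seed = NULL) {
  stopifnot(inherits(tab, "genotype_table"))
  if (n_sim < 100) stop_domain("n_sim must be at least 100")
  seed_rng(seed)
  demes <- levels(tab$deme)
  loci <- tab$loci
  # per-deme, per-locus frequency tables with floors
  freqs <- lapply(demes, function(d) lapply(loci, function(lc) {
    f <- allele_freqs(tab, d, lc)
    n <- sum(tab$deme == d & !is.na(tab$a[, lc]))
    floor_val <- if (is.null(freq_floor)) 1 / (2 * n + 1) else freq_floor
    attr(f, "floor") <- floor_val
    f
  }))
  names(freqs) <- demes
  geno_ll <- function(fr, x, y) {
    fl <- attr(fr, "floor")
    px <- if (x %in% names(fr)) fr[[as.character(x)]] else fl
    py <- if (y %in% names(fr)) fr[[as.character(y)]] else fl
    if (x == y) log(px * py) else log(2 * px * py)
  }
  # simulated null log-likelihood per deme x sim x locus
  sim_ll <- lapply(demes, function(d) {
    m <- matrix(NA_real_, n_sim, length(loci))
    for (l in seq_along(loci)) {
      fr <- freqs[[d]][[l]]
      if (!length(fr)) next
      als <- as.integer(names(fr))
      ga <- als[sample.int(length(als), n_sim, replace = TRUE, prob = fr)]
      gb <- als[sample.int(length(als), n_sim, replace = TRUE, prob = fr)]
      m[, l] <- mapply(function(x, y) geno_ll(fr, x, y), ga, gb)
    }
    m
  })
  names(sim_ll) <- demes
  res <- list()
  for (i in seq_along(tab$samples)) {
    typed <- which(!is.na(tab$a[i, ]))
    if (!length(typed)) {
      warning("skipping untyped individual ", tab$samples[i])
      next
    }
    ll <- vapply(demes, function(d) {
      sum(vapply(typed, function(l)
        geno_ll(freqs[[d]][[l]], tab$a[i, l], tab$b[i, l]), 0))
    }, 0)
    home <- as.character(tab$deme[i])
    # exclusion compares only loci with reference frequencies in the home deme
    typed_home <- typed[vapply(typed, function(l)
      length(freqs[[home]][[l]]) > 0L, TRUE)]
    ll_home <- sum(vapply(typed_home, function(l)
      geno_ll(freqs[[home]][[l]], tab$a[i, l], tab$b[i, l]), 0))
    null_ll <- rowSums(sim_ll[[home]][, typed_home, drop = FALSE])
    p_excl <- (1 + sum(null_ll <= ll_home)) / (n_sim + 1)
    res[[length(res) + 1L]] <- data.frame(
      individual = tab$samples[i], sampling_deme = home,
      assigned_deme = demes[which.max(ll)], loglik_home = ll[[home]],
      exclusion_p = p_excl, excluded = p_excl < alpha)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
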