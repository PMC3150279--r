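#' Construct a haplotype alignment
#'
#' Container for an aligned set of equal-length nucleotide sequences with a
#' deme label per sample and optional outgroup sequences. Outgroups are
#' carried alongside the ingroup and excluded from all ingroup statistics;
#' they orient singletons in [fu_li_d()] and fixed differences in
#' [mk_test()].
#'
#' @param sequences character vector of sequence strings (or a character
#'   matrix, one row per sample, one column per site), named by sample.
#' @param demes character/factor of deme labels, one per ingroup sample.
#' @param outgroup optional sequences in the same format.
#' @return An object of class `haplotype_alignment`.
#' @export
haplotype_alignment <- function(sequences, demes, outgroup = NULL) {
  seq_mat <- to_seq_matrix(sequences)
  if (length(demes) != nrow(seq_mat))
    stop_domain("one deme label per sequence required")
  out_mat <- if (!is.null(outgroup)) to_seq_matrix(outgroup) else NULL
  if (!is.null(out_mat) && ncol(out_mat) != ncol(seq_mat))
    stop_domain("outgroup sequences must have the alignment length")
  structure(list(seq = seq_mat, deme = factor(demes), outgroup = out_mat,
                 L = ncol(seq_mat)),
            class = "haplotype_alignment")
}

to_seq_matrix <- function(x) {
  if (is.matrix(x)) {
    m <- toupper(x)
  } else {
    if (length(unique(nchar(x))) != 1L)
      stop_domain("all sequences must have the same length")
    m <- do.call(rbind, strsplit(toupper(x), ""))
    rownames(m) <- names(x)
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("seq", seq_len(nrow(m)))
  m
}

#' @export
print.haplotype_alignment <- function(x, ...) {
  cat("Haplotype alignment:", nrow(x$seq), "ingroup sequences x", x$L,
      "sites;", nlevels(x$deme), "demes;",
      if (is.null(x$outgroup)) "no outgroup" else
        paste(nrow(x$outgroup), "outgroup sequence(s)"), "\n")
  invisible(x)
}

# columns free of gaps/ambiguities (complete deletion). include_outgroup
# additionally requires clean outgroup states in the retained columns.
retained_columns <- function(aln, include_outgroup = FALSE) {
  ok <- colSums(!matrix(aln$seq %in% c("A", "C", "G", "T"),
                        nrow(aln$seq))) == 0L
  if (include_outgroup && !is.null(aln$outgroup))
    ok <- ok & colSums(!matrix(aln$outgroup %in% c("A", "C", "G", "T"),
                               nrow(aln$outgroup))) == 0L
  which(ok)
}

#' Sequence polymorphism summary
#'
#' Computes, for the full sample and/or each deme: the number of segregating
#' sites S, the number of distinct haplotypes Nhap, the unbiased haplotype
#' diversity Hd = n(1 - sum p_i^2)/(n - 1), the per-site nucleotide
#' diversity pi (mean pairwise difference over retained sites), and the
#' per-locus Watterson estimator theta_w = S / a_{n-1}. Columns containing
#' gaps or ambiguity codes are removed first (complete deletion);
#' haplotypes are defined by exact string equality on the retained columns.
#'
#' @param aln a [haplotype_alignment()].
#' @param scope `"all"`, `"per_deme"`, or `"both"`.
#' @return A data frame with one row per scope unit.
#' @export
polymorphism_summary <- function(aln, scope = c("both", "all", "per_deme")) {
  stopifnot(inherits(aln, "haplotype_alignment"))
  scope <- match.arg(scope)
  keep <- retained_columns(aln)
  rows <- list()
  if (scope %in% c("both", "all"))
    rows[["all"]] <- summarize_block(aln$seq[, keep, drop = FALSE], "all")
  if (scope %in% c("both", "per_deme")) {
    for (d in levels(aln$deme)) {
      block <- aln$seq[aln$deme == d, keep, drop = FALSE]
      rows[[d]] <- summarize_block(block, d)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

summarize_block <- function(mat, label) {
  n <- nrow(mat)
  if (n < 2L)
    stop_domain("at least two sequences required (deme '", label, "')")
  L <- ncol(mat)
  hap <- apply(mat, 1L, paste, collapse = "")
  counts <- table(hap)
  p <- as.numeric(counts) / n
  hd <- n * (1 - sum(p^2)) / (n - 1)
  poly <- 0L
  pi_sum <- 0
  denom <- n * (n - 1)
  for (j in seq_len(L)) {
    tab <- tabulate(factor(mat[, j], levels = c("A", "C", "G", "T")), 4L)
    if (sum(tab > 0L) > 1L) {
      poly <- poly + 1L
      pi_sum <- pi_sum + (1 - sum(tab * (tab - 1L)) / denom)
    }
  }
  data.frame(scope = label, n = n, S = poly, Nhap = length(counts),
             Hd = hd, pi = if (L > 0) pi_sum / L else NA_real_,
             theta_w = poly / harmonic(n - 1L))
}

# mean pairwise differences per locus (not per site) on retained columns
mean_pairwise_diff <- function(mat) {
  n <- nrow(mat)
  denom <- n * (n - 1)
  tot <- 0
  for (j in seq_len(ncol(mat))) {
    tab <- tabulate(factor(mat[, j], levels = c("A", "C", "G", "T")), 4L)
    tot <- tot + (1 - sum(tab * (tab - 1L)) / denom)
  }
  tot
}

# log unsigned Stirling numbers of the first kind |s(n, 1..n)|
log_stirling_row <- function(n) {
  row <- -Inf
  row[1] <- 0  # |s(1,1)| = 1
  if (n == 1L) return(row)
  for (m in 2:n) {
    new <- numeric(m)
    new[1] <- log(m - 1) + row[1]
    if (m > 2L)
      for (k in 2:(m - 1))
        new[k] <- logsumexp(c(row[k - 1], log(m - 1) + row[k]))
    new[m] <- 0
    row <- new
  }
  row
}

# log P(K = 1..n | theta, n) under the Ewens sampling distribution
log_ewens_pmf <- function(n, theta) {
  ls <- log_stirling_row(n)
  lr <- sum(log(theta + 0:(n - 1)))  # log rising factorial
  ls + (1:n) * log(theta) - lr
}

#' Fu's Fs neutrality statistic
#'
#' Fs = ln(S'/(1 - S')) where S' is the probability of observing at least
#' the sampled number of distinct haplotypes under the Ewens sampling
#' distribution with theta estimated by the mean number of pairwise
#' differences. Large negative values indicate an excess of rare
#' haplotypes, as expected after population growth. The Ewens probabilities
#' use a Stirling-number recursion carried in log space.
#'
#' @param aln a [haplotype_alignment()], or a character matrix of sequences.
#' @return A list with `fs`, the haplotype count `k_obs`, `theta_pi` and
#'   `s_prime`.
#' @export
fu_fs <- function(aln) {
  mat <- if (inherits(aln, "haplotype_alignment"))
    aln$seq[, retained_columns(aln), drop = FALSE] else to_seq_matrix(aln)
  n <- nrow(mat)
  if (n < 2L) stop_domain("at least two sequences required")
  theta <- mean_pairwise_diff(mat)
  if (theta <= 0)
    stop_domain("Fu's Fs is undefined for monomorphic data")
  k_obs <- length(unique(apply(mat, 1L, paste, collapse = "")))
  lp <- log_ewens_pmf(n, theta)
  log_tail <- logsumexp(lp[k_obs:n])
  if (k_obs == 1L)
    stop_domain("Fu's Fs is undefined when S' = 1")
  log_head <- logsumexp(lp[1:(k_obs - 1L)])
  list(fs = log_tail - log_head, k_obs = k_obs, theta_pi = theta,
       s_prime = exp(log_tail - logsumexp(c(log_tail, log_head))))
}

#' Fu and Li's D and D* neutrality statistics
#'
#' Contrasts the total number of mutations eta with the number carried on
#' external branches (singletons), using the published variance
#' coefficients. Variant `"D"` orients singletons with the alignment's
#' outgroup (a derived allele seen in exactly one ingroup sequence);
#' variant `"D_star"` needs no outgroup and counts alleles observed once.
#' Negative values indicate an excess of recent (external-branch) mutations.
#'
#' @param aln a [haplotype_alignment()]; for variant `"D"` it must carry an
#'   outgroup.
#' @param variant `"D"` (outgroup-rooted) or `"D_star"`.
#' @return A list with the statistic `d`, `eta` and the singleton count.
#' @export
fu_li_d <- function(aln, variant = c("D", "D_star")) {
  stopifnot(inherits(aln, "haplotype_alignment"))
  variant <- match.arg(variant)
  n <- nrow(aln$seq)
  if (n < 3L) stop_domain("at least three sequences required")
  if (variant == "D" && is.null(aln$outgroup))
    stop_domain("variant 'D' requires an outgroup; use variant 'D_star'")
  keep <- retained_columns(aln, include_outgroup = (variant == "D"))
  mat <- aln$seq[, keep, drop = FALSE]
  eta <- 0L; sing <- 0L
  for (j in seq_len(ncol(mat))) {
    tab <- table(mat[, j])
    if (length(tab) < 2L) next
    eta <- eta + length(tab) - 1L
    if (variant == "D") {
      anc <- names(which.max(table(aln$outgroup[, keep[j]])))
      sing <- sing + sum(tab == 1L & names(tab) != anc)
    } else {
      sing <- sing + sum(tab == 1L)
    }
  }
  if (eta == 0L) stop_domain("no polymorphism: statistic undefined")
  a <- harmonic(n - 1L)
  b <- harmonic2(n - 1L)
  cn <- if (n == 2L) 1 else 2 * (n * a - 2 * (n - 1)) / ((n - 1) * (n - 2))
  if (variant == "D") {
    vD <- 1 + a^2 / (b + a^2) * (cn - (n + 1) / (n - 1))
    uD <- a - 1 - vD
    d <- (eta - a * sing) / sqrt(uD * eta + vD * eta^2)
  } else {
    an1 <- a + 1 / n
    dn <- cn + (n - 2) / (n - 1)^2 +
      2 / (n - 1) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)
    vDs <- ((n / (n - 1))^2 * b + a^2 * dn -
              2 * n * a * (a + 1) / (n - 1)^2) / (a^2 + b)
    uDs <- n / (n - 1) * (a - n / (n - 1)) - vDs
    d <- (n / (n - 1) * eta - a * sing) / sqrt(uDs * eta + vDs * eta^2)
  }
  list(d = d, eta = eta, singletons = sing, variant = variant)
}

#' McDonald-Kreitman test of selective neutrality
#'
#' Tabulates synonymous and nonsynonymous changes that are polymorphic
#' within the ingroup versus fixed between ingroup and outgroup, and tests
#' independence with Fisher's exact test (two-sided). The alignment must be
#' a protein-coding frame (length divisible by three). Codons containing
#' gaps or ambiguities in any sequence are excluded. Changes are classified
#' against the ingroup consensus codon, one mutation per extra allele.
#' When either margin of the table is empty the test carries no evidence
#' and P = 1 is returned by convention.
#'
#' @param aln a [haplotype_alignment()] with an outgroup.
#' @param code `"vertebrate_mitochondrial"` (default, for mtDNA fragments)
#'   or `"standard"`.
#' @return A list with the 2x2 `table` (rows syn/nonsyn, columns
#'   polymorphic/fixed) and the Fisher `p_value`.
#' @export
mk_test <- function(aln, code = c("vertebrate_mitochondrial", "standard")) {
  stopifnot(inherits(aln, "haplotype_alignment"))
  code <- match.arg(code)
  if (is.null(aln$outgroup)) stop_domain("mk_test requires an outgroup")
  if (aln$L %% 3L != 0L)
    stop_domain("alignment length must be divisible by 3 (in-frame coding)")
  gc_id <- if (code == "standard") "1" else "2"
  code_tab <- Biostrings::getGeneticCode(gc_id)
  translate1 <- function(codon) unname(code_tab[codon])
  tab <- matrix(0L, 2L, 2L,
                dimnames = list(c("synonymous", "nonsynonymous"),
                                c("polymorphic", "fixed")))
  acgt <- c("A", "C", "G", "T")
  for (cod in seq_len(aln$L / 3L)) {
    cols <- (3L * cod - 2L):(3L * cod)
    ing <- aln$seq[, cols, drop = FALSE]
    outg <- aln$outgroup[, cols, drop = FALSE]
    if (any(!ing %in% acgt) || any(!outg %in% acgt)) next
    cons <- apply(ing, 2L, function(x) names(which.max(table(x))))
    outc <- apply(outg, 2L, function(x) names(which.max(table(x))))
    for (pos in 1:3) {
      alleles <- unique(ing[, pos])
      syn_of <- function(allele, ref) {
        c1 <- cons; c1[pos] <- ref
        c2 <- cons; c2[pos] <- allele
        translate1(paste(c1, collapse = "")) ==
          translate1(paste(c2, collapse = ""))
      }
      if (length(alleles) > 1L) {
        ref <- cons[pos]
        for (al in setdiff(alleles, ref)) {
          row <- if (syn_of(al, ref)) 1L else 2L
          tab[row, 1L] <- tab[row, 1L] + 1L
        }
      } else if (alleles != outc[pos]) {
        row <- if (syn_of(outc[pos], alleles)) 1L else 2L
        tab[row, 2L] <- tab[row, 2L] + 1L
      }
    }
  }
  p <- if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) 1
       else stats::fisher.test(tab)$p.value
  list(table = tab, p_value = p)
}

#' Between-deme sequence distance matrices
#'
#' `"p_distance"` returns mean pairwise uncorrected p-distance between the
#' members of each pair of demes (per retained site). `"phi_st"` returns
#' pairwise Phi_ST computed from AMOVA variance components on the matrix of
#' pairwise nucleotide differences, truncated below at zero. Demes with
#' fewer than two sequences are excluded (with a warning) from Phi_ST.
#'
#' @param aln a [haplotype_alignment()].
#' @param kind `"p_distance"` or `"phi_st"`.
#' @return A symmetric matrix with zero diagonal, labelled by deme.
#' @export
distance_matrices <- function(aln, kind = c("p_distance", "phi_st")) {
  stopifnot(inherits(aln, "haplotype_alignment"))
  kind <- match.arg(kind)
  keep <- retained_columns(aln)
  mat <- aln$seq[, keep, drop = FALSE]
  deme <- droplevels(aln$deme)
  if (kind == "phi_st") {
    small <- names(which(table(deme) < 2L))
    if (length(small)) {
      warning("excluding demes with n < 2 from Phi_ST: ",
              paste(small, collapse = ", "))
      sel <- !deme %in% small
      mat <- mat[sel, , drop = FALSE]
      deme <- droplevels(deme[sel])
    }
    if (nlevels(deme) < 2L) stop_domain("Phi_ST needs at least two demes")
  }
  dd <- pairwise_diff_matrix(mat)
  lv <- levels(deme)
  out <- matrix(0, nlevels(deme), nlevels(deme), dimnames = list(lv, lv))
  for (i in seq_along(lv)[-1]) for (j in seq_len(i - 1L)) {
    xi <- which(deme == lv[i]); xj <- which(deme == lv[j])
    if (kind == "p_distance") {
      v <- mean(dd[xi, xj, drop = FALSE]) / length(keep)
    } else {
      v <- phi_st_pair(dd, xi, xj)
    }
    out[i, j] <- out[j, i] <- v
  }
  out
}

pairwise_diff_matrix <- function(mat) {
  n <- nrow(mat)
  dd <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    dd[i, j] <- dd[j, i] <- sum(mat[i, ] != mat[j, ])
  dd
}

# two-deme Phi_ST from AMOVA variance components; pairwise differences are
# treated as squared distances (the convention for haplotype data)
phi_st_pair <- function(dd, xi, xj) {
  ni <- length(xi); nj <- length(xj); N <- ni + nj
  all_idx <- c(xi, xj)
  ssd_t <- sum(dd[all_idx, all_idx]) / (2 * N)
  ssd_w <- sum(dd[xi, xi]) / (2 * ni) + sum(dd[xj, xj]) / (2 * nj)
  ssd_a <- ssd_t - ssd_w
  df_w <- N - 2L
  sig_w <- if (df_w > 0) ssd_w / df_w else 0
  n_prime <- (N - (ni^2 + nj^2) / N)  # / (P - 1) with P = 2
  sig_a <- (ssd_a - sig_w) / n_prime
  if (sig_a + sig_w <= 0) return(0)
  max(0, sig_a / (sig_a + sig_w))
}
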