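#' Gower-centred inner-product matrix of a distance matrix
#'
#' G = -1/2 J D^2 J with J = I - 11'/n the centring projector. For a
#' Euclidean distance matrix this recovers the centred Gram matrix of the
#' underlying coordinates; for semi-metric genetic distances (Phi_ST, F_ST)
#' G may have negative eigenvalues, and the analysis operates on G
#' directly. A square-root transform of D beforehand is available for
#' callers who prefer a Euclidean embedding.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @param sqrt_transform take sqrt(D) before centring.
#' @return The centred matrix G (rows and columns sum to zero).
#' @export
gower_center <- function(D, sqrt_transform = FALSE) {
  D <- assert_square_dist(D)
  if (sqrt_transform) D <- sqrt(D)
  n <- nrow(D)
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  dimnames(G) <- dimnames(D)
  (G + t(G)) / 2
}

# hat matrix of [1 X] via QR; drops redundant columns with a warning
hat_matrix <- function(X, warn = TRUE) {
  X <- as.matrix(X)
  Xc <- cbind(`(Intercept)` = 1, X)
  qr_x <- qr(Xc)
  # one-hot sets are expected to be collinear with the intercept by exactly
  # one column; warn only beyond that
  if (warn && qr_x$rank < ncol(X))
    warning("rank-deficient predictor set: redundant columns dropped")
  Q <- qr.Q(qr_x)[, seq_len(qr_x$rank), drop = FALSE]
  list(H = tcrossprod(Q), m = qr_x$rank - 1L)
}

db_fstat <- function(G, H, m) {
  n <- nrow(G)
  IH <- diag(n) - H
  ss_fit <- sum(H * (G %*% H))       # tr(H G H)
  ss_res <- sum(IH * (G %*% IH))     # tr((I-H) G (I-H))
  df_res <- n - m - 1L
  f <- (ss_fit / m) / (ss_res / df_res)
  list(f = f, ss_fit = ss_fit, ss_res = ss_res,
       pct_var = 100 * ss_fit / sum(diag(G)))
}

#' Marginal permutation test of one predictor set (dbRDA)
#'
#' McArdle-Anderson trace form of distance-based redundancy analysis:
#' pseudo-F = [tr(HGH)/m] / [tr((I-H)G(I-H))/(n-m-1)] with H the hat matrix
#' of the predictor set (plus intercept) and m its rank. Significance comes
#' from simultaneous permutation of the rows and columns of the distance
#' matrix (equivalently of G), with the add-one correction.
#'
#' @param G Gower-centred matrix from [gower_center()].
#' @param X predictor set: matrix or data frame, rows matching G.
#' @param n_perm number of permutations (>= 99).
#' @param seed optional integer seed.
#' @return List with `pseudo_f`, `p_value`, `pct_var`, `m`, `n_perm`.
#' @export
marginal_test <- function(G, X, n_perm = 9999, seed = NULL) {
  G <- as.matrix(G)
  X <- as.matrix(X)
  if (nrow(X) != nrow(G)) stop_domain("X rows must match the distance matrix")
  if (n_perm < 99) stop_domain("n_perm must be at least 99")
  seed_rng(seed)
  hm <- hat_matrix(X)
  obs <- db_fstat(G, hm$H, hm$m)
  n <- nrow(G)
  hits <- 0L
  for (r in seq_len(n_perm)) {
    p <- sample.int(n)
    fp <- db_fstat(G[p, p], hm$H, hm$m)$f
    if (fp >= obs$f - 1e-12) hits <- hits + 1L
  }
  list(pseudo_f = obs$f, p_value = (1 + hits) / (n_perm + 1),
       pct_var = obs$pct_var, m = hm$m, n_perm = n_perm)
}

#' Forward selection over predictor sets (dbRDA)
#'
#' Sequential tests in the style of DISTLM forward: at each step every
#' remaining predictor set is fitted conditional on the sets already
#' included, the best (largest conditional pseudo-F) is taken, and its
#' conditional P value is obtained by permuting the multivariate residual
#' matrix under the reduced model (Freedman-Lane). Selection stops when no
#' candidate reaches `alpha_stop`, unless `report_all` forces all sets in.
#' Marginal tests for every set and the pairwise correlations of the
#' predictor columns (a collinearity check) are reported alongside.
#'
#' @param G Gower-centred matrix from [gower_center()].
#' @param sets named list of predictor matrices (rows matching G).
#' @param n_perm permutations per test.
#' @param alpha_stop stopping level for the conditional P (default 1:
#'   report-all; set e.g. 0.05 for a conventional stop rule).
#' @param seed optional integer seed.
#' @return An object of class `dbrda_result` with the marginal table, the
#'   selection table (order, conditional P, cumulative percent variation)
#'   and the predictor correlation matrix.
#' @export
forward_selection <- function(G, sets, n_perm = 999, alpha_stop = 1,
                              seed = NULL) {
  G <- as.matrix(G)
  if (length(sets) < 2L) stop_domain("at least two predictor sets required")
  if (is.null(names(sets))) stop_domain("sets must be named")
  seed_rng(seed)
  n <- nrow(G)
  tr_g <- sum(diag(G))
  marginal <- do.call(rbind, lapply(names(sets), function(nm) {
    mt <- marginal_test(G, sets[[nm]], n_perm = n_perm)
    data.frame(set = nm, pseudo_f = mt$pseudo_f, p_value = mt$p_value,
               pct_var = mt$pct_var)
  }))
  included <- character(0)
  remaining <- names(sets)
  steps <- list()
  while (length(remaining)) {
    X_inc <- if (length(included))
      do.call(cbind, lapply(sets[included], as.matrix)) else NULL
    hm_red <- if (is.null(X_inc)) list(H = matrix(1 / n, n, n), m = 0L)
              else hat_matrix(X_inc, warn = FALSE)
    cand <- lapply(remaining, function(nm) {
      conditional_f(G, hm_red, sets[[nm]], X_inc)
    })
    fs <- vapply(cand, `[[`, 0, "f")
    best <- which.max(fs)
    # permutation of residuals under the reduced model
    IHr <- diag(n) - hm_red$H
    E <- IHr %*% G %*% IHr
    Gfit <- G - E
    hits <- 0L
    for (r in seq_len(n_perm)) {
      p <- sample.int(n)
      Gp <- Gfit + E[p, p]
      fp <- conditional_f(Gp, hm_red, sets[[remaining[best]]], X_inc)$f
      if (fp >= fs[best] - 1e-12) hits <- hits + 1L
    }
    p_cond <- (1 + hits) / (n_perm + 1)
    cum_pct <- 100 * cand[[best]]$ss_full / tr_g
    steps[[length(steps) + 1L]] <- data.frame(
      set = remaining[best], conditional_f = fs[best], p_value = p_cond,
      cum_pct_var = cum_pct)
    if (p_cond > alpha_stop) {
      steps[[length(steps)]] <- NULL
      break
    }
    included <- c(included, remaining[best])
    remaining <- remaining[-best]
  }
  selection <- if (length(steps)) do.call(rbind, steps) else
    data.frame(set = character(0), conditional_f = numeric(0),
               p_value = numeric(0), cum_pct_var = numeric(0))
  allX <- do.call(cbind, lapply(sets, as.matrix))
  structure(list(marginal = marginal, selection = selection,
                 correlations = suppressWarnings(stats::cor(allX)),
                 n_perm = n_perm),
            class = "dbrda_result")
}

conditional_f <- function(G, hm_red, Z, X_inc) {
  n <- nrow(G)
  X_full <- if (is.null(X_inc)) as.matrix(Z) else cbind(X_inc, as.matrix(Z))
  hm_full <- hat_matrix(X_full, warn = FALSE)
  ss_full <- sum(hm_full$H * (G %*% hm_full$H))
  ss_red <- sum(hm_red$H * (G %*% hm_red$H))
  m_add <- hm_full$m - hm_red$m
  IH <- diag(n) - hm_full$H
  ss_res <- sum(IH * (G %*% IH))
  df_res <- n - hm_full$m - 1L
  f <- if (m_add > 0L && df_res > 0L)
    ((ss_full - ss_red) / m_add) / (ss_res / df_res) else -Inf
  list(f = f, ss_full = ss_full)
}

#' @export
print.dbrda_result <- function(x, ...) {
  cat("dbRDA marginal tests:\n")
  print(x$marginal, row.names = FALSE, digits = 4)
  cat("\nForward selection:\n")
  print(x$selection, row.names = FALSE, digits = 4)
  invisible(x)
}
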