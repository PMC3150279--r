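#' Minimum number of sorting events (Fitch parsimony length)
#'
#' Counts the minimum number of character-state changes of an unordered
#' multistate character (here: the deme of each tip) on a rooted tree, by
#' Fitch's bottom-up set intersection/union pass. This is the
#' Slatkin-Maddison sorting statistic s: the minimum number of
#' migration/sorting events needed to explain the geographic distribution of
#' tips on the genealogy. The count is invariant to re-rooting. Polytomies
#' in a `phylo` input are resolved arbitrarily with zero-length branches,
#' which does not alter the parsimony length of an unordered character.
#'
#' @param tree a `gene_tree` from [simulate_gene_tree()] or an ape `phylo`.
#' @param tip_states character/factor of tip states. For a `gene_tree` the
#'   default is its deme labels; for a `phylo`, a vector named by tip label
#'   or ordered as `tree$tip.label`.
#' @return Integer parsimony length (0 when all tips share one state).
#' @examples
#' m <- build_model("single", total_ne = 100)
#' g <- simulate_gene_tree(m, c(A = 4, B = 4), seed = 7)
#' fitch_steps(g)
#' @export
fitch_steps <- function(tree, tip_states = NULL) {
  if (inherits(tree, "gene_tree")) {
    states <- if (is.null(tip_states)) tree$tip_deme else factor(tip_states)
    if (length(states) != tree$n_tip)
      stop_domain("one state per tip required")
    if (anyNA(states)) stop_domain("every tip must be labelled")
    return(fitch_merges(tree$merges, as.integer(states)))
  }
  if (!inherits(tree, "phylo")) stop_domain("tree must be gene_tree or phylo")
  phy <- tree
  if (is.null(tip_states)) stop_domain("tip_states required for a phylo tree")
  if (!is.null(names(tip_states))) {
    miss <- setdiff(phy$tip.label, names(tip_states))
    if (length(miss))
      stop_domain("tips without a state: ", paste(miss, collapse = ", "))
    tip_states <- tip_states[phy$tip.label]
  }
  states <- factor(tip_states)
  if (length(states) != ape::Ntip(phy)) stop_domain("one state per tip required")
  if (anyNA(states)) stop_domain("every tip must be labelled")
  if (!ape::is.binary(phy)) phy <- ape::multi2di(phy)
  fitch_phylo(phy, as.integer(states))
}

# Fitch pass over the merge matrix of a gene_tree (children precede parents)
fitch_merges <- function(merges, state_idx) {
  n <- length(state_idx)
  if (max(state_idx) > 30L)
    stop_domain("more than 30 states not supported")
  masks <- integer(2L * n - 1L)
  masks[seq_len(n)] <- bitwShiftL(1L, state_idx - 1L)
  steps <- 0L
  for (k in seq_len(n - 1L)) {
    a <- masks[merges[k, 1L]]
    b <- masks[merges[k, 2L]]
    m <- bitwAnd(a, b)
    if (m == 0L) {
      m <- bitwOr(a, b)
      steps <- steps + 1L
    }
    masks[n + k] <- m
  }
  steps
}

fitch_phylo <- function(phy, state_idx) {
  if (max(state_idx) > 30L)
    stop_domain("more than 30 states not supported")
  n <- ape::Ntip(phy)
  phy <- ape::reorder.phylo(phy, "postorder")
  masks <- integer(n + phy$Nnode)
  masks[seq_len(n)] <- bitwShiftL(1L, state_idx - 1L)
  steps <- 0L
  e1 <- phy$edge[, 1L]; e2 <- phy$edge[, 2L]
  for (i in seq_along(e1)) {
    p <- e1[i]
    m <- masks[p]
    child <- masks[e2[i]]
    if (m == 0L) {
      masks[p] <- child
    } else {
      a <- bitwAnd(m, child)
      if (a == 0L) {
        masks[p] <- bitwOr(m, child)
        steps <- steps + 1L
      } else masks[p] <- a
    }
  }
  steps
}

#' Observed sorting statistic of a genealogy
#'
#' Computes the Slatkin-Maddison S of an observed genealogy given the
#' deme assignment of its samples. This is [fitch_steps()] of the deme
#' character; the same observed value is compared against the null
#' distribution of every candidate refugium model.
#'
#' @param genealogy an ape `phylo`, or a path to a newick file.
#' @param deme_assignment named character vector (or two-column data frame
#'   `sample`, `deme`) assigning each tip to a deme.
#' @return Integer S.
#' @export
observed_s <- function(genealogy, deme_assignment) {
  if (is.character(genealogy) && length(genealogy) == 1L)
    genealogy <- ape::read.tree(genealogy)
  if (is.data.frame(deme_assignment)) {
    deme_assignment <- stats::setNames(
      as.character(deme_assignment[[2L]]), deme_assignment[[1L]])
  }
  extra <- setdiff(genealogy$tip.label, names(deme_assignment))
  if (length(extra))
    stop_domain("tips missing from the deme assignment: ",
                paste(extra, collapse = ", "))
  fitch_steps(genealogy, deme_assignment)
}

#' Null distribution of the sorting statistic under a refugium model
#'
#' Simulates `n_sims` gene trees within the model with
#' [simulate_gene_tree()] and computes [fitch_steps()] of the deme character
#' on each, yielding the null distribution of S against which an observed
#' genealogy is judged.
#'
#' @param model a [build_model()] object.
#' @param deme_sizes named tip counts per deme.
#' @param n_sims number of simulated gene trees (>= 100).
#' @param seed optional integer seed.
#' @param statistic `"parsimony"` for the Slatkin-Maddison S (default) or
#'   `"deep_coalescence"` for the topological extra-lineage count within the
#'   model's population tree.
#' @return An object of class `s_null` with the sorted simulated values and
#'   their mean and SD.
#' @export
null_distribution <- function(model, deme_sizes = study_demes(),
                              n_sims = 10000, seed = NULL,
                              statistic = c("parsimony", "deep_coalescence")) {
  stopifnot(inherits(model, "refugium_model"))
  statistic <- match.arg(statistic)
  if (n_sims < 100) stop_domain("n_sims must be at least 100")
  if (!all(names(deme_sizes) %in% names(model$deme_to_branch)))
    stop_domain("deme_sizes must match the model's demes")
  seed_rng(seed)
  s <- integer(n_sims)
  if (statistic == "parsimony") {
    state_idx <- rep(seq_along(deme_sizes), deme_sizes)
    for (i in seq_len(n_sims)) {
      g <- sim_gene_tree_raw(model, deme_sizes)
      s[i] <- fitch_merges(g$merges, state_idx)
    }
  } else {
    for (i in seq_len(n_sims)) {
      g <- sim_gene_tree_raw(model, deme_sizes)
      s[i] <- deep_coalescence(g, model)
    }
  }
  structure(list(s = sort(s), mean = mean(s), sd = stats::sd(s),
                 n_sims = n_sims, model = model$hypothesis,
                 statistic = statistic, seed = seed),
            class = "s_null")
}

#' @export
print.s_null <- function(x, ...) {
  cat(sprintf("Null %s distribution under the %s model: mean %.2f, SD %.2f (%d sims)\n",
              if (x$statistic == "parsimony") "S" else "deep-coalescence",
              x$model, x$mean, x$sd, x$n_sims))
  invisible(x)
}

#' Test a refugium model against an observed sorting statistic
#'
#' One-tailed simulation test: an observed genealogy that is *more*
#' geographically sorted (smaller S) than the model predicts rejects the
#' model. The p-value uses the add-one correction
#' p = (1 + #\{S_sim <= S_obs\}) / (n_sims + 1), with ties counted in the
#' rejection tail.
#'
#' @param observed_s integer observed S.
#' @param null an `s_null` from [null_distribution()].
#' @param alpha rejection level (default 0.05).
#' @return A `sorting_test_result` with the observed value, null moments,
#'   p-value and rejection decision.
#' @export
test_model <- function(observed_s, null, alpha = 0.05) {
  stopifnot(inherits(null, "s_null"))
  if (length(null$s) == 0L) stop_domain("empty null distribution")
  p <- (1 + sum(null$s <= observed_s)) / (null$n_sims + 1)
  structure(list(observed_s = observed_s, null_mean = null$mean,
                 null_sd = null$sd, p_value = p, n_sims = null$n_sims,
                 model = null$model, seed = null$seed, alpha = alpha,
                 rejected = p < alpha),
            class = "sorting_test_result")
}

#' @export
print.sorting_test_result <- function(x, ...) {
  cat(sprintf(
    "%s model: observed S = %d vs null mean %.2f (SD %.2f), p = %.4g -> %s\n",
    x$model, x$observed_s, x$null_mean, x$null_sd, x$p_value,
    if (x$rejected) "rejected" else "not rejected"))
  invisible(x)
}

#' Deep-coalescence cost of a gene tree within a population tree
#'
#' Topological count of extra gene lineages (Maddison's deep coalescences):
#' for every non-root branch of the population tree, the minimum number of
#' gene lineages that must exit the branch rootward is the number of maximal
#' gene-tree clades composed purely of tips sampled from that branch's
#' demes; the cost sums (exit count - 1) over those branches. Zero when the
#' refugia are reciprocally monophyletic in the gene tree. Offered as a
#' secondary sorting statistic; the headline statistic is [fitch_steps()].
#'
#' @param tree a `gene_tree` or deme-labelled `phylo`.
#' @param model a [build_model()] object supplying the population tree.
#' @return Integer deep-coalescence count.
#' @export
deep_coalescence <- function(tree, model) {
  stopifnot(inherits(model, "refugium_model"))
  if (inherits(tree, "phylo")) tree <- gene_tree_from_phylo(tree)
  stopifnot(inherits(tree, "gene_tree"))
  demes <- levels(tree$tip_deme)
  if (!all(demes %in% names(model$deme_to_branch)))
    stop_domain("gene-tree demes must map onto the model")
  n <- tree$n_tip
  deme_idx <- as.integer(tree$tip_deme)
  if (length(demes) > 30L) stop_domain("more than 30 demes not supported")
  masks <- integer(2L * n - 1L)
  masks[seq_len(n)] <- bitwShiftL(1L, deme_idx - 1L)
  for (k in seq_len(n - 1L))
    masks[n + k] <- bitwOr(masks[tree$merges[k, 1L]], masks[tree$merges[k, 2L]])
  parent <- integer(2L * n - 1L)
  for (k in seq_len(n - 1L)) parent[tree$merges[k, ]] <- n + k
  br <- model$branches
  cost <- 0L
  for (bi in seq_len(nrow(br))) {
    if (is.na(br$parent[bi])) next
    in_branch <- names(model$deme_to_branch)[
      branch_descends(model, bi)[model$deme_to_branch]]
    amask <- sum(bitwShiftL(1L, which(demes %in% in_branch) - 1L))
    if (amask == 0L) next
    pure <- bitwAnd(masks, bitwNot(amask)) == 0L & masks != 0L
    maximal <- pure & !pure[pmax(parent, 1L)]
    maximal[parent == 0L] <- pure[parent == 0L]
    cost <- cost + sum(maximal) - 1L
  }
  as.integer(cost)
}

# logical vector over branches: does branch b descend from (or equal) bi?
branch_descends <- function(model, bi) {
  br <- model$branches
  out <- logical(nrow(br))
  for (b in seq_len(nrow(br))) {
    cur <- b
    while (!is.na(cur)) {
      if (cur == bi) { out[b] <- TRUE; break }
      cur <- br$parent[cur]
    }
  }
  out
}
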