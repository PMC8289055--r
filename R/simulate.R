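# Evolver-style sequence simulation along a tree under JTT+Gamma, recording
# the state at every internal node, plus the two calibrations built on it:
# ancestral-inference accuracy of the CCS assumption, and the simulation
# null for convergent-call counts.

#' Simulate one gene along a tree, recording internal-node states
#'
#' Draws a root sequence i.i.d. from the model's equilibrium frequencies,
#' assigns each site one of the k discrete-gamma rate categories uniformly
#' (shared across the whole tree, the usual rates-across-sites semantics),
#' and evolves states down each branch using the transition matrix
#' `P(t * rate)`. Random numbers are consumed in a documented order —
#' rate categories, then the root sequence, then branches in root-to-tip
#' (reverse postorder) order — so results are fully reproducible from
#' `seed`.
#'
#' @param tree rooted [ape::phylo] tree with non-negative branch lengths.
#' @param model an `aa_model`.
#' @param n_sites number of sites (>= 1).
#' @param seed optional integer; when supplied the RNG state is set locally
#'   (and restored afterwards).
#' @return object of class `sim_dataset`: list with `tree`, `states`
#'   (integer matrix, rows = all nodes in ape numbering, with tip rows named
#'   by taxon and internal rows `node_<k>`), `site_categories`, `model`,
#'   `seed`.
#' @export
simulate_gene <- function(tree, model, n_sites, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  .sim_gene_impl(tree, model, n_sites, seed = seed)
}

.sim_gene_impl <- function(tree, model, n_sites, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "aa_model"),
            n_sites >= 1)
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  ntip <- length(tree$tip.label)
  nnode_tot <- ntip + tree$Nnode
  k <- length(model$rates)

  cat_idx <- sample.int(k, n_sites, replace = TRUE)
  states <- matrix(NA_integer_, nnode_tot, n_sites)
  root <- ntip + 1L
  states[root, ] <- sample.int(20L, n_sites, replace = TRUE,
                               prob = model$pi)

  post <- ape::reorder.phylo(tree, "postorder")
  for (e in rev(seq_len(nrow(post$edge)))) {     # root-to-tip
    p <- post$edge[e, 1L]; ch <- post$edge[e, 2L]
    t <- post$edge.length[e]
    for (c in seq_len(k)) {
      idx <- which(cat_idx == c)
      if (!length(idx)) next
      P <- transition_matrix(model, t, model$rates[c])
      par <- states[p, idx]
      for (s in unique(par)) {
        j <- idx[par == s]
        states[ch, j] <- sample.int(20L, length(j), replace = TRUE,
                                    prob = P[s, ])
      }
    }
  }
  rownames(states) <- c(tree$tip.label,
                        paste0("node_", (ntip + 1L):nnode_tot))
  structure(list(tree = tree, states = states, site_categories = cat_idx,
                 model = model, seed = seed),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("Simulated dataset: %d sites, %d tips, %d internal nodes\n",
              ncol(x$states), length(x$tree$tip.label), x$tree$Nnode))
  invisible(x)
}

#' Leaf sequences of a simulated dataset as an alignment
#' @param sim a `sim_dataset`.
#' @param gene_id gene identifier for the resulting alignment.
#' @return an `ortho_aln` over the tree's tips.
#' @export
sim_leaf_alignment <- function(sim, gene_id = "sim") {
  ntip <- length(sim$tree$tip.label)
  mat <- matrix(AA_ALPHABET[sim$states[seq_len(ntip), , drop = FALSE]],
                nrow = ntip, dimnames = list(sim$tree$tip.label, NULL))
  ortho_aln(mat, gene_id = gene_id)
}

#' Internal-node sequences of a simulated dataset
#' @param sim a `sim_dataset`.
#' @return named character vector of internal-node residue strings
#'   (including the root, `node_<ntip+1>`).
#' @export
sim_node_sequences <- function(sim) {
  ntip <- length(sim$tree$tip.label)
  idx <- (ntip + 1L):nrow(sim$states)
  stats::setNames(
    apply(matrix(AA_ALPHABET[sim$states[idx, , drop = FALSE]],
                 nrow = length(idx)), 1L, paste, collapse = ""),
    rownames(sim$states)[idx])
}

#' Accuracy of the outgroup-as-ancestor assumption at conservative sites
#'
#' The CCS criterion assumes that, at a conservative site, the ancestors of
#' the two tested clusters carried the outgroup residue. Given a simulation
#' with recorded internal-node states, this restricts to sites that pass the
#' conservative criterion on the simulated *leaves* (same rule as
#' [classify_site()]) and returns the fraction of those sites at which the
#' simulated outgroup state equals the true simulated state at *both*
#' checked ancestral nodes — the MRCAs of the two clusters on the tested
#' (non-control) side. Sites conservative in both directions contribute one
#' instance per direction.
#'
#' @param sim a `sim_dataset`.
#' @param design a [species_design()]; all design taxa must be tips of the
#'   simulated tree.
#' @param include_ingroup_root if `TRUE`, additionally require the MRCA of
#'   all sixteen ingroup taxa to match the outgroup state.
#' @return fraction in `[0, 1]`, or `NA` (with a warning) when the
#'   simulation contains no conservative sites.
#' @export
ancestral_accuracy <- function(sim, design, include_ingroup_root = FALSE) {
  aln <- sim_leaf_alignment(sim)
  mat <- unclass(aln)
  O <- mat[design$outgroup, ]
  all_eq_O <- function(tx) {
    G <- mat[tx, , drop = FALSE]
    colSums(G == matrix(O, nrow(G), ncol(G), byrow = TRUE)) == nrow(G)
  }
  cons_fg <- all_eq_O(design$bg1) & all_eq_O(design$bg2)
  cons_bg <- all_eq_O(design$fg1) & all_eq_O(design$fg2)

  node_of <- function(tx) ape::getMRCA(sim$tree, tx)
  out_state <- sim$states[design$outgroup, ]
  hits <- logical(0)
  for (side in list(list(mask = cons_fg, cl = list(design$fg1, design$fg2)),
                    list(mask = cons_bg, cl = list(design$bg1, design$bg2)))) {
    idx <- which(side$mask)
    if (!length(idx)) next
    n1 <- node_of(side$cl[[1L]]); n2 <- node_of(side$cl[[2L]])
    ok <- sim$states[n1, idx] == out_state[idx] &
          sim$states[n2, idx] == out_state[idx]
    if (include_ingroup_root) {
      nr <- node_of(c(design$fg1, design$fg2, design$bg1, design$bg2))
      ok <- ok & sim$states[nr, idx] == out_state[idx]
    }
    hits <- c(hits, ok)
  }
  if (!length(hits)) {
    warning("no conservative sites in simulation; accuracy undefined")
    return(NA_real_)
  }
  mean(hits)
}

#' Simulation null distribution of convergent-call counts
#'
#' Repeatedly simulates alignments of `n_sites` columns under the model on
#' the given tree (no planted convergence) and runs the CCS caller on the
#' simulated leaves, yielding the per-replicate foreground/background call
#' counts used as an empirical null.
#'
#' @param tree rooted [ape::phylo] with branch lengths.
#' @param model an `aa_model`.
#' @param design a [species_design()].
#' @param n_sites sites per replicate.
#' @param reps number of replicates (>= 1).
#' @param seed integer seed for the whole run.
#' @inheritParams classify_site
#' @return data.frame with columns `rep`, `foreground`, `background`.
#' @export
null_convergence <- function(tree, model, design, n_sites, reps,
                             seed = NULL, min_shared_per_cluster = 3L) {
  stopifnot(reps >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  res <- matrix(0L, reps, 2L)
  for (r in seq_len(reps)) {
    sim <- .sim_gene_impl(tree, model, n_sites)
    calls <- scan_gene(sim_leaf_alignment(sim, gene_id = paste0("null", r)),
                       design, min_shared_per_cluster)
    res[r, ] <- c(sum(calls$direction == "foreground"),
                  sum(calls$direction == "background"))
  }
  data.frame(rep = seq_len(reps), foreground = res[, 1L],
             background = res[, 2L])
}
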