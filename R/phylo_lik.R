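# Fixed-topology phylogenetic likelihood under a reversible amino-acid model
# with discrete-gamma rates, plus coordinate-ascent estimation of branch
# lengths and the gamma shape (the parameter-estimation step normally done
# with codeml).

# --- internal workspace -----------------------------------------------------

# Compress an alignment to unique site patterns restricted to the tree's
# tips, and precompute per-tip conditional-likelihood matrices.
.lik_workspace <- function(aln, tree) {
  taxa <- aln_taxa(aln)
  if (!all(taxa %in% tree$tip.label))
    stop("taxa absent from tree: ",
         paste(setdiff(taxa, tree$tip.label), collapse = ", "))
  if (!all(tree$tip.label %in% taxa))
    tree <- ape::keep.tip(tree, taxa)
  mat <- unclass(aln)[tree$tip.label, , drop = FALSE]

  col_str <- do.call(paste0, lapply(seq_len(nrow(mat)), function(i) mat[i, ]))
  upat <- unique(col_str)
  first <- match(upat, col_str)
  weights <- tabulate(match(col_str, upat), nbins = length(upat))

  ntip <- length(tree$tip.label)
  npat <- length(upat)
  tipD <- vector("list", ntip)
  for (i in seq_len(ntip)) {
    st <- match(mat[i, first], AA_ALPHABET)   # NA => missing data
    D <- matrix(0, npat, 20L)
    obs <- !is.na(st)
    D[cbind(which(obs), st[obs])] <- 1
    D[!obs, ] <- 1
    tipD[[i]] <- D
  }

  post <- ape::reorder.phylo(tree, "postorder")
  list(tree = tree, edge = post$edge, elen = post$edge.length,
       ntip = ntip, nnode = tree$Nnode, root = ntip + 1L,
       npat = npat, weights = weights, tipD = tipD)
}

# Row maxima of an npat x 20 matrix, avoiding apply().
.row_max <- function(M) do.call(pmax, lapply(seq_len(ncol(M)), function(j) M[, j]))

# Post-order pass for one rate category. Returns scaled conditional
# likelihoods D (list over nodes), per-node log scale factors, and the
# per-edge child messages M[[e]] = D_child %*% t(P_e) used by the up pass.
.down_pass <- function(ws, model, rate, elen = ws$elen) {
  nnode_tot <- ws$ntip + ws$nnode
  D <- vector("list", nnode_tot)
  logs <- vector("list", nnode_tot)
  zero <- numeric(ws$npat)
  for (i in seq_len(ws$ntip)) { D[[i]] <- ws$tipD[[i]]; logs[[i]] <- zero }
  M <- vector("list", nrow(ws$edge))
  for (e in seq_len(nrow(ws$edge))) {
    p <- ws$edge[e, 1L]; ch <- ws$edge[e, 2L]
    P <- transition_matrix(model, elen[e], rate)
    Me <- D[[ch]] %*% t(P)
    M[[e]] <- Me
    if (is.null(D[[p]])) {
      D[[p]] <- Me
      logs[[p]] <- logs[[ch]]
    } else {
      D[[p]] <- D[[p]] * Me
      logs[[p]] <- logs[[p]] + logs[[ch]]
    }
    if (ch > ws$ntip) {   # rescale internal-node products to avoid underflow
      s <- .row_max(D[[p]])
      s[s <= 0] <- 1
      D[[p]] <- D[[p]] / s
      logs[[p]] <- logs[[p]] + log(s)
    }
  }
  list(D = D, logs = logs, M = M)
}

# log-sum-exp across the columns of an npat x k matrix
.log_mean_exp <- function(L) {
  m <- .row_max(L)
  m + log(rowMeans(exp(L - m)))
}

#' Phylogenetic log-likelihood of an alignment on a tree
#'
#' Felsenstein's pruning algorithm over unique site patterns, mixed over the
#' model's discrete-gamma rate categories with equal weights. Gaps, `X` and
#' `?` contribute partial likelihood one for every residue. Numerical
#' underflow is prevented by per-node rescaling in log space.
#'
#' @param aln an `ortho_aln` whose taxa are all leaves of `tree`.
#' @param tree an [ape::phylo] tree with branch lengths (extra leaves are
#'   pruned).
#' @param model an `aa_model` from [build_model()].
#' @return the total log-likelihood (sum over sites).
#' @export
log_likelihood <- function(aln, tree, model) {
  ws <- .lik_workspace(aln, tree)
  .loglik_ws(ws, model)
}

.loglik_ws <- function(ws, model, elen = ws$elen) {
  k <- length(model$rates)
  L <- matrix(0, ws$npat, k)
  for (c in seq_len(k)) {
    dp <- .down_pass(ws, model, model$rates[c], elen)
    lik <- as.vector(dp$D[[ws$root]] %*% model$pi)
    L[, c] <- log(lik) + dp$logs[[ws$root]]
  }
  sum(ws$weights * .log_mean_exp(L))
}

#' Empirical residue frequencies of an alignment
#'
#' Observed residue proportions pooled over all taxa and columns, missing
#' symbols excluded. Residues never observed are floored at 1e-6 before
#' renormalization so the resulting frequencies are strictly positive.
#'
#' @param aln an `ortho_aln` (amino-acid).
#' @return named numeric vector of 20 frequencies summing to one.
#' @export
empirical_frequencies <- function(aln) {
  cnt <- table(factor(unclass(aln), levels = AA_ALPHABET))
  f <- as.numeric(cnt) / sum(cnt)
  f <- pmax(f, 1e-6)
  f <- f / sum(f)
  names(f) <- AA_ALPHABET
  f
}

#' Estimate branch lengths and the gamma shape by coordinate ascent
#'
#' Fits, on a fixed topology, the branch lengths and/or the gamma shape
#' `alpha` of a JTT+Gamma model by cyclic 1-D maximization (Brent/golden
#' section via [stats::optimize()]) of the pruning log-likelihood. Branch
#' lengths are bounded to `[1e-8, 20]` and `alpha` to `[0.02, 50]`.
#' Equilibrium frequencies are the empirical residue proportions of the
#' alignment (the usual "+F" practice). Each edge is optimized against
#' partial likelihoods that are refreshed along a root-to-tip walk, so the
#' objective is exact at every step and the log-likelihood never decreases.
#'
#' @param aln an `ortho_aln`.
#' @param tree starting tree; zero branch lengths are re-initialized to 0.05
#'   when branch lengths are optimized.
#' @param optimize character vector, subset of
#'   `c("alpha", "branch_lengths")`.
#' @param alpha starting gamma shape.
#' @param k number of gamma categories.
#' @param tol stop when a full sweep improves the log-likelihood by less
#'   than this (log units).
#' @param max_iter maximum number of sweeps; non-convergence gives a
#'   warning and `converged = FALSE`.
#' @return object of class `fitted_params`: list with `tree` (fitted branch
#'   lengths), `alpha`, `freqs`, `log_likelihood`, `model`, `converged`,
#'   `iterations`.
#' @export
fit_parameters <- function(aln, tree,
                           optimize = c("alpha", "branch_lengths"),
                           alpha = 1, k = 4, tol = 1e-6, max_iter = 200) {
  if (length(optimize))
    optimize <- match.arg(optimize, several.ok = TRUE)
  do_alpha <- "alpha" %in% optimize
  do_bl <- "branch_lengths" %in% optimize
  freqs <- empirical_frequencies(aln)
  model <- build_model(freqs, alpha = alpha, k = k)

  ws <- .lik_workspace(aln, tree)
  elen <- ws$elen
  if (do_bl) elen[elen <= 0] <- 0.05

  ll <- .loglik_ws(ws, model, elen)
  if (!do_alpha && !do_bl) {
    fit_tree <- .tree_with_lengths(ws, elen)
    return(structure(list(tree = fit_tree, alpha = alpha, freqs = freqs,
                          log_likelihood = ll, model = model,
                          converged = TRUE, iterations = 0L),
                     class = "fitted_params"))
  }

  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    ll_old <- ll
    if (do_bl) elen <- .optim_edges(ws, model, elen)
    if (do_alpha) {
      f <- function(a) {
        model$rates <- discrete_gamma_rates(a, k)
        .loglik_ws(ws, model, elen)
      }
      lo <- max(0.02, alpha / 3); hi <- min(50, alpha * 3)
      opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-4)
      if (opt$objective > f(alpha)) alpha <- opt$maximum
      model$rates <- discrete_gamma_rates(alpha, k)
      model$alpha <- alpha
    }
    ll <- .loglik_ws(ws, model, elen)
    if (ll < ll_old - 1e-9)
      warning("log-likelihood decreased during sweep (numerical)")
    if (ll - ll_old < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("fit_parameters did not converge in ", max_iter,
            " sweeps; returning best-so-far parameters")

  structure(list(tree = .tree_with_lengths(ws, elen), alpha = alpha,
                 freqs = freqs, log_likelihood = ll, model = model,
                 converged = converged, iterations = it),
            class = "fitted_params")
}

#' @export
print.fitted_params <- function(x, ...) {
  cat("Fitted JTT+Gamma parameters\n")
  cat(sprintf("  log-likelihood: %.4f\n", x$log_likelihood))
  cat(sprintf("  alpha: %.4f  (k = %d categories)\n", x$alpha, x$model$k))
  cat(sprintf("  tree length: %.4f over %d branches\n",
              sum(x$tree$edge.length), nrow(x$tree$edge)))
  if (!x$converged) cat("  WARNING: not converged\n")
  invisible(x)
}

.tree_with_lengths <- function(ws, elen) {
  tr <- ws$tree
  post <- ape::reorder.phylo(tr, "postorder")
  # map postorder edge order back onto the tree's native edge order
  key <- paste(post$edge[, 1L], post$edge[, 2L])
  tr$edge.length <- elen[match(paste(tr$edge[, 1L], tr$edge[, 2L]), key)]
  tr
}

# One sweep of exact single-edge optimizations. Edges are visited root-to-tip
# (reverse postorder); "up" partials are extended across each edge only after
# its new length is chosen, and "down" partials depend only on the subtree
# below an edge (not yet modified in the sweep), so every 1-D objective is
# the exact log-likelihood as a function of that edge length.
.optim_edges <- function(ws, model, elen) {
  k <- length(model$rates)
  ne <- nrow(ws$edge)
  dps <- lapply(seq_len(k), function(c) .down_pass(ws, model, model$rates[c], elen))

  nnode_tot <- ws$ntip + ws$nnode
  Up <- vector("list", k)       # Up[[c]][[node]]
  ulog <- vector("list", k)
  for (c in seq_len(k)) {
    Up[[c]] <- vector("list", nnode_tot)
    Up[[c]][[ws$root]] <- matrix(1, ws$npat, 20L)
    ulog[[c]] <- vector("list", nnode_tot)
    ulog[[c]][[ws$root]] <- numeric(ws$npat)
  }
  edges_by_parent <- split(seq_len(ne), ws$edge[, 1L])

  for (e in rev(seq_len(ne))) {           # reverse postorder = root-to-tip
    p <- ws$edge[e, 1L]; ch <- ws$edge[e, 2L]
    sibs <- setdiff(edges_by_parent[[as.character(p)]], e)
    Fmat <- vector("list", k)
    flog <- vector("list", k)
    for (c in seq_len(k)) {
      Fc <- Up[[c]][[p]]
      lc <- ulog[[c]][[p]]
      for (s in sibs) {
        Fc <- Fc * dps[[c]]$M[[s]]
        lc <- lc + dps[[c]]$logs[[ws$edge[s, 2L]]]
      }
      sc <- .row_max(Fc); sc[sc <= 0] <- 1
      Fmat[[c]] <- (Fc / sc) * rep(model$pi, each = ws$npat)
      flog[[c]] <- lc + log(sc)
    }
    Dch <- lapply(seq_len(k), function(c) dps[[c]]$D[[ch]])
    dlog <- lapply(seq_len(k), function(c) dps[[c]]$logs[[ch]])

    obj <- function(t) {
      L <- matrix(0, ws$npat, k)
      for (c in seq_len(k)) {
        P <- transition_matrix(model, t, model$rates[c])
        lik <- rowSums(Fmat[[c]] * (Dch[[c]] %*% t(P)))
        L[, c] <- log(lik) + flog[[c]] + dlog[[c]]
      }
      sum(ws$weights * .log_mean_exp(L))
    }
    t0 <- elen[e]
    lo <- max(1e-8, t0 / 10); hi <- min(20, max(t0 * 10, 1))
    opt <- stats::optimize(obj, c(lo, hi), maximum = TRUE, tol = 1e-7)
    if (opt$objective > obj(t0)) elen[e] <- opt$maximum

    # extend the up partials across this edge with its (possibly new) length
    for (c in seq_len(k)) {
      P <- transition_matrix(model, elen[e], model$rates[c])
      Fc <- Up[[c]][[p]]
      lc <- ulog[[c]][[p]]
      for (s in sibs) {
        Fc <- Fc * dps[[c]]$M[[s]]
        lc <- lc + dps[[c]]$logs[[ws$edge[s, 2L]]]
      }
      sc <- .row_max(Fc); sc[sc <= 0] <- 1
      Up[[c]][[ch]] <- (Fc / sc) %*% t(P)
      ulog[[c]][[ch]] <- lc + log(sc)
      # refresh the child message with the new length for later siblings
      dps[[c]]$M[[e]] <- dps[[c]]$D[[ch]] %*% t(transition_matrix(model, elen[e], model$rates[c]))
    }
  }
  elen
}
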