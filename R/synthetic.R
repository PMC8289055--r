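# Desk-scale synthetic study generator: the 17-taxon symmetric design, its
# tree, and per-gene alignments evolved under JTT+Gamma with optional
# planted convergent columns, so the whole pipeline runs without any
# external data.

#' Default 17-taxon topology and design
#'
#' A rooted 17-leaf tree mirroring the study layout: an outgroup sister to
#' two ingroup clades, each clade pairing a four-taxon foreground cluster
#' with its four-taxon aplacental control cluster — mammals with aplacental
#' tetrapods, syngnathids with aplacental teleosts. Every branch gets the
#' same default length, so the foreground and background sides are exactly
#' mirrored (the symmetry the two-cell chi-square comparison relies on).
#'
#' @param branch_length common branch length (expected substitutions/site,
#'   default 0.1) used for every level unless overridden below.
#' @param tip_length,pair_length,cluster_stem,clade_stem,ingroup_stem,outgroup_length
#'   optional per-level branch lengths (leaf branches, within-cluster pair
#'   stems, cluster stems, clade stems, the ingroup stem, and the outgroup
#'   branch). Foreground and background sides always receive identical
#'   lengths, so the tree stays mirrored whatever the values.
#' @return list with elements `tree` ([ape::phylo]) and `design`
#'   ([species_design()]): fg1 = mammals, fg2 = syngnathids,
#'   bg1 = tetrapods, bg2 = teleosts, outgroup = `outgroup_shark`.
#' @export
default_topology <- function(branch_length = 0.1,
                             tip_length = branch_length,
                             pair_length = branch_length,
                             cluster_stem = branch_length,
                             clade_stem = branch_length,
                             ingroup_stem = branch_length,
                             outgroup_length = branch_length) {
  cl <- function(nm) sprintf("((%s_1:%g,%s_2:%g):%g,(%s_3:%g,%s_4:%g):%g):%g",
                             nm, tip_length, nm, tip_length, pair_length,
                             nm, tip_length, nm, tip_length, pair_length,
                             cluster_stem)
  nwk <- sprintf("(outgroup_shark:%g,((%s,%s):%g,(%s,%s):%g):%g);",
                 outgroup_length,
                 cl("mammal"), cl("tetrapod"), clade_stem,
                 cl("syngnathid"), cl("teleost"), clade_stem, ingroup_stem)
  tree <- read_tree(text = nwk)
  design <- species_design(
    outgroup = "outgroup_shark",
    fg1 = paste0("mammal_", 1:4),
    fg2 = paste0("syngnathid_", 1:4),
    bg1 = paste0("tetrapod_", 1:4),
    bg2 = paste0("teleost_", 1:4))
  list(tree = tree, design = design)
}

#' Generate a complete synthetic study with planted convergent sites
#'
#' Simulates `n_genes` alignments of `gene_length` columns under JTT+Gamma
#' on the default (or a supplied) 17-taxon tree, then overwrites randomly
#' chosen columns with planted convergent patterns: the outgroup and all
#' eight control taxa are set to an ancestral residue `O` drawn from the
#' equilibrium frequencies, and the tested clusters to a derived residue
#' `d != O` (also drawn from the equilibrium frequencies, excluding `O`).
#' With `support_mode = "strict"` all eight tested taxa carry `d`
#' (8-of-8); with `"minimal"` only the first three taxa of each cluster
#' carry `d` and the fourth carries `O` (3+3, the weakest pattern the
#' default caller accepts).
#'
#' @param n_genes number of genes.
#' @param gene_length columns per gene.
#' @param alpha gamma shape for the neutral background.
#' @param planted_fg,planted_bg number of foreground / background planted
#'   sites across the whole study.
#' @param seed integer seed.
#' @param support_mode `"strict"` or `"minimal"` (see above).
#' @param topology optional list(tree, design) as from [default_topology()].
#' @param k gamma categories.
#' @return object of class `synthetic_study`: list with `design`, `tree`,
#'   `genes` (named list of `ortho_aln`), `truth` (data.frame `gene_id`,
#'   `column`, `direction`, `ancestral`, `derived`), `params`.
#' @export
generate_study <- function(n_genes, gene_length, alpha = 0.8,
                           planted_fg = 0L, planted_bg = 0L, seed = 1L,
                           support_mode = c("strict", "minimal"),
                           topology = NULL, k = 4L) {
  support_mode <- match.arg(support_mode)
  n_plant <- planted_fg + planted_bg
  if (n_plant > n_genes * gene_length)
    stop("cannot plant ", n_plant, " sites into ",
         n_genes * gene_length, " columns")
  if (is.null(topology)) topology <- default_topology()
  tree <- topology$tree
  design <- topology$design
  model <- build_model("jtt-default", alpha = alpha, k = k)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  genes <- vector("list", n_genes)
  names(genes) <- sprintf("gene%03d", seq_len(n_genes))
  for (g in seq_len(n_genes))
    genes[[g]] <- sim_leaf_alignment(
      .sim_gene_impl(tree, model, gene_length), gene_id = names(genes)[g])

  truth <- data.frame(gene_id = character(0), column = integer(0),
                      direction = character(0), ancestral = character(0),
                      derived = character(0), stringsAsFactors = FALSE)
  if (n_plant > 0L) {
    cells <- sample.int(n_genes * gene_length, n_plant)  # no collisions
    dir <- rep(c("foreground", "background"), c(planted_fg, planted_bg))
    pi <- model$pi
    for (i in seq_len(n_plant)) {
      g <- (cells[i] - 1L) %/% gene_length + 1L
      col <- (cells[i] - 1L) %% gene_length + 1L
      O <- sample(AA_ALPHABET, 1L, prob = pi)
      d <- sample(AA_ALPHABET[AA_ALPHABET != O], 1L,
                  prob = pi[AA_ALPHABET != O])
      if (dir[i] == "foreground") {
        target <- list(design$fg1, design$fg2)
        control <- c(design$bg1, design$bg2)
      } else {
        target <- list(design$bg1, design$bg2)
        control <- c(design$fg1, design$fg2)
      }
      mat <- unclass(genes[[g]])
      mat[c(design$outgroup, control), col] <- O
      for (cl in target) {
        if (support_mode == "strict") mat[cl, col] <- d
        else { mat[cl[1:3], col] <- d; mat[cl[4L], col] <- O }
      }
      genes[[g]] <- ortho_aln(mat, gene_id = names(genes)[g])
      truth <- rbind(truth, data.frame(
        gene_id = names(genes)[g], column = col, direction = dir[i],
        ancestral = O, derived = d, stringsAsFactors = FALSE))
    }
    truth <- truth[order(truth$gene_id, truth$column), , drop = FALSE]
    rownames(truth) <- NULL
  }
  structure(list(design = design, tree = tree, genes = genes, truth = truth,
                 params = list(n_genes = n_genes, gene_length = gene_length,
                               alpha = alpha, planted_fg = planted_fg,
                               planted_bg = planted_bg, seed = seed,
                               support_mode = support_mode, k = k)),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "Synthetic study: %d genes x %d columns, alpha = %g, seed = %d\n",
    p$n_genes, p$gene_length, p$alpha, p$seed))
  cat(sprintf("  planted: %d foreground, %d background (%s support)\n",
              p$planted_fg, p$planted_bg, p$support_mode))
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Writes per-gene FASTA files, the design TSV, the Newick tree and the
#' truth table of planted sites into a directory.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @return invisible vector of written paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (g in names(study$genes))
    paths <- c(paths, write_alignment(study$genes[[g]],
                                      file.path(dir, paste0(g, ".fasta"))))
  paths <- c(paths,
             write_design(study$design, file.path(dir, "design.tsv")),
             write_tree(study$tree, file.path(dir, "tree.nwk")))
  tp <- file.path(dir, "truth.tsv")
  utils::write.table(study$truth, tp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, tp))
}
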