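# Reading and writing of the standard formats the pipeline touches:
# amino-acid / nucleotide alignments (FASTA, PHYLIP), Newick trees, and the
# tab-separated species-design file.

#' Construct an ortholog alignment object
#'
#' An `ortho_aln` stores one gene's aligned sequences as a character matrix
#' (rows = taxa, columns = alignment positions). Residues are upper-cased
#' and validated against the amino-acid alphabet (ACDEFGHIKLMNPQRSTVWY plus
#' `-` for gaps and `X`/`?` for unknowns) or, with `type = "nt"`, against
#' IUPAC nucleotides.
#'
#' @param sequences named character vector of equal-length sequence strings,
#'   or a character matrix with taxon rownames.
#' @param gene_id identifier for the gene (default `"gene"`).
#' @param type `"aa"` (default) or `"nt"`.
#' @return an `ortho_aln`: character matrix with attributes `gene_id`, `type`.
#' @export
ortho_aln <- function(sequences, gene_id = "gene", type = c("aa", "nt")) {
  type <- match.arg(type)
  if (is.matrix(sequences)) {
    mat <- toupper(sequences)
  } else {
    sequences <- stats::setNames(toupper(as.character(sequences)),
                                 names(sequences))
    if (is.null(names(sequences)) || anyNA(names(sequences)))
      stop("sequences must be named by taxon")
    lens <- nchar(sequences)
    if (length(unique(lens)) > 1L) {
      bad <- names(sequences)[lens != lens[1L]][1L]
      stop(sprintf(
        "alignment is ragged: taxon '%s' has length %d, expected %d",
        bad, nchar(sequences[[bad]]), lens[1L]))
    }
    mat <- do.call(rbind, strsplit(sequences, "", fixed = TRUE))
    rownames(mat) <- names(sequences)
  }
  if (anyDuplicated(rownames(mat)))
    stop("duplicate taxon name: ",
         rownames(mat)[duplicated(rownames(mat))][1L])
  ok <- if (type == "aa") c(AA_ALPHABET, AA_MISSING)
        else c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N", "-", "?")
  bad <- which(!(mat %in% ok))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(mat))
    stop(sprintf(
      "illegal character '%s' for taxon '%s' at column %d",
      mat[bad[1L]], rownames(mat)[i[1L]], i[2L]))
  }
  structure(mat, gene_id = gene_id, type = type, class = "ortho_aln")
}

#' @export
print.ortho_aln <- function(x, ...) {
  cat(sprintf("ortholog alignment '%s' (%s): %d taxa x %d columns\n",
              attr(x, "gene_id"), attr(x, "type"), nrow(x), ncol(x)))
  invisible(x)
}

#' Taxa of an alignment
#' @param aln an `ortho_aln`.
#' @return character vector of taxon names.
#' @export
aln_taxa <- function(aln) rownames(aln)

#' Sequences of an alignment as strings
#' @param aln an `ortho_aln`.
#' @return named character vector of sequence strings.
#' @export
aln_strings <- function(aln) {
  stats::setNames(apply(unclass(aln), 1L, paste, collapse = ""),
                  rownames(aln))
}

#' Read a multiple alignment
#'
#' @param path file path.
#' @param format `"fasta"` or `"phylip"` (sequential and interleaved PHYLIP
#'   are both accepted, with relaxed whitespace-delimited names).
#' @param gene_id gene identifier; defaults to the file stem.
#' @param type `"aa"` or `"nt"`, see [ortho_aln()].
#' @return an `ortho_aln`.
#' @export
read_alignment <- function(path, format = c("fasta", "phylip"),
                           gene_id = NULL, type = c("aa", "nt")) {
  format <- match.arg(format)
  type <- match.arg(type)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(gene_id)) gene_id <- tools::file_path_sans_ext(basename(path))
  seqs <- switch(format,
    fasta = {
      recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                                 forceDNAtolower = FALSE)
      stats::setNames(vapply(recs, `[[`, "", 1L), names(recs))
    },
    phylip = .read_phylip(path))
  ortho_aln(seqs, gene_id = gene_id, type = type)
}

# Relaxed PHYLIP: "ntaxa nsites" header; names are whitespace-delimited
# tokens; sequence blocks may be sequential or interleaved and may contain
# internal spaces. No installed package reads both amino-acid dialects with
# the validation we need, so this stays in-package.
.read_phylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]]))
  if (length(hdr) < 2L || anyNA(hdr[1:2]))
    stop("malformed PHYLIP header: ", lines[1L])
  ntax <- hdr[1L]; nsite <- hdr[2L]
  body <- lines[-1L]
  if (length(body) < ntax) stop("PHYLIP file has fewer records than header")
  nm <- character(ntax)
  sq <- character(ntax)
  for (i in seq_len(ntax)) {
    tok <- strsplit(trimws(body[i]), "\\s+")[[1L]]
    nm[i] <- tok[1L]
    sq[i] <- paste(tok[-1L], collapse = "")
  }
  extra <- body[-seq_len(ntax)]
  if (length(extra)) {   # interleaved continuation blocks
    i <- 0L
    for (ln in extra) {
      i <- i %% ntax + 1L
      sq[i] <- paste0(sq[i], gsub("\\s+", "", ln))
    }
  }
  if (any(nchar(sq) != nsite))
    stop(sprintf("taxon '%s' has %d sites, header says %d",
                 nm[which(nchar(sq) != nsite)[1L]],
                 nchar(sq)[which(nchar(sq) != nsite)[1L]], nsite))
  stats::setNames(sq, nm)
}

#' Write an alignment to FASTA or PHYLIP (sequential)
#'
#' @param aln an `ortho_aln`.
#' @param path output file.
#' @param format `"fasta"` or `"phylip"`.
#' @return invisible path.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  s <- aln_strings(aln)
  lines <- switch(format,
    fasta = as.vector(rbind(paste0(">", names(s)), unname(s))),
    phylip = c(sprintf("%d %d", length(s), ncol(aln)),
               sprintf("%s  %s", names(s), unname(s))))
  writeLines(lines, path)
  invisible(path)
}

#' Read a rooted Newick tree
#'
#' Wraps [ape::read.tree()]; missing branch lengths are set to 0 with a
#' warning, and duplicate leaf names are rejected.
#'
#' @param path file path (or a literal Newick string via `text`).
#' @param text optional Newick string, bypassing `path`.
#' @return an [ape::phylo] tree.
#' @export
read_tree <- function(path = NULL, text = NULL) {
  tr <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tr)) stop("failed to parse Newick input")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf name: ",
         tr$tip.label[duplicated(tr$tip.label)][1L])
  if (is.null(tr$edge.length)) {
    warning("tree has no branch lengths; setting all to 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  } else if (anyNA(tr$edge.length)) {
    warning("tree has missing branch lengths; setting them to 0")
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (any(tr$edge.length < 0)) stop("negative branch length in tree")
  tr
}

#' Write a tree to Newick
#' @param tree an [ape::phylo] tree.
#' @param path output file.
#' @return invisible path.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Construct the symmetric species design
#'
#' The experimental layout of the convergence scan: one outgroup taxon `O`
#' whose residue proxies the ancestral state, two foreground clusters (the
#' "placental" clades whose convergence is of interest), and two background
#' clusters (matched aplacental controls). All five groups must be disjoint
#' and clusters must have at least 2 taxa (4 in the full design).
#'
#' @param outgroup single taxon name.
#' @param fg1,fg2 character vectors: the two foreground clusters.
#' @param bg1,bg2 character vectors: the two background clusters.
#' @return object of class `species_design`.
#' @export
species_design <- function(outgroup, fg1, fg2, bg1, bg2) {
  groups <- list(outgroup = outgroup, fg1 = fg1, fg2 = fg2,
                 bg1 = bg1, bg2 = bg2)
  if (length(outgroup) != 1L) stop("exactly one outgroup taxon required")
  sizes <- lengths(groups[c("fg1", "fg2", "bg1", "bg2")])
  if (any(sizes < 2L)) stop("each cluster needs >= 2 taxa")
  all_tax <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_tax))
    stop("design groups are not disjoint: taxon '",
         all_tax[duplicated(all_tax)][1L], "' appears twice")
  structure(groups, class = "species_design")
}

#' @export
print.species_design <- function(x, ...) {
  cat("Symmetric species design\n")
  cat("  outgroup:", x$outgroup, "\n")
  for (g in c("fg1", "fg2", "bg1", "bg2"))
    cat(sprintf("  %s (%d): %s\n", g, length(x[[g]]),
                paste(x[[g]], collapse = ", ")))
  invisible(x)
}

#' All taxa of a design
#' @param design a `species_design`.
#' @return character vector.
#' @export
design_taxa <- function(design)
  unlist(design[c("outgroup", "fg1", "fg2", "bg1", "bg2")], use.names = FALSE)

#' Read a species design from a TSV file
#'
#' Expects two tab-separated columns `taxon` and `group`, with group values
#' in `outgroup`, `fg1`, `fg2`, `bg1`, `bg2`. Taxon names are matched
#' case-sensitively downstream.
#'
#' @param path file path.
#' @return a `species_design`.
#' @export
read_design <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("taxon", "group") %in% names(df)))
    stop("design file needs columns 'taxon' and 'group'")
  valid <- c("outgroup", "fg1", "fg2", "bg1", "bg2")
  if (!all(df$group %in% valid))
    stop("unknown group label(s): ",
         paste(setdiff(df$group, valid), collapse = ", "))
  if (!any(df$group == "outgroup")) stop("design has no outgroup row")
  g <- split(df$taxon, factor(df$group, levels = valid))
  species_design(g$outgroup, g$fg1, g$fg2, g$bg1, g$bg2)
}

#' Write a species design to TSV
#' @param design a `species_design`.
#' @param path output file.
#' @return invisible path.
#' @export
write_design <- function(design, path) {
  df <- data.frame(
    taxon = design_taxa(design),
    group = rep(c("outgroup", "fg1", "fg2", "bg1", "bg2"),
                c(1L, lengths(design[c("fg1", "fg2", "bg1", "bg2")]))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
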