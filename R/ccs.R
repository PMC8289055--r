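# Convergence at conservative sites (CCS).
#
# A column is *conservative* for one side of the symmetric design when all
# eight taxa of the opposite (control) side carry, determinately, the same
# residue as the outgroup O; the ancestors of both tested clusters are then
# assumed to be O. A *convergent* substitution is called when one identical
# derived residue d != O is shared by at least `min_shared_per_cluster` taxa
# in EACH of the two tested clusters (default 3-of-4 per cluster, i.e. at
# least six of the eight taxa overall).

# Vectorized classification of every column of a taxa x sites character
# matrix. Returns a data.frame with one row per column.
.classify_columns <- function(mat, design, min_shared_per_cluster = 3L,
                              rule = c("per-cluster", "total")) {
  rule <- match.arg(rule)
  need <- design_taxa(design)
  if (!all(need %in% rownames(mat)))
    stop("design taxa absent from alignment: ",
         paste(setdiff(need, rownames(mat)), collapse = ", "))
  n <- ncol(mat)
  O <- mat[design$outgroup, ]
  o_ok <- !(O %in% AA_MISSING)

  grp <- lapply(design[c("fg1", "fg2", "bg1", "bg2")],
                function(tx) mat[tx, , drop = FALSE])
  Om <- function(G) matrix(O, nrow(G), n, byrow = TRUE)
  all_eq_O <- function(G)
    colSums(G == Om(G) & !matrix(G %in% AA_MISSING, nrow(G), n)) == nrow(G)

  cons_for_fg <- o_ok & all_eq_O(grp$bg1) & all_eq_O(grp$bg2)
  cons_for_bg <- o_ok & all_eq_O(grp$fg1) & all_eq_O(grp$fg2)

  # support counts per candidate derived residue: n x 20 matrices
  counts <- function(G)
    matrix(vapply(AA_ALPHABET, function(d) colSums(G == d), numeric(n)),
           nrow = n)
  test_side <- function(Ga, Gb) {
    ca <- counts(Ga); cb <- counts(Gb)
    not_O <- outer(O, AA_ALPHABET, "!=")
    ok <- if (rule == "per-cluster")
      ca >= min_shared_per_cluster & cb >= min_shared_per_cluster
    else
      (ca + cb) >= 2L * min_shared_per_cluster
    ok <- ok & not_O
    ncand <- rowSums(ok)
    d <- rep(NA_character_, n)
    hit <- ncand == 1L
    if (any(hit)) d[hit] <- AA_ALPHABET[max.col(ok[hit, , drop = FALSE],
                                                "first")]
    list(derived = d, ambiguous = ncand > 1L)
  }
  fg <- test_side(grp$fg1, grp$fg2)
  bg <- test_side(grp$bg1, grp$bg2)

  direction <- rep("none", n)
  direction[cons_for_fg & !cons_for_bg] <- "foreground"
  direction[cons_for_bg & !cons_for_fg] <- "background"
  derived <- rep(NA_character_, n)
  ambiguous <- logical(n)
  i <- direction == "foreground"
  derived[i] <- fg$derived[i]; ambiguous[i] <- fg$ambiguous[i]
  i <- direction == "background"
  derived[i] <- bg$derived[i]; ambiguous[i] <- bg$ambiguous[i]

  data.frame(
    column = seq_len(n),
    direction = direction,
    ancestral = ifelse(o_ok, O, NA_character_),
    derived = derived,
    is_convergent = !is.na(derived),
    ambiguous = ambiguous,
    stringsAsFactors = FALSE)
}

#' Classify a single alignment column under the CCS criterion
#'
#' @param column named character vector (taxon -> residue) covering at least
#'   all design taxa.
#' @param design a [species_design()].
#' @param min_shared_per_cluster minimum number of taxa per tested cluster
#'   that must share the identical derived residue (default 3).
#' @param rule `"per-cluster"` (the displayed condition
#'   `P_1i = P_1j = P_1k = P_2i = P_2j = P_2k != O`, at least
#'   `min_shared_per_cluster` in each cluster) or `"total"` (any split
#'   summing to `2 * min_shared_per_cluster`).
#' @return a `site_call`: list with `direction`
#'   (`"foreground"`/`"background"`/`"none"`: the side being tested for
#'   convergence, i.e. the side whose controls all match the outgroup;
#'   `"none"` when neither or both sides are conservative),
#'   `ancestral_state` (the outgroup residue), `derived_state`,
#'   `supporting_taxa`, `is_convergent`, `ambiguous` and `label`
#'   (e.g. `"D12E"`, 1-based position). Columns where two distinct derived
#'   residues both reach the threshold are rejected as ambiguous.
#' @examples
#' d <- species_design("O", c("p1","p2"), c("p3","p4"),
#'                     c("a1","a2"), c("a3","a4"))
#' col <- c(O="D", a1="D", a2="D", a3="D", a4="D",
#'          p1="E", p2="E", p3="E", p4="E")
#' classify_site(col, d, min_shared_per_cluster = 2)
#' @export
classify_site <- function(column, design, min_shared_per_cluster = 3L,
                          rule = c("per-cluster", "total")) {
  if (is.null(names(column))) stop("column must be a named residue vector")
  if (!(design$outgroup %in% names(column)))
    stop("outgroup taxon '", design$outgroup, "' absent from column")
  mat <- matrix(toupper(column), ncol = 1L,
                dimnames = list(names(column), NULL))
  df <- .classify_columns(mat, design, min_shared_per_cluster,
                          match.arg(rule))
  supp <- character(0)
  if (df$is_convergent) {
    side <- if (df$direction == "foreground") c(design$fg1, design$fg2)
            else c(design$bg1, design$bg2)
    supp <- side[mat[side, 1L] == df$derived]
  }
  structure(list(
    direction = df$direction,
    ancestral_state = df$ancestral,
    derived_state = df$derived,
    supporting_taxa = supp,
    is_convergent = df$is_convergent,
    ambiguous = df$ambiguous,
    label = if (df$is_convergent)
      paste0(df$ancestral, df$column, df$derived) else NA_character_
  ), class = "site_call")
}

#' Scan one gene alignment for convergent substitutions
#'
#' Applies the CCS classification to every column and returns the convergent
#' calls. Columns whose outgroup residue is a gap or `X` are skipped (the
#' assumed ancestral state is undefined there); ambiguous columns (two
#' derived residues reaching the threshold, impossible with 4-taxon clusters
#' at the default threshold) are dropped with a message.
#'
#' @param aln an `ortho_aln` containing all design taxa.
#' @param design a [species_design()].
#' @inheritParams classify_site
#' @param drop_gapped_columns if `TRUE`, columns containing any gap/unknown
#'   in any design taxon are skipped before classification (off by default;
#'   missing data already cannot support conservativeness or a derived
#'   residue).
#' @return data.frame with columns `gene_id`, `column` (1-based), `direction`,
#'   `ancestral`, `derived`, `n_support_1`, `n_support_2`,
#'   `supporting_taxa` (comma-joined), `label` — one row per convergent call,
#'   ordered by column.
#' @export
scan_gene <- function(aln, design, min_shared_per_cluster = 3L,
                      rule = c("per-cluster", "total"),
                      drop_gapped_columns = FALSE) {
  rule <- match.arg(rule)
  mat <- unclass(aln)
  keep <- rep(TRUE, ncol(mat))
  if (drop_gapped_columns) {
    sub <- mat[design_taxa(design), , drop = FALSE]
    keep <- colSums(matrix(sub %in% AA_MISSING, nrow(sub))) == 0L
  }
  df <- .classify_columns(mat[, keep, drop = FALSE], design,
                          min_shared_per_cluster, rule)
  df$column <- which(keep)[df$column]
  if (any(df$ambiguous))
    message(sum(df$ambiguous), " ambiguous column(s) rejected in gene ",
            attr(aln, "gene_id"))
  calls <- df[df$is_convergent, , drop = FALSE]
  if (nrow(calls) == 0L) return(.empty_calls())
  sup <- lapply(seq_len(nrow(calls)), function(r) {
    side <- if (calls$direction[r] == "foreground")
      list(design$fg1, design$fg2) else list(design$bg1, design$bg2)
    lapply(side, function(tx) tx[mat[tx, calls$column[r]] == calls$derived[r]])
  })
  data.frame(
    gene_id = attr(aln, "gene_id"),
    column = calls$column,
    direction = calls$direction,
    ancestral = calls$ancestral,
    derived = calls$derived,
    n_support_1 = vapply(sup, function(s) length(s[[1L]]), 0L),
    n_support_2 = vapply(sup, function(s) length(s[[2L]]), 0L),
    supporting_taxa = vapply(sup, function(s)
      paste(unlist(s), collapse = ","), ""),
    label = paste0(calls$ancestral, calls$column, calls$derived),
    stringsAsFactors = FALSE)
}

.empty_calls <- function() {
  data.frame(gene_id = character(0), column = integer(0),
             direction = character(0), ancestral = character(0),
             derived = character(0), n_support_1 = integer(0),
             n_support_2 = integer(0), supporting_taxa = character(0),
             label = character(0), stringsAsFactors = FALSE)
}

#' Aggregate per-gene CCS calls into a convergence report
#'
#' @param gene_calls a named list of per-gene call data.frames (from
#'   [scan_gene()]), or a single combined data.frame with a `gene_id`
#'   column.
#' @return object of class `convergence_report`: list with `calls` (combined
#'   data.frame, ordered by gene then column), `foreground_count`,
#'   `background_count`, `genes_with_foreground`, `multi_site_genes`
#'   (genes with >= 2 foreground convergent sites), `chi2_stat`, `p_value`
#'   (NA when no calls at all).
#' @export
aggregate_calls <- function(gene_calls) {
  calls <- if (is.data.frame(gene_calls)) gene_calls
           else do.call(rbind, unname(gene_calls))
  if (is.null(calls) || nrow(calls) == 0L) calls <- .empty_calls()
  calls <- calls[order(calls$gene_id, calls$column), , drop = FALSE]
  rownames(calls) <- NULL
  fg <- calls[calls$direction == "foreground", , drop = FALSE]
  f <- nrow(fg)
  b <- sum(calls$direction == "background")
  per_gene_fg <- table(fg$gene_id)
  chi2 <- if (f + b > 0L) symmetric_chi2(f, b)
          else list(statistic = NA_real_, p_value = NA_real_)
  structure(list(
    calls = calls,
    foreground_count = f,
    background_count = b,
    genes_with_foreground = length(per_gene_fg),
    multi_site_genes = sum(per_gene_fg >= 2L),
    chi2_stat = chi2$statistic,
    p_value = chi2$p_value
  ), class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("CCS convergence report\n")
  cat(sprintf("  foreground convergent substitutions: %d\n",
              x$foreground_count))
  cat(sprintf("  background convergent substitutions: %d\n",
              x$background_count))
  cat(sprintf("  genes with foreground calls: %d (%d with >= 2 sites)\n",
              x$genes_with_foreground, x$multi_site_genes))
  if (is.na(x$chi2_stat)) {
    cat("  chi-square: NA (no calls)\n")
  } else {
    cat(sprintf("  chi-square (1 df, equal-expectation): %.4f, P = %.4g\n",
                x$chi2_stat, x$p_value))
  }
  invisible(x)
}

#' Two-cell chi-square comparison of foreground vs background counts
#'
#' The symmetric design implies equal expected convergence in both groups,
#' so the foreground and background totals are compared by a Pearson
#' goodness-of-fit test against expectation (n/2, n/2):
#' \eqn{\chi^2 = (f-b)^2/(f+b)} on 1 degree of freedom.
#'
#' @param foreground_count,background_count non-negative integer counts.
#' @return list with `statistic` and `p_value` (both `NA`, with a warning,
#'   when both counts are zero).
#' @examples
#' symmetric_chi2(125, 36)   # the headline comparison
#' @export
symmetric_chi2 <- function(foreground_count, background_count) {
  f <- foreground_count; b <- background_count
  if (f < 0 || b < 0) stop("counts must be non-negative")
  if (f + b == 0) {
    warning("both counts are zero; chi-square undefined")
    return(list(statistic = NA_real_, p_value = NA_real_))
  }
  stat <- (f - b)^2 / (f + b)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}
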