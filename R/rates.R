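# Molecular-rate utilities: Tajima's relative rate test, extraction of
# fourfold-degenerate third codon positions, and the Kimura two-parameter
# neutral distance.

.as_chars <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) strsplit(toupper(x), "")[[1L]]
  else toupper(as.character(x))
}

#' Tajima's relative rate test
#'
#' Three-sequence test of rate equality between two ingroups against an
#' outgroup. Sites with any missing symbol are excluded; `m1` counts sites
#' where only ingroup 1 differs (ingroup 2 agreeing with the outgroup), `m2`
#' the converse. Under rate equality `m1` and `m2` have equal expectation,
#' tested by \eqn{\chi^2 = (m_1-m_2)^2/(m_1+m_2)} on 1 df (the usual
#' approximation), or by an exact two-sided binomial test with
#' `exact = TRUE`.
#'
#' @param ingroup1,ingroup2,outgroup equal-length sequences (strings or
#'   character vectors; amino acid or nucleotide).
#' @param exact use [stats::binom.test()] instead of the chi-square
#'   approximation for the p-value.
#' @param missing symbols treated as missing data.
#' @return object of class `rrt_result`: list with `m1`, `m2`,
#'   `n_sites_used`, `chi2`, `p_value`. `m1 + m2 == 0` gives `chi2 = 0`,
#'   `p_value = 1`.
#' @examples
#' tajima_rrt("AAAAAARRRK", "AAAAAAAAAK", "AAAAAAAAAA")
#' @export
tajima_rrt <- function(ingroup1, ingroup2, outgroup, exact = FALSE,
                       missing = c("-", "X", "?", "N", "*")) {
  s1 <- .as_chars(ingroup1); s2 <- .as_chars(ingroup2)
  so <- .as_chars(outgroup)
  if (length(s1) != length(s2) || length(s1) != length(so))
    stop(sprintf("sequence lengths differ: %d, %d, %d",
                 length(s1), length(s2), length(so)))
  use <- !(s1 %in% missing | s2 %in% missing | so %in% missing)
  s1 <- s1[use]; s2 <- s2[use]; so <- so[use]
  m1 <- sum(s1 != s2 & s1 != so & s2 == so)
  m2 <- sum(s2 != s1 & s2 != so & s1 == so)
  if (m1 + m2 == 0L) {
    chi2 <- 0; p <- 1
  } else {
    chi2 <- (m1 - m2)^2 / (m1 + m2)
    p <- if (exact) stats::binom.test(m1, m1 + m2, 0.5)$p.value
         else stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  structure(list(m1 = m1, m2 = m2, n_sites_used = sum(use),
                 chi2 = chi2, p_value = p),
            class = "rrt_result")
}

#' @export
print.rrt_result <- function(x, ...) {
  cat("Tajima relative rate test\n")
  cat(sprintf("  unique differences: m1 = %d, m2 = %d (over %d sites)\n",
              x$m1, x$m2, x$n_sites_used))
  cat(sprintf("  chi-square = %.4f, P = %.4g\n", x$chi2, x$p_value))
  invisible(x)
}

# Dinucleotide prefixes whose four codons encode one amino acid, derived
# from the standard genetic code.
.fourfold_prefixes <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    nts <- c("T", "C", "A", "G")
    pre <- as.vector(outer(nts, nts, paste0))
    four <- vapply(pre, function(p) {
      aa <- vapply(nts, function(n3)
        seqinr::translate(strsplit(paste0(p, n3), "")[[1L]]), "")
      length(unique(aa)) == 1L && !any(aa == "*")
    }, TRUE)
    cache <<- pre[four]
    cache
  }
})

#' Extract fourfold-degenerate sites from a codon alignment
#'
#' Retains a codon column when, across all taxa (strict mode): every codon
#' is gap- and ambiguity-free, all codons share the same first two
#' nucleotides, and that dinucleotide prefix heads a fourfold-degenerate
#' family of the standard genetic code (TC, CT, CC, CG, AC, GT, GC, GG).
#' The output is the concatenation of the third positions of the retained
#' codons — positions evolving free of amino-acid constraint in every
#' lineage. `mode = "reference"` relaxes the identical-prefix requirement
#' to the reference taxon's codon being fourfold-degenerate (all codons
#' must still be determinate).
#'
#' @param codon_aln nucleotide `ortho_aln` with length divisible by 3, in
#'   frame.
#' @param mode `"strict"` (default) or `"reference"`.
#' @param ref_taxon reference taxon for `mode = "reference"` (default:
#'   first taxon).
#' @return nucleotide `ortho_aln` of the third positions, with attribute
#'   `codon_positions` (1-based indices of the retained codon columns in
#'   the source alignment).
#' @export
extract_4d <- function(codon_aln, mode = c("strict", "reference"),
                       ref_taxon = NULL) {
  mode <- match.arg(mode)
  mat <- unclass(codon_aln)
  if (ncol(mat) %% 3L != 0L)
    stop("alignment length ", ncol(mat), " is not divisible by 3")
  L <- ncol(mat) %/% 3L
  p1 <- mat[, seq(1L, by = 3L, length.out = L), drop = FALSE]
  p2 <- mat[, seq(2L, by = 3L, length.out = L), drop = FALSE]
  p3 <- mat[, seq(3L, by = 3L, length.out = L), drop = FALSE]

  strict_nt <- c("A", "C", "G", "T")
  bad <- matrix(!(p1 %in% strict_nt) | !(p2 %in% strict_nt) |
                !(p3 %in% strict_nt), nrow = nrow(mat))
  determinate <- colSums(bad) == 0L
  ff <- .fourfold_prefixes()
  if (mode == "strict") {
    same1 <- apply(p1, 2L, function(x) length(unique(x)) == 1L)
    same2 <- apply(p2, 2L, function(x) length(unique(x)) == 1L)
    prefix <- paste0(p1[1L, ], p2[1L, ])
    keep <- determinate & same1 & same2 & prefix %in% ff
  } else {
    if (is.null(ref_taxon)) ref_taxon <- rownames(mat)[1L]
    prefix <- paste0(p1[ref_taxon, ], p2[ref_taxon, ])
    keep <- determinate & prefix %in% ff
  }
  out <- ortho_aln(p3[, keep, drop = FALSE],
                   gene_id = paste0(attr(codon_aln, "gene_id"), "_4d"),
                   type = "nt")
  attr(out, "codon_positions") <- which(keep)
  out
}

#' Kimura two-parameter distance between two nucleotide sequences
#'
#' \eqn{d = -\tfrac12 \ln\!\big((1-2P-Q)\sqrt{1-2Q}\big)} with `P` the
#' proportion of transition differences and `Q` of transversion
#' differences, computed after pairwise exclusion of sites where either
#' sequence has a gap or ambiguity. Saturated pairs (non-positive log
#' argument) return `Inf` with a warning.
#'
#' @param seq1,seq2 equal-length nucleotide sequences (strings or character
#'   vectors).
#' @return distance in substitutions per site.
#' @examples
#' k2p_distance("ACGTACGTAC", "ACGTACGTAC")   # 0
#' @export
k2p_distance <- function(seq1, seq2) {
  a <- .as_chars(seq1); b <- .as_chars(seq2)
  if (length(a) != length(b))
    stop(sprintf("sequence lengths differ: %d vs %d",
                 length(a), length(b)))
  nt <- c("A", "C", "G", "T")
  use <- a %in% nt & b %in% nt
  a <- a[use]; b <- b[use]
  n <- length(a)
  if (n == 0L) stop("no comparable sites")
  diff <- a != b
  purine <- function(x) x %in% c("A", "G")
  ts <- diff & (purine(a) == purine(b))       # A<->G, C<->T
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  arg <- (1 - 2 * P - Q) * sqrt(1 - 2 * Q)
  if (is.nan(arg) || arg <= 0) {
    warning("sequences saturated; K2P distance infinite")
    return(Inf)
  }
  -0.5 * log(arg)
}
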