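test_that("the relative rate test counts lineage-unique differences", {
  r0 <- tajima_rrt("AAAA", "AAAA", "AAAA")
  expect_equal(r0$m1, 0L)
  expect_equal(r0$m2, 0L)
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p_value, 1)

  # m1 = 3 (only ingroup 1 differs), m2 = 1, over 10 sites
  out <- "AAAAAAAAAA"
  in1 <- "RRRAAAAAAA"
  in2 <- "AAARAAAAAA"
  r <- tajima_rrt(in1, in2, out)
  expect_equal(r$m1, 3L)
  expect_equal(r$m2, 1L)
  expect_equal(r$n_sites_used, 10L)
  expect_equal(r$chi2, 1.0)
  expect_equal(r$p_value, pchisq(1, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(r$p_value, 0.3173105, tolerance = 1e-6)

  # swapping the ingroups swaps m1/m2, chi2 and p unchanged
  rs <- tajima_rrt(in2, in1, out)
  expect_equal(rs$m1, r$m2)
  expect_equal(rs$m2, r$m1)
  expect_equal(rs$chi2, r$chi2)
  expect_equal(rs$p_value, r$p_value)

  # sites where all three differ count for neither lineage
  r3 <- tajima_rrt("R", "K", "A")
  expect_equal(c(r3$m1, r3$m2), c(0L, 0L))

  # missing data excluded before counting
  rm <- tajima_rrt("RAXA", "AAA-", "AAAA")
  expect_equal(rm$n_sites_used, 2L)   # the X and - columns are dropped
  expect_equal(rm$m1, 1L)
  expect_equal(rm$m2, 0L)

  expect_error(tajima_rrt("AAA", "AA", "AAA"), "lengths differ")

  # exact mode agrees with a direct binomial computation
  re <- tajima_rrt(in1, in2, out, exact = TRUE)
  expect_equal(re$p_value, binom.test(3, 4, 0.5)$p.value)
})

test_that("fourfold extraction keeps exactly the code-sanctioned columns", {
  # glycine family: retained, third positions concatenated
  aln <- ortho_aln(c(t1 = "GGT", t2 = "GGC", t3 = "GGA"), type = "nt")
  out <- extract_4d(aln)
  expect_equal(ncol(out), 1L)
  expect_equal(unname(aln_strings(out)), c("T", "C", "A"))
  expect_equal(attr(out, "codon_positions"), 1L)

  # differing prefix: rejected
  aln2 <- ortho_aln(c(t1 = "GGT", t2 = "GAT"), type = "nt")
  expect_equal(ncol(extract_4d(aln2)), 0L)

  expect_error(extract_4d(ortho_aln(c(a = "GGTA", b = "GGTA"), type = "nt")),
               "divisible by 3")
})

test_that("a toy codon alignment agrees with a genetic-code oracle", {
  skip_if_not_installed("Biostrings")
  # 10 codon columns mixing 4-fold, 2-fold, stop-adjacent and gapped cases
  codons <- list(
    t1 = c("GGT", "ATG", "CTA", "TTA", "ACG", "AAA", "TCT", "GG-", "TGG", "GTA"),
    t2 = c("GGC", "ATG", "CTG", "TTG", "ACC", "AAG", "TCA", "GGA", "TGG", "GTC"),
    t3 = c("GGA", "ATG", "CTC", "TTA", "ACT", "AAA", "TCG", "GGC", "TGG", "GTG"))
  aln <- ortho_aln(vapply(codons, paste, "", collapse = ""), type = "nt")
  out <- extract_4d(aln)

  # oracle: per column, check determinacy, shared prefix, and that the
  # prefix's four codons translate identically under the standard code
  GC <- Biostrings::GENETIC_CODE
  keep <- vapply(1:10, function(j) {
    cs <- vapply(codons, `[`, "", j)
    if (any(!strsplit(paste(cs, collapse = ""), "")[[1]] %in%
            c("A", "C", "G", "T"))) return(FALSE)
    pre <- substr(cs, 1, 2)
    if (length(unique(pre)) != 1L) return(FALSE)
    fam <- GC[paste0(pre[1], c("A", "C", "G", "T"))]
    length(unique(fam)) == 1L && !any(fam == "*")
  }, TRUE)
  expect_equal(attr(out, "codon_positions"), which(keep))
  expect_equal(ncol(out), sum(keep))

  # taxon order invariance
  out2 <- extract_4d(ortho_aln(unclass(aln)[c(3, 1, 2), ], type = "nt"))
  expect_equal(attr(out2, "codon_positions"), attr(out, "codon_positions"))

  # relaxed per-reference mode keeps at least the strict columns
  outr <- extract_4d(aln, mode = "reference", ref_taxon = "t1")
  expect_true(all(attr(out, "codon_positions") %in%
                  attr(outr, "codon_positions")))
})

test_that("K2P distances follow the closed form and its bounds", {
  expect_equal(k2p_distance("ACGTACGTAC", "ACGTACGTAC"), 0)

  # 10 transitions, 0 transversions over 100 sites: d = -log(0.8)/2
  s1 <- strrep("A", 100)
  s2 <- paste0(strrep("G", 10), strrep("A", 90))
  expect_equal(k2p_distance(s1, s2), -0.5 * log(0.8), tolerance = 1e-12)
  expect_equal(k2p_distance(s2, s1), k2p_distance(s1, s2))

  # matches the reference implementation on random pairs, and dominates
  # the raw p-distance (Jensen)
  skip_if_not_installed("ape")
  set.seed(10)
  for (i in 1:10) {
    n <- 300
    a <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    b <- a
    mut <- runif(n) < 0.15
    b[mut] <- sample(c("A", "C", "G", "T"), sum(mut), replace = TRUE)
    d_pkg <- k2p_distance(paste(a, collapse = ""), paste(b, collapse = ""))
    bin <- ape::as.DNAbin(rbind(x = tolower(a), y = tolower(b)))
    d_ape <- as.numeric(ape::dist.dna(bin, model = "K80"))
    expect_equal(d_pkg, d_ape, tolerance = 1e-10)
    expect_gte(d_pkg, mean(a != b) - 1e-12)
  }

  # pairwise deletion of missing sites
  expect_equal(k2p_distance("ACGTN-", "ACGAAC"),
               k2p_distance("ACGT", "ACGA"))

  # saturation
  expect_warning(d <- k2p_distance(strrep("A", 10), strrep("G", 10)),
                 "saturated")
  expect_identical(d, Inf)
  expect_error(k2p_distance("ACG", "AC"), "lengths differ")
})
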