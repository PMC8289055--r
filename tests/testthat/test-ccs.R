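paper_design <- function()
  species_design("shark", paste0("mam", 1:4), paste0("syn", 1:4),
                 paste0("tet", 1:4), paste0("tel", 1:4))

column17 <- function(O, fg, bg) {
  d <- paper_design()
  stats::setNames(c(O, fg, bg),
                  c("shark", d$fg1, d$fg2, d$bg1, d$bg2))
}

test_that("the canonical convergent patterns are called correctly", {
  d <- paper_design()

  # all eight foreground taxa derived: the D->E two-cluster pattern
  call <- classify_site(column17("D", rep("E", 8), rep("D", 8)), d)
  expect_true(call$is_convergent)
  expect_equal(call$direction, "foreground")
  expect_equal(call$ancestral_state, "D")
  expect_equal(call$derived_state, "E")
  expect_length(call$supporting_taxa, 8L)

  # 3+3 support with one leftover per cluster: the I->V style pattern
  call2 <- classify_site(
    column17("I", c("V", "V", "V", "I", "V", "V", "V", "L"), rep("I", 8)), d)
  expect_true(call2$is_convergent)
  expect_equal(call2$derived_state, "V")
  expect_length(call2$supporting_taxa, 6L)

  # invariant both ways: conservative but non-convergent
  call3 <- classify_site(column17("K", rep("K", 8), rep("K", 8)), d)
  expect_false(call3$is_convergent)
  expect_equal(call3$direction, "none")

  # background-direction call is symmetric
  call4 <- classify_site(column17("D", rep("D", 8), rep("E", 8)), d)
  expect_true(call4$is_convergent)
  expect_equal(call4$direction, "background")
})

test_that("missing data breaks conservativeness and cannot support calls", {
  d <- paper_design()
  # gap in a control taxon destroys the conservative premise
  col <- column17("D", rep("E", 8), c("-", rep("D", 7)))
  expect_false(classify_site(col, d)$is_convergent)
  # gap among the tested taxa cannot count toward the threshold
  col2 <- column17("D", c("E", "E", "-", "I", rep("E", 4)), rep("D", 8))
  expect_false(classify_site(col2, d)$is_convergent)
  # but the non-supporting taxon may be missing
  col3 <- column17("D", c("E", "E", "E", "-", rep("E", 4)), rep("D", 8))
  expect_true(classify_site(col3, d)$is_convergent)
  # gapped outgroup: undefined ancestral state, site skipped
  col4 <- column17("-", rep("E", 8), rep("D", 8))
  expect_equal(classify_site(col4, d)$direction, "none")
  expect_error(classify_site(c(a = "A"), d), "outgroup")
})

test_that("classification matches the brute-force rule on random columns", {
  d <- small_design()
  set.seed(42)
  for (i in 1:400) {
    col <- stats::setNames(sample(c("A", "R", "N", "-"), 9, replace = TRUE),
                           small_design_taxa())
    bf <- brute_force_ccs(col, d, min_shared = 2)
    got <- classify_site(col, d, min_shared_per_cluster = 2)
    expected_conv <- !is.na(bf$derived)
    expect_identical(got$is_convergent, expected_conv)
    if (expected_conv) {
      expect_identical(got$direction, bf$direction)
      expect_identical(got$derived_state, bf$derived)
    }
  }
})

test_that("ambiguous columns (two qualifying residues) are rejected", {
  d <- small_design()
  # with 2-taxon clusters and threshold 1, two residues can both qualify
  col <- stats::setNames(c("R", "N", "R", "N", "A", "A", "A", "A", "A"),
                         small_design_taxa())
  got <- classify_site(col, d, min_shared_per_cluster = 1)
  expect_false(got$is_convergent)
  expect_true(got$ambiguous)
})

test_that("the total-split rule differs from per-cluster only as documented", {
  d <- paper_design()
  # 4+2 split: fails per-cluster (needs 3+3), passes >=6-total
  col <- column17("D", c("E", "E", "E", "E", "E", "E", "D", "D"), rep("D", 8))
  expect_false(classify_site(col, d, rule = "per-cluster")$is_convergent)
  expect_true(classify_site(col, d, rule = "total")$is_convergent)
})

test_that("scan_gene reports 1-based convergent columns only", {
  st <- generate_study(3, 100, alpha = 0.8, planted_fg = 4, planted_bg = 1,
                       seed = 11)
  calls <- do.call(rbind, lapply(st$genes, scan_gene, design = st$design))
  found <- merge(st$truth, calls,
                 by = c("gene_id", "column"))
  expect_equal(nrow(found), nrow(st$truth))
  expect_identical(found$direction.x, found$direction.y)
  expect_identical(found$derived.x, found$derived.y)

  # an alignment of identical columns yields no calls
  flat <- ortho_aln(stats::setNames(rep(strrep("K", 50), 17),
                                    design_taxa(st$design)))
  expect_equal(nrow(scan_gene(flat, st$design)), 0L)

  # labels follow the ancestral<column>derived convention
  expect_true(all(grepl("^[A-Y][0-9]+[A-Y]$", calls$label)))
  expect_identical(calls$label,
                   paste0(calls$ancestral, calls$column, calls$derived))
})

test_that("swapping foreground and background labels swaps the counts", {
  st <- generate_study(4, 300, alpha = 0.8, planted_fg = 6, planted_bg = 2,
                       seed = 23)
  swapped <- species_design(st$design$outgroup,
                            fg1 = st$design$bg1, fg2 = st$design$bg2,
                            bg1 = st$design$fg1, bg2 = st$design$fg2)
  r1 <- aggregate_calls(lapply(st$genes, scan_gene, design = st$design))
  r2 <- aggregate_calls(lapply(st$genes, scan_gene, design = swapped))
  expect_equal(r1$foreground_count, r2$background_count)
  expect_equal(r1$background_count, r2$foreground_count)
})

test_that("raising the support threshold never adds calls", {
  st <- generate_study(3, 400, alpha = 0.8, planted_fg = 5, planted_bg = 5,
                       seed = 31, support_mode = "minimal")
  n_calls <- vapply(2:4, function(thr)
    nrow(do.call(rbind, lapply(st$genes, scan_gene, design = st$design,
                               min_shared_per_cluster = thr))), 0L)
  expect_true(all(diff(n_calls) <= 0))
})

test_that("aggregation arithmetic and the two-cell chi-square are exact", {
  mk <- function(g, cols, dirs) data.frame(
    gene_id = rep(g, length(cols)), column = cols, direction = dirs,
    ancestral = rep("A", length(cols)), derived = rep("R", length(cols)),
    n_support_1 = rep(3L, length(cols)), n_support_2 = rep(3L, length(cols)),
    supporting_taxa = rep("", length(cols)),
    label = paste0("A", cols, "R", recycle0 = TRUE),
    stringsAsFactors = FALSE)
  rep <- aggregate_calls(list(
    mk("g1", c(5L, 9L), c("foreground", "foreground")),
    mk("g2", c(2L, 7L), c("foreground", "background")),
    mk("g3", 1L, "foreground")[0L, ]))
  expect_equal(rep$foreground_count, 3L)
  expect_equal(rep$background_count, 1L)
  expect_equal(rep$genes_with_foreground, 2L)
  expect_equal(rep$multi_site_genes, 1L)
  expect_equal(rep$chi2_stat, 1.0)
  expect_equal(rep$p_value, pchisq(1, 1, lower.tail = FALSE),
               tolerance = 1e-12)

  empty <- aggregate_calls(list())
  expect_equal(empty$foreground_count, 0L)
  expect_true(is.na(empty$p_value))

  expect_equal(symmetric_chi2(10, 10)$statistic, 0)
  expect_equal(symmetric_chi2(10, 10)$p_value, 1)
  expect_equal(symmetric_chi2(3, 1)$statistic, 1.0)
  expect_equal(symmetric_chi2(3, 1)$p_value, 0.3173105, tolerance = 1e-6)
  expect_warning(res <- symmetric_chi2(0, 0), "zero")
  expect_true(is.na(res$statistic))

  # totals always equal the sum over genes on random synthetic reports
  set.seed(7)
  for (i in 1:20) {
    ng <- sample(1:6, 1)
    lst <- lapply(seq_len(ng), function(g) {
      n <- sample(0:4, 1)
      mk(paste0("g", g), seq_len(n),
         sample(c("foreground", "background"), n, replace = TRUE))
    })
    rp <- aggregate_calls(lst)
    expect_equal(rp$foreground_count + rp$background_count,
                 sum(vapply(lst, nrow, 0L)))
  }
})
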