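test_that("two-taxon likelihood matches the closed form", {
  m <- build_model(alpha = 1, k = 1)
  tr <- read_tree(text = "(ta:0.3,tb:0);")
  for (pair in list(c("M", "R"), c("A", "A"), c("W", "C"))) {
    aln <- ortho_aln(c(ta = pair[1], tb = pair[2]))
    P <- transition_matrix(m, 0.3)
    expect_equal(log_likelihood(aln, tr, m),
                 log(m$pi[[pair[1]]] * P[pair[1], pair[2]]),
                 tolerance = 1e-10)
  }
})

test_that("likelihood is invariant to taxon order and weights patterns", {
  tp <- default_topology()
  m <- build_model(alpha = 0.8, k = 4)
  sim <- simulate_gene(tp$tree, m, 120, seed = 2)
  aln <- sim_leaf_alignment(sim)
  ll <- log_likelihood(aln, tp$tree, m)

  perm <- unclass(aln)[sample(nrow(aln)), , drop = FALSE]
  expect_equal(log_likelihood(ortho_aln(perm), tp$tree, m), ll,
               tolerance = 1e-10)

  dbl <- cbind(unclass(aln), unclass(aln))
  expect_equal(log_likelihood(ortho_aln(dbl), tp$tree, m), 2 * ll,
               tolerance = 1e-8)

  # an all-missing column contributes exactly zero log-likelihood
  gap <- cbind(unclass(aln),
               matrix("-", nrow(aln), 1, dimnames = list(aln_taxa(aln))))
  expect_equal(log_likelihood(ortho_aln(gap), tp$tree, m), ll,
               tolerance = 1e-8)
})

test_that("likelihood agrees with an independent pruning implementation", {
  skip_if_not_installed("phangorn")
  tp <- default_topology()
  for (alpha in c(0.5, 1.5)) {
    m <- build_model(alpha = alpha, k = 4)
    sim <- simulate_gene(tp$tree, m, 200, seed = round(10 * alpha))
    aln <- sim_leaf_alignment(sim)
    pd <- phangorn::phyDat(unclass(aln), type = "AA")
    oracle <- phangorn::pml(tp$tree, pd, bf = as.numeric(m$pi),
                            model = "JTT", k = 4, shape = alpha)$logLik
    expect_equal(log_likelihood(aln, tp$tree, m), oracle, tolerance = 1e-6)
  }
})

test_that("likelihood is invariant under re-rooting (reversible model)", {
  tp <- default_topology()
  m <- build_model(alpha = 0.8, k = 2)
  sim <- simulate_gene(tp$tree, m, 100, seed = 9)
  aln <- sim_leaf_alignment(sim)
  ll <- log_likelihood(aln, tp$tree, m)
  rerooted <- ape::root(ape::unroot(tp$tree), outgroup = "mammal_1",
                        resolve.root = TRUE)
  expect_equal(log_likelihood(aln, rerooted, m), ll, tolerance = 1e-8)
})

test_that("missing data cannot see through gaps", {
  # a fully gapped taxon must not change the likelihood of the others
  m <- build_model(alpha = 1, k = 1)
  tr3 <- read_tree(text = "((a:0.2,b:0.1):0.05,c:0.4);")
  aln3 <- ortho_aln(c(a = "MKV", b = "MRV", c = "---"))
  tr2 <- read_tree(text = "(a:0.2,b:0.1);")
  aln2 <- ortho_aln(c(a = "MKV", b = "MRV"))
  expect_equal(log_likelihood(aln3, tr3, m), log_likelihood(aln2, tr2, m),
               tolerance = 1e-8)
})

test_that("fitting is a monotone ascent with a no-op contract", {
  t5 <- five_taxon_tree()
  m <- build_model(alpha = 0.8, k = 4)
  sim <- simulate_gene(t5, m, 800, seed = 4)
  aln <- sim_leaf_alignment(sim)

  # no-op: nothing optimized returns the inputs and their likelihood
  fit0 <- fit_parameters(aln, t5, optimize = character(0), alpha = 0.8)
  expect_equal(fit0$tree$edge.length, t5$edge.length)
  expect_equal(fit0$alpha, 0.8)
  m_emp <- build_model(empirical_frequencies(aln), alpha = 0.8, k = 4)
  expect_equal(fit0$log_likelihood, log_likelihood(aln, t5, m_emp),
               tolerance = 1e-8)

  # ascent: fitted likelihood >= starting likelihood
  start <- t5
  start$edge.length <- rep(0.3, nrow(t5$edge))
  m_start <- build_model(empirical_frequencies(aln), alpha = 2, k = 4)
  ll_start <- log_likelihood(aln, start, m_start)
  fit <- fit_parameters(aln, start, alpha = 2)
  expect_gte(fit$log_likelihood, ll_start)
  # and the reported likelihood is reproducible from the fitted parameters
  m_fit <- build_model(empirical_frequencies(aln), alpha = fit$alpha, k = 4)
  expect_equal(log_likelihood(aln, fit$tree, m_fit), fit$log_likelihood,
               tolerance = 1e-6)
})

test_that("empirical frequencies count residues and exclude missing", {
  aln <- ortho_aln(c(a = "AAR-", b = "AARX"))
  f <- empirical_frequencies(aln)
  expect_equal(sum(f), 1, tolerance = 1e-12)
  expect_equal(f[["A"]], 4 / 6, tolerance = 1e-3)
  expect_equal(f[["R"]], 2 / 6, tolerance = 1e-3)
  expect_true(all(f > 0))   # floored, never exactly zero
})
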