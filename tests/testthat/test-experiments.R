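test_that("deviation classes follow the accuracy bands", {
  expect_equal(classify_deviation(0.59, 0.5, "alpha"), "moderately inaccurate")
  expect_equal(classify_deviation(1.0, 1.0, "alpha"), "accurate")
  expect_equal(classify_deviation(0.109, 0.1, "alpha"), "accurate")
  expect_equal(classify_deviation(0.126, 0.1, "alpha"), "inaccurate")
  expect_equal(classify_deviation(18.0, 18.9, "tree_length"), "accurate")
  # absolute bands at p_inv truth zero
  expect_equal(classify_deviation(0.005, 0, "p_inv"), "accurate")
  expect_equal(classify_deviation(0.03, 0, "p_inv"), "moderately inaccurate")
  expect_equal(classify_deviation(0.06, 0, "p_inv"), "inaccurate")
  expect_error(classify_deviation(0.5, 0, "alpha"), "p_inv")
  expect_error(classify_deviation(0.5, 0, "tree_length"), "p_inv")
})

test_that("replicate seeds are deterministic and spread out", {
  s1 <- replicate_seed(1, 6, 0.5, 0, 1)
  expect_identical(s1, replicate_seed(1, 6, 0.5, 0, 1))
  grid <- expand.grid(size = c(6, 24), alpha = c(0.1, 0.5), p = c(0, 0.5),
                      rep = 1:5)
  seeds <- mapply(replicate_seed, 1, grid$size, grid$alpha, grid$p, grid$rep)
  expect_equal(anyDuplicated(seeds), 0L)
  expect_true(all(seeds > 0 & seeds < 2^31))
})

test_that("a small grid runs deterministically and aggregates consistently", {
  cfg <- grid_config(tree_sizes = 6, alphas = 0.5, p_invs = c(0, 0.5),
                     replicates = 2, n_sites = 300, base_seed = 5,
                     fit = fit_config(n_starts = 3, epsilon = 0.05))
  g1 <- run_grid(cfg)
  g2 <- run_grid(cfg)
  expect_equal(g1$replicates, g2$replicates)
  expect_equal(nrow(g1$replicates), 4)
  expect_equal(nrow(g1$cells), 2)
  expect_true(all(g1$cells$n + g1$cells$n_failed == 2))
  # regenerating the per-cell summary is idempotent
  expect_equal(summarize_grid(g1$replicates), g1$cells)
  expect_output(print(g1), "grid_result")
})

test_that("the truth-beats-fit percentage counts only real wins", {
  tab <- data.frame(size = c(6, 6, 6, 24),
                    loglik_true = c(-10, -10, -10, -5),
                    loglik_fit = c(-10, -9.5, -10.2, -5))
  expect_equal(truth_beats_estimate_pct(tab), 25)
  expect_equal(truth_beats_estimate_pct(tab, tree_size = 24), 0)
  # fitted equal to truth everywhere: no wins
  tab$loglik_fit <- tab$loglik_true
  expect_equal(truth_beats_estimate_pct(tab), 0)
  # floating-point ties are not wins
  tab$loglik_fit <- tab$loglik_true - 1e-6
  expect_equal(truth_beats_estimate_pct(tab), 0)
  expect_error(truth_beats_estimate_pct(tab[0, ]), "no replicates")
  expect_error(truth_beats_estimate_pct(data.frame(a = 1)), "columns")
})

test_that("surface scans agree with plain evaluation and locate the maximum", {
  tr <- make_balanced_tree(6, 0.1, 0.2)
  aln <- simulate_alignment(tr, rate_mixture(0.5, 0.3), 500, 4, seed = 6)
  pat <- compress_patterns(aln)
  s1 <- surface_scan(aln, tr, 0.5, 0.3)
  expect_equal(dim(s1$loglik), c(1L, 1L))
  expect_equal(s1$loglik[1, 1], loglik_at(tr, 0.5, 0.3, pat, 4))
  expect_equal(s1$peaks$delta_lnl, 0)

  ag <- c(0.3, 0.5, 0.9)
  pg <- c(0.1, 0.3, 0.5)
  s3 <- surface_scan(pat, tr, ag, pg)
  expect_equal(dim(s3$loglik), c(3L, 3L))
  expect_true(max(s3$loglik) >= s3$loglik[1, 1])
  expect_equal(max(s3$peaks$loglik), max(s3$loglik))
  for (i in seq_along(ag))
    expect_equal(s3$loglik[i, 2], loglik_at(tr, ag[i], 0.3, pat, 4))
  # re-optimized scans can only improve on fixed branch lengths
  s3r <- surface_scan(pat, tr, 0.5, 0.3, mode = "reoptimize",
                      config = fit_config(epsilon = 0.05))
  expect_gte(s3r$loglik[1, 1], s1$loglik[1, 1] - 1e-9)
})

test_that("a difficult dataset shows multiple local maxima along the alpha/p_inv ridge", {
  # long alignment from the hardest cell: a second optimum with larger
  # alpha and nonzero p_inv competes with the one near the truth
  tr <- make_balanced_tree(6, 0.1, 0.2)
  aln <- simulate_alignment(tr, rate_mixture(0.5, 0.0), 100000, 4,
                            seed = replicate_seed(1, 6, 0.5, 0, 15))
  s <- surface_scan(compress_patterns(aln), tr,
                    alpha_grid = c(0.4, 0.5, 0.6, 0.7, 0.85),
                    pinv_grid = c(0, 0.05, 0.1, 0.15, 0.2), kappa = 4)
  expect_gte(nrow(s$peaks), 2)
  # the competing optima lie within a few log-units of each other
  expect_lt(diff(range(s$peaks$loglik[1:2])), 50)
})
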