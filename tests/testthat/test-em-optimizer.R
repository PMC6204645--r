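# Toy pattern_likelihoods builder: explicit L matrix on the log scale.
toy_liks <- function(L, weights) {
  structure(list(loglik = log(L), weights = weights),
            class = "pattern_likelihoods")
}

toy_patterns <- function(counts, const) {
  structure(list(states = matrix(0L, length(counts), 2),
                 counts = counts, n = sum(counts), taxa = c("a", "b"),
                 const_state = const),
            class = "pattern_table")
}

test_that("the EM update of p_inv matches hand arithmetic", {
  mix <- rate_mixture(1, 0.4, 2)
  # one constant pattern (count 3), one variable (count 1), k = 2
  L <- rbind(c(0.25, 0.20, 0.10),
             c(0,    0.05, 0.30))
  pat <- toy_patterns(c(3L, 1L), c(0L, -1L))
  pl <- toy_liks(L, mix$weights)
  got <- em_step_pinv(pat, pl, mix)
  w <- mix$weights
  post1 <- (0.25 * w[1]) / (0.25 * w[1] + 0.20 * w[2] + 0.10 * w[3])
  expect_equal(c(got), (3 * post1 + 1 * 0) / 4, tolerance = 1e-12)
  expect_equal(attr(got, "posterior"), c(post1, 0), tolerance = 1e-12)
})

test_that("EM fixed points: no constant sites gives zero; flat likelihoods stay put", {
  mix <- rate_mixture(1, 0.3, 4)
  pat <- toy_patterns(c(2L, 2L), c(-1L, -1L))
  pl <- toy_liks(matrix(c(0, 0, rep(0.2, 8)), 2, 5), mix$weights)
  expect_equal(c(em_step_pinv(pat, pl, mix)), 0)
  # L identical across categories: the update returns the current weight
  pat2 <- toy_patterns(c(1L, 1L), c(0L, 1L))
  pl2 <- toy_liks(matrix(0.2, 2, 5), mix$weights)
  expect_equal(c(em_step_pinv(pat2, pl2, mix)), mix$p_inv, tolerance = 1e-12)
})

test_that("outer-iteration log-likelihood traces never decrease", {
  tr <- make_balanced_tree(6, 0.1, 0.2)
  for (seed in c(101, 102, 103)) {
    aln <- simulate_alignment(tr, rate_mixture(0.5, 0.4), 2000, 4, seed = seed)
    fit <- fit_ig(tr, aln, fit_config(n_starts = 6))
    for (trc in fit$traces)
      expect_true(all(diff(trc) >= -1e-6))
  }
})

test_that("the multi-start fit dominates a single start on the same data", {
  tr <- make_balanced_tree(6, 0.1, 0.2)
  for (seed in c(31, 32)) {
    aln <- simulate_alignment(tr, rate_mixture(0.5, 0.0), 5000, 4, seed = seed)
    pat <- compress_patterns(aln)
    multi <- fit_ig(tr, pat, fit_config(n_starts = 10))
    single <- fit_ig(tr, pat, fit_config(n_starts = 1))
    expect_gte(multi$loglik, single$loglik - 1e-6)
    expect_gte(multi$loglik, max(multi$start_loglik) - 1e-9)
  }
})

test_that("branch-length optimization recovers the closed-form two-taxon MLE", {
  # JC limit: kappa = 1, no rate heterogeneity
  tr <- parse_newick("(A:0.05,B:0.05);")
  set.seed(44)
  aln <- simulate_alignment(tr, rate_mixture(1e7, 0), 4000, kappa = 1, seed = 44)
  pat <- compress_patterns(aln)
  mix <- rate_mixture(1e7, 0)
  opt <- optimize_branch_lengths(tr, mix, pat, kappa = 1)
  phat <- mean(aln[1, ] != aln[2, ])
  d_mle <- -3 / 4 * log(1 - 4 / 3 * phat)
  expect_equal(tree_length(opt), d_mle, tolerance = 1e-4)
  # identical sequences drive every branch to the lower bound
  aln2 <- matrix("A", 2, 50, dimnames = list(c("A", "B"), NULL))
  opt2 <- optimize_branch_lengths(tr, mix, compress_patterns(aln2), kappa = 1,
                                  bounds = c(1e-6, 100))
  expect_true(all(opt2$edge.length <= 1e-6 + 1e-12))
})

test_that("a branch sweep never decreases the log-likelihood", {
  set.seed(55)
  for (trial in 1:4) {
    tr <- rand_tree(5)
    aln <- rand_aln(tr$tip.label, 80)
    pat <- compress_patterns(aln)
    mix <- rate_mixture(runif(1, 0.3, 2), runif(1, 0, 0.5))
    before <- log_likelihood(tr, mix, pat, 4)
    opt <- optimize_branch_lengths(tr, mix, pat, 4)
    expect_gte(attr(opt, "loglik"), before - 1e-9)
    expect_equal(attr(opt, "loglik"), log_likelihood(opt, mix, pat, 4),
                 tolerance = 1e-9)
  }
})

test_that("scalar optimizers recover generating values and never lose likelihood", {
  tr <- make_balanced_tree(6, 0.1, 0.2)
  aln <- simulate_alignment(tr, rate_mixture(1, 0), 30000, 4, seed = 77)
  pat <- compress_patterns(aln)
  oa <- optimize_alpha(tr, pat, p_inv = 0, alpha = 0.3, kappa = 4)
  expect_equal(oa$alpha, 1, tolerance = 0.1)
  expect_false(oa$at_bound)
  # entry point no worse than before
  ll_entry <- loglik_at(tr, 0.3, 0, pat, 4)
  expect_gte(oa$loglik, ll_entry)
  # starting at the optimum does not move away (no likelihood decrease)
  oa2 <- optimize_alpha(tr, pat, p_inv = 0, alpha = oa$alpha, kappa = 4)
  expect_gte(oa2$loglik, oa$loglik - 1e-6)

  okap <- optimize_kappa(tr, rate_mixture(1, 0), pat, kappa = 1.5)
  expect_equal(okap$kappa, 4, tolerance = 0.4)
  expect_false(okap$at_bound)
  expect_gte(okap$loglik, loglik_at(tr, 1, 0, pat, 1.5))
})

test_that("an all-constant alignment is handled without errors", {
  tr <- make_balanced_tree(6, 0.1, 0.2)
  aln <- matrix("C", 6, 40, dimnames = list(tr$tip.label, NULL))
  fit <- suppressWarnings(fit_ig(tr, aln, fit_config(n_starts = 3, max_outer = 5)))
  expect_true(is.finite(fit$loglik))
  expect_true(fit$p_inv >= 0 && fit$p_inv < 1)
})

test_that("taxon mismatches are rejected", {
  tr <- make_balanced_tree(6, 0.1, 0.2)
  aln <- simulate_alignment(tr, rate_mixture(1, 0), 50, 4, seed = 1)
  rownames(aln)[1] <- "other"
  expect_error(fit_ig(tr, aln), "do not match")
})

test_that("parameters are recovered within 10% in the reference recovery setting", {
  # 6-taxon tree, alpha = 1.0, p_inv = 0.5, long alignments
  tr <- make_balanced_tree(6, 0.1, 0.2)
  n_rep <- 20
  est <- t(vapply(seq_len(n_rep), function(r) {
    seed <- replicate_seed(7, 6, 1.0, 0.5, r)
    aln <- simulate_alignment(tr, rate_mixture(1.0, 0.5), 100000, 4, seed = seed)
    fit <- fit_ig(tr, compress_patterns(aln))
    c(fit$alpha, fit$p_inv, fit$tree_length)
  }, numeric(3)))
  expect_lt(abs(mean(est[, 1]) - 1.0) / 1.0, 0.10)
  expect_lt(abs(mean(est[, 2]) - 0.5) / 0.5, 0.10)
  expect_lt(abs(mean(est[, 3]) - 1.0) / 1.0, 0.10)
})

test_that("fit results serialize to a report and a summary row", {
  tr <- make_balanced_tree(6, 0.1, 0.2)
  aln <- simulate_alignment(tr, rate_mixture(1, 0.2), 1000, 4, seed = 12)
  fit <- fit_ig(tr, aln, fit_config(n_starts = 3))
  rep <- fit_report(fit)
  expect_named(rep, c("estimates", "loglik", "tree", "starts", "traces",
                      "at_bounds", "n_sites", "n_patterns"))
  expect_equal(rep$estimates$alpha, fit$alpha)
  json <- jsonlite::toJSON(rep, auto_unbox = TRUE)
  expect_true(jsonlite::validate(json))
  row <- as.data.frame(fit)
  expect_equal(nrow(row), 1)
  expect_equal(row$loglik, fit$loglik)
  # loglik_at at the fitted parameters reproduces the fitted log-likelihood
  pat <- compress_patterns(aln)
  expect_equal(loglik_at(fit$tree, fit$alpha, fit$p_inv, pat, fit$kappa),
               fit$loglik, tolerance = 1e-6)
})
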