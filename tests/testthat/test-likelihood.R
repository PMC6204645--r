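test_that("pattern compression conserves sites and keeps first-occurrence order", {
  aln <- rbind(s1 = c("A", "A", "C", "A"), s2 = c("A", "A", "G", "A"))
  pat <- compress_patterns(aln)
  expect_equal(pat$counts, c(3L, 1L))
  expect_equal(pat$n, 4L)
  expect_equal(pat$states[1, ], c(0L, 0L))
  expect_equal(pat$states[2, ], c(1L, 2L))
  expect_equal(pat$const_state, c(0L, -1L))

  set.seed(8)
  aln2 <- rand_aln(paste0("t", 1:4), 300, p_missing = 0.05)
  pat2 <- compress_patterns(aln2)
  expect_equal(sum(pat2$counts), 300L)
  expect_equal(nrow(unique(pat2$states)), nrow(pat2$states))
  expect_equal(constant_fraction(pat2),
               mean(apply(aln2, 2, function(col) {
                 nm <- col[col != "N"]
                 length(nm) == 0 || all(nm == nm[1])
               })))
})

test_that("pruning equals brute-force enumeration on small trees", {
  set.seed(21)
  for (trial in 1:6) {
    n <- sample(3:5, 1)
    tr <- rand_tree(n)
    aln <- rand_aln(tr$tip.label, 25, p_missing = if (trial %% 2) 0.1 else 0)
    mix <- rate_mixture(runif(1, 0.2, 2), runif(1, 0, 0.6),
                        k = sample(2:4, 1))
    kap <- runif(1, 0.5, 8)
    got <- log_likelihood(tr, mix, compress_patterns(aln), kap)
    want <- brute_loglik(tr, aln, mix, kap)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("per-category likelihoods match closed forms on two taxa", {
  tr <- parse_newick("(A:0.07,B:0.05);")
  aln <- rbind(A = c("A", "C"), B = c("A", "G"))
  pat <- compress_patterns(aln)
  mix <- rate_mixture(0.7, 0.2)
  pl <- pattern_category_likelihoods(tr, mix, pat, kappa = 4)
  for (j in 2:5) {
    P <- k2p_transition_matrix(0.12 * mix$rates[j], 4)
    # constant pattern (A,A): 0.25 * P(same); variable (C,G): 0.25 * P(C->G)
    expect_equal(unname(exp(pl$loglik[1, j])), 0.25 * P[1, 1],
                 tolerance = 1e-12)
    expect_equal(unname(exp(pl$loglik[2, j])), 0.25 * P[2, 3],
                 tolerance = 1e-12)
  }
  # the invariable category can only produce constant patterns
  expect_equal(unname(exp(pl$loglik[1, 1])), 0.25)
  expect_equal(unname(pl$loglik[2, 1]), -Inf)
})

test_that("mixture log-likelihood lies between the per-category extremes", {
  set.seed(5)
  tr <- rand_tree(5)
  aln <- rand_aln(tr$tip.label, 100)
  pat <- compress_patterns(aln)
  mix <- rate_mixture(0.4, 0.3)
  ll <- log_likelihood(tr, mix, pat, 4)
  percat <- vapply(2:5, function(j) {
    fake <- mix
    fake$rates <- c(0, rep(mix$rates[j], 4))
    log_likelihood(tr, structure(fake, class = "rate_mixture"), pat, 4)
  }, numeric(1))
  # with variable sites present the invariable category alone is -Inf, so
  # the bound comes from the variable categories
  expect_gte(ll, min(percat))
  expect_lte(ll, max(percat) + 1e-9)
})

test_that("log-likelihood is invariant to re-rooting and to rate/length rescaling", {
  set.seed(13)
  tr <- rand_tree(6)
  aln <- rand_aln(tr$tip.label, 150)
  pat <- compress_patterns(aln)
  mix <- rate_mixture(0.8, 0.25)
  ll <- log_likelihood(tr, mix, pat, 4)
  rr <- ape::root(tr, outgroup = 3, resolve.root = TRUE)
  expect_equal(log_likelihood(rr, mix, pat, 4), ll, tolerance = 1e-8)
  # multiply all branch lengths by c, divide all rates by c
  cc <- 2.7
  tr2 <- tr
  tr2$edge.length <- tr$edge.length * cc
  mix2 <- mix
  mix2$rates <- mix$rates / cc
  expect_equal(log_likelihood(tr2, mix2, pat, 4), ll, tolerance = 1e-8)
})

test_that("compression is a pure refactor of the column-by-column sum", {
  set.seed(17)
  tr <- rand_tree(4)
  aln <- rand_aln(tr$tip.label, 40)
  mix <- rate_mixture(1.2, 0.1)
  total <- log_likelihood(tr, mix, compress_patterns(aln), 4)
  bycol <- sum(vapply(seq_len(ncol(aln)), function(i)
    log_likelihood(tr, mix, compress_patterns(aln[, i, drop = FALSE]), 4),
    numeric(1)))
  expect_equal(total, bycol, tolerance = 1e-9)
})

test_that("likelihood stays finite for 96 taxa at extreme rates", {
  tr <- make_balanced_tree(96, 0.1)
  tr$edge.length <- tr$edge.length * 10
  set.seed(1)
  aln <- rand_aln(tr$tip.label, 50)
  ll <- log_likelihood(tr, rate_mixture(0.05, 0.8), compress_patterns(aln), 4)
  expect_true(is.finite(ll))
  expect_lt(ll, 0)
})

test_that("likelihoods agree with an independent implementation", {
  skip_if_not_installed("phangorn")
  tr <- make_balanced_tree(6, 0.1, 0.2)
  aln <- simulate_alignment(tr, rate_mixture(0.7, 0.3), 400, 4, seed = 3)
  pat <- compress_patterns(aln)
  pd <- phangorn::phyDat(aln, type = "DNA")
  for (cse in list(c(1, 0, 4), c(0.7, 0.3, 4), c(0.5, 0.5, 1))) {
    mine <- log_likelihood(tr, rate_mixture(cse[1], cse[2]), pat, cse[3])
    ref <- phangorn::pml(tr, pd, bf = rep(0.25, 4),
                         Q = c(1, cse[3], 1, 1, cse[3], 1),
                         k = 4, shape = cse[1], inv = cse[2])$logLik
    expect_equal(mine, ref, tolerance = 1e-8)
  }
})

test_that("loglik_at matches log_likelihood and reports taxon mismatches", {
  tr <- make_balanced_tree(6, 0.1, 0.2)
  aln <- simulate_alignment(tr, rate_mixture(0.5, 0.2), 200, 4, seed = 4)
  pat <- compress_patterns(aln)
  expect_equal(loglik_at(tr, 0.5, 0.2, pat, 4),
               log_likelihood(tr, rate_mixture(0.5, 0.2), pat, 4))
  expect_equal(loglik_at(tr, 0.5, 0.2, aln, 4),
               loglik_at(tr, 0.5, 0.2, pat, 4))
  bad <- aln
  rownames(bad)[1] <- "zz"
  expect_error(loglik_at(tr, 0.5, 0.2, bad, 4), "do not match")
})
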