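#' Configuration for the I+G estimation heuristic
#'
#' @param epsilon convergence threshold on the outer-iteration
#'   log-likelihood improvement (log-likelihood units).
#' @param n_starts number of `p_inv` starting values, evenly spaced
#'   (endpoints included) between 0 and the observed constant-site
#'   fraction.
#' @param alpha_init initial Gamma shape for every start.
#' @param kappa_init initial transition/transversion rate ratio.
#' @param alpha_bounds search interval for the shape parameter.
#' @param blen_bounds per-branch length bounds.
#' @param kappa_bounds search interval for kappa.
#' @param max_outer hard cap on outer iterations per start.
#' @param n_categories number of Gamma categories k.
#' @param n_sweeps Newton-Raphson branch sweeps per outer iteration.
#' @param optimize_kappa set `FALSE` to hold kappa fixed at `kappa_init`.
#' @return a `fit_config` list.
#' @export
fit_config <- function(epsilon = 0.01, n_starts = 10, alpha_init = 1.0,
                       kappa_init = 2.0, alpha_bounds = c(0.02, 100),
                       blen_bounds = c(1e-6, 100), kappa_bounds = c(0.01, 1000),
                       max_outer = 100, n_categories = 4, n_sweeps = 1,
                       optimize_kappa = TRUE) {
  stopifnot(epsilon > 0, n_starts >= 1, alpha_init > 0, kappa_init > 0,
            length(alpha_bounds) == 2, alpha_bounds[1] > 0,
            alpha_bounds[1] < alpha_bounds[2],
            length(blen_bounds) == 2, blen_bounds[1] > 0,
            blen_bounds[1] < blen_bounds[2],
            length(kappa_bounds) == 2, kappa_bounds[1] > 0,
            kappa_bounds[1] < kappa_bounds[2],
            max_outer >= 1, n_categories >= 1, n_sweeps >= 1)
  structure(list(epsilon = epsilon, n_starts = as.integer(n_starts),
                 alpha_init = alpha_init, kappa_init = kappa_init,
                 alpha_bounds = alpha_bounds, blen_bounds = blen_bounds,
                 kappa_bounds = kappa_bounds, max_outer = as.integer(max_outer),
                 n_categories = as.integer(n_categories),
                 n_sweeps = as.integer(n_sweeps),
                 optimize_kappa = isTRUE(optimize_kappa)),
            class = "fit_config")
}

#' Expectation-maximization update of the invariable proportion
#'
#' E-step: posterior probability that each site is invariable,
#' `P(r_0 | D_i) = L[i,0] w_0 / sum_j L[i,j] w_j`. M-step: the updated
#' `p_inv` is the count-weighted mean of these posteriors over sites. The
#' update can never exceed the constant-site fraction because the posterior
#' is zero for every variable pattern.
#'
#' @param patterns a [compress_patterns()] table.
#' @param pat_liks [pattern_category_likelihoods()] computed at the current
#'   parameters.
#' @param mixture the current [rate_mixture()] (supplies the weights).
#' @return the updated `p_inv`, with the per-pattern posteriors in
#'   attribute `"posterior"`.
#' @export
em_step_pinv <- function(patterns, pat_liks, mixture) {
  stopifnot(inherits(patterns, "pattern_table"),
            inherits(pat_liks, "pattern_likelihoods"))
  a <- sweep(pat_liks$loglik, 2L, log(mixture$weights), "+")
  m <- do.call(pmax, as.data.frame(a))
  bad <- !is.finite(m)
  if (any(bad))
    stop("pattern ", which(bad)[1L],
         " has zero likelihood under every mixture category")
  post0 <- exp(a[, 1L] - m) / rowSums(exp(a - m))
  p_new <- sum(patterns$counts * post0) / patterns$n
  attr(p_new, "posterior") <- post0
  p_new
}

#' Brent optimization of the Gamma shape parameter
#'
#' Derivative-free scalar maximization of the log-likelihood over `alpha`
#' (on the log scale) with everything else held fixed. The returned point
#' never has a lower log-likelihood than the entry point.
#'
#' @param tree tree with current branch lengths.
#' @param patterns a [compress_patterns()] table.
#' @param p_inv current invariable proportion (held fixed).
#' @param alpha entry value of the shape parameter.
#' @param kappa current kappa (held fixed).
#' @param k number of Gamma categories.
#' @param bounds search interval.
#' @param tol Brent tolerance on log(alpha).
#' @return list with `alpha`, `loglik`, and `at_bound` (flag).
#' @export
optimize_alpha <- function(tree, patterns, p_inv, alpha = 1, kappa = 4, k = 4,
                           bounds = c(0.02, 100), tol = 1e-4) {
  f <- function(la) log_likelihood(tree, rate_mixture(exp(la), p_inv, k),
                                   patterns, kappa)
  alpha <- min(max(alpha, bounds[1]), bounds[2])
  ll0 <- f(log(alpha))
  opt <- optimize(f, interval = log(bounds), maximum = TRUE, tol = tol)
  if (opt$objective > ll0) {
    alpha <- exp(opt$maximum)
    ll0 <- opt$objective
  }
  at_bound <- alpha / bounds[1] < 1.001 || alpha / bounds[2] > 0.999
  list(alpha = alpha, loglik = ll0, at_bound = at_bound)
}

#' Quasi-Newton optimization of the substitution parameter
#'
#' One-dimensional L-BFGS-B maximization of the log-likelihood over
#' log(kappa), everything else fixed; the entry point is kept when the
#' optimizer cannot improve on it.
#'
#' @inheritParams optimize_alpha
#' @param mixture current [rate_mixture()].
#' @param kappa entry value.
#' @param bounds search interval for kappa.
#' @return list with `kappa`, `loglik`, and `at_bound`.
#' @export
optimize_kappa <- function(tree, mixture, patterns, kappa = 2,
                           bounds = c(0.01, 1000)) {
  f <- function(lk) -log_likelihood(tree, mixture, patterns, exp(lk))
  kappa <- min(max(kappa, bounds[1]), bounds[2])
  ll0 <- -f(log(kappa))
  opt <- optim(log(kappa), f, method = "L-BFGS-B",
               lower = log(bounds[1]), upper = log(bounds[2]),
               control = list(factr = 1e9))
  if (-opt$value > ll0) {
    kappa <- exp(opt$par)
    ll0 <- -opt$value
  }
  at_bound <- kappa / bounds[1] < 1.001 || kappa / bounds[2] > 0.999
  list(kappa = kappa, loglik = ll0, at_bound = at_bound)
}

#' Newton-Raphson branch-length optimization
#'
#' One sweep (or more) of safeguarded per-branch Newton-Raphson on the
#' mixture log-likelihood: each branch is optimized conditionally on the
#' current values of all others (Gauss-Seidel order from the root), with
#' analytic first and second derivatives of the K2P transition
#' probabilities and fallback step-halving whenever a Newton step would
#' leave the bounds or decrease the likelihood. The total log-likelihood
#' never decreases.
#'
#' @param tree tree whose branch lengths are optimized.
#' @param mixture current [rate_mixture()].
#' @param patterns a [compress_patterns()] table.
#' @param kappa current kappa.
#' @param bounds per-branch bounds.
#' @param n_sweeps number of sweeps.
#' @return the tree with updated branch lengths; the final log-likelihood
#'   is in attribute `"loglik"`.
#' @export
optimize_branch_lengths <- function(tree, mixture, patterns, kappa = 4,
                                    bounds = c(1e-6, 100), n_sweeps = 1) {
  inp <- prepare_engine_input(tree, patterns)
  tr <- inp$tree
  tr$edge.length <- pmin(pmax(tr$edge.length, bounds[1]), bounds[2])
  out <- ig_branch_sweep_cpp(tr$edge, tr$edge.length, inp$states,
                             as.numeric(patterns$counts),
                             invariable_liks(patterns),
                             mixture$rates[-1L], mixture$weights, kappa,
                             bounds[1], bounds[2], as.integer(n_sweeps))
  tr$edge.length <- out$blen
  attr(tr, "loglik") <- out$loglik
  tr
}

#' Fit the I+G model on a fixed tree topology
#'
#' Maximum-likelihood estimation of the Gamma shape `alpha`, the invariable
#' proportion `p_inv`, the K2P parameter `kappa` and all branch lengths on
#' a fixed topology, with the EM multi-start heuristic. For each of
#' `n_starts` starting values of `p_inv` -- evenly spaced between 0 and the
#' observed constant-site fraction, endpoints included, with `alpha` always
#' started at `alpha_init` -- the outer loop iterates: (i) Newton-Raphson
#' branch lengths, (ii) quasi-Newton kappa, (iii) E-step posteriors,
#' (iv) EM update of `p_inv`, (v) Brent search for `alpha`; it stops when
#' the outer-iteration log-likelihood improvement is at most `epsilon`.
#' The best-scoring start is returned (ties within 1e-6 log-likelihood
#' units resolved toward the smaller `p_inv`).
#'
#' When the EM step changes `p_inv`, the mean-rate-1 normalization rescales
#' the variable-category rates by the old-to-new `(1 - p_inv)` ratio; the
#' branch lengths are rescaled by the inverse factor in the same step so
#' that the rate-times-length products -- and hence the likelihood -- match
#' the fixed-rate EM update exactly, preserving the EM ascent guarantee.
#' Because that compensation leaves the per-category pattern likelihoods
#' unchanged, the E/M update is iterated to its fixed point within each
#' outer iteration at negligible cost; the conditional log-likelihood in
#' `p_inv` is concave, so this inner loop converges monotonically to the
#' conditional optimum and cannot alter which optimum a start reaches.
#'
#' @param tree the (true or assumed) topology, an [ape::phylo]; its branch
#'   lengths are the starting values (0.1 per branch when absent).
#' @param aln an alignment matrix or a [compress_patterns()] table.
#' @param config a [fit_config()].
#' @return an object of class `ig_fit` with elements `alpha`, `p_inv`,
#'   `kappa`, `tree` (fitted branch lengths), `tree_length`, `loglik`,
#'   `start_index`, `start_pinv`, `traces` (outer-iteration log-likelihoods
#'   per start), `n_outer`, `converged`, `at_bounds`, and `config`.
#' @examples
#' tr <- make_balanced_tree(6, 0.1, 0.2)
#' aln <- simulate_alignment(tr, rate_mixture(1, 0.3), 2000, seed = 7)
#' fit <- fit_ig(tr, aln, fit_config(n_starts = 4))
#' c(fit$alpha, fit$p_inv)
#' @export
fit_ig <- function(tree, aln, config = fit_config()) {
  stopifnot(inherits(tree, "phylo"), inherits(config, "fit_config"))
  patterns <- if (inherits(aln, "pattern_table")) aln else compress_patterns(aln)
  if (!setequal(tree$tip.label, patterns$taxa) ||
      length(tree$tip.label) != length(patterns$taxa))
    stop("tree tips and alignment taxa do not match")

  cf <- constant_fraction(patterns)
  starts <- seq(0, min(cf, 1 - 1e-8), length.out = config$n_starts)
  starts <- unique(starts)
  k <- config$n_categories

  inp <- prepare_engine_input(
    {
      tr0 <- tree
      if (is.null(tr0$edge.length)) tr0$edge.length <- rep(0.1, nrow(tr0$edge))
      tr0
    }, patterns)
  eng <- list(edge = inp$tree$edge, states = inp$states,
              counts = as.numeric(patterns$counts),
              l0 = invariable_liks(patterns))
  blen0 <- pmin(pmax(inp$tree$edge.length, config$blen_bounds[1]),
                config$blen_bounds[2])

  runs <- vector("list", length(starts))
  for (s in seq_along(starts)) {
    run <- fit_one_start(eng, blen0, starts[s], cf, config, k)
    if (!run$converged)
      warning("start ", s, ": outer loop hit the iteration cap (",
              config$max_outer, ") without converging")
    runs[[s]] <- run
    runs[[s]]$tree <- within_tree(inp$tree, run$blen)
  }

  lls <- vapply(runs, `[[`, numeric(1), "loglik")
  cand <- which(lls >= max(lls) - 1e-6)
  best <- cand[which.min(vapply(runs[cand], `[[`, numeric(1), "p_inv"))]
  b <- runs[[best]]

  structure(
    list(alpha = b$alpha, p_inv = b$p_inv, kappa = b$kappa, tree = b$tree,
         tree_length = tree_length(b$tree), loglik = b$loglik,
         start_index = best, start_pinv = starts,
         traces = lapply(runs, `[[`, "trace"),
         n_outer = vapply(runs, `[[`, integer(1), "n_outer"),
         converged = vapply(runs, `[[`, logical(1), "converged"),
         at_bounds = b$at_bounds,
         start_loglik = lls,
         n_sites = patterns$n, n_patterns = length(patterns$counts),
         config = config),
    class = "ig_fit"
  )
}

## Internal: replace branch lengths on a phylo skeleton.
within_tree <- function(tr, blen) {
  tr$edge.length <- blen
  tr
}

## Internal: mixture log-likelihood on cached engine input.
eng_loglik <- function(eng, blen, alpha, p, k, kap) {
  m <- rate_mixture(alpha, p, k)
  ig_mix_loglik_cpp(eng$edge, blen, eng$states, eng$counts, eng$l0,
                    m$rates[-1L], m$weights, kap)
}

## Internal: one start of the estimation heuristic on cached engine input
## (postorder edge matrix, tip state codes, pattern counts, invariable-
## category likelihoods). p_max is the constant-site fraction.
fit_one_start <- function(eng, blen, p0, p_max, config, k) {
  p <- p0
  alpha <- config$alpha_init
  kap <- config$kappa_init
  ll_prev <- -Inf
  trace <- numeric(0)
  it <- 0L
  alpha_bound <- kappa_bound <- FALSE
  th_prev <- NULL
  repeat {
    it <- it + 1L
    mix <- rate_mixture(alpha, p, k)
    rv <- mix$rates[-1L]
    sw <- ig_branch_sweep_cpp(eng$edge, blen, eng$states, eng$counts,
                              eng$l0, rv, mix$weights, kap,
                              config$blen_bounds[1], config$blen_bounds[2],
                              config$n_sweeps)                        # Step 2
    blen <- sw$blen
    if (config$optimize_kappa) {                                      # Step 3
      fk <- function(lk) -ig_mix_loglik_cpp(eng$edge, blen, eng$states,
                                            eng$counts, eng$l0, rv,
                                            mix$weights, exp(lk))
      ll_entry <- -fk(log(kap))
      ok <- optim(log(kap), fk, method = "L-BFGS-B",
                  lower = log(config$kappa_bounds[1]),
                  upper = log(config$kappa_bounds[2]),
                  control = list(factr = 1e9))
      if (-ok$value > ll_entry) kap <- exp(ok$par)
      kappa_bound <- kap / config$kappa_bounds[1] < 1.001 ||
        kap / config$kappa_bounds[2] > 0.999
    }
    # Steps 4-5: E-step posteriors and M-step p_inv update, iterated to
    # the conditional fixed point (the category likelihoods are invariant
    # under the compensated mean-rate-1 rescale)
    lv <- ig_cat_loglik_cpp(eng$edge, blen, eng$states, rv, kap)
    p_new <- em_pinv_fixed_point(lv, log(eng$l0), eng$counts, p, k)
    if (p_new != p) {
      blen <- pmin(pmax(blen * (1 - p_new) / (1 - p),
                        config$blen_bounds[1]), config$blen_bounds[2])
      p <- p_new
    }
    fa <- function(la) {                                              # Step 6
      m <- rate_mixture(exp(la), p, k)
      ig_mix_loglik_cpp(eng$edge, blen, eng$states, eng$counts, eng$l0,
                        m$rates[-1L], m$weights, kap)
    }
    ll <- fa(log(alpha))
    oa <- optimize(fa, log(config$alpha_bounds), maximum = TRUE, tol = 1e-4)
    if (oa$objective > ll) {
      alpha <- exp(oa$maximum)
      ll <- oa$objective
    }

    # Ridge acceleration: the EM/Brent alternation moves slowly along the
    # correlated (alpha, p_inv) ridge, so extrapolate geometrically along
    # the most recent direction in (log alpha, p_inv) and keep the best
    # strictly improving point. Pure hill climbing: the ascent guarantee
    # and the fixed points of the heuristic are unchanged.
    if (!is.null(th_prev)) {
      dir <- c(log(alpha) - th_prev[1], p - th_prev[2])
      if (any(abs(dir) > 1e-10)) {
        best <- NULL
        step <- 1
        while (step <= 4096) {
          la_c <- min(max(log(alpha) + step * dir[1],
                          log(config$alpha_bounds[1])),
                      log(config$alpha_bounds[2]))
          p_c <- min(max(p + step * dir[2], 0), min(p_max, 1 - 1e-8))
          ll_c <- eng_loglik(eng, blen, exp(la_c), p_c, k, kap)
          if (ll_c <= ll + 1e-9) break
          ll <- ll_c
          best <- c(la_c, p_c)
          step <- step * 2
        }
        if (!is.null(best)) {
          alpha <- exp(best[1])
          p <- best[2]
        }
      }
    }
    th_prev <- c(log(alpha), p)

    alpha_bound <- alpha / config$alpha_bounds[1] < 1.001 ||
      alpha / config$alpha_bounds[2] > 0.999
    trace <- c(trace, ll)
    if ((is.finite(ll_prev) && ll - ll_prev <= config$epsilon) ||
        it >= config$max_outer)
      break                                                           # Step 7
    ll_prev <- ll
  }
  list(alpha = alpha, p_inv = p, kappa = kap, blen = blen,
       loglik = trace[length(trace)], trace = trace, n_outer = it,
       converged = it < config$max_outer,
       at_bounds = c(alpha = alpha_bound, kappa = kappa_bound,
                     blen = any(blen <= config$blen_bounds[1] * 1.001 |
                                blen >= config$blen_bounds[2] * 0.999)))
}

## Internal: fixed point of the E/M update of p_inv with the per-category
## pattern log-likelihoods held fixed. The conditional log-likelihood is
## concave in p_inv (log of a linear function per pattern), so the EM
## iteration ascends monotonically to the conditional maximum.
em_pinv_fixed_point <- function(lv, log_l0, counts, p, k,
                                max_iter = 500L, tol = 1e-10) {
  m <- log_l0
  for (j in seq_len(ncol(lv))) m <- pmax(m, lv[, j])
  e0 <- ifelse(is.finite(log_l0), exp(log_l0 - m), 0)
  sv <- rowSums(exp(lv - m))
  n <- sum(counts)
  for (iter in seq_len(max_iter)) {
    num <- p * e0
    denom <- num + ((1 - p) / k) * sv
    p_new <- min(sum(counts * num / denom) / n, 1 - 1e-8)
    if (abs(p_new - p) <= tol) {
      p <- p_new
      break
    }
    p <- p_new
  }
  p
}

#' @export
print.ig_fit <- function(x, ...) {
  cat("I+G maximum-likelihood fit (fixed topology)\n")
  cat(sprintf("  alpha  = %.4f%s\n", x$alpha,
              if (x$at_bounds["alpha"]) " [at bound]" else ""))
  cat(sprintf("  p_inv  = %.4f\n", x$p_inv))
  cat(sprintf("  kappa  = %.4f (ts/tv = %.4f)%s\n", x$kappa, x$kappa / 2,
              if (x$at_bounds["kappa"]) " [at bound]" else ""))
  cat(sprintf("  tree length = %.4f\n", x$tree_length))
  cat(sprintf("  log-likelihood = %.4f (best of %d starts, start p_inv = %.4g)\n",
              x$loglik, length(x$start_pinv), x$start_pinv[x$start_index]))
  cat(sprintf("  sites = %d (%d patterns); outer iterations: %s\n",
              x$n_sites, x$n_patterns, paste(x$n_outer, collapse = " ")))
  invisible(x)
}

#' Serialize a fit
#'
#' `fit_report()` returns a plain list (estimates, log-likelihood, start
#' traces, boundary flags) suitable for `jsonlite::write_json()`;
#' `as.data.frame.ig_fit()` gives a one-row summary for CSV output.
#'
#' @param fit an [fit_ig()] result.
#' @return a named list.
#' @export
fit_report <- function(fit) {
  stopifnot(inherits(fit, "ig_fit"))
  list(estimates = list(alpha = fit$alpha, p_inv = fit$p_inv,
                        kappa = fit$kappa, tstv = fit$kappa / 2,
                        tree_length = fit$tree_length),
       loglik = fit$loglik,
       tree = write_newick(fit$tree),
       starts = list(p_inv = fit$start_pinv, chosen = fit$start_index,
                     loglik = fit$start_loglik, n_outer = fit$n_outer,
                     converged = fit$converged),
       traces = fit$traces,
       at_bounds = as.list(fit$at_bounds),
       n_sites = fit$n_sites, n_patterns = fit$n_patterns)
}

#' @export
as.data.frame.ig_fit <- function(x, ...) {
  data.frame(alpha = x$alpha, p_inv = x$p_inv, kappa = x$kappa,
             tree_length = x$tree_length, loglik = x$loglik,
             start_index = x$start_index,
             n_outer = x$n_outer[x$start_index],
             converged = x$converged[x$start_index],
             at_bound = any(x$at_bounds))
}
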