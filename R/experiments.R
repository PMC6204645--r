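#' Configuration for an accuracy simulation grid
#'
#' Defines the simulation study: balanced trees of the given sizes, a grid
#' of generating `(alpha, p_inv)` pairs, replicate alignments per cell, and
#' the fit settings. The default grid is the full study design: trees of
#' 6, 24 and 96 taxa (uniform branch lengths 0.1, one internal branch of
#' 0.2 on the 6-taxon tree), `alpha` in {0.1, 0.5, 1.0}, `p_inv` in
#' {0.0, 0.1, ..., 0.9}, 100 replicates of 100,000 sites per cell, under
#' K2P with an expected-counts transition/transversion ratio of 2.
#' `scaled_profile()` is the same grid at desk scale (10 replicates of
#' 10,000 sites).
#'
#' @param tree_sizes taxon counts of the balanced trees.
#' @param alphas generating Gamma shape values.
#' @param p_invs generating invariable proportions.
#' @param replicates alignments per (tree, alpha, p_inv) cell.
#' @param n_sites alignment length.
#' @param branch_length uniform branch length.
#' @param long_internal_6 length of the long internal branch on the
#'   6-taxon tree (`NULL` to disable).
#' @param tstv transition/transversion ratio.
#' @param tstv_kind `"counts"` (expected-counts ratio R, the Seq-Gen
#'   convention; kappa = 2R) or `"rate"` (kappa itself).
#' @param k number of Gamma categories.
#' @param base_seed base seed; every replicate draws a deterministic seed
#'   from it so any cell can be re-run in isolation.
#' @param fit a [fit_config()].
#' @param ... arguments forwarded to `grid_config()`.
#' @return a `grid_config` list.
#' @export
grid_config <- function(tree_sizes = c(6, 24, 96), alphas = c(0.1, 0.5, 1.0),
                        p_invs = seq(0, 0.9, by = 0.1), replicates = 100,
                        n_sites = 100000, branch_length = 0.1,
                        long_internal_6 = 0.2, tstv = 2,
                        tstv_kind = c("counts", "rate"), k = 4,
                        base_seed = 1, fit = fit_config()) {
  tstv_kind <- match.arg(tstv_kind)
  stopifnot(length(tree_sizes) >= 1, length(alphas) >= 1, length(p_invs) >= 1,
            replicates >= 1, n_sites >= 1, all(alphas > 0),
            all(p_invs >= 0 & p_invs < 1), inherits(fit, "fit_config"))
  kappa <- if (tstv_kind == "counts") tstv_to_kappa(tstv) else tstv
  structure(list(tree_sizes = as.integer(tree_sizes), alphas = alphas,
                 p_invs = p_invs, replicates = as.integer(replicates),
                 n_sites = as.integer(n_sites),
                 branch_length = branch_length,
                 long_internal_6 = long_internal_6,
                 tstv = tstv, tstv_kind = tstv_kind, kappa = kappa,
                 k = as.integer(k), base_seed = as.integer(base_seed),
                 fit = fit),
            class = "grid_config")
}

#' @rdname grid_config
#' @export
scaled_profile <- function(...) {
  grid_config(replicates = 10, n_sites = 10000, ...)
}

#' Deterministic per-replicate seed
#'
#' Mixes the base seed with the cell coordinates and replicate index by a
#' Lehmer-style integer recurrence modulo 2^31 - 1, so every replicate is
#' reproducible in isolation.
#'
#' @param base_seed integer base seed.
#' @param size,alpha,p_inv cell coordinates.
#' @param rep replicate index.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
replicate_seed <- function(base_seed, size, alpha, p_inv, rep) {
  h <- abs(as.numeric(base_seed)) %% 2147483647
  for (v in c(size, round(alpha * 1000), round(p_inv * 1000), rep))
    h <- (h * 48271 + v + 1) %% 2147483647
  as.integer(h) + 1L
}

## Internal: the simulation tree for one grid cell.
cell_tree <- function(config, size) {
  make_balanced_tree(size, config$branch_length,
                     if (size == 6L) config$long_internal_6 else NULL)
}

#' Run the accuracy simulation grid
#'
#' For every cell of the grid and every replicate: simulate an alignment,
#' fit the I+G model on the true topology with [fit_ig()], and record the
#' estimates, the fitted log-likelihood and the log-likelihood at the true
#' generating parameters (true branch lengths, kappa, alpha, p_inv).
#' Individual replicate failures are caught, reported as a warning and
#' recorded as `NA` rows rather than aborting the grid.
#'
#' @param config a [grid_config()].
#' @param verbose print one line per cell.
#' @return an object of class `grid_result`: list with `replicates` (one
#'   row per replicate), `cells` (per-cell means and accuracy classes, see
#'   [summarize_grid()]), and `config`.
#' @export
run_grid <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "grid_config"))
  rows <- list()
  for (size in config$tree_sizes) {
    tree <- cell_tree(config, size)
    tl_true <- tree_length(tree)
    for (alpha in config$alphas) {
      for (p_inv in config$p_invs) {
        if (verbose)
          message(sprintf("cell: %d taxa, alpha = %g, p_inv = %g", size, alpha, p_inv))
        for (r in seq_len(config$replicates)) {
          seed <- replicate_seed(config$base_seed, size, alpha, p_inv, r)
          row <- tryCatch({
            aln <- simulate_alignment(tree, rate_mixture(alpha, p_inv, config$k),
                                      config$n_sites, config$kappa, seed)
            pat <- compress_patterns(aln)
            fit <- fit_ig(tree, pat, config$fit)
            ll_true <- loglik_at(tree, alpha, p_inv, pat, config$kappa, config$k)
            data.frame(size = size, alpha_true = alpha, pinv_true = p_inv,
                       rep = r, seed = seed,
                       alpha_hat = fit$alpha, pinv_hat = fit$p_inv,
                       kappa_hat = fit$kappa, tl_hat = fit$tree_length,
                       tl_true = tl_true,
                       loglik_fit = fit$loglik, loglik_true = ll_true,
                       n_patterns = fit$n_patterns,
                       converged = all(fit$converged),
                       at_bound = any(fit$at_bounds), failed = FALSE)
          }, error = function(e) {
            warning(sprintf("replicate failed (%d taxa, alpha=%g, p_inv=%g, rep %d): %s",
                            size, alpha, p_inv, r, conditionMessage(e)))
            data.frame(size = size, alpha_true = alpha, pinv_true = p_inv,
                       rep = r, seed = seed,
                       alpha_hat = NA_real_, pinv_hat = NA_real_,
                       kappa_hat = NA_real_, tl_hat = NA_real_,
                       tl_true = tl_true,
                       loglik_fit = NA_real_, loglik_true = NA_real_,
                       n_patterns = NA_integer_, converged = NA,
                       at_bound = NA, failed = TRUE)
          })
          rows[[length(rows) + 1L]] <- row
        }
      }
    }
  }
  replicates <- do.call(rbind, rows)
  structure(list(replicates = replicates,
                 cells = summarize_grid(replicates),
                 config = config),
            class = "grid_result")
}

#' Per-cell summary of a grid run
#'
#' Aggregates the per-replicate table into per-cell means of the estimated
#' shape, invariable proportion and tree length, and classifies each mean
#' against its generating value with [classify_deviation()]. Regenerating
#' the summary from the same table is idempotent.
#'
#' @param replicates the per-replicate data frame from [run_grid()].
#' @return a data frame with one row per (size, alpha, p_inv) cell.
#' @export
summarize_grid <- function(replicates) {
  ok <- replicates[!replicates$failed & !is.na(replicates$alpha_hat), ]
  keys <- unique(data.frame(size = replicates$size,
                            alpha_true = replicates$alpha_true,
                            pinv_true = replicates$pinv_true,
                            stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    kk <- keys[i, ]
    sub <- ok[ok$size == kk$size & ok$alpha_true == kk$alpha_true &
              ok$pinv_true == kk$pinv_true, ]
    all_n <- sum(replicates$size == kk$size &
                 replicates$alpha_true == kk$alpha_true &
                 replicates$pinv_true == kk$pinv_true)
    if (nrow(sub) == 0L)
      return(data.frame(kk, n = 0L, n_failed = all_n,
                        alpha_mean = NA_real_, pinv_mean = NA_real_,
                        tl_mean = NA_real_, tl_true = NA_real_,
                        class_alpha = NA_character_, class_pinv = NA_character_,
                        class_tl = NA_character_, accurate = NA))
    am <- mean(sub$alpha_hat); pm <- mean(sub$pinv_hat); tm <- mean(sub$tl_hat)
    ca <- classify_deviation(am, kk$alpha_true, "alpha")
    cp <- classify_deviation(pm, kk$pinv_true, "p_inv")
    ct <- classify_deviation(tm, sub$tl_true[1L], "tree_length")
    data.frame(kk, n = nrow(sub), n_failed = all_n - nrow(sub),
               alpha_mean = am, pinv_mean = pm, tl_mean = tm,
               tl_true = sub$tl_true[1L],
               class_alpha = ca, class_pinv = cp, class_tl = ct,
               accurate = all(c(ca, cp, ct) == "accurate"))
  }))
  rownames(out) <- NULL
  out
}

#' Classify the deviation of a mean estimate from the truth
#'
#' Relative-deviation bands: accurate below 10%, moderately inaccurate from
#' 10% to 25%, inaccurate above 25%. When the generating `p_inv` is 0 the
#' relative deviation is undefined and absolute bands apply instead: the
#' mean estimate is accurate up to 0.01, moderately inaccurate up to 0.05,
#' inaccurate above. A zero truth for the shape or the tree length is an
#' error.
#'
#' @param estimate_mean mean of the estimates over replicates.
#' @param truth generating value.
#' @param quantity `"alpha"`, `"p_inv"` or `"tree_length"`.
#' @return `"accurate"`, `"moderately inaccurate"` or `"inaccurate"`.
#' @examples
#' classify_deviation(0.59, 0.5, "alpha")   # moderately inaccurate
#' classify_deviation(0.06, 0.0, "p_inv")   # inaccurate
#' @export
classify_deviation <- function(estimate_mean, truth,
                               quantity = c("alpha", "p_inv", "tree_length")) {
  quantity <- match.arg(quantity)
  if (!is.finite(estimate_mean) || !is.finite(truth) || truth < 0)
    stop("'estimate_mean' and 'truth' must be finite and 'truth' nonnegative")
  if (truth == 0) {
    if (quantity != "p_inv")
      stop("a zero truth is only meaningful for p_inv")
    d <- abs(estimate_mean)
    if (d <= 0.01) "accurate"
    else if (d <= 0.05) "moderately inaccurate"
    else "inaccurate"
  } else {
    dev <- abs(estimate_mean - truth) / truth
    if (dev < 0.10) "accurate"
    else if (dev <= 0.25) "moderately inaccurate"
    else "inaccurate"
  }
}

#' Percentage of replicates where the truth beats the fit
#'
#' Fraction (in percent) of replicates whose log-likelihood at the true
#' generating parameters exceeds the fitted log-likelihood by more than
#' `tol`. The tolerance (default 1e-4) avoids counting floating-point ties
#' as wins. A nonzero percentage indicates optimizer entrapment in local
#' optima.
#'
#' @param replicates per-replicate table from [run_grid()] (or any data
#'   frame with `loglik_true` and `loglik_fit` columns).
#' @param tree_size optional filter on the `size` column.
#' @param tol log-likelihood comparison tolerance.
#' @return a percentage in `[0, 100]`.
#' @export
truth_beats_estimate_pct <- function(replicates, tree_size = NULL, tol = 1e-4) {
  if (!all(c("loglik_true", "loglik_fit") %in% names(replicates)))
    stop("'replicates' must contain loglik_true and loglik_fit columns")
  tab <- replicates[!is.na(replicates$loglik_true) & !is.na(replicates$loglik_fit), ]
  if (!is.null(tree_size)) tab <- tab[tab$size %in% tree_size, ]
  if (nrow(tab) == 0L) stop("no replicates to compare")
  100 * mean(tab$loglik_true - tab$loglik_fit > tol)
}

#' Log-likelihood surface over (alpha, p_inv)
#'
#' Evaluates the log-likelihood of one alignment on a grid of shape and
#' invariable-proportion values. With `mode = "fixed"` the supplied branch
#' lengths and kappa are held fixed; with `mode = "reoptimize"` branch
#' lengths (and kappa) are re-optimized at every grid point (a constrained
#' fit). The result records all grid-local maxima and their log-likelihood
#' differences from the global grid maximum, which makes the bimodal
#' structure of difficult datasets visible.
#'
#' @param aln alignment matrix or [compress_patterns()] table.
#' @param tree tree with branch lengths.
#' @param alpha_grid,pinv_grid grid values.
#' @param kappa K2P parameter.
#' @param k Gamma categories.
#' @param mode `"fixed"` or `"reoptimize"`.
#' @param config [fit_config()] used in `"reoptimize"` mode.
#' @return an object of class `ll_surface`: list with `alpha`, `p_inv`,
#'   `loglik` (matrix, alpha in rows), `peaks` (data frame of grid-local
#'   maxima with `delta_lnl`), and `mode`.
#' @export
surface_scan <- function(aln, tree, alpha_grid, pinv_grid, kappa = 4, k = 4,
                         mode = c("fixed", "reoptimize"),
                         config = fit_config()) {
  mode <- match.arg(mode)
  stopifnot(length(alpha_grid) >= 1, length(pinv_grid) >= 1,
            all(alpha_grid > 0), all(pinv_grid >= 0 & pinv_grid < 1))
  patterns <- if (inherits(aln, "pattern_table")) aln else compress_patterns(aln)
  M <- matrix(NA_real_, length(alpha_grid), length(pinv_grid),
              dimnames = list(alpha = signif(alpha_grid, 6),
                              p_inv = signif(pinv_grid, 6)))
  for (ia in seq_along(alpha_grid)) {
    for (ip in seq_along(pinv_grid)) {
      if (mode == "fixed") {
        M[ia, ip] <- loglik_at(tree, alpha_grid[ia], pinv_grid[ip],
                               patterns, kappa, k)
      } else {
        mix <- rate_mixture(alpha_grid[ia], pinv_grid[ip], k)
        tr <- tree
        kap <- kappa
        ll_prev <- -Inf
        repeat {
          tr <- optimize_branch_lengths(tr, mix, patterns, kap,
                                        config$blen_bounds, config$n_sweeps)
          if (config$optimize_kappa)
            kap <- optimize_kappa(tr, mix, patterns, kap, config$kappa_bounds)$kappa
          ll <- log_likelihood(tr, mix, patterns, kap)
          if (ll - ll_prev <= config$epsilon) break
          ll_prev <- ll
        }
        M[ia, ip] <- ll
      }
    }
  }
  structure(list(alpha = alpha_grid, p_inv = pinv_grid, loglik = M,
                 peaks = find_grid_peaks(M, alpha_grid, pinv_grid),
                 mode = mode),
            class = "ll_surface")
}

## Internal: local maxima on a grid (4-neighborhood), sorted by height.
find_grid_peaks <- function(M, alpha_grid, pinv_grid) {
  nr <- nrow(M); nc <- ncol(M)
  peaks <- list()
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      v <- M[i, j]
      nb <- c(if (i > 1) M[i - 1, j], if (i < nr) M[i + 1, j],
              if (j > 1) M[i, j - 1], if (j < nc) M[i, j + 1])
      if (is.null(nb) || all(v >= nb))
        peaks[[length(peaks) + 1L]] <-
          data.frame(alpha = alpha_grid[i], p_inv = pinv_grid[j], loglik = v)
    }
  }
  out <- do.call(rbind, peaks)
  out$delta_lnl <- out$loglik - max(M)
  out[order(-out$loglik), , drop = FALSE]
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf("grid_result: %d cells, %d replicates each, %d sites\n",
              nrow(x$cells), x$config$replicates, x$config$n_sites))
  acc <- sum(x$cells$accurate, na.rm = TRUE)
  cat(sprintf("accurate cells: %d / %d\n", acc, nrow(x$cells)))
  for (s in unique(x$cells$size))
    cat(sprintf("truth beats fit (%d taxa): %.3f%%\n", s,
                truth_beats_estimate_pct(x$replicates, s)))
  invisible(x)
}
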