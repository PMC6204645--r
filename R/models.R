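#' Kimura two-parameter transition probability matrix
#'
#' Closed-form transition probabilities under the K2P model with the
#' instantaneous rate matrix scaled to one expected substitution per unit
#' branch length at stationarity (uniform base frequencies), so branch
#' lengths are expected substitutions per site. With transition rate
#' `kappa * beta` and transversion rate `beta`, the scaling gives
#' `beta = 1 / (kappa + 2)`.
#'
#' @param t evolutionary distance (branch length times rate), >= 0.
#' @param kappa transition/transversion *rate* ratio (> 0); `kappa = 1`
#'   reduces to Jukes-Cantor.
#' @return a 4x4 row-stochastic matrix in the state order A, C, G, T.
#' @examples
#' k2p_transition_matrix(0.1, 4)
#' @export
k2p_transition_matrix <- function(t, kappa) {
  if (!is.numeric(t) || length(t) != 1L || t < 0)
    stop("'t' must be a single nonnegative number")
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 0)
    stop("'kappa' must be a single positive number")
  beta <- 1 / (kappa + 2)
  e1 <- exp(-4 * beta * t)
  e2 <- exp(-2 * (kappa + 1) * beta * t)
  p_same <- 0.25 + 0.25 * e1 + 0.5 * e2
  p_ti   <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv   <- 0.25 - 0.25 * e1
  m <- matrix(p_tv, 4L, 4L, dimnames = list(c("A", "C", "G", "T"),
                                            c("A", "C", "G", "T")))
  ## transitions: A<->G, C<->T
  m[cbind(1:4, c(3L, 4L, 1L, 2L))] <- p_ti
  diag(m) <- p_same
  m
}

#' Convert between the two transition/transversion conventions
#'
#' The expected-counts ratio R (transitions over transversions among
#' observed substitutions, the Seq-Gen convention) and the instantaneous
#' rate ratio kappa are related by `kappa = 2 * R` under uniform base
#' frequencies, because each state has one transition partner but two
#' transversion partners.
#'
#' @param tstv expected-counts transition/transversion ratio R.
#' @param kappa instantaneous rate ratio.
#' @return the value in the other convention.
#' @export
tstv_to_kappa <- function(tstv) {
  if (any(tstv <= 0)) stop("'tstv' must be positive")
  2 * tstv
}

#' @rdname tstv_to_kappa
#' @export
kappa_to_tstv <- function(kappa) {
  if (any(kappa <= 0)) stop("'kappa' must be positive")
  kappa / 2
}

#' Discrete-Gamma category rates
#'
#' Equal-probability discretization of the Gamma(alpha, mean 1)
#' distribution into `k` categories. With `type = "mean"` (the default,
#' matching the discretization used by Seq-Gen and most ML programs) each
#' category is represented by its conditional mean, computed through the
#' regularized incomplete gamma function; `type = "median"` uses category
#' medians. Rates are renormalized to average exactly 1, absorbing
#' floating-point drift.
#'
#' @param alpha Gamma shape parameter (> 0).
#' @param k number of categories (>= 1).
#' @param type `"mean"` or `"median"` category representatives.
#' @return a vector of `k` increasing positive rates with mean 1.
#' @examples
#' discrete_gamma_rates(0.5, 4)
#' @export
discrete_gamma_rates <- function(alpha, k = 4, type = c("mean", "median")) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("'alpha' must be a single positive number")
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop("'k' must be a positive integer")
  type <- match.arg(type)
  k <- as.integer(k)
  if (type == "mean") {
    b <- qgamma(seq(0, 1, length.out = k + 1L), shape = alpha, rate = alpha)
    r <- k * diff(pgamma(b, shape = alpha + 1, rate = alpha))
  } else {
    r <- qgamma((seq_len(k) - 0.5) / k, shape = alpha, rate = alpha)
  }
  r / mean(r)
}

#' Invariable-sites plus discrete-Gamma rate mixture
#'
#' The (k+1)-category site-rate mixture: category 0 has rate 0 and weight
#' `p_inv`; categories 1..k carry the discrete-Gamma rates with equal
#' weights `(1 - p_inv) / k`. The Gamma rates are divided by `1 - p_inv`
#' so the mixture mean rate is exactly 1 *including* the invariable
#' category; branch lengths therefore remain expected substitutions per
#' site averaged over all sites, which makes estimated tree lengths
#' directly comparable to generating tree lengths.
#'
#' @param alpha Gamma shape parameter (> 0).
#' @param p_inv proportion of invariable sites, in `[0, 1)`.
#' @param k number of Gamma categories (default 4).
#' @param type discretization type, see [discrete_gamma_rates()].
#' @return an object of class `rate_mixture` with fields `alpha`, `p_inv`,
#'   `k`, `rates` (length k+1, first entry 0) and `weights` (length k+1,
#'   summing to 1, with `sum(weights * rates) == 1`).
#' @examples
#' mix <- rate_mixture(0.5, 0.5)
#' sum(mix$weights * mix$rates)  # 1
#' @export
rate_mixture <- function(alpha, p_inv = 0, k = 4, type = c("mean", "median")) {
  if (!is.numeric(p_inv) || length(p_inv) != 1L || p_inv < 0 || p_inv >= 1)
    stop("'p_inv' must lie in [0, 1)")
  type <- match.arg(type)
  rv <- discrete_gamma_rates(alpha, k, type) / (1 - p_inv)
  structure(
    list(alpha = alpha, p_inv = p_inv, k = as.integer(k),
         rates = c(0, rv),
         weights = c(p_inv, rep((1 - p_inv) / k, k)),
         type = type),
    class = "rate_mixture"
  )
}

#' @export
print.rate_mixture <- function(x, ...) {
  cat(sprintf("I+G rate mixture: alpha = %.4g, p_inv = %.4g, k = %d (%s rates)\n",
              x$alpha, x$p_inv, x$k, x$type))
  cat("rates:  ", paste(signif(x$rates, 5), collapse = " "), "\n")
  cat("weights:", paste(signif(x$weights, 5), collapse = " "), "\n")
  invisible(x)
}
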