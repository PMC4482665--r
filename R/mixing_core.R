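#' Diet proportion vector
#'
#' Validates and normalizes a vector of proportional source contributions on
#' the simplex (all entries non-negative, summing to one).
#'
#' @param p Numeric vector of proportions.
#' @param tol Maximum allowed deviation of \code{sum(p)} from 1 before an
#'   error is raised; within tolerance the vector is renormalized exactly.
#' @return Numeric vector summing to 1.
#' @export
diet_proportions <- function(p, tol = 1e-6) {
  if (any(!is.finite(p))) stop("non-finite proportions")
  if (any(p < -tol)) stop("negative proportions")
  p <- pmax(p, 0)
  s <- sum(p)
  if (abs(s - 1) > tol) stop("proportions sum to ", format(s), ", not 1")
  p / s
}

#' Dirichlet prior specification
#'
#' The default prior on diet proportions is the uniform Dirichlet (all alpha
#' equal to 1), flat over compositions. An alternative places independent
#' Uniform(0, \code{hyper_upper}) hyperpriors on each concentration parameter
#' and samples alpha jointly with the proportions.
#'
#' @param form "dirichlet" (fixed alpha) or "dirichlet_uniform_hyper".
#' @param alpha Concentration parameter(s) for the fixed form; scalar values
#'   are recycled across components. Default 1.
#' @param hyper_upper Upper bound of the uniform hyperprior. Default 100.
#' @return An object of class \code{prior_spec}.
#' @export
prior_spec <- function(form = c("dirichlet", "dirichlet_uniform_hyper"),
                       alpha = 1, hyper_upper = 100) {
  form <- match.arg(form)
  if (any(alpha <= 0)) stop("alpha must be positive")
  if (hyper_upper <= 0) stop("hyper_upper must be positive")
  structure(list(form = form, alpha = alpha, hyper_upper = hyper_upper),
            class = "prior_spec")
}

#' Mixture mean per tracer
#'
#' The expected biomarker value of a consumer whose diet is the convex
#' combination \code{p} of the library's source groups:
#' u_j = sum_i p_i (m_ji + f_ji), where m is the library mean and f the mean
#' trophic fractionation (broadcast across groups when given per tracer).
#'
#' @param p Diet proportions over the library's groups.
#' @param lib A \code{source_library}.
#' @param frac A \code{fractionation_spec}, or NULL for none.
#' @return Named numeric vector, one mean per tracer.
#' @export
mixture_mean <- function(p, lib, frac = NULL) {
  p <- diet_proportions(p)
  if (length(p) != length(lib$groups))
    stop("length of p does not match number of source groups")
  fm <- .frac_matrices(frac, lib)
  drop((lib$mean + fm$f) %*% p)
}

#' Mixture variance per tracer
#'
#' sigma_j^2 = sum_i p_i^2 (s_ji^2 + g_ji^2): variance of the mixture given
#' source signature SDs s and fractionation SDs g. Because the weights enter
#' squared, the mixture variance at interior diets is smaller than the
#' weighted average of the per-source variances. A small variance floor keeps
#' the likelihood finite when source uncertainty is scaled to near zero.
#'
#' @inheritParams mixture_mean
#' @param var_floor Added to every tracer variance. Default 1e-12.
#' @return Named numeric vector of variances.
#' @export
mixture_variance <- function(p, lib, frac = NULL, var_floor = 1e-12) {
  p <- diet_proportions(p)
  if (length(p) != length(lib$groups))
    stop("length of p does not match number of source groups")
  fm <- .frac_matrices(frac, lib)
  drop((lib$sd^2 + fm$g^2) %*% p^2) + var_floor
}

#' Gaussian log-likelihood of one consumer
#'
#' Tracers are treated as independent: the log-likelihood is the sum over
#' tracers of normal densities with the mixture mean and mixture SD. The
#' normality of the mixture follows from the Central Limit Theorem for linear
#' combinations of source signatures; for fatty-acid proportions the
#' approximation improves as more FAs enter the sum.
#'
#' @param x Named numeric vector of one consumer's tracer values (library
#'   tracer order, or named so it can be reordered).
#' @inheritParams mixture_variance
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(x, p, lib, frac = NULL, var_floor = 1e-12) {
  if (any(!is.finite(x))) stop("non-finite consumer values")
  if (!is.null(names(x))) {
    miss <- setdiff(lib$tracers$names, names(x))
    if (length(miss))
      stop("consumer is missing tracer(s): ", paste(miss, collapse = ", "))
    x <- x[lib$tracers$names]
  } else if (length(x) != length(lib$tracers$names)) {
    stop("consumer length does not match tracer count")
  }
  u <- mixture_mean(p, lib, frac)
  v <- mixture_variance(p, lib, frac, var_floor)
  sum(stats::dnorm(x, u, sqrt(v), log = TRUE))
}

#' Log prior density of diet proportions
#'
#' For the fixed Dirichlet form, the Dirichlet log density at \code{p}. For
#' the uniform-hyperparameter form the density is evaluated jointly with a
#' supplied alpha draw: Dirichlet(p; alpha) plus the uniform log density of
#' alpha on (0, hyper_upper)^K.
#'
#' @param p Diet proportions.
#' @param spec A \code{prior_spec}.
#' @param alpha Sampled concentration vector, required for the
#'   hyperparameter form.
#' @return Scalar log prior density.
#' @export
log_prior <- function(p, spec = prior_spec(), alpha = NULL) {
  p <- diet_proportions(p)
  K <- length(p)
  if (spec$form == "dirichlet") {
    a <- rep_len(spec$alpha, K)
    .ldirichlet(p, a)
  } else {
    if (is.null(alpha)) stop("alpha draw required for the hyperprior form")
    if (any(alpha <= 0) || any(alpha > spec$hyper_upper))
      return(-Inf)
    .ldirichlet(p, alpha) - K * log(spec$hyper_upper)
  }
}

.ldirichlet <- function(p, a) {
  # boundary zeros are admissible only for a_i = 1 (density constant there)
  lp <- ifelse(p > 0, log(p), ifelse(a == 1, 0, -Inf))
  lgamma(sum(a)) - sum(lgamma(a)) + sum((a - 1) * lp)
}

# Additive log-ratio transform and inverse, last component as reference.
.alr <- function(p) {
  K <- length(p)
  log(pmax(p[-K], 1e-300)) - log(max(p[K], 1e-300))
}

.alr_inv <- function(theta) {
  e <- exp(c(theta, 0) - max(c(theta, 0)))
  e / sum(e)
}
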