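#' MCMC configuration
#'
#' Settings for posterior sampling. The default profile matches the protocol
#' used throughout the package's simulation studies: 100,000 iterations per
#' chain with a 50,000-iteration burn-in and a thinning rate of 50, on two
#' chains. The "fast" profile (10,000 / 5,000 / thin 5) is intended for
#' pipelines and retains the same oracle-checked accuracy on small problems.
#'
#' @param iterations Iterations per chain.
#' @param burn_in Burn-in iterations discarded per chain (must be smaller than
#'   \code{iterations}).
#' @param thin Keep every \code{thin}-th post-burn-in draw.
#' @param chains Number of independent chains. Default 2.
#' @param seed Integer seed; identical configurations give identical draws.
#' @param prior A \code{\link{prior_spec}}.
#' @param target_accept Acceptance rate targeted by step-size adaptation.
#' @param var_floor Variance floor passed to the likelihood.
#' @param init "grid" (coarse simplex search for a starting point, then
#'   per-chain jitter) or "uniform" (start at equal proportions).
#' @param use_likelihood Set FALSE to sample from the prior alone (used for
#'   prior-recovery checks).
#' @param profile Optional shortcut: "full" (the defaults above) or "fast".
#' @return An object of class \code{mcmc_config}.
#' @export
mcmc_config <- function(iterations = 100000, burn_in = 50000, thin = 50,
                        chains = 2, seed = 1L, prior = prior_spec(),
                        target_accept = 0.3, var_floor = 1e-12,
                        init = c("grid", "uniform"), use_likelihood = TRUE,
                        profile = NULL) {
  init <- match.arg(init)
  if (!is.null(profile)) {
    profile <- match.arg(profile, c("full", "fast"))
    if (profile == "fast") {
      iterations <- 10000; burn_in <- 5000; thin <- 5
    }
  }
  if (burn_in >= iterations) stop("burn_in must be smaller than iterations")
  if (thin < 1) stop("thin must be >= 1")
  if (chains < 1) stop("at least one chain required")
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 chains = as.integer(chains), seed = as.integer(seed),
                 prior = prior, target_accept = target_accept,
                 var_floor = var_floor, init = init,
                 use_likelihood = use_likelihood),
            class = "mcmc_config")
}

# One adaptive random-walk Metropolis chain. lp must accept a state vector
# and return the log target density. Step size follows a Robbins-Monro
# schedule toward target_accept during burn-in; the proposal covariance is
# refreshed periodically from the burn-in history (frozen afterwards).
.run_chain <- function(lp, state0, n_iter, burn_in, thin, target_accept) {
  d <- length(state0)
  s <- 2.38 / sqrt(d)
  L <- diag(d)
  cur <- state0
  lcur <- lp(cur)
  if (!is.finite(lcur)) stop("non-finite log posterior at the initial state")
  n_keep <- (n_iter - burn_in) %/% thin
  kept <- matrix(NA_real_, n_keep, d)
  hist <- matrix(NA_real_, burn_in, d)
  k <- 0L
  n_acc <- 0L
  for (i in seq_len(n_iter)) {
    prop <- cur + s * drop(L %*% stats::rnorm(d))
    lprop <- lp(prop)
    a <- if (is.finite(lprop)) exp(min(0, lprop - lcur)) else 0
    if (stats::runif(1) < a) {
      cur <- prop; lcur <- lprop; n_acc <- n_acc + 1L
    }
    if (i <= burn_in) {
      hist[i, ] <- cur
      s <- s * exp(min(0.25, i^-0.6) * (a - target_accept))
      if (i %% 500L == 0L && i >= 1000L) {
        C <- stats::cov(hist[(i %/% 2):i, , drop = FALSE])
        ch <- tryCatch(chol(C + diag(1e-10, d)), error = function(e) NULL)
        if (!is.null(ch)) L <- t(ch)
      }
    } else if ((i - burn_in) %% thin == 0L) {
      k <- k + 1L
      kept[k, ] <- cur
    }
  }
  list(draws = kept[seq_len(k), , drop = FALSE],
       accept_rate = n_acc / n_iter, step = s)
}

# Build the log-posterior closure for one consumer. State layout: the first
# K-1 entries are additive log-ratio coordinates of p; under the uniform
# hyperprior, K further entries hold the Dirichlet concentration vector.
.make_logpost <- function(x, lib, frac, cfg) {
  fm <- .frac_matrices(frac, lib)
  M <- lib$mean + fm$f
  V <- lib$sd^2 + fm$g^2
  J <- nrow(M); K <- ncol(M)
  floor_ <- cfg$var_floor
  use_lik <- cfg$use_likelihood
  xv <- as.numeric(x)
  prior <- cfg$prior
  hyper <- prior$form == "dirichlet_uniform_hyper"
  a_fix <- rep_len(prior$alpha, K)
  const <- -J / 2 * log(2 * pi)
  function(state) {
    th <- state[seq_len(K - 1L)]
    if (any(abs(th) > 500)) return(-Inf)
    e <- exp(c(th, 0))
    p <- e / sum(e)
    lp <- sum(log(p))                       # alr Jacobian
    if (hyper) {
      al <- state[K:(2 * K - 1L)]
      if (any(al <= 0) || any(al > prior$hyper_upper)) return(-Inf)
      a <- al
    } else {
      a <- a_fix
    }
    lp <- lp + lgamma(sum(a)) - sum(lgamma(a)) + sum((a - 1) * log(p))
    if (use_lik) {
      u <- drop(M %*% p)
      v <- drop(V %*% (p * p)) + floor_
      r <- xv - u
      lp <- lp + const - 0.5 * sum(r * r / v + log(v))
    }
    lp
  }
}

# Coarse simplex search for a high-density starting composition.
.grid_init <- function(lp_fun, K, step = 0.02) {
  P <- .simplex_grid(K, step)
  best <- -Inf; pbest <- rep(1 / K, K)
  for (i in seq_len(nrow(P))) {
    p <- (P[i, ] + 1e-3) / (1 + K * 1e-3)
    v <- lp_fun(.alr(p))
    if (is.finite(v) && v > best) { best <- v; pbest <- p }
  }
  .alr(pbest)
}

# Lattice of compositions with spacing `step` (cell centers).
.simplex_grid <- function(K, step) {
  g <- seq(step / 2, 1 - step / 2, by = step)
  if (K == 2) {
    cbind(g, 1 - g)
  } else if (K == 3) {
    E <- as.matrix(expand.grid(p1 = g, p2 = g))
    E <- E[rowSums(E) < 1, , drop = FALSE]
    cbind(E, 1 - rowSums(E))
  } else if (K == 4) {
    E <- as.matrix(expand.grid(p1 = g, p2 = g, p3 = g))
    E <- E[rowSums(E) < 1, , drop = FALSE]
    cbind(E, 1 - rowSums(E))
  } else {
    stop("simplex grids are limited to at most 4 source groups")
  }
}

#' Fit the mixing model to one consumer
#'
#' Samples the posterior over diet proportions, proportional to the Gaussian
#' mixture likelihood times the Dirichlet prior, with an adaptive random-walk
#' Metropolis sampler on additive log-ratio coordinates (the log-ratio
#' Jacobian is included, so draws target the stated density on the simplex).
#'
#' @param x Named numeric vector of one consumer's tracer values.
#' @param lib A \code{source_library}.
#' @param frac A \code{fractionation_spec} or NULL.
#' @param cfg An \code{\link{mcmc_config}}.
#' @param consumer_id Optional identifier stored with the result.
#' @return An object of class \code{diet_posterior}: \code{draws} (matrix of
#'   retained compositions, one column per group), \code{diagnostics}
#'   (split-chain potential scale reduction and effective sample size per
#'   group; components with Rhat above 1.05 are flagged, not fatal),
#'   \code{accept_rate}, \code{consumer_id}.
#' @export
fit_consumer <- function(x, lib, frac = NULL, cfg = mcmc_config(),
                         consumer_id = NULL) {
  if (cfg$use_likelihood) {
    if (!is.null(names(x))) {
      miss <- setdiff(lib$tracers$names, names(x))
      if (length(miss))
        stop("consumer is missing tracer(s): ", paste(miss, collapse = ", "))
      x <- x[lib$tracers$names]
    } else if (length(x) != length(lib$tracers$names)) {
      stop("consumer length does not match the library tracer count")
    }
    if (any(!is.finite(x))) stop("non-finite consumer values")
  } else {
    x <- rep(0, length(lib$tracers$names))
  }
  K <- length(lib$groups)
  lp <- .make_logpost(x, lib, frac, cfg)
  hyper <- cfg$prior$form == "dirichlet_uniform_hyper"
  d <- (K - 1L) + if (hyper) K else 0L
  set.seed(cfg$seed)
  th0 <- if (cfg$init == "grid" && cfg$use_likelihood) {
    lp_th <- if (hyper) function(th) lp(c(th, rep(1, K))) else lp
    .grid_init(lp_th, K)
  } else {
    rep(0, K - 1L)
  }
  state0 <- c(th0, if (hyper) rep(1, K))
  chains <- vector("list", cfg$chains)
  for (ch in seq_len(cfg$chains)) {
    s0 <- state0
    s0[seq_len(K - 1L)] <- s0[seq_len(K - 1L)] +
      0.1 * stats::rnorm(K - 1L)
    chains[[ch]] <- .run_chain(lp, s0, cfg$iterations, cfg$burn_in,
                               cfg$thin, cfg$target_accept)
  }
  to_p <- function(th_mat) {
    P <- t(apply(th_mat[, seq_len(K - 1L), drop = FALSE], 1, .alr_inv))
    colnames(P) <- lib$groups
    P
  }
  p_chains <- lapply(chains, function(cc) to_p(cc$draws))
  draws <- do.call(rbind, p_chains)
  alpha_draws <- if (hyper) {
    do.call(rbind, lapply(chains, function(cc)
      cc$draws[, K:(2 * K - 1L), drop = FALSE]))
  } else NULL
  diag_df <- .mcmc_diagnostics(p_chains)
  structure(list(
    draws = draws,
    consumer_id = consumer_id,
    diagnostics = diag_df,
    accept_rate = mean(vapply(chains, function(cc) cc$accept_rate, 1)),
    alpha_draws = alpha_draws,
    groups = lib$groups,
    cfg = cfg
  ), class = "diet_posterior")
}

# Split-chain potential scale reduction and a Geyer-style effective sample
# size, per mixture component.
.mcmc_diagnostics <- function(p_chains) {
  K <- ncol(p_chains[[1]])
  halves <- list()
  for (pc in p_chains) {
    n <- nrow(pc)
    if (n >= 4) {
      halves <- c(halves, list(pc[1:(n %/% 2), , drop = FALSE],
                               pc[(n %/% 2 + 1):n, , drop = FALSE]))
    } else {
      halves <- c(halves, list(pc))
    }
  }
  rhat <- ess <- numeric(K)
  for (k in seq_len(K)) {
    seqs <- lapply(halves, function(h) h[, k])
    n <- min(lengths(seqs))
    seqs <- lapply(seqs, function(s) s[seq_len(n)])
    mns <- vapply(seqs, mean, 1)
    vars <- vapply(seqs, stats::var, 1)
    W <- mean(vars)
    B <- n * stats::var(mns)
    rhat[k] <- if (W > 1e-15) sqrt(((n - 1) / n * W + B / n) / W) else 1
    ess_k <- 0
    for (s in seqs) {
      if (stats::var(s) < 1e-15) { ess_k <- ess_k + length(s); next }
      ac <- stats::acf(s, lag.max = min(100, length(s) - 1), plot = FALSE,
                       demean = TRUE)$acf[-1]
      pos <- which(ac < 0.05)
      tau <- 1 + 2 * sum(ac[seq_len(if (length(pos)) pos[1] - 1 else length(ac))])
      ess_k <- ess_k + length(s) / max(tau, 1)
    }
    ess[k] <- ess_k
  }
  data.frame(group = colnames(p_chains[[1]]), rhat = rhat, ess = ess,
             flagged = rhat > 1.05, stringsAsFactors = FALSE)
}

#' Fit the mixing model to many consumers
#'
#' Each consumer is fitted independently with its own seed (base seed plus
#' consumer index), and the per-consumer posteriors are pooled by equal-weight
#' concatenation of draws. Pooling (rather than assuming a shared diet) keeps
#' the dispersion of the pooled posterior from collapsing as the number of
#' consumers grows.
#'
#' @param consumers Numeric matrix, one row per consumer, tracer columns.
#' @param lib A \code{source_library}.
#' @param frac A \code{fractionation_spec} or NULL.
#' @param cfg An \code{\link{mcmc_config}}; \code{cfg$seed} is the base seed.
#' @return List with \code{posteriors} (per-consumer \code{diet_posterior})
#'   and \code{pooled} (a \code{pooled_posterior}).
#' @export
fit_many <- function(consumers, lib, frac = NULL, cfg = mcmc_config()) {
  consumers <- as.matrix(consumers)
  if (nrow(consumers) < 1) stop("at least one consumer required")
  ids <- rownames(consumers) %||% as.character(seq_len(nrow(consumers)))
  posts <- vector("list", nrow(consumers))
  for (i in seq_len(nrow(consumers))) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i
    posts[[i]] <- tryCatch(
      fit_consumer(consumers[i, ], lib, frac, cfg_i, consumer_id = ids[i]),
      error = function(e) stop("consumer '", ids[i], "': ",
                               conditionMessage(e), call. = FALSE)
    )
  }
  list(posteriors = posts, pooled = pool_posteriors(posts))
}

#' Pool per-consumer posteriors
#'
#' Unweighted concatenation of per-consumer posterior draws; the pooled
#' distribution is the equal-weight mixture of the individual posteriors.
#'
#' @param posteriors List of \code{diet_posterior} objects over the same
#'   source groups.
#' @return An object of class \code{pooled_posterior}.
#' @export
pool_posteriors <- function(posteriors) {
  if (length(posteriors) == 0) stop("nothing to pool")
  groups <- posteriors[[1]]$groups
  for (p in posteriors) {
    if (!identical(p$groups, groups))
      stop("posteriors are defined over different source groups")
  }
  structure(list(
    draws = do.call(rbind, lapply(posteriors, function(p) p$draws)),
    n_consumers = length(posteriors),
    groups = groups
  ), class = "pooled_posterior")
}

#' Posterior summary table
#'
#' Median, 2.5th and 97.5th percentile (the 95 percent credible interval),
#' mean and SD of each source group's proportional contribution. Quantiles
#' use linear interpolation between order statistics.
#'
#' @param posterior A \code{diet_posterior} or \code{pooled_posterior}.
#' @param min_draws Minimum number of draws required. Default 100.
#' @return Data frame with one row per source group.
#' @export
posterior_summary <- function(posterior, min_draws = 100) {
  draws <- posterior$draws
  if (nrow(draws) < min_draws)
    stop("too few draws for a stable summary (", nrow(draws), " < ",
         min_draws, ")")
  q <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
             type = 7)
  data.frame(
    group = colnames(draws),
    median = q[2, ],
    q2.5 = q[1, ],
    q97.5 = q[3, ],
    mean = colMeans(draws),
    sd = apply(draws, 2, stats::sd),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' @export
print.diet_posterior <- function(x, ...) {
  cat(sprintf("<diet_posterior%s: %d draws>\n",
              if (!is.null(x$consumer_id)) paste0(" ", x$consumer_id) else "",
              nrow(x$draws)))
  print(posterior_summary(x), digits = 3)
  invisible(x)
}

#' @export
print.pooled_posterior <- function(x, ...) {
  cat(sprintf("<pooled_posterior: %d consumers, %d draws>\n",
              x$n_consumers, nrow(x$draws)))
  print(posterior_summary(x), digits = 3)
  invisible(x)
}

#' Binned posterior density curve
#'
#' Computes evenly spaced empirical quantiles of one component's draws (1000
#' quantiles, i.e. 1/10th-percentile steps, by default) and histograms them
#' into equal-width bins on [0, 1], normalized so the curve integrates to 1.
#' This is the standard display for pooled posteriors over many consumers.
#'
#' @param posterior A \code{diet_posterior} or \code{pooled_posterior}.
#' @param component Group name or column index.
#' @param n_quantiles Number of quantile points. Default 1000.
#' @param bins Number of bins on [0, 1]. Default 40.
#' @return Data frame with \code{bin_mid}, \code{count}, \code{density}.
#' @export
density_curve <- function(posterior, component = 1, n_quantiles = 1000,
                          bins = 40) {
  v <- posterior$draws[, component]
  probs <- (seq_len(n_quantiles) - 0.5) / n_quantiles
  q <- stats::quantile(v, probs = probs, type = 7, names = FALSE)
  breaks <- seq(0, 1, length.out = bins + 1)
  q <- pmin(pmax(q, 0), 1)
  idx <- pmin(findInterval(q, breaks, rightmost.closed = TRUE), bins)
  counts <- tabulate(idx, nbins = bins)
  width <- 1 / bins
  data.frame(
    bin_mid = (breaks[-1] + breaks[-(bins + 1)]) / 2,
    count = counts,
    density = counts / (n_quantiles * width)
  )
}

#' Grid-integration posterior (validation oracle)
#'
#' Evaluates likelihood times prior on a dense barycentric lattice of the
#' simplex and normalizes, giving a sampler-independent approximation of the
#' posterior for problems with up to 4 source groups. Used to validate the
#' MCMC sampler: marginal quantiles of both routes must agree.
#'
#' @param x Named numeric vector of one consumer's tracer values.
#' @param lib A \code{source_library} (at most 4 groups).
#' @param frac A \code{fractionation_spec} or NULL.
#' @param prior A fixed-form \code{\link{prior_spec}}.
#' @param grid_step Lattice spacing. Default 0.002 (use a coarser step for
#'   4 groups).
#' @param var_floor Variance floor. Default 1e-12.
#' @return An object of class \code{grid_posterior} with the lattice
#'   \code{P}, normalized weights \code{w}, and group names.
#' @export
oracle_posterior <- function(x, lib, frac = NULL, prior = prior_spec(),
                             grid_step = 0.002, var_floor = 1e-12) {
  K <- length(lib$groups)
  if (K > 4) stop("grid oracle refuses more than 4 source groups")
  if (prior$form != "dirichlet")
    stop("grid oracle supports the fixed Dirichlet prior only")
  if (!is.null(names(x))) x <- x[lib$tracers$names]
  fm <- .frac_matrices(frac, lib)
  M <- lib$mean + fm$f
  V <- lib$sd^2 + fm$g^2
  P <- .simplex_grid(K, grid_step)
  U <- P %*% t(M)
  S2 <- (P * P) %*% t(V) + var_floor
  X <- matrix(as.numeric(x), nrow(P), length(x), byrow = TRUE)
  ll <- rowSums(stats::dnorm(X, U, sqrt(S2), log = TRUE))
  a <- rep_len(prior$alpha, K)
  lpr <- drop(log(P) %*% (a - 1))
  lp <- ll + lpr
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  structure(list(P = P, w = w, groups = lib$groups, grid_step = grid_step),
            class = "grid_posterior")
}

#' Marginal quantiles from a grid posterior
#'
#' @param oracle A \code{grid_posterior}.
#' @param component Group name or column index.
#' @param probs Probabilities. Default the summary set
#'   c(0.025, 0.25, 0.5, 0.75, 0.975).
#' @return Named numeric vector of quantiles.
#' @export
oracle_quantiles <- function(oracle, component = 1,
                             probs = c(0.025, 0.25, 0.5, 0.75, 0.975)) {
  pk <- if (is.character(component))
    oracle$P[, match(component, oracle$groups)] else oracle$P[, component]
  ord <- order(pk)
  cw <- cumsum(oracle$w[ord])
  q <- stats::approx(cw, pk[ord], xout = probs, rule = 2, ties = "ordered")$y
  stats::setNames(q, paste0(probs * 100, "%"))
}

#' Export posterior draws and summary to files
#'
#' Writes the draws as CSV (one row per draw, one column per group) and the
#' summary with diagnostics as JSON.
#'
#' @param posterior A \code{diet_posterior} or \code{pooled_posterior}.
#' @param draws_csv Path for the draws CSV, or NULL to skip.
#' @param summary_json Path for the JSON summary, or NULL to skip.
#' @return Invisibly, the summary data frame.
#' @export
export_posterior <- function(posterior, draws_csv = NULL,
                             summary_json = NULL) {
  smry <- posterior_summary(posterior)
  if (!is.null(draws_csv)) {
    utils::write.csv(as.data.frame(posterior$draws), draws_csv,
                     row.names = FALSE)
  }
  if (!is.null(summary_json)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("jsonlite is required for JSON export")
    payload <- list(summary = smry)
    if (!is.null(posterior$diagnostics))
      payload$diagnostics <- posterior$diagnostics
    jsonlite::write_json(payload, summary_json, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(smry)
}
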