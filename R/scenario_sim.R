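#' Scenario specification
#'
#' Describes one pseudo-consumer experiment: the true diet, the number of
#' simulated consumers and the batch size they are processed in, the scaling
#' applied to resource (library) SDs before fitting, whether consumers carry
#' simulation noise or are exact mixtures, and an optional fixed fractionation
#' offset (in SD units per tracer) applied when generating consumers.
#'
#' @param weights True diet proportions (named by group where possible).
#' @param n_consumers Number of pseudo-consumers. Default 1000.
#' @param group_size Batch size for batch-level summaries. Default 100.
#' @param seed Simulation seed.
#' @param resource_sd_scale Multiplier applied to library SDs before fitting,
#'   in (0, 1]. Default 1; 0.01 gives the "virtually no resource uncertainty"
#'   condition.
#' @param consumer_noise TRUE to simulate consumers with full source and
#'   fractionation noise; FALSE for a single exact mixture consumer.
#' @param fractionation_sd_scale Multiplier applied to the model-side
#'   fractionation SDs before fitting, or NULL (the default) to reuse
#'   \code{resource_sd_scale}: a minimized-uncertainty condition minimizes
#'   all model-side uncertainty, fractionation included.
#' @param fractionation_offset Numeric vector of per-tracer offsets in units
#'   of the fractionation SD (e.g. c(1.96, -1.96)), or NULL for none.
#' @return An object of class \code{scenario_spec}.
#' @export
scenario_spec <- function(weights, n_consumers = 1000, group_size = 100,
                          seed = 1L, resource_sd_scale = 1,
                          consumer_noise = TRUE,
                          fractionation_sd_scale = NULL,
                          fractionation_offset = NULL) {
  weights <- diet_proportions(weights)
  if (resource_sd_scale <= 0 || resource_sd_scale > 1)
    stop("resource_sd_scale must be in (0, 1]")
  if (n_consumers < 1) stop("n_consumers must be positive")
  structure(list(weights = weights, n_consumers = as.integer(n_consumers),
                 group_size = as.integer(group_size), seed = as.integer(seed),
                 resource_sd_scale = resource_sd_scale,
                 consumer_noise = isTRUE(consumer_noise),
                 fractionation_sd_scale = fractionation_sd_scale %||%
                   resource_sd_scale,
                 fractionation_offset = fractionation_offset),
            class = "scenario_spec")
}

#' Simulate stable-isotope consumers on a pure diet
#'
#' Each pseudo-consumer's tracer value is one draw from the source group's
#' signature distribution plus one trophic fractionation draw:
#' x_j = Normal(m_j, s_j) + Normal(f_j, g_j). Fractionation is drawn once per
#' consumer per tracer (consumer-level), so the expected SD of a pure-diet
#' consumer is sqrt(s_j^2 + g_j^2).
#'
#' @param group Source group name.
#' @param lib A \code{source_library}.
#' @param frac A \code{fractionation_spec} or NULL.
#' @param n Number of consumers.
#' @param seed Seed.
#' @return Matrix, one row per consumer, tracer columns.
#' @export
simulate_pure_si <- function(group, lib, frac = NULL, n = 1000, seed = 1L) {
  if (!group %in% lib$groups) stop("unknown group: ", group)
  w <- stats::setNames(as.numeric(lib$groups == group), lib$groups)
  simulate_mixed_si(w, lib, frac, n, seed)
}

#' Simulate stable-isotope consumers on a mixed diet
#'
#' Per consumer, each source group's tracer vector is drawn from
#' Normal(m, s), the draws are combined with the diet weights, and a single
#' Normal(f, g) fractionation draw per tracer is added. The resulting
#' per-tracer variance is sum_i w_i^2 s_i^2 + g^2.
#'
#' @param weights Diet proportions over the library's groups.
#' @inheritParams simulate_pure_si
#' @param fractionation_offset Optional per-tracer shift in units of g,
#'   applied as a fixed offset f + offset * g with the random fractionation
#'   term suppressed (used by the fractionation sensitivity design).
#' @return Matrix, one row per consumer, tracer columns.
#' @export
simulate_mixed_si <- function(weights, lib, frac = NULL, n = 1000, seed = 1L,
                              fractionation_offset = NULL) {
  weights <- diet_proportions(weights)
  K <- length(lib$groups); J <- length(lib$tracers$names)
  if (length(weights) != K) stop("weights length does not match group count")
  fm <- .frac_matrices(frac, lib)
  f_vec <- rowMeans(fm$f)   # consumer-level fractionation: one draw per tracer
  g_vec <- rowMeans(fm$g)
  set.seed(seed)
  x <- matrix(0, n, J, dimnames = list(NULL, lib$tracers$names))
  for (i in seq_len(K)) {
    if (weights[i] == 0) next
    src <- matrix(stats::rnorm(n * J, rep(lib$mean[, i], each = n),
                               rep(lib$sd[, i], each = n)), n, J)
    x <- x + weights[i] * src
  }
  if (is.null(fractionation_offset)) {
    x <- x + matrix(stats::rnorm(n * J, rep(f_vec, each = n),
                                 rep(g_vec, each = n)), n, J)
  } else {
    if (length(fractionation_offset) != J)
      stop("fractionation_offset length does not match tracer count")
    shift <- f_vec + fractionation_offset * g_vec
    x <- x + matrix(shift, n, J, byrow = TRUE)
  }
  x
}

#' Simulate fatty-acid consumers on a mixed diet by profile resampling
#'
#' Per consumer, one individual feeding-trial profile is sampled uniformly
#' with replacement from each source group's raw profiles, and the sampled
#' profiles are combined as the weights-weighted sum. Because the combination
#' is convex, simulated consumers stay inside the convex hull of the library
#' profiles and closed profiles stay closed.
#'
#' @param weights Diet proportions over the groups.
#' @param lib A \code{source_library} with \code{raw_profiles}, or a named
#'   list of per-group profile matrices (rows = individuals).
#' @param n Number of consumers.
#' @param seed Seed.
#' @return Matrix, one row per consumer, tracer columns.
#' @export
simulate_mixed_fa <- function(weights, lib, n = 1000, seed = 1L) {
  if (inherits(lib, "source_library")) {
    if (is.null(lib$raw_profiles))
      stop("library carries no raw profiles to resample")
    labs <- vapply(lib$raw_profiles, function(p) p$label, character(1))
    groups <- lib$groups
    mats <- lapply(groups, function(g) {
      do.call(rbind, lapply(lib$raw_profiles[labs == g],
                            function(p) p$values))
    })
    names(mats) <- groups
  } else {
    mats <- lib
    groups <- names(mats)
  }
  weights <- diet_proportions(weights)
  if (length(weights) != length(groups))
    stop("weights length does not match group count")
  for (g in groups) {
    if (is.null(mats[[g]]) || nrow(mats[[g]]) == 0)
      stop("group '", g, "' has no profiles")
  }
  J <- ncol(mats[[1]])
  set.seed(seed)
  x <- matrix(0, n, J, dimnames = list(NULL, colnames(mats[[1]])))
  for (i in seq_along(groups)) {
    if (weights[i] == 0) next
    idx <- sample.int(nrow(mats[[i]]), n, replace = TRUE)
    x <- x + weights[i] * mats[[i]][idx, , drop = FALSE]
  }
  x
}

#' Exact (noise-free) mixture consumer
#'
#' The deterministic biomarker profile of a consumer whose diet is exactly
#' \code{weights}: the mixture mean with zero uncertainty.
#'
#' @inheritParams mixture_mean
#' @param weights Diet proportions.
#' @return Named numeric vector of tracer values.
#' @export
exact_mixture_consumer <- function(weights, lib, frac = NULL) {
  mixture_mean(weights, lib, frac)
}

#' Scale library uncertainty
#'
#' Multiplies every SD in the library by \code{factor}, leaving means
#' untouched. \code{factor = 0.01} produces the near-zero resource
#' uncertainty condition used in sensitivity designs (the model does not
#' admit exactly zero source variance).
#'
#' @param lib A \code{source_library}.
#' @param factor Positive multiplier.
#' @return A new \code{source_library}.
#' @export
scale_library_uncertainty <- function(lib, factor) {
  if (factor <= 0) stop("factor must be positive")
  source_library(lib$mean, lib$sd * factor, lib$tracers$kind,
                 raw_profiles = lib$raw_profiles)
}

# Fit a batch of consumers and package pooled + per-batch summaries.
.fit_scenario <- function(consumers, lib, frac, cfg, group_size, label,
                          spec = NULL) {
  fits <- fit_many(consumers, lib, frac, cfg)
  n <- length(fits$posteriors)
  batches <- split(seq_len(n), ceiling(seq_len(n) / group_size))
  batch_summaries <- lapply(batches, function(idx)
    posterior_summary(pool_posteriors(fits$posteriors[idx])))
  structure(list(
    label = label,
    summary = posterior_summary(fits$pooled),
    batch_summaries = batch_summaries,
    pooled = fits$pooled,
    spec = spec
  ), class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result:", x$label, ">\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Run one pseudo-consumer scenario end to end
#'
#' Generates consumers according to the specification (noisy simulation or an
#' exact mixture; optional fixed fractionation offset), fits every consumer
#' against the (possibly SD-scaled) library, and returns pooled and per-batch
#' summaries.
#'
#' @param spec A \code{\link{scenario_spec}}.
#' @param lib A \code{source_library}.
#' @param frac A \code{fractionation_spec} or NULL.
#' @param cfg An \code{\link{mcmc_config}}.
#' @return A \code{scenario_result}.
#' @export
run_scenario <- function(spec, lib, frac = NULL, cfg = mcmc_config()) {
  fm <- .frac_matrices(frac, lib)
  offset <- spec$fractionation_offset
  if (spec$consumer_noise) {
    consumers <- if (lib$tracers$kind == "si_delta") {
      simulate_mixed_si(spec$weights, lib, frac, spec$n_consumers, spec$seed,
                        fractionation_offset = offset)
    } else {
      simulate_mixed_fa(spec$weights, lib, spec$n_consumers, spec$seed)
    }
  } else {
    x <- exact_mixture_consumer(spec$weights, lib,
                                fractionation_spec(rowMeans(fm$f),
                                                   rowMeans(fm$g) * 0))
    if (!is.null(offset)) x <- x + offset * rowMeans(fm$g)
    consumers <- matrix(x, 1, length(x),
                        dimnames = list("exact", names(x)))
  }
  fit_lib <- if (spec$resource_sd_scale != 1)
    scale_library_uncertainty(lib, spec$resource_sd_scale) else lib
  fit_frac <- frac
  if (!is.null(frac) && spec$fractionation_sd_scale != 1) {
    fit_frac <- fractionation_spec(frac$mean,
                                   frac$sd * spec$fractionation_sd_scale)
  }
  .fit_scenario(consumers, fit_lib, fit_frac, cfg, spec$group_size,
                label = sprintf("weights=%s sd_scale=%g noise=%s",
                                paste(round(spec$weights, 3), collapse = "/"),
                                spec$resource_sd_scale, spec$consumer_noise),
                spec = spec)
}

#' Resource-by-consumer uncertainty sensitivity design
#'
#' Runs the 2 x 2 design crossing resource uncertainty (library SDs at full
#' scale, or divided by 100) with consumer uncertainty (consumers simulated
#' with full noise, or a single exact mixture consumer). Simulated consumers
#' always carry the full fractionation noise; on the model side the
#' fractionation SDs are scaled together with the resource SDs in the
#' low-uncertainty cells (a minimized condition minimizes all model-side
#' uncertainty), unless \code{scale_fractionation_sd = FALSE}.
#'
#' @param weights True diet proportions.
#' @param lib A \code{source_library}.
#' @param frac A \code{fractionation_spec} or NULL.
#' @param cfg An \code{\link{mcmc_config}}.
#' @param n_consumers Consumers per noisy cell. Default 1000.
#' @param group_size Batch size. Default 100.
#' @param seed Simulation seed. Default \code{cfg$seed}.
#' @param sd_scale Scale for the low-uncertainty cells. Default 0.01.
#' @param scale_fractionation_sd Scale model-side fractionation SDs together
#'   with the resource SDs. Default TRUE.
#' @return Named list of four \code{scenario_result}s:
#'   \code{resource100_consumer100}, \code{resource100_consumer0},
#'   \code{resource0_consumer100}, \code{resource0_consumer0}.
#' @export
run_uncertainty_matrix <- function(weights, lib, frac = NULL,
                                   cfg = mcmc_config(), n_consumers = 1000,
                                   group_size = 100, seed = cfg$seed,
                                   sd_scale = 0.01,
                                   scale_fractionation_sd = TRUE) {
  cells <- list(
    resource100_consumer100 = c(scale = 1, noise = TRUE),
    resource100_consumer0 = c(scale = 1, noise = FALSE),
    resource0_consumer100 = c(scale = sd_scale, noise = TRUE),
    resource0_consumer0 = c(scale = sd_scale, noise = FALSE)
  )
  out <- vector("list", length(cells))
  names(out) <- names(cells)
  for (nm in names(cells)) {
    sp <- scenario_spec(weights,
                        n_consumers = if (cells[[nm]][["noise"]]) n_consumers else 1,
                        group_size = group_size, seed = seed,
                        resource_sd_scale = cells[[nm]][["scale"]],
                        consumer_noise = as.logical(cells[[nm]][["noise"]]),
                        fractionation_sd_scale =
                          if (scale_fractionation_sd) NULL else 1)
    out[[nm]] <- run_scenario(sp, lib, frac, cfg)
    out[[nm]]$label <- nm
  }
  out
}

#' Fractionation-assumption sensitivity grid
#'
#' Quantifies how strongly the trophic fractionation assumption drives
#' stable-isotope outputs when every other source of uncertainty is
#' minimized. Resource SDs are divided by 100 and the consumer is the exact
#' mixture; the consumer is then generated with its fractionation shifted by
#' a fixed offset of +/- 1.96 fractionation SDs per tracer (a 95 percent
#' confidence excursion) while the fitted model keeps assuming the mean
#' fractionation with zero fractionation variance. Five cells are run: the
#' mean-fractionation reference and the four sign combinations for the two
#' isotopes. With \code{shift_model = TRUE} the convention is inverted (the
#' model's assumed fractionation is shifted, consumers stay at the mean);
#' the two conventions give mirrored cells.
#'
#' @param weights True diet proportions.
#' @param lib A \code{source_library} (stable isotope kind).
#' @param frac A \code{fractionation_spec} with non-zero SDs.
#' @param cfg An \code{\link{mcmc_config}}.
#' @param z Offset magnitude in SD units. Default 1.96.
#' @param sd_scale Resource SD scale. Default 0.01.
#' @param shift_model Invert the shift convention. Default FALSE.
#' @return List with \code{results} (named list of \code{scenario_result})
#'   and \code{table} (long-form data frame: cell, group, median, mean, sd).
#' @export
run_fractionation_grid <- function(weights, lib, frac, cfg = mcmc_config(),
                                   z = 1.96, sd_scale = 0.01,
                                   shift_model = FALSE) {
  if (lib$tracers$kind != "si_delta")
    stop("the fractionation grid applies to stable-isotope libraries")
  fm <- .frac_matrices(frac, lib)
  g_vec <- rowMeans(fm$g)
  f_vec <- rowMeans(fm$f)
  if (all(g_vec == 0))
    stop("fractionation SDs are all zero; the grid is meaningless")
  J <- length(g_vec)
  if (J != 2)
    stop("the +/- grid is defined for two tracers (carbon and nitrogen)")
  offs <- list(`C mean / N mean` = c(0, 0),
               `C +1.96 / N +1.96` = c(z, z),
               `C +1.96 / N -1.96` = c(z, -z),
               `C -1.96 / N +1.96` = c(-z, z),
               `C -1.96 / N -1.96` = c(-z, -z))
  names(offs) <- sub("1\\.96", format(z), names(offs))
  fit_lib <- scale_library_uncertainty(lib, sd_scale)
  fit_frac <- fractionation_spec(f_vec, g_vec * 0)  # fixed-shift design: g = 0
  results <- vector("list", length(offs))
  names(results) <- names(offs)
  for (nm in names(offs)) {
    off <- offs[[nm]]
    if (shift_model) {
      x <- exact_mixture_consumer(weights, lib, fractionation_spec(f_vec, g_vec * 0))
      cell_frac <- fractionation_spec(f_vec + off * g_vec, g_vec * 0)
    } else {
      x <- exact_mixture_consumer(weights, lib, fractionation_spec(f_vec, g_vec * 0)) +
        off * g_vec
      cell_frac <- fit_frac
    }
    consumers <- matrix(x, 1, length(x), dimnames = list("exact", names(x)))
    results[[nm]] <- .fit_scenario(consumers, fit_lib, cell_frac, cfg,
                                   group_size = 1, label = nm)
  }
  tab <- do.call(rbind, lapply(names(results), function(nm) {
    s <- results[[nm]]$summary
    data.frame(cell = nm, group = s$group, median = s$median,
               mean = s$mean, sd = s$sd, stringsAsFactors = FALSE)
  }))
  list(results = results, table = tab)
}
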