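test_that("sampling is reproducible for a fixed seed and configuration", {
  si <- si_fixture()
  x <- exact_mixture_consumer(c(0.8, 0.1, 0.1), si$library)
  a <- fit_consumer(x, si$library, si$fractionation, quick_cfg(seed = 42))
  b <- fit_consumer(x, si$library, si$fractionation, quick_cfg(seed = 42))
  expect_identical(a$draws, b$draws)
  c2 <- fit_consumer(x, si$library, si$fractionation, quick_cfg(seed = 43))
  expect_false(identical(a$draws, c2$draws))
})

test_that("two sources with identical signatures are exchangeable", {
  m <- matrix(c(0, 5, 0, 5, 8, 2), 2, 3,
              dimnames = list(c("c", "n"), c("A", "Aclone", "B")))
  s <- matrix(1, 2, 3, dimnames = dimnames(m))
  lib <- source_library(m, s, "si_delta")
  post <- fit_consumer(c(c = 1, n = 4.5), lib, NULL, oracle_cfg(seed = 8))
  sm <- posterior_summary(post)
  expect_lt(abs(sm$median[1] - sm$median[2]), 0.05)
  expect_lt(abs(sm$mean[1] - sm$mean[2]), 0.05)
})

test_that("pooling concatenates draws with equal weight", {
  si <- si_fixture()
  x <- exact_mixture_consumer(c(0.8, 0.1, 0.1), si$library)
  a <- fit_consumer(x, si$library, si$fractionation, quick_cfg(seed = 1))
  pooled1 <- pool_posteriors(list(a))
  expect_identical(pooled1$draws, a$draws)
  b <- fit_consumer(x, si$library, si$fractionation, quick_cfg(seed = 2))
  pooled2 <- pool_posteriors(list(a, b))
  expect_equal(nrow(pooled2$draws), nrow(a$draws) + nrow(b$draws))
  # duplicating a posterior leaves every quantile unchanged
  twin <- pool_posteriors(list(a, a))
  probs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  expect_equal(apply(twin$draws, 2, quantile, probs = probs),
               apply(a$draws, 2, quantile, probs = probs))
  bad <- a; bad$groups <- rev(a$groups)
  expect_error(pool_posteriors(list(a, bad)), "different source groups")
})

test_that("summaries handle degenerate draws and refuse tiny samples", {
  draws <- matrix(rep(c(0.5, 0.3, 0.2), each = 200), 200, 3,
                  dimnames = list(NULL, c("A", "B", "C")))
  sm <- posterior_summary(fake_posterior(draws))
  expect_equal(sm$median, c(0.5, 0.3, 0.2))
  expect_equal(sm$q2.5, sm$q97.5)
  expect_equal(sm$sd, c(0, 0, 0))
  expect_error(posterior_summary(fake_posterior(draws[1:50, ])), "too few")
})

test_that("prior-only sampling recovers flat-Dirichlet marginals", {
  si <- si_fixture()
  cfg <- mcmc_config(iterations = 30000, burn_in = 5000, thin = 5, seed = 3,
                     use_likelihood = FALSE, init = "uniform")
  post <- fit_consumer(NULL, si$library, NULL, cfg)
  sm <- posterior_summary(post)
  # K = 3 flat Dirichlet: marginal Beta(1,2), mean 1/3, median 1 - sqrt(1/2)
  expect_lt(max(abs(sm$mean - 1 / 3)), 0.02)
  expect_lt(max(abs(sm$median - (1 - sqrt(0.5)))), 0.025)
  expect_true(all(abs(rowSums(post$draws) - 1) < 1e-10))
})

test_that("density curves bin 1/10th-percentile quantiles and integrate to 1", {
  pt <- fake_posterior(matrix(rep(c(0.5, 0.5), each = 500), 500, 2,
                              dimnames = list(NULL, c("A", "B"))))
  dc <- density_curve(pt, "A")
  expect_equal(sum(dc$count > 0), 1)
  expect_equal(sum(dc$density) / 40, 1)
  set.seed(9)
  un <- fake_posterior(matrix(runif(8000), 4000, 2,
                              dimnames = list(NULL, c("A", "B"))))
  dcu <- density_curve(un, "A")
  expect_equal(nrow(dcu), 40)
  expect_true(all(abs(dcu$count - 25) <= 10))
  expect_equal(sum(dcu$density) / 40, 1)
})

test_that("grid oracle recovers the prior when the likelihood is flat", {
  # a huge variance floor with zero source SD makes sigma constant in p,
  # so the likelihood carries no information about the diet
  lib <- toy_lib_2x1(sa = 0, sb = 0)
  orc <- oracle_posterior(c(t1 = 5), lib, grid_step = 0.002,
                          var_floor = 1e10)
  # K = 2 flat Dirichlet marginal is Uniform(0, 1)
  q <- oracle_quantiles(orc, "A", probs = c(0.25, 0.5, 0.75))
  expect_lt(max(abs(unname(q) - c(0.25, 0.5, 0.75))), 0.005)
})

test_that("grid oracle concentrates on a feasible exact mixture as noise vanishes", {
  lib <- toy_lib_3x2()
  tiny <- scale_library_uncertainty(lib, 0.01)
  x <- exact_mixture_consumer(c(0.6, 0.3, 0.1), tiny)
  orc <- oracle_posterior(x, tiny, grid_step = 0.002)
  expect_lt(abs(unname(oracle_quantiles(orc, "A", 0.5)) - 0.6), 0.003)
  expect_lt(abs(unname(oracle_quantiles(orc, "B", 0.5)) - 0.3), 0.003)
  big <- source_library(matrix(0, 2, 5,
                               dimnames = list(c("c", "n"), letters[1:5])),
                        matrix(1, 2, 5,
                               dimnames = list(c("c", "n"), letters[1:5])),
                        "si_delta")
  expect_error(oracle_posterior(c(c = 0, n = 0), big), "4 source groups")
})

test_that("sampler marginals agree with the grid oracle on a 2-source toy", {
  lib <- toy_lib_2x1()
  x <- c(t1 = 3)
  probs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  orc <- oracle_posterior(x, lib)
  post <- fit_consumer(x, lib, NULL, oracle_cfg(seed = 21))
  q_mcmc <- quantile(post$draws[, "A"], probs = probs)
  expect_lt(max(abs(unname(q_mcmc) -
                      unname(oracle_quantiles(orc, "A", probs)))), 0.02)
})

test_that("the uniform hyperprior form samples jointly and stays in support", {
  si <- si_fixture()
  x <- exact_mixture_consumer(c(0.8, 0.1, 0.1), si$library)
  cfg <- quick_cfg(seed = 5, prior = prior_spec("dirichlet_uniform_hyper"))
  post <- fit_consumer(x, si$library, si$fractionation, cfg)
  expect_true(all(abs(rowSums(post$draws) - 1) < 1e-10))
  expect_true(all(post$alpha_draws > 0 & post$alpha_draws <= 100))
  # posteriors under the two priors tell a broadly consistent story
  ref <- fit_consumer(x, si$library, si$fractionation, quick_cfg(seed = 5))
  expect_lt(abs(posterior_summary(post)$median[1] -
                  posterior_summary(ref)$median[1]), 0.15)
})

test_that("fit_many assigns per-consumer seeds and reports failures by id", {
  si <- si_fixture()
  cons <- simulate_mixed_si(c(0.8, 0.1, 0.1), si$library, si$fractionation,
                            n = 3, seed = 2)
  rownames(cons) <- c("d1", "d2", "d3")
  res <- fit_many(cons, si$library, si$fractionation, quick_cfg(seed = 10))
  expect_length(res$posteriors, 3)
  expect_identical(vapply(res$posteriors, function(p) p$consumer_id, ""),
                   c("d1", "d2", "d3"))
  expect_equal(nrow(res$pooled$draws),
               sum(vapply(res$posteriors, function(p) nrow(p$draws), 1L)))
  # distinct seeds: replicate consumers do not produce identical chains
  expect_false(identical(res$posteriors[[1]]$draws,
                         res$posteriors[[2]]$draws))
  bad <- cons; bad[2, 1] <- NA
  expect_error(fit_many(bad, si$library, si$fractionation, quick_cfg()),
               "d2")
})

test_that("posterior exports write draws CSV and JSON summaries", {
  skip_if_not_installed("jsonlite")
  si <- si_fixture()
  x <- exact_mixture_consumer(c(0.8, 0.1, 0.1), si$library)
  post <- fit_consumer(x, si$library, si$fractionation, quick_cfg(seed = 1))
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  export_posterior(post, csv, js)
  back <- read.csv(csv)
  expect_equal(nrow(back), nrow(post$draws))
  expect_identical(names(back), c("Diatoms", "Chlorophytes", "Cyanobacteria"))
  parsed <- jsonlite::read_json(js)
  expect_length(parsed$summary, 3)
  expect_equal(parsed$summary[[1]]$median,
               posterior_summary(post)$median[1], tolerance = 1e-12)
})
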