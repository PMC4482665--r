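test_that("pure-diet SI simulation matches closed-form moments", {
  si <- si_fixture()
  x <- simulate_pure_si("Diatoms", si$library, si$fractionation,
                        n = 10000, seed = 1)
  # consumer-level fractionation draw: SD = sqrt(s^2 + g^2)
  expect_equal(mean(x[, "d13C"]), -29.8, tolerance = 0.1)
  expect_equal(sd(x[, "d13C"]), sqrt(2.3^2 + 1.3^2), tolerance = 0.06)
  expect_equal(mean(x[, "d15N"]), 7.5, tolerance = 0.06)
  expect_equal(sd(x[, "d15N"]), sqrt(1.5^2 + 1.0^2), tolerance = 0.05)
  # degenerate case: no source noise, no fractionation noise
  z <- scale_library_uncertainty(si$library, 1e-12)
  x0 <- simulate_pure_si("Diatoms", z, NULL, n = 5, seed = 2)
  expect_equal(unname(x0), matrix(rep(c(-29.8, 7.5), each = 5), 5, 2),
               tolerance = 1e-6)
  expect_error(simulate_pure_si("Kelp", si$library), "unknown group")
})

test_that("mixed-diet SI simulation composes source draws and fractionation", {
  si <- si_fixture()
  w <- c(0.8, 0.1, 0.1)
  x <- simulate_mixed_si(w, si$library, si$fractionation, n = 10000, seed = 3)
  expect_equal(mean(x[, "d13C"]), -28.79, tolerance = 0.08)
  expect_equal(mean(x[, "d15N"]), 7.15, tolerance = 0.06)
  # variance: sum w^2 s^2 + g^2
  expect_equal(sd(x[, "d13C"]),
               sqrt(0.64 * 2.3^2 + 0.01 * 2.6^2 + 0.01 * 3.0^2 + 1.3^2),
               tolerance = 0.06)
  # vertex weights reduce to the pure simulator exactly (same seed)
  a <- simulate_mixed_si(c(1, 0, 0), si$library, si$fractionation, 50, seed = 7)
  b <- simulate_pure_si("Diatoms", si$library, si$fractionation, 50, seed = 7)
  expect_identical(a, b)
  # zero uncertainty everywhere collapses to the exact mixture mean
  z <- scale_library_uncertainty(si$library, 1e-12)
  x0 <- simulate_mixed_si(w, z, NULL, n = 4, seed = 5)
  expect_equal(unname(x0[1, ]), c(-28.79, 7.15), tolerance = 1e-6)
  expect_equal(unname(x0[4, ]), c(-28.79, 7.15), tolerance = 1e-6)
})

test_that("FA resampling simulator is a convex combination of real profiles", {
  mats <- list(
    A = matrix(c(10, 90), 1, 2, dimnames = list(NULL, c("t1", "t2"))),
    B = matrix(c(50, 50), 1, 2, dimnames = list(NULL, c("t1", "t2"))),
    C = matrix(c(30, 70), 1, 2, dimnames = list(NULL, c("t1", "t2")))
  )
  x <- simulate_mixed_fa(c(0.8, 0.1, 0.1), mats, n = 3, seed = 1)
  expect_equal(unname(x[1, ]), c(16, 84))
  expect_equal(unname(rowSums(x)), rep(100, 3))

  gen <- generate_fa_library(default_fa_templates(), seed = 4)
  sim <- simulate_mixed_fa(c(0.8, 0.1, 0.1), gen$library, n = 200, seed = 5)
  expect_equal(unname(rowSums(sim)), rep(100, 200), tolerance = 1e-9)
  # tracer-wise convex hull of the library profiles contains every consumer
  allp <- do.call(rbind, lapply(gen$profiles, function(p) p$values))
  expect_true(all(sweep(sim, 2, apply(allp, 2, max)) <= 1e-9))
  expect_true(all(sweep(sim, 2, apply(allp, 2, min)) >= -1e-9))
  # vertex weights return actual library profiles
  v <- simulate_mixed_fa(c(1, 0, 0), gen$library, n = 20, seed = 6)
  labs <- sapply(gen$profiles, function(p) p$label)
  diat <- do.call(rbind, lapply(gen$profiles[labs == "diatoms"],
                                function(p) p$values))
  hits <- apply(v, 1, function(r)
    any(apply(diat, 1, function(d) max(abs(d - r)) < 1e-12)))
  expect_true(all(hits))
})

test_that("exact mixture consumers are deterministic and linear in weights", {
  si <- si_fixture()
  expect_equal(unname(exact_mixture_consumer(c(0.8, 0.1, 0.1), si$library)),
               c(-28.79, 7.15))
  f <- fractionation_spec(c(d13C = 0.4, d15N = 3.4), c(d13C = 1, d15N = 1))
  expect_equal(unname(exact_mixture_consumer(c(0, 1, 0), si$library, f)),
               c(-23.7 + 0.4, 8.7 + 3.4))
  w1 <- c(0.8, 0.1, 0.1); w2 <- c(0.2, 0.5, 0.3)
  expect_equal(exact_mixture_consumer(0.5 * w1 + 0.5 * w2, si$library),
               0.5 * exact_mixture_consumer(w1, si$library) +
                 0.5 * exact_mixture_consumer(w2, si$library))
})

test_that("library uncertainty scaling acts on SDs only and composes", {
  si <- si_fixture()
  lib <- si$library
  expect_equal(scale_library_uncertainty(lib, 1)$sd, lib$sd)
  small <- scale_library_uncertainty(lib, 0.01)
  expect_equal(small$sd["d13C", "Diatoms"], 0.023)
  expect_equal(small$mean, lib$mean)
  twice <- scale_library_uncertainty(scale_library_uncertainty(lib, 0.1), 0.1)
  expect_equal(twice$sd, small$sd)
  expect_error(scale_library_uncertainty(lib, 0), "positive")
})

test_that("posterior sits between prior and truth under full SI uncertainty", {
  si <- si_fixture()
  sp <- scenario_spec(c(0.8, 0.1, 0.1), n_consumers = 12, group_size = 6,
                      seed = 31)
  res <- run_scenario(sp, si$library, si$fractionation, quick_cfg(seed = 31))
  med <- res$summary$median[1]
  expect_gt(med, 1 / 3)
  expect_lt(med, 0.8)
  expect_length(res$batch_summaries, 2)
})

test_that("fractionation grid shifts consumers by z times g and needs g > 0", {
  si <- si_fixture()
  zf <- zero_fractionation(si$library)
  expect_error(run_fractionation_grid(c(0.8, 0.1, 0.1), si$library, zf),
               "all zero")
  fa <- generate_fa_library(default_fa_templates(), seed = 1)$library
  expect_error(run_fractionation_grid(c(0.8, 0.1, 0.1), fa, zf),
               "stable-isotope")
  grid <- run_fractionation_grid(c(0.8, 0.1, 0.1), si$library,
                                 si$fractionation, quick_cfg(seed = 12))
  expect_length(grid$results, 5)
  expect_equal(nrow(grid$table), 15)
  ref <- grid$results[["C mean / N mean"]]$summary
  expect_equal(ref$median, c(0.8, 0.1, 0.1), tolerance = 0.01)
  # offsets are +/- 1.96 fractionation SDs: 2.548 permil for carbon
  pp <- grid$results[["C +1.96 / N +1.96"]]
  expect_true(all(pp$pooled$draws >= 0))
  x_ref <- exact_mixture_consumer(c(0.8, 0.1, 0.1), si$library)
  expect_equal(unname(x_ref + c(1.96 * 1.3, 1.96 * 1.0)),
               unname(x_ref) + c(2.548, 1.96))
})

test_that("the 2x2 uncertainty matrix reaches accurate recovery in its clean cell", {
  si <- si_fixture()
  cells <- run_uncertainty_matrix(c(0.8, 0.1, 0.1), si$library,
                                  si$fractionation, quick_cfg(seed = 17),
                                  n_consumers = 6, group_size = 3)
  expect_named(cells, c("resource100_consumer100", "resource100_consumer0",
                        "resource0_consumer100", "resource0_consumer0"))
  clean <- cells$resource0_consumer0$summary
  expect_equal(clean$median, c(0.8, 0.1, 0.1), tolerance = 0.01)
  expect_lt(clean$q97.5[1] - clean$q2.5[1], 0.1)
  # the noisy-everything cell is far more dispersed
  noisy <- cells$resource100_consumer100$summary
  expect_gt(noisy$q97.5[1] - noisy$q2.5[1], 0.4)
})
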