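test_that("Kragten combination reduces to quadrature identities", {
  expect_identical(combine_uncertainty_kragten(0, c(0, 0)), 0)
  expect_equal(combine_uncertainty_kragten(0.3, 0.4), 0.5)
  expect_error(combine_uncertainty_kragten(-0.1, 0.2), ">= 0")
})

test_that("Kragten combination matches Monte-Carlo propagation", {
  set.seed(42)
  for (i in 1:10) {
    sds <- runif(1 + sample(1:3, 1), 0.05, 1.5)
    combined <- combine_uncertainty_kragten(sds[1], sds[-1])
    draws <- rowSums(vapply(sds, function(s) rnorm(1e5, 0, s),
                            numeric(1e5)))
    expect_equal(combined, sd(draws), tolerance = 0.03)
  }
})

test_that("norleucine normalisation is an additive shift anchored on Nle", {
  d <- c(Ala = -20, Phe = -25, Nle = -27.59)
  expect_identical(norleucine_normalize(d, -27.59, -27.59), d + 0)
  shifted <- norleucine_normalize(d, -28.59, -27.59)
  expect_equal(shifted[c("Ala", "Phe")], d[c("Ala", "Phe")] + 1.0)
  expect_identical(unname(shifted["Nle"]), -27.59)
  expect_error(norleucine_normalize(d, NA_real_, -27.59), "norleucine")
})

test_that("nitrogen calibration recovers forced and simulated lines", {
  ident <- data.frame(aa = c("a", "b", "c"), raw_delta = c(0, 5, 10),
                      true_delta = c(0, 5, 10))
  cal <- calibrate_n15(c(x = 3), ident)
  expect_equal(unname(cal$delta), 3)
  expect_equal(cal$residual_sd, 0, tolerance = 1e-12)

  two <- data.frame(aa = c("a", "b"), raw_delta = c(0, 10),
                    true_delta = c(1, 11))
  expect_equal(unname(calibrate_n15(c(x = 5), two)$delta), 6)
  expect_error(calibrate_n15(c(x = 1), two[1, ]), ">= 2")

  # slope recovery: 9 standards, slope 0.98, intercept 0.5, noise 0.2
  hits <- 0L
  true_raw <- seq(-5, 43, length.out = 9)
  for (seed in 1:200) {
    set.seed(seed)
    std <- data.frame(aa = paste0("s", 1:9), raw_delta = true_raw,
                      true_delta = 0.98 * true_raw + 0.5 + rnorm(9, 0, 0.2))
    if (abs(calibrate_n15(numeric(), std)$slope - 0.98) <= 0.02) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / 200, 0.90)
})

test_that("derivatization correction obeys exact mass balance", {
  counts <- default_carbon_counts()
  ala <- counts[counts$aa == "Ala", ]
  # equal deltas are a fixed point
  expect_equal(correct_derivatization_c13(-30, -30, ala), -30)

  # alanine standard: invert the mass balance, then correct forward
  dc <- (ala$n_C * (-19.31) + ala$n_D * (-40.46)) / ala$n_DC
  expect_equal(correct_derivatization_c13(dc, -40.46, ala), -19.31,
               tolerance = 1e-9)

  # randomized counts and deltas: forward o inverse = identity to 1e-9
  set.seed(7)
  for (i in 1:50) {
    row <- data.frame(aa = "X", n_C = sample(2:9, 1), n_D = sample(2:9, 1))
    row$n_DC <- row$n_C + row$n_D
    true_c <- runif(1, -35, -10)
    fac <- runif(1, -50, -35)
    dc <- (row$n_C * true_c + row$n_D * fac) / row$n_DC
    expect_equal(correct_derivatization_c13(dc, fac, row), true_c,
                 tolerance = 1e-9)
    expect_equal(derive_correction_factor(dc, true_c, row), fac,
                 tolerance = 1e-9)
  }

  bad <- data.frame(aa = "X", n_C = 3, n_D = 5, n_DC = 9)
  expect_error(correct_derivatization_c13(-20, -40, bad), "n_DC")
})

test_that("correction factors averaged over a session recover the generating factor", {
  counts <- default_carbon_counts()
  leu <- counts[counts$aa == "Leu", ]
  fac_true <- -45.03
  set.seed(3)
  for (rep in 1:10) {
    raw <- (leu$n_C * (-13.78) + leu$n_D * fac_true) / leu$n_DC +
      rnorm(10, 0, 0.3)
    facs <- vapply(raw, derive_correction_factor, numeric(1),
                   true_delta = -13.78, counts = leu)
    se <- sd(facs) / sqrt(10)
    expect_lt(abs(mean(facs) - fac_true), 3 * se + 1e-9)
  }
})

test_that("error propagation matches its closed form and the MC oracle", {
  expect_identical(propagate_correction_error(0, 0, 0, 3, 5, 3), 0)
  # sigma_DC alone with n_C = n_D doubles
  expect_equal(propagate_correction_error(0, 0, 0.7, 4, 4, 4), 1.4)
  expect_error(propagate_correction_error(0.1, 0.1, 0.1, 3, 5, 0), "n_C")

  # MC oracle through the two-step correction chain; also adjudicates the
  # exponent reading: the squared-ratio form must agree, the literal
  # unsquared reading must not (for at least some inputs).
  set.seed(11)
  any_unsquared_off <- FALSE
  for (i in 1:12) {
    n_C <- sample(2:9, 1); n_D <- sample(2:9, 1); n_S <- sample(2:9, 1)
    s_S <- runif(1, 0, 1); s_DS <- runif(1, 0.2, 2); s_DC <- runif(1, 0.2, 2)
    n <- 1e5
    d_S <- rnorm(n, -20, s_S); d_DS <- rnorm(n, -30, s_DS)
    d_DC <- rnorm(n, -28, s_DC)
    fac <- ((n_S + n_D) * d_DS - n_S * d_S) / n_D
    corrected <- ((n_C + n_D) * d_DC - n_D * fac) / n_C
    mc <- sd(corrected)
    sq <- propagate_correction_error(s_S, s_DS, s_DC, n_S, n_D, n_C)
    un <- propagate_correction_error(s_S, s_DS, s_DC, n_S, n_D, n_C,
                                     squared_ratios = FALSE)
    expect_equal(sq, mc, tolerance = 0.05)
    if (abs(un - mc) / mc > 0.05) any_unsquared_off <- TRUE
  }
  expect_true(any_unsquared_off)
})

test_that("a noiseless session reduces back to the generating truths", {
  sc <- sim_scenario(seed = 5, replicate_sd = 0, drift = 0)
  truths <- data.frame(
    sample_id = "s1",
    analyte = c("Ala", "Val", "Leu", "Phe", "Glx", "Phe", "Lys", "Glx"),
    element = c(rep("C", 5), rep("N", 3)),
    delta = c(-22, -24, -26, -25.5, -23, 6.2, 5.1, 9.3),
    stringsAsFactors = FALSE)
  gc <- make_gc_session(sc, truths)
  red <- reduce_session(gc$session, gc$standard_truths, gc$counts)
  key <- paste(red$analyte, red$element)
  for (r in seq_len(nrow(truths))) {
    i <- match(paste(truths$analyte[r], truths$element[r]), key)
    expect_equal(red$delta[i], truths$delta[r], tolerance = 1e-6)
  }
  expect_true(all(red$n_replicates == 3L))
})

test_that("norleucine anchoring removes common-mode drift", {
  truths <- data.frame(sample_id = rep(c("s1", "s2"), each = 2),
                       analyte = c("Leu", "Phe"), element = "C",
                       delta = c(-26, -25.5), stringsAsFactors = FALSE)
  run_err <- function(seed, rep_sd, drift) {
    sc <- sim_scenario(seed = seed, replicate_sd = rep_sd, drift = drift)
    gc <- make_gc_session(sc, truths)
    red <- reduce_session(gc$session, gc$standard_truths, gc$counts)
    red <- red[red$element == "C", ]
    mean(abs(red$delta - truths$delta[match(paste(red$sample_id,
                                                  red$analyte),
                                            paste(truths$sample_id,
                                                  truths$analyte))]))
  }
  # without replicate noise the per-injection anchor removes common-mode
  # drift essentially completely (>= 90% required)
  pure <- vapply(1:20, run_err, numeric(1), rep_sd = 0, drift = 0.5)
  expect_lt(mean(pure), 0.1 * 0.5)
  # with noise, adding drift must not degrade accuracy beyond noise alone
  noisy_drift <- vapply(1:30, run_err, numeric(1), rep_sd = 0.05,
                        drift = 0.5)
  noisy_plain <- vapply(1:30, run_err, numeric(1), rep_sd = 0.05,
                        drift = 0)
  expect_lt(mean(noisy_drift), 1.25 * mean(noisy_plain) + 0.01)
})

test_that("reduced uncertainties dominate replicate-only scatter and runs are deterministic", {
  sc <- sim_scenario(seed = 9, replicate_sd = 0.4)
  truths <- data.frame(sample_id = "s1",
                       analyte = c("Leu", "Phe", "Phe"),
                       element = c("C", "C", "N"),
                       delta = c(-26, -25.5, 6.0), stringsAsFactors = FALSE)
  gc <- make_gc_session(sc, truths)
  red <- reduce_session(gc$session, gc$standard_truths, gc$counts)
  # replicate-only sd per AA, recomputed by anchoring each sample injection
  # to its own norleucine peak exactly as the reducer does
  counts <- gc$counts
  for (r in seq_len(nrow(red))) {
    el <- red$element[r]
    smp <- gc$session[gc$session$role == "sample" &
                        gc$session$element == el, ]
    std_nle <- gc$session[gc$session$role == "standard" &
                            gc$session$element == el &
                            gc$session$analyte == "Nle", "delta"]
    target <- if (el == "C") mean(std_nle) else 14.31
    anchored <- vapply(unique(smp$injection), function(inj) {
      d <- smp[smp$injection == inj, ]
      d$delta[d$analyte == red$analyte[r]] +
        (target - d$delta[d$analyte == "Nle"])
    }, numeric(1))
    rep_sd <- sd(anchored)
    floor_sd <- if (el == "C") {
      row <- counts[counts$aa == red$analyte[r], ]
      rep_sd * row$n_DC / row$n_C
    } else rep_sd
    expect_gte(red$sd[r] + 1e-9, floor_sd)
  }
  red2 <- reduce_session(make_gc_session(sc, truths)$session,
                         gc$standard_truths, gc$counts)
  expect_identical(as.data.frame(red), as.data.frame(red2))

  # a missing bracket is an error
  no_std <- gc$session[gc$session$role != "standard", ]
  expect_error(reduce_session(no_std, gc$standard_truths, gc$counts),
               "bracket")

  # a missing triplicate is a warning, not an error
  drop_inj <- gc$session[!(gc$session$sample_id == "s1" &
                             gc$session$injection ==
                               max(gc$session$injection[gc$session$role ==
                                                          "sample"])), ]
  expect_warning(reduce_session(drop_inj, gc$standard_truths, gc$counts),
                 "replicate")
})

test_that("propagated carbon sd is at least the scaled replicate term", {
  counts <- default_carbon_counts()
  for (aa in c("Ala", "Glx", "Lys")) {
    row <- counts[counts$aa == aa, ]
    s <- propagate_correction_error(0.1, 0.3, 0.5, row$n_C, row$n_D,
                                    row$n_C)
    expect_gte(s, 0.5 * row$n_DC / row$n_C)
  }
})
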