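test_that("model catalogue resolves the documented signal sets", {
  src <- make_sources(sim_scenario(seed = 1))
  spec1 <- build_model_spec("model1", src)
  expect_identical(nrow(spec1$signals), 6L)
  expect_true(all(spec1$signals$routing == "source_direct"))
  expect_true(all(spec1$offset_mean == 0))
  expect_identical(spec1$scale, "protein")

  spec2 <- build_model_spec("model2", src)
  expect_identical(nrow(spec2$signals), 10L)
  expect_setequal(
    paste(spec2$signals$element, spec2$signals$analyte)[7:10],
    c("C Ala", "C Glx", "C Asx", "N Glx"))
  expect_identical(spec2$scale, "whole_diet")

  for (m in c("model0p", "model0wd")) {
    sp <- build_model_spec(m, src)
    expect_identical(nrow(sp$signals), 2L)
    expect_true(all(sp$signals$analyte == "bulk"))
  }

  # a protein-free source cannot enter a protein-scale model
  src4 <- add_olive_oil_source(src)
  expect_error(build_model_spec("model1", src4), "protein-free")
  expect_s3_class(suppressWarnings(build_model_spec("model2", src4)),
                  "model_spec")

  # a source lacking a required measurement is a spec error listing the gap
  broken <- src
  broken[[1]]$signals <- broken[[1]]$signals[
    broken[[1]]$signals$analyte != "Leu", ]
  expect_error(build_model_spec("model1", broken), "Leu")
})

test_that("source routing produces the documented signal values", {
  src <- make_sources(sim_scenario(seed = 1))
  cer <- src$cereals
  cfg <- model_config()

  # source_direct returns the measured value untouched
  v <- source_signal_value(cer, list(element = "C", analyte = "Phe",
                                     routing = "source_direct"), cfg)
  expect_equal(unname(v["mean"]),
               cer$signals$mean[cer$signals$analyte == "Phe" &
                                  cer$signals$element == "C"])

  # carbon pool with identical macronutrient deltas equals that delta
  same <- source_group("same",
    signals = data.frame(element = c("C", "N"), analyte = "bulk",
                         mean = c(-24, 5), sd = 0, stringsAsFactors = FALSE),
    aa_concentrations = c(Phe = 0.05),
    macronutrients = c(protein = 0.3, carbohydrate = 0.5, lipid = 0.2),
    macro_offsets = data.frame(macronutrient = c("protein", "carbohydrate",
                                                 "lipid"),
                               mean = 0, sd = 0, stringsAsFactors = FALSE))
  vp <- source_signal_value(same, list(element = "C", analyte = "Glx",
                                       routing = "carbon_pool"), cfg)
  expect_equal(unname(vp["mean"]), -24)

  # weighted pool: 50% carb / 30% protein / 20% lipid at (-24, -20, -28)
  mix <- source_group("mix",
    signals = data.frame(element = c("C", "N"), analyte = "bulk",
                         mean = c(0, 5), sd = 0, stringsAsFactors = FALSE),
    aa_concentrations = c(Phe = 0.05),
    macronutrients = c(protein = 0.3, carbohydrate = 0.5, lipid = 0.2),
    macro_offsets = data.frame(
      macronutrient = c("protein", "carbohydrate", "lipid"),
      mean = c(-20, -24, -28), sd = 0, stringsAsFactors = FALSE))
  vm <- source_signal_value(mix, list(element = "C", analyte = "Glx",
                                      routing = "carbon_pool"), cfg)
  expect_equal(unname(vm["mean"]), 0.5 * -24 + 0.3 * -20 + 0.2 * -28)

  # nitrogen pool shifts bulk d15N by exactly the trophic offset
  vn <- source_signal_value(cer, list(element = "N", analyte = "Glx",
                                      routing = "nitrogen_pool"), cfg)
  bulk_n <- cer$signals$mean[cer$signals$analyte == "bulk" &
                               cer$signals$element == "N"]
  expect_equal(unname(vn["mean"]), bulk_n + cfg$trophic_n15_glx[["mean"]])

  # glycolytic routing without carbohydrate falls back to the carbon pool
  fish <- src$marine_fish
  expect_warning(
    vf <- source_signal_value(fish, list(element = "C", analyte = "Ala",
                                         routing = "glycolytic"), cfg),
    "carbon pool")
  expect_equal(vf, source_signal_value(fish,
                                       list(element = "C", analyte = "Ala",
                                            routing = "carbon_pool"), cfg))
  expect_error(
    source_signal_value(fish, list(element = "C", analyte = "Ala",
                                   routing = "glycolytic"),
                        model_config(glycolytic_fallback = FALSE)),
    "carbohydrate")
})

test_that("concentration weights are normalised carrier products", {
  src <- make_sources(sim_scenario(seed = 1))
  sig <- list(element = "C", analyte = "Phe", routing = "source_direct")
  # equal concentrations reduce to linear mixing
  eq <- lapply(1:3, function(i) {
    s <- src[[i]]; s$aa_concentrations[] <- 0.05
    s$macronutrients <- c(protein = 0.5, carbohydrate = 0.3, lipid = 0.2)
    s
  })
  f <- c(0.2, 0.5, 0.3)
  expect_equal(concentration_weights(f, sig, eq, "whole_diet"), f)

  # f = (1/2, 1/2), q = (2, 1) -> w = (2/3, 1/3)
  two <- eq[1:2]
  two[[1]]$aa_concentrations["Phe"] <- 0.10
  two[[2]]$aa_concentrations["Phe"] <- 0.05
  expect_equal(concentration_weights(c(0.5, 0.5), sig, two, "whole_diet"),
               c(2 / 3, 1 / 3))

  # permutation equivariance over random fractions and concentrations
  set.seed(21)
  for (i in 1:20) {
    qs <- runif(3, 0.01, 0.3)
    srcs <- lapply(1:3, function(k) {
      s <- eq[[k]]; s$aa_concentrations["Phe"] <- qs[k]; s
    })
    f <- as.numeric(rmultinom(1, 100, runif(3))) / 100
    if (any(f == 0)) f <- (f + 0.01) / sum(f + 0.01)
    w <- concentration_weights(f, sig, srcs, "whole_diet")
    perm <- sample(3)
    w_perm <- concentration_weights(f[perm], sig, srcs[perm], "whole_diet")
    expect_equal(w_perm, w[perm])
    expect_simplex(w)
  }

  oil <- add_olive_oil_source(src)[[4]]
  w_oil <- concentration_weights(c(0.25, 0.25, 0.25, 0.25),
                                 list(element = "N", analyte = "Phe",
                                      routing = "source_direct"),
                                 c(src, list(oil)), "whole_diet")
  expect_identical(unname(w_oil[4]), 0)
  expect_error(concentration_weights(c(1, 0), sig,
                                     list(oil, oil), "whole_diet"),
               "degenerate")
})

test_that("forward prediction is convex in the source values", {
  src <- make_sources(sim_scenario(seed = 1))
  spec <- build_model_spec("model1", src)
  # single source: prediction equals that source's value + offset
  p <- forward_predict(c(1, 0, 0), spec)
  expect_equal(p$mean, spec$vbar[, 1] + spec$offset_mean,
               ignore_attr = TRUE)
  # equal signal values: prediction independent of fractions
  same <- toy_sources()
  same <- lapply(same, function(s) { s$signals$mean <- c(-20, -18, -19, 5,
                                                         -20, 8); s })
  sp_same <- toy_spec(same)
  p1 <- forward_predict(c(0.8, 0.1, 0.1), sp_same)
  p2 <- forward_predict(c(0.1, 0.2, 0.7), sp_same)
  expect_equal(p1$mean, p2$mean)
})

test_that("the sampler recovers degenerate diets and is seed-deterministic", {
  src <- toy_sources()
  spec <- toy_spec(src)
  cons <- toy_consumer(c(1, 0, 0), src, s_meas = 0.3, noise = FALSE)
  ft <- fit(cons$signals, spec, seed = 3)
  expect_gte(ft$percentiles$p50[1], 0.95)
  # every retained draw lies on the simplex
  expect_true(all(ft$chains >= 0))
  expect_lt(max(abs(rowSums(ft$chains) - 1)), 1e-12)

  ft2 <- fit(cons$signals, spec, seed = 3)
  expect_identical(ft$percentiles, ft2$percentiles)
  expect_identical(ft$chains, ft2$chains)
  ft3 <- fit(cons$signals, spec, seed = 4)
  expect_false(identical(ft$chains, ft3$chains))

  # missing signal and non-positive sd are errors
  expect_error(fit(cons$signals[-1, ], spec), "lacks signal")
  bad <- cons$signals; bad$sd[1] <- 0
  expect_error(fit(bad, spec), "sd > 0")
})

test_that("posterior mode matches a brute-force grid-search oracle", {
  src <- toy_sources(source_sd = 0.01)
  spec <- toy_spec(src, source_sd = 0.01)
  for (seed in 1:3) {
    f_true <- list(c(0.5, 0.25, 0.25), c(0.2, 0.6, 0.2),
                   c(1, 1, 1) / 3)[[seed]]
    cons <- toy_consumer(f_true, src, s_meas = 0.4, seed = seed)
    ft <- fit(cons$signals, spec, seed = 100 + seed)
    mode_hat <- posterior_mode(ft)
    oracle <- grid_search_mle(cons$signals$delta, cons$signals$sd,
                              cons$vbar, cons$q)
    expect_lt(max(abs(mode_hat - oracle$f)), 0.02)
  }
})

test_that("identical sources return the flat Dirichlet prior", {
  same <- toy_sources(source_sd = 0)
  same <- lapply(same, function(s) { s$signals$mean <- c(-20, -18, -19, 5,
                                                         -20, 8); s })
  spec <- toy_spec(same, source_sd = 0)
  cons <- toy_consumer(c(1, 1, 1) / 3, same, s_meas = 0.5, noise = FALSE)
  ft <- fit(cons$signals, spec, seed = 5, iterations = 20000, chains = 2)
  # Dirichlet(1,1,1) marginals are Beta(1,2); absolute Monte-Carlo slack
  for (k in 1:3) {
    expect_lt(abs(mean(ft$chains[, k]) - 1 / 3), 0.02)
    expect_lt(abs(sd(ft$chains[, k]) - sqrt(2) / 6), 0.02)
    expect_lt(abs(unname(quantile(ft$chains[, k], 0.5)) -
                    qbeta(0.5, 1, 2)), 0.03)
  }
})

test_that("widening measurement sds never narrows the 68% intervals", {
  src <- toy_sources()
  spec <- toy_spec(src)
  cons <- toy_consumer(c(0.5, 0.3, 0.2), src, s_meas = 0.3, seed = 9)
  ft_narrow <- fit(cons$signals, spec, seed = 11)
  wide <- cons$signals
  wide$sd <- wide$sd * 3
  ft_wide <- fit(wide, spec, seed = 11)
  w_narrow <- ft_narrow$percentiles$p84 - ft_narrow$percentiles$p16
  w_wide <- ft_wide$percentiles$p84 - ft_wide$percentiles$p16
  expect_true(all(w_wide >= w_narrow))
})

test_that("relabeling sources permutes the percentile table exactly", {
  src <- toy_sources()
  spec <- toy_spec(src)
  cons <- toy_consumer(c(0.5, 0.3, 0.2), src, s_meas = 0.4, seed = 13)
  ft <- fit(cons$signals, spec, seed = 17)
  # renaming sources (same data order) permutes only the labels
  relabeled <- src
  relabeled[[1]]$name <- "zeta"
  spec_r <- toy_spec(relabeled)
  ft_r <- fit(cons$signals, spec_r, seed = 17)
  expect_identical(ft_r$percentiles$p50, ft$percentiles$p50)
  expect_identical(ft_r$percentiles$source[1], "zeta")
  # reordering sources permutes the table within Monte-Carlo error
  perm <- c(3, 1, 2)
  spec_p <- toy_spec(src[perm])
  ft_p <- fit(cons$signals, spec_p, seed = 17)
  i <- match(ft$percentiles$source, ft_p$percentiles$source)
  expect_equal(ft_p$percentiles$p50[i], ft$percentiles$p50,
               tolerance = 0.02)
})

test_that("protein/whole-diet cross-check overlaps on shared truths and flags conflicts", {
  sc <- sim_scenario(seed = 6)
  src <- make_sources(sc)
  cc <- make_consumers(sc, src)
  cons <- cc$consumers[[3]]
  spec1 <- build_model_spec("model1", src)
  spec2 <- build_model_spec("model2", src)
  f1 <- fit(cons$signals, spec1, seed = 21)
  f2 <- fit(cons$signals, spec2, seed = 22)
  rep_ok <- fit_protein_vs_wholediet_crosscheck(f1, f2, src)
  expect_true(all(rep_ok$overlap))
  # metric is symmetric: jaccard unchanged if chains are swapped via
  # an identity-protein conversion
  expect_true(all(rep_ok$jaccard >= 0 & rep_ok$jaccard <= 1))

  # adversarial: feed the protein model a consumer whose source-AA signals
  # say "all cereal protein" but hand the cross-check a whole-diet fit that
  # says "almost no cereal" -- the intervals cannot overlap
  cons_a <- toy_consumer(c(1, 0, 0), toy_sources(), noise = FALSE)
  fa <- fit(cons_a$signals, toy_spec(toy_sources()), seed = 31)
  cons_b <- toy_consumer(c(0, 0, 1), toy_sources(), noise = FALSE)
  fb <- fit(cons_b$signals, toy_spec(toy_sources()), seed = 32)
  fb$scale <- "whole_diet"
  rep_bad <- fit_protein_vs_wholediet_crosscheck(fa, fb, toy_sources())
  expect_false(all(rep_bad$overlap))
})

test_that("the olive-oil source is lipid-only and Suess-shifted", {
  src <- make_sources(sim_scenario(seed = 1))
  oil0 <- add_olive_oil_source(src, c(mean = -29, sd = 1),
                               c(mean = 0, sd = 0))[[4]]
  expect_equal(oil0$signals$mean[oil0$signals$element == "C"], -29)
  oil <- add_olive_oil_source(src, c(mean = -29, sd = 1),
                              c(mean = 1.5, sd = 0.2))[[4]]
  expect_equal(oil$signals$mean[oil$signals$element == "C"], -27.5)
  expect_identical(unname(oil$macronutrients),
                   c(0, 0, 1))
})
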