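# End-to-end driver: simulate -> reduce -> predict cereals -> fit -> report.
# The numbered scripts under analysis/ are thin narrative wrappers over the
# stage functions below; run_pipeline() chains all stages for one seed.

.write_csv15 <- function(df, path) {
  out <- as.data.frame(df)
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      out[[col]] <- formatC(out[[col]], format = "g", digits = 15)
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
}

#' Fit one model to every individual of a cohort
#'
#' @param consumers the \code{consumers} element of
#'   \code{\link{make_consumers}} output.
#' @param spec a \code{\link{build_model_spec}} result.
#' @param burn_in,iterations,seed MCMC settings; individual \code{i} uses
#'   seed \code{seed + 1000 * i} so fits are independent but reproducible.
#' @return named list of \code{"diet_posterior"} objects.
#' @export
fit_cohort <- function(consumers, spec, burn_in = 5000, iterations = 10000,
                       seed = 0) {
  out <- lapply(seq_along(consumers), function(i) {
    fit(consumers[[i]]$signals, spec, burn_in = burn_in,
        iterations = iterations, seed = seed + 1000L * i)
  })
  names(out) <- vapply(consumers, function(cn) cn$id, character(1))
  out
}

.percentile_long <- function(posteriors) {
  do.call(rbind, lapply(names(posteriors), function(id) {
    cbind(data.frame(individual = id, stringsAsFactors = FALSE),
          posteriors[[id]]$percentiles)
  }))
}

#' Run the full synthetic study for one seed
#'
#' Chains every stage of the pipeline on synthetic data generated from
#' \code{scenario}: source baselines and a consumer cohort, a raw GC-C-IRMS
#' session for the first individual's amino-acid values (reduced back to an
#' isotope table), a modern/charred grain set (offsets computed and
#' archaeological amino-acid values predicted), per-individual fits of the
#' protein-scale (model 1) and whole-diet (model 2) mixing models, the
#' protein/whole-diet cross-check, and the between-sex cohort summaries.
#' All tables are written as CSV under \code{out_dir} together with a
#' provenance record; outputs are a pure function of \code{scenario} and the
#' MCMC settings, so repeat runs are byte-identical.
#'
#' @param scenario a \code{\link{sim_scenario}}.
#' @param out_dir output directory (created if needed).
#' @param burn_in,iterations MCMC settings per fit.
#' @return invisibly, a list with all in-memory stage results.
#' @export
run_pipeline <- function(scenario, out_dir, burn_in = 5000,
                         iterations = 10000) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- scenario$seed

  # -- simulate ------------------------------------------------------------
  sources <- make_sources(scenario)
  cohort <- make_consumers(scenario, sources)
  .write_csv15(cohort$truth, file.path(out_dir, "truth.csv"))
  cons_tab <- do.call(rbind, lapply(cohort$consumers, function(cn) {
    data.frame(sample_id = cn$id, sex = cn$sex, tissue = "collagen",
               analyte = cn$signals$analyte, element = cn$signals$element,
               delta = cn$signals$delta, sd = cn$signals$sd,
               n_replicates = 3L, stringsAsFactors = FALSE)
  }))
  write_isotope_table(isotope_table(cons_tab),
                      file.path(out_dir, "consumers.csv"))

  # -- reduce a GC session (first individual's true AA values) -------------
  spec2 <- build_model_spec("model2", sources)
  f1 <- cohort$truth$wholediet_fraction[cohort$truth$individual == "ind01"]
  pred <- forward_predict(f1, spec2)
  gc_truth <- data.frame(sample_id = "ind01", analyte = pred$analyte,
                         element = pred$element, delta = pred$mean,
                         stringsAsFactors = FALSE)
  gc_truth <- gc_truth[gc_truth$analyte != "bulk", ]
  gc <- make_gc_session(scenario, gc_truth)
  reduced <- reduce_session(gc$session, gc$standard_truths, gc$counts)
  write_isotope_table(reduced, file.path(out_dir, "reduced_session.csv"))

  # -- cereals -------------------------------------------------------------
  grains <- make_grains(scenario)
  offsets <- compute_offsets(grains$moderns)
  .write_csv15(offsets, file.path(out_dir, "cereal_offsets.csv"))
  predicted <- predict_aa_values(grains$charred, offsets)
  .write_csv15(predicted, file.path(out_dir, "cereal_predicted.csv"))

  # -- fit -----------------------------------------------------------------
  spec1 <- build_model_spec("model1", sources)
  fits1 <- fit_cohort(cohort$consumers, spec1, burn_in, iterations, seed)
  fits2 <- fit_cohort(cohort$consumers, spec2, burn_in, iterations,
                      seed + 500000L)
  .write_csv15(.percentile_long(fits1), file.path(out_dir,
                                                  "fits_model1.csv"))
  .write_csv15(.percentile_long(fits2), file.path(out_dir,
                                                  "fits_model2.csv"))
  cross <- do.call(rbind, lapply(names(fits1), function(id) {
    cbind(data.frame(individual = id, stringsAsFactors = FALSE),
          fit_protein_vs_wholediet_crosscheck(fits1[[id]], fits2[[id]],
                                              sources))
  }))
  .write_csv15(cross, file.path(out_dir, "crosscheck.csv"))

  # -- report --------------------------------------------------------------
  sexes <- vapply(cohort$consumers, function(cn) cn$sex, character(1))
  names(sexes) <- names(fits1)
  cohort1 <- summarize_cohort(fits1, sexes)
  cohort2 <- summarize_cohort(fits2, sexes)
  .write_csv15(cohort1$groups, file.path(out_dir, "cohort_model1.csv"))
  .write_csv15(cohort2$groups, file.path(out_dir, "cohort_model2.csv"))

  write_provenance(out_dir,
                   list(scenario_seed = seed, burn_in = burn_in,
                        iterations = iterations,
                        n_individuals = scenario$n_male + scenario$n_female),
                   seed)

  invisible(list(sources = sources, cohort = cohort, reduced = reduced,
                 offsets = offsets, predicted = predicted, fits1 = fits1,
                 fits2 = fits2, crosscheck = cross, cohort1 = cohort1,
                 cohort2 = cohort2))
}
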