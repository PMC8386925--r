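# Synthetic-data generators: source baselines, consumer cohorts, GC-C-IRMS
# sessions and grain sets, so that every pipeline stage is testable without
# any measured input. All generators are pure functions of
# (scenario, seed): the same scenario yields identical outputs.
#
# The default templates emulate the statistical structure of a first-century
# Mediterranean coastal diet study -- a C3 cereal staple, terrestrial animal
# products, and marine fish that is clearly enriched in both 13C and 15N --
# but the numbers are explicitly synthetic.

#' In-house amino-acid standard reference values
#'
#' EA-IRMS values of the standard mixture used by the synthetic GC sessions:
#' true delta13C of the underivatized standards, the mean delta13C correction
#' factor of their NAIP derivative groups, and true delta15N of the nitrogen
#' standards (norleucine is the internal anchor for both elements).
#'
#' @return data frame (\code{aa}, \code{element}, \code{true_delta},
#'   \code{true_sd}, \code{factor_mean}, \code{factor_sd}).
#' @export
aa_standard_reference <- function() {
  c13 <- data.frame(
    aa = c("Ala", "Gly", "Val", "Leu", "Ile", "Nle", "Thr", "Ser", "Pro",
           "Asx", "Met", "Glx", "Hyp", "Phe", "Lys", "Tyr"),
    element = "C",
    true_delta = c(-19.31, -33.31, -10.89, -13.78, -24.89, -27.59, -10.46,
                   -12.54, -12.33, -27.52, -29.88, -28.57, -12.52, -11.52,
                   -13.7, -24.85),
    true_sd = c(0.02, 0.02, 0.02, 0.06, 0.07, 0.02, 0.01, 0.09, 0.02, 0.12,
                0.14, 0.09, 0.03, 0.05, 0.11, 0.02),
    factor_mean = c(-40.46, -39.73, -45.57, -45.03, -46.31, -43.43, -48.52,
                    -46.56, -42.27, -37.27, -41.82, -36.73, -47.97, -45.36,
                    -48.29, -48.71),
    factor_sd = c(1.22, 1.02, 1.39, 2.10, 1.81, 1.63, 1.25, 1.19, 1.41,
                  1.09, 2.12, 1.10, 1.13, 1.46, 2.29, 1.23),
    stringsAsFactors = FALSE)
  n15 <- data.frame(
    aa = c("Ala", "Gly", "Val", "Leu", "Nle", "Asx", "Glx", "Hyp", "Phe"),
    element = "N",
    true_delta = c(43.25, 1.76, -5.21, 6.22, 14.31, 35.2, -4.52, -9.17,
                   1.70),
    true_sd = c(0.07, 0.06, 0.05, 0.05, 0.23, 0.05, 0.06, 0.05, 0.06),
    factor_mean = NA_real_, factor_sd = NA_real_,
    stringsAsFactors = FALSE)
  rbind(c13, n15)
}

# Amino-acid composition of source protein (weight fractions). Collagen for
# the animal sources; grain storage protein for the cereals.
.AA_COMP_COLLAGEN <- c(Gly = 0.330, Pro = 0.120, Hyp = 0.090, Ala = 0.110,
                       Glx = 0.070, Asx = 0.045, Ser = 0.035, Lys = 0.026,
                       Leu = 0.024, Val = 0.023, Thr = 0.018, Phe = 0.012,
                       Ile = 0.011, Met = 0.006, Tyr = 0.003)
.AA_COMP_GRAIN <- c(Glx = 0.300, Pro = 0.100, Leu = 0.070, Ser = 0.050,
                    Asx = 0.050, Phe = 0.046, Val = 0.044, Gly = 0.040,
                    Ala = 0.035, Ile = 0.035, Thr = 0.030, Tyr = 0.030,
                    Lys = 0.025, Met = 0.015)

.default_templates <- function() {
  sig <- function(el, aa, mean, sd) {
    data.frame(element = el, analyte = aa, mean = mean, sd = sd,
               stringsAsFactors = FALSE)
  }
  list(
    cereals = list(
      signals = rbind(
        sig("C", c("bulk", "Leu", "Val", "Ile", "Phe"),
            c(-23.5, -27.5, -25.5, -26.0, -26.5), c(0.3, rep(0.5, 4))),
        sig("N", c("bulk", "Phe", "Lys"), c(4.0, 3.0, 2.0),
            c(0.5, 0.6, 0.6))),
      aa_concentrations = .AA_COMP_GRAIN,
      macronutrients = c(protein = 0.12, carbohydrate = 0.85, lipid = 0.03),
      macro_offsets = data.frame(
        macronutrient = c("protein", "carbohydrate", "lipid"),
        mean = c(1.0, 0.5, -3.0), sd = c(0.5, 0.3, 1.0),
        stringsAsFactors = FALSE)),
    terrestrial_animals = list(
      signals = rbind(
        sig("C", c("bulk", "Leu", "Val", "Ile", "Phe"),
            c(-20.0, -23.5, -21.5, -22.0, -24.0), c(0.4, rep(0.5, 4))),
        sig("N", c("bulk", "Phe", "Lys"), c(7.0, 6.5, 5.0),
            c(0.7, 0.6, 0.6))),
      aa_concentrations = .AA_COMP_COLLAGEN,
      macronutrients = c(protein = 0.50, carbohydrate = 0.05, lipid = 0.45),
      macro_offsets = data.frame(
        macronutrient = c("protein", "carbohydrate", "lipid"),
        mean = c(-2.0, -1.0, -8.0), sd = c(0.5, 0.5, 1.0),
        stringsAsFactors = FALSE)),
    marine_fish = list(
      signals = rbind(
        sig("C", c("bulk", "Leu", "Val", "Ile", "Phe"),
            c(-12.5, -16.5, -14.5, -15.0, -17.0), c(0.5, rep(0.6, 4))),
        sig("N", c("bulk", "Phe", "Lys"), c(11.0, 9.0, 10.0),
            c(0.8, 0.7, 0.7))),
      aa_concentrations = .AA_COMP_COLLAGEN,
      macronutrients = c(protein = 0.75, carbohydrate = 0, lipid = 0.25),
      macro_offsets = data.frame(
        macronutrient = c("protein", "lipid"),
        mean = c(-2.0, -7.0), sd = c(0.5, 1.0), stringsAsFactors = FALSE))
  )
}

#' Define a simulation scenario
#'
#' Bundles every knob of the synthetic study. Defaults emulate the study
#' conditions the pipeline is designed for: 17 consumers (11 male, 6
#' female), three isotopically separable sources, per-signal measurement
#' sds drawn from 0.3-1.5 per mil, and sex-structured diets whose
#' marine-protein ratio (male/female) is 1.6.
#'
#' @param seed integer master seed.
#' @param n_male,n_female cohort composition.
#' @param diet_protein_male,diet_protein_female per-sex mean diet as
#'   fractions of dietary protein (cereals, terrestrial_animals,
#'   marine_fish).
#' @param dirichlet_concentration concentration of the per-individual
#'   Dirichlet around the sex mean (higher = less between-individual
#'   spread).
#' @param noise_range range (per mil) the per-signal measurement sds are
#'   drawn from.
#' @param min_separation minimum pairwise source separation in standardised
#'   source-AA signal space (Mahalanobis-style distance); 0 marks the
#'   scenario as deliberately degenerate.
#' @param source_jitter sd of the seeded jitter applied to template source
#'   means (per mil).
#' @param replicate_sd GC replicate noise; \code{drift} total common-mode
#'   drift across a session; \code{n_cal} nitrogen instrument scale
#'   (slope, intercept); \code{grain_noise} modern-grain measurement sd;
#'   \code{charred_noise} charred-grain bulk sd.
#' @param templates source templates (see package vignette); override for
#'   non-default baselines.
#' @return list with class \code{"sim_scenario"}.
#' @export
sim_scenario <- function(seed = 1,
                         n_male = 11, n_female = 6,
                         diet_protein_male = c(cereals = 0.35,
                                               terrestrial_animals = 0.35,
                                               marine_fish = 0.30),
                         diet_protein_female = c(cereals = 0.37,
                                                 terrestrial_animals = 0.4425,
                                                 marine_fish = 0.1875),
                         dirichlet_concentration = 150,
                         noise_range = c(0.3, 1.5),
                         min_separation = 3,
                         source_jitter = 0.2,
                         replicate_sd = 0.3,
                         drift = 0,
                         n_cal = c(slope = 0.98, intercept = 0.5),
                         grain_noise = 0.15,
                         charred_noise = 0.2,
                         templates = .default_templates()) {
  stopifnot(abs(sum(diet_protein_male) - 1) < 1e-9,
            abs(sum(diet_protein_female) - 1) < 1e-9,
            all(noise_range > 0), length(noise_range) == 2)
  structure(as.list(environment()), class = "sim_scenario")
}

.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# Pairwise separation of two sources in standardised source-AA signal space.
.source_separation <- function(a, b) {
  sig_a <- a$signals[a$signals$analyte != "bulk", ]
  key <- paste(sig_a$element, sig_a$analyte)
  sig_b <- b$signals[match(key, paste(b$signals$element, b$signals$analyte)), ]
  pooled <- sqrt((sig_a$sd^2 + sig_b$sd^2) / 2)
  sqrt(sum(((sig_a$mean - sig_b$mean) / pooled)^2))
}

#' Generate the source baselines of a scenario
#'
#' Builds the three food-source groups from the scenario templates with a
#' seeded jitter on every signal mean, and checks that all source pairs are
#' separated in standardised source-AA space by at least
#' \code{scenario$min_separation}.
#'
#' @param scenario a \code{\link{sim_scenario}}.
#' @return named list of \code{\link{source_group}}s; attribute
#'   \code{"degenerate"} is \code{TRUE} when \code{min_separation == 0}.
#' @export
make_sources <- function(scenario) {
  set.seed(scenario$seed)
  sources <- lapply(names(scenario$templates), function(nm) {
    tpl <- scenario$templates[[nm]]
    sig <- tpl$signals
    sig$mean <- sig$mean + stats::rnorm(nrow(sig), 0, scenario$source_jitter)
    source_group(nm, sig, tpl$aa_concentrations, tpl$macronutrients,
                 tpl$macro_offsets)
  })
  names(sources) <- names(scenario$templates)
  if (scenario$min_separation > 0) {
    for (i in seq_along(sources)) {
      for (j in seq_len(i - 1)) {
        d <- .source_separation(sources[[i]], sources[[j]])
        if (d < scenario$min_separation) {
          stop("sources '", names(sources)[i], "' and '", names(sources)[j],
               "' are separated by only ", round(d, 2), " (< ",
               scenario$min_separation, "); widen the template means or ",
               "lower min_separation", call. = FALSE)
        }
      }
    }
  }
  attr(sources, "degenerate") <- scenario$min_separation == 0
  sources
}

#' Generate a consumer cohort under the forward model
#'
#' Each individual's whole-diet fractions are drawn from a sex-specific
#' Dirichlet (the sex means are the scenario's protein-scale diets converted
#' to dry-weight shares via the sources' protein contents); every model-2
#' signal is computed by \code{\link{forward_predict}} and perturbed with
#' Gaussian noise at a per-signal sd drawn from \code{scenario$noise_range}.
#'
#' @param scenario a \code{\link{sim_scenario}}.
#' @param sources output of \code{\link{make_sources}}.
#' @param noise_sd optional single sd overriding the scenario range (0 gives
#'   noiseless consumers equal to the forward predictions).
#' @return list with \code{consumers} (per individual: \code{id},
#'   \code{sex}, signal data frame), and \code{truth} (data frame of true
#'   whole-diet and protein-scale fractions per individual).
#' @export
make_consumers <- function(scenario, sources, noise_sd = NULL) {
  set.seed(scenario$seed + 1L)
  spec2 <- build_model_spec("model2", sources)
  prot <- vapply(sources, function(s) s$macronutrients[["protein"]],
                 numeric(1))
  to_wd <- function(fp) { w <- fp / prot; w / sum(w) }
  sexes <- c(rep("male", scenario$n_male), rep("female", scenario$n_female))
  mean_wd <- list(male = to_wd(scenario$diet_protein_male),
                  female = to_wd(scenario$diet_protein_female))
  consumers <- list()
  truth <- list()
  for (i in seq_along(sexes)) {
    id <- sprintf("ind%02d", i)
    f_wd <- .rdirichlet(scenario$dirichlet_concentration *
                          mean_wd[[sexes[i]]])
    pred <- forward_predict(f_wd, spec2)
    sd_i <- if (is.null(noise_sd)) {
      stats::runif(nrow(pred), scenario$noise_range[1],
                   scenario$noise_range[2])
    } else rep(noise_sd, nrow(pred))
    delta <- pred$mean + stats::rnorm(nrow(pred)) * sd_i
    consumers[[id]] <- list(
      id = id, sex = sexes[i],
      signals = data.frame(element = pred$element, analyte = pred$analyte,
                           delta = delta,
                           sd = pmax(sd_i, 1e-6),
                           stringsAsFactors = FALSE))
    f_p <- protein_fractions(f_wd, sources)
    truth[[id]] <- data.frame(
      individual = id, sex = sexes[i], source = names(sources),
      wholediet_fraction = as.numeric(f_wd),
      protein_fraction = as.numeric(f_p), stringsAsFactors = FALSE)
  }
  list(consumers = consumers, truth = do.call(rbind, truth))
}

#' Generate a raw GC-C-IRMS session
#'
#' Builds the per-peak delta table of a session: triplicate injections per
#' sample with a standard-mixture injection before every block of three,
#' for both element modes. Carbon peaks are derivatized through the forward
#' mass balance using the reference correction factors; nitrogen peaks pass
#' through a linear instrument response. A common-mode per-injection term
#' carries optional linear drift; norleucine is present in every injection.
#'
#' @param scenario a \code{\link{sim_scenario}} (uses \code{replicate_sd},
#'   \code{drift}, \code{n_cal}).
#' @param truths data frame (\code{sample_id}, \code{analyte},
#'   \code{element}, \code{delta}) of true underivatized values.
#' @return list: \code{session} (long per-peak table), \code{standard_truths}
#'   (EA-IRMS reference table), \code{counts} (carbon-count table),
#'   \code{generating_factors} (the correction factors used).
#' @export
make_gc_session <- function(scenario, truths) {
  set.seed(scenario$seed + 2L)
  ref <- aa_standard_reference()
  counts <- default_carbon_counts()
  samples <- unique(truths$sample_id)
  derivatize <- function(aa, delta_c) {
    row <- counts[match(aa, counts$aa), ]
    fac <- ref$factor_mean[ref$aa == aa & ref$element == "C"]
    (row$n_C * delta_c + row$n_D * fac) / row$n_DC
  }
  nle_c <- ref$true_delta[ref$aa == "Nle" & ref$element == "C"]
  nle_n <- ref$true_delta[ref$aa == "Nle" & ref$element == "N"]
  rows <- list()
  inj <- 0L
  n_inj_total <- length(samples) * 3 + length(samples) + 1
  common_mode <- function(inj) scenario$drift * inj / n_inj_total
  emit <- function(role, sid, aa, el, true_val, inj) {
    raw <- if (el == "C") derivatize(aa, true_val)
           else scenario$n_cal[["slope"]] * true_val +
                scenario$n_cal[["intercept"]]
    raw <- raw + common_mode(inj) + stats::rnorm(1, 0, scenario$replicate_sd)
    data.frame(injection = inj, role = role, sample_id = sid, analyte = aa,
               element = el, delta = raw, stringsAsFactors = FALSE)
  }
  std_injection <- function(inj) {
    out <- list()
    for (el in c("C", "N")) {
      std <- ref[ref$element == el, ]
      for (r in seq_len(nrow(std))) {
        out[[length(out) + 1]] <- emit("standard", "std_mix", std$aa[r], el,
                                       std$true_delta[r], inj)
      }
    }
    do.call(rbind, out)
  }
  for (b in seq_along(samples)) {
    inj <- inj + 1L
    rows[[length(rows) + 1]] <- std_injection(inj)
    sid <- samples[b]
    tr <- truths[truths$sample_id == sid, ]
    for (rep_i in 1:3) {
      inj <- inj + 1L
      for (r in seq_len(nrow(tr))) {
        rows[[length(rows) + 1]] <- emit("sample", sid, tr$analyte[r],
                                         tr$element[r], tr$delta[r], inj)
      }
      # the spiked norleucine internal standard, both modes
      rows[[length(rows) + 1]] <- emit("sample", sid, "Nle", "C", nle_c, inj)
      rows[[length(rows) + 1]] <- emit("sample", sid, "Nle", "N", nle_n, inj)
    }
  }
  inj <- inj + 1L
  rows[[length(rows) + 1]] <- std_injection(inj)
  list(session = do.call(rbind, rows),
       standard_truths = ref[, c("aa", "element", "true_delta", "true_sd")],
       counts = counts,
       generating_factors = ref[ref$element == "C",
                                c("aa", "factor_mean", "factor_sd")])
}

# True AA-minus-bulk offsets used by the grain generator (per mil).
.GRAIN_TRUE_OFFSETS <- rbind(
  data.frame(aa = c("Leu", "Val", "Ile", "Phe"), element = "C",
             offset = c(-4.0, -2.0, -2.5, -3.0), stringsAsFactors = FALSE),
  data.frame(aa = c("Phe", "Lys"), element = "N",
             offset = c(-1.0, 0.5), stringsAsFactors = FALSE))

#' Generate modern and charred grain sets
#'
#' Three modern grains carry bulk values plus AA values displaced from bulk
#' by a fixed true offset vector (plus measurement noise); four charred
#' archaeological grains carry bulk values only, shifted by the configured
#' charring offsets plus noise.
#'
#' @param scenario a \code{\link{sim_scenario}}.
#' @param charring_offsets per-element charring offsets applied by the
#'   generator (defaults \code{\link{default_charring_offsets}}).
#' @return list: \code{moderns} and \code{charred}
#'   (\code{\link{isotope_table}}s), \code{truth} (true offsets and true
#'   archaeological AA values).
#' @export
make_grains <- function(scenario,
                        charring_offsets = default_charring_offsets()) {
  set.seed(scenario$seed + 3L)
  offs <- .GRAIN_TRUE_OFFSETS
  species <- c("Hordeum vulgare", "Triticum monococcum", "Triticum durum")
  bulk_c <- -23.5 + stats::rnorm(3, 0, 0.4)
  bulk_n <- 4.0 + stats::rnorm(3, 0, 0.6)
  gn <- scenario$grain_noise
  rows <- list()
  for (i in 1:3) {
    sid <- sprintf("modern%02d", i)
    rows[[length(rows) + 1]] <- data.frame(
      sample_id = sid, sex = "unknown", tissue = species[i],
      analyte = "bulk", element = c("C", "N"),
      delta = c(bulk_c[i], bulk_n[i]) + stats::rnorm(2, 0, gn),
      sd = gn, n_replicates = 2L, stringsAsFactors = FALSE)
    for (r in seq_len(nrow(offs))) {
      true_bulk <- if (offs$element[r] == "C") bulk_c[i] else bulk_n[i]
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sid, sex = "unknown", tissue = species[i],
        analyte = offs$aa[r], element = offs$element[r],
        delta = true_bulk + offs$offset[r] + stats::rnorm(1, 0, gn),
        sd = gn, n_replicates = 3L, stringsAsFactors = FALSE)
    }
  }
  moderns <- isotope_table(do.call(rbind, rows))

  arch_c <- -23.2 + stats::rnorm(4, 0, 0.4)
  arch_n <- 4.2 + stats::rnorm(4, 0, 0.5)
  cn <- scenario$charred_noise
  charred_rows <- lapply(1:4, function(i) {
    data.frame(
      sample_id = sprintf("charred%02d", i), sex = "unknown",
      tissue = "charred grain", analyte = "bulk", element = c("C", "N"),
      delta = c(arch_c[i] + charring_offsets$C[["mean"]],
                arch_n[i] + charring_offsets$N[["mean"]]) +
        stats::rnorm(2, 0, cn),
      sd = cn, n_replicates = 2L, stringsAsFactors = FALSE)
  })
  charred <- isotope_table(do.call(rbind, charred_rows))

  true_aa <- do.call(rbind, lapply(seq_len(nrow(offs)), function(r) {
    base <- if (offs$element[r] == "C") arch_c else arch_n
    data.frame(aa = offs$aa[r], element = offs$element[r],
               delta = mean(base) + offs$offset[r], stringsAsFactors = FALSE)
  }))
  list(moderns = moderns, charred = charred,
       truth = list(offsets = offs, arch_bulk_c = arch_c,
                    arch_bulk_n = arch_n, true_aa = true_aa))
}
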