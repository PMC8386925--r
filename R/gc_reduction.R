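# GC-C-IRMS data reduction: norleucine normalisation, nitrogen calibration,
# derivatization-carbon correction, and uncertainty propagation.
#
# Measurements of N-acetyl-i-propyl (NAIP) amino-acid esters carry exogenous
# derivative carbon; the correction removes it by isotope mass balance
#   n_DC * d13C_DC = n_C * d13C_C + n_D * d13C_D
# where C is the underivatized amino acid, D the derivative group and DC the
# derivatized compound.

#' Default NAIP derivative carbon-count table
#'
#' Carbon counts of the underivatized amino acid (\code{n_C}), of the
#' derivative group added by acetylation/esterification (\code{n_D}: 2 per
#' acetylated amine plus 3 per esterified carboxyl), and of the derivatized
#' compound (\code{n_DC = n_C + n_D}). Asx and Glx carry a second ester, Lys
#' and Tyr a second acetyl. Override by passing a modified table where a
#' different derivative chemistry is used.
#'
#' @return data frame with columns \code{aa}, \code{n_C}, \code{n_D},
#'   \code{n_DC}.
#' @export
default_carbon_counts <- function() {
  n_C <- c(Ala = 3, Gly = 2, Val = 5, Leu = 6, Ile = 6, Thr = 4, Ser = 3,
           Pro = 5, Asx = 4, Glx = 5, Phe = 9, Lys = 6, Tyr = 9, Hyp = 5,
           Met = 5, Nle = 6)
  n_D <- c(Ala = 5, Gly = 5, Val = 5, Leu = 5, Ile = 5, Thr = 5, Ser = 5,
           Pro = 5, Asx = 8, Glx = 8, Phe = 5, Lys = 7, Tyr = 7, Hyp = 5,
           Met = 5, Nle = 5)
  data.frame(aa = names(n_C), n_C = unname(n_C), n_D = unname(n_D),
             n_DC = unname(n_C + n_D), stringsAsFactors = FALSE)
}

.counts_row <- function(counts, aa) {
  i <- match(aa, counts$aa)
  if (is.na(i)) stop("no carbon counts for amino acid '", aa, "'",
                     call. = FALSE)
  row <- counts[i, ]
  validate_counts(row)
  row
}

#' @keywords internal
validate_counts <- function(row) {
  if (any(c(row$n_C, row$n_D, row$n_DC) < 1)) {
    stop("carbon counts must be >= 1", call. = FALSE)
  }
  if (row$n_DC != row$n_C + row$n_D) {
    stop("invalid carbon counts for ", row$aa,
         ": n_DC must equal n_C + n_D", call. = FALSE)
  }
  invisible(row)
}

#' Combine measurement uncertainties (Kragten-style quadrature)
#'
#' Combines the standard deviation of sample replicates with the standard
#' deviations of the reference materials used in the run, treating the
#' contributions as independent so they add in quadrature.
#'
#' @param replicate_sd 1-sigma of the sample replicates (per mil).
#' @param reference_sds numeric vector of reference-material 1-sigmas.
#' @return combined 1-sigma (per mil).
#' @export
combine_uncertainty_kragten <- function(replicate_sd, reference_sds = numeric()) {
  sds <- c(replicate_sd, reference_sds)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop("all standard deviations must be finite and >= 0", call. = FALSE)
  }
  sqrt(sum(sds^2))
}

#' Normalise a run to the norleucine internal standard
#'
#' Every amino-acid delta in the run is shifted by the difference between the
#' norleucine anchor value and the norleucine measured in this run. Because
#' norleucine is co-injected, the shift removes common-mode instrumental
#' drift and any per-hydrolysis offset.
#'
#' @param sample_deltas named numeric vector (names are AA codes) of deltas.
#' @param sample_nle the norleucine delta measured in this run.
#' @param standard_nle_true the anchor value norleucine is pinned to.
#' @return named numeric vector of shifted deltas; \code{Nle}, if present,
#'   maps exactly to \code{standard_nle_true}.
#' @export
norleucine_normalize <- function(sample_deltas, sample_nle, standard_nle_true) {
  if (!is.finite(sample_nle)) {
    stop("reduction error: norleucine peak missing from run", call. = FALSE)
  }
  out <- sample_deltas + (standard_nle_true - sample_nle)
  if ("Nle" %in% names(out)) out[["Nle"]] <- standard_nle_true
  out
}

#' Calibrate nitrogen deltas against a standard mixture
#'
#' Ordinary least squares of true on raw values across the nitrogen
#' standards; samples are mapped through the fitted line. The residual
#' standard deviation of the fit is reported so it can be folded into the
#' output uncertainty.
#'
#' @param raw named numeric vector of raw sample deltas per AA.
#' @param standards data frame with columns \code{aa}, \code{raw_delta},
#'   \code{true_delta} (one row per nitrogen standard).
#' @return list with \code{delta} (calibrated named vector), \code{slope},
#'   \code{intercept}, \code{residual_sd}.
#' @export
calibrate_n15 <- function(raw, standards) {
  if (nrow(standards) < 2) {
    stop("calibration error: need >= 2 nitrogen standards", call. = FALSE)
  }
  fit <- stats::lm(true_delta ~ raw_delta, data = standards)
  co <- stats::coef(fit)
  # summary.lm warns on an exactly collinear (noise-free) calibration;
  # a zero residual sd is the correct answer there
  resid_sd <- if (nrow(standards) > 2) {
    suppressWarnings(summary(fit)$sigma)
  } else 0
  list(delta = co[[1]] + co[[2]] * raw,
       slope = co[[2]], intercept = co[[1]], residual_sd = resid_sd)
}

#' Remove derivative carbon from a measured delta
#'
#' Solves the isotope mass balance for the underivatized amino acid:
#' \code{d13C_C = (n_DC * d13C_DC - n_D * d13C_D) / n_C}.
#'
#' @param delta_DC measured delta of the derivatized compound (per mil).
#' @param delta_D correction factor: effective delta of the derivative
#'   carbon, including the kinetic isotope effect of derivatization.
#' @param counts one row of a carbon-count table (\code{n_C}, \code{n_D},
#'   \code{n_DC}).
#' @return corrected delta of the underivatized amino acid (per mil).
#' @export
correct_derivatization_c13 <- function(delta_DC, delta_D, counts) {
  validate_counts(counts)
  (counts$n_DC * delta_DC - counts$n_D * delta_D) / counts$n_C
}

#' Derive a correction factor from a standard of known composition
#'
#' Inverts the mass balance for the derivative group:
#' \code{d13C_D = (n_DC * d13C_DC - n_C * d13C_C) / n_D}, using a standard
#' whose underivatized (true) and derivatized (raw) deltas are both known.
#' Averaging across bracketing standard injections is done by the caller.
#'
#' @param raw_delta measured delta of the derivatized standard.
#' @param true_delta known delta of the underivatized standard.
#' @param counts one row of a carbon-count table.
#' @return the correction factor \code{d13C_D} (per mil).
#' @export
derive_correction_factor <- function(raw_delta, true_delta, counts) {
  validate_counts(counts)
  (counts$n_DC * raw_delta - counts$n_C * true_delta) / counts$n_D
}

#' Propagate derivatization-correction uncertainty
#'
#' The corrected delta inherits error from the nonderivatized standard (S),
#' the derivatized standard (DS) and the derivatized compound (DC):
#' \deqn{\sigma^2 = \sigma_S^2 (n_S/n_C)^2 + \sigma_{DS}^2 ((n_S+n_D)/n_C)^2 +
#'       \sigma_{DC}^2 ((n_C+n_D)/n_C)^2}
#' With \code{squared_ratios = FALSE} the second and third ratios enter
#' unsquared (an alternative typographic reading of the propagation formula);
#' the squared form is the default and is the one consistent with first-order
#' Gaussian propagation through the mass balance (see the package vignette).
#'
#' @param sigma_S sd of the nonderivatized standard (per mil).
#' @param sigma_DS sd of the derivatized standard (per mil).
#' @param sigma_DC sd of the derivatized compound (per mil).
#' @param n_S carbons in the nonderivatized standard.
#' @param n_D carbons in the derivative group.
#' @param n_C carbons in the underivatized compound.
#' @param squared_ratios logical; see Details.
#' @return propagated 1-sigma (per mil).
#' @export
propagate_correction_error <- function(sigma_S, sigma_DS, sigma_DC,
                                       n_S, n_D, n_C,
                                       squared_ratios = TRUE) {
  if (n_C <= 0) stop("n_C must be > 0", call. = FALSE)
  if (any(c(sigma_S, sigma_DS, sigma_DC) < 0)) {
    stop("sigmas must be >= 0", call. = FALSE)
  }
  r1 <- n_S / n_C
  r2 <- (n_S + n_D) / n_C
  r3 <- (n_C + n_D) / n_C
  if (squared_ratios) {
    sqrt(sigma_S^2 * r1^2 + sigma_DS^2 * r2^2 + sigma_DC^2 * r3^2)
  } else {
    sqrt(sigma_S^2 * r1^2 + sigma_DS^2 * r2 + sigma_DC^2 * r3)
  }
}

.trip_stats <- function(x) {
  c(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else 0,
    n = length(x))
}

#' Reduce a GC-C-IRMS session to a per-AA isotope table
#'
#' Takes the per-peak deltas of a session (triplicate sample injections with
#' a standard-mixture injection bracketing every three sample injections) and
#' produces corrected per-AA deltas with propagated uncertainties:
#' \itemize{
#'   \item every injection is normalised to its own norleucine peak,
#'     removing common-mode drift and per-hydrolysis offsets;
#'   \item carbon deltas are corrected for derivative carbon using correction
#'     factors averaged over the session's standard injections;
#'   \item nitrogen deltas are mapped through an OLS calibration of true on
#'     raw values across the standard mixture;
#'   \item uncertainties combine replicate scatter, standard scatter and
#'     reference-material uncertainty in quadrature (carbon additionally via
#'     the derivatization error-propagation formula).
#' }
#' Samples with fewer than three injections are reduced with a warning and a
#' reduced \code{n_replicates}; triplicates where one injection lies more
#' than three replicate-sds from the median are flagged in the
#' \code{"outliers"} attribute, never dropped.
#'
#' @param session data frame of per-peak deltas with columns
#'   \code{injection} (run order), \code{role} (\code{"sample"} or
#'   \code{"standard"}), \code{sample_id}, \code{analyte}, \code{element},
#'   \code{delta}.
#' @param standard_truths data frame with columns \code{aa}, \code{element},
#'   \code{true_delta}, \code{true_sd}: the standard mixture's EA-IRMS
#'   values.
#' @param counts carbon-count table (default \code{default_carbon_counts()}).
#' @param squared_ratios propagation-formula reading, see
#'   \code{\link{propagate_correction_error}}.
#' @param tissue tissue label written into the output table.
#' @return an \code{\link{isotope_table}} with one row per
#'   (sample, analyte, element), with attributes \code{"outliers"} (data
#'   frame of flagged triplicates) and \code{"calibration"} (nitrogen fit
#'   summary).
#' @export
reduce_session <- function(session, standard_truths,
                           counts = default_carbon_counts(),
                           squared_ratios = TRUE, tissue = "collagen") {
  stopifnot(all(c("injection", "role", "sample_id", "analyte", "element",
                  "delta") %in% names(session)))
  session$analyte <- canonical_analyte(session$analyte)
  std <- session[session$role == "standard", ]
  smp <- session[session$role == "sample", ]
  n_std_inj <- length(unique(std$injection))
  n_smp_inj <- length(unique(smp$injection))
  if (n_std_inj < ceiling(n_smp_inj / 3) || n_std_inj < 1) {
    stop("reduction error: need at least one standard bracket per three ",
         "sample injections (got ", n_std_inj, " standard and ", n_smp_inj,
         " sample injections)", call. = FALSE)
  }

  truths <- standard_truths
  truths$aa <- canonical_analyte(truths$aa)
  truth_of <- function(aa, el, what) {
    i <- which(truths$aa == aa & truths$element == el)
    if (length(i) == 0) return(NA_real_)
    truths[[what]][i[1]]
  }

  # Per-injection norleucine anchoring, separately per element mode.
  anchor_injection <- function(df, el, target) {
    out <- df[df$element == el, ]
    split_out <- split(out, out$injection)
    split_out <- lapply(split_out, function(inj) {
      nle <- inj$delta[inj$analyte == "Nle"]
      if (length(nle) == 0) {
        stop("reduction error: norleucine peak missing from injection ",
             inj$injection[1], call. = FALSE)
      }
      inj$delta <- as.numeric(
        norleucine_normalize(stats::setNames(inj$delta, inj$analyte),
                             nle[1], target))
      inj
    })
    do.call(rbind, split_out)
  }

  out_rows <- list()
  outliers <- list()
  calib_info <- NULL

  for (el in intersect(c("C", "N"), unique(session$element))) {
    # Anchor target: the session-mean standard Nle on the measured scale for
    # carbon (samples and standards share the derivatized scale); the known
    # Nle value for nitrogen.
    std_nle <- std$delta[std$element == el & std$analyte == "Nle"]
    if (length(std_nle) == 0) {
      stop("reduction error: standard mixture lacks a norleucine peak (",
           el, " mode)", call. = FALSE)
    }
    target <- if (el == "C") mean(std_nle) else truth_of("Nle", "N",
                                                         "true_delta")
    std_el <- anchor_injection(std, el, target)
    smp_el <- anchor_injection(smp, el, target)

    # Per-AA standard statistics across bracketing injections.
    std_stats <- do.call(rbind, lapply(split(std_el, std_el$analyte),
      function(d) data.frame(aa = d$analyte[1], raw_mean = mean(d$delta),
                             raw_sd = if (nrow(d) > 1) stats::sd(d$delta) else 0,
                             stringsAsFactors = FALSE)))

    if (el == "N") {
      cal_tab <- std_stats
      cal_tab$true_delta <- vapply(cal_tab$aa, truth_of, numeric(1),
                                   el = "N", what = "true_delta")
      cal_tab <- cal_tab[is.finite(cal_tab$true_delta), ]
      cal <- calibrate_n15(numeric(), data.frame(
        aa = cal_tab$aa, raw_delta = cal_tab$raw_mean,
        true_delta = cal_tab$true_delta, stringsAsFactors = FALSE))
      calib_info <- cal[c("slope", "intercept", "residual_sd")]
    }

    for (sid in unique(smp_el$sample_id)) {
      d_s <- smp_el[smp_el$sample_id == sid, ]
      for (aa in setdiff(unique(d_s$analyte), "Nle")) {
        reps <- d_s$delta[d_s$analyte == aa]
        st <- .trip_stats(reps)
        if (st[["n"]] < 3) {
          warning("sample ", sid, " ", aa, " (", el, "): only ", st[["n"]],
                  " replicate(s); reduced n flagged", call. = FALSE)
        }
        if (st[["n"]] >= 3 && st[["sd"]] > 0 &&
            any(abs(reps - stats::median(reps)) > 3 * st[["sd"]])) {
          outliers[[length(outliers) + 1]] <- data.frame(
            sample_id = sid, analyte = aa, element = el,
            stringsAsFactors = FALSE)
        }
        if (el == "C") {
          row <- .counts_row(counts, aa)
          std_i <- match(aa, std_stats$aa)
          if (is.na(std_i)) next  # no bracketing standard for this AA
          true_d <- truth_of(aa, "C", "true_delta")
          true_sd <- truth_of(aa, "C", "true_sd")
          if (!is.finite(true_d)) next
          factor_D <- derive_correction_factor(std_stats$raw_mean[std_i],
                                               true_d, row)
          delta <- correct_derivatization_c13(st[["mean"]], factor_D, row)
          sd_out <- propagate_correction_error(
            sigma_S = if (is.finite(true_sd)) true_sd else 0,
            sigma_DS = std_stats$raw_sd[std_i],
            sigma_DC = st[["sd"]],
            n_S = row$n_C, n_D = row$n_D, n_C = row$n_C,
            squared_ratios = squared_ratios)
        } else {
          delta <- as.numeric(cal$intercept + cal$slope * st[["mean"]])
          tsd <- truth_of(aa, "N", "true_sd")
          if (!is.finite(tsd)) tsd <- 0
          sd_out <- combine_uncertainty_kragten(st[["sd"]],
                                                c(cal$residual_sd, tsd))
        }
        out_rows[[length(out_rows) + 1]] <- data.frame(
          sample_id = sid, sex = "unknown", tissue = tissue, analyte = aa,
          element = el, delta = delta, sd = sd_out,
          n_replicates = as.integer(st[["n"]]), stringsAsFactors = FALSE)
      }
    }
  }

  tab <- isotope_table(do.call(rbind, out_rows))
  attr(tab, "outliers") <- if (length(outliers)) do.call(rbind, outliers)
                           else NULL
  attr(tab, "calibration") <- calib_info
  tab
}
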