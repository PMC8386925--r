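# Concentration-dependent Bayesian mixing models with metabolic routing.
#
# Four model structures over the same engine:
#   model0p  - bulk collagen d13C/d15N, protein-routed source values
#   model0wd - bulk collagen d13C/d15N, macronutrient-scrambled source values
#   model1   - source amino acids only (C: Leu, Val, Ile, Phe; N: Phe, Lys);
#              fractions are shares of dietary protein
#   model2   - model1 plus trophic AAs (C: Ala glycolytic, Glx/Asx from the
#              metabolic carbon pool; N: Glx from the nitrogen pool);
#              fractions are shares of whole diet by dry weight
#
# Routing classes (per signal) decide where a source's value for that signal
# comes from and which carrier concentration weights the source:
#   source_direct - measured AA value; carrier = AA fraction of protein
#                   (times protein fraction of dry weight on the whole-diet
#                   scale)
#   glycolytic    - carbohydrate d13C; carrier = carbohydrate mass
#   carbon_pool   - mass-weighted macronutrient d13C; carrier = total dry mass
#   nitrogen_pool - bulk d15N plus the trophic Glx shift; carrier = protein
#   bulk_protein  - bulk value routed from protein; carrier = protein
#   bulk_scrambled- carbon as carbon_pool, nitrogen as bulk_protein;
#                   carrier = total dry mass (C) / protein (N)

.MACROS <- c("protein", "carbohydrate", "lipid")

#' Construct a food-source group
#'
#' @param name source name (e.g. \code{"cereals"}).
#' @param signals data frame (\code{element}, \code{analyte}, \code{mean},
#'   \code{sd}) of measured isotope values: per-AA values plus \code{bulk}
#'   rows per element.
#' @param aa_concentrations named numeric vector: fraction of the source's
#'   protein made up by each AA (by weight).
#' @param macronutrients named numeric \code{c(protein=, carbohydrate=,
#'   lipid=)} fractions of dry weight, summing to 1.
#' @param macro_offsets data frame (\code{macronutrient}, \code{mean},
#'   \code{sd}): delta13C offset of each macronutrient from the measured bulk
#'   value.
#' @return a list with class \code{"source_group"}.
#' @export
source_group <- function(name, signals, aa_concentrations,
                         macronutrients, macro_offsets) {
  stopifnot(all(c("element", "analyte", "mean", "sd") %in% names(signals)))
  signals$analyte <- canonical_analyte(signals$analyte)
  if (any(signals$sd < 0)) stop("signal sds must be >= 0", call. = FALSE)
  m <- macronutrients[.MACROS]
  if (anyNA(m)) stop("macronutrients must name ",
                     paste(.MACROS, collapse = ", "), call. = FALSE)
  if (any(m < 0 | m > 1) || abs(sum(m) - 1) > 1e-9) {
    stop("macronutrient fractions must lie in [0,1] and sum to 1",
         call. = FALSE)
  }
  if (any(aa_concentrations < 0)) {
    stop("aa_concentrations must be >= 0", call. = FALSE)
  }
  structure(list(name = name, signals = signals,
                 aa_concentrations = aa_concentrations,
                 macronutrients = m, macro_offsets = macro_offsets),
            class = "source_group")
}

.sig_lookup <- function(source, element, analyte) {
  s <- source$signals
  i <- which(s$element == element & s$analyte == analyte)
  if (length(i) == 0) return(NULL)
  c(mean = s$mean[i[1]], sd = s$sd[i[1]])
}

.macro_offset <- function(source, macro) {
  mo <- source$macro_offsets
  i <- which(mo$macronutrient == macro)
  if (length(i) == 0) {
    stop("source '", source$name, "' lacks a delta13C offset for ",
         macro, call. = FALSE)
  }
  c(mean = mo$mean[i[1]], sd = mo$sd[i[1]])
}

.carbon_pool_value <- function(source) {
  bulk <- .sig_lookup(source, "C", "bulk")
  if (is.null(bulk)) {
    stop("source '", source$name, "' lacks a bulk d13C value", call. = FALSE)
  }
  fr <- source$macronutrients
  mu <- bulk[["mean"]]
  v <- bulk[["sd"]]^2
  for (m in .MACROS) {
    if (fr[[m]] > 0) {
      off <- .macro_offset(source, m)
      mu <- mu + fr[[m]] * off[["mean"]]
      v <- v + fr[[m]]^2 * off[["sd"]]^2
    }
  }
  c(mean = mu, sd = sqrt(v))
}

#' Default mixing-model configuration
#'
#' Tunable offsets and their 1-sigmas (per mil):
#' \describe{
#'   \item{source_direct_offset_sd}{diet-to-collagen fractionation allowance
#'     for source AAs; their fractionation is negligible (<1 per mil) so the
#'     mean is 0 and the default sd 0.5.}
#'   \item{trophic_c_offset}{diet-to-collagen offset for trophic carbon
#'     signals (Ala, Glx, Asx), mean 0 with a conservative sd of 1.}
#'   \item{trophic_n15_glx}{shift between a food's bulk nitrogen pool and
#'     collagen Glx, +8 +/- 1, the consumer-feeding-study convention.}
#'   \item{bulk_c_offset, bulk_n_offset}{diet-to-collagen offsets for the
#'     bulk models (0p/0wd): +4.8 +/- 0.5 and +5.5 +/- 0.5.}
#'   \item{glycolytic_fallback}{when a source has no carbohydrate mass, route
#'     its glycolytic signal value from the carbon pool (with a warning)
#'     instead of erroring.}
#' }
#'
#' @param ... named overrides of the defaults.
#' @return list of configuration values.
#' @export
model_config <- function(...) {
  cfg <- list(
    source_direct_offset_sd = 0.5,
    trophic_c_offset = c(mean = 0, sd = 1.0),
    trophic_n15_glx = c(mean = 8.0, sd = 1.0),
    bulk_c_offset = c(mean = 4.8, sd = 0.5),
    bulk_n_offset = c(mean = 5.5, sd = 0.5),
    glycolytic_fallback = TRUE
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg
}

#' Isotope value a source presents to one signal
#'
#' Applies the signal's routing class to the source's measurements (see the
#' header comment of this module), propagating uncertainties in quadrature.
#'
#' @param source a \code{\link{source_group}}.
#' @param signal list or one-row data frame with \code{element},
#'   \code{analyte}, \code{routing}.
#' @param config a \code{\link{model_config}} list.
#' @return \code{c(mean, sd)} in per mil.
#' @export
source_signal_value <- function(source, signal, config = model_config()) {
  routing <- signal$routing
  el <- signal$element
  if (routing == "source_direct") {
    v <- .sig_lookup(source, el, signal$analyte)
    if (is.null(v)) {
      stop("source '", source$name, "' lacks a measured ", el, " value for ",
           signal$analyte, call. = FALSE)
    }
    return(v)
  }
  if (routing == "glycolytic") {
    if (source$macronutrients[["carbohydrate"]] <= 0) {
      if (!isTRUE(config$glycolytic_fallback)) {
        stop("source '", source$name, "' has no carbohydrate mass for a ",
             "glycolytic signal", call. = FALSE)
      }
      warning("source '", source$name, "' has no carbohydrate mass; ",
              "glycolytic signal routed from the carbon pool", call. = FALSE)
      return(.carbon_pool_value(source))
    }
    bulk <- .sig_lookup(source, "C", "bulk")
    off <- .macro_offset(source, "carbohydrate")
    return(c(mean = bulk[["mean"]] + off[["mean"]],
             sd = sqrt(bulk[["sd"]]^2 + off[["sd"]]^2)))
  }
  if (routing == "carbon_pool") return(.carbon_pool_value(source))
  if (routing == "nitrogen_pool") {
    bulk <- .sig_lookup(source, "N", "bulk")
    if (is.null(bulk)) {
      stop("source '", source$name, "' lacks a bulk d15N value",
           call. = FALSE)
    }
    tr <- config$trophic_n15_glx
    return(c(mean = bulk[["mean"]] + tr[["mean"]],
             sd = sqrt(bulk[["sd"]]^2 + tr[["sd"]]^2)))
  }
  if (routing == "bulk_protein") {
    bulk <- .sig_lookup(source, el, "bulk")
    if (is.null(bulk)) {
      stop("source '", source$name, "' lacks a bulk ", el, " value",
           call. = FALSE)
    }
    if (el == "C") {
      off <- .macro_offset(source, "protein")
      return(c(mean = bulk[["mean"]] + off[["mean"]],
               sd = sqrt(bulk[["sd"]]^2 + off[["sd"]]^2)))
    }
    return(bulk)
  }
  if (routing == "bulk_scrambled") {
    if (el == "C") return(.carbon_pool_value(source))
    bulk <- .sig_lookup(source, "N", "bulk")
    return(bulk)
  }
  stop("unknown routing class '", routing, "'", call. = FALSE)
}

# Carrier concentration of a signal in a source (the q of the
# concentration-dependent weights), on the model's fraction scale.
.carrier_q <- function(source, signal, scale) {
  fr <- source$macronutrients
  routing <- signal$routing
  if (routing == "source_direct") {
    aa <- signal$analyte
    conc <- source$aa_concentrations[aa]
    conc <- if (length(conc) == 0 || is.na(conc)) 0 else unname(conc)
    return(if (scale == "protein") conc else conc * fr[["protein"]])
  }
  if (routing == "glycolytic") return(fr[["carbohydrate"]])
  if (routing %in% c("carbon_pool")) return(1)
  if (routing %in% c("nitrogen_pool")) return(fr[["protein"]])
  if (routing == "bulk_protein") {
    return(if (scale == "protein") 1 else fr[["protein"]])
  }
  if (routing == "bulk_scrambled") {
    return(if (signal$element == "C") 1 else fr[["protein"]])
  }
  stop("unknown routing class '", routing, "'", call. = FALSE)
}

.signal_table <- function(model_name, config) {
  sd0 <- config$source_direct_offset_sd
  trc <- config$trophic_c_offset
  src_direct <- data.frame(
    element = c("C", "C", "C", "C", "N", "N"),
    analyte = c("Leu", "Val", "Ile", "Phe", "Phe", "Lys"),
    routing = "source_direct", offset_mean = 0, offset_sd = sd0,
    stringsAsFactors = FALSE)
  switch(model_name,
    model1 = src_direct,
    model2 = rbind(src_direct, data.frame(
      element = c("C", "C", "C", "N"),
      analyte = c("Ala", "Glx", "Asx", "Glx"),
      routing = c("glycolytic", "carbon_pool", "carbon_pool",
                  "nitrogen_pool"),
      offset_mean = 0,
      offset_sd = c(trc[["sd"]], trc[["sd"]], trc[["sd"]],
                    config$trophic_n15_glx[["sd"]] * 0),
      stringsAsFactors = FALSE)),
    model0p = data.frame(
      element = c("C", "N"), analyte = "bulk", routing = "bulk_protein",
      offset_mean = c(config$bulk_c_offset[["mean"]],
                      config$bulk_n_offset[["mean"]]),
      offset_sd = c(config$bulk_c_offset[["sd"]],
                    config$bulk_n_offset[["sd"]]),
      stringsAsFactors = FALSE),
    model0wd = data.frame(
      element = c("C", "N"), analyte = "bulk", routing = "bulk_scrambled",
      offset_mean = c(config$bulk_c_offset[["mean"]],
                      config$bulk_n_offset[["mean"]]),
      offset_sd = c(config$bulk_c_offset[["sd"]],
                    config$bulk_n_offset[["sd"]]),
      stringsAsFactors = FALSE),
    stop("unknown model_name '", model_name, "'; valid: model0p, model0wd, ",
         "model1, model2", call. = FALSE))
}

#' Build a fully resolved model specification
#'
#' Resolves the named model's signal set against a set of sources:
#' precomputes every source's per-signal value (mean, sd) and carrier
#' concentration, and validates that each source provides the measurements
#' its nonzero-carrier signals require.
#'
#' Model 1 and model 0p estimate fractions of dietary protein; model 2 and
#' model 0wd estimate fractions of whole diet by dry weight. A protein-scale
#' model over a protein-free source (e.g. olive oil) is a specification
#' error.
#'
#' @param model_name one of \code{"model0p"}, \code{"model0wd"},
#'   \code{"model1"}, \code{"model2"}.
#' @param sources list of \code{\link{source_group}} objects.
#' @param config a \code{\link{model_config}} list.
#' @return list with class \code{"model_spec"}: the signal table, the scale,
#'   matrices \code{vbar}, \code{vsd}, \code{q} (signals x sources) and the
#'   per-signal offset moments.
#' @export
build_model_spec <- function(model_name, sources, config = model_config()) {
  signals <- .signal_table(model_name, config)
  scale <- if (model_name %in% c("model1", "model0p")) "protein"
           else "whole_diet"
  K <- length(sources)
  if (K < 2) stop("need at least two sources", call. = FALSE)
  src_names <- vapply(sources, function(s) s$name, character(1))
  if (scale == "protein") {
    prot <- vapply(sources, function(s) s$macronutrients[["protein"]],
                   numeric(1))
    if (any(prot <= 0)) {
      stop("spec error: protein-scale model over protein-free source(s): ",
           paste(src_names[prot <= 0], collapse = ", "), call. = FALSE)
    }
  }
  S <- nrow(signals)
  vbar <- vsd <- qmat <- matrix(NA_real_, S, K,
                                dimnames = list(NULL, src_names))
  gaps <- character()
  for (s in seq_len(S)) {
    sig <- signals[s, ]
    for (k in seq_len(K)) {
      qmat[s, k] <- .carrier_q(sources[[k]], sig, scale)
      if (qmat[s, k] > 0) {
        v <- tryCatch(source_signal_value(sources[[k]], sig, config),
                      error = function(e) conditionMessage(e))
        if (is.character(v)) {
          gaps <- c(gaps, v)
          next
        }
        vbar[s, k] <- v[["mean"]]
        vsd[s, k] <- v[["sd"]]
      } else {
        vbar[s, k] <- 0
        vsd[s, k] <- 0
      }
    }
    if (all(qmat[s, ] == 0)) {
      gaps <- c(gaps, paste0("signal (", sig$element, ", ", sig$analyte,
                             ") has zero carrier concentration in every ",
                             "source"))
    }
  }
  if (length(gaps) > 0) {
    stop("spec error:\n  ", paste(unique(gaps), collapse = "\n  "),
         call. = FALSE)
  }
  structure(list(model_name = model_name, scale = scale, signals = signals,
                 sources = sources, source_names = src_names,
                 vbar = vbar, vsd = vsd, q = qmat,
                 offset_mean = signals$offset_mean,
                 offset_sd = signals$offset_sd, config = config),
            class = "model_spec")
}

#' Concentration-dependent mixing weights for one signal
#'
#' \eqn{w_i = f_i q_i / \sum_j f_j q_j}, where \eqn{q_i} is source \eqn{i}'s
#' concentration of the signal's carrier.
#'
#' @param diet_fractions numeric simplex vector over sources.
#' @param signal list with \code{element}, \code{analyte}, \code{routing}.
#' @param sources list of \code{\link{source_group}}s.
#' @param scale \code{"protein"} or \code{"whole_diet"}.
#' @return numeric simplex vector of weights.
#' @export
concentration_weights <- function(diet_fractions, signal, sources,
                                  scale = "whole_diet") {
  stopifnot(length(diet_fractions) == length(sources))
  if (any(diet_fractions < -1e-12) ||
      abs(sum(diet_fractions) - 1) > 1e-9) {
    stop("diet_fractions must lie on the simplex", call. = FALSE)
  }
  q <- vapply(sources, .carrier_q, numeric(1), signal = signal,
              scale = scale)
  num <- diet_fractions * q
  tot <- sum(num)
  if (tot <= 0) {
    stop("degenerate signal: zero carrier concentration under these ",
         "fractions", call. = FALSE)
  }
  num / tot
}

#' Predicted consumer values under given diet fractions
#'
#' For each signal of a resolved model spec, the predicted consumer value is
#' the concentration-weighted mean of the source values plus the
#' diet-to-consumer offset. The predictive sd combines source-value
#' uncertainty (weighted in quadrature) and offset uncertainty; measurement
#' noise is not included.
#'
#' @param diet_fractions simplex vector over the spec's sources.
#' @param spec a \code{\link{build_model_spec}} result.
#' @return data frame (\code{element}, \code{analyte}, \code{mean},
#'   \code{sd}).
#' @export
forward_predict <- function(diet_fractions, spec) {
  stopifnot(inherits(spec, "model_spec"))
  f <- diet_fractions
  if (any(f < -1e-12) || abs(sum(f) - 1) > 1e-9) {
    stop("diet_fractions must lie on the simplex", call. = FALSE)
  }
  S <- nrow(spec$signals)
  mu <- sd <- numeric(S)
  for (s in seq_len(S)) {
    num <- f * spec$q[s, ]
    w <- num / sum(num)
    mu[s] <- sum(w * spec$vbar[s, ]) + spec$offset_mean[s]
    sd[s] <- sqrt(sum(w^2 * spec$vsd[s, ]^2) + spec$offset_sd[s]^2)
  }
  data.frame(element = spec$signals$element, analyte = spec$signals$analyte,
             mean = mu, sd = sd, stringsAsFactors = FALSE)
}

.match_consumer <- function(consumer, spec) {
  key_c <- paste(consumer$element, consumer$analyte)
  key_s <- paste(spec$signals$element, spec$signals$analyte)
  i <- match(key_s, key_c)
  if (anyNA(i)) {
    stop("consumer lacks signal(s): ",
         paste(key_s[is.na(i)], collapse = ", "), call. = FALSE)
  }
  m <- consumer$delta[i]
  s <- consumer$sd[i]
  if (any(!is.finite(s)) || any(s <= 0)) {
    stop("every consumer signal needs sd > 0", call. = FALSE)
  }
  list(m = m, sd = s)
}

#' Fit the mixing model to one consumer
#'
#' Posterior over diet fractions under a flat Dirichlet(1,...,1) prior,
#' Gaussian priors on source values and offsets at their (mean, sd), and a
#' Gaussian likelihood per signal at the measured value's sd. The Gaussian
#' source values and offsets are linear in the likelihood given the
#' fractions, so they are marginalised analytically and the sampler walks
#' only the fraction simplex: component-wise random-walk Metropolis-Hastings
#' on additive-logratio coordinates, with per-coordinate step adaptation
#' during burn-in (frozen afterwards, preserving detailed balance).
#'
#' @param consumer data frame with columns \code{element}, \code{analyte},
#'   \code{delta}, \code{sd} covering every signal of the spec (an
#'   \code{\link{isotope_table}} works).
#' @param spec a \code{\link{build_model_spec}} result.
#' @param burn_in discarded adaptation iterations (default 5000).
#' @param iterations retained iterations (default 10000).
#' @param seed integer RNG seed; same seed and inputs give bit-identical
#'   results.
#' @param chains number of chains (seeds \code{seed + 0:(chains-1)}); draws
#'   are pooled for the percentile table.
#' @return object of class \code{"diet_posterior"}: \code{chains} (pooled
#'   draws x sources), \code{loglik} per draw, \code{percentiles} (source x
#'   {2.5, 16, 50, 84, 97.5}), \code{diagnostics} (acceptance rate(s), lag
#'   autocorrelations, convergence warning flag), and the settings used.
#' @export
fit <- function(consumer, spec, burn_in = 5000, iterations = 10000,
                seed = 0, chains = 1) {
  stopifnot(inherits(spec, "model_spec"))
  obs <- .match_consumer(consumer, spec)
  K <- length(spec$source_names)
  draws <- vector("list", chains)
  lls <- vector("list", chains)
  acc <- numeric(chains)
  for (ch in seq_len(chains)) {
    set.seed(as.integer(seed) + ch - 1L)
    res <- .mh_sample_cpp(obs$m, obs$sd^2, spec$vbar, spec$vsd^2, spec$q,
                          spec$offset_mean, spec$offset_sd^2,
                          as.integer(burn_in), as.integer(iterations),
                          rep(0, K - 1), 0.5, 50L, 0.44)
    colnames(res$chains) <- spec$source_names
    draws[[ch]] <- res$chains
    lls[[ch]] <- res$loglik
    acc[ch] <- res$acceptance_rate
  }
  chains_mat <- do.call(rbind, draws)
  loglik <- unlist(lls)
  probs <- c(0.025, 0.16, 0.5, 0.84, 0.975)
  pct <- t(apply(chains_mat, 2, stats::quantile, probs = probs))
  colnames(pct) <- c("p2.5", "p16", "p50", "p84", "p97.5")
  lag_ac <- vapply(c(1L, 5L, 10L, 50L), function(l) {
    mean(vapply(seq_len(K), function(k) {
      x <- draws[[1]][, k]
      stats::cor(x[seq_len(length(x) - l)], x[-seq_len(l)])
    }, numeric(1)))
  }, numeric(1))
  conv_warn <- any(acc < 0.05 | acc > 0.8)
  if (conv_warn) {
    warning("acceptance rate outside [0.05, 0.8] after adaptation; ",
            "inspect diagnostics", call. = FALSE)
  }
  structure(list(
    chains = chains_mat, loglik = loglik, observed = obs, spec = spec,
    percentiles = data.frame(source = spec$source_names, pct,
                             row.names = NULL, check.names = FALSE),
    diagnostics = list(acceptance_rate = acc,
                       lag_autocorr = stats::setNames(lag_ac,
                         paste0("lag", c(1, 5, 10, 50))),
                       convergence_warning = conv_warn),
    model_name = spec$model_name, scale = spec$scale,
    source_names = spec$source_names,
    settings = list(burn_in = burn_in, iterations = iterations,
                    seed = seed, chains = chains)),
    class = "diet_posterior")
}

#' @export
print.diet_posterior <- function(x, ...) {
  cat("Diet posterior (", x$model_name, ", ", x$scale, " scale; ",
      nrow(x$chains), " draws)\n", sep = "")
  print(x$percentiles, digits = 3)
  cat("acceptance rate:",
      paste(sprintf("%.2f", x$diagnostics$acceptance_rate), collapse = ", "),
      "\n")
  invisible(x)
}

# Marginal log-likelihood on the fraction scale (R mirror of the sampler's
# target, used to polish the posterior mode).
.marginal_loglik <- function(f, spec, m, s_meas) {
  ll <- 0
  for (s in seq_len(nrow(spec$signals))) {
    num <- f * spec$q[s, ]
    tot <- sum(num)
    if (tot <= 0) return(-Inf)
    w <- num / tot
    mu <- sum(w * spec$vbar[s, ]) + spec$offset_mean[s]
    v <- s_meas[s]^2 + sum(w^2 * spec$vsd[s, ]^2) + spec$offset_sd[s]^2
    ll <- ll + stats::dnorm(m[s], mu, sqrt(v), log = TRUE)
  }
  ll
}

#' Posterior mode of the diet fractions
#'
#' Starts from the retained draw with the highest marginal log-likelihood
#' and, by default, polishes it with a Nelder-Mead ascent of the same
#' marginal likelihood on additive-logratio coordinates; under the flat
#' Dirichlet prior this is the maximum-a-posteriori estimate.
#'
#' @param posterior a \code{"diet_posterior"}.
#' @param polish logical; refine the best draw by local optimisation.
#' @return named numeric simplex vector.
#' @export
posterior_mode <- function(posterior, polish = TRUE) {
  best <- posterior$chains[which.max(posterior$loglik), ]
  if (!polish) return(best)
  spec <- posterior$spec
  m <- posterior$observed$m
  s_meas <- posterior$observed$sd
  K <- length(best)
  eps <- 1e-10
  z0 <- log(pmax(best[-K], eps)) - log(max(best[K], eps))
  opt <- stats::optim(z0, function(z) {
    ez <- exp(c(z, 0) - max(c(z, 0)))
    -.marginal_loglik(ez / sum(ez), spec, m, s_meas)
  }, method = "Nelder-Mead",
     control = list(maxit = 500, reltol = 1e-12))
  ez <- exp(c(opt$par, 0) - max(c(opt$par, 0)))
  stats::setNames(ez / sum(ez), names(best))
}

#' Convert whole-diet fractions to implied protein fractions
#'
#' @param f simplex vector of whole-diet (dry weight) fractions.
#' @param sources the matching list of \code{\link{source_group}}s.
#' @return simplex vector of fractions of dietary protein.
#' @export
protein_fractions <- function(f, sources) {
  p <- vapply(sources, function(s) s$macronutrients[["protein"]], numeric(1))
  num <- f * p
  if (sum(num) <= 0) stop("no protein in the mixture", call. = FALSE)
  num / sum(num)
}

#' Cross-check protein-scale and whole-diet-scale fits
#'
#' Converts every whole-diet posterior draw to implied protein fractions via
#' the sources' protein contents, and compares the 68% credible intervals
#' (16th-84th percentiles) with the protein-scale model's, per source. The
#' overlap metric is the Jaccard index of the two intervals (symmetric in the
#' two models).
#'
#' @param fit_protein a model-1 (or 0p) \code{"diet_posterior"}.
#' @param fit_wholediet a model-2 (or 0wd) \code{"diet_posterior"} over the
#'   same sources.
#' @param sources the source list both fits used.
#' @return data frame per source: both intervals, \code{overlap} (logical),
#'   \code{jaccard}.
#' @export
fit_protein_vs_wholediet_crosscheck <- function(fit_protein, fit_wholediet,
                                                sources) {
  stopifnot(fit_protein$scale == "protein",
            fit_wholediet$scale == "whole_diet")
  p <- vapply(sources, function(s) s$macronutrients[["protein"]], numeric(1))
  wd <- fit_wholediet$chains
  num <- sweep(wd, 2, p, "*")
  conv <- num / rowSums(num)
  common <- intersect(fit_protein$source_names, colnames(conv))
  out <- lapply(common, function(src) {
    a <- stats::quantile(fit_protein$chains[, src], c(0.16, 0.84))
    b <- stats::quantile(conv[, src], c(0.16, 0.84))
    inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
    uni <- max(a[2], b[2]) - min(a[1], b[1])
    data.frame(source = src, protein_lo = a[[1]], protein_hi = a[[2]],
               implied_lo = b[[1]], implied_hi = b[[2]],
               overlap = inter > 0,
               jaccard = if (uni > 0) inter / uni else 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Append an olive-oil source
#'
#' A lipid-only source (protein 0, carbohydrate 0, lipid 1) whose bulk d13C
#' is the modern Mediterranean olive-oil value shifted by the Suess
#' correction (the industrial-era depletion of atmospheric d13C). It carries
#' no nitrogen or protein signal, so it can only enter whole-diet models
#' through the metabolic carbon pool.
#'
#' @param sources list of \code{\link{source_group}}s to extend.
#' @param modern_oil_d13C \code{c(mean, sd)} of modern olive-oil d13C.
#' @param suess_correction \code{c(mean, sd)} added to translate the modern
#'   value to the pre-industrial atmosphere (positive shift).
#' @return the extended source list.
#' @export
add_olive_oil_source <- function(sources,
                                 modern_oil_d13C = c(mean = -29.0, sd = 1.0),
                                 suess_correction = c(mean = 1.5, sd = 0.2)) {
  oil_c <- modern_oil_d13C[["mean"]] + suess_correction[["mean"]]
  oil_sd <- sqrt(modern_oil_d13C[["sd"]]^2 + suess_correction[["sd"]]^2)
  oil <- source_group(
    name = "olive_oil",
    signals = data.frame(element = c("C", "N"), analyte = "bulk",
                         mean = c(oil_c, 0), sd = c(oil_sd, 0),
                         stringsAsFactors = FALSE),
    aa_concentrations = stats::setNames(numeric(0), character(0)),
    macronutrients = c(protein = 0, carbohydrate = 0, lipid = 1),
    macro_offsets = data.frame(macronutrient = "lipid", mean = 0, sd = 0,
                               stringsAsFactors = FALSE))
  c(sources, list(oil))
}
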