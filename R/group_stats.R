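# Between-sex cohort statistics over per-individual posterior medians.

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact distribution when the combined sample size is at most 25 and there
#' are no ties; normal approximation with tie correction (and continuity
#' correction) otherwise. Applied in this pipeline to per-individual
#' posterior medians, never to pooled posterior draws, so the sample size is
#' the number of individuals.
#'
#' @param group_a,group_b numeric vectors (non-empty).
#' @return list with \code{statistic} (the rank-sum U of \code{group_a}) and
#'   \code{p_value}.
#' @export
wilcoxon_rank_sum <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  comb <- c(group_a, group_b)
  if (length(unique(comb)) == 1) {
    # every observation tied: no evidence against identical distributions
    return(list(statistic = length(group_a) * length(group_b) / 2,
                p_value = 1))
  }
  ties <- anyDuplicated(comb) > 0
  exact <- (length(group_a) + length(group_b) <= 25) && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = min(1, ht$p.value))
}

#' Summarise a fitted cohort by sex
#'
#' Collects every individual's per-source posterior percentiles, computes
#' sex-group means and SDs of the posterior medians, the male/female ratio
#' of group means, and a two-sided Wilcoxon rank-sum test per source at the
#' 0.05 level. With a single-sex cohort the summaries are still emitted and
#' the tests are skipped with a message. \code{bonferroni = TRUE} adjusts the
#' p-values across sources (off by default: each source is reported at the
#' nominal level).
#'
#' @param posteriors named list of \code{"diet_posterior"} objects, one per
#'   individual.
#' @param sexes character vector (\code{"male"}/\code{"female"}) named or
#'   ordered like \code{posteriors}.
#' @param alpha significance level for flagging (default 0.05).
#' @param bonferroni logical; adjust p-values across sources.
#' @return list of class \code{"cohort_result"}: \code{individuals} (long
#'   percentile table), \code{groups} (per-source sex means/SDs, ratio, test
#'   statistic, p-value, significance flag).
#' @export
summarize_cohort <- function(posteriors, sexes, alpha = 0.05,
                             bonferroni = FALSE) {
  n <- length(posteriors)
  stopifnot(n >= 1, length(sexes) == n)
  ids <- names(posteriors)
  if (is.null(ids)) ids <- sprintf("ind%02d", seq_len(n))
  if (!is.null(names(sexes))) sexes <- sexes[ids]
  sexes <- as.character(sexes)

  indiv <- do.call(rbind, lapply(seq_len(n), function(i) {
    p <- posteriors[[i]]$percentiles
    cbind(data.frame(individual = ids[i], sex = sexes[i],
                     stringsAsFactors = FALSE), p)
  }))
  rownames(indiv) <- NULL

  sources <- unique(indiv$source)
  both_sexes <- all(c("male", "female") %in% sexes)
  if (!both_sexes) {
    message("single-sex cohort: between-sex tests skipped")
  }
  groups <- do.call(rbind, lapply(sources, function(src) {
    med <- indiv$p50[indiv$source == src]
    sx <- indiv$sex[indiv$source == src]
    gm <- function(s, f) if (any(sx == s)) f(med[sx == s]) else NA_real_
    row <- data.frame(
      source = src,
      mean_male = gm("male", mean), sd_male = gm("male", stats::sd),
      n_male = sum(sx == "male"),
      mean_female = gm("female", mean), sd_female = gm("female", stats::sd),
      n_female = sum(sx == "female"), stringsAsFactors = FALSE)
    row$ratio_male_female <- row$mean_male / row$mean_female
    if (both_sexes) {
      wt <- wilcoxon_rank_sum(med[sx == "male"], med[sx == "female"])
      row$statistic <- wt$statistic
      row$p_value <- wt$p_value
    } else {
      row$statistic <- NA_real_
      row$p_value <- NA_real_
    }
    row
  }))
  if (bonferroni && both_sexes) {
    groups$p_value <- stats::p.adjust(groups$p_value, method = "bonferroni")
  }
  groups$significant <- !is.na(groups$p_value) & groups$p_value < alpha
  rownames(groups) <- NULL
  structure(list(individuals = indiv, groups = groups, alpha = alpha),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("Cohort of", length(unique(x$individuals$individual)),
      "individuals\n\nGroup summary (posterior medians):\n")
  print(x$groups, digits = 3)
  invisible(x)
}
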