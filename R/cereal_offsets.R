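# Prediction of amino-acid isotope values for archaeological cereals.
#
# Endogenous AAs cannot be recovered from charred grains, so per-AA values
# are predicted from bulk values: modern grains of the same C3 cereal species
# give an AA-minus-bulk offset per (AA, element); archaeological bulk values
# are first corrected for the isotopic effect of charring, then shifted by
# the offsets, with all uncertainties combined in quadrature.

#' Default charring-correction offsets
#'
#' Mean shift (charred minus uncharred, per mil) imparted by charring, per
#' element, with a 1-sigma taken equal to the mean as a conservative reading
#' of charring-experiment variability. Subtracted from charred bulk values
#' before offsets are applied.
#'
#' @return list with elements \code{C} and \code{N}, each \code{c(mean, sd)}.
#' @export
default_charring_offsets <- function() {
  list(C = c(mean = 0.11, sd = 0.11), N = c(mean = 0.31, sd = 0.31))
}

#' Compute AA-minus-bulk offsets from modern grains
#'
#' For each (AA, element) measured in the modern grains, the offset is the
#' mean over samples of (AA delta - bulk delta); its sd combines the
#' between-sample scatter with the AA and bulk measurement sds in quadrature.
#'
#' @param moderns an \code{\link{isotope_table}} of modern grain
#'   measurements; each \code{sample_id} must carry a \code{bulk} row and at
#'   least one AA row per element.
#' @return data frame (\code{aa}, \code{element}, \code{mean}, \code{sd},
#'   \code{n}) with class \code{"offset_table"}.
#' @export
compute_offsets <- function(moderns) {
  moderns <- isotope_table(moderns)
  aa_rows <- moderns[moderns$analyte != "bulk", ]
  if (nrow(aa_rows) == 0) {
    stop("no modern samples with amino-acid values", call. = FALSE)
  }
  bulk <- moderns[moderns$analyte == "bulk", ]
  key <- interaction(aa_rows$analyte, aa_rows$element, drop = TRUE)
  out <- lapply(split(aa_rows, key), function(d) {
    el <- d$element[1]
    ib <- match(paste(d$sample_id, el), paste(bulk$sample_id, bulk$element))
    if (anyNA(ib)) {
      stop("modern sample(s) ", paste(d$sample_id[is.na(ib)], collapse = ", "),
           " lack a bulk ", el, " value", call. = FALSE)
    }
    diffs <- d$delta - bulk$delta[ib]
    meas_var <- mean(d$sd^2 + bulk$sd[ib]^2)
    between <- if (length(diffs) > 1) stats::sd(diffs) else 0
    data.frame(aa = d$analyte[1], element = el, mean = mean(diffs),
               sd = sqrt(between^2 + meas_var), n = length(diffs),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("offset_table", "data.frame")
  out
}

#' Correct a charred bulk value for charring
#'
#' @param delta bulk delta of the charred grain (per mil).
#' @param sd its 1-sigma.
#' @param element \code{"C"} or \code{"N"}.
#' @param charring_offsets list as returned by
#'   \code{\link{default_charring_offsets}}.
#' @return \code{c(delta, sd)}: charring offset subtracted, sds in
#'   quadrature.
#' @export
correct_charring <- function(delta, sd, element,
                             charring_offsets = default_charring_offsets()) {
  off <- charring_offsets[[element]]
  if (is.null(off)) {
    stop("no charring offset configured for element '", element, "'",
         call. = FALSE)
  }
  c(delta = delta - off[["mean"]], sd = sqrt(sd^2 + off[["sd"]]^2))
}

#' Predict per-AA isotope values for archaeological grains
#'
#' Charring-corrects each archaeological bulk value, applies the modern-grain
#' AA-minus-bulk offsets, and pools across grains: the prediction for each
#' (AA, element) is the mean over grains of (corrected bulk + offset), with
#' an uncertainty combining, in quadrature, the bulk measurement sd, the
#' charring sd, the offset sd and the between-grain scatter.
#'
#' @param charred an \code{\link{isotope_table}} of archaeological grain bulk
#'   values (analyte \code{"bulk"} only).
#' @param offsets an \code{"offset_table"} from \code{\link{compute_offsets}}.
#' @param charring_offsets per-element charring offsets.
#' @param aas optional character vector restricting the predicted AAs.
#' @return data frame (\code{aa}, \code{element}, \code{delta}, \code{sd},
#'   \code{n_grains}) with attribute \code{"skipped"} listing any requested
#'   AA/element pairs absent from the offset table.
#' @export
predict_aa_values <- function(charred, offsets,
                              charring_offsets = default_charring_offsets(),
                              aas = NULL) {
  charred <- isotope_table(charred)
  bulk <- charred[charred$analyte == "bulk", ]
  if (nrow(bulk) == 0) {
    stop("archaeological grains must carry bulk values", call. = FALSE)
  }
  if (!is.null(aas)) {
    want <- offsets[offsets$aa %in% aas, ]
    skipped <- setdiff(aas, offsets$aa)
  } else {
    want <- offsets
    skipped <- character()
  }
  rows <- list()
  for (i in seq_len(nrow(want))) {
    el <- want$element[i]
    b <- bulk[bulk$element == el, ]
    if (nrow(b) == 0) next
    per_grain <- t(vapply(seq_len(nrow(b)), function(j) {
      cc <- correct_charring(b$delta[j], b$sd[j], el, charring_offsets)
      c(cc[["delta"]] + want$mean[i], sqrt(cc[["sd"]]^2 + want$sd[i]^2))
    }, numeric(2)))
    between <- if (nrow(b) > 1) stats::sd(per_grain[, 1]) else 0
    rows[[length(rows) + 1]] <- data.frame(
      aa = want$aa[i], element = el,
      delta = mean(per_grain[, 1]),
      sd = sqrt(mean(per_grain[, 2]^2) / nrow(b) + between^2 / nrow(b)),
      n_grains = nrow(b), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
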