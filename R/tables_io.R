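# Tabular I/O: isotope tables, run configurations, provenance records.

#' Controlled vocabulary of amino-acid codes
#'
#' Three-letter codes for the amino acids handled by the pipeline.
#' Asparagine/aspartate and glutamine/glutamate are indistinguishable after
#' acid hydrolysis of collagen and are always collapsed to \code{Asx} and
#' \code{Glx}; \code{Nle} is the norleucine internal standard; \code{Hyp} is
#' hydroxyproline.
#'
#' @format Character vector of valid analyte codes (excluding \code{"bulk"}).
#' @export
AA_CODES <- c("Ala", "Gly", "Val", "Leu", "Ile", "Thr", "Ser", "Pro",
              "Asx", "Glx", "Phe", "Lys", "Tyr", "Hyp", "Met", "Nle")

# Synonyms collapsed at ingest (acid hydrolysis chemistry: Asn->Asx etc.)
.AA_SYNONYMS <- c(Asp = "Asx", Asn = "Asx", Glu = "Glx", Gln = "Glx")

.SEX_LEVELS <- c("male", "female", "unknown")

.ISOTOPE_COLS <- c("sample_id", "sex", "tissue", "analyte", "element",
                   "delta", "sd", "n_replicates")

#' Canonicalise an analyte code
#'
#' Maps pre-hydrolysis amino-acid names (Asp/Asn/Glu/Gln) onto their
#' hydrolysis products (Asx/Glx) and validates against the controlled
#' vocabulary. \code{"bulk"} is passed through.
#'
#' @param analyte character vector of analyte codes.
#' @return character vector of canonical codes.
#' @export
canonical_analyte <- function(analyte) {
  out <- as.character(analyte)
  hit <- out %in% names(.AA_SYNONYMS)
  out[hit] <- .AA_SYNONYMS[out[hit]]
  bad <- !(out %in% c("bulk", AA_CODES))
  if (any(bad)) {
    stop("unknown analyte code(s): ", paste(unique(out[bad]), collapse = ", "),
         "; valid codes are 'bulk' and ", paste(AA_CODES, collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Construct a validated isotope table
#'
#' The central exchange format of the pipeline: one row per
#' (sample, analyte, element) measurement. Deltas are per mil vs VPDB for
#' carbon and vs AIR for nitrogen; \code{sd} is the 1-sigma measurement
#' uncertainty.
#'
#' @param df data frame with columns \code{sample_id}, \code{sex},
#'   \code{tissue}, \code{analyte}, \code{element}, \code{delta}, \code{sd},
#'   \code{n_replicates}.
#' @return the validated data frame with class \code{"isotope_table"}.
#' @export
isotope_table <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(.ISOTOPE_COLS, names(df))
  if (length(missing_cols) > 0) {
    stop("isotope table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[, .ISOTOPE_COLS]
  df$sample_id <- as.character(df$sample_id)
  df$tissue <- as.character(df$tissue)
  df$sex <- as.character(df$sex)
  if (!all(df$sex %in% .SEX_LEVELS)) {
    stop("sex must be one of ", paste(.SEX_LEVELS, collapse = ", "),
         call. = FALSE)
  }
  df$analyte <- canonical_analyte(df$analyte)
  df$element <- as.character(df$element)
  if (!all(df$element %in% c("C", "N"))) {
    stop("element must be 'C' (vs VPDB) or 'N' (vs AIR)", call. = FALSE)
  }
  for (col in c("delta", "sd")) {
    v <- df[[col]]
    if (!is.numeric(v) || anyNA(v)) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(v))))
      stop("non-numeric or missing '", col, "' in row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    df[[col]] <- as.numeric(v)
  }
  if (any(df$sd < 0)) stop("sd must be >= 0", call. = FALSE)
  df$n_replicates <- as.integer(df$n_replicates)
  if (anyNA(df$n_replicates) || any(df$n_replicates < 1)) {
    stop("n_replicates must be an integer >= 1", call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("isotope_table", "data.frame")
  df
}

#' Read an isotope table from CSV
#'
#' @param path path to a UTF-8 CSV file with a header row.
#' @return an \code{isotope_table}.
#' @export
read_isotope_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  missing_cols <- setdiff(.ISOTOPE_COLS, names(raw))
  if (length(missing_cols) > 0) {
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("delta", "sd")) {
    num <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(num) & nzchar(trimws(raw[[col]])) | is.na(num))
    if (length(bad) > 0) {
      # +1 for the header line: report file line numbers
      stop("parse error in ", path, ": non-numeric '", col, "' on line(s) ",
           paste(bad + 1L, collapse = ", "), call. = FALSE)
    }
    raw[[col]] <- num
  }
  raw$n_replicates <- as.integer(raw$n_replicates)
  isotope_table(raw)
}

#' Write an isotope table to CSV
#'
#' Values are serialized with full double precision (15 significant digits)
#' so that a write/read cycle is the identity.
#'
#' @param table an \code{isotope_table}.
#' @param path output path.
#' @export
write_isotope_table <- function(table, path) {
  table <- isotope_table(table)
  out <- as.data.frame(table)
  for (col in c("delta", "sd")) {
    out[[col]] <- formatC(out[[col]], format = "g", digits = 15)
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok),
                        call. = FALSE)
  invisible(NULL)
}

.VALID_MODELS <- c("model0p", "model0wd", "model1", "model2")

#' Load a run configuration
#'
#' Configurations are YAML. Absent MCMC settings default to a burn-in of 5000
#' iterations followed by 10000 retained iterations, the standard BUGS-style
#' run length for this class of mixing model; the seed defaults to 0.
#'
#' @param path path to a YAML config file.
#' @return a list with class \code{"run_config"}: \code{model_name},
#'   optional table paths, \code{mcmc} (\code{burn_in}, \code{iterations},
#'   \code{seed}), \code{olive_oil_enabled}.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (is.null(cfg$model_name)) stop("config error: model_name is required",
                                    call. = FALSE)
  if (!cfg$model_name %in% .VALID_MODELS) {
    stop("config error: unknown model_name '", cfg$model_name,
         "'; valid names: ", paste(.VALID_MODELS, collapse = ", "),
         call. = FALSE)
  }
  mcmc <- cfg$mcmc
  if (is.null(mcmc)) mcmc <- list()
  if (is.null(mcmc$burn_in)) mcmc$burn_in <- 5000L
  if (is.null(mcmc$iterations)) mcmc$iterations <- 10000L
  if (is.null(mcmc$seed)) mcmc$seed <- 0L
  mcmc$burn_in <- as.integer(mcmc$burn_in)
  mcmc$iterations <- as.integer(mcmc$iterations)
  mcmc$seed <- as.integer(mcmc$seed)
  if (mcmc$burn_in < 0) stop("config error: burn_in must be >= 0",
                             call. = FALSE)
  if (mcmc$iterations < 1) stop("config error: iterations must be >= 1",
                                call. = FALSE)
  cfg$mcmc <- mcmc
  if (is.null(cfg$olive_oil_enabled)) cfg$olive_oil_enabled <- FALSE
  cfg$olive_oil_enabled <- isTRUE(cfg$olive_oil_enabled)
  for (p in c("source_table", "consumer_table", "offsets_table")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]])) {
      stop("config error: ", p, " path not resolvable: ", cfg[[p]],
           call. = FALSE)
    }
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Write a provenance record next to run outputs
#'
#' Records the configuration (hashed and verbatim), the seed, and package /
#' R versions so that any output directory is self-describing. The record is
#' deliberately timestamp-free so that repeat runs of the same configuration
#' and seed are byte-identical.
#'
#' @param out_dir directory the run writes into (created if needed).
#' @param config a \code{run_config} or plain list describing the run.
#' @param seed integer seed used for the run.
#' @return the provenance list, invisibly.
#' @export
write_provenance <- function(out_dir, config, seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  prov <- list(
    config = config,
    config_hash = sprintf("%08x", sum(utf8ToInt(as.character(cfg_json)) *
                                        (seq_len(nchar(cfg_json)) %% 251 + 1)) %%
                            .Machine$integer.max),
    seed = as.integer(seed),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("aadiet"))
  )
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(prov)
}
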