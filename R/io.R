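# columns that must parse as numbers in any cohort file
NUMERIC_COHORT_COLUMNS <- c("sbp", "dbp", paste0("sbp", 1:3), paste0("dbp", 1:3),
                            "age", "weight", "stratum")

#' Write a cohort as CSV with a column manifest
#'
#' RFC-4180 CSV, UTF-8, header row, "." decimal separator, one row per
#' participant. Numeric cells are serialised with 17 significant digits so
#' a write-read round trip reproduces every double exactly. A manifest
#' listing column names and types is written alongside
#' (`<path>.manifest`).
#'
#' @param cohort Cohort `data.frame`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  out <- cohort
  types <- vapply(cohort, function(x)
    if (is.numeric(x)) "numeric" else if (is.logical(x)) "logical" else "character",
    character(1L))
  for (j in seq_along(out)) {
    x <- out[[j]]
    if (is.numeric(x)) {
      s <- sprintf("%.17g", x)
      s[is.na(x)] <- NA_character_
      out[[j]] <- s
    } else if (is.factor(x)) {
      out[[j]] <- as.character(x)
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  utils::write.csv(data.frame(column = names(cohort), type = unname(types),
                              stringsAsFactors = FALSE),
                   paste0(path, ".manifest"), row.names = FALSE)
  invisible(path)
}

#' Read a cohort CSV
#'
#' Accepts LF or CRLF line endings and quoted fields. Column types come
#' from the manifest written by [write_cohort()] when present, otherwise
#' from inference with a fixed set of known numeric columns (`sbp`, `dbp`,
#' replicates, `age`, `weight`, `stratum`). A cell that fails numeric
#' coercion raises an error naming the row and column. Empty cells are
#' preserved as missing.
#'
#' @param path CSV path.
#' @return A `data.frame`; known categorical survey variables stay
#'   character.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = "")
  manifest_path <- paste0(path, ".manifest")
  types <- NULL
  if (file.exists(manifest_path)) {
    m <- utils::read.csv(manifest_path, colClasses = "character")
    types <- stats::setNames(m$type, m$column)
  }
  for (nm in names(raw)) {
    want <- if (!is.null(types) && nm %in% names(types)) types[[nm]]
            else infer_column_type(raw[[nm]], nm)
    if (want == "numeric") {
      x <- raw[[nm]]
      val <- suppressWarnings(as.numeric(x))
      bad <- which(is.na(val) & !is.na(x))
      if (length(bad))
        stop("cannot parse '", x[bad[[1L]]], "' as a number (column '", nm,
             "', data row ", bad[[1L]], ")", call. = FALSE)
      raw[[nm]] <- val
    } else if (want == "logical") {
      raw[[nm]] <- as.logical(raw[[nm]])
    }
  }
  raw
}

infer_column_type <- function(x, name) {
  if (name %in% NUMERIC_COHORT_COLUMNS) return("numeric")
  nonmiss <- x[!is.na(x)]
  if (length(nonmiss) && all(nonmiss %in% c("TRUE", "FALSE"))) return("logical")
  if (length(nonmiss) && !any(is.na(suppressWarnings(as.numeric(nonmiss)))))
    return("numeric")
  "character"
}

# defaults for every recognised configuration key
config_defaults <- function() {
  list(
    seed = NULL,
    data = NULL,
    generator = list(n = 3646L, sd_sbp = 16, sd_dbp = 10, rho = 0.7307,
                     replicates = 1L, measurement_sd_sbp = 5, measurement_sd_dbp = 4,
                     n_strata = 10L, psus_per_stratum = 20L,
                     weight_sdlog = 0, psu_sd = 0, medication_prob = 0),
    model = NULL,                     # NULL = the default 11-term spec
    screening = list(p_threshold = 0.20, vif_threshold = 10),
    inference = list(robust = FALSE, design_df = NULL))
}

#' Load and validate a YAML run configuration
#'
#' Unknown keys (top level or nested) are rejected; all violations are
#' reported at once. Missing keys take their documented defaults, so an
#' empty file yields the default configuration. The merged configuration is
#' returned as a [run_config()].
#'
#' @param path YAML file path.
#' @return A `bp_run_config`.
#' @export
#' @examples
#' cfg <- load_config(system.file("extdata", "example-config.yaml",
#'                                package = "bpjoint"))
#' cfg$generator$n
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  # keep short keys like "n" as keys (YAML 1.1 would read them as booleans);
  # boolean values must be spelled true/false
  bool_handler <- function(v) {
    if (tolower(v) %in% c("true", "false")) tolower(v) == "true" else v
  }
  user <- yaml::read_yaml(path, handlers = list("bool#yes" = bool_handler,
                                                "bool#no" = bool_handler)) %||% list()
  if (!is.list(user)) stop("config must be a YAML mapping", call. = FALSE)
  defs <- config_defaults()
  problems <- character(0L)

  extra <- setdiff(names(user), names(defs))
  if (length(extra))
    problems <- c(problems, paste0("unknown key(s): ", paste(extra, collapse = ", ")))
  for (section in c("generator", "screening", "inference")) {
    if (!is.null(user[[section]])) {
      if (!is.list(user[[section]])) {
        problems <- c(problems, paste0("'", section, "' must be a mapping"))
        next
      }
      bad <- setdiff(names(user[[section]]), names(defs[[section]]))
      if (length(bad))
        problems <- c(problems, paste0("unknown key(s) in ", section, ": ",
                                       paste(bad, collapse = ", ")))
      defs[[section]] <- utils::modifyList(defs[[section]], user[[section]])
    }
  }
  for (k in c("seed", "data")) if (!is.null(user[[k]])) defs[[k]] <- user[[k]]

  g <- defs$generator
  if (!is_count(g$n)) problems <- c(problems, "generator.n must be a non-negative integer")
  for (k in c("sd_sbp", "sd_dbp", "measurement_sd_sbp", "measurement_sd_dbp",
              "weight_sdlog", "psu_sd"))
    if (!is_scalar_number(g[[k]]) || g[[k]] < 0)
      problems <- c(problems, paste0("generator.", k, " must be >= 0"))
  s <- defs$screening
  if (!is_scalar_number(s$p_threshold) || s$p_threshold <= 0 || s$p_threshold > 1)
    problems <- c(problems, "screening.p_threshold must be in (0, 1]")
  if (!is_scalar_number(s$vif_threshold) || s$vif_threshold <= 0)
    problems <- c(problems, "screening.vif_threshold must be positive")
  if (!is.null(defs$seed) && (!is.numeric(defs$seed) || defs$seed != trunc(defs$seed)))
    problems <- c(problems, "seed must be an integer")
  if (length(problems))
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)

  run_config(
    generator = generator_config(
      n = g$n,
      sigma = residual_covariance(g$sd_sbp, g$sd_dbp, g$rho),
      measurement = measurement_settings(g$replicates, g$measurement_sd_sbp,
                                         g$measurement_sd_dbp),
      design = survey_design(g$n_strata, g$psus_per_stratum,
                             g$weight_sdlog, g$psu_sd),
      medication_prob = g$medication_prob),
    data = defs$data,
    model = steps_model_spec(),
    p_threshold = s$p_threshold,
    vif_threshold = s$vif_threshold,
    robust = isTRUE(defs$inference$robust),
    design_df = defs$inference$design_df,
    seed = if (!is.null(defs$seed)) as.integer(defs$seed) else NULL)
}
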