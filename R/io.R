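# Parameter-file and result serialization. Parameters live in a JSON file
# mirroring the published tables (one entry per parameter with baseline,
# low, high, kind); tabular outputs are CSV; result files carry provenance
# (package version, seed, digest of the parameter file).

PARAMS_SCHEMA_VERSION <- 1L

#' Load a parameter file
#'
#' Reads a JSON parameter file and validates it; any invariant violation is
#' reported with the offending field name. The shipped default file (the
#' published probability and cost tables, 2017 USD) is at
#' `system.file("extdata", "parameters.json", package = "msucost")`.
#'
#' @param path Path to the JSON file; defaults to the shipped file.
#' @return A validated `msu_parameters` data.frame.
#' @export
#' @examples
#' params <- load_parameters()
#' param_value(params, "n_census")
load_parameters <- function(path = default_parameter_file()) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path)
  if (is.null(raw$parameters)) {
    stop("parameter file has no 'parameters' object: ", path, call. = FALSE)
  }
  rows <- lapply(names(raw$parameters), function(nm) {
    e <- raw$parameters[[nm]]
    for (f in c("baseline", "low", "high", "kind")) {
      if (is.null(e[[f]])) {
        stop(sprintf("parameter '%s' is missing field '%s'", nm, f), call. = FALSE)
      }
    }
    data.frame(name = nm, baseline = as.numeric(e$baseline),
               low = as.numeric(e$low), high = as.numeric(e$high),
               kind = as.character(e$kind), stringsAsFactors = FALSE)
  })
  params <- do.call(rbind, rows)
  # preserve canonical ordering where known
  canon <- vapply(PARAM_DEFS, `[[`, character(1), 1)
  params <- params[order(match(params$name, canon)), ]
  rownames(params) <- NULL
  class(params) <- c("msu_parameters", "data.frame")
  v <- validate_parameters(params)
  if (length(v)) {
    stop("invalid parameter file ", path, ":\n",
         paste("  -", v, collapse = "\n"), call. = FALSE)
  }
  params
}

#' @rdname load_parameters
#' @export
default_parameter_file <- function() {
  system.file("extdata", "parameters.json", package = "msucost", mustWork = TRUE)
}

#' Write a parameter set to JSON
#'
#' @param params An `msu_parameters` data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  entries <- lapply(seq_len(nrow(params)), function(i) {
    list(baseline = params$baseline[i], low = params$low[i],
         high = params$high[i], kind = params$kind[i])
  })
  names(entries) <- params$name
  jsonlite::write_json(
    list(schema_version = PARAMS_SCHEMA_VERSION, currency = "USD 2017",
         parameters = entries),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Restate all cost parameters in another price-index year
#'
#' Applies [adjust_cost_to_base_year()] uniformly to the baseline, low and
#' high of every cost-kind parameter; probabilities and counts are
#' untouched.
#'
#' @param params An `msu_parameters` data.frame.
#' @param index_source,index_target Price-index values (see
#'   [adjust_cost_to_base_year()]).
#' @return The adjusted parameter set.
#' @export
adjust_parameters_cpi <- function(params, index_source, index_target) {
  costs <- params$kind == "cost"
  for (col in c("baseline", "low", "high")) {
    params[[col]][costs] <- adjust_cost_to_base_year(params[[col]][costs],
                                                     index_source, index_target)
  }
  params
}

#' Write an evaluation result with provenance
#'
#' Serializes an [evaluate()] result to JSON, recording the package version,
#' the seed (if any), and an MD5 digest of the parameter file the run used.
#'
#' @param result An `msu_evaluation` object.
#' @param path Output JSON file.
#' @param parameter_file Path of the parameter file used (digested into the
#'   provenance block); `NULL` to skip.
#' @param seed Seed used, if the analysis was stochastic.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path, parameter_file = NULL, seed = NULL) {
  out <- list(
    provenance = provenance_block(parameter_file, seed),
    results = list(
      cost_st_total = result$cost_st_total,
      cost_msu_total = result$cost_msu_total,
      incremental_cost = result$incremental_cost,
      transfers_averted = result$transfers_averted,
      transfers_averted_air = result$transfers_averted_air,
      transfers_averted_ground = result$transfers_averted_ground,
      ed_encounters_averted = result$ed_encounters_averted,
      per_patient_cost_st = result$per_patient_cost_st,
      per_patient_cost_msu_variable = result$per_patient_cost_msu_variable,
      n_census = result$n_census
    ),
    options = unclass(result$options)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

provenance_block <- function(parameter_file = NULL, seed = NULL) {
  block <- list(package = "msucost",
                version = as.character(utils::packageVersion("msucost")))
  if (!is.null(seed)) block$seed <- seed
  if (!is.null(parameter_file) && file.exists(parameter_file)) {
    block$parameter_file <- basename(parameter_file)
    block$parameter_digest <- unname(tools::md5sum(parameter_file))
  }
  block
}

#' Read and write a cohort table
#'
#' CSV round-trip of a [simulate_cohort()] table; `NA` encodes
#' not-applicable (a conditional field whose condition did not hold).
#'
#' @param cohort A cohort data.frame.
#' @param path CSV file.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` the
#'   cohort data.frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  logical_cols <- c("tpa_eligible", "tpa_received", "initial_csc",
                    "needs_transfer", "transfer_air_indicated", "air_feasible")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character",
                                       stroke_type = "character"))
  for (col in logical_cols) df[[col]] <- as.logical(df[[col]])
  df
}
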