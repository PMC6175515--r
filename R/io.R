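#' Read and validate a nest-record table
#'
#' Reads a delimited text file (comma-separated by default, header row
#' required) into a validated nest-record data frame. Required columns:
#' \code{nest_id}, \code{species}, \code{flush_distance_m},
#' \code{defence_category}, \code{fate}; optional columns
#' \code{initiation_date} and \code{measurement_date} (ISO-8601) are parsed
#' when present, so nest age at measurement can be computed. Species and fate
#' vocabularies are matched case-insensitively. Rows that fail validation are
#' reported with their row numbers and the read fails; spreadsheet sources
#' should be exported to CSV first.
#'
#' @param path Path to the delimited file.
#' @param column_map Optional named character vector mapping required schema
#'   names to the file's column names, e.g.
#'   \code{c(flush_distance_m = "FlushDist")}.
#' @param sep Field separator, default \code{","}.
#' @param missing_token Strings treated as missing, default
#'   \code{c("", "NA")}.
#' @return A validated data frame of nest records.
#' @export
read_nest_table <- function(path, column_map = NULL, sep = ",",
                            missing_token = c("", "NA")) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE,
                           na.strings = missing_token,
                           colClasses = "character",
                           check.names = FALSE)
  if (!is.null(column_map)) {
    for (schema_name in names(column_map)) {
      i <- match(column_map[[schema_name]], names(raw))
      if (is.na(i)) stop("mapped column not found: ", column_map[[schema_name]])
      names(raw)[i] <- schema_name
    }
  }
  required <- c("nest_id", "species", "flush_distance_m", "defence_category",
                "fate")
  miss <- setdiff(required, names(raw))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  validate_nest_records(raw)
}

#' Validate raw nest records
#'
#' Normalises vocabularies and types and reports every invalid row by number.
#'
#' @param raw Data frame with at least the required schema columns (character
#'   or native types).
#' @return A validated, typed nest-record data frame.
#' @export
validate_nest_records <- function(raw) {
  n <- nrow(raw)
  problems <- character(0)
  note <- function(rows, what) {
    if (length(rows))
      problems <<- c(problems,
                     sprintf("row %d: %s", rows, what))
  }
  species <- tolower(trimws(as.character(raw$species)))
  bad <- which(!is.na(species) & !species %in% c("sandpiper", "phalarope"))
  note(bad, "unknown species token")
  fate <- tolower(trimws(as.character(raw$fate)))
  bad <- which(!is.na(fate) & !fate %in% c("hatched", "depredated", "unknown"))
  note(bad, "unknown fate token")
  flush <- suppressWarnings(as.numeric(raw$flush_distance_m))
  bad <- which(!is.na(raw$flush_distance_m) & is.na(flush))
  note(bad, "unparseable flush_distance_m")
  note(which(!is.na(flush) & flush < 0), "negative flush_distance_m")
  cat_num <- suppressWarnings(as.numeric(raw$defence_category))
  bad <- which(!is.na(raw$defence_category) &
                 (is.na(cat_num) | !cat_num %in% 1:4))
  note(bad, "defence_category not in 1..4")
  if (length(problems))
    stop("invalid nest records:\n  ", paste(problems, collapse = "\n  "))
  out <- data.frame(nest_id = as.character(raw$nest_id),
                    species = species,
                    flush_distance_m = flush,
                    defence_category = as.integer(cat_num),
                    fate = fate)
  for (col in c("initiation_date", "measurement_date")) {
    if (col %in% names(raw)) out[[col]] <- as.Date(as.character(raw[[col]]))
  }
  out
}

#' Write a nest-record table as delimited text
#'
#' @param records Nest-record data frame.
#' @param path Output path (comma-separated, header row, UTF-8).
#' @return \code{path}, invisibly.
#' @export
write_nest_table <- function(records, path) {
  utils::write.table(records, path, sep = ",", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Nest age at measurement, in days
#'
#' @param records Nest records carrying \code{initiation_date} and
#'   \code{measurement_date} columns.
#' @return Integer days between initiation and measurement.
#' @export
nest_age_days <- function(records) {
  stopifnot(all(c("initiation_date", "measurement_date") %in% names(records)))
  as.integer(records$measurement_date - records$initiation_date)
}

.result_as_list <- function(x) {
  if (inherits(x, "dip_test"))
    return(list(type = "dip_test", statistic = unname(x$statistic),
                p_value = x$p.value, n = unname(x$parameter),
                n_null_samples = x$n_null_samples, seed = x$seed))
  if (inherits(x, "ordinal_fit"))
    return(list(type = "ordinal_fit", cutpoints = unname(x$cutpoints),
                coefficients = as.list(x$coefficients),
                log_likelihood = x$log_likelihood,
                term_tests = x$term_tests, chi_square = x$chi_square,
                converged = x$converged, n = x$n))
  if (inherits(x, "fate_logistic"))
    return(list(type = "fate_logistic", coefficients = as.list(x$coefficients),
                standard_errors = as.list(x$standard_errors),
                wald_p_values = as.list(x$wald_p_values),
                converged = x$converged, n = x$n))
  if (inherits(x, "t_test_result"))
    return(list(type = "t_test", statistic = unname(x$statistic),
                df = unname(x$parameter), p_value = x$p.value,
                variant = x$variant))
  if (inherits(x, "nest_summary"))
    return(list(type = "nest_summary", per_species = x$per_species,
                category_proportions = as.data.frame(x$category_proportions),
                bin_proportions = as.list(x$bin_proportions),
                bin_breaks = x$bin_breaks))
  if (is.data.frame(x)) return(x)
  as.list(x)
}

#' Write analysis results as structured text
#'
#' Writes one JSON file per named result (full numeric precision), a combined
#' human-readable \code{report.txt}, and a \code{config.json} echoing the
#' resolved configuration and seeds so a run can be reproduced from its
#' outputs alone. Reruns with identical inputs and seeds produce
#' byte-identical machine-readable files.
#'
#' @param results Named list of result objects (dip tests, fits, summaries,
#'   data frames).
#' @param output_dir Directory to write into (created if needed).
#' @param config Optional list echoed to \code{config.json}.
#' @return Character vector of files written, invisibly.
#' @export
write_results <- function(results, output_dir, config = NULL) {
  if (!dir.exists(output_dir))
    dir.create(output_dir, recursive = TRUE)
  if (file.access(output_dir, mode = 2) != 0)
    stop("output directory is not writable: ", output_dir)
  stopifnot(is.list(results))
  if (length(results) && is.null(names(results)))
    stop("'results' must be a named list")
  written <- character(0)
  for (nm in names(results)) {
    p <- file.path(output_dir, paste0(nm, ".json"))
    jsonlite::write_json(.result_as_list(results[[nm]]), p,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, p)
  }
  rp <- file.path(output_dir, "report.txt")
  txt <- unlist(lapply(names(results), function(nm) {
    c(sprintf("== %s ==", nm),
      utils::capture.output(print(results[[nm]])), "")
  }))
  writeLines(c("flushrisk analysis report", "", txt), rp)
  written <- c(written, rp)
  cp <- file.path(output_dir, "config.json")
  jsonlite::write_json(if (is.null(config)) list() else config, cp,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  written <- c(written, cp)
  invisible(written)
}
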