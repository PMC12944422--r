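#' Column-name schema for measurement tables
#'
#' Maps the canonical column names used throughout the package to the names
#' found in an input CSV, and declares which device labels denote the test
#' and the reference instrument.
#'
#' @param participant_id,round,device,replicate,temperature,group Column
#'   names in the file. `group` is optional (participant attribute such as a
#'   skin-phototype category); set to `NULL` if absent.
#' @param test_label,reference_label Values of the device column identifying
#'   the test and reference instrument.
#' @return A named list of class `"measurement_schema"`.
#' @export
measurement_schema <- function(participant_id = "participant_id",
                               round = "round",
                               device = "device",
                               replicate = "replicate",
                               temperature = "temperature_c",
                               group = "group",
                               test_label = "test",
                               reference_label = "reference") {
  structure(
    list(participant_id = participant_id, round = round, device = device,
         replicate = replicate, temperature = temperature, group = group,
         test_label = test_label, reference_label = reference_label),
    class = "measurement_schema"
  )
}

#' Read a long-format measurement table from CSV
#'
#' One row per reading: participant, round, device, replicate index and
#' temperature in degrees Celsius. Device labels are normalised to
#' `"test"` / `"reference"` according to the schema.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema A [measurement_schema()] mapping canonical names to the
#'   file's column names.
#' @return A tibble with columns `participant_id` (character), `round`
#'   (character), `device` (`"test"`/`"reference"`), `replicate` (integer),
#'   `temperature_c` (double) and, when present in the file, `group`.
#' @export
read_measurements <- function(path, schema = measurement_schema()) {
  if (!file.exists(path)) {
    stop("measurement file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("participant_id", "round", "device", "replicate", "temperature")
  for (field in required) {
    col <- schema[[field]]
    if (!col %in% names(raw)) {
      stop("schema error: required column '", col, "' (", field,
           ") not present in ", path, call. = FALSE)
    }
  }
  temp_raw <- raw[[schema$temperature]]
  temp <- suppressWarnings(as.numeric(temp_raw))
  bad <- which(is.na(temp) & !is.na(temp_raw) & temp_raw != "")
  if (length(bad) > 0) {
    # +1 for the header row so the numbers match the file
    stop("unparsable temperature value(s) at file line(s): ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  }
  rep_raw <- raw[[schema$replicate]]
  rep_idx <- suppressWarnings(as.integer(rep_raw))
  bad_rep <- which(is.na(rep_idx) & !is.na(rep_raw) & rep_raw != "")
  if (length(bad_rep) > 0) {
    stop("unparsable replicate index at file line(s): ",
         paste(bad_rep + 1L, collapse = ", "), call. = FALSE)
  }
  device <- raw[[schema$device]]
  device <- dplyr::case_when(
    device == schema$test_label ~ "test",
    device == schema$reference_label ~ "reference",
    TRUE ~ NA_character_
  )
  if (anyNA(device)) {
    stop("unknown device label(s): ",
         paste(unique(raw[[schema$device]][is.na(device)]), collapse = ", "),
         "; expected '", schema$test_label, "' or '", schema$reference_label,
         "'", call. = FALSE)
  }
  out <- tibble::tibble(
    participant_id = as.character(raw[[schema$participant_id]]),
    round = as.character(raw[[schema$round]]),
    device = device,
    replicate = rep_idx,
    temperature_c = temp
  )
  if (!is.null(schema$group) && schema$group %in% names(raw)) {
    out$group <- as.character(raw[[schema$group]])
  }
  out
}

#' Write a measurement table to CSV
#'
#' Writes the canonical header
#' `participant_id,round,device,replicate,temperature_c[,group]`; reading the
#' file back with [read_measurements()] reproduces the table.
#'
#' @param table A measurement tibble as returned by [read_measurements()] or
#'   [generate_study()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(table, path) {
  stopifnot(is.data.frame(table))
  cols <- c("participant_id", "round", "device", "replicate", "temperature_c")
  missing <- setdiff(cols, names(table))
  if (length(missing) > 0) {
    stop("table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if ("group" %in% names(table)) cols <- c(cols, "group")
  readr::write_csv(table[cols], path, progress = FALSE)
  invisible(path)
}

#' Validate a measurement table
#'
#' Reports (never fixes) violations of the measurement-table invariants:
#' non-finite temperatures, replicate indices below 1, duplicated
#' `(participant, round, device, replicate)` keys, and unequal replicate
#' counts across the cells of the design.
#'
#' @param table A measurement tibble.
#' @return A tibble with columns `issue` and `detail`; zero rows when the
#'   table is clean.
#' @export
validate_measurements <- function(table) {
  issues <- list()
  add <- function(issue, detail) {
    issues[[length(issues) + 1L]] <<- tibble::tibble(issue = issue, detail = detail)
  }
  if (any(!is.finite(table$temperature_c))) {
    add("non_finite_temperature",
        paste0(sum(!is.finite(table$temperature_c)), " reading(s) not finite"))
  }
  if (any(table$replicate < 1L, na.rm = TRUE)) {
    add("replicate_below_one",
        paste0(sum(table$replicate < 1L, na.rm = TRUE), " replicate index(es) < 1"))
  }
  dup <- table |>
    dplyr::count(.data$participant_id, .data$round, .data$device, .data$replicate) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0) {
    add("duplicate_key",
        paste0(nrow(dup), " duplicated (participant, round, device, replicate) key(s): ",
               paste(utils::head(paste(dup$participant_id, dup$round, dup$device,
                                       dup$replicate, sep = "/"), 5L),
                     collapse = ", ")))
  }
  counts <- table |>
    dplyr::count(.data$participant_id, .data$round, .data$device)
  if (nrow(counts) > 0 && dplyr::n_distinct(counts$n) > 1L) {
    add("unequal_replicate_counts",
        paste0("replicate counts per (participant, round, device) cell range from ",
               min(counts$n), " to ", max(counts$n)))
  }
  if (length(issues) == 0) {
    return(tibble::tibble(issue = character(), detail = character()))
  }
  dplyr::bind_rows(issues)
}

#' Pair test and reference replicates
#'
#' The two devices measure sequentially, so replicate *i* of the test device
#' is paired with replicate *i* of the reference device within each
#' `(participant, round)` cell. The difference column is always
#' `diff = t_test - t_ref` (test minus reference), so a test instrument that
#' reads low yields a negative bias.
#'
#' @param table A measurement tibble with both devices present for every
#'   `(participant, round)` cell.
#' @return A tibble with one row per shared replicate:
#'   `participant_id`, `round`, `replicate`, `t_test`, `t_ref`, `diff`
#'   (and `group` when present).
#' @export
pair_replicates <- function(table) {
  stopifnot(is.data.frame(table))
  have <- table |>
    dplyr::distinct(.data$participant_id, .data$round, .data$device) |>
    dplyr::count(.data$participant_id, .data$round)
  missing_dev <- dplyr::filter(have, .data$n < 2L)
  if (nrow(missing_dev) > 0) {
    stop("unpaired data: device missing for (participant, round): ",
         paste(paste(missing_dev$participant_id, missing_dev$round, sep = "/"),
               collapse = ", "), call. = FALSE)
  }
  keep <- c("participant_id", "round", "replicate", "device", "temperature_c",
            intersect("group", names(table)))
  wide <- table[keep] |>
    tidyr::pivot_wider(names_from = "device", values_from = "temperature_c")
  unmatched <- dplyr::filter(wide, is.na(.data$test) | is.na(.data$reference))
  if (nrow(unmatched) > 0) {
    stop("unpaired data: ", nrow(unmatched),
         " replicate(s) present for only one device, e.g. ",
         paste(utils::head(paste(unmatched$participant_id, unmatched$round,
                                 unmatched$replicate, sep = "/"), 5L),
               collapse = ", "), call. = FALSE)
  }
  out <- wide |>
    dplyr::rename(t_test = "test", t_ref = "reference") |>
    dplyr::mutate(diff = .data$t_test - .data$t_ref) |>
    dplyr::arrange(.data$participant_id, .data$round, .data$replicate)
  front <- c("participant_id", "round", "replicate", "t_test", "t_ref", "diff")
  out[c(front, setdiff(names(out), front))]
}
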