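SCAN_COLUMNS <- c("time_min", "scan_no", "fragment_id", "isotopologue",
                  "intensity", "peak_noise", "resolution", "microscans",
                  "charge", "channel")

# Per-row invariant check; returns a character vector of messages, one per
# offending row, each naming the 1-based data-row number.
scan_row_violations <- function(scans) {
  msgs <- character(0)
  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows) > 0) {
      sprintf("row %d: %s", rows, what)
    } else character(0)
  }
  msgs <- c(
    msgs,
    bad(!is.finite(scans$time_min), "time_min is not a finite number"),
    bad(is.finite(scans$intensity) & scans$intensity < 0, "intensity < 0"),
    bad(!is.finite(scans$intensity), "intensity is not a finite number"),
    bad(is.finite(scans$peak_noise) & scans$peak_noise <= 0, "peak_noise <= 0"),
    bad(!is.finite(scans$peak_noise), "peak_noise is not a finite number"),
    bad(is.finite(scans$resolution) & scans$resolution <= 0, "resolution <= 0"),
    bad(is.finite(scans$microscans) & scans$microscans < 1, "microscans < 1"),
    bad(is.finite(scans$charge) & scans$charge < 1, "charge < 1"),
    bad(!scans$channel %in% c("sample", "reference"),
        "channel is not 'sample' or 'reference'")
  )
  msgs
}

#' Read a scan-level isotopologue table
#'
#' Reads the tab-separated scan-table dialect produced by Orbitrap
#' isotopologue extraction tools (and by [write_scan_table()]): one row per
#' spectrum and isotopologue, with the ion intensity, peak noise, resolving
#' power, microscan count, charge and the sample/reference channel flag.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A tibble with columns
#'   `time_min, scan_no, fragment_id, isotopologue, intensity, peak_noise,
#'   resolution, microscans, charge, channel`, in file order.
#' @seealso [write_scan_table()], [validate_scans()]
#' @export
read_scan_table <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  missing <- setdiff(SCAN_COLUMNS, header)
  if (length(missing) > 0) {
    abort(paste0("Scan table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  scans <- suppressWarnings(readr::read_tsv(
    path,
    col_types = readr::cols(
      time_min = readr::col_double(),
      scan_no = readr::col_integer(),
      fragment_id = readr::col_character(),
      isotopologue = readr::col_character(),
      intensity = readr::col_double(),
      peak_noise = readr::col_double(),
      resolution = readr::col_double(),
      microscans = readr::col_integer(),
      charge = readr::col_integer(),
      channel = readr::col_character()
    ),
    progress = FALSE
  ))
  problems <- readr::problems(scans)
  if (nrow(problems) > 0) {
    p <- problems[1, ]
    abort(sprintf(
      "Parse error at data row %d, column %d: expected %s, got '%s'.",
      # readr counts the header as row 1
      as.integer(p$row) - 1L, as.integer(p$col), p$expected, p$actual
    ))
  }
  scans <- scans[SCAN_COLUMNS]
  msgs <- scan_row_violations(scans)
  if (length(msgs) > 0) {
    abort(paste0("Invalid scan record(s):\n",
                 paste(head(msgs, 10), collapse = "\n")))
  }
  scans
}

#' Write a scan-level isotopologue table
#'
#' Serializes scan records to the tab-separated dialect read by
#' [read_scan_table()], with full-precision reals so that a write/read
#' round-trip reproduces the records.
#'
#' @param scans A tibble of scan records (see [read_scan_table()] for the
#'   column contract).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scan_table <- function(scans, path) {
  if (!is.data.frame(scans) || nrow(scans) == 0) {
    abort("`scans` must be a nonempty data frame.")
  }
  missing <- setdiff(SCAN_COLUMNS, names(scans))
  if (length(missing) > 0) {
    abort(paste0("Scan table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  msgs <- scan_row_violations(scans)
  if (length(msgs) > 0) {
    abort(paste0("Refusing to write invalid scan record(s):\n",
                 paste(head(msgs, 10), collapse = "\n")))
  }
  readr::write_tsv(scans[SCAN_COLUMNS], path, progress = FALSE)
  invisible(path)
}

#' Diagnostic report on a set of scan records
#'
#' Summarizes per-fragment isotopologue coverage (flagging fragments whose
#' basepeak rows are absent), channel alternation, and time monotonicity
#' within each channel's scan ordering. Always returns a report rather than
#' erroring, so it can be used to triage a suspect file.
#'
#' @param scans A scan-record tibble.
#' @param specs Optional isotopologue spec table used to decide which
#'   isotopologues (in particular the basepeak) each fragment should carry.
#' @return A list of class `"scan_report"` with elements `clean` (logical),
#'   `coverage` (tibble), `monotonicity_violations` (tibble of offending
#'   `channel`/`scan_no`), `row_violations` (character), and
#'   `channel_switches` (integer).
#' @export
validate_scans <- function(scans, specs = NULL) {
  row_violations <- scan_row_violations(scans)

  coverage <- dplyr::summarise(
    dplyr::group_by(scans, .data$fragment_id),
    isotopologues = list(sort(unique(.data$isotopologue))),
    .groups = "drop"
  )
  coverage$missing <- purrr::map2(
    coverage$fragment_id, coverage$isotopologues,
    function(f, have) {
      if (is.null(specs)) return(character(0))
      want <- specs$isotopologue[specs$fragment_id == f]
      setdiff(want, have)
    }
  )
  coverage$gap <- lengths(coverage$missing) > 0

  ordered <- dplyr::arrange(scans, .data$channel, .data$scan_no, .data$time_min)
  mono <- dplyr::summarise(
    dplyr::group_by(ordered, .data$channel, .data$scan_no),
    time_min = .data$time_min[1], .groups = "drop"
  )
  mono <- dplyr::arrange(mono, .data$channel, .data$scan_no)
  viol <- dplyr::filter(
    dplyr::mutate(dplyr::group_by(mono, .data$channel),
                  reversed = c(FALSE, diff(.data$time_min) <= 0)),
    .data$reversed
  )
  viol <- dplyr::select(dplyr::ungroup(viol), "channel", "scan_no", "time_min")

  by_scan <- dplyr::summarise(
    dplyr::group_by(dplyr::arrange(scans, .data$time_min), .data$scan_no),
    channel = .data$channel[1], time_min = .data$time_min[1],
    .groups = "drop"
  )
  by_scan <- dplyr::arrange(by_scan, .data$time_min)
  switches <- sum(by_scan$channel[-1] != by_scan$channel[-nrow(by_scan)])

  structure(
    list(
      clean = length(row_violations) == 0 && nrow(viol) == 0 &&
        !any(coverage$gap),
      coverage = coverage,
      monotonicity_violations = viol,
      row_violations = row_violations,
      channel_switches = as.integer(switches)
    ),
    class = "scan_report"
  )
}

#' @export
print.scan_report <- function(x, ...) {
  cat(if (x$clean) "Scan table: clean\n" else "Scan table: issues found\n")
  cat(sprintf("  fragments: %s\n",
              paste(x$coverage$fragment_id, collapse = ", ")))
  gaps <- x$coverage$fragment_id[x$coverage$gap]
  if (length(gaps) > 0) {
    cat(sprintf("  coverage gaps: %s\n", paste(gaps, collapse = ", ")))
  }
  cat(sprintf("  channel switches: %d\n", x$channel_switches))
  cat(sprintf("  monotonicity violations: %d\n",
              nrow(x$monotonicity_violations)))
  if (length(x$row_violations) > 0) {
    cat(sprintf("  invalid rows: %d\n", length(x$row_violations)))
  }
  invisible(x)
}
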