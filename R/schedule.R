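#' Build a standard-sample bracketing schedule
#'
#' Lays out alternating reference/sample segments of fixed valve period
#' over a run, reference-first by default, mirroring a bracketed infusion
#' experiment (a 180-min run with 20-min switching gives 5 reference and 4
#' sample segments). Each segment's usable window excludes a leading guard
#' interval after the valve switch, during which flow is still settling.
#'
#' @param duration_min Total run length in minutes (> 0).
#' @param switch_period_min Valve switching period in minutes (default 20).
#' @param first_channel Channel of the first segment (default
#'   `"reference"`).
#' @param guard_min Guard time discarded at the start of each segment
#'   (default 2; must be < `switch_period_min`).
#' @return A tibble of class `"bracket_schedule"` with columns
#'   `segment, start_min, end_min, channel, usable_start_min`, plus
#'   attributes `switch_period_min` and `guard_min`.
#' @examples
#' build_schedule(180, 20)
#' @export
build_schedule <- function(duration_min, switch_period_min = 20,
                           first_channel = c("reference", "sample"),
                           guard_min = 2) {
  first_channel <- match.arg(first_channel)
  if (!is.numeric(duration_min) || duration_min <= 0) {
    abort("`duration_min` must be positive.")
  }
  if (!is.numeric(switch_period_min) || switch_period_min <= 0) {
    abort("`switch_period_min` must be positive.")
  }
  if (guard_min < 0 || guard_min >= switch_period_min) {
    abort("`guard_min` must satisfy 0 <= guard < switch period.")
  }
  if (duration_min < switch_period_min) {
    warn("Run shorter than one valve period; schedule has a single segment.")
  }
  n_seg <- max(1L, ceiling(duration_min / switch_period_min - 1e-9))
  starts <- (seq_len(n_seg) - 1) * switch_period_min
  ends <- pmin(starts + switch_period_min, duration_min)
  channels <- rep(c(first_channel,
                    setdiff(c("reference", "sample"), first_channel)),
                  length.out = length(starts))
  out <- tibble(
    segment = seq_along(starts),
    start_min = starts,
    end_min = ends,
    channel = channels,
    usable_start_min = pmin(starts + guard_min, ends)
  )
  structure(out,
            class = c("bracket_schedule", class(tibble())),
            switch_period_min = switch_period_min,
            guard_min = guard_min)
}

# Channel at a vector of times under a schedule (half-open segments).
schedule_channel <- function(schedule, time_min) {
  idx <- findInterval(time_min, schedule$start_min)
  idx[idx < 1] <- NA_integer_
  ch <- schedule$channel[idx]
  ch[time_min >= max(schedule$end_min)] <- NA_character_
  ch
}

#' Cut a run into processing blocks along a bracketing schedule
#'
#' Within each schedule segment, forms consecutive fixed-length processing
#' windows (default 15 min) starting at the segment's usable start (after
#' guard-time trimming) and aggregates each window with
#' [aggregate_block()]. A trailing remainder shorter than `block_min` is
#' dropped; windows containing no spectra, or whose basepeak collects no
#' ions (e.g. sample segments after an eluting peak has passed), are
#' skipped with a warning.
#'
#' @param scans Scan-record tibble covering the run.
#' @param schedule A [build_schedule()] result.
#' @param specs Isotopologue spec table.
#' @param block_min Processing-block length in minutes (default 15).
#' @param constants A [processing_constants()] list.
#' @return A tibble of block results (rows per block and isotopologue, see
#'   [aggregate_block()]), with an extra `segment` column and a block
#'   midpoint `mid_min`.
#' @export
segment_blocks <- function(scans, schedule, specs, block_min = 15,
                           constants = processing_constants()) {
  usable_len <- schedule$end_min - schedule$usable_start_min
  if (block_min > max(usable_len)) {
    abort("`block_min` exceeds every segment's usable length.")
  }
  out <- purrr::map_dfr(seq_len(nrow(schedule)), function(i) {
    seg <- schedule[i, ]
    starts <- seq(seg$usable_start_min, seg$end_min, by = block_min)
    starts <- starts[starts + block_min <= seg$end_min + 1e-9]
    if (length(starts) == 0) return(NULL)
    purrr::map_dfr(starts, function(s) {
      window <- c(s, min(s + block_min, seg$end_min))
      seg_scans <- scans[scans$channel == seg$channel, , drop = FALSE]
      block <- tryCatch(
        aggregate_block(seg_scans, window, specs, constants),
        error = function(e) {
          warn(sprintf("Skipping block [%g, %g) in segment %d: %s",
                       window[1], window[2], seg$segment,
                       conditionMessage(e)))
          NULL
        }
      )
      if (is.null(block)) return(NULL)
      dplyr::mutate(block, segment = seg$segment,
                    mid_min = (window[1] + window[2]) / 2)
    })
  })
  out
}
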