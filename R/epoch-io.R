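#' Read per-epoch activity labels from CSV
#'
#' Reads a long-format epoch file with one row per 60-second epoch and columns
#' `participant_id`, `timestamp` (ISO-8601) and `label` (lowercase). The file
#' may cover any number of participants; rows must be in time order within a
#' participant, with no duplicate timestamps. Unknown labels are rejected.
#'
#' Gaps in wear time are represented by missing rows, never by imputed labels;
#' downstream validity screening ([find_valid_segments()]) treats any break in
#' the `epoch_seconds` spacing as a hard gap.
#'
#' @param path Path to the CSV file.
#' @param epoch_seconds Epoch length in seconds (default 60).
#' @return A tibble with columns `participant_id` (character), `timestamp`
#'   (POSIXct, UTC) and `label` (character), ordered by participant and time.
#' @export
read_epoch_csv <- function(path, epoch_seconds = 60) {
  if (!file.exists(path)) stop(sprintf("epoch file not found: %s", path), call. = FALSE)
  df <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  required <- c("participant_id", "timestamp", "label")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("epoch CSV is missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0) {
    warning("epoch CSV contains a header but no rows; returning empty tibble",
            call. = FALSE)
    return(tibble::tibble(
      participant_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
      label = character()
    ))
  }
  ts <- as.POSIXct(df$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  if (anyNA(ts)) {
    stop(sprintf("unparseable timestamp at row %d: %s",
                 which(is.na(ts))[1], df$timestamp[which(is.na(ts))[1]]), call. = FALSE)
  }
  lab <- tolower(df$label)
  bad <- !(lab %in% raw_labels())
  if (any(bad)) {
    stop(sprintf("unknown activity label at row %d: '%s'",
                 which(bad)[1], df$label[which(bad)[1]]), call. = FALSE)
  }
  out <- tibble::tibble(
    participant_id = as.character(df$participant_id),
    timestamp = ts,
    label = lab
  )
  # timestamps must be strictly increasing within participant in file order
  check <- out |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(.dt = c(Inf, diff(as.numeric(.data$timestamp)))) |>
    dplyr::ungroup()
  dup <- check$.row[check$.dt == 0]
  if (length(dup) > 0) {
    stop(sprintf("duplicate timestamp within participant at row %d", dup[1]),
         call. = FALSE)
  }
  nonmono <- check$.row[check$.dt < 0]
  if (length(nonmono) > 0) {
    stop(sprintf("non-monotone timestamps within participant: first offending row %d",
                 nonmono[1]), call. = FALSE)
  }
  dplyr::arrange(out, .data$participant_id, .data$timestamp)
}

#' Write per-epoch activity labels to CSV
#'
#' Inverse of [read_epoch_csv()]; timestamps are written as ISO-8601 UTC so
#' that a read/write cycle round-trips.
#'
#' @param epochs Epoch tibble (`participant_id`, `timestamp`, `label`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_epoch_csv <- function(epochs, path) {
  stopifnot(all(c("participant_id", "timestamp", "label") %in% names(epochs)))
  out <- tibble::tibble(
    participant_id = epochs$participant_id,
    timestamp = format(epochs$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    label = epochs$label
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Remap raw labels to the four analysis labels
#'
#' Applies a raw-to-analysis mapping (default: cycling and running both become
#' walking, see [default_label_remap()]) and reports how many epochs were
#' remapped. Labels that are neither analysis labels nor mapping keys raise an
#' error.
#'
#' @param epochs Epoch tibble with a `label` column.
#' @param mapping Named character vector, names = raw labels, values =
#'   analysis labels.
#' @param quiet Suppress the remap-count message.
#' @return The epoch tibble with remapped labels. The number of remapped
#'   epochs per raw label is attached as attribute `"remap_counts"`.
#' @export
remap_labels <- function(epochs, mapping = default_label_remap(), quiet = FALSE) {
  lab <- epochs$label
  unknown <- setdiff(unique(lab), c(analysis_labels(), names(mapping)))
  if (length(unknown) > 0) {
    stop(sprintf("label(s) not in mapping and not analysis labels: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (any(!(mapping %in% analysis_labels()))) {
    stop("mapping values must be analysis labels", call. = FALSE)
  }
  hit <- lab %in% names(mapping)
  counts <- table(lab[hit])
  if (any(hit)) lab[hit] <- unname(mapping[lab[hit]])
  out <- epochs
  out$label <- lab
  attr(out, "remap_counts") <- as.list(counts)
  if (!quiet && sum(hit) > 0) {
    message(sprintf("remapped %d epoch(s): %s", sum(hit),
                    paste(sprintf("%s->%s (%d)", names(counts),
                                  mapping[names(counts)], counts), collapse = ", ")))
  }
  out
}

# run index per participant: a new run starts wherever the spacing deviates
# from epoch_seconds (gaps are never bridged)
add_run_index <- function(epochs, epoch_seconds = 60) {
  epochs |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(
      .gap = c(FALSE, diff(as.numeric(.data$timestamp)) != epoch_seconds),
      run = cumsum(.data$.gap) + 1L
    ) |>
    dplyr::select(-".gap") |>
    dplyr::ungroup()
}

#' Extract each participant's longest valid contiguous segment
#'
#' Wear-time screening: a participant is retained only if their label stream
#' contains a run of contiguous epochs (exact `epoch_seconds` spacing, no
#' gaps) spanning at least `min_hours` hours. For retained participants the
#' longest such run (earliest wins ties) is kept; everything else is dropped.
#' Because a retained run spans a full 24 hours or more, it necessarily covers
#' both day-time and night-time clock hours.
#'
#' Participants with no qualifying run are excluded and listed in the
#' `"exclusions"` attribute (id, longest run length, reason), mirroring the
#' exclusion of residents who removed their sensors before 24 consecutive
#' hours of wear.
#'
#' @param epochs Epoch tibble (`participant_id`, `timestamp`, `label`).
#' @param min_hours Minimum contiguous span, in hours (default 24).
#' @param epoch_seconds Epoch length in seconds; must divide 3600.
#' @param quiet Suppress the exclusion message.
#' @return Tibble of retained epochs (the selected run per participant),
#'   with attribute `"exclusions"`.
#' @export
find_valid_segments <- function(epochs, min_hours = 24, epoch_seconds = 60,
                                quiet = FALSE) {
  if (3600 %% epoch_seconds != 0) {
    stop("epoch_seconds must divide 3600", call. = FALSE)
  }
  min_epochs <- ceiling(min_hours * 3600 / epoch_seconds)
  runs <- add_run_index(epochs, epoch_seconds)
  pick <- runs |>
    dplyr::count(.data$participant_id, .data$run) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::slice_max(.data$n, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  kept_ids <- pick$participant_id[pick$n >= min_epochs]
  excl <- pick |>
    dplyr::filter(!(.data$participant_id %in% kept_ids)) |>
    dplyr::transmute(
      .data$participant_id,
      longest_run_epochs = .data$n,
      reason = sprintf("longest contiguous run %d epochs < required %d", .data$n, min_epochs)
    )
  if (!quiet && nrow(excl) > 0) {
    message(sprintf("excluded %d participant(s) with < %g h contiguous wear: %s",
                    nrow(excl), min_hours, paste(excl$participant_id, collapse = ", ")))
  }
  out <- runs |>
    dplyr::inner_join(
      dplyr::filter(pick, .data$participant_id %in% kept_ids),
      by = c("participant_id", "run")
    ) |>
    dplyr::select("participant_id", "timestamp", "label") |>
    dplyr::arrange(.data$participant_id, .data$timestamp)
  attr(out, "exclusions") <- excl
  out
}

#' Number of complete valid days per participant
#'
#' @param segments Output of [find_valid_segments()].
#' @param epoch_seconds Epoch length in seconds.
#' @return Tibble: `participant_id`, `n_epochs`, `n_valid_days`
#'   (`floor(n_epochs / epochs_per_day)`).
#' @export
valid_days <- function(segments, epoch_seconds = 60) {
  epd <- as.integer(86400 / epoch_seconds)
  segments |>
    dplyr::count(.data$participant_id, name = "n_epochs") |>
    dplyr::mutate(n_valid_days = .data$n_epochs %/% epd)
}

#' Split valid segments into consecutive 24-hour day windows
#'
#' Day windows are rolling 1440-epoch (at 60 s) blocks anchored at each
#' participant's first valid epoch, not calendar midnights: this makes the
#' 24-hour perspective literal and maximises usable data. A trailing remainder
#' shorter than one day is discarded from daily means (with a warning); bout
#' detection still sees it when run on the whole segment.
#'
#' @param segments Output of [find_valid_segments()].
#' @param epoch_seconds Epoch length in seconds.
#' @param quiet Suppress the remainder warning.
#' @return Tibble `participant_id`, `timestamp`, `label`, `day` (1-based
#'   window index); remainder epochs are dropped.
#' @export
split_days <- function(segments, epoch_seconds = 60, quiet = FALSE) {
  epd <- as.integer(86400 / epoch_seconds)
  out <- segments |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(
      .idx = dplyr::row_number() - 1L,
      day = .data$.idx %/% epd + 1L,
      .full = dplyr::n() %/% epd
    ) |>
    dplyr::ungroup()
  n_dropped <- sum(out$day > out$.full)
  if (n_dropped > 0 && !quiet) {
    warning(sprintf("discarding %d remainder epoch(s) shorter than a full day window",
                    n_dropped), call. = FALSE)
  }
  out |>
    dplyr::filter(.data$day <= .data$.full) |>
    dplyr::select("participant_id", "timestamp", "label", "day")
}
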