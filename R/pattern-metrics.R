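#' Daily time-use: mean minutes per activity
#'
#' For each participant, counts epochs per activity within each day window and
#' averages across windows, giving mean minutes/day spent walking, standing,
#' sitting and lying. With fully labelled 60-second epochs the four columns
#' sum to exactly 1440 per participant.
#'
#' @param days Day-window tibble from [split_days()] (`participant_id`,
#'   `label`, `day`).
#' @param epoch_minutes Minutes per epoch (default 1).
#' @return Tibble: `participant_id`, `n_valid_days`, `minutes_walking`,
#'   `minutes_standing`, `minutes_sitting`, `minutes_lying`.
#' @export
time_use <- function(days, epoch_minutes = 1) {
  if (nrow(days) == 0) stop("no day windows supplied", call. = FALSE)
  assert_analysis_labels(days$label)
  days |>
    dplyr::count(.data$participant_id, .data$day, .data$label) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(n_valid_days = dplyr::n_distinct(.data$day)) |>
    dplyr::group_by(.data$participant_id, .data$n_valid_days, .data$label) |>
    dplyr::summarise(minutes = sum(.data$n) * epoch_minutes, .groups = "drop") |>
    dplyr::mutate(
      minutes = .data$minutes / .data$n_valid_days,
      label = factor(.data$label, levels = analysis_labels())
    ) |>
    tidyr::pivot_wider(
      names_from = "label", values_from = "minutes", names_prefix = "minutes_",
      names_expand = TRUE, values_fill = 0
    )
}

#' Percentage of the day spent sedentary
#'
#' `100 * (minutes_sitting + minutes_lying) / 1440`. Applied to the cohort's
#' printed daily means (17.6 min walking, 1.1 h standing, 9.9 h sitting,
#' 12.7 h lying) this gives 94.2%, i.e. roughly 94% of the day sedentary.
#'
#' @param tu Either a time-use tibble from [time_use()] (a `pct_sedentary`
#'   value is computed per row) or a numeric vector
#'   `c(walking, standing, sitting, lying)` in minutes/day.
#' @return Numeric vector of percentages.
#' @export
#' @examples
#' percent_sedentary(c(17.6, 66, 594, 762)) # 94.2
percent_sedentary <- function(tu) {
  if (is.numeric(tu)) {
    stopifnot(length(tu) == 4, all(tu >= 0))
    return(100 * (tu[3] + tu[4]) / 1440)
  }
  stopifnot(all(c("minutes_sitting", "minutes_lying") %in% names(tu)))
  100 * (tu$minutes_sitting + tu$minutes_lying) / 1440
}

#' Detect activity bouts by run-length encoding
#'
#' A bout is a maximal run of consecutive epochs sharing one activity label —
#' a continuous period of the activity sustained without interruption. Every
#' epoch belongs to exactly one bout; sequence boundaries terminate bouts.
#' The input must be one contiguous stretch of analysis labels (gaps split
#' the data upstream).
#'
#' @param labels Character vector of analysis labels for contiguous epochs.
#' @param epoch_minutes Minutes per epoch (default 1).
#' @return Tibble: `activity`, `start_epoch` (1-based), `duration_minutes`.
#' @export
#' @examples
#' detect_bouts(c("walking", "walking", "sitting", "sitting", "sitting", "walking"))
detect_bouts <- function(labels, epoch_minutes = 1) {
  if (length(labels) == 0) stop("empty label sequence", call. = FALSE)
  assert_analysis_labels(labels)
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  tibble::tibble(
    activity = r$values,
    start_epoch = ends - r$lengths + 1L,
    duration_minutes = r$lengths * epoch_minutes
  )
}

#' Bout-duration bin edges per activity
#'
#' Walking and standing use narrow bins (1-2, 2-3, 3-10, 10-30, >30 min);
#' sitting and lying use broad bins (1-5, 5-10, 10-30, 30-60, >60 min),
#' reflecting the short active bouts and long sedentary bouts typical of
#' nursing-home residents. Bins are half-open `[lo, hi)`, so a 2.0-minute
#' walking bout falls in "2-3 min".
#'
#' @param activity One of the four analysis labels.
#' @return Numeric vector of bin edges (last edge `Inf`).
#' @export
bout_bin_edges <- function(activity) {
  stopifnot(length(activity) == 1)
  if (activity %in% active_labels()) c(1, 2, 3, 10, 30, Inf)
  else if (activity %in% sedentary_labels()) c(1, 5, 10, 30, 60, Inf)
  else stop(sprintf("no bin scheme for activity '%s'", activity), call. = FALSE)
}

bout_bin_labels <- function(edges) {
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  ifelse(is.infinite(hi), sprintf(">%g min", lo), sprintf("%g-%g min", lo, hi))
}

#' Bin bouts into the per-activity duration histogram
#'
#' Each bout is assigned to exactly one half-open `[lo, hi)` duration bin and
#' counts are expressed as daily means (divided by `n_valid_days`). At
#' 60-second epochs all durations are integer minutes >= 1, so the 1-minute
#' bin floor captures every bout; sub-minute bouts (possible only with
#' shorter epochs) are excluded with a message.
#'
#' @param bouts Bout tibble from [detect_bouts()].
#' @param n_valid_days Number of valid days the bouts were observed over.
#' @return Tibble: `activity`, `bin` (ordered factor per activity scheme),
#'   `daily_mean_count`, on the full activity-by-bin grid.
#' @export
bin_bouts <- function(bouts, n_valid_days) {
  stopifnot(n_valid_days >= 1)
  bad <- setdiff(unique(bouts$activity), analysis_labels())
  if (length(bad) > 0) {
    stop(sprintf("no bin scheme for activity '%s'", bad[1]), call. = FALSE)
  }
  sub <- bouts$duration_minutes < 1
  if (any(sub)) {
    message(sprintf("excluding %d sub-minute bout(s) from histograms", sum(sub)))
    bouts <- bouts[!sub, , drop = FALSE]
  }
  grid <- purrr::map_dfr(analysis_labels(), function(a) {
    edges <- bout_bin_edges(a)
    tibble::tibble(activity = a, bin = bout_bin_labels(edges))
  })
  binned <- purrr::map_dfr(analysis_labels(), function(a) {
    edges <- bout_bin_edges(a)
    labs <- bout_bin_labels(edges)
    d <- bouts$duration_minutes[bouts$activity == a]
    idx <- findInterval(d, edges)  # half-open [lo, hi)
    tibble::tibble(activity = a, bin = labs[idx])
  })
  counts <- binned |> dplyr::count(.data$activity, .data$bin)
  grid |>
    dplyr::left_join(counts, by = c("activity", "bin")) |>
    dplyr::mutate(
      daily_mean_count = dplyr::coalesce(.data$n, 0L) / n_valid_days,
      activity = factor(.data$activity, levels = analysis_labels())
    ) |>
    dplyr::select("activity", "bin", "daily_mean_count") |>
    dplyr::arrange(.data$activity)
}

#' Count sedentary-to-active posture transitions
#'
#' Counts adjacent-epoch label changes matching exactly the four ordered
#' pairs lying->standing, lying->walking, sitting->standing and
#' sitting->walking. All other adjacent pairs (including lying->sitting and
#' standing->walking) are ignored; an indirect path such as
#' lying->sitting->standing counts once, at the sedentary-to-active step.
#'
#' @param labels Character vector of analysis labels for contiguous epochs.
#' @return Tibble with columns `from`, `to`, `n` (one row per counted pair)
#'   and attribute `"total"` = sum of `n`.
#' @export
#' @examples
#' count_transitions(c("lying", "sitting", "standing", "walking", "sitting", "walking"))
count_transitions <- function(labels) {
  assert_analysis_labels(labels)
  pairs <- transition_pairs()
  out <- pairs
  if (length(labels) < 2) {
    out$n <- 0L
  } else {
    from_v <- labels[-length(labels)]
    to_v <- labels[-1]
    out$n <- purrr::map2_int(pairs$from, pairs$to,
                             function(f, t) sum(from_v == f & to_v == t))
  }
  attr(out, "total") <- sum(out$n)
  out
}

#' Per-participant activity-pattern summary
#'
#' Bundles the three outcome families for each participant in a valid
#' segment tibble:
#' * daily time-use means (computed over complete day windows),
#' * bout histograms as daily mean counts per duration bin (bouts are
#'   detected on the whole contiguous segment, so a bout spanning a
#'   day-window cut is counted once, on the day it starts; the trailing
#'   remainder after the last full day is included in bout detection),
#' * daily mean sedentary-to-active transitions with per-pair daily means
#'   (counted over complete day windows, consistent with the time-use
#'   denominator).
#'
#' @param segments Valid-segment tibble from [find_valid_segments()].
#' @param epoch_seconds Epoch length in seconds.
#' @return One row per participant: `participant_id`, `n_valid_days`,
#'   `minutes_*` (4), `pct_sedentary`, `bouts_<activity>_<bin>` (20, daily
#'   mean counts), `trans_<from>_<to>` (4, daily means) and
#'   `transitions_daily` (their sum).
#' @export
summarize_cohort <- function(segments, epoch_seconds = 60) {
  epoch_minutes <- epoch_seconds / 60
  days <- split_days(segments, epoch_seconds, quiet = TRUE)
  tu <- time_use(days, epoch_minutes)
  tu$pct_sedentary <- percent_sedentary(tu)
  ndays <- stats::setNames(tu$n_valid_days, tu$participant_id)

  # bouts on the whole contiguous segment (vectorised run-length encoding;
  # equals detect_bouts() per participant — enforced by tests)
  assert_analysis_labels(segments$label)
  n <- nrow(segments)
  new_bout <- c(TRUE, segments$label[-1] != segments$label[-n] |
                  segments$participant_id[-1] != segments$participant_id[-n])
  bout_tbl <- tibble::tibble(
    participant_id = segments$participant_id[new_bout],
    activity = segments$label[new_bout],
    duration_minutes = tabulate(cumsum(new_bout)) * epoch_minutes
  )
  grid <- purrr::map_dfr(analysis_labels(), function(a) {
    tibble::tibble(activity = a, bin = bout_bin_labels(bout_bin_edges(a)))
  })
  bout_tbl$bin <- NA_character_
  for (a in analysis_labels()) {
    sel <- bout_tbl$activity == a
    edges <- bout_bin_edges(a)
    bout_tbl$bin[sel] <- bout_bin_labels(edges)[
      findInterval(bout_tbl$duration_minutes[sel], edges)]
  }
  per_boutcols <- bout_tbl |>
    dplyr::count(.data$participant_id, .data$activity, .data$bin) |>
    tidyr::complete(participant_id = tu$participant_id, grid,
                    fill = list(n = 0L)) |>
    dplyr::mutate(
      daily_mean_count = .data$n / unname(ndays[.data$participant_id]),
      col = sprintf("bouts_%s_%s", .data$activity, bin_code(.data$bin))
    ) |>
    dplyr::select("participant_id", "col", "daily_mean_count") |>
    tidyr::pivot_wider(names_from = "col", values_from = "daily_mean_count")

  # transitions on complete day windows (vectorised adjacent-pair scan;
  # equals count_transitions() per participant — enforced by tests)
  m <- nrow(days)
  lab_from <- days$label[-m]
  lab_to <- days$label[-1]
  same <- days$participant_id[-m] == days$participant_id[-1]
  pairs <- transition_pairs()
  per_trans <- purrr::map2_dfr(pairs$from, pairs$to, function(f, t) {
    hit <- same & lab_from == f & lab_to == t
    tibble::tibble(participant_id = days$participant_id[-m][hit],
                   col = sprintf("trans_%s_%s", f, t))
  }) |>
    dplyr::count(.data$participant_id, .data$col) |>
    tidyr::complete(participant_id = tu$participant_id,
                    col = sprintf("trans_%s_%s", pairs$from, pairs$to),
                    fill = list(n = 0L)) |>
    dplyr::mutate(daily = .data$n / unname(ndays[.data$participant_id])) |>
    dplyr::select("participant_id", "col", "daily") |>
    tidyr::pivot_wider(names_from = "col", values_from = "daily")
  per_trans$transitions_daily <- rowSums(per_trans[, -1, drop = FALSE])

  tu |>
    dplyr::left_join(per_boutcols, by = "participant_id") |>
    dplyr::left_join(per_trans, by = "participant_id")
}

#' @rdname summarize_cohort
#' @param segment One participant's valid-segment tibble.
#' @export
summarize_participant <- function(segment, epoch_seconds = 60) {
  stopifnot(dplyr::n_distinct(segment$participant_id) == 1)
  summarize_cohort(segment, epoch_seconds)
}

bin_code <- function(bin) {
  x <- gsub(" min$", "", bin)
  x <- gsub("^>", "gt", x)
  gsub("-", "_", x)
}

#' Write per-participant activity summaries to CSV
#'
#' @param summaries Output of [summarize_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(summaries, path) {
  readr::write_csv(summaries, path, progress = FALSE)
  invisible(path)
}
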