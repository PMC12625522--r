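# Fixture builders and independent oracles shared across the suite.
# Oracles are deliberately naive (element-by-element loops, textbook
# formulas) and never call the implementation they check.

make_epochs <- function(labels, id = "p1",
                        start = as.POSIXct("2024-03-01 00:00:00", tz = "UTC"),
                        epoch_seconds = 60) {
  tibble::tibble(
    participant_id = id,
    timestamp = start + (seq_along(labels) - 1) * epoch_seconds,
    label = labels
  )
}

random_labels <- function(n) {
  sample(c("walking", "standing", "sitting", "lying"), n, replace = TRUE)
}

write_epoch_fixture <- function(epochs, path = tempfile(fileext = ".csv")) {
  df <- data.frame(
    participant_id = epochs$participant_id,
    timestamp = format(epochs$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    label = epochs$label
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# brute-force run-length scan: one epoch at a time
oracle_bouts <- function(labels) {
  starts <- integer(0)
  acts <- character(0)
  durs <- integer(0)
  cur_start <- 1L
  for (i in seq_along(labels)) {
    if (i > 1 && labels[i] != labels[i - 1]) {
      starts <- c(starts, cur_start)
      acts <- c(acts, labels[i - 1])
      durs <- c(durs, i - cur_start)
      cur_start <- i
    }
  }
  starts <- c(starts, cur_start)
  acts <- c(acts, labels[length(labels)])
  durs <- c(durs, length(labels) - cur_start + 1L)
  data.frame(activity = acts, start_epoch = starts, duration = durs)
}

# brute-force adjacent-pair scan for the four counted posture transitions
oracle_transitions <- function(labels) {
  counted <- c("lying>standing", "lying>walking", "sitting>standing", "sitting>walking")
  total <- 0L
  if (length(labels) >= 2) {
    for (i in seq_len(length(labels) - 1)) {
      key <- paste0(labels[i], ">", labels[i + 1])
      if (key %in% counted) total <- total + 1L
    }
  }
  total
}

# textbook tie-corrected Kruskal-Wallis H via the rank-sum formula
oracle_kw_h <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  rs <- tapply(r, groups, sum)
  ns <- tapply(r, groups, length)
  h <- 12 / (N * (N + 1)) * sum(rs^2 / ns) - 3 * (N + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  h / corr
}

# quick synthetic summaries table (activity metrics only) for association
# tests that do not need full label sequences
make_summaries <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tibble::tibble(
    participant_id = sprintf("s%04d", seq_len(n)),
    minutes_walking = rlnorm(n, log(15), 0.6),
    minutes_standing = rlnorm(n, log(60), 0.6),
    minutes_lying = rlnorm(n, log(750), 0.15),
    minutes_sitting = pmax(60, 1440 - rlnorm(n, log(15), 0.6) -
                             rlnorm(n, log(60), 0.6) - rlnorm(n, log(750), 0.15)),
    transitions_daily = rpois(n, 22)
  )
}
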