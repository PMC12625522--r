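#' Default synthetic-cohort configuration
#'
#' Four severity groups (25 no-CI/MCI, 73 mild, 47 moderate, 18 severe; 163
#' residents in all) with group-specific semi-Markov dwell calibrations whose
#' simulated cohorts reproduce the descriptive structure reported for
#' nursing-home residents: overall daily means of about 17.6 min walking,
#' 66 min (1.1 h) standing, 594 min (9.9 h) sitting and 762 min (12.7 h)
#' lying; about 22 counted sedentary-to-active transitions per day overall
#' with group means near 22 / 27 / 21 / 10 (a decreasing trend from mild to
#' severe dementia); less standing (about 27 vs 89 min) and more lying in
#' severe than in mild dementia. Group values not individually reported
#' (walking by group; standing in the no-CI/MCI and moderate groups) are
#' chosen once so the group mixture matches the overall means. Clinical
#' scores are drawn from group-specific marginal distributions matching the
#' reported group summaries (NPI subsyndrome and SPPB means/SDs, CDR bands,
#' age, sex, BMI) and are independent of the activity sequences given the
#' group.
#'
#' @param n_total Total cohort size; group sizes are scaled proportionally
#'   from the default 25/73/47/18 split.
#' @param wear_days Days of valid wear per participant.
#' @param seed Default seed used by [simulate_cohort()].
#' @return Object of class `"cohort_config"`.
#' @export
default_cohort_config <- function(n_total = 163, wear_days = 2, seed = 1L) {
  groups <- list(
    noci_mci = list(
      n = 25,
      minutes = c(walking = 22, standing = 70, sitting = 613, lying = 735),
      transitions = 22,
      npi_item_means = c(agitation = 1.04 / 3, psychosis = 0.68 / 2,
                         affective = 0.92 / 2, apathy = 0.08, other = 0.96 / 4),
      sppb = c(mean = 1.84, sd = 1.89),
      age = c(mean = 88.5, sd = 8.9),
      bmi = c(mean = 24.4, sd = 4.5),
      pct_female = 0.56,
      cdr_grid = NA
    ),
    mild_dementia = list(
      n = 73,
      minutes = c(walking = 20, standing = 89.31, sitting = 604.69, lying = 726),
      transitions = 27,
      npi_item_means = c(agitation = 2.58 / 3, psychosis = 0.96 / 2,
                         affective = 1.58 / 2, apathy = 0.44, other = 1.69 / 4),
      sppb = c(mean = 2.68, sd = 2.83),
      age = c(mean = 88.7, sd = 7.1),
      bmi = c(mean = 26.7, sd = 5.8),
      pct_female = 0.68,
      cdr_grid = seq(4.5, 9, by = 0.5)
    ),
    moderate_dementia = list(
      n = 47,
      minutes = c(walking = 15, standing = 45, sitting = 593.2, lying = 786.8),
      transitions = 21,
      npi_item_means = c(agitation = 7.04 / 3, psychosis = 3.04 / 2,
                         affective = 3.38 / 2, apathy = 1.04, other = 3.56 / 4),
      sppb = c(mean = 1.85, sd = 2.08),
      age = c(mean = 86.0, sd = 7.4),
      bmi = c(mean = 26.5, sd = 5.7),
      pct_female = 0.51,
      cdr_grid = seq(9.5, 15.5, by = 0.5)
    ),
    severe_dementia = list(
      n = 18,
      minutes = c(walking = 6, standing = 27.34, sitting = 525.86, lying = 880.8),
      transitions = 10,
      npi_item_means = c(agitation = 6.44 / 3, psychosis = 1.56 / 2,
                         affective = 3.61 / 2, apathy = 2.28, other = 1.67 / 4),
      sppb = c(mean = 0.28, sd = 0.75),
      age = c(mean = 87.4, sd = 7.0),
      bmi = c(mean = 23.6, sd = 4.8),
      pct_female = 0.72,
      cdr_grid = seq(16, 18, by = 0.5)
    )
  )
  if (n_total != 163) {
    sizes <- round(n_total * c(25, 73, 47, 18) / 163)
    sizes[2] <- n_total - sum(sizes[-2])
    for (i in seq_along(groups)) groups[[i]]$n <- sizes[i]
  }
  new_cohort_config(groups, wear_days = wear_days, seed = seed,
                    association_truth = "group_structured")
}

#' Null (association-free) cohort configuration
#'
#' Every severity group shares one StateParams set calibrated to the overall
#' cohort means, and clinical scores are drawn independently of the activity
#' sequences, so every true association coefficient between activity metrics
#' and clinical predictors — including the severity ordinal — is exactly
#' zero. Used for type-I-error studies.
#'
#' @param n Total cohort size; split across the four groups in the default
#'   25/73/47/18 proportions.
#' @inheritParams default_cohort_config
#' @return Object of class `"cohort_config"`.
#' @export
null_cohort_config <- function(n = 163, wear_days = 1, seed = 1L) {
  base <- default_cohort_config(wear_days = wear_days, seed = seed)
  sizes <- round(n * c(25, 73, 47, 18) / 163)
  sizes[1] <- n - sum(sizes[-1])
  overall <- c(walking = 17.6, standing = 66, sitting = 594.4, lying = 762)
  groups <- purrr::imap(base$groups, function(g, nm) {
    g$minutes <- overall
    g$transitions <- 22
    g
  })
  for (i in seq_along(groups)) groups[[i]]$n <- sizes[i]
  new_cohort_config(groups, wear_days = wear_days, seed = seed,
                    association_truth = "null")
}

new_cohort_config <- function(groups, wear_days, seed, association_truth,
                              transition = default_transition_matrix(),
                              dwell_sdlog = default_dwell_sdlog(),
                              tempo_sdlog = 0.55, active_sdlog = 0.45) {
  stopifnot(all(vapply(groups, function(g) g$n, numeric(1)) >= 1))
  params <- purrr::map(groups, function(g) {
    calibrate_state_params(g$minutes, g$transitions,
                           transition = transition, dwell_sdlog = dwell_sdlog,
                           tempo_sdlog = tempo_sdlog, active_sdlog = active_sdlog)
  })
  structure(
    list(groups = groups, params = params, wear_days = wear_days,
         epoch_seconds = 60, transition = transition, dwell_sdlog = dwell_sdlog,
         tempo_sdlog = tempo_sdlog, active_sdlog = active_sdlog,
         association_truth = association_truth, seed = seed),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  ns <- vapply(x$groups, function(g) g$n, numeric(1))
  cat(sprintf("cohort_config: %d participants (%s), %g wear day(s), truth = %s\n",
              sum(ns), paste(ns, collapse = "/"), x$wear_days, x$association_truth))
  invisible(x)
}

# frequency (1-4) and severity (1-3) distributions used for present NPI items
npi_fs_probs <- function() {
  list(freq = c(0.35, 0.30, 0.20, 0.15), sev = c(0.50, 0.35, 0.15))
}

# mean of f*s for a present item under npi_fs_probs()
npi_fs_mean <- function() {
  p <- npi_fs_probs()
  sum(1:4 * p$freq) * sum(1:3 * p$sev)
}

# draw one group's NPI items: each item present with probability chosen so
# the expected item score matches the target mean; present items score f*s
draw_npi_items <- function(n, item_means) {
  cl <- npi_cluster_map()
  items <- npi_item_names()
  cluster_of <- stats::setNames(rep("other", length(items)), items)
  cluster_of[cl$nps_agitation] <- "agitation"
  cluster_of[cl$nps_psychosis] <- "psychosis"
  cluster_of[cl$nps_affective] <- "affective"
  cluster_of[cl$nps_apathy] <- "apathy"
  p <- npi_fs_probs()
  m <- npi_fs_mean()
  out <- purrr::map(items, function(it) {
    prob <- min(0.95, item_means[[cluster_of[[it]]]] / m)
    present <- stats::runif(n) < prob
    f <- sample(1:4, n, replace = TRUE, prob = p$freq)
    s <- sample(1:3, n, replace = TRUE, prob = p$sev)
    ifelse(present, f * s, 0L)
  })
  names(out) <- items
  tibble::as_tibble(out)
}

# split an SPPB total into balance/gait/chair sub-scores (capacity 4 each)
split_sppb <- function(total) {
  vapply(total, function(t) {
    slots <- rep(1:3, each = 4)
    take <- if (t > 0) sample(slots, t) else integer(0)
    c(sum(take == 1), sum(take == 2), sum(take == 3))
  }, numeric(3))
}

draw_group_clinical <- function(n, g, level) {
  sppb_tot <- pmin(12, pmax(0, round(stats::rnorm(n, g$sppb[["mean"]], g$sppb[["sd"]]))))
  sub <- split_sppb(sppb_tot)
  items <- draw_npi_items(n, as.list(g$npi_item_means))
  has_dementia <- level != "noci_mci"
  cdr <- if (has_dementia) sample(g$cdr_grid, n, replace = TRUE) else rep(NA_real_, n)
  dplyr::bind_cols(items, tibble::tibble(
    sppb_balance = sub[1, ], sppb_gait = sub[2, ], sppb_chair = sub[3, ],
    dx_dementia = has_dementia,
    dx_mci = if (has_dementia) FALSE else stats::runif(n) < 0.84,
    cdr_sob = cdr,
    age = pmin(103, pmax(70, round(stats::rnorm(n, g$age[["mean"]], g$age[["sd"]]), 1))),
    sex = ifelse(stats::runif(n) < g$pct_female, "female", "male"),
    bmi = pmin(52, pmax(16, round(stats::rnorm(n, g$bmi[["mean"]], g$bmi[["sd"]]), 1)))
  ))
}

#' Simulate a full synthetic cohort
#'
#' End-to-end generator: per participant, draws heterogeneity multipliers
#' (lognormal tempo on all dwells, mean-preserving; lognormal active-time
#' multiplier on walking/standing dwells), simulates a contiguous
#' `wear_days`-long activity-label sequence from the group's calibrated
#' semi-Markov process, and draws clinical scores from the group's marginal
#' distributions. Identical config and seed give identical output.
#'
#' @param config A `"cohort_config"` from [default_cohort_config()] or
#'   [null_cohort_config()].
#' @param seed Integer seed; defaults to the config's own.
#' @return Object of class `"cohort_sim"`: list with `epochs` (label
#'   stream), `clinical` (raw clinical table), and `truth` — the ground-truth
#'   ledger (per-group calibration targets and achieved values, heterogeneity
#'   SDs, association truth, seed).
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(seed, {
    k <- 0L
    epochs <- list()
    clinical <- list()
    for (level in names(config$groups)) {
      g <- config$groups[[level]]
      params <- config$params[[level]]
      clin <- draw_group_clinical(g$n, g, level)
      ids <- sprintf("p%04d", k + seq_len(g$n))
      clin <- dplyr::mutate(clin, participant_id = ids, group = level, .before = 1)
      for (i in seq_len(g$n)) {
        tempo <- stats::rlnorm(1, config$tempo_sdlog^2 / 2, config$tempo_sdlog)
        act <- stats::rlnorm(1, -config$active_sdlog^2 / 2, config$active_sdlog)
        epochs[[ids[i]]] <- simulate_activity_sequence(
          params, duration_hours = config$wear_days * 24,
          participant_id = ids[i], tempo = tempo, active_scale = act,
          epoch_seconds = config$epoch_seconds
        )
      }
      clinical[[level]] <- clin
      k <- k + g$n
    }
    truth <- list(
      seed = seed,
      association = config$association_truth,
      wear_days = config$wear_days,
      groups = purrr::imap(config$groups, function(g, nm) {
        cal <- attr(config$params[[nm]], "calibration")
        list(n = g$n, target_minutes = as.list(g$minutes),
             target_transitions = g$transitions,
             achieved_minutes = as.list(cal$achieved_minutes),
             achieved_transitions = cal$achieved_transitions,
             clamped = as.list(cal$clamped))
      }),
      tempo_sdlog = config$tempo_sdlog,
      active_sdlog = config$active_sdlog
    )
    structure(
      list(
        epochs = dplyr::bind_rows(epochs),
        clinical = dplyr::bind_rows(clinical),
        truth = truth
      ),
      class = "cohort_sim"
    )
  })
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("cohort_sim: %d participants, %d epochs, truth = %s\n",
              dplyr::n_distinct(x$clinical$participant_id), nrow(x$epochs),
              x$truth$association))
  invisible(x)
}

#' Generate clinical outcomes with a known activity association
#'
#' Given per-participant activity summaries, draws clinical scores whose
#' dependence on one activity metric carries a known conditional log-link
#' coefficient, providing ground truth for parameter-recovery studies.
#'
#' Construction: with `L = log(metric)` (zeros shifted by 0.5), the latent
#' physical-function score is `X = center + lambda (L - mean(L)) +
#' noise_sd * Z`. When `(L, X)` are jointly Gaussian the reverse regression
#' is exactly log-linear: `E[metric | X] = exp(a + b X)` with
#' `b = lambda var(L) / (lambda^2 var(L) + noise_sd^2)`. `lambda` is solved
#' so that `b` equals the requested coefficient, which the truth ledger
#' stores as the ground truth. Rounding and clipping the latent score to the
#' integer 0-12 SPPB range perturbs this slightly; the clipped fraction is
#' reported and a warning raised if it exceeds 20%. NPI items, severity and
#' demographics are drawn independently of activity (their true coefficients
#' are zero).
#'
#' @param summaries Activity summary tibble from [summarize_cohort()].
#' @param sppb_coef Target conditional coefficient of the SPPB score in the
#'   gamma log-link regression of `outcome` on the clinical predictors; 0
#'   makes all clinical scores independent of activity.
#' @param outcome Activity metric column carrying the association.
#' @param noise_sd SD of the latent SPPB noise.
#' @param sppb_center Center of the latent SPPB scale.
#' @param seed Optional seed.
#' @return Clinical tibble (same format as [simulate_cohort()]'s) with
#'   attribute `"truth"`: the implied coefficient, `lambda`, the achieved
#'   clip rate.
#' @export
simulate_clinical_outcomes <- function(summaries, sppb_coef = 0,
                                       outcome = "minutes_walking",
                                       noise_sd = 1.5, sppb_center = 2,
                                       seed = NULL) {
  stopifnot(outcome %in% names(summaries))
  with_seed(seed, {
    n <- nrow(summaries)
    y <- pmax(summaries[[outcome]], 0.5)
    L <- log(y)
    s2 <- stats::var(L)
    if (sppb_coef == 0) {
      lambda <- 0
    } else {
      disc <- 1 - 4 * sppb_coef^2 * noise_sd^2 / s2
      if (disc < 0) {
        noise_sd <- 0.9 * sqrt(s2) / (2 * abs(sppb_coef))
        message(sprintf("noise_sd reduced to %.3g so the target coefficient is attainable",
                        noise_sd))
        disc <- 1 - 4 * sppb_coef^2 * noise_sd^2 / s2
      }
      lambda <- (1 - sqrt(disc)) / (2 * sppb_coef)
    }
    latent <- sppb_center + lambda * (L - mean(L)) + noise_sd * stats::rnorm(n)
    sppb_tot <- round(latent)
    clipped <- sppb_tot < 0 | sppb_tot > 12
    clip_rate <- mean(clipped)
    if (clip_rate > 0.2) {
      warning(sprintf("%.1f%% of SPPB scores clipped to [0, 12]; ground truth distorted",
                      100 * clip_rate), call. = FALSE)
    }
    sppb_tot <- pmin(12, pmax(0, sppb_tot))
    sub <- split_sppb(sppb_tot)

    overall_items <- c(agitation = 4.05 / 3, psychosis = 1.58 / 2,
                       affective = 2.22 / 2, apathy = 0.76, other = 2.09 / 4)
    items <- draw_npi_items(n, as.list(overall_items))
    lev <- sample(severity_levels(), n, replace = TRUE,
                  prob = c(25, 73, 47, 18) / 163)
    grids <- list(mild_dementia = seq(4.5, 9, 0.5),
                  moderate_dementia = seq(9.5, 15.5, 0.5),
                  severe_dementia = seq(16, 18, 0.5))
    cdr <- vapply(lev, function(l) {
      if (l == "noci_mci") NA_real_ else sample(grids[[l]], 1)
    }, numeric(1))
    out <- dplyr::bind_cols(tibble::tibble(
      participant_id = summaries$participant_id,
      group = lev
    ), items, tibble::tibble(
      sppb_balance = sub[1, ], sppb_gait = sub[2, ], sppb_chair = sub[3, ],
      dx_dementia = lev != "noci_mci",
      dx_mci = ifelse(lev == "noci_mci", stats::runif(n) < 0.84, FALSE),
      cdr_sob = cdr,
      age = pmin(103, pmax(70, round(stats::rnorm(n, 87.7, 7.5), 1))),
      sex = ifelse(stats::runif(n) < 0.62, "female", "male"),
      bmi = pmin(52, pmax(16, round(stats::rnorm(n, 26, 5.5), 1)))
    ))
    attr(out, "truth") <- list(outcome = outcome, sppb_coef = sppb_coef,
                               lambda = lambda, noise_sd = noise_sd,
                               clip_rate = clip_rate)
    out
  })
}

#' Write a simulated cohort to disk
#'
#' Emits the pipeline's own input formats: `epochs.csv`, `clinical.csv` and
#' `truth.json` under `dir`.
#'
#' @param cohort A `"cohort_sim"` object.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    epochs = file.path(dir, "epochs.csv"),
    clinical = file.path(dir, "clinical.csv"),
    truth = file.path(dir, "truth.json")
  )
  write_epoch_csv(cohort$epochs, paths[["epochs"]])
  readr::write_csv(cohort$clinical, paths[["clinical"]], progress = FALSE)
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("jsonlite is required to write truth.json", call. = FALSE)
  }
  jsonlite::write_json(cohort$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
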