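#' @keywords internal
#' Evaluate code under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Default embedded-chain transition matrix
#'
#' Next-state probabilities of the semi-Markov activity process (rows = from,
#' columns = to; order walking, standing, sitting, lying; no self
#' transitions). All jumps are allowed — lying to sitting happens in real
#' life — while only the four sedentary-to-active pairs are *counted* as
#' transitions by the metrics. Shared across severity groups; groups differ
#' in dwell times.
#'
#' @return 4x4 row-stochastic matrix with zero diagonal.
#' @export
default_transition_matrix <- function() {
  m <- matrix(c(
    # to:  walking standing sitting lying
    0.00, 0.30, 0.55, 0.15,  # from walking
    0.30, 0.00, 0.60, 0.10,  # from standing
    0.30, 0.40, 0.00, 0.30,  # from sitting
    0.05, 0.20, 0.75, 0.00   # from lying
  ), nrow = 4, byrow = TRUE)
  dimnames(m) <- list(analysis_labels(), analysis_labels())
  m
}

#' Stationary distribution of an embedded Markov chain
#'
#' @param P Row-stochastic transition matrix.
#' @return Probability vector `pi` with `pi %*% P = pi`.
#' @export
stationary_distribution <- function(P) {
  k <- nrow(P)
  A <- rbind(t(diag(k) - P), rep(1, k))
  b <- c(rep(0, k), 1)
  pi_ <- qr.solve(A, b)
  stats::setNames(pmax(pi_, 0) / sum(pmax(pi_, 0)), rownames(P))
}

# Gauss-Hermite nodes/weights for E[g(Z)], Z ~ N(0,1) (Golub-Welsch on the
# probabilists' Hermite recurrence).
gh_normal <- function(n = 21) {
  if (n == 1) return(list(x = 0, w = 1))
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1))
  J[cbind(1:(n - 1), 2:n)] <- off
  J[cbind(2:n, 1:(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = e$vectors[1, ]^2)
}

# Mean of a lognormal dwell time after discretisation to whole epochs
# (round to nearest, floor 1). Exact sum up to K epochs; beyond K the
# rounding bias is negligible and the lognormal partial expectation
# E[X 1(X > K + 1/2)] is used for the tail.
disc_dwell_mean <- function(meanlog, sdlog) {
  K <- min(2000, max(3, ceiling(stats::qlnorm(1 - 1e-6, meanlog, sdlog))))
  k <- seq_len(K)
  upper <- stats::plnorm(k + 0.5, meanlog, sdlog)
  lower <- c(0, upper[-K])
  tail_mean <- exp(meanlog + sdlog^2 / 2) *
    stats::pnorm((meanlog + sdlog^2 - log(K + 0.5)) / sdlog)
  sum(k * (upper - lower)) + tail_mean
}

# Discretised dwell mean averaged over a lognormal participant-level
# multiplier with log-multiplier ~ N(mu_l, sd_l^2).
mixed_disc_dwell_mean <- function(meanlog, sdlog, mu_l = 0, sd_l = 0, gh = gh_normal(15)) {
  if (sd_l == 0 && mu_l == 0) return(disc_dwell_mean(meanlog, sdlog))
  vals <- vapply(gh$x, function(z) disc_dwell_mean(meanlog + mu_l + sd_l * z, sdlog),
                 numeric(1))
  sum(gh$w * vals)
}

# Solve the lognormal location so the (multiplier-mixed) discretised dwell
# mean hits `target` minutes. Returns meanlog with attr "clamped" if the
# target sits below the 1-epoch floor.
solve_dwell_meanlog <- function(target, sdlog, mu_l = 0, sd_l = 0) {
  gh <- gh_normal(15)
  f <- function(m) mixed_disc_dwell_mean(m, sdlog, mu_l, sd_l, gh) - target
  lo <- log(0.02)
  hi <- log(max(target * 4, 10))
  if (f(lo) >= 0) {
    # target at/below the discretisation floor: use the smallest location
    m <- lo
    attr(m, "clamped") <- TRUE
    return(m)
  }
  while (f(hi) < 0) hi <- hi + 1
  m <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  attr(m, "clamped") <- FALSE
  m
}

#' Semi-Markov state parameters
#'
#' Bundles the embedded-chain transition matrix with per-state lognormal
#' dwell-time distributions (minutes). Dwell locations are stored on the log
#' scale; use [calibrate_state_params()] to derive them from daily time-use
#' and transition targets.
#'
#' @param transition Row-stochastic 4x4 matrix over the analysis labels,
#'   zero diagonal.
#' @param dwell_meanlog,dwell_sdlog Named numeric vectors (walking,
#'   standing, sitting, lying): lognormal parameters of dwell minutes.
#' @return Object of class `"state_params"`.
#' @export
state_params <- function(transition, dwell_meanlog, dwell_sdlog) {
  labs <- analysis_labels()
  stopifnot(
    all(dim(transition) == c(4, 4)),
    all(abs(rowSums(transition) - 1) < 1e-8),
    all(diag(transition) == 0),
    all(transition >= 0)
  )
  dimnames(transition) <- list(labs, labs)
  dwell_meanlog <- stats::setNames(as.numeric(dwell_meanlog)[seq_len(4)], labs)
  dwell_sdlog <- stats::setNames(as.numeric(dwell_sdlog)[seq_len(4)], labs)
  stopifnot(all(is.finite(dwell_meanlog)), all(dwell_sdlog > 0))
  structure(list(transition = transition,
                 dwell_meanlog = dwell_meanlog,
                 dwell_sdlog = dwell_sdlog),
            class = "state_params")
}

default_dwell_sdlog <- function() {
  c(walking = 0.6, standing = 0.7, sitting = 0.9, lying = 1.0)
}

#' Calibrate semi-Markov dwell times to time-use and transition targets
#'
#' For a semi-Markov process the expected fraction of time in state s is
#' `pi_s * E[dwell_s] / sum_k pi_k * E[dwell_k]` (`pi` = stationary
#' distribution of the embedded chain), and the expected number of counted
#' sedentary-to-active transitions per day is `J * q`, where `J = 1440 /
#' sum_k pi_k E[dwell_k]` is the daily jump rate and `q` the stationary
#' probability that a jump is one of the four counted pairs. Given target
#' daily minutes per state and a target daily transition count, this solves
#' those identities for the per-state mean dwells, then inverts each
#' lognormal location so that the *discretised* dwell (rounded to whole
#' epochs, floored at 1) — averaged over the participant-level heterogeneity
#' multipliers, if any — achieves the solved mean. A target below the
#' 1-epoch floor (very little time in many short bouts) is clamped to the
#' floor and the achieved value reported.
#'
#' @param minutes Named vector of target daily minutes (walking, standing,
#'   sitting, lying); should sum to 1440.
#' @param transitions_per_day Target daily count of the four
#'   sedentary-to-active pairs.
#' @param transition Embedded-chain matrix.
#' @param dwell_sdlog Lognormal dwell shape per state.
#' @param tempo_sdlog,active_sdlog Heterogeneity: SDs (log scale) of the
#'   participant-level tempo multiplier (all states; log-mean `+sd^2/2` so
#'   the mean transition count is preserved) and the active-time multiplier
#'   (walking/standing only; log-mean `-sd^2/2` so mean active minutes are
#'   preserved).
#' @return `state_params` object with attribute `"calibration"` (targets,
#'   achieved dwell means and minutes, expected transitions).
#' @export
calibrate_state_params <- function(minutes, transitions_per_day,
                                   transition = default_transition_matrix(),
                                   dwell_sdlog = default_dwell_sdlog(),
                                   tempo_sdlog = 0, active_sdlog = 0,
                                   gh_nodes = 9, max_iter = 10) {
  labs <- analysis_labels()
  minutes <- minutes[labs]
  stopifnot(all(minutes > 0), abs(sum(minutes) - 1440) < 1)
  pi_ <- stationary_distribution(transition)[labs]
  sed <- sedentary_labels()
  act <- active_labels()
  q <- sum(vapply(sed, function(s) pi_[[s]] * sum(transition[s, act]), numeric(1)))
  J <- transitions_per_day / q          # total jumps per day
  C <- 1440 / J                         # mean dwell across jumps, minutes
  d_target <- (minutes / 1440) * C / pi_

  is_act <- labs %in% act
  mu_l <- ifelse(is_act, tempo_sdlog^2 / 2 - active_sdlog^2 / 2, tempo_sdlog^2 / 2)
  sd_l <- ifelse(is_act, sqrt(tempo_sdlog^2 + active_sdlog^2), tempo_sdlog)
  names(mu_l) <- names(sd_l) <- labs

  # initial locations: match the mixed discretised dwell mean per state
  meanlog <- numeric(4); names(meanlog) <- labs
  clamped <- logical(4); names(clamped) <- labs
  for (s in labs) {
    m <- solve_dwell_meanlog(d_target[[s]], dwell_sdlog[[s]], mu_l[[s]], sd_l[[s]])
    meanlog[s] <- as.numeric(m)
    clamped[s] <- attr(m, "clamped")
  }

  # Participant-level expectations over the (tempo, active) multiplier grid:
  # per-participant time fractions and transition counts are ratios of the
  # realised dwell means, so the cohort means are E[ratio], not
  # ratio-of-means; a Gauss-Hermite grid over the two log-multipliers makes
  # that expectation cheap and deterministic, and a fixed-point update on
  # the dwell locations matches the targets (short active dwells interact
  # with the 1-epoch floor, so a closed form is not available).
  ght <- gh_normal(gh_nodes)
  lt <- tempo_sdlog^2 / 2 + tempo_sdlog * ght$x            # log tempo nodes
  la <- -active_sdlog^2 / 2 + active_sdlog * ght$x         # log active nodes
  wt <- ght$w
  achieved <- function(meanlog) {
    # D[s, i, j]: discretised dwell mean of state s at tempo node i, active node j
    nn <- length(lt)
    mins <- stats::setNames(numeric(4), labs)
    trans <- 0
    D <- array(0, c(4, nn, nn))
    for (si in seq_along(labs)) {
      s <- labs[si]
      for (i in seq_len(nn)) {
        if (is_act[si]) {
          for (j in seq_len(nn)) {
            D[si, i, j] <- disc_dwell_mean(meanlog[[s]] + lt[i] + la[j], dwell_sdlog[[s]])
          }
        } else {
          D[si, i, ] <- disc_dwell_mean(meanlog[[s]] + lt[i], dwell_sdlog[[s]])
        }
      }
    }
    for (i in seq_len(length(lt))) {
      for (j in seq_len(length(la))) {
        denom <- sum(pi_ * D[, i, j])
        w <- wt[i] * wt[j]
        mins <- mins + w * 1440 * pi_ * D[, i, j] / denom
        trans <- trans + w * 1440 * q / denom
      }
    }
    list(minutes = mins, transitions = trans)
  }

  ach <- achieved(meanlog)
  for (it in seq_len(max_iter)) {
    step <- log(minutes / ach$minutes) + log(ach$transitions / transitions_per_day)
    step[clamped] <- pmax(step[clamped], 0)  # clamped states cannot shrink further
    meanlog <- meanlog + step
    floor_hit <- meanlog < log(0.02)
    meanlog[floor_hit] <- log(0.02)
    clamped <- clamped | floor_hit
    ach <- achieved(meanlog)
    err <- max(abs(ach$minutes[!clamped] - minutes[!clamped]))
    terr <- abs(ach$transitions - transitions_per_day)
    if (err < 0.25 && terr < 0.1) break
  }

  params <- state_params(transition, meanlog, dwell_sdlog[labs])
  attr(params, "calibration") <- list(
    target_minutes = minutes,
    target_transitions = transitions_per_day,
    target_dwell = d_target,
    achieved_minutes = ach$minutes,
    achieved_transitions = ach$transitions,
    clamped = clamped,
    tempo_sdlog = tempo_sdlog,
    active_sdlog = active_sdlog
  )
  params
}

#' Simulate one participant's activity-label sequence
#'
#' Draws an alternating (state, dwell) sequence from the semi-Markov process
#' — next state from the embedded chain, dwell minutes from the state's
#' lognormal — discretises dwells to whole epochs (rounded to nearest,
#' minimum 1) and emits contiguous 60-second epoch labels. The initial state
#' is drawn from the embedded chain's stationary distribution. The same seed
#' always yields the same sequence.
#'
#' @param params `state_params` object.
#' @param duration_hours Length of the sequence (>= 24).
#' @param seed Optional integer seed.
#' @param participant_id Identifier written into the output.
#' @param start_time First epoch timestamp (POSIXct, UTC).
#' @param epoch_seconds Epoch length in seconds.
#' @param tempo Participant-level multiplier on all dwell times.
#' @param active_scale Additional multiplier on walking/standing dwells.
#' @return Epoch tibble (`participant_id`, `timestamp`, `label`) of exactly
#'   `duration_hours * 3600 / epoch_seconds` rows, with attribute
#'   `"dwells"`: the underlying (state, dwell-epochs) tibble for oracle
#'   checks.
#' @export
simulate_activity_sequence <- function(params, duration_hours = 24, seed = NULL,
                                       participant_id = "sim1",
                                       start_time = as.POSIXct("2024-01-01 00:00:00", tz = "UTC"),
                                       epoch_seconds = 60,
                                       tempo = 1, active_scale = 1) {
  stopifnot(inherits(params, "state_params"), duration_hours >= 24)
  n_epochs <- as.integer(duration_hours * 3600 / epoch_seconds)
  labs <- analysis_labels()
  logmult <- log(tempo) + ifelse(labs %in% active_labels(), log(active_scale), 0)
  names(logmult) <- labs
  with_seed(seed, {
    pi_ <- stationary_distribution(params$transition)
    cp <- apply(params$transition, 1, cumsum)  # column per from-state
    states <- integer(0)
    dwells <- integer(0)
    s <- sample.int(4, 1, prob = pi_)
    total <- 0L
    while (total < n_epochs) {
      block <- 256L
      st <- integer(block)
      u <- stats::runif(block)
      prev <- s
      for (i in seq_len(block)) {
        prev <- findInterval(u[i], cp[, prev]) + 1L
        st[i] <- prev
      }
      st <- c(s, st[-block])  # dwell applies to the state being occupied
      dw_cont <- stats::rlnorm(block,
                               params$dwell_meanlog[st] + logmult[st],
                               params$dwell_sdlog[st])
      dw <- pmax(1L, as.integer(round(dw_cont * 60 / epoch_seconds)))
      states <- c(states, st)
      dwells <- c(dwells, dw)
      total <- total + sum(dw)
      s <- findInterval(u[block], cp[, st[block]]) + 1L
    }
    keep <- which(cumsum(dwells) >= n_epochs)[1]
    states <- states[seq_len(keep)]
    dwells <- dwells[seq_len(keep)]
    dwells[keep] <- dwells[keep] - (sum(dwells) - n_epochs)
    lab_seq <- labs[rep(states, dwells)]
    out <- tibble::tibble(
      participant_id = participant_id,
      timestamp = start_time + (seq_len(n_epochs) - 1L) * epoch_seconds,
      label = lab_seq
    )
    attr(out, "dwells") <- tibble::tibble(state = labs[states], dwell_epochs = dwells)
    out
  })
}
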