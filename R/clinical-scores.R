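#' Names of the twelve NPI-NH symptom items
#'
#' Each item is scored frequency (0-4) times severity (0-3), giving 0-12 per
#' item and a 0-144 total.
#'
#' @return Character vector of the column names used for item scores.
#' @export
npi_item_names <- function() {
  paste0("npi_", c(
    "delusions", "hallucinations", "agitation_aggression", "depression",
    "anxiety", "euphoria", "apathy", "disinhibition", "irritability",
    "motor", "night", "appetite"
  ))
}

npi_cluster_map <- function() {
  list(
    nps_agitation = c("npi_agitation_aggression", "npi_disinhibition", "npi_irritability"),
    nps_psychosis = c("npi_delusions", "npi_hallucinations"),
    nps_affective = c("npi_depression", "npi_anxiety"),
    nps_apathy    = "npi_apathy"
  )
}

#' Cluster NPI-NH items into subsyndromes
#'
#' Adds the four subsyndrome scores used for nursing-home residents —
#' agitation (agitation/aggression + disinhibition + irritability, 0-36),
#' psychosis (delusions + hallucinations, 0-24), affective (depression +
#' anxiety, 0-24) and apathy (the apathy item, 0-12) — plus the 0-144 total
#' over all twelve items. Higher scores indicate more severe symptoms.
#'
#' @param clinical Tibble containing the twelve [npi_item_names()] columns
#'   (each an integer 0-12).
#' @return The input with `nps_agitation`, `nps_psychosis`, `nps_affective`,
#'   `nps_apathy` and `npi_total` columns added.
#' @export
npi_subsyndromes <- function(clinical) {
  items <- npi_item_names()
  missing <- setdiff(items, names(clinical))
  if (length(missing) > 0) {
    stop(sprintf("missing NPI item column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  for (it in items) {
    v <- clinical[[it]]
    bad <- which(!is.na(v) & (v < 0 | v > 12))
    if (length(bad) > 0) {
      stop(sprintf("NPI item '%s' out of range [0, 12] at row %d (value %s)",
                   it, bad[1], v[bad[1]]), call. = FALSE)
    }
  }
  cl <- npi_cluster_map()
  out <- clinical
  for (nm in names(cl)) {
    out[[nm]] <- rowSums(as.data.frame(clinical[, cl[[nm]], drop = FALSE]))
  }
  out$npi_total <- rowSums(as.data.frame(clinical[, items, drop = FALSE]))
  out
}

#' SPPB total score
#'
#' Sums the balance, 4-metre gait and repeated chair-stand sub-test scores
#' (each 0-4) into the 0-12 Short Physical Performance Battery total. A
#' sub-test that a resident attempted but could not complete is scored 0
#' (encode it as `NA` with the matching `attempted_*` flag `TRUE`); higher
#' totals indicate better physical function.
#'
#' @param balance,gait,chair Integer sub-test scores 0-4, `NA` if not
#'   completed.
#' @param attempted_balance,attempted_gait,attempted_chair Logical flags:
#'   `TRUE` if the sub-test was attempted. An attempted sub-test with a
#'   missing score contributes 0; an unattempted one leaves the total `NA`.
#' @return Tibble: `sppb_balance`, `sppb_gait`, `sppb_chair`, `sppb_total`.
#' @export
#' @examples
#' sppb_total(4, 4, 3)
#' sppb_total(NA, 2, 1, attempted_balance = TRUE) # balance attempted, not completed
sppb_total <- function(balance, gait, chair,
                       attempted_balance = TRUE, attempted_gait = TRUE,
                       attempted_chair = TRUE) {
  n <- max(length(balance), length(gait), length(chair))
  fix <- function(score, attempted, nm) {
    score <- rep_len(score, n)
    attempted <- rep_len(attempted, n)
    bad <- which(!is.na(score) & (score < 0 | score > 4 | score != round(score)))
    if (length(bad) > 0) {
      stop(sprintf("SPPB %s score out of range 0-4 at row %d (value %s)",
                   nm, bad[1], score[bad[1]]), call. = FALSE)
    }
    # attempted but unable to complete -> 0
    score[is.na(score) & attempted] <- 0
    score
  }
  b <- fix(balance, attempted_balance, "balance")
  g <- fix(gait, attempted_gait, "gait")
  c_ <- fix(chair, attempted_chair, "chair")
  tibble::tibble(
    sppb_balance = b, sppb_gait = g, sppb_chair = c_,
    sppb_total = b + g + c_
  )
}

#' @rdname sppb_total
#' @param clinical Tibble with columns `sppb_balance`, `sppb_gait`,
#'   `sppb_chair` and optional `attempted_*` logical columns.
#' @return For `score_sppb()`: the input with sub-scores normalised and
#'   `sppb_total` added.
#' @export
score_sppb <- function(clinical) {
  need <- c("sppb_balance", "sppb_gait", "sppb_chair")
  missing <- setdiff(need, names(clinical))
  if (length(missing) > 0) {
    stop(sprintf("missing SPPB column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  att <- function(nm) {
    if (nm %in% names(clinical)) clinical[[nm]] else TRUE
  }
  s <- sppb_total(clinical$sppb_balance, clinical$sppb_gait, clinical$sppb_chair,
                  att("attempted_balance"), att("attempted_gait"), att("attempted_chair"))
  out <- clinical
  out[names(s)] <- s
  out
}

#' Severity-group levels
#'
#' @return Character vector of the four ordered levels: combined no cognitive
#'   impairment / mild cognitive impairment, then mild, moderate and severe
#'   dementia.
#' @export
severity_levels <- function() {
  c("noci_mci", "mild_dementia", "moderate_dementia", "severe_dementia")
}

#' Cognitive-impairment and dementia-severity grouping
#'
#' Residents without a DSM-5 dementia diagnosis (with or without mild
#' cognitive impairment) form one combined group; residents with dementia
#' are staged by CDR sum-of-boxes: 4.5-9.0 mild, 9.5-15.5 moderate,
#' 16.0-18.0 severe. A dementia diagnosis with CDR-SOB 0.5-4.0 ("questionable
#' to very mild") falls outside the named bands; by default the DSM-5
#' diagnosis dominates and such cases are staged mild (with a warning);
#' `very_mild = "noci_mci"` assigns them to the combined non-dementia group
#' instead.
#'
#' @param has_dementia Logical: DSM-5 dementia diagnosis.
#' @param has_mci Logical: mild cognitive impairment (only relevant when
#'   `has_dementia` is `FALSE`).
#' @param cdr_sob CDR sum-of-boxes, 0-18 in 0.5 steps; required when
#'   `has_dementia` is `TRUE`, ignored otherwise.
#' @param very_mild Band assignment for dementia with CDR-SOB <= 4.0.
#' @return Ordered factor with levels [severity_levels()].
#' @export
#' @examples
#' severity_group(TRUE, FALSE, 4.5)   # mild dementia
#' severity_group(TRUE, FALSE, 16.0)  # severe dementia
#' severity_group(FALSE, TRUE, NA)    # combined no-CI / MCI group
severity_group <- function(has_dementia, has_mci = FALSE, cdr_sob = NA_real_,
                           very_mild = c("mild_dementia", "noci_mci")) {
  very_mild <- match.arg(very_mild)
  n <- max(length(has_dementia), length(has_mci), length(cdr_sob))
  has_dementia <- rep_len(as.logical(has_dementia), n)
  has_mci <- rep_len(as.logical(has_mci), n)
  cdr_sob <- rep_len(as.numeric(cdr_sob), n)

  dem <- which(has_dementia)
  if (any(is.na(cdr_sob[dem]))) {
    stop("cdr_sob is required for every participant with a dementia diagnosis",
         call. = FALSE)
  }
  chk <- cdr_sob[dem]
  off <- which(chk < 0 | chk > 18 | abs(chk * 2 - round(chk * 2)) > 1e-8)
  if (length(off) > 0) {
    stop(sprintf("cdr_sob must lie in [0, 18] on a 0.5 grid; got %s", chk[off[1]]),
         call. = FALSE)
  }

  lev <- severity_levels()
  out <- rep(lev[1], n)
  vm <- has_dementia & cdr_sob <= 4.0
  if (any(vm)) {
    warning(sprintf(
      "%d dementia case(s) with CDR-SOB <= 4.0 (questionable/very mild band) assigned to %s",
      sum(vm), very_mild), call. = FALSE)
  }
  out[has_dementia & cdr_sob <= 4.0] <- very_mild
  out[has_dementia & cdr_sob >= 4.5 & cdr_sob <= 9.0] <- lev[2]
  out[has_dementia & cdr_sob >= 9.5 & cdr_sob <= 15.5] <- lev[3]
  out[has_dementia & cdr_sob >= 16.0] <- lev[4]
  factor(out, levels = lev, ordered = TRUE)
}

#' Numeric 1-4 code for the severity groups
#'
#' @param severity Factor from [severity_group()].
#' @return Integer vector, 1 = no-CI/MCI ... 4 = severe dementia.
#' @export
severity_code <- function(severity) {
  as.integer(factor(as.character(severity), levels = severity_levels()))
}

#' Read a participant clinical table from CSV
#'
#' Expects one row per participant with `participant_id`, the twelve NPI
#' item columns ([npi_item_names()]) or their frequency/severity halves
#' (`<item>_freq` 0-4 and `<item>_sev` 0-3, multiplied on ingest), SPPB
#' sub-scores, `dx_dementia`, `dx_mci`, `cdr_sob`, `age`, `sex`, `bmi`.
#'
#' @param path CSV path.
#' @return Tibble with NPI items as 0-12 products.
#' @export
read_clinical_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("clinical file not found: %s", path), call. = FALSE)
  df <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  if (!"participant_id" %in% names(df)) {
    stop("clinical CSV is missing required column(s): participant_id", call. = FALSE)
  }
  df$participant_id <- as.character(df$participant_id)
  for (it in npi_item_names()) {
    fs <- paste0(it, c("_freq", "_sev"))
    if (!it %in% names(df) && all(fs %in% names(df))) {
      f <- df[[fs[1]]]
      s <- df[[fs[2]]]
      if (any(!is.na(f) & (f < 0 | f > 4)) || any(!is.na(s) & (s < 0 | s > 3))) {
        stop(sprintf("frequency/severity out of range for %s", it), call. = FALSE)
      }
      df[[it]] <- f * s
    }
  }
  tibble::as_tibble(df)
}

#' Score a clinical table end to end
#'
#' Convenience wrapper: NPI subsyndromes, SPPB totals, severity groups and
#' their numeric codes in one call.
#'
#' @param clinical Clinical tibble (see [read_clinical_csv()]).
#' @inheritParams severity_group
#' @return Scored tibble with `nps_*`, `npi_total`, `sppb_total`, `severity`
#'   and `severity_code` columns.
#' @export
score_clinical <- function(clinical, very_mild = c("mild_dementia", "noci_mci")) {
  out <- npi_subsyndromes(clinical)
  out <- score_sppb(out)
  out$severity <- severity_group(out$dx_dementia, out$dx_mci, out$cdr_sob,
                                 very_mild = match.arg(very_mild))
  out$severity_code <- severity_code(out$severity)
  out
}
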