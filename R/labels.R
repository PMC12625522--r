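#' Activity label vocabularies
#'
#' The epoch classifier emits six raw labels over 60-second windows. After
#' remapping (see [remap_labels()]) only four analysis labels remain:
#' walking, standing, sitting and lying. Sitting and lying are flagged
#' sedentary; walking and standing are flagged active.
#'
#' @return Character vector of labels, lowercase.
#' @export
#' @examples
#' analysis_labels()
#' raw_labels()
analysis_labels <- function() c("walking", "standing", "sitting", "lying")

#' @rdname analysis_labels
#' @export
raw_labels <- function() c(analysis_labels(), "running", "cycling")

#' @rdname analysis_labels
#' @export
sedentary_labels <- function() c("sitting", "lying")

#' @rdname analysis_labels
#' @export
active_labels <- function() c("walking", "standing")

#' Is a label sedentary?
#'
#' @param label character vector of analysis labels.
#' @return Logical vector: `TRUE` for sitting/lying, `FALSE` for
#'   walking/standing, `NA` otherwise.
#' @export
is_sedentary <- function(label) {
  out <- rep(NA, length(label))
  out[label %in% sedentary_labels()] <- TRUE
  out[label %in% active_labels()] <- FALSE
  out
}

#' Default raw-to-analysis label remapping
#'
#' Visual inspection of lower-back/thigh accelerometer data from walker users
#' shows that epochs classified as cycling are in fact walking (leaning on a
#' walker with a low step frequency mimics cycling), so cycling is remapped to
#' walking. Running is remapped to walking as well; it does not occur in this
#' population, so the choice is inert on faithful data but keeps the mapping
#' total and deterministic.
#'
#' @return Named character vector: names are raw labels, values the analysis
#'   labels they become.
#' @export
default_label_remap <- function() {
  c(cycling = "walking", running = "walking")
}

# ordered sedentary -> active pairs that count as a transition
transition_pairs <- function() {
  tibble::tibble(
    from = c("lying", "lying", "sitting", "sitting"),
    to   = c("standing", "walking", "standing", "walking")
  )
}

assert_analysis_labels <- function(label, arg = "label") {
  bad <- setdiff(unique(label), analysis_labels())
  if (length(bad) > 0) {
    stop(sprintf(
      "`%s` contains non-analysis labels: %s. Remap raw labels first (see remap_labels()).",
      arg, paste(bad, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(label)
}
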