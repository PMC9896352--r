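#' Onboarding label space
#'
#' The label space is the ordered set of answers to the two multi-select
#' onboarding questions ("how are you feeling" and "which areas of your life
#' does this impact"). Every card label vector and every user response vector
#' is laid out against this ordering, so the space must be fixed and shared.
#' Catch-all answers ("Something else") are retained in the space but flagged
#' non-informative: they never contribute to similarity.
#'
#' @param feelings Character vector of answers to the feelings question.
#' @param impacts Character vector of answers to the impact-areas question.
#' @param non_informative Answers treated as carrying no signal.
#'
#' @return A tibble of class `label_space` with columns `question`
#'   (`"feeling"` or `"impact"`), `label`, `label_id` (unique coordinate
#'   name), and `informative` (logical).
#' @export
#' @examples
#' space <- default_label_space()
#' sum(space$informative) # 14 informative coordinates
label_space <- function(feelings, impacts, non_informative = "Something else") {
  stopifnot(is.character(feelings), is.character(impacts))
  if (anyDuplicated(feelings) || anyDuplicated(impacts)) {
    abort("labels must be unique within each question")
  }
  space <- tibble(
    question = c(rep("feeling", length(feelings)), rep("impact", length(impacts))),
    label = c(feelings, impacts)
  )
  space$informative <- !(space$label %in% non_informative)
  # Coordinate names must be unique even though the catch-all answer appears
  # under both questions.
  space$label_id <- ifelse(
    duplicated(space$label) | duplicated(space$label, fromLast = TRUE),
    paste0(space$label, " (", space$question, ")"),
    space$label
  )
  class(space) <- c("label_space", class(space))
  space
}

#' @rdname label_space
#' @export
default_label_space <- function() {
  label_space(
    feelings = c(
      "Anxious", "Depressed", "Grieving", "Not motivated",
      "Overwhelmed", "Stressed", "Something else"
    ),
    impacts = c(
      "Career", "Dating", "Family", "Hobbies", "Personal finance",
      "Personal growth", "Physical health", "Social life", "Something else"
    )
  )
}

#' Onboarding response
#'
#' A user's answers to the two onboarding questions. Both questions are
#' multi-select and the app forces at least one selection per question.
#'
#' @param feelings Character vector of selected feelings.
#' @param impacts Character vector of selected impact areas.
#' @param space Label space to validate against.
#'
#' @return A list of class `onboarding_response` with elements `feelings`
#'   and `impacts`.
#' @export
#' @examples
#' onboarding_response(c("Anxious", "Depressed"), "Career")
onboarding_response <- function(feelings, impacts, space = default_label_space()) {
  stopifnot(is.character(feelings), is.character(impacts))
  if (length(feelings) == 0 || length(impacts) == 0) {
    abort("each onboarding question requires at least one selection")
  }
  bad_f <- setdiff(feelings, space$label[space$question == "feeling"])
  bad_i <- setdiff(impacts, space$label[space$question == "impact"])
  if (length(bad_f) + length(bad_i) > 0) {
    abort(sprintf(
      "unknown onboarding label(s): %s",
      paste(c(bad_f, bad_i), collapse = ", ")
    ))
  }
  structure(
    list(feelings = unique(feelings), impacts = unique(impacts)),
    class = "onboarding_response"
  )
}

#' Read an onboarding response from JSON
#'
#' Expects an object with keys `feelings` and `impacts`, each an array of
#' answer strings.
#'
#' @param path Path to a JSON file.
#' @inheritParams onboarding_response
#' @return An [onboarding_response()].
#' @export
read_onboarding_response <- function(path, space = default_label_space()) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$feelings) || is.null(obj$impacts)) {
    abort("onboarding response JSON must have keys 'feelings' and 'impacts'")
  }
  onboarding_response(obj$feelings, obj$impacts, space)
}

# TRUE when the response carries no usable signal (only catch-all answers on
# both questions); such users are routed to random recommendations.
is_uninformative_response <- function(response, space = default_label_space()) {
  inf_f <- space$label[space$question == "feeling" & space$informative]
  inf_i <- space$label[space$question == "impact" & space$informative]
  !any(response$feelings %in% inf_f) && !any(response$impacts %in% inf_i)
}
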