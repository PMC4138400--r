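#' Construct an ODI questionnaire response
#'
#' The Oswestry Disability Index (ODI) has ten items scored 0-5, higher
#' meaning greater perceived disability.  Missing items are allowed (coded
#' `NA`) as long as at least one item is answered.
#'
#' @param item_scores integer vector of up to 10 item scores in 0..5,
#'   `NA` for unanswered items.
#' @param subject_id,visit_id identifiers.
#' @return An `odi_response` object.
#' @export
odi_response <- function(item_scores, subject_id = "", visit_id = "") {
  if (length(item_scores) < 1L || length(item_scores) > 10L) {
    gs_abort("ODI has between 1 and 10 items", "gs_invalid_input")
  }
  answered <- !is.na(item_scores)
  if (!any(answered)) {
    gs_abort("all ODI items missing", "gs_invalid_input")
  }
  sc <- item_scores[answered]
  if (any(sc != round(sc)) || any(sc < 0) || any(sc > 5)) {
    gs_abort("ODI item scores must be integers in 0..5", "gs_invalid_data")
  }
  structure(
    list(
      item_scores = as.integer(item_scores),
      subject_id = as.character(subject_id),
      visit_id = as.character(visit_id)
    ),
    class = "odi_response"
  )
}

#' Score an ODI response onto the 0-1 index
#'
#' The index is the mean item score normalized by the item maximum:
#' `sum(answered) / (5 * n_answered)`.  Missing items are excluded from
#' numerator and denominator (the standard ODI renormalization), so the
#' index always lies in \[0, 1\]; with all ten items answered it reduces to
#' the usual ODI score.
#'
#' @param response an `odi_response`, or a bare numeric vector of item
#'   scores.
#' @return list with `value` (in \[0, 1\]) and `n_answered`.
#' @examples
#' odi_index(odi_response(rep(3L, 10)))$value  # 0.6
#' @export
odi_index <- function(response) {
  if (!inherits(response, "odi_response")) {
    response <- odi_response(response)
  }
  sc <- response$item_scores
  answered <- !is.na(sc)
  list(value = sum(sc[answered]) / (5 * sum(answered)),
       n_answered = sum(answered))
}

#' Classify a patient as functional or nonfunctional
#'
#' Patients whose post-intervention ODI index is at most 0.6 are classified
#' as "functional"; above 0.6 as "nonfunctional".  The boundary itself is
#' functional (the rule is inclusive).
#'
#' @param odi_post ODI index value(s) in \[0, 1\], or the list returned by
#'   [odi_index()].
#' @return character vector of `"functional"` / `"nonfunctional"`.
#' @export
classify_functional <- function(odi_post) {
  if (is.list(odi_post)) odi_post <- odi_post$value
  if (any(odi_post < 0 | odi_post > 1, na.rm = TRUE)) {
    gs_abort("ODI index must lie in [0, 1]", "gs_invalid_data")
  }
  ifelse(odi_post <= 0.6, "functional", "nonfunctional")
}
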