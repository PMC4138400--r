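#' Built-in spring table of the handgrip device
#'
#' The handle of the spring-loaded handgrip device is resisted by three
#' springs acting in parallel; five interchangeable springs are available.
#' Constants are in lbs/inch.
#'
#' @param path optional path to a JSON file `{"S1": 0.38, ...}` overriding
#'   the built-in constants.
#' @return data.frame with columns `label` and `constant` (lbs/inch).
#' @export
spring_table <- function(path = NULL) {
  if (is.null(path)) {
    return(data.frame(
      label = paste0("S", 1:5),
      constant = c(0.38, 0.88, 1.94, 5.10, 10.70),
      stringsAsFactors = FALSE
    ))
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!length(raw) || !all(vapply(raw, is.numeric, logical(1)))) {
    gs_abort("spring table JSON must map labels to numeric lbs/inch",
             "gs_format_error")
  }
  k <- unlist(raw)
  if (any(k <= 0)) gs_abort("spring constants must be > 0", "gs_invalid_data")
  data.frame(label = names(k), constant = unname(k), stringsAsFactors = FALSE)
}

#' Select springs calibrating device resistance to a subject's MVC
#'
#' Springs act in parallel, so the effective constant of a subset is the sum
#' of its members' constants and the resistance at full grasp is
#' `effective_constant * grip_displacement`.  All subsets of `subset_size`
#' springs are enumerated; the chosen subset is the one whose resistance, as
#' a fraction of the subject's MVC, falls inside `band` and is closest to
#' the band midpoint.  If no subset lands in the band the closest subset is
#' returned with `out_of_band = TRUE`.  Ties in distance to the midpoint are
#' broken toward the stiffer subset so the choice is deterministic.
#'
#' @param mvc the subject's maximum voluntary contraction in lbs.
#' @param grip_displacement handle travel at full grasp in inches (default 1).
#' @param springs data.frame as returned by [spring_table()].
#' @param subset_size number of springs mounted at once (default 3).
#' @param band target resistance band as a fraction of MVC (default
#'   `c(0.70, 0.80)`).
#' @return A `spring_set`: labels, constants, `effective_constant`
#'   (lbs/inch), `resistance_at_full_grip` (lbs), `fraction_of_mvc`, and
#'   `out_of_band` flag.
#' @examples
#' select_springs(mvc = 20)
#' @export
select_springs <- function(mvc, grip_displacement = 1.0,
                           springs = spring_table(), subset_size = 3L,
                           band = c(0.70, 0.80)) {
  gs_check_scalar(mvc, "mvc")
  gs_check_scalar(grip_displacement, "grip_displacement")
  if (nrow(springs) < subset_size) {
    gs_abort(sprintf("need at least %d springs, have %d",
                     subset_size, nrow(springs)), "gs_invalid_input")
  }
  mid <- mean(band)
  subsets <- utils::combn(nrow(springs), subset_size)
  eff <- colSums(matrix(springs$constant[subsets], nrow = subset_size))
  frac <- eff * grip_displacement / mvc
  in_band <- frac >= band[1] & frac <= band[2]
  pool <- if (any(in_band)) which(in_band) else seq_along(frac)
  dist <- abs(frac[pool] - mid)
  # ties toward the stiffer set: order by distance, then decreasing stiffness
  best <- pool[order(dist, -eff[pool])][1L]
  idx <- subsets[, best]
  structure(
    list(
      labels = springs$label[idx],
      constants = springs$constant[idx],
      effective_constant = eff[best],
      resistance_at_full_grip = eff[best] * grip_displacement,
      fraction_of_mvc = frac[best],
      out_of_band = !any(in_band),
      band = band
    ),
    class = "spring_set"
  )
}

#' @export
print.spring_set <- function(x, ...) {
  cat(sprintf(
    "<spring_set> {%s}: k_eff %.2f lbs/inch, resistance %.2f lbs = %.1f%% of MVC%s\n",
    paste(x$labels, collapse = ","), x$effective_constant,
    x$resistance_at_full_grip, 100 * x$fraction_of_mvc,
    if (x$out_of_band) " [outside target band]" else ""))
  invisible(x)
}
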