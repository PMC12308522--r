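#' Legal fish size categories for underwater visual census records
#'
#' Divers record the total length of each fish to the nearest legal size
#' category rather than as a continuous measurement. The bin labels (in cm)
#' follow the standard reef-survey convention: 2.5 cm classes up to 15 cm,
#' 5 cm classes to 30 cm, 10 cm classes to 50 cm, and 12.5 cm classes above
#' 50 cm, extended up to `max_cm`.
#'
#' @param max_cm Largest length (cm) the label set must reach (default 200).
#' @return Strictly increasing numeric vector of bin labels in cm.
#' @examples
#' legal_size_categories()
#' @export
legal_size_categories <- function(max_cm = 200) {
  stopifnot(is.numeric(max_cm), length(max_cm) == 1, max_cm >= 15)
  labels <- c(seq(2.5, 15, by = 2.5), seq(20, 30, by = 5), seq(40, 50, by = 10))
  if (max_cm > 50) {
    labels <- c(labels, seq(62.5, max_cm + 12.5, by = 12.5))
    labels <- labels[labels <= max(max_cm, 62.5)]
  }
  labels
}

#' Snap a true length to the nearest legal size category
#'
#' Returns the legal bin label closest to each length; exact midpoints are
#' broken downward so that estimated sizes are conservative.
#'
#' @param length_cm Numeric vector of true total lengths in cm (> 0).
#' @param categories Ordered label set, by default [legal_size_categories()].
#' @return Numeric vector of bin labels, same length as `length_cm`.
#' @examples
#' nearest_size_category(c(13, 56))
#' @export
nearest_size_category <- function(length_cm, categories = legal_size_categories()) {
  if (!is.numeric(length_cm) || any(!is.finite(length_cm)) || any(length_cm <= 0)) {
    stop("`length_cm` must be finite and positive", call. = FALSE)
  }
  categories <- sort(categories)
  # bin boundaries are midpoints between adjacent labels; left-open intervals
  # put an exact midpoint into the lower bin (ties broken downward)
  cuts <- (categories[-1] + categories[-length(categories)]) / 2
  categories[findInterval(length_cm, cuts, left.open = TRUE) + 1]
}
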