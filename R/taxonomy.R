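#' Activity taxonomies
#'
#' An activity taxonomy is an ordered set of (name, abbreviation) pairs.
#' [default_taxonomy()] returns the 15-activity taxonomy used throughout the
#' package: nine daily activities (stair climbing, postural transitions,
#' walking, squatting, jump rope) and six fall types.
#'
#' @param classes data.frame with columns `name` and `abbreviation`.
#' @return An object of class `activity_taxonomy`: a data.frame with columns
#'   `name` and `abbreviation`, one row per class.
#' @examples
#' tax <- default_taxonomy()
#' nrow(tax)            # 15
#' tax$abbreviation[1]  # "UPS"
#' @export
activity_taxonomy <- function(classes) {
  stopifnot(is.data.frame(classes), all(c("name", "abbreviation") %in% names(classes)))
  if (anyDuplicated(classes$abbreviation))
    stop("activity abbreviations must be unique", call. = FALSE)
  out <- data.frame(name = as.character(classes$name),
                    abbreviation = as.character(classes$abbreviation),
                    stringsAsFactors = FALSE)
  class(out) <- c("activity_taxonomy", "data.frame")
  out
}

#' @rdname activity_taxonomy
#' @export
default_taxonomy <- function() {
  activity_taxonomy(data.frame(
    name = c("Going upstairs", "Going downstairs", "Sitting on a chair",
             "Getting up from a chair", "Lying up on the bed",
             "Lying down on the bed", "Walking", "Squat and rise", "Jump rope",
             "Fall forward", "Fall forward on one's knees", "Fall back",
             "Look to the left and fall", "Look to the right and fall",
             "Fall out of the bed"),
    abbreviation = c("UPS", "DWS", "SC", "GC", "LUB", "LDB", "WK", "SQ", "JR",
                     "FF", "FFK", "FB", "LF", "RF", "FOB"),
    stringsAsFactors = FALSE))
}
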