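# Behavior alphabets: the coded state space of the play-observation streams.

.CORE6 <- data.frame(
  code = c("nonverbal_initiation", "responsive_behavior", "emotional_sharing",
           "joint_attention", "speech_initiation", "avoidance"),
  display_name = c("Nonverbal initiation", "Responsive behavior",
                   "Emotional sharing", "Joint attention",
                   "Speech initiation", "Avoidance behavior"),
  min_duration = c(1, 0.5, 2, 1.5, 1, 3),
  stringsAsFactors = FALSE
)

.FULL7 <- rbind(.CORE6, data.frame(
  code = "stereotypy", display_name = "Stereotyped actions",
  min_duration = 2.5, stringsAsFactors = FALSE
))

#' Behavior coding alphabet
#'
#' Construct the ordered set of coded behavior categories used throughout the
#' package. The `"core6"` preset holds the six social-interaction categories
#' on which group-level transition matrices are defined; `"full7"` adds
#' stereotypy, needed for avoidance--stereotypy chain analyses. Each category
#' carries the minimum codable duration (seconds) used by [segment_events()].
#'
#' @param preset `"core6"` (default) or `"full7"`.
#' @param categories Optional data frame with columns `code`, `display_name`,
#'   `min_duration` to define a custom alphabet (overrides `preset`).
#' @return A `behavior_alphabet`: a data frame with columns `code`,
#'   `display_name`, `min_duration` and one row per category.
#' @examples
#' behavior_alphabet()
#' behavior_alphabet("full7")
#' @export
behavior_alphabet <- function(preset = c("core6", "full7"), categories = NULL) {
  if (is.null(categories)) {
    preset <- match.arg(preset)
    categories <- if (preset == "core6") .CORE6 else .FULL7
  } else {
    categories <- as.data.frame(categories, stringsAsFactors = FALSE)
    req <- c("code", "display_name", "min_duration")
    if (!all(req %in% names(categories)))
      stop("custom alphabet needs columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(categories$code))
    stop("category codes must be unique within an alphabet")
  if (any(categories$min_duration < 0))
    stop("min_duration must be >= 0")
  rownames(categories) <- NULL
  structure(categories, class = c("behavior_alphabet", "data.frame"))
}

#' @export
print.behavior_alphabet <- function(x, ...) {
  cat("Behavior alphabet (", nrow(x), " categories)\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Number of categories in an alphabet
#' @param alphabet A [behavior_alphabet()].
#' @return Integer count of categories.
#' @export
alphabet_size <- function(alphabet) nrow(alphabet)

# internal: assert codes belong to the alphabet
.check_codes <- function(codes, alphabet, what = "category") {
  bad <- setdiff(unique(codes), alphabet$code)
  if (length(bad))
    stop("unknown ", what, " code(s) not in alphabet: ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}
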