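#' Momentary item schema for the six symptom composites
#'
#' Maps the twelve momentary items to the six depressive symptom composites.
#' Items marked reversed are mapped x -> 100 - x before averaging:
#' * anhedonia = mean(indifferent, listless, enthusiastic (reversed))
#' * depressed_mood = mean(down, cheerful (reversed))
#' * appetite_change = hungry (deviation item, used as given)
#' * restlessness = mean(calm (reversed), stressed, relaxed (reversed))
#' * irritability = irritated
#' * lethargy = mean(tired, energetic (reversed))
#'
#' @return Named list: composite -> data frame of (item, reversed).
#' @export
ema_item_schema <- function() {
  list(
    anhedonia = data.frame(
      item = c("indifferent", "listless", "enthusiastic"),
      reversed = c(FALSE, FALSE, TRUE)),
    depressed_mood = data.frame(
      item = c("down", "cheerful"),
      reversed = c(FALSE, TRUE)),
    appetite_change = data.frame(
      item = "hungry", reversed = FALSE),
    restlessness = data.frame(
      item = c("calm", "stressed", "relaxed"),
      reversed = c(TRUE, FALSE, TRUE)),
    irritability = data.frame(
      item = "irritated", reversed = FALSE),
    lethargy = data.frame(
      item = c("tired", "energetic"),
      reversed = c(FALSE, TRUE))
  )
}

#' Reverse-score a visual analogue scale item
#' @param x Values in \[0, 100\].
#' @return `100 - x`.
#' @export
reverse_vas <- function(x) {
  if (any(x < 0 | x > 100, na.rm = TRUE)) stop("VAS items must lie in [0, 100]")
  100 - x
}

#' Build symptom composites from momentary item responses
#'
#' Averages each composite's indicators after reverse-scoring, keeping all
#' variables on the 0-100 visual analogue scale. A composite is missing only
#' when all of its indicators are missing; otherwise it is the mean of the
#' available indicators (whole-beep missingness makes partial availability
#' rare in practice).
#'
#' @param items A matrix or data frame with one row per beep and columns
#'   named as in [ema_item_schema()] (extra columns are ignored).
#' @return A matrix with one row per beep and the six composite columns in
#'   [symptom_names()] order.
#' @examples
#' b <- data.frame(down = 80, cheerful = 20, indifferent = 50, listless = 50,
#'                 enthusiastic = 50, hungry = 50, calm = 100, stressed = 0,
#'                 relaxed = 100, irritated = 0, tired = 50, energetic = 50)
#' composite_symptoms(b)[, "depressed_mood"]  # 80
#' @export
composite_symptoms <- function(items) {
  items <- as.data.frame(items)
  schema <- ema_item_schema()
  needed <- unique(unlist(lapply(schema, `[[`, "item")))
  miss_cols <- setdiff(needed, names(items))
  if (length(miss_cols))
    stop("missing item columns: ", paste(miss_cols, collapse = ", "))
  bad <- vapply(needed, function(cl) any(items[[cl]] < 0 | items[[cl]] > 100,
                                         na.rm = TRUE), logical(1))
  if (any(bad))
    stop("item values outside [0, 100]: ", paste(needed[bad], collapse = ", "))
  out <- sapply(schema, function(sp) {
    vals <- sapply(seq_len(nrow(sp)), function(i) {
      v <- items[[sp$item[i]]]
      if (sp$reversed[i]) 100 - v else v
    })
    vals <- matrix(vals, nrow = nrow(items))
    rowMeans(vals, na.rm = TRUE)
  })
  out <- matrix(out, nrow = nrow(items),
                dimnames = list(NULL, names(schema)))
  out[is.nan(out)] <- NA_real_  # all indicators missing
  out[, symptom_names(), drop = FALSE]
}
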