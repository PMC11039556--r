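#' Score the Inventory of Depressive Symptomatology, Self-Report (IDS-SR)
#'
#' The IDS-SR has 30 items rated 0-3, of which 28 enter the total score:
#' appetite change is asked as a decrease/increase pair (items 11/12) and
#' weight change likewise (items 13/14), and each pair contributes a single
#' item. Here each pair contributes its maximum, so the total ranges 0-84.
#' Severity categories follow the published bands: 0-13 none, 14-21 mild,
#' 22-30 moderate, 31-38 severe, 39+ very severe.
#'
#' @param items Integer vector of 30 item scores, each in 0-3, in standard
#'   item order (11 = appetite decrease, 12 = appetite increase, 13 = weight
#'   decrease, 14 = weight increase).
#' @return A list of class `severity_result` with `total` (integer, 0-84)
#'   and `category` (factor: none/mild/moderate/severe/very severe).
#' @examples
#' score_ids_sr(rep(0L, 30))$category   # "none"
#' @export
score_ids_sr <- function(items) {
  items <- as.integer(items)
  if (length(items) != 30L) stop("IDS-SR requires exactly 30 items")
  if (anyNA(items) || any(items < 0L | items > 3L))
    stop("every IDS-SR item must be an integer in 0-3")
  scored <- items[-c(11L, 12L, 13L, 14L)]
  total <- sum(scored) + max(items[11:12]) + max(items[13:14])
  structure(list(total = total, category = severity_category(total)),
            class = "severity_result")
}

#' Severity category from an IDS-SR total score
#' @param total Integer total in 0-84.
#' @return Factor with levels none, mild, moderate, severe, very severe.
#' @export
severity_category <- function(total) {
  if (any(total < 0 | total > 84)) stop("IDS-SR total must be in 0-84")
  cut(total, breaks = c(-1, 13, 21, 30, 38, 84),
      labels = c("none", "mild", "moderate", "severe", "very severe"))
}

#' @export
print.severity_result <- function(x, ...) {
  cat(sprintf("IDS-SR total %d (%s depression)\n", x$total,
              as.character(x$category)))
  invisible(x)
}

#' Group participants by identical symptom severity total
#'
#' A severity group is the set of participants sharing one IDS-SR total
#' score; only totals attained by at least two participants form groups
#' (matching on severity requires at least one partner). Participants with a
#' unique total are reported as excluded, never silently dropped.
#'
#' @param ids Character vector of participant identifiers.
#' @param totals Integer vector of IDS-SR totals, parallel to `ids`.
#' @return A list of class `severity_grouping` with `groups` (named list:
#'   severity total -> member ids), `sizes`, `excluded` (ids with unique
#'   totals) and `n_groups`.
#' @export
build_severity_groups <- function(ids, totals) {
  if (length(ids) != length(totals)) stop("ids and totals must be parallel")
  if (length(ids) < 1L) stop("at least one participant required")
  totals <- as.integer(totals)
  tab <- table(totals)
  matched <- as.integer(names(tab)[tab >= 2L])
  groups <- lapply(matched, function(s) ids[totals == s])
  names(groups) <- as.character(matched)
  structure(
    list(
      groups = groups,
      sizes = vapply(groups, length, integer(1)),
      excluded = ids[!(totals %in% matched)],
      n_groups = length(groups)
    ),
    class = "severity_grouping"
  )
}

#' @export
print.severity_grouping <- function(x, ...) {
  cat(sprintf("%d severity groups (sizes %s); %d participant(s) excluded\n",
              x$n_groups,
              if (x$n_groups) paste(range(x$sizes), collapse = "-") else "-",
              length(x$excluded)))
  invisible(x)
}
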