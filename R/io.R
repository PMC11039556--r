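# File exchange: long-format EMA CSV (the canonical format — one row per
# participant x beep, missingness explicit as empty cells), ground-truth
# JSON sidecars for simulated studies, network exports and run manifests.

#' Read long-format EMA data
#'
#' Expects a CSV with header `participant_id, day, beep` plus numeric value
#' columns (symptom composites or raw items), values in \[0, 100\] or empty
#' for missing. The beep grid is reconstructed and validated against the
#' study design; rows outside the grid or duplicated (participant, day,
#' beep) combinations are hard errors naming the offending line. Beeps
#' absent from the file are treated as missing.
#'
#' @param path CSV path.
#' @param design A [study_design()].
#' @param variables Optional expected value-column names; by default all
#'   non-key columns are used (and reported).
#' @return Named list of [symptom_series()], one per participant.
#' @export
read_ema_long <- function(path, design = study_design(), variables = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  key <- c("participant_id", "day", "beep")
  if (!all(key %in% names(df)))
    stop("EMA file must have columns participant_id, day, beep")
  value_cols <- setdiff(names(df), key)
  if (!is.null(variables)) {
    unknown <- setdiff(value_cols, variables)
    if (length(unknown))
      message("ignoring unknown columns: ", paste(unknown, collapse = ", "))
    missing_cols <- setdiff(variables, value_cols)
    if (length(missing_cols))
      stop("missing value columns: ", paste(missing_cols, collapse = ", "))
    value_cols <- variables
  }
  if (!length(value_cols)) stop("no value columns found")
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  bad_grid <- df$day < 1L | df$day > design$n_days |
    df$beep < 1L | df$beep > design$beeps_per_day
  if (any(bad_grid))
    stop("rows outside the beep grid at line(s): ",
         paste(utils::head(line[bad_grid], 5L), collapse = ", "))
  for (cl in value_cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- !is.na(v) & (v < 0 | v > 100)
    if (any(bad))
      stop(sprintf("column '%s' outside [0, 100] at line(s): %s", cl,
                   paste(utils::head(line[bad], 5L), collapse = ", ")))
    df[[cl]] <- v
  }
  keys <- paste(df$participant_id, df$day, df$beep)
  if (anyDuplicated(keys)) {
    d <- which(duplicated(keys))[1L]
    stop(sprintf("duplicate (participant, day, beep) row at line %d: %s",
                 line[d], keys[d]))
  }
  out <- list()
  for (pid in unique(df$participant_id)) {
    sub <- df[df$participant_id == pid, , drop = FALSE]
    t_idx <- (sub$day - 1L) * design$beeps_per_day + sub$beep
    Y <- matrix(NA_real_, design$max_assessments, length(value_cols),
                dimnames = list(NULL, value_cols))
    Y[t_idx, ] <- as.matrix(sub[, value_cols, drop = FALSE])
    out[[as.character(pid)]] <- symptom_series(pid, Y, design,
                                               variables = value_cols)
  }
  out
}

#' Write series as long-format EMA CSV
#'
#' Inverse of [read_ema_long()]: one row per participant x beep, missing
#' values as empty cells. `read_ema_long(write_ema_long(x))` restores values
#' and missingness exactly.
#'
#' @param series_list Named list of [symptom_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ema_long <- function(series_list, path) {
  rows <- lapply(series_list, function(s) {
    data.frame(participant_id = s$id, day = s$day, beep = s$beep,
               s$values, check.names = FALSE, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a simulated study: EMA CSV plus ground-truth JSON sidecar
#'
#' @param study A `simulated_study` from [build_null_study()] or
#'   [build_alternative_study()].
#' @param dir Output directory (created if needed).
#' @param stem File stem (default "study").
#' @return Named character vector of the written paths, invisibly.
#' @export
write_study <- function(study, dir, stem = "study") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ema <- file.path(dir, paste0(stem, "_ema.csv"))
  truth <- file.path(dir, paste0(stem, "_truth.json"))
  write_ema_long(study$series, ema)
  truth_list <- lapply(study$participants$id, function(pid) {
    tg <- study$truth[[pid]]
    i <- match(pid, study$participants$id)
    list(id = pid, group = study$participants$group[i],
         severity = study$participants$severity[i],
         mu = tg$mu, B = tg$B, K = tg$K)
  })
  jsonlite::write_json(
    list(participants = truth_list,
         design = study$design[c("n_days", "beeps_per_day", "inter_beep_hours")]),
    truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(ema = ema, truth = truth))
}

#' Export a fitted network model
#'
#' Writes `prefix.json` (mu, B, K, Omega, loglik, n_params, convergence)
#' and two edge-list CSVs ready for standard graph tooling:
#' `prefix_temporal.csv` (from, to, weight; entry b_ij is the edge from j to
#' i) and `prefix_contemporaneous.csv` (i, j, weight; upper triangle of the
#' partial-correlation matrix).
#'
#' @param model A `gvar_model`.
#' @param prefix Output path prefix.
#' @param drop_zero Omit zero-weight edges (default TRUE; relevant for
#'   sparse LASSO fits).
#' @return Named character vector of paths, invisibly.
#' @export
write_gvar_model <- function(model, prefix, drop_zero = TRUE) {
  jpath <- paste0(prefix, ".json")
  jsonlite::write_json(
    list(id = model$id, variables = model$variables, mu = model$mu,
         B = model$B, K = model$K, Omega = model$Omega,
         loglik = model$loglik, n_params = model$n_params,
         n_obs = model$n_obs, convergence = model$convergence),
    jpath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  v <- model$variables
  tmp <- expand.grid(to = seq_along(v), from = seq_along(v))
  tedges <- data.frame(from = v[tmp$from], to = v[tmp$to],
                       weight = as.numeric(model$B[cbind(tmp$to, tmp$from)]))
  ut <- which(upper.tri(model$Omega), arr.ind = TRUE)
  cedges <- data.frame(i = v[ut[, 1]], j = v[ut[, 2]],
                       weight = model$Omega[ut])
  if (drop_zero) {
    tedges <- tedges[tedges$weight != 0, , drop = FALSE]
    cedges <- cedges[cedges$weight != 0, , drop = FALSE]
  }
  tpath <- paste0(prefix, "_temporal.csv")
  cpath <- paste0(prefix, "_contemporaneous.csv")
  utils::write.csv(tedges, tpath, row.names = FALSE)
  utils::write.csv(cedges, cpath, row.names = FALSE)
  invisible(c(json = jpath, temporal = tpath, contemporaneous = cpath))
}

#' Write a run manifest
#'
#' Records the configuration, seed, package version and timestamp of an
#' analysis run so every output artifact is reproducible from its manifest.
#'
#' @param path Output JSON path.
#' @param config Named list of configuration values.
#' @param seed The master seed used.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seed) {
  jsonlite::write_json(
    list(config = config, seed = seed,
         package = as.character(utils::packageVersion("idionet")),
         r_version = R.version.string,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
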