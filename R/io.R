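#' Construct a pattern store from an event table and matrices
#'
#' Builds the container the similarity engine consumes: per-participant,
#' per-ROI trial-by-voxel matrices whose rows align with the participant's
#' trials in chronological (onset) order.
#'
#' @param events event table.
#' @param patterns named list: `patterns[[participant_id]][[roi_name]]` is a
#'   matrix with one row per trial of that participant.
#' @return A `pattern_store`.
#' @export
pattern_store <- function(events, patterns) {
  stopifnot(is.data.frame(events), is.list(patterns))
  index <- list()
  roi_names <- character(0)
  for (pid in names(patterns)) {
    ev <- events[events$participant_id == pid, , drop = FALSE]
    ev <- ev[order(ev$onset), , drop = FALSE]
    ev$row <- seq_len(nrow(ev))
    index[[pid]] <- ev
    roi_names <- union(roi_names, names(patterns[[pid]]))
    for (roi in names(patterns[[pid]])) {
      abort_if(nrow(patterns[[pid]][[roi]]) != nrow(ev),
               sprintf("matrix for %s/%s has %d rows but %d trials",
                       pid, roi, nrow(patterns[[pid]][[roi]]), nrow(ev)))
    }
  }
  structure(list(patterns = patterns, index = index, roi_names = roi_names),
            class = "pattern_store")
}

# Schema-validated TSV I/O for the pipeline's tabular artifacts, plus a
# plain-text container for pattern matrices (one TSV per participant x ROI
# with a sidecar index mapping rows to trials).

events_schema <- list(
  participant_id = "character", session = "integer", run = "integer",
  trial = "integer", onset = "numeric", image_id = "character",
  exposure = "integer", is_filler = "logical")

final_test_schema <- list(
  participant_id = "character", image_id = "character",
  item_type = "character", confidence = "integer",
  frequency_response = "integer", timeline_estimate = "numeric",
  actual_E1_onset = "numeric", cr_e1 = "logical", hit_e2 = "logical",
  hit_e3 = "logical")

coerce_checked <- function(df, schema, file) {
  missing_cols <- setdiff(names(schema), names(df))
  abort_if(length(missing_cols) > 0L,
           sprintf("%s: missing column(s) %s", file,
                   paste(missing_cols, collapse = ", ")))
  for (nm in names(schema)) {
    df[[nm]] <- switch(schema[[nm]],
                       character = as.character(df[[nm]]),
                       integer = as.integer(df[[nm]]),
                       numeric = as.numeric(df[[nm]]),
                       logical = as.logical(df[[nm]]))
  }
  tibble::as_tibble(df[, names(schema)])
}

check_range <- function(df, col, ok, file) {
  bad <- which(!ok)
  abort_if(length(bad) > 0L,
           sprintf("%s: column '%s' out of range at row %d (value %s)",
                   file, col, bad[1L], df[[col]][bad[1L]]))
}

#' Write / read the event table as TSV
#'
#' Tab-separated UTF-8 with a header row; onsets in seconds from experiment
#' start, sessions/runs/trials 1-based, exposure indices in 1-3. Reading
#' validates the schema and value ranges and errors naming the file, column
#' and first offending row.
#'
#' @param events event table.
#' @param path file path.
#' @return `read_events()` returns the validated tibble.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  df <- coerce_checked(df, events_schema, path)
  check_range(df, "session", df$session >= 1L, path)
  check_range(df, "run", df$run >= 1L, path)
  check_range(df, "trial", df$trial >= 1L, path)
  check_range(df, "exposure", df$exposure %in% 1:3, path)
  check_range(df, "onset", is.finite(df$onset) & df$onset >= 0, path)
  df
}

#' Write / read the final-test table as TSV
#'
#' @param final_test final-test table.
#' @param path file path.
#' @return `read_final_test()` returns the validated tibble.
#' @export
write_final_test <- function(final_test, path) {
  utils::write.table(final_test, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_final_test
#' @export
read_final_test <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  df <- coerce_checked(df, final_test_schema, path)
  check_range(df, "confidence", df$confidence %in% 1:6, path)
  check_range(df, "item_type", df$item_type %in% c("old", "novel"), path)
  est <- df$timeline_estimate
  check_range(df, "timeline_estimate",
              is.na(est) | (est >= 0 & est <= 1), path)
  df
}

#' Write / read a pattern store as plain-text matrices with a sidecar index
#'
#' One `<participant>_<roi>.tsv` matrix file per participant and ROI plus an
#' `index.tsv` mapping matrix rows to participant/session/run/trial. Intended
#' for small exports; patterns are normally kept in memory.
#'
#' @param store a `pattern_store`.
#' @param dir output directory (created if needed).
#' @return `read_pattern_store()` returns a `pattern_store`.
#' @export
write_pattern_store <- function(store, dir) {
  stopifnot(inherits(store, "pattern_store"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- list()
  for (pid in names(store$index)) {
    ev <- store$index[[pid]]
    idx[[pid]] <- tibble::tibble(participant_id = pid, row = ev$row,
                                 session = ev$session, run = ev$run,
                                 trial = ev$trial, onset = ev$onset,
                                 image_id = ev$image_id,
                                 exposure = ev$exposure,
                                 is_filler = ev$is_filler)
    for (roi in store$roi_names) {
      utils::write.table(store$patterns[[pid]][[roi]],
                         file.path(dir, paste0(pid, "_", roi, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
    }
  }
  utils::write.table(do.call(rbind, idx), file.path(dir, "index.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_pattern_store
#' @export
read_pattern_store <- function(dir) {
  index_path <- file.path(dir, "index.tsv")
  abort_if(!file.exists(index_path),
           sprintf("%s: sidecar index.tsv not found", dir))
  idx <- utils::read.table(index_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  patterns <- list()
  index <- list()
  mats <- list.files(dir, pattern = "\\.tsv$")
  mats <- setdiff(mats, "index.tsv")
  roi_names <- character(0)
  for (f in mats) {
    stem <- sub("\\.tsv$", "", f)
    pid <- sub("_[^_]+$", "", stem)
    roi <- sub("^.*_", "", stem)
    roi_names <- union(roi_names, roi)
    mat <- as.matrix(utils::read.table(file.path(dir, f), sep = "\t"))
    dimnames(mat) <- NULL
    ev <- tibble::as_tibble(idx[idx$participant_id == pid, , drop = FALSE])
    abort_if(nrow(ev) != nrow(mat),
             sprintf("%s: %d matrix rows but %d index rows for %s",
                     f, nrow(mat), nrow(ev), pid))
    patterns[[pid]][[roi]] <- mat
    index[[pid]] <- ev
  }
  structure(list(patterns = patterns, index = index, roi_names = roi_names),
            class = "pattern_store")
}
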