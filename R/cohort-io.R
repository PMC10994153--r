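#' Read and validate a cohort table
#'
#' Reads a comma-delimited UTF-8 cohort file in the package's wide dialect
#' (columns \code{glucose_0..glucose_120}, \code{insulin_0..insulin_120}
#' plus demographics and labs) or a long dialect (one row per time point
#' with columns \code{id, time, glucose, insulin} and per-participant
#' metadata repeated), and validates every row against the participant
#' record invariants. Rows failing validation are excluded from the
#' returned cohort and reported, with row index and reason, in the
#' \code{"rejected"} attribute — mirroring a study analysis that excludes
#' participants with incomplete OGTT measurements or a missing HbA1c
#' rather than silently dropping them.
#'
#' @param path file path.
#' @param schema "wide" (default) or "long".
#' @return data.frame of class \code{ogtt_cohort} containing the valid
#'   records; \code{attr(, "rejected")} is a data.frame (row, id, reason).
#' @export
read_cohort <- function(path, schema = c("wide", "long")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (schema == "long") raw <- long_to_wide(raw)
  validate_cohort(raw)
}

gcols <- function(prefix = "glucose") paste0(prefix, "_", c(0, 30, 60, 90, 120))

required_cohort_columns <- function() {
  c("id", "age", "sex", "race", "ethnicity", "bmi_percentile", "hba1c",
    gcols("glucose"), gcols("insulin"))
}

long_to_wide <- function(raw) {
  need <- c("id", "time", "glucose", "insulin")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop(sprintf("schema error: long file is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  }
  meta_cols <- setdiff(names(raw), c("time", "glucose", "insulin"))
  wide <- stats::reshape(
    raw[c("id", "time", "glucose", "insulin")],
    idvar = "id", timevar = "time", direction = "wide", sep = "_")
  names(wide) <- sub("^(glucose|insulin)_(\\d+)$", "\\1_\\2", names(wide))
  meta <- raw[!duplicated(raw$id), meta_cols, drop = FALSE]
  out <- merge(meta, wide, by = "id", sort = FALSE)
  rownames(out) <- NULL
  out
}

validate_cohort <- function(raw) {
  miss <- setdiff(required_cohort_columns(), names(raw))
  if (length(miss)) {
    stop(sprintf("schema error: missing required column(s): %s",
                 paste(miss, collapse = ", ")))
  }
  series_cols <- c(gcols("glucose"), gcols("insulin"))
  bad_cells <- NULL
  for (cl in series_cols) {
    if (!is.numeric(raw[[cl]])) {
      v <- suppressWarnings(as.numeric(raw[[cl]]))
      newly_na <- which(is.na(v) & !is.na(raw[[cl]]) & raw[[cl]] != "")
      if (length(newly_na)) {
        bad_cells <- c(bad_cells, sprintf("%s[row %d]", cl, newly_na))
      }
      raw[[cl]] <- v
    }
  }
  if (length(bad_cells)) {
    stop(sprintf("parse error: non-numeric glucose/insulin cells: %s",
                 paste(bad_cells, collapse = ", ")))
  }
  if (nrow(raw) == 0L) {
    warning("cohort file has a header but no rows")
    rej <- data.frame(row = integer(), id = character(), reason = character())
    attr(raw, "rejected") <- rej
    class(raw) <- c("ogtt_cohort", "data.frame")
    return(raw)
  }

  G <- as.matrix(raw[gcols("glucose")])
  I <- as.matrix(raw[gcols("insulin")])
  reason <- rep(NA_character_, nrow(raw))
  flag <- function(cond, why) {
    reason[is.na(reason) & cond] <<- why
  }
  flag(rowSums(is.finite(G) & G > 0) < 5L | rowSums(is.finite(I) & I > 0) < 5L,
       "incomplete OGTT")
  flag(!is.finite(raw$hba1c), "missing HbA1c")
  flag(!is.finite(raw$bmi_percentile) | raw$bmi_percentile < 85,
       "BMI percentile below 85th (inclusion rule)")
  flag(!is.finite(raw$age) | raw$age < 0, "invalid age")
  for (cl in intersect(c("hba1c", "total_chol", "ldl", "hdl", "triglycerides",
                         "waist_cm", "sbp", "dbp"), names(raw))) {
    flag(!is.na(raw[[cl]]) & raw[[cl]] < 0, sprintf("negative %s", cl))
  }

  bad <- which(!is.na(reason))
  rejected <- data.frame(row = bad,
                         id = as.character(raw$id[bad]),
                         reason = reason[bad], stringsAsFactors = FALSE)
  if (nrow(rejected)) {
    message(sprintf("read_cohort: excluded %d row(s): %s", nrow(rejected),
                    paste(sprintf("row %d (%s)", rejected$row, rejected$reason),
                          collapse = "; ")))
  }
  out <- raw[setdiff(seq_len(nrow(raw)), bad), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  class(out) <- c("ogtt_cohort", "data.frame")
  out
}

#' Write result tables and a run manifest
#'
#' Writes each named table as a comma-delimited UTF-8 file
#' (\code{<name>.csv}; missing values as empty fields) plus
#' \code{manifest.txt} recording the config hash, seed, written files and a
#' timestamp.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory (created if absent).
#' @param config optional \code{ogtt_config} recorded in the manifest.
#' @return invisibly, a data.frame manifest (file, rows).
#' @export
write_results <- function(tables, out_dir, config = NULL) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2L) != 0L) {
    stop(sprintf("I/O error: directory not writable: %s", out_dir))
  }
  files <- character(0)
  rows <- integer(0)
  for (nm in names(tables)) {
    f <- file.path(out_dir, paste0(nm, ".csv"))
    tab <- as.data.frame(tables[[nm]])
    # serialize doubles at full precision so a write/read round trip is exact
    for (cl in names(tab)) {
      if (is.double(tab[[cl]])) {
        x <- sprintf("%.17g", tab[[cl]])
        x[is.na(tab[[cl]])] <- NA_character_
        tab[[cl]] <- x
      }
    }
    utils::write.csv(tab, f, row.names = FALSE, na = "")
    files <- c(files, basename(f))
    rows <- c(rows, nrow(tables[[nm]]))
  }
  manifest <- c(
    sprintf("config_hash: %s", if (is.null(config)) "none" else config_hash(config)),
    sprintf("seed: %s", if (is.null(config)) "none" else config$seed),
    sprintf("file: %s (%d rows)", files, rows),
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(data.frame(file = files, rows = rows, stringsAsFactors = FALSE))
}
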