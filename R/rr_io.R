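#' Construct an RR-interval series
#'
#' An \code{rr_series} holds the ordered beat-to-beat intervals of one
#' recording session together with the subject/session metadata used by the
#' downstream cohort analysis. Intervals are in milliseconds; device
#' resolution is typically 1 ms but edited beats may be non-integer, so the
#' intervals are stored as doubles.
#'
#' @param intervals Numeric vector of RR intervals in ms, all positive,
#'   length at least 2.
#' @param subject_id Subject identifier (coerced to character).
#' @param sex \code{"M"}, \code{"F"} or \code{NA}.
#' @param mission Mission / crew cohort label (1, 2, 3) or \code{NA}.
#' @param month One of \code{"BASELINE"}, \code{"Feb"} ... \code{"Oct"}, or
#'   \code{NA}.
#' @param source File path the series was read from, or \code{"synthetic"}.
#'
#' @return An object of class \code{rr_series}: a list with elements
#'   \code{intervals}, \code{subject_id}, \code{sex}, \code{mission},
#'   \code{month}, \code{source}.
#' @export
rr_series <- function(intervals, subject_id = NA_character_, sex = NA_character_,
                      mission = NA, month = NA_character_, source = "synthetic") {
  intervals <- as.numeric(intervals)
  if (length(intervals) < 2L)
    .stop2("an RR series needs at least 2 intervals", "icehrv_short_series")
  if (anyNA(intervals) || any(intervals <= 0))
    .stop2("all RR intervals must be positive and non-missing",
           "icehrv_invalid_interval")
  if (!is.na(sex) && !sex %in% c("M", "F"))
    stop("sex must be 'M', 'F' or NA", call. = FALSE)
  if (!is.na(month) && !month %in% .MONTH_LABELS)
    stop("month must be one of ", paste(.MONTH_LABELS, collapse = ", "),
         call. = FALSE)
  structure(list(intervals = intervals,
                 subject_id = as.character(subject_id),
                 sex = sex, mission = mission, month = month,
                 source = source),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  dur <- sum(x$intervals) / 1000
  cat(sprintf("RR series: %s [%s, %s]  %d beats, %.1f s, mean RR %.1f ms\n",
              x$subject_id, x$sex %||% NA, x$month %||% NA,
              length(x$intervals), dur, mean(x$intervals)))
  invisible(x)
}

#' @export
length.rr_series <- function(x) length(x$intervals)

#' Recording duration of an RR or NN series
#'
#' @param x An \code{rr_series} or \code{nn_series}.
#' @return Duration in seconds (cumulative sum of intervals).
#' @export
rr_duration <- function(x) {
  iv <- if (inherits(x, "nn_series")) x$nn_intervals else x$intervals
  sum(iv) / 1000
}

#' Read one RR-interval session file
#'
#' Two plain-text dialects are supported. \code{"plain"} files carry one
#' interval (ms) per line; blank lines and lines starting with \code{#} are
#' ignored. \code{"hrm"} files are a minimal subset of the Polar HRM export:
#' intervals are read from the lines following a \code{[HRData]} section
#' header (up to the next \code{[...]} header); everything before is ignored.
#'
#' @param path Path to the file.
#' @param dialect \code{"plain"} (default) or \code{"hrm"}.
#' @param subject_id,sex,mission,month Session metadata (from the manifest;
#'   the file itself carries none).
#' @return An [rr_series] with intervals in file order and
#'   \code{source = path}.
#' @export
read_rr_file <- function(path, dialect = c("plain", "hrm"),
                         subject_id = NA_character_, sex = NA_character_,
                         mission = NA, month = NA_character_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "hrm") {
    start <- grep("^\\s*\\[HRData\\]\\s*$", lines)
    if (!length(start))
      stop("no [HRData] section in ", path, call. = FALSE)
    lines <- lines[seq.int(start[1L] + 1L, length(lines))]
    nxt <- grep("^\\s*\\[", lines)
    if (length(nxt)) lines <- lines[seq_len(nxt[1L] - 1L)]
    offset <- start[1L]
  } else offset <- 0L
  keep <- !grepl("^\\s*(#|$)", lines)
  vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
  if (!length(vals))
    .stop2(paste0("empty RR series in ", path), "icehrv_empty_series")
  if (anyNA(vals)) {
    bad <- which(keep)[which(is.na(vals))[1L]] + offset
    stop("non-numeric RR value at line ", bad, " of ", path, call. = FALSE)
  }
  if (any(vals <= 0))
    .stop2(paste0("non-positive RR interval in ", path),
           "icehrv_invalid_interval")
  rr_series(vals, subject_id = subject_id, sex = sex, mission = mission,
            month = month, source = path)
}

#' Read a cohort manifest
#'
#' The manifest is a CSV with columns \code{subject_id}, \code{sex},
#' \code{mission}, \code{month}, \code{rr_file}. One \code{BASELINE} row per
#' subject is expected for modelling; \code{(subject_id, month)} pairs must
#' be unique.
#'
#' @param path Path to the manifest CSV.
#' @return A data.frame with the five manifest columns, validated.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "sex", "mission", "month", "rr_file")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("manifest missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(m$month), .MONTH_LABELS)
  if (length(bad))
    stop("manifest has invalid month label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  key <- paste(m$subject_id, m$month)
  if (anyDuplicated(key))
    stop("duplicate (subject_id, month) in manifest: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  m
}

#' Load every RR series listed in a manifest
#'
#' Rows whose file is missing are reported in the \code{missing} attribute
#' (and via a warning), never silently dropped.
#'
#' @param manifest A manifest data.frame (see [read_manifest()]) or a path
#'   to one.
#' @param base_dir Directory that relative \code{rr_file} paths are resolved
#'   against; defaults to the manifest's directory when \code{manifest} is a
#'   path, else \code{"."}.
#' @param dialect RR file dialect passed to [read_rr_file()].
#' @return A list of [rr_series], with attribute \code{missing}: a
#'   data.frame of manifest rows whose file was absent.
#' @export
load_cohort <- function(manifest, base_dir = NULL, dialect = "plain") {
  if (is.character(manifest) && length(manifest) == 1L) {
    base_dir <- base_dir %||% dirname(manifest)
    manifest <- read_manifest(manifest)
  }
  base_dir <- base_dir %||% "."
  if (!nrow(manifest)) {
    warning("empty manifest: no sessions loaded")
    return(structure(list(), missing = manifest))
  }
  key <- paste(manifest$subject_id, manifest$month)
  if (anyDuplicated(key))
    stop("duplicate (subject_id, month) in manifest", call. = FALSE)
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", manifest$rr_file), manifest$rr_file,
                  file.path(base_dir, manifest$rr_file))
  ok <- file.exists(paths)
  if (any(!ok))
    warning(sum(!ok), " manifest row(s) point to missing files; reported in ",
            "attr(,'missing')")
  series <- lapply(which(ok), function(i)
    read_rr_file(paths[i], dialect = dialect,
                 subject_id = manifest$subject_id[i], sex = manifest$sex[i],
                 mission = manifest$mission[i], month = manifest$month[i]))
  names(series) <- key[ok]
  structure(series, missing = manifest[!ok, , drop = FALSE])
}

#' Write a result table as CSV
#'
#' Writes UTF-8 CSV with a header and '.' as decimal separator. When the
#' table has \code{subject_id} and \code{month} columns the rows are ordered
#' deterministically by subject, then month (BASELINE first, then Feb..Oct).
#'
#' @param x A data.frame.
#' @param path Output path.
#' @return Invisibly, the (possibly reordered) data.frame written.
#' @export
write_hrv_table <- function(x, path) {
  if (all(c("subject_id", "month") %in% names(x)) && nrow(x)) {
    ord <- order(x$subject_id,
                 match(as.character(x$month), .MONTH_LABELS))
    x <- x[ord, , drop = FALSE]
  }
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(x)
}
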