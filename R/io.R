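# Activity vocabularies for the two supported CSV dialects.
HASC_LABELS <- c("stay", "walk", "jog", "skip", "stUp", "stDown")
CHEST_LABELS <- c("computer_work",            # 1
                  "stand_walk_stairs",        # 2
                  "standing",                 # 3
                  "walking",                  # 4
                  "stairs",                   # 5
                  "walk_and_talk",            # 6
                  "talk_while_standing")      # 7

#' Read an accelerometer recording in the HASC CSV dialect
#'
#' Parses headerless `timestamp,x,y,z` rows (timestamps in seconds from
#' recording start). Fully-`NA` rows (`t,NA,NA,NA`) are recorded as missing
#' samples with their timestamp retained. Two collection modes are
#' supported: `segmented` files hold a single activity for the whole
#' recording, with the label taken from the `label` argument or, failing
#' that, matched against the six-activity vocabulary in the file name;
#' `sequential` files hold several activities in a row and take per-row
#' labels from a companion label track (`label_track`), a headered CSV of
#' `start,end,label` intervals in seconds (half-open `[start, end)`).
#'
#' @param path CSV file path.
#' @param mode `"segmented"` or `"sequential"`.
#' @param label Activity label for segmented mode (one of `stay, walk, jog,
#'   skip, stUp, stDown`).
#' @param label_track Path to the interval label track for sequential mode.
#' @param subject_id Subject identifier; default the file name stem.
#' @return A tri-axial [sensor_series()].
#' @export
read_hasc <- function(path, mode = c("segmented", "sequential"),
                      label = NULL, label_track = NULL, subject_id = NULL) {
  mode <- match.arg(mode)
  raw <- utils::read.csv(path, header = FALSE,
                         col.names = c("t", "x", "y", "z"),
                         colClasses = "character", strip.white = TRUE)
  parse_num <- function(col, name) {
    bad <- !is.na(col) & col != "NA" & is.na(suppressWarnings(as.numeric(col)))
    if (any(bad))
      stop(sprintf("%s: non-numeric value '%s' in column %s, line %d",
                   path, col[which(bad)[1L]], name, which(bad)[1L]),
           call. = FALSE)
    out <- suppressWarnings(as.numeric(col))
    out[col == "NA"] <- NA_real_
    out
  }
  t <- parse_num(raw$t, "timestamp")
  if (anyNA(t)) stop(sprintf("%s: missing timestamp, line %d", path,
                             which(is.na(t))[1L]), call. = FALSE)
  if (any(diff(t) < 0))
    stop(sprintf("%s: decreasing timestamp at line %d", path,
                 which(diff(t) < 0)[1L] + 1L), call. = FALSE)
  vals <- cbind(x = parse_num(raw$x, "x"), y = parse_num(raw$y, "y"),
                z = parse_num(raw$z, "z"))

  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))

  labels <- if (mode == "segmented") {
    if (is.null(label)) {
      hit <- HASC_LABELS[vapply(HASC_LABELS, grepl, TRUE, x = basename(path),
                                ignore.case = TRUE)]
      if (length(hit) != 1L)
        stop(sprintf("%s: cannot infer activity label; pass `label`", path),
             call. = FALSE)
      label <- hit
    }
    if (!label %in% HASC_LABELS)
      stop(sprintf("%s: unknown activity label '%s'", path, label),
           call. = FALSE)
    rep(label, length(t))
  } else {
    if (is.null(label_track))
      stop("sequential mode needs a label_track file", call. = FALSE)
    iv <- utils::read.csv(label_track, stringsAsFactors = FALSE)
    if (!all(c("start", "end", "label") %in% names(iv)))
      stop(sprintf("%s: label track needs start,end,label columns",
                   label_track), call. = FALSE)
    bad <- setdiff(iv$label, HASC_LABELS)
    if (length(bad))
      stop(sprintf("%s: unknown activity label '%s'", label_track, bad[1L]),
           call. = FALSE)
    lab <- rep(NA_character_, length(t))
    for (i in seq_len(nrow(iv)))
      lab[t >= iv$start[i] & t < iv$end[i]] <- iv$label[i]
    lab
  }
  sensor_series(vals, timestamps = t, labels = labels,
                subject_id = subject_id)
}

#' Read a chest-mounted accelerometer recording
#'
#' Parses headerless `sample_number,x,y,z,label` rows sampled at a fixed
#' 52 Hz. Timestamps are synthesized from the sample number as
#' `(sample_number - 1) / 52` seconds, so the first sample sits at 0 and 52
#' samples span one second. Labels are the integer activity codes 1–7,
#' mapped to named classes; rows labeled 0 (unlabeled) are dropped with a
#' message reporting the count.
#'
#' @param path CSV file path.
#' @param subject_id Subject identifier; default the file name stem.
#' @param sampling_rate Nominal rate in Hz (default 52).
#' @return A tri-axial [sensor_series()] with per-row class labels.
#' @export
read_chest <- function(path, subject_id = NULL, sampling_rate = 52) {
  raw <- utils::read.csv(path, header = FALSE,
                         col.names = c("i", "x", "y", "z", "label"),
                         colClasses = "character", strip.white = TRUE)
  num <- function(col, name) {
    bad <- !is.na(col) & col != "NA" & is.na(suppressWarnings(as.numeric(col)))
    if (any(bad))
      stop(sprintf("%s: non-numeric value '%s' in column %s, line %d",
                   path, col[which(bad)[1L]], name, which(bad)[1L]),
           call. = FALSE)
    out <- suppressWarnings(as.numeric(col))
    out[col == "NA"] <- NA_real_
    out
  }
  i <- num(raw$i, "sample_number")
  lab_code <- num(raw$label, "label")
  if (any(is.na(lab_code) | lab_code < 0 | lab_code > 7 |
            lab_code != round(lab_code)))
    stop(sprintf("%s: activity label outside 0-7, line %d", path,
                 which(is.na(lab_code) | lab_code < 0 | lab_code > 7)[1L]),
         call. = FALSE)
  drop <- lab_code == 0
  if (any(drop))
    message(sprintf("%s: dropping %d unlabeled (label 0) rows", path,
                    sum(drop)))
  keep <- !drop
  vals <- cbind(x = num(raw$x, "x"), y = num(raw$y, "y"),
                z = num(raw$z, "z"))[keep, , drop = FALSE]
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  sensor_series(vals, timestamps = (i[keep] - 1) / sampling_rate,
                sampling_rate = sampling_rate,
                labels = CHEST_LABELS[lab_code[keep]],
                subject_id = subject_id)
}

#' Write a sensor series as HASC-dialect CSV
#'
#' Headerless `timestamp,x,y,z` rows; masked rows are serialized with the
#' literal token `NA` in every channel. `read_hasc()` round-trips the
#' result.
#'
#' @param series A [sensor_series()].
#' @param path Output path.
#' @param labels If `TRUE`, append the per-row label as a final column
#'   (used when exporting synthetic data).
#' @return `path`, invisibly.
#' @export
write_sensor_csv <- function(series, path, labels = FALSE) {
  stopifnot(inherits(series, "sensor_series"))
  df <- data.frame(t = series$timestamps, series$values,
                   check.names = FALSE)
  if (labels && !is.null(series$labels)) df$label <- series$labels
  utils::write.table(df, path, sep = ",", na = "NA", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a feature table
#'
#' Plain CSV with a header; undefined features are serialized as `NA`.
#'
#' @param features A `har_features` table.
#' @param path File path.
#' @return `write_feature_csv`: `path`, invisibly. `read_feature_csv`: the
#'   `har_features` table.
#' @export
write_feature_csv <- function(features, path) {
  stopifnot(inherits(features, "har_features"))
  utils::write.csv(as.data.frame(features), path, row.names = FALSE,
                   na = "NA")
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- c("subject_id", "window_start", "label", "n_valid")
  if (!all(meta %in% names(df)))
    stop(sprintf("%s: not a feature table (missing metadata columns)", path),
         call. = FALSE)
  structure(df, feature_cols = setdiff(names(df), meta),
            class = c("har_features", "data.frame"))
}
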