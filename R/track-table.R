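#' Construct and validate a track table
#'
#' A track table is the canonical long-format container for 3D cell
#' trajectories: one row per cell per frame, with positions in
#' micrometres and per-track condition (e.g. `"HT"`, `"LT"`,
#' `"LT+TGFB"`) and phenotype labels (`"R"`, `"P"`, `"D"`, `"A1"`,
#' `"A2"`, `"A3"`, `"B"` or `"unknown"`).
#'
#' @param df data.frame with columns `track_id`, `frame`, `time_s`,
#'   `x_um`, `y_um`, `z_um` and optionally `condition`, `phenotype`
#'   (missing labels are filled with `"unknown"`).
#' @param frame_interval_s optional frame interval; when given, `time_s`
#'   is checked to equal `frame * frame_interval_s`.
#' @return a validated `track_table` (a data.frame sorted by
#'   `(track_id, frame)`).
#' @export
track_table <- function(df, frame_interval_s = NULL) {
  required <- c("track_id", "frame", "time_s", "x_um", "y_um", "z_um")
  for (col in required) {
    m3d_assert(col %in% names(df), "migr3d_format_error",
               "track table is missing required column '%s'", col)
  }
  if (is.null(df$condition)) df$condition <- "unknown"
  if (is.null(df$phenotype)) df$phenotype <- "unknown"
  df$condition[is.na(df$condition) | df$condition == ""] <- "unknown"
  df$phenotype[is.na(df$phenotype) | df$phenotype == ""] <- "unknown"

  df$track_id <- as.character(df$track_id)
  df$frame <- as.integer(df$frame)
  for (col in c("time_s", "x_um", "y_um", "z_um")) {
    df[[col]] <- as.double(df[[col]])
  }
  df <- df[order(df$track_id, df$frame),
           c(required, "condition", "phenotype"), drop = FALSE]
  rownames(df) <- NULL

  m3d_assert(all(df$frame >= 0L), "migr3d_validation_error",
             "negative frame indices")
  num <- as.matrix(df[, c("time_s", "x_um", "y_um", "z_um")])
  m3d_assert(all(is.finite(num)), "migr3d_validation_error",
             "non-finite time or coordinates in track table")

  for (id in unique(df$track_id)) {
    fr <- df$frame[df$track_id == id]
    m3d_assert(!anyDuplicated(fr), "migr3d_validation_error",
               "duplicated (track_id, frame) pair in track '%s'", id)
    m3d_assert(all(diff(fr) > 0L), "migr3d_validation_error",
               "frames not strictly increasing in track '%s'", id)
  }
  if (!is.null(frame_interval_s)) {
    m3d_assert(
      all(abs(df$time_s - df$frame * frame_interval_s) <
            1e-6 * max(1, frame_interval_s)),
      "migr3d_validation_error",
      "time_s does not equal frame * frame_interval_s")
  }
  class(df) <- c("track_table", "data.frame")
  df
}

# vendor column names of an Imaris-like export mapped to canonical ones
.imaris_column_map <- c(
  "Position X" = "x_um", "Position Y" = "y_um", "Position Z" = "z_um",
  "Time" = "frame", "TrackID" = "track_id",
  "Condition" = "condition", "Phenotype" = "phenotype")

#' Read a 3D track table from CSV
#'
#' @param path CSV file. The canonical dialect has the header
#'   `track_id,frame,time_s,x_um,y_um,z_um,condition,phenotype`; the
#'   `imaris_export` dialect maps vendor columns ("Position X", "Time",
#'   "TrackID", ...) onto canonical fields, with `Time` interpreted as a
#'   1-based frame counter.
#' @param dialect `"plain_csv"` or `"imaris_export"`.
#' @param frame_interval_s frame interval in seconds, used to fill
#'   `time_s` for dialects that do not carry it and to cross-check it
#'   where present.
#' @return a [track_table()].
#' @export
read_tracks <- function(path, dialect = c("plain_csv", "imaris_export"),
                        frame_interval_s = NULL) {
  dialect <- match.arg(dialect)
  m3d_assert(file.exists(path), "migr3d_io_error", "no such file: %s", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)

  if (dialect == "imaris_export") {
    need <- c("Position X", "Position Y", "Position Z", "Time", "TrackID")
    for (col in need) {
      m3d_assert(col %in% names(df), "migr3d_format_error",
                 "imaris export is missing required column '%s'", col)
    }
    keep <- names(df) %in% names(.imaris_column_map)
    df <- df[, keep, drop = FALSE]
    names(df) <- .imaris_column_map[names(df)]
    df$frame <- as.integer(df$frame) - 1L   # vendor Time counter is 1-based
    if (is.null(frame_interval_s)) frame_interval_s <- 1200
    df$time_s <- df$frame * frame_interval_s
  }
  track_table(df, frame_interval_s = frame_interval_s)
}

#' Write a track table to CSV
#'
#' Columns are written in the stable canonical order
#' `track_id,frame,time_s,x_um,y_um,z_um,condition,phenotype` so that
#' `read_tracks(write_tracks(x))` reproduces `x`.
#'
#' @param table a [track_table()].
#' @param path output file.
#' @export
write_tracks <- function(table, path) {
  table <- track_table(table)
  out <- as.data.frame(table)
  for (col in c("time_s", "x_um", "y_um", "z_um")) {
    # 17 significant digits: doubles survive the text round trip exactly
    out[[col]] <- formatC(out[[col]], digits = 17, format = "g")
  }
  ok <- tryCatch({
    write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  m3d_assert(ok, "migr3d_io_error", "cannot write track table to %s", path)
  invisible(path)
}

#' Split a track table into per-track position matrices
#'
#' @param table a [track_table()].
#' @return named list (one element per track id) of lists with
#'   `pos` (n x 3 matrix of x/y/z in um), `time_s`, `frame`,
#'   `condition`, `phenotype`.
#' @export
split_tracks <- function(table) {
  table <- track_table(table)
  out <- lapply(split(seq_len(nrow(table)), table$track_id), function(i) {
    sub <- table[i, , drop = FALSE]
    list(pos = as.matrix(sub[, c("x_um", "y_um", "z_um")]),
         time_s = sub$time_s, frame = sub$frame,
         condition = sub$condition[1], phenotype = sub$phenotype[1])
  })
  out
}
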