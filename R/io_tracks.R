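#' Describe the layout of a stacked track table
#'
#' Track tables stack multiple particles vertically in the same columns:
#' each particle contributes exactly `frames_per_particle` consecutive data
#' rows, numbered 1..NF in the frame column, and particle k occupies data
#' rows `(k-1)*NF + 1` to `k*NF` (the first file row is a header and is
#' skipped). Columns may be named by spreadsheet letter (`"A"`, `"B"`, ...,
#' position in the sheet) or by header name. Coordinates recorded in pixels
#' are converted on read by `pixel_ratio` (length units per pixel); leave
#' it at 1 when coordinates are already in physical units.
#'
#' @param frame_column,x_column,y_column column identifiers (letter or
#'   header name); must be pairwise distinct.
#' @param z_column optional Z column identifier for 3D tracks.
#' @param frames_per_particle NF, frames per particle (>= 2).
#' @param n_particles number of stacked particles (>= 1).
#' @param pixel_ratio length units per pixel (> 0); 1 = no conversion.
#' @param length_unit,time_unit unit labels attached to the trajectories.
#' @param time_per_frame TF, time between frames in `time_unit` (> 0).
#' @return a `"track_table_spec"` list.
#' @export
track_table_spec <- function(frame_column = "A", x_column = "B",
                             y_column = "C", z_column = NULL,
                             frames_per_particle, n_particles,
                             pixel_ratio = 1, length_unit = "um",
                             time_unit = "min", time_per_frame) {
  frames_per_particle <- as.integer(frames_per_particle)
  n_particles <- as.integer(n_particles)
  if (frames_per_particle < 2L)
    stop("`frames_per_particle` must be at least 2", call. = FALSE)
  if (n_particles < 1L)
    stop("`n_particles` must be at least 1", call. = FALSE)
  if (!is.numeric(pixel_ratio) || pixel_ratio <= 0)
    stop("`pixel_ratio` must be positive", call. = FALSE)
  if (!is.numeric(time_per_frame) || time_per_frame <= 0)
    stop("`time_per_frame` must be positive", call. = FALSE)
  cols <- c(frame_column, x_column, y_column, z_column)
  if (anyDuplicated(cols))
    stop("frame, x, y (and z) columns must be pairwise distinct",
         call. = FALSE)
  structure(
    list(frame_column = frame_column, x_column = x_column,
         y_column = y_column, z_column = z_column,
         frames_per_particle = frames_per_particle,
         n_particles = n_particles,
         pixel_ratio = as.numeric(pixel_ratio),
         length_unit = length_unit, time_unit = time_unit,
         time_per_frame = as.numeric(time_per_frame)),
    class = "track_table_spec")
}

# Resolve a column identifier (spreadsheet letter or header name) to an
# index into `df`. Letters are positional: A = 1, B = 2, ..., Z = 26,
# AA = 27, ... A single letter that also happens to be a header name is
# resolved as a header name first.
resolve_column <- function(df, id) {
  if (is.numeric(id)) {
    idx <- as.integer(id)
    if (idx < 1L || idx > ncol(df))
      stop("column index ", idx, " out of range", call. = FALSE)
    return(idx)
  }
  id <- as.character(id)
  hit <- which(names(df) == id)
  if (length(hit) == 1L) return(hit)
  if (grepl("^[A-Za-z]{1,3}$", id)) {
    letters_idx <- utf8ToInt(toupper(id)) - utf8ToInt("A") + 1L
    idx <- sum(letters_idx * 26L^((length(letters_idx) - 1L):0L))
    if (idx >= 1L && idx <= ncol(df)) return(as.integer(idx))
  }
  stop("column '", id, "' not found (tried header names and ",
       "spreadsheet letters; table has ", ncol(df), " columns)",
       call. = FALSE)
}

# Read the raw data region of a track table. CSV/TSV (by extension, with a
# delimiter sniff fallback) or XLSX via readxl. First row is the header.
read_track_table <- function(path, sheet = NULL) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading spreadsheets requires the 'readxl' package",
           call. = FALSE)
    df <- readxl::read_excel(path, sheet = if (is.null(sheet)) 1 else sheet,
                             col_types = "text", .name_repair = "minimal")
    df <- as.data.frame(df, stringsAsFactors = FALSE)
  } else {
    sep <- if (ext == "tsv") "\t"
           else if (ext == "csv") ","
           else {
             first <- readLines(path, n = 1L)
             if (grepl("\t", first)) "\t" else ","
           }
    df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                            colClasses = "character", check.names = FALSE,
                            stringsAsFactors = FALSE, comment.char = "")
  }
  df
}

#' Read stacked particle tracks from a delimited or spreadsheet file
#'
#' Reads the table described by a [track_table_spec()], slices it into one
#' block of `frames_per_particle` rows per particle, validates the frame
#' numbering of every block, applies the pixel-to-length conversion and
#' returns one [trajectory()] per particle. Columns beyond those named in
#' the spec (e.g. a particle label column) are ignored and do not affect
#' the result.
#'
#' @param path a CSV, TSV or XLSX file whose first row is a header.
#' @param spec a [track_table_spec()].
#' @param sheet worksheet name or index for spreadsheet input (default:
#'   first sheet).
#' @return list of `n_particles` [trajectory()] objects; particle ids are
#'   `"particle_1"`, `"particle_2"`, ... in stacking order.
#'
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(frame = rep(1:3, 2), x = c(0, 1, 2, 5, 5, 5),
#'                      y = 0), f, row.names = FALSE)
#' spec <- track_table_spec(frame_column = "frame", x_column = "x",
#'                          y_column = "y", frames_per_particle = 3,
#'                          n_particles = 2, time_per_frame = 1)
#' read_tracks(f, spec)
#' @export
read_tracks <- function(path, spec, sheet = NULL) {
  stopifnot(inherits(spec, "track_table_spec"))
  df <- read_track_table(path, sheet = sheet)

  nf <- spec$frames_per_particle
  np <- spec$n_particles
  needed <- nf * np
  if (nrow(df) < needed)
    stop(sprintf(paste0("truncated table: %d data rows present but ",
                        "%d needed (%d particles x %d frames)"),
                 nrow(df), needed, np, nf), call. = FALSE)

  ci <- vapply(c(spec$frame_column, spec$x_column, spec$y_column,
                 spec$z_column),
               function(id) resolve_column(df, id), integer(1))
  dim <- length(ci) - 1L  # 2 or 3 coordinate columns

  as_num <- function(col_idx, what) {
    raw <- df[[col_idx]][seq_len(needed)]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.finite(v))
    if (length(bad) > 0L)
      stop(sprintf("non-numeric %s value '%s' at data row %d (file row %d)",
                   what, raw[bad[1L]], bad[1L], bad[1L] + 1L), call. = FALSE)
    v
  }
  frames <- as_num(ci[1L], "frame")
  coords <- vapply(seq_len(dim),
                   function(k) as_num(ci[1L + k], c("x", "y", "z")[k]),
                   numeric(needed))
  coords <- matrix(coords, needed, dim) * spec$pixel_ratio

  lapply(seq_len(np), function(k) {
    rows <- ((k - 1L) * nf + 1L):(k * nf)
    fr <- frames[rows]
    if (!isTRUE(all.equal(fr, as.numeric(seq_len(nf)))))
      stop(sprintf(paste0("particle %d: frame numbers are not 1..%d ",
                          "consecutive (data rows %d-%d)"),
                   k, nf, rows[1L], rows[length(rows)]), call. = FALSE)
    trajectory(coords[rows, , drop = FALSE],
               time_per_frame = spec$time_per_frame,
               particle_id = sprintf("particle_%d", k),
               length_unit = spec$length_unit,
               time_unit = spec$time_unit)
  })
}

#' Write per-particle reports, cohort block and MSD tables
#'
#' Writes `<stem>_particles.csv` -- one row per particle with the derived
#' statistics, followed by cohort rows (`cohort_mean` and `cohort_SD` or
#' `cohort_SEM` per the small/large cohort rule, plus per-statistic
#' effective n) -- and `<stem>_msd.csv` with the per-lag MSD of every
#' particle and the cohort-average curve. Missing statistics (e.g. the
#' moving speed of a particle that never moved) are written as empty
#' cells, not zeros.
#'
#' @param reports list of `"particle_report"` objects.
#' @param cohort the matching [cohort_summary()].
#' @param stem output path stem; directory must exist.
#' @return invisibly, the paths written.
#' @export
write_particle_reports <- function(reports, cohort, stem) {
  if (length(reports) == 0L)
    stop("at least one particle report is required", call. = FALSE)
  stopifnot(inherits(cohort, "cohort_summary"))

  per <- do.call(rbind, lapply(reports, function(r) {
    data.frame(record = as.character(r$particle_id),
               mean_moving_speed = r$mean_moving_speed,
               percent_time_in_motion = r$percent_time_in_motion,
               n_pauses = as.numeric(r$n_pauses),
               mean_pause_duration = if (r$n_pauses > 0)
                 mean(r$pause_durations) else NA_real_,
               persistence = r$persistence,
               diffusion_coefficient = r$diffusion_coefficient,
               stringsAsFactors = FALSE)
  }))
  s <- cohort$stats
  grab <- function(col) as.numeric(s[[col]][match(names(per)[-1L], s$statistic)])
  block <- data.frame(record = c("cohort_mean",
                                 paste0("cohort_", cohort$dispersion_kind),
                                 "cohort_n_used"),
                      stringsAsFactors = FALSE)
  stat_cols <- rbind(grab("mean"), grab("dispersion"), grab("n_used"))
  colnames(stat_cols) <- names(per)[-1L]
  block <- cbind(block, as.data.frame(stat_cols))
  tab <- rbind(per, block)

  p_particles <- paste0(stem, "_particles.csv")
  utils::write.csv(format_numeric(tab), p_particles, row.names = FALSE,
                   quote = FALSE, na = "")

  p_msd <- paste0(stem, "_msd.csv")
  msd_rows <- list()
  for (r in reports) {
    if (is.null(r$msd)) next
    msd_rows[[length(msd_rows) + 1L]] <-
      data.frame(record = as.character(r$particle_id),
                 lag_frames = r$msd$lag_frames, lag = r$msd$lag,
                 msd = r$msd$msd, n_increments = r$msd$n_increments,
                 stringsAsFactors = FALSE)
  }
  if (!is.null(cohort$mean_msd))
    msd_rows[[length(msd_rows) + 1L]] <-
      data.frame(record = "cohort_mean",
                 lag_frames = cohort$mean_msd$lag_frames,
                 lag = cohort$mean_msd$lag,
                 msd = cohort$mean_msd$msd,
                 n_increments = cohort$mean_msd$n_particles,
                 stringsAsFactors = FALSE)
  msd_tab <- if (length(msd_rows) > 0) do.call(rbind, msd_rows)
             else data.frame(record = character(0), lag_frames = numeric(0),
                             lag = numeric(0), msd = numeric(0),
                             n_increments = numeric(0))
  utils::write.csv(format_numeric(msd_tab), p_msd, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(c(particles = p_particles, msd = p_msd))
}

# full-precision numeric formatting so a write/read round trip preserves
# values to >= 10 significant digits
format_numeric <- function(df) {
  df[] <- lapply(df, function(col) {
    if (is.numeric(col)) {
      out <- vapply(col, function(v)
        if (is.na(v)) NA_character_ else format(v, digits = 15,
                                                scientific = FALSE),
        character(1))
      out
    } else col
  })
  df
}

#' Write the segment table of one or more particles
#'
#' One row per segment: particle id, start/end frame, net displacement,
#' elapsed time, speed, and state, grouped by particle in input order.
#' An empty mapping yields a header-only file.
#'
#' @param segments_by_particle named list mapping particle id to a segment
#'   table from [skypad_scan()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_segments <- function(segments_by_particle, path) {
  rows <- list()
  for (id in names(segments_by_particle)) {
    segs <- segments_by_particle[[id]]
    if (nrow(segs) == 0L) next
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(particle_id = id, stringsAsFactors = FALSE),
            as.data.frame(segs))
  }
  tab <- if (length(rows) > 0) do.call(rbind, rows)
         else data.frame(particle_id = character(0), start_frame = integer(0),
                         end_frame = integer(0), span_frames = integer(0),
                         net_displacement = numeric(0),
                         elapsed_time = numeric(0), speed = numeric(0),
                         state = character(0))
  utils::write.csv(format_numeric(tab), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Write trajectories in the stacked track-table layout
#'
#' Emits the same stacked layout [read_tracks()] consumes (frame, x, y,
#' optionally z, and a particle label column), so synthetic cohorts can be
#' round-tripped through the file interface for end-to-end tests.
#'
#' @param trajs list of [trajectory()] objects with equal frame counts.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_tracks <- function(trajs, path) {
  stopifnot(length(trajs) > 0,
            all(vapply(trajs, inherits, logical(1), "trajectory")))
  nfs <- vapply(trajs, n_frames, integer(1))
  if (length(unique(nfs)) != 1L)
    stop("all trajectories must have the same number of frames",
         call. = FALSE)
  dims <- vapply(trajs, function(t) t$dim, integer(1))
  if (length(unique(dims)) != 1L)
    stop("all trajectories must share dimensionality", call. = FALSE)
  rows <- lapply(trajs, function(t) {
    d <- data.frame(frame = seq_len(n_frames(t)),
                    x = t$positions[, 1L], y = t$positions[, 2L])
    if (t$dim == 3L) d$z <- t$positions[, 3L]
    d$particle <- as.character(t$particle_id)
    d
  })
  utils::write.csv(format_numeric(do.call(rbind, rows)), path,
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
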