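# Plain-text interchange: song annotation CSVs, behavior CSVs, and study
# manifests mapping session ids to their files.

#' Read / write song annotation CSVs
#'
#' Columns `start_s,end_s,mode` with mode in {sine, pulse}; ordering and
#' overlap are validated on read.
#'
#' @param path CSV file path.
#' @param duration session duration; default the last interval end.
#' @param session_id identifier; default the file name.
#' @return `read_song_csv`: a [song_annotation].
#' @export
read_song_csv <- function(path, duration = NULL, session_id = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("start_s", "end_s", "mode") %in% names(df)))
    stop("song CSV needs columns start_s,end_s,mode")
  if (is.null(session_id))
    session_id <- sub("\\.csv$", "", basename(path))
  if (is.null(duration))
    duration <- if (nrow(df) > 0) max(df$end_s) else 1
  song_annotation(data.frame(start = df$start_s, end = df$end_s,
                             mode = df$mode),
                  duration = duration, session_id = session_id)
}

#' @rdname read_song_csv
#' @param annotation a [song_annotation].
#' @export
write_song_csv <- function(annotation, path) {
  iv <- annotation$intervals
  write.csv(data.frame(start_s = iv$start, end_s = iv$end, mode = iv$mode),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write behavior CSVs
#'
#' Columns `t_s,walking_speed_mm_s` plus optional `forward_mm_s`,
#' `lateral_mm_s`.
#'
#' @param path CSV file path.
#' @return `read_behavior_csv`: a data.frame with internal column names
#'   `t`, `walking_speed` (and `forward`, `lateral` when present).
#' @export
read_behavior_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("t_s", "walking_speed_mm_s") %in% names(df)))
    stop("behavior CSV needs columns t_s,walking_speed_mm_s")
  out <- data.frame(t = df$t_s, walking_speed = df$walking_speed_mm_s)
  if ("forward_mm_s" %in% names(df)) out$forward <- df$forward_mm_s
  if ("lateral_mm_s" %in% names(df)) out$lateral <- df$lateral_mm_s
  out
}

#' @rdname read_behavior_csv
#' @param behavior behavior data.frame (internal column names).
#' @export
write_behavior_csv <- function(behavior, path) {
  out <- data.frame(t_s = behavior$t,
                    walking_speed_mm_s = behavior$walking_speed)
  if (!is.null(behavior$forward)) out$forward_mm_s <- behavior$forward
  if (!is.null(behavior$lateral)) out$lateral_mm_s <- behavior$lateral
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a study to disk / load it back
#'
#' Writes one song CSV and one behavior CSV per session plus a YAML
#' manifest mapping session ids to files and durations.
#'
#' @param sessions list of [nc_session].
#' @param dir output directory (created if needed).
#' @return `write_study`: the manifest path, invisibly.
#' @export
write_study <- function(sessions, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  entries <- lapply(sessions, function(s) {
    songf <- file.path(dir, paste0(s$session_id, "_song.csv"))
    behf <- file.path(dir, paste0(s$session_id, "_behavior.csv"))
    write_song_csv(s$song, songf)
    write_behavior_csv(s$behavior, behf)
    list(song = basename(songf), behavior = basename(behf),
         duration_s = s$song$duration)
  })
  names(entries) <- vapply(sessions, `[[`, character(1), "session_id")
  manifest <- file.path(dir, "sessions.yaml")
  if (requireNamespace("yaml", quietly = TRUE)) {
    yaml::write_yaml(entries, manifest)
  } else {
    lines <- unlist(lapply(names(entries), function(id) {
      e <- entries[[id]]
      c(paste0(id, ":"),
        paste0("  song: ", e$song),
        paste0("  behavior: ", e$behavior),
        paste0("  duration_s: ", format(e$duration_s)))
    }))
    writeLines(lines, manifest)
  }
  invisible(manifest)
}

#' @rdname write_study
#' @param manifest path to a `sessions.yaml` manifest.
#' @return `read_study`: a list of [nc_session].
#' @export
read_study <- function(manifest) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read manifests")
  entries <- yaml::read_yaml(manifest)
  dir <- dirname(manifest)
  lapply(names(entries), function(id) {
    e <- entries[[id]]
    song <- read_song_csv(file.path(dir, e$song), duration = e$duration_s,
                          session_id = id)
    nc_session(id, song, read_behavior_csv(file.path(dir, e$behavior)))
  })
}
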