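TRACK_CSV_HEADER <- "# sptmsd tracks v1; columns: track_id,frame,t_s,x_um,y_um[,model]; units: s, um"
LOC_CSV_HEADER <- "# sptmsd localizations v1; columns: frame,x_um,y_um,quality,intensity; units: um"

#' Write / read tracks as CSV
#'
#' Plain CSV with a versioned comment header naming columns and units.
#' Coordinates are written with 6 decimal digits (sub-nm; the stated
#' round-trip precision).
#'
#' @param tracks `spt_tracks` data.frame.
#' @param path file path.
#' @param frame_interval_s frame interval stored nowhere in the CSV; pass
#'   it to the reader (or rely on `t_s`).
#' @return `write_tracks_csv` returns `path` invisibly; `read_tracks_csv`
#'   returns an `spt_tracks` data.frame.
#' @export
write_tracks_csv <- function(tracks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(TRACK_CSV_HEADER, con)
  df <- as.data.frame(tracks)
  num <- intersect(c("t_s", "x_um", "y_um"), names(df))
  df[num] <- lapply(df[num], function(v) sprintf("%.6f", v))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path, frame_interval_s = NULL) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("track_id", "frame", "t_s", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop("track CSV must have columns ", paste(need, collapse = ", "))
  if (is.null(frame_interval_s) && nrow(df) > 1) {
    dts <- diff(df$t_s) / diff(df$frame)
    dts <- dts[is.finite(dts) & dts > 0]
    frame_interval_s <- if (length(dts)) stats::median(dts) else 1
  }
  structure(df, class = c("spt_tracks", "data.frame"),
            frame_interval = frame_interval_s)
}

#' Write / read localizations as CSV
#' @param locs `spt_localizations` data.frame.
#' @param path file path.
#' @param frame_interval_s,pixel_size_nm calibration attached on read.
#' @return the path (write) or an `spt_localizations` data.frame (read).
#' @export
write_locs_csv <- function(locs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(LOC_CSV_HEADER, con)
  df <- as.data.frame(locs)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_locs_csv
#' @export
read_locs_csv <- function(path, frame_interval_s = NULL,
                          pixel_size_nm = NULL) {
  df <- utils::read.csv(path, comment.char = "#")
  structure(df, class = c("spt_localizations", "data.frame"),
            frame_interval = frame_interval_s,
            pixel_size_nm = pixel_size_nm)
}

#' Write / read tracks in the simplified "Tracks" XML dialect
#'
#' The dialect consumed by common MSD analyzers: a root `Tracks` element
#' with `particle` children, each holding `detection` elements with `t`,
#' `x`, `y` (and `z`, written as 0) attributes.  Time semantics are carried
#' by the root: when a `frameInterval` attribute (seconds) is present, `t`
#' is a frame index and times are `t * frameInterval`; without it, `t` is
#' in seconds.  The writer emits frame indices plus `frameInterval` and
#' coordinates with 6 decimals; write followed by read is lossless at that
#' precision.
#'
#' @param tracks `spt_tracks` data.frame.
#' @param path file path.
#' @param frame_interval_s frame interval written to the root attribute;
#'   defaults to the tracks attribute.
#' @return `write_tracks_xml` returns `path` invisibly; `read_tracks_xml`
#'   an `spt_tracks` data.frame.
#' @export
write_tracks_xml <- function(tracks, path, frame_interval_s = NULL) {
  if (is.null(frame_interval_s))
    frame_interval_s <- attr(tracks, "frame_interval")
  if (is.null(frame_interval_s)) frame_interval_s <- 1
  doc <- xml2::xml_new_root("Tracks",
                            nTracks = length(unique(tracks$track_id)),
                            frameInterval = sprintf("%.9g", frame_interval_s),
                            spaceUnits = "um", timeUnits = "s")
  for (tr in split_tracks(tracks)) {
    p <- xml2::xml_add_child(doc, "particle",
                             nSpots = nrow(tr))
    for (r in seq_len(nrow(tr))) {
      xml2::xml_add_child(p, "detection",
                          t = sprintf("%d", as.integer(tr$frame[r])),
                          x = sprintf("%.6f", tr$x_um[r]),
                          y = sprintf("%.6f", tr$y_um[r]),
                          z = "0")
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname write_tracks_xml
#' @export
read_tracks_xml <- function(path) {
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "Tracks")
    stop("expected a root <Tracks> element, found <",
         xml2::xml_name(doc), ">")
  fi_attr <- xml2::xml_attr(doc, "frameInterval")
  frame_interval <- if (!is.na(fi_attr)) as.numeric(fi_attr) else NA_real_
  particles <- xml2::xml_find_all(doc, "./particle")
  if (length(particles) == 0)
    return(empty_tracks(if (is.na(frame_interval)) 1 else frame_interval))
  rows <- lapply(seq_along(particles), function(i) {
    det <- xml2::xml_find_all(particles[[i]], "./detection")
    if (length(det) == 0)
      stop("particle ", i, " has no detection elements")
    t <- suppressWarnings(as.numeric(xml2::xml_attr(det, "t")))
    x <- suppressWarnings(as.numeric(xml2::xml_attr(det, "x")))
    y <- suppressWarnings(as.numeric(xml2::xml_attr(det, "y")))
    if (anyNA(t) || anyNA(x) || anyNA(y))
      stop("particle ", i, ": detection missing or non-numeric t/x/y")
    if (!is.na(frame_interval)) {
      data.frame(track_id = i, frame = as.integer(round(t)),
                 t_s = t * frame_interval, x_um = x, y_um = y)
    } else {
      dt <- if (length(t) > 1) min(diff(sort(unique(t)))) else 1
      data.frame(track_id = i, frame = as.integer(round(t / dt)),
                 t_s = t, x_um = x, y_um = y)
    }
  })
  structure(do.call(rbind, rows),
            class = c("spt_tracks", "data.frame"),
            frame_interval = if (is.na(frame_interval)) NULL
                             else frame_interval)
}

#' Write / read a movie as multi-page 16-bit TIFF
#'
#' Physical calibration is not stored in the TIFF; it travels in a YAML/JSON
#' sidecar config (see [read_config()]) and must be supplied to the reader.
#'
#' @param movie `spt_movie`.
#' @param path TIFF path.
#' @param pixel_size_nm,frame_interval_s calibration for the reader.
#' @return `write_movie_tiff` returns `path` invisibly; `read_movie_tiff`
#'   an `spt_movie`.
#' @export
write_movie_tiff <- function(movie, path) {
  frames <- lapply(seq_len(dim(movie$frames)[1]), function(f) {
    m <- movie$frames[f, , ]
    m[m < 0] <- 0; m[m > 65535] <- 65535
    round(m) / 65535
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path, pixel_size_nm, frame_interval_s) {
  stopifnot(pixel_size_nm > 0, frame_interval_s > 0)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  arr <- array(0, dim = c(length(pages), ny, nx))
  for (f in seq_along(pages)) arr[f, , ] <- pages[[f]]
  structure(list(frames = arr, pixel_size_nm = pixel_size_nm,
                 frame_interval_s = frame_interval_s),
            class = "spt_movie")
}

#' Read a pipeline/simulation configuration (YAML or JSON)
#'
#' @param path file path ending in .yaml/.yml or .json.
#' @return a named list.
#' @export
read_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}
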