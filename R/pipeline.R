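#' Default pipeline configuration
#'
#' All tunable parameters of the detect -> link -> msd -> stats pipeline,
#' resolved deterministically and echoed verbatim into the run manifest.
#' Acquisition defaults match the targeted TIRF regime (65 nm pixels,
#' 58.8 Hz).
#'
#' @param ... named overrides of the defaults (nested lists are replaced
#'   field-wise).
#' @return nested named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    pixel_size_nm = 65,
    frame_interval_ms = 1000 / 58.8,
    rng_seed = 1L,
    detect = list(spot_diameter_um = 0.3, quality_threshold = "auto",
                  use_median_filter = TRUE),
    link = list(max_link_distance_um = 0.5, max_gap_distance_um = 0.8,
                max_frame_gap = 2L, min_spots = 10L),
    msd = list(fit_window_ms = 200, r2_gate = 0.8, d = 2L,
               band = c(0.9, 1.1), ensemble_weighting = "by_pairs")
  )
  ov <- list(...)
  for (nm in names(ov)) {
    if (is.list(ov[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(ov[[nm]])] <- ov[[nm]]
    else cfg[[nm]] <- ov[[nm]]
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Run the full tracking-and-MSD pipeline on a movie
#'
#' Executes detect -> link -> msd -> stats and writes all outputs plus a
#' manifest into `out_dir`: `locs.csv`, `tracks.csv`, `tracks.xml`,
#' `fits.csv`, `ensemble.csv`, `stats.json`, `manifest.json`.  Identical
#' config and inputs give identical outputs.  A movie with no detectable
#' spots yields empty tables and a stats summary stating `"no tracks"`,
#' not an error.
#'
#' @param config a [pipeline_config()] (or plain named list from
#'   [read_config()]).
#' @param movie either an `spt_movie` or a path to a multi-page TIFF.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results
#'   (`locs`, `tracks`, `fits`, `ensemble`, `stats`) and `out_dir`.
#' @export
run_pipeline <- function(config, movie, out_dir) {
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, as.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dt <- config$frame_interval_ms / 1000

  movie_path <- NULL
  if (is.character(movie)) {
    movie_path <- movie
    movie <- read_movie_tiff(movie, config$pixel_size_nm, dt)
  }

  stage <- "detect"
  res <- tryCatch({
    locs <- detect_spots(movie,
                         spot_diameter_um = config$detect$spot_diameter_um,
                         quality_threshold = config$detect$quality_threshold,
                         use_median_filter = config$detect$use_median_filter)
    write_locs_csv(locs, file.path(out_dir, "locs.csv"))

    stage <- "link"
    lcfg <- link_config(config$link$max_link_distance_um,
                        config$link$max_gap_distance_um,
                        config$link$max_frame_gap,
                        config$link$min_spots)
    tracks <- filter_tracks(link_frames(locs, lcfg, frame_interval_s = dt),
                            min_spots = lcfg$min_spots)
    write_tracks_csv(tracks, file.path(out_dir, "tracks.csv"))
    write_tracks_xml(tracks, file.path(out_dir, "tracks.xml"),
                     frame_interval_s = dt)

    stage <- "msd"
    n_tracks <- length(unique(tracks$track_id))
    if (n_tracks == 0) {
      fits <- data.frame()
      ens <- data.frame()
      stats_out <- list(note = "no tracks", n_tracks = 0)
    } else {
      fits <- fit_tracks(tracks,
                         fit_window_s = config$msd$fit_window_ms / 1000,
                         r2_gate = config$msd$r2_gate, d = config$msd$d,
                         band = config$msd$band)
      curves <- lapply(split_tracks(tracks), tamsd)
      ens <- ensemble_msd(curves,
                          weighting = config$msd$ensemble_weighting)
      stage <- "stats"
      fr <- tryCatch(class_fractions(fits), error = function(e) NULL)
      stats_out <- list(
        n_tracks = n_tracks,
        n_gate_passing = sum(fits$passed_gate, na.rm = TRUE),
        band = config$msd$band,
        class_fractions = fr,
        alpha = if (any(fits$passed_gate, na.rm = TRUE))
          box_stats(fits$alpha[fits$passed_gate]) else NULL,
        neg_log10_D = if (any(fits$passed_gate, na.rm = TRUE))
          box_stats(fits$neg_log10_D[fits$passed_gate]) else NULL)
    }
    utils::write.csv(fits, file.path(out_dir, "fits.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(ens), file.path(out_dir, "ensemble.csv"),
                     row.names = FALSE)
    jsonlite::write_json(stats_out, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "columns")
    list(locs = locs, tracks = tracks, fits = fits, ensemble = ens,
         stats = stats_out)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         " (partial outputs kept in ", out_dir, ")", call. = FALSE)
  })

  manifest <- list(
    package = "sptmsd",
    version = as.character(utils::packageVersion("sptmsd")),
    config = unclass(config),
    input = if (!is.null(movie_path))
      list(path = movie_path,
           md5 = unname(tools::md5sum(movie_path))) else "in-memory movie",
    n_localizations = nrow(res$locs),
    n_tracks = res$stats$n_tracks)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$out_dir <- out_dir
  invisible(res)
}
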