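#' Linking configuration
#'
#' Parameters of the two-stage LAP tracker.  The distance gates and the
#' minimum track length are mandatory inputs (results depend on them) and
#' are echoed into all output metadata.
#'
#' @param max_link_distance_um frame-to-frame gate (um).
#' @param max_gap_distance_um gap-closing gate (um).
#' @param max_frame_gap maximum number of missed frames bridged by gap
#'   closing (0 disables gap closing).
#' @param min_spots minimum localized points per track kept by
#'   [filter_tracks()].
#' @return list of class `link_config`.
#' @export
link_config <- function(max_link_distance_um = 0.5,
                        max_gap_distance_um = 0.8,
                        max_frame_gap = 2L,
                        min_spots = 10L) {
  if (!is.numeric(max_link_distance_um) || max_link_distance_um <= 0)
    stop("field 'max_link_distance_um' must be > 0")
  if (!is.numeric(max_gap_distance_um) || max_gap_distance_um <= 0)
    stop("field 'max_gap_distance_um' must be > 0")
  if (!is.numeric(max_frame_gap) || max_frame_gap < 0)
    stop("field 'max_frame_gap' must be >= 0")
  if (!is.numeric(min_spots) || min_spots < 2)
    stop("field 'min_spots' must be >= 2")
  structure(list(max_link_distance_um = max_link_distance_um,
                 max_gap_distance_um = max_gap_distance_um,
                 max_frame_gap = as.integer(max_frame_gap),
                 min_spots = as.integer(min_spots)),
            class = "link_config")
}

# Distance-gated min-cost assignment with rejection between two point sets.
# Minimizing sum of squared distances plus a cost gate^2 per unassigned
# point is equivalent to a maximum-weight bipartite matching with edge
# benefit gate^2 - d^2 (> 0 inside the gate).  Returns an integer vector:
# for each point in `a`, the index of its partner in `b`, or NA.
lap_match <- function(ax, ay, bx, by, gate, greedy = FALSE) {
  na <- length(ax); nb <- length(bx)
  if (na == 0 || nb == 0) return(rep(NA_integer_, na))
  d2 <- outer(ax, bx, "-")^2 + outer(ay, by, "-")^2
  ok <- which(d2 < gate^2, arr.ind = TRUE)
  if (nrow(ok) == 0) return(rep(NA_integer_, na))
  if (greedy) return(greedy_match(ok, d2, na))
  w <- gate^2 - d2[ok]
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, na), rep(TRUE, nb)),
    edges = as.vector(rbind(ok[, 1], na + ok[, 2])), directed = FALSE)
  m <- igraph::max_bipartite_match(g, weights = w,
                                   eps = max(w) * 1e-10)
  partner <- m$matching[seq_len(na)]
  out <- rep(NA_integer_, na)
  matched <- !is.na(partner)
  out[matched] <- as.integer(partner[matched]) - na
  out
}

# nearest-neighbour alternative, for sensitivity analysis
greedy_match <- function(ok, d2, na) {
  ord <- order(d2[ok])
  out <- rep(NA_integer_, na)
  used_b <- logical(max(ok[, 2]))
  for (r in ord) {
    i <- ok[r, 1]; j <- ok[r, 2]
    if (is.na(out[i]) && !used_b[j]) {
      out[i] <- j
      used_b[j] <- TRUE
    }
  }
  out
}

#' Link localizations into tracks (two-stage LAP)
#'
#' Stage 1 links detections between consecutive frames by globally optimal
#' distance-gated assignment (cost = squared distance; pairs beyond
#' `max_link_distance_um` are forbidden); unassigned detections open new
#' segments.  Stage 2 closes gaps: a segment end may join a segment start
#' when the frame difference is in `[2, max_frame_gap + 1]` and the
#' distance is at most `max_gap_distance_um`, again by a single global
#' assignment over all candidate end-start pairs.  Gap frames carry no
#' interpolated positions.  Every detection belongs to at most one track.
#'
#' @param locs `spt_localizations` data.frame (columns `frame`, `x_um`,
#'   `y_um`; must be sorted by frame) or any data.frame with those columns.
#' @param cfg a [link_config()].
#' @param frame_interval_s frame interval used to assign times; taken from
#'   the localization table attributes when present.
#' @param greedy use greedy nearest-neighbour matching instead of the
#'   optimal assignment (sensitivity analysis only).
#'
#' @return `spt_tracks` data.frame with columns `track_id`, `frame`, `t_s`,
#'   `x_um`, `y_um`, sorted by track then frame.  Tracks are *not* yet
#'   length-filtered; see [filter_tracks()].
#' @export
link_frames <- function(locs, cfg = link_config(),
                        frame_interval_s = NULL, greedy = FALSE) {
  if (!inherits(cfg, "link_config")) stop("cfg must be a link_config")
  if (is.null(frame_interval_s))
    frame_interval_s <- attr(locs, "frame_interval")
  if (is.null(frame_interval_s)) frame_interval_s <- 1
  if (nrow(locs) == 0)
    return(empty_tracks(frame_interval_s))
  if (is.unsorted(locs$frame)) stop("localizations must be sorted by frame")

  n <- nrow(locs)
  nxt <- rep(NA_integer_, n)        # successor row within a segment
  frames <- sort(unique(locs$frame))
  rows_of <- split(seq_len(n), locs$frame)

  # Stage 1: frame-to-frame assignment between consecutive frame pairs
  for (fi in seq_len(length(frames) - 1L)) {
    if (frames[fi + 1L] - frames[fi] != 1L) next
    a <- rows_of[[as.character(frames[fi])]]
    b <- rows_of[[as.character(frames[fi + 1L])]]
    mt <- lap_match(locs$x_um[a], locs$y_um[a],
                    locs$x_um[b], locs$y_um[b],
                    cfg$max_link_distance_um, greedy = greedy)
    nxt[a[!is.na(mt)]] <- b[mt[!is.na(mt)]]
  }

  segs <- collect_segments(nxt)

  # Stage 2: gap closing by one global assignment over end-start pairs
  if (cfg$max_frame_gap > 0 && length(segs) > 1) {
    ends <- vapply(segs, function(s) s[length(s)], integer(1))
    starts <- vapply(segs, function(s) s[1], integer(1))
    ef <- locs$frame[ends]; sf <- locs$frame[starts]
    # gate by frame difference first; distance gate handled by lap_match,
    # but frame-gap feasibility differs per pair, so build a pair list
    cand <- which(outer(sf, ef, "-") >= 2 &
                    outer(sf, ef, "-") <= cfg$max_frame_gap + 1L,
                  arr.ind = TRUE)  # rows: (start_seg, end_seg)
    if (nrow(cand) > 0) {
      d2 <- (locs$x_um[ends[cand[, 2]]] - locs$x_um[starts[cand[, 1]]])^2 +
            (locs$y_um[ends[cand[, 2]]] - locs$y_um[starts[cand[, 1]]])^2
      keep <- d2 < cfg$max_gap_distance_um^2
      cand <- cand[keep, , drop = FALSE]; d2 <- d2[keep]
      if (nrow(cand) > 0) {
        ns <- length(segs)
        w <- cfg$max_gap_distance_um^2 - d2
        g <- igraph::make_bipartite_graph(
          types = c(rep(FALSE, ns), rep(TRUE, ns)),
          edges = as.vector(rbind(cand[, 2], ns + cand[, 1])),
          directed = FALSE)
        m <- igraph::max_bipartite_match(g, weights = w,
                                         eps = max(w) * 1e-10)
        succ <- m$matching[seq_len(ns)] - ns  # for each end-seg, start-seg
        segs <- merge_segments(segs, succ)
      }
    }
  }

  # order tracks by (first frame, x, y) for determinism
  ord <- order(vapply(segs, function(s) locs$frame[s[1]], numeric(1)),
               vapply(segs, function(s) locs$x_um[s[1]], numeric(1)),
               vapply(segs, function(s) locs$y_um[s[1]], numeric(1)))
  segs <- segs[ord]
  rows <- unlist(segs)
  res <- data.frame(track_id = rep(seq_along(segs), lengths(segs)),
                    frame = locs$frame[rows],
                    t_s = locs$frame[rows] * frame_interval_s,
                    x_um = locs$x_um[rows],
                    y_um = locs$y_um[rows])
  structure(res, class = c("spt_tracks", "data.frame"),
            frame_interval = frame_interval_s, link_config = cfg)
}

empty_tracks <- function(frame_interval_s) {
  structure(data.frame(track_id = integer(), frame = integer(),
                       t_s = numeric(), x_um = numeric(), y_um = numeric()),
            class = c("spt_tracks", "data.frame"),
            frame_interval = frame_interval_s)
}

# walk successor pointers into maximal chains (each row has at most one
# predecessor by construction of the assignments)
collect_segments <- function(nxt) {
  n <- length(nxt)
  has_pred <- logical(n)
  has_pred[nxt[!is.na(nxt)]] <- TRUE
  heads <- which(!has_pred)
  lapply(heads, function(h) {
    out <- h
    while (!is.na(nxt[out[length(out)]]))
      out <- c(out, nxt[out[length(out)]])
    out
  })
}

# succ[e] = index of the segment whose start joins the end of segment e
merge_segments <- function(segs, succ) {
  ns <- length(segs)
  merged_into <- rep(NA_integer_, ns)
  for (e in seq_len(ns)) if (!is.na(succ[e])) merged_into[succ[e]] <- e
  roots <- which(is.na(merged_into))
  out <- vector("list", length(roots))
  for (k in seq_along(roots)) {
    cur <- roots[k]
    rows <- segs[[cur]]
    while (!is.na(succ[cur])) {
      cur <- succ[cur]
      rows <- c(rows, segs[[cur]])
    }
    out[[k]] <- rows
  }
  out
}

#' Filter tracks by number of localized points
#'
#' Keeps tracks with at least `min_spots` localized points (frames bridged
#' by gap closing do not count).  This is the "number of spots in track"
#' filter used to discard short, blink-dominated tracks.
#'
#' @param tracks `spt_tracks` data.frame.
#' @param min_spots minimum number of points (>= 2).
#' @return the filtered `spt_tracks`, original ids and order preserved.
#' @export
filter_tracks <- function(tracks, min_spots = 10L) {
  if (min_spots < 2) stop("min_spots must be >= 2")
  counts <- table(tracks$track_id)
  keep_ids <- names(counts)[counts >= min_spots]
  out <- tracks[as.character(tracks$track_id) %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  attrs <- attributes(tracks)
  structure(out, class = c("spt_tracks", "data.frame"),
            frame_interval = attrs$frame_interval,
            link_config = attrs$link_config)
}

#' Split an `spt_tracks` table into a list of per-track data.frames
#' @param tracks `spt_tracks` data.frame.
#' @return named list of data.frames, one per track id.
#' @export
split_tracks <- function(tracks) {
  split(as.data.frame(tracks)[c("frame", "t_s", "x_um", "y_um")],
        tracks$track_id)
}
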