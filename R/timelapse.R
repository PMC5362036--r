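#' @include measure.R
NULL

#' Dispersal episodes from a classified ratio trace
#'
#' A dispersal episode is a maximal run of at least \code{minRun}
#' consecutive cytosolic-classified frames (the debounce rule: a single
#' isolated cytosolic frame is treated as noise). Undefined ratios (NA)
#' break runs. Onset is the time of the first frame of the run counted
#' from the first supplied frame; duration is the run length times the
#' frame interval.
#'
#' @param ratios numeric vector of per-frame membrane/cytosol ratios (NA
#'   allowed for missing/unmeasurable frames).
#' @param threshold classification threshold.
#' @param frameIntervalMin minutes between consecutive frames.
#' @param minRun minimum consecutive cytosolic frames (default 2).
#' @return data.frame with columns onset_min, duration_min, first_frame,
#'   last_frame (frames 0-based); zero rows when no episode.
#' @examples
#' dispersalEpisodes(c(0.9, 0.9, 0.6, 0.65, 0.6, 0.9, 0.95),
#'                   frameIntervalMin = 3)  # onset 6, duration 9
#' @export
dispersalEpisodes <- function(ratios, threshold = 0.7,
                              frameIntervalMin = 3, minRun = 2L) {
  cyto <- !is.na(ratios) & classifyRatio(ratios, threshold) == "cytosolic"
  out <- data.frame(onset_min = numeric(), duration_min = numeric(),
                    first_frame = integer(), last_frame = integer())
  if (!any(cyto)) return(out)
  r <- rle(cyto)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= minRun
  if (!any(keep)) return(out)
  first <- starts[keep] - 1L  # 0-based frame indices
  last <- ends[keep] - 1L
  data.frame(onset_min = first * frameIntervalMin,
             duration_min = (last - first + 1L) * frameIntervalMin,
             first_frame = first, last_frame = last)
}

#' Quantify a time-lapse series and detect dispersal episodes
#'
#' Measures every cell in every frame (ids must match across frames;
#' tracking is supplied by the caller or by simulator ground truth) and
#' extracts per-cell dispersal episodes from the classified ratio traces.
#' A cell id missing from a frame leaves a gap that breaks episode runs
#' and is flagged in the measurement table.
#'
#' @param frames list of numeric matrices, one per frame, time-ordered.
#' @param outlineSets list of [OutlineSet-class], parallel to
#'   \code{frames}.
#' @param params a [CompartmentParams-class].
#' @param frameIntervalMin minutes between frames.
#' @param minRun debounce: minimum consecutive cytosolic frames per
#'   episode.
#' @return list(measurements = data.frame with frame column,
#'   episodes = data.frame with cell_id, onset_min, duration_min,
#'   first_frame, last_frame).
#' @export
measureTimeseries <- function(frames, outlineSets,
                              params = compartmentParams(),
                              frameIntervalMin = 3, minRun = 2L) {
  stopifnot(length(frames) == length(outlineSets))
  nF <- length(frames)
  meas <- vector("list", nF)
  for (k in seq_len(nF)) {
    df <- measureCells(frames[[k]], outlineSets[[k]], params)
    df$frame <- k - 1L
    meas[[k]] <- df
  }
  meas <- do.call(rbind, meas)
  ids <- unique(meas$cell_id)
  counts <- table(meas$cell_id)
  gapIds <- names(counts)[counts < nF]
  if (length(gapIds)) {
    sel <- meas$cell_id %in% gapIds
    meas$flags[sel] <- ifelse(nzchar(meas$flags[sel]),
                              paste0(meas$flags[sel], ";gap"), "gap")
  }
  eps <- lapply(ids, function(id) {
    sub <- meas[meas$cell_id == id, ]
    trace <- rep(NA_real_, nF)
    trace[sub$frame + 1L] <- sub$ratio
    ep <- dispersalEpisodes(trace, params@threshold, frameIntervalMin,
                            minRun)
    if (nrow(ep)) cbind(cell_id = id, ep) else NULL
  })
  eps <- do.call(rbind, eps)
  if (is.null(eps))
    eps <- data.frame(cell_id = character(), onset_min = numeric(),
                      duration_min = numeric(), first_frame = integer(),
                      last_frame = integer())
  list(measurements = meas, episodes = eps)
}
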