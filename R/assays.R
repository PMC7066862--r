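#' Relative RNA level from qRT-PCR threshold cycles (2^-ddCt)
#'
#' Difference-of-differences quantification against a reference transcript
#' (here, a spike-in plasmid gene such as *bla*) and a baseline condition:
#' \deqn{\Delta\Delta C_T = (C_{T,target} - C_{T,ref})_{time\,x}
#'   - (C_{T,target} - C_{T,ref})_{time\,0}}
#' and the relative level is `efficiency^-ddCt` (perfect doubling per
#' cycle, `efficiency = 2`, by default). Replicate Ct values may be passed
#' as vectors; they are arithmetic-mean-averaged before differencing. The
#' result is invariant to adding a constant to all four Ct values
#' (plate-offset invariance).
#'
#' @param ct_target_x,ct_ref_x threshold cycles for target and reference at
#'   the condition of interest.
#' @param ct_target_0,ct_ref_0 threshold cycles at the baseline (steady
#'   state).
#' @param efficiency amplification factor per cycle.
#' @return Relative RNA level (1 = unchanged from baseline).
#' @examples
#' ddct_ratio(22, 15, 20, 15)   # target two cycles later: level 0.25
#' @export
ddct_ratio <- function(ct_target_x, ct_ref_x, ct_target_0, ct_ref_0,
                       efficiency = 2) {
  cts <- c(ct_target_x, ct_ref_x, ct_target_0, ct_ref_0)
  if (any(!is.finite(cts)) || any(cts <= 0))
    stop("all Ct values must be finite and positive")
  if (!is.finite(efficiency) || efficiency <= 1)
    stop("efficiency must be > 1")
  ddct <- (mean(ct_target_x) - mean(ct_ref_x)) -
    (mean(ct_target_0) - mean(ct_ref_0))
  efficiency^(-ddct)
}

#' Northern-blot band quantification relative to the spike-in transcript
#'
#' Each target band's intensity is divided by the spike-in reference band
#' in the same lane (cancelling per-lane loading and exposure), and the
#' resulting ratio is expressed relative to the mean ratio over the
#' steady-state lanes.
#'
#' @param bands data.frame with columns `lane`, `band_id`, `intensity`
#'   (non-negative phosphor-imager units), one row per band per lane.
#' @param reference_band_id id of the spike-in reference band, present in
#'   every lane.
#' @param steady_lanes lane ids of the pre-starvation samples.
#' @return data.frame with `lane`, `band_id`, `ratio` (target/reference)
#'   and `relative` (ratio over steady mean), target bands only.
#' @export
northern_relative <- function(bands, reference_band_id, steady_lanes) {
  bands <- as.data.frame(bands, stringsAsFactors = FALSE)
  req <- c("lane", "band_id", "intensity")
  if (length(setdiff(req, names(bands))))
    stop("bands needs columns lane, band_id, intensity")
  if (any(bands$intensity < 0)) stop("negative band intensity")
  if (!length(steady_lanes)) stop("need at least one steady-state lane")
  lanes <- unique(bands$lane)
  if (length(setdiff(steady_lanes, lanes)))
    stop("steady lane absent from band table")
  ref <- bands[bands$band_id == reference_band_id, , drop = FALSE]
  if (length(setdiff(lanes, ref$lane)))
    stop("reference band missing in lane ",
         setdiff(lanes, ref$lane)[1])
  if (any(ref$intensity == 0))
    stop("zero reference intensity in lane ", ref$lane[ref$intensity == 0][1])
  ref_by_lane <- stats::setNames(ref$intensity, ref$lane)
  tgt <- bands[bands$band_id != reference_band_id, , drop = FALSE]
  tgt$ratio <- tgt$intensity / ref_by_lane[as.character(tgt$lane)]
  out <- do.call(rbind, lapply(split(tgt, tgt$band_id), function(d) {
    base <- mean(d$ratio[d$lane %in% steady_lanes])
    if (is.na(base) || base == 0)
      stop("no steady-state signal for band ", d$band_id[1])
    d$relative <- d$ratio / base
    d
  }))
  rownames(out) <- NULL
  out[, c("lane", "band_id", "ratio", "relative")]
}
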