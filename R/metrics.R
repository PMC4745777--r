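#' Wound (scratch) closure percentage
#'
#' `(Area_T1 - Area_T2) / Area_T1 * 100`, where T1 is the gap area at 0 h
#' and T2 at the assay endpoint, in any one consistent unit. Negative
#' values (the gap widened) are reported as-is, never clipped. If an
#' initial gap width is supplied it is checked against the usual 0.60-0.75
#' mm guidance with a warning outside that window.
#'
#' @param area_t1 Initial gap area (> 0).
#' @param area_t2 Endpoint gap area (>= 0).
#' @param gap_width_mm Optional initial wound-gap width (mm) for the
#'   guidance check.
#' @return Closure percentage in (-Inf, 100]; exactly 100 iff
#'   `area_t2 = 0`.
#' @examples
#' wound_closure_pct(0.70, 0.35)  # 50
#' @export
wound_closure_pct <- function(area_t1, area_t2, gap_width_mm = NULL) {
  stopifnot(length(area_t1) == length(area_t2))
  if (any(!is.finite(area_t1)) || any(area_t1 <= 0))
    stop("initial gap area must be finite and > 0", call. = FALSE)
  if (any(!is.finite(area_t2)) || any(area_t2 < 0))
    stop("endpoint gap area must be finite and >= 0", call. = FALSE)
  if (!is.null(gap_width_mm) &&
      any(gap_width_mm < 0.60 | gap_width_mm > 0.75))
    warning("initial wound gap outside the 0.60-0.75 mm guidance",
            call. = FALSE)
  (area_t1 - area_t2) / area_t1 * 100
}

#' Measurement relative to vehicle control
#'
#' The ratio treated/control used for percent invasion, relative
#' fluorescence intensity and relative colony formation (all expressed
#' relative to DMSO-treated cells). Transitive:
#' `relative_to_control(a, b) * relative_to_control(b, c) ==
#' relative_to_control(a, c)`.
#'
#' @param treated Non-negative measurement(s).
#' @param control Positive control measurement(s).
#' @return Unitless ratio(s).
#' @examples
#' relative_to_control(6, 100)  # 0.06
#' @export
relative_to_control <- function(treated, control) {
  if (any(!is.finite(control)) || any(control <= 0))
    stop("control measurement must be finite and > 0", call. = FALSE)
  if (any(!is.finite(treated)) || any(treated < 0))
    stop("treated measurement must be finite and >= 0", call. = FALSE)
  treated / control
}

#' Tumour volume by the modified ellipsoidal formula
#'
#' `volume = length * width^2 / 2` (mm^3 for mm inputs). By convention
#' length is the larger calliper dimension; swapped inputs are corrected
#' with a warning. Homogeneous of degree 3 under uniform scaling.
#'
#' @param length,width Calliper dimensions in mm (> 0).
#' @return Volume in mm^3.
#' @examples
#' tumor_volume(10, 5)  # 125
#' @export
tumor_volume <- function(length, width) {
  stopifnot(base::length(length) == base::length(width))
  if (any(!is.finite(length)) || any(!is.finite(width)) ||
      any(length <= 0) || any(width <= 0))
    stop("tumour dimensions must be finite and > 0", call. = FALSE)
  swap <- width > length
  if (any(swap)) {
    warning("width > length; dimensions swapped to enforce convention",
            call. = FALSE)
    tmp <- length[swap]; length[swap] <- width[swap]; width[swap] <- tmp
  }
  length * width^2 / 2
}

#' Tumour volume fold change relative to baseline
#'
#' `current / baseline`, the fold regulation relative to the initial
#' tumour volume. Which day supplies the baseline (implantation,
#' randomisation, treatment start) is the caller's choice; it is an
#' explicit input here.
#'
#' @param current Current volume (mm^3, >= 0).
#' @param baseline Baseline volume (mm^3, > 0).
#' @return Unitless fold change.
#' @examples
#' volume_fold_change(1480, 50)  # 29.6
#' @export
volume_fold_change <- function(current, baseline) {
  if (any(!is.finite(baseline)) || any(baseline <= 0))
    stop("baseline volume must be finite and > 0", call. = FALSE)
  if (any(!is.finite(current)) || any(current < 0))
    stop("current volume must be finite and >= 0", call. = FALSE)
  current / baseline
}

#' Percent positive cells
#'
#' `100 * positive / total`, the marker-positive fraction of counted cells
#' in an image (e.g. E-cadherin-positive cells in an IHC slide). Counting
#' and segmentation happen upstream; this consumes the resulting counts.
#'
#' @param positive Count of marker-positive cells (0 <= positive <=
#'   total).
#' @param total Total cell count (> 0).
#' @return Percentage in \[0, 100\].
#' @examples
#' percent_positive_cells(30, 100)  # 30
#' @export
percent_positive_cells <- function(positive, total) {
  stopifnot(length(positive) == length(total))
  if (any(!is.finite(total)) || any(total <= 0))
    stop("total count must be finite and > 0", call. = FALSE)
  if (any(!is.finite(positive)) || any(positive < 0) ||
      any(positive > total))
    stop("positive count must lie in [0, total]", call. = FALSE)
  100 * positive / total
}
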