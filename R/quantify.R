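# Hypertensive-retinopathy quantification: the vessel-density ratio
# R_vessel = N_v / (N_non - N_v), its longitudinal trend across
# visits, and signed post-segmentation change maps.
#
# The printed formula divides by N_non - N_v even though the prose
# describes a plain vessel/non-vessel ratio; the printed form is the
# default and the plain ratio is available behind `denominator`.

#' Vessel-density ratio of a segmented mask
#'
#' Counts vessel (`N_v`) and non-vessel (`N_non`) pixels, restricted to
#' the FOV when one is given, and reports
#' `R_vessel = N_v / (N_non - N_v)` (default) or the plain
#' `N_v / N_non` variant.
#'
#' @param mask binary vessel mask
#' @param fov optional binary field-of-view mask
#' @param denominator `"difference"` (the printed formula) or
#'   `"total"` (plain ratio)
#' @param visit_id,subject_id optional identifiers carried through
#' @return object of class `vn_quant_report`: list(n_vessel,
#'   n_nonvessel, r_vessel, visit_id, subject_id)
#' @export
vessel_ratio <- function(mask, fov = NULL, denominator = c("difference", "total"),
                         visit_id = NA_character_, subject_id = NA_character_) {
  denominator <- match.arg(denominator)
  v <- as.logical(mask)
  if (!is.null(fov)) {
    if (!all(dim(fov) == dim(mask))) input_error("FOV shape mismatch")
    v <- v[as.logical(fov)]
  }
  nv <- sum(v); nn <- sum(!v)
  den <- if (denominator == "difference") nn - nv else nn
  if (nv > 0 && den <= 0)
    stop(errorCondition(
      sprintf("R_vessel undefined: denominator %d - %d <= 0", nn, nv),
      class = c("vn_ratio_error", "error")))
  r <- if (nv == 0) 0 else nv / den
  structure(list(n_vessel = nv, n_nonvessel = nn, r_vessel = r,
                 denominator = denominator,
                 visit_id = visit_id, subject_id = subject_id),
            class = "vn_quant_report")
}

#' Longitudinal R_vessel trend
#'
#' For reports ordered by visit, returns the consecutive differences
#' `delta_k = r_k - r_(k-1)` with their signs; a negative delta is
#' consistent with vascular constriction (vessel loss), a positive one
#' with new vessel growth.
#'
#' @param reports list of [vessel_ratio()] reports in visit order
#' @return data.frame with from, to, delta, direction
#'   (`"decrease"`/`"increase"`/`"stable"`); zero rows for < 2 visits
#' @export
ratio_trend <- function(reports) {
  n <- length(reports)
  if (n < 2L)
    return(data.frame(from = character(0), to = character(0),
                      delta = numeric(0), direction = character(0)))
  r <- vapply(reports, function(x) x$r_vessel, 1)
  ids <- vapply(reports, function(x) x$visit_id, "")
  delta <- diff(r)
  data.frame(from = ids[-n], to = ids[-1], delta = delta,
             direction = ifelse(delta < 0, "decrease",
                                ifelse(delta > 0, "increase", "stable")))
}

#' Signed change map between two visits
#'
#' Subtracts successive segmentations: +1 where vessel appears in the
#' later mask, -1 where it disappears, 0 elsewhere.  Antisymmetric:
#' `change_map(a, b) == -change_map(b, a)`.
#'
#' @param mask_prev,mask_next binary masks of identical shape
#' @return integer matrix in \{-1, 0, 1\}
#' @export
change_map <- function(mask_prev, mask_next) {
  if (!all(dim(mask_prev) == dim(mask_next))) input_error("mask shape mismatch")
  matrix(as.integer(mask_next > 0) - as.integer(mask_prev > 0),
         nrow(mask_prev), ncol(mask_prev))
}
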