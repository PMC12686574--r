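#' Chitotriosidase activity from plate fluorescence
#'
#' Macrophage-activation readout from a 4-MU-chitotrioside plate assay:
#' activity in nM/h/mL computed as
#' `(T - B) / Std * (60 / incubation_time) * (1000 / volume)`,
#' where `T` is the test-sample fluorescence, `B` the blank and `Std` the
#' fluorescence of the standard. The time factor converts the incubation
#' (minutes) to hours and the volume factor the sample volume (microlitres)
#' to millilitres. A blank exceeding the test gives a negative activity,
#' which is kept (not clamped) and flagged with a warning.
#'
#' @param T_fluor Test-sample fluorescence (a.u.).
#' @param B_fluor Blank fluorescence (a.u.).
#' @param Std_fluor Standard fluorescence (a.u.), must be positive.
#' @param incubation_time Incubation time in minutes, must be positive.
#' @param volume Sample volume in microlitres, must be positive.
#' @return Activity in nM/h/mL; vectorised.
#' @examples
#' chitotriosidase_activity(500, 100, 200, incubation_time = 6, volume = 10)
#' @export
chitotriosidase_activity <- function(T_fluor, B_fluor, Std_fluor,
                                     incubation_time = 6, volume = 10) {
  if (any(Std_fluor <= 0)) stop("standard fluorescence must be positive")
  if (any(incubation_time <= 0)) stop("incubation time must be positive")
  if (any(volume <= 0)) stop("volume must be positive")
  act <- (T_fluor - B_fluor) / Std_fluor *
    (60 / incubation_time) * (1000 / volume)
  if (any(act < 0))
    warning("blank exceeds test fluorescence for ", sum(act < 0),
            " reading(s); negative activity reported")
  act
}

#' Fold change by the delta-delta-Ct method
#'
#' `2^-ddCt` with
#' `ddCt = (Cq_target_sample - Cq_housekeeper_sample) -
#'         (Cq_target_calibrator - Cq_housekeeper_calibrator)`.
#'
#' @param cq_target_sample,cq_housekeeper_sample Quantification cycles of the
#'   target and housekeeper gene in the sample.
#' @param cq_target_calibrator,cq_housekeeper_calibrator The same in the
#'   calibrator (e.g. the young wild-type group).
#' @return Fold change relative to the calibrator; vectorised.
#' @examples
#' ddct_fold_change(24, 20, 26, 20)  # 4-fold up
#' @export
ddct_fold_change <- function(cq_target_sample, cq_housekeeper_sample,
                             cq_target_calibrator, cq_housekeeper_calibrator) {
  cq <- c(cq_target_sample, cq_housekeeper_sample,
          cq_target_calibrator, cq_housekeeper_calibrator)
  if (any(!is.finite(cq))) stop("all Cq values must be finite")
  ddct <- (cq_target_sample - cq_housekeeper_sample) -
    (cq_target_calibrator - cq_housekeeper_calibrator)
  2^(-ddct)
}

#' Telomere / centromere FISH intensity ratio
#'
#' Relative telomere length per nucleus: mean telomere-probe intensity
#' divided by mean centromere-probe intensity.
#'
#' @param mean_telomere_intensity,mean_centromere_intensity Per-nucleus mean
#'   probe intensities; vectorised elementwise.
#' @return Intensity ratio per nucleus.
#' @export
telo_cent_ratio <- function(mean_telomere_intensity,
                            mean_centromere_intensity) {
  if (any(mean_centromere_intensity <= 0))
    stop("centromere intensity must be positive")
  mean_telomere_intensity / mean_centromere_intensity
}

#' Percentage of positive cells
#'
#' `100 * n_positive / n_total`, e.g. percent EdU-positive cells per field of
#' view.
#'
#' @param n_positive Number of positive cells (0 <= n_positive <= n_total).
#' @param n_total Total cells counted, must be positive.
#' @return Percentage in \[0, 100\]; vectorised.
#' @export
percent_positive <- function(n_positive, n_total) {
  if (any(n_total <= 0)) stop("n_total must be positive")
  if (any(n_positive < 0 | n_positive > n_total))
    stop("need 0 <= n_positive <= n_total")
  100 * n_positive / n_total
}

#' Compute chitotriosidase activity for a plate TSV
#'
#' Reads a table with columns `sample`, `T`, `B`, `Std`, `time_min`,
#' `volume_ul` and appends an `activity_nM_h_mL` column plus a `flag_negative`
#' indicator for blank-over-test readings.
#'
#' @param file Path to the plate TSV.
#' @return Data frame with the computed activity.
#' @export
read_plate_activity <- function(file) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("sample", "T", "B", "Std", "time_min", "volume_ul")
  if (!all(need %in% names(tab)))
    stop("plate file needs columns: ", paste(need, collapse = ", "))
  tab$activity_nM_h_mL <- suppressWarnings(
    chitotriosidase_activity(tab$T, tab$B, tab$Std,
                             incubation_time = tab$time_min,
                             volume = tab$volume_ul))
  tab$flag_negative <- tab$activity_nM_h_mL < 0
  tab
}
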