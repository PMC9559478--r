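#' Month-derived grazing label schemes
#'
#' In the study region nearly all herds graze from April to September,
#' with full grazing roughly May-August, so the calendar month of a milk
#' test can stand in for the (unrecorded) feeding regime. Three nested
#' schemes define the GRASS and NOGRASS month sets, each balanced (same
#' number of months per modality); all other months are OTHERS:
#' \itemize{
#'   \item scheme 1: GRASS = May-Aug, NOGRASS = Nov-Feb;
#'   \item scheme 2: GRASS = Jun-Aug, NOGRASS = Dec-Feb;
#'   \item scheme 3: GRASS = Jul-Aug, NOGRASS = Jan-Feb.
#' }
#' The sets nest: scheme 3 is a subset of scheme 2, itself of scheme 1.
#'
#' @param scheme_id integer 1, 2 or 3.
#' @return list with `scheme_id`, `grass_months`, `nograss_months`.
#' @examples
#' grass_scheme(2)
#' @export
grass_scheme <- function(scheme_id) {
  if (!scheme_id %in% 1:3) {
    stop("`scheme_id` must be 1, 2 or 3", call. = FALSE)
  }
  sets <- list(
    list(grass = c(5L, 6L, 7L, 8L), nograss = c(11L, 12L, 1L, 2L)),
    list(grass = c(6L, 7L, 8L),     nograss = c(12L, 1L, 2L)),
    list(grass = c(7L, 8L),         nograss = c(1L, 2L))
  )
  s <- sets[[scheme_id]]
  list(scheme_id = as.integer(scheme_id),
       grass_months = s$grass, nograss_months = s$nograss)
}

#' Assign the GRASS/NOGRASS/OTHERS modality from the test month
#'
#' @param month integer vector in 1..12.
#' @param scheme a scheme from [grass_scheme()], or a scheme id 1..3.
#' @return character vector in `c("GRASS", "NOGRASS", "OTHERS")`.
#' @examples
#' assign_grass_label(1:12, grass_scheme(1))
#' @export
assign_grass_label <- function(month, scheme) {
  if (is.numeric(scheme)) scheme <- grass_scheme(scheme)
  if (any(!month %in% 1:12)) {
    stop("`month` must be in 1..12", call. = FALSE)
  }
  out <- rep("OTHERS", length(month))
  out[month %in% scheme$grass_months] <- "GRASS"
  out[month %in% scheme$nograss_months] <- "NOGRASS"
  out
}

#' Label a trait table under one scheme
#'
#' Appends a `modality` column derived from the `month` column.
#'
#' @param records data.frame with a `month` column.
#' @param scheme a scheme from [grass_scheme()], or a scheme id 1..3.
#' @return `records` with an added `modality` column.
#' @export
label_records <- function(records, scheme) {
  if (!"month" %in% names(records)) {
    stop("records must have a `month` column", call. = FALSE)
  }
  records$modality <- assign_grass_label(records$month, scheme)
  records
}

#' Build the binary modeling subset from labeled records
#'
#' Drops OTHERS rows and attaches the binary target `y` (GRASS = 1, the
#' positive class; NOGRASS = 0). Original row order is preserved.
#'
#' @param records data.frame with a `modality` column (see
#'   [label_records()]).
#' @return data.frame of GRASS/NOGRASS rows with an added integer column
#'   `y`.
#' @export
build_modeling_subset <- function(records) {
  if (!"modality" %in% names(records)) {
    stop("records must carry a `modality` column; see label_records()",
         call. = FALSE)
  }
  keep <- records$modality != "OTHERS"
  out <- records[keep, , drop = FALSE]
  n_grass <- sum(out$modality == "GRASS")
  n_nograss <- sum(out$modality == "NOGRASS")
  if (n_grass == 0L || n_nograss == 0L) {
    stop("degenerate labels: need at least one GRASS and one NOGRASS record ",
         sprintf("(got %d GRASS, %d NOGRASS)", n_grass, n_nograss),
         call. = FALSE)
  }
  out$y <- as.integer(out$modality == "GRASS")
  out
}

#' Split records into calibration and validation sets by farm
#'
#' The partition is at the farm level: every record of a farm falls on the
#' same side, so validation farms are truly unseen. A fraction
#' `calibration_fraction` of farms (default 0.30, the study protocol) is
#' drawn at random into the calibration set.
#'
#' @param records data.frame with a `farm_id` column.
#' @param calibration_fraction proportion of farms calibrated, in (0, 1).
#' @param seed integer RNG seed.
#' @return list with elements `calibration` and `validation`
#'   (data.frames), plus `calibration_farms` and `validation_farms`.
#' @examples
#' d <- generate_dataset(10, 1, seed = 3)
#' sp <- split_by_farm(d, 0.3, seed = 3)
#' length(sp$calibration_farms)  # 3
#' @export
split_by_farm <- function(records, calibration_fraction = 0.30, seed = 1) {
  if (!"farm_id" %in% names(records)) {
    stop("records must have a `farm_id` column", call. = FALSE)
  }
  if (calibration_fraction <= 0 || calibration_fraction >= 1) {
    stop("`calibration_fraction` must be in (0, 1)", call. = FALSE)
  }
  farms <- sort(unique(records$farm_id))
  if (length(farms) < 2L) {
    stop("need at least 2 farms to split", call. = FALSE)
  }
  n_cal <- max(1L, round(calibration_fraction * length(farms)))
  if (n_cal >= length(farms)) n_cal <- length(farms) - 1L
  cal_farms <- with_seed(seed, sort(sample(farms, n_cal)))
  val_farms <- setdiff(farms, cal_farms)
  list(calibration = records[records$farm_id %in% cal_farms, , drop = FALSE],
       validation = records[records$farm_id %in% val_farms, , drop = FALSE],
       calibration_farms = cal_farms,
       validation_farms = val_farms)
}
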