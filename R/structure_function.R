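#' Blank-corrected, OD-normalized, autofluorescence-subtracted expression
#'
#' Gene expression readout of a culture: fluorescence and optical density are
#' first corrected by subtracting a media blank, fluorescence is normalized
#' by optical density (FL/OD), and the FL/OD of an autofluorescence-control
#' culture (antisense plasmid without the reporter) is subtracted.
#'
#' @param fl_raw,od_raw Raw fluorescence and OD600 of the culture.
#' @param blank_fl,blank_od Media blank values.
#' @param autofluor_flod FL/OD of the autofluorescence-control culture
#'   (already blank-corrected), default 0.
#' @return Corrected FL/OD (may be near 0 or slightly negative for dark
#'   cultures). Vectorized over measurements.
#' @examples
#' normalize_flod(1000, 0.25, blank_fl = 100, blank_od = 0.05,
#'                autofluor_flod = 500)
#' @export
normalize_flod <- function(fl_raw, od_raw, blank_fl, blank_od,
                           autofluor_flod = 0) {
  od <- od_raw - blank_od
  if (any(od <= 0)) {
    stop("corrected OD is non-positive: culture too dilute or blank mismatch")
  }
  (fl_raw - blank_fl) / od - autofluor_flod
}

#' Read a plate-reader table
#'
#' CSV with columns `sample`, `fl`, `od`, `role` where role is one of
#' `culture`, `blank`, `autofluor-control`.
#'
#' @param path CSV file.
#' @return Data.frame with those columns.
#' @export
read_plate_reader <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "fl", "od", "role")
  if (!all(need %in% names(df))) {
    stop("plate-reader table must have columns ", paste(need, collapse = ", "))
  }
  ok <- c("culture", "blank", "autofluor-control")
  if (!all(df$role %in% ok)) {
    stop("role must be one of ", paste(ok, collapse = ", "))
  }
  df
}

#' Corrected FL/OD for every culture of a plate-reader table
#'
#' Blank values are averaged over `blank` rows; the autofluorescence FL/OD is
#' the mean blank-corrected FL/OD over `autofluor-control` rows.
#'
#' @param plate Data.frame from [read_plate_reader()].
#' @return Data.frame with columns `sample` and `flod` for the culture rows.
#' @export
plate_flod <- function(plate) {
  blanks <- plate[plate$role == "blank", , drop = FALSE]
  if (!nrow(blanks)) stop("no blank rows in plate table")
  bfl <- mean(blanks$fl); bod <- mean(blanks$od)
  auto <- plate[plate$role == "autofluor-control", , drop = FALSE]
  auto_flod <- if (nrow(auto)) {
    mean(normalize_flod(auto$fl, auto$od, bfl, bod, autofluor_flod = 0))
  } else 0
  cultures <- plate[plate$role == "culture", , drop = FALSE]
  data.frame(sample = cultures$sample,
             flod = normalize_flod(cultures$fl, cultures$od, bfl, bod, auto_flod),
             stringsAsFactors = FALSE)
}

#' Expression fold change and percent repression
#'
#' Replicate corrected FL/OD values are averaged per state first, then the
#' ratio of means is taken (matching the convention of normalizing to the
#' control-state mean). `fold = mean(a)/mean(b)`; when state A is the
#' repressed state, `percent_repression = 100 * (1 - mean(a)/mean(b))`.
#'
#' @param flod_a,flod_b Replicate corrected FL/OD values for the two states.
#' @return List with `fold` and `percent_repression`.
#' @export
expression_fold_change <- function(flod_a, flod_b) {
  ma <- mean(flod_a); mb <- mean(flod_b)
  if (ma <= 0 || mb <= 0) stop("state means must be positive")
  list(fold = ma / mb, percent_repression = 100 * (1 - ma / mb))
}

#' Sliding-window scan for the dominant Shine-Dalgarno sequence
#'
#' Sums reactivities over every `window_length`-nucleotide window for the ON
#' and OFF states and locates the window with the largest ON-minus-OFF
#' difference: the ribosome-binding-site region whose exposure changes most
#' between functional states. Ties go to the smallest start index.
#'
#' @param rho_on,rho_off Equal-length reactivity vectors (1-based positions,
#'   position 1 = transcription start).
#' @param window_length Window size in nucleotides (default 6, the length of
#'   a Shine-Dalgarno motif).
#' @param missing How to treat missing (`NA`) values: `"zero"` (contribute 0
#'   to window sums, default) or `"skip"` (windows containing a missing value
#'   are excluded from the maximum).
#' @return Object of class `window_scan` with `window_length`, `sums_on`,
#'   `sums_off`, `diff`, `best_start` and `best_diff`.
#' @export
sd_window_scan <- function(rho_on, rho_off, window_length = 6L,
                           missing = c("zero", "skip")) {
  missing <- match.arg(missing)
  if (length(rho_on) != length(rho_off)) stop("profiles have unequal lengths")
  n <- length(rho_on)
  if (n < window_length) stop("profiles shorter than the window")
  wsum <- function(v) {
    has_na <- is.na(v)
    v0 <- ifelse(has_na, 0, v)
    cs <- cumsum(c(0, v0))
    s <- cs[(window_length + 1L):(n + 1L)] - cs[1:(n - window_length + 1L)]
    if (missing == "skip") {
      cna <- cumsum(c(0, has_na))
      bad <- (cna[(window_length + 1L):(n + 1L)] -
                cna[1:(n - window_length + 1L)]) > 0
      s[bad] <- NA_real_
    }
    s
  }
  sums_on <- wsum(rho_on)
  sums_off <- wsum(rho_off)
  d <- sums_on - sums_off
  if (all(is.na(d))) stop("all windows contain missing values")
  best <- which.max(d)  # first index attaining the max
  structure(list(window_length = as.integer(window_length),
                 sums_on = sums_on, sums_off = sums_off, diff = d,
                 best_start = as.integer(best), best_diff = d[best]),
            class = "window_scan")
}

#' Reactivity fold change over a window
#'
#' Ratio of summed reactivities, ON over OFF, across an inclusive 1-based
#' window (e.g. the ribosome binding site identified by [sd_window_scan()]).
#' Missing values contribute 0 to the sums.
#'
#' @param rho_on,rho_off Reactivity vectors.
#' @param window Inclusive 1-based `c(start, end)`.
#' @return The fold change `sum(on[window]) / sum(off[window])`.
#' @export
window_fold_change <- function(rho_on, rho_off, window) {
  window <- as.integer(window)
  if (length(window) != 2L || window[1L] > window[2L] || window[1L] < 1L ||
      window[2L] > min(length(rho_on), length(rho_off))) {
    stop("window out of range")
  }
  idx <- window[1L]:window[2L]
  s_off <- sum(rho_off[idx], na.rm = TRUE)
  if (s_off <= 0) {
    stop("OFF-state window sum is zero; report absolute window sums instead")
  }
  sum(rho_on[idx], na.rm = TRUE) / s_off
}

#' Structure-function report
#'
#' Combines the window scan, the window reactivity fold change and the
#' expression fold change into one report, written as TSV (per-window sums)
#' plus JSON (summary).
#'
#' @param rho_on,rho_off Reactivity vectors for the two functional states.
#' @param flod_on,flod_off Replicate corrected FL/OD values.
#' @param window_length Window size for the scan.
#' @param path Optional output stem; writes `<path>.tsv` and `<path>.json`.
#' @return List with `scan`, `window`, `window_fold_change`,
#'   `expression_fold_change`, `percent_repression`.
#' @export
structure_function_report <- function(rho_on, rho_off, flod_on, flod_off,
                                      window_length = 6L, path = NULL) {
  scan <- sd_window_scan(rho_on, rho_off, window_length)
  window <- c(scan$best_start, scan$best_start + scan$window_length - 1L)
  wfc <- window_fold_change(rho_on, rho_off, window)
  efc <- expression_fold_change(flod_on, flod_off)
  out <- list(scan = scan, window = window, window_fold_change = wfc,
              expression_fold_change = efc$fold,
              percent_repression = efc$percent_repression)
  if (!is.null(path)) {
    tsv <- data.frame(start = seq_along(scan$sums_on),
                      sum_on = scan$sums_on, sum_off = scan$sums_off,
                      diff = scan$diff)
    utils::write.table(tsv, paste0(path, ".tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(best_window = window, window_fold_change = wfc,
           expression_fold_change = efc$fold,
           percent_repression = efc$percent_repression),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  out
}
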