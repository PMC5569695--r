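# Reduction of element strain time-histories to the cumulative strain damage
# measure (CSDM) and maximum principal strain (MPS).
#
# Inputs are per-element first-principal-strain series as exported by a
# finite-element head model; no strain-tensor computation happens here.
# CSDM uses the running maximum of each element's strain, so it is
# nondecreasing over the impact window; reference (undeformed) element
# volumes are used for the volume weighting.

#' Construct an element strain history
#'
#' @param time Uniform time base (s).
#' @param strain Numeric matrix, `length(time)` rows by one column per
#'   element, of first principal strain (dimensionless, `>= -1`).
#' @param volumes Strictly positive element volumes (mm^3).
#' @param regions Character region label per element.
#' @return Object of class `strain_history`.
#' @export
strain_history <- function(time, strain, volumes, regions) {
  strain <- as.matrix(strain)
  if (nrow(strain) != length(time)) stop("strain series not aligned with time base")
  if (ncol(strain) < 1L) stop("strain history must contain at least one element")
  if (length(volumes) != ncol(strain)) stop("one volume per element required")
  if (any(volumes <= 0)) stop("element volumes must be strictly positive")
  if (any(strain < -1)) stop("strains below -1 are not physical")
  if (length(regions) != ncol(strain)) stop("one region label per element required")
  check_uniform_time(time, "strain time base")
  colnames(strain) <- paste0("e", seq_len(ncol(strain)))
  structure(list(time = time, strain = strain, volumes = as.numeric(volumes),
                 regions = as.character(regions)),
            class = "strain_history")
}

#' Cumulative strain damage measure
#'
#' Volume fraction of the modelled brain whose running-maximum first
#' principal strain reaches or exceeds the threshold (default 15%) by the
#' end of the window. Comparison is `>=` ("reaches or exceeds").
#'
#' @param history A `strain_history`.
#' @param threshold Strain threshold (`>= 0`), default 0.15.
#' @return Fraction in `[0, 1]`.
#' @export
csdm <- function(history, threshold = 0.15) {
  if (threshold < 0) stop("threshold must be nonnegative")
  if (ncol(history$strain) == 0L) stop("empty element set")
  peaks <- apply(history$strain, 2, max)
  sum(history$volumes[peaks >= threshold]) / sum(history$volumes)
}

#' CSDM running series over time
#'
#' @param history A `strain_history`.
#' @param threshold Strain threshold, default 0.15.
#' @return Numeric series of the measure at each sample (nondecreasing).
#' @export
csdm_series <- function(history, threshold = 0.15) {
  if (threshold < 0) stop("threshold must be nonnegative")
  run <- apply(history$strain, 2, cummax)
  tot <- sum(history$volumes)
  as.numeric((run >= threshold) %*% history$volumes) / tot
}

#' Maximum principal strain and its location
#'
#' Global maximum over all elements and all times. Ties are broken by the
#' earliest time at which the maximum is attained, then by the lowest
#' element id.
#'
#' @param history A `strain_history`.
#' @return List with `value`, `element` (integer id), `region`, `time`.
#' @export
mps <- function(history) {
  if (ncol(history$strain) == 0L) stop("empty element set")
  m <- max(history$strain)
  hitlist <- which(history$strain == m, arr.ind = TRUE)
  first <- hitlist[order(hitlist[, "row"], hitlist[, "col"]), , drop = FALSE][1, ]
  list(value = m, element = unname(first["col"]),
       region = history$regions[first["col"]],
       time = history$time[first["row"]])
}

#' Running maximum-strain series over time
#'
#' @param history A `strain_history`.
#' @return Numeric nondecreasing series of the global running maximum.
#' @export
mps_series <- function(history) {
  cummax(apply(history$strain, 1, max))
}

#' Plateau (stable-maximum) check over an analysis window
#'
#' The strain reductions are computed over an 80 ms window chosen so both
#' measures reach a stable maximum. A measure series passes iff its value at
#' the window end equals its values over the final 10% of the window within
#' `1e-9`.
#'
#' @param series Measure series (e.g. from [csdm_series()] or
#'   [mps_series()]).
#' @param time Time base of the series (s).
#' @param window Window length (s), default 0.08.
#' @return Logical.
#' @export
stable_max_check <- function(series, time, window = 0.08) {
  if (length(series) != length(time)) stop("series and time base differ in length")
  span <- time[length(time)] - time[1]
  if (window > span + 1e-12) stop("window longer than the available series")
  t_end <- time[1] + window
  idx_end <- which.min(abs(time - t_end))
  tail_idx <- which(time >= time[1] + 0.9 * window & time <= t_end + 1e-12)
  all(abs(series[tail_idx] - series[idx_end]) <= 1e-9)
}

#' Reduce a strain history to its scalar strain measures
#'
#' @param history A `strain_history`.
#' @param threshold CSDM strain threshold, default 0.15.
#' @param window Stable-maximum window (s), default 0.08; skipped (with
#'   `NA`) when the series is shorter than the window.
#' @return One-row data frame: `csdm15`, `mps`, `mps_element`, `mps_region`,
#'   `stable_max`.
#' @export
reduce_strain <- function(history, threshold = 0.15, window = 0.08) {
  m <- mps(history)
  span <- history$time[length(history$time)] - history$time[1]
  stable <- if (span + 1e-12 >= window) {
    stable_max_check(csdm_series(history, threshold), history$time, window) &&
      stable_max_check(mps_series(history), history$time, window)
  } else NA
  data.frame(csdm15 = csdm(history, threshold), mps = m$value,
             mps_element = m$element, mps_region = m$region,
             stable_max = stable, stringsAsFactors = FALSE)
}

#' Per-location percentages of peak-strain locations by region
#'
#' @param measures Data frame with one row per impact carrying `location`
#'   and `mps_region` columns.
#' @param locations Location groups to tabulate.
#' @return Data frame with `location`, `region`, `percent`; percentages sum
#'   to 100 within each location. Locations with no records are omitted
#'   with a warning; missing labels raise an error listing the offending
#'   rows.
#' @export
region_summary <- function(measures,
                           locations = c("front", "back", "side")) {
  bad <- which(is.na(measures$location) | is.na(measures$mps_region))
  if (length(bad)) {
    stop("missing location/region labels in records: ",
         paste(bad, collapse = ", "))
  }
  out <- list()
  for (loc in locations) {
    sub <- measures[measures$location == loc, , drop = FALSE]
    if (nrow(sub) == 0L) {
      warning("no records for location '", loc, "'; omitted")
      next
    }
    tab <- table(sub$mps_region)
    out[[loc]] <- data.frame(location = loc, region = names(tab),
                             percent = 100 * as.numeric(tab) / nrow(sub),
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a strain history to CSV (with element sidecar)
#'
#' @param history A `strain_history`.
#' @param path Output CSV path (`t,e1..eN`).
#' @param sidecar Element sidecar CSV path (`element,volume,region`).
#' @return `path`, invisibly.
#' @export
write_strain_history_csv <- function(history, path,
                                     sidecar = sub("\\.csv$", "_elements.csv", path)) {
  utils::write.csv(data.frame(t = history$time, history$strain), path,
                   row.names = FALSE)
  utils::write.csv(data.frame(element = colnames(history$strain),
                              volume = history$volumes,
                              region = history$regions),
                   sidecar, row.names = FALSE)
  invisible(path)
}

#' Read a strain history from CSV
#'
#' @param path CSV path with header `t,e1..eN`.
#' @param sidecar Element sidecar CSV path (`element,volume,region`).
#' @return A `strain_history`.
#' @export
read_strain_history_csv <- function(path,
                                    sidecar = sub("\\.csv$", "_elements.csv", path)) {
  df <- utils::read.csv(path)
  side <- utils::read.csv(sidecar, stringsAsFactors = FALSE)
  strain_history(time = df$t, strain = as.matrix(df[, -1, drop = FALSE]),
                 volumes = side$volume, regions = side$region)
}
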