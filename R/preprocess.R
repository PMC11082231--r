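#' Default segment-to-region map
#'
#' Each view's speckle-tracking points are grouped into three functional
#' wall regions by contiguous, near-equal thirds: short axis 1-16
#' (anterior septal), 17-32 (inferior septal), 33-48 (lateral); apical
#' four chamber 1-16 (interventricular septum), 17-33 (apex), 34-49
#' (lateral). The map can be overridden with explicit index lists, which
#' must still partition the view's full range.
#'
#' @param view `"A4C"` or `"SAX_MID"`.
#' @param region_map Optional named list `region -> integer vector`
#'   overriding the default for this view.
#' @return Named list of integer vectors, one per region, in canonical
#'   region order.
#' @export
#' @examples
#' lengths(default_region_map("A4C"))  # 16, 17, 16
default_region_map <- function(view, region_map = NULL) {
  view <- match.arg(view, .VIEWS)
  regions <- .VIEW_REGIONS[[view]]
  if (is.null(region_map)) {
    region_map <- if (view == "A4C") {
      list(sept = 1:16, apex = 17:33, lat = 34:49)
    } else {
      list(ant_sept = 1:16, inf_sept = 17:32, lat = 33:48)
    }
  }
  .assert(setequal(names(region_map), regions),
          sprintf("region map for %s must name regions %s", view,
                  paste(regions, collapse = ", ")))
  region_map <- region_map[regions]
  all_idx <- sort(unlist(region_map, use.names = FALSE))
  .assert(!anyDuplicated(all_idx),
          "region map regions overlap: each segment must belong to exactly one region")
  .assert(identical(as.integer(all_idx), seq_len(.VIEW_NSEG[[view]])),
          sprintf("region map must partition 1..%d for view %s",
                  .VIEW_NSEG[[view]], view))
  lapply(region_map, as.integer)
}

#' Segment indices of one region
#' @inheritParams default_region_map
#' @param region Region name within the view.
#' @return Integer vector of segment indices.
#' @export
region_segments <- function(view, region, region_map = NULL) {
  rm <- default_region_map(view, region_map)
  .assert(region %in% names(rm), sprintf("unknown region %s for view %s", region, view))
  rm[[region]]
}

#' Region of each segment index
#' @inheritParams default_region_map
#' @param segments Integer vector of segment indices.
#' @return Character vector of region names.
#' @export
segment_region <- function(view, segments, region_map = NULL) {
  rm <- default_region_map(view, region_map)
  lut <- character(.VIEW_NSEG[[view]])
  for (r in names(rm)) lut[rm[[r]]] <- r
  lut[segments]
}

#' Resample one trace onto a uniform cycle grid by cubic spline
#'
#' Standardizes a trace to `T` uniformly spaced cycle fractions on
#' `[0, 1]` with an interpolating cubic spline through its finite samples.
#' Non-finite samples are dropped before fitting (spline repair); fewer
#' than 4 finite samples is an error. Natural boundary conditions are the
#' default; `bc = "fmm"` selects R's exact-for-cubics end conditions.
#'
#' @param trace A [strain_trace], or a list with `times` and `values`.
#' @param T Number of grid points (>= 5), default 100.
#' @param bc Spline boundary condition, `"natural"` (default) or `"fmm"`.
#' @return Numeric vector of `T` values on `seq(0, 1, length.out = T)`.
#' @export
resample_cycle <- function(trace, T = 100L, bc = c("natural", "fmm")) {
  bc <- match.arg(bc)
  .assert(T >= 5L, "resampling grid needs T >= 5")
  tt <- trace$times; vv <- trace$values
  fin <- is.finite(vv) & is.finite(tt)
  .assert(sum(fin) >= 4L,
          "unresamplable series: fewer than 4 finite samples")
  tt <- tt[fin]; vv <- vv[fin]
  ord <- order(tt)
  grid <- seq(0, 1, length.out = T)
  stats::spline(tt[ord], vv[ord], xout = grid, method = bc, ties = "ordered")$y
}

#' Pointwise mean of resampled series
#'
#' Averages the resampled curves of all segments in one (region, measure)
#' group into the regional mean strain curve.
#'
#' @param series A list of equal-length numeric vectors, or a matrix with
#'   one series per row.
#' @return Numeric vector, the element-wise arithmetic mean.
#' @export
mean_regional_curve <- function(series) {
  if (is.list(series)) {
    .assert(length(series) > 0L, "missing region: no series to average")
    .assert(length(unique(lengths(series))) == 1L,
            "series must share the same grid length")
    series <- do.call(rbind, series)
  }
  .assert(!is.null(dim(series)) && nrow(series) > 0L,
          "missing region: no series to average")
  .assert(all(is.finite(series)), "regional series contain non-finite values")
  colMeans(series)
}

#' Takens delay embedding of a curve
#'
#' Maps a scalar series to `d`-dimensional phase-space points
#' `(x[i], x[i + tau], ..., x[i + (d-1) tau])`, one point per valid start
#' index, in start-index order.
#'
#' @param values Numeric vector of length `T`.
#' @param d Embedding dimension (default 3).
#' @param tau Delay in samples (default 2).
#' @return A `T - (d-1) * tau` by `d` numeric matrix (the point cloud).
#' @export
#' @examples
#' delay_embed(1:7)  # three points: (1,3,5), (2,4,6), (3,5,7)
delay_embed <- function(values, d = 3L, tau = 2L) {
  d <- as.integer(d); tau <- as.integer(tau)
  .assert(d >= 2L && tau >= 1L, "need d >= 2 and tau >= 1")
  n <- length(values) - (d - 1L) * tau
  .assert(n >= 1L, sprintf(
    "series too short to embed: length %d with d=%d, tau=%d", length(values), d, tau))
  .assert(all(is.finite(values)), "cannot embed non-finite values")
  out <- vapply(seq_len(d) - 1L,
                function(j) values[seq_len(n) + j * tau], numeric(n))
  if (n == 1L) out <- matrix(out, nrow = 1L)
  out
}

#' Regional mean curves for every patient and (measure, region)
#'
#' The per-patient preprocessing stage: each segmental trace is spline
#' resampled to the uniform cycle grid (per segment, before averaging),
#' then segments of each wall region are averaged into the regional mean
#' curve.
#'
#' @param cohort A [strain_cohort].
#' @param T Resampling grid size (default 100).
#' @param region_map Optional list `view -> region map` override.
#' @param bc Spline boundary condition passed to [resample_cycle].
#' @return A `data.table` with columns `patient_id, measure, region, row_label`
#'   and a list-column `curve` of length-`T` numeric vectors, rows ordered
#'   patient-major then canonical row order.
#' @export
regional_curves <- function(cohort, T = 100L, region_map = NULL, bc = "natural") {
  dat <- cohort$data
  rmap <- lapply(setNames(.VIEWS, .VIEWS), function(v)
    default_region_map(v, region_map[[v]]))
  reg <- character(nrow(dat))
  for (v in .VIEWS) {
    ix <- dat$view == v
    reg[ix] <- segment_region(v, dat$segment[ix], region_map[[v]])
  }
  dat <- data.table::copy(dat)
  data.table::set(dat, j = "region", value = reg)
  # resample each series, then average within (patient, measure, region)
  res <- dat[, {
    per_seg <- lapply(split(seq_len(.N), segment), function(ix) {
      resample_cycle(list(times = time[ix], values = value[ix]), T = T, bc = bc)
    })
    list(curve = list(mean_regional_curve(per_seg)))
  }, by = c("patient_id", "measure", "region")]
  data.table::set(res, j = "row_label", value = paste(res$measure, res$region, sep = "_"))
  lv <- canonical_row_labels()
  res <- res[order(match(res$patient_id, names(cohort$labels)), match(res$row_label, lv))]
  res
}
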