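#' A single segmental strain trace
#'
#' One myocardial point's strain or strain-rate time course over one
#' cardiac cycle. Times are cycle fractions in `[0, 1]` (inputs in ms are
#' rescaled by the parser, taking the last sample as the cycle length).
#'
#' @param patient_id Opaque patient identifier.
#' @param view `"A4C"` (49 points) or `"SAX_MID"` (48 points).
#' @param segment Integer segment index within the view's range.
#' @param measure One of `"LS"`, `"LSR"` (A4C) or `"CS"`, `"CSR"`, `"RS"`,
#'   `"RSR"` (SAX_MID). Strain in %, strain rate in 1/s.
#' @param times Strictly increasing cycle fractions in `[0, 1]`.
#' @param values Numeric vector, same length as `times`. Non-finite
#'   entries are tolerated here and handled by the completeness filter /
#'   spline repair downstream.
#' @return An object of class `strain_trace`.
#' @export
strain_trace <- function(patient_id, view, segment, measure, times, values) {
  view <- match.arg(view, .VIEWS)
  measure <- match.arg(measure, .MEASURES)
  segment <- as.integer(segment)
  .assert(.MEASURE_VIEW[[measure]] == view,
          sprintf("measure %s is not acquired in view %s", measure, view))
  .assert(segment >= 1L && segment <= .VIEW_NSEG[[view]],
          sprintf("segment out of range: %d for view %s", segment, view))
  .assert(length(times) == length(values), "times/values length mismatch")
  .assert(length(times) >= 4L, "a strain trace needs at least 4 samples")
  .assert(all(is.finite(times)) && all(diff(times) > 0),
          "times must be finite and strictly increasing")
  .assert(min(times) >= 0 && max(times) <= 1,
          "times must be cycle fractions in [0, 1]")
  structure(
    list(patient_id = as.character(patient_id), view = view,
         segment = segment, measure = measure,
         times = as.numeric(times), values = as.numeric(values)),
    class = "strain_trace"
  )
}

#' @export
print.strain_trace <- function(x, ...) {
  cat(sprintf("<strain_trace> %s %s seg %d %s: %d samples\n",
              x$patient_id, x$view, x$segment, x$measure, length(x$times)))
  invisible(x)
}

.detect_sep <- function(header_line) {
  if (grepl("\t", header_line, fixed = TRUE)) "\t" else ","
}

.REQUIRED_COLS <- c("patient_id", "view", "segment", "measure", "time", "value")

#' Parse a long-format segmental strain table
#'
#' Reads the package's delimited dialect: TSV or CSV (auto-detected from
#' the header line) with columns `patient_id, view, segment, measure,
#' time, value`; one row per sample. One file may mix views. Times may be
#' in ms or cycle fraction; a series whose maximum time exceeds 1.5 is
#' taken to be in ms and rescaled so its last sample is cycle fraction 1.
#'
#' @param input Path to a file, or the table text itself (a single string
#'   containing newlines, or a character vector of lines).
#' @param view Optional view to assume when the table has no `view`
#'   column, and to validate against when it does.
#' @return A list of [strain_trace] objects, one per (patient, view,
#'   segment, measure) series present, ordered by those keys.
#' @export
parse_strain_table <- function(input, view = NULL) {
  lines <- if (length(input) == 1L && (file.exists(input) || grepl("\n", input))) {
    if (file.exists(input)) readLines(input, warn = FALSE)
    else strsplit(input, "\n", fixed = TRUE)[[1]]
  } else as.character(input)
  lines <- lines[nzchar(trimws(lines))]
  .assert(length(lines) >= 1L, "strain table has no header line")
  sep <- .detect_sep(lines[[1]])
  fields <- strsplit(lines, sep, fixed = TRUE)
  header <- trimws(fields[[1]])
  have_view <- "view" %in% header
  need <- setdiff(.REQUIRED_COLS, if (have_view) character() else "view")
  miss <- setdiff(need, header)
  .assert(length(miss) == 0L,
          "strain table header is missing column(s): ", paste(miss, collapse = ", "))
  nf <- lengths(fields)
  ragged <- which(nf != length(header))
  .assert(length(ragged) == 0L,
          sprintf("parse error at row %d: %d field(s), expected %d",
                  ragged[1], nf[ragged[1]], length(header)))
  if (length(fields) == 1L) {
    warning("strain table has an empty body; returning no traces")
    return(list())
  }
  body <- fields[-1]
  tab <- as.data.table(do.call(rbind, body))
  data.table::setnames(tab, header)
  row_no <- seq_len(nrow(tab)) + 1L  # file row numbers (header = 1)

  num <- function(col) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !toupper(trimws(tab[[col]])) %in% c("NA", "NAN", ""))
    .assert(length(bad) == 0L,
            sprintf("parse error at row %d: non-numeric %s '%s'",
                    row_no[bad[1]], col, tab[[col]][bad[1]]))
    v
  }
  tab[, `:=`(segment = num("segment"), time = num("time"), value = num("value"))]
  .assert(!anyNA(tab$segment) && !anyNA(tab$time),
          "segment and time must not be missing")
  if (!have_view) {
    .assert(!is.null(view), "table has no 'view' column and no view was given")
    data.table::set(tab, j = "view", value = view)
  } else if (!is.null(view)) {
    .assert(all(tab$view == view), "table 'view' column disagrees with the view argument")
  }
  badv <- which(!tab$view %in% .VIEWS)
  .assert(length(badv) == 0L,
          sprintf("parse error at row %d: unknown view '%s'", row_no[badv[1]], tab$view[badv[1]]))
  badm <- which(!tab$measure %in% .MEASURES)
  .assert(length(badm) == 0L,
          sprintf("parse error at row %d: unknown measure '%s'", row_no[badm[1]], tab$measure[badm[1]]))
  mv <- .MEASURE_VIEW[tab$measure] != tab$view
  .assert(!any(mv),
          sprintf("parse error at row %d: measure %s does not belong to view %s",
                  row_no[which(mv)[1]], tab$measure[which(mv)[1]], tab$view[which(mv)[1]]))
  seg_bad <- which(tab$segment < 1 | tab$segment > .VIEW_NSEG[tab$view] |
                     tab$segment != round(tab$segment))
  .assert(length(seg_bad) == 0L,
          sprintf("parse error at row %d: segment out of range (%g for view %s)",
                  row_no[seg_bad[1]], tab$segment[seg_bad[1]], tab$view[seg_bad[1]]))
  dup <- duplicated(tab[, c("patient_id", "view", "segment", "measure", "time")])
  .assert(!any(dup),
          sprintf("parse error at row %d: duplicate (segment, measure, time) key",
                  row_no[which(dup)[1]]))

  key <- paste(tab$patient_id, tab$view, tab$measure,
               formatC(tab$segment, width = 2, flag = "0"), sep = "\r")
  ord <- order(key, tab$time)
  tab <- tab[ord]; key <- key[ord]
  out <- lapply(split(seq_len(nrow(tab)), factor(key, levels = unique(key))), function(ix) {
    tt <- tab$time[ix]
    if (max(tt) > 1.5) tt <- tt / max(tt)  # ms -> cycle fraction, cycle = last sample
    strain_trace(tab$patient_id[ix[1]], tab$view[ix[1]], tab$segment[ix[1]],
                 tab$measure[ix[1]], tt, tab$value[ix])
  })
  names(out) <- NULL
  out
}

#' Convert traces to the long-format table
#'
#' @param traces List of [strain_trace] objects.
#' @return A `data.table` with the dialect's six columns.
#' @export
as_strain_table <- function(traces) {
  data.table::rbindlist(lapply(traces, function(tr) {
    data.table(patient_id = tr$patient_id, view = tr$view,
               segment = tr$segment, measure = tr$measure,
               time = tr$times, value = tr$values)
  }))
}

#' Write traces in the long-format dialect
#'
#' @param traces List of [strain_trace] objects or a long table.
#' @param path Output path; `.csv` suffix writes CSV, anything else TSV.
#' @export
write_strain_table <- function(traces, path) {
  tab <- if (data.table::is.data.table(traces)) traces else as_strain_table(traces)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  out <- data.table::copy(tab)
  # 17 significant digits round-trips doubles bit-exactly through the parser
  for (cl in c("time", "value"))
    data.table::set(out, j = cl, value = sprintf("%.17g", out[[cl]]))
  fwrite(out, path, sep = sep, quote = FALSE)
  invisible(path)
}

#' A labelled strain cohort
#'
#' @param traces List of [strain_trace] objects (or a long `data.table`
#'   in the dialect of [parse_strain_table]).
#' @param labels Named character vector (or two-column data frame
#'   `patient_id, label`) with labels in `{CP, RCM, NL}`.
#' @return Object of class `strain_cohort` with elements `data` (long
#'   `data.table`) and `labels` (named character).
#' @export
strain_cohort <- function(traces, labels) {
  dat <- if (data.table::is.data.table(traces)) data.table::copy(traces) else as_strain_table(traces)
  if (is.data.frame(labels)) labels <- setNames(as.character(labels[[2]]), labels[[1]])
  labels <- labels[!duplicated(names(labels))]
  .assert(all(labels %in% c("CP", "RCM", "NL")),
          "labels must be CP, RCM or NL")
  pids <- unique(dat$patient_id)
  miss <- setdiff(pids, names(labels))
  .assert(length(miss) == 0L, "patients without a label: ", paste(head(miss, 5), collapse = ", "))
  structure(list(data = dat, labels = labels[pids]), class = "strain_cohort")
}

#' @export
print.strain_cohort <- function(x, ...) {
  tb <- table(factor(x$labels, levels = c("CP", "RCM", "NL")))
  cat(sprintf("<strain_cohort> %d patients (CP %d, RCM %d, NL %d), %d series\n",
              length(x$labels), tb[["CP"]], tb[["RCM"]], tb[["NL"]],
              nrow(unique(x$data[, c("patient_id", "view", "segment", "measure")]))))
  invisible(x)
}

#' Extract the trace list from a cohort
#' @param cohort A `strain_cohort`.
#' @param patient_id Optional single patient to extract.
#' @return List of [strain_trace] objects.
#' @export
strain_traces <- function(cohort, patient_id = NULL) {
  dat <- cohort$data
  if (!is.null(patient_id)) dat <- dat[dat$patient_id %in% patient_id, ]
  key <- paste(dat$patient_id, dat$view, dat$measure,
               formatC(dat$segment, width = 2, flag = "0"), sep = "\r")
  lapply(split(seq_len(nrow(dat)), factor(key, levels = unique(key))), function(ix) {
    ord <- ix[order(dat$time[ix])]
    strain_trace(dat$patient_id[ord[1]], dat$view[ord[1]], dat$segment[ord[1]],
                 dat$measure[ord[1]], dat$time[ord], dat$value[ord])
  })
}

#' Read a two-column label file
#' @param path CSV with header `patient_id,label`.
#' @return Named character vector of labels.
#' @export
read_labels <- function(path) {
  tab <- fread(path, colClasses = "character")
  .assert(all(c("patient_id", "label") %in% names(tab)),
          "label file must have columns patient_id,label")
  setNames(tab$label, tab$patient_id)
}

#' The default 18 required (measure, region) pairs
#' @return data.frame with columns `measure`, `region`, `view`.
#' @export
required_pairs_default <- function() {
  do.call(rbind, lapply(.MEASURES, function(m) {
    v <- .MEASURE_VIEW[[m]]
    data.frame(measure = m, region = .VIEW_REGIONS[[v]], view = v,
               stringsAsFactors = FALSE)
  }))
}

#' Apply the completeness exclusion rule
#'
#' A patient is retained only if every required (measure, region) pair can
#' be formed: every segment of the region must be present for that measure
#' with at least 4 finite samples (a series with >= 4 finite samples but
#' internal NaNs is considered repairable by the spline resampler; fewer
#' finite samples counts as a missing series). The kept and dropped sets
#' partition the cohort; patient order is preserved.
#'
#' @param cohort A [strain_cohort].
#' @param required_pairs Data frame `measure, region` (default: all 18
#'   combinations, see [required_pairs_default()]).
#' @param region_map Optional custom region map (see [default_region_map]).
#' @return List with `kept` (a `strain_cohort`) and `dropped` (data.frame
#'   `patient_id, reason`; zero rows when nobody is dropped).
#' @export
filter_complete <- function(cohort, required_pairs = NULL, region_map = NULL) {
  if (is.null(required_pairs)) required_pairs <- required_pairs_default()
  if (!"view" %in% names(required_pairs))
    required_pairs$view <- .MEASURE_VIEW[required_pairs$measure]
  dat <- cohort$data
  ok_tab <- dat[, list(ok = sum(is.finite(value)) >= 4L),
                by = c("patient_id", "view", "segment", "measure")]
  pids <- names(cohort$labels)
  reasons <- character(0); dropped_ids <- character(0)
  for (pid in pids) {
    sub <- ok_tab[ok_tab$patient_id == pid, ]
    fail <- NULL
    for (i in seq_len(nrow(required_pairs))) {
      m <- required_pairs$measure[i]; r <- required_pairs$region[i]
      v <- required_pairs$view[i]
      segs <- region_segments(v, r, region_map)
      have <- sub[sub$measure == m & sub$ok, ]$segment
      if (!all(segs %in% have)) { fail <- c(m, r); break }
    }
    if (!is.null(fail)) {
      dropped_ids <- c(dropped_ids, pid)
      reasons <- c(reasons,
                   sprintf("missing or unusable series for (%s, %s)", fail[1], fail[2]))
    }
  }
  keep <- setdiff(pids, dropped_ids)
  kept <- structure(list(data = dat[dat$patient_id %in% keep, ],
                         labels = cohort$labels[keep]),
                    class = "strain_cohort")
  list(kept = kept,
       dropped = data.frame(patient_id = dropped_ids, reason = reasons,
                            stringsAsFactors = FALSE))
}

#' Summarise a filtered cohort as a JSON-ready list
#' @param kept Retained [strain_cohort].
#' @param dropped `dropped` data frame from [filter_complete].
#' @return List with per-class counts and drop records.
#' @export
cohort_summary <- function(kept, dropped = NULL) {
  tb <- table(factor(kept$labels, levels = c("CP", "RCM", "NL")))
  out <- list(n_patients = length(kept$labels),
              n_per_class = as.list(setNames(as.integer(tb), names(tb))))
  out$dropped <- if (is.null(dropped) || nrow(dropped) == 0L) list()
  else lapply(seq_len(nrow(dropped)), function(i)
    list(patient_id = dropped$patient_id[i], reason = dropped$reason[i]))
  out
}
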