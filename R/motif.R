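#' Assemble one patient's 18 x 50 strain motif
#'
#' Stacks the 18 persistence images — one per (measure, wall region)
#' combination — into the patient-specific motif matrix, rows in the
#' canonical order of [canonical_row_labels()].
#'
#' @param images Named list mapping each canonical row label
#'   (`"{measure}_{region}"`) to a `persistence_image` (or bare numeric
#'   pixel vector). All 18 keys must be present and no extras.
#' @param subject Patient id (or class-average tag) stored on the motif.
#' @return Object of class `strain_motif`: list with `matrix` (18 x
#'   `npix`), `row_labels` and `subject`.
#' @export
assemble_motif <- function(images, subject = "") {
  want <- canonical_row_labels()
  missing <- setdiff(want, names(images))
  .assert(length(missing) == 0L,
          "missing persistence image(s) for: ", paste(missing, collapse = ", "))
  extra <- setdiff(names(images), want)
  .assert(length(extra) == 0L,
          "unexpected image key(s): ", paste(extra, collapse = ", "))
  rows <- lapply(images[want], function(im) {
    if (inherits(im, "persistence_image")) im$pixels else as.numeric(im)
  })
  .assert(length(unique(lengths(rows))) == 1L,
          "all images must have the same pixel count")
  mat <- do.call(rbind, rows)
  .assert(all(is.finite(mat)) && all(mat >= 0),
          "motif entries must be finite and nonnegative")
  rownames(mat) <- want
  colnames(mat) <- sprintf("px%02d", seq_len(ncol(mat)))
  structure(list(matrix = mat, row_labels = want, subject = subject),
            class = "strain_motif")
}

#' @export
print.strain_motif <- function(x, ...) {
  cat(sprintf("<strain_motif> %s: %d x %d (rows = measure_region, cols = persistence pixels)\n",
              x$subject, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Flatten a motif into the named 900-feature vector
#'
#' Row-major order; names follow `"{measure}_{region}_px{01..50}"`.
#'
#' @param motif A `strain_motif`.
#' @return Named numeric vector of length `18 * npix` (900 by default).
#' @export
flatten_motif <- function(motif) {
  v <- as.numeric(t(motif$matrix))
  names(v) <- canonical_feature_names(ncol(motif$matrix))
  v
}

#' Rebuild a motif from a flattened feature vector
#' @param features Named vector as produced by [flatten_motif].
#' @param subject Subject tag for the rebuilt motif.
#' @return A `strain_motif`; `unflatten_motif(flatten_motif(m))`
#'   reproduces `m` exactly.
#' @export
unflatten_motif <- function(features, subject = "") {
  npix <- length(features) / 18L
  .assert(npix == round(npix), "feature vector length must be a multiple of 18")
  .assert(identical(names(features), canonical_feature_names(npix)),
          "feature names do not follow the canonical scheme")
  mat <- matrix(features, nrow = 18L, ncol = npix, byrow = TRUE)
  rows <- canonical_row_labels()
  assemble_motif(setNames(split(mat, row(mat))[as.character(1:18)], rows),
                 subject = subject)
}

#' Element-wise average motif of a class
#' @param motifs Non-empty list of `strain_motif` objects sharing row
#'   labels and pixel count.
#' @param label Tag stored as the average motif's subject.
#' @return A `strain_motif`.
#' @export
class_average_motif <- function(motifs, label) {
  .assert(length(motifs) > 0L, "cannot average an empty set of motifs")
  dims <- vapply(motifs, function(m) dim(m$matrix), integer(2))
  .assert(all(dims == dims[, 1]), "motifs must share dimensions")
  acc <- Reduce(`+`, lapply(motifs, `[[`, "matrix")) / length(motifs)
  out <- motifs[[1]]
  out$matrix <- acc
  out$subject <- label
  out
}

#' Write a motif as CSV (row labels in the first column)
#' @param motif A `strain_motif`.
#' @param path Output CSV path.
#' @export
write_motif_csv <- function(motif, path) {
  df <- data.frame(row_label = rownames(motif$matrix), motif$matrix,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a motif written by [write_motif_csv]
#' @param path CSV path.
#' @param subject Subject tag to attach.
#' @return A `strain_motif`.
#' @export
read_motif_csv <- function(path, subject = "") {
  df <- read.csv(path, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  assemble_motif(setNames(split(mat, row(mat))[as.character(seq_len(nrow(mat)))],
                          df[[1]]), subject = subject)
}

#' Render a motif heatmap
#'
#' Heatmap in the workflow's orientation: (measure, region) rows along the
#' x-axis, persistence pixel position 1..50 on the y-axis, colour =
#' pixel intensity on a fixed perceptually uniform palette (viridis).
#' Output is deterministic for a fixed motif and renderer settings.
#'
#' @param motif A `strain_motif`.
#' @param path Output PNG path.
#' @param width,height Device size in pixels.
#' @param palette Palette name passed to [grDevices::hcl.colors].
#' @return `path`, invisibly. A `.json` sidecar records the colormap and
#'   intensity range.
#' @export
render_motif <- function(motif, path, width = 900, height = 600,
                         palette = "viridis") {
  m <- motif$matrix
  grDevices::png(path, width = width, height = height)
  op <- par(mar = c(7, 4, 3, 1))
  on.exit({ par(op); grDevices::dev.off() }, add = TRUE)
  zlim <- range(m)
  if (zlim[1] == zlim[2]) zlim <- zlim + c(0, 1e-12)
  image(x = seq_len(nrow(m)), y = seq_len(ncol(m)), z = m,
        col = grDevices::hcl.colors(100, palette), zlim = zlim,
        xlab = "", ylab = "persistence pixel", axes = FALSE,
        main = paste("Strain motif:", motif$subject))
  axis(1, at = seq_len(nrow(m)), labels = rownames(m), las = 2, cex.axis = 0.7)
  axis(2)
  box()
  jsonlite::write_json(
    list(palette = palette, zlim = zlim, subject = motif$subject),
    paste0(sub("\\.png$", "", path), ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
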