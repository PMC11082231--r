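#' Extract per-patient strain motifs from a cohort
#'
#' Runs the full topological feature-extraction stage: regional mean
#' curves (spline-resampled, segment-averaged), delay embedding (d = 3,
#' tau = 2 by default), dimension-0 Rips persistence, and linear
#' persistence images stacked into one 18 x `npix` motif per patient.
#'
#' Image bounds: with `bounds_mode = "cohort"` (default) the persistence
#' axis of each (measure, region) row is fitted over that row's diagrams
#' across the whole cohort, so pixel position carries the absolute
#' persistence scale and motifs are comparable across patients; with
#' `"diagram"` each image uses its own diagram's automatic bounds.
#'
#' @param cohort A [strain_cohort] (should already have passed
#'   [filter_complete]).
#' @param T Resampling grid size (default 100; clouds have `T - 4`
#'   points at the default embedding).
#' @param embed_d,embed_tau Delay-embedding dimension and lag.
#' @param npix Pixels per persistence image.
#' @param variance Gaussian variance of the persistence image.
#' @param bounds_mode `"cohort"` or `"diagram"`.
#' @param region_map Optional region-map override (list by view).
#' @param bc Spline boundary condition.
#' @return Named list of `strain_motif` objects (one per patient), with
#'   the per-row bounds used attached as attribute `"bounds"`.
#' @export
extract_motifs <- function(cohort, T = 100L, embed_d = 3L, embed_tau = 2L,
                           npix = 50L, variance = 0.005,
                           bounds_mode = c("cohort", "diagram"),
                           region_map = NULL, bc = "natural") {
  bounds_mode <- match.arg(bounds_mode)
  curves <- regional_curves(cohort, T = T, region_map = region_map, bc = bc)
  diagrams <- lapply(curves$curve, function(v)
    rips_h0(delay_embed(v, d = embed_d, tau = embed_tau)))
  row_lab <- curves$row_label
  bounds_by_row <- NULL
  if (bounds_mode == "cohort") {
    bounds_by_row <- lapply(split(diagrams, row_lab), function(ds)
      auto_bounds(unlist(lapply(ds, persistence_values)), npix))
  }
  pids <- names(cohort$labels)
  motifs <- lapply(pids, function(pid) {
    ix <- which(curves$patient_id == pid)
    imgs <- lapply(ix, function(i) {
      b <- if (bounds_mode == "cohort") bounds_by_row[[row_lab[i]]] else NULL
      persistence_image(diagrams[[i]], npix = npix, variance = variance,
                        bounds = b)
    })
    names(imgs) <- row_lab[ix]
    assemble_motif(imgs, subject = pid)
  })
  names(motifs) <- pids
  attr(motifs, "bounds") <- bounds_by_row
  motifs
}

#' Motif feature table
#'
#' Flattens a list of motifs into the samples x 900 feature matrix used
#' by the classifiers.
#'
#' @param motifs Named list of `strain_motif`s (as from [extract_motifs]).
#' @return Numeric matrix, rownames = patient ids, colnames =
#'   [canonical_feature_names()].
#' @export
motif_feature_table <- function(motifs) {
  t(vapply(motifs, flatten_motif,
           numeric(18L * ncol(motifs[[1]]$matrix))))
}

#' Train the full classifier battery
#'
#' Reproduces the modelling stage: shadow-feature selection on the motif
#' table, then the three binary tasks (logistic regression for CP-vs-RCM
#' and CP-vs-NL; random forest for RCM-vs-NL), the multiclass random
#' forest, the single-feature GLS logistic baselines for the same tasks,
#' and paired DeLong comparisons of each topological model against its
#' GLS counterpart (binary tasks share fold assignments, so scores are
#' paired by patient).
#'
#' @param features Motif feature matrix (patients x 900).
#' @param gls One-column GLS feature matrix from [gls_feature].
#' @param labels Named labels (CP/RCM/NL) matching the feature rows.
#' @param seed Master seed for selection, folds and forests.
#' @param k CV folds (default 10).
#' @param boruta Run shadow-feature selection first (default TRUE).
#' @param boruta_args Extra arguments for [boruta_select].
#' @param nested_selection Refit selection inside each CV training fold
#'   instead of once upfront.
#' @param num_trees Forest size.
#' @return Object of class `strain_models`: list with `selection`,
#'   `selected_features`, `binary` (per-task lists holding `ph`, `gls`
#'   [model_report]s and `comparison`), `multiclass` (PH
#'   [multiclass_report]), `multiclass_gls`, and `seed`.
#' @export
train_strain_models <- function(features, gls, labels, seed = 1L, k = 10L,
                                boruta = TRUE, boruta_args = list(),
                                nested_selection = FALSE, num_trees = 500L) {
  .assert(identical(rownames(features), names(labels)) &&
            identical(rownames(gls), names(labels)),
          "feature rows and labels must align")
  labels <- as.character(labels)
  names(labels) <- rownames(features)
  selection <- NULL
  selected <- colnames(features)
  if (boruta && !nested_selection) {
    selection <- do.call(boruta_select,
                         modifyList(list(x = features, y = labels, seed = seed),
                                    boruta_args))
    if (length(selection$confirmed) > 0L) selected <- selection$confirmed
  }
  xsel <- features[, selected, drop = FALSE]

  tasks <- list(
    CP_vs_RCM  = list(classes = c("CP", "RCM"), positive = "CP",
                      model = "logistic_regression"),
    CP_vs_NL   = list(classes = c("CP", "NL"), positive = "CP",
                      model = "logistic_regression"),
    RCM_vs_NL  = list(classes = c("RCM", "NL"), positive = "RCM",
                      model = "random_forest"))
  binary <- lapply(tasks, function(tk) {
    ix <- labels %in% tk$classes
    ph <- crossval_train(xsel[ix, , drop = FALSE], labels[ix], tk$model,
                         positive = tk$positive, k = k, seed = seed,
                         nested_selection = nested_selection,
                         boruta_args = boruta_args, num_trees = num_trees)
    gl <- crossval_train(gls[ix, , drop = FALSE], labels[ix],
                         "logistic_regression", positive = tk$positive,
                         k = k, seed = seed)
    cmp <- delong_compare(ph$scores, gl$scores, labels[ix],
                          positive = tk$positive)
    list(ph = ph, gls = gl, comparison = cmp)
  })

  multiclass <- multiclass_report(xsel, labels, k = k, seed = seed,
                                  num_trees = num_trees)
  # GLS multiclass baseline: one-vs-rest single-feature logistic models
  lev <- sort(unique(labels))
  gls_per_class <- lapply(lev, function(cl) {
    crossval_train(gls, ifelse(labels == cl, cl, "rest"),
                   "logistic_regression", positive = cl, k = k, seed = seed)
  })
  names(gls_per_class) <- lev
  multiclass_gls <- list(
    per_class = gls_per_class,
    macro_auc = mean(vapply(gls_per_class, `[[`, numeric(1), "auc")),
    macro_sensitivity = mean(vapply(gls_per_class, `[[`, numeric(1), "sensitivity")),
    macro_specificity = mean(vapply(gls_per_class, `[[`, numeric(1), "specificity")),
    levels = lev)
  structure(list(selection = selection, selected_features = selected,
                 binary = binary, multiclass = multiclass,
                 multiclass_gls = multiclass_gls, seed = seed, k = k),
            class = "strain_models")
}

#' @export
print.strain_models <- function(x, ...) {
  cat("<strain_models>\n")
  if (!is.null(x$selection))
    cat(sprintf("  selection: %d/%d features confirmed\n",
                length(x$selection$confirmed), length(x$selection$hits)))
  for (nm in names(x$binary)) {
    b <- x$binary[[nm]]
    cat(sprintf("  %-10s PH AUC %.3f vs GLS AUC %.3f (DeLong p = %.3g)\n",
                nm, b$ph$auc, b$gls$auc, b$comparison$p_value))
  }
  cat(sprintf("  multiclass PH macro AUC %.3f vs GLS %.3f\n",
              x$multiclass$macro_auc, x$multiclass_gls$macro_auc))
  invisible(x)
}
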