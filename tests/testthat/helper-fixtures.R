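# Shared fixtures built in code at test time.

# A compact preset so simulated patients are cheap in tests.
small_preset <- function(label) {
  p <- class_preset(label)
  p$n_samples_range <- c(12L, 12L)
  p
}

small_spec <- function(n_per_class, seed = 1L) {
  presets <- lapply(setNames(names(n_per_class), names(n_per_class)), small_preset)
  synthetic_spec(n_per_class = n_per_class, seed = seed, presets = presets)
}

# Long-format table text for parser tests.
table_text <- function(rows, header = "patient_id\tview\tsegment\tmeasure\ttime\tvalue") {
  paste(c(header, rows), collapse = "\n")
}

tsv_row <- function(pid, view, seg, meas, t, v) {
  paste(pid, view, seg, meas, t, v, sep = "\t")
}

# Uniformly random 3-D cloud.
random_cloud <- function(n, d = 3L) matrix(runif(n * d), n, d)

# Independent single-linkage merge heights via stats::hclust.
single_linkage_heights <- function(cloud) {
  sort(stats::hclust(stats::dist(cloud), method = "single")$height)
}
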