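# End-to-end orchestration: segment every tile, pool per-segment mean
# spectra, quality-test, preprocess, and classify, with seeded
# reproducibility throughout.

#' Pipeline configuration
#'
#' @param seg a [segmentation_config()].
#' @param qt_enabled run the quality test (default TRUE).
#' @param qt_mode,qt_combine rejection mode passed to [calibrate_qt()].
#' @param prep a [preprocess_config()].
#' @param embed_method `"umap"` (default) or `"pca"`.
#' @param n_neighbors,min_dist UMAP parameters.
#' @param knn_features `"spectra"` (default; kNN on the full preprocessed
#'   second-derivative vectors) or `"embedding"` (kNN on the 2-D
#'   coordinates).
#' @param k_nn,k_folds kNN neighbours and cross-validation folds.
#' @param n_permutations label permutations for the silhouette test.
#' @param segment which compartment to classify: `"cell"`,
#'   `"cytoplasm"` or `"nucleus"`.
#' @param positive_class the disease (positive) class label.
#' @param seed global seed; all stage seeds derive from it.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(seg = segmentation_config(),
                            qt_enabled = TRUE,
                            qt_mode = "two_sided", qt_combine = "both",
                            prep = preprocess_config(),
                            embed_method = c("umap", "pca"),
                            n_neighbors = 15L, min_dist = 0.1,
                            knn_features = c("spectra", "embedding"),
                            k_nn = 5L, k_folds = 3L,
                            n_permutations = 999L,
                            segment = c("cell", "cytoplasm", "nucleus"),
                            positive_class = "HD",
                            seed = 0L) {
  structure(list(seg = seg, qt_enabled = qt_enabled, qt_mode = qt_mode,
                 qt_combine = qt_combine, prep = prep,
                 embed_method = match.arg(embed_method),
                 n_neighbors = as.integer(n_neighbors),
                 min_dist = min_dist,
                 knn_features = match.arg(knn_features),
                 k_nn = as.integer(k_nn), k_folds = as.integer(k_folds),
                 n_permutations = as.integer(n_permutations),
                 segment = match.arg(segment),
                 positive_class = positive_class,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# rbind spectra sets sharing one axis
combine_spectra <- function(sets) {
  sets <- sets[!vapply(sets, is.null, logical(1))]
  stopifnot(length(sets) >= 1L)
  nu <- sets[[1]]$wavenumber
  for (s in sets)
    if (!isTRUE(all.equal(s$wavenumber, nu)))
      stop("cannot combine spectra sets with different axes")
  spectra_set(do.call(rbind, lapply(sets, function(s) s$absorbance)), nu,
              do.call(rbind, lapply(sets, function(s) s$meta)))
}

#' Segment all tiles of a study and pool per-segment mean spectra
#'
#' @param study a `phantom_study` or any list with a `manifest`
#'   data.frame (`sample_id`, `class_label`, and either `path` to ENVI
#'   headers or phantom seeds) interpretable by [study_tile()].
#' @param seg_config a [segmentation_config()].
#' @return a [spectra_set()] with records for every cell and compartment.
#' @export
collect_segment_spectra <- function(study, seg_config = segmentation_config()) {
  sets <- vector("list", nrow(study$manifest))
  for (i in seq_len(nrow(study$manifest))) {
    tile <- study_tile(study, i)
    seg <- segment_cube(tile$cube, seg_config)
    sets[[i]] <- extract_mean_spectra(tile$cube, seg,
                                      sample_id = study$manifest$sample_id[i],
                                      class_label = tile$class_label)
  }
  combine_spectra(sets)
}

# QT calibrated per segment kind: a mean spectrum's noise scales with the
# pixel count of its segment, so whole-cell, cytoplasm and nucleus spectra
# have systematically different SNR levels; judging each record against
# cutoffs calibrated on its own segment population avoids rejecting one
# compartment wholesale for being cleaner or noisier than another.
qt_filter <- function(records, config) {
  metrics <- compute_qt_metrics(records)
  pass <- logical(n_spectra(records))
  thresholds <- list()
  for (seg in unique(records$meta$segment)) {
    idx <- records$meta$segment == seg
    thr <- calibrate_qt(metrics[idx, , drop = FALSE],
                        mode = config$qt_mode,
                        combine = config$qt_combine)
    pass[idx] <- apply_qt(metrics[idx, , drop = FALSE], thr)$results$pass
    thresholds[[seg]] <- thr
  }
  list(records = records[pass],
       thresholds = thresholds,
       report = structure(list(results = data.frame(pass = pass),
                               pass_fraction = mean(pass),
                               n = length(pass), n_pass = sum(pass)),
                          class = "qt_report"))
}

# classification of one preprocessed segment subset
classify_spectra <- function(prep_set, config) {
  labels <- prep_set$meta$class_label
  x <- prep_set$absorbance
  emb <- if (config$embed_method == "umap")
    umap_embed(x, n_neighbors = min(config$n_neighbors,
                                    nrow(x) - 1L),
               min_dist = config$min_dist, seed = config$seed)
  else pca_embed(x, 2L)
  perm <- permutation_test(emb$coordinates, labels,
                           n_permutations = config$n_permutations,
                           seed = config$seed + 1L)
  feats <- if (config$knn_features == "spectra") x else emb$coordinates
  conf <- knn_crossval(feats, labels, k_nn = config$k_nn,
                       k_folds = config$k_folds,
                       seed = config$seed + 2L,
                       positive = config$positive_class)
  structure(list(segment = unique(prep_set$meta$segment),
                 n = n_spectra(prep_set),
                 embedding = emb,
                 silhouette = perm$S,
                 permutation_p = perm$permutation_p,
                 n_permutations = perm$n_permutations,
                 confusion = conf,
                 accuracy = conf$accuracy,
                 sensitivity = conf$sensitivity,
                 specificity = conf$specificity,
                 seed = config$seed),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(paste0("<classification_report> segment %s, n = %d: ",
                     "S = %.3f (p = %.4g), A = %.3f, SEN = %.3f, ",
                     "SPEC = %.3f\n"),
              paste(x$segment, collapse = "/"), x$n, x$silhouette,
              x$permutation_p, x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}

#' Run the full spectral-phenotyping pipeline
#'
#' Segmentation, per-segment mean spectra, quality testing (calibrated
#' on the pooled nucleus + cytoplasm records of the study itself),
#' second-derivative preprocessing, and classification of the chosen
#' compartment. Deterministic for a fixed study and config.
#'
#' @param study a study object (see [collect_segment_spectra()]).
#' @param config a [pipeline_config()].
#' @return a `classification_report` with the QT report and record
#'   counts attached.
#' @export
run_pipeline <- function(study, config = pipeline_config()) {
  classes <- unique(study$manifest$class_label)
  if (length(classes) < 2L)
    stop("study manifest contains a single class; nothing to classify")
  records <- collect_segment_spectra(study, config$seg)
  qt <- NULL
  if (config$qt_enabled) {
    qt <- qt_filter(records, config)
    records <- qt$records
  }
  sel <- records[records$meta$segment == config$segment]
  if (length(unique(sel$meta$class_label)) < 2L)
    stop("after quality testing only one class remains in segment ",
         config$segment)
  prep <- preprocess(sel, config$prep)
  report <- classify_spectra(prep, config)
  report$qt_pass_fraction <- if (is.null(qt)) NA_real_ else
    qt$report$pass_fraction
  report$n_records_total <- n_spectra(records)
  report$config <- config
  report
}

#' Compare classification across subcellular segments
#'
#' Runs one segmentation and quality test, then classifies the whole-cell,
#' cytoplasm and nucleus mean spectra separately, returning one row of
#' silhouette/permutation/confusion metrics per segment — the study-level
#' summary of how strongly the disease signal depends on the compartment
#' the spectra come from.
#'
#' @param study a study object.
#' @param config a [pipeline_config()]; its `segment` field is ignored.
#' @return a data.frame with columns `segment`, `n`, `S`,
#'   `permutation_p`, `accuracy`, `sensitivity`, `specificity`, plus the
#'   per-segment reports as attribute `"reports"`.
#' @export
compare_segments <- function(study, config = pipeline_config()) {
  classes <- unique(study$manifest$class_label)
  if (length(classes) < 2L)
    stop("study manifest contains a single class; nothing to classify")
  records <- collect_segment_spectra(study, config$seg)
  if (config$qt_enabled)
    records <- qt_filter(records, config)$records
  reports <- list()
  for (seg in c("cell", "cytoplasm", "nucleus")) {
    sel <- records[records$meta$segment == seg]
    if (n_spectra(sel) == 0L) next
    prep <- preprocess(sel, config$prep)
    reports[[seg]] <- classify_spectra(prep, config)
  }
  out <- do.call(rbind, lapply(reports, function(r)
    data.frame(segment = paste(r$segment, collapse = "/"), n = r$n,
               S = r$silhouette, permutation_p = r$permutation_p,
               accuracy = r$accuracy, sensitivity = r$sensitivity,
               specificity = r$specificity)))
  rownames(out) <- NULL
  attr(out, "reports") <- reports
  out
}

#' Serialize a classification report to JSON
#'
#' Writes embedding coordinates, silhouette and permutation statistics,
#' confusion counts and derived metrics, and the full configuration.
#' Output contains no timestamps, so identical runs produce
#' byte-identical files.
#'
#' @param report a `classification_report`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_report_json <- function(report, path) {
  payload <- list(
    segment = report$segment,
    n = report$n,
    silhouette = report$silhouette,
    permutation_p = report$permutation_p,
    n_permutations = report$n_permutations,
    confusion = report$confusion[c("TP", "TN", "FP", "FN", "accuracy",
                                   "sensitivity", "specificity", "k_nn",
                                   "k_folds", "seed", "positive")],
    qt_pass_fraction = report$qt_pass_fraction,
    n_records_total = report$n_records_total,
    embedding = list(method = report$embedding$method,
                     params = report$embedding$params,
                     seed = report$embedding$seed,
                     coordinates = report$embedding$coordinates),
    config = unclass_config(report$config),
    seed = report$seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

unclass_config <- function(config) {
  if (is.null(config)) return(NULL)
  out <- unclass(config)
  out$seg <- unclass(out$seg)
  out$prep <- unclass(out$prep)
  out
}
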