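# Dataset I/O: the directory-manifest convention (CSV with image_path,
# patient_id, label), class-per-folder auto-discovery for OCT2017-style
# trees, and 8-bit grayscale PNG round-tripping of generated datasets.

#' Read a dataset manifest
#'
#' @param path CSV file with columns `image_path`, `patient_id`, `label`.
#' @return Data frame of sample records.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_path", "patient_id", "label")
  miss <- setdiff(need, names(m))
  if (length(miss)) {
    stop("manifest is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  m
}

#' Discover a class-per-folder image tree
#'
#' Walks `dir`, taking each subdirectory name as the class label and
#' extracting the patient identifier from each filename with a capture
#' group, as in OCT2017-style layouts (`CNV-81630-1.png` has patient
#' `81630`).
#'
#' @param dir Root directory.
#' @param patient_pattern Regex whose first capture group is the patient
#'   id; files that do not match get their full basename as patient id
#'   (one patient per file).
#' @return Manifest data frame (`image_path`, `patient_id`, `label`).
#' @export
discover_dataset <- function(dir, patient_pattern = "-([0-9]+)-") {
  classes <- list.dirs(dir, recursive = FALSE, full.names = FALSE)
  out <- list()
  for (cl in classes) {
    files <- list.files(file.path(dir, cl), pattern = "\\.png$",
                        full.names = FALSE)
    if (!length(files)) next
    m <- regmatches(files, regexec(patient_pattern, files))
    pid <- vapply(seq_along(m), function(i) {
      if (length(m[[i]]) >= 2L) m[[i]][2L] else
        sub("\\.png$", "", files[i])
    }, character(1))
    out[[cl]] <- data.frame(image_path = file.path(cl, files),
                            patient_id = paste0(cl, "-", pid),
                            label = cl, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Load the images referenced by a manifest
#'
#' PNGs are read as grayscale in `[0, 1]`; RGB(A) files are averaged over
#' the color channels.
#'
#' @param manifest Data frame from [read_manifest()] or
#'   [discover_dataset()].
#' @param base_dir Directory that `image_path` entries are relative to.
#' @return List of numeric matrices, one per record.
#' @export
load_manifest_images <- function(manifest, base_dir = ".") {
  lapply(manifest$image_path, function(p) {
    img <- png::readPNG(file.path(base_dir, p))
    if (length(dim(img)) == 3L) img <- apply(img[, , 1:3], c(1, 2), mean)
    img
  })
}

#' Write a generated dataset as a PNG tree with a manifest
#'
#' Serializes intensities to 8-bit grayscale PNGs in a class-per-folder
#' tree and writes `manifest.csv` at the root, the layout
#' [discover_dataset()] and the training pipeline consume.
#'
#' @param dataset Output of [generate_oct_dataset()].
#' @param dir Output directory (created if needed).
#' @return The manifest data frame, invisibly.
#' @export
write_oct_dataset <- function(dataset, dir) {
  rec <- dataset$records
  paths <- file.path(rec$label, paste0(rec$image_id, ".png"))
  for (cl in unique(rec$label)) {
    dir.create(file.path(dir, cl), recursive = TRUE, showWarnings = FALSE)
  }
  for (i in seq_len(nrow(rec))) {
    img8 <- round(dataset$images[i, , ] * 255) / 255
    png::writePNG(img8, file.path(dir, paths[i]))
  }
  manifest <- data.frame(image_path = paths, patient_id = rec$patient_id,
                         label = rec$label, stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Write an evaluation report to CSV and JSON
#'
#' Emits the per-class and overall metric block plus the confusion matrix.
#'
#' @param report Output of [evaluate_predictions()].
#' @param prefix Path prefix; files `<prefix>_metrics.csv`,
#'   `<prefix>_confusion.csv` and `<prefix>.json` are written.
#' @return `prefix`, invisibly.
#' @export
write_metrics_report <- function(report, prefix) {
  utils::write.csv(report$per_class, paste0(prefix, "_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(unclass(report$confusion)),
                   paste0(prefix, "_confusion.csv"))
  jsonlite::write_json(list(per_class = report$per_class,
                            overall = report$overall,
                            confusion = unclass(report$confusion)),
                       paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}
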