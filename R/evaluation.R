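# Multi-class evaluation: confusion matrices, per-class accuracy /
# sensitivity / precision and their macro averages (overall sensitivity OS,
# overall precision OP) plus micro overall accuracy OA, cross-fold
# aggregation, paired t-tests, and the Gaussian-noise / PSNR robustness
# harness.

#' Multi-class confusion matrix
#'
#' Cell (r, c) counts samples whose true class is r and predicted class is
#' c. Labels are 1-based integers in `1..n_classes` (factors are accepted
#' and converted).
#'
#' @param true,predicted Equal-length label vectors.
#' @param n_classes Class count; defaults to the number of factor levels
#'   or the largest label seen.
#' @param labels Optional class names for the dimnames.
#' @return An `I x I` integer matrix of class `"hctnet_confusion"`.
#' @export
confusion_matrix <- function(true, predicted, n_classes = NULL,
                             labels = NULL) {
  if (is.factor(true) || is.factor(predicted)) {
    lev <- union(levels(as.factor(true)), levels(as.factor(predicted)))
    if (is.null(labels)) labels <- lev
    true <- as.integer(factor(true, levels = lev))
    predicted <- as.integer(factor(predicted, levels = lev))
  }
  if (length(true) != length(predicted)) {
    stop("true and predicted must have equal length", call. = FALSE)
  }
  if (is.null(n_classes)) n_classes <- max(true, predicted)
  bad <- which(true < 1L | true > n_classes | predicted < 1L |
                 predicted > n_classes)
  if (length(bad)) {
    stop(sprintf("label out of range 1..%d at index %d", n_classes,
                 bad[1L]), call. = FALSE)
  }
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(true)) {
    cm[true[i], predicted[i]] <- cm[true[i], predicted[i]] + 1L
  }
  if (is.null(labels)) labels <- as.character(seq_len(n_classes))
  dimnames(cm) <- list(true = labels, predicted = labels)
  class(cm) <- c("hctnet_confusion", "matrix", "array")
  cm
}

#' @export
print.hctnet_confusion <- function(x, ...) {
  y <- x
  attr(y, "class") <- NULL
  print(y)
  invisible(x)
}

#' Per-class TP/FP/FN/TN counts
#'
#' @param cm A confusion matrix from [confusion_matrix()].
#' @return Data frame with one row per class; for every class
#'   `TP + FP + FN + TN` equals the total sample count.
#' @export
cm_counts <- function(cm) {
  n <- sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  data.frame(class = rownames(cm), TP = as.integer(tp),
             FP = as.integer(fp), FN = as.integer(fn),
             TN = as.integer(n - tp - fp - fn), row.names = NULL)
}

#' Per-class accuracy, sensitivity and precision
#'
#' For class i: accuracy `(TP+TN)/N`, sensitivity (recall) `TP/(TP+FN)`,
#' precision `TP/(TP+FP)`, each as a percentage. A zero denominator (class
#' absent from the truth, or never predicted) yields `NA` — a deliberate
#' sentinel that [overall_metrics()] excludes from macro averages with a
#' warning rather than silently reporting 0 or 100.
#'
#' @param cm A confusion matrix from [confusion_matrix()].
#' @return Data frame with columns `class`, `accuracy`, `sensitivity`,
#'   `precision` (percent).
#' @export
per_class_metrics <- function(cm) {
  ct <- cm_counts(cm)
  n <- sum(cm)
  div <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)
  data.frame(class = ct$class,
             accuracy = 100 * (ct$TP + ct$TN) / n,
             sensitivity = div(ct$TP, ct$TP + ct$FN),
             precision = div(ct$TP, ct$TP + ct$FP),
             row.names = NULL)
}

#' Macro average of a per-class metric
#'
#' Unweighted mean across classes. `NA` sentinels (degenerate classes) are
#' excluded with a warning.
#'
#' @param values Per-class metric values (percent).
#' @return Scalar macro average.
#' @examples
#' macro_mean(c(92.23, 87.96, 77.36, 96.73))  # 88.57
#' @export
macro_mean <- function(values) {
  if (anyNA(values)) {
    warning(sprintf("%d undefined per-class value(s) excluded from the macro average",
                    sum(is.na(values))), call. = FALSE)
  }
  mean(values, na.rm = TRUE)
}

#' Overall accuracy, sensitivity and precision
#'
#' OA is the micro accuracy `100 * trace / N`; OS and OP are the macro
#' (unweighted) means of per-class sensitivity and precision.
#'
#' @param cm A confusion matrix from [confusion_matrix()].
#' @return One-row data frame with columns `OA`, `OS`, `OP` (percent).
#' @export
overall_metrics <- function(cm) {
  pc <- per_class_metrics(cm)
  data.frame(OA = 100 * sum(diag(cm)) / sum(cm),
             OS = macro_mean(pc$sensitivity),
             OP = macro_mean(pc$precision))
}

#' Full evaluation report for one test set
#'
#' @param true,predicted Label vectors (see [confusion_matrix()]).
#' @param n_classes,labels Passed to [confusion_matrix()].
#' @return List with `confusion`, `per_class` and `overall`.
#' @export
evaluate_predictions <- function(true, predicted, n_classes = NULL,
                                 labels = NULL) {
  cm <- confusion_matrix(true, predicted, n_classes, labels)
  list(confusion = cm, per_class = per_class_metrics(cm),
       overall = overall_metrics(cm))
}

#' Aggregate per-fold metric reports
#'
#' Cross-validation results are combined as the unweighted mean of the
#' per-repetition metrics (metrics first, then averaged). Pooling the
#' confusion matrices before computing metrics is available as an
#' alternative mode.
#'
#' @param reports For `"mean"`: a list of one-row overall-metric data
#'   frames (or a matrix-like of per-fold values). For `"pool"`: a list of
#'   confusion matrices.
#' @param mode `"mean"` (default) or `"pool"`.
#' @return One-row data frame of aggregated metrics.
#' @export
aggregate_folds <- function(reports, mode = c("mean", "pool")) {
  mode <- match.arg(mode)
  if (mode == "pool") {
    cm <- Reduce(`+`, lapply(reports, unclass))
    class(cm) <- c("hctnet_confusion", "matrix", "array")
    return(overall_metrics(cm))
  }
  df <- do.call(rbind, reports)
  as.data.frame(as.list(colMeans(df)))
}

#' Paired t-test between two per-fold metric vectors
#'
#' Two-sided paired t-test on the per-fold differences. When the
#' differences have zero variance the test statistic is undefined; the
#' result is flagged degenerate instead of dividing by zero.
#'
#' @param values_a,values_b Equal-length (k >= 2) per-fold metric values.
#' @return List of class `"hctnet_paired_ttest"`: `t`, `df`, `p_value`,
#'   `mean_diff`, `degenerate`.
#' @export
paired_ttest <- function(values_a, values_b) {
  if (length(values_a) != length(values_b) || length(values_a) < 2L) {
    stop("paired t-test needs two equal-length vectors with k >= 2",
         call. = FALSE)
  }
  d <- values_a - values_b
  if (stats::sd(d) == 0) {
    return(structure(list(t = NA_real_, df = length(d) - 1L,
                          p_value = NA_real_, mean_diff = mean(d),
                          degenerate = TRUE),
                     class = "hctnet_paired_ttest"))
  }
  tt <- stats::t.test(values_a, values_b, paired = TRUE)
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, mean_diff = mean(d),
                 degenerate = FALSE),
            class = "hctnet_paired_ttest")
}

#' @export
print.hctnet_paired_ttest <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("Paired t-test: degenerate (zero-variance differences), mean diff %.4g\n",
                x$mean_diff))
  } else {
    cat(sprintf("Paired t-test: t = %.4f, df = %d, p = %.4g, mean diff %.4g\n",
                x$t, x$df, x$p_value, x$mean_diff))
  }
  invisible(x)
}

#' Add i.i.d. Gaussian noise to an image
#'
#' Zero-mean Gaussian noise of standard deviation `sigma` is added in the
#' original intensity domain and the result is clipped to the valid
#' range. Deterministic for a fixed seed.
#'
#' @param image Numeric matrix or array.
#' @param sigma Noise standard deviation (same units as the intensities).
#' @param seed Optional integer seed.
#' @param range Valid intensity range to clip to.
#' @return Noisy image with the same shape.
#' @export
add_gaussian_noise <- function(image, sigma, seed = NULL,
                               range = c(0, 1)) {
  if (sigma < 0) stop("sigma must be nonnegative", call. = FALSE)
  if (sigma == 0) return(image)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(set_rng_state(old))
    set.seed(seed)
  }
  out <- image + stats::rnorm(length(image), sd = sigma)
  out[out < range[1L]] <- range[1L]
  out[out > range[2L]] <- range[2L]
  out
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(peak^2 / MSE)` in decibels. Identical images have zero MSE;
#' the sentinel `Inf` is returned for that case.
#'
#' @param reference,test Equal-shaped numeric images.
#' @param peak Peak intensity; defaults to 255 when the reference looks
#'   8-bit (values above 1.5) and 1 otherwise.
#' @return PSNR in dB (`Inf` for identical images).
#' @export
psnr <- function(reference, test, peak = NULL) {
  if (!all(dim(reference) == dim(test)) ||
      length(reference) != length(test)) {
    stop("reference and test images must have the same shape",
         call. = FALSE)
  }
  if (is.null(peak)) peak <- if (max(reference) > 1.5) 255 else 1
  mse <- mean((as.numeric(reference) - as.numeric(test))^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Calibrate the noise level to a target mean PSNR
#'
#' Finds by bisection the Gaussian noise standard deviation whose mean
#' PSNR over a sample of images (noise re-drawn per image, clipping
#' included) hits a target — e.g. 26.91 dB for the noise-robustness
#' protocol. Mean PSNR is monotone decreasing in sigma, so bisection
#' converges; per-image noise seeds are derived deterministically from
#' `seed`.
#'
#' @param images List of matrices or rank-3 array (n, rows, cols) in
#'   `[0, 1]`.
#' @param target_psnr Target mean PSNR in dB.
#' @param seed Integer seed for the noise draws.
#' @param tol Acceptable |mean PSNR - target| in dB.
#' @param max_iter Bisection iteration cap.
#' @return List with `sigma`, `mean_psnr`, `iterations`.
#' @export
calibrate_noise_sigma <- function(images, target_psnr = 26.91, seed = 1L,
                                  tol = 0.01, max_iter = 60L) {
  if (is.array(images) && length(dim(images)) == 3L) {
    images <- lapply(seq_len(dim(images)[1L]),
                     function(i) images[i, , ])
  }
  mean_psnr <- function(sigma) {
    mean(vapply(seq_along(images), function(i) {
      noisy <- add_gaussian_noise(images[[i]], sigma,
                                  seed = seed + i, range = c(0, 1))
      psnr(images[[i]], noisy, peak = 1)
    }, numeric(1)))
  }
  lo <- 1e-4
  hi <- 1
  if (mean_psnr(lo) < target_psnr) {
    stop("target PSNR too high to reach with sigma >= 1e-4",
         call. = FALSE)
  }
  it <- 0L
  repeat {
    it <- it + 1L
    mid <- sqrt(lo * hi)
    p <- mean_psnr(mid)
    if (abs(p - target_psnr) <= tol || it >= max_iter) {
      return(list(sigma = mid, mean_psnr = p, iterations = it))
    }
    if (p > target_psnr) lo <- mid else hi <- mid
  }
}

#' Bundled published per-class benchmark results
#'
#' Per-class accuracy, sensitivity and precision (percent), and the
#' reported overall metrics, of five OCT B-scan classifiers on the
#' OCT2017 (4-class) and Srinivasan2014 (3-class) benchmarks. These serve
#' as fixtures for the macro-average metric identities and for
#' improvement-delta computations; they are inputs, not outputs, of this
#' package.
#'
#' @param dataset `"oct2017"` or `"srinivasan2014"`.
#' @return Data frame with columns `method`, `class`, `accuracy`,
#'   `sensitivity`, `precision`, `reported_oa`, `reported_os`,
#'   `reported_op`.
#' @export
reference_results <- function(dataset = c("oct2017", "srinivasan2014")) {
  dataset <- match.arg(dataset)
  path <- system.file("extdata",
                      paste0(dataset, "_reference_metrics.csv"),
                      package = "hctnet", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
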