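# Method-agreement statistics as used to validate the device against
# digital planimetry and probe measurements. The denominator conventions
# (device value for accuracy, smaller value for reproducibility, signed
# device mean for depth) reproduce the published per-row columns exactly and
# are locked by fixture tests; each result records the formula it used.

agreement_report <- function(per_item, aggregates, formula) {
  structure(c(list(per_item = per_item, formula = formula), aggregates),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> [%s]\n", x$formula))
  for (nm in setdiff(names(x), c("per_item", "formula")))
    cat(sprintf("  %s = %.4f\n", nm, x[[nm]]))
  invisible(x)
}

#' Accuracy of device measurements against a reference
#'
#' Per item, the relative error `e_i = |device - reference| / device`
#' (device value in the denominator); the aggregate accuracy is
#' `100 * (1 - mean(e_i))` percent.
#'
#' @param device Device measurements (nonzero).
#' @param reference Reference (e.g. planimetry) measurements, same units.
#' @return An `agreement_report` with `accuracy_pct` and per-item errors.
#' @export
accuracy_vs_reference <- function(device, reference) {
  if (length(device) != length(reference) || !length(device))
    stop("device and reference must be nonempty vectors of equal length")
  if (any(device == 0))
    stop(sprintf("zero device value for item(s): %s",
                 paste(which(device == 0), collapse = ", ")))
  e <- abs(device - reference) / device
  agreement_report(data.frame(device = device, reference = reference,
                              abs_error = abs(device - reference),
                              rel_error = e),
                   list(accuracy_pct = 100 * (1 - mean(e))),
                   "rel_error=|device-ref|/device; accuracy=100(1-mean)")
}

#' Precision of paired repeated device measurements
#'
#' Per pair, reproducibility `r_i = |m1 - m2| / min(m1, m2)` and coefficient
#' of variation `cv_i = (|m1 - m2| / sqrt(2)) / mean(m1, m2)` (the two-value
#' sample sd over the mean). Aggregates: `precision_pct = 100 (1 - mean r_i)`
#' and `mean_cv_pct = 100 mean(cv_i)`.
#'
#' @param m1,m2 Paired repeated measurements (positive, same units).
#' @return An `agreement_report` with `precision_pct`, `mean_cv_pct`.
#' @export
paired_precision <- function(m1, m2) {
  if (length(m1) != length(m2) || !length(m1))
    stop("m1 and m2 must be nonempty vectors of equal length")
  if (any(m1 <= 0) || any(m2 <= 0)) stop("measurements must be positive")
  d <- abs(m1 - m2)
  r <- d / pmin(m1, m2)
  cv <- (d / sqrt(2)) / ((m1 + m2) / 2)
  agreement_report(data.frame(m1 = m1, m2 = m2, diff = d,
                              reproducibility = r, cv = cv),
                   list(precision_pct = 100 * (1 - mean(r)),
                        mean_cv_pct = 100 * mean(cv)),
                   "reproducibility=diff/min; cv=(diff/sqrt2)/mean")
}

#' Depth agreement against probe measurements
#'
#' Handles the sensor's resolution-floor sentinel (`+/-3 mm`): sentinel rows
#' contribute zero error, zero spread and zero CV. For measured rows the
#' signed relative error is `s_i = |device_mean - probe| / device_mean`
#' (negative for hypergranulation rows whose device mean is negative), the
#' precision term is `p_i = |m1 - m2| / min(|m1|, |m2|)`, and the CV is the
#' two-value sample sd over the (signed) device mean.
#'
#' @param m1,m2 Repeated device depths in mm (`NA` on sentinel rows).
#' @param probe Probe depths in mm (the reference).
#' @param sentinel Logical: row reported as the +/-3 mm floor.
#' @return An `agreement_report` with `accuracy_pct`, `precision_pct` and
#'   `mean_cv_pct` (mean absolute CV).
#' @export
depth_agreement <- function(m1, m2, probe, sentinel = NULL) {
  n <- length(probe)
  sentinel <- sentinel %||% (is.na(m1) & is.na(m2))
  if (length(m1) != n || length(m2) != n || length(sentinel) != n)
    stop("m1, m2, probe, sentinel must have equal length")
  dev_mean <- (m1 + m2) / 2
  meas <- !sentinel
  if (any(meas & (is.na(m1) | is.na(m2))))
    stop("non-sentinel rows must have both device measurements")
  if (any(meas & dev_mean == 0))
    stop(sprintf("zero device mean for non-sentinel item(s): %s",
                 paste(which(meas & dev_mean == 0), collapse = ", ")))
  s <- p <- cv <- numeric(n)
  s[meas] <- abs(dev_mean[meas] - probe[meas]) / dev_mean[meas]
  p[meas] <- abs(m1[meas] - m2[meas]) /
    pmin(abs(m1[meas]), abs(m2[meas]))
  cv[meas] <- (abs(m1[meas] - m2[meas]) / sqrt(2)) / dev_mean[meas]
  agreement_report(data.frame(m1 = m1, m2 = m2, probe = probe,
                              sentinel = sentinel, rel_error = s,
                              precision = p, cv = cv),
                   list(accuracy_pct = 100 * (1 - mean(s)),
                        precision_pct = 100 * (1 - mean(p)),
                        mean_cv_pct = 100 * mean(abs(cv))),
                   "signed rel_error=|mean-probe|/mean; sentinel rows -> 0")
}

as_groups <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("id", "value") %in% names(groups)))
    groups <- split(groups$value, groups$id)
  }
  if (!is.list(groups) || !length(groups)) stop("need a nonempty group list")
  lapply(groups, as.numeric)
}

#' Precision of repeated measurements (groups of 2 or more)
#'
#' Per group, the relative spread `g_i = (max - min) / min`, defined as 0
#' when all values are 0 (a wound with no such tissue, measured as none every
#' time); `precision_pct = 100 (1 - mean g_i)`. A group whose minimum is 0
#' but maximum is not has an undefined ratio and raises an error. For
#' two-value groups this is identical to [paired_precision()]'s
#' reproducibility.
#'
#' @param groups List of numeric vectors (>= 2 nonnegative values each), or a
#'   data frame with columns `id` and `value`.
#' @return An `agreement_report` with `precision_pct`.
#' @export
repeated_precision <- function(groups) {
  groups <- as_groups(groups)
  g <- vapply(seq_along(groups), function(i) {
    v <- groups[[i]]
    if (length(v) < 2) stop(sprintf("group '%s' has fewer than 2 values",
                                    names(groups)[i] %||% i))
    if (any(v < 0)) stop("values must be nonnegative")
    if (min(v) == 0) {
      if (max(v) > 0)
        stop(sprintf("group '%s': min is 0 with max > 0 (undefined ratio)",
                     names(groups)[i] %||% i))
      return(0)
    }
    (max(v) - min(v)) / min(v)
  }, numeric(1))
  agreement_report(data.frame(id = names(groups) %||% seq_along(groups),
                              spread = g),
                   list(precision_pct = 100 * (1 - mean(g))),
                   "spread=(max-min)/min; all-zero group -> 0")
}

#' Mean coefficient of variation across repeated-measurement groups
#'
#' Per group, the sample (n-1) standard deviation over the mean; an all-zero
#' group contributes 0.
#'
#' @inheritParams repeated_precision
#' @return An `agreement_report` with `mean_cv_pct`.
#' @export
group_cv <- function(groups) {
  groups <- as_groups(groups)
  cv <- vapply(seq_along(groups), function(i) {
    v <- groups[[i]]
    if (length(v) < 2) stop(sprintf("group '%s' has fewer than 2 values",
                                    names(groups)[i] %||% i))
    if (all(v == 0)) return(0)
    if (mean(v) == 0) stop(sprintf("group '%s': zero mean with nonzero sd",
                                   names(groups)[i] %||% i))
    sd(v) / mean(v)
  }, numeric(1))
  agreement_report(data.frame(id = names(groups) %||% seq_along(groups),
                              cv = cv),
                   list(mean_cv_pct = 100 * mean(cv)),
                   "cv=sample_sd/mean; all-zero group -> 0")
}

#' Per-wound agreement between two tissue percentages
#'
#' The smaller of the two percentages divided by the larger; two zeros agree
#' perfectly (1.0).
#'
#' @param a,b Nonnegative percentages (vectorized).
#' @return Agreement ratio(s) in [0, 1].
#' @export
fraction_agreement <- function(a, b) {
  if (any(a < 0) || any(b < 0)) stop("percentages must be >= 0")
  ifelse(a == 0 & b == 0, 1, pmin(a, b) / pmax(a, b))
}

#' Binary tissue-presence evaluation
#'
#' Per-class accuracy of categorical presence calls: each image carries one
#' true class and one predicted class from `{other, slough, necrosis}`;
#' accuracy per class is the fraction of that class's images predicted
#' correctly, and the total predictions routed to each class are tabulated.
#'
#' @param truth,predicted Character vectors of per-image classes.
#' @param classes Allowed class labels.
#' @return An object of class `binary_eval_table`: data frame with
#'   `class`, `n_images`, `n_correct`, `accuracy_pct`, `total_predicted`.
#' @export
binary_eval <- function(truth, predicted,
                        classes = c("other", "slough", "necrosis")) {
  if (length(truth) != length(predicted) || !length(truth))
    stop("truth and predicted must be nonempty and aligned")
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad))
    stop(sprintf("label(s) outside the class set: %s",
                 paste(bad, collapse = ", ")))
  out <- data.frame(
    class = classes,
    n_images = vapply(classes, function(k) sum(truth == k), numeric(1)),
    n_correct = vapply(classes, function(k)
      sum(truth == k & predicted == k), numeric(1)),
    total_predicted = vapply(classes, function(k) sum(predicted == k),
                             numeric(1)),
    row.names = NULL)
  out$accuracy_pct <- 100 * out$n_correct / pmax(out$n_images, 1)
  structure(out, class = c("binary_eval_table", "data.frame"))
}

#' Binary evaluation from published per-class counts
#'
#' @param n_images Images per true class.
#' @param n_correct Correct predictions per true class.
#' @param classes Class labels.
#' @param total_predicted Optional predictions routed to each class.
#' @return A `binary_eval_table`.
#' @export
binary_eval_counts <- function(n_images, n_correct,
                               classes = c("other", "slough", "necrosis"),
                               total_predicted = NA) {
  if (any(n_correct > n_images)) stop("n_correct cannot exceed n_images")
  out <- data.frame(class = classes, n_images = n_images,
                    n_correct = n_correct,
                    total_predicted = total_predicted,
                    accuracy_pct = 100 * n_correct / pmax(n_images, 1),
                    row.names = NULL)
  structure(out, class = c("binary_eval_table", "data.frame"))
}

#' Bundled clinical-evaluation fixture tables
#'
#' Measurement tables transcribed from the device's clinical and bench
#' validation: surface-area accuracy pairs (device vs planimetry),
#' surface-area repeated pairs, depth vs probe (with sentinel rows),
#' binary tissue-call counts, per-wound tissue percentages (device vs
#' planimetry), and repeated tissue percentages.
#'
#' @param name One of `"area_accuracy"`, `"area_precision"`, `"depth"`,
#'   `"binary"`, `"tissue_accuracy"`, `"tissue_precision"`.
#' @return The table as a data frame.
#' @export
eval_table <- function(name = c("area_accuracy", "area_precision", "depth",
                                "binary", "tissue_accuracy",
                                "tissue_precision")) {
  name <- match.arg(name)
  file <- switch(name,
                 area_accuracy = "table2.csv", area_precision = "table3.csv",
                 depth = "table4.csv", binary = "table5.csv",
                 tissue_accuracy = "table6.csv",
                 tissue_precision = "table7.csv")
  path <- system.file("extdata", file, package = "woundlidar")
  if (path == "") stop("fixture table not found: ", file)
  read.csv(path, stringsAsFactors = FALSE)
}
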