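#' Confusion counts from aligned prediction and observation vectors
#'
#' @param predicted,observed Equal-length vectors of 0/1 (or logical);
#'   positive = 1.
#' @return A list of class `confusion_counts` with fields `TP`, `TN`, `FP`,
#'   `FN`.
#' @export
confusion <- function(predicted, observed) {
  predicted <- as.integer(predicted)
  observed <- as.integer(observed)
  if (length(predicted) != length(observed))
    stop("`predicted` and `observed` must have equal length", call. = FALSE)
  if (length(predicted) &&
      (!all(predicted %in% 0:1) || !all(observed %in% 0:1)))
    stop("labels must be 0/1", call. = FALSE)
  structure(list(TP = sum(predicted == 1L & observed == 1L),
                 TN = sum(predicted == 0L & observed == 0L),
                 FP = sum(predicted == 1L & observed == 0L),
                 FN = sum(predicted == 0L & observed == 1L)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d TN=%d FP=%d FN=%d\n",
              x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

#' Classification metrics
#'
#' Accuracy is (TP+TN)/(TP+TN+FP+FN); the F1 score is TP/\[TP+(FP+FN)/2\];
#' precision is TP/(TP+FP); sensitivity is TP/(TP+FN). A metric whose
#' denominator is zero is undefined and reported as `NA` — precision, for
#' instance, is undefined when there are no positive predictions at all.
#'
#' @param c A [confusion()] result.
#' @return A proportion in \[0,1\], or `NA_real_` when undefined.
#' @export
accuracy <- function(c) {
  tot <- c$TP + c$TN + c$FP + c$FN
  if (tot == 0) NA_real_ else (c$TP + c$TN) / tot
}

#' @rdname accuracy
#' @export
f1 <- function(c) {
  den <- c$TP + 0.5 * (c$FP + c$FN)
  if (den == 0) NA_real_ else c$TP / den
}

#' @rdname accuracy
#' @export
precision <- function(c) {
  if (c$TP + c$FP == 0) NA_real_ else c$TP / (c$TP + c$FP)
}

#' @rdname accuracy
#' @export
sensitivity <- function(c) {
  if (c$TP + c$FN == 0) NA_real_ else c$TP / (c$TP + c$FN)
}

#' All four metrics at once
#'
#' @param c A [confusion()] result.
#' @return Named numeric vector `accuracy`, `f1`, `precision`,
#'   `sensitivity` (with `NA` for undefined entries).
#' @export
metric_report <- function(c) {
  c(accuracy = accuracy(c), f1 = f1(c),
    precision = precision(c), sensitivity = sensitivity(c))
}

#' Summarize replicate metrics into a learning curve
#'
#' Aggregates a long-format table of per-replicate metric values into per
#' (model, trait, training-size, metric) means and standard errors over
#' replicates. SEM is the sample standard deviation divided by the square
#' root of the replicate count, and is `NA` with fewer than two replicates.
#' By default a cell where any replicate's metric is undefined is reported
#' as missing, matching how undefined precision is usually displayed on
#' learning curves; `na_rm = TRUE` instead averages the defined replicates.
#'
#' @param metrics Tibble with columns `model`, `trait`, `n_train`,
#'   `replicate`, `metric`, `value` (as emitted by [run_replicates()]).
#' @param na_rm Average over defined replicates instead of blanking the
#'   cell.
#' @return A tibble with columns `model`, `trait`, `n_train`, `metric`,
#'   `mean`, `sem`, `n_replicates`.
#' @export
summarize_curve <- function(metrics, na_rm = FALSE) {
  need <- c("model", "trait", "n_train", "metric", "value")
  stopifnot(all(need %in% names(metrics)))
  key <- interaction(metrics$model, metrics$trait, metrics$n_train,
                     metrics$metric, drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(seq_len(nrow(metrics)), key), function(i) {
    v <- metrics$value[i]
    any_na <- anyNA(v)
    if (na_rm) v <- v[!is.na(v)]
    n <- length(v)
    m <- if (n == 0L || (!na_rm && any_na)) NA_real_ else mean(v)
    s <- if (n >= 2L && !is.na(m)) stats::sd(v) / sqrt(n) else NA_real_
    tibble::tibble(model = metrics$model[i[1]], trait = metrics$trait[i[1]],
                   n_train = metrics$n_train[i[1]],
                   metric = metrics$metric[i[1]],
                   mean = m, sem = s, n_replicates = length(i))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$model, out$trait, out$n_train, out$metric), ]
}

#' Completeness of another trait source relative to a reference
#'
#' How much of a reference set of trait-positive species another source
#' covers, as a percentage. By default the raw count ratio
#' `100 * n_other / n_reference` is reported, which is how database
#' completeness is usually quoted (the other source's count over ours);
#' `intersect = TRUE` instead counts only species present in both sets
#' (case-folded exact name match).
#'
#' @param reference Character vector of reference positive species names.
#' @param other Character vector of the other source's positive species
#'   names.
#' @param intersect Count only the overlap.
#' @return A percentage (may exceed 100 in ratio mode if the other source
#'   lists more species).
#' @export
completeness <- function(reference, other, intersect = FALSE) {
  reference <- unique(tolower(reference))
  other <- unique(tolower(other))
  if (length(reference) == 0L)
    stop("reference positive set is empty", call. = FALSE)
  n <- if (intersect) length(base::intersect(other, reference))
       else length(other)
  100 * n / length(reference)
}
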