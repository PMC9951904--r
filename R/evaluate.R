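#' Pixelwise confusion counts between predicted and true masks
#'
#' @param pred,truth Binary masks ([binary_mask] or 0/1 matrices) of equal
#'   shape.
#' @return A `confusion_counts` object: `TP`, `FP`, `TN`, `FN` (their sum is
#'   the number of pixels compared).
#' @export
confusion <- function(pred, truth) {
  p <- as_pixel_matrix_or_array(pred)
  g <- as_pixel_matrix_or_array(truth)
  if (!all(dim(p) == dim(g)))
    stop("confusion: shapes differ", call. = FALSE)
  if (!all(p %in% c(0, 1)) || !all(g %in% c(0, 1)))
    stop("confusion: masks must be binary", call. = FALSE)
  structure(list(TP = sum(p == 1 & g == 1), FP = sum(p == 1 & g == 0),
                 TN = sum(p == 0 & g == 0), FN = sum(p == 0 & g == 1)),
            class = "confusion_counts")
}

#' Accuracy, recall and precision from confusion counts
#'
#' `AC = (TP+TN)/(TP+TN+FP+FN)`, `RE = TP/(TP+FN)`, `PR = TP/(TP+FP)`.
#' A zero denominator yields 0 with the `"degenerate"` attribute set (e.g.
#' recall on an empty truth mask).
#'
#' @param c A `confusion_counts` object.
#' @return Fraction in `[0, 1]`.
#' @export
accuracy <- function(c) {
  tot <- c$TP + c$TN + c$FP + c$FN
  if (tot == 0) return(structure(0, degenerate = TRUE))
  (c$TP + c$TN) / tot
}

#' @rdname accuracy
#' @export
recall <- function(c) {
  den <- c$TP + c$FN
  if (den == 0) return(structure(0, degenerate = TRUE))
  c$TP / den
}

#' @rdname accuracy
#' @export
precision <- function(c) {
  den <- c$TP + c$FP
  if (den == 0) return(structure(0, degenerate = TRUE))
  c$TP / den
}

dice_from_counts <- function(c) {
  den <- 2 * c$TP + c$FP + c$FN
  if (den == 0) return(structure(1, degenerate = TRUE))
  2 * c$TP / den
}

jaccard_from_counts <- function(c) {
  den <- c$TP + c$FP + c$FN
  if (den == 0) return(structure(1, degenerate = TRUE))
  c$TP / den
}

#' Dice similarity coefficient
#'
#' `DSC = 2|P intersect G| / (|P| + |G|)`. When both masks are empty the
#' degenerate convention `DSC = 1` applies (flagged with attribute
#' `degenerate`), so liver-free slices do not poison averages.
#'
#' @param pred,truth Binary masks of equal shape.
#' @return Fraction in `[0, 1]`.
#' @export
dice <- function(pred, truth) dice_from_counts(confusion(pred, truth))

#' Dice loss, `1 - DSC`
#' @inheritParams dice
#' @return Fraction in `[0, 1]`.
#' @export
dice_loss <- function(pred, truth) 1 - dice(pred, truth)

#' Jaccard similarity coefficient (IoU)
#'
#' `JSC = |P intersect G| / |P union G|`; related to Dice by
#' `DSC = 2 JSC / (1 + JSC)`. Both-empty masks give 1 (flagged).
#'
#' @inheritParams dice
#' @return Fraction in `[0, 1]`.
#' @export
jaccard <- function(pred, truth) jaccard_from_counts(confusion(pred, truth))

#' Full metric report for one predicted/true mask pair
#'
#' @param pred,truth Binary masks of equal shape.
#' @param prob Optional probability map for the BCE entry.
#' @return A one-row data frame with columns `accuracy`, `recall`,
#'   `precision`, `dice`, `jaccard`, `dice_loss` and (if `prob` given)
#'   `bce`.
#' @export
metric_report <- function(pred, truth, prob = NULL) {
  cc <- confusion(pred, truth)
  out <- data.frame(accuracy = as.numeric(accuracy(cc)),
                    recall = as.numeric(recall(cc)),
                    precision = as.numeric(precision(cc)),
                    dice = as.numeric(dice_from_counts(cc)),
                    jaccard = as.numeric(jaccard_from_counts(cc)),
                    dice_loss = 1 - as.numeric(dice_from_counts(cc)))
  if (!is.null(prob)) out$bce <- bce_loss(prob, truth)
  out
}

#' Aggregate per-slice (or per-patient) metric reports
#'
#' Arithmetic mean and population standard deviation per metric, with a
#' percentage formatting helper matching the conventional
#' `"97.86 +/- 4.65"` reporting style.
#'
#' @param reports Data frame of per-unit metric rows (as from
#'   [metric_report()], row-bound), or a list of such one-row frames.
#' @return A data frame with one row per metric: `metric`, `mean`, `sd`
#'   (population), `formatted` (percent, two decimals).
#' @export
aggregate_metrics <- function(reports) {
  if (is.list(reports) && !is.data.frame(reports))
    reports <- do.call(rbind, reports)
  if (!nrow(reports)) stop("aggregate_metrics: empty report list", call. = FALSE)
  num <- reports[vapply(reports, is.numeric, logical(1))]
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  data.frame(metric = names(num),
             mean = vapply(num, mean, numeric(1)),
             sd = vapply(num, pop_sd, numeric(1)),
             formatted = vapply(num, function(x)
               sprintf("%.2f ± %.2f", 100 * mean(x), 100 * pop_sd(x)),
               character(1)),
             row.names = NULL)
}

#' Evaluate a directory pair of predicted and truth masks
#'
#' Matches PNG files by name between the two directories, computes the
#' per-slice metric suite and returns slice rows plus the aggregate.
#'
#' @param pred_dir,truth_dir Directories of single-channel PNG masks with
#'   matching file names.
#' @return List with `per_slice` (data frame, one row per file) and
#'   `summary` (from [aggregate_metrics()]).
#' @export
evaluate_masks <- function(pred_dir, truth_dir) {
  files <- intersect(list.files(pred_dir, pattern = "\\.png$"),
                     list.files(truth_dir, pattern = "\\.png$"))
  if (!length(files))
    stop("evaluate_masks: no matching PNG mask files", call. = FALSE)
  rows <- lapply(files, function(f) {
    p <- read_mask_png(file.path(pred_dir, f))
    g <- read_mask_png(file.path(truth_dir, f))
    cbind(data.frame(unit = f), metric_report(p, g))
  })
  per_slice <- do.call(rbind, rows)
  list(per_slice = per_slice,
       summary = aggregate_metrics(per_slice[-1]))
}
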