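#' @name metrics
#' @title Standard confusion-matrix evaluation metrics
#'
#' @description
#' The metrics classifiers are conventionally scored with, all computed from a
#' 2x2 confusion matrix: prediction accuracy (PA), true/false positive rates
#' and specificity, the Matthews correlation coefficient (MCC), the F1 score,
#' Cohen's kappa, and Youden's J. These are provided as the comparison
#' baseline for the Bayes-factor evidence in [min_log_bayes_factor()]; none of
#' them depends on the test-set size once the cell proportions are fixed,
#' which is precisely their limitation.
#'
#' A metric whose defining ratio has a zero denominator is *undefined* and
#' returned as `NA_real_` (serialized as `null` in JSON reports) — an
#' informative outcome, not an error. Only an empty matrix raises.
#'
#' The mapping of cells to TP/TN/FP/FN requires choosing which true class is
#' "positive". The default `positive = 2` designates the second row (the
#' patient class under the conventional H/P ordering). PA and kappa do not
#' depend on this choice; MCC and Youden's J are invariant under it; the
#' rates swap (TPR with SPC) and F1 changes.
#'
#' @param cm A [confusion_matrix()] object.
#' @param positive Which true-class row (1 or 2) is the positive class.
NULL

# TP/TN/FP/FN under the positive-row convention
cm_cells <- function(cm, positive = 2L) {
  assert_cm(cm)
  if (!positive %in% c(1L, 2L)) stop("positive must be 1 or 2", call. = FALSE)
  z <- cm$z
  if (positive == 2L)
    list(tp = z[2L, 2L], tn = z[1L, 1L], fp = z[1L, 2L], fn = z[2L, 1L])
  else
    list(tp = z[1L, 1L], tn = z[2L, 2L], fp = z[2L, 1L], fn = z[1L, 2L])
}

ratio_or_na <- function(num, den) if (den == 0) NA_real_ else num / den

#' @rdname metrics
#' @return `prediction_accuracy()`: the fraction of correctly classified
#'   examples, `(m - e)/m`.
#' @export
prediction_accuracy <- function(cm) {
  assert_cm(cm)
  (cm$m - cm$e) / cm$m
}

#' @rdname metrics
#' @return `class_rates()`: named vector `c(tpr =, fpr =, spc =)`; any rate
#'   with an empty margin is `NA`.
#' @export
class_rates <- function(cm, positive = 2L) {
  k <- cm_cells(cm, positive)
  c(tpr = ratio_or_na(k$tp, k$tp + k$fn),
    fpr = ratio_or_na(k$fp, k$fp + k$tn),
    spc = ratio_or_na(k$tn, k$fp + k$tn))
}

#' @rdname metrics
#' @return `mcc()`: the Matthews correlation coefficient in \[-1, 1\], `NA`
#'   when any of the four margin factors is zero.
#' @export
mcc <- function(cm, positive = 2L) {
  k <- cm_cells(cm, positive)
  den2 <- (k$tp + k$fp) * (k$tp + k$fn) * (k$tn + k$fp) * (k$tn + k$fn)
  if (den2 == 0) return(NA_real_)
  (k$tp * k$tn - k$fp * k$fn) / sqrt(den2)
}

#' @rdname metrics
#' @return `f1_score()`: `2 TP / (2 TP + FP + FN)`, `NA` when the denominator
#'   is zero (no example is positive in truth or prediction).
#' @export
f1_score <- function(cm, positive = 2L) {
  k <- cm_cells(cm, positive)
  ratio_or_na(2 * k$tp, 2 * k$tp + k$fp + k$fn)
}

#' Chance-expected agreement rPA
#'
#' The agreement rate expected if predictions were drawn independently with
#' the observed marginal frequencies; the reference point of Cohen's kappa.
#'
#' @inheritParams metrics
#' @export
random_pa <- function(cm) {
  k <- cm_cells(cm, 2L)
  ((k$tn + k$fp) * (k$tn + k$fn) + (k$fn + k$tp) * (k$fp + k$tp)) / cm$m^2
}

#' @rdname metrics
#' @return `cohen_kappa()`: `(PA - rPA)/(1 - rPA)`, `NA` when `rPA = 1`.
#' @export
cohen_kappa <- function(cm) {
  rpa <- random_pa(cm)
  if (rpa == 1) return(NA_real_)
  (prediction_accuracy(cm) - rpa) / (1 - rpa)
}

#' @rdname metrics
#' @return `youden_j()`: `TPR + SPC - 1`, `NA` when either rate is undefined.
#' @export
youden_j <- function(cm, positive = 2L) {
  r <- class_rates(cm, positive)
  unname(r["tpr"] + r["spc"] - 1)
}

#' All standard metrics for one confusion matrix
#'
#' @inheritParams metrics
#' @return A `metric_report` list with elements `pa`, `tpr`, `fpr`, `spc`,
#'   `mcc`, `f1`, `kappa`, `rpa`, `youden_j`; undefined metrics are `NA`.
#' @export
metric_report <- function(cm, positive = 2L) {
  r <- class_rates(cm, positive)
  structure(
    list(pa = prediction_accuracy(cm),
         tpr = unname(r["tpr"]), fpr = unname(r["fpr"]), spc = unname(r["spc"]),
         mcc = mcc(cm, positive),
         f1 = f1_score(cm, positive),
         kappa = cohen_kappa(cm),
         rpa = random_pa(cm),
         youden_j = youden_j(cm, positive)),
    class = "metric_report")
}

#' @export
print.metric_report <- function(x, digits = 4, ...) {
  v <- vapply(unclass(x), function(u) round(u, digits), numeric(1))
  out <- format(v, nsmall = 0)
  out[is.na(v)] <- "undefined"
  cat(paste0(format(names(v), width = 9), " ", out, collapse = "\n"), "\n")
  invisible(x)
}
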