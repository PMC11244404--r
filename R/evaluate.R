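#' Confusion matrix for RH/ND predictions
#'
#' RH (road hypnosis) is the positive class.
#'
#' @param y_true,y_pred Equal-length character vectors of RH/ND labels.
#' @return List of class \code{confusion_matrix}: integer counts
#'   \code{TP}, \code{TN}, \code{FP}, \code{FN}.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("label vectors differ in length (", length(y_true), " vs ",
         length(y_pred), ")", call. = FALSE)
  }
  ok <- c("RH", "ND")
  if (!all(y_true %in% ok) || !all(y_pred %in% ok)) {
    stop("labels must be 'RH' or 'ND'", call. = FALSE)
  }
  structure(list(
    TP = sum(y_true == "RH" & y_pred == "RH"),
    TN = sum(y_true == "ND" & y_pred == "ND"),
    FP = sum(y_true == "ND" & y_pred == "RH"),
    FN = sum(y_true == "RH" & y_pred == "ND")),
    class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2,
              dimnames = list(truth = c("RH", "ND"),
                              predicted = c("RH", "ND")))
  print(m)
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' ACC = (TP+TN)/n, SEN = TP/(TP+FN), SPE = TN/(TN+FP),
#' GM = sqrt(SEN * SPE). A metric whose denominator is zero is reported as
#' \code{NA} ("undefined"), never silently as 0. \code{gm_form =
#' "product"} returns the literal product SEN * SPE instead of the
#' geometric mean, for auditing against reports that print the product.
#'
#' @param cm A \code{\link{confusion}} result (or a list with TP/TN/FP/FN).
#' @param gm_form \code{"sqrt"} (geometric mean, default) or
#'   \code{"product"}.
#' @return List of class \code{metric_report}: \code{ACC}, \code{SEN},
#'   \code{SPE}, \code{GM}, all fractions in [0, 1], plus the counts.
#' @export
metrics <- function(cm, gm_form = c("sqrt", "product")) {
  gm_form <- match.arg(gm_form)
  n <- cm$TP + cm$TN + cm$FP + cm$FN
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  sen <- div(cm$TP, cm$TP + cm$FN)
  spe <- div(cm$TN, cm$TN + cm$FP)
  gm <- if (is.na(sen) || is.na(spe)) NA_real_
        else if (gm_form == "sqrt") sqrt(sen * spe) else sen * spe
  structure(list(ACC = (cm$TP + cm$TN) / n, SEN = sen, SPE = spe, GM = gm,
                 counts = cm, gm_form = gm_form),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("ACC %.2f%%  SEN %.2f%%  SPE %.2f%%  GM %.2f%%\n",
              100 * x$ACC, 100 * x$SEN, 100 * x$SPE, 100 * x$GM))
  invisible(x)
}

#' Rank models by accuracy
#'
#' @param reports Named list of \code{\link{metrics}} results (names =
#'   model labels), all computed on the same test split.
#' @return Data frame sorted by decreasing ACC (stable: ties keep the
#'   input order) with columns model, ACC, SEN, SPE, GM.
#' @export
compare_models <- function(reports) {
  if (length(reports) < 2) stop("need at least two reports", call. = FALSE)
  ns <- vapply(reports, function(r) {
    cm <- r$counts; cm$TP + cm$TN + cm$FP + cm$FN
  }, 0)
  if (length(unique(ns)) != 1) {
    stop("reports cover different test-set sizes; refusing to rank",
         call. = FALSE)
  }
  d <- data.frame(model = names(reports),
                  ACC = vapply(reports, `[[`, 0, "ACC"),
                  SEN = vapply(reports, `[[`, 0, "SEN"),
                  SPE = vapply(reports, `[[`, 0, "SPE"),
                  GM = vapply(reports, `[[`, 0, "GM"),
                  row.names = NULL)
  d[order(-d$ACC), , drop = FALSE]
}
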