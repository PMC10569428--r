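# AAMI evaluation metrics: per-class one-vs-rest sensitivity, specificity
# and positive predictive value, plus overall accuracy, from a multi-class
# confusion matrix.

#' Confusion matrix of true vs predicted classes
#'
#' @param truth,estimate Equal-length vectors of class labels; pairs where
#'   either is \code{NA} (PAD positions) are dropped.
#' @param classes Class levels (rows = truth, columns = prediction).
#' @return A \code{C x C} integer matrix of counts.
#' @export
#' @examples
#' confusion(c("N", "V", "N"), c("N", "V", "V"), c("N", "V"))
confusion <- function(truth, estimate, classes = aami_classes()) {
  keep <- !is.na(truth) & !is.na(estimate)
  truth <- truth[keep]; estimate <- estimate[keep]
  bad <- setdiff(unique(c(truth, estimate)), classes)
  if (length(bad)) stop("labels outside the class set: ", paste(bad, collapse = ", "))
  m <- table(factor(truth, levels = classes), factor(estimate, levels = classes))
  matrix(as.integer(m), length(classes), length(classes),
         dimnames = list(truth = classes, estimate = classes))
}

#' One-vs-rest metrics for a single class
#'
#' Treating class \code{cls} as positive: \code{TP} is its diagonal entry,
#' \code{FN} the rest of its row, \code{FP} the rest of its column, and
#' \code{TN} the remainder, giving \code{SEN = TP/(TP+FN)},
#' \code{PPV = TP/(TP+FP)} and \code{SPEC = TN/(TN+FP)}.  A metric with a
#' zero denominator is returned as \code{NaN} (flagged, not silently
#' zeroed).
#'
#' @param cm Confusion matrix from [confusion()].
#' @param cls Class name (a row/column of \code{cm}).
#' @return Named list with \code{tp}, \code{fn}, \code{fp}, \code{tn},
#'   \code{sen}, \code{spec}, \code{ppv} and \code{undefined} (character
#'   vector naming any zero-denominator metrics).
#' @export
class_metrics <- function(cm, cls) {
  i <- match(cls, rownames(cm))
  if (is.na(i)) stop("unknown class: ", cls)
  tp <- cm[i, i]
  fn <- sum(cm[i, ]) - tp
  fp <- sum(cm[, i]) - tp
  tn <- sum(cm) - tp - fn - fp
  ratio <- function(num, den) if (den == 0) NaN else num / den
  out <- list(tp = tp, fn = fn, fp = fp, tn = tn,
              sen = ratio(tp, tp + fn),
              spec = ratio(tn, tn + fp),
              ppv = ratio(tp, tp + fp))
  out$undefined <- c("sen", "spec", "ppv")[is.nan(c(out$sen, out$spec, out$ppv))]
  out
}

#' Overall accuracy
#'
#' The default (\code{"multiclass"}) is the plain correct fraction,
#' \code{trace(cm) / sum(cm)}.  \code{"macro_ovr"} instead averages the
#' one-vs-rest accuracies \code{(TP+TN)/(TP+TN+FP+FN)} over classes — the
#' literal per-class formula — which is larger for imbalanced data.
#'
#' @param cm Confusion matrix.
#' @param method \code{"multiclass"} (default) or \code{"macro_ovr"}.
#' @return Accuracy as a fraction in [0, 1].
#' @export
overall_acc <- function(cm, method = c("multiclass", "macro_ovr")) {
  method <- match.arg(method)
  if (sum(cm) == 0) stop("empty confusion matrix")
  if (method == "multiclass") return(sum(diag(cm)) / sum(cm))
  mean(vapply(rownames(cm), function(cl) {
    m <- class_metrics(cm, cl)
    (m$tp + m$tn) / sum(cm)
  }, numeric(1)))
}

#' Per-class evaluation report
#'
#' Builds the standard report table: overall accuracy plus per-class SEN,
#' SPEC and PPV in AAMI class order.  Class Q is customarily excluded from
#' headline comparison tables because of its tiny sample size; set
#' \code{include_q = FALSE} to drop it from the table (it still counts
#' toward the confusion matrix and overall accuracy).
#'
#' @param truth,estimate Label vectors (or a data frame via the
#'   \code{data} argument).
#' @param data Optional data frame holding the label columns; if supplied,
#'   \code{truth} and \code{estimate} are column names (default
#'   \code{"label"}, \code{".pred_class"}, matching [predict.mwcaps_fit()]).
#' @param classes Class levels.
#' @param include_q Keep class Q rows in the table?
#' @return An object of class \code{aami_report}: list with the confusion
#'   matrix, the per-class metrics tibble and overall accuracy.
#' @export
#' @examples
#' eval_report(c("N", "V", "N", "S"), c("N", "V", "N", "N"))
eval_report <- function(truth = "label", estimate = ".pred_class",
                        data = NULL, classes = aami_classes(),
                        include_q = TRUE) {
  if (!is.null(data)) {
    truth <- data[[truth]]
    estimate <- data[[estimate]]
  }
  cm <- confusion(truth, estimate, classes)
  metrics <- purrr::map_dfr(classes, function(cl) {
    m <- class_metrics(cm, cl)
    tibble::tibble(class = cl, n = m$tp + m$fn, sen = m$sen, spec = m$spec,
                   ppv = m$ppv)
  })
  if (!include_q) metrics <- dplyr::filter(metrics, .data$class != "Q")
  structure(
    list(confusion = cm, metrics = metrics,
         acc = overall_acc(cm), n = sum(cm)),
    class = "aami_report"
  )
}

# two-decimal percent with half-even (banker's) rounding
percent2 <- function(x) {
  ifelse(is.nan(x), "--", sprintf("%.2f", round(100 * x, 2)))
}

#' @export
print.aami_report <- function(x, ...) {
  cat("AAMI evaluation (", x$n, " beats)  ACC ", percent2(x$acc), "%\n",
      sep = "")
  tab <- dplyr::mutate(x$metrics,
                       dplyr::across(c("sen", "spec", "ppv"), percent2))
  print.data.frame(as.data.frame(tab), row.names = FALSE)
  invisible(x)
}

#' Write / read an evaluation report as CSV
#'
#' The CSV holds one row per class (columns \code{class}, \code{n},
#' \code{sen}, \code{spec}, \code{ppv}) plus a final \code{ACC} row; values
#' are fractions, not percentages, so the file round-trips exactly.
#'
#' @param report An [eval_report()].
#' @param path Output path.
#' @return \code{write_report_csv()} returns \code{path} invisibly;
#'   \code{read_report_csv()} returns a tibble.
#' @export
write_report_csv <- function(report, path) {
  tab <- dplyr::bind_rows(
    report$metrics,
    tibble::tibble(class = "ACC", n = report$n, sen = NA_real_,
                   spec = NA_real_, ppv = report$acc)
  )
  readr::write_csv(tab, path)
  invisible(path)
}

#' @rdname write_report_csv
#' @export
read_report_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(class = "c"))
}

# ---- broom-style methods ---------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an evaluation report
#'
#' @param x An \code{aami_report}.
#' @param ... Unused.
#' @return One row per class and metric: \code{class}, \code{metric},
#'   \code{value}.
#' @method tidy aami_report
#' @export
tidy.aami_report <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, c("sen", "spec", "ppv"),
                      names_to = "metric", values_to = "value")
}

#' @rdname tidy.aami_report
#' @method glance aami_report
#' @export
glance.aami_report <- function(x, ...) {
  tibble::tibble(n = x$n, acc = x$acc,
                 macro_sen = mean(x$metrics$sen, na.rm = TRUE),
                 macro_ppv = mean(x$metrics$ppv, na.rm = TRUE))
}

#' Tidy a model fit (per-epoch loss history)
#'
#' @param x An \code{mwcaps_fit}.
#' @param ... Unused.
#' @method tidy mwcaps_fit
#' @export
tidy.mwcaps_fit <- function(x, ...) x$history

#' @rdname tidy.mwcaps_fit
#' @method glance mwcaps_fit
#' @export
glance.mwcaps_fit <- function(x, ...) {
  tibble::tibble(variant = x$model$config$variant,
                 n_params = x$model$n_params,
                 epochs = nrow(x$history),
                 final_loss = utils::tail(x$history$loss, 1),
                 n_train_beats = x$n_train_beats)
}

# ---- plots -----------------------------------------------------------------

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an evaluation report
#'
#' Heatmap of the (row-normalised) confusion matrix with count labels.
#'
#' @param object An \code{aami_report}.
#' @param ... Unused.
#' @method autoplot aami_report
#' @export
autoplot.aami_report <- function(object, ...) {
  cm <- object$confusion
  df <- tibble::tibble(
    truth = factor(rep(rownames(cm), ncol(cm)), levels = rev(rownames(cm))),
    estimate = factor(rep(colnames(cm), each = nrow(cm)), levels = colnames(cm)),
    n = as.vector(cm),
    frac = as.vector(cm / pmax(1L, rowSums(cm)))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$estimate, .data$truth, fill = .data$frac)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8",
                                 limits = c(0, 1), name = "row fraction") +
    ggplot2::labs(x = "predicted class", y = "true class",
                  title = sprintf("ACC %s%%", percent2(object$acc)))
}

#' Plot a training-loss history
#'
#' @param object An \code{mwcaps_fit}.
#' @param ... Unused.
#' @method autoplot mwcaps_fit
#' @export
autoplot.mwcaps_fit <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "epoch", y = "mean masked cross-entropy",
                  title = object$model$config$variant)
}

#' Plot synthetic or extracted beats by class
#'
#' Overlays a few beats per class, one facet per AAMI class present.
#'
#' @param beats A beats tibble.
#' @param max_per_class Beats drawn per class.
#' @export
plot_beats <- function(beats, max_per_class = 5L) {
  df <- beats |>
    dplyr::filter(!is.na(.data$label)) |>
    dplyr::group_by(.data$label) |>
    dplyr::slice_head(n = max_per_class) |>
    dplyr::ungroup() |>
    dplyr::mutate(beat = dplyr::row_number()) |>
    tidyr::unnest_longer("samples", values_to = "amplitude", indices_to = "sample")
  ggplot2::ggplot(df, ggplot2::aes(.data$sample, .data$amplitude,
                                   group = .data$beat)) +
    ggplot2::geom_line(alpha = 0.6, linewidth = 0.3) +
    ggplot2::facet_wrap(~label) +
    ggplot2::labs(x = "sample (of 280)", y = "normalized amplitude")
}
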