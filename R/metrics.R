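#' Default cortical metric panel
#'
#' The twelve vertex-wise metrics the pipeline was designed around: six
#' surface-morphometry ("structural") metrics and six resting-state BOLD
#' derivatives ("functional") metrics. The pipeline itself is agnostic to the
#' metric names; this panel is the default for the synthetic generator and the
#' pair-group summaries.
#'
#' @return A tibble with columns `metric` and `class`
#'   (`"structural"` or `"functional"`).
#' @examples
#' default_metrics()
#' @export
default_metrics <- function() {
  tibble::tibble(
    metric = c("vol", "area", "thick", "curv", "lgi", "sulc",
               "alff", "falff", "dc", "ec", "reho", "reho2"),
    class = rep(c("structural", "functional"), each = 6L)
  )
}

#' Metric class lookup
#'
#' @param metrics Character vector of metric names.
#' @param classes Optional named character vector mapping metric name to class;
#'   defaults to the panel in [default_metrics()].
#' @return Character vector of classes aligned with `metrics`.
#' @keywords internal
metric_class_of <- function(metrics, classes = NULL) {
  if (is.null(classes)) {
    d <- default_metrics()
    classes <- stats::setNames(d$class, d$metric)
  }
  unknown <- setdiff(metrics, names(classes))
  if (length(unknown) > 0) {
    rlang::abort(paste0("No class assigned for metric(s): ",
                        paste(unknown, collapse = ", ")))
  }
  unname(classes[metrics])
}
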