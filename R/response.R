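#' A measured person-visit response
#'
#' Bundles one OGTT's measured plasma series, the overlapping CGM trace, and
#' the subject context.  The t = 0 rows are retained here but are routed to
#' the model as inputs, never as fitted data points.
#'
#' @param id Response identifier (string).
#' @param ogtt Data frame with columns `time`, `glucose`, `insulin`
#'   (min, mmol/L, mU/L).  Missing samples are absent rows or `NA` values.
#' @param context A [subject_context()].
#' @param cgm Optional data frame with columns `time`, `glucose` for the
#'   interstitial trace on its 5-min grid; `NULL` when no CGM file exists.
#' @return An object of class `subject_response`.
#' @export
subject_response <- function(id, ogtt, context, cgm = NULL) {
  stopifnot(is.data.frame(ogtt),
            all(c("time", "glucose", "insulin") %in% names(ogtt)),
            inherits(context, "subject_context"))
  if (!is.null(cgm))
    stopifnot(is.data.frame(cgm), all(c("time", "glucose") %in% names(cgm)))
  structure(list(id = as.character(id),
                 ogtt = as_tibble(ogtt),
                 cgm = if (is.null(cgm)) NULL else as_tibble(cgm),
                 context = context),
            class = "subject_response")
}

#' @export
print.subject_response <- function(x, ...) {
  cat("<subject_response> ", x$id, "\n",
      "  OGTT samples: ", sum(stats::complete.cases(x$ogtt)), "\n",
      "  CGM samples:  ", if (is.null(x$cgm)) 0 else nrow(x$cgm), "\n",
      sep = "")
  invisible(x)
}
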