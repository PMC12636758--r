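#' WHO bone-health classes
#'
#' Ordered class labels used throughout the package: `normal`,
#' `osteopenia`, `osteoporosis`.
#'
#' @return Character vector of the three class labels.
#' @export
who_classes <- function() {
  c("normal", "osteopenia", "osteoporosis")
}

#' Classify a DXA T-score into its WHO bone-health category
#'
#' Applies the WHO densitometric criteria: normal for T > -1, osteopenia
#' for -2.5 < T <= -1, osteoporosis for T <= -2.5. The boundary values -1
#' and -2.5 belong to osteopenia and osteoporosis respectively.
#'
#' @param tscore Numeric vector of T-scores (standard deviations from the
#'   young-healthy reference mean).
#' @return Factor with levels `normal`, `osteopenia`, `osteoporosis`.
#' @examples
#' classify_who(c(0.05, -1.63, -4.19))
#' classify_who(c(-1, -2.5)) # boundary values
#' @export
classify_who <- function(tscore) {
  if (!is.numeric(tscore)) {
    stop("`tscore` must be numeric", call. = FALSE)
  }
  if (any(!is.finite(tscore))) {
    stop("`tscore` contains non-finite values", call. = FALSE)
  }
  cls <- ifelse(tscore > -1, "normal",
    ifelse(tscore > -2.5, "osteopenia", "osteoporosis")
  )
  factor(cls, levels = who_classes())
}
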