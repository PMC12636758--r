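#' Quantify one Raman band
#'
#' Quantifies a band inside its window after subtracting the linear
#' chord between the window endpoints (a local background estimate).
#' `height` is the maximum of the chord-corrected signal; `area` its
#' trapezoidal integral. The chord correction makes both quantifiers
#' insensitive to residual linear background but slightly underestimates
#' wide peaks whose wings reach the window edges; the bias is a fixed
#' property of the quantifier and cancels in group comparisons.
#'
#' @param spectrum A `bundle_spectrum` or `clean_spectrum`.
#' @param band One row of a [bone_bands()]-style table (needs `center`,
#'   `half_window`).
#' @param quantifier `"height"` (default) or `"area"`.
#' @return The band quantity (counts, or counts * cm^-1 for area).
#' @export
band_intensity <- function(spectrum, band,
                           quantifier = c("height", "area")) {
  quantifier <- match.arg(quantifier)
  x <- spectrum$shift_cm
  y <- spectrum$intensity
  idx <- which(x >= band$center - band$half_window &
    x <= band$center + band$half_window)
  if (length(idx) < 3) {
    stop("band window around ", band$center, " cm^-1 is empty", call. = FALSE)
  }
  xs <- x[idx]
  ys <- y[idx]
  k <- length(idx)
  chord <- ys[1] + (ys[k] - ys[1]) * (xs - xs[1]) / (xs[k] - xs[1])
  d <- ys - chord
  if (quantifier == "height") {
    max(d)
  } else {
    sum(diff(xs) * (d[-k] + d[-1]) / 2)
  }
}

#' Normalize a spectrum to its phosphate band
#'
#' Divides the spectrum by the PO4 band quantity so that the phosphate
#' band quantity of the output equals 1; all band ratios are invariant
#' under this rescaling.
#'
#' @param spectrum A `clean_spectrum` (or `bundle_spectrum`).
#' @param bands Band table ([bone_bands()]); the `PO4` row defines the
#'   reference.
#' @param quantifier Passed to [band_intensity()].
#' @return The normalized spectrum (baseline and noise sd, if present,
#'   are rescaled consistently).
#' @export
normalize_to_phosphate <- function(spectrum, bands = bone_bands(),
                                   quantifier = "height") {
  po4 <- bands[bands$band == "PO4", ]
  if (nrow(po4) != 1) stop("`bands` must contain one PO4 row", call. = FALSE)
  q <- band_intensity(spectrum, po4, quantifier)
  if (!is.finite(q) || q <= 0) {
    stop("nonpositive phosphate signal; spectrum unusable", call. = FALSE)
  }
  spectrum$intensity <- spectrum$intensity / q
  if (!is.null(spectrum$baseline)) spectrum$baseline <- spectrum$baseline / q
  if (!is.null(spectrum$sigma_noise)) {
    spectrum$sigma_noise <- spectrum$sigma_noise / q
  }
  spectrum$meta$po4_quantity <- q
  spectrum
}

#' Compute the five diagnostic band ratios of one spectrum
#'
#' PO4/CO3, PO4/AmideIII, PO4/CH2, PO4/AmideI and CO3/AmideIII, computed
#' from chord-corrected band quantities. Ratios are invariant under any
#' positive rescaling of the spectrum. A nonpositive denominator yields
#' NA with a warning.
#'
#' @param spectrum A `clean_spectrum`.
#' @param bands Band table ([bone_bands()]).
#' @param quantifier Passed to [band_intensity()].
#' @return One-row data frame: `specimen_id`, `offset_mm`, and one
#'   column per ratio (named `PO4_CO3`, `PO4_AmideIII`, `PO4_CH2`,
#'   `PO4_AmideI`, `CO3_AmideIII`).
#' @export
compute_ratio_set <- function(spectrum, bands = bone_bands(),
                              quantifier = "height") {
  q <- vapply(
    seq_len(nrow(bands)),
    function(i) band_intensity(spectrum, bands[i, ], quantifier), 0
  )
  names(q) <- bands$band
  defs <- ratio_definitions()
  vals <- numeric(nrow(defs))
  for (i in seq_len(nrow(defs))) {
    den <- q[[defs$den[i]]]
    if (!is.finite(den) || den <= 0) {
      warning("nonpositive ", defs$den[i], " band; ", defs$ratio[i],
        " set to NA",
        call. = FALSE
      )
      vals[i] <- NA_real_
    } else {
      vals[i] <- q[[defs$num[i]]] / den
    }
  }
  out <- data.frame(
    specimen_id = spectrum$meta$specimen_id %||% NA_character_,
    offset_mm = spectrum$offset_mm,
    stringsAsFactors = FALSE
  )
  out[gsub("/", "_", defs$ratio)] <- as.list(vals)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Star annotation of a p-value
#'
#' Maps p-values to the conventional annotation: p <= 0.0001 `****`,
#' p <= 0.001 `***`, p <= 0.01 `**`, p <= 0.05 `*`, otherwise `ns`
#' (bounds inclusive).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Character vector of annotations.
#' @examples
#' significance_stars(c(0.0386, 0.0007, 0.05, 0.2))
#' @export
significance_stars <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  ifelse(p <= 1e-4, "****",
    ifelse(p <= 1e-3, "***",
      ifelse(p <= 0.01, "**",
        ifelse(p <= 0.05, "*", "ns")
      )
    )
  )
}

#' Pairwise WHO-group comparisons of band ratios
#'
#' For every ratio column and each of the three class pairs (N-OP,
#' N-OPE, OPE-OP), runs a two-sided two-sample test: Mann-Whitney U
#' (mid-rank ties convention; exact when sample sizes permit and no ties
#' are present) or Welch's t. With `correction = "bonferroni"` p-values
#' are multiplied by the number of pairs tested per ratio and capped at
#' 1.
#'
#' @param ratios Data frame from rbinding [compute_ratio_set()] rows,
#'   plus a `who_class` column.
#' @param method `"wilcox"` (default) or `"welch"`.
#' @param correction `"bonferroni"` (default) or `"none"`.
#' @return Data frame with `ratio`, `pair`, `p_value`, `stars`.
#' @export
pairwise_group_tests <- function(ratios,
                                 method = c("wilcox", "welch"),
                                 correction = c("bonferroni", "none")) {
  method <- match.arg(method)
  correction <- match.arg(correction)
  if (!"who_class" %in% names(ratios)) {
    stop("`ratios` needs a who_class column", call. = FALSE)
  }
  pairs <- list(
    "N-OP" = c("normal", "osteoporosis"),
    "N-OPE" = c("normal", "osteopenia"),
    "OPE-OP" = c("osteopenia", "osteoporosis")
  )
  ratio_cols <- gsub("/", "_", ratio_definitions()$ratio)
  ratio_cols <- intersect(ratio_cols, names(ratios))
  if (!length(ratio_cols)) stop("no ratio columns found", call. = FALSE)
  rows <- list()
  for (rc in ratio_cols) {
    for (pn in names(pairs)) {
      g1 <- ratios[[rc]][ratios$who_class == pairs[[pn]][1]]
      g2 <- ratios[[rc]][ratios$who_class == pairs[[pn]][2]]
      g1 <- g1[is.finite(g1)]
      g2 <- g2[is.finite(g2)]
      if (length(g1) < 2 || length(g2) < 2) {
        warning("comparison ", rc, " ", pn,
          " skipped: a group has fewer than 2 members",
          call. = FALSE
        )
        next
      }
      p <- if (method == "wilcox") {
        suppressWarnings(wilcox.test(g1, g2, exact = NULL)$p.value)
      } else {
        t.test(g1, g2)$p.value
      }
      if (correction == "bonferroni") p <- min(1, length(pairs) * p)
      rows[[length(rows) + 1]] <- data.frame(
        ratio = gsub("_", "/", rc), pair = pn, p_value = p,
        stars = significance_stars(p), stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(NULL)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
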