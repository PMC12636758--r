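#' Specification of a synthetic cadaver cohort
#'
#' Defines the statistical structure of a simulated donor cohort: class
#' composition, per-class T-score distributions (truncated to the WHO
#' interval of each class so labels and scores never conflict), and the
#' link between T-score and the band amplitudes of the two bone layers.
#'
#' The generative model for band `b` in layer `l` of a specimen with
#' T-score `t` is
#' \deqn{A_{b,l} = a_b (1 + \kappa_l \beta_b (t_{ref} - t)) (1 + \eta) + \epsilon_{b,l}}
#' where `a_b` is the band's baseline amplitude, `beta_b` its link slope
#' (`link_slope` column of `bands`; zero for phosphate, whose amplitude is
#' the fixed reference), `kappa_l` the layer link strength (1 for the
#' subcortical layer, `surface_link` for the surface cortex, encoding that
#' disease-related compositional change is stronger at depth), `eta` a
#' per-specimen biological heterogeneity factor shared by all linked bands
#' (sd `matrix_sd`), and `epsilon` independent per-band noise (sd
#' `residual_sd * a_b`). Lower T-score therefore raises matrix-band
#' amplitudes relative to phosphate.
#'
#' @param n_per_class Named integer vector of donors per WHO class;
#'   default `c(normal = 8, osteopenia = 6, osteoporosis = 11)`.
#' @param tscore_mean,tscore_sd Named numeric vectors of per-class T-score
#'   means and SDs. Defaults are the distal 1/3-radius values of the
#'   emulated cohort: 0.05 +/- 0.45, -1.63 +/- 0.38, -4.19 +/- 0.90.
#' @param bands Band table as [bone_bands()]; its `base_amplitude` and
#'   `link_slope` columns drive the generator.
#' @param t_ref Reference T-score at which linked bands take their
#'   baseline amplitude (default 0, the young-healthy reference).
#' @param surface_link Link strength of the surface cortex relative to the
#'   subcortical layer (default 0.3).
#' @param matrix_sd SD of the shared per-specimen heterogeneity factor
#'   (default 0.06).
#' @param residual_sd Relative SD of independent per-band amplitude noise
#'   (default 0.035).
#' @param subsurface_weights Named vector mapping collection offset (mm)
#'   to the subcortical layer weight; weights of the two layers sum to 1
#'   at every offset. Default `c("0" = 0.2, "3" = 0.5, "6" = 0.6)`.
#' @param fluor_amplitude Median fluorescence background amplitude
#'   (counts) at the low-shift end of the axis (default 3000).
#' @param fluor_sd Lognormal sd of the per-specimen fluorescence amplitude
#'   (default 0.3).
#' @param fluor_shape Polynomial coefficients (constant first) of the
#'   baseline shape over the axis rescaled to \[-1, 1\]; must be positive
#'   over that interval.
#' @param axis_jitter_sd SD (cm^-1) of the per-specimen band-position
#'   jitter (default 0.2).
#' @param seed Integer RNG seed; a fixed seed makes the generated cohort
#'   bitwise reproducible. `NULL` draws from the current RNG stream.
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_per_class = c(normal = 8, osteopenia = 6, osteoporosis = 11),
                        tscore_mean = c(normal = 0.05, osteopenia = -1.63, osteoporosis = -4.19),
                        tscore_sd = c(normal = 0.45, osteopenia = 0.38, osteoporosis = 0.90),
                        bands = bone_bands(),
                        t_ref = 0,
                        surface_link = 0.3,
                        matrix_sd = 0.06,
                        residual_sd = 0.035,
                        subsurface_weights = c("0" = 0.2, "3" = 0.5, "6" = 0.6),
                        fluor_amplitude = 3000,
                        fluor_sd = 0.3,
                        fluor_shape = c(1, -0.35, 0.10, 0.05),
                        axis_jitter_sd = 0.2,
                        seed = NULL) {
  cls <- names(n_per_class)
  if (is.null(cls) || !all(cls %in% who_classes())) {
    stop("`n_per_class` must be named with WHO classes (",
      paste(who_classes(), collapse = ", "), ")",
      call. = FALSE
    )
  }
  if (any(n_per_class < 1)) {
    stop("each included class needs at least one donor", call. = FALSE)
  }
  if (!all(cls %in% names(tscore_mean)) || !all(cls %in% names(tscore_sd))) {
    stop("`tscore_mean`/`tscore_sd` must cover every class in `n_per_class`",
      call. = FALSE
    )
  }
  if (any(tscore_sd < 0) || matrix_sd < 0 || residual_sd < 0 ||
    fluor_sd < 0 || axis_jitter_sd < 0) {
    stop("all standard deviations must be >= 0", call. = FALSE)
  }
  if (any(bands$base_amplitude <= 0)) {
    stop("band base amplitudes must be positive", call. = FALSE)
  }
  w <- subsurface_weights
  if (any(w < 0 | w > 1)) {
    stop("subsurface weights must lie in [0, 1]", call. = FALSE)
  }
  u <- seq(-1, 1, length.out = 101)
  if (any(polyval(fluor_shape, u) <= 0)) {
    stop("`fluor_shape` must be positive over [-1, 1]", call. = FALSE)
  }
  structure(
    list(
      n_per_class = n_per_class, tscore_mean = tscore_mean,
      tscore_sd = tscore_sd, bands = bands, t_ref = t_ref,
      surface_link = surface_link, matrix_sd = matrix_sd,
      residual_sd = residual_sd, subsurface_weights = w,
      fluor_amplitude = fluor_amplitude, fluor_sd = fluor_sd,
      fluor_shape = fluor_shape, axis_jitter_sd = axis_jitter_sd,
      seed = seed
    ),
    class = "cohort_spec"
  )
}

# WHO class -> admissible (open/closed per classify_who) T-score interval.
who_interval <- function(class) {
  switch(class,
    normal = c(-1, Inf),
    osteopenia = c(-2.5, -1),
    osteoporosis = c(-Inf, -2.5),
    stop("unknown WHO class: ", class, call. = FALSE)
  )
}

# Inverse-CDF draw from N(mu, sd) truncated to (lo, hi]; rejection guard
# keeps the label consistent at interval boundaries.
rtrunc_norm <- function(n, mu, sd, lo, hi, class) {
  t <- qnorm(runif(n, pnorm(lo, mu, sd), pnorm(hi, mu, sd)), mu, sd)
  bad <- which(as.character(classify_who(t)) != class)
  for (i in bad) {
    for (k in 1:100) {
      t[i] <- qnorm(runif(1, pnorm(lo, mu, sd), pnorm(hi, mu, sd)), mu, sd)
      if (as.character(classify_who(t[i])) == class) break
    }
  }
  t
}

#' Generate a synthetic cadaver cohort with known ground truth
#'
#' Draws one specimen per donor according to a [cohort_spec()]: a T-score
#' from the class's truncated normal distribution, band amplitudes for the
#' surface-cortex and subcortical layers via the amplitude link model, a
#' per-specimen fluorescence background, and a small band-position jitter.
#'
#' @param spec A [cohort_spec()].
#' @return A list of `ground_truth_specimen` objects (class
#'   `bone_cohort`), each with `specimen_id`, `who_class`, `tscore`,
#'   `layer_amplitudes` (bands x layers matrix), `fluorescence_coeffs`
#'   and `axis_jitter`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(seed = 1))
#' length(cohort)
#' cohort_table(cohort)[1:3, ]
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    stop("`spec` must be a cohort_spec", call. = FALSE)
  }
  with_seed(spec$seed, {
    classes <- rep(names(spec$n_per_class), spec$n_per_class)
    bands <- spec$bands
    linked <- bands$link_slope > 0
    kappa <- c(surface = spec$surface_link, subcortical = 1)
    specimens <- vector("list", length(classes))
    for (i in seq_along(classes)) {
      cl <- classes[i]
      iv <- who_interval(cl)
      t_i <- rtrunc_norm(
        1, spec$tscore_mean[[cl]], spec$tscore_sd[[cl]],
        iv[1], iv[2], cl
      )
      eta <- rnorm(1, 0, spec$matrix_sd)
      amp <- sapply(kappa, function(k) {
        a <- bands$base_amplitude * (1 + k * bands$link_slope * (spec$t_ref - t_i))
        a[linked] <- a[linked] * (1 + eta)
        a + rnorm(nrow(bands), 0, spec$residual_sd * bands$base_amplitude)
      })
      amp <- pmax(amp, 1e-6)
      rownames(amp) <- bands$band
      f0 <- spec$fluor_amplitude *
        exp(rnorm(1, 0, spec$fluor_sd) - spec$fluor_sd^2 / 2)
      shape <- spec$fluor_shape
      jshape <- shape
      if (length(shape) >= 2) {
        jshape[2] <- shape[2] * (1 + rnorm(1, 0, 0.1))
      }
      u <- seq(-1, 1, length.out = 101)
      if (any(polyval(jshape, u) <= 0)) jshape <- shape
      specimens[[i]] <- structure(
        list(
          specimen_id = sprintf("S%02d", i),
          who_class = cl,
          tscore = t_i,
          layer_amplitudes = amp,
          fluorescence_coeffs = f0 * jshape,
          axis_jitter = rnorm(1, 0, spec$axis_jitter_sd)
        ),
        class = "ground_truth_specimen"
      )
    }
    structure(specimens, class = "bone_cohort", spec = spec)
  })
}

#' Tabulate a synthetic cohort's metadata
#'
#' @param cohort A `bone_cohort` from [generate_cohort()].
#' @return Data frame with `specimen_id`, `who_class`, `tscore`.
#' @export
cohort_table <- function(cohort) {
  data.frame(
    specimen_id = vapply(cohort, `[[`, "", "specimen_id"),
    who_class = vapply(cohort, `[[`, "", "who_class"),
    tscore = vapply(cohort, `[[`, 0, "tscore"),
    stringsAsFactors = FALSE
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic SORS bone cohort specification\n")
  cat(
    " donors:",
    paste(sprintf("%s=%d", names(x$n_per_class), x$n_per_class), collapse = ", "),
    "\n"
  )
  cat(
    " T-score:",
    paste(sprintf(
      "%s %.2f+/-%.2f", names(x$n_per_class),
      x$tscore_mean[names(x$n_per_class)], x$tscore_sd[names(x$n_per_class)]
    ), collapse = ", "), "\n"
  )
  cat(
    " subsurface weights:",
    paste(sprintf("%smm=%.2f", names(x$subsurface_weights), x$subsurface_weights),
      collapse = ", "
    ), "\n"
  )
  invisible(x)
}
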