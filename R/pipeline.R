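#' Configuration of the full SORS bone analysis pipeline
#'
#' Collects every stage's configuration with the processing constants at
#' their standard values (5 replicate frames, 499 spectral pixels,
#' baseline order 7 with 10 iterations at 0.05% convergence, 10-MAD
#' cosmic threshold, PLS ranks 1-9).
#'
#' @param seed Global RNG seed for the run.
#' @param cohort A [cohort_spec()] (its `seed` defaults to the global
#'   one at run time if unset).
#' @param detector A [detector_spec()].
#' @param layout A [bundle_layout()].
#' @param offsets Offsets (mm) to simulate and process.
#' @param pls_offsets Offsets for which a LOOCV-PLSR report is built
#'   (default 0 and 3 mm).
#' @param cosmic A [cosmic_ray_config()].
#' @param fluorescence A [fluorescence_config()].
#' @param bands Band table ([bone_bands()]).
#' @param quantifier Band quantifier, `"height"` or `"area"`.
#' @param test_method,correction Passed to [pairwise_group_tests()].
#' @param ranks Candidate PLS ranks (default 1:9).
#' @param per_fold_rank Per-fold rank selection (default FALSE).
#' @param normalize_predictors Use phosphate-normalized spectra as PLSR
#'   predictors (default TRUE).
#' @param n_frames Replicate frames per site (default 5).
#' @param noise_window Signal-free window (cm^-1) for the noise-floor
#'   estimate.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            cohort = cohort_spec(),
                            detector = detector_spec(),
                            layout = bundle_layout(),
                            offsets = c(0, 3, 6),
                            pls_offsets = c(0, 3),
                            cosmic = cosmic_ray_config(),
                            fluorescence = fluorescence_config(),
                            bands = bone_bands(),
                            quantifier = "height",
                            test_method = "wilcox",
                            correction = "bonferroni",
                            ranks = 1:9,
                            per_fold_rank = FALSE,
                            normalize_predictors = TRUE,
                            n_frames = 5,
                            noise_window = c(1750, 1800)) {
  if (!all(as.character(offsets) %in% names(layout$rows))) {
    stop("every requested offset needs bundle rows in `layout`", call. = FALSE)
  }
  if (!all(pls_offsets %in% offsets)) {
    stop("`pls_offsets` must be a subset of `offsets`", call. = FALSE)
  }
  structure(
    list(
      seed = seed, cohort = cohort, detector = detector, layout = layout,
      offsets = offsets, pls_offsets = pls_offsets, cosmic = cosmic,
      fluorescence = fluorescence, bands = bands, quantifier = quantifier,
      test_method = test_method, correction = correction, ranks = ranks,
      per_fold_rank = per_fold_rank,
      normalize_predictors = normalize_predictors,
      n_frames = n_frames, noise_window = noise_window
    ),
    class = "pipeline_config"
  )
}

#' Run the full SORS bone analysis pipeline
#'
#' Executes the fixed stage order on a synthetic cohort: instrument
#' calibration (rectification fit, axis calibration, response model)
#' from a rendered calibration set; per-specimen frame simulation; frame
#' processing (dark subtraction, rectification, response correction,
#' bundle extraction); spectral cleanup (cosmic-ray rejection, frame
#' averaging, fluorescence removal, noise-floor clipping, phosphate
#' normalization); band ratios with pairwise WHO-group statistics; and a
#' LOOCV-PLSR T-score report per requested offset. Identical config and
#' seed give identical results.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory; when given, spectra, ratio
#'   and comparison tables, prediction tables, `metrics.json` and
#'   `manifest.json` are written there.
#' @return Object of class `sors_run`: `cohort` (metadata table),
#'   `axis`, `spectra` (per specimen/offset `clean_spectrum`s),
#'   `ratios`, `comparisons` (per offset), `cv` (per PLS offset),
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t_start <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(label, t0) {
    timings[[label]] <<- round(proc.time()[["elapsed"]] - t0, 3)
  }
  cohort_spec_ <- config$cohort
  if (is.null(cohort_spec_$seed)) cohort_spec_$seed <- config$seed
  det <- config$detector
  layout <- config$layout

  with_seed(config$seed, {
    # --- calibration -----------------------------------------------------
    t0 <- proc.time()[["elapsed"]]
    calib <- generate_calibration_set(det)
    rmap <- fit_rectification(calib)
    rect <- lapply(
      calib[c("neon", "acetaminophen", "white", "glass")],
      function(fr) apply_rectification(dark_subtract(fr, calib$dark), rmap)
    )
    axis <- calibrate_axis(
      rect$neon, calib$neon_lines_visible,
      rect$acetaminophen, calib$acetaminophen_shifts_visible
    )
    resp <- response_model(rect$white, rect$glass, calib$glass_certified, axis)
    tick("calibration_s", t0)

    # --- cohort and frame processing ------------------------------------
    t0 <- proc.time()[["elapsed"]]
    cohort <- generate_cohort(cohort_spec_)
    taxis <- true_axis(det)
    offsets <- config$offsets
    spectra <- list()
    ratio_rows <- list()
    for (sp in cohort) {
      clean <- lapply(offsets, function(off) {
        render_clean_spectrum(sp, off, taxis,
          bands = cohort_spec_$bands,
          weights = cohort_spec_$subsurface_weights
        )
      })
      frames <- render_frame_stack(clean, sp, det, layout, config$n_frames)
      per_off <- lapply(offsets, function(off) {
        matrix(0, config$n_frames, det$crop_length)
      })
      names(per_off) <- as.character(offsets)
      for (k in seq_along(frames)) {
        fr <- apply_response(
          apply_rectification(dark_subtract(frames[[k]], calib$dark), rmap),
          resp
        )
        ex <- extract_bundle_spectra(fr, layout, axis)
        for (key in names(per_off)) {
          per_off[[key]][k, ] <- ex[[key]]$intensity
        }
      }
      for (key in names(per_off)) {
        st <- frame_stack(per_off[[key]], axis$shift_cm, as.numeric(key),
          meta = list(specimen_id = sp$specimen_id)
        )
        st <- reject_cosmic_rays(st, config$cosmic)
        avg <- average_frames(st)
        avg$meta$specimen_id <- sp$specimen_id
        cl <- remove_fluorescence(avg, config$fluorescence)
        cl <- clip_to_noise_floor(cl, window = config$noise_window)
        cl <- normalize_to_phosphate(cl, config$bands, config$quantifier)
        spectra[[paste0(sp$specimen_id, "_", key, "mm")]] <- cl
        rr <- compute_ratio_set(cl, config$bands, config$quantifier)
        rr$who_class <- sp$who_class
        rr$tscore <- sp$tscore
        ratio_rows[[length(ratio_rows) + 1]] <- rr
      }
    }
    ratios <- do.call(rbind, ratio_rows)
    tick("processing_s", t0)

    # --- group statistics ------------------------------------------------
    t0 <- proc.time()[["elapsed"]]
    n_specimens <- length(cohort)
    comparisons <- list()
    if (min(table(factor(ratios$who_class, who_classes()))) >= 2) {
      for (off in offsets) {
        comparisons[[paste0(off, "mm")]] <- pairwise_group_tests(
          ratios[ratios$offset_mm == off, ],
          method = config$test_method, correction = config$correction
        )
      }
    } else {
      warning("group statistics skipped: a WHO class has fewer than 2 specimens",
        call. = FALSE
      )
    }
    tick("statistics_s", t0)

    # --- PLSR ------------------------------------------------------------
    t0 <- proc.time()[["elapsed"]]
    cv <- list()
    tab <- cohort_table(cohort)
    if (n_specimens >= 3) {
      for (off in config$pls_offsets) {
        key <- paste0("_", off, "mm")
        X <- do.call(rbind, lapply(tab$specimen_id, function(id) {
          s <- spectra[[paste0(id, key)]]
          if (config$normalize_predictors) {
            s$intensity
          } else {
            s$intensity * s$meta$po4_quantity
          }
        }))
        cv[[paste0(off, "mm")]] <- loocv_select_rank(
          X, tab$tscore,
          ranks = config$ranks, per_fold = config$per_fold_rank
        )
      }
    } else {
      warning("LOOCV-PLSR skipped: fewer than 3 specimens", call. = FALSE)
    }
    tick("plsr_s", t0)

    manifest <- list(
      package = "sorsbone",
      version = as.character(packageVersion("sorsbone")),
      seed = config$seed,
      n_specimens = n_specimens,
      offsets = offsets,
      lambda0_nm = axis$lambda0_nm,
      axis_residual_cm = axis$residual_cm,
      config_hash = config_hash(config),
      timings = as.list(timings),
      total_s = round(proc.time()[["elapsed"]] - t_start, 3)
    )
    run <- structure(
      list(
        cohort = tab, axis = axis, spectra = spectra, ratios = ratios,
        comparisons = comparisons, cv = cv, manifest = manifest
      ),
      class = "sors_run"
    )
    if (!is.null(out_dir)) write_run(run, out_dir)
    run
  })
}

# Stable md5 of the configuration (serialized to a temp file; timings and
# other run products never enter the hash).
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f, version = 2)
  unname(tools::md5sum(f))
}

write_run <- function(run, out_dir) {
  dir.create(file.path(out_dir, "spectra"),
    recursive = TRUE,
    showWarnings = FALSE
  )
  for (nm in names(run$spectra)) {
    write_spectra(run$spectra[[nm]], file.path(out_dir, "spectra", paste0(nm, ".csv")))
  }
  write.csv(run$ratios, file.path(out_dir, "ratios.csv"), row.names = FALSE)
  for (nm in names(run$comparisons)) {
    write.csv(run$comparisons[[nm]],
      file.path(out_dir, paste0("comparisons_", nm, ".csv")),
      row.names = FALSE
    )
  }
  metrics <- list()
  for (nm in names(run$cv)) {
    cvr <- run$cv[[nm]]
    write.csv(
      data.frame(
        specimen_id = run$cohort$specimen_id,
        measured_t = run$cohort$tscore,
        predicted_t = cvr$predictions,
        true_class = as.character(cvr$true_class),
        predicted_class = as.character(cvr$predicted_class)
      ),
      file.path(out_dir, paste0("predictions_", nm, ".csv")),
      row.names = FALSE
    )
    metrics[[nm]] <- list(
      rmse_cv_per_rank = as.list(cvr$rmse_cv),
      optimal_rank = cvr$optimal_rank,
      pearson_r = cvr$r, rmse_cv = cvr$rmse,
      classification_accuracy = cvr$accuracy
    )
  }
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
    auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(out_dir)
}

#' @export
print.sors_run <- function(x, ...) {
  cat(sprintf(
    "SORS bone analysis run: %d specimens, offsets %s\n",
    nrow(x$cohort), paste(x$manifest$offsets, collapse = "/")
  ))
  for (nm in names(x$cv)) {
    cat(" ", nm, ": ", sep = "")
    print(x$cv[[nm]])
  }
  invisible(x)
}

#' Write a spectrum to CSV
#'
#' Fixed dialect: UTF-8, `.` decimal, header `shift_cm,intensity`, full
#' double precision. [read_spectra()] round-trips exactly.
#'
#' @param spectrum A `bundle_spectrum` or `clean_spectrum`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_spectra <- function(spectrum, path) {
  df <- data.frame(
    shift_cm = formatC(spectrum$shift_cm, format = "g", digits = 17),
    intensity = formatC(spectrum$intensity, format = "g", digits = 17)
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a spectrum from CSV
#'
#' @param path File written by [write_spectra()] (or any CSV with
#'   numeric `shift_cm` and `intensity` columns and a strictly
#'   increasing axis).
#' @param offset_mm Offset tag to attach (default NA).
#' @return A `bundle_spectrum`.
#' @export
read_spectra <- function(path, offset_mm = NA_real_) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0) {
    stop("empty spectrum file: ", path, call. = FALSE)
  }
  df <- read.csv(path, fileEncoding = "UTF-8")
  if (!all(c("shift_cm", "intensity") %in% names(df))) {
    stop("malformed header in ", path,
      ": expected columns shift_cm, intensity",
      call. = FALSE
    )
  }
  if (nrow(df) == 0) stop("no data rows in ", path, call. = FALSE)
  for (col in c("shift_cm", "intensity")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) {
      stop("non-numeric ", col, " at data line ", bad[1], " of ", path,
        call. = FALSE
      )
    }
    df[[col]] <- v
  }
  if (any(!is.finite(df$shift_cm)) || any(diff(df$shift_cm) <= 0)) {
    stop("axis in ", path, " is not strictly increasing", call. = FALSE)
  }
  new_bundle_spectrum(df$shift_cm, df$intensity, offset_mm,
    meta = list(source = path)
  )
}
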