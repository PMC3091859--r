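#' Experiment configuration
#'
#' Assembles and validates the configuration for a full synthetic
#' calibration experiment. Every study-level default (59 samples, 20/39
#' train/validation split, truncation bounds 0.20--4.34 ug/g with target
#' moments 1.69/0.95, 19-band instrument layout, A_max = 10) is a named
#' field and can be overridden.
#'
#' @param n_samples,n_train,n_test cohort size and split.
#' @param conc_mean,conc_sd,conc_range concentration distribution targets.
#' @param height,width phantom size in pixels.
#' @param noise_sd reflectance noise SD.
#' @param a_max largest PLS component count evaluated by LOOCV
#'   (multispectral model; the colour model is capped at 3 variables).
#' @param remove_outliers screen the training pool with
#'   [screen_outliers()] and drop flagged samples from training (they are
#'   kept in the test set untouched)?
#' @param outlier_alpha flagging quantile.
#' @param fat_removal segment and exclude fat before spectrum extraction?
#' @param seed master seed for cohort generation and the train/test split.
#' @return A validated list of class `experiment_config`.
#' @export
experiment_config <- function(n_samples = 59, n_train = 20, n_test = 39,
                              conc_mean = 1.69, conc_sd = 0.95,
                              conc_range = c(0.20, 4.34),
                              height = 60, width = 80, noise_sd = 0.01,
                              a_max = 10, remove_outliers = TRUE,
                              outlier_alpha = 0.975, fat_removal = TRUE,
                              seed = 1) {
  cfg <- list(n_samples = n_samples, n_train = n_train, n_test = n_test,
              conc_mean = conc_mean, conc_sd = conc_sd,
              conc_range = conc_range, height = height, width = width,
              noise_sd = noise_sd, a_max = a_max,
              remove_outliers = remove_outliers,
              outlier_alpha = outlier_alpha, fat_removal = fat_removal,
              seed = seed)
  problems <- character()
  if (n_samples != n_train + n_test) {
    problems <- c(problems, "n_samples must equal n_train + n_test")
  }
  if (conc_range[1] >= conc_range[2]) {
    problems <- c(problems, "conc_range must be ordered")
  }
  if (a_max < 1) problems <- c(problems, "a_max must be >= 1")
  if (noise_sd < 0) problems <- c(problems, "noise_sd must be >= 0")
  if (height < 8 || width < 8) {
    problems <- c(problems, "height/width too small for segmentation")
  }
  if (length(problems)) {
    stop("config error: ", paste(problems, collapse = "; "))
  }
  structure(cfg, class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' @param path YAML file whose keys match [experiment_config()] arguments.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(experiment_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("config error: unknown fields: ", paste(bad, collapse = ", "))
  }
  if (!is.null(vals$conc_range)) vals$conc_range <- as.numeric(vals$conc_range)
  do.call(experiment_config, vals)
}

# one sample through the image pipeline: segmentation -> ROI -> features
.process_sample <- function(ph, fat_removal, obs) {
  seg <- segment_fillet(ph$cube)
  if (fat_removal) {
    seeds <- list(meat = ph$masks$roi$data, fat = ph$masks$fat$data)
    fat <- segment_fat(ph$cube, seg$fillet, seeds)
    roi <- roi_mask(seg$fillet, fat)
  } else {
    roi <- roi_mask(seg$fillet)
  }
  rgb <- cube_to_rgb(ph$cube, obs)
  list(spectrum = extract_mean_spectrum(ph$cube, roi),
       rgb = rgb_mean_features(rgb, roi),
       roi = roi)
}

#' Run the full synthetic calibration experiment
#'
#' Orchestrates the complete workflow: generate a phantom cohort; segment
#' each cube (MNF + Otsu for the fillet, CDA + Otsu for fat); extract one
#' mean spectrum and one mean-sRGB feature triple per sample; split into
#' training and validation sets; screen training spectra for outliers;
#' select the PLS component count by LOOCV; fit and validate both the
#' 19-band multispectral model and the 3-variable sRGB baseline; and
#' report metrics, predictions and the cross-validation curve.
#'
#' @param config an [experiment_config()].
#' @param lib an [endmember_library()].
#' @return A list of class `experiment_report`; see the fields
#'   `cohort`, `outliers`, `multispectral`, `srgb`, `predictions`,
#'   `rmsecv`.
#' @export
run_experiment <- function(config = experiment_config(),
                           lib = endmember_library()) {
  obs <- cie_observer()
  cspec <- cohort_spec(n_samples = config$n_samples,
                       n_train = config$n_train, n_test = config$n_test,
                       conc_mean = config$conc_mean, conc_sd = config$conc_sd,
                       conc_range = config$conc_range,
                       height = config$height, width = config$width,
                       noise_sd = config$noise_sd, seed = config$seed)
  cohort <- generate_cohort(cspec, lib)
  y <- cohort$reference$concentration
  n <- length(y)

  feats <- lapply(cohort$samples, .process_sample,
                  fat_removal = config$fat_removal, obs = obs)
  X <- do.call(rbind, lapply(feats, `[[`, "spectrum"))
  Xrgb <- do.call(rbind, lapply(feats, function(f) unname(f$rgb)))
  colnames(Xrgb) <- c("R", "G", "B")
  rownames(X) <- rownames(Xrgb) <- cohort$reference$sample_id

  set.seed(config$seed + 1000L)
  train <- sort(sample.int(n, config$n_train))
  test <- setdiff(seq_len(n), train)

  flagged <- integer(0)
  if (config$remove_outliers && config$n_train >= 5) {
    scr <- screen_outliers(X[train, , drop = FALSE],
                           alpha = config$outlier_alpha)
    flagged <- train[scr$flagged]
    train_used <- setdiff(train, flagged)
  } else {
    train_used <- train
  }

  fit_branch <- function(Xm, a_cap) {
    a_max <- min(a_cap, ncol(Xm), length(train_used) - 2L)
    cv <- loocv_select(Xm[train_used, , drop = FALSE], y[train_used],
                       a_max = a_max)
    model <- plsr_fit(Xm[train_used, , drop = FALSE], y[train_used],
                      ncomp = cv$ncomp)
    pred <- predict(model, Xm[test, , drop = FALSE])
    list(cv = cv, model = model, pred = pred,
         metrics = prediction_metrics(y[test], pred))
  }
  ms <- fit_branch(X, config$a_max)
  rgbm <- fit_branch(Xrgb, 3L)

  report <- list(
    schema = "astaxmap-report/1",
    config = unclass(config),
    cohort = list(n = n,
                  mean = mean(y), sd = stats::sd(y),
                  min = min(y), max = max(y)),
    split = list(train = train, test = test),
    outliers = flagged,
    rmsecv = ms$cv$rmsecv,
    ncomp = ms$cv$ncomp,
    multispectral = list(r2 = ms$metrics$r2, rmsep = ms$metrics$rmsep,
                         std_error = ms$metrics$std_error,
                         ncomp = ms$cv$ncomp),
    srgb = list(r2 = rgbm$metrics$r2, rmsep = rgbm$metrics$rmsep,
                std_error = rgbm$metrics$std_error,
                ncomp = rgbm$cv$ncomp),
    predictions = data.frame(
      sample_id = cohort$reference$sample_id[test],
      reference = y[test],
      multispectral = unname(ms$pred),
      srgb = unname(rgbm$pred)),
    models = list(multispectral = ms$model, srgb = rgbm$model),
    spectra = X, rgb_features = Xrgb,
    cohort_data = cohort)
  class(report) <- "experiment_report"
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>\n")
  cat(sprintf("  cohort: n = %d, mean %.2f, sd %.2f, range [%.2f, %.2f] ug/g\n",
              x$cohort$n, x$cohort$mean, x$cohort$sd, x$cohort$min,
              x$cohort$max))
  cat(sprintf("  outliers removed from training: %d\n", length(x$outliers)))
  cat(sprintf("  multispectral: A = %d, RMSEP = %.3f, r2 = %.3f\n",
              x$multispectral$ncomp, x$multispectral$rmsep,
              x$multispectral$r2))
  cat(sprintf("  sRGB baseline: A = %d, RMSEP = %.3f, r2 = %.3f\n",
              x$srgb$ncomp, x$srgb$rmsep, x$srgb$r2))
  invisible(x)
}

#' Write an experiment report to JSON
#'
#' Serializes the scalar results, split, RMSECV curve and per-sample
#' predictions (models and raw data are omitted).
#'
#' @param report an `experiment_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- list(schema = report$schema, config = report$config,
              cohort = report$cohort, outliers = report$outliers,
              rmsecv = as.numeric(report$rmsecv), ncomp = report$ncomp,
              multispectral = report$multispectral, srgb = report$srgb,
              predictions = report$predictions)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
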