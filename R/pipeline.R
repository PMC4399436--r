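#' Plan configuration for the verification pipeline
#'
#' Normalizes a configuration list (or JSON file) describing a verification
#' run. Volumes and images may be given either as file paths or as in-memory
#' objects.
#'
#' @param config list or path to a JSON file with elements:
#'   `energy` ("6MV"/"10MV"), `fields` (list of `list(epid=..., fluence=...,
#'   gantry_deg=...)`; each field needs a gantry angle and either a raw EPID
#'   image or a ready fluence map), `density` (path or [volume_grid]),
#'   `planned` (optional planned dose), `structures` (optional named list of
#'   masks or a label volume path plus `structure_names`), `prescribed_Gy`,
#'   `gamma_criteria` (list of `c(dose_pct, dist_mm)` pairs),
#'   `override_to_water` (logical), `epid` (kernel/correction parameters),
#'   `seed`.
#' @return an object of class `plan_config`.
#' @export
plan_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  defaults <- list(energy = "6MV", prescribed_Gy = 66.0,
                   gamma_criteria = list(c(3, 3), c(2, 2)),
                   threshold_pct = 10, override_to_water = FALSE,
                   sad_cm = 100, seed = 1L, epid = list())
  config <- modifyList(defaults, config)
  if (is.null(config$fields) || !length(config$fields))
    stop("plan config needs >= 1 field")
  if (is.null(config$density)) stop("plan config needs a density grid")
  structure(config, class = "plan_config")
}

resolve_volume <- function(x, kind) {
  if (inherits(x, "volume_grid")) return(x)
  if (is.character(x)) return(read_volume(x, kind = kind))
  stop("cannot resolve volume input")
}

resolve_epid <- function(x) {
  if (inherits(x, "epid_image")) return(x)
  stop("EPID field input must be an epid_image (DICOM/TIFF import not bundled)")
}

stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(expr),
                  error = function(e) stop("stage '", name, "' failed: ",
                                           conditionMessage(e), call. = FALSE))
  message(sprintf("[epidose] stage %-12s %6.2f s", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full verification pipeline
#'
#' Chains fluence reconstruction, dose reconstruction, optional
#' water-override, gamma analysis against the planned dose and structure
#' dose-difference metrics / DVHs, and returns (optionally writes) a report.
#'
#' @param config a [plan_config()] (or list / JSON path accepted by it).
#' @param out_dir optional output directory; when given, the dose grid
#'   (NRRD), gamma grids and a JSON report are written there.
#' @return list with `dose` ([volume_grid]), `gamma` (list of
#'   `gamma_result`), `metrics` (list of `dose_diff_report`), `dvh` and
#'   `report` (plain list mirrored to JSON).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- plan_config(config)
  set.seed(config$seed)
  ep <- config$epid
  params <- do.call(kernel_params, ep[names(ep) %in% c("c", "mu_s", "mu_l")])
  cm_args <- ep[names(ep) %in% names(formals(correction_model))]
  corr <- do.call(correction_model, cm_args)

  density <- stage("density", resolve_volume(config$density, "density"))
  structures <- list()
  if (!is.null(config$structures)) {
    if (is.character(config$structures)) {
      labels <- read_volume(config$structures, "generic")
      nms <- config$structure_names
      structures <- lapply(seq_along(nms), function(i)
        structure_mask(labels$values == i, nms[i]))
      names(structures) <- nms
    } else {
      structures <- lapply(names(config$structures), function(nm)
        structure_mask(check_mask(density, config$structures[[nm]]), nm))
      names(structures) <- names(config$structures)
    }
  }
  if (isTRUE(config$override_to_water)) {
    body <- structures[["BODY"]]
    if (is.null(body)) body <- structure_mask(array(TRUE, dim(density$values)),
                                              "BODY")
    density <- override_to_water(density, body)
  }

  fields <- stage("fluence", lapply(config$fields, function(fd) {
    fl <- if (!is.null(fd$fluence)) {
      if (inherits(fd$fluence, "fluence_map")) fd$fluence
      else read_fluence_csv(fd$fluence)
    } else {
      epid_to_fluence(resolve_epid(fd$epid), params, corr,
                      sad_cm = config$sad_cm)
    }
    list(fluence = fl, gantry_deg = fd$gantry_deg)
  }))

  model <- stage("beam_model", {
    bm <- config$beam_model
    if (is.null(bm)) beam_model(config$energy) else bm
  })
  dose <- stage("dose", reconstruct_plan_dose(fields, density, model,
                                              sad_cm = config$sad_cm))

  gamma <- list()
  metrics <- list()
  dvh <- list()
  if (!is.null(config$planned)) {
    planned <- resolve_volume(config$planned, "dose")
    gamma <- stage("gamma", lapply(config$gamma_criteria, function(cr) {
      gamma_3d(planned, dose,
               gamma_criteria(cr[1], cr[2], config$threshold_pct))
    }))
    names(gamma) <- vapply(config$gamma_criteria, function(cr)
      sprintf("%g%%/%gmm", cr[1], cr[2]), character(1))
    if (length(structures)) {
      metrics <- stage("metrics", lapply(structures, function(sm)
        dose_difference_metrics(dose, planned, sm, config$prescribed_Gy)))
      dvh <- lapply(structures, function(sm) compute_dvh(dose, sm))
    }
  }

  report <- list(
    energy = config$energy,
    n_fields = length(fields),
    voxels = dim(dose$values),
    prescribed_Gy = config$prescribed_Gy,
    dose_max = max(dose$values),
    gamma = lapply(gamma, function(g) list(
      dose_crit_pct = g$criteria$dose_crit_pct,
      dist_crit_mm = g$criteria$dist_crit_mm,
      threshold_pct = g$criteria$threshold_pct,
      pass_rate_pct = g$pass_rate_pct,
      n_evaluated = g$n_evaluated)),
    structures = lapply(metrics, function(m) list(
      d_mean_epid = m$d_mean_epid, d_mean_tps = m$d_mean_tps,
      d_max_epid = m$d_max_epid, d_max_tps = m$d_max_tps,
      diff_mean_pct = m$diff_mean_pct, diff_max_pct = m$diff_max_pct)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_volume(dose, file.path(out_dir, "dose.nrrd"))
    for (nm in names(gamma))
      write_volume(gamma[[nm]]$gamma,
                   file.path(out_dir, paste0("gamma_", gsub("[%/]", "", nm),
                                             ".nrrd")))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(dose = dose, gamma = gamma, metrics = metrics, dvh = dvh,
       report = report)
}
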