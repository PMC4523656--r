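#' Study configuration
#'
#' Describes a full variability study: a phantom family, a set of
#' montages, grid resolutions and solver/metric options. Montages whose
#' electrodes are all cephalic run on the layered-sphere head at
#' `voxel_size_head`; montages with an extracephalic reference run on the
#' whole-body phantom at `voxel_size_body`.
#'
#' @param profiles named list of [anthropometry_params()] (default: the
#'   three-member family).
#' @param montages montage names among `"A"`, `"B"`, `"C"`, `"D"`, or a
#'   list of [montage_spec()]s.
#' @param voxel_size_head,voxel_size_body voxel edges in mm (defaults 1
#'   and 2).
#' @param current_mA injected current (default 1).
#' @param solver a [solver_config()].
#' @param tissues tissue names for the descriptive statistics.
#' @param robust_peak see [tissue_descriptive_stats()].
#' @param out_dir optional directory for cached per-case results.
#' @return A `study_config` list.
#' @export
study_config <- function(profiles = default_profiles(),
                         montages = c("A", "B", "C", "D"),
                         voxel_size_head = 1, voxel_size_body = 2,
                         current_mA = 1, solver = solver_config(),
                         tissues = c("brain_grey_matter",
                                     "brain_white_matter", "cerebellum",
                                     "medulla_oblongata", "pons",
                                     "midbrain", "thalamus"),
                         robust_peak = FALSE, out_dir = NULL) {
  stopifnot(length(profiles) >= 1, length(montages) >= 1)
  specs <- lapply(montages, function(mm)
    if (inherits(mm, "montage_spec")) mm else standard_montage(mm))
  if (is.character(montages)) names(specs) <- montages else
    names(specs) <- vapply(specs, `[[`, "", "name")
  structure(list(profiles = profiles, montages = specs,
                 voxel_size_head = voxel_size_head,
                 voxel_size_body = voxel_size_body,
                 current_mA = current_mA, solver = solver,
                 tissues = tissues, robust_peak = robust_peak,
                 out_dir = out_dir),
            class = "study_config")
}

montage_needs_body <- function(spec) {
  any(vapply(spec$electrodes, `[[`, "", "position") %in%
        c("right_arm", "right_tibia"))
}

config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf, version = 2)
  unname(tools::md5sum(tf))
}

#' Run the full variability study
#'
#' For every (phantom, montage) pair: place the electrodes, solve,
#' normalize to the injected current, and compute per-tissue descriptive
#' statistics of |E| and the V70/V50 focality fractions of grey and white
#' matter. Across the family it then computes the coefficient of
#' variability (dB) of the peak and median |E| per (montage, tissue), and
#' runs the Kruskal-Wallis omnibus test (with conditional Mann-Whitney /
#' Bonferroni post hoc) on V70 and on V50, the sampling unit being the
#' (montage x tissue) cell so each family member contributes
#' `length(montages) * 2` values. Fully deterministic: no randomness
#' anywhere in the pipeline.
#'
#' @param config a [study_config()].
#' @return A `study_report`: data frames `stats`, `focality`,
#'   `variability`, `solver_log`, list `tests` (`V70`, `V50`), and
#'   `provenance`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  cache_dir <- NULL
  if (!is.null(config$out_dir)) {
    cache_dir <- file.path(config$out_dir, "cache")
    dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  }
  table <- default_conductivity_table()
  needs_body <- vapply(config$montages, montage_needs_body, TRUE)
  phantoms <- list(head = list(), body = list())
  for (nm in names(config$profiles)) {
    p <- config$profiles[[nm]]
    if (any(!needs_body)) {
      p$voxel_size <- config$voxel_size_head
      phantoms$head[[nm]] <- build_layered_sphere_head(p)
    }
    if (any(needs_body)) {
      p$voxel_size <- config$voxel_size_body
      phantoms$body[[nm]] <- build_body_phantom(p)
    }
  }
  stats_rows <- list(); foc_rows <- list(); log_rows <- list()
  for (mname in names(config$montages)) {
    spec <- config$montages[[mname]]
    spec$injected_current_mA <- config$current_mA
    kind <- if (montage_needs_body(spec)) "body" else "head"
    for (pname in names(config$profiles)) {
      case_id <- paste(pname, mname, sep = "_")
      case_key <- config_hash(list(profile = config$profiles[[pname]],
                                   spec = spec, kind = kind,
                                   vox = c(config$voxel_size_head,
                                           config$voxel_size_body),
                                   solver = config$solver,
                                   robust = config$robust_peak,
                                   tissues = config$tissues))
      cached <- NULL
      if (!is.null(cache_dir)) {
        cf <- file.path(cache_dir, paste0(case_key, ".rds"))
        if (file.exists(cf)) cached <- readRDS(cf)
      }
      if (is.null(cached)) {
        cached <- tryCatch(
          run_case(phantoms[[kind]][[pname]], spec, table, config,
                   pname, mname),
          error = function(e) stop("stage [", case_id, "]: ",
                                   conditionMessage(e), call. = FALSE))
        if (!is.null(cache_dir)) saveRDS(cached, cf, version = 2)
      }
      stats_rows[[case_id]] <- cached$stats
      foc_rows[[case_id]] <- cached$focality
      log_rows[[case_id]] <- cached$log
    }
  }
  stats <- do.call(rbind, c(stats_rows, list(make.row.names = FALSE)))
  focality <- do.call(rbind, c(foc_rows, list(make.row.names = FALSE)))
  solver_log <- do.call(rbind, c(log_rows, list(make.row.names = FALSE)))

  variability <- NULL
  tests <- list(V70 = NULL, V50 = NULL)
  if (length(config$profiles) >= 2) {
    vr <- list()
    for (mname in unique(stats$montage))
      for (ti in unique(stats$tissue))
        for (st in c("peak", "median")) {
          vals <- stats[stats$montage == mname & stats$tissue == ti, st]
          vr[[paste(mname, ti, st)]] <-
            data.frame(montage = mname, tissue = ti, statistic = st,
                       cv_db = cv_db(vals), stringsAsFactors = FALSE)
        }
    variability <- do.call(rbind, c(vr, list(make.row.names = FALSE)))
    for (vv in c("V70", "V50")) {
      groups <- lapply(names(config$profiles), function(pn)
        focality[focality$model == pn, vv])
      names(groups) <- names(config$profiles)
      tests[[vv]] <- kw_with_posthoc(groups)
    }
  }
  structure(list(stats = stats, focality = focality,
                 variability = variability, tests = tests,
                 solver_log = solver_log,
                 provenance = list(
                   config_hash = config_hash(config),
                   package_version =
                     as.character(utils::packageVersion("tdcsfield")),
                   n_models = length(config$profiles),
                   n_montages = length(config$montages))),
            class = "study_report")
}

run_case <- function(phantom, spec, table, config, pname, mname) {
  placed <- place_montage(phantom, spec)
  sol <- tdcs_solve(placed, table, config$solver)
  amp <- sol$E$amplitude
  labels <- placed$volume
  srows <- lapply(config$tissues, function(ti) {
    row <- tissue_descriptive_stats(amp, tissue_mask(labels, ti), ti,
                                    robust_peak = config$robust_peak)
    cbind(data.frame(model = pname, montage = mname,
                     stringsAsFactors = FALSE), row)
  })
  frows <- lapply(c(grey = "brain_grey_matter",
                    white = "brain_white_matter"), function(ti) {
    m <- tissue_mask(labels, ti)
    data.frame(model = pname, montage = mname, tissue = ti,
               V70 = focality_volume_fraction(amp, m, 0.7,
                                              config$robust_peak),
               V50 = focality_volume_fraction(amp, m, 0.5,
                                              config$robust_peak),
               stringsAsFactors = FALSE)
  })
  list(stats = do.call(rbind, c(srows, list(make.row.names = FALSE))),
       focality = do.call(rbind, c(frows, list(make.row.names = FALSE))),
       log = data.frame(model = pname, montage = mname,
                        unknowns = sum(sol$system$unknown),
                        iterations = sol$iterations,
                        relative_residual = sol$relative_residual,
                        provisional_current_mA = sol$provisional_current_mA,
                        achieved_current_mA = sol$achieved_current_mA,
                        stringsAsFactors = FALSE))
}

#' @method print study_report
#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("study_report: %d models x %d montages\n",
              x$provenance$n_models, x$provenance$n_montages))
  cat("\nFocality (V70/V50, % of tissue volume):\n")
  print(format_focality_table(x))
  if (!is.null(x$tests$V70)) {
    cat(sprintf("\nKruskal-Wallis on V70: H = %.3f, p = %.3f\n",
                x$tests$V70$omnibus$statistic, x$tests$V70$omnibus$p_value))
    cat(sprintf("Kruskal-Wallis on V50: H = %.3f, p = %.3f\n",
                x$tests$V50$omnibus$statistic, x$tests$V50$omnibus$p_value))
  }
  invisible(x)
}

#' Compact focality table
#'
#' One row per (montage, tissue), V70 and V50 columns per model, the
#' layout used to compare the family side by side.
#'
#' @param report a `study_report`.
#' @return A data frame.
#' @export
format_focality_table <- function(report) {
  f <- report$focality
  models <- unique(f$model)
  out <- unique(f[, c("montage", "tissue")])
  for (m in models) {
    sub <- f[f$model == m, ]
    idx <- match(paste(out$montage, out$tissue),
                 paste(sub$montage, sub$tissue))
    out[[paste0(m, "_V70")]] <- round(sub$V70[idx], 1)
    out[[paste0(m, "_V50")]] <- round(sub$V50[idx], 1)
  }
  rownames(out) <- NULL
  out
}

#' Write a study report to disk
#'
#' JSON for machines plus one tidy CSV per table. Deterministic: repeated
#' runs with the same configuration produce byte-identical payloads.
#'
#' @param report a `study_report`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  payload <- list(stats = report$stats, focality = report$focality,
                  variability = report$variability,
                  tests = lapply(report$tests, function(t) {
                    if (is.null(t)) return(NULL)
                    list(omnibus = unclass(t$omnibus), posthoc = t$posthoc)
                  }),
                  solver_log = report$solver_log,
                  provenance = report$provenance)
  jsonlite::write_json(payload, file.path(dir, "study_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "columns")
  write.csv(report$stats, file.path(dir, "tissue_stats.csv"),
            row.names = FALSE)
  write.csv(report$focality, file.path(dir, "focality.csv"),
            row.names = FALSE)
  if (!is.null(report$variability))
    write.csv(report$variability, file.path(dir, "variability_cv_db.csv"),
              row.names = FALSE)
  invisible(dir)
}

#' Generate small on-disk fixtures
#'
#' Writes a reduced phantom family (head and body NIfTI label volumes at
#' most 64 voxels per axis), the four standard montage JSONs, a three-shell
#' model JSON, and a manifest CSV listing every file with its MD5
#' checksum.
#'
#' @param out_dir writable directory.
#' @param scale `"small"` (reduced stature, coarse voxels) or `"default"`.
#' @return Character vector of the written paths (manifest last),
#'   invisibly.
#' @export
generate_fixtures <- function(out_dir, scale = c("small", "default")) {
  scale <- match.arg(scale)
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0)
    stop("output directory is not writable: ", out_dir)
  ref <- reference_adult_params()
  if (scale == "small") {
    prof <- scale_profile(ref, "fixture_small", 0.9)
    prof$voxel_size <- 2
    body_vox <- 6
  } else {
    prof <- scale_profile(ref, "fixture_default", 1.75)
    prof$voxel_size <- 2
    body_vox <- 4
  }
  paths <- character(0)
  head <- build_layered_sphere_head(prof)
  paths <- c(paths, write_label_volume(head, file.path(out_dir,
                                                       "head_small.nii")))
  paths <- c(paths, paste0(paths[length(paths)], ".json"))
  prof_body <- prof; prof_body$voxel_size <- body_vox
  body <- build_body_phantom(prof_body)
  p <- write_label_volume(body, file.path(out_dir, "body_small.nii"))
  paths <- c(paths, p, paste0(p, ".json"))
  for (m in c("A", "B", "C", "D")) {
    p <- file.path(out_dir, paste0("montage_", m, ".json"))
    write_montage_spec(standard_montage(m), p)
    paths <- c(paths, p)
  }
  tab <- default_conductivity_table()
  shells <- shell_model(radii = c(40, 44, 48),
                        sigmas = sigma_lookup(tab, c("brain_grey_matter",
                                                     "skull", "skin")),
                        L = 80)
  p <- file.path(out_dir, "shell_model.json")
  write_shell_model(shells, p)
  paths <- c(paths, p)
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  mp <- file.path(out_dir, "manifest.csv")
  write.csv(manifest, mp, row.names = FALSE)
  invisible(c(paths, mp))
}
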