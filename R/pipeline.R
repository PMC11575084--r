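#' Pipeline configuration
#'
#' Names the T0/T1/T2 scan files, the landmark file, an optional oriented
#' reference mesh that T0 is additionally registered onto, the ICP
#' parameters, the colormap span and the output directory. All randomness
#' in a run flows from the single `seed`.
#'
#' @param t0,t1,t2 mesh file paths (STL, PLY or VTK polydata).
#' @param landmarks landmark JSON file path (see [read_landmarks]).
#' @param reference optional oriented reference mesh path.
#' @param roi either `"landmarks"` (build the ROI from the landmark file)
#'   or a `roi_spec` / path to a ROI JSON file.
#' @param icp an `icp_params`.
#' @param span colormap half-range in mm, or NULL for the automatic 95th
#'   percentile.
#' @param out_dir output directory for the report and visual artifacts;
#'   NULL suppresses file output.
#' @param seed integer seed.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(t0, t1, t2, landmarks, reference = NULL,
                            roi = "landmarks", icp = icp_params(),
                            span = NULL, out_dir = NULL, seed = 0L) {
  for (p in c(t0, t1, t2, landmarks, reference))
    if (!file.exists(p)) stop("input file does not exist: ", p)
  if (!(identical(roi, "landmarks") || inherits(roi, "roi_spec") ||
        (is.character(roi) && file.exists(roi))))
    stop("roi must be \"landmarks\", a roi_spec, or a ROI JSON file path")
  structure(list(t0 = t0, t1 = t1, t2 = t2, landmarks = landmarks,
                 reference = reference, roi = roi, icp = icp,
                 span = span, out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

# order-insensitive content hash (FNV-1a over the canonical config JSON)
fnv1a_hex <- function(txt) {
  bytes <- as.integer(charToRaw(txt))
  h <- 0x811c9dc5
  for (b in bytes) {
    # xor on the low byte only (b < 256); h itself may exceed .Machine$integer.max
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b)
    # 32-bit multiply by 16777619 in double-safe pieces
    h <- (h * 403 + ((h * 256) %% 2^32) * 65536) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_hash <- function(config) {
  desc <- list(t0 = basename(config$t0), t1 = basename(config$t1),
               t2 = basename(config$t2),
               landmarks = basename(config$landmarks),
               reference = if (is.null(config$reference)) "" else
                 basename(config$reference),
               icp = unclass(config$icp), span = config$span,
               seed = config$seed)
  fnv1a_hex(as.character(jsonlite::toJSON(desc, auto_unbox = TRUE, digits = NA)))
}

#' Run the full swelling-analysis pipeline on a scan triplet
#'
#' Executes, in order: anonymization of all scans; landmark orientation of
#' T0 into the canonical anatomical frame (plus, when a reference mesh is
#' supplied, ICP refinement onto it); ICP registration of T1 and T2 onto
#' oriented T0; ROI construction; and for each pair T0-T1, T1-T2, T0-T2 the
#' signed distance field of the later scan against the earlier, its mean
#' over the ROI, ROI clipping and closing of both scans, and their volume
#' difference (later minus earlier, so swelling onset is positive). Writes
#' the colormap and displacement-vector artifacts per pair plus the report
#' as JSON and CSV when `out_dir` is set.
#'
#' @param config a `pipeline_config`.
#' @return a `swelling_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  stage <- function(name, expr) {
    log_lines <<- c(log_lines, paste0("stage: ", name))
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  meshes <- stage("read", list(T0 = read_mesh(config$t0),
                               T1 = read_mesh(config$t1),
                               T2 = read_mesh(config$t2)))
  meshes <- stage("anonymize", lapply(meshes, anonymize_mesh))
  lms <- stage("landmarks", read_landmarks(config$landmarks))
  orient <- stage("orient", orient_by_landmarks(lms))
  t0 <- apply_transform(meshes$T0, orient)
  lms_canon <- transform_landmarks(lms, orient)
  ref_rms <- NA_real_
  if (!is.null(config$reference)) {
    refmesh <- stage("reference", read_mesh(config$reference))
    fit <- stage("register_T0_reference",
                 icp_register(t0, refmesh, refine_params(config$icp, config$seed, 0L)))
    t0 <- apply_transform(t0, fit$transform)
    lms_canon <- transform_landmarks(lms_canon, fit$transform)
    ref_rms <- fit$rms
  }
  reg1 <- stage("register_T1", icp_register(meshes$T1, t0,
                                            refine_params(config$icp, config$seed, 1L)))
  reg2 <- stage("register_T2", icp_register(meshes$T2, t0,
                                            refine_params(config$icp, config$seed, 2L)))
  t1 <- apply_transform(meshes$T1, reg1$transform)
  t2 <- apply_transform(meshes$T2, reg2$transform)
  roi <- stage("roi", if (inherits(config$roi, "roi_spec")) config$roi
               else if (identical(config$roi, "landmarks"))
                 roi_from_landmarks(lms_canon)
               else roi_from_json(config$roi))
  scans <- list(T0 = t0, T1 = t1, T2 = t2)
  reg_rms <- c(T0 = ref_rms, T1 = reg1$rms, T2 = reg2$rms)
  clipped <- stage("clip", lapply(scans, clip_to_roi, roi = roi))
  closed <- stage("close", lapply(clipped, close_mesh))
  for (nm in names(closed))
    if (!diagnose_mesh(closed[[nm]])$is_watertight)
      stop("pipeline invariant breach: ", nm, " not watertight after closing")
  vols <- vapply(closed, function(m) mesh_volume(m)$volume, 0)
  holes <- vapply(closed, function(m) attr(m, "n_holes_filled"), 0L)
  pairs <- list(c("T0", "T1"), c("T1", "T2"), c("T0", "T2"))
  if (!is.null(config$out_dir))
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  pair_results <- list()
  for (pr in pairs) {
    earlier <- pr[1]; later <- pr[2]
    lbl <- paste0(earlier, "-", later)
    field <- stage(paste0("distance_", lbl),
                   signed_distance_field(scans[[later]], scans[[earlier]],
                                         pair_label = lbl))
    m <- stage(paste0("mean_", lbl), mean_linear_difference(field, roi))
    if (!is.null(config$out_dir)) {
      stage(paste0("colormap_", lbl),
            colormap_export(field,
                            file.path(config$out_dir,
                                      paste0("colormap_", lbl, ".ply")),
                            span = config$span))
      stage(paste0("vectors_", lbl),
            displacement_vector_export(field,
                                       file.path(config$out_dir,
                                                 paste0("vectors_", lbl, ".vtk"))))
    }
    pair_results[[lbl]] <- list(
      pair = lbl,
      linear_difference_mean = as.numeric(m),
      linear_difference_sd = attr(m, "sd"),
      n_roi_vertices = attr(m, "n"),
      volume_earlier = vols[[earlier]],
      volume_later = vols[[later]],
      volume_difference = vols[[later]] - vols[[earlier]],
      registration_rms = reg_rms[[later]])
  }
  report <- structure(list(
    pairs = pair_results,
    volumes = as.list(vols),
    n_holes_filled = as.list(holes),
    registration_rms = as.list(reg_rms),
    provenance = list(config_hash = config_hash(config),
                      package_version = as.character(packageVersion("swellkit")),
                      seed = config$seed)),
    class = "swelling_report")
  if (!is.null(config$out_dir)) {
    report_to_json(report, file.path(config$out_dir, "report.json"))
    report_to_csv(report, file.path(config$out_dir, "report.csv"))
    writeLines(log_lines, file.path(config$out_dir, "pipeline.log"))
  }
  report
}

# per-scan ICP seed derived from the single config seed
refine_params <- function(icp, seed, offset) {
  icp$seed <- as.integer((as.numeric(seed) * 131 + offset) %% .Machine$integer.max)
  icp
}

#' @export
print.swelling_report <- function(x, ...) {
  cat("swelling_report\n")
  for (p in x$pairs)
    cat(sprintf("  %s: linear %+0.3f +/- %0.3f mm, volume %+0.1f mm^3 (n=%d)\n",
                p$pair, p$linear_difference_mean, p$linear_difference_sd,
                p$volume_difference, p$n_roi_vertices))
  invisible(x)
}

#' Write a swelling report as JSON
#'
#' Full-precision, canonical field order; byte-identical for identical
#' inputs and seed.
#'
#' @param report a `swelling_report`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
report_to_json <- function(report, path) {
  writeLines(jsonlite::toJSON(unclass(report), digits = NA, auto_unbox = TRUE,
                              pretty = TRUE), path)
  invisible(path)
}

#' Write a swelling report as CSV (one row per scan pair)
#'
#' @param report a `swelling_report`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
report_to_csv <- function(report, path) {
  rows <- do.call(rbind, lapply(report$pairs, function(p)
    data.frame(pair = p$pair,
               linear_difference_mean_mm = p$linear_difference_mean,
               linear_difference_sd_mm = p$linear_difference_sd,
               n_roi_vertices = p$n_roi_vertices,
               volume_earlier_mm3 = p$volume_earlier,
               volume_later_mm3 = p$volume_later,
               volume_difference_mm3 = p$volume_difference,
               registration_rms_mm = p$registration_rms)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(rows), collapse = ","), con)
  for (i in seq_len(nrow(rows))) {
    vals <- vapply(rows[i, ], function(x)
      if (is.numeric(x)) fmt_g(x) else as.character(x), "")
    writeLines(paste(vals, collapse = ","), con)
  }
  invisible(path)
}
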