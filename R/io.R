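#' Read a NIfTI-1 volume
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return An `fs_volume` whose grid affine is the NIfTI index-to-world
#'   transform (0-based voxel indices).
#' @export
read_volume <- function(path) {
  img <- tryCatch(RNifti::readNifti(path), error = function(e)
    stop_fieldshim(sprintf("not a readable NIfTI-1 file (%s): %s",
                           path, conditionMessage(e)), "fs_format_error"))
  d <- dim(img)
  if (length(d) != 3L)
    stop_fieldshim(sprintf("expected a 3D volume, got %dD", length(d)),
                   "fs_format_error")
  A <- matrix(structure(RNifti::xform(img), dim = c(4L, 4L)), 4, 4)
  vox <- sqrt(colSums(A[1:3, 1:3]^2))
  g <- voxel_grid(d, vox, index_to_world = A)
  volume(array(as.vector(img), d), g)
}

#' Write a volume as NIfTI-1
#'
#' @param vol An `fs_volume` (or [field_map()]); logical volumes are
#'   written as 0/1.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  v <- vol$values
  if (is.logical(v)) storage.mode(v) <- "integer"
  img <- RNifti::asNifti(v)
  RNifti::pixdim(img) <- vol$grid$voxel_size_mm
  img <- RNifti::`sform<-`(img, structure(vol$grid$index_to_world,
                                          code = 2L))
  img <- RNifti::`qform<-`(img, structure(vol$grid$index_to_world,
                                          code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write a plain-text 4x4 affine transform
#'
#' Row-major, whitespace-separated; `#`-prefixed header lines carry the
#' space labels and degrees of freedom.
#'
#' @param path File path.
#' @return An [affine_transform()].
#' @export
read_transform <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, value = TRUE, invert = TRUE)
  body <- body[nzchar(trimws(body))]
  vals <- as.numeric(unlist(strsplit(trimws(body), "\\s+")))
  if (length(vals) != 16 || any(is.na(vals)))
    stop_fieldshim("transform file must hold 16 numbers",
                   "fs_format_error")
  get_tag <- function(tag, default) {
    m <- regmatches(hdr, regexpr(paste0(tag, ":\\s*\\S+"), hdr))
    m <- unlist(m)
    if (length(m)) sub(paste0(tag, ":\\s*"), "", m[1]) else default
  }
  affine_transform(matrix(vals, 4, 4, byrow = TRUE),
                   source = get_tag("source", "source"),
                   target = get_tag("target", "target"),
                   dof = as.integer(get_tag("dof", "12")))
}

#' @rdname read_transform
#' @param transform An [affine_transform()] to write.
#' @export
write_transform <- function(transform, path) {
  hdr <- sprintf("# source: %s target: %s dof: %d",
                 transform$source, transform$target, transform$dof)
  body <- apply(transform$matrix, 1, function(r)
    paste(sprintf("%.12g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read / write a shim setting as JSON
#'
#' @param path File path.
#' @return A [shim_setting()].
#' @export
read_shim <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  shim_setting(unlist(obj$coefficients),
               max_order = obj$max_order %||% NULL)
}

#' @rdname read_shim
#' @param setting A [shim_setting()] to write.
#' @export
write_shim <- function(setting, path) {
  jsonlite::write_json(list(coefficients = as.list(setting$coefficients),
                            max_order = setting$max_order),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a coil calibration set as JSON
#'
#' Serialized as `{coil_name: {term: coefficient_per_unit}}` with fitted
#' residuals alongside.
#'
#' @param calib A [calibrate_coils()] result.
#' @param path Output path.
#' @export
write_calibration <- function(calib, path) {
  jsonlite::write_json(
    lapply(unclass(calib), function(cc) list(
      coefficients_per_unit = as.list(cc$coefficients_per_unit),
      residual = cc$residual, n_settings = cc$n_settings)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a harmonic basis as a 4D NIfTI plus a term manifest
#'
#' @param basis A [build_basis()] result.
#' @param path Output `.nii.gz` path; a `.json` sidecar listing the term
#'   order is written next to it.
#' @export
write_basis <- function(basis, path) {
  arr <- array(basis$B, c(basis$grid$shape, nrow(basis$terms)))
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(basis$grid$index_to_world,
                                          code = 2L))
  RNifti::writeNifti(img, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(max_order = basis$max_order,
                            terms = basis$terms$name),
                       side, auto_unbox = TRUE)
  invisible(path)
}

#' Write / read a template bundle (mean, std, count volumes + manifest)
#'
#' @param template A [build_template()] result.
#' @param dir Directory to create.
#' @export
write_template <- function(template, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- template$grid
  write_volume(template$mean, file.path(dir, "mean.nii.gz"))
  write_volume(volume(template$std, g), file.path(dir, "std.nii.gz"))
  write_volume(volume(template$count, g), file.path(dir, "count.nii.gz"))
  if (!is.null(template$structural))
    write_volume(template$structural, file.path(dir, "structural.nii.gz"))
  if (!is.null(template$brain_mask))
    write_volume(volume(template$brain_mask, g),
                 file.path(dir, "brain_mask.nii.gz"))
  jsonlite::write_json(list(n = template$n, shape = g$shape,
                            voxel_size_mm = g$voxel_size_mm),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_template
#' @export
read_template <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  mean_v <- read_volume(file.path(dir, "mean.nii.gz"))
  std_v <- read_volume(file.path(dir, "std.nii.gz"))
  cnt_v <- read_volume(file.path(dir, "count.nii.gz"))
  g <- mean_v$grid
  structural <- if (file.exists(file.path(dir, "structural.nii.gz")))
    read_volume(file.path(dir, "structural.nii.gz")) else NULL
  brain_mask <- if (file.exists(file.path(dir, "brain_mask.nii.gz")))
    as_mask(read_volume(file.path(dir, "brain_mask.nii.gz"))$values)
    else NULL
  cnt <- cnt_v$values
  structure(list(
    mean = field_map(mean_v$values, g, brain_mask = cnt > 0,
                     provenance = "synthetic",
                     shim_state = "baseline-removed"),
    std = std_v$values, count = cnt, n = man$n, grid = g,
    structural = structural, brain_mask = brain_mask),
    class = "template_result")
}

#' Write a synthetic cohort to disk
#'
#' Per-subject NIfTI volumes (field, structural, brain mask and, when
#' simulated, the wrapped dual-echo phases), plain-text true transforms,
#' baseline-shim JSON, and a cohort manifest with the generator
#' configuration.
#'
#' @param cohort An [sample_cohort()] result.
#' @param dir Output directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects) {
    sd <- file.path(dir, s$id)
    dir.create(sd, showWarnings = FALSE)
    write_volume(s$field_true, file.path(sd, "field.nii.gz"))
    write_volume(s$structural, file.path(sd, "structural.nii.gz"))
    write_volume(volume(s$brain_mask, s$field_true$grid),
                 file.path(sd, "brain_mask.nii.gz"))
    write_transform(s$transform, file.path(sd, "subject_to_standard.txt"))
    write_shim(s$baseline_shim, file.path(sd, "baseline_shim.json"))
    if (!is.null(s$phases)) {
      write_volume(s$phases$phase1, file.path(sd, "phase1.nii.gz"))
      write_volume(s$phases$phase2, file.path(sd, "phase2.nii.gz"))
    }
  }
  std_dir <- file.path(dir, "standard")
  dir.create(std_dir, showWarnings = FALSE)
  write_volume(cohort$standard$structural,
               file.path(std_dir, "structural.nii.gz"))
  write_volume(volume(cohort$standard$brain_mask, cohort$standard$grid),
               file.path(std_dir, "brain_mask.nii.gz"))
  write_volume(cohort$standard$field, file.path(std_dir, "field.nii.gz"))
  cfg <- cohort$config
  class(cfg) <- NULL
  jsonlite::write_json(
    list(config = cfg,
         subjects = vapply(cohort$subjects, `[[`, "", "id")),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#' @param dir Cohort directory.
#' @return An `fs_cohort`.
#' @export
read_cohort <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  config <- do.call(cohort_config,
                    man$config[names(man$config) %in%
                                 names(formals(cohort_config))])
  subjects <- lapply(man$subjects, function(id) {
    sd <- file.path(dir, id)
    fld <- read_volume(file.path(sd, "field.nii.gz"))
    msk <- as_mask(read_volume(file.path(sd, "brain_mask.nii.gz"))$values)
    s <- list(
      id = id,
      field_true = field_map(fld$values, fld$grid, brain_mask = msk,
                             provenance = "synthetic",
                             shim_state = "baseline-removed"),
      structural = read_volume(file.path(sd, "structural.nii.gz")),
      brain_mask = msk,
      transform = read_transform(file.path(sd,
                                           "subject_to_standard.txt")),
      baseline_shim = read_shim(file.path(sd, "baseline_shim.json")))
    if (file.exists(file.path(sd, "phase1.nii.gz"))) {
      p1 <- read_volume(file.path(sd, "phase1.nii.gz"))
      p2 <- read_volume(file.path(sd, "phase2.nii.gz"))
      s$phases <- list(
        phase1 = phase_volume(p1$values, p1$grid, wrapped = TRUE),
        phase2 = phase_volume(p2$values, p2$grid, wrapped = TRUE),
        TE1_ms = config$TE1_ms, dTE_ms = config$dTE_ms)
    }
    s
  })
  std_dir <- file.path(dir, "standard")
  struct <- read_volume(file.path(std_dir, "structural.nii.gz"))
  bmask <- as_mask(read_volume(file.path(std_dir,
                                         "brain_mask.nii.gz"))$values)
  fld <- read_volume(file.path(std_dir, "field.nii.gz"))
  standard <- list(grid = struct$grid, model = NULL,
                   field = field_map(fld$values, fld$grid,
                                     brain_mask = bmask,
                                     provenance = "synthetic",
                                     shim_state = "baseline-removed"),
                   structural = struct, brain_mask = bmask)
  structure(list(subjects = subjects, standard = standard,
                 config = config),
            class = "fs_cohort")
}

#' Write an evaluation's tidy tables
#'
#' @param evaluation A [loocv_evaluate()] result.
#' @param dir Output directory; writes `results.csv`,
#'   `distributions.csv` (when present) and `summary.json`.
#' @export
write_evaluation <- function(evaluation, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(evaluation$results, file.path(dir, "results.csv"),
            row.names = FALSE)
  if (!is.null(evaluation$distributions))
    write.csv(evaluation$distributions,
              file.path(dir, "distributions.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(summary = evaluation$summary, max_order = evaluation$max_order,
         n_subjects = evaluation$n_subjects,
         transform_source = evaluation$transform_source),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
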