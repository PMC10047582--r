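#' Specification of a synthetic multiparametric phantom case
#'
#' Describes the geometry and signal model of one simulated postoperative
#' glioblastoma case: a spherical surgical cavity, a surrounding peritumoral
#' shell, and a cone-shaped recurrence subregion hugging the cavity edge
#' whose intensities are shifted and re-textured relative to the edematous
#' remainder.  Five correlated modality channels (T1w, T1ce, T2w, FLAIR,
#' ADC roles) are produced per case.
#'
#' Texture is realized as smoothed Gaussian random fields with a
#' class-specific correlation length; modalities share a latent field mixed
#' with per-modality noise, emulating multiparametric redundancy.  The
#' `effect_size` is the standardized shift of the recurrence-class mean
#' relative to the total per-voxel standard deviation, applied per modality
#' scaled by `modality_effect` (negative for ADC, where diffusion drops in
#' cellular tumor); `effect_size = 0` yields statistically
#' indistinguishable classes.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param spacing_mm voxel size in mm per axis.
#' @param cavity_radius_mm radius of the spherical surgical cavity.
#' @param shell_thickness_mm width of the peritumoral shell beyond the
#'   cavity edge.
#' @param recurrence_solid_angle_deg full apex angle of the recurrence cone
#'   (360 covers the whole shell).
#' @param recurrence_depth_mm radial extent of recurrence beyond the cavity
#'   edge; must not exceed `shell_thickness_mm`.
#' @param effect_size standardized mean-intensity shift of recurrence
#'   voxels.
#' @param texture_corr_len_mm named length-2 vector
#'   (`nonrecurrence`, `recurrence`): Gaussian random-field correlation
#'   length per class, in mm.  Equal by default, so `effect_size` alone
#'   controls class separability and `effect_size = 0` is an exact null;
#'   setting them apart adds a texture (smoothness) contrast between
#'   infiltrated and edematous tissue on top of the mean shift.
#' @param noise_sd additive white-noise scale relative to the unit-variance
#'   texture field.
#' @param modality_effect named per-modality multiplier of `effect_size`.
#' @param latent_weight share (0..1) of texture variance common to all
#'   modalities.
#' @param brain_margin_mm brain support extends this far beyond the shell.
#' @param cavity_intensity_shift additive intensity offset of cavity
#'   voxels.  The default 0 keeps the intensity field stationary across
#'   the brain support, so kernel features carry no distance-to-cavity cue
#'   and `effect_size = 0` is an exact null; a negative value emulates the
#'   dark fluid-filled resection cavity of real postoperative scans (at
#'   the price of a proximity cue, which the real data also carry).
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @return an object of class `phantom_spec`.
#' @seealso [generate_phantom()], [generate_cohort()]
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64),
                         spacing_mm = c(1, 1, 1),
                         cavity_radius_mm = 8,
                         shell_thickness_mm = 12,
                         recurrence_solid_angle_deg = 60,
                         recurrence_depth_mm = 10,
                         effect_size = 2,
                         texture_corr_len_mm = c(nonrecurrence = 3, recurrence = 3),
                         noise_sd = 0.5,
                         modality_effect = c(T1w = 0.5, T1ce = 1, T2w = 0.5,
                                             FLAIR = 0.8, ADC = -0.8),
                         latent_weight = 0.5,
                         brain_margin_mm = 4,
                         cavity_intensity_shift = 0,
                         seed = NULL) {
  geom <- c(cavity_radius_mm, shell_thickness_mm, recurrence_solid_angle_deg,
            recurrence_depth_mm, brain_margin_mm)
  if (any(!is.finite(geom)) || any(geom <= 0))
    stop("all geometric fields must be positive")
  if (recurrence_depth_mm > shell_thickness_mm + 1e-9)
    stop("recurrence_depth_mm must not exceed shell_thickness_mm")
  if (length(grid_shape) != 3L || any(grid_shape < 8))
    stop("grid_shape must be three values of at least 8")
  if (any(spacing_mm <= 0)) stop("spacing must be positive")
  if (!all(c("nonrecurrence", "recurrence") %in% names(texture_corr_len_mm)))
    stop("texture_corr_len_mm needs elements 'nonrecurrence' and 'recurrence'")
  if (length(modality_effect) != 5L || is.null(names(modality_effect)))
    stop("modality_effect must be a named length-5 vector")
  if (latent_weight < 0 || latent_weight > 1)
    stop("latent_weight must be in [0, 1]")
  extent <- grid_shape * spacing_mm
  if (cavity_radius_mm + shell_thickness_mm >= min(extent) / 2)
    stop("degenerate geometry: cavity and shell larger than grid")
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing_mm = as.numeric(spacing_mm),
                 cavity_radius_mm = cavity_radius_mm,
                 shell_thickness_mm = shell_thickness_mm,
                 recurrence_solid_angle_deg = recurrence_solid_angle_deg,
                 recurrence_depth_mm = recurrence_depth_mm,
                 effect_size = effect_size,
                 texture_corr_len_mm = texture_corr_len_mm,
                 noise_sd = noise_sd,
                 modality_effect = modality_effect,
                 latent_weight = latent_weight,
                 brain_margin_mm = brain_margin_mm,
                 cavity_intensity_shift = cavity_intensity_shift,
                 seed = seed),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("<phantom_spec> grid %s @ %s mm, cavity %g mm, shell %g mm,\n",
                     "  recurrence cone %g deg x %g mm deep, effect size %g, seed %s\n"),
              paste(x$grid_shape, collapse = "x"),
              paste(format(x$spacing_mm, digits = 3), collapse = "x"),
              x$cavity_radius_mm, x$shell_thickness_mm,
              x$recurrence_solid_angle_deg, x$recurrence_depth_mm,
              x$effect_size, if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

modality_roles <- function() c("T1w", "T1ce", "T2w", "FLAIR", "ADC")

gauss_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(3.5 * sigma_vox))
  k <- exp(-0.5 * ((-r:r) / sigma_vox)^2)
  k / sum(k)
}

# stationary Gaussian random field with exactly unit marginal variance:
# white noise on a padded grid, separable Gaussian smoothing, central crop,
# analytic normalization (variance of smoothed white noise = prod sum(k^2))
grf <- function(dm, spacing, corr_len_mm) {
  if (corr_len_mm <= 0) return(array(rnorm(prod(dm)), dm))
  ks <- lapply(1:3, function(a) gauss_kernel_1d(corr_len_mm / spacing[a]))
  pad <- sapply(ks, function(k) (length(k) - 1L) %/% 2L)
  dmp <- dm + 2L * pad
  w <- array(rnorm(prod(dmp)), dmp)
  w <- cpp_convolve_sep(w, dmp, ks[[1L]], ks[[2L]], ks[[3L]])
  w <- w[(pad[1L] + 1L):(pad[1L] + dm[1L]),
         (pad[2L] + 1L):(pad[2L] + dm[2L]),
         (pad[3L] + 1L):(pad[3L] + dm[3L]), drop = FALSE]
  w / prod(sapply(ks, function(k) sqrt(sum(k^2))))
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Generate one synthetic phantom case
#'
#' Builds a coregistered [case bundle][generate_phantom] with five modality
#' volumes, a cavity mask, a peritumoral mask and a follow-up
#' enhancing-tumor mask whose overlap with the peritumor is the intended
#' recurrence subregion.  The follow-up mask additionally bulges into the
#' cavity so downstream clipping logic is exercised.  Deterministic for a
#' fixed `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @param case_id identifier stored in the bundle.
#' @param center_offset_mm cavity-center displacement from the grid center,
#'   in mm.
#' @param direction length-3 vector giving the recurrence-cone axis (need
#'   not be normalized).
#' @return an object of class `case_bundle`: named list with `modalities`
#'   (list of five [voxel_grid]s), `cavity_mask`, `peritumor_mask`,
#'   `followup_enhancing_mask`, `brain_mask` (all [mask_volume]s),
#'   `case_id` and `meta`.
#' @export
generate_phantom <- function(spec, case_id = "case_001",
                             center_offset_mm = c(0, 0, 0),
                             direction = c(1, 0, 0)) {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$grid_shape
  sp <- spec$spacing_mm
  u <- direction / sqrt(sum(direction^2))

  center <- (dm - 1) / 2 * sp + center_offset_mm
  dx <- (seq_len(dm[1L]) - 1) * sp[1L] - center[1L]
  dy <- (seq_len(dm[2L]) - 1) * sp[2L] - center[2L]
  dz <- (seq_len(dm[3L]) - 1) * sp[3L] - center[3L]
  r2 <- outer(outer(dx^2, dy^2, "+"), dz^2, "+")
  r <- sqrt(r2)
  dot <- outer(outer(dx * u[1L], dy * u[2L], "+"), dz * u[3L], "+")
  cosang <- dot / pmax(r, 1e-9)

  Rc <- spec$cavity_radius_mm
  Th <- spec$shell_thickness_mm
  cav <- r <= Rc
  shell <- r > Rc & r <= Rc + Th
  brain <- r <= Rc + Th + spec$brain_margin_mm
  cos_half <- cos(spec$recurrence_solid_angle_deg / 2 * pi / 180)
  in_cone <- if (spec$recurrence_solid_angle_deg >= 360) {
    array(TRUE, dm)
  } else {
    cosang >= cos_half - 1e-12
  }
  rec <- shell & r <= Rc + spec$recurrence_depth_mm + 1e-9 & in_cone
  followup <- rec | (cav & r >= Rc - 3 & in_cone)

  if (!any(shell)) stop("degenerate geometry: empty peritumoral shell")

  roles <- modality_roles()
  mu <- c(T1w = 100, T1ce = 120, T2w = 80, FLAIR = 90, ADC = 140)
  s_tot <- sqrt(1 + spec$noise_sd^2)
  l_nr <- spec$texture_corr_len_mm[["nonrecurrence"]]
  l_r <- spec$texture_corr_len_mm[["recurrence"]]
  wlat <- spec$latent_weight

  retexture <- abs(l_r - l_nr) > 1e-9
  modalities <- with_seed(spec$seed, {
    shared_nr <- grf(dm, sp, l_nr)
    shared_r <- if (retexture) grf(dm, sp, l_r) else shared_nr
    out <- vector("list", 5L)
    names(out) <- roles
    recn <- as.numeric(rec)
    for (m in roles) {
      own_nr <- grf(dm, sp, l_nr)
      own_r <- if (retexture) grf(dm, sp, l_r) else own_nr
      tex_nr <- sqrt(wlat) * shared_nr + sqrt(1 - wlat) * own_nr
      # a single continuous field unless the classes are explicitly
      # re-textured: an independent recurrence field would leave a texture
      # discontinuity at the region boundary that kernels can detect even
      # at effect size 0
      tex <- if (retexture) {
        tex_r <- sqrt(wlat) * shared_r + sqrt(1 - wlat) * own_r
        tex_nr * (1 - recn) + tex_r * recn
      } else tex_nr
      img <- mu[[m]] + tex +
        spec$effect_size * spec$modality_effect[[m]] * s_tot * recn +
        spec$noise_sd * array(rnorm(prod(dm)), dm)
      if (spec$cavity_intensity_shift != 0)
        img[cav] <- img[cav] + spec$cavity_intensity_shift
      img[!brain] <- 0
      out[[m]] <- voxel_grid(img, sp)
    }
    out
  })

  structure(list(modalities = modalities,
                 cavity_mask = as_mask(cav, modalities[[1L]]),
                 peritumor_mask = as_mask(shell, modalities[[1L]]),
                 followup_enhancing_mask = as_mask(followup, modalities[[1L]]),
                 brain_mask = as_mask(brain, modalities[[1L]]),
                 case_id = case_id,
                 meta = list(spec = spec, direction = u,
                             center_offset_mm = center_offset_mm)),
            class = "case_bundle")
}

#' @export
print.case_bundle <- function(x, ...) {
  cat(sprintf("<case_bundle> %s: %d modalities, peritumor %d voxels, cavity %d voxels\n",
              x$case_id, length(x$modalities), mask_count(x$peritumor_mask),
              mask_count(x$cavity_mask)))
  invisible(x)
}

#' Generate a phantom cohort with train/test split
#'
#' Per-case geometry (cavity position and recurrence direction) is jittered
#' from per-case subseeds derived from `seed`, so a fixed seed reproduces
#' the cohort exactly and train/test cases are disjoint.
#'
#' @param n_train,n_test number of training / testing cases (each >= 1).
#' @param spec shared [phantom_spec()]; its `seed` field is ignored in
#'   favor of per-case subseeds.
#' @param seed cohort-level RNG seed.
#' @return an object of class `phantom_cohort`: list with elements `train`
#'   and `test` (lists of `case_bundle`s), plus `spec` and `seed`.
#' @export
generate_cohort <- function(n_train, n_test, spec, seed = 1L) {
  stopifnot(n_train >= 1L, n_test >= 1L, inherits(spec, "phantom_spec"))
  n <- n_train + n_test
  params <- with_seed(seed, {
    list(subseed = sample.int(.Machine$integer.max - 1L, n),
         offset = matrix(runif(3L * n, -4, 4), ncol = 3L),
         dir = matrix(rnorm(3L * n), ncol = 3L))
  })
  ids <- c(sprintf("train_%02d", seq_len(n_train)),
           sprintf("test_%02d", seq_len(n_test)))
  cases <- lapply(seq_len(n), function(i) {
    spec_i <- spec
    spec_i$seed <- params$subseed[i]
    generate_phantom(spec_i, case_id = ids[i],
                     center_offset_mm = params$offset[i, ],
                     direction = params$dir[i, ])
  })
  structure(list(train = cases[seq_len(n_train)],
                 test = cases[n_train + seq_len(n_test)],
                 spec = spec, seed = seed),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d training + %d testing cases, seed %s\n",
              length(x$train), length(x$test), x$seed))
  invisible(x)
}

#' Write / read a case bundle as NIfTI files
#'
#' Each case is stored as `<dir>/<case_id>/<role>.nii.gz` (five modalities
#' plus `cavity`, `peritumor`, `followup_enhancing` and `brain` masks) with
#' a JSON sidecar `phantom.json` holding the generating spec and seed.
#'
#' @param bundle a `case_bundle`.
#' @param dir cohort directory.
#' @return `write_case_bundle()` returns the case directory;
#'   `read_case_bundle()` the reconstructed `case_bundle`.
#' @export
write_case_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "case_bundle"))
  cdir <- file.path(dir, bundle$case_id)
  dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
  for (m in names(bundle$modalities))
    write_volume(bundle$modalities[[m]], file.path(cdir, paste0(m, ".nii.gz")))
  write_volume(bundle$cavity_mask, file.path(cdir, "cavity.nii.gz"))
  write_volume(bundle$peritumor_mask, file.path(cdir, "peritumor.nii.gz"))
  write_volume(bundle$followup_enhancing_mask,
               file.path(cdir, "followup_enhancing.nii.gz"))
  write_volume(bundle$brain_mask, file.path(cdir, "brain.nii.gz"))
  meta <- bundle$meta
  meta$spec <- unclass(meta$spec)
  jsonlite::write_json(list(case_id = bundle$case_id, meta = meta),
                       file.path(cdir, "phantom.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(cdir)
}

#' @rdname write_case_bundle
#' @param case_dir directory of one written case.
#' @export
read_case_bundle <- function(case_dir) {
  roles <- modality_roles()
  modalities <- lapply(roles, function(m)
    read_volume(file.path(case_dir, paste0(m, ".nii.gz"))))
  names(modalities) <- roles
  meta <- NULL
  sidecar <- file.path(case_dir, "phantom.json")
  if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar)
  structure(list(modalities = modalities,
                 cavity_mask = read_mask(file.path(case_dir, "cavity.nii.gz")),
                 peritumor_mask = read_mask(file.path(case_dir, "peritumor.nii.gz")),
                 followup_enhancing_mask =
                   read_mask(file.path(case_dir, "followup_enhancing.nii.gz")),
                 brain_mask = read_mask(file.path(case_dir, "brain.nii.gz")),
                 case_id = basename(case_dir),
                 meta = meta$meta),
            class = "case_bundle")
}
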