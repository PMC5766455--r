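#' Synthetic phantom specification
#'
#' Parametric description of the zero-motion phantom: a porcine-tibia-like
#' cortical shaft (with fibula) carrying a tibial tray, suspended in a 2 %
#' gelatin cylinder. Units are mm throughout. Geometry defaults are a
#' plausible adult-knee scale; the intensity model is a simple label->mean
#' map (gelatin high, trabecular medium, cortical low, metal zero) with a
#' fixed-radius signal-void halo around the metal emulating the residual
#' metal artifact of a low-field MARS acquisition.
#'
#' The bone frame has the shaft axis along +z (proximal up), the resection
#' plane at z = 0, anterior at +y and the fibula (lateral side) at +x.
#' `implant_pose` is the rigid pose of the implant in this frame; the
#' default applies a 5 degree posterior slope about the ML axis, the
#' standard surgical alignment of a tibial tray.
#'
#' @param shaft_length tibia shaft length below the resection, mm.
#' @param outer_radius_prox,outer_radius_dist outer cortical radii at the
#'   resection and at the distal end (linear taper), mm.
#' @param cortical_thickness cortical wall thickness, mm.
#' @param fibula_offset,fibula_radius,fibula_z0,fibula_z1 solid cortical
#'   fibula cylinder: lateral offset, radius and z extent, mm.
#' @param gelatin_radius,gelatin_z0,gelatin_z1 gelatin container cylinder, mm.
#' @param plate_width,plate_depth,plate_thickness tibial tray plate, mm
#'   (width = medial-lateral, depth = posterior-anterior).
#' @param plate_posterior_ratio posterior/anterior width ratio of the
#'   trapezoidal plate outline (trays narrow posteriorly).
#' @param notch_width,notch_depth rectangular notch cut into the posterior
#'   plate edge (a landmarking feature), mm.
#' @param stem_length,stem_radius,stem_radius_tip tapered stem below the
#'   plate, mm.
#' @param implant_pose [rigid_transform] of the implant in the bone frame.
#' @param intensity named vector of label means (arbitrary signal units):
#'   `gelatin`, `trabecular`, `cortical`, `metal`.
#' @param artifact_halo_mm radius of the signal void beyond the metal, mm.
#' @param noise_sigma Rician noise scale (signal units); default 2 % of the
#'   gelatin mean.
#' @param seed integer seed for the acquisition noise.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shaft_length = 110,
                         outer_radius_prox = 32,
                         outer_radius_dist = 16,
                         cortical_thickness = 5,
                         fibula_offset = 45,
                         fibula_radius = 6,
                         fibula_z0 = -105,
                         fibula_z1 = -15,
                         gelatin_radius = 75,
                         gelatin_z0 = -120,
                         gelatin_z1 = 20,
                         plate_width = 70,
                         plate_depth = 45,
                         plate_posterior_ratio = 0.75,
                         plate_thickness = 4,
                         notch_width = 10,
                         notch_depth = 6,
                         stem_length = 40,
                         stem_radius = 6,
                         stem_radius_tip = 4,
                         implant_pose = rigid_transform(
                           rotation_about_axis(c(1, 0, 0), 5)),
                         intensity = c(gelatin = 200, trabecular = 120,
                                       cortical = 50, metal = 0),
                         artifact_halo_mm = 2,
                         noise_sigma = 4,
                         seed = 1L) {
  num <- c(shaft_length, outer_radius_prox, outer_radius_dist,
           cortical_thickness, fibula_radius, gelatin_radius, plate_width,
           plate_depth, plate_thickness, stem_length, stem_radius,
           stem_radius_tip, artifact_halo_mm)
  if (any(num <= 0)) stop("geometry error: all radii/lengths must be positive")
  if (noise_sigma < 0) stop("geometry error: noise_sigma must be >= 0")
  assert_transform(implant_pose, "implant_pose")
  stopifnot(all(c("gelatin", "trabecular", "cortical", "metal") %in%
                  names(intensity)))
  spec <- structure(list(
    shaft_length = shaft_length, outer_radius_prox = outer_radius_prox,
    outer_radius_dist = outer_radius_dist,
    cortical_thickness = cortical_thickness,
    fibula_offset = fibula_offset, fibula_radius = fibula_radius,
    fibula_z0 = fibula_z0, fibula_z1 = fibula_z1,
    gelatin_radius = gelatin_radius, gelatin_z0 = gelatin_z0,
    gelatin_z1 = gelatin_z1,
    plate_width = plate_width, plate_depth = plate_depth,
    plate_posterior_ratio = plate_posterior_ratio,
    plate_thickness = plate_thickness,
    notch_width = notch_width, notch_depth = notch_depth,
    stem_length = stem_length, stem_radius = stem_radius,
    stem_radius_tip = stem_radius_tip,
    implant_pose = implant_pose,
    intensity = intensity, artifact_halo_mm = artifact_halo_mm,
    noise_sigma = noise_sigma, seed = as.integer(seed)
  ), class = "phantom_spec")
  # containment: the posed stem must stay inside the cortical canal
  clear <- cpp_implant_clearance(spec_for_cpp(spec), 50L)
  if (clear <= 0) {
    stop(sprintf("geometry error: implant stem violates the cortical canal (clearance %.2f mm)",
                 clear))
  }
  spec
}

# plate outline: CCW trapezoid (tibial trays narrow posteriorly) with a
# rectangular notch on the posterior (-y) edge, centered on x = 0
plate_polygon <- function(spec) {
  hw <- spec$plate_width / 2; hd <- spec$plate_depth / 2
  pw <- hw * spec$plate_posterior_ratio
  nw <- spec$notch_width / 2; nd <- spec$notch_depth
  rbind(
    c(pw, -hd), c(hw, hd), c(-hw, hd), c(-pw, -hd),
    c(-nw, -hd), c(-nw, -hd + nd), c(nw, -hd + nd), c(nw, -hd)
  )
}

spec_for_cpp <- function(spec) {
  c(unclass(spec)[setdiff(names(spec), "implant_pose")],
    list(plate_polygon = plate_polygon(spec),
         implant_pose_R = spec$implant_pose$R,
         implant_pose_t = spec$implant_pose$t))
}

#' MRI acquisition sampling preset
#'
#' Defines the transverse sampling grid: in-plane field of view and matrix
#' (square), slice thickness and number of slices. The low-field
#' metal-artifact-reduction (MARS) follow-up preset samples 180 mm / 224 x
#' 224 in-plane (0.8036 mm) at 3 mm slices; the high-resolution reference
#' preset samples 200 mm / 512 x 512 at 0.4 mm slices.
#'
#' @param fov_mm in-plane field of view, mm.
#' @param matrix in-plane matrix size (n x n).
#' @param slice_thickness_mm slice thickness, mm.
#' @param n_slices number of slices; `NULL` to size from the phantom at
#'   acquisition time (phantom extent plus margin).
#' @param orientation slice orientation; only "transverse" is supported.
#' @return object of class `acquisition_preset`.
#' @export
acquisition_preset <- function(fov_mm, matrix, slice_thickness_mm,
                               n_slices = NULL, orientation = "transverse") {
  if (fov_mm <= 0 || matrix <= 0 || slice_thickness_mm <= 0) {
    stop("preset error: fov, matrix and slice thickness must be positive")
  }
  orientation <- match.arg(orientation, "transverse")
  structure(list(fov_mm = fov_mm, matrix = as.integer(matrix),
                 slice_thickness_mm = slice_thickness_mm,
                 n_slices = if (is.null(n_slices)) NULL else as.integer(n_slices),
                 orientation = orientation,
                 in_plane_spacing = fov_mm / matrix),
            class = "acquisition_preset")
}

#' @rdname acquisition_preset
#' @export
mars_preset <- function(n_slices = NULL) {
  acquisition_preset(180, 224, 3, n_slices)
}

#' @rdname acquisition_preset
#' @export
reference_preset <- function(n_slices = NULL) {
  acquisition_preset(200, 512, 0.4, n_slices)
}

#' Build the parametric phantom geometry
#'
#' Constructs watertight triangulated reference models of the bone (tibia
#' cortical shell plus fibula, two closed components) and of the implant
#' (plate extrusion plus stem, two closed components overlapping at their
#' junction) in the bone frame, together with named implant landmarks
#' (including `posterior_edge` and `distal_notch`). Deterministic for a
#' given spec. The implant mesh and landmarks are returned in the implant's
#' own (canonical) frame; apply `spec$implant_pose` to place them in bone.
#'
#' @param spec [phantom_spec].
#' @return list with `bone_mesh`, `implant_mesh`, `landmarks` (named Nx3
#'   matrix, implant frame) and `frame` (the [anatomical_frame] at the
#'   implant mesh centroid).
#' @export
build_phantom_geometry <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  ro0 <- spec$outer_radius_prox; ro1 <- spec$outer_radius_dist
  w <- spec$cortical_thickness
  tibia <- tube_mesh(c(0, 0), router0 = ro1, router1 = ro0,
                     rinner0 = max(ro1 - w, 0.5), rinner1 = ro0 - w,
                     z0 = -spec$shaft_length, z1 = 0)
  fibula <- cylinder_mesh(c(spec$fibula_offset, 0), spec$fibula_radius,
                          spec$fibula_radius, spec$fibula_z0, spec$fibula_z1,
                          n_theta = 24, n_z = 20)
  bone <- mesh_subdivide(merge_meshes(tibia, fibula), max_edge = 5)
  # refine the plate so vertex density is roughly uniform: its caps come
  # out of ear clipping with very few vertices and would otherwise be
  # invisible to vertex-subsampled alignment; the stem is already fine
  plate <- mesh_subdivide(
    extrude_polygon(plate_polygon(spec), 0, spec$plate_thickness),
    max_edge = 3)
  # the stem is embedded 1 mm into the plate so the union is solid
  stem <- cylinder_mesh(c(0, 0), spec$stem_radius_tip, spec$stem_radius,
                        -spec$stem_length, 1, n_theta = 28, n_z = 16)
  implant <- merge_meshes(plate, stem)
  hw <- spec$plate_width / 2; hd <- spec$plate_depth / 2
  landmarks <- rbind(
    posterior_edge = c(hw / 2, -hd, spec$plate_thickness),
    distal_notch   = c(0, 0, -spec$stem_length),
    notch_corner_medial = c(-spec$notch_width / 2, -hd, spec$plate_thickness),
    notch_corner_lateral = c(spec$notch_width / 2, -hd, spec$plate_thickness),
    anterior_edge  = c(0, hd, spec$plate_thickness),
    lateral_corner = c(hw, hd, 0)
  )
  frame <- anatomical_frame(origin = mesh_centroid(implant))
  list(bone_mesh = bone, implant_mesh = implant, landmarks = landmarks,
       frame = frame)
}

default_n_slices <- function(spec, preset) {
  extent <- (spec$gelatin_z1 - spec$gelatin_z0)
  # 10 % margin plus room for the +-5 mm / +-5 degree relocations
  as.integer(ceiling(extent * 1.1 / preset$slice_thickness_mm) + 8L)
}

grid_geometry <- function(spec, preset) {
  n_sl <- if (is.null(preset$n_slices)) default_n_slices(spec, preset) else preset$n_slices
  sp <- c(preset$in_plane_spacing, preset$in_plane_spacing,
          preset$slice_thickness_mm)
  dims <- c(preset$matrix, preset$matrix, n_sl)
  zc <- (spec$gelatin_z0 + spec$gelatin_z1) / 2
  origin <- c(-(dims[1] - 1) / 2 * sp[1], -(dims[2] - 1) / 2 * sp[2],
              zc - (dims[3] - 1) / 2 * sp[3])
  list(dims = dims, spacing = sp, origin = origin)
}

#' Simulate one MRI acquisition of the phantom
#'
#' Samples the relocated phantom on the preset grid: each voxel intensity is
#' the label mean averaged over sub-voxel sample points (linear
#' partial-volume mixing at boundaries); everything within
#' `artifact_halo_mm` of the metal is a signal void; Rician noise (the
#' magnitude-MRI noise model) is added with scale `spec$noise_sigma` seeded
#' by `spec$seed + acq_index`, so output is deterministic for a fixed spec.
#'
#' @param bone_mesh,implant_mesh reference meshes from
#'   [build_phantom_geometry] (used for the field-of-view containment
#'   check; intensities are sampled from the parametric spec itself).
#' @param relocation [rigid_transform] of the whole phantom in the scanner
#'   frame.
#' @param preset [acquisition_preset].
#' @param spec [phantom_spec].
#' @param acq_index acquisition number (enters the noise seed).
#' @param subsamples per-axis sub-voxel sampling counts for partial-volume
#'   mixing; the default samples the thick slice direction more finely.
#' @return [mmri_volume].
#' @export
voxelize_acquisition <- function(bone_mesh, implant_mesh, relocation, preset,
                                 spec, acq_index = 1L,
                                 subsamples = c(2L, 2L, 4L)) {
  assert_transform(relocation, "relocation")
  gg <- grid_geometry(spec, preset)
  # field-of-view check: the relocated phantom (gelatin container corners)
  # must fit inside the grid
  zs <- c(spec$gelatin_z0, spec$gelatin_z1)
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  rim <- do.call(rbind, lapply(zs, function(z)
    cbind(spec$gelatin_radius * cos(th), spec$gelatin_radius * sin(th), z)))
  rim_w <- transform_points(relocation, rim)
  lo <- gg$origin - gg$spacing / 2
  hi <- gg$origin + (gg$dims - 1) * gg$spacing + gg$spacing / 2
  if (any(sweep(rim_w, 2, lo, "-") < 0) || any(sweep(rim_w, 2, hi, "-") > 0)) {
    stop("field-of-view error: relocated phantom exceeds the sampling grid")
  }
  arr <- cpp_voxelize(as.integer(gg$dims), gg$spacing, gg$origin,
                      relocation$R, relocation$t, spec_for_cpp(spec),
                      as.integer(subsamples))
  if (spec$noise_sigma > 0) {
    arr <- with_seed(spec$seed + as.integer(acq_index), {
      n <- length(arr)
      array(sqrt((arr + rnorm(n, 0, spec$noise_sigma))^2 +
                   rnorm(n, 0, spec$noise_sigma)^2), dim = dim(arr))
    })
  }
  mmri_volume(arr, gg$spacing, gg$origin)
}

# evaluate expr with a local RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

#' Generate a series of simulated acquisitions with ground truth
#'
#' Emulates the zero-motion experiment: the phantom is "relocated" between
#' acquisitions by a seeded rigid transform — rotation about the scanner
#' longitudinal axis uniform in ±`max_rotation_deg` (the dominant
#' left/right roll from supine), a small tilt about the two transverse axes
#' uniform in ±`max_tilt_deg`, and a translation uniform in
#' ±`max_translation_mm` per axis. With `injected_migration = NULL` the
#' implant-in-bone pose is held exactly constant (zero motion); otherwise
#' the stated per-pair migration is applied between consecutive
#' acquisitions and recorded in the manifest.
#'
#' The manifest carries, per acquisition, the true relocation and
#' implant-in-bone pose plus world-space seed points (tibia cortex, fibula,
#' stem interior) and implant landmark positions — the scripted stand-ins
#' for the interactive steps of the semi-automatic workflow.
#'
#' @param spec [phantom_spec].
#' @param preset [acquisition_preset].
#' @param n_acq number of acquisitions (>= 3); the experiment design uses 12.
#' @param max_rotation_deg maximal roll about the scanner axis, degrees.
#' @param injected_migration `NULL` (zero motion) or a [migration_record]
#'   applied between consecutive acquisitions.
#' @param seed master seed for relocations and noise.
#' @param max_tilt_deg,max_translation_mm relocation nuisance magnitudes.
#' @param subsamples passed to [voxelize_acquisition].
#' @return list with `volumes` (list of [mmri_volume]) and `manifest`.
#' @export
generate_series <- function(spec, preset, n_acq = 12L, max_rotation_deg = 25,
                            injected_migration = NULL, seed = 1L,
                            max_tilt_deg = 5, max_translation_mm = 5,
                            subsamples = c(2L, 2L, 4L)) {
  if (n_acq < 3L) stop("series error: need at least 3 acquisitions")
  if (max_rotation_deg < 0) stop("series error: max_rotation_deg must be >= 0")
  spec$seed <- as.integer(seed)
  geom <- build_phantom_geometry(spec)
  zero_inject <- is.null(injected_migration) ||
    all(abs(c(injected_migration$t_ml, injected_migration$t_dp,
              injected_migration$t_pa, injected_migration$r_fe,
              injected_migration$r_ei, injected_migration$r_vv)) == 0)
  # injected migrations act about the implant midpoint as posed in the bone
  # frame, matching the frame the pipeline reports in
  mig_frame <- anatomical_frame(origin = mesh_centroid(
    transform_mesh(spec$implant_pose, geom$implant_mesh)))
  mig_tr <- if (!zero_inject) compose_6dof(injected_migration, mig_frame)
  # relocations pivot about the phantom's own center (rolling the container
  # in place), so the distal end does not swing out of the field of view
  pivot <- c(0, 0, (spec$gelatin_z0 + spec$gelatin_z1) / 2)
  relocs <- with_seed(seed, lapply(seq_len(n_acq), function(i) {
    roll <- runif(1, -max_rotation_deg, max_rotation_deg)
    tilt <- runif(2, -max_tilt_deg, max_tilt_deg)
    R <- rotation_about_axis(c(0, 0, 1), roll) %*%
      rotation_about_axis(c(1, 0, 0), tilt[1]) %*%
      rotation_about_axis(c(0, 1, 0), tilt[2])
    shift <- runif(3, -max_translation_mm, max_translation_mm)
    rigid_transform(R, pivot - as.numeric(R %*% pivot) + shift)
  }))
  # canonical material points for scripted seeding, in the bone frame
  zmid <- -spec$shaft_length / 2
  f <- -zmid / spec$shaft_length
  rmid <- spec$outer_radius_prox +
    f * (spec$outer_radius_dist - spec$outer_radius_prox) -
    spec$cortical_thickness / 2
  seed_bone <- rbind(tibia = c(0, rmid, zmid),
                     fibula = c(spec$fibula_offset, 0,
                                (spec$fibula_z0 + spec$fibula_z1) / 2))
  seed_implant_local <- c(0, 0, -spec$stem_length / 2)
  pose <- spec$implant_pose
  volumes <- vector("list", n_acq)
  acq <- vector("list", n_acq)
  for (i in seq_len(n_acq)) {
    if (i > 1L && !zero_inject) pose <- compose_transforms(mig_tr, pose)
    spec_i <- spec
    spec_i$implant_pose <- pose
    volumes[[i]] <- voxelize_acquisition(geom$bone_mesh, geom$implant_mesh,
                                         relocs[[i]], preset, spec_i,
                                         acq_index = i,
                                         subsamples = subsamples)
    imp_world <- compose_transforms(relocs[[i]], pose)
    acq[[i]] <- list(
      index = i,
      relocation = relocs[[i]],
      implant_in_bone = pose,
      seed_points = list(bone = transform_points(relocs[[i]], seed_bone),
                         implant = drop(transform_points(
                           imp_world, seed_implant_local))),
      landmarks_world = {
        lm <- transform_points(imp_world, geom$landmarks)
        rownames(lm) <- rownames(geom$landmarks)
        lm
      }
    )
  }
  manifest <- list(frame = mig_frame, seed = as.integer(seed),
                   preset = preset, spec = spec,
                   injected_migration = injected_migration,
                   landmarks_model = geom$landmarks,
                   acquisitions = acq)
  list(volumes = volumes, manifest = manifest)
}
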