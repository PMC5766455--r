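#' Implant-in-bone pose of one acquisition
#'
#' Combines the bone and implant registrations of an acquisition into the
#' pose of the implant with respect to the bone, expressed in the
#' reference coordinate system: `implant_in_bone =
#' invert(bone) o implant`. Any global relocation applied to the whole
#' acquisition cancels algebraically.
#'
#' @param bone,implant `registration_result`s of one acquisition.
#' @param index acquisition index.
#' @return object of class `acquisition_pose`.
#' @export
relative_pose <- function(bone, implant, index = NA_integer_) {
  stopifnot(inherits(bone, "registration_result"),
            inherits(implant, "registration_result"))
  structure(list(index = as.integer(index),
                 implant_in_bone = compose_transforms(
                   invert_transform(bone$transform), implant$transform),
                 rms = c(bone = bone$rms, implant = implant$rms)),
            class = "acquisition_pose")
}

#' Cyclic acquisition pairing
#'
#' The pairing of the zero-motion analysis: each acquisition against the
#' next, closing the cycle with (n, 1), so n acquisitions yield n pairs
#' (1,2), (2,3), ..., (n-1,n), (n,1).
#'
#' @param n number of acquisitions (>= 3).
#' @return n x 2 integer matrix of ordered (acquisition, reference) pairs.
#' @export
cyclic_pairs <- function(n) {
  if (n < 3L) stop("series error: need at least 3 acquisitions")
  cbind(seq_len(n), c(seq_len(n)[-1], 1L))
}

#' Migration between two acquisitions
#'
#' The rigid migration `M = pose_b o invert(pose_a)` (mapping
#' acquisition-a implant positions onto acquisition-b positions in the
#' bone frame), decomposed into six anatomical degrees of freedom about
#' the implant midpoint. Zero true motion yields an all-zero record up to
#' measurement error.
#'
#' @param pose_a,pose_b `acquisition_pose`s.
#' @param frame [anatomical_frame] (origin at the implant midpoint).
#' @return [migration_record].
#' @export
pair_migration <- function(pose_a, pose_b, frame) {
  stopifnot(inherits(pose_a, "acquisition_pose"),
            inherits(pose_b, "acquisition_pose"))
  M <- compose_transforms(pose_b$implant_in_bone,
                          invert_transform(pose_a$implant_in_bone))
  decompose_6dof(M, frame, pair = c(pose_a$index, pose_b$index))
}

records_to_table <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    data.frame(acquisition = r$pair[1], reference_acquisition = r$pair[2],
               t_ml = r$t_ml, t_dp = r$t_dp, t_pa = r$t_pa,
               r_fe = r$r_fe, r_ei = r$r_ei, r_vv = r$r_vv)
  }))
}

#' Run the full migration pipeline over a series
#'
#' Executes segment -> register -> relative pose -> cyclic pair migration
#' for a series of acquisitions. Any stage failure is re-raised with the
#' acquisition index and stage named.
#'
#' @param volumes list of [mmri_volume] (>= 3).
#' @param refs list with `bone` and `implant` reference meshes and `frame`
#'   (an [anatomical_frame]); ignored for the model-free method beyond the
#'   frame, where acquisition 1's segmentations become the references.
#' @param method "mmri-m", "mmri-a" or "mmri-w".
#' @param config list of per-stage parameters:
#'   `bone_window`, `implant_window` (intensity windows),
#'   `bone_seeds`, `implant_seeds` (per-acquisition lists of world-mm seed
#'   points, one row per connected component),
#'   `bone_erase`, `implant_erase` (optional per-acquisition lists of Nx3
#'   voxel-index matrices, the scripted manual-erase step),
#'   `landmarks` (for mmri-m: list with `model` and per-acquisition `seg`),
#'   `closing_radius`, `closing_mode`, `smooth_sigma`,
#'   `implant_offset_mm` (inward normal offset of the implant surface
#'   compensating the metal-artifact signal void),
#'   `refine_iterations` (passes of [refine_surface_subvoxel] on both
#'   surfaces; 0 disables),
#'   `n_sample`, `tol_mm`, `max_iter`, `trim`, `seed`.
#' @return list with `records` (data frame, one row per cyclic pair),
#'   `poses`, `registrations`, `segmentations`, `frame`, `provenance`.
#' @export
run_series <- function(volumes, refs, method = c("mmri-a", "mmri-m", "mmri-w"),
                       config = list()) {
  method <- match.arg(method)
  n <- length(volumes)
  if (n < 3L) stop("series error: need at least 3 acquisitions")
  cfg <- utils::modifyList(list(closing_radius = 1L, closing_mode = "slice",
                                smooth_sigma = 0.5, n_sample = 6000L,
                                tol_mm = 1e-4, max_iter = 100L, trim = 0,
                                implant_offset_mm = 0, refine_iterations = 3L,
                                seed = 1L), config)
  for (nm in c("bone_window", "implant_window", "bone_seeds", "implant_seeds")) {
    if (is.null(cfg[[nm]])) {
      stop(sprintf("configuration error: config$%s is required", nm))
    }
  }
  if (is.null(cfg$bone_erase)) cfg$bone_erase <- vector("list", n)
  if (is.null(cfg$implant_erase)) cfg$implant_erase <- vector("list", n)
  if (method == "mmri-m" &&
      (is.null(cfg$landmarks) || is.null(cfg$landmarks$model) ||
       is.null(cfg$landmarks$seg))) {
    stop("configuration error: mmri-m requires config$landmarks (model + per-acquisition seg)")
  }
  stage <- function(i, what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("acquisition %d, stage %s: %s", i, what,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  segs <- vector("list", n)
  for (i in seq_len(n)) {
    vol <- volumes[[i]]
    to_vox <- function(pts) {
      if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
      round(world_to_voxel(vol, pts))
    }
    segs[[i]] <- stage(i, "segment", list(
      bone = segment_structure(vol, cfg$bone_window,
                               to_vox(cfg$bone_seeds[[i]]),
                               erase = cfg$bone_erase[[i]],
                               closing_radius = cfg$closing_radius,
                               closing_mode = cfg$closing_mode,
                               smooth_sigma = cfg$smooth_sigma),
      implant = segment_structure(vol, cfg$implant_window,
                                  to_vox(cfg$implant_seeds[[i]]),
                                  erase = cfg$implant_erase[[i]],
                                  closing_radius = cfg$closing_radius,
                                  closing_mode = cfg$closing_mode,
                                  smooth_sigma = cfg$smooth_sigma)
    ))
    for (k in seq_len(cfg$refine_iterations)) {
      segs[[i]]$bone$mesh <- refine_surface_subvoxel(segs[[i]]$bone$mesh, vol,
                                                     cfg$bone_window)
      segs[[i]]$implant$mesh <- refine_surface_subvoxel(segs[[i]]$implant$mesh,
                                                        vol, cfg$implant_window)
    }
    if (cfg$implant_offset_mm != 0) {
      # compensate the artifact signal void: the apparent implant surface
      # sits one halo radius outside the metal
      segs[[i]]$implant$mesh <- mesh_offset(segs[[i]]$implant$mesh,
                                            -cfg$implant_offset_mm)
    }
  }
  use_refs <- refs
  if (method == "mmri-w") {
    use_refs <- list(bone = segs[[1]]$bone$mesh,
                     implant = segs[[1]]$implant$mesh)
  }
  regs <- vector("list", n)
  poses <- vector("list", n)
  for (i in seq_len(n)) {
    lm_i <- if (method == "mmri-m") {
      list(model = cfg$landmarks$model, seg = cfg$landmarks$seg[[i]])
    }
    regs[[i]] <- stage(i, "register",
      register_acquisition(segs[[i]]$bone$mesh, segs[[i]]$implant$mesh,
                           use_refs, method = method, landmarks = lm_i,
                           n_sample = cfg$n_sample, tol_mm = cfg$tol_mm,
                           max_iter = cfg$max_iter, seed = cfg$seed,
                           trim = cfg$trim))
    poses[[i]] <- relative_pose(regs[[i]]$bone, regs[[i]]$implant, index = i)
  }
  frame <- if (method == "mmri-w") {
    # model-free: report about the acquisition-1 implant centroid on grid axes
    anatomical_frame(origin = mesh_centroid(use_refs$implant))
  } else refs$frame
  pairs <- cyclic_pairs(n)
  records <- lapply(seq_len(n), function(k) {
    stage(pairs[k, 1], "migrate",
          pair_migration(poses[[pairs[k, 1]]], poses[[pairs[k, 2]]], frame))
  })
  list(records = records_to_table(records), migration_records = records,
       poses = poses, registrations = regs, segmentations = segs,
       frame = frame,
       provenance = list(method = method, n_acquisitions = n,
                         config = cfg[setdiff(names(cfg),
                                              c("bone_seeds", "implant_seeds",
                                                "landmarks"))],
                         euler_convention = euler_convention_tag(),
                         registration_rms = t(vapply(
                           poses, function(p) p$rms, numeric(2)))))
}

#' Run the pipeline on a simulated series
#'
#' Convenience wrapper binding [generate_series] output to [run_series]:
#' segmentation windows are derived from the phantom intensity model
#' (cut midway between adjacent label means), and seed points, landmarks
#' and the anatomical frame are taken from the ground-truth manifest — the
#' scripted equivalents of the interactive steps. The manual erase step is
#' scripted too: bone-mask voxels inside the metal-artifact shell around
#' the implant (partial-volume voxels whose mixed intensity falls into the
#' bone window) are erased, and ICP runs with 10 % correspondence trimming
#' to absorb the resulting artifact-cropped regions.
#'
#' @param series list from [generate_series].
#' @param method registration method.
#' @param config overrides merged over the derived configuration.
#' @return see [run_series].
#' @export
run_synthetic_series <- function(series, method = c("mmri-a", "mmri-m", "mmri-w"),
                                 config = list()) {
  method <- match.arg(method)
  man <- series$manifest
  geom <- build_phantom_geometry(man$spec)
  ints <- man$spec$intensity
  gg <- grid_geometry(man$spec, man$preset)
  erase_margin <- man$spec$artifact_halo_mm + max(gg$spacing)
  bone_erase <- lapply(man$acquisitions, function(a) {
    spec_i <- man$spec
    spec_i$implant_pose <- a$implant_in_bone
    near <- cpp_near_implant_mask(as.integer(gg$dims), gg$spacing, gg$origin,
                                  a$relocation$R, a$relocation$t,
                                  spec_for_cpp(spec_i), erase_margin)
    which(array(near, dim = gg$dims), arr.ind = TRUE)
  })
  derived <- list(
    # metal/void vs cortical: cut halfway; cortical vs trabecular likewise
    implant_window = c(-ints[["cortical"]] / 2,
                       (ints[["metal"]] + ints[["cortical"]]) / 2),
    bone_window = c((ints[["metal"]] + ints[["cortical"]]) / 2,
                    (ints[["cortical"]] + ints[["trabecular"]]) / 2),
    bone_erase = bone_erase,
    trim = 0.1,
    implant_offset_mm = man$spec$artifact_halo_mm,
    bone_seeds = lapply(man$acquisitions, function(a) a$seed_points$bone),
    implant_seeds = lapply(man$acquisitions, function(a)
      matrix(a$seed_points$implant, ncol = 3)),
    landmarks = list(model = {
      lm <- transform_points(man$spec$implant_pose, man$landmarks_model)
      rownames(lm) <- rownames(man$landmarks_model)
      lm
    }, seg = lapply(man$acquisitions, function(a) a$landmarks_world))
  )
  posed_implant <- transform_mesh(man$spec$implant_pose, geom$implant_mesh)
  refs <- list(bone = geom$bone_mesh,
               implant = posed_implant,
               frame = anatomical_frame(origin = mesh_centroid(posed_implant)))
  run_series(series$volumes, refs, method,
             utils::modifyList(derived, config))
}
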