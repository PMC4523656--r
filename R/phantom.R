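#' Anthropometry parameters for a synthetic phantom
#'
#' Parametric stand-ins for MRI-derived whole-body anatomical models: a
#' layered-sphere head (scalp skin, skull, CSF, grey matter, white matter,
#' plus deep sub-regions) and a simplified body assembled from a neck
#' cylinder, trunk ellipsoid, arm and leg cylinders, each layered
#' skin/fat/muscle with a bone core. All linear dimensions are in mm except
#' `height` (m). The default family is produced by isotropic scaling of one
#' reference adult geometry by stature, so the members differ only in
#' overall size unless per-layer overrides are given.
#'
#' @param name profile name.
#' @param height standing height in m.
#' @param head_outer_radius scalp outer radius, mm.
#' @param layers named list of head layer thicknesses in mm:
#'   `scalp`, `skull`, `csf`, `grey`; white matter fills the remainder.
#' @param voxel_size voxel edge, mm (1 or 2 by default usage).
#' @param trunk_semi_axes numeric(3) ellipsoid semi-axes (x = antero-
#'   posterior, y = lateral, z = cranio-caudal), mm.
#' @param neck_radius,neck_length,arm_radius,arm_length,leg_radius limb
#'   primitive dimensions, mm.
#' @param skin_thickness,fat_thickness body layer thicknesses, mm.
#' @param bone_fraction fraction of a limb radius occupied by the bone core.
#' @param margin air margin around the anatomy, mm (leaves room for
#'   electrodes).
#' @return An `anthropometry_params` object (list).
#' @export
anthropometry_params <- function(name, height, head_outer_radius,
                                 layers = list(scalp = 6, skull = 7,
                                               csf = 3, grey = 5),
                                 voxel_size = 1,
                                 trunk_semi_axes = c(100, 150, 300),
                                 neck_radius = 55, neck_length = 60,
                                 arm_radius = 40, arm_length = 600,
                                 leg_radius = 55,
                                 skin_thickness = 4, fat_thickness = 8,
                                 bone_fraction = 0.3, margin = 12) {
  p <- list(name = name, height = height,
            head_outer_radius = head_outer_radius, layers = layers,
            voxel_size = voxel_size, trunk_semi_axes = trunk_semi_axes,
            neck_radius = neck_radius, neck_length = neck_length,
            arm_radius = arm_radius, arm_length = arm_length,
            leg_radius = leg_radius, skin_thickness = skin_thickness,
            fat_thickness = fat_thickness, bone_fraction = bone_fraction,
            margin = margin)
  stopifnot(height > 0, head_outer_radius > 0, voxel_size > 0,
            all(unlist(layers) > 0), all(trunk_semi_axes > 0))
  if (sum(unlist(layers)) >= head_outer_radius)
    stop("head layer thicknesses must sum to less than the outer radius")
  class(p) <- "anthropometry_params"
  p
}

#' Reference adult geometry and the default three-member family
#'
#' `reference_adult_params()` is a 1.75 m adult with a 90 mm scalp radius.
#' `scale_profile()` scales every linear dimension isotropically by
#' stature. `default_profiles()` returns the three default members:
#' an adult female analogue (1.63 m), an adult male analogue (1.77 m) and
#' an adolescent analogue (1.47 m).
#'
#' @param voxel_size voxel edge in mm for the returned profiles.
#' @return `default_profiles()`: named list of `anthropometry_params`.
#' @export
reference_adult_params <- function(voxel_size = 1) {
  anthropometry_params("reference_adult", height = 1.75,
                       head_outer_radius = 90, voxel_size = voxel_size)
}

#' @rdname reference_adult_params
#' @param ref reference `anthropometry_params`.
#' @param name new profile name.
#' @param height new stature in m; the scale factor is `height/ref$height`.
#' @param layer_overrides optional named list replacing individual head
#'   layer thicknesses (mm) after scaling, for e.g. skull/CSF sensitivity
#'   studies.
#' @export
scale_profile <- function(ref, name, height, layer_overrides = NULL) {
  s <- height / ref$height
  layers <- lapply(ref$layers, function(t) t * s)
  if (!is.null(layer_overrides)) layers[names(layer_overrides)] <- layer_overrides
  anthropometry_params(
    name = name, height = height,
    head_outer_radius = ref$head_outer_radius * s, layers = layers,
    voxel_size = ref$voxel_size,
    trunk_semi_axes = ref$trunk_semi_axes * s,
    neck_radius = ref$neck_radius * s, neck_length = ref$neck_length * s,
    arm_radius = ref$arm_radius * s, arm_length = ref$arm_length * s,
    leg_radius = ref$leg_radius * s,
    skin_thickness = ref$skin_thickness * s,
    fat_thickness = ref$fat_thickness * s,
    bone_fraction = ref$bone_fraction, margin = ref$margin)
}

#' @rdname reference_adult_params
#' @export
default_profiles <- function(voxel_size = 1) {
  ref <- reference_adult_params(voxel_size)
  list(ella_like = scale_profile(ref, "ella_like", 1.63),
       duke_like = scale_profile(ref, "duke_like", 1.77),
       billie_like = scale_profile(ref, "billie_like", 1.47))
}

# Head layer outer radii (mm), outermost first: scalp, skull, csf, grey,
# white.
head_layer_radii <- function(params) {
  R <- params$head_outer_radius
  t <- params$layers
  r <- c(scalp = R,
         skull = R - t$scalp,
         csf = R - t$scalp - t$skull,
         grey = R - t$scalp - t$skull - t$csf,
         white = R - t$scalp - t$skull - t$csf - t$grey)
  if (any(diff(r) >= 0) || r[["white"]] <= 0)
    stop("head layer thicknesses exceed the outer radius")
  r
}

# Deep brain sub-regions as fixed fractional coordinates of the white
# sphere; the masks only exist to make per-tissue statistics computable,
# they are not anatomically faithful shapes. Assigned only where the
# current label is white matter (or cerebellum for the brainstem overlap).
deep_structure_specs <- function(r_w) {
  list(
    thalamus = list(kind = "spheres", radius = 0.13 * r_w,
                    centres = rbind(c(0, 0.14, 0.08), c(0, -0.14, 0.08)) * r_w),
    cerebellum = list(kind = "sphere", radius = 0.30 * r_w,
                      centre = c(-0.45, 0, -0.42) * r_w),
    midbrain = list(kind = "zcyl", radius = 0.11 * r_w, x0 = -0.10 * r_w,
                    zrange = c(-0.34, -0.18) * r_w),
    pons = list(kind = "zcyl", radius = 0.13 * r_w, x0 = -0.12 * r_w,
                zrange = c(-0.52, -0.34) * r_w),
    medulla_oblongata = list(kind = "zcyl", radius = 0.10 * r_w,
                             x0 = -0.14 * r_w,
                             zrange = c(-0.70, -0.52) * r_w))
}

# Paint deep structures into `lab` (3-D int array) around a head centre.
# xs, ys, zs are the world coordinates of the grid axes.
paint_deep_structures <- function(lab, xs, ys, zs, centre, r_w, lmap) {
  white_id <- lmap[["brain_white_matter"]]
  cere_id <- lmap[["cerebellum"]]
  specs <- deep_structure_specs(r_w)
  order_names <- c("cerebellum", "thalamus", "midbrain", "pons",
                   "medulla_oblongata")
  dx <- xs - centre[1]; dy <- ys - centre[2]; dz <- zs - centre[3]
  for (nm in order_names) {
    sp <- specs[[nm]]
    id <- lmap[[nm]]
    allowed <- if (nm %in% c("midbrain", "pons", "medulla_oblongata"))
      c(white_id, cere_id) else white_id
    if (sp$kind %in% c("sphere", "spheres")) {
      centres <- if (sp$kind == "sphere") rbind(sp$centre) else sp$centres
      mask <- array(FALSE, dim(lab))
      for (k in seq_len(nrow(centres))) {
        d2 <- outer(outer((dx - centres[k, 1])^2, (dy - centres[k, 2])^2,
                          `+`), (dz - centres[k, 3])^2, `+`)
        mask <- mask | (d2 <= sp$radius^2)
      }
    } else {
      rad2 <- outer((dx - sp$x0)^2, dy^2, `+`)
      inz <- dz >= sp$zrange[1] & dz <= sp$zrange[2]
      mask <- outer(rad2 <= sp$radius^2, inz, `&`)
    }
    target <- mask & array(lab %in% allowed, dim(lab))
    if (!any(target)) {
      # degenerate resolution: claim the white-matter voxel nearest the
      # structure centre so every tissue mask is non-empty
      cc <- if (sp$kind == "zcyl")
        centre + c(sp$x0, 0, mean(sp$zrange)) else
          centre + (if (sp$kind == "sphere") sp$centre else sp$centres[1, ])
      whites <- which(lab == white_id)
      if (length(whites)) {
        w <- arrayInd(whites, dim(lab))
        d2 <- (xs[w[, 1]] - cc[1])^2 + (ys[w[, 2]] - cc[2])^2 +
          (zs[w[, 3]] - cc[3])^2
        lab[whites[which.min(d2)]] <- id
      }
    } else {
      lab[target] <- id
    }
  }
  lab
}

# label a head sphere (layers + deep structures) into lab/depth arrays over
# the full grid coordinate axes; returns list(lab, depth) updated
paint_head <- function(lab, depth, xs, ys, zs, centre, params, lmap) {
  radii <- head_layer_radii(params)
  d2 <- outer(outer((xs - centre[1])^2, (ys - centre[2])^2, `+`),
              (zs - centre[3])^2, `+`)
  r <- sqrt(d2)
  inside <- r <= radii[["scalp"]]
  hd <- radii[["scalp"]] - r
  newlab <- array(0L, dim(lab))
  newlab[r <= radii[["scalp"]]] <- lmap[["skin"]]
  newlab[r <= radii[["skull"]]] <- lmap[["skull"]]
  newlab[r <= radii[["csf"]]] <- lmap[["cerebrospinal_fluid"]]
  newlab[r <= radii[["grey"]]] <- lmap[["brain_grey_matter"]]
  newlab[r <= radii[["white"]]] <- lmap[["brain_white_matter"]]
  take <- inside & (hd > depth)
  lab[take] <- newlab[take]
  depth[take] <- hd[take]
  list(lab = lab, depth = depth)
}

#' Build a layered-sphere head phantom
#'
#' Concentric spheres: scalp skin, skull, CSF, grey matter, white matter,
#' with deep sub-region masks (thalamus, midbrain, pons, medulla oblongata,
#' cerebellum) painted inside the white sphere at fixed fractional
#' coordinates. The grid is centred on the sphere with an odd voxel count
#' per axis, so the construction is exactly mirror-symmetric about the
#' midsagittal plane. Deterministic given the parameters.
#'
#' @param params an `anthropometry_params`.
#' @return A `label_volume` with `geometry$kind == "sphere_head"`.
#' @export
build_layered_sphere_head <- function(params) {
  lmap <- default_label_map()
  h <- params$voxel_size
  R <- params$head_outer_radius
  radii <- head_layer_radii(params)
  n_half <- ceiling((R + params$margin) / h)
  xs <- (-n_half:n_half) * h
  dims <- rep(2L * n_half + 1L, 3L)
  lab <- array(0L, dims)
  depth <- array(-Inf, dims)
  res <- paint_head(lab, depth, xs, xs, xs, c(0, 0, 0), params, lmap)
  lab <- paint_deep_structures(res$lab, xs, xs, xs, c(0, 0, 0),
                               radii[["white"]], lmap)
  geometry <- list(kind = "sphere_head", centre = c(0, 0, 0),
                   outer_radius = R, layer_radii = as.list(radii),
                   params = unclass(params))
  label_volume(lab, spacing = h, origin = rep(-n_half * h, 3),
               label_map = lmap, geometry = geometry)
}

# layered cylinder/ellipsoid painter: given depth-from-surface array and
# inside mask on the full grid, competes against current depth
paint_layered <- function(lab, depth, inside, pdepth, bone_mask, params,
                          lmap) {
  newlab <- array(lmap[["muscle"]], dim(lab))
  newlab[pdepth <= params$skin_thickness] <- lmap[["skin"]]
  newlab[pdepth > params$skin_thickness &
           pdepth <= params$skin_thickness + params$fat_thickness] <-
    lmap[["fat"]]
  if (!is.null(bone_mask)) newlab[bone_mask] <- lmap[["bone"]]
  take <- inside & (pdepth > depth)
  lab[take] <- newlab[take]
  depth[take] <- pdepth[take]
  list(lab = lab, depth = depth)
}

#' Build a simplified whole-body phantom
#'
#' Head sphere (as [build_layered_sphere_head()]) plus neck cylinder, trunk
#' ellipsoid, two arms and two legs, each layered skin/fat/muscle with a
#' bone core. Feet rest at z = 0 and the head vertex reaches the standing
#' height. All primitives overlap their neighbours so the conductive
#' anatomy is a single 6-connected component. Skin surface patches on the
#' lateral right mid-upper-arm and the anteromedial right mid-tibia are
#' recorded in the geometry metadata for extracephalic reference
#' electrodes.
#'
#' @param params an `anthropometry_params`.
#' @return A `label_volume` with `geometry$kind == "body"`.
#' @export
build_body_phantom <- function(params) {
  lmap <- default_label_map()
  h <- params$voxel_size
  R <- params$head_outer_radius
  H <- params$height * 1000
  m <- params$margin
  ax <- params$trunk_semi_axes[1]
  ay <- params$trunk_semi_axes[2]
  az <- params$trunk_semi_axes[3]
  z_head <- H - R
  z_trunk_top <- z_head - R - params$neck_length
  z_te <- z_trunk_top - az
  if (z_te - az <= 0)
    stop("body primitives do not fit the requested height: ",
         "trunk would extend below the feet")
  arm_top <- z_te + 0.8 * az
  arm_bot <- max(arm_top - params$arm_length, 0.05 * H)
  y_arm <- 0.75 * ay
  y_leg <- 0.45 * ay
  leg_top <- z_te - 0.55 * az
  ext_x <- max(ax, R) + m
  ext_y <- max(ay, y_arm + params$arm_radius) + m
  nxh <- ceiling(ext_x / h); nyh <- ceiling(ext_y / h)
  xs <- (-nxh:nxh) * h
  ys <- (-nyh:nyh) * h
  zs <- seq(-m, H + m + h, by = h)
  dims <- c(length(xs), length(ys), length(zs))
  lab <- array(0L, dims)
  depth <- array(-Inf, dims)

  zcyl <- function(lab, depth, x0, y0, radius, zlo, zhi, bone_frac) {
    rad2 <- outer((xs - x0)^2, (ys - y0)^2, `+`)
    inz <- zs >= zlo & zs <= zhi
    inside <- outer(rad2 <= radius^2, inz, `&`)
    pdepth <- outer(radius - sqrt(rad2), rep(0, length(zs)), `+`)
    bone <- outer(rad2 <= (bone_frac * radius)^2, inz, `&`)
    paint_layered(lab, depth, inside, pdepth, bone, params, lmap)
  }

  # trunk ellipsoid with a posterior spine column
  mnorm <- sqrt(outer(outer((xs / ax)^2, (ys / ay)^2, `+`),
                      ((zs - z_te) / az)^2, `+`))
  inside <- mnorm <= 1
  pdepth <- (1 - mnorm) * min(ax, ay, az)
  spine <- outer(outer((xs + 0.4 * ax)^2, ys^2, `+`) <= (0.15 * ax)^2,
                 abs(zs - z_te) <= 0.95 * az, `&`)
  res <- paint_layered(lab, depth, inside, pdepth, spine & (mnorm <= 0.9),
                       params, lmap)
  # neck
  res <- zcyl(res$lab, res$depth, 0, 0, params$neck_radius,
              z_trunk_top - 10, z_head, 0.25)
  # arms (left +y, right -y)
  res <- zcyl(res$lab, res$depth, 0, y_arm, params$arm_radius,
              arm_bot, arm_top, params$bone_fraction)
  res <- zcyl(res$lab, res$depth, 0, -y_arm, params$arm_radius,
              arm_bot, arm_top, params$bone_fraction)
  # legs
  res <- zcyl(res$lab, res$depth, 0, y_leg, params$leg_radius,
              0, leg_top, params$bone_fraction)
  res <- zcyl(res$lab, res$depth, 0, -y_leg, params$leg_radius,
              0, leg_top, params$bone_fraction)
  # head last against depth, then deep structures on the head subgrid
  res <- paint_head(res$lab, res$depth, xs, ys, zs, c(0, 0, z_head),
                    params, lmap)
  lab <- paint_deep_structures(res$lab, xs, ys, zs, c(0, 0, z_head),
                               head_layer_radii(params)[["white"]], lmap)

  geometry <- list(
    kind = "body", centre = c(0, 0, z_head), outer_radius = R,
    layer_radii = as.list(head_layer_radii(params)),
    right_arm = list(axis_xy = c(0, -y_arm), radius = params$arm_radius,
                     zrange = c(arm_bot, arm_top),
                     site_z = arm_top - 0.25 * (arm_top - arm_bot),
                     site_dir = c(0, -1)),
    right_tibia = list(axis_xy = c(0, -y_leg), radius = params$leg_radius,
                       zrange = c(0, leg_top),
                       site_z = 0.30 * leg_top,
                       site_dir = c(1, 0.5) / sqrt(1.25)),
    params = unclass(params))
  label_volume(lab, spacing = h,
               origin = c(-nxh * h, -nyh * h, -m),
               label_map = lmap, geometry = geometry)
}

#' Build a phantom family
#'
#' Builds one phantom per anthropometry profile (all sharing the tissue
#' vocabulary), by default the three-member family emulating two adults and
#' one adolescent.
#'
#' @param profiles named list of `anthropometry_params` (>= 2, unique
#'   names).
#' @param kind `"head"` for layered-sphere heads, `"body"` for whole-body
#'   phantoms.
#' @param voxel_size optional voxel edge (mm) overriding each profile's.
#' @return A `phantom_family`: named list of `label_volume`s.
#' @export
make_phantom_family <- function(profiles = default_profiles(),
                                kind = c("head", "body"),
                                voxel_size = NULL) {
  kind <- match.arg(kind)
  if (length(profiles) < 2) stop("a family needs at least 2 profiles")
  nms <- vapply(profiles, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate profile names: ",
                               paste(nms[duplicated(nms)], collapse = ", "))
  build <- if (kind == "head") build_layered_sphere_head else
    build_body_phantom
  fam <- lapply(profiles, function(p) {
    if (!is.null(voxel_size)) p$voxel_size <- voxel_size
    build(p)
  })
  names(fam) <- nms
  class(fam) <- "phantom_family"
  fam
}
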