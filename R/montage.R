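#' Electrode and montage specifications
#'
#' Clinical tDCS electrodes are modelled as a highly conductive rectangular
#' pad (5 x 7 cm, 5.9e7 S/m) on a saline sponge (7 x 8 cm, 0.3 S/m) that
#' contacts the skin. Pad and sponge sizes are given as
#' `c(long, short)` in mm; the long axis runs antero-posteriorly on the
#' scalp and along the limb axis at extracephalic sites.
#'
#' @param position one of the supported 10-20 labels (`F3`, `F4`, `T3`,
#'   `C3`, `C4`, `Fz`, ...) or an extracephalic site (`right_arm`,
#'   `right_tibia`).
#' @param role `"active"` or `"reference"`.
#' @param pad_size,sponge_size numeric(2) `c(long, short)` mm; the pad must
#'   fit inside the sponge footprint.
#' @param pad_thickness,sponge_thickness mm.
#' @return An `electrode_spec` (list).
#' @export
electrode_spec <- function(position, role = c("active", "reference"),
                           pad_size = c(70, 50), sponge_size = c(80, 70),
                           pad_thickness = 1, sponge_thickness = 5) {
  role <- match.arg(role)
  if (any(pad_size > sponge_size))
    stop("pad must be fully contained within the sponge footprint")
  structure(list(position = position, role = role, pad_size = pad_size,
                 sponge_size = sponge_size, pad_thickness = pad_thickness,
                 sponge_thickness = sponge_thickness),
            class = "electrode_spec")
}

#' @rdname electrode_spec
#' @param name montage name.
#' @param electrodes list of `electrode_spec`s: at least one active and
#'   exactly one reference.
#' @param injected_current_mA total injected current, mA (default 1).
#' @export
montage_spec <- function(name, electrodes, injected_current_mA = 1) {
  roles <- vapply(electrodes, `[[`, "", "role")
  if (sum(roles == "active") < 1 || sum(roles == "reference") != 1)
    stop("a montage needs >= 1 active and exactly 1 reference electrode")
  if (injected_current_mA <= 0) stop("injected current must be positive")
  structure(list(name = name, electrodes = electrodes,
                 injected_current_mA = injected_current_mA),
            class = "montage_spec")
}

#' The four standard clinical montages
#'
#' * `A`: active on F3, return on F4 (bifrontal, intracephalic);
#' * `B`: active on T3, reference on the right arm;
#' * `C`: two active pads on C3 and C4 (wired in parallel at the same
#'   potential, sharing the total current), reference on the right arm;
#' * `D`: active on Fz, reference on the right tibia.
#'
#' All inject a total of 1 mA by default.
#'
#' @param name `"A"`, `"B"`, `"C"` or `"D"`.
#' @return A `montage_spec`.
#' @export
standard_montage <- function(name) {
  defs <- list(
    A = list(c("F3", "active"), c("F4", "reference")),
    B = list(c("T3", "active"), c("right_arm", "reference")),
    C = list(c("C3", "active"), c("C4", "active"),
             c("right_arm", "reference")),
    D = list(c("Fz", "active"), c("right_tibia", "reference")))
  if (length(name) != 1 || !name %in% names(defs))
    stop("unknown montage name: ", paste(name, collapse = ","),
         " (expected A, B, C or D)")
  montage_spec(name, lapply(defs[[name]], function(e)
    electrode_spec(e[1], e[2])))
}

#' Montage specs as JSON
#' @param spec a `montage_spec`.
#' @param path JSON file path.
#' @export
write_montage_spec <- function(spec, path) {
  payload <- unclass(spec)
  payload$electrodes <- lapply(payload$electrodes, unclass)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_montage_spec
#' @export
read_montage_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  electrodes <- lapply(x$electrodes, function(e)
    electrode_spec(e$position, e$role, unlist(e$pad_size),
                   unlist(e$sponge_size), e$pad_thickness,
                   e$sponge_thickness))
  montage_spec(x$name, electrodes, x$injected_current_mA)
}

# unit vector for (inclination from vertex, azimuth from +x toward +y), deg
sph_unit <- function(theta, alpha) {
  th <- theta * pi / 180; al <- alpha * pi / 180
  c(sin(th) * cos(al), sin(th) * sin(al), cos(th))
}

# 10-20 positions as fixed angles on the fitted scalp sphere: 20% steps of
# the nasion-inion and ear-to-ear arcs are 18 degrees of inclination, and
# 10% of the circumference circle is 36 degrees of azimuth. F3/F4 (and
# P3/P4) are spherical midpoints of their neighbours, which is the
# classical crossing construction.
ten_twenty_unit <- function(position) {
  base <- list(Cz = c(0, 0),
               Fz = c(36, 0), Pz = c(36, 180),
               C3 = c(36, 90), C4 = c(36, -90),
               Fpz = c(72, 0), Oz = c(72, 180),
               Fp1 = c(72, 18), Fp2 = c(72, -18),
               F7 = c(72, 54), F8 = c(72, -54),
               T3 = c(72, 90), T4 = c(72, -90),
               T5 = c(72, 126), T6 = c(72, -126),
               O1 = c(72, 162), O2 = c(72, -162))
  mid <- function(a, b) { v <- a + b; v / sqrt(sum(v^2)) }
  if (position %in% names(base))
    return(sph_unit(base[[position]][1], base[[position]][2]))
  derived <- switch(position,
    F3 = mid(sph_unit(36, 0), sph_unit(72, 54)),
    F4 = mid(sph_unit(36, 0), sph_unit(72, -54)),
    P3 = mid(sph_unit(36, 180), sph_unit(72, 126)),
    P4 = mid(sph_unit(36, 180), sph_unit(72, -126)),
    NULL)
  if (is.null(derived))
    stop("unsupported 10-20 position: ", position)
  derived
}

#' Locate a 10-20 scalp position on a phantom
#'
#' Realizes the named position as fixed angular coordinates on the
#' phantom's scalp sphere and returns the surface point with a tangent
#' frame: `normal` (outward), `t1` (antero-posterior tangent, the pad long
#' axis), `t2` (`normal x t1`).
#'
#' @param head a `label_volume` whose geometry is a sphere head (or a body
#'   phantom, whose head part is used).
#' @param position supported 10-20 label.
#' @return list with `point` (mm world), `normal`, `t1`, `t2`.
#' @export
locate_1020 <- function(head, position) {
  g <- head$geometry
  if (is.null(g) || !g$kind %in% c("sphere_head", "body"))
    stop("phantom has no sphere-head geometry metadata")
  u <- ten_twenty_unit(position)
  centre <- g$centre
  R <- g$outer_radius
  t1 <- c(1, 0, 0) - u[1] * u
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(u[2] * t1[3] - u[3] * t1[2],
          u[3] * t1[1] - u[1] * t1[3],
          u[1] * t1[2] - u[2] * t1[1])
  list(point = centre + R * u, normal = u, t1 = t1, t2 = t2)
}

# site descriptor for any electrode position: either a spherical-cap site
# on the scalp or a cylindrical patch on a limb
locate_site <- function(phantom, position) {
  g <- phantom$geometry
  if (position %in% c("right_arm", "right_tibia")) {
    if (is.null(g) || g$kind != "body")
      stop("extracephalic position '", position,
           "' requires a body phantom")
    limb <- g[[position]]
    list(kind = "cylinder", axis_xy = limb$axis_xy, radius = limb$radius,
         site_z = limb$site_z, site_dir = limb$site_dir,
         zrange = limb$zrange)
  } else {
    loc <- locate_1020(phantom, position)
    list(kind = "sphere", centre = g$centre, radius = g$outer_radius,
         loc = loc)
  }
}

#' Place a montage's electrodes on a phantom
#'
#' Sponge voxels fill the sponge footprint in shells that follow the local
#' surface (radial shells on the scalp sphere, cylindrical shells on a
#' limb), starting at the skin; pad voxels fill the pad footprint on top of
#' the sponge. Thicknesses are realized as whole voxel shells (at least
#' one). Where two electrodes' nominal footprints approach each other
#' (e.g. bifrontal pads on a small head), each electrode only claims
#' voxels nearer its own centre than any other electrode's centre by at
#' least one voxel, which squeezes the sponges apart symmetrically and
#' guarantees no saline bridge; a warning reports how many voxels were
#' clipped. Placement is purely geometric and therefore bit-reproducible.
#'
#' @param phantom a `label_volume` from the phantom builders.
#' @param spec a `montage_spec`.
#' @return A `placed_montage`: list with `volume` (labels including sponge
#'   and pad), `active_nodes` and `reference_nodes` (1-based linear voxel
#'   indices of pad-conductor voxels), and `spec`.
#' @export
place_montage <- function(phantom, spec) {
  stopifnot(inherits(phantom, "label_volume"), inherits(spec, "montage_spec"))
  vol <- phantom
  h <- vol$spacing
  lmap <- vol$label_map
  node_sets <- list(active = integer(0), reference = integer(0))
  sites <- lapply(spec$electrodes, function(e)
    locate_site(phantom, e$position))
  centres <- lapply(sites, function(s) {
    if (s$kind == "sphere") s$loc$point else
      c(s$axis_xy + s$radius * s$site_dir, s$site_z)
  })
  for (ei in seq_along(spec$electrodes)) {
    e <- spec$electrodes[[ei]]
    site <- sites[[ei]]
    n_sp <- max(1L, round(e$sponge_thickness / h))
    n_pad <- max(1L, round(e$pad_thickness / h))
    if (site$kind == "sphere") {
      ctr <- site$centre; R <- site$radius
      loc <- site$loc
      half <- max(e$sponge_size) / 2 * 1.4 + (n_sp + n_pad + 2) * h
      rng <- lapply(1:3, function(a) {
        co <- axis_coords(vol, a)
        which(co >= loc$point[a] - half & co <= loc$point[a] + half)
      })
      idx <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
      w <- cbind(axis_coords(vol, 1)[idx[, 1]],
                 axis_coords(vol, 2)[idx[, 2]],
                 axis_coords(vol, 3)[idx[, 3]])
      v <- sweep(w, 2, ctr)
      r <- sqrt(rowSums(v^2))
      shell <- ceiling((r - R) / h - 1e-9)
      vhat <- v / r
      ca <- pmin(1, pmax(-1, vhat %*% loc$normal))
      ang <- acos(ca)
      d <- vhat - outer(as.vector(ca), loc$normal)
      dn <- sqrt(rowSums(d^2))
      dn[dn == 0] <- 1
      d <- d / dn
      u <- R * ang * (d %*% loc$t1)
      wv <- R * ang * (d %*% loc$t2)
    } else {
      rng <- lapply(1:3, function(a) seq_len(dim(vol$labels)[a]))
      half_u <- max(e$sponge_size) / 2 + 2 * h
      zco <- axis_coords(vol, 3)
      rng[[3]] <- which(zco >= site$site_z - half_u &
                          zco <= site$site_z + half_u)
      idx <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
      wx <- axis_coords(vol, 1)[idx[, 1]] - site$axis_xy[1]
      wy <- axis_coords(vol, 2)[idx[, 2]] - site$axis_xy[2]
      wz <- axis_coords(vol, 3)[idx[, 3]]
      w <- cbind(wx + site$axis_xy[1], wy + site$axis_xy[2], wz)
      rho <- sqrt(wx^2 + wy^2)
      shell <- ceiling((rho - site$radius) / h - 1e-9)
      u <- wz - site$site_z  # long axis along the limb
      beta <- atan2(wy, wx) - atan2(site$site_dir[2], site$site_dir[1])
      beta <- atan2(sin(beta), cos(beta))
      wv <- site$radius * beta
      r <- rho
    }
    lin <- idx[, 1] + dim(vol$labels)[1] * (idx[, 2] - 1L) +
      prod(dim(vol$labels)[1:2]) * (idx[, 3] - 1L)
    in_sponge <- shell >= 1 & shell <= n_sp &
      abs(u) <= e$sponge_size[1] / 2 & abs(wv) <= e$sponge_size[2] / 2
    in_pad <- shell > n_sp & shell <= n_sp + n_pad &
      abs(u) <= e$pad_size[1] / 2 & abs(wv) <= e$pad_size[2] / 2
    if (length(centres) > 1 && any(in_sponge | in_pad)) {
      d_own <- sqrt(rowSums(sweep(w, 2, centres[[ei]])^2))
      d_other <- rep(Inf, nrow(w))
      for (k in seq_along(centres)[-ei])
        d_other <- pmin(d_other,
                        sqrt(rowSums(sweep(w, 2, centres[[k]])^2)))
      near_own <- d_own <= d_other - h
      clipped <- sum((in_sponge | in_pad) & !near_own)
      if (clipped > 0)
        warning("electrode at ", e$position, ": ", clipped,
                " voxels clipped to keep a gap from a neighbouring ",
                "electrode", call. = FALSE)
      in_sponge <- in_sponge & near_own
      in_pad <- in_pad & near_own
    }
    tgt <- lin[in_sponge | in_pad]
    cur <- vol$labels[tgt]
    if (any(cur != 0L))
      stop("electrode at ", e$position, " overlaps existing non-air ",
           "voxels (another electrode or tissue); ",
           sum(cur != 0L), " voxels affected")
    vol$labels[lin[in_sponge]] <- lmap[["sponge"]]
    vol$labels[lin[in_pad]] <- lmap[["electrode_pad"]]
    node_sets[[e$role]] <- c(node_sets[[e$role]], lin[in_pad])
  }
  structure(list(volume = vol, active_nodes = sort(node_sets$active),
                 reference_nodes = sort(node_sets$reference),
                 spec = spec),
            class = "placed_montage")
}
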