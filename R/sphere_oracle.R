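#' Multilayer-sphere analytic model
#'
#' Verification standard for the voxel solver: the potential induced in a
#' homogeneous or concentric multilayer sphere by a point current source
#' and sink on its outer surface has a classical Legendre-series solution.
#' Per-shell radial coefficients follow from a 2x2 transfer-matrix
#' recursion enforcing continuity of the potential and of the radial
#' current density at each interface; the outer insulated boundary carries
#' the injected current as a surface delta expanded in Legendre
#' polynomials.
#'
#' @param radii outer radii of the shells in mm, strictly increasing
#'   (innermost first).
#' @param sigmas conductivity of each shell, S/m, all > 0.
#' @param source,sink unit vectors (or points, normalized internally) on
#'   the outer surface for the +I and -I electrodes.
#' @param current_mA injected current, mA.
#' @param L series truncation order (>= 1).
#' @return A `shell_model` list.
#' @export
shell_model <- function(radii, sigmas, source = c(0, 0, 1),
                        sink = c(sin(pi / 3), 0, -cos(pi / 3)),
                        current_mA = 1, L = 100) {
  stopifnot(length(radii) == length(sigmas), all(diff(radii) > 0),
            all(radii > 0), all(sigmas > 0), L >= 1)
  nrm <- function(v) v / sqrt(sum(v^2))
  structure(list(radii = radii, sigmas = sigmas, source = nrm(source),
                 sink = nrm(sink), current_mA = current_mA, L = as.integer(L)),
            class = "shell_model")
}

#' @rdname shell_model
#' @param model a `shell_model`.
#' @param path JSON path.
#' @export
write_shell_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname shell_model
#' @export
read_shell_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  shell_model(x$radii, x$sigmas, x$source, x$sink, x$current_mA, x$L)
}

# Radial coefficients (a_jl, b_jl) per shell for phi written in the
# normalized radius rho = r/R as sum_l c_l (a_j rho^l + b_j rho^-(l+1))
# P_l(cos gamma). Innermost shell has b = 0; interface continuity gives a
# closed-form 2x2 update; the outer Neumann condition fixes c_l.
shell_coefficients <- function(model) {
  S <- length(model$radii)
  R_m <- model$radii[S] * 1e-3
  t <- model$radii / model$radii[S]
  I_A <- model$current_mA * 1e-3
  L <- model$L
  a <- matrix(0, L, S); b <- matrix(0, L, S)
  cl <- numeric(L)
  for (l in seq_len(L)) {
    aj <- 1; bj <- 0
    a[l, 1] <- aj
    for (j in seq_len(S - 1)) {
      tj <- t[j]
      s_in <- model$sigmas[j]; s_out <- model$sigmas[j + 1]
      F1 <- aj * tj^l + bj * tj^(-(l + 1))
      F2 <- s_in * (l * aj * tj^(l - 1) - (l + 1) * bj * tj^(-(l + 2)))
      aj <- ((l + 1) * F1 + tj * F2 / s_out) * tj^(-l) / (2 * l + 1)
      bj <- (l * F1 - tj * F2 / s_out) * tj^(l + 1) / (2 * l + 1)
      a[l, j + 1] <- aj; b[l, j + 1] <- bj
    }
    deriv <- l * aj - (l + 1) * bj  # d/drho at rho = 1
    cl[l] <- I_A * (2 * l + 1) /
      (4 * pi * R_m * model$sigmas[S] * deriv)
  }
  list(a = a, b = b, cl = cl, t = t)
}

#' Analytic potential of a shell model at interior points
#'
#' Superposition of the +I source and -I sink series, truncated at the
#' model's order L (Legendre polynomials by upward recurrence, radial
#' powers accumulated incrementally, so memory stays O(points)). Points
#' close to the outer surface converge like `(r/R)^L`, so near-surface
#' evaluation needs a few hundred terms. A tail-magnitude estimate (last
#' term relative to the result scale) is attached; if it exceeds
#' `tail_tol` an error suggests a larger L.
#'
#' @param model a [shell_model()].
#' @param points n x 3 matrix of points (mm), strictly inside the outer
#'   radius.
#' @param tail_tol acceptable relative magnitude of the last series term.
#' @return Numeric vector of potentials (V) with attribute
#'   `"tail_estimate"`.
#' @export
analytic_potential <- function(model, points, tail_tol = 1e-3) {
  points <- rbind(points)
  r <- sqrt(rowSums(points^2))
  R <- model$radii[length(model$radii)]
  if (any(r >= R))
    stop("all points must lie strictly inside the outer radius")
  co <- shell_coefficients(model)
  L <- model$L
  S <- length(model$radii)
  shell_idx <- findInterval(r / R, co$t) + 1L
  shell_idx[shell_idx > S] <- S
  rho <- r / R
  rhat <- points / ifelse(r > 0, r, 1)
  x1 <- as.vector(rhat %*% model$source)
  x2 <- as.vector(rhat %*% model$sink)
  x1[r == 0] <- 0; x2[r == 0] <- 0
  # recurrences: P_l for both electrode axes, rho^l and rho^-(l+1)
  p1m <- rep(1, length(rho)); p1 <- x1
  p2m <- rep(1, length(rho)); p2 <- x2
  rho_pow <- rho                        # rho^1
  inv_rho <- ifelse(rho > 0, 1 / rho, 0)
  rho_inv_pow <- inv_rho^2              # rho^-2
  inner <- shell_idx == 1L              # b = 0 there
  phi <- numeric(length(rho))
  last_term <- 0
  for (l in seq_len(L)) {
    bterm <- co$b[l, shell_idx] * rho_inv_pow
    bterm[inner] <- 0
    radial <- co$a[l, shell_idx] * rho_pow + bterm
    term <- co$cl[l] * radial * (p1 - p2)
    phi <- phi + term
    if (l == L) last_term <- max(abs(term))
    pn1 <- ((2 * l + 1) * x1 * p1 - l * p1m) / (l + 1)
    p1m <- p1; p1 <- pn1
    pn2 <- ((2 * l + 1) * x2 * p2 - l * p2m) / (l + 1)
    p2m <- p2; p2 <- pn2
    rho_pow <- rho_pow * rho
    rho_inv_pow <- rho_inv_pow * inv_rho
  }
  scale <- max(abs(phi), na.rm = TRUE)
  tail <- if (scale > 0) last_term / scale else 0
  if (tail > tail_tol)
    stop(sprintf(paste0("series tail estimate %.2e exceeds %.1e; ",
                        "increase the truncation order L"), tail, tail_tol))
  attr(phi, "tail_estimate") <- tail
  phi
}

#' Voxelize a shell model into a label volume
#'
#' Shells are labelled innermost-first with synthetic ids 1..S; the
#' conductivity table for [assign_conductivity()] is generated to match.
#'
#' @param model a [shell_model()].
#' @param voxel_size mm.
#' @param margin air margin, mm.
#' @return list with `volume` (a `label_volume`) and `table` (a matching
#'   `conductivity_table`).
#' @export
voxelize_shell_model <- function(model, voxel_size, margin = 10) {
  R <- model$radii[length(model$radii)]
  n_half <- ceiling((R + margin) / voxel_size)
  xs <- (-n_half:n_half) * voxel_size
  r <- sqrt(outer(outer(xs^2, xs^2, `+`), xs^2, `+`))
  S <- length(model$radii)
  lab <- array(0L, rep(length(xs), 3))
  for (j in rev(seq_len(S))) lab[r <= model$radii[j]] <- 0L
  # assign outermost first then overwrite inwards
  for (j in rev(seq_len(S))) lab[r <= model$radii[j]] <- as.integer(j)
  lmap <- c(air = 0L)
  shells <- paste0("shell_", seq_len(S))
  lmap <- c(lmap, stats::setNames(seq_len(S), shells),
            sponge = 20L, electrode_pad = 21L)
  df <- data.frame(canonical_label = c(shells, "air", "sponge",
                                       "electrode_pad"),
                   aliases = "",
                   sigma_S_per_m = c(model$sigmas, 0, 0.3, 5.9e7),
                   source = "synthetic_shell_model",
                   stringsAsFactors = FALSE)
  vol <- label_volume(lab, spacing = voxel_size,
                      origin = rep(-n_half * voxel_size, 3),
                      label_map = lmap,
                      geometry = list(kind = "sphere_head",
                                      centre = c(0, 0, 0),
                                      outer_radius = R))
  list(volume = vol, table = new_conductivity_table(df))
}

#' Finite-difference solve of a shell model with small surface electrodes
#'
#' Places small square pad/sponge electrodes at the model's source and
#' sink directions, solves, and normalizes to the model current. Used by
#' [oracle_compare()].
#'
#' @param model a [shell_model()].
#' @param voxel_size mm.
#' @param electrode_mm edge length of the small square electrodes, mm.
#' @param config a [solver_config()].
#' @return A `tdcs_solution` (with the voxelized `volume` attached).
#' @export
solve_shell_model_fd <- function(model, voxel_size, electrode_mm = 12,
                                 config = solver_config()) {
  vox <- voxelize_shell_model(model, voxel_size)
  vol <- vox$volume
  sz <- c(electrode_mm, electrode_mm)
  mk <- function(role) electrode_spec("custom", role, pad_size = sz,
                                      sponge_size = sz + 2 * vol$spacing)
  spec <- montage_spec("shell", list(mk("active"), mk("reference")),
                       injected_current_mA = model$current_mA)
  # place at arbitrary unit vectors (not 10-20 named positions)
  placed <- place_at_directions(vol, spec,
                                list(model$source, model$sink))
  sol <- tdcs_solve(placed, vox$table, config)
  sol$volume <- placed$volume
  sol$electrode_mm <- electrode_mm
  sol
}

# place a montage's electrodes at explicit unit directions on a sphere
# phantom (bypasses the named-position lookup)
place_at_directions <- function(vol, spec, directions) {
  g <- vol$geometry
  stopifnot(g$kind == "sphere_head")
  h <- vol$spacing
  node_sets <- list(active = integer(0), reference = integer(0))
  for (k in seq_along(spec$electrodes)) {
    e <- spec$electrodes[[k]]
    u <- directions[[k]]
    t1 <- c(1, 0, 0) - u[1] * u
    if (sqrt(sum(t1^2)) < 1e-6) t1 <- c(0, 1, 0) - u[2] * u
    t1 <- t1 / sqrt(sum(t1^2))
    t2 <- c(u[2] * t1[3] - u[3] * t1[2], u[3] * t1[1] - u[1] * t1[3],
            u[1] * t1[2] - u[2] * t1[1])
    loc <- list(point = g$centre + g$outer_radius * u, normal = u,
                t1 = t1, t2 = t2)
    n_sp <- max(1L, round(e$sponge_thickness / h))
    n_pad <- max(1L, round(e$pad_thickness / h))
    half <- max(e$sponge_size) / 2 * 1.4 + (n_sp + n_pad + 2) * h
    rng <- lapply(1:3, function(a) {
      co <- axis_coords(vol, a)
      which(co >= loc$point[a] - half & co <= loc$point[a] + half)
    })
    idx <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
    w <- cbind(axis_coords(vol, 1)[idx[, 1]],
               axis_coords(vol, 2)[idx[, 2]],
               axis_coords(vol, 3)[idx[, 3]])
    v <- sweep(w, 2, g$centre)
    r <- sqrt(rowSums(v^2))
    shell <- ceiling((r - g$outer_radius) / h - 1e-9)
    vhat <- v / r
    ca <- pmin(1, pmax(-1, vhat %*% u))
    ang <- acos(ca)
    d <- vhat - outer(as.vector(ca), u)
    dn <- sqrt(rowSums(d^2)); dn[dn == 0] <- 1
    d <- d / dn
    uu <- g$outer_radius * ang * (d %*% t1)
    wv <- g$outer_radius * ang * (d %*% t2)
    lin <- idx[, 1] + dim(vol$labels)[1] * (idx[, 2] - 1L) +
      prod(dim(vol$labels)[1:2]) * (idx[, 3] - 1L)
    in_sponge <- shell >= 1 & shell <= n_sp &
      abs(uu) <= e$sponge_size[1] / 2 & abs(wv) <= e$sponge_size[2] / 2
    in_pad <- shell > n_sp & shell <= n_sp + n_pad &
      abs(uu) <= e$pad_size[1] / 2 & abs(wv) <= e$pad_size[2] / 2
    cur <- vol$labels[lin[in_sponge | in_pad]]
    if (any(cur != 0L)) stop("electrode placement overlaps non-air voxels")
    vol$labels[lin[in_sponge]] <- vol$label_map[["sponge"]]
    vol$labels[lin[in_pad]] <- vol$label_map[["electrode_pad"]]
    node_sets[[e$role]] <- c(node_sets[[e$role]], lin[in_pad])
  }
  structure(list(volume = vol, active_nodes = sort(node_sets$active),
                 reference_nodes = sort(node_sets$reference), spec = spec),
            class = "placed_montage")
}

#' Compare a finite-difference solution against the analytic series
#'
#' Errors are evaluated at conductive voxel centres, excluding a band
#' around each electrode (default two voxels' worth of the exclusion
#' radius scale) where the point-source idealization of the oracle and the
#' finite pad of the FD model legitimately differ. The two solutions are
#' gauge-aligned by removing the mean difference before computing errors
#' (the interior Neumann problem fixes the potential only up to a
#' constant).
#'
#' @param fd_solution a `tdcs_solution` from [solve_shell_model_fd()].
#' @param model the same [shell_model()].
#' @param exclude_mm radius around each electrode centre to exclude;
#'   default the larger of two voxels and 1.25 times the FD electrode
#'   size, since within the pad's own footprint the point-source
#'   idealization and the finite pad legitimately disagree by an amount
#'   that does not shrink with the grid.
#' @param outer_margin_mm thickness of the outermost rim to exclude
#'   (default one voxel): voxel centres within half a voxel of the
#'   spherical boundary see the staircase surface rather than the sphere,
#'   and the series converges arbitrarily slowly there.
#' @return list with `relative_l2`, `max_abs`, `n_points`, and a
#'   `per_shell` data frame.
#' @export
oracle_compare <- function(fd_solution, model, exclude_mm = NULL,
                           outer_margin_mm = NULL) {
  phi <- fd_solution$phi
  vol <- fd_solution$volume
  if (is.null(vol)) stop("fd_solution lacks its voxelized volume")
  R <- model$radii[length(model$radii)]
  if (abs(vol$geometry$outer_radius - R) > 1e-9)
    stop("grid and shell model do not match")
  h <- phi$spacing
  if (is.null(exclude_mm)) {
    pad_mm <- if (!is.null(fd_solution$electrode_mm))
      fd_solution$electrode_mm else 0
    exclude_mm <- max(2 * h, 1.25 * pad_mm)
  }
  if (is.null(outer_margin_mm)) outer_margin_mm <- h
  ok <- which(!is.na(phi$phi) &
                vol$labels != vol$label_map[["sponge"]] &
                vol$labels != vol$label_map[["electrode_pad"]])
  w <- voxel_world(vol, ok)
  r <- sqrt(rowSums(w^2))
  keep <- r < R - outer_margin_mm
  d_src <- sqrt(rowSums(sweep(w, 2, R * model$source)^2))
  d_snk <- sqrt(rowSums(sweep(w, 2, R * model$sink)^2))
  keep <- keep & d_src > exclude_mm & d_snk > exclude_mm
  ok <- ok[keep]; w <- w[keep, , drop = FALSE]
  ana <- analytic_potential(model, w)
  fd <- phi$phi[ok]
  shift <- mean(fd - ana)
  fd <- fd - shift
  err <- fd - ana
  shell_of <- findInterval(sqrt(rowSums(w^2)) / R,
                           model$radii / R) + 1L
  shell_of[shell_of > length(model$radii)] <- length(model$radii)
  per_shell <- do.call(rbind, lapply(seq_along(model$radii), function(j) {
    m <- shell_of == j
    data.frame(shell = j,
               relative_l2 = sqrt(sum(err[m]^2) / max(sum(ana[m]^2),
                                                      .Machine$double.eps)),
               max_abs = if (any(m)) max(abs(err[m])) else NA_real_,
               n = sum(m))
  }))
  list(relative_l2 = sqrt(sum(err^2) / sum(ana^2)),
       max_abs = max(abs(err)), n_points = length(ok),
       gauge_shift = shift, per_shell = per_shell)
}
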