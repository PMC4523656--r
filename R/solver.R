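#' Solver configuration
#'
#' @param relative_residual_tolerance stopping criterion for the
#'   preconditioned conjugate-gradient solver (relative to the right-hand
#'   side norm).
#' @param max_iterations iteration cap; exceeding it is an error.
#' @param solver_kind `"pcg"` (symmetric Gauss-Seidel preconditioned
#'   conjugate gradients) or `"direct"` (sparse Cholesky, small grids).
#' @return A `solver_config` list.
#' @export
solver_config <- function(relative_residual_tolerance = 1e-8,
                          max_iterations = 50000L,
                          solver_kind = c("pcg", "direct")) {
  stopifnot(relative_residual_tolerance > 0, max_iterations >= 1)
  structure(list(relative_residual_tolerance = relative_residual_tolerance,
                 max_iterations = as.integer(max_iterations),
                 solver_kind = match.arg(solver_kind)),
            class = "solver_config")
}

# Face conductances between voxel pairs along one axis: harmonic mean of
# the two voxel conductivities times face area over spacing. With
# isotropic spacing h (mm), g = sigma_face * h * 1e-3 siemens. A zero
# conductivity on either side gives zero conductance, which encodes the
# insulating (no-flux) condition at skin-air faces and at the bounding
# box.
face_conductance <- function(s1, s2, spacing_mm) {
  num <- 2 * s1 * s2
  den <- s1 + s2
  g <- ifelse(den > 0, num / den, 0)
  g * spacing_mm * 1e-3
}

#' Assemble the finite-volume Laplace system
#'
#' Seven-point box-integration discretization of `div(sigma grad phi) = 0`
#' on the voxel grid. Unknowns are the conductive voxels 6-connected to
#' the electrodes, excluding the pad voxels, which enter as Dirichlet
#' boundary values (all active pads at +1 V, the reference pad at 0 V; the
#' physical scale is fixed afterwards by [normalize_to_current()]).
#'
#' @param sigma_vol a `conductivity_volume` for the placed label volume.
#' @param placed a `placed_montage`.
#' @return An `fd_system`: sparse SPD matrix `A`, right-hand side `b`,
#'   index maps, and references to the inputs.
#' @export
assemble_system <- function(sigma_vol, placed) {
  stopifnot(inherits(placed, "placed_montage"))
  dims <- dim(sigma_vol$sigma)
  n <- prod(dims)
  sigma <- sigma_vol$sigma
  h <- sigma_vol$spacing
  if (length(placed$active_nodes) == 0 || length(placed$reference_nodes) == 0)
    stop("empty electrode node set")
  cond <- as.vector(sigma > 0)
  comp <- as.vector(flood_fill(array(cond, dims), placed$active_nodes))
  if (!any(comp[placed$reference_nodes]))
    stop("active and reference electrodes are not connected through ",
         "conductive voxels")
  dir_val <- rep(NA_real_, n)
  dir_val[placed$active_nodes] <- 1
  dir_val[placed$reference_nodes] <- 0
  unknown <- comp & is.na(dir_val)
  uid <- integer(n)
  uid[unknown] <- seq_len(sum(unknown))
  nu <- sum(unknown)

  ii <- vector("list", 9L); jj <- vector("list", 9L); xx <- vector("list", 9L)
  bb <- numeric(nu)
  k <- 0L
  strides <- c(1L, dims[1], dims[1] * dims[2])
  for (axis in 1:3) {
    slab <- slice.index(array(0L, dims), axis)
    first <- as.vector(slab <= dims[axis] - 1L)
    i1 <- which(first & comp)
    i2 <- i1 + strides[axis]
    keep <- comp[i2]
    i1 <- i1[keep]; i2 <- i2[keep]
    g <- face_conductance(sigma[i1], sigma[i2], h)
    nz <- g > 0
    i1 <- i1[nz]; i2 <- i2[nz]; g <- g[nz]
    u1 <- uid[i1]; u2 <- uid[i2]
    both <- u1 > 0L & u2 > 0L
    if (any(both)) {
      k <- k + 1L
      ii[[k]] <- c(u1[both], u2[both], u1[both], u2[both])
      jj[[k]] <- c(u2[both], u1[both], u1[both], u2[both])
      xx[[k]] <- c(-g[both], -g[both], g[both], g[both])
    }
    d1 <- u1 > 0L & u2 == 0L  # unknown next to a Dirichlet pad voxel
    if (any(d1)) {
      k <- k + 1L
      ii[[k]] <- u1[d1]; jj[[k]] <- u1[d1]; xx[[k]] <- g[d1]
      bb_add <- g[d1] * dir_val[i2[d1]]
      bb[u1[d1]] <- bb[u1[d1]] +
        ifelse(is.na(bb_add), 0, bb_add)
    }
    d2 <- u2 > 0L & u1 == 0L
    if (any(d2)) {
      k <- k + 1L
      ii[[k]] <- u2[d2]; jj[[k]] <- u2[d2]; xx[[k]] <- g[d2]
      bb_add <- g[d2] * dir_val[i1[d2]]
      bb[u2[d2]] <- bb[u2[d2]] + ifelse(is.na(bb_add), 0, bb_add)
    }
  }
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(nu, nu))
  structure(list(A = A, b = bb, uid = uid, unknown = unknown,
                 dir_val = dir_val, dims = dims, spacing = h,
                 sigma_vol = sigma_vol, placed = placed,
                 component = comp),
            class = "fd_system")
}

#' Solve for the electric potential
#'
#' @param system an `fd_system` from [assemble_system()].
#' @param config a [solver_config()].
#' @return A `potential_volume`: `phi` (V, 3-D array, `NA` on air and on
#'   conductive voxels not connected to the electrodes), plus solver
#'   diagnostics (`iterations`, `relative_residual`).
#' @export
solve_potential <- function(system, config = solver_config()) {
  stopifnot(inherits(system, "fd_system"))
  if (config$solver_kind == "direct") {
    x <- as.numeric(Matrix::solve(system$A, system$b))
    it <- NA_integer_
    relres <- as.numeric(sqrt(sum((system$b - system$A %*% x)^2)) /
                           sqrt(sum(system$b^2)))
  } else {
    A <- methods::as(system$A, "CsparseMatrix")
    res <- .pcg_sgs(A@p, A@i, A@x, system$b,
                    config$relative_residual_tolerance,
                    config$max_iterations)
    if (res$relative_residual > config$relative_residual_tolerance)
      stop(sprintf(
        "PCG did not converge in %d iterations (relative residual %.3e)",
        config$max_iterations, res$relative_residual))
    x <- res$x
    it <- res$iterations
    relres <- res$relative_residual
  }
  phi <- rep(NA_real_, prod(system$dims))
  phi[system$unknown] <- x
  fixed <- !is.na(system$dir_val)
  phi[fixed] <- system$dir_val[fixed]
  phi[!system$component] <- NA_real_
  phi[fixed] <- system$dir_val[fixed]
  structure(list(phi = array(phi, system$dims), spacing = system$spacing,
                 origin = system$sigma_vol$origin,
                 iterations = it, relative_residual = relres),
            class = "potential_volume")
}

#' Electric field and current density from the potential
#'
#' `E = -grad(phi)` by central differences on conductive voxels, falling
#' back to one-sided differences where a neighbour is air or outside the
#' solved domain (tissue-air faces, electrode-adjacent voxels);
#' `J = sigma * E` voxelwise. Air voxels carry zero field by definition.
#'
#' @param phi a `potential_volume`.
#' @param sigma_vol the matching `conductivity_volume`.
#' @return list with `E` and `J` `field_volume`s: `values` (4-D array,
#'   last dimension the component; V/m and A/m^2) and `amplitude`
#'   (Euclidean norm).
#' @export
compute_fields <- function(phi, sigma_vol) {
  dims <- dim(phi$phi)
  h_m <- phi$spacing * 1e-3
  p <- phi$phi
  ok <- !is.na(p) & sigma_vol$sigma > 0
  E <- array(0, c(dims, 3L))
  strides <- c(1L, dims[1], dims[1] * dims[2])
  pv <- as.vector(p)
  okv <- as.vector(ok)
  n <- length(pv)
  for (axis in 1:3) {
    s <- strides[axis]
    slab <- as.vector(slice.index(array(0L, dims), axis))
    hasm <- slab > 1L
    hasp <- slab < dims[axis]
    vm <- rep(FALSE, n); vp <- rep(FALSE, n)
    vm[hasm] <- okv[which(hasm) - s]
    vp[hasp] <- okv[which(hasp) + s]
    vm <- vm & okv; vp <- vp & okv
    grad <- numeric(n)
    central <- vm & vp
    icen <- which(central)
    grad[icen] <- (pv[icen + s] - pv[icen - s]) / (2 * h_m)
    ifwd <- which(okv & vp & !vm)
    grad[ifwd] <- (pv[ifwd + s] - pv[ifwd]) / h_m
    ibwd <- which(okv & vm & !vp)
    grad[ibwd] <- (pv[ibwd] - pv[ibwd - s]) / h_m
    E[, , , axis] <- array(-grad, dims)
  }
  amp_E <- sqrt(E[, , , 1]^2 + E[, , , 2]^2 + E[, , , 3]^2)
  J <- E * as.vector(sigma_vol$sigma)
  amp_J <- amp_E * sigma_vol$sigma
  list(E = structure(list(values = E, amplitude = amp_E, units = "V/m",
                          spacing = phi$spacing, origin = phi$origin),
                     class = "field_volume"),
       J = structure(list(values = J, amplitude = amp_J, units = "A/m^2",
                          spacing = phi$spacing, origin = phi$origin),
                     class = "field_volume"))
}

#' Signed current through the closed surface around a voxel set
#'
#' Sums the face currents `g * (phi_in - phi_out)` over every grid face
#' separating the set from the rest of the conductive domain. With the
#' set equal to the active pad(s) this is the injected current; by the
#' discrete divergence theorem any separating closed surface gives the
#' same value up to the solver residual.
#'
#' @param system an `fd_system`.
#' @param phi a `potential_volume` solved on it.
#' @param voxel_set 1-based linear indices defining the enclosed set.
#' @return Net outward current in mA.
#' @export
surface_current <- function(system, phi, voxel_set) {
  dims <- system$dims
  sigma <- as.vector(system$sigma_vol$sigma)
  h <- system$spacing
  pv <- as.vector(phi$phi)
  inset <- rep(FALSE, prod(dims))
  inset[voxel_set] <- TRUE
  total <- 0
  strides <- c(1L, dims[1], dims[1] * dims[2])
  for (axis in 1:3) {
    slab <- as.vector(slice.index(array(0L, dims), axis))
    i1 <- which(slab <= dims[axis] - 1L)
    i2 <- i1 + strides[axis]
    cross <- xor(inset[i1], inset[i2])
    i1 <- i1[cross]; i2 <- i2[cross]
    g <- face_conductance(sigma[i1], sigma[i2], h)
    dphi <- ifelse(inset[i1], pv[i1] - pv[i2], pv[i2] - pv[i1])
    dphi[is.na(dphi)] <- 0
    total <- total + sum(g * dphi)
  }
  total * 1e3  # A -> mA
}

#' Discrete divergence of J at non-electrode conductive voxels
#'
#' Conservation diagnostic: net face current out of each voxel, normalized
#' by the mean absolute face current. Near zero (solver tolerance)
#' everywhere off the electrodes.
#'
#' @inheritParams surface_current
#' @return list with `max_relative` and the raw `divergence` array (A).
#' @export
divergence_residual <- function(system, phi) {
  dims <- system$dims
  sigma <- as.vector(system$sigma_vol$sigma)
  h <- system$spacing
  pv <- as.vector(phi$phi)
  div <- numeric(prod(dims))
  totflux <- 0
  nfaces <- 0
  strides <- c(1L, dims[1], dims[1] * dims[2])
  for (axis in 1:3) {
    slab <- as.vector(slice.index(array(0L, dims), axis))
    i1 <- which(slab <= dims[axis] - 1L)
    i2 <- i1 + strides[axis]
    g <- face_conductance(sigma[i1], sigma[i2], h)
    nz <- g > 0 & !is.na(pv[i1]) & !is.na(pv[i2])
    i1 <- i1[nz]; i2 <- i2[nz]; g <- g[nz]
    f <- g * (pv[i1] - pv[i2])
    div[i1] <- div[i1] + f
    div[i2] <- div[i2] - f
    totflux <- totflux + sum(abs(f))
    nfaces <- nfaces + length(f)
  }
  interior <- system$unknown
  scale <- totflux / max(nfaces, 1L)
  list(max_relative = max(abs(div[interior])) / scale,
       divergence = array(div, dims))
}

#' Scale a solution to the target injected current
#'
#' The Laplace problem is linear, so the provisional unit-volt solution is
#' rescaled by `target / achieved`, where the achieved current is the
#' summed signed face current over the closed voxel surface enclosing the
#' active pad(s).
#'
#' @param solution a `tdcs_solution` from [tdcs_solve()] (or a list with
#'   `phi`, `E`, `J`, `system`).
#' @param target_mA target total injected current, mA.
#' @return The solution with `phi`, `E`, `J` scaled, and
#'   `achieved_current_mA` / `provisional_current_mA` recorded.
#' @export
normalize_to_current <- function(solution, target_mA) {
  I0 <- surface_current(solution$system, solution$phi,
                        solution$system$placed$active_nodes)
  if (!is.finite(I0) || abs(I0) < 1e-12)
    stop("achieved current is ~0 (open circuit): cannot normalize")
  sc <- target_mA / I0
  solution$phi$phi <- solution$phi$phi * sc
  for (f in c("E", "J")) {
    solution[[f]]$values <- solution[[f]]$values * sc
    solution[[f]]$amplitude <- solution[[f]]$amplitude * abs(sc)
  }
  solution$provisional_current_mA <- I0
  solution$achieved_current_mA <- surface_current(
    solution$system, solution$phi, solution$system$placed$active_nodes)
  solution$scale_factor <- sc
  solution
}

#' Full forward solve for one placed montage
#'
#' Assigns conductivities, assembles and solves the finite-volume system,
#' derives E and J, and normalizes to the montage's injected current.
#'
#' @param placed a `placed_montage`.
#' @param table a `conductivity_table`.
#' @param config a [solver_config()].
#' @param normalize normalize to the montage's injected current (default
#'   TRUE).
#' @return A `tdcs_solution`: `phi`, `E`, `J`, `system`,
#'   `achieved_current_mA`, solver diagnostics.
#' @export
tdcs_solve <- function(placed, table = default_conductivity_table(),
                       config = solver_config(), normalize = TRUE) {
  sigma_vol <- assign_conductivity(placed$volume, table)
  system <- assemble_system(sigma_vol, placed)
  phi <- solve_potential(system, config)
  fields <- compute_fields(phi, sigma_vol)
  sol <- structure(list(phi = phi, E = fields$E, J = fields$J,
                        system = system,
                        iterations = phi$iterations,
                        relative_residual = phi$relative_residual),
                   class = "tdcs_solution")
  if (normalize)
    sol <- normalize_to_current(sol, placed$spec$injected_current_mA)
  sol
}
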