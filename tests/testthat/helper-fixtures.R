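# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# coarse reference-adult head with montage A solved (used by several
# solver and metrics tests)
small_head_solution <- function() {
  fixture("small_head_solution", function() {
    p <- reference_adult_params(voxel_size = 4)
    head <- build_layered_sphere_head(p)
    placed <- suppressWarnings(place_montage(head, standard_montage("A")))
    sol <- tdcs_solve(placed)
    list(params = p, head = head, placed = placed, sol = sol)
  })
}

# coarse body phantom for extracephalic placement tests
small_body <- function() {
  fixture("small_body", function() {
    p <- reference_adult_params(voxel_size = 6)
    build_body_phantom(p)
  })
}

# a tiny bar phantom with Dirichlet ends, as a hand-checkable system:
# dims (nx,1,1) would make 6-neighbour assembly degenerate at the single
# transverse voxel, so the bar is nx x 1 x 1 literally (transverse faces
# simply have no neighbours).
bar_system <- function(nx = 3, sigma = 1, spacing = 1) {
  lab <- array(1L, c(nx, 1L, 1L))
  vol <- label_volume(lab, spacing = spacing,
                      label_map = c(air = 0L, tissue = 1L,
                                    sponge = 20L, electrode_pad = 21L))
  sv <- structure(list(sigma = array(sigma, dim(lab)),
                       spacing = spacing, origin = vol$origin),
                  class = "conductivity_volume")
  placed <- structure(list(volume = vol, active_nodes = 1L,
                           reference_nodes = nx,
                           spec = montage_spec("bar", list(
                             electrode_spec("F3", "active"),
                             electrode_spec("F4", "reference")))),
                      class = "placed_montage")
  assemble_system(sv, placed)
}

# assemble a system for an arbitrary sigma array with given Dirichlet
# node sets (1-based linear indices)
raw_system <- function(sigma_arr, active, reference, spacing = 1,
                       current_mA = 1) {
  lab <- array(1L, dim(sigma_arr))
  lab[sigma_arr == 0] <- 0L
  vol <- label_volume(lab, spacing = spacing,
                      label_map = c(air = 0L, tissue = 1L,
                                    sponge = 20L, electrode_pad = 21L))
  sv <- structure(list(sigma = sigma_arr, spacing = spacing,
                       origin = vol$origin),
                  class = "conductivity_volume")
  placed <- structure(list(volume = vol, active_nodes = as.integer(active),
                           reference_nodes = as.integer(reference),
                           spec = montage_spec("raw", list(
                             electrode_spec("F3", "active"),
                             electrode_spec("F4", "reference")),
                             injected_current_mA = current_mA)),
                      class = "placed_montage")
  assemble_system(sv, placed)
}

solve_raw <- function(system, config = solver_config()) {
  phi <- solve_potential(system, config)
  fields <- compute_fields(phi, system$sigma_vol)
  structure(list(phi = phi, E = fields$E, J = fields$J, system = system),
            class = "tdcs_solution")
}

axis_coords_for_test <- function(vol, a)
  vol$origin[a] + (seq_len(dim(vol$labels)[a]) - 1) * vol$spacing

# all n! orderings of seq_len(n), one per row (used as a permutation oracle)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}
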