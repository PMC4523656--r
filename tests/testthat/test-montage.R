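test_that("the four standard montages have the prescribed electrodes", {
  pos <- function(m) vapply(standard_montage(m)$electrodes, `[[`, "",
                            "position")
  rol <- function(m) vapply(standard_montage(m)$electrodes, `[[`, "",
                            "role")
  expect_identical(pos("A"), c("F3", "F4"))
  expect_identical(pos("B"), c("T3", "right_arm"))
  expect_identical(pos("C"), c("C3", "C4", "right_arm"))
  expect_identical(rol("C"), c("active", "active", "reference"))
  expect_identical(pos("D"), c("Fz", "right_tibia"))
  for (m in c("A", "B", "C", "D"))
    expect_identical(standard_montage(m)$injected_current_mA, 1)
  expect_error(standard_montage("E"), "unknown montage")
})

test_that("montage specs validate their electrode roles and round-trip", {
  expect_error(montage_spec("x", list(electrode_spec("F3", "active"))),
               "exactly 1 reference")
  expect_error(electrode_spec("F3", "active", pad_size = c(90, 50)),
               "contained within the sponge")
  tf <- withr::local_tempfile(fileext = ".json")
  spec <- standard_montage("C")
  write_montage_spec(spec, tf)
  back <- read_montage_spec(tf)
  expect_equal(unclass(back), unclass(spec), ignore_attr = TRUE)
})

test_that("10-20 positions land at the standard angular coordinates", {
  head <- small_head_solution()$head
  fz <- locate_1020(head, "Fz")
  # midline: no lateral offset
  expect_lt(abs(fz$point[2]), head$spacing)
  expect_gt(fz$point[1], 0)  # anterior
  c3 <- locate_1020(head, "C3"); c4 <- locate_1020(head, "C4")
  expect_equal(c3$point * c(1, -1, 1), c4$point, tolerance = 1e-9)
  expect_gt(c3$point[2], 0)  # left is +y
  f3 <- locate_1020(head, "F3")
  expect_gt(f3$point[1], 0)  # anterior of the vertex
  expect_gt(f3$point[2], 0)  # left of the midline
  # all named points lie on the scalp sphere
  for (p in c("Fz", "Cz", "Pz", "F3", "F4", "T3", "C3", "C4", "F7"))
    expect_equal(sqrt(sum(locate_1020(head, p)$point^2)),
                 head$geometry$outer_radius, tolerance = 1e-9)
  expect_error(locate_1020(head, "XX"), "unsupported 10-20")
})

test_that("pad voxel count matches the nominal pad volume", {
  # single scalp electrode far from any neighbour: no clipping
  p <- reference_adult_params(voxel_size = 2)
  head <- build_layered_sphere_head(p)
  spec <- montage_spec("fz_oz", list(electrode_spec("Fz", "active"),
                                     electrode_spec("Oz", "reference")))
  placed <- place_montage(head, spec)
  h <- head$spacing
  n_pad_shells <- max(1, round(1 / h))
  expected <- 35e2 * (n_pad_shells * h) / h^3  # 35 cm^2 footprint
  expect_lt(abs(length(placed$active_nodes) - expected) / expected, 0.10)
  expect_lt(abs(length(placed$reference_nodes) - expected) / expected, 0.10)
})

test_that("montage A placement is mirror-symmetric about the midsagittal plane", {
  placed <- small_head_solution()$placed
  lab <- placed$volume$labels
  expect_identical(lab, lab[, dim(lab)[2]:1, ])
})

test_that("pads touch skin only through their sponge", {
  placed <- small_head_solution()$placed
  lab <- placed$volume$labels
  lmap <- placed$volume$label_map
  pad <- which(lab == lmap[["electrode_pad"]])
  d <- dim(lab)
  strides <- c(1, d[1], d[1] * d[2], -1, -d[1], -d[1] * d[2])
  for (s in strides) {
    nb <- pad + s
    nb <- nb[nb >= 1 & nb <= prod(d)]
    expect_false(any(lab[nb] == lmap[["skin"]]))
  }
  # every sponge voxel is near skin or pad: sponges form the only bridge
  sponge <- which(lab == lmap[["sponge"]])
  touches <- matrix(FALSE, length(sponge), 2)
  for (s in strides) {
    nb <- sponge + s
    ok <- nb >= 1 & nb <= prod(d)
    touches[ok, 1] <- touches[ok, 1] | lab[nb[ok]] == lmap[["skin"]]
    touches[ok, 2] <- touches[ok, 2] | lab[nb[ok]] == lmap[["electrode_pad"]]
  }
  expect_gt(sum(touches[, 1]), 0)
  expect_gt(sum(touches[, 2]), 0)
})

test_that("placement is deterministic and validates preconditions", {
  head <- small_head_solution()$head
  p1 <- suppressWarnings(place_montage(head, standard_montage("A")))
  p2 <- suppressWarnings(place_montage(head, standard_montage("A")))
  expect_identical(p1$volume$labels, p2$volume$labels)
  expect_identical(p1$active_nodes, p2$active_nodes)
  # extracephalic montage on a head-only phantom
  expect_error(place_montage(head, standard_montage("B")),
               "requires a body phantom")
})

test_that("extracephalic montages place on the body phantom", {
  body <- small_body()
  for (m in c("B", "C", "D")) {
    placed <- place_montage(body, standard_montage(m))
    expect_gt(length(placed$active_nodes), 0)
    expect_gt(length(placed$reference_nodes), 0)
    expect_length(intersect(placed$active_nodes, placed$reference_nodes), 0)
  }
})
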