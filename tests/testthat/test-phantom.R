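test_that("layered sphere head has the constructed layer radii", {
  p <- anthropometry_params("t", height = 1.7, head_outer_radius = 85,
                            layers = list(scalp = 6, skull = 7, csf = 3,
                                          grey = 4),
                            voxel_size = 2)
  head <- build_layered_sphere_head(p)
  lmap <- head$label_map
  centre_idx <- (dim(head)[1] + 1) / 2
  # white-matter sphere radius 85 - 20 = 65 mm; the origin voxel is white
  expect_identical(head$labels[centre_idx, centre_idx, centre_idx],
                   lmap[["brain_white_matter"]])
  r_on_axis <- abs(axis_coords_for_test(head, 1))
  on_axis <- head$labels[, centre_idx, centre_idx]
  expect_true(all(on_axis[r_on_axis <= 65 - 2] %in%
                    c(lmap[["brain_white_matter"]], lmap[["thalamus"]],
                      lmap[["midbrain"]], lmap[["pons"]],
                      lmap[["medulla_oblongata"]], lmap[["cerebellum"]])))
  # layer radii: white 65, grey 69, csf 72, skull 79, scalp 85
  at_r <- function(r) on_axis[match(r, axis_coords_for_test(head, 1))]
  expect_identical(at_r(64), lmap[["brain_white_matter"]])
  expect_identical(at_r(68), lmap[["brain_grey_matter"]])
  expect_identical(at_r(70), lmap[["cerebrospinal_fluid"]])
  expect_identical(at_r(74), lmap[["skull"]])
  expect_identical(at_r(80), lmap[["skin"]])
  expect_identical(at_r(86), 0L)
  # deterministic
  expect_identical(head$labels, build_layered_sphere_head(p)$labels)
  # impossible layering errors
  p_bad <- p; p_bad$layers$skull <- 80
  expect_error(build_layered_sphere_head(p_bad), "exceed")
})

test_that("grey-shell voxel volume approximates the analytic shell volume", {
  p <- anthropometry_params("t", height = 1.7, head_outer_radius = 85,
                            layers = list(scalp = 6, skull = 7, csf = 3,
                                          grey = 4),
                            voxel_size = 1)
  head <- build_layered_sphere_head(p)
  n_grey <- sum(head$labels == head$label_map[["brain_grey_matter"]])
  analytic <- 4 * pi / 3 * (69^3 - 65^3)
  expect_lt(abs(n_grey * 1 - analytic) / analytic, 0.05)
})

test_that("the sphere head is watertight (no buried air)", {
  head <- small_head_solution()$head
  R <- head$geometry$outer_radius
  h <- head$spacing
  centre <- head$geometry$centre
  d2 <- (axis_coords_for_test(head, 1) - centre[1])^2
  r <- sqrt(outer(outer(d2, (axis_coords_for_test(head, 2) - centre[2])^2,
                        `+`),
                  (axis_coords_for_test(head, 3) - centre[3])^2, `+`))
  expect_false(any(head$labels == 0L & r <= R - h))
})

test_that("halving the voxel size changes tissue volumes by < 3%", {
  p1 <- reference_adult_params(voxel_size = 2)
  p2 <- reference_adult_params(voxel_size = 1)
  h1 <- build_layered_sphere_head(p1)
  h2 <- build_layered_sphere_head(p2)
  for (ti in c("skin", "skull", "cerebrospinal_fluid",
               "brain_grey_matter", "brain_white_matter")) {
    v1 <- sum(tissue_mask(h1, ti)) * p1$voxel_size^3
    v2 <- sum(tissue_mask(h2, ti)) * p2$voxel_size^3
    expect_lt(abs(v1 - v2) / v2, 0.03, label = paste(ti, "volume change"))
  }
})

test_that("body phantom height matches the profile within one voxel", {
  body <- small_body()
  p <- body$geometry$params
  nz <- which(apply(body$labels > 0, 3, any))
  zs <- body$origin[3] + (nz - 1) * body$spacing
  extent <- max(zs) - min(zs) + body$spacing  # voxel edges
  expect_lt(abs(extent - p$height * 1000), body$spacing)
})

test_that("body phantom is one 6-connected conductive component", {
  body <- small_body()
  m <- body$labels > 0L
  comp <- flood_fill(m, which.max(m))
  expect_identical(sum(comp), sum(m))
})

test_that("extracephalic patch centroids lie on the skin surface", {
  body <- small_body()
  d <- dim(body)
  for (site_name in c("right_arm", "right_tibia")) {
    s <- body$geometry[[site_name]]
    pt <- c(s$axis_xy + s$radius * s$site_dir, s$site_z)
    idx <- round((pt - body$origin) / body$spacing) + 1
    # walk inward along -site_dir until we are on a skin voxel
    lab_here <- body$labels[idx[1], idx[2], idx[3]]
    if (lab_here == 0L) {
      step <- -c(s$site_dir, 0)
      for (k in 1:3) {
        idx2 <- round((pt + k * body$spacing * step - body$origin) /
                        body$spacing) + 1
        if (body$labels[idx2[1], idx2[2], idx2[3]] != 0L) { idx <- idx2; break }
      }
    }
    expect_identical(body$labels[idx[1], idx[2], idx[3]],
                     body$label_map[["skin"]],
                     label = paste(site_name, "is skin"))
    nbrs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))
    has_air <- any(apply(nbrs, 1, function(o) {
      i <- idx + o
      body$labels[i[1], i[2], i[3]] == 0L
    }))
    expect_true(has_air, label = paste(site_name, "touches air"))
  }
})

test_that("the default family scales isotropically with stature", {
  profs <- default_profiles()
  expect_length(profs, 3)
  fam <- make_phantom_family(profs, kind = "head", voxel_size = 8)
  expect_length(fam, 3)
  r_b <- fam$billie_like$geometry$outer_radius
  r_d <- fam$duke_like$geometry$outer_radius
  expect_lt(r_b, r_d)
  expect_equal(r_b / r_d, 1.47 / 1.77, tolerance = 1e-10)
  # all linear dimensions share the ratio
  pb <- profs$billie_like; pd <- profs$duke_like
  expect_equal(pb$trunk_semi_axes / pd$trunk_semi_axes,
               rep(1.47 / 1.77, 3), tolerance = 1e-10)
  expect_error(make_phantom_family(list(profs[[1]], profs[[1]])),
               "duplicate")
  expect_error(make_phantom_family(profs[1]), "at least 2")
})

test_that("every deep-structure mask is non-empty even at coarse voxels", {
  head <- make_phantom_family(default_profiles(), kind = "head",
                              voxel_size = 8)$billie_like
  for (ti in c("thalamus", "midbrain", "pons", "medulla_oblongata",
               "cerebellum"))
    expect_gt(sum(tissue_mask(head, ti)), 0, label = ti)
})

test_that("label volumes round-trip through NIfTI plus sidecar", {
  head <- small_head_solution()$head
  tf <- withr::local_tempfile(fileext = ".nii")
  write_label_volume(head, tf)
  back <- read_label_volume(tf)
  expect_identical(back$labels, head$labels)
  expect_identical(back$spacing, head$spacing)
  expect_identical(back$origin, head$origin)
  expect_identical(back$label_map, head$label_map)
})
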