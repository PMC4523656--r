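test_that("a uniform bar solves to the linear potential", {
  sys <- bar_system(nx = 3)
  phi <- solve_potential(sys, solver_config(solver_kind = "direct"))
  expect_equal(phi$phi[2, 1, 1], 0.5, tolerance = 1e-12)
  sys9 <- bar_system(nx = 9)
  phi9 <- solve_potential(sys9)
  expect_equal(as.vector(phi9$phi), seq(1, 0, length.out = 9),
               tolerance = 1e-7)
})

test_that("the assembled matrix is symmetric and diagonally dominant", {
  set.seed(7)
  sig <- array(runif(64, 0.01, 2), c(4, 4, 4))
  sys <- raw_system(sig, active = 1, reference = 64)
  A <- as.matrix(sys$A)
  expect_equal(A, t(A), tolerance = 0)
  offdiag <- rowSums(abs(A)) - 2 * abs(diag(A))
  expect_true(all(diag(A) + 1e-14 >= -offdiag))
  expect_true(all(diag(A) > 0))
})

test_that("PCG matches a dense direct solve on a random-conductivity grid", {
  set.seed(11)
  sig <- array(runif(64, 0.01, 2), c(4, 4, 4))
  sys <- raw_system(sig, active = c(1, 2), reference = 64)
  phi_pcg <- solve_potential(sys, solver_config(1e-12, 10000))
  dense <- solve(as.matrix(sys$A), sys$b)
  expect_lt(max(abs(phi_pcg$phi[sys$unknown] - dense)), 1e-10)
})

test_that("a homogeneous cube with two Dirichlet faces gives a 1-D ramp", {
  n <- 9
  sig <- array(1, c(n, n, n))
  face1 <- which(slice.index(sig, 1) == 1)
  face2 <- which(slice.index(sig, 1) == n)
  sys <- raw_system(sig, active = face1, reference = face2)
  phi <- solve_potential(sys)
  expected <- seq(1, 0, length.out = n)
  for (i in seq_len(n))
    expect_lt(max(abs(phi$phi[i, , ] - expected[i])), 1e-6)
})

test_that("field derivation recovers constant and linear potentials", {
  n <- 7
  sig <- array(0.5, c(n, n, n))
  sv <- structure(list(sigma = sig, spacing = 2, origin = c(0, 0, 0)),
                  class = "conductivity_volume")
  mkphi <- function(vals) structure(
    list(phi = vals, spacing = 2, origin = c(0, 0, 0),
         iterations = 0L, relative_residual = 0),
    class = "potential_volume")
  # uniform potential: E identically zero
  f <- compute_fields(mkphi(array(3, c(n, n, n))), sv)
  expect_true(all(f$E$values == 0))
  # phi = -k x: |E| = k everywhere, J = sigma E
  k <- 4.2
  x_m <- (slice.index(sig, 1) - 1) * 2e-3
  f <- compute_fields(mkphi(array(-k * x_m, c(n, n, n))), sv)
  expect_equal(as.vector(f$E$amplitude), rep(k, n^3), tolerance = 1e-12)
  expect_equal(f$J$values, f$E$values * 0.5, tolerance = 1e-12)
})

test_that("E and J have identical normalized distributions within one tissue", {
  fx <- small_head_solution()
  gm <- tissue_mask(fx$placed$volume, "brain_grey_matter")
  e <- fx$sol$E$amplitude[gm]
  j <- fx$sol$J$amplitude[gm]
  expect_equal(j / e, rep(0.027512, sum(gm)), tolerance = 1e-12)
  expect_equal(j / max(j), e / max(e), tolerance = 1e-12)
})

test_that("normalization scales the solution to the target current", {
  fx <- small_head_solution()
  sol <- fx$sol
  expect_equal(sol$achieved_current_mA, 1, tolerance = 1e-3)
  # scale factor is target / provisional by linearity
  expect_equal(sol$scale_factor, 1 / sol$provisional_current_mA,
               tolerance = 1e-12)
  sol2 <- normalize_to_current(sol, 2)
  expect_equal(sol2$achieved_current_mA, 2, tolerance = 2e-3)
  expect_equal(sol2$E$amplitude, 2 * sol$E$amplitude, tolerance = 1e-12)
})

test_that("current is conserved across any separating closed surface", {
  fx <- small_head_solution()
  sys <- fx$sol$system
  phi <- fx$sol$phi
  I_act <- surface_current(sys, phi, sys$placed$active_nodes)
  I_ref <- surface_current(sys, phi, sys$placed$reference_nodes)
  expect_equal(I_act, -I_ref, tolerance = 1e-3 * abs(I_act))
  # dilate the active set by one voxel: same enclosed current
  d <- dim(fx$placed$volume$labels)
  grown <- unique(as.vector(outer(sys$placed$active_nodes,
                                  c(0, 1, -1, d[1], -d[1],
                                    d[1] * d[2], -d[1] * d[2]), `+`)))
  grown <- grown[grown >= 1 & grown <= prod(d)]
  I_grown <- surface_current(sys, phi, grown)
  expect_equal(I_grown, I_act, tolerance = 1e-3 * abs(I_act))
  # half-space cut along the midsagittal plane separates F3 from F4
  y_idx <- slice.index(array(0L, d), 2)
  centre_y <- (d[2] + 1) / 2
  upper <- which(y_idx > centre_y)
  I_half <- surface_current(sys, phi, upper)
  expect_equal(abs(I_half), abs(I_act), tolerance = 1e-3 * abs(I_act))
})

test_that("discrete divergence of J vanishes off the electrodes", {
  fx <- small_head_solution()
  dv <- divergence_residual(fx$sol$system, fx$sol$phi)
  expect_lt(dv$max_relative, 1e-3)
})

test_that("doubling the injected current doubles the field", {
  fx <- small_head_solution()
  sol2 <- normalize_to_current(fx$sol, 2)
  # exact up to the recomputation of the achieved current
  expect_equal(sol2$scale_factor, 2, tolerance = 1e-9)
  expect_equal(sol2$E$values, fx$sol$E$values * 2, tolerance = 1e-9)
})

test_that("global conductivity scaling leaves J invariant and scales E by 1/k", {
  set.seed(3)
  sig <- array(runif(5^3, 0.05, 1), c(5, 5, 5))
  k <- 3.7
  run <- function(s) {
    sys <- raw_system(s, active = 1, reference = 125)
    sol <- solve_raw(sys, solver_config(1e-12, 5000))
    sol <- normalize_to_current(sol, 1)
    sol
  }
  s1 <- run(sig); s2 <- run(sig * k)
  expect_equal(s2$J$amplitude, s1$J$amplitude, tolerance = 1e-8)
  expect_equal(s2$E$amplitude, s1$E$amplitude / k, tolerance = 1e-8)
})

test_that("geometric scaling by k maps |E| to |E|/k^2 at fixed current", {
  set.seed(5)
  sig <- array(runif(6^3, 0.05, 1), c(6, 6, 6))
  k <- 2
  run <- function(h) {
    sys <- raw_system(sig, active = 1:2, reference = 215:216, spacing = h)
    normalize_to_current(solve_raw(sys, solver_config(1e-12, 5000)), 1)
  }
  s1 <- run(2); s2 <- run(2 * k)
  expect_equal(s2$E$amplitude, s1$E$amplitude / k^2, tolerance = 1e-9)
})

test_that("solver failure modes raise informative errors", {
  # disconnected electrodes
  sig <- array(1, c(5, 1, 1))
  sig[3] <- 0
  expect_error(raw_system(sig, active = 1, reference = 5),
               "not connected")
  # iteration cap
  sys <- bar_system(nx = 30)
  expect_error(solve_potential(sys, solver_config(1e-14, 2)),
               "did not converge")
})

test_that("tightening the tolerance changes the solution only marginally", {
  fx <- small_head_solution()
  sys <- fx$sol$system
  p1 <- solve_potential(sys, solver_config(1e-6, 50000))
  p2 <- solve_potential(sys, solver_config(1e-10, 50000))
  num <- sqrt(sum((p1$phi - p2$phi)^2, na.rm = TRUE))
  den <- sqrt(sum(p2$phi^2, na.rm = TRUE))
  expect_lt(num / den, 1e-5)
})

test_that("montage A on a symmetric head yields a symmetric field", {
  fx <- small_head_solution()
  a <- fx$sol$E$amplitude
  asym <- max(abs(a - a[, dim(a)[2]:1, ])) / max(a)
  expect_lt(asym, 0.01)
})
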