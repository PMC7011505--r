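test_that("geometric moments match impulses, hand sums and the naive loop", {
  g <- matrix(0, 16, 16); g[5, 8] <- 1     # impulse at (4, 7)
  m <- geometric_moments(g, 2)
  expect_equal(m["i0", "j0"], 1)
  expect_equal(m["i1", "j0"], 4)
  expect_equal(m["i0", "j1"], 7)
  ones <- matrix(0, 8, 8); ones[1:2, 1:2] <- 1
  m2 <- geometric_moments(ones, 2)
  expect_equal(m2["i0", "j0"], 4)
  expect_equal(m2["i1", "j0"], 2)
  expect_equal(m2["i0", "j1"], 2)
  expect_equal(m2["i1", "j1"], 1)
  expect_true(all(geometric_moments(matrix(0, 8, 8), 3) == 0, na.rm = TRUE))
  set.seed(5)
  r <- matrix(runif(32 * 32), 32, 32)
  mr <- geometric_moments(r, 3)
  for (i in 0:3) for (j in 0:(3 - i))
    expect_equal(mr[i + 1, j + 1], moments_naive(r, i, j),
                 tolerance = 1e-9)
})

test_that("centre of mass and central moments behave on canonical inputs", {
  S <- 31
  blob <- outer(exp(-((0:30) - 15)^2 / 18), exp(-((0:30) - 15)^2 / 18))
  ms <- central_moments(blob)
  expect_equal(ms$xc, 15, tolerance = 1e-9)
  expect_equal(ms$yc, 15, tolerance = 1e-9)
  expect_equal(ms$mu11, 0, tolerance = 1e-9)
  two <- matrix(0, 21, 21); two[10 - 4 + 1, 11] <- 1; two[10 + 4 + 1, 11] <- 1
  ms2 <- central_moments(two)
  expect_equal(ms2$mu20, 2 * 16)
  expect_equal(ms2$mu02, 0)
  expect_error(central_moments(matrix(0, 10, 10)), "blank")
  expect_s3_class(
    tryCatch(central_moments(matrix(0, 10, 10)), condition = identity),
    "kd2d_degenerate")
})

test_that("principal angle recovers orientation with a stable frame", {
  S <- 61
  bar <- matrix(0, S, S); bar[29:33, 11:51] <- 1   # long axis along y
  ms <- central_moments(bar)
  pa <- principal_angle(ms)
  # major axis is the column direction: +-pi/2 after axis ordering
  expect_equal(abs(pa$theta), pi / 2, tolerance = 1e-6)
  expect_false(pa$ambiguous)
  disk <- outer(exp(-((0:60) - 30)^2 / 50), exp(-((0:60) - 30)^2 / 50))
  expect_true(principal_angle(central_moments(disk))$ambiguous)
  expect_equal(principal_angle(central_moments(disk))$theta, 0)
})

test_that("rotating a pattern rotates its recovered principal angle", {
  icons <- make_icons(9, 60, seed = 3)
  ink <- 255 - icons[[4]]$pixels            # wedge: strongly oriented
  S <- 150; const <- prep_step(S)
  theta_of <- function(px) {
    fr <- frame_icon(px, S)
    ft <- auxiliary_image(fr, shift_weight(const$Wc, 75, 75))
    principal_angle(central_moments(ft))$theta
  }
  t0 <- theta_of(255 - ink)
  t30 <- theta_of(255 - kd2d:::transform_icon(ink, 30, 1))
  dtheta <- (t30 - t0) * 180 / pi
  # angle advances by the applied rotation modulo 90 (axis relabeling)
  err <- min(abs(((dtheta - 30 + 45) %% 90) - 45),
             abs(((dtheta + 30 + 45) %% 90) - 45))
  expect_lt(err, 1)
})

test_that("normalized invariants pin mass, centre and product moment", {
  set.seed(9)
  for (rep in 1:5) {
    S <- 64
    g <- test_blob(S, 20 + rep * 3, 40 - rep * 2)
    beta <- S^2 / 12
    inv <- geometric_invariants(g, beta = beta)
    c0 <- (S - 1) / 2
    expect_equal(inv$lam[1, 1], beta)                       # lambda_00
    expect_equal(inv$lam[2, 1] / beta, c0, tolerance = 1e-6)
    expect_equal(inv$lam[1, 2] / beta, c0, tolerance = 1e-6)
    expect_equal(inv$lam[2, 2] / beta, c0^2, tolerance = 1e-5)
  }
})

test_that("invariants are unchanged by integer translation", {
  S <- 99
  base <- test_blob(S, 49, 49, width = 8)
  shifted <- test_blob(S, 49 + 13, 49 - 8, width = 8)
  li <- geometric_invariants(base)$lam
  ls <- geometric_invariants(shifted)$lam
  expect_lt(max(rel_err(ls, li)), 1e-3)
})
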