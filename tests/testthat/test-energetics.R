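test_that("Coulomb energy matches hand values and the brute-force sum", {
  xyz <- rbind(c(0, 0, 0), c(3.32, 0, 0))
  expect_equal(coulomb_energy(xyz, c(0, 0)), 0)
  expect_equal(coulomb_energy(xyz, c(1, -1)), -332.0637 / 3.32,
               tolerance = 1e-12)
  set.seed(601)
  pts <- matrix(stats::runif(60, 0, 12), ncol = 3)
  q <- stats::rnorm(20)
  brute <- 0
  for (i in 1:19) for (j in (i + 1):20)
    brute <- brute + 332.0637 * q[i] * q[j] / sqrt(sum((pts[i, ] - pts[j, ])^2))
  expect_equal(coulomb_energy(pts, q), brute, tolerance = 1e-10)
  expect_equal(coulomb_energy(pts, q, dielectric = 4), brute / 4,
               tolerance = 1e-10)
  expect_error(coulomb_energy(rbind(c(0, 0, 0), c(0, 0, 0)), c(1, 1)),
               "coincident")
})

test_that("Lennard-Jones energy has the correct minimum, tail and sum", {
  rmin2 <- c(1.9, 1.9); eps <- c(0.1, 0.2)
  rmin <- sum(rmin2); emin <- sqrt(prod(eps))
  at_min <- lj_energy(rbind(c(0, 0, 0), c(rmin, 0, 0)), rmin2, eps)
  expect_equal(at_min, -emin, tolerance = 1e-12)
  far <- lj_energy(rbind(c(0, 0, 0), c(500, 0, 0)), rmin2, eps)
  expect_lt(abs(far), 1e-10)
  set.seed(602)
  pts <- matrix(stats::runif(30, 0, 10), ncol = 3)
  r2v <- stats::runif(10, 1.5, 2); ev <- stats::runif(10, 0.05, 0.3)
  brute <- 0
  for (i in 1:9) for (j in (i + 1):10) {
    rm <- r2v[i] + r2v[j]; ee <- sqrt(ev[i] * ev[j])
    r <- sqrt(sum((pts[i, ] - pts[j, ])^2))
    brute <- brute + ee * ((rm / r)^12 - 2 * (rm / r)^6)
  }
  expect_equal(lj_energy(pts, r2v, ev), brute, tolerance = 1e-10)
})

test_that("generalized Born reproduces the Born-ion closed form", {
  for (q in c(1, -2)) for (R in c(1.5, 3)) {
    got <- gb_energy(matrix(0, 1, 3), q, born_radii = R)
    want <- -(332.0637 / 2) * (1 - 1 / 78.5) * q^2 / R
    expect_equal(got, want, tolerance = 1e-8)
  }
  expect_equal(gb_energy(matrix(stats::rnorm(9), 3), c(0, 0, 0),
                         born_radii = c(1, 2, 3)), 0)
})

test_that("two-atom GB energy equals the stated formula evaluated directly", {
  xyz <- rbind(c(0, 0, 0), c(4, 0, 0))
  q <- c(0.8, -0.5); B <- c(1.7, 2.1)
  fgb <- function(r, bi, bj) sqrt(r^2 + bi * bj * exp(-r^2 / (4 * bi * bj)))
  pref <- -(332.0637 / 2) * (1 - 1 / 78.5)
  want <- pref * (q[1]^2 / B[1] + q[2]^2 / B[2] +
                    2 * q[1] * q[2] / fgb(4, B[1], B[2]))
  expect_equal(gb_energy(xyz, q, born_radii = B), want, tolerance = 1e-10)
})

test_that("effective Born radii are positive and shrink toward the surface", {
  m <- fx_pentamer()
  heavy <- which(m$atoms$element != "H")
  B <- effective_born_radii(m$coords[heavy, ], m$atoms$gb_radius[heavy])
  expect_true(all(B > 0))
  expect_true(all(B >= m$atoms$gb_radius[heavy] - 0.09 - 1e-9))
  expect_error(effective_born_radii(matrix(0, 1, 3), 0.05),
               "radius <= offset")
})

test_that("LCPO is exact for isolated spheres and additive when separated", {
  r <- 1.7
  one <- lcpo_sasa(matrix(0, 1, 3), r)
  expect_equal(one$total, 4 * pi * (r + 1.4)^2, tolerance = 1e-12)
  two <- lcpo_sasa(rbind(c(0, 0, 0), c(100, 0, 0)), c(1.7, 1.5))
  expect_equal(two$total, 4 * pi * (3.1^2 + 2.9^2), tolerance = 1e-12)
})

test_that("LCPO total area stays within 5 percent of a Shrake-Rupley oracle", {
  set.seed(603)
  for (rep in 1:4) {
    nat <- sample(5:10, 1)
    repeat {
      xyz <- matrix(stats::runif(nat * 3, 0, 7), ncol = 3)
      if (min(stats::dist(xyz)) > 2.6) break
    }
    radii <- stats::runif(nat, 1.5, 1.9)
    got <- lcpo_sasa(xyz, radii)$total
    want <- shrake_rupley_sasa(xyz, radii)
    expect_lt(abs(got - want) / want, 0.05)
  }
})

test_that("the non-polar term is linear in area with the default gamma", {
  expect_equal(nonpolar_energy(0), 0)
  expect_equal(nonpolar_energy(1000), 7.2)
  s <- stats::runif(1, 100, 900)
  expect_equal(nonpolar_energy(2 * s), 2 * nonpolar_energy(s))
  expect_error(nonpolar_energy(-1), "non-negative")
})

test_that("single-trajectory decomposition identities hold exactly", {
  m <- fx_complex()
  tr <- simulate_trajectory(m, scenario("stable", noise_sigma = 0.05, seed = 8),
                            n_frames = 4)
  e <- mmgbsa(tr, stride = 2)
  pf <- e$per_frame
  expect_true(all(pf$dE_int == 0))
  expect_lt(max(abs(pf$dG_bind - (pf$dE_ele + pf$dE_vdW + pf$dG_GB + pf$dG_np))),
            1e-9)
  expect_lt(max(abs(pf$dG_solv - (pf$dG_GB + pf$dG_np))), 1e-9)
  expect_error(mmgbsa(tr, receptor = 1:10, ligand = 10:20), "partition")
})

test_that("a hand-built toy complex reproduces independent term evaluations", {
  at <- data.frame(
    name = c("X1", "X2", "X3", "Y1"),
    element = "C", res_name = "GLY",
    chain_id = c("A", "A", "A", "L"),
    res_internal = c(1L, 2L, 3L, 1L),
    charge = c(0.5, -0.3, 0.2, -0.4),
    is_ligand = c(FALSE, FALSE, FALSE, TRUE))
  xyz <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0), c(3, 3, 1))
  m <- fibril_model(at, xyz)
  tr <- trajectory(m, array(xyz, c(4, 3, 1)))
  e <- mmgbsa(tr, gb = FALSE)
  # independent evaluation: only receptor-ligand cross terms survive deltas
  q <- at$charge; r2 <- m$atoms$rmin2; ep <- m$atoms$eps
  ele <- 0; vdw <- 0
  for (i in 1:3) {
    r <- sqrt(sum((xyz[i, ] - xyz[4, ])^2))
    ele <- ele + 332.0637 * q[i] * q[4] / r
    rm <- r2[i] + r2[4]; ee <- sqrt(ep[i] * ep[4])
    vdw <- vdw + ee * ((rm / r)^12 - 2 * (rm / r)^6)
  }
  expect_equal(e$per_frame$dE_ele, ele, tolerance = 1e-8)
  expect_equal(e$per_frame$dE_vdW, vdw, tolerance = 1e-8)
  expect_equal(e$per_frame$dG_GB, 0)
  expect_equal(e$per_frame$dG_bind, ele + vdw, tolerance = 1e-8)
})

test_that("a far-separated uncharged ligand does not bind", {
  m <- fx_complex()
  at <- m$atoms
  at$charge <- 0
  xyz <- m$coords
  xyz[at$is_ligand, 1] <- xyz[at$is_ligand, 1] + 500
  m0 <- fibril_model(at, xyz)
  tr <- trajectory(m0, array(xyz, c(nrow(at), 3, 1)))
  e <- mmgbsa(tr, gb = FALSE)
  expect_lt(abs(e$per_frame$dE_ele), 1e-10)
  expect_lt(abs(e$per_frame$dE_vdW), 1e-6)
  expect_lt(abs(e$per_frame$dG_bind), 1e-6)
  # gas-phase terms are isometry invariant
  moved <- random_isometry(m$coords)
  expect_equal(coulomb_energy(moved, m$atoms$charge),
               coulomb_energy(m$coords, m$atoms$charge), tolerance = 1e-6)
})
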