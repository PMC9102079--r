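test_that("superposition removes rigid motions exactly", {
  set.seed(401)
  x <- matrix(stats::rnorm(30), ncol = 3)
  same <- kabsch_superpose(x, x)
  expect_equal(same$rmsd, 0, tolerance = 1e-10)
  expect_equal(same$rotation, diag(3), tolerance = 1e-8)
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  rot <- kabsch_superpose(x %*% Rz, x)
  expect_equal(rot$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(rot$rotation), 1, tolerance = 1e-10)
})

test_that("superposition matches brute-force minimisation over rotations", {
  set.seed(402)
  rmsd_at <- function(ang, a, b) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    R <- matrix(c(cy * cz, -cy * sz, sy,
                  cx * sz + sx * sy * cz, cx * cz - sx * sy * sz, -sx * cy,
                  sx * sz - cx * sy * cz, sx * cz + cx * sy * sz, cx * cy),
                3, 3, byrow = TRUE)
    ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
    sqrt(mean(rowSums((ac %*% R - bc)^2)))
  }
  for (rep in 1:5) {
    a <- matrix(stats::rnorm(12), ncol = 3)
    b <- matrix(stats::rnorm(12), ncol = 3)
    got <- kabsch_superpose(a, b)$rmsd
    best <- Inf
    for (k in 1:40) {   # multistart Nelder-Mead over Euler angles
      o <- stats::optim(stats::runif(3, -pi, pi), rmsd_at, a = a, b = b,
                        control = list(reltol = 1e-14, maxit = 3000))
      best <- min(best, o$value)
    }
    expect_equal(got, best, tolerance = 1e-6)
    expect_lte(got, best + 1e-9)   # never worse than the search
  }
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "3 points")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("radius of gyration follows the mass-weighted definition", {
  m <- fx_pentamer()
  expect_equal(radius_of_gyration(m, selection = 1L), 0)
  at <- data.frame(name = c("X1", "X2"), element = c("C", "C"),
                   res_name = "GLY", chain_id = "A", res_internal = c(1L, 2L),
                   is_ligand = FALSE)
  two <- fibril_model(at, rbind(c(0, 0, 0), c(10, 0, 0)))
  expect_equal(radius_of_gyration(two), 5)
  set.seed(403)
  sel <- sample(nrow(m$atoms), 50)
  xyz <- m$coords
  direct <- {
    mm <- m$atoms$mass[sel]
    com <- colSums(xyz[sel, ] * mm) / sum(mm)
    s <- 0
    for (i in seq_along(sel)) s <- s + mm[i] * sum((xyz[sel[i], ] - com)^2)
    sqrt(s / sum(mm))
  }
  expect_equal(radius_of_gyration(m, selection = sel), direct,
               tolerance = 1e-10)
  moved <- random_isometry(xyz)
  expect_equal(radius_of_gyration(m, moved, sel),
               radius_of_gyration(m, xyz, sel), tolerance = 1e-8)
})

test_that("RMSD series start at zero and track structural change", {
  m <- fx_pentamer()
  tr0 <- simulate_trajectory(m, scenario("stable", noise_sigma = 0, seed = 1),
                             n_frames = 5)
  s0 <- rmsd_series(tr0)
  expect_true(all(abs(s0$rmsd) < 1e-8))
  trd <- simulate_trajectory(m, scenario("dissociation", chains = "E",
                                         noise_sigma = 0.05, seed = 2),
                             n_frames = 120)
  sd_ <- rmsd_series(trd)
  expect_lt(sd_$rmsd[1], 0.2)
  expect_gt(sd_$rmsd[120], sd_$rmsd[1] + 1)
})

test_that("frame clustering matches a naive agglomeration oracle", {
  set.seed(404)
  for (rep in 1:25) {
    n <- sample(4:10, 1)
    X <- matrix(stats::rnorm(n * 9, sd = 2), nrow = n)   # 3 pseudo-atoms
    eps <- stats::runif(1, 1, 4)
    got <- average_linkage_cluster(X, epsilon = eps)
    D <- as.matrix(stats::dist(X) / sqrt(3))
    want <- oracle_average_linkage(D, eps)
    expect_equal(got$n_clusters, max(want))
    expect_identical(canon_partition(got$labels), canon_partition(want))
  }
})

test_that("clustering collapses and splits at the epsilon extremes", {
  m <- fx_pentamer()
  tr <- simulate_trajectory(m, scenario("stable", noise_sigma = 0.05, seed = 3),
                            n_frames = 12)
  one <- average_linkage_cluster(tr, epsilon = 1e6)
  expect_equal(one$n_clusters, 1)
  all_split <- average_linkage_cluster(tr, epsilon = 1e-9)
  expect_equal(all_split$n_clusters, 12)
  # two bundles far apart in conformation space cluster perfectly
  # (an internal rescaling, not a rigid shift, survives the pre-fit)
  sep <- tr
  sep$coords[, , 7:12] <- sep$coords[, , 7:12] * 1.5
  two <- average_linkage_cluster(sep, epsilon = 4.5)
  expect_equal(two$n_clusters, 2)
  expect_equal(length(unique(two$labels[1:6])), 1)
  expect_equal(length(unique(two$labels[7:12])), 1)
})

test_that("cluster-quality indices equal hand-computed values", {
  one <- clustering_metrics(rep(1, 4), matrix(stats::rnorm(12), 4))
  expect_true(is.na(one["DBI"]) && is.na(one["pSF"]))
  expect_equal(unname(one["SSR_SST"]), 0)
  # two zero-spread point clusters: perfect separation
  X <- rbind(matrix(0, 3, 2), matrix(5, 3, 2))
  two <- clustering_metrics(c(1, 1, 1, 2, 2, 2), X)
  expect_equal(unname(two["SSR_SST"]), 1)
  expect_equal(unname(two["DBI"]), 0)
  # small labelled set, all three indices by explicit arithmetic
  X <- matrix(c(0, 0, 1, 0, 0, 1, 10, 0, 11, 0), ncol = 2, byrow = TRUE)
  lab <- c(1, 1, 1, 2, 2)
  c1 <- colMeans(X[1:3, ]); c2 <- colMeans(X[4:5, ])
  grand <- colMeans(X)
  ssw <- sum(sweep(X[1:3, ], 2, c1)^2) + sum(sweep(X[4:5, ], 2, c2)^2)
  sst <- sum(sweep(X, 2, grand)^2)
  ssb <- sst - ssw
  s1 <- mean(sqrt(rowSums(sweep(X[1:3, ], 2, c1)^2)))
  s2 <- mean(sqrt(rowSums(sweep(X[4:5, ], 2, c2)^2)))
  dbi <- (s1 + s2) / sqrt(sum((c1 - c2)^2))
  psf <- (ssb / 1) / (ssw / 3)
  got <- clustering_metrics(lab, X)
  expect_equal(unname(got["DBI"]), dbi, tolerance = 1e-10)
  expect_equal(unname(got["pSF"]), psf, tolerance = 1e-10)
  expect_equal(unname(got["SSR_SST"]), ssb / sst, tolerance = 1e-10)
})
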