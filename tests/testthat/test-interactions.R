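test_that("hydrogen-bond criterion applies both distance and angle cutoffs", {
  m <- toy_hbond_model(1, 1)
  xyz <- m$coords
  # collinear N-H...O at 3.0 A
  xyz[1, ] <- c(0, 0, 0)        # N
  xyz[2, ] <- c(1.0, 0, 0)      # H
  xyz[3, ] <- c(-1, 1, 0)       # CA
  xyz[4, ] <- c(4.2, 0, 0)      # C
  xyz[5, ] <- c(3.0, 0, 0)      # O
  expect_equal(nrow(detect_hbonds(m, xyz, pairing = "all")), 1)
  xyz[5, ] <- c(3.3, 0, 0); xyz[4, ] <- c(4.5, 0, 0)
  expect_equal(nrow(detect_hbonds(m, xyz, pairing = "all")), 0)  # distance fails
  xyz[5, ] <- c(0.8, 2.8, 0); xyz[4, ] <- c(0.8, 4, 0)
  d <- sqrt(sum(xyz[5, ]^2))
  expect_lt(d, 3.2)
  expect_equal(nrow(detect_hbonds(m, xyz, pairing = "all")), 0)  # angle fails
})

test_that("randomized hydrogen-bond geometries match the brute-force oracle", {
  set.seed(301)
  m <- toy_hbond_model(6, 6)
  for (rep in 1:200) {
    xyz <- random_hbond_coords(m)
    got <- detect_hbonds(m, xyz, pairing = "all")
    want <- oracle_hbonds(m, xyz)
    expect_identical(sort(sprintf("%s:%d|%s:%d", got$chain1, got$res1,
                                  got$chain2, got$res2)), want)
  }
})

test_that("salt-bridge detection matches a plain distance scan", {
  m <- toy_saltbridge_model()
  set.seed(302)
  for (rep in 1:200) {
    xyz <- matrix(stats::runif(nrow(m$atoms) * 3, 0, 9), ncol = 3)
    got <- detect_salt_bridges(m, xyz)
    expect_identical(sort(got$chain_pair), oracle_salt_bridges(m, xyz))
  }
  # 4.6 A is just beyond the cutoff
  xyz <- m$coords * 0
  xyz[, 1] <- seq_len(nrow(m$atoms)) * 50   # spread everything far apart
  cg_a <- which(m$atoms$chain_id == "A" & m$atoms$name == "CG")
  nz_a <- which(m$atoms$chain_id == "A" & m$atoms$name == "NZ")
  xyz[nz_a, ] <- xyz[cg_a, ] + c(4.6, 0, 0)
  expect_equal(nrow(detect_salt_bridges(m, xyz)), 0)
  xyz[nz_a, ] <- xyz[cg_a, ] + c(4.5, 0, 0)
  expect_equal(nrow(detect_salt_bridges(m, xyz)), 1)
})

test_that("stacking detection agrees with explicit centroid computation", {
  m <- fx_pentamer()
  set.seed(303)
  for (rep in 1:60) {
    xyz <- m$coords + matrix(stats::rnorm(length(m$coords), sd = 1.2),
                             ncol = 3)
    got <- detect_stacking(m, xyz)
    expect_identical(sort(sprintf("%s-%s|%d", got$chain1, got$chain2,
                                  got$position)),
                     oracle_stacking(m, xyz))
  }
  # boundary: centroids at 4.8 detected, 5.6 not
  st <- detect_stacking(m)
  expect_equal(nrow(st), 8)
  m20 <- build_pentamer(fibril_blueprint(rise = 5.6))
  expect_equal(nrow(detect_stacking(m20)), 0)
})

test_that("contact counting equals the brute-force double loop", {
  m <- fx_pentamer()
  g1 <- which(m$atoms$chain_id == "E" & m$atoms$element != "H")
  g2 <- which(m$atoms$chain_id != "E" & m$atoms$element != "H")
  set.seed(304)
  for (rep in 1:5) {
    xyz <- m$coords + matrix(stats::rnorm(length(m$coords), sd = 2), ncol = 3)
    expect_identical(contact_count(m, xyz, g1, g2),
                     oracle_contacts(xyz[g1, ], xyz[g2, ]))
  }
  far <- m$coords
  far[g1, 1] <- far[g1, 1] + 100
  expect_identical(contact_count(m, far, g1, g2), 0L)
  expect_error(contact_count(m, m$coords, g1, c(g1[1], g2)), "disjoint")
})

test_that("detectors are invariant under rigid isometries of the frame", {
  m <- fx_pentamer()
  set.seed(305)
  for (rep in 1:5) {
    xyz <- m$coords + matrix(stats::rnorm(length(m$coords), sd = 0.3), ncol = 3)
    moved <- random_isometry(xyz)
    expect_identical(suppressWarnings(detect_hbonds(m, xyz))$id,
                     suppressWarnings(detect_hbonds(m, moved))$id)
    expect_identical(detect_salt_bridges(m, xyz)$id,
                     detect_salt_bridges(m, moved)$id)
    expect_identical(detect_stacking(m, xyz)$id, detect_stacking(m, moved)$id)
  }
})

test_that("occupancy tiers are lower-inclusive and cutoffs act monotonically", {
  # hand-built trajectory: one salt bridge present in exactly 70 of 100 frames
  m <- toy_saltbridge_model()
  xyz <- m$coords * 0
  xyz[, 1] <- seq_len(nrow(m$atoms)) * 50
  cg_a <- which(m$atoms$chain_id == "A" & m$atoms$name == "CG")
  nz_a <- which(m$atoms$chain_id == "A" & m$atoms$name == "NZ")
  coords <- array(0, c(nrow(m$atoms), 3, 100))
  for (f in 1:100) {
    fr <- xyz
    fr[nz_a, ] <- fr[cg_a, ] + c(if (f <= 70) 3 else 40, 0, 0)
    coords[, , f] <- fr
  }
  tr <- trajectory(m, coords)
  tab <- occupancy(tr, "salt_bridge")
  expect_equal(tab$occupancy, 0.70)
  expect_equal(as.character(tab$tier), ">=70%")
  # raising the cutoff can only add interactions
  m2 <- fx_pentamer()
  tr2 <- simulate_trajectory(m2, scenario("stable", noise_sigma = 0.4, seed = 6),
                             n_frames = 20)
  t_narrow <- suppressWarnings(occupancy(tr2, "hbond", d_max = 3.0))
  t_wide <- suppressWarnings(occupancy(tr2, "hbond", d_max = 3.4))
  expect_true(all(t_narrow$id %in% t_wide$id))
  expect_true(all(t_wide[match(t_narrow$id, t_wide$id), "occupancy"] >=
                    t_narrow$occupancy))
})

test_that("global salt-bridge occurrence sums per-pair occupancies", {
  m <- toy_saltbridge_model()
  base <- m$coords * 0
  base[, 1] <- seq_len(nrow(m$atoms)) * 50
  # intra occupancies by chain: A = 1.0, B = 0.5, C = 0.5, D = 0, E = 0
  plan <- c(A = 1, B = 0.5, C = 0.5, D = 0, E = 0)
  nfr <- 40
  coords <- array(0, c(nrow(m$atoms), 3, nfr))
  for (f in seq_len(nfr)) {
    fr <- base
    for (ch in names(plan)) {
      cg <- which(m$atoms$chain_id == ch & m$atoms$name == "CG")
      nz <- which(m$atoms$chain_id == ch & m$atoms$name == "NZ")
      on <- f <= plan[[ch]] * nfr
      fr[nz, ] <- fr[cg, ] + c(if (on) 3 else 40, 0, 0)
    }
    coords[, , f] <- fr
  }
  g <- global_salt_bridge_occurrence(trajectory(m, coords))
  expect_equal(unname(g["intra_percent"]), 200)
  expect_equal(unname(g["inter_percent"]), 0)
  # all intra formed in every frame caps at 500
  all_on <- base
  for (ch in names(plan)) {
    cg <- which(m$atoms$chain_id == ch & m$atoms$name == "CG")
    nz <- which(m$atoms$chain_id == ch & m$atoms$name == "NZ")
    all_on[nz, ] <- all_on[cg, ] + c(3, 0, 0)
  }
  g2 <- global_salt_bridge_occurrence(
    trajectory(m, array(all_on, c(nrow(m$atoms), 3, 2))))
  expect_equal(unname(g2["intra_percent"]), 500)
})

test_that("pose ranking follows mean rank with dominance respected", {
  single <- rank_poses(data.frame(contacts = 10, e_interaction = -5,
                                  e_total = -100))
  expect_equal(single$final_rank, 1)
  poses <- data.frame(label = c("dom", "b", "c"),
                      contacts = c(50, 40, 30),
                      e_interaction = c(-30, -20, -10),
                      e_total = c(-300, -200, -100))
  expect_equal(rank_poses(poses)$label, c("dom", "b", "c"))
  # hand-computed mean ranks
  p5 <- data.frame(label = letters[1:5],
                   contacts = c(10, 50, 30, 50, 20),
                   e_interaction = c(-1, -9, -5, -2, -8),
                   e_total = c(-10, -50, -90, -20, -70))
  # ranks: contacts desc: a5 b1 c3 d1 e4 ; e_int: a5 b1 c3 d4 e2 ;
  # e_tot: a5 b3 c1 d4 e2 -> means: a5, b5/3, c7/3, d3, e8/3
  got <- rank_poses(p5)
  expect_equal(got$label, c("b", "c", "e", "d", "a"))
  expect_equal(got$mean_rank, c(5 / 3, 7 / 3, 8 / 3, 3, 5))
})
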