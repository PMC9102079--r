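# Shared fixtures (built once per test run) and independent brute-force
# oracles used by the oracle-equivalence suites.

.fx <- new.env(parent = emptyenv())

fx_pentamer <- function() {
  if (is.null(.fx$pentamer)) .fx$pentamer <- build_pentamer()
  .fx$pentamer
}

fx_complex <- function() {
  if (is.null(.fx$complex))
    .fx$complex <- build_pentamer(ligand = "MIFFFE", ligand_site = "core")
  .fx$complex
}

# --- tiny hand-made models --------------------------------------------------

# A model of `nd` donor residues (N + H) on chain A and `na` acceptor
# residues (C + O) on chain B, for randomized hydrogen-bond geometry tests.
toy_hbond_model <- function(nd = 6, na = 6) {
  rows <- list()
  for (i in seq_len(nd)) {
    rows[[length(rows) + 1]] <- data.frame(
      name = c("N", "H", "CA"), element = c("N", "H", "C"),
      res_name = "GLY", chain_id = "A", res_internal = i,
      is_ligand = FALSE, stringsAsFactors = FALSE)
  }
  for (j in seq_len(na)) {
    rows[[length(rows) + 1]] <- data.frame(
      name = c("C", "O"), element = c("C", "O"),
      res_name = "GLY", chain_id = "B", res_internal = j,
      is_ligand = FALSE, stringsAsFactors = FALSE)
  }
  at <- do.call(rbind, rows)
  fibril_model(at, matrix(0, nrow(at), 3))
}

random_hbond_coords <- function(model, span = 8) {
  at <- model$atoms
  xyz <- matrix(stats::runif(nrow(at) * 3, 0, span), ncol = 3)
  # keep H near its N (bonded geometry), CA anywhere
  for (i in which(at$name == "H")) {
    xyz[i, ] <- xyz[i - 1, ] + .unit_vec(stats::rnorm(3)) * 1.0
  }
  for (i in which(at$name == "O")) {
    xyz[i, ] <- xyz[i - 1, ] + .unit_vec(stats::rnorm(3)) * 1.23
  }
  xyz
}

.unit_vec <- function(v) v / sqrt(sum(v^2))

# Oracle: plain double loop over donors x acceptors applying both criteria.
oracle_hbonds <- function(model, coords, d_max = 3.2, angle_min = 120) {
  at <- model$atoms
  dn <- which(at$name == "N")
  ac <- which(at$name == "O")
  found <- character(0)
  for (i in dn) {
    h <- which(at$chain_id == at$chain_id[i] &
                 at$res_internal == at$res_internal[i] & at$name == "H")
    for (j in ac) {
      if (at$chain_id[i] == at$chain_id[j] &&
          at$res_internal[i] == at$res_internal[j]) next
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      if (d > d_max) next
      v1 <- coords[i, ] - coords[h, ]
      v2 <- coords[j, ] - coords[h, ]
      ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
      if (ang >= angle_min)
        found <- c(found, sprintf("%s:%d|%s:%d", at$chain_id[i],
                                  at$res_internal[i], at$chain_id[j],
                                  at$res_internal[j]))
    }
  }
  sort(found)
}

# A five-chain model carrying only the salt-bridge atoms (plus CA anchors).
toy_saltbridge_model <- function() {
  rows <- list()
  for (c in 1:5) {
    rows[[length(rows) + 1]] <- data.frame(
      name = c("CA", "CG"), element = "C",
      res_name = "ASP", chain_id = LETTERS[c], res_internal = 7L,
      is_ligand = FALSE, stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      name = c("CA", "NZ"), element = c("C", "N"),
      res_name = "LYS", chain_id = LETTERS[c], res_internal = 12L,
      is_ligand = FALSE, stringsAsFactors = FALSE)
  }
  at <- do.call(rbind, rows)
  fibril_model(at, matrix(stats::runif(nrow(at) * 3, 0, 10), ncol = 3))
}

oracle_salt_bridges <- function(model, coords, d_max = 4.5) {
  at <- model$atoms
  chains <- unique(at$chain_id)
  found <- character(0)
  for (ci in seq_along(chains)) {
    cg <- which(at$chain_id == chains[ci] & at$name == "CG" & at$res_internal == 7)
    for (cj in seq_along(chains)) {
      if (!(cj == ci || cj == ci + 1)) next
      nz <- which(at$chain_id == chains[cj] & at$name == "NZ" & at$res_internal == 12)
      if (!length(cg) || !length(nz)) next
      d <- sqrt(sum((coords[cg, ] - coords[nz, ])^2))
      if (d <= d_max)
        found <- c(found, sprintf("%s-%s", chains[ci], chains[cj]))
    }
  }
  sort(found)
}

oracle_stacking <- function(model, coords, d_max = 5.5, positions = c(3, 4)) {
  at <- model$atoms
  chains <- unique(at$chain_id[!at$is_ligand])
  ring <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  found <- character(0)
  for (ci in seq_len(length(chains) - 1)) for (p in positions) {
    i1 <- which(at$chain_id == chains[ci] & at$res_internal == p & at$name %in% ring)
    i2 <- which(at$chain_id == chains[ci + 1] & at$res_internal == p & at$name %in% ring)
    if (length(i1) < 6 || length(i2) < 6) next
    c1 <- colMeans(coords[i1, , drop = FALSE])
    c2 <- colMeans(coords[i2, , drop = FALSE])
    if (sqrt(sum((c1 - c2)^2)) <= d_max)
      found <- c(found, sprintf("%s-%s|%d", chains[ci], chains[ci + 1], p))
  }
  sort(found)
}

oracle_contacts <- function(coords1, coords2, d_max = 4.5) {
  cnt <- 0L
  for (i in seq_len(nrow(coords1))) for (j in seq_len(nrow(coords2))) {
    if (sqrt(sum((coords1[i, ] - coords2[j, ])^2)) <= d_max) cnt <- cnt + 1L
  }
  cnt
}

# Naive O(n^3) average-linkage agglomeration on a distance matrix, stopping
# when the smallest inter-cluster average distance exceeds epsilon.
oracle_average_linkage <- function(D, epsilon) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  repeat {
    k <- length(clusters)
    if (k == 1) break
    best <- c(NA, NA); best_d <- Inf
    for (a in 1:(k - 1)) for (b in (a + 1):k) {
      d <- mean(D[clusters[[a]], clusters[[b]]])
      if (d < best_d) { best_d <- d; best <- c(a, b) }
    }
    if (best_d > epsilon) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  labels <- integer(n)
  for (a in seq_along(clusters)) labels[clusters[[a]]] <- a
  labels
}

# Canonical form of a partition: labels renumbered by first appearance.
canon_partition <- function(labels) match(labels, unique(labels))

# Shrake-Rupley numerical SASA oracle on a golden-spiral point set.
shrake_rupley_sasa <- function(coords, radii, probe = 1.4, npts = 12000) {
  k <- seq_len(npts)
  golden <- (1 + sqrt(5)) / 2
  z <- 1 - (2 * k - 1) / npts
  th <- 2 * pi * k / golden
  sp <- cbind(sqrt(1 - z^2) * cos(th), sqrt(1 - z^2) * sin(th), z)
  R <- radii + probe
  n <- nrow(coords)
  tot <- 0
  for (i in seq_len(n)) {
    pts <- sweep(sp * R[i], 2, coords[i, ], "+")
    acc <- rep(TRUE, npts)
    for (j in setdiff(seq_len(n), i)) {
      acc <- acc & rowSums(sweep(pts, 2, coords[j, ])^2) > R[j]^2
    }
    tot <- tot + 4 * pi * R[i]^2 * mean(acc)
  }
  tot
}

# --- internal-coordinate peptide backbone builder (NeRF) --------------------

.nerf_place <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  bc <- .unit_vec(c - b)
  nv <- .unit_vec(pracma_cross(b - a, bc))
  M <- cbind(bc, pracma_cross(nv, bc), nv)
  as.numeric(M %*% d2 + c)
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
}

# Ideal poly-alanine backbone with the given (phi, psi); returns a
# fibril_model with N, CA, C, O atoms (no amide H, exercising the
# reconstruction path of the assigner).
build_ideal_backbone <- function(n_res, phi, psi, omega = 180) {
  N <- matrix(0, n_res, 3); CA <- matrix(0, n_res, 3); C <- matrix(0, n_res, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  C[1, ] <- CA[1, ] + 1.525 * c(-cos(111.2 * pi / 180), sin(111.2 * pi / 180), 0)
  for (i in seq_len(n_res)) {
    if (i > 1) {
      N[i, ] <- .nerf_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ], 1.329, 116.2, psi)
      CA[i, ] <- .nerf_place(CA[i - 1, ], C[i - 1, ], N[i, ], 1.458, 121.7, omega)
      C[i, ] <- .nerf_place(C[i - 1, ], N[i, ], CA[i, ], 1.525, 111.2, phi)
    }
  }
  O <- matrix(0, n_res, 3)
  for (i in seq_len(n_res)) {
    ref <- if (i < n_res) N[i + 1, ] else C[i, ] + (C[i, ] - N[i, ])
    dir <- -(.unit_vec(ref - C[i, ]) + .unit_vec(CA[i, ] - C[i, ]))
    O[i, ] <- C[i, ] + 1.231 * .unit_vec(dir)
  }
  rows <- do.call(rbind, lapply(seq_len(n_res), function(i)
    data.frame(name = c("N", "CA", "C", "O"),
               element = c("N", "C", "C", "O"), res_name = "ALA",
               chain_id = "A", res_internal = i, is_ligand = FALSE,
               stringsAsFactors = FALSE)))
  xyz <- do.call(rbind, lapply(seq_len(n_res), function(i)
    rbind(N[i, ], CA[i, ], C[i, ], O[i, ])))
  fibril_model(rows, xyz)
}

# Random rigid isometry (rotation + translation) applied to all rows.
random_isometry <- function(coords) {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  R <- matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]), 2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)),
    3, 3, byrow = TRUE)
  sweep(coords %*% R, 2, stats::rnorm(3, sd = 5), "+")
}
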