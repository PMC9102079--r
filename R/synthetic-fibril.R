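# Idealized U-shaped pentamer builder and stand-in trajectory simulator.
#
# The builder produces a pseudo-atom model whose geometry *guarantees* the
# three interaction criteria used throughout the analysis battery:
#   (a) inter-chain backbone hydrogen-bond ladders (donor-acceptor <= 3.2 A,
#       donor-H-acceptor angle >= 120 deg),
#   (b) stacked Phe rings at internal positions 3 and 4 with neighbouring
#       ring centroids <= 5.5 A apart,
#   (c) Asp(7) CG to Lys(12) NZ salt bridges <= 4.5 A, intra-chain and
#       between chain i and chain i+1.
# Chains are identical and stacked in register along the fibril (y) axis at
# the cross-beta rise. Within a chain the amide H of residue i points
# "up" (+y) for odd i and "down" (-y) for even i, and the carbonyl O of
# residue i sits on the donor column of residue i-1 of the facing chain;
# this alternating ladder is what makes the Kabsch-Sander parallel-bridge
# patterns come out true for every pair of neighbouring chains.

#' Blueprint for the idealized U-shaped pentamer
#'
#' @param n_chains Number of fibril chains (5).
#' @param n_res Residues per chain (26, amyloid-beta 17-42).
#' @param strand1_range,turn_range,strand2_range Internal residue intervals;
#'   must partition 1..n_res.
#' @param rise Inter-chain stacking distance along the fibril axis, Angstrom.
#' @param strand_step In-strand advance per residue, Angstrom.
#' @param phe_positions Internal positions of the stacked Phe rings
#'   (3 and 4, i.e. amyloid-beta F19/F20).
#' @param asp_position,lys_position Internal positions of the Asp/Lys salt
#'   bridge partners (7 and 12, i.e. D23/K28).
#' @return A list of class \code{fibril_blueprint}.
#' @export
fibril_blueprint <- function(n_chains = 5L, n_res = 26L,
                             strand1_range = 1:10, turn_range = 11:16,
                             strand2_range = 17:26,
                             rise = 4.8, strand_step = 3.47,
                             phe_positions = c(3L, 4L),
                             asp_position = 7L, lys_position = 12L) {
  if (rise <= 0) .stopf("rise must be positive")
  if (!identical(sort(c(strand1_range, turn_range, strand2_range)),
                 seq_len(n_res)))
    .stopf("strand1/turn/strand2 ranges must partition 1..%d", n_res)
  structure(list(n_chains = as.integer(n_chains), n_res = as.integer(n_res),
                 strand1_range = strand1_range, turn_range = turn_range,
                 strand2_range = strand2_range, rise = rise,
                 strand_step = strand_step, phe_positions = phe_positions,
                 asp_position = asp_position, lys_position = lys_position),
            class = "fibril_blueprint")
}

# Amyloid-beta 17-42 one-letter sequence; internal position 1 is Abeta 17.
.ABETA_17_42 <- strsplit("LVFFAEDVGSNKGAIIGLMVGGVVIA", "")[[1]]

.BACKBONE_CHARGES <- c(N = -0.4157, H = 0.2719, CA = 0.0337, C = 0.5973,
                       O = -0.5679, CB = 0)

# In-plane (x, z) path of one U-shaped chain: residue positions and unit
# tangents/outward normals. The turn sweeps the heading from 0 to pi.
.chain_path <- function(bp) {
  n <- bp$n_res
  s1_end <- max(bp$strand1_range)
  s2_start <- min(bp$strand2_range)
  n_turn_steps <- s2_start - s1_end           # steps carrying the turn
  heading <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    heading[i] <- if (i < s1_end) 0
      else if (i >= s2_start) pi
      else (i - s1_end + 1) * pi / n_turn_steps
  }
  pos <- matrix(0, n, 2)
  for (i in seq_len(n - 1)) {
    pos[i + 1, ] <- pos[i, ] + bp$strand_step * c(cos(heading[i]), sin(heading[i]))
  }
  tangent <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    a <- if (i == 1) pos[1, ] - bp$strand_step * c(cos(heading[1]), sin(heading[1])) else pos[i - 1, ]
    b <- if (i == n) pos[n, ] + bp$strand_step * c(cos(heading[n - 1]), sin(heading[n - 1])) else pos[i + 1, ]
    tangent[i, ] <- .unit(b - a)
  }
  normal <- cbind(tangent[, 2], -tangent[, 1])  # outward side of the U
  list(pos = pos, tangent = tangent, normal = normal)
}

# Assemble the atom rows of one chain at fibril-axis offset y0.
.build_chain <- function(bp, path, chain_id, y0, sequence) {
  n <- bp$n_res
  dir <- ifelse(seq_len(n) %% 2 == 1, 1, -1)   # amide H direction along y
  ncol_xz <- path$pos - 1.2 * path$tangent     # donor (N) columns
  # carbonyl column of residue i = donor column of residue i-1
  prev_col <- rbind(path$pos[1, ] - bp$strand_step * path$tangent[1, ] -
                      1.2 * path$tangent[1, ], ncol_xz[-n, , drop = FALSE])
  rows <- list()
  add <- function(name, xz, y, element = NULL, charge = 0) {
    rows[[length(rows) + 1L]] <<- list(name = name, x = xz[1], y = y, z = xz[2],
                                       element = element, charge = charge)
  }
  ring_names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  sb_mid <- (path$pos[bp$asp_position, ] + path$pos[bp$lys_position, ]) / 2
  res_rows <- integer(0)
  for (i in seq_len(n)) {
    n_before <- length(rows)
    q <- path$pos[i, ]
    add("N", ncol_xz[i, ], y0, "N", .BACKBONE_CHARGES[["N"]])
    add("H", ncol_xz[i, ], y0 + dir[i] * 1.0, "H", .BACKBONE_CHARGES[["H"]])
    add("CA", q, y0, "C", .BACKBONE_CHARGES[["CA"]])
    add("C", prev_col[i, ], y0 + dir[i] * 0.67, "C", .BACKBONE_CHARGES[["C"]])
    add("O", prev_col[i, ], y0 + dir[i] * 1.9, "O", .BACKBONE_CHARGES[["O"]])
    add("CB", q + 1.5 * path$normal[i, ], y0, "C", .BACKBONE_CHARGES[["CB"]])
    if (i %in% bp$phe_positions) {
      centre <- q + 3.0 * path$normal[i, ]
      for (k in 0:5) {
        ang <- k * pi / 3
        add(ring_names[k + 1],
            centre + 1.39 * (cos(ang) * path$tangent[i, ] + sin(ang) * path$normal[i, ]),
            y0, "C", 0)
      }
    }
    if (i == bp$asp_position) {
      add("CG", sb_mid, y0 + 1.0, "C", 0)
      add("OD1", sb_mid + c(0.6, 0.6), y0 + 1.0, "O", -1)
    }
    if (i == bp$lys_position) add("NZ", sb_mid, y0 - 1.0, "N", 1)
    res_rows <- c(res_rows, rep(i, length(rows) - n_before))
  }
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(name = r$name, x = r$x, y = r$y, z = r$z, element = r$element,
               charge = r$charge, stringsAsFactors = FALSE)))
  df$chain_id <- chain_id
  df$res_internal <- res_rows
  df$res_name <- unname(.AA3[sequence[res_rows]])
  df$is_ligand <- FALSE
  df
}

# A straight hexapeptide ligand running along the fibril axis at `centre`,
# side chains pointing along z with sign `side`.
.build_ligand <- function(sequence, centre, side) {
  aa <- strsplit(sequence, "")[[1]]
  if (length(aa) != 6L) .stopf("ligand must be a hexapeptide")
  rows <- list()
  add <- function(name, p, element, charge = 0, res = NULL) {
    rows[[length(rows) + 1L]] <<- list(name = name, x = p[1], y = p[2], z = p[3],
                                       element = element, charge = charge, res = res)
  }
  ring_names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  for (j in 1:6) {
    p <- centre + c(0, (j - 3.5) * 3.47, 0)
    add("N", p + c(0, -1.2, 0), "N", .BACKBONE_CHARGES[["N"]], j)
    add("H", p + c(0, -1.2, side * 1.0), "H", .BACKBONE_CHARGES[["H"]], j)
    add("CA", p, "C", .BACKBONE_CHARGES[["CA"]], j)
    add("C", p + c(0, 1.2, 0), "C", .BACKBONE_CHARGES[["C"]], j)
    add("O", p + c(1.23, 1.2, 0), "O", .BACKBONE_CHARGES[["O"]], j)
    add("CB", p + c(0, 0, side * 1.5), "C", 0, j)
    if (aa[j] %in% c("F", "W", "Y")) {
      centre_ring <- p + c(0, 0, side * 3.0)
      for (k in 0:5) {
        ang <- k * pi / 3
        add(ring_names[k + 1], centre_ring + 1.39 * c(cos(ang), sin(ang), 0),
            "C", 0, j)
      }
    }
    if (aa[j] == "D") add("OD1", p + c(0, 0, side * 2.5), "O", -1, j)
    if (aa[j] == "E") add("OE1", p + c(0, 0, side * 2.5), "O", -1, j)
    if (aa[j] == "K") add("NZ", p + c(0, 0, side * 2.5), "N", 1, j)
  }
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(name = r$name, x = r$x, y = r$y, z = r$z, element = r$element,
               charge = r$charge, res_internal = r$res, stringsAsFactors = FALSE)))
  df$chain_id <- "L"
  df$res_name <- unname(.AA3[aa[df$res_internal]])
  df$is_ligand <- TRUE
  df
}

#' Build the idealized U-shaped pentamer, optionally with a bound hexapeptide
#'
#' Chains A-E are identical, stacked in register along the fibril axis. The
#' construction guarantees, for the default blueprint: inter-chain backbone
#' hydrogen bonds for every neighbouring chain pair, neighbouring Phe ring
#' centroids at positions 3/4 within the stacking cutoff, and intra- plus
#' inter-chain Asp7-Lys12 salt-bridge geometry. A ligand, when given, is
#' placed near one of three named sites without steric overlap.
#'
#' @param blueprint A \code{\link{fibril_blueprint}}.
#' @param ligand Optional hexapeptide sequence (e.g. \code{"MIFFFE"}).
#' @param ligand_site One of \code{"core"} (facing the position-3 ring stack),
#'   \code{"surface"} (position-4 stack) or \code{"cterm"} (beyond the
#'   strand-2 C-termini).
#' @return A \code{fibril_model}; ligand atoms carry \code{res_serial}
#'   131..136.
#' @export
build_pentamer <- function(blueprint = fibril_blueprint(), ligand = NULL,
                           ligand_site = c("core", "surface", "cterm")) {
  bp <- blueprint
  path <- .chain_path(bp)
  sequence <- .ABETA_17_42[seq_len(bp$n_res)]
  sequence[bp$phe_positions] <- "F"
  sequence[bp$asp_position] <- "D"
  sequence[bp$lys_position] <- "K"
  chains <- LETTERS[seq_len(bp$n_chains)]
  parts <- lapply(seq_along(chains), function(c)
    .build_chain(bp, path, chains[c], (c - 1) * bp$rise, sequence))
  df <- do.call(rbind, parts)
  if (!is.null(ligand)) {
    ligand_site <- match.arg(ligand_site)
    y_mid <- (bp$n_chains - 1) * bp$rise / 2
    centre <- switch(ligand_site,
      core = {
        q <- path$pos[bp$phe_positions[1], ] + 7.5 * path$normal[bp$phe_positions[1], ]
        c(q[1], y_mid, q[2])
      },
      surface = {
        q <- path$pos[bp$phe_positions[2], ] + 7.5 * path$normal[bp$phe_positions[2], ]
        c(q[1], y_mid, q[2])
      },
      cterm = {
        q <- path$pos[bp$n_res, ] + 5.5 * path$tangent[bp$n_res, ]
        c(q[1], y_mid, q[2])
      })
    side <- switch(ligand_site, core = -1, surface = -1, cterm = 1)
    ldf <- .build_ligand(ligand, centre, side)
    fib_xyz <- as.matrix(df[df$element != "H", c("x", "y", "z")])
    lig_xyz <- as.matrix(ldf[ldf$element != "H", c("x", "y", "z")])
    dmin <- min(.cross_dist(lig_xyz, fib_xyz))
    if (dmin < 2.0)
      .stopf("ligand placement at site '%s' violates the steric constraint (min heavy-atom distance %.2f A < 2.0 A)",
             ligand_site, dmin)
    df <- rbind(df, ldf)
  }
  coords <- as.matrix(df[, c("x", "y", "z")])
  atoms <- df[, c("name", "element", "res_name", "chain_id", "res_internal",
                  "charge", "is_ligand")]
  model <- fibril_model(atoms, coords)
  model$blueprint <- bp
  model
}

#' Scenario for a synthetic stand-in trajectory
#'
#' @param kind \code{"stable"} (Gaussian noise about the ideal coordinates),
#'   \code{"perturbed"} (additionally, per frame, a Bernoulli-toggled rigid
#'   2 Angstrom outward displacement of designated chains, so that each
#'   guaranteed interaction involving them holds in about
#'   \code{target_occupancy} of frames) or \code{"dissociation"} (from
#'   \code{t_start} on, rigid outward drift of the designated chains at
#'   \code{drift_velocity} plus slow tumbling).
#' @param noise_sigma Per-atom Gaussian noise s.d. in Angstrom. Defaults to
#'   0.1 for stable/dissociation and 0.05 for perturbed (small against the
#'   0.3 Angstrom hydrogen-bond margin, so toggling dominates occupancy).
#' @param target_occupancy Fraction of frames in which the perturbed chains'
#'   interactions hold.
#' @param chains Chains displaced (perturbed) or drifting (dissociation).
#' @param t_start Onset of dissociation drift, ps.
#' @param drift_velocity Outward drift speed, Angstrom/ps.
#' @param tumble_rate Tumbling angular rate of drifting chains, rad/ps.
#' @param seed Integer RNG seed; identical scenarios give bit-identical
#'   trajectories.
#' @return A list of class \code{fibril_scenario}.
#' @export
scenario <- function(kind = c("stable", "perturbed", "dissociation"),
                     noise_sigma = NULL, target_occupancy = 0.5,
                     chains = NULL, t_start = NULL, drift_velocity = 0.05,
                     tumble_rate = 0.002, seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(noise_sigma))
    noise_sigma <- if (kind == "perturbed") 0.05 else 0.1
  if (is.null(chains)) chains <- if (kind == "dissociation") "E" else "A"
  if (kind == "dissociation" && length(chains) == 0)
    .stopf("dissociation scenario needs at least one dissociating chain")
  if (kind == "perturbed" &&
      (target_occupancy < 0 || target_occupancy > 1))
    .stopf("target_occupancy must lie in [0, 1]")
  structure(list(kind = kind, noise_sigma = noise_sigma,
                 target_occupancy = target_occupancy, chains = chains,
                 t_start = t_start, drift_velocity = drift_velocity,
                 tumble_rate = tumble_rate, seed = as.integer(seed)),
            class = "fibril_scenario")
}

# Rodrigues rotation matrix about unit axis u by angle theta.
.rotation_about <- function(u, theta) {
  u <- .unit(u)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Outward displacement direction for a chain: away from the fibril centre
# along the stacking axis.
.outward_direction <- function(model, chain) {
  at <- model$atoms
  chains <- unique(at$chain_id[!at$is_ligand])
  mid <- (length(chains) + 1) / 2
  pos <- match(chain, chains)
  if (is.na(pos)) .stopf("chain %s not in model", chain)
  c(0, if (pos <= mid) -1 else 1, 0)
}

#' Simulate a stand-in trajectory for a fibril model
#'
#' Every frame is the ideal coordinates plus i.i.d. Gaussian noise (never a
#' random walk, so occupancy targets are stationary), with the scenario's
#' rigid-body perturbation or drift applied on top. Deterministic given
#' (model, scenario, n_frames, dt).
#'
#' @param model A \code{fibril_model} (typically from
#'   \code{\link{build_pentamer}}).
#' @param scenario A \code{\link{scenario}}.
#' @param n_frames Number of frames (>= 2).
#' @param dt Frame spacing in ps (default 2).
#' @param replica_id Replica label carried on the trajectory.
#' @return A \code{fibril_trajectory}.
#' @export
simulate_trajectory <- function(model, scenario, n_frames, dt = 2,
                                replica_id = 1L) {
  if (n_frames < 2) .stopf("n_frames must be >= 2")
  sc <- scenario
  times <- (seq_len(n_frames) - 1) * dt
  if (sc$kind == "dissociation") {
    if (is.null(sc$t_start)) sc$t_start <- times[ceiling(n_frames / 2)]
    if (sc$t_start < times[1] || sc$t_start > times[n_frames])
      .stopf("t_start (%g ps) outside the trajectory span", sc$t_start)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(sc$seed)

  na <- nrow(model$atoms)
  base <- model$coords
  chain_idx <- lapply(sc$chains, function(ch)
    which(model$atoms$chain_id == ch & !model$atoms$is_ligand))
  # fixed draw order: toggles, tumble axes, then the noise block
  toggles <- if (sc$kind == "perturbed")
    stats::rbinom(n_frames, 1L, 1 - sc$target_occupancy) else integer(n_frames)
  axes <- lapply(sc$chains, function(ch) .unit(stats::rnorm(3)))
  noise <- array(stats::rnorm(na * 3 * n_frames, 0, sc$noise_sigma),
                 dim = c(na, 3, n_frames))

  coords <- array(0, dim = c(na, 3, n_frames))
  for (f in seq_len(n_frames)) {
    xyz <- base
    if (sc$kind == "perturbed" && toggles[f] == 1L) {
      for (k in seq_along(sc$chains)) {
        dir <- .outward_direction(model, sc$chains[k])
        xyz[chain_idx[[k]], ] <- sweep(xyz[chain_idx[[k]], , drop = FALSE], 2,
                                       2.0 * dir, "+")
      }
    }
    if (sc$kind == "dissociation" && times[f] >= sc$t_start) {
      dtd <- times[f] - sc$t_start
      for (k in seq_along(sc$chains)) {
        idx <- chain_idx[[k]]
        dir <- .outward_direction(model, sc$chains[k])
        centroid <- colMeans(base[idx, , drop = FALSE])
        R <- .rotation_about(axes[[k]], sc$tumble_rate * dtd)
        moved <- sweep(base[idx, , drop = FALSE], 2, centroid) %*% t(R)
        xyz[idx, ] <- sweep(moved, 2, centroid + sc$drift_velocity * dtd * dir, "+")
      }
    }
    coords[, , f] <- xyz + noise[, , f]
  }
  trajectory(model, coords, times = times, replica_id = replica_id,
             label = sc$kind)
}
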