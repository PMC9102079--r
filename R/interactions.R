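# Geometric interaction detectors and occupancy statistics.
#
# Criteria (all configurable):
#   hydrogen bond: donor-acceptor distance <= 3.2 A and donor-H-acceptor
#                  angle >= 120 degrees;
#   salt bridge:   Asp(7) CG to Lys(12) NZ <= 4.5 A, same chain or
#                  neighbouring chains (Asp in the preceding chain);
#   stacking:      Phe ring centroids of neighbouring chains <= 5.5 A at
#                  internal positions 3 and 4;
#   contact:       heavy-atom pair across two groups <= 4.5 A.

.SIDECHAIN_DONORS <- c("NZ", "NE", "NH1", "NH2", "ND2", "NE2", "NE1",
                       "ND1", "OG", "OG1", "OH")
.SIDECHAIN_ACCEPTORS <- c("OD1", "OD2", "OE1", "OE2", "OG", "OG1", "OH", "ND1")
.RING_NAMES <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")

# Enumerate hydrogen-bond donors (heavy atom + one row per attached or
# reconstructable H) and acceptors, plus the allowed donor/acceptor pairing
# mask. Precomputed once per topology so per-frame evaluation is cheap.
.hbond_sites <- function(model, pairing = c("interchain", "fibril_ligand", "all")) {
  pairing <- match.arg(pairing)
  at <- model$atoms
  res_key <- paste(at$chain_id, at$res_internal)

  donors <- list()
  skipped <- 0L
  for (i in which(at$name == "N")) {
    same_res <- which(res_key == res_key[i])
    h <- same_res[at$name[same_res] %in% c("H", "HN", "H1")]
    if (length(h)) {
      donors[[length(donors) + 1L]] <- list(heavy = i, h = h[1], ca = NA, cprev = NA)
    } else {
      ca <- same_res[at$name[same_res] == "CA"]
      prev <- which(at$chain_id == at$chain_id[i] &
                      at$res_internal == at$res_internal[i] - 1L &
                      at$is_ligand == at$is_ligand[i] & at$name == "C")
      if (length(ca) && length(prev)) {
        donors[[length(donors) + 1L]] <- list(heavy = i, h = NA_integer_,
                                              ca = ca[1], cprev = prev[1])
      } else skipped <- skipped + 1L
    }
  }
  for (i in which(at$name %in% .SIDECHAIN_DONORS & at$element %in% c("N", "O"))) {
    same_res <- which(res_key == res_key[i])
    stem <- substring(at$name[i], 2)
    h <- same_res[at$element[same_res] == "H" &
                    startsWith(at$name[same_res], paste0("H", stem))]
    if (length(h)) {
      for (hh in h) donors[[length(donors) + 1L]] <-
        list(heavy = i, h = hh, ca = NA, cprev = NA)
    } else skipped <- skipped + 1L
  }
  if (skipped > 0)
    .warnf("%d donor(s) without an attached or reconstructable hydrogen were skipped",
           skipped)
  acceptors <- which(at$name %in% c("O", "OXT") |
                       at$name %in% .SIDECHAIN_ACCEPTORS)

  dheavy <- vapply(donors, `[[`, integer(1), "heavy")
  dh <- vapply(donors, function(d) as.integer(d$h), integer(1))
  dca <- vapply(donors, function(d) as.integer(d$ca), integer(1))
  dcp <- vapply(donors, function(d) as.integer(d$cprev), integer(1))
  mask <- matrix(TRUE, length(donors), length(acceptors))
  if (length(donors) && length(acceptors)) {
    drk <- res_key[dheavy]; ark <- res_key[acceptors]
    mask <- outer(drk, ark, "!=")  # never intra-residue
    dch <- at$chain_id[dheavy]; ach <- at$chain_id[acceptors]
    dlig <- at$is_ligand[dheavy]; alig <- at$is_ligand[acceptors]
    if (pairing == "interchain") {
      mask <- mask & outer(dch, ach, "!=") & outer(!dlig, !alig, "&")
    } else if (pairing == "fibril_ligand") {
      mask <- mask & outer(dlig, alig, "!=")  # exactly one side on the ligand
    }
  }
  list(donors = donors, dheavy = dheavy, dh = dh, dca = dca, dcp = dcp,
       acceptors = acceptors, mask = mask, atoms = at)
}

# Logical (n_donor_rows x n_acceptors) presence matrix for one frame.
.hbond_eval <- function(sites, coords, d_max, angle_min) {
  nd <- length(sites$donors)
  na_ <- length(sites$acceptors)
  if (nd == 0 || na_ == 0) return(matrix(FALSE, nd, na_))
  D <- coords[sites$dheavy, , drop = FALSE]
  H <- matrix(0, nd, 3)
  has_h <- !is.na(sites$dh)
  if (any(has_h)) H[has_h, ] <- coords[sites$dh[has_h], , drop = FALSE]
  for (k in which(!has_h)) {
    H[k, ] <- reconstruct_amide_h(coords[sites$dheavy[k], ],
                                  coords[sites$dca[k], ], coords[sites$dcp[k], ])
  }
  A <- coords[sites$acceptors, , drop = FALSE]
  dist_ok <- .cross_dist(D, A) <= d_max & sites$mask
  hit <- which(dist_ok, arr.ind = TRUE)
  if (nrow(hit)) {
    ang <- .angle_at(D[hit[, 1], , drop = FALSE], H[hit[, 1], , drop = FALSE],
                     A[hit[, 2], , drop = FALSE])
    dist_ok[hit[ang < angle_min, , drop = FALSE]] <- FALSE
  }
  dist_ok
}

.hbond_format <- function(sites, present) {
  hit <- which(present, arr.ind = TRUE)
  at <- sites$atoms
  if (nrow(hit) == 0) {
    return(data.frame(kind = character(0), chain1 = character(0),
                      res1 = integer(0), atom1 = character(0),
                      chain2 = character(0), res2 = integer(0),
                      atom2 = character(0), chain_pair = character(0),
                      id = character(0)))
  }
  di <- sites$dheavy[hit[, 1]]
  ai <- sites$acceptors[hit[, 2]]
  out <- data.frame(
    kind = "hbond",
    chain1 = at$chain_id[di], res1 = at$res_internal[di], atom1 = at$name[di],
    chain2 = at$chain_id[ai], res2 = at$res_internal[ai], atom2 = at$name[ai],
    stringsAsFactors = FALSE)
  out$chain_pair <- paste0(out$chain1, "-", out$chain2)
  out$id <- sprintf("hbond|%s:%d:%s|%s:%d:%s", out$chain1, out$res1, out$atom1,
                    out$chain2, out$res2, out$atom2)
  out <- out[!duplicated(out$id), , drop = FALSE]  # collapse multiple H routes
  rownames(out) <- NULL
  out
}

#' Detect hydrogen bonds in one frame
#'
#' All donor/acceptor pairs with donor-acceptor distance at most \code{d_max}
#' and donor-H-acceptor angle at least \code{angle_min} degrees. Donors are
#' backbone amide N (an ideal amide H is reconstructed when absent; chain-start
#' N without H is skipped with a warning) plus template side-chain N/O with
#' attached hydrogens; acceptors are backbone O plus side-chain O (and His
#' ND1). Intra-residue pairs are excluded.
#'
#' @param model A \code{fibril_model} providing the topology.
#' @param coords Frame coordinates (default: the model's reference
#'   coordinates).
#' @param d_max Donor-acceptor distance cutoff, Angstrom.
#' @param angle_min Donor-H-acceptor angle cutoff, degrees.
#' @param pairing \code{"interchain"} (between fibril chains),
#'   \code{"fibril_ligand"} or \code{"all"}.
#' @return Data frame of interactions, one row per donor-acceptor pair.
#' @export
detect_hbonds <- function(model, coords = model$coords, d_max = 3.2,
                          angle_min = 120,
                          pairing = c("interchain", "fibril_ligand", "all")) {
  if (d_max <= 0 || angle_min <= 0 || angle_min > 180)
    .stopf("invalid hydrogen-bond criterion")
  sites <- .hbond_sites(model, match.arg(pairing))
  .hbond_format(sites, .hbond_eval(sites, coords, d_max, angle_min))
}

# Candidate Asp-CG / Lys-NZ pairs: 5 intra + 4 inter for the pentamer.
.saltbridge_sites <- function(model, asp_position = 7L, lys_position = 12L) {
  at <- model$atoms
  chains <- unique(at$chain_id[!at$is_ligand])
  cg <- nz <- setNames(rep(NA_integer_, length(chains)), chains)
  for (ch in chains) {
    i <- which(at$chain_id == ch & !at$is_ligand &
                 at$res_internal == asp_position & at$name == "CG")
    j <- which(at$chain_id == ch & !at$is_ligand &
                 at$res_internal == lys_position & at$name == "NZ")
    if (length(i)) cg[ch] <- i[1] else
      .warnf("chain %s: no CG atom at position %d; pair skipped", ch, asp_position)
    if (length(j)) nz[ch] <- j[1] else
      .warnf("chain %s: no NZ atom at position %d; pair skipped", ch, lys_position)
  }
  rows <- list()
  for (k in seq_along(chains)) {
    if (!is.na(cg[k]) && !is.na(nz[k]))
      rows[[length(rows) + 1L]] <- data.frame(
        subtype = "intra", chain1 = chains[k], chain2 = chains[k],
        cg = cg[k], nz = nz[k], stringsAsFactors = FALSE)
    if (k < length(chains) && !is.na(cg[k]) && !is.na(nz[k + 1]))
      rows[[length(rows) + 1L]] <- data.frame(
        subtype = "inter", chain1 = chains[k], chain2 = chains[k + 1],
        cg = cg[k], nz = nz[k + 1], stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

.saltbridge_format <- function(sites, model, keep, asp_position, lys_position) {
  out <- sites[keep, , drop = FALSE]
  if (!nrow(out)) {
    return(data.frame(kind = character(0), subtype = character(0),
                      chain1 = character(0), res1 = integer(0), atom1 = character(0),
                      chain2 = character(0), res2 = integer(0), atom2 = character(0),
                      chain_pair = character(0), id = character(0)))
  }
  data.frame(kind = "salt_bridge", subtype = out$subtype,
             chain1 = out$chain1, res1 = asp_position, atom1 = "CG",
             chain2 = out$chain2, res2 = lys_position, atom2 = "NZ",
             chain_pair = paste0(out$chain1, "-", out$chain2),
             id = sprintf("salt_bridge|%s|%s:%d:CG|%s:%d:NZ", out$subtype,
                          out$chain1, asp_position, out$chain2, lys_position),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Detect Asp-Lys salt bridges in one frame
#'
#' For each chain the intra-chain pair (Asp CG, Lys NZ) and for each
#' neighbouring chain pair the inter-chain pair (Asp CG in the preceding
#' chain, Lys NZ in the succeeding chain) are evaluated against the distance
#' cutoff.
#'
#' @inheritParams detect_hbonds
#' @param d_max CG-NZ distance cutoff, Angstrom.
#' @param asp_position,lys_position Internal residue positions of the
#'   bridge partners.
#' @return Data frame of present salt bridges with an intra/inter
#'   \code{subtype} column.
#' @export
detect_salt_bridges <- function(model, coords = model$coords, d_max = 4.5,
                                asp_position = 7L, lys_position = 12L) {
  sites <- .saltbridge_sites(model, asp_position, lys_position)
  if (is.null(sites))
    return(.saltbridge_format(data.frame(), model, logical(0),
                              asp_position, lys_position))
  d <- .row_norms(coords[sites$cg, , drop = FALSE] -
                    coords[sites$nz, , drop = FALSE])
  .saltbridge_format(sites, model, d <= d_max, asp_position, lys_position)
}

# Ring-atom indices per (chain, position); incomplete rings are skipped.
.stacking_sites <- function(model, positions = c(3L, 4L)) {
  at <- model$atoms
  chains <- unique(at$chain_id[!at$is_ligand])
  rings <- list()
  for (ch in chains) for (p in positions) {
    idx <- which(at$chain_id == ch & !at$is_ligand & at$res_internal == p &
                   at$name %in% .RING_NAMES)
    if (length(idx) < 6L) {
      .warnf("chain %s position %d: incomplete aromatic ring (%d atoms); skipped",
             ch, p, length(idx))
      next
    }
    rings[[paste(ch, p)]] <- list(chain = ch, position = p, idx = idx)
  }
  pairs <- list()
  for (k in seq_len(length(chains) - 1)) for (p in positions) {
    a <- rings[[paste(chains[k], p)]]
    b <- rings[[paste(chains[k + 1], p)]]
    if (!is.null(a) && !is.null(b))
      pairs[[length(pairs) + 1L]] <- list(chain1 = chains[k], chain2 = chains[k + 1],
                                          position = p, idx1 = a$idx, idx2 = b$idx)
  }
  pairs
}

#' Detect Phe-Phe stacking between neighbouring chains in one frame
#'
#' An interaction is present when the two ring centroids (default) or the
#' closest ring-atom pair lie within \code{d_max}. The result carries the
#' internal position so that position-3 (Phe19) and position-4 (Phe20)
#' tallies stay separable.
#'
#' @inheritParams detect_hbonds
#' @param d_max Distance cutoff, Angstrom.
#' @param positions Internal positions carrying the stacked rings.
#' @param method \code{"centroid"} or \code{"minatom"}.
#' @return Data frame of present stacking interactions.
#' @export
detect_stacking <- function(model, coords = model$coords, d_max = 5.5,
                            positions = c(3L, 4L),
                            method = c("centroid", "minatom")) {
  method <- match.arg(method)
  pairs <- .stacking_sites(model, positions)
  rows <- list()
  for (p in pairs) {
    d <- if (method == "centroid") {
      sqrt(sum((colMeans(coords[p$idx1, , drop = FALSE]) -
                  colMeans(coords[p$idx2, , drop = FALSE]))^2))
    } else {
      min(.cross_dist(coords[p$idx1, , drop = FALSE],
                      coords[p$idx2, , drop = FALSE]))
    }
    if (d <= d_max)
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "stacking", position = p$position,
        chain1 = p$chain1, res1 = p$position, atom1 = "ring",
        chain2 = p$chain2, res2 = p$position, atom2 = "ring",
        chain_pair = paste0(p$chain1, "-", p$chain2),
        id = sprintf("stacking|%s-%s|pos%d", p$chain1, p$chain2, p$position),
        stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(kind = character(0), position = integer(0),
                      chain1 = character(0), res1 = integer(0), atom1 = character(0),
                      chain2 = character(0), res2 = integer(0), atom2 = character(0),
                      chain_pair = character(0), id = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count molecular contacts between two atom groups
#'
#' Number of heavy-atom pairs across the two (disjoint) groups within
#' \code{d_max}.
#'
#' @inheritParams detect_hbonds
#' @param group1,group2 Integer atom index vectors (as from
#'   \code{\link{select_atoms}}).
#' @param d_max Contact distance cutoff, Angstrom.
#' @return Integer count.
#' @export
contact_count <- function(model, coords = model$coords, group1, group2,
                          d_max = 4.5) {
  if (length(intersect(group1, group2)))
    .stopf("contact groups must be disjoint")
  heavy <- model$atoms$element != "H"
  g1 <- group1[heavy[group1]]
  g2 <- group2[heavy[group2]]
  if (!length(g1) || !length(g2)) return(0L)
  sum(.cross_dist(coords[g1, , drop = FALSE], coords[g2, , drop = FALSE]) <= d_max)
}

.tier_bands <- function(occ) {
  cut(occ, breaks = c(-Inf, 0.3, 0.5, 0.7, Inf),
      labels = c("<30%", "30-50%", "50-70%", ">=70%"), right = FALSE)
}

#' Interaction occupancy over a trajectory
#'
#' Runs a detector on every frame (optionally strided) and reports, for the
#' union of interactions ever observed, the fraction of frames in which each
#' was present, tiered at the 30/50/70\% thresholds (boundaries inclusive at
#' the lower edge: occupancy exactly 0.70 falls in the \code{">=70\%"} tier).
#'
#' @param traj A \code{fibril_trajectory}.
#' @param type \code{"hbond"}, \code{"salt_bridge"} or \code{"stacking"}.
#' @param ... Passed to the underlying detector (cutoffs, pairing, ...).
#' @param stride Use every \code{stride}-th frame.
#' @return A data frame of class \code{occupancy_table} with per-interaction
#'   metadata, \code{occupancy} in [0, 1] and \code{tier}; attribute
#'   \code{n_frames} records the number of frames analysed.
#' @export
occupancy <- function(traj, type = c("hbond", "salt_bridge", "stacking"), ...,
                      stride = 1L) {
  type <- match.arg(type)
  model <- traj$topology
  frames <- seq(1L, n_frames(traj), by = stride)
  nf <- length(frames)
  dots <- list(...)

  if (type == "hbond") {
    d_max <- dots$d_max %||% 3.2
    angle_min <- dots$angle_min %||% 120
    pairing <- dots$pairing %||% "interchain"
    sites <- .hbond_sites(model, pairing)
    counts <- matrix(0L, length(sites$donors), length(sites$acceptors))
    for (f in frames)
      counts <- counts + .hbond_eval(sites, traj$coords[, , f], d_max, angle_min)
    meta <- .hbond_format(sites, counts > 0)
    # re-collapse multi-H donor rows by taking the max count per unique pair
    hit <- which(counts > 0, arr.ind = TRUE)
    ids <- sprintf("hbond|%s:%d:%s|%s:%d:%s",
                   sites$atoms$chain_id[sites$dheavy[hit[, 1]]],
                   sites$atoms$res_internal[sites$dheavy[hit[, 1]]],
                   sites$atoms$name[sites$dheavy[hit[, 1]]],
                   sites$atoms$chain_id[sites$acceptors[hit[, 2]]],
                   sites$atoms$res_internal[sites$acceptors[hit[, 2]]],
                   sites$atoms$name[sites$acceptors[hit[, 2]]])
    occ <- tapply(counts[hit], ids, max) / nf
    meta$occupancy <- as.numeric(occ[meta$id])
  } else if (type == "salt_bridge") {
    asp <- dots$asp_position %||% 7L
    lys <- dots$lys_position %||% 12L
    d_max <- dots$d_max %||% 4.5
    sites <- .saltbridge_sites(model, asp, lys)
    counts <- rep(0L, if (is.null(sites)) 0L else nrow(sites))
    if (length(counts)) {
      for (f in frames) {
        xyz <- traj$coords[, , f]
        d <- .row_norms(xyz[sites$cg, , drop = FALSE] - xyz[sites$nz, , drop = FALSE])
        counts <- counts + (d <= d_max)
      }
    }
    meta <- .saltbridge_format(sites, model, counts > 0, asp, lys)
    meta$occupancy <- counts[counts > 0] / nf
  } else {
    d_max <- dots$d_max %||% 5.5
    positions <- dots$positions %||% c(3L, 4L)
    method <- dots$method %||% "centroid"
    pairs <- .stacking_sites(model, positions)
    counts <- rep(0L, length(pairs))
    for (f in frames) {
      xyz <- traj$coords[, , f]
      for (k in seq_along(pairs)) {
        p <- pairs[[k]]
        d <- if (method == "centroid")
          sqrt(sum((colMeans(xyz[p$idx1, , drop = FALSE]) -
                      colMeans(xyz[p$idx2, , drop = FALSE]))^2))
        else min(.cross_dist(xyz[p$idx1, , drop = FALSE], xyz[p$idx2, , drop = FALSE]))
        counts[k] <- counts[k] + (d <= d_max)
      }
    }
    keep <- counts > 0
    meta <- do.call(rbind, lapply(which(keep), function(k) {
      p <- pairs[[k]]
      data.frame(kind = "stacking", position = p$position,
                 chain1 = p$chain1, res1 = p$position, atom1 = "ring",
                 chain2 = p$chain2, res2 = p$position, atom2 = "ring",
                 chain_pair = paste0(p$chain1, "-", p$chain2),
                 id = sprintf("stacking|%s-%s|pos%d", p$chain1, p$chain2, p$position),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(meta))
      meta <- data.frame(kind = character(0), position = integer(0),
                         chain1 = character(0), res1 = integer(0),
                         atom1 = character(0), chain2 = character(0),
                         res2 = integer(0), atom2 = character(0),
                         chain_pair = character(0), id = character(0))
    meta$occupancy <- counts[keep] / nf
  }
  meta$tier <- .tier_bands(meta$occupancy)
  attr(meta, "n_frames") <- nf
  class(meta) <- c("occupancy_table", class(meta))
  meta
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tier summary of an occupancy table
#'
#' Counts of interactions with occupancy at or above each threshold, plus the
#' "sum of all present" count (occupancy at or above the lowest tier).
#'
#' @param tab An \code{occupancy_table}.
#' @param thresholds Occupancy thresholds.
#' @return Named numeric vector of counts.
#' @export
tier_counts <- function(tab, thresholds = c(0.3, 0.5, 0.7)) {
  out <- vapply(thresholds, function(t) sum(tab$occupancy >= t), numeric(1))
  names(out) <- sprintf(">=%d%%", round(thresholds * 100))
  c(out, total_present = sum(tab$occupancy >= min(thresholds)))
}

#' Global salt-bridge occurrence percentages
#'
#' Sum of per-pair occupancies times 100, separately over the five intra-chain
#' pairs (range 0-500) and the four neighbouring-chain pairs (range 0-400).
#' Values above 100 simply mean that more than one pair is persistently
#' formed.
#'
#' @param traj A \code{fibril_trajectory}.
#' @param ... Passed to the salt-bridge detector.
#' @return Named vector \code{c(intra_percent, inter_percent)}.
#' @export
global_salt_bridge_occurrence <- function(traj, ...) {
  tab <- occupancy(traj, "salt_bridge", ...)
  c(intra_percent = 100 * sum(tab$occupancy[tab$subtype == "intra"]),
    inter_percent = 100 * sum(tab$occupancy[tab$subtype == "inter"]))
}

#' Rank docking poses by contacts and energies
#'
#' Each pose is ranked separately by (1) number of fibril-ligand contacts
#' (descending), (2) fibril-ligand interaction energy (ascending, kcal/mol)
#' and (3) overall energy (ascending); the final order is by mean rank, with
#' ties broken by criterion (1) and then input order.
#'
#' @param poses Data frame with columns \code{contacts},
#'   \code{e_interaction}, \code{e_total} (and optionally \code{label}).
#' @param top_n Optionally keep only the best \code{top_n} poses.
#' @return The input rows ordered by final rank, with rank columns added.
#' @export
rank_poses <- function(poses, top_n = NULL) {
  if (nrow(poses) < 1) .stopf("need at least one pose")
  r1 <- rank(-poses$contacts, ties.method = "min")
  r2 <- rank(poses$e_interaction, ties.method = "min")
  r3 <- rank(poses$e_total, ties.method = "min")
  mean_rank <- (r1 + r2 + r3) / 3
  ord <- order(mean_rank, r1, seq_len(nrow(poses)))
  out <- poses[ord, , drop = FALSE]
  out$rank_contacts <- r1[ord]
  out$rank_interaction <- r2[ord]
  out$rank_total <- r3[ord]
  out$mean_rank <- mean_rank[ord]
  out$final_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  if (!is.null(top_n)) out <- out[seq_len(min(top_n, nrow(out))), , drop = FALSE]
  out
}
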