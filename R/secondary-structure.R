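# Kabsch-Sander style secondary-structure assignment.
#
# Backbone hydrogen bonds are scored with the electrostatic energy
#   E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)  [kcal/mol]
# and accepted when E < -0.5. Bridges between residues (same chain at
# sequence separation >= 3, or different chains) follow the standard
# parallel/antiparallel patterns; helices come from runs of i->i+3/4/5
# turns; bend from C-alpha curvature above 70 degrees. Category priority:
# helix > sheet > turn > bend > coil.

.SS_LEVELS <- c("parallel-beta", "antiparallel-beta", "helix-310",
                "helix-alpha", "helix-pi", "turn", "bend", "coil")

# Residue-level backbone table for one topology: atom indices of N, H, CA,
# C, O per residue, with chain bookkeeping. H may be reconstructable.
.residue_backbone <- function(model) {
  at <- model$atoms
  key <- paste(at$chain_id, at$res_internal, at$is_ligand)
  ures <- unique(key)
  idx_of <- function(k, nm) {
    i <- which(key == k & at$name == nm)
    if (length(i)) i[1] else NA_integer_
  }
  res <- data.frame(
    chain = at$chain_id[match(ures, key)],
    res_internal = at$res_internal[match(ures, key)],
    is_ligand = at$is_ligand[match(ures, key)],
    stringsAsFactors = FALSE)
  for (nm in c("N", "H", "CA", "C", "O"))
    res[[nm]] <- vapply(ures, idx_of, integer(1), nm = nm)
  # previous residue in the same chain (for H reconstruction)
  res$prev <- NA_integer_
  for (r in seq_len(nrow(res))) {
    p <- which(res$chain == res$chain[r] & res$is_ligand == res$is_ligand[r] &
                 res$res_internal == res$res_internal[r] - 1L)
    if (length(p)) res$prev[r] <- p[1]
  }
  res
}

# n_res x n_res logical matrix: hb[i, j] TRUE when the amide NH of residue i
# donates to the carbonyl CO of residue j.
.ks_hbond_matrix <- function(res, coords, warn = TRUE) {
  n <- nrow(res)
  N <- coords[res$N, , drop = FALSE]
  CA <- coords[res$CA, , drop = FALSE]
  C <- coords[res$C, , drop = FALSE]
  O <- coords[res$O, , drop = FALSE]
  H <- matrix(NA_real_, n, 3)
  ok_donor <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!is.na(res$H[i])) {
      H[i, ] <- coords[res$H[i], ]
    } else if (!is.na(res$prev[i]) && !is.na(res$C[res$prev[i]]) &&
               !is.na(res$N[i]) && !is.na(res$CA[i])) {
      H[i, ] <- reconstruct_amide_h(N[i, ], CA[i, ], coords[res$C[res$prev[i]], ])
    } else ok_donor[i] <- FALSE
  }
  ok_acceptor <- !is.na(res$C) & !is.na(res$O)
  hb <- matrix(FALSE, n, n)
  don <- which(ok_donor & !is.na(res$N))
  acc <- which(ok_acceptor)
  if (length(don) && length(acc)) {
    rON <- .cross_dist(N[don, , drop = FALSE], O[acc, , drop = FALSE])
    rCH <- .cross_dist(H[don, , drop = FALSE], C[acc, , drop = FALSE])
    rOH <- .cross_dist(H[don, , drop = FALSE], O[acc, , drop = FALSE])
    rCN <- .cross_dist(N[don, , drop = FALSE], C[acc, , drop = FALSE])
    # guard clashes so 1/r does not explode into spurious assignments
    rON <- pmax(rON, 0.5); rCH <- pmax(rCH, 0.5)
    rOH <- pmax(rOH, 0.5); rCN <- pmax(rCN, 0.5)
    E <- 0.084 * 332 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
    hb[don, acc] <- E < -0.5
    diag(hb) <- FALSE   # a residue never bonds itself
  }
  hb
}

#' Assign secondary structure for one frame
#'
#' Kabsch-Sander style assignment over the backbone hydrogen-bond network;
#' categories are parallel/antiparallel beta, 3-10/alpha/pi helix, turn,
#' bend and coil. Residues with missing backbone atoms are labelled coil
#' with a warning.
#'
#' @param model A \code{fibril_model}.
#' @param coords Frame coordinates (default: reference coordinates).
#' @param include_ligand Assign the ligand residues too (default FALSE:
#'   fibril chains only, matching the convention of reporting fibril
#'   secondary structure).
#' @return Data frame with \code{chain}, \code{res_internal} and \code{ss}
#'   (factor with the eight category levels).
#' @export
assign_secondary_structure <- function(model, coords = model$coords,
                                       include_ligand = FALSE) {
  res <- .residue_backbone(model)
  if (!include_ligand) res <- res[!res$is_ligand, , drop = FALSE]
  n <- nrow(res)
  incomplete <- is.na(res$N) | is.na(res$CA) | is.na(res$C) | is.na(res$O)
  if (any(incomplete))
    .warnf("%d residue(s) with missing backbone atoms labelled coil",
           sum(incomplete))
  hb <- .ks_hbond_matrix(res, coords)

  same_chain <- outer(res$chain, res$chain, "==") &
    outer(res$is_ligand, res$is_ligand, "==")
  seqsep <- outer(res$res_internal, res$res_internal, "-")
  # successor/predecessor within a chain (NA at termini)
  succ <- prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    s <- which(same_chain[i, ] & seqsep[, i] == 1L)
    p <- which(same_chain[i, ] & seqsep[, i] == -1L)
    if (length(s)) succ[i] <- s[1]
    if (length(p)) prev[i] <- p[1]
  }
  hb_at <- function(i, j) {
    ok <- !is.na(i) & !is.na(j)
    out <- rep(FALSE, length(ok))
    out[ok] <- hb[cbind(i[ok], j[ok])]
    out
  }

  # --- bridges -------------------------------------------------------------
  par_bridge <- antipar_bridge <- rep(FALSE, n)
  cand <- which((!same_chain | abs(seqsep) >= 3L), arr.ind = TRUE)
  cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
  if (nrow(cand)) {
    i <- cand[, 1]; j <- cand[, 2]
    par <- (hb_at(prev[i], j) & hb_at(j, succ[i])) |
           (hb_at(prev[j], i) & hb_at(i, succ[j]))
    anti <- (hb_at(i, j) & hb_at(j, i)) |
            (hb_at(prev[i], succ[j]) & hb_at(prev[j], succ[i]))
    for (r in which(par)) { par_bridge[i[r]] <- TRUE; par_bridge[j[r]] <- TRUE }
    for (r in which(anti)) { antipar_bridge[i[r]] <- TRUE; antipar_bridge[j[r]] <- TRUE }
  }

  # --- turns and helices ---------------------------------------------------
  turn_start <- list()   # turn_start[[as.character(nn)]][i]: hb(i+nn -> i)
  in_turn <- rep(FALSE, n)
  for (nn in 3:5) {
    ts <- rep(FALSE, n)
    for (i in seq_len(n)) {
      j <- i
      ok <- TRUE
      for (step in seq_len(nn)) {       # walk nn successors within the chain
        j <- succ[j]
        if (is.na(j)) { ok <- FALSE; break }
      }
      if (ok && hb[j, i]) ts[i] <- TRUE
    }
    turn_start[[as.character(nn)]] <- ts
    for (i in which(ts)) {
      j <- i
      for (step in seq_len(nn - 1)) { j <- succ[j]; in_turn[j] <- TRUE }
    }
  }
  helix <- rep(NA_character_, n)
  mark_helix <- function(nn, label, helix) {
    ts <- turn_start[[as.character(nn)]]
    for (i in seq_len(n)) {
      if (ts[i] && !is.na(prev[i]) && ts[prev[i]]) {
        j <- i
        for (step in 0:(nn - 1)) {
          if (is.na(helix[j])) helix[j] <- label
          j <- succ[j]
          if (is.na(j)) break
        }
      }
    }
    helix
  }
  helix <- mark_helix(4, "helix-alpha", helix)
  helix <- mark_helix(3, "helix-310", helix)
  helix <- mark_helix(5, "helix-pi", helix)

  # --- bend ----------------------------------------------------------------
  bend <- rep(FALSE, n)
  for (i in seq_len(n)) {
    p2 <- prev[i]; if (!is.na(p2)) p2 <- prev[p2]
    s2 <- succ[i]; if (!is.na(s2)) s2 <- succ[s2]
    if (!is.na(p2) && !is.na(s2) && !incomplete[i] && !incomplete[p2] &&
        !incomplete[s2]) {
      v1 <- coords[res$CA[i], ] - coords[res$CA[p2], ]
      v2 <- coords[res$CA[s2], ] - coords[res$CA[i], ]
      ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                 (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
      bend[i] <- ang > 70
    }
  }

  ss <- rep("coil", n)
  ss[bend] <- "bend"
  ss[in_turn] <- "turn"
  ss[antipar_bridge] <- "antiparallel-beta"
  ss[par_bridge] <- "parallel-beta"   # parallel takes precedence on ties
  ss[!is.na(helix)] <- helix[!is.na(helix)]
  ss[incomplete] <- "coil"
  data.frame(chain = res$chain, res_internal = res$res_internal,
             ss = factor(ss, levels = .SS_LEVELS), stringsAsFactors = FALSE)
}

#' Secondary-structure occupancy over a trajectory
#'
#' Percentage of (residue, frame) pairs in each category, with the derived
#' beta-sheet sum (parallel + antiparallel) reported alongside.
#'
#' @param traj A \code{fibril_trajectory}.
#' @param stride Use every \code{stride}-th frame.
#' @param include_ligand Include ligand residues (default FALSE).
#' @return Named numeric vector of percentages for the eight categories plus
#'   \code{sum_beta}; percentages over the categories sum to 100.
#' @export
ss_occupancy <- function(traj, stride = 1L, include_ligand = FALSE) {
  frames <- seq(1L, n_frames(traj), by = stride)
  counts <- setNames(numeric(length(.SS_LEVELS)), .SS_LEVELS)
  for (f in frames) {
    a <- assign_secondary_structure(traj$topology, traj$coords[, , f],
                                    include_ligand = include_ligand)
    tab <- table(a$ss)
    counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
  }
  pct <- 100 * counts / sum(counts)
  c(pct, sum_beta = unname(pct["parallel-beta"] + pct["antiparallel-beta"]))
}
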