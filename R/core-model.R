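# Domain containers and numbering conventions.
#
# Three residue numberings coexist on every atom of a protofibril model:
#   * res_internal: 1..26 within each fibril chain,
#   * res_abeta:    amyloid-beta numbering 17..42 (= res_internal + 16),
#   * res_serial:   continuous across chains, chain A 1-26, B 27-52, ...,
#                   E 105-130, ligand 131-136.
# All analyzers address atoms through the topology table, so the maps are
# populated once at construction / read time.

#' Construct a fibril model
#'
#' A fibril model bundles a topology table (one row per atom) with the
#' reference coordinates of those atoms. The topology carries all three
#' residue numbering conventions plus per-atom mass, partial charge,
#' Lennard-Jones class and generalized-Born radius.
#'
#' @param atoms Data frame with columns \code{serial}, \code{name},
#'   \code{element}, \code{res_name}, \code{chain_id}, \code{res_internal},
#'   \code{res_abeta}, \code{res_serial}, \code{mass}, \code{charge},
#'   \code{rmin2}, \code{eps}, \code{gb_radius}, \code{is_ligand}.
#'   Missing parameter columns are filled from element lookups.
#' @param coords Numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @return An object of class \code{fibril_model}.
#' @export
fibril_model <- function(atoms, coords) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  coords <- as.matrix(coords)
  if (nrow(atoms) != nrow(coords) || ncol(coords) != 3L) {
    .stopf("coords must be an n x 3 matrix matching the atom table (%d atoms)",
           nrow(atoms))
  }
  needed <- c("name", "res_name", "chain_id")
  miss <- setdiff(needed, names(atoms))
  if (length(miss)) .stopf("atom table lacks column(s): %s",
                           paste(miss, collapse = ", "))
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$element)) atoms$element <- .element_from_name(atoms$name)
  if (is.null(atoms$mass)) atoms$mass <- element_mass(atoms$element)
  if (is.null(atoms$charge)) atoms$charge <- 0
  if (is.null(atoms$rmin2) || is.null(atoms$eps)) {
    vdw <- .vdw_for_element(atoms$element)
    atoms$rmin2 <- vdw[, "rmin2"]
    atoms$eps <- vdw[, "eps"]
  }
  if (is.null(atoms$gb_radius)) atoms$gb_radius <- .gb_radius_for_element(atoms$element)
  if (is.null(atoms$is_ligand)) atoms$is_ligand <- FALSE
  atoms <- .fill_numbering(atoms)
  if (any(!is.finite(coords))) .stopf("non-finite coordinates in model")
  if (any(atoms$mass <= 0)) .stopf("non-positive atomic mass in model")
  dimnames(coords) <- NULL
  structure(list(atoms = atoms, coords = coords), class = "fibril_model")
}

# Populate res_internal / res_abeta / res_serial from chain order and residue
# order of appearance, when absent.
.fill_numbering <- function(atoms) {
  chains <- unique(atoms$chain_id)
  res_internal <- integer(nrow(atoms))
  res_serial <- integer(nrow(atoms))
  offset <- 0L
  for (ch in chains) {
    idx <- which(atoms$chain_id == ch)
    key <- if (!is.null(atoms$res_id)) {
      atoms$res_id[idx]
    } else if (!is.null(atoms$res_internal)) {
      atoms$res_internal[idx]
    } else {
      # contiguous runs of identical residue names form one residue each
      cumsum(c(TRUE, atoms$res_name[idx][-1] !=
                       atoms$res_name[idx][-length(idx)]))
    }
    ri <- match(key, unique(key))
    res_internal[idx] <- ri
    res_serial[idx] <- ri + offset
    offset <- offset + max(ri)
  }
  if (is.null(atoms$res_internal)) atoms$res_internal <- res_internal
  if (is.null(atoms$res_serial)) atoms$res_serial <- res_serial
  if (is.null(atoms$res_abeta)) atoms$res_abeta <- atoms$res_internal + 16L
  atoms
}

#' @export
print.fibril_model <- function(x, ...) {
  nch <- length(unique(x$atoms$chain_id[!x$atoms$is_ligand]))
  cat(sprintf("fibril_model: %d atoms, %d fibril chain(s)%s\n",
              nrow(x$atoms), nch,
              if (any(x$atoms$is_ligand)) " + ligand" else ""))
  invisible(x)
}

#' Validate the pentamer contract of a fibril model
#'
#' Checks that the model has exactly five fibril chains with identical
#' residue counts (26) and identical per-residue atom layouts, that the dual
#' numbering maps are consistent (\code{res_abeta = res_internal + 16};
#' \code{res_serial} continuous in chain order A < B < C < D < E < ligand),
#' and that the neighbour relation is the stacked-chain one.
#'
#' @param model A \code{fibril_model}.
#' @return Invisibly \code{TRUE}; otherwise an error describing the first
#'   violated invariant.
#' @export
validate_pentamer <- function(model) {
  at <- model$atoms
  fib <- at[!at$is_ligand, ]
  chains <- unique(fib$chain_id)
  if (length(chains) != 5L)
    .stopf("expected 5 fibril chains, found %d", length(chains))
  layouts <- lapply(chains, function(ch) {
    sub <- fib[fib$chain_id == ch, ]
    if (max(sub$res_internal) != 26L || length(unique(sub$res_internal)) != 26L)
      .stopf("chain %s does not have 26 residues", ch)
    paste(sub$res_internal, sub$name, sub$res_name, sep = ":")
  })
  for (i in seq_along(layouts)[-1]) {
    if (!identical(layouts[[i]], layouts[[1]]))
      .stopf("chain %s atom layout differs from chain %s", chains[i], chains[1])
  }
  if (!all(fib$res_abeta == fib$res_internal + 16L))
    .stopf("res_abeta != res_internal + 16")
  # continuous serial across chains in order
  expect_serial <- fib$res_internal + 26L * (match(fib$chain_id, chains) - 1L)
  if (!all(fib$res_serial == expect_serial))
    .stopf("res_serial is not continuous across chains")
  lig <- at[at$is_ligand, ]
  if (nrow(lig) && !all(lig$res_serial == lig$res_internal + 130L))
    .stopf("ligand res_serial must run 131..136")
  invisible(TRUE)
}

#' Pairs of neighbouring chains in a stacked pentamer
#'
#' @param model A \code{fibril_model}.
#' @return Two-column character matrix of neighbouring chain ids,
#'   (A,B), (B,C), (C,D), (D,E) for the canonical pentamer.
#' @export
neighbor_chain_pairs <- function(model) {
  chains <- unique(model$atoms$chain_id[!model$atoms$is_ligand])
  cbind(chains[-length(chains)], chains[-1])
}

#' Construct a trajectory
#'
#' A trajectory is a topology (a \code{fibril_model}) plus a time-ordered
#' stack of coordinate frames.
#'
#' @param topology A \code{fibril_model}.
#' @param coords Numeric array of dimension \code{n_atoms x 3 x n_frames}
#'   (a single \code{n_atoms x 3} matrix is promoted to one frame).
#' @param times Frame times in ps, strictly increasing. Default: frames at
#'   the conventional 2 ps save interval starting at 0.
#' @param replica_id Integer replica label (>= 1).
#' @param label Free-text label.
#' @return An object of class \code{fibril_trajectory}.
#' @export
trajectory <- function(topology, coords, times = NULL, replica_id = 1L,
                       label = "") {
  if (!inherits(topology, "fibril_model")) .stopf("topology must be a fibril_model")
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L)
    .stopf("coords must be an n_atoms x 3 x n_frames array")
  if (dim(coords)[1] != nrow(topology$atoms))
    .stopf("coordinate count (%d) does not match topology atom count (%d)",
           dim(coords)[1], nrow(topology$atoms))
  nf <- dim(coords)[3]
  if (nf < 1L) .stopf("trajectory needs at least one frame")
  if (is.null(times)) times <- (seq_len(nf) - 1) * 2
  if (length(times) != nf) .stopf("times length does not match frame count")
  if (nf > 1 && any(diff(times) <= 0)) .stopf("frame times must be strictly increasing")
  if (any(times < 0)) .stopf("frame times must be >= 0")
  structure(list(topology = topology, coords = coords, times = as.numeric(times),
                 replica_id = as.integer(replica_id), label = label),
            class = "fibril_trajectory")
}

#' @export
print.fibril_trajectory <- function(x, ...) {
  cat(sprintf("fibril_trajectory: %d frames x %d atoms, t = %g..%g ps (replica %d%s)\n",
              n_frames(x), nrow(x$topology$atoms), x$times[1],
              x$times[n_frames(x)], x$replica_id,
              if (nzchar(x$label)) paste0(", ", x$label) else ""))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A \code{fibril_trajectory}.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Coordinates of one frame
#' @param traj A \code{fibril_trajectory}.
#' @param i Frame index (1-based).
#' @return \code{n_atoms x 3} matrix in Angstrom.
#' @export
frame_coords <- function(traj, i) {
  if (i < 1 || i > n_frames(traj)) .stopf("frame index %d out of range", i)
  matrix(traj$coords[, , i], ncol = 3)
}

#' Select atom indices from a topology
#'
#' @param model A \code{fibril_model} (or the topology of a trajectory).
#' @param what One of \code{"all"}, \code{"calpha"}, \code{"backbone"}
#'   (N, CA, C, O), \code{"heavy"} (non-hydrogen).
#' @param chains Optional character vector of chain ids to keep.
#' @param ligand One of \code{"exclude"}, \code{"include"}, \code{"only"}.
#' @return Integer vector of atom row indices.
#' @export
select_atoms <- function(model, what = c("all", "calpha", "backbone", "heavy"),
                         chains = NULL, ligand = c("include", "exclude", "only")) {
  what <- match.arg(what)
  ligand <- match.arg(ligand)
  at <- model$atoms
  keep <- switch(what,
    all = rep(TRUE, nrow(at)),
    calpha = at$name == "CA",
    backbone = at$name %in% c("N", "CA", "C", "O"),
    heavy = at$element != "H")
  if (!is.null(chains)) keep <- keep & at$chain_id %in% chains
  keep <- switch(ligand,
    include = keep,
    exclude = keep & !at$is_ligand,
    only = keep & at$is_ligand)
  which(keep)
}

#' Frames recorded per replica
#'
#' Bookkeeping for the trajectory record: a 100 ns run saved every 2 ps
#' yields 50,000 structures.
#'
#' @param duration_ns Run length in ns (> 0).
#' @param save_interval_ps Coordinate save interval in ps (> 0).
#' @return Integer-valued frame count.
#' @export
frames_per_replica <- function(duration_ns, save_interval_ps) {
  if (duration_ns <= 0 || save_interval_ps <= 0)
    .stopf("duration and save interval must be positive")
  n <- duration_ns * 1000 / save_interval_ps
  if (abs(n - round(n)) > 1e-9 * max(1, n))
    .stopf("duration (%g ns) is not divisible by the save interval (%g ps)",
           duration_ns, save_interval_ps)
  round(n)
}

#' Reconstruct an ideal amide hydrogen
#'
#' Places H on the bisector of the C(prev)-N and CA-N directions, in-plane,
#' at 1.01 Angstrom from N. Used by analyzers that need amide hydrogens when
#' a structure ships without them.
#'
#' @param n,ca,c_prev 3-vectors: positions of the amide N, its CA, and the
#'   carbonyl C of the preceding residue.
#' @return 3-vector position of the reconstructed H.
#' @export
reconstruct_amide_h <- function(n, ca, c_prev) {
  b <- .unit(.unit(n - ca) + .unit(n - c_prev))
  n + 1.01 * b
}

# ---------------------------------------------------------------------------
# Multi-model PDB I/O

#' Read a multi-model PDB file as a trajectory
#'
#' Parsing is delegated to \code{bio3d::read.pdb}; the topology is built from
#' MODEL 1 and every model becomes a frame. The numbering conventions
#' (\code{res_internal}, \code{res_abeta}, \code{res_serial}) are populated
#' from chain order and residue order of appearance. Atom masses come from an
#' element lookup; charges default to 0 unless a REMARK map written by
#' \code{\link{write_multimodel_pdb}} is present.
#'
#' @param path Path to a PDB file with one or more MODEL blocks (plain ATOM
#'   records count as a single model).
#' @param time_step_ps Time spacing assigned to successive models (default
#'   2 ps, the conventional save interval).
#' @return A \code{fibril_trajectory}.
#' @export
read_multimodel_pdb <- function(path, time_step_ps = 2) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  known <- c("ATOM  ", "HETATM", "MODEL ", "ENDMDL", "TER   ", "TER",
             "END   ", "END", "REMARK", "HEADER", "TITLE ", "CRYST1",
             "MASTER", "CONECT", "SEQRES", "EXPDTA", "AUTHOR", "COMPND")
  unknown <- setdiff(unique(trimws(rec[nzchar(trimws(rec))])), trimws(known))
  if (length(unknown))
    .warnf("skipping unknown PDB record type(s): %s", paste(unknown, collapse = ", "))

  # Pre-scan MODEL blocks so inconsistent atom counts are reported by index.
  model_starts <- grep("^MODEL", lines)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (length(model_starts) > 1) {
    ends <- c(model_starts[-1] - 1L, length(lines))
    counts <- vapply(seq_along(model_starts), function(i)
      sum(is_atom[model_starts[i]:ends[i]]), integer(1))
    bad <- which(counts != counts[1])
    if (length(bad))
      .stopf("inconsistent atom count in MODEL %d (%d atoms, expected %d)",
             bad[1], counts[bad[1]], counts[1])
  }
  if (!any(is_atom)) .stopf("no ATOM/HETATM records in %s", path)

  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  if (any(is.na(at$chain) | at$chain == ""))
    .stopf("missing chain IDs in %s", path)

  element <- at$elesy
  if (is.null(element) || all(is.na(element)) || all(element == ""))
    element <- .element_from_name(at$elety)
  element[is.na(element) | element == ""] <-
    .element_from_name(at$elety[is.na(element) | element == ""])

  atoms <- data.frame(
    serial = seq_len(nrow(at)),
    name = at$elety,
    element = element,
    res_name = at$resid,
    chain_id = at$chain,
    res_id = paste(at$chain, at$resno, at$insert),
    stringsAsFactors = FALSE
  )
  atoms$is_ligand <- !(atoms$chain_id %in% c("A", "B", "C", "D", "E"))
  model <- fibril_model(atoms, matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE))
  model$atoms$res_id <- NULL

  nf <- nrow(pdb$xyz)
  coords <- array(0, dim = c(nrow(model$atoms), 3L, nf))
  for (i in seq_len(nf)) coords[, , i] <- matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE)
  trajectory(model, coords, times = (seq_len(nf) - 1) * time_step_ps,
             label = basename(path))
}

#' Write a trajectory as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame, TER between chains, \code{\%8.3f}
#' coordinate fields, 1-based residue numbering using \code{res_internal} per
#' chain; the continuous \code{res_serial} convention is recorded in REMARK
#' 300 lines.
#'
#' @param traj A \code{fibril_trajectory}.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_multimodel_pdb <- function(traj, path) {
  if (!inherits(traj, "fibril_trajectory")) .stopf("need a fibril_trajectory")
  at <- traj$topology$atoms
  if (any(traj$coords >= 1e4 - 5e-4 | traj$coords <= -1e3 + 5e-4))
    .stopf("coordinates not representable in the %%8.3f PDB field")
  con <- file(path, "w")
  on.exit(close(con))
  chains <- unique(at$chain_id)
  for (ch in chains) {
    idx <- which(at$chain_id == ch)
    writeLines(sprintf("REMARK 300 RES_SERIAL CHAIN %s INTERNAL %d..%d SERIAL %d..%d",
                       ch, min(at$res_internal[idx]), max(at$res_internal[idx]),
                       min(at$res_serial[idx]), max(at$res_serial[idx])), con)
  }
  fmt_name <- function(nm) {
    ifelse(nchar(nm) >= 4, substr(nm, 1, 4), sprintf(" %-3s", nm))
  }
  names4 <- fmt_name(at$name)
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- matrix(traj$coords[, , f], ncol = 3)
    serial <- 0L
    for (ch in chains) {
      idx <- which(at$chain_id == ch)
      serial_block <- serial + seq_along(idx)
      writeLines(sprintf(
        "%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        ifelse(at$is_ligand[idx], "HETATM", "ATOM"),
        serial_block, names4[idx], "", at$res_name[idx], ch,
        at$res_internal[idx], "", xyz[idx, 1], xyz[idx, 2], xyz[idx, 3],
        1, 0, at$element[idx]), con)
      serial <- serial + length(idx)
      writeLines(sprintf("TER   %5d      %3s %1s%4d",
                         serial + 1L, at$res_name[idx[length(idx)]], ch,
                         at$res_internal[idx[length(idx)]]), con)
      serial <- serial + 1L
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
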