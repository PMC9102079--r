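# Superposition, RMSD series, radius of gyration, and hierarchical
# average-linkage clustering of trajectory frames with quality indices.

#' Kabsch least-squares superposition
#'
#' Optimal rotation and translation mapping \code{mobile} onto
#' \code{reference} in the (weighted) least-squares sense, with the
#' reflection corrected so that \code{det(rotation) = +1}.
#'
#' @param mobile,reference Point sets as n x 3 matrices (n >= 3,
#'   non-collinear).
#' @param weights Optional non-negative per-point weights.
#' @return List with \code{rotation} (3 x 3), \code{translation} (length 3)
#'   and \code{rmsd} (Angstrom); the fit is
#'   \code{mobile \%*\% rotation + translation}.
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n < 3 || nrow(reference) != n)
    .stopf("need two matched point sets with at least 3 points")
  w <- if (is.null(weights)) rep(1, n) else weights
  if (length(w) != n || any(w < 0) || sum(w) <= 0) .stopf("invalid weights")
  w <- w / sum(w)
  mc <- colSums(mobile * w)
  rc <- colSums(reference * w)
  M <- sweep(mobile, 2, mc)
  R0 <- sweep(reference, 2, rc)
  sv_m <- svd(M * sqrt(w))$d
  if (sv_m[2] < 1e-9 * max(sv_m[1], 1))
    .stopf("degenerate (collinear) point set")
  H <- crossprod(M * w, R0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- M %*% rot
  rmsd <- sqrt(sum(w * rowSums((fitted - R0)^2)))
  list(rotation = rot, translation = rc - mc %*% rot, rmsd = rmsd)
}

# Apply a superposition of the selection to all atoms of a frame.
.fit_frame <- function(xyz, sel, ref_sel, weights = NULL) {
  sup <- kabsch_superpose(xyz[sel, , drop = FALSE], ref_sel, weights)
  sweep(xyz %*% sup$rotation, 2, as.numeric(sup$translation), "+")
}

#' RMSD time series against a reference frame
#'
#' Each frame is superposed (Kabsch) on the reference over the selection,
#' then the RMSD over that selection is reported. Use
#' \code{ligand = "exclude"} for fibril-only curves and
#' \code{ligand = "include"} for fibril-plus-ligand curves.
#'
#' @param traj A \code{fibril_trajectory}.
#' @param what Atom selection: \code{"backbone"} (default) or
#'   \code{"calpha"}.
#' @param ligand Passed to \code{\link{select_atoms}}.
#' @param reference Reference coordinates for the full topology (defaults to
#'   the first frame).
#' @param fit Superpose before measuring (default TRUE).
#' @return Data frame with columns \code{time} (ps) and \code{rmsd}
#'   (Angstrom).
#' @export
rmsd_series <- function(traj, what = c("backbone", "calpha"),
                        ligand = c("exclude", "include"),
                        reference = NULL, fit = TRUE) {
  what <- match.arg(what)
  ligand <- match.arg(ligand)
  sel <- select_atoms(traj$topology, what, ligand = ligand)
  if (!length(sel)) .stopf("empty selection")
  if (is.null(reference)) reference <- frame_coords(traj, 1)
  if (nrow(reference) != nrow(traj$topology$atoms))
    .stopf("reference does not match the topology")
  ref_sel <- reference[sel, , drop = FALSE]
  rmsd <- vapply(seq_len(n_frames(traj)), function(f) {
    xyz <- traj$coords[sel, , f]
    if (fit) kabsch_superpose(xyz, ref_sel)$rmsd
    else sqrt(mean(rowSums((xyz - ref_sel)^2)))
  }, numeric(1))
  data.frame(time = traj$times, rmsd = rmsd)
}

#' Mass-weighted radius of gyration
#'
#' \eqn{R_g = \sqrt{\sum_i m_i |r_i - r_{com}|^2 / \sum_i m_i}} with
#' \eqn{r_{com}} the mass-weighted centroid of the selection.
#'
#' @param model A \code{fibril_model} providing masses.
#' @param coords Frame coordinates (default: reference coordinates).
#' @param selection Integer atom indices (default: all fibril atoms,
#'   matching the convention of reporting fibril compactness without the
#'   ligand).
#' @return Radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(model, coords = model$coords,
                               selection = NULL) {
  if (is.null(selection)) selection <- select_atoms(model, "all", ligand = "exclude")
  if (!length(selection)) .stopf("empty selection")
  m <- model$atoms$mass[selection]
  x <- coords[selection, , drop = FALSE]
  com <- colSums(x * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(x, 2, com)^2)) / sum(m))
}

#' Radius-of-gyration time series
#'
#' @inheritParams radius_of_gyration
#' @param traj A \code{fibril_trajectory}.
#' @return Data frame with columns \code{time} and \code{rg}.
#' @export
rg_series <- function(traj, selection = NULL) {
  if (is.null(selection))
    selection <- select_atoms(traj$topology, "all", ligand = "exclude")
  rg <- vapply(seq_len(n_frames(traj)), function(f)
    radius_of_gyration(traj$topology, traj$coords[, , f], selection), numeric(1))
  data.frame(time = traj$times, rg = rg)
}

#' Hierarchical average-linkage clustering of frames by C-alpha RMSD
#'
#' Frames are first superposed on a common reference (the first frame by
#' default) over the C-alpha selection; agglomerative merging with average
#' linkage then proceeds on the pairwise RMSD matrix and stops when the
#' minimum inter-cluster average distance exceeds \code{epsilon}.
#'
#' @param traj A \code{fibril_trajectory}, or a numeric matrix with one row
#'   per frame of flattened, pre-fitted C-alpha coordinates.
#' @param epsilon Merge cutoff in Angstrom (the "minimum distance between
#'   clusters" scheme; default 4.5).
#' @param stride Use every \code{stride}-th frame.
#' @param reference Optional full-topology reference coordinates for the
#'   pre-fit (e.g. the first frame of replica 1 when clustering combined
#'   replicas).
#' @return List of class \code{clustering_result}: \code{labels} (frame to
#'   cluster id), \code{n_clusters}, \code{linkage_epsilon}, \code{metrics}
#'   (DBI, pSF, SSR/SST at the cut), \code{metrics_neighbors} (same indices
#'   one merge earlier/later), \code{hclust} and the frame matrix used.
#' @export
average_linkage_cluster <- function(traj, epsilon = 4.5, stride = 1L,
                                    reference = NULL) {
  if (inherits(traj, "fibril_trajectory")) {
    sel <- select_atoms(traj$topology, "calpha", ligand = "exclude")
    if (!length(sel)) .stopf("no C-alpha atoms in topology")
    frames <- seq(1L, n_frames(traj), by = stride)
    if (is.null(reference)) reference <- frame_coords(traj, 1)
    ref_sel <- reference[sel, , drop = FALSE]
    X <- t(vapply(frames, function(f) {
      xyz <- traj$coords[sel, , f]
      sup <- kabsch_superpose(xyz, ref_sel)
      as.numeric(sweep(xyz %*% sup$rotation, 2, as.numeric(sup$translation), "+"))
    }, numeric(3 * length(sel))))
    m <- length(sel)
  } else {
    X <- as.matrix(traj)
    m <- ncol(X) / 3
    frames <- seq_len(nrow(X))
  }
  n <- nrow(X)
  if (n < 2) .stopf("need at least 2 frames to cluster")
  # Euclidean distance over flattened coordinates divided by sqrt(n_atoms)
  # equals the (pre-fitted) pairwise RMSD.
  d <- stats::dist(X) / sqrt(m)
  hc <- stats::hclust(d, method = "average")
  labels <- stats::cutree(hc, h = epsilon)
  k <- max(labels)
  Xr <- X / sqrt(m)   # metric space in which distances are RMSDs
  metrics <- clustering_metrics(labels, Xr)
  neigh <- list()
  for (kk in c(k - 1L, k + 1L)) {
    if (kk >= 1 && kk <= n) {
      lab <- stats::cutree(hc, k = kk)
      neigh[[as.character(kk)]] <- clustering_metrics(lab, Xr)
    }
  }
  structure(list(labels = labels, frames = frames, n_clusters = k,
                 linkage_epsilon = epsilon, metrics = metrics,
                 metrics_neighbors = neigh, hclust = hc, X = Xr),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("clustering_result: %d frames -> %d cluster(s) at epsilon = %g A\n",
              length(x$labels), x$n_clusters, x$linkage_epsilon))
  cat(sprintf("  DBI = %s, pSF = %s, SSR/SST = %.4f\n",
              format(x$metrics["DBI"]), format(x$metrics["pSF"]),
              x$metrics["SSR_SST"]))
  invisible(x)
}

#' Cluster-quality indices
#'
#' Davies-Bouldin index (lower is better), pseudo-F statistic (higher is
#' better) and the explained-variance ratio SSR/SST (equivalent to the
#' determination coefficient R^2). For a single cluster DBI and pSF are
#' undefined (NA) and SSR/SST is 0.
#'
#' @param labels Integer cluster labels, one per observation.
#' @param X Observation matrix (rows = observations) in the metric space of
#'   interest; for frame clustering, flattened coordinates divided by
#'   sqrt(n_atoms) so Euclidean distance equals RMSD.
#' @return Named vector \code{c(DBI, pSF, SSR_SST)}.
#' @export
clustering_metrics <- function(labels, X) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(labels) != n) .stopf("labels do not match observations")
  ids <- sort(unique(labels))
  k <- length(ids)
  grand <- colMeans(X)
  sst <- sum(sweep(X, 2, grand)^2)
  centroids <- matrix(0, k, ncol(X))
  s <- numeric(k)   # mean member-centroid distance
  ssw <- 0
  for (i in seq_len(k)) {
    rows <- which(labels == ids[i])
    centroids[i, ] <- colMeans(X[rows, , drop = FALSE])
    dev <- sweep(X[rows, , drop = FALSE], 2, centroids[i, ])
    ssw <- ssw + sum(dev^2)
    s[i] <- mean(sqrt(rowSums(dev^2)))
  }
  ssb <- sst - ssw
  ssr_sst <- if (sst > 0) ssb / sst else 0
  if (k == 1) return(c(DBI = NA_real_, pSF = NA_real_, SSR_SST = ssr_sst))
  dc <- as.matrix(stats::dist(centroids))
  ratios <- vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) (s[i] + s[j]) / dc[i, j],
               numeric(1)))
  }, numeric(1))
  dbi <- mean(ratios)
  psf <- if (n > k) (ssb / (k - 1)) / (ssw / (n - k)) else NA_real_
  c(DBI = dbi, pSF = psf, SSR_SST = ssr_sst)
}
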