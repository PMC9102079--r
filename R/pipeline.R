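# End-to-end orchestration: run synthetic (or file-based) systems through
# the full analysis battery and emit the report tables, plus the
# chain-dissociation event detector.

#' Analysis configuration
#'
#' Collects every threshold and run setting used by
#' \code{\link{run_pipeline}} with the package defaults: hydrogen bonds
#' 3.2 Angstrom / 120 degrees, stacking 5.5, salt bridges 4.5, contacts 4.5,
#' cluster epsilon 4.5, occupancy tiers 30/50/70\%, 2 ps per frame.
#'
#' @param scenarios List of scenario specs; each is a list with \code{name},
#'   \code{kind} (stable/perturbed/dissociation), optional \code{ligand}
#'   and \code{ligand_site}, \code{n_frames}, and any
#'   \code{\link{scenario}} field. Alternatively a spec may carry
#'   \code{path} to a multi-model PDB plus \code{replica_id}.
#' @param n_replicas Replicas per scenario (seeds are derived per replica).
#' @param dt Frame spacing, ps.
#' @param stride Analysis stride for occupancy/secondary structure.
#' @param cluster_stride Extra stride for clustering.
#' @param hbond_d,hbond_angle,stacking_d,saltbridge_d,contact_d,cluster_epsilon
#'   Detector thresholds.
#' @param outdir Output directory for the report bundle.
#' @param seed Global seed; scenario replica seeds derive from it.
#' @param dissociation_span_ns,dissociation_floor Event detector knobs
#'   (see \code{\link{detect_dissociation}}).
#' @return A list of class \code{analysis_config}.
#' @export
analysis_config <- function(scenarios = list(), n_replicas = 1L, dt = 2,
                            stride = 1L, cluster_stride = 5L,
                            hbond_d = 3.2, hbond_angle = 120,
                            stacking_d = 5.5, saltbridge_d = 4.5,
                            contact_d = 4.5, cluster_epsilon = 4.5,
                            outdir = "fibrilbreak_report", seed = 1L,
                            dissociation_span_ns = 0.2,
                            dissociation_floor = 8) {
  if (any(c(hbond_d, hbond_angle, stacking_d, saltbridge_d, contact_d,
            cluster_epsilon) <= 0))
    .stopf("all thresholds must be positive")
  structure(mget(names(formals(analysis_config))), class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Keys mirror the arguments of \code{\link{analysis_config}}.
#'
#' @param path YAML file path.
#' @return An \code{analysis_config}.
#' @export
read_analysis_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(analysis_config, vals)
}

#' Detect a chain dissociation event
#'
#' An event is declared when, from some frame onward, the chain has zero
#' inter-chain heavy-atom contacts with the remaining fibril chains
#' (cutoff \code{contact_d}) and its minimum inter-atomic distance to them
#' is at least \code{distance_floor}, continuously for at least
#' \code{contact_free_span} ns. The onset is the first frame of the
#' qualifying span; the event is persistent when the span extends to the
#' trajectory end.
#'
#' @param traj A \code{fibril_trajectory}.
#' @param chain Chain id to test.
#' @param contact_free_span Minimum contact-free duration, ns.
#' @param distance_floor Minimum separation, Angstrom.
#' @param contact_d Contact cutoff, Angstrom.
#' @param stride Evaluate every \code{stride}-th frame.
#' @return \code{NULL}, or a list of class \code{dissociation_event} with
#'   \code{chain}, \code{onset} (ps), \code{persistent} and an
#'   \code{evidence} data frame (contact count, minimum distance and fibril
#'   radius of gyration per analysed frame).
#' @export
detect_dissociation <- function(traj, chain, contact_free_span = 5,
                                distance_floor = 8, contact_d = 4.5,
                                stride = 1L) {
  top <- traj$topology
  at <- top$atoms
  if (!chain %in% at$chain_id[!at$is_ligand]) .stopf("chain %s not in topology", chain)
  heavy <- at$element != "H"
  g1 <- which(at$chain_id == chain & !at$is_ligand & heavy)
  g2 <- which(at$chain_id != chain & !at$is_ligand & heavy)
  fib <- select_atoms(top, "all", ligand = "exclude")
  frames <- seq(1L, n_frames(traj), by = stride)
  cc <- integer(length(frames))
  mind <- rg <- numeric(length(frames))
  for (fx in seq_along(frames)) {
    xyz <- traj$coords[, , frames[fx]]
    d <- .cross_dist(xyz[g1, , drop = FALSE], xyz[g2, , drop = FALSE])
    cc[fx] <- sum(d <= contact_d)
    mind[fx] <- min(d)
    rg[fx] <- radius_of_gyration(top, xyz, fib)
  }
  times <- traj$times[frames]
  evidence <- data.frame(time = times, contacts = cc, min_distance = mind,
                         rg = rg)
  free <- cc == 0L & mind >= distance_floor
  runs <- rle(free)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  span_ps <- contact_free_span * 1000
  for (r in which(runs$values)) {
    if (times[ends[r]] - times[starts[r]] >= span_ps) {
      return(structure(list(chain = chain, onset = times[starts[r]],
                            persistent = ends[r] == length(frames),
                            evidence = evidence),
                       class = "dissociation_event"))
    }
  }
  NULL
}

#' @export
print.dissociation_event <- function(x, ...) {
  cat(sprintf("dissociation_event: chain %s, onset %g ps, %s\n", x$chain,
              x$onset, if (x$persistent) "persistent" else "transient"))
  invisible(x)
}

# Concatenate replica trajectories into one (times shifted to stay strictly
# increasing); used for the combined-replica analyses.
.combine_replicas <- function(trajs) {
  coords <- do.call(function(...) {
    arrs <- list(...)
    array(unlist(arrs), dim = c(dim(arrs[[1]])[1:2],
                                sum(vapply(arrs, function(a) dim(a)[3], numeric(1)))))
  }, lapply(trajs, `[[`, "coords"))
  times <- numeric(0)
  off <- 0
  for (tr in trajs) {
    times <- c(times, tr$times + off)
    off <- max(times) + (tr$times[2] - tr$times[1])
  }
  trajectory(trajs[[1]]$topology, coords, times = times,
             label = paste0(trajs[[1]]$label, "+combined"))
}

.write_tsv <- function(df, path, digits = NULL) {
  if (!is.null(digits)) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) round(x, digits))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' For every configured system: simulate (or load) the replicas, then
#' produce cluster counts, the MM-GBSA energy summary (ligand-bound systems),
#' the radius-of-gyration summary with all/dissociated/non-dissociated
#' splits, secondary-structure occupancies with the beta-sheet sum, global
#' salt-bridge occurrence, hydrogen-bond and salt-bridge occupancy tables
#' with a per-chain-pair tier map, stacking occupancies separated by ring
#' position, per-replica RMSD series, and detected dissociation events.
#' Everything is written as TSV into the output directory together with a
#' manifest recording every threshold, seed and output checksum. A stage
#' failure aborts the run, naming the stage and removing partial outputs.
#'
#' @param config An \code{\link{analysis_config}} (or path to a YAML file).
#' @return Invisibly, a list of per-system results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_analysis_config(config)
  cfg <- config
  if (!length(cfg$scenarios)) .stopf("no systems configured")
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(df, name, digits = NULL) {
    p <- .write_tsv(df, file.path(cfg$outdir, name), digits)
    written <<- c(written, p)
    p
  }
  fail <- function(stage, err) {
    unlink(written)
    .stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(err))
  }
  results <- list()

  for (si in seq_along(cfg$scenarios)) {
    spec <- cfg$scenarios[[si]]
    name <- spec$name %||% paste0("system", si)

    trajs <- tryCatch({
      if (!is.null(spec$path)) {
        list(read_multimodel_pdb(spec$path, time_step_ps = cfg$dt))
      } else {
        model <- build_pentamer(fibril_blueprint(),
                                ligand = spec$ligand,
                                ligand_site = spec$ligand_site %||% "core")
        lapply(seq_len(cfg$n_replicas), function(rep) {
          sc <- scenario(kind = spec$kind %||% "stable",
                         noise_sigma = spec$noise_sigma,
                         target_occupancy = spec$target_occupancy %||% 0.5,
                         chains = spec$chains,
                         t_start = spec$t_start,
                         drift_velocity = spec$drift_velocity %||% 0.05,
                         seed = cfg$seed + 1000L * si + rep)
          simulate_trajectory(model, sc, n_frames = spec$n_frames %||% 100L,
                              dt = cfg$dt, replica_id = rep)
        })
      }
    }, error = function(e) fail(paste0(name, "/input"), e))
    combined <- if (length(trajs) > 1) .combine_replicas(trajs) else trajs[[1]]
    top <- combined$topology
    res <- list(name = name, trajectories = trajs)

    # --- dissociation events (per replica, every fibril chain) -------------
    res$events <- tryCatch({
      ev <- list()
      for (rep in seq_along(trajs)) {
        for (ch in unique(top$atoms$chain_id[!top$atoms$is_ligand])) {
          e <- detect_dissociation(trajs[[rep]], ch,
                                   contact_free_span = cfg$dissociation_span_ns,
                                   distance_floor = cfg$dissociation_floor,
                                   contact_d = cfg$contact_d,
                                   stride = cfg$stride)
          if (!is.null(e)) ev[[length(ev) + 1L]] <-
              data.frame(replica = rep, chain = e$chain, onset_ps = e$onset,
                         persistent = e$persistent)
        }
      }
      if (length(ev)) do.call(rbind, ev) else
        data.frame(replica = integer(0), chain = character(0),
                   onset_ps = numeric(0), persistent = logical(0))
    }, error = function(e) fail(paste0(name, "/dissociation"), e))
    emit(res$events, sprintf("%s_dissociation.tsv", name))
    ds_reps <- unique(res$events$replica)

    # --- clustering --------------------------------------------------------
    res$clustering <- tryCatch(
      average_linkage_cluster(combined, epsilon = cfg$cluster_epsilon,
                              stride = cfg$cluster_stride,
                              reference = frame_coords(trajs[[1]], 1)),
      error = function(e) fail(paste0(name, "/clustering"), e))
    emit(data.frame(frame = res$clustering$frames,
                    cluster = res$clustering$labels),
         sprintf("%s_clusters.tsv", name))

    # --- radius of gyration ------------------------------------------------
    res$rg <- tryCatch({
      per_rep <- lapply(trajs, rg_series)
      all_rg <- unlist(lapply(per_rep, `[[`, "rg"))
      ds_rg <- unlist(lapply(ds_reps, function(r) per_rep[[r]]$rg))
      nds_rg <- unlist(lapply(setdiff(seq_along(trajs), ds_reps),
                              function(r) per_rep[[r]]$rg))
      data.frame(subset = c("all", "ds", "nds"),
                 mean_rg = c(mean(all_rg),
                             if (length(ds_rg)) mean(ds_rg) else NA,
                             if (length(nds_rg)) mean(nds_rg) else NA))
    }, error = function(e) fail(paste0(name, "/rg"), e))
    emit(res$rg, sprintf("%s_rg.tsv", name), digits = 1)

    # --- secondary structure -----------------------------------------------
    res$ss <- tryCatch(ss_occupancy(combined, stride = cfg$stride),
                       error = function(e) fail(paste0(name, "/ss"), e))
    emit(data.frame(category = names(res$ss), percent = as.numeric(res$ss)),
         sprintf("%s_ss.tsv", name), digits = 1)

    # --- hydrogen bonds ----------------------------------------------------
    res$hbonds <- tryCatch(
      occupancy(combined, "hbond", d_max = cfg$hbond_d,
                angle_min = cfg$hbond_angle, pairing = "interchain",
                stride = cfg$stride),
      error = function(e) fail(paste0(name, "/hbonds"), e))
    emit(as.data.frame(res$hbonds), sprintf("%s_hbonds.tsv", name))
    map <- as.data.frame(table(chain_pair = res$hbonds$chain_pair,
                               tier = res$hbonds$tier))
    emit(map, sprintf("%s_hbond_map.tsv", name))

    # --- salt bridges ------------------------------------------------------
    res$saltbridges <- tryCatch(
      occupancy(combined, "salt_bridge", d_max = cfg$saltbridge_d,
                stride = cfg$stride),
      error = function(e) fail(paste0(name, "/saltbridges"), e))
    emit(as.data.frame(res$saltbridges), sprintf("%s_saltbridges.tsv", name))
    res$sb_global <- global_salt_bridge_occurrence(combined,
                                                   d_max = cfg$saltbridge_d,
                                                   stride = cfg$stride)
    emit(data.frame(subset = names(res$sb_global),
                    percent = as.numeric(res$sb_global)),
         sprintf("%s_saltbridge_global.tsv", name), digits = 1)

    # --- stacking ----------------------------------------------------------
    res$stacking <- tryCatch(
      occupancy(combined, "stacking", d_max = cfg$stacking_d,
                stride = cfg$stride),
      error = function(e) fail(paste0(name, "/stacking"), e))
    emit(as.data.frame(res$stacking), sprintf("%s_stacking.tsv", name))

    # --- RMSD series -------------------------------------------------------
    res$rmsd <- tryCatch(lapply(seq_along(trajs), function(rep) {
      fib <- rmsd_series(trajs[[rep]], "backbone", ligand = "exclude")
      out <- data.frame(time = fib$time, rmsd_fibril = fib$rmsd)
      if (any(top$atoms$is_ligand)) {
        out$rmsd_with_ligand <-
          rmsd_series(trajs[[rep]], "backbone", ligand = "include")$rmsd
      }
      emit(out, sprintf("%s_rmsd_rep%d.tsv", name, rep))
      out
    }), error = function(e) fail(paste0(name, "/rmsd"), e))

    # --- energetics (ligand-bound systems) ---------------------------------
    if (any(top$atoms$is_ligand)) {
      res$energy <- tryCatch(
        mmgbsa(combined, stride = max(cfg$stride, 5L)),
        error = function(e) fail(paste0(name, "/energy"), e))
      emit(res$energy$summary, sprintf("%s_energy.tsv", name), digits = 1)
    }
    results[[name]] <- res
  }

  manifest <- c(
    sprintf("fibrilbreak run manifest"),
    sprintf("seed: %d", cfg$seed),
    sprintf("thresholds: hbond_d=%g hbond_angle=%g stacking_d=%g saltbridge_d=%g contact_d=%g cluster_epsilon=%g",
            cfg$hbond_d, cfg$hbond_angle, cfg$stacking_d, cfg$saltbridge_d,
            cfg$contact_d, cfg$cluster_epsilon),
    sprintf("stride: %d  cluster_stride: %d  dt: %g ps  replicas: %d",
            cfg$stride, cfg$cluster_stride, cfg$dt, cfg$n_replicas),
    sprintf("dissociation: span=%g ns floor=%g A", cfg$dissociation_span_ns,
            cfg$dissociation_floor),
    "outputs:",
    sprintf("  %s  %s", tools::md5sum(written), basename(written)))
  writeLines(manifest, file.path(cfg$outdir, "run_manifest.txt"))
  invisible(results)
}
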