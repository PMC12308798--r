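## Config-driven orchestration: run the full analysis battery on synthetic
## or file-based systems and write diff-able TSV tables with a JSON
## metadata sidecar.

#' Build an analysis configuration
#'
#' Hyperparameters default to the reference protocol: 15 Angstrom
#' fingerprint cutoff on a 201 x 101 grid, t-SNE perplexity 100 and early
#' exaggeration 4, HDBSCAN minimum cluster size 50, hydrogen-bond criterion
#' 3.5 Angstrom / 30 degrees, five analysis blocks.
#'
#' @param systems named list of system entries; each entry is either a
#'   [synthetic_system_spec()] or a list with `topology_path`,
#'   `trajectory_path` and `lipid_spec`.
#' @param window optional `c(start, end)` ps analysis window.
#' @param n_blocks block count for block-averaged errors (default 5).
#' @param g3_cutoff,g3_bins fingerprint grid (defaults 15, `c(201, 101)`).
#' @param perplexity,early_exaggeration,min_cluster_size embedding/cluster
#'   hyperparameters (defaults 100, 4, 50).
#' @param hbond_dcut,hbond_angle hydrogen-bond criterion (3.5, 30).
#' @param out_dir output directory.
#' @param seed master seed; per-stage seeds are fanned out deterministically.
#' @param run_motifs run the (expensive) conformational-motif stage
#'   (default `TRUE`).
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(systems, window = NULL, n_blocks = 5,
                            g3_cutoff = 15, g3_bins = c(201L, 101L),
                            perplexity = 100, early_exaggeration = 4,
                            min_cluster_size = 50, hbond_dcut = 3.5,
                            hbond_angle = 30, out_dir = tempfile("lamellr_"),
                            seed = 1L, run_motifs = TRUE) {
  stopifnot(is.list(systems), length(systems) >= 1, !is.null(names(systems)))
  for (nm in names(systems)) {
    s <- systems[[nm]]
    if (!inherits(s, "synthetic_system_spec")) {
      if (is.null(s$topology_path)) {
        stop("config error: system '", nm,
             "' has neither a synthetic spec nor a topology_path",
             call. = FALSE)
      }
      if (!file.exists(s$topology_path)) {
        stop("config error: missing topology file for system '", nm, "': ",
             s$topology_path, call. = FALSE)
      }
      if (!is.null(s$trajectory_path) && !file.exists(s$trajectory_path)) {
        stop("config error: missing trajectory file for system '", nm, "': ",
             s$trajectory_path, call. = FALSE)
      }
    }
  }
  structure(list(systems = systems, window = window, n_blocks = n_blocks,
                 g3_cutoff = g3_cutoff, g3_bins = g3_bins,
                 perplexity = perplexity,
                 early_exaggeration = early_exaggeration,
                 min_cluster_size = min_cluster_size,
                 hbond_dcut = hbond_dcut, hbond_angle = hbond_angle,
                 out_dir = out_dir, seed = as.integer(seed),
                 run_motifs = run_motifs),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Top-level keys mirror the arguments of [analysis_config()]; each entry of
#' `systems` either names file paths or carries a `synthetic:` block whose
#' keys are passed to [synthetic_system_spec()].
#'
#' @param path YAML file.
#' @return an `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  systems <- lapply(cfg$systems, function(s) {
    if (!is.null(s$synthetic)) {
      do.call(synthetic_system_spec, s$synthetic)
    } else s
  })
  names(systems) <- names(cfg$systems)
  args <- cfg[setdiff(names(cfg), "systems")]
  do.call(analysis_config, c(list(systems = systems), args))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes, per system: membrane geometry (APL by box and Voronoi, electron
#' density profile, thickness), chain order (order-parameter profile, tilt,
#' splay, tail rotational ACF, tail-tail RDF), the conformational-motif
#' stage (fingerprints, similarity matrix, embedding + clustering,
#' characterisation), and interface analysis (hydrogen-bond statistics,
#' hydrogen-bond ACF, glycerol ACF with double-exponential fit). Every
#' stochastic step is seeded from the master seed; outputs are TSV tables
#' plus a `run_metadata.json` sidecar. A stage failure aborts with the stage
#' name; outputs written so far are preserved.
#'
#' @param config an [analysis_config()].
#' @return (invisibly) a named list of per-system result summaries.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  meta <- list(package_version = as.character(utils::packageVersion("lamellr")),
               seed = config$seed,
               parameters = config[setdiff(names(config), c("systems"))],
               started = format(t0), systems = list())
  results <- list()
  for (nm in names(config$systems)) {
    stage <- "load"
    res <- tryCatch({
      entry <- config$systems[[nm]]
      gt <- NULL
      if (inherits(entry, "synthetic_system_spec")) {
        entry$seed <- stage_seed(config$seed, "generator") + match(nm, names(config$systems))
        sm <- generate_membrane_trajectory(entry)
        traj <- sm$traj; gt <- sm
        n_per_leaflet <- entry$n_per_leaflet
        n_leaflets <- if (entry$arrangement == "single_bilayer") 2L else 4L
      } else {
        traj <- load_trajectory(entry$topology_path, entry$trajectory_path,
                                entry$lipid_spec)
        n_per_leaflet <- entry$n_per_leaflet %||%
          (traj$n_lipids %/% (entry$n_leaflets %||% 2L))
        n_leaflets <- entry$n_leaflets %||% 2L
      }
      if (!is.null(config$window)) {
        traj <- select_window(traj, config$window[1], config$window[2])
      }
      sysdir <- file.path(config$out_dir, nm)
      dir.create(sysdir, showWarnings = FALSE)

      stage <- "geometry"
      leaf <- assign_leaflets(traj, n_leaflets)
      axy <- apl_xy(traj, n_per_leaflet)
      avor <- apl_voronoi(traj, leaf)
      prof <- density_profile(traj, weighting = "electron",
                              n_blocks = config$n_blocks)
      th <- thickness_from_profile(prof, "overall")
      write_tsv(data.frame(metric = c("apl_xy", "apl_vor_mean",
                                      "apl_vor_median", "apl_vor_mode",
                                      "membrane_thickness"),
                           value = c(axy$mean, avor$mean, avor$median,
                                     avor$mode, th$thickness),
                           sd = c(axy$sd, stats::sd(avor$areas), NA, NA,
                                  th$sd)),
                file.path(sysdir, "geometry.tsv"))
      write_tsv(prof, file.path(sysdir, "density_profile.tsv"))

      stage <- "chain_order"
      scd <- scd_profile(traj, n_blocks = config$n_blocks)
      tilt <- tilt_distribution(traj, leaf)
      sp1 <- splay_distribution(traj, c("C9", "C5", "C22"))
      sp2 <- splay_distribution(traj, c("C20", "C5", "C35"))
      tacf <- vector_acf(traj, c("C7", "C20"))
      rdf <- rdf_2d(traj, leaf, paste0("C", 7:35),
                    r_max = min(traj$box[, 1:2]) / 2 * 0.95)
      write_tsv(scd, file.path(sysdir, "scd_profile.tsv"))
      write_tsv(data.frame(vector = rep(names(tilt),
                                        each = nrow(tilt[[1]])),
                           do.call(rbind, tilt)),
                file.path(sysdir, "tilt.tsv"))
      write_tsv(cbind(splay = 1, sp1), file.path(sysdir, "splay1.tsv"))
      write_tsv(cbind(splay = 2, sp2), file.path(sysdir, "splay2.tsv"))
      write_tsv(tacf, file.path(sysdir, "tail_acf.tsv"))
      write_tsv(rdf, file.path(sysdir, "tail_rdf.tsv"))

      motifs <- NULL
      if (config$run_motifs) {
        stage <- "conformation_ml"
        h <- compute_g3_all(traj, cutoff = config$g3_cutoff,
                            bins = config$g3_bins)
        sim <- build_similarity_matrix(h)
        cl <- embed_and_cluster(sim, perplexity = config$perplexity,
                                early_exaggeration = config$early_exaggeration,
                                min_cluster_size = config$min_cluster_size,
                                seed = stage_seed(config$seed, "embedding"))
        motifs <- characterize_clusters(cl, h)
        write_tsv(data.frame(lipid = seq_along(cl$labels),
                             tsne1 = cl$embedding[, 1],
                             tsne2 = cl$embedding[, 2],
                             pca1 = cl$pca_embedding[, 1],
                             pca2 = cl$pca_embedding[, 2],
                             cluster = cl$labels,
                             planted_motif = if (!is.null(gt)) gt$motif else NA),
                  file.path(sysdir, "motif_embedding.tsv"))
        write_tsv(motifs$scores, file.path(sysdir, "motif_scores.tsv"))
        write_tsv(motifs$fractions, file.path(sysdir, "motif_fractions.tsv"))
      }

      stage <- "interface"
      hb <- hbond_statistics(traj, d_cut = config$hbond_dcut,
                             angle_cut = config$hbond_angle)
      write_tsv(data.frame(class = c("inter", "intra"),
                           mean = c(hb$inter$mean, hb$intra$mean),
                           sd = c(hb$inter$sd, hb$intra$sd)),
                file.path(sysdir, "hbond_per_molecule.tsv"))
      write_tsv(hb$water_by_group, file.path(sysdir, "hbond_water_groups.tsv"))
      gacf <- glycerol_acf(traj)
      write_tsv(gacf, file.path(sysdir, "glycerol_acf.tsv"))
      gfit <- tryCatch(fit_double_exponential(gacf), error = function(e) NULL)
      if (!is.null(gfit)) {
        write_tsv(data.frame(tau1 = gfit$tau1, a1 = gfit$a1,
                             tau2 = gfit$tau2, a2 = gfit$a2, b = gfit$b,
                             degenerate = gfit$degenerate),
                  file.path(sysdir, "glycerol_fit.tsv"))
      }
      list(apl = axy, apl_vor = avor, thickness = th, scd = scd,
           tilt = tilt, motifs = motifs, hbonds = hb, glycerol_fit = gfit,
           leaflets = leaf, ground_truth = gt)
    }, error = function(e) {
      stop("pipeline aborted in stage '", stage, "' for system '", nm,
           "': ", conditionMessage(e), call. = FALSE)
    })
    results[[nm]] <- res
    meta$systems[[nm]] <- list(status = "ok")
  }
  meta$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(meta, file.path(config$out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(results)
}

#' Write a named synthetic fixture to disk
#'
#' Known fixtures: `motif4` (single bilayer, 1000 lipids, 250 per motif,
#' frame-averaged fingerprint window), `bilayer_small` (2 x 100 lipids,
#' 100 frames) and `interdigitated_small` (4-leaflet interleaved system).
#' Writes a GRO coordinate file, a multi-frame GRO trajectory and a
#' ground-truth TSV (lipid id, motif, leaflet).
#'
#' @param spec_name fixture name.
#' @param dir output directory (created if needed).
#' @param seed master seed.
#' @return (invisibly) list with the `synthetic_membrane` and file paths.
#' @export
generate_fixtures <- function(spec_name = c("motif4", "bilayer_small",
                                            "interdigitated_small"),
                              dir = tempfile("fixtures_"), seed = 1L) {
  if (!spec_name[1] %in% c("motif4", "bilayer_small", "interdigitated_small")) {
    stop("unknown fixture '", spec_name[1],
         "'; known: motif4, bilayer_small, interdigitated_small",
         call. = FALSE)
  }
  spec_name <- match.arg(spec_name)
  spec <- switch(spec_name,
    motif4 = synthetic_system_spec(n_per_leaflet = 500, n_frames = 12,
                                   frame_dt = 100, seed = seed),
    bilayer_small = synthetic_system_spec(n_per_leaflet = 100, n_frames = 100,
                                          frame_dt = 100, seed = seed,
                                          tail_resample = FALSE),
    interdigitated_small = synthetic_system_spec(
      arrangement = "interdigitated", n_per_leaflet = 50, apl_target = 72.0,
      n_frames = 11, frame_dt = 100, seed = seed))
  sm <- generate_membrane_trajectory(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  topo_path <- file.path(dir, paste0(spec_name, ".gro"))
  traj_path <- file.path(dir, paste0(spec_name, "_traj.gro"))
  gt_path <- file.path(dir, paste0(spec_name, "_truth.tsv"))
  write_gro(sm$traj, topo_path, frames = 1L)
  write_gro(sm$traj, traj_path)
  write_tsv(data.frame(lipid = seq_len(sm$traj$n_lipids), motif = sm$motif,
                       leaflet = sm$leaflet), gt_path)
  invisible(list(membrane = sm, topology = topo_path, trajectory = traj_path,
                 truth = gt_path))
}
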