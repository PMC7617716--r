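#' Build a run manifest for the fixtures -> complexes -> reports pipeline
#'
#' Declares the study layout: which GQ topologies, how many peptide
#' conformers (cluster representatives), which planted pose mode and
#' trajectory treatment each complex receives, plus seeds and all
#' thresholds. Job count is `length(gq_specs) * n_conformers`.
#'
#' @param gq_specs named list of [gq_spec()]s.
#' @param sequence peptide one-letter sequence.
#' @param n_conformers number of conformer representatives docked per GQ.
#' @param n_raw_conformers size of the raw ensemble clustered down to
#'   `n_conformers`; `NULL` skips the clustering stage and uses raw
#'   conformers directly.
#' @param pose_modes planted pose mode per job, recycled over jobs.
#' @param unstable_jobs integer indices of jobs simulated with progressive
#'   strand displacement (planted unstable complexes); all other jobs get
#'   thermal noise only.
#' @param n_frames frames per pseudo-trajectory.
#' @param noise_sigma positional noise, Angstrom.
#' @param displacement strand displacement per frame for unstable jobs,
#'   Angstrom.
#' @param seed master seed; all per-stage seeds derive from it.
#' @param config threshold configuration, see [default_config()].
#' @return a `RunManifest` list.
#' @export
run_manifest <- function(gq_specs, sequence = rgg_like_sequence(),
                         n_conformers = 4, n_raw_conformers = NULL,
                         pose_modes = c("end_stack", "groove", "loop"),
                         unstable_jobs = integer(0),
                         n_frames = 10, noise_sigma = 0.08,
                         displacement = 1.5,
                         seed = 1, config = default_config()) {
  stopifnot(length(gq_specs) >= 1, n_conformers >= 1, n_frames >= 2)
  if (is.null(names(gq_specs))) {
    names(gq_specs) <- paste0("gq", seq_along(gq_specs))
  }
  stopifnot(all(vapply(gq_specs, inherits, logical(1), "GQSpec")))
  m <- structure(list(
    gq_specs = gq_specs, sequence = sequence,
    n_conformers = as.integer(n_conformers),
    n_raw_conformers = n_raw_conformers,
    pose_modes = pose_modes, unstable_jobs = as.integer(unstable_jobs),
    n_frames = as.integer(n_frames), noise_sigma = noise_sigma,
    displacement = displacement, seed = as.integer(seed),
    config = config), class = "RunManifest")
  m$hash <- manifest_hash(m)
  m
}

#' Stable content hash of a manifest
#'
#' Serialized to a temporary file and hashed with MD5; carried on every
#' pipeline output so tables can be traced to the run that produced them.
#'
#' @param manifest a `RunManifest`.
#' @return 32-character hex string.
#' @export
manifest_hash <- function(manifest) {
  m <- unclass(manifest)
  m$hash <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  # text serialization for a stable digest
  dput(m, file = tmp, control = c("keepNA", "keepInteger", "showAttributes",
                                  "digits17"))
  unname(tools::md5sum(tmp))
}

#' Enumerate the complex jobs of a manifest
#'
#' Cartesian product of GQ systems and conformer indices in stable,
#' GQ-major order, with the planted pose mode and trajectory treatment each
#' job receives.
#'
#' @param manifest a `RunManifest`.
#' @return data.frame with columns `job`, `gq_id`, `conformer`, `pose_mode`,
#'   `unstable`, `seed`.
#' @examples
#' specs <- list(dna = gq_spec(), rna = gq_spec(nucleic_kind = "RNA"))
#' nrow(enumerate_complexes(run_manifest(specs, n_conformers = 3)))  # 6
#' @export
enumerate_complexes <- function(manifest) {
  stopifnot(inherits(manifest, "RunManifest"))
  if (!length(manifest$gq_specs)) stop("no GQ systems in manifest")
  if (manifest$n_conformers < 1) stop("no conformers in manifest")
  jobs <- expand.grid(conformer = seq_len(manifest$n_conformers),
                      gq_id = names(manifest$gq_specs),
                      stringsAsFactors = FALSE)[, c("gq_id", "conformer")]
  jobs <- jobs[order(match(jobs$gq_id, names(manifest$gq_specs)),
                     jobs$conformer), ]
  rownames(jobs) <- NULL
  jobs$job <- seq_len(nrow(jobs))
  jobs$pose_mode <- rep_len(manifest$pose_modes, nrow(jobs))
  jobs$unstable <- jobs$job %in% manifest$unstable_jobs
  jobs$seed <- (manifest$seed %% 100000L) * 1000L + jobs$job
  jobs[c("job", "gq_id", "conformer", "pose_mode", "unstable", "seed")]
}

#' Run the full analysis pipeline
#'
#' Stages: build GQ fixtures; generate the peptide conformer ensemble
#' (optionally cluster a larger raw ensemble and keep medoid
#' representatives); place each conformer on each GQ in its planted pose;
#' simulate a seeded pseudo-trajectory per complex; per complex compute the
#' quartet-stability series, binding-mode interaction matrices and contact
#' map; pool per GQ (merged contact maps, occupancy grid) and across
#' complexes (stability scatter table). Per-job failures are isolated,
#' logged and reported in a failure table without aborting the run. Jobs
#' whose result file already exists under `out_dir` are reloaded, making
#' reruns resumable; all outputs carry the manifest hash.
#'
#' @param manifest a `RunManifest`.
#' @param out_dir output directory (created if needed). `NULL` keeps all
#'   results in memory only.
#' @param verbose print per-stage progress.
#' @return a report bundle: list with `jobs`, `scatter`, `stability`
#'   (per-complex series), `mode_matrices`, `contact_maps` (pooled per GQ),
#'   `occupancy` (per GQ), `failures`, `cluster_result`, `manifest`.
#' @export
run_all <- function(manifest, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(manifest, "RunManifest"))
  cfg <- manifest$config
  crit <- hbond_criterion(cfg$thresholds$hbond_donor_acceptor_max,
                          cfg$thresholds$hbond_h_angle_max)
  syn <- cfg$synonyms
  say <- function(...) if (verbose) message(...)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  say("stage 1: fixtures")
  gqs <- lapply(seq_along(manifest$gq_specs), function(i) {
    build_gq(manifest$gq_specs[[i]], seed = manifest$seed + i)
  })
  names(gqs) <- names(manifest$gq_specs)

  say("stage 2: conformers")
  cluster_result <- NULL
  if (!is.null(manifest$n_raw_conformers)) {
    raw <- make_peptide_conformers(manifest$sequence,
                                   n = manifest$n_raw_conformers,
                                   seed = manifest$seed + 101L)
    feats <- featurize(raw)
    cluster_result <- cluster_conformers(
      feats, k = manifest$n_conformers,
      perplexity = cfg$clustering$perplexity, seed = manifest$seed + 102L,
      max_iter = cfg$clustering$max_iter)
    conformers <- representatives(raw, cluster_result)
  } else {
    conformers <- make_peptide_conformers(manifest$sequence,
                                          n = manifest$n_conformers,
                                          seed = manifest$seed + 101L)
  }

  jobs <- enumerate_complexes(manifest)
  say("stage 3: ", nrow(jobs), " complex jobs")
  job_results <- vector("list", nrow(jobs))
  failures <- data.frame(job = integer(0), gq_id = character(0),
                         error = character(0), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(jobs))) {
    jb <- jobs[i, ]
    cache <- if (!is.null(out_dir)) {
      file.path(out_dir, sprintf("job_%03d.rds", jb$job))
    }
    if (!is.null(cache) && file.exists(cache)) {
      job_results[[i]] <- readRDS(cache)
      next
    }
    job_results[i] <- list(tryCatch({
      gq <- gqs[[jb$gq_id]]
      conf <- get_frame(conformers, jb$conformer)
      cpx <- place_peptide(gq, conf, pose_spec(jb$pose_mode), seed = jb$seed,
                           synonyms = syn)
      traj <- make_unfolding_trajectory(
        cpx, n_frames = manifest$n_frames,
        strand_displacement_per_frame =
          if (jb$unstable) manifest$displacement else 0,
        noise_sigma = manifest$noise_sigma, seed = jb$seed + 1L,
        synonyms = syn)
      assign <- detect_quartets(cpx, crit, syn)
      series <- quartet_hbond_series(traj, assign, crit,
                                     cutoff = cfg$thresholds$instability_cutoff,
                                     synonyms = syn)
      mats <- lapply(stats::setNames(nm = c("end_stack", "groove", "loop")),
                     function(m) interaction_matrix(
                       traj, assign, mode = m,
                       cutoff = cfg$thresholds$mode_cutoff, synonyms = syn))
      cmap <- contact_map(traj, cutoff = cfg$thresholds$mode_cutoff,
                          min_lifetime = cfg$thresholds$min_lifetime,
                          synonyms = syn,
                          residue_offset = cfg$contact_map$residue_offset)
      res <- list(job = jb$job, gq_id = jb$gq_id, traj = traj,
                  series = series, matrices = mats, contact_map = cmap)
      if (!is.null(cache)) saveRDS(res, cache)
      res
    }, error = function(e) {
      failures <<- rbind(failures, data.frame(
        job = jb$job, gq_id = jb$gq_id, error = conditionMessage(e),
        stringsAsFactors = FALSE))
      say("job ", jb$job, " failed: ", conditionMessage(e))
      NULL
    }))
  }

  say("stage 4: pooled reports")
  ok <- !vapply(job_results, is.null, logical(1))
  series_list <- stats::setNames(
    lapply(job_results[ok], `[[`, "series"),
    sprintf("%s_c%02d", jobs$gq_id[ok], jobs$conformer[ok]))
  scatter <- if (any(ok)) {
    stability_scatter(series_list, cutoff = cfg$thresholds$instability_cutoff)
  } else NULL

  pooled_maps <- list(); occupancy <- list(); pooled_mats <- list()
  for (g in names(gqs)) {
    sel <- which(ok & jobs$gq_id == g)
    if (!length(sel)) next
    pooled_maps[[g]] <- merge_maps(lapply(job_results[sel], `[[`,
                                          "contact_map"))
    for (m in c("end_stack", "groove", "loop")) {
      mats <- lapply(job_results[sel], function(r) r$matrices[[m]])
      pooled_mats[[g]][[m]] <- Reduce(`+`, mats) / length(mats)
    }
    # pooled occupancy: frames of all this GQ's trajectories share one
    # topology, so concatenate and grid once
    trajs <- lapply(job_results[sel], `[[`, "traj")
    coords <- do.call(abind3, lapply(trajs, `[[`, "coords"))
    occupancy[[g]] <- occupancy_grid(
      ensemble(trajs[[1]]$topology, coords),
      spacing = cfg$grid$spacing, cutoff = cfg$thresholds$occupancy_cutoff,
      margin = cfg$grid$margin, synonyms = syn)
  }

  bundle <- list(jobs = jobs, scatter = scatter, stability = series_list,
                 mode_matrices = pooled_mats, contact_maps = pooled_maps,
                 occupancy = occupancy, failures = failures,
                 cluster_result = cluster_result, manifest = manifest)
  if (!is.null(out_dir)) write_report_bundle(bundle, out_dir)
  bundle
}

# rbind for frame-major 3-D coordinate arrays
abind3 <- function(...) {
  parts <- list(...)
  n <- sum(vapply(parts, function(p) dim(p)[1], numeric(1)))
  out <- array(NA_real_, dim = c(n, dim(parts[[1]])[2], 3))
  at <- 0
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

#' Write a pipeline report bundle as TSV/DX files
#'
#' Every file starts with a `# manifest_hash:` comment line.
#'
#' @param bundle result of [run_all()].
#' @param out_dir output directory.
#' @return invisibly, `out_dir`.
#' @export
write_report_bundle <- function(bundle, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  hx <- paste("manifest_hash:", bundle$manifest$hash)
  if (!is.null(bundle$scatter)) {
    write_tsv_matrix(bundle$scatter, file.path(out_dir, "stability_scatter.tsv"),
                     comment = hx)
  }
  if (nrow(bundle$failures)) {
    write_tsv_matrix(bundle$failures, file.path(out_dir, "failures.tsv"),
                     comment = hx)
  }
  for (g in names(bundle$contact_maps)) {
    write_tsv_matrix(bundle$contact_maps[[g]],
                     file.path(out_dir, paste0("contact_map_", g, ".tsv")),
                     comment = hx)
    plot_heatmap(bundle$contact_maps[[g]]$values,
                 file.path(out_dir, paste0("contact_map_", g, ".png")),
                 main = paste("contact lifetime:", g))
  }
  for (g in names(bundle$mode_matrices)) {
    for (m in names(bundle$mode_matrices[[g]])) {
      mat <- bundle$mode_matrices[[g]][[m]]
      write_tsv_matrix(unclass(mat),
                       file.path(out_dir,
                                 paste0("interactions_", g, "_", m, ".tsv")),
                       comment = hx)
      plot_heatmap(mat, file.path(out_dir,
                                  paste0("interactions_", g, "_", m, ".png")),
                   main = paste(g, m))
    }
  }
  for (g in names(bundle$occupancy)) {
    write_dx(bundle$occupancy[[g]],
             file.path(out_dir, paste0("occupancy_", g, ".dx")))
  }
  per_frame <- do.call(rbind, lapply(names(bundle$stability), function(id) {
    s <- bundle$stability[[id]]
    data.frame(complex_id = id,
               frame = seq_along(s$per_frame_quartet_hbonds),
               quartet_hbonds = s$per_frame_quartet_hbonds,
               intermolecular_hbonds = s$per_frame_intermolecular_hbonds,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(per_frame)) {
    write_tsv_matrix(per_frame, file.path(out_dir, "hbond_series.tsv"),
                     comment = hx)
  }
  invisible(out_dir)
}
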