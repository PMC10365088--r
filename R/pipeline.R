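# Experiment drivers binding the stages into the two-arm comparison:
# simulate -> (Mcorr | Mres) -> CLAHE + segmentation -> metrics. Every stage
# persists its outputs and is individually re-runnable; all randomness flows
# from the master seed through named per-stage sub-seeds.

#' Experiment configuration
#'
#' Bundles phantom, waveform, sequence, reconstruction, segmentation, and
#' evaluation parameters. Two presets are provided: `"desk"` (matrix 64,
#' 200 interleaves of 32 lines, single coil, 20 CS iterations), sized so a
#' full two-arm run completes in about a minute on one CPU, and
#' `"protocol"` matching the published whole-heart protocol geometry
#' (matrix 192, 382 interleaves of 32 lines, fov 220 mm, 4 coils).
#'
#' @param preset `"desk"` or `"protocol"`
#' @param seed master seed
#' @param ... named overrides of top-level fields (e.g. `snr_db`,
#'   `n_coils`, `cs = cs_config(...)`, `seq = sequence_params(...)`)
#' @return object of class `experiment_config`
#' @export
experiment_config <- function(preset = c("desk", "protocol"), seed = 1L, ...) {
  preset <- match.arg(preset)
  base <- if (preset == "desk") {
    # RR interval 0.9 s: a realistic heart rate that also keeps the cardiac
    # sampling incommensurate with the 4 s breathing period, so interleaves
    # sample the full displacement distribution
    list(seq = sequence_params(fov = 220, matrix = 64, n_interleaves = 200,
                               lines_per_interleaf = 32,
                               interleaf_interval_s = 0.9),
         n_coils = 1,
         cs = cs_config(lambda = 0.1, n_iterations = 20))
  } else {
    list(seq = sequence_params(fov = 220, matrix = 192, n_interleaves = 382,
                               lines_per_interleaf = 32),
         n_coils = 4,
         cs = cs_config(lambda = 0.1, n_iterations = 50))
  }
  cfg <- list(preset = preset,
              seed = as.integer(seed),
              anatomy = default_anatomy(confounders = TRUE),
              waveform = resp_waveform(seed = derive_seed(seed, "waveform")),
              seq = base$seq,
              n_coils = base$n_coils,
              snr_db = 30,
              cs = base$cs,
              n_bins = 4L,
              resp_band_hz = c(0.1, 0.5),
              clahe = list(clip_limit = 0.01, n_tiles = 8),
              seg = list(roi_mm = 60, closing_radius_vox = 1))
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  cfg$waveform$seed <- derive_seed(cfg$seed, "waveform")
  structure(cfg, class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("<experiment_config> preset %s, seed %d, matrix %d, %d interleaves x %d lines, %d coil(s)\n",
              x$preset, x$seed, x$seq$matrix, x$seq$n_interleaves,
              x$seq$lines_per_interleaf, x$n_coils))
  invisible(x)
}

#' Serialise / restore an experiment configuration (YAML)
#'
#' @param cfg [experiment_config()]
#' @param path YAML file
#' @return `path` / the restored config
#' @export
write_config <- function(cfg, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  plain <- list(
    preset = cfg$preset, seed = cfg$seed,
    seq = unclass(cfg$seq), n_coils = cfg$n_coils, snr_db = cfg$snr_db,
    cs = unclass(cfg$cs), n_bins = cfg$n_bins,
    resp_band_hz = cfg$resp_band_hz, clahe = cfg$clahe, seg = cfg$seg,
    waveform = unclass(cfg$waveform),
    anatomy = list(
      components = lapply(cfg$anatomy$components, unclass),
      roles = cfg$anatomy$roles,
      ap_fraction = cfg$anatomy$ap_fraction))
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  p <- yaml::read_yaml(path)
  comps <- lapply(p$anatomy$components, function(c)
    ellipsoid_component(c$name, c$center, c$semi_axes, c$intensity,
                        c$motion_scale, c$rotation))
  names(comps) <- vapply(comps, function(c) c$name, character(1))
  cfg <- list(preset = p$preset, seed = p$seed,
              anatomy = anatomy_spec(comps, p$anatomy$roles,
                                     ap_fraction = p$anatomy$ap_fraction %||% 0),
              waveform = do.call(resp_waveform, p$waveform[
                c("amplitude", "period", "shape_exponent", "drift_rate",
                  "jitter_sd", "seed")]),
              seq = do.call(sequence_params, p$seq[
                c("fov", "matrix", "n_interleaves", "lines_per_interleaf",
                  "interleaf_duration_ms", "interleaf_interval_s",
                  "samples_per_line")]),
              n_coils = p$n_coils, snr_db = p$snr_db,
              cs = do.call(cs_config, p$cs[
                c("lambda", "n_iterations", "tv_mode", "inner_iterations",
                  "accuracy", "dcf")]),
              n_bins = p$n_bins, resp_band_hz = p$resp_band_hz,
              clahe = p$clahe, seg = p$seg)
  structure(cfg, class = "experiment_config")
}

#' Simulate an acquisition and write all stage outputs
#'
#' Writes the k-space container, ground-truth volume and LV mask at
#' end-expiration, the per-interleaf displacement series (CSV), and the
#' resolved configuration (YAML).
#'
#' @param cfg [experiment_config()]
#' @param out_dir output directory (created if missing)
#' @return the `kspace_dataset`, invisibly
#' @export
run_simulate <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- image_grid(cfg$seq$matrix, cfg$seq$fov)
  traj <- make_phyllotaxis(cfg$seq$n_interleaves, cfg$seq$lines_per_interleaf,
                           cfg$seq$interleaf_interval_s,
                           cfg$seq$interleaf_duration_ms)
  ks <- simulate_acquisition(cfg$anatomy, cfg$waveform, cfg$seq, traj,
                             n_coils = cfg$n_coils, snr_db = cfg$snr_db,
                             seed = derive_seed(cfg$seed, "noise"),
                             grid = grid)
  write_kspace(ks, file.path(out_dir, "kspace.rds"))
  truth <- rasterize(cfg$anatomy, 0, grid)
  write_volume(truth$volume, grid, file.path(out_dir, "truth_volume.nii.gz"))
  write_volume(truth$mask, grid, file.path(out_dir, "truth_lv_mask.nii.gz"))
  write.csv(data.frame(interleaf = seq_along(ks$truth$displacement_mm),
                       timestamp_s = ks$truth$timestamp_s,
                       displacement_mm = ks$truth$displacement_mm),
            file.path(out_dir, "displacement.csv"), row.names = FALSE)
  write_config(cfg, file.path(out_dir, "config.yaml"))
  invisible(ks)
}

#' Reconstruct one arm from persisted k-space
#'
#' `arm = "mcorr"` writes one motion-corrected NIfTI plus the estimated
#' shifts (CSV); `arm = "mres"` writes `n_bins` motion-resolved NIfTIs
#' (`mres_resp1..`, bin 1 = end-expiration) plus the respiratory signal /
#' bin assignment and the per-iteration CS objective (CSV).
#'
#' @param cfg [experiment_config()]
#' @param out_dir directory holding `kspace.rds` (outputs written here too)
#' @param arm `"mcorr"` or `"mres"`
#' @return list of reconstructed volumes, invisibly
#' @export
run_recon <- function(cfg, out_dir, arm = c("mcorr", "mres")) {
  arm <- match.arg(arm)
  path <- file.path(out_dir, "kspace.rds")
  if (!file.exists(path))
    phr_stop("missing_input", "kspace.rds not found: run run_simulate first")
  ks <- read_kspace(path)
  grid <- image_grid(cfg$seq$matrix, cfg$seq$fov)
  if (arm == "mcorr") {
    projs <- extract_si_projections(ks)
    band <- isolate_heart_band(projs)
    shifts <- estimate_shifts(band)
    write_shifts(shifts, file.path(out_dir, "shifts.csv"))
    vol <- reconstruct_mcorr(ks, shifts, grid)
    write_volume(vol, grid, file.path(out_dir, "mcorr.nii.gz"))
    invisible(list(mcorr = vol))
  } else {
    projs <- extract_si_projections(ks)
    resp <- extract_resp_signal(projs, fs = 1 / cfg$seq$interleaf_interval_s,
                                band = cfg$resp_band_hz)
    bins <- assign_bins(resp, cfg$n_bins)
    write_bins(resp, bins, file.path(out_dir, "bins.csv"))
    cs <- cs_reconstruct(ks, bins, cfg$cs, grid)
    write.csv(data.frame(iteration = seq_along(cs$objective),
                         objective = cs$objective),
              file.path(out_dir, "cs_objective.csv"), row.names = FALSE)
    for (b in seq_len(cfg$n_bins)) {
      write_volume(cs$volumes[[b]], grid,
                   file.path(out_dir, sprintf("mres_resp%d.nii.gz", b)))
    }
    invisible(cs$volumes)
  }
}

#' Run one synthetic subject end to end, in memory
#'
#' Convenience driver used by the cohort evaluation: simulates one subject,
#' reconstructs both arms, CLAHE-filters all five volumes, segments them
#' with the classical segmenter seeded at the phantom LV centroid ("auto"),
#' and pairs each with its displacement-matched ground-truth mask
#' ("manual"): the end-expiration mask for Mcorr (reference position of the
#' shift correction), the bin-mean-displacement mask for each Mres bin.
#'
#' @param cfg [experiment_config()]
#' @param mcorr_weights optional cached [iterative_dcf()] weights for the
#'   gridded Mcorr reconstruction (they depend only on the trajectory, so a
#'   cohort can compute them once); default: computed here
#' @return list with `volumes`, `auto` masks, `manual` masks, `shifts`,
#'   `resp`, `bins`, `ks` (dataset), `grid`
#' @export
run_subject <- function(cfg, mcorr_weights = NULL) {
  grid <- image_grid(cfg$seq$matrix, cfg$seq$fov)
  traj <- make_phyllotaxis(cfg$seq$n_interleaves, cfg$seq$lines_per_interleaf,
                           cfg$seq$interleaf_interval_s,
                           cfg$seq$interleaf_duration_ms)
  ks <- simulate_acquisition(cfg$anatomy, cfg$waveform, cfg$seq, traj,
                             n_coils = cfg$n_coils, snr_db = cfg$snr_db,
                             seed = derive_seed(cfg$seed, "noise"),
                             grid = grid)
  projs <- extract_si_projections(ks)
  band <- isolate_heart_band(projs)
  shifts <- estimate_shifts(band)
  if (is.null(mcorr_weights)) {
    op_full <- nufft_op(ks$kpoints, grid, accuracy = "fast")
    mcorr_weights <- iterative_dcf(op_full, density_compensation(ks),
                                   n_iter = 10)
  }
  mcorr_vol <- reconstruct_mcorr(ks, shifts, grid, weights = mcorr_weights)
  resp <- extract_resp_signal(projs, fs = 1 / cfg$seq$interleaf_interval_s,
                              band = cfg$resp_band_hz)
  bins <- assign_bins(resp, cfg$n_bins)
  cs <- cs_reconstruct(ks, bins, cfg$cs, grid)

  d_il <- ks$truth$displacement_mm
  manual_mcorr <- rasterize(cfg$anatomy, 0, grid)$mask
  manual_mres <- lapply(seq_len(cfg$n_bins), function(b)
    rasterize(cfg$anatomy, mean(d_il[bins$bin == b]), grid)$mask)

  # CLAHE once per volume, then segment with the seed at the phantom LV
  # centroid of the matching reference
  seed_of <- function(mask) round(colMeans(which(mask, arr.ind = TRUE)))
  filt_mcorr <- clahe3d(mcorr_vol, cfg$clahe$clip_limit, cfg$clahe$n_tiles)
  filt_mres <- lapply(cs$volumes, clahe3d, clip_limit = cfg$clahe$clip_limit,
                      n_tiles = cfg$clahe$n_tiles)
  seg_one <- function(filt, manual) {
    segment_lv(filt, seed_of(manual), grid$spacing,
               roi_mm = cfg$seg$roi_mm,
               closing_radius_vox = cfg$seg$closing_radius_vox)
  }
  auto_mcorr <- seg_one(filt_mcorr, manual_mcorr)
  auto_mres <- lapply(seq_len(cfg$n_bins), function(b)
    seg_one(filt_mres[[b]], manual_mres[[b]]))

  out <- list(
    volumes = c(list(mcorr = mcorr_vol), cs$volumes),
    mcorr = list(volume = filt_mcorr, auto = auto_mcorr),
    mres = lapply(seq_len(cfg$n_bins), function(b)
      list(volume = filt_mres[[b]], auto = auto_mres[[b]])),
    manual = list(mcorr = manual_mcorr, mres = manual_mres),
    shifts = shifts, resp = resp, bins = bins, objective = cs$objective,
    ks = ks, grid = grid)
  attr(out, "mcorr_weights") <- mcorr_weights
  out
}

#' Run a cohort of synthetic subjects and evaluate the study
#'
#' @param cfg base [experiment_config()]; each subject uses
#'   `seed = derive_seed(cfg$seed, paste0("subject", i))`
#' @param n_subjects cohort size
#' @param out_dir optional directory for the metrics report files
#' @return [evaluate_study()] report with attribute `subjects`
#' @export
run_cohort <- function(cfg, n_subjects, out_dir = NULL) {
  subs <- vector("list", n_subjects)
  mcorr_weights <- NULL
  for (i in seq_len(n_subjects)) {
    ci <- cfg
    ci$seed <- derive_seed(cfg$seed, paste0("subject", i))
    ci$waveform$seed <- derive_seed(ci$seed, "waveform")
    subs[[i]] <- run_subject(ci, mcorr_weights = mcorr_weights)
    if (is.null(mcorr_weights))
      mcorr_weights <- attr(subs[[i]], "mcorr_weights")
  }
  grid <- subs[[1]]$grid
  report <- evaluate_study(lapply(subs, function(s)
    list(mcorr = s$mcorr, mres = s$mres, manual = s$manual)),
    spacing = grid$spacing)
  if (!is.null(out_dir)) write_metrics_report(report, out_dir)
  attr(report, "subjects") <- subs
  report
}

#' Evaluate persisted reconstructions
#'
#' File-based counterpart of [run_cohort()]: reads the volumes and masks a
#' previous [run_simulate()]/[run_recon()] pair wrote under each subject
#' directory, segments, and writes the metrics report.
#'
#' @param cfg [experiment_config()]
#' @param subject_dirs character vector of directories, each holding
#'   `kspace.rds`, `mcorr.nii.gz`, `mres_resp*.nii.gz`, `truth_lv_mask.nii.gz`
#' @param out_dir report directory
#' @return [evaluate_study()] report
#' @export
run_evaluate <- function(cfg, subject_dirs, out_dir) {
  grid <- image_grid(cfg$seq$matrix, cfg$seq$fov)
  subs <- lapply(subject_dirs, function(d) {
    need <- c("mcorr.nii.gz", sprintf("mres_resp%d.nii.gz", seq_len(cfg$n_bins)),
              "bins.csv", "kspace.rds")
    miss <- need[!file.exists(file.path(d, need))]
    if (length(miss))
      phr_stop("missing_input",
               sprintf("%s missing %s: rerun run_simulate/run_recon",
                       d, paste(miss, collapse = ", ")))
    ks <- read_kspace(file.path(d, "kspace.rds"))
    bins_df <- read.csv(file.path(d, "bins.csv"))
    cfg_s <- read_config(file.path(d, "config.yaml"))
    d_il <- ks$truth$displacement_mm
    manual_mcorr <- rasterize(cfg_s$anatomy, 0, grid)$mask
    manual_mres <- lapply(seq_len(cfg$n_bins), function(b)
      rasterize(cfg_s$anatomy, mean(d_il[bins_df$bin == b]), grid)$mask)
    seed_of <- function(mask) round(colMeans(which(mask, arr.ind = TRUE)))
    seg_one <- function(vol, manual) {
      filt <- clahe3d(vol, cfg$clahe$clip_limit, cfg$clahe$n_tiles)
      list(volume = filt,
           auto = segment_lv(filt, seed_of(manual), grid$spacing,
                             roi_mm = cfg$seg$roi_mm,
                             closing_radius_vox = cfg$seg$closing_radius_vox))
    }
    mcorr <- seg_one(read_volume(file.path(d, "mcorr.nii.gz"))$vol, manual_mcorr)
    mres <- lapply(seq_len(cfg$n_bins), function(b)
      seg_one(read_volume(file.path(d, sprintf("mres_resp%d.nii.gz", b)))$vol,
              manual_mres[[b]]))
    list(mcorr = mcorr, mres = mres,
         manual = list(mcorr = manual_mcorr, mres = manual_mres))
  })
  report <- evaluate_study(subs, spacing = grid$spacing)
  write_metrics_report(report, out_dir)
  report
}
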