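# Pipeline orchestration over a synthetic scene: configuration with the
# study constants as defaults, staged execution, CSV/JSON artifacts.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    n_subjects = 8L,
    n_bins = 20L,
    extension_bins = list(CA1 = 10L, CA2 = 10L),
    vein_threshold = -3,
    artery_threshold = 1,
    breathhold_cutoff_s = 246,
    task_cutoff_s = 128,
    math_shift_volumes = 2L,
    drop_initial_volumes = 3L,
    vein_masking = TRUE,
    percent_normalize = FALSE,
    tes_ms = c(2, 6, 10, 14, 17, 21),
    breathhold_blocks = 6L,
    breathhold_tr_s = 40.992,
    task_tr_s = 2.21,
    task_volumes = 489L,
    task_trials = 44L,
    scene = list(n_long = 12L, n_trans = 36L, fold_turns = 0.6,
                 thickness = 2.5, voxel_mm = 0.9, vascular_voxel_mm = 0.5,
                 thermal_sd = 30)
  )
}

#' Pipeline configuration
#'
#' Merges user settings over the built-in defaults, which carry the study
#' constants (20 depth bins, CA1/CA2 extension 10, vein/artery thresholds
#' -3/1 a.u., high-pass cutoffs 246 s and 128 s, TE list, 44 trials of 489
#' volumes at TR 2.21 s, 6 breath-hold blocks of TR 40.992 s). Unknown keys
#' are rejected.
#'
#' @param ... settings overriding the defaults (nested lists allowed).
#' @return a validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  if (length(user) == 1L && is.null(names(user)) && is.list(user[[1L]]))
    user <- user[[1L]]
  def <- pipeline_defaults()
  merge_into <- function(base, upd, path = "") {
    for (nm in names(upd)) {
      if (!nm %in% names(base))
        stop("unknown config key: ", paste0(path, nm))
      if (is.list(base[[nm]]) && is.list(upd[[nm]]))
        base[[nm]] <- merge_into(base[[nm]], upd[[nm]],
                                 paste0(path, nm, "."))
      else base[[nm]] <- upd[[nm]]
    }
    base
  }
  structure(merge_into(def, user), class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return a [pipeline_config].
#' @export
read_config <- function(path) pipeline_config(yaml::read_yaml(path))

#' @param config a [pipeline_config].
#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

write_csv_out <- function(df, path) {
  utils::write.csv(format(df, digits = 10, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  path
}

#' Run the analysis pipeline on a synthetic scene
#'
#' Executes the stages in dependency order on data simulated from the
#' configured scene: `simulate` (surfaces, vascular volumes, breath-hold and
#' task runs per subject), `vessels` (filtering, projection, density),
#' `breathhold` (T2* fits, weighted signal change, slopes), `glm` (laminar
#' contrast profiles) and `stats` (signed-rank density tests with Hochberg
#' adjustment, slope-density mixed model, depth-model comparisons). Every
#' CSV artifact and a JSON manifest are written under `out_dir`.
#'
#' @param config a [pipeline_config].
#' @param stage `"all"` or one of the stage names (earlier stages are run as
#'   needed).
#' @param out_dir output directory.
#' @return the manifest (named list of artifact paths), invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), stage = "all",
                         out_dir = tempfile("hippolaminar_")) {
  stages_all <- c("simulate", "vessels", "breathhold", "glm", "stats")
  stage <- match.arg(stage, c("all", stages_all))
  want <- if (stage == "all") stages_all
          else stages_all[seq_len(match(stage, stages_all))]
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cfg <- config
  manifest <- list()
  sc <- cfg$scene

  surface <- make_surface_sheet(sc$n_long, sc$n_trans, sc$fold_turns,
                                sc$thickness)
  scheme <- build_sampling_scheme(surface, cfg$n_bins,
                                  unlist(cfg$extension_bins))
  manifest$surfaces <- as.list(write_surface_set(surface, out_dir))
  subjects <- seq_len(cfg$n_subjects)
  subj_seed <- function(s, k) (cfg$seed * 1000L + s * 10L + k) %% .Machine$integer.max

  dens_list <- list(); slope_list <- list(); t2s_list <- list()
  z_list <- list()
  ran_vessels <- "vessels" %in% want
  ran_bh <- "breathhold" %in% want
  ran_glm <- "glm" %in% want
  for (s in subjects) {
    truth <- default_ground_truth(surface, thermal_sd = sc$thermal_sd,
                                  seed = subj_seed(s, 1L))
    if (ran_vessels) {
      vasc <- make_vascular_volumes(surface, truth, sc$vascular_voxel_mm,
                                    seed = subj_seed(s, 2L))
      vein <- rescale_vesselness(frangi_veins(vasc$swi), "vein", vasc$mask)
      art <- rescale_vesselness(haar_arteries(vasc$tof), "artery", vasc$mask)
      maps <- list(
        vein_inner = project_to_surface(vein, surface$vertices_inner,
                                        surface$labels, "vein", "inner"),
        vein_outer = project_to_surface(vein, surface$vertices_outer,
                                        surface$labels, "vein", "outer"))
      dtab <- vessel_density_table(maps$vein_inner, maps$vein_outer,
                                   cfg$vein_threshold)
      dtab$subject <- s
      dens_list[[s]] <- dtab
      if (s == 1L) {
        vein_mask <- make_vein_mask(maps$vein_inner, cfg$vein_threshold)
        adens <- vessel_density(
          project_to_surface(art, surface$vertices_outer, surface$labels,
                             "artery", "outer"), cfg$artery_threshold)
        manifest$artery_density <- write_csv_out(
          adens, file.path(out_dir, "artery_density_outer.csv"))
      }
    }
    if (ran_bh) {
      bh <- make_multiecho_breathhold(surface, truth, cfg$tes_ms,
                                      make_breathhold_events(cfg$breathhold_blocks,
                                                             cfg$breathhold_tr_s),
                                      seed = subj_seed(s, 3L), voxel_mm = 0.8)
      w <- echo_weights(cfg$tes_ms)
      for (sf in names(scheme$subfields)) {
        ser <- highpass_trim(multiecho_from_sim(bh, scheme, sf),
                             cfg$breathhold_cutoff_s, 1L)
        prof <- breathhold_change(ser, w,
                                  if (cfg$percent_normalize) "percent" else "none")
        if (sf != "CA4/DG") {
          sl <- profile_slope(prof)
          slope_list[[length(slope_list) + 1L]] <-
            data.frame(subject = s, subfield = sf, slope = sl["slope"],
                       se = sl["se"])
        }
        rest_means <- apply(ser$profiles[, , ser$condition == "rest",
                                         drop = FALSE], c(1, 2), mean)
        # depths sampling outside the sheet (extension bins in background)
        # carry no decaying signal and are left unfitted
        fitable <- apply(rest_means, 1L, function(r) all(r > 0))
        t2 <- data.frame(s0 = rep(NA_real_, nrow(rest_means)),
                         t2star = NA_real_)
        if (any(fitable))
          t2[fitable, c("s0", "t2star")] <-
            fit_t2star(rest_means[fitable, , drop = FALSE],
                       cfg$tes_ms)[, c("s0", "t2star")]
        t2s_list[[length(t2s_list) + 1L]] <-
          data.frame(subject = s, subfield = sf,
                     depth_fraction = prof$depth_fraction,
                     t2star = t2$t2star, s0 = t2$s0,
                     ds_weighted = prof$ds)
      }
    }
    if (ran_glm) {
      am <- make_am_timeseries(surface, truth, cfg$task_volumes,
                               cfg$task_tr_s, seed = subj_seed(s, 4L),
                               n_trials = cfg$task_trials,
                               voxel_mm = sc$voxel_mm)
      design <- build_design(am$events, am$motion, NULL, cfg$task_tr_s,
                             cfg$task_cutoff_s, cfg$drop_initial_volumes)
      keep_vols <- (cfg$drop_initial_volumes + 1L):cfg$task_volumes
      mvol <- condition_volumes(am$events, "math", cfg$math_shift_volumes,
                                cfg$drop_initial_volumes)
      prof4d <- sample_profiles(am$bold, scheme)
      mask_arg <- if (cfg$vein_masking && ran_vessels) vein_mask else NULL
      agg <- aggregate_profiles(prof4d, mask_arg)
      for (sf in names(agg)) {
        Y <- agg[[sf]]$mean[, keep_vols, drop = FALSE]
        Z <- baseline_z(Y, mvol)
        fit <- rwls_fit(Z, design)
        ctr <- laminar_contrasts(fit$coefficients)
        ctr$depth_fraction <- agg[[sf]]$depth_fraction
        ctr$subject <- s; ctr$subfield <- sf
        z_list[[length(z_list) + 1L]] <- ctr
      }
    }
  }

  if (ran_vessels) {
    dens <- do.call(rbind, dens_list)
    manifest$vein_density <- write_csv_out(
      dens, file.path(out_dir, "vein_density.csv"))
  }
  if (ran_bh) {
    slopes <- do.call(rbind, slope_list)
    manifest$slopes <- write_csv_out(slopes, file.path(out_dir, "slopes.csv"))
    manifest$t2star <- write_csv_out(do.call(rbind, t2s_list),
                                     file.path(out_dir, "t2star_profiles.csv"))
  }
  if (ran_glm) {
    zz <- do.call(rbind, z_list)
    manifest$contrasts <- write_csv_out(
      zz, file.path(out_dir, "contrast_profiles.csv"))
  }
  if ("stats" %in% want) {
    dens <- do.call(rbind, dens_list)
    sf_names <- unique(dens$subfield)
    sf_fam <- c("Subiculum", "CA1", "CA2", "CA3")
    tests <- lapply(sf_fam, function(sf) {
      d <- dens$delta_rho[dens$subfield == sf]
      wt <- tryCatch(wilcoxon_exact(d),
                     error = function(e) list(W = NA, n = length(d),
                                              p_exact = NA))
      data.frame(subfield = sf, W = wt$W, n = wt$n, p = wt$p_exact)
    })
    tt <- do.call(rbind, tests)
    ok <- !is.na(tt$p)
    tt$p_up <- NA_real_
    if (any(ok)) tt$p_up[ok] <- hochberg_stepup(tt$p[ok])
    manifest$density_tests <- write_csv_out(
      tt, file.path(out_dir, "density_tests.csv"))
    slopes <- do.call(rbind, slope_list)
    sd_df <- merge(slopes,
                   stats::aggregate(delta_rho ~ subject + subfield, dens, mean),
                   by = c("subject", "subfield"))
    if (nrow(sd_df) >= 10L &&
        length(unique(sd_df$subject)) >= 2L) {
      m <- slope_density_model(sd_df)
      manifest$slope_density_model <- write_csv_out(
        data.frame(estimate = m$coef["estimate"], se = m$coef["se"],
                   F = m$test$F, df1 = m$test$df1, df2 = m$test$df2,
                   p = m$test$p, r2_marginal = m$r2["marginal"],
                   r2_conditional = m$r2["conditional"]),
        file.path(out_dir, "slope_density_model.csv"))
    }
    if (ran_glm && cfg$n_subjects >= 2L) {
      zz <- do.call(rbind, z_list)
      cmp <- lapply(setdiff(unique(zz$subfield), "CA4/DG"), function(sf) {
        d <- zz[zz$subfield == sf, ]
        out <- compare_depth_models(
          data.frame(z = d$memory_gt_math, depth = d$depth_fraction,
                     subject = d$subject))
        out$subfield <- sf
        out
      })
      manifest$depth_model_tests <- write_csv_out(
        do.call(rbind, cmp), file.path(out_dir, "depth_model_tests.csv"))
    }
  }
  manifest$config <- write_config(cfg, file.path(out_dir, "config.yaml"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}
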