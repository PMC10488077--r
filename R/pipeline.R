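#' Region-group labels of the study design
#'
#' Injured eyes contribute a scar (Sc) and an incision-adjoining (Ad)
#' region; uninjured eyes contribute a single Un region. Crossed with the
#' treatment groups this yields the five units of analysis: Sc-ACA, Sc-Ctr,
#' Ad-ACA, Ad-Ctr and Un.
#'
#' @return Character vector of the five region-group labels.
#' @export
region_groups <- function() c("Sc-ACA", "Sc-Ctr", "Ad-ACA", "Ad-Ctr", "Un")

#' Demo study configuration
#'
#' Planted per-region-group generator settings for the synthetic study.
#' Defaults emulate the study's qualitative findings: scar regions have
#' shorter, more curved, less aligned fibrils; the scar region of the
#' treated group has reduced relative collagen and proteoglycan content;
#' collagen leads the proteoglycan depth transition (positive
#' `lag_layers`) in the Un and Sc-ACA region-groups and trails it
#' (negative) in Sc-Ctr, Ad-ACA and Ad-Ctr.
#'
#' @param n_layers Depth layers per spectral series (default 25).
#' @param rois_per_region Imaged ROIs per region (default 3).
#' @param image_size Fibril image side in pixels (default 160).
#' @param n_fibers Fibers per ROI image (default 18).
#' @param spectra_noise_sd Absorbance noise (default 0.002).
#' @param background_noise_sd Image background noise in gray levels
#'   (default 4).
#' @param null_effects If `TRUE`, every region-group shares the Un
#'   settings (no planted differences) - used for calibration studies.
#' @return A list of class `demo_config`.
#' @export
demo_config <- function(n_layers = 25, rois_per_region = 3,
                        image_size = 160, n_fibers = 18,
                        spectra_noise_sd = 0.002, background_noise_sd = 4,
                        null_effects = FALSE) {
  un <- list(collagen_amp = 0.50, pg_amp = 0.30, lag_layers = 4,
             length_mean = 90, length_sd = 12, width_px = 3,
             orientation_kappa = 30, curvature_amp = 0.03)
  regions <- if (null_effects) {
    stats::setNames(rep(list(un), 5), region_groups())
  } else {
    list(
      "Sc-ACA" = list(collagen_amp = 0.35, pg_amp = 0.18, lag_layers = 4,
                      length_mean = 55, length_sd = 10, width_px = 3,
                      orientation_kappa = 1.5, curvature_amp = 0.15),
      "Sc-Ctr" = list(collagen_amp = 0.37, pg_amp = 0.28, lag_layers = -4,
                      length_mean = 55, length_sd = 10, width_px = 3,
                      orientation_kappa = 1.5, curvature_amp = 0.15),
      "Ad-ACA" = list(collagen_amp = 0.50, pg_amp = 0.30, lag_layers = -4,
                      length_mean = 88, length_sd = 12, width_px = 3,
                      orientation_kappa = 25, curvature_amp = 0.04),
      "Ad-Ctr" = list(collagen_amp = 0.45, pg_amp = 0.28, lag_layers = -4,
                      length_mean = 70, length_sd = 12, width_px = 3,
                      orientation_kappa = 8, curvature_amp = 0.10),
      "Un" = un)
  }
  score_probs <- if (null_effects) {
    list(Ctr = rep(0.2, 5), ACA = rep(0.2, 5))
  } else {
    # mild shifts for depth/opacity/edema/fibrosis, strong separation for
    # vascularization and inflammation (the study's significant parameters)
    mild_ctr <- c(0.30, 0.30, 0.20, 0.15, 0.05)
    mild_aca <- c(0.10, 0.20, 0.25, 0.25, 0.20)
    strong_ctr <- c(0.55, 0.30, 0.10, 0.05, 0.00)
    strong_aca <- c(0.00, 0.05, 0.15, 0.35, 0.45)
    params <- c("depth", "opacity", "edema", "vascularization", "fibrosis",
                "inflammation")
    ctr <- rbind(mild_ctr, mild_ctr, mild_ctr, strong_ctr, mild_ctr,
                 strong_ctr)
    aca <- rbind(mild_aca, mild_aca, mild_ctr, strong_aca, mild_aca,
                 strong_aca)
    rownames(ctr) <- rownames(aca) <- params
    list(Ctr = ctr, ACA = aca)
  }
  structure(list(n_layers = n_layers, rois_per_region = rois_per_region,
                 image_size = image_size, n_fibers = n_fibers,
                 spectra_noise_sd = spectra_noise_sd,
                 background_noise_sd = background_noise_sd,
                 regions = regions, score_probs = score_probs,
                 jitter = list(amp_frac = 0.04, length_frac = 0.06,
                               kappa_frac = 0.15, midpoint_sd = 0.5),
                 null_effects = null_effects),
            class = "demo_config")
}

new_sub_seed <- function() sample.int(.Machine$integer.max - 1, 1)

#' Generate a complete synthetic demo study
#'
#' Builds the full study layout (6 ACA + 4 Ctr injured eyes with Sc and Ad
#' regions, 10 Un eyes with an Un region): per eye-region a depth-resolved
#' spectral series and `rois_per_region` fibril images, all with per-eye
#' parameter jitter around the planted region-group settings, plus one
#' ordinal score table for the injured eyes. With `dir` given, everything
#' is also written to disk (CSV spectra, PNG images, CSV scores and ground
#' truth, a manifest and a resolved YAML config copy).
#'
#' @param seed Integer seed driving every random choice.
#' @param config A [demo_config()].
#' @param dir Optional output directory (created if missing).
#' @param include_spectra,include_fibrils,include_scores Logical switches
#'   for the three data modalities.
#' @param fibril_mode `"render"` (rasterize images; default) or
#'   `"ground_truth"` (keep only sampled centerline ground truth - used for
#'   fast statistical calibration runs).
#' @return An object of class `study_layout`.
#' @export
make_demo_study <- function(seed = 1, config = demo_config(), dir = NULL,
                            include_spectra = TRUE, include_fibrils = TRUE,
                            include_scores = TRUE,
                            fibril_mode = c("render", "ground_truth")) {
  fibril_mode <- match.arg(fibril_mode)
  set.seed(seed)
  eyes <- data.frame(
    eye_id = c(sprintf("ACA%02d", 1:6), sprintf("CTR%02d", 1:4),
               sprintf("UN%02d", 1:10)),
    group = c(rep("ACA", 6), rep("Ctr", 4), rep("Un", 10)))
  units <- do.call(rbind, lapply(seq_len(nrow(eyes)), function(i) {
    regs <- if (eyes$group[i] == "Un") "Un" else c("Sc", "Ad")
    data.frame(eye_id = eyes$eye_id[i], group = eyes$group[i], region = regs)
  }))
  units$region_group <- ifelse(units$group == "Un", "Un",
                               paste(units$region, units$group, sep = "-"))
  data <- list()
  jt <- config$jitter
  for (i in seq_len(nrow(units))) {
    rg <- units$region_group[i]
    pars <- config$regions[[rg]]
    unit <- list()
    if (include_spectra) {
      bands <- default_sim_bands()
      bands$amplitude[bands$name == "collagen"] <-
        pars$collagen_amp * exp(stats::rnorm(1, 0, jt$amp_frac))
      bands$amplitude[bands$name == "pg"] <-
        pars$pg_amp * exp(stats::rnorm(1, 0, jt$amp_frac))
      mid <- (config$n_layers + 1) / 2 + stats::rnorm(1, 0, jt$midpoint_sd)
      profiles <- list(
        collagen = list(type = "sigmoid", lo = 0.7, hi = 1.3,
                        midpoint = mid, rate = 2),
        pg = list(type = "sigmoid", lo = 0.7, hi = 1.3,
                  midpoint = mid, rate = 2))
      scfg <- spectral_sim_config(
        n_layers = config$n_layers, bands = bands,
        depth_profiles = profiles, lag_layers = pars$lag_layers,
        noise_sd = config$spectra_noise_sd, seed = new_sub_seed())
      unit$spectra <- generate_depth_series(scfg)
    }
    if (include_fibrils) {
      unit$fibrils <- lapply(seq_len(config$rois_per_region), function(r) {
        fcfg <- fibril_sim_config(
          image_size = config$image_size, n_fibers = config$n_fibers,
          length_mean = pars$length_mean * exp(stats::rnorm(1, 0, jt$length_frac)),
          length_sd = pars$length_sd, width_px = pars$width_px,
          orientation_mu = stats::runif(1, 0, pi),
          orientation_kappa = pars$orientation_kappa *
            exp(stats::rnorm(1, 0, jt$kappa_frac)),
          curvature_amp = pars$curvature_amp,
          background_noise_sd = config$background_noise_sd,
          seed = new_sub_seed())
        if (fibril_mode == "render") {
          generate_fibril_image(fcfg)
        } else {
          set.seed(fcfg$seed)
          paths <- sample_fiber_paths(fcfg)
          list(image = NULL,
               ground_truth = ground_truth_from_paths(paths, fcfg$width_px),
               paths = paths, config = fcfg)
        }
      })
    }
    data[[paste(units$eye_id[i], units$region[i], sep = "|")]] <- unit
  }
  scores <- NULL
  if (include_scores) {
    sc_cfg <- score_sim_config(n_ctr = 4, n_aca = 6,
                               grade_probs = config$score_probs,
                               seed = new_sub_seed())
    scores <- generate_scores(sc_cfg)
  }
  layout <- structure(list(units = units, data = data, scores = scores,
                           config = config, seed = seed,
                           fibril_mode = fibril_mode),
                      class = "study_layout")
  if (!is.null(dir)) write_study_layout(layout, dir)
  layout
}

#' @export
print.study_layout <- function(x, ...) {
  cat(sprintf("<study_layout> %d eyes, %d eye-region units, seed %d\n",
              length(unique(x$units$eye_id)), nrow(x$units), x$seed))
  invisible(x)
}

#' Write a study layout to disk
#'
#' Spectra as CSV matrices, images as 8-bit PNG, per-image ground truth as
#' CSV (fiber id, vertex list, width), scores as CSV, plus `manifest.csv`
#' and a resolved `config.yaml`.
#'
#' @param layout A `study_layout` (with in-memory data).
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_study_layout <- function(layout, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- layout$units
  manifest$spectra_path <- NA_character_
  manifest$image_paths <- NA_character_
  for (i in seq_len(nrow(manifest))) {
    key <- paste(manifest$eye_id[i], manifest$region[i], sep = "|")
    unit <- layout$data[[key]]
    stem <- paste(manifest$eye_id[i], manifest$region[i], sep = "_")
    if (!is.null(unit$spectra)) {
      p <- file.path(dir, paste0(stem, "_spectra.csv"))
      write_spectral_series(unit$spectra$series, p)
      manifest$spectra_path[i] <- basename(p)
    }
    if (!is.null(unit$fibrils)) {
      imgs <- character(0)
      for (r in seq_along(unit$fibrils)) {
        roi <- unit$fibrils[[r]]
        if (!is.null(roi$image)) {
          p <- file.path(dir, sprintf("%s_roi%02d.png", stem, r))
          write_fibril_image(roi$image, p)
          imgs <- c(imgs, basename(p))
        }
        gt <- roi$ground_truth
        if (!is.null(gt) && nrow(gt)) {
          gt$vertices <- vapply(roi$paths, function(p2) {
            paste(sprintf("%.2f %.2f", p2[, 1], p2[, 2]), collapse = ";")
          }, character(1))
          utils::write.csv(gt, file.path(
            dir, sprintf("%s_roi%02d_truth.csv", stem, r)), row.names = FALSE)
        }
      }
      manifest$image_paths[i] <- paste(imgs, collapse = ";")
    }
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  if (!is.null(layout$scores)) {
    write_score_table(layout$scores, file.path(dir, "scores.csv"))
  }
  cfg <- layout$config
  cfg$regions <- lapply(cfg$regions, function(x) lapply(x, as.vector))
  cfg$score_probs <- lapply(cfg$score_probs, function(m) {
    if (is.matrix(m)) apply(m, 1, as.vector, simplify = FALSE) else as.vector(m)
  })
  yaml::write_yaml(list(seed = layout$seed, fibril_mode = layout$fibril_mode,
                        config = cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a study layout back from disk
#'
#' Reconstructs an in-memory `study_layout` from a directory written by
#' [write_study_layout()] (spectra, rendered images, scores).
#'
#' @param dir Directory containing `manifest.csv`.
#' @return A `study_layout`.
#' @export
read_study_layout <- function(dir) {
  mf_path <- file.path(dir, "manifest.csv")
  if (!file.exists(mf_path)) stop("no manifest.csv in ", dir)
  manifest <- utils::read.csv(mf_path)
  data <- list()
  problems <- character(0)
  for (i in seq_len(nrow(manifest))) {
    key <- paste(manifest$eye_id[i], manifest$region[i], sep = "|")
    unit <- list()
    if (!is.na(manifest$spectra_path[i]) && nzchar(manifest$spectra_path[i])) {
      p <- file.path(dir, manifest$spectra_path[i])
      if (file.exists(p)) {
        unit$spectra <- list(series = read_spectral_series(p))
      } else {
        problems <- c(problems, paste("missing spectra file:", p))
      }
    }
    if (!is.na(manifest$image_paths[i]) && nzchar(manifest$image_paths[i])) {
      imgs <- strsplit(manifest$image_paths[i], ";")[[1]]
      unit$fibrils <- list()
      for (fn in imgs) {
        p <- file.path(dir, fn)
        if (file.exists(p)) {
          unit$fibrils[[length(unit$fibrils) + 1]] <-
            list(image = read_fibril_image(p))
        } else {
          problems <- c(problems, paste("missing image file:", p))
        }
      }
    }
    data[[key]] <- unit
  }
  if (length(problems)) {
    stop("study layout incomplete:\n  ", paste(problems, collapse = "\n  "))
  }
  scores <- NULL
  sp <- file.path(dir, "scores.csv")
  if (file.exists(sp)) scores <- read_score_table(sp)
  cfg <- NULL; seed <- NA_integer_
  cp <- file.path(dir, "config.yaml")
  if (file.exists(cp)) {
    y <- yaml::read_yaml(cp)
    seed <- y$seed
  }
  units <- manifest[, c("eye_id", "group", "region", "region_group")]
  structure(list(units = units, data = data, scores = scores,
                 config = cfg, seed = seed, fibril_mode = "render"),
            class = "study_layout")
}

gt_roi_summary <- function(gt) {
  if (is.null(gt) || nrow(gt) == 0) {
    return(data.frame(n_fibers = 0, mean_length = NA_real_,
                      mean_width = NA_real_, mean_straightness = NA_real_,
                      anisotropy = NA_real_))
  }
  th <- gt$orientation
  data.frame(n_fibers = nrow(gt), mean_length = mean(gt$length_px),
             mean_width = mean(gt$width_px),
             mean_straightness = mean(gt$straightness),
             anisotropy = sqrt(mean(cos(2 * th))^2 + mean(sin(2 * th))^2))
}

#' Run the full study analysis
#'
#' Executes the complete analysis chain on a study layout: per eye-region
#' FTIR composition (coadd, Gaussian deconvolution, collagen/amide II and
#' PG/amide II ratios), per region-group depth two-dimensional correlation
#' with a Noda sequencing call on the 1338/1064 cm^-1 cross-peak, per
#' eye-region fibril morphometry (ROI means averaged per eye), one-way
#' ANOVA + Tukey HSD of every parameter across the five region-groups, and
#' Mann-Whitney comparisons of the ordinal scores. Per-unit failures are
#' flagged in the output tables, never dropped silently. Given a fixed
#' layout the result is deterministic.
#'
#' @param layout A `study_layout`.
#' @param min_fiber_length Minimum traced fiber length in pixels
#'   (default 10).
#' @return An object of class `study_report` with data-frame elements
#'   `composition`, `twodcs`, `morphometry`, `anova` (plus `anova_fits`),
#'   `score_stats`, and a `provenance` list.
#' @export
run_study <- function(layout, min_fiber_length = 10) {
  stopifnot(inherits(layout, "study_layout"))
  units <- layout$units
  comp_rows <- list()
  morph_rows <- list()
  for (i in seq_len(nrow(units))) {
    key <- paste(units$eye_id[i], units$region[i], sep = "|")
    unit <- layout$data[[key]]
    if (!is.null(unit$spectra)) {
      res <- tryCatch(
        fit_composition(coadd(unit$spectra$series),
                        region_label = units$region_group[i]),
        error = function(e) e)
      if (inherits(res, "error")) {
        comp_rows[[key]] <- data.frame(
          eye_id = units$eye_id[i], group = units$group[i],
          region = units$region[i], region_group = units$region_group[i],
          collagen_ratio = NA_real_, pg_ratio = NA_real_,
          rms = NA_real_, converged = FALSE,
          flags = paste0("fit_error: ", conditionMessage(res)))
      } else {
        comp_rows[[key]] <- data.frame(
          eye_id = units$eye_id[i], group = units$group[i],
          region = units$region[i], region_group = units$region_group[i],
          collagen_ratio = res$composition$collagen_ratio,
          pg_ratio = res$composition$pg_ratio,
          rms = max(vapply(res$models, function(m) m$diagnostics$rms,
                           numeric(1))),
          converged = res$converged,
          flags = if (res$converged) "" else "non_converged_fit")
      }
    }
    if (!is.null(unit$fibrils)) {
      roi_rows <- lapply(unit$fibrils, function(roi) {
        if (!is.null(roi$image)) {
          r <- roi_morphometry(roi$image, region_label = units$region_group[i],
                               min_length = min_fiber_length)
          r[, c("n_fibers", "mean_length", "mean_width",
                "mean_straightness", "anisotropy")]
        } else {
          gt_roi_summary(roi$ground_truth)
        }
      })
      roi_df <- do.call(rbind, roi_rows)
      morph_rows[[key]] <- data.frame(
        eye_id = units$eye_id[i], group = units$group[i],
        region = units$region[i], region_group = units$region_group[i],
        n_rois = nrow(roi_df),
        n_fibers = sum(roi_df$n_fibers),
        mean_length = mean(roi_df$mean_length, na.rm = TRUE),
        mean_width = mean(roi_df$mean_width, na.rm = TRUE),
        mean_straightness = mean(roi_df$mean_straightness, na.rm = TRUE),
        anisotropy = mean(roi_df$anisotropy, na.rm = TRUE))
    }
  }
  composition <- if (length(comp_rows)) {
    do.call(rbind, c(comp_rows, list(make.row.names = FALSE)))
  } else NULL
  morphometry <- if (length(morph_rows)) {
    do.call(rbind, c(morph_rows, list(make.row.names = FALSE)))
  } else NULL

  # depth 2D correlation per region-group on the eye-averaged series
  twodcs_rows <- list()
  for (rg in unique(units$region_group)) {
    keys <- paste(units$eye_id[units$region_group == rg],
                  units$region[units$region_group == rg], sep = "|")
    mats <- list(); wn <- NULL
    for (key in keys) {
      sp <- layout$data[[key]]$spectra
      if (!is.null(sp)) {
        mats[[length(mats) + 1]] <- sp$series$absorbance
        wn <- sp$series$wavenumbers
      }
    }
    if (!length(mats)) next
    avg <- Reduce(`+`, mats) / length(mats)
    series <- ftir_series(wn, avg)
    maps <- correlation_maps(series)
    cp <- extract_cross_peak(maps)
    sq <- sequencing_call(cp)
    twodcs_rows[[rg]] <- data.frame(
      region_group = rg, n_eyes = length(mats), nu1 = cp$nu1, nu2 = cp$nu2,
      phi = cp$phi, psi = cp$psi, direction = sq$direction,
      order = sq$order)
  }
  twodcs <- if (length(twodcs_rows)) {
    do.call(rbind, c(twodcs_rows, list(make.row.names = FALSE)))
  } else NULL

  # group statistics across the five region-groups (eye-level values)
  anova_rows <- list(); anova_fits <- list()
  stat_source <- list()
  if (!is.null(morphometry)) {
    for (p in c("mean_length", "mean_width", "mean_straightness",
                "anisotropy")) {
      stat_source[[p]] <- morphometry[, c("region_group", p)]
    }
  }
  if (!is.null(composition)) {
    for (p in c("collagen_ratio", "pg_ratio")) {
      stat_source[[p]] <- composition[, c("region_group", p)]
    }
  }
  for (p in names(stat_source)) {
    df <- stat_source[[p]]
    ok <- is.finite(df[[p]])
    res <- tryCatch(anova_tukey(df[[p]][ok], df$region_group[ok]),
                    error = function(e) e)
    if (inherits(res, "error")) {
      anova_rows[[p]] <- data.frame(parameter = p, f = NA_real_,
                                    df_between = NA, df_within = NA,
                                    p = NA_real_,
                                    flags = conditionMessage(res))
    } else {
      anova_fits[[p]] <- res
      anova_rows[[p]] <- data.frame(parameter = p, f = res$f,
                                    df_between = res$df_between,
                                    df_within = res$df_within, p = res$p,
                                    flags = "")
    }
  }
  anova <- if (length(anova_rows)) {
    do.call(rbind, c(anova_rows, list(make.row.names = FALSE)))
  } else NULL

  score_stats <- NULL
  if (!is.null(layout$scores)) {
    rows <- list()
    for (p in unique(layout$scores$parameter)) {
      sub <- layout$scores[layout$scores$parameter == p, ]
      ctr <- sub$grade[sub$group == "Ctr"]
      aca <- sub$grade[sub$group == "ACA"]
      mw <- mann_whitney(ctr, aca)
      rows[[p]] <- data.frame(parameter = p, u = mw$u, z = mw$z, p = mw$p,
                              mean_rank_ctr = mw$mean_rank_a,
                              mean_rank_aca = mw$mean_rank_b,
                              n_ctr = mw$n_a, n_aca = mw$n_b)
    }
    score_stats <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }

  structure(list(composition = composition, twodcs = twodcs,
                 morphometry = morphometry, anova = anova,
                 anova_fits = anova_fits, score_stats = score_stats,
                 provenance = list(seed = layout$seed,
                                   fibril_mode = layout$fibril_mode,
                                   n_units = nrow(units),
                                   package_version =
                                     as.character(utils::packageVersion("stromaspec")))),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  if (!is.null(x$anova)) {
    cat("ANOVA across region-groups:\n")
    print(x$anova, row.names = FALSE)
  }
  if (!is.null(x$twodcs)) {
    cat("Depth 2D-correlation sequencing calls:\n")
    print(x$twodcs[, c("region_group", "phi", "psi", "direction", "order")],
          row.names = FALSE)
  }
  if (!is.null(x$score_stats)) {
    cat("Mann-Whitney score comparisons (Ctr vs ACA):\n")
    print(x$score_stats, row.names = FALSE)
  }
  invisible(x)
}

#' Write the study report tables as CSV files
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("composition", "twodcs", "morphometry", "anova",
               "score_stats")) {
    if (!is.null(report[[nm]])) {
      utils::write.csv(report[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  if (length(report$anova_fits)) {
    tk <- do.call(rbind, lapply(names(report$anova_fits), function(p) {
      cbind(parameter = p, report$anova_fits[[p]]$tukey)
    }))
    utils::write.csv(tk, file.path(dir, "tukey.csv"), row.names = FALSE)
  }
  yaml::write_yaml(report$provenance, file.path(dir, "provenance.yaml"))
  invisible(dir)
}
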