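#' Write / read a plain key = value configuration file
#'
#' One `key = value` pair per line; blank lines and `#` comments are
#' ignored on read. Values are parsed back to numeric / logical where
#' possible so a config round-trips losslessly.
#'
#' @param kv named list of scalar values.
#' @param path file path.
#' @return `write_config_file`: `path`, invisibly. `read_config_file`:
#'   named list.
#' @export
write_config_file <- function(kv, path) {
  lines <- vapply(names(kv), function(k) {
    v <- kv[[k]]
    paste0(k, " = ", paste(format(v, digits = 17, scientific = FALSE,
                                  trim = TRUE), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config_file
#' @export
read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(m) != 3L) stop("malformed config line: ", ln)
    key <- trimws(m[2]); val <- trimws(m[3])
    parts <- trimws(strsplit(val, ",")[[1]])
    num <- suppressWarnings(as.numeric(parts))
    parsed <- if (!anyNA(num)) num
              else if (all(parts %in% c("TRUE", "FALSE"))) as.logical(parts)
              else parts
    out[[key]] <- parsed
  }
  out
}

#' Configuration for one pipeline run
#'
#' Bundles everything one sample run needs: the input (a phantom
#' configuration or a TIFF path), the threshold method, morphometry
#' parameters and the output location. Every parameter has a documented
#' default, so `run_config()` with no arguments describes a complete run.
#'
#' @param phantom a [phantom_config()] (used when `input_tiff` is `NULL`).
#' @param input_tiff optional path to a multi-page grayscale TIFF to
#'   analyse instead of a phantom.
#' @param voxel_size voxel edge, micrometres (for TIFF input).
#' @param threshold `"isodata"`, `"minimum"` or `"fixed"`.
#' @param fixed_t threshold value when `threshold = "fixed"`.
#' @param close_radius leaf-mask closing radius, voxels.
#' @param connectivity component connectivity for cavity detection.
#' @param cavity_min_volume_um3 minimum sub-stomatal cavity volume.
#' @param cavity_surface surface searched for cavities.
#' @param cavity_band_um sub-epidermal search band width, micrometres.
#' @param match_radius_um stoma-to-cavity lateral matching radius.
#' @param spongy_band,palisade_band fractional-depth bands for layer-slice
#'   selection (`NULL` to skip).
#' @param out_dir output directory (`NULL`: nothing is written).
#' @param seed integer seed governing phantom generation and rendering.
#' @param sample_id label used in outputs and error messages.
#' @return List of class `run_config`.
#' @export
run_config <- function(phantom = phantom_config(), input_tiff = NULL,
                       voxel_size = 2.75, threshold = "isodata",
                       fixed_t = NULL, close_radius = 2, connectivity = 26L,
                       cavity_min_volume_um3 = 8000,
                       cavity_surface = "abaxial", cavity_band_um = 15,
                       match_radius_um = 30, spongy_band = c(0.5, 1),
                       palisade_band = NULL, out_dir = NULL, seed = 1L,
                       sample_id = "sample") {
  structure(list(phantom = phantom, input_tiff = input_tiff,
                 voxel_size = voxel_size, threshold = threshold,
                 fixed_t = fixed_t, close_radius = close_radius,
                 connectivity = connectivity,
                 cavity_min_volume_um3 = cavity_min_volume_um3,
                 cavity_surface = cavity_surface,
                 cavity_band_um = cavity_band_um,
                 match_radius_um = match_radius_um,
                 spongy_band = spongy_band, palisade_band = palisade_band,
                 out_dir = out_dir, seed = as.integer(seed),
                 sample_id = sample_id),
            class = "run_config")
}

.stage <- function(config, stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s | %s] %s", config$sample_id, stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full quantification pipeline on one sample
#'
#' Phantom (or TIFF) -> leaf mask -> tissue threshold -> airspace (XOR) ->
#' porosity profile, total porosity, exposed surface area, sub-stomatal
#' cavities, layer slices. Deterministic given `(config, seed)`. When
#' `out_dir` is set, writes the profile, cavity and summary CSVs plus the
#' three mask TIFF stacks.
#'
#' @param config a [run_config()].
#' @return List of class `sample_result`: `summary` (one-row data frame),
#'   `profile`, `cavities`, `stoma_match`, the three masks, and `truth`
#'   when the input was a phantom.
#' @export
run_sample <- function(config) {
  stopifnot(inherits(config, "run_config"))
  truth <- NULL
  if (is.null(config$input_tiff)) {
    truth <- .stage(config, "phantom",
                    build_label_volume(config$phantom, seed = config$seed))
    volume <- .stage(config, "render",
                     render_grayscale(truth, config$phantom,
                                      seed = config$seed + 1L))
    epi_um <- config$phantom$epidermis_thickness
  } else {
    volume <- .stage(config, "read",
                     read_volume_tiff(config$input_tiff,
                                      voxel_size = config$voxel_size))
    epi_um <- NA_real_
  }
  leaf <- .stage(config, "leaf_mask",
                 make_leaf_mask(volume, method = config$threshold,
                                fixed_t = config$fixed_t,
                                close_radius = config$close_radius))
  tissue <- .stage(config, "threshold",
                   segment_tissue(volume, leaf, method = config$threshold,
                                  fixed_t = config$fixed_t))
  airspace <- .stage(config, "xor", extract_airspace(leaf, tissue))
  profile <- .stage(config, "profile", porosity_profile(airspace, leaf))
  total <- .stage(config, "porosity", total_porosity(airspace, leaf))
  sa <- .stage(config, "surface_area", surface_area(tissue, airspace))

  cavities <- NULL; stoma_match <- NULL
  frac <- NA_real_; n_cav <- NA_integer_
  if (!is.na(epi_um)) {
    cavities <- .stage(config, "cavities",
                       detect_cavities(airspace, leaf, epi_um,
                                       min_volume_um3 = config$cavity_min_volume_um3,
                                       surface = config$cavity_surface,
                                       band_width_um = config$cavity_band_um,
                                       connectivity = config$connectivity))
    n_cav <- nrow(cavities)
    if (!is.null(truth) && nrow(truth$stoma_sites) > 0L) {
      sites <- truth$stoma_sites[truth$stoma_sites$surface == config$cavity_surface, ]
      if (nrow(sites) > 0L) {
        stoma_match <- .stage(config, "stoma_match",
                              match_cavities_to_stomata(cavities, sites,
                                                        config$match_radius_um))
        frac <- attr(stoma_match, "fraction_subtended")
      }
    }
  }

  spongy_idx <- if (!is.null(config$spongy_band))
    select_spongy_slice(profile, config$spongy_band) else NA_integer_
  palisade_idx <- if (!is.null(config$palisade_band))
    select_palisade_slice(profile, config$palisade_band) else NA_integer_

  summary_row <- data.frame(
    sample_id = config$sample_id,
    seed = config$seed,
    total_porosity_pct = total,
    sa_total_um2 = sa$total_um2,
    sa_per_tissue_volume = sa$per_tissue_volume,
    sa_per_leaf_area = sa$per_leaf_area,
    n_cavities = n_cav,
    stoma_cavity_fraction = frac,
    spongy_slice = spongy_idx,
    spongy_porosity_pct = if (!is.na(spongy_idx))
      profile$porosity_pct[spongy_idx] else NA_real_,
    palisade_slice = palisade_idx,
    palisade_porosity_pct = if (!is.na(palisade_idx))
      profile$porosity_pct[palisade_idx] else NA_real_)

  result <- structure(list(summary = summary_row, profile = profile,
                           cavities = cavities, stoma_match = stoma_match,
                           leaf = leaf, tissue = tissue, airspace = airspace,
                           truth = truth, config = config),
                      class = "sample_result")
  if (!is.null(config$out_dir)) .write_sample_outputs(result)
  result
}

.write_sample_outputs <- function(result) {
  cfg <- result$config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(cfg$out_dir, cfg$sample_id)
  write.csv(result$profile, paste0(base, "_profile.csv"), row.names = FALSE)
  if (!is.null(result$cavities))
    write.csv(result$cavities, paste0(base, "_cavities.csv"), row.names = FALSE)
  write.csv(result$summary, paste0(base, "_summary.csv"), row.names = FALSE)
  write_volume_tiff(result$leaf, paste0(base, "_leaf_mask.tif"))
  write_volume_tiff(result$tissue, paste0(base, "_tissue_mask.tif"))
  write_volume_tiff(result$airspace, paste0(base, "_airspace_mask.tif"))
  invisible(base)
}

#' Run a cohort of samples and compute line-level statistics
#'
#' Runs [run_sample()] on every configuration, joins the per-sample rows
#' with their line assignment and optional gas-exchange measurements, and
#' computes (i) the line-mean correlation of porosity versus gs (the
#' convention used for line-level scatter plots), (ii) the same correlation
#' over individual sample pairs, and (iii) one-way ANOVA with Tukey letters
#' across lines for porosity. Every statistic is recomputable from the
#' per-sample table alone.
#'
#' @param configs list of [run_config()] objects.
#' @param lines character vector assigning each config to a line.
#' @param gas optional data frame with columns `sample_id`, `gs`, `A400`;
#'   iWUE is derived as `A400 / gs`.
#' @return List of class `cohort_report`: `samples` (per-sample rows with
#'   line and gas columns), `line_means`, `cor_line_means`, `cor_samples`,
#'   `anova_porosity`, `tukey_porosity`, `profiles`.
#' @export
run_cohort <- function(configs, lines, gas = NULL) {
  stopifnot(is.list(configs), length(configs) == length(lines))
  results <- lapply(configs, run_sample)
  samples <- do.call(rbind, lapply(results, `[[`, "summary"))
  samples$line <- as.character(lines)
  if (!is.null(gas)) {
    stopifnot(all(c("sample_id", "gs", "A400") %in% names(gas)))
    samples <- merge(samples, gas[, c("sample_id", "gs", "A400")],
                     by = "sample_id", sort = FALSE)
    samples$iwue <- iwue(samples$A400, samples$gs)
  }
  samples <- samples[order(samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  profiles <- lapply(results, `[[`, "profile")
  names(profiles) <- vapply(results, function(r) r$summary$sample_id, character(1))
  cohort_stats(samples, profiles = profiles)
}

#' Cohort statistics from a per-sample summary table
#'
#' The statistical half of [run_cohort()], usable directly on a per-sample
#' data frame (columns `sample_id`, `line`, `total_porosity_pct` and
#' optionally `gs`).
#'
#' @param samples per-sample data frame.
#' @param profiles optional named list of porosity profiles.
#' @return A `cohort_report` list.
#' @export
cohort_stats <- function(samples, profiles = NULL) {
  has_gs <- "gs" %in% names(samples) && !all(is.na(samples$gs))
  line_means <- do.call(rbind, lapply(split(samples, samples$line), function(d) {
    data.frame(line = d$line[1],
               porosity_pct = mean(d$total_porosity_pct),
               gs = if (has_gs) mean(d$gs) else NA_real_,
               n = nrow(d))
  }))
  line_means <- line_means[order(line_means$line), , drop = FALSE]
  rownames(line_means) <- NULL

  cor_line <- NULL; cor_samp <- NULL
  if (has_gs) {
    if (nrow(line_means) >= 3L)
      cor_line <- tryCatch(pearson_test(line_means$porosity_pct, line_means$gs),
                           error = function(e) NULL)
    if (nrow(samples) >= 3L)
      cor_samp <- tryCatch(pearson_test(samples$total_porosity_pct, samples$gs),
                           error = function(e) NULL)
  }
  groups <- split(samples$total_porosity_pct, samples$line)
  anova_por <- NULL; tukey_por <- NULL
  if (length(groups) >= 2L && all(lengths(groups) >= 2L)) {
    anova_por <- tryCatch(oneway_anova(groups), error = function(e) NULL)
    tukey_por <- tryCatch(tukey_hsd(groups), error = function(e) NULL)
  }
  structure(list(samples = samples, line_means = line_means,
                 cor_line_means = cor_line, cor_samples = cor_samp,
                 anova_porosity = anova_por, tukey_porosity = tukey_por,
                 profiles = profiles),
            class = "cohort_report")
}

#' Write cohort figures
#'
#' Porosity-versus-depth profiles (one curve per sample, coloured by line)
#' and the line-mean porosity versus gs scatter, both as vector PDF files.
#' Purely presentational.
#'
#' @param report a `cohort_report`.
#' @param dir output directory.
#' @return Character vector of written paths, invisibly.
#' @export
make_figures <- function(report, dir) {
  stopifnot(inherits(report, "cohort_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (!is.null(report$profiles) && length(report$profiles) > 0L) {
    prof <- do.call(rbind, lapply(names(report$profiles), function(id) {
      p <- report$profiles[[id]]
      line <- report$samples$line[match(id, report$samples$sample_id)]
      data.frame(sample_id = id, line = line, depth_um = p$depth_um,
                 porosity_pct = p$porosity_pct)
    }))
    g <- ggplot2::ggplot(prof[!is.na(prof$porosity_pct), ],
                         ggplot2::aes(x = .data$depth_um, y = .data$porosity_pct,
                                      group = .data$sample_id,
                                      colour = .data$line)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "Depth from adaxial surface (µm)",
                    y = "Mesophyll porosity (%)", colour = "Line") +
      ggplot2::theme_minimal()
    f <- file.path(dir, "porosity_profiles.pdf")
    ggplot2::ggsave(f, g, width = 6, height = 4, device = grDevices::pdf)
    paths <- c(paths, f)
  }
  lm <- report$line_means
  if (!all(is.na(lm$gs))) {
    g2 <- ggplot2::ggplot(lm, ggplot2::aes(x = .data$porosity_pct, y = .data$gs)) +
      ggplot2::geom_point(size = 2) +
      ggplot2::labs(x = "Mean mesophyll porosity (%)",
                    y = expression(g[s] ~ (mol ~ m^-2 ~ s^-1))) +
      ggplot2::theme_minimal()
    f2 <- file.path(dir, "porosity_vs_gs.pdf")
    ggplot2::ggsave(f2, g2, width = 5, height = 4, device = grDevices::pdf)
    paths <- c(paths, f2)
  }
  invisible(paths)
}
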