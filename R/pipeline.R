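# End-to-end pipeline runs and the command-line dispatch.

#' Run the full study pipeline on the synthetic fixture
#'
#' Generates the paired imaging + mapping fixture, segments the rendered
#' scenes and extracts image traits, computes per-line least-square
#' means, the trait correlation matrix and the residual-variance F test,
#' scans both traits for QTL with permutation thresholds, and writes
#' every result as a deterministic CSV under `out_dir`.
#'
#' @param seed Integer RNG seed driving the fixture and the permutation
#'   thresholds.
#' @param out_dir Output directory (created if absent).
#' @param config A [pipeline_config()].
#' @param n_scenes Number of scenes rendered and segmented.
#' @return Invisibly, a list with the in-memory results (`fixture`,
#'   `imaging`, `line_means`, `correlations`, `ftest`, `scans`,
#'   `thresholds`, `peaks`, `files`).
#' @export
run_study <- function(seed, out_dir, config = pipeline_config(), n_scenes = 16) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  digest <- config_digest(config)
  fx <- generate_study_fixture(seed, n_scenes = n_scenes)

  # imaging stage: segment every scene, compare to rendered ground truth
  imaging <- do.call(rbind, lapply(seq_along(fx$scenes), function(i) {
    sc <- fx$scenes[[i]]
    mask <- segment_plant(sc$image, config$segmentation)
    tp <- sum(mask & sc$truth_mask)
    f1 <- if (tp == 0) 0 else 2 * tp / (sum(mask) + sum(sc$truth_mask))
    data.frame(scene = i,
               line_id = fx$scene_info$line_id[i],
               replicate = fx$scene_info$replicate[i],
               ph_px = suppressWarnings(projected_height(mask)),
               area_px = pixel_area(mask),
               truth_ph_px = sc$truth_base_row - sc$truth_tip_row + 1L,
               truth_area_px = sc$truth_area_px,
               f1 = f1, stringsAsFactors = FALSE)
  }))

  ph_records <- data.frame(line_id = imaging$line_id,
                           replicate = imaging$replicate,
                           trait = "PH_px", value = as.numeric(imaging$ph_px),
                           stringsAsFactors = FALSE)
  records <- rbind(fx$records, ph_records)

  # trait statistics on the population-scale traits
  means_ph <- least_square_means(records, "PH_mm")
  means_fw <- least_square_means(records, "FW_g")
  means <- rbind(means_ph, means_fw)
  correlations <- trait_correlation_matrix(means)
  ftest <- trait_variance_ftest(records, "PH_mm", "FW_g")

  # QTL stage
  probs <- conditional_genotype_probs(fx$map, fx$genotypes,
                                      step_cM = config$qtl$step_cM)
  scans <- list(); thresholds <- list(); peaks <- list()
  for (tr in c("PH_mm", "FW_g")) {
    lm_tr <- if (tr == "PH_mm") means_ph else means_fw
    scans[[tr]] <- interval_mapping_scan(probs, lm_tr, trait = tr)
    thresholds[[tr]] <- permutation_threshold(
      probs, lm_tr, trait = tr, n_perm = config$qtl$n_perm,
      alpha = config$qtl$alpha, seed = seed + match(tr, c("PH_mm", "FW_g")))
    peaks[[tr]] <- call_qtl_peaks(scans[[tr]], thresholds[[tr]],
                                  drop_lod = config$qtl$drop_lod)
  }
  all_peaks <- do.call(rbind, peaks)
  rownames(all_peaks) <- NULL

  files <- c(
    traits = file.path(out_dir, "traits.csv"),
    imaging = file.path(out_dir, "imaging_report.csv"),
    means = file.path(out_dir, "line_means.csv"),
    correlations = file.path(out_dir, "correlations.csv"),
    ftest = file.path(out_dir, "variance_ftest.csv"),
    scan_ph = file.path(out_dir, "scan_PH_mm.csv"),
    scan_fw = file.path(out_dir, "scan_FW_g.csv"),
    thresholds = file.path(out_dir, "thresholds.csv"),
    peaks = file.path(out_dir, "peaks.csv"))
  write_trait_table(records, files["traits"])
  write_annotated_csv(imaging, files["imaging"], seed, digest)
  write_annotated_csv(means, files["means"], seed, digest)
  write_annotated_csv(correlations, files["correlations"], seed, digest)
  write_annotated_csv(
    data.frame(df1 = ftest$df1, df2 = ftest$df2, f_stat = ftest$f_stat,
               p_value = ftest$p_value), files["ftest"], seed, digest)
  write_annotated_csv(as.data.frame(scans[["PH_mm"]]), files["scan_ph"], seed, digest)
  write_annotated_csv(as.data.frame(scans[["FW_g"]]), files["scan_fw"], seed, digest)
  write_annotated_csv(
    data.frame(trait = names(thresholds),
               alpha = vapply(thresholds, `[[`, 0, "alpha"),
               n_perm = vapply(thresholds, `[[`, 0L, "n_perm"),
               threshold_lod = vapply(thresholds, `[[`, 0, "threshold_lod")),
    files["thresholds"], seed, digest)
  write_annotated_csv(all_peaks, files["peaks"], seed, digest)

  invisible(list(fixture = fx, imaging = imaging, line_means = means,
                 correlations = correlations, ftest = ftest, scans = scans,
                 thresholds = thresholds, peaks = all_peaks, files = files))
}

cli_usage <- function() {
  paste(
    "usage: phenoscan <command> [options]",
    "",
    "commands:",
    "  simulate --seed S --out DIR                 write the synthetic fixture to disk",
    "  segment  --image PNG [--config YML] --out DIR   segment image(s), write mask + traits",
    "  stats    --traits CSV --out DIR             LS means, correlations, variance F test",
    "  scan     --traits CSV --trait NAME --map CSV --geno CSV --seed S --out DIR",
    "           [--n-perm N] [--alpha A] [--step S]    LOD profile, threshold and peaks",
    "  run-all  --seed S --out DIR [--n-perm N]    full fixture pipeline",
    sep = "\n")
}

cli_opt <- function(args, flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 0L) return(default)
  if (i[1] == length(args)) stop("missing value for ", flag, call. = FALSE)
  args[i[1] + 1L]
}

#' Command-line entry point
#'
#' Thin dispatcher behind the `inst/cli/phenoscan.R` script. Exposed as
#' a function so the command surface is testable in-process.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0L) { message(cli_usage()); return(invisible(2L)) }
    cmd <- args[1]; rest <- args[-1]
    out <- cli_opt(rest, "--out", "phenoscan_out")
    seed <- as.integer(cli_opt(rest, "--seed", "1"))
    switch(cmd,
      "simulate" = {
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        fx <- generate_study_fixture(seed)
        write_trait_table(fx$records, file.path(out, "traits.csv"))
        write_map_csv(fx$map, file.path(out, "map.csv"))
        write_genotypes_csv(fx$genotypes, file.path(out, "genotypes.csv"))
        for (i in seq_along(fx$scenes))
          write_image(fx$scenes[[i]]$image,
                      file.path(out, sprintf("scene_%02d.png", i)))
        message("fixture written to ", out)
      },
      "segment" = {
        img_paths <- args[which(args == "--image") + 1L]
        if (length(img_paths) == 0L) stop("segment needs --image", call. = FALSE)
        cfg_path <- cli_opt(rest, "--config")
        cfg <- if (is.null(cfg_path)) pipeline_config() else read_config(cfg_path)
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        entries <- lapply(seq_along(img_paths), function(i)
          list(line_id = tools::file_path_sans_ext(basename(img_paths[i])),
               replicate = 1L, image = img_paths[i]))
        rec <- extract_traits_batch(entries, cfg$segmentation, cfg$mm_per_px)
        for (i in seq_along(img_paths)) {
          mask <- segment_plant(read_image(img_paths[i]), cfg$segmentation)
          write_mask(mask, file.path(out, paste0(
            tools::file_path_sans_ext(basename(img_paths[i])), "_mask.png")))
        }
        write_trait_table(rec, file.path(out, "traits.csv"))
        message("segmented ", length(img_paths), " image(s) into ", out)
      },
      "stats" = {
        rec <- read_trait_table(cli_opt(rest, "--traits"))
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        traits <- unique(rec$trait)
        means <- do.call(rbind, lapply(traits, function(tr)
          least_square_means(rec, tr)))
        write_annotated_csv(means, file.path(out, "line_means.csv"), seed)
        if (length(traits) >= 2) {
          write_annotated_csv(trait_correlation_matrix(means),
                              file.path(out, "correlations.csv"), seed)
          ft <- trait_variance_ftest(rec, traits[1], traits[2])
          write_annotated_csv(
            data.frame(trait_x = traits[1], trait_y = traits[2], df1 = ft$df1,
                       df2 = ft$df2, f_stat = ft$f_stat, p_value = ft$p_value),
            file.path(out, "variance_ftest.csv"), seed)
        }
        message("statistics written to ", out)
      },
      "scan" = {
        alpha <- as.numeric(cli_opt(rest, "--alpha", "0.05"))
        if (alpha <= 0 || alpha >= 1) stop("--alpha must be in (0, 1)", call. = FALSE)
        n_perm <- as.integer(cli_opt(rest, "--n-perm", "1000"))
        step <- as.numeric(cli_opt(rest, "--step", "1"))
        trait <- cli_opt(rest, "--trait")
        if (is.null(trait)) stop("scan needs --trait", call. = FALSE)
        rec <- read_trait_table(cli_opt(rest, "--traits"))
        mg <- read_map_and_genotypes(cli_opt(rest, "--map"), cli_opt(rest, "--geno"))
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        means <- least_square_means(rec, trait)
        probs <- conditional_genotype_probs(mg$map, mg$genotypes, step_cM = step)
        scan <- interval_mapping_scan(probs, means, trait = trait)
        thr <- permutation_threshold(probs, means, trait = trait,
                                     n_perm = n_perm, alpha = alpha, seed = seed)
        pk <- call_qtl_peaks(scan, thr)
        write_annotated_csv(as.data.frame(scan),
                            file.path(out, paste0("scan_", trait, ".csv")), seed)
        write_annotated_csv(
          data.frame(trait = trait, alpha = alpha, n_perm = n_perm,
                     threshold_lod = thr$threshold_lod),
          file.path(out, "thresholds.csv"), seed)
        write_annotated_csv(pk, file.path(out, "peaks.csv"), seed)
        message("scan for ", trait, " written to ", out)
      },
      "run-all" = {
        n_perm <- as.integer(cli_opt(rest, "--n-perm", "1000"))
        cfg <- pipeline_config(n_perm = n_perm, seed = seed)
        run_study(seed, out, cfg)
        message("full pipeline results written to ", out)
      },
      {
        message("unknown command '", cmd, "'\n", cli_usage())
        return(invisible(2L))
      })
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
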