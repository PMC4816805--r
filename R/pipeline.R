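#' @title Pipeline orchestration
#' @name pipeline_cli
#' @description
#' Runs the analysis stages (`simulate` -> `vbm` -> `anova` -> `rsa` ->
#' `report`) in dependency order against a config, writing cluster
#' tables, correlation reports and a run manifest with content checksums
#' so that identical (config, seed) runs are verifiably identical. All
#' randomness flows through explicitly recorded seeds.
NULL

.default_pipeline_config <- function() {
  list(seed = 1L, n_perm = 199L,
       forming_threshold_p = 0.005, connectivity = 18L,
       absolute_threshold = 0.05, smooth_fwhm = 10,
       interest = "bais_vividness",
       sphere = list(center = c(0, 0, 0), radius = 12),
       synth = list())
}

#' Load a pipeline configuration
#'
#' @param config `NULL` (defaults), a YAML file path, or a named list;
#'   supplied keys override the defaults, and entries under `synth`
#'   override [synth_config()] arguments.
#' @return a named list with class `pipeline_config`.
#' @export
load_pipeline_config <- function(config = NULL) {
  base <- .default_pipeline_config()
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(config)) {
    for (nm in names(config)) base[[nm]] <- config[[nm]]
  }
  base$seed <- as.integer(base$seed)
  base$n_perm <- as.integer(base$n_perm)
  structure(base, class = c("pipeline_config", "list"))
}

#' Parse an "x,y,z,r" sphere specification
#'
#' @param spec string like `"0,0,0,12"` (mm).
#' @return list with `center` and `radius`.
#' @export
parse_sphere_spec <- function(spec) {
  v <- as.numeric(strsplit(spec, ",")[[1]])
  if (length(v) != 4 || anyNA(v)) stop("sphere spec must be 'x,y,z,radius'")
  list(center = v[1:3], radius = v[4])
}

.log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the analysis pipeline
#'
#' Executes the requested stages on synthetic data in dependency order,
#' writing under `out_dir`: `cohort.csv`, `gm.nii.gz` and per-condition
#' functional stacks, `truth.json`, the VBM t/Z maps and permutation
#' cluster table, the condition F map and cluster table, per-subject
#' similarity summaries, a correlation report JSON, and
#' `run_manifest.json` with an MD5 checksum of every output.
#'
#' @param config see [load_pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param stages subset of `c("simulate","vbm","anova","rsa","report")`;
#'   earlier stages must have run (this run or a previous one into the
#'   same `out_dir`).
#' @return the run manifest, invisibly.
#' @export
run_pipeline <- function(config = NULL, out_dir,
                         stages = c("simulate", "vbm", "anova", "rsa", "report")) {
  cfg <- load_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scfg <- do.call(synth_config, c(cfg$synth, list(seed = cfg$seed)))
  paths <- list(cohort = file.path(out_dir, "cohort.csv"),
                gm = file.path(out_dir, "gm.nii.gz"),
                func = file.path(out_dir, "func"),
                truth = file.path(out_dir, "truth.json"),
                config = file.path(out_dir, "config.yaml"),
                tmap = file.path(out_dir, "vbm_t.nii.gz"),
                zmap = file.path(out_dir, "vbm_z.nii.gz"),
                vbm_clusters = file.path(out_dir, "vbm_clusters.csv"),
                roi_gm = file.path(out_dir, "vbm_roi_gm.csv"),
                fmap = file.path(out_dir, "anova_f.nii.gz"),
                anova_clusters = file.path(out_dir, "anova_clusters.csv"),
                rsa = file.path(out_dir, "rsa_summaries.csv"),
                report = file.path(out_dir, "report.json"),
                manifest = file.path(out_dir, "run_manifest.json"))

  need <- function(p, stage) {
    if (!file.exists(p))
      stop(sprintf("missing %s: run the '%s' stage first", p, stage), call. = FALSE)
  }

  if ("simulate" %in% stages) {
    .log_stage("simulate", "seed %d: cohort n=%d, structural %s, functional %s",
               cfg$seed, scfg$n_structural,
               paste(scfg$structural_grid$shape, collapse = "x"),
               paste(scfg$functional_grid$shape, collapse = "x"))
    cohort <- gen_cohort(scfg)
    gm <- gen_gm_maps(cohort, scfg)
    fn <- gen_condition_tmaps(cohort, scfg)
    write_cohort(cohort, paths$cohort)
    write_volume_stack(gm$stack, paths$gm)
    dir.create(paths$func, showWarnings = FALSE)
    cs <- fn$stack
    for (j in seq_along(cs$conditions)) {
      st <- volume_stack(cs$data[, j, ], cs$grid, kind = "t",
                         subject_ids = cs$subject_ids)
      write_volume_stack(st, file.path(paths$func,
                                       paste0(cs$conditions[j], ".nii.gz")))
    }
    jsonlite::write_json(list(gm = list(d = gm$truth$d,
                                        target_r = gm$truth$target_r),
                              rsa = list(z_target = fn$truth$z_target,
                                         zrot_target = fn$truth$zrot_target,
                                         coupling = fn$truth$coupling)),
                         paths$truth, auto_unbox = TRUE, digits = NA)
    yaml::write_yaml(list(seed = cfg$seed, n_perm = cfg$n_perm,
                          interest = cfg$interest, sphere = cfg$sphere),
                     paths$config)
  }

  if ("vbm" %in% stages) {
    for (p in c(paths$cohort, paths$gm)) need(p, "simulate")
    cohort <- read_cohort(paths$cohort)
    stack <- read_volume_stack(paths$gm, kind = "gray_matter")
    stack <- gaussian_smooth(stack, cfg$smooth_fwhm)
    mask <- absolute_mask(stack, cfg$absolute_threshold)
    .log_stage("vbm", "mask retains %d/%d voxels", sum(mask$values),
               length(mask$values))
    design <- make_design(cohort, interest = cfg$interest)
    tmap <- fit_voxelwise_t(stack, design, mask = mask)
    .log_stage("vbm", "t map df=%d, %d voxels excluded", tmap$df,
               attr(tmap, "n_excluded"))
    zvals <- tmap$values
    ok <- !is.na(zvals)
    zvals[ok] <- z_from_t(zvals[ok], tmap$df)
    write_volume(tmap, paths$tmap)
    write_volume(volume_map(zvals, tmap$grid, "other"), paths$zmap)
    tab <- cluster_fwe(stack, design, forming_threshold_p = cfg$forming_threshold_p,
                       n_perm = cfg$n_perm, seed = cfg$seed,
                       connectivity = cfg$connectivity, mask = mask)
    .log_stage("vbm", "%d cluster(s), %d permutations", nrow(tab), cfg$n_perm)
    write_cluster_table(tab, paths$vbm_clusters)
    sig <- as.data.frame(tab)[tab$p_fwe <= 0.05, , drop = FALSE]
    roi <- if (nrow(sig)) {
      cl <- attr(tab, "clusters")[[which.max(tab$size * (tab$p_fwe <= 0.05))]]
      sel <- rep(FALSE, n_voxels(stack$grid)); sel[cl] <- TRUE
      adjusted_roi_gm(stack, unclass(design)[, -(1:2), drop = FALSE], sel)
    } else rep(NA_real_, nrow(cohort))
    utils::write.csv(data.frame(subject_id = cohort$subject_id,
                                adjusted_roi_gm = roi),
                     paths$roi_gm, row.names = FALSE)
  }

  if ("anova" %in% stages || "rsa" %in% stages) {
    cond_files <- file.path(paths$func, paste0(c(vocal_conditions, "rotated"), ".nii.gz"))
  }

  if ("anova" %in% stages) {
    for (p in cond_files) need(p, "simulate")
    stacks <- lapply(cond_files, read_volume_stack, kind = "t")
    cstack <- condition_stack(stacks)
    fmap <- rm_anova_f(cstack)
    .log_stage("anova", "F df=(%d,%d)", fmap$df[1], fmap$df[2])
    write_volume(fmap, paths$fmap)
    tab <- anova_cluster_fwe(cstack, forming_threshold_p = cfg$forming_threshold_p,
                             n_perm = cfg$n_perm, seed = cfg$seed + 1L,
                             connectivity = cfg$connectivity)
    .log_stage("anova", "%d cluster(s)", nrow(tab))
    write_cluster_table(tab, paths$anova_clusters)
  }

  if ("rsa" %in% stages) {
    for (p in c(cond_files, paths$cohort)) need(p, "simulate")
    cohort <- read_cohort(paths$cohort)
    stacks <- lapply(cond_files, read_volume_stack, kind = "t")
    cstack <- condition_stack(stacks)
    cstack$subject_ids <- cohort$subject_id[seq_len(dim(cstack$data)[1])]
    sphere <- make_sphere_mask(cfg$sphere$center, cfg$sphere$radius, cstack$grid)
    .log_stage("rsa", "sphere %d voxels at (%s) mm", sphere$n_voxels,
               paste(cfg$sphere$center, collapse = ", "))
    summ <- rsa_summary(cstack, sphere)
    utils::write.csv(as.data.frame(summ), paths$rsa, row.names = FALSE)
  }

  if ("report" %in% stages) {
    for (p in c(paths$cohort, paths$rsa)) need(p, "prior stages")
    cohort <- read_cohort(paths$cohort)
    summ <- utils::read.csv(paths$rsa, stringsAsFactors = FALSE)
    class(summ) <- c("similarity_summary", "data.frame")
    fc <- cohort[match(summ$subject_id, cohort$subject_id), , drop = FALSE]
    nuis <- as.matrix(fc[, .nuisance_default])
    beh <- pearson_r(cohort$bais_vividness, cohort$bais_control)
    vv <- pearson_r(cohort$bais_vividness, cohort$vviq_vividness)
    sim <- similarity_behavior_link(summ, cohort, score = cfg$interest)
    simp <- similarity_behavior_link(summ, fc, score = cfg$interest,
                                     covariates = nuis)
    rot <- similarity_behavior_link(summ, cohort, score = cfg$interest,
                                    which = "vocal_vs_rotated")
    report <- list(
      vividness_control_r = beh$r, vividness_control_p = beh$p_two_sided,
      vividness_vviq_r = vv$r, vividness_vviq_p = vv$p_two_sided,
      similarity_vividness_r = sim$r, similarity_vividness_p = sim$p_two_sided,
      similarity_vividness_partial_r = simp$r,
      rotated_similarity_vividness_r = rot$r,
      mean_within_vocal_z = mean(summ$mean_z_within_vocal),
      sd_within_vocal_z = stats::sd(summ$mean_z_within_vocal))
    if (file.exists(paths$roi_gm)) {
      roi <- utils::read.csv(paths$roi_gm, stringsAsFactors = FALSE)
      if (!anyNA(roi$adjusted_roi_gm)) {
        rr <- pearson_r(roi$adjusted_roi_gm, cohort$bais_vividness)
        report$roi_gm_vividness_r <- rr$r
        report$roi_gm_vividness_p <- rr$p_two_sided
      }
    }
    jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA)
    .log_stage("report", "similarity-vividness r = %.3f", sim$r)
  }

  written <- Filter(file.exists, unlist(paths[setdiff(names(paths), c("func", "manifest"))]))
  func_files <- if (dir.exists(paths$func))
    list.files(paths$func, full.names = TRUE) else character(0)
  written <- c(written, func_files)
  manifest <- list(seed = cfg$seed, n_perm = cfg$n_perm,
                   stages = stages,
                   config_hash = unname(tools::md5sum(paths$config)),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   outputs = lapply(stats::setNames(nm = basename(written)),
                                    function(nm) NULL))
  manifest$outputs <- Map(function(p) list(path = p,
                                           md5 = unname(tools::md5sum(p))),
                          written)
  names(manifest$outputs) <- basename(written)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE)
  invisible(manifest)
}
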