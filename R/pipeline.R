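#' Save / load a segmentation model checkpoint
#'
#' The checkpoint is a self-describing list (configuration, parameters,
#' batch-norm statistics, loss history) serialized with `saveRDS`.
#'
#' @param model A `segnet`.
#' @param path Checkpoint path (`.rds`).
#' @return `path` (`save_segnet`) or the restored model (`load_segnet`).
#' @export
save_segnet <- function(model, path) {
  saveRDS(list(cfg = model$cfg, input_size = model$input_size,
               par = model$par, bn_stats = model$bn_stats,
               loss_history = model$loss_history), path)
  invisible(path)
}

#' @rdname save_segnet
#' @export
load_segnet <- function(path) {
  st <- readRDS(path)
  model <- build_segnet(st$cfg, st$input_size)
  model$par <- st$par
  model$bn_stats <- st$bn_stats
  model$loss_history <- st$loss_history
  model
}

#' Pipeline configuration
#'
#' One schema-validated object holding the per-stage settings of the full
#' analysis: phantom cohort generation, subject-wise splitting, network
#' training, multi-atlas HR refinement, template meshing, motion
#' decomposition and regional reporting.
#'
#' @param n_subjects Cohort size.
#' @param jitter Geometric jitter of the cohort.
#' @param split Train/validation/test fractions (sums to 1; subject-wise).
#' @param base_spec The cohort's [phantom_spec()].
#' @param net A [net_config()].
#' @param augment An [augment_spec()] or `NULL`.
#' @param atlas_k_ed,atlas_k_es Atlases fused per phase.
#' @param affine_iter,ffd_iter Registration iterations.
#' @param template_vertices Named vertex budgets for the template meshes.
#' @param structures Mesh structures analysed (endocardial surfaces).
#' @param qc_cap,qc_max_frac Mesh-projection QC thresholds.
#' @param apex_frac Apical-cap fraction for segment assignment.
#' @param seed Global seed.
#' @param out_dir Output directory (`NULL` for none).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(n_subjects = 10, jitter = 0.1,
                            split = c(train = 0.6, val = 0.1, test = 0.3),
                            base_spec = phantom_spec(),
                            net = net_config(base_features = 8, epochs = 20),
                            augment = augment_spec(),
                            atlas_k_ed = 5, atlas_k_es = 3,
                            affine_iter = 60, ffd_iter = 40,
                            template_vertices = c(lv_endo = 2000,
                                                  rv_endo = 2000),
                            structures = c("lv_endo", "rv_endo"),
                            qc_cap = 1, qc_max_frac = 0.05,
                            apex_frac = 0.05, seed = 1L, out_dir = NULL) {
  stopifnot(n_subjects >= 3, abs(sum(split) - 1) < 1e-9, all(split >= 0),
            inherits(base_spec, "phantom_spec"), inherits(net, "net_config"),
            is.null(augment) || inherits(augment, "augment_spec"),
            all(structures %in% c("lv_endo", "lv_epi", "rv_endo", "rv_epi")))
  structure(list(n_subjects = as.integer(n_subjects), jitter = jitter,
                 split = split, base_spec = base_spec, net = net,
                 augment = augment, atlas_k_ed = atlas_k_ed,
                 atlas_k_es = atlas_k_es, affine_iter = affine_iter,
                 ffd_iter = ffd_iter, template_vertices = template_vertices,
                 structures = structures, qc_cap = qc_cap,
                 qc_max_frac = qc_max_frac, apex_frac = apex_frac,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror the [pipeline_config()] arguments; nested
#' `phantom`, `net` and `augment` blocks set the corresponding
#' sub-configurations.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("n_subjects", "jitter", "atlas_k_ed", "atlas_k_es",
              "affine_iter", "ffd_iter", "qc_cap", "qc_max_frac",
              "apex_frac", "seed", "out_dir", "structures"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  if (!is.null(y$split)) args$split <- unlist(y$split)
  if (!is.null(y$phantom)) args$base_spec <- do.call(phantom_spec, y$phantom)
  if (!is.null(y$net)) args$net <- do.call(net_config, y$net)
  if (!is.null(y$augment)) args$augment <- do.call(augment_spec, y$augment)
  do.call(pipeline_config, args)
}

# subject-wise split by fractions, seeded
split_cohort <- function(n, split, seed) {
  idx <- with_seed(seed, sample.int(n))
  n_train <- max(2, round(split[["train"]] * n))
  n_val <- max(0, round(split[["val"]] * n))
  if (n_train + n_val >= n) n_val <- max(0, n - n_train - 1)
  list(train = sort(idx[seq_len(n_train)]),
       val = if (n_val > 0) sort(idx[n_train + seq_len(n_val)]) else integer(0),
       test = sort(idx[(n_train + n_val + 1):n]))
}

#' Run the full phantom-to-regions pipeline
#'
#' Stages, in order: (1) generate the seeded phantom cohort; (2)
#' subject-wise split; (3) train the FCN on the training subjects' ED/ES
#' cine slices; (4) predict ED/ES thick-slice segmentations for the test
#' subjects; (5) build the atlas library from the training subjects' HR
#' labels and fuse a HR label per test subject and phase (rank, affine,
#' FFD, vote); (6) build the average template, align subjects to it
#' rigidly, and build template meshes; (7) nonrigidly propagate the
#' template meshes to each subject/phase, with projection QC (failing
#' subjects are excluded and listed); (8) decompose wall motion and emit
#' per-subject and group regional tables, including the 28-segment table.
#' Reruns with the same configuration reproduce label artifacts
#' bit-exactly.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print stage progress.
#' @return A `pipeline_result` list; see Details.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  say("[1/8] phantom cohort (n = %d)", config$n_subjects)
  cohort <- generate_cohort(config$n_subjects, config$base_spec,
                            jitter = config$jitter, seed = config$seed,
                            cine_frames = FALSE)
  say("[2/8] subject-wise split")
  sp <- split_cohort(config$n_subjects, config$split, config$seed + 1L)
  train <- cohort[sp$train]
  val <- cohort[sp$val]
  test <- cohort[sp$test]
  say("[3/8] training FCN on %d subjects", length(train))
  d <- dim(train[[1]]$study$frames[[1]]$values)
  model <- build_segnet(config$net, d[1:2])
  model <- train_segnet(model, train, config$net, aug = config$augment,
                        val_cohort = if (length(val)) val else NULL)
  say("[4/8] predicting %d test subjects", length(test))
  preds <- lapply(test, function(s)
    predict_study(model, s$study, es_frame = s$es_frame))
  say("[5/8] multi-atlas HR refinement")
  lib_labels <- c(lapply(train, function(s) s$labels_hr$ed),
                  lapply(train, function(s) s$labels_hr$es))
  lib_phases <- rep(c("ED", "ES"), each = length(train))
  lib <- atlas_library(lib_labels, lib_phases,
                       ids = paste0(rep(sapply(train, `[[`, "id"), 2),
                                    "_", lib_phases))
  excluded <- list()
  fused <- lapply(seq_along(test), function(i) {
    tryCatch(
      list(ed = atlas_fit(preds[[i]]$ed, lib, "ED", k = config$atlas_k_ed,
                          affine_iter = config$affine_iter,
                          ffd_iter = config$ffd_iter),
           es = atlas_fit(preds[[i]]$es, lib, "ES", k = config$atlas_k_es,
                          affine_iter = config$affine_iter,
                          ffd_iter = config$ffd_iter)),
      error = function(e) structure(conditionMessage(e), class = "stage_fail"))
  })
  say("[6/8] template and template meshes")
  template <- build_template(lib)
  tmeshes <- lapply(config$structures, function(st)
    build_template_mesh(template$label, st,
                        target_vertices = config$template_vertices[[st]]))
  names(tmeshes) <- config$structures
  say("[7/8] correspondence and motion")
  subjects <- list()
  for (i in seq_along(test)) {
    id <- test[[i]]$id
    if (inherits(fused[[i]], "stage_fail")) {
      excluded[[id]] <- sprintf("atlas fitting failed: %s", fused[[i]])
      next
    }
    geom <- tryCatch({
      aligned <- lapply(fused[[i]], function(ph)
        align_to_template(ph$label, template))
      axis <- fit_centreline(aligned$ed$label)
      ins <- find_insertion_angle(aligned$ed$label, axis)
      list(aligned = aligned, axis = axis, ins = ins)
    }, error = function(e) structure(conditionMessage(e),
                                     class = "stage_fail"))
    if (inherits(geom, "stage_fail")) {
      excluded[[id]] <- sprintf("template alignment failed: %s", geom)
      next
    }
    aligned <- geom$aligned
    axis <- geom$axis
    ins <- geom$ins
    fields <- list()
    segss <- list()
    ok <- TRUE
    for (st in config$structures) {
      tfs <- list(
        ed = register_ffd(aligned$ed$label, template$label,
                          init = register_affine(aligned$ed$label,
                                                 template$label,
                                                 max_iter = config$affine_iter),
                          max_iter = config$ffd_iter),
        es = register_ffd(aligned$es$label, template$label,
                          init = register_affine(aligned$es$label,
                                                 template$label,
                                                 max_iter = config$affine_iter),
                          max_iter = config$ffd_iter))
      cm <- correspond(tmeshes[[st]], aligned$ed$label, aligned$es$label,
                       tfs, centreline = axis, cap = config$qc_cap,
                       max_fail_frac = config$qc_max_frac)
      if (cm$qc$flag) {
        excluded[[id]] <- sprintf(
          "mesh QC failure on %s: %.1f%% of projections beyond %g mm", st,
          100 * cm$qc$frac_over, cm$qc$cap)
        ok <- FALSE
        break
      }
      fields[[st]] <- decompose_motion(cm)
      segss[[st]] <- assign_segments(cm, ins, apex_frac = config$apex_frac)
    }
    if (!ok) next
    subjects[[id]] <- list(id = id, prediction = preds[[i]],
                           fused = fused[[i]], aligned = aligned,
                           axis = axis, insertion = ins,
                           fields = fields, segments = segss,
                           regional = lapply(config$structures, function(st)
                             regional_summary(fields[[st]], segss[[st]])))
    names(subjects[[id]]$regional) <- config$structures
  }
  say("[8/8] regional reporting (%d analysed, %d excluded)",
      length(subjects), length(excluded))
  regional28 <- NULL
  if (length(subjects) > 0 &&
      all(c("lv_endo", "rv_endo") %in% config$structures)) {
    lv_group <- group_regional_summary(
      lapply(subjects, function(s) s$regional$lv_endo))
    rv_group <- group_regional_summary(
      lapply(subjects, function(s) s$regional$rv_endo))
    regional28 <- bullseye_table(lv_group, rv_group)
  }
  result <- structure(
    list(config = config, model = model, split = sp, template = template,
         template_meshes = tmeshes, subjects = subjects,
         excluded = excluded, regional28 = regional28,
         loss_history = model$loss_history),
    class = "pipeline_result")
  if (!is.null(out_dir)) {
    save_segnet(model, file.path(out_dir, "model.rds"))
    save_volume(template$label, file.path(out_dir, "template.nii.gz"))
    for (id in names(subjects)) {
      s <- subjects[[id]]
      save_volume(s$aligned$ed$label,
                  file.path(out_dir, paste0(id, "_hr_ed.nii.gz")))
      save_volume(s$aligned$es$label,
                  file.path(out_dir, paste0(id, "_hr_es.nii.gz")))
      for (st in names(s$fields))
        write_motion_csv(s$fields[[st]],
                         file.path(out_dir, paste0(id, "_", st,
                                                   "_motion.csv")))
    }
    if (!is.null(regional28))
      utils::write.csv(regional28, file.path(out_dir, "regional28.csv"),
                       row.names = FALSE)
    summary_report <- list(
      n_subjects = config$n_subjects, analysed = names(subjects),
      excluded = excluded, seed = config$seed)
    writeLines(yaml::as.yaml(summary_report),
               file.path(out_dir, "summary.yaml"))
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d subjects analysed, %d excluded\n",
              length(x$subjects), length(x$excluded)))
  if (!is.null(x$regional28))
    cat(sprintf("  28-segment table: %d rows\n", nrow(x$regional28)))
  invisible(x)
}
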