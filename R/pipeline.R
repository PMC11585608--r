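#' Run the full desk-scale pipeline
#'
#' Orchestrates simulate -> train -> infer/baseline -> evaluate on seeded
#' phantom data, writing every artifact plus a manifest (content hashes,
#' stage, seed, wall time) and the effective configuration into
#' `out_dir`.  Deterministic stages reproduce identical hashes when rerun
#' with the same configuration.
#'
#' @param out_dir run directory (created if missing).
#' @param seed master seed; stage seeds are derived from it.
#' @param n_train,n_val,n_test phantom counts per split.
#' @param shape_thin thin-phantom shape `(D_thin, H, W)`.
#' @param preset model preset (see [dls_config()]).
#' @param L input slice count for the model.
#' @param crop training crop `(L, h, w)`.
#' @param max_epochs training epoch cap for the run.
#' @param stages character subset of
#'   `c("simulate", "train", "infer", "evaluate")`; later stages expect
#'   earlier artifacts to exist.
#' @param verbose print progress.
#' @return The manifest list, invisibly; the quality report is written to
#'   `evaluation/report.json` and returned in `$report` when the evaluate
#'   stage runs.
#' @export
run_pipeline <- function(out_dir, seed = 1L, n_train = 8L, n_val = 2L,
                         n_test = 4L, shape_thin = c(41L, 64L, 64L),
                         preset = "tiny", L = 4L, crop = c(3L, 24L, 24L),
                         max_epochs = 60L,
                         stages = c("simulate", "train", "infer", "evaluate"),
                         verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path) else list()
  cfg_echo <- list(seed = seed, n_train = n_train, n_val = n_val,
                   n_test = n_test, shape_thin = shape_thin,
                   preset = preset, L = L, crop = crop,
                   max_epochs = max_epochs, stages = stages)
  jsonlite::write_json(cfg_echo, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  note <- function(stage, files, status = "ok", t0) {
    files <- files[file.exists(files)]
    manifest[[stage]] <<- list(
      stage = stage, status = status, seed = seed,
      elapsed_s = round(as.numeric(Sys.time()) - t0, 2),
      files = as.list(stats::setNames(
        unname(tools::md5sum(files)),
        sub(paste0("^", out_dir, "/?"), "", files))))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE)
  }
  say <- function(...) if (verbose) message(sprintf(...))

  sim_dir <- file.path(out_dir, "volumes")
  split_paths <- function(split, n) list(
    thin = file.path(sim_dir, sprintf("%s_%02d_thin.nii.gz", split, seq_len(n))),
    thick = file.path(sim_dir, sprintf("%s_%02d_thick.nii.gz", split, seq_len(n))))
  splits <- list(train = split_paths("train", n_train),
                 val = split_paths("val", n_val),
                 test = split_paths("test", n_test))

  if ("simulate" %in% stages) {
    t0 <- as.numeric(Sys.time()); say("stage simulate")
    dir.create(sim_dir, showWarnings = FALSE)
    base <- phantom_config(shape_thin = shape_thin)
    offs <- c(train = 0L, val = 1000L, test = 2000L)
    prov <- list()
    for (split in names(splits)) {
      n <- length(splits[[split]]$thin)
      ds <- make_paired_dataset(n, base, seed = seed + offs[[split]])
      for (i in seq_len(n)) {
        write_volume(ds[[i]]$thin, splits[[split]]$thin[i])
        write_volume(ds[[i]]$thick, splits[[split]]$thick[i])
        prov[[basename(splits[[split]]$thin[i])]] <-
          attr(ds[[i]]$thin, "provenance")
      }
    }
    jsonlite::write_json(prov, file.path(sim_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = 4)
    note("simulate", c(unlist(lapply(splits, unlist)),
                       file.path(sim_dir, "provenance.json")), t0 = t0)
  }

  load_split <- function(split) {
    ps <- splits[[split]]
    lapply(seq_along(ps$thin), function(i)
      list(thin = read_volume(ps$thin[i]), thick = read_volume(ps$thick[i]),
           r = 5L))
  }

  ckpt <- file.path(out_dir, "checkpoint.rds")
  if ("train" %in% stages) {
    t0 <- as.numeric(Sys.time()); say("stage train")
    model <- new_dls_model(dls_config(preset, L = L), seed = seed)
    # desk-scale optimization settings (see the methods vignette)
    tcfg <- train_config(seed = seed, crop = crop, max_epochs = max_epochs,
                         lr0 = 3e-3, loss = "l2", min_crop_sd = 0.02,
                         grad_clip = 1)
    fit <- train_dls(model, load_split("train"), load_split("val"), tcfg,
                     verbose = verbose)
    save_checkpoint(fit$model, ckpt)
    utils::write.csv(fit$state$history,
                     file.path(out_dir, "training_log.csv"),
                     row.names = FALSE)
    note("train", c(ckpt, file.path(out_dir, "training_log.csv")), t0 = t0)
  }

  pred_dir <- file.path(out_dir, "predictions")
  if ("infer" %in% stages) {
    t0 <- as.numeric(Sys.time()); say("stage infer")
    if (!file.exists(ckpt)) {
      note("infer", character(), status = "failed: missing checkpoint",
           t0 = t0)
      stop(sprintf(
        "run_pipeline: stage 'infer' requires checkpoint '%s'", ckpt))
    }
    model <- load_checkpoint(ckpt)
    dir.create(pred_dir, showWarnings = FALSE)
    test <- load_split("test")
    outs <- character()
    for (i in seq_along(test)) {
      dls <- synthesize_thin(model, test[[i]]$thick, tile = c(64L, 64L))
      bis <- bicubic_baseline(test[[i]]$thick)
      pd <- file.path(pred_dir, sprintf("test_%02d_dls.nii.gz", i))
      pb <- file.path(pred_dir, sprintf("test_%02d_bis.nii.gz", i))
      write_volume(dls, pd); write_volume(bis, pb)
      outs <- c(outs, pd, pb)
    }
    note("infer", outs, t0 = t0)
  }

  report <- NULL
  if ("evaluate" %in% stages) {
    t0 <- as.numeric(Sys.time()); say("stage evaluate")
    test <- load_split("test")
    dls <- lapply(seq_along(test), function(i)
      read_volume(file.path(pred_dir, sprintf("test_%02d_dls.nii.gz", i))))
    bis <- lapply(seq_along(test), function(i)
      read_volume(file.path(pred_dir, sprintf("test_%02d_bis.nii.gz", i))))
    report <- quality_report(lapply(test, `[[`, "thin"), dls, bis)
    ev_dir <- file.path(out_dir, "evaluation")
    dir.create(ev_dir, showWarnings = FALSE)
    jsonlite::write_json(
      list(per_case = report$per_case, summary = report$summary,
           p_values = report$p_values),
      file.path(ev_dir, "report.json"), auto_unbox = TRUE, digits = 6,
      dataframe = "columns")
    note("evaluate", file.path(ev_dir, "report.json"), t0 = t0)
  }

  out <- manifest
  out$report <- report
  invisible(out)
}
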