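#' Full-pipeline configuration
#'
#' Bundles every stage's parameters behind two named presets matching the
#' two working resolutions: `points15000` (target 15,000 points; K_f = 64,
#' K1 = 32, K2 = 32) and `points4096` (target 4096; K_f = 16, K1 = 8,
#' K2 = 8). Both presets share beta1 = beta2 = 0.85, alpha1 = 5,
#' alpha2 = 9, mu = 0.30. Any field can be overridden.
#'
#' @param preset `"points15000"` or `"points4096"`.
#' @param target_n,k1,beta1,alpha1,k_f,mu,k2,beta2,alpha2 stage parameter
#'   overrides; `NULL` keeps the preset value.
#' @param upsample if `TRUE`, labels are transferred back to the raw cloud
#'   when the input was down-sampled (default `TRUE`).
#' @param seed seed for the pipeline's (only) stochastic fallback, the
#'   base-point collision perturbation (default 0).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(preset = c("points15000", "points4096"),
                            target_n = NULL, k1 = NULL, beta1 = NULL,
                            alpha1 = NULL, k_f = NULL, mu = NULL, k2 = NULL,
                            beta2 = NULL, alpha2 = NULL, upsample = TRUE,
                            seed = 0L) {
  preset <- match.arg(preset)
  p <- if (preset == "points15000")
    list(target_n = 15000L, k1 = 32L, k_f = 64L, k2 = 32L)
  else
    list(target_n = 4096L, k1 = 8L, k_f = 16L, k2 = 8L)
  cfg <- list(preset = preset,
              target_n = as.integer(target_n %||% p$target_n),
              k1 = as.integer(k1 %||% p$k1),
              beta1 = beta1 %||% 0.85,
              alpha1 = alpha1 %||% 5,
              k_f = as.integer(k_f %||% p$k_f),
              mu = mu %||% 0.30,
              k2 = as.integer(k2 %||% p$k2),
              beta2 = beta2 %||% 0.85,
              alpha2 = alpha2 %||% 9,
              upsample = isTRUE(upsample),
              seed = as.integer(seed))
  structure(cfg, class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full stem-leaf segmentation pipeline
#'
#' read -> adaptive down-sampling -> stem segmentation -> leaf instance
#' segmentation -> assembled labeling (stem = 0, leaves 1..n_l by
#' descending size) -> optional label up-sampling back to the raw cloud ->
#' labeled cloud written to `out_path` plus a JSON report sidecar
#' (`<out_path>.json`) with organ counts, the parameters used, and stage
#' timings. Partial artifacts are removed if a stage fails.
#'
#' @param in_path input cloud file (see [read_cloud()]), or a
#'   [point_cloud()] directly.
#' @param out_path output file for the labeled cloud (format by extension),
#'   or `NULL` to skip writing.
#' @param cfg a [pipeline_config()].
#' @return a `segmentation_result` (invisibly when writing); its `labels`
#'   refer to the cloud actually segmented; when up-sampling applied, the
#'   written file holds the raw cloud's labels and the result carries them
#'   in `raw_labels`.
#' @export
run_pipeline <- function(in_path, out_path = NULL,
                         cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  t0 <- proc.time()[[3L]]
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(out_path)) unlink(c(out_path, paste0(out_path, ".json")))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  raw <- if (inherits(in_path, "point_cloud")) in_path
         else stage("read", read_cloud(in_path))
  timings <- c(read = proc.time()[[3L]] - t0)

  t1 <- proc.time()[[3L]]
  work <- stage("downsample",
                adaptive_downsample(raw, downsample_config(cfg$target_n)))
  timings["downsample"] <- proc.time()[[3L]] - t1

  t1 <- proc.time()[[3L]]
  st <- stage("stem", segment_stem(
    work, alpha1 = cfg$alpha1,
    qsp = qsp_config(cfg$k1, cfg$beta1),
    feat = stem_feature_config(cfg$k_f),
    mnvg = mnvg_config(mu = cfg$mu)))
  timings["stem"] <- proc.time()[[3L]] - t1

  t1 <- proc.time()[[3L]]
  leaf_cloud <- subset_cloud(st$aligned, st$leaf_indices)
  lf <- stage("leaf", segment_leaves(
    leaf_cloud, leaf_config(cfg$k2, cfg$beta2, cfg$alpha2)))
  result <- assemble_result(st$stem_indices, st$leaf_indices,
                            lf$instance_ids, st$aligned, st$alignment)
  timings["leaf"] <- proc.time()[[3L]] - t1

  if (cfg$upsample && n_points(raw) > n_points(work)) {
    seg <- point_cloud(work$points, result$labels)  # original coordinates
    result$raw_labels <- upsample_labels(raw, seg)$labels
  }

  if (!is.null(out_path)) {
    stage("write", {
      out_labels <- result$raw_labels %||% result$labels
      out_cloud <- if (!is.null(result$raw_labels))
        point_cloud(raw$points, out_labels)
      else point_cloud(work$points, out_labels)
      write_cloud(out_cloud, out_path)
      report <- list(
        n_input = n_points(raw), n_segmented = n_points(work),
        n_leaves = result$n_leaves,
        organ_sizes = as.list(table(out_labels)),
        parameters = unclass(cfg)[setdiff(names(unclass(cfg)), NULL)],
        timings_sec = as.list(round(timings, 4L)))
      jsonlite::write_json(report, paste0(out_path, ".json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    })
  }
  if (is.null(out_path)) result else invisible(result)
}

cli_fail <- function(status, ...) {
  message(...)
  structure(status, class = "dfsp_exit")
}

parse_flags <- function(args) {
  flags <- list(); pos <- character()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (startsWith(a, "--")) {
      key <- gsub("-", "_", substring(a, 3L))
      if (i < length(args) && !startsWith(args[[i + 1L]], "--")) {
        flags[[key]] <- args[[i + 1L]]; i <- i + 2L
      } else { flags[[key]] <- TRUE; i <- i + 1L }
    } else { pos <- c(pos, a); i <- i + 1L }
  }
  list(flags = flags, pos = pos)
}

num <- function(x) if (is.null(x)) NULL else as.numeric(x)

#' Command-line entry point
#'
#' Subcommands: `segment IN OUT`, `downsample IN OUT`, `synth --out OUT`,
#' `eval PRED TRUTH`. A JSON config file (`--config cfg.json`, keys as in
#' [pipeline_config()]) can preload parameters; explicit flags override it.
#' Designed to be wrapped by an Rscript launcher
#' (`system.file("cli", "dfsp.R", package = "dfsp")`).
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status, invisibly: 0 success, 2 validation error,
#'   3 I/O error.
#' @export
dfsp_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch(dfsp_cli_run(args), dfsp_validation = function(e) 2L)
  invisible(if (inherits(status, "dfsp_exit")) unclass(status) else 0L)
}

dfsp_cli_run <- function(args) {
  if (length(args) < 1L)
    return(cli_fail(2L, "usage: dfsp <segment|downsample|synth|eval> ..."))
  cmd <- args[[1L]]
  pa <- parse_flags(args[-1L])
  fl <- pa$flags; pos <- pa$pos

  if (cmd %in% c("segment", "downsample", "eval") &&
      (length(pos) < 2L))
    return(cli_fail(2L, "two positional arguments required for '", cmd, "'"))
  if (cmd %in% c("segment", "downsample", "eval") && !file.exists(pos[[1L]]))
    return(cli_fail(3L, "input file not found: ", pos[[1L]]))

  switch(cmd,
    segment = {
      base <- if (!is.null(fl$config))
        do.call(pipeline_config, jsonlite::read_json(fl$config, simplifyVector = TRUE))
      else pipeline_config(preset = fl$preset %||% "points15000")
      cfg <- pipeline_config(
        preset = fl$preset %||% base$preset,
        target_n = num(fl$target_n) %||% base$target_n,
        k1 = num(fl$k1) %||% base$k1, beta1 = num(fl$beta1) %||% base$beta1,
        alpha1 = num(fl$alpha1) %||% base$alpha1,
        k_f = num(fl$kf) %||% base$k_f, mu = num(fl$mu) %||% base$mu,
        k2 = num(fl$k2) %||% base$k2, beta2 = num(fl$beta2) %||% base$beta2,
        alpha2 = num(fl$alpha2) %||% base$alpha2)
      tryCatch({ run_pipeline(pos[[1L]], pos[[2L]], cfg); 0L },
               error = function(e) cli_fail(2L, conditionMessage(e)))
    },
    downsample = {
      tryCatch({
        cl <- read_cloud(pos[[1L]])
        out <- adaptive_downsample(cl, downsample_config(
          target_n = num(fl$target_n) %||% 15000L,
          initial_interval = num(fl$interval),
          seed_index = num(fl$seed_index) %||% 1L))
        write_cloud(out, pos[[2L]])
        0L
      }, error = function(e) cli_fail(2L, conditionMessage(e)))
    },
    synth = {
      if (is.null(fl$out)) return(cli_fail(2L, "synth requires --out"))
      tryCatch({
        spec <- plant_spec(n_leaves = num(fl$leaves) %||% 6L,
                           seed = num(fl$seed) %||% 1L,
                           points_total = num(fl$points) %||% 15000L)
        cloud <- generate_plant(spec)
        write_cloud(cloud, fl$out)
        jsonlite::write_json(unclass(spec)[names(spec) != "leaf_length_profile"],
                             paste0(fl$out, ".json"), auto_unbox = TRUE,
                             digits = NA)
        0L
      }, error = function(e) cli_fail(2L, conditionMessage(e)))
    },
    eval = {
      tryCatch({
        pred <- read_cloud(pos[[1L]]); truth <- read_cloud(pos[[2L]])
        if (is.null(pred$labels) || is.null(truth$labels))
          stop("both clouds must carry labels")
        sc <- score_plant(pred$labels, truth$labels)
        out <- list(precision = sc$p_p, recall = sc$r_p, micro_f1 = sc$f_p,
                    n_organs = sc$n_o)
        if (!is.null(fl$json))
          jsonlite::write_json(out, fl$json, auto_unbox = TRUE, digits = NA)
        else cat(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA), "\n")
        0L
      }, error = function(e) cli_fail(2L, conditionMessage(e)))
    },
    cli_fail(2L, "unknown subcommand: ", cmd))
}
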