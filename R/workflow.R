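#' Content hash of a set of input files
#'
#' Order-independent SHA-256 digest over the file bytes: each file is
#' hashed individually, the sorted per-file digests are concatenated and
#' hashed again. Used as the project identifier for deduplication and
#' resumability.
#'
#' @param files character vector of file paths (may be empty).
#' @return Hex digest string; the empty set yields the digest of the
#'   empty string (a defined sentinel).
#' @export
content_hash <- function(files) {
  if (!length(files)) return(digest::digest("", algo = "sha256",
                                            serialize = FALSE))
  if (!all(file.exists(files)))
    stop("unreadable file(s): ",
         paste(files[!file.exists(files)], collapse = ", "))
  hashes <- vapply(files, function(f)
    digest::digest(f, algo = "sha256", file = TRUE), character(1))
  digest::digest(paste(sort(unname(hashes)), collapse = ""),
                 algo = "sha256", serialize = FALSE)
}

pipeline_stages <- c("upload", "segmentation", "geometry", "mesh",
                     "simulation", "postprocessing")

read_status <- function(dir) {
  p <- file.path(dir, "status.json")
  if (file.exists(p)) jsonlite::read_json(p, simplifyVector = TRUE)
  else stats::setNames(as.list(rep("pending", length(pipeline_stages))),
                       pipeline_stages)
}

write_status <- function(dir, status) {
  jsonlite::write_json(status, file.path(dir, "status.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Run the diagnostics pipeline
#'
#' Orchestrates the stages segmentation -> geometry -> mesh ->
#' simulation -> flow post-processing with per-stage status tracking
#' under a project directory named by the content hash of the inputs.
#' Each stage is idempotent: an existing stage product (from a previous
#' run with the same configuration) is reused. A stage failure marks the
#' project failed at that stage and leaves earlier products untouched.
#'
#' @param config a list (or path to a YAML file) with sections
#'   \describe{
#'     \item{out_dir}{project root directory.}
#'     \item{phantom}{generator spec: `kind` (`duct`,
#'       `two_passage_airway`, `labeled_head`) plus generator
#'       arguments; alternatively `geometry` may name an STL/PLY file.}
#'     \item{segmentation}{for labeled-head input: `iters`, `seed`.}
#'     \item{mesh}{`l_uniform`, optional `boundary_refine`.}
#'     \item{simulation}{`n_iter`, `avg_iter`, `vdot` (ml/s) or `dp`
#'       (Pa), `thermal`.}
#'     \item{postprocessing}{`n_stations`.}
#'     \item{fourphase}{optional: paths `left`/`right` of waveform CSVs
#'       to analyze and overlay.}
#'   }
#' @return A list of class `pipeline_report` with the project id, stage
#'   statuses, and (as far as the stages ran) the flow summary,
#'   centerline profiles, operating-point classification and 4-PR
#'   overlay table.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$out_dir))
  cfg_bytes <- jsonlite::toJSON(config, auto_unbox = TRUE)
  input_files <- c(config$geometry,
                   config$fourphase$left, config$fourphase$right)
  pid <- substr(digest::digest(paste(
    content_hash(input_files %||% character(0)), cfg_bytes),
    algo = "sha256", serialize = FALSE), 1, 16)
  dir <- file.path(config$out_dir, pid)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  status <- read_status(dir)
  report <- list(project_id = pid, dir = dir)
  product <- function(name) file.path(dir, paste0(name, ".rds"))

  run_stage <- function(name, fun) {
    if (identical(status[[name]], "done") && file.exists(product(name))) {
      return(readRDS(product(name)))
    }
    status[[name]] <<- "running"; write_status(dir, status)
    out <- tryCatch(fun(), error = function(e) e)
    if (inherits(out, "error")) {
      status[[name]] <<- "failed"; write_status(dir, status)
      stop(sprintf("pipeline failed at stage '%s': %s", name,
                   conditionMessage(out)), call. = FALSE)
    }
    saveRDS(out, product(name))
    status[[name]] <<- "done"; write_status(dir, status)
    out
  }

  run_stage("upload", function() list(inputs = input_files, config = config))

  seg <- run_stage("segmentation", function() {
    ph <- config$phantom
    if (!is.null(ph) && identical(ph$kind, "labeled_head")) {
      args <- ph[setdiff(names(ph), "kind")]
      head <- do.call(make_labeled_head, args)
      sc <- config$segmentation %||% list()
      iters <- sc$iters %||% 300
      air_ids <- c(0L, 1L, 2L, 3L, 4L, 5L, 6L)
      X <- lapply(seq_len(dim(head$intensity)[3]),
                  function(z) head$intensity[, , z])
      Y <- lapply(seq_len(dim(head$intensity)[3]), function(z)
        (head$labels$voxels[, , z] %in% air_ids) * 1L)
      ds <- slice_dataset(X, Y, n_classes = 2L)
      model <- build_cnn(cnn_spec(n_conv_layers = 1, filters_per_layer = 6,
                                  n_classes = 2), seed = sc$seed %||% 1L)
      tr <- train_cnn(model, ds, loss_config("cbce"), max_iter = iters,
                      seed = sc$seed %||% 1L)
      pred <- predict_segmentation(tr$model, head$intensity)
      list(kind = "labeled_head", head = head, model = tr$model,
           prediction = pred, history = tr$history)
    } else {
      list(kind = "geometry", note = "direct geometry input; nothing to segment")
    }
  })

  geom <- run_stage("geometry", function() {
    ph <- config$phantom
    if (!is.null(config$geometry)) return(read_surface(config$geometry))
    if (identical(seg$kind, "labeled_head")) {
      lv <- label_volume(seg$prediction,
                         spacing = seg$head$labels$spacing,
                         class_names = c(non_air = 0L, air = 1L))
      lv <- dissolve_small_components(lv)
      return(extract_surface(lv, 1L))
    }
    args <- ph[setdiff(names(ph), "kind")]
    switch(ph$kind,
           duct = do.call(make_duct, args),
           two_passage_airway = do.call(make_two_passage_airway, args),
           stop("unknown phantom kind: ", ph$kind))
  })

  can_simulate <- !is.null(geom$patch) &&
    "pharynx" %in% levels(geom$patch)

  mesh <- run_stage("mesh", function() {
    mc <- config$mesh %||% list()
    generate_mesh(geom, l_uniform = mc$l_uniform %||% 5,
                  l_final = mc$l_final %||% (mc$l_uniform %||% 5),
                  boundary_refine = isTRUE(mc$boundary_refine))
  })

  if (can_simulate) {
    sim <- run_stage("simulation", function() {
      sc <- config$simulation %||% list()
      grid <- mesh_to_grid(mesh)
      props <- fluid_properties(nu_lat = sc$nu_lat %||% 0.05)
      bcs <- if (!is.null(sc$dp))
        boundary_spec(pharynx = list(mode = "pressure", dp = sc$dp))
      else
        boundary_spec(pharynx = list(mode = "volume_flux",
                                     vdot = sc$vdot %||% 250,
                                     gain = sc$gain %||% 1e-6))
      run_simulation(grid, props, bcs,
                     n_iter = sc$n_iter %||% 4000,
                     avg_iter = sc$avg_iter %||% 1000,
                     patch_normals = attr(geom, "patch_normals"),
                     thermal = sc$thermal %||% TRUE)
    })

    post <- run_stage("postprocessing", function() {
      pc <- config$postprocessing %||% list()
      fs <- boundary_summary(sim)
      cls <- attr(geom, "centerlines")
      profiles <- if (!is.null(cls))
        centerline_profiles(sim, cls, n_stations = pc$n_stations %||% 15)
      vdot_cm3s <- abs(fs$mdot_pharynx) / (sim$props$rho0 * 1e-3)
      dp_tot <- max(abs(unlist(fs[grep("^dp_tot", names(fs))])))
      op <- NULL
      if (dp_tot > 0 && vdot_cm3s > 0) {
        r_op <- dp_tot / vdot_cm3s
        lr <- log_effective_resistance(r_op)
        op <- c(list(r_op = r_op, lr = lr), classify_resistance(lr, "one"))
      }
      list(summary = fs, profiles = profiles, operating_point = op)
    })
    report$summary <- post$summary
    report$profiles <- post$profiles
    report$operating_point <- post$operating_point
    if (!is.null(config$fourphase)) {
      fp <- config$fourphase
      left <- if (!is.null(fp$left)) load_recording(fp$left, "left")
      right <- if (!is.null(fp$right)) load_recording(fp$right, "right")
      report$fourphase <- analyze_4pr(left = left, right = right)
      sim_pts <- data.frame(
        delta_p = report$summary$dp_tot_left %||%
          report$summary[[grep("^dp_tot", names(report$summary))[1]]],
        vdot = abs(report$summary$mdot_pharynx) / (sim$props$rho0 * 1e-3),
        sr = 0)
      rec <- left %||% right
      report$overlay <- overlay_data(rec, rec, sim_pts)
    }
  } else {
    status$simulation <- "done"
    status$postprocessing <- "done"
    write_status(dir, status)
    report$note <- "geometry has no open pharynx patch; flow stages skipped"
    report$geometry <- geom
  }
  report$status <- read_status(dir)
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> project %s\n", x$project_id))
  st <- unlist(x$status)
  cat(sprintf("  stages: %s\n",
              paste(sprintf("%s=%s", names(st), st), collapse = ", ")))
  if (!is.null(x$operating_point))
    cat(sprintf("  operating point: R=%.4g Pa.s/cm^3 -> class %d (%s)\n",
                x$operating_point$r_op, x$operating_point$class,
                x$operating_point$label))
  invisible(x)
}
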