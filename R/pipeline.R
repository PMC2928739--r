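# Configured analysis pipeline: a single YAML file describes the inputs
# (files or synthetic generators), named residue selections, and the
# analyses to run; the pipeline executes the stages in dependency order and
# writes a report bundle (CSV/PDB outputs, a checksummed manifest, a log).
# Reruns with an identical config produce bit-identical outputs.

pipeline_stages <- c("rmsd", "msf", "distance", "correlation",
                     "windowed_correlation", "autocorrelation",
                     "clustering", "pca")

#' Validate a pipeline configuration
#'
#' Parses (if given a path) and validates an analysis configuration,
#' collecting every schema violation rather than stopping at the first.
#' Suspicious-but-legal settings (e.g. an autocorrelation delay beyond half
#' the trajectory span) produce warnings, not errors.
#'
#' @param config path to a YAML config file, or an equivalent named list.
#' @return validated config of class `"analysis_config"`, with any warning
#'   messages in the `"warnings"` attribute.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  errs <- character(0); warns <- character(0)
  err <- function(...) errs <<- c(errs, paste0(...))
  wrn <- function(...) warns <<- c(warns, paste0(...))

  if (is.null(config$inputs) || length(config$inputs) == 0L) {
    err("inputs: at least one input trajectory is required")
  }
  spans <- list()
  for (nm in names(config$inputs)) {
    inp <- config$inputs[[nm]]
    if (is.null(inp$file) == is.null(inp$synthetic)) {
      err("inputs.", nm, ": exactly one of 'file' or 'synthetic' required")
      next
    }
    eq <- inp$equilibration_end %||% 0
    if (!is.numeric(eq) || eq < 0) {
      err("inputs.", nm, ".equilibration_end: must be >= 0")
    }
    if (!is.null(inp$file)) {
      st <- inp$stride %||% 1
      if (!is.numeric(st) || st < 1) {
        err("inputs.", nm, ".stride: must be a positive integer")
      }
      fi <- inp$frame_interval %||% 1
      if (!is.numeric(fi) || fi <= 0) {
        err("inputs.", nm, ".frame_interval: must be positive")
      }
    } else {
      sy <- inp$synthetic
      gen <- sy$generator %||% "gaussian"
      if (!gen %in% c("gaussian", "rotational_diffusion", "rotation_event",
                      "multibasin")) {
        err("inputs.", nm, ".synthetic.generator: unknown generator '",
            gen, "'")
      }
      fr <- sy$frames %||% 1000
      fi <- sy$frame_interval %||% 0.1
      if (!is.numeric(fr) || fr < 1) {
        err("inputs.", nm, ".synthetic.frames: must be positive")
      }
      if (!is.numeric(fi) || fi <= 0) {
        err("inputs.", nm, ".synthetic.frame_interval: must be positive")
      }
      if (is.numeric(fr) && is.numeric(fi) && fi > 0) {
        spans[[nm]] <- (fr - 1) * fi
      }
    }
  }
  selnames <- c("all", names(config$selections))
  for (nm in names(config$selections)) {
    s <- config$selections[[nm]]
    if (is.null(s$chain) && is.null(s$resno) && is.null(s$index)) {
      err("selections.", nm, ": needs at least one of chain/resno/index")
    }
  }
  check_sel <- function(stage, i, field, val) {
    if (is.null(val)) return()
    if (!val %in% selnames) {
      err("analyses.", stage, "[", i, "].", field,
          ": selection '", val, "' is not defined")
    }
  }
  check_traj <- function(stage, i, val) {
    for (v in val) {
      if (!v %in% names(config$inputs)) {
        err("analyses.", stage, "[", i, "]: trajectory '", v,
            "' is not an input")
      }
    }
  }
  an <- config$analyses %||% list()
  for (stage in names(an)) {
    if (!stage %in% pipeline_stages) {
      err("analyses.", stage, ": unknown stage (expected one of ",
          paste(pipeline_stages, collapse = ", "), ")")
      next
    }
    for (i in seq_along(an[[stage]])) {
      a <- an[[stage]][[i]]
      trajs <- a$trajectories %||% a$trajectory
      if (is.null(trajs)) {
        err("analyses.", stage, "[", i, "]: missing 'trajectory'")
      } else {
        check_traj(stage, i, unlist(trajs))
      }
      check_sel(stage, i, "fit", a$fit)
      check_sel(stage, i, "measure", a$measure)
      check_sel(stage, i, "selection", a$selection)
      check_sel(stage, i, "exclude", a$exclude)
      check_sel(stage, i, "a", a$a)
      check_sel(stage, i, "b", a$b)
      check_sel(stage, i, "block_a", a$block_a)
      check_sel(stage, i, "block_b", a$block_b)
      if (stage == "clustering") {
        if (is.null(a$radius) || !is.numeric(a$radius) || a$radius <= 0) {
          err("analyses.clustering[", i, "].radius: must be > 0")
        }
      }
      if (stage == "autocorrelation") {
        d <- unlist(a$delays)
        if (is.null(d) || !is.numeric(d) || any(d < 0)) {
          err("analyses.autocorrelation[", i,
              "].delays: must be nonnegative numbers")
        } else {
          tn <- unlist(trajs)[1]
          sp <- spans[[tn %||% ""]]
          if (!is.null(sp)) {
            if (any(d >= sp)) {
              err("analyses.autocorrelation[", i, "].delays: delay ",
                  max(d), " ns is not below the trajectory span ", sp,
                  " ns")
            } else if (any(d > sp / 2)) {
              wrn("analyses.autocorrelation[", i, "].delays: delay ",
                  max(d), " ns exceeds half the trajectory span (", sp,
                  " ns); the average will run over few frame pairs")
            }
          }
        }
      }
      if (stage == "windowed_correlation" &&
          (is.null(a$windows) || length(a$windows) == 0L)) {
        err("analyses.windowed_correlation[", i,
            "].windows: at least one (start, end] window required")
      }
    }
  }
  if (length(errs) > 0L) {
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  }
  attr(config, "warnings") <- warns
  class(config) <- c("analysis_config", class(config))
  config
}

build_synthetic_input <- function(sy, equilibration_end) {
  gen <- sy$generator %||% "gaussian"
  chains <- unlist(sy$chains %||% c(A = 20L))
  blocks <- lapply(sy$blocks, function(b) {
    list(members = unlist(b$members), rho = b$rho,
         window = if (!is.null(b$window)) unlist(b$window))
  })
  if (length(blocks) == 0L) blocks <- NULL
  events <- lapply(sy$events, function(e) {
    list(time = e$time, chain = e$chain, angle = e$angle,
         axis = unlist(e$axis), translation = unlist(e$translation))
  })
  if (length(events) == 0L) events <- NULL
  spec <- synthetic_spec(
    chains = chains, frames = sy$frames %||% 1000L,
    frame_interval = sy$frame_interval %||% 0.1,
    seed = sy$seed %||% 1L,
    variances = unlist(sy$variances %||% 0.25),
    blocks = blocks, temporal = sy$temporal %||% "white",
    theta = sy$theta %||% 1, D = sy$D %||% 0.1,
    events = events, basins = sy$basins,
    equilibration_end = equilibration_end)
  switch(gen,
         gaussian = generate_gaussian_trajectory(spec),
         rotational_diffusion = generate_rotational_diffusion_bonds(spec),
         rotation_event = generate_rotation_event(spec),
         multibasin = generate_multibasin_ensemble(spec))
}

resolve_config_selection <- function(config, name, top) {
  if (is.null(name) || identical(name, "all")) {
    return(select_residues(top))
  }
  s <- config$selections[[name]]
  select_residues(top, chain = unlist(s$chain), resno = unlist(s$resno),
                  index = unlist(s$index))
}

#' Run the configured analysis pipeline
#'
#' Loads or generates the configured inputs, executes the requested stages
#' in dependency order, and writes a report bundle to the output directory:
#' one CSV per analysis (plus centroid/medoid PDBs for clustering), a
#' `pipeline.log`, and a `manifest.json` recording the package version, a
#' hash of the configuration, and an MD5 checksum of every output file. A
#' rerun with identical configuration reproduces identical checksums. Any
#' stage error aborts the run, naming the stage in the log and marking the
#' manifest incomplete.
#'
#' @param config path to a YAML config, or a config list; validated with
#'   [validate_config()] first.
#' @param out_dir output directory (created if needed); defaults to the
#'   config's `output_dir`.
#' @param stages optional character vector restricting which stages run.
#' @param verbose echo progress to the console?
#' @return (invisibly) the manifest as a list.
#' @export
run_pipeline <- function(config, out_dir = NULL, stages = NULL,
                         verbose = FALSE) {
  config <- validate_config(config)
  for (w in attr(config, "warnings")) warning(w, call. = FALSE)
  out_dir <- out_dir %||% config$output_dir %||% stop(
    "no output directory: set 'output_dir' in the config or pass out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(level, ...) {
    line <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    level, paste0(...))
    cat(line, "\n", file = log_path, append = TRUE)
    if (verbose) message(line)
  }
  if (is.null(stages)) {
    stages <- pipeline_stages
  } else if (!all(stages %in% pipeline_stages)) {
    stop("unknown stage(s): ",
         paste(setdiff(stages, pipeline_stages), collapse = ", "))
  }
  cat("", file = log_path)  # truncate any previous log
  logf("info", "pipeline start")

  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(config), cfg_file)
  config_hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)

  outputs <- character(0)
  emit <- function(x, name, writer = write_results) {
    path <- file.path(out_dir, name)
    writer(x, path)
    outputs <<- c(outputs, name)
    logf("info", "wrote ", name)
  }
  manifest <- list(package = "ensdyn",
                   version = as.character(utils::packageVersion("ensdyn")),
                   config_hash = config_hash, status = "incomplete",
                   stages = stages, outputs = list())
  write_manifest <- function() {
    sums <- as.list(tools::md5sum(file.path(out_dir, outputs)))
    names(sums) <- outputs
    manifest$outputs <<- sums
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  current_stage <- "load_inputs"
  result <- tryCatch({
    trajs <- list()
    for (nm in names(config$inputs)) {
      inp <- config$inputs[[nm]]
      eq <- inp$equilibration_end %||% 0
      if (!is.null(inp$file)) {
        tr <- read_trajectory(inp$file, stride = inp$stride %||% 1L,
                              frame_interval = inp$frame_interval %||% 1)
        tr$equilibration_end <- eq
      } else {
        tr <- build_synthetic_input(inp$synthetic, eq)
        logf("debug", "generated synthetic input '", nm, "' (seed ",
             inp$synthetic$seed %||% 1L, ")")
      }
      trajs[[nm]] <- tr
      logf("info", "input '", nm, "': ", n_frames(tr), " frames x ",
           nrow(tr$topology), " residues, equilibration <= ", eq, " ns")
    }
    reference <- if (!is.null(config$reference$file)) {
      read_reference_structure(config$reference$file)$coords
    } else {
      frame_coords(trajs[[config$reference$from %||% 1L]], 1L)
    }

    an <- config$analyses %||% list()
    run_one <- function(stage, i, a) {
      tag <- a$name %||% as.character(i)
      tn <- unlist(a$trajectories %||% a$trajectory)
      tr <- trajs[[tn[1]]]
      top <- tr$topology
      sel <- function(x) resolve_config_selection(config, x, top)
      switch(stage,
        rmsd = emit(rmsd_timeseries(tr, reference, sel(a$fit),
                                    sel(a$measure)),
                    sprintf("rmsd_%s.csv", tag)),
        msf = emit(as.data.frame(mean_square_fluctuations(
                     tr, sel(a$fit), sel(a$measure),
                     exclude_mask = if (!is.null(a$exclude)) sel(a$exclude))),
                   sprintf("msf_%s.csv", tag)),
        distance = emit(distance_timeseries(tr, sel(a$a), sel(a$b),
                                            mode = a$mode %||% "calpha"),
                        sprintf("distance_%s.csv", tag)),
        correlation = emit(unclass_matrix(cross_correlation_matrix(
                             tr, sel(a$fit),
                             window = if (!is.null(a$window))
                               unlist(a$window))),
                           sprintf("correlation_%s.csv", tag)),
        windowed_correlation = {
          wc <- windowed_correlations(
            tr, lapply(a$windows, unlist), sel(a$fit),
            block_a = if (!is.null(a$block_a)) sel(a$block_a),
            block_b = if (!is.null(a$block_b)) sel(a$block_b))
          for (j in seq_along(wc$matrices)) {
            emit(unclass_matrix(wc$matrices[[j]]),
                 sprintf("correlation_%s_window%d.csv", tag, j))
          }
          if (!is.null(wc$block_contrast)) {
            emit(wc$block_contrast,
                 sprintf("correlation_%s_block_contrast.csv", tag))
          }
        },
        autocorrelation = emit(unclass_matrix(bond_autocorrelation(
                                 tr, unlist(a$delays))),
                               sprintf("autocorrelation_%s.csv", tag)),
        clustering = {
          tl <- trajs[tn]
          cm <- cluster_conformations(tl, reference, sel(a$fit),
                                      radius = a$radius,
                                      seed = a$seed %||% 1L,
                                      selection = sel(a$selection))
          emit(cm$occupancy, sprintf("clustering_%s_occupancy.csv", tag))
          tlall <- do.call(rbind, lapply(names(cm$timeline), function(s)
            cbind(trajectory = s, cm$timeline[[s]])))
          emit(tlall, sprintf("clustering_%s_timeline.csv", tag))
          sub <- tl[[1]]$topology[cm$selection, , drop = FALSE]
          subtop <- topology(sub$chain, sub$resno, sub$resname)
          arr <- array(0, c(length(cm$centroids), nrow(subtop), 3L))
          for (k in seq_along(cm$centroids)) arr[k, , ] <- cm$centroids[[k]]
          emit(trajectory(subtop, arr, frame_interval = 1),
               sprintf("clustering_%s_centroids.pdb", tag),
               writer = write_trajectory_pdb)
          med <- representative_structures(cm)
          arrm <- array(0, c(length(med), nrow(subtop), 3L))
          for (k in seq_along(med)) arrm[k, , ] <- med[[k]]$coords
          emit(trajectory(subtop, arrm, frame_interval = 1),
               sprintf("clustering_%s_medoids.pdb", tag),
               writer = write_trajectory_pdb)
        },
        pca = {
          tl <- trajs[tn]
          pm <- pca_fit(tl, reference, sel(a$fit),
                        selection = sel(a$selection))
          emit(data.frame(component = seq_along(pm$eigenvalues),
                          eigenvalue = pm$eigenvalues,
                          proportion = pm$proportions,
                          cumulative = pm$cumulative),
               sprintf("pca_%s_eigenvalues.csv", tag))
          comps <- as.integer(unlist(a$components %||% c(1L, 2L)))
          for (s in tn) {
            emit(pca_project(trajs[[s]], pm, comps),
                 sprintf("pca_%s_projection_%s.csv", tag, s))
          }
        })
    }
    for (stage in intersect(pipeline_stages, names(an))) {
      if (!stage %in% stages) next
      current_stage <- stage
      for (i in seq_along(an[[stage]])) {
        logf("info", "stage ", stage, "[", i, "]")
        run_one(stage, i, an[[stage]][[i]])
      }
    }
    manifest$status <- "complete"
    write_manifest()
    logf("info", "pipeline complete: ", length(outputs), " output(s)")
    manifest
  }, error = function(e) {
    manifest$status <<- "incomplete"
    manifest$failed_stage <<- current_stage
    manifest$error <<- conditionMessage(e)
    write_manifest()
    logf("error", "stage '", current_stage, "' failed: ",
         conditionMessage(e))
    stop("pipeline stage '", current_stage, "' failed: ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(result)
}

# strip S3 class/attrs so write_results sees a plain labeled matrix
unclass_matrix <- function(m) {
  out <- unclass(m)
  attributes(out) <- list(dim = dim(out), dimnames = dimnames(out))
  out
}
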