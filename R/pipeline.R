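#' Pipeline configuration
#'
#' Assembles and validates everything one end-to-end run needs: the two epoch
#' land-use inputs (each either a raster path or a simulation spec, exactly
#' one per epoch), the threat/sensitivity parameterization, quality and
#' grading settings, the zonal table for driver attribution (a path or a
#' [zonal_design()]), and the output directory.
#'
#' @param epoch_a,epoch_b Either a file path to a land-use raster or a
#'   [sim_config()]. When epoch_b is a [transition_model()], epoch b is
#'   simulated by evolving epoch a with it.
#' @param threats A [threat_table()] or a CSV path.
#' @param sensitivity A [sensitivity_table()] or a CSV path.
#' @param access Optional accessibility raster path or [value_raster()].
#' @param years Epoch separation in years.
#' @param k,z Quality parameters (see [compute_quality()]).
#' @param quality_scheme,degradation_scheme [grade_scheme()]s.
#' @param zonal A [zonal_design()], a CSV path, or `NULL` to skip the
#'   detector stage.
#' @param detector_args List of extra arguments to [run_detectors()].
#' @param out_dir Output directory (created if absent).
#' @param seed Integer master seed for every stochastic stage.
#' @param verbose Log stage progress to stderr.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(epoch_a, epoch_b, threats = poyang_threats(),
                            sensitivity = poyang_sensitivity(),
                            access = NULL, years = 10, k = 0.5, z = 2.5,
                            quality_scheme = quality_grades(),
                            degradation_scheme = NULL,
                            zonal = NULL, detector_args = list(),
                            out_dir = tempfile("habiq_run_"), seed = 1L,
                            verbose = FALSE) {
  check_epoch <- function(x, nm) {
    ok <- inherits(x, c("sim_config", "lu_raster", "transition_model")) ||
      (is.character(x) && length(x) == 1L)
    if (!ok) stop("`", nm, "` must be a raster path, lu_raster, sim_config ",
                  "or (epoch_b) transition_model", call. = FALSE)
    if (is.character(x) && !file.exists(x)) {
      stop("`", nm, "` file does not exist: ", x, call. = FALSE)
    }
  }
  check_epoch(epoch_a, "epoch_a")
  check_epoch(epoch_b, "epoch_b")
  if (is.character(threats)) threats <- read_params(threats, if (is.character(sensitivity)) sensitivity else stop("give both parameter paths or both objects", call. = FALSE))$threats
  threats <- threat_table(threats)
  if (is.character(sensitivity)) {
    sensitivity <- sensitivity_table(
      readr::read_csv(sensitivity, show_col_types = FALSE), threats = threats)
  } else {
    sensitivity <- sensitivity_table(sensitivity, threats = threats)
  }
  if (is.character(access) && !file.exists(access)) {
    stop("accessibility raster does not exist: ", access, call. = FALSE)
  }
  if (is.character(zonal) && !file.exists(zonal)) {
    stop("zonal table does not exist: ", zonal, call. = FALSE)
  }
  structure(
    list(epoch_a = epoch_a, epoch_b = epoch_b, threats = threats,
         sensitivity = sensitivity, access = access, years = years,
         k = k, z = z, quality_scheme = quality_scheme,
         degradation_scheme = degradation_scheme, zonal = zonal,
         detector_args = detector_args, out_dir = out_dir,
         seed = as.integer(seed), verbose = isTRUE(verbose)),
    class = "pipeline_config"
  )
}

log_stage <- function(cfg, ...) {
  if (cfg$verbose) message("[habiq] ", ...)
  invisible(NULL)
}

resolve_epoch <- function(x, cfg, seed, base = NULL) {
  if (inherits(x, "lu_raster")) return(x)
  if (is.character(x)) return(read_raster(x))
  if (inherits(x, "sim_config")) return(generate_landuse(x, seed = seed))
  if (inherits(x, "transition_model")) {
    if (is.null(base)) stop("epoch_a must resolve before a transition_model epoch_b",
                            call. = FALSE)
    return(evolve_landuse(base, x, seed = seed))
  }
  stop("unresolvable epoch input", call. = FALSE)
}

# round-then-write so reruns under the same seed are byte-identical
write_csv_fixed <- function(df, path, digits = 10) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, digits))
  readr::write_csv(df, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: resolve/simulate the two epoch rasters; compute
#' degradation and quality for each epoch; classify both surfaces and
#' cross-tabulate quality grades with land use; build the transfer matrix and
#' land-use dynamics; run the geographical detectors on the zonal table.
#' Every output is a raster (`.asc`) or CSV under `cfg$out_dir`, and the run
#' report lists each file with its checksum, so a rerun with the same config
#' and seed is byte-identical.
#'
#' @param cfg A [pipeline_config()].
#' @return A `run_report`: tibble of stages (status, seconds) plus a
#'   `manifest` attribute (file, md5) and the key result objects in
#'   `$results`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  results <- list()
  written <- character()
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    log_stage(cfg, "stage: ", name)
    val <- tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    stages[[name]] <<- proc.time()[["elapsed"]] - t0
    val
  }
  out <- function(file) {
    path <- file.path(cfg$out_dir, file)
    written <<- c(written, path)
    path
  }

  lu_a <- run_stage("epoch_a", function()
    resolve_epoch(cfg$epoch_a, cfg, seed = sub_seed(cfg$seed, 11L)))
  lu_b <- run_stage("epoch_b", function()
    resolve_epoch(cfg$epoch_b, cfg, seed = sub_seed(cfg$seed, 12L), base = lu_a))
  write_raster(lu_a, out("landuse_a.asc"))
  write_raster(lu_b, out("landuse_b.asc"))

  access <- if (is.character(cfg$access)) read_raster(cfg$access, integer = FALSE) else cfg$access

  hq <- run_stage("habitat_quality", function() {
    lapply(list(a = lu_a, b = lu_b), function(lu) {
      D <- compute_degradation(lu, cfg$threats, cfg$sensitivity, access = access)
      Q <- compute_quality(D, lu, cfg$sensitivity, k = cfg$k, z = cfg$z)
      list(D = D, Q = Q)
    })
  })
  for (ep in names(hq)) {
    write_raster(hq[[ep]]$D, out(paste0("degradation_", ep, ".asc")))
    write_raster(hq[[ep]]$Q, out(paste0("quality_", ep, ".asc")))
  }
  grading <- run_stage("grading", function() {
    dscheme <- cfg$degradation_scheme %||% {
      dmax <- max(unlist(lapply(hq, function(e) max(e$D$values, na.rm = TRUE))))
      degradation_grades(upper = max(0.2, dmax * 1.0000001))
    }
    gq <- classify_raster(hq$b$Q, cfg$quality_scheme)
    gd <- classify_raster(hq$b$D, dscheme)
    xt <- summarize_by_landuse(gq, lu_b)
    write_csv_fixed(gq$areas, out("quality_grade_areas.csv"))
    write_csv_fixed(gd$areas, out("degradation_grade_areas.csv"))
    write_csv_fixed(xt, out("quality_by_landuse.csv"))
    list(quality = gq, degradation = gd, crosstab = xt)
  })
  change <- run_stage("land_change", function() {
    tm <- transfer_matrix(lu_a, lu_b, years = cfg$years)
    rep <- transition_shares(tm)
    write_transfer_csv(tm, out("transfer_matrix.csv"))
    write_csv_fixed(rep$classes, out("dynamics.csv"))
    write_csv_fixed(rep$shares, out("transition_shares.csv"))
    list(matrix = tm, report = rep)
  })
  detect <- run_stage("geodetector", function() {
    if (is.null(cfg$zonal)) return(NULL)
    tab <- if (is.character(cfg$zonal)) {
      readr::read_csv(cfg$zonal, show_col_types = FALSE)
    } else {
      generate_zonal_table(cfg$zonal, seed = sub_seed(cfg$seed, 13L))
    }
    args <- c(list(table = tab), cfg$detector_args)
    if (is.null(args$seed)) args$seed <- sub_seed(cfg$seed, 14L)
    rep <- do.call(run_detectors, args)
    write_csv_fixed(tab, out("zonal_table.csv"))
    write_csv_fixed(rep$factor, out("detector_factors.csv"))
    if (nrow(rep$interaction)) {
      write_csv_fixed(rep$interaction, out("detector_interactions.csv"))
    }
    if (nrow(rep$ecological)) {
      write_csv_fixed(rep$ecological, out("detector_ecological.csv"))
    }
    rep
  })

  manifest <- tibble::tibble(
    file = basename(written),
    md5 = unname(tools::md5sum(written))
  )
  report <- tibble::tibble(
    stage = names(stages),
    status = "ok",
    seconds = round(unlist(stages), 3)
  )
  results <- list(lu_a = lu_a, lu_b = lu_b, quality = hq$b$Q,
                  degradation = hq$b$D, grading = grading,
                  change = change, detectors = detect)
  structure(list(stages = report, manifest = manifest, results = results,
                 out_dir = cfg$out_dir, seed = cfg$seed),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed", x$seed, "->", x$out_dir, "\n")
  print(x$stages)
  cat("\nManifest:\n")
  print(x$manifest)
  invisible(x)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file mirrors the arguments of [pipeline_config()]; epoch entries are
#' either `path: file.asc` or a `simulate:` block with `rows`, `cols`,
#' `cell_size`, `codes`, `proportions`, `autocorr_scale`, and `zonal` is
#' either `path:` or a `design:` block mirroring [zonal_design()].
#'
#' @param path Config file path (`.yml`, `.yaml` or `.json`).
#' @param out_dir,seed Optional overrides.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path, out_dir = NULL, seed = NULL) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("config must be YAML or JSON", call. = FALSE)
  parse_epoch <- function(e) {
    if (is.character(e)) return(e)
    if (!is.null(e$path)) return(e$path)
    if (!is.null(e$simulate)) {
      s <- e$simulate
      return(sim_config(s$rows, s$cols, s$cell_size %||% 30,
                        codes = unlist(s$codes),
                        proportions = unlist(s$proportions),
                        autocorr_scale = s$autocorr_scale %||% 0))
    }
    stop("epoch entry needs `path` or `simulate`", call. = FALSE)
  }
  zonal <- if (is.null(raw[["zonal"]])) NULL else if (is.character(raw[["zonal"]])) {
    raw[["zonal"]]
  } else if (!is.null(raw[["zonal"]][["path"]])) raw[["zonal"]][["path"]] else {
    d <- raw[["zonal"]][["design"]]
    zonal_design(d$n_units, unlist(d$n_strata), unlist(d$between_fraction),
                 noise_sd = d$noise_sd %||% 1)
  }
  pipeline_config(
    epoch_a = parse_epoch(raw[["epoch_a"]]),
    epoch_b = parse_epoch(raw[["epoch_b"]]),
    threats = if (is.null(raw[["threats"]])) poyang_threats() else raw[["threats"]],
    sensitivity = if (is.null(raw[["sensitivity"]])) poyang_sensitivity() else raw[["sensitivity"]],
    access = raw[["access"]],
    years = raw[["years"]] %||% 10,
    k = raw[["k"]] %||% 0.5, z = raw[["z"]] %||% 2.5,
    zonal = zonal,
    out_dir = out_dir %||% raw[["out_dir"]] %||% tempfile("habiq_run_"),
    seed = seed %||% raw[["seed"]] %||% 1L,
    verbose = isTRUE(raw[["verbose"]])
  )
}
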