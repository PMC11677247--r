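#' Orchestration pipeline
#'
#' Stage sequencing (build, materials, load, simulate, classify, report),
#' verification drivers (stiffness convergence), field output and the
#' command-line entry point.
#'
#' @name pipeline
NULL

#' Secant stiffness from force/displacement data
#'
#' With a target, the displacement at the first crossing of the target
#' force is interpolated from the histories; without one, the last point is
#' used. Scalars work directly: `stiffness(44.48, 28e-6)` is the stiffness
#' of a 10-pound load settling 28 um.
#'
#' @param force force history, N.
#' @param displacement displacement history, m (same length).
#' @param target target force, N (optional).
#' @return secant stiffness, kN/mm.
#' @export
stiffness <- function(force, displacement, target = NULL) {
  stopifnot(length(force) == length(displacement))
  if (any(!is.finite(force)) || any(!is.finite(displacement)))
    stop("non-finite history values", call. = FALSE)
  if (is.null(target)) {
    Ft <- force[length(force)]
    ut <- displacement[length(displacement)]
  } else {
    if (target <= 0) stop("target force must be positive", call. = FALSE)
    idx <- which(force >= target)[1]
    if (is.na(idx)) stop("force history never reaches the target", call. = FALSE)
    if (idx == 1) {
      ut <- displacement[1]
    } else {
      f <- (target - force[idx - 1]) / (force[idx] - force[idx - 1])
      ut <- displacement[idx - 1] + f * (displacement[idx] - displacement[idx - 1])
    }
    Ft <- target
  }
  if (!(Ft > 0)) stop("zero force: stiffness undefined", call. = FALSE)
  if (abs(ut) < 1e-15) stop("zero displacement: stiffness undefined", call. = FALSE)
  (Ft / ut) / 1e6
}

#' Discretization convergence of the physiological benchmark stiffness
#'
#' Runs the physiological ramp on the same geometry at several element
#' diameters and reports the secant stiffness of each together with the
#' maximum pairwise relative difference (in percent of the pair mean).
#'
#' @param spec benchmark `osseo_spec` (its `d` is overridden).
#' @param diameters element diameters to run, m (at least 3).
#' @param target target force, N.
#' @param materials material table.
#' @param ... passed to [simulate_physio()].
#' @return data.frame `d`, `N`, `stiffness_kN_mm`; attribute `spread_pct`.
#' @export
convergence_study <- function(spec = model_spec(),
                              diameters = c(500, 400, 1000 / 3) * 1e-6,
                              target = 100,
                              materials = load_material_table(), ...) {
  if (length(diameters) < 3) stop("need at least 3 diameters", call. = FALSE)
  rows <- lapply(diameters, function(dd) {
    sp <- spec
    sp$d <- dd
    model <- build_model(sp, materials)
    run <- simulate_physio(model, physio_protocol(target = target), ...)
    data.frame(d = dd, N = nrow(model$positions),
               stiffness_kN_mm = run$stiffness_kN_mm)
  })
  out <- do.call(rbind, rows)
  ord <- order(out$d, decreasing = TRUE)
  if (is.unsorted(out$N[ord]))
    stop("element count not monotone in diameter: packing bug", call. = FALSE)
  S <- out$stiffness_kN_mm
  spread <- 0
  for (i in seq_along(S)) for (j in seq_along(S)) if (j > i) {
    spread <- max(spread, abs(S[i] - S[j]) / mean(c(S[i], S[j])))
  }
  attr(out, "spread_pct") <- 100 * spread
  out
}

region_codes <- function(region) {
  lev <- c("gingiva", "cortical", "cancellous", "implant", "shell",
           "fibrous_interface", "applicator", "dentin", "PDL", "base", "bulk")
  match(region, lev)
}

#' Write element fields as a legacy-VTK point cloud (plus CSV summary)
#'
#' One point per element with scalar fields (region and material ids, mean
#' stress, von Mises stress, pore pressure, shear strain, and fate label if
#' a threshold set is given). Values are written at float32 precision.
#'
#' @param model an `osseo_model`.
#' @param run an `osseo_run` (final state fields); optional.
#' @param path output `.vtk` path.
#' @param th thresholds for fate labels (optional).
#' @return the path, invisibly.
#' @export
write_fields <- function(model, run = NULL, path, th = NULL) {
  n <- nrow(model$positions)
  con <- try(suppressWarnings(file(path, "w")), silent = TRUE)
  if (inherits(con, "try-error"))
    stop(sprintf("cannot write '%s'", path), call. = FALSE)
  on.exit(close(con))
  fm <- function(x) sprintf("%.8g", x)
  writeLines(c("# vtk DataFile Version 3.0",
               "osseowave element fields", "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", n)), con)
  writeLines(apply(model$positions, 1, function(r)
    paste(fm(r), collapse = " ")), con)
  scalars <- list(region_id = region_codes(model$region),
                  material_id = as.integer(factor(model$material)))
  if (!is.null(run)) {
    scalars$mean_stress <- run$sbar
    scalars$von_mises <- run$vm
    scalars$pore_pressure <- run$P
    scalars$shear_strain <- run$shear
    if (!is.null(th)) {
      scalars$fate_id <- as.integer(classify_fate(run$sbar, run$shear, th))
    }
  }
  writeLines(sprintf("POINT_DATA %d", n), con)
  for (nm in names(scalars)) {
    writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"),
               con)
    writeLines(fm(as.numeric(scalars[[nm]])), con)
  }
  invisible(path)
}

#' Read a legacy-VTK point cloud written by [write_fields()]
#'
#' @param path `.vtk` file path.
#' @return list `points` (matrix) and `data` (named list of scalars).
#' @export
read_vtk_points <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)[1]
  n <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  toks <- unlist(strsplit(trimws(lines[(ip + 1):(ip + n)]), "[[:space:]]+"))
  pts <- matrix(as.numeric(toks[nzchar(toks)]), ncol = 3, byrow = TRUE)
  data <- list()
  isc <- grep("^SCALARS", lines)
  for (i in isc) {
    nm <- strsplit(lines[i], "\\s+")[[1]][2]
    data[[nm]] <- as.numeric(lines[(i + 2):(i + 1 + n)])
  }
  list(points = pts, data = data)
}

#' Write the per-sample zone-fraction table as CSV
#'
#' Long format: one row per time sample and label.
#'
#' @param report an `osseo_fate_report`.
#' @param path output `.csv` path.
#' @return the path, invisibly.
#' @export
write_fraction_csv <- function(report, path) {
  per <- attr(report$fates, "per_sample")
  df <- data.frame(sample = rep(seq_len(nrow(per)), times = ncol(per)),
                   label = rep(colnames(per), each = nrow(per)),
                   fraction = as.numeric(per))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

default_run_config <- function() {
  list(geometry = list(), phase = 1, seed = 1,
       protocol = list(type = "eswt", EFD = c(0.02, 0.15, 0.26)),
       record_every = 5, outdir = NULL, keep_runs = FALSE,
       thresholds = list())
}

#' Load a scenario configuration
#'
#' @param path YAML file or a config list.
#' @return validated config list.
#' @export
load_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  full <- default_run_config()
  full[names(cfg)] <- cfg
  if (!full$protocol$type %in% c("eswt", "physio"))
    stop("protocol type must be 'eswt' or 'physio'", call. = FALSE)
  full
}

#' Run a complete analysis scenario
#'
#' Stage sequence: build geometry and materials, apply the loading
#' protocol (ESWT pulse train per energy flux density, or physiological
#' ramp per force target), simulate, classify the peri-implant zone, and
#' summarize. Deterministic for a fixed configuration and seed. When an
#' output directory is given, the resolved configuration, a VTK snapshot
#' and CSV/JSON summaries are written next to each other.
#'
#' @param config a config list or YAML path (see [load_run_config()]).
#' @return an `osseo_scenario`: list with `summary` (data.frame),
#'   `reports` (fate reports per ESWT run) or `histories` (physio runs),
#'   and `config`.
#' @export
run_scenario <- function(config) {
  cfg <- load_run_config(config)
  set.seed(cfg$seed)
  spec <- do.call(model_spec, c(cfg$geometry,
                                list(phase = cfg$phase, seed = cfg$seed)))
  model <- build_model(spec)
  th <- do.call(mechanobio_thresholds, cfg$thresholds)
  outdir <- cfg$outdir
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  reports <- list()
  histories <- list()
  runs <- list()
  rows <- list()
  if (cfg$protocol$type == "eswt") {
    for (efd in cfg$protocol$EFD) {
      run <- simulate_eswt(model, eswt_protocol(EFD = efd),
                           record_every = cfg$record_every)
      rep <- fate_report(run, th)
      tag <- sprintf("efd%.3g", efd)
      reports[[tag]] <- rep
      if (isTRUE(cfg$keep_runs)) runs[[tag]] <- run
      fr <- stats::setNames(rep$fates$fraction, rep$fates$label)
      rows[[tag]] <- data.frame(
        phase = spec$phase, EFD = efd, t(fr),
        transport_sufficient = rep$transport_sufficient,
        max_shear_pct = 100 * run$max_zone_pair_shear)
      if (!is.null(outdir)) {
        write_fields(model, run,
                     file.path(outdir, sprintf("fields_phase%d_%s.vtk",
                                               spec$phase, tag)), th)
        write_fraction_csv(rep,
                           file.path(outdir, sprintf("fractions_phase%d_%s.csv",
                                                     spec$phase, tag)))
      }
    }
  } else {
    for (tgt in cfg$protocol$targets) {
      run <- simulate_physio(model, physio_protocol(target = tgt),
                             record_every = cfg$record_every)
      tag <- sprintf("F%g", tgt)
      histories[[tag]] <- data.frame(t = run$t, force = run$F_ramp,
                                     force_smooth = run$F_ramp_smooth,
                                     displacement = run$u_ramp)
      if (isTRUE(cfg$keep_runs)) runs[[tag]] <- run
      rows[[tag]] <- data.frame(
        phase = spec$phase, target_N = tgt,
        stiffness_kN_mm = run$stiffness_kN_mm,
        u_at_target_um = 1e6 * run$u_ramp_at_target)
      if (!is.null(outdir)) {
        write_fields(model, run,
                     file.path(outdir, sprintf("fields_phase%d_%s.vtk",
                                               spec$phase, tag)), th)
        utils::write.csv(histories[[tag]],
                         file.path(outdir, sprintf("history_phase%d_%s.csv",
                                                   spec$phase, tag)),
                         row.names = FALSE)
      }
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  out <- list(summary = summary, reports = reports, histories = histories,
              runs = runs, config = cfg,
              model_summary = summarize_model(model))
  class(out) <- "osseo_scenario"
  if (!is.null(outdir)) {
    yaml::write_yaml(cfg[setdiff(names(cfg), "outdir")],
                     file.path(outdir, "resolved_config.yaml"))
    utils::write.csv(summary, file.path(outdir, "summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(package = "osseowave",
           n_elements = out$model_summary$n, phase = spec$phase,
           seed = cfg$seed, protocol = cfg$protocol),
      file.path(outdir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.osseo_scenario <- function(x, ...) {
  cat(sprintf("<osseo_scenario> %s protocol, phase %d, %d elements\n",
              x$config$protocol$type, x$config$phase, x$model_summary$n))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

cli_usage <- function() {
  paste(
    "usage: osseowave <command> [options]",
    "",
    "commands:",
    "  build    --config FILE [--seed N]        build a model, print a summary",
    "  run      --config FILE [--outdir DIR] [--seed N]",
    "           run a scenario, write fields and summaries",
    "  verify   [--suite modulus|wave|undrained|terzaghi|energy|all]",
    "           run analytic verification oracles",
    "  classify --fields FILE.vtk               classify a saved field snapshot",
    "  report   --outdir DIR                    print the summary of a run",
    "",
    "global options: --log-level LEVEL",
    sep = "\n")
}

parse_cli_args <- function(argv) {
  opts <- list()
  i <- 1
  while (i <= length(argv)) {
    a <- argv[i]
    if (startsWith(a, "--")) {
      if (i == length(argv) || startsWith(argv[i + 1], "--"))
        stop(sprintf("missing value for option %s", a), call. = FALSE)
      opts[[substring(a, 3)]] <- argv[i + 1]
      i <- i + 2
    } else {
      stop(sprintf("unexpected argument '%s'", a), call. = FALSE)
    }
  }
  opts
}

#' Command-line entry point
#'
#' Thin shell interface over the package functions; see
#' `inst/scripts/osseowave.R` for the executable wrapper.
#'
#' @param argv character vector of arguments.
#' @return integer exit code (0 on success).
#' @export
osseo_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0) {
    cat(cli_usage(), "\n")
    return(2L)
  }
  cmd <- argv[1]
  opts <- try(parse_cli_args(argv[-1]), silent = TRUE)
  if (inherits(opts, "try-error")) {
    cat(attr(opts, "condition")$message, "\n")
    cat(cli_usage(), "\n")
    return(2L)
  }
  seed <- if (!is.null(opts$seed)) as.integer(opts$seed) else 1L
  if (cmd == "build") {
    if (is.null(opts$config)) { cat(cli_usage(), "\n"); return(2L) }
    cfg <- load_run_config(opts$config)
    spec <- do.call(model_spec, c(cfg$geometry,
                                  list(phase = cfg$phase, seed = seed)))
    print(build_model(spec))
    return(0L)
  }
  if (cmd == "run") {
    if (is.null(opts$config)) { cat(cli_usage(), "\n"); return(2L) }
    cfg <- load_run_config(opts$config)
    if (!is.null(opts$outdir)) cfg$outdir <- opts$outdir
    cfg$seed <- seed
    print(run_scenario(cfg))
    return(0L)
  }
  if (cmd == "verify") {
    suites <- if (is.null(opts$suite) || opts$suite == "all")
      c("modulus", "wave", "undrained", "terzaghi", "energy") else opts$suite
    res <- verify_suite(suites)
    print(res, row.names = FALSE)
    return(if (all(res$pass)) 0L else 1L)
  }
  if (cmd == "classify") {
    if (is.null(opts$fields)) { cat(cli_usage(), "\n"); return(2L) }
    vtk <- read_vtk_points(opts$fields)
    if (is.null(vtk$data$mean_stress)) {
      cat("snapshot carries no stress fields\n")
      return(1L)
    }
    fates <- classify_fate(vtk$data$mean_stress, vtk$data$shear_strain)
    print(zone_fractions(fates, levels = FATE_LEVELS), row.names = FALSE)
    return(0L)
  }
  if (cmd == "report") {
    if (is.null(opts$outdir)) { cat(cli_usage(), "\n"); return(2L) }
    f <- file.path(opts$outdir, "summary.csv")
    if (!file.exists(f)) { cat("no summary.csv in outdir\n"); return(1L) }
    print(utils::read.csv(f), row.names = FALSE)
    return(0L)
  }
  cat(sprintf("unknown command '%s'\n", cmd))
  cat(cli_usage(), "\n")
  2L
}
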