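#' Read and validate a simulation config file
#'
#' Flat JSON whose keys mirror [sim_params()] argument names (and units).
#' Unknown keys are rejected loudly rather than silently ignored.
#'
#' @param path JSON file.
#' @return named list of `sim_params` arguments.
#' @export
read_sim_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- names(formals(sim_params))
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0)
    stop("read_sim_config: unknown keys: ", paste(unknown, collapse = ", "),
         "; allowed keys are the sim_params() arguments")
  cfg
}

#' Write a run manifest
#'
#' Written before computation starts: command, resolved configuration,
#' seed(s), package version, output paths and timestamp -- enough to replay
#' the run exactly.
#'
#' @param out_dir output directory; @param command command name;
#' @param config resolved configuration list; @param seed seed(s);
#' @param outputs named list/vector of output paths.
#' @return manifest list, invisibly; written to `manifest.json`.
#' @export
write_manifest <- function(out_dir, command, config, seed, outputs) {
  man <- list(command = command, config = config, seed = seed,
              package = "actring",
              version = as.character(utils::packageVersion("actring")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              outputs = outputs)
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(man)
}

#' Write a skeleton in SWC format
#'
#' One sample per polyline point (type 0, radius 1); parent links encode the
#' polyline chains; each polyline starts a new root (-1 parent), closed
#' polylines repeat their first point id as the final parent.
#'
#' @param skel a skeleton; @param path output file.
#' @return `path` invisibly.
#' @export
write_swc <- function(skel, path) {
  lines <- c("# SWC export: actin bundle skeleton",
             "# columns: id type x y z radius parent")
  id <- 0
  for (q in seq_along(skel$polylines)) {
    p <- skel$polylines[[q]]
    first <- id + 1
    for (i in seq_len(nrow(p))) {
      id <- id + 1
      parent <- if (i == 1) -1 else id - 1
      if (skel$closed[q] && i == nrow(p)) parent <- first
      lines <- c(lines, sprintf("%d 0 %.4f %.4f %.4f 1 %d",
                                id, p[i, 1], p[i, 2], p[i, 3], parent))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

.cli_args <- function(argv, spec) {
  # spec: named list default values; flags are --name value
  out <- spec
  i <- 1
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a)
    key <- gsub("-", "_", substring(a, 3))
    if (!key %in% names(spec)) stop("unknown flag --", substring(a, 3))
    out[[key]] <- utils::type.convert(argv[i + 1], as.is = TRUE)
    i <- i + 2
  }
  out
}

#' Command-line entry points
#'
#' Thin wrappers over the package functions, used by the `actring` script in
#' `inst/cli/`. Each writes a run manifest before computing and returns 0 on
#' success.
#'
#' * `cmd_simulate`: `--config FILE --seed N --out DIR` -- one simulation;
#'   writes `trajectory.rds` and `trajectory.csv`.
#' * `cmd_sweep`: `--grid FILE --replicates N --seed N --out DIR` -- ring
#'   probability sweep; writes `ring_probability.csv`, per-replicate
#'   `ring_report_<c>_<r>.json` and `mip_<c>_<r>.tif` (16-bit).
#' * `cmd_quantify`: `--stack BASE [--membrane BASE] --out DIR
#'   [--seg_len 1] [--proximity_mode cubic]` -- image pipeline; writes
#'   `geometry.json`, `skeleton.swc`, `curvature.csv`, `proximity.csv`,
#'   `ring_report.json`.
#' * `cmd_synth`: `--kind K --n N --seed N --out DIR` (or
#'   `--suite TRUE`) -- synthetic stacks.
#'
#' @param argv character vector of command-line arguments.
#' @return 0 invisibly on success (errors propagate as R errors).
#' @name cli
NULL

#' @rdname cli
#' @export
cmd_simulate <- function(argv = character(0)) {
  a <- .cli_args(argv, list(config = NA, seed = 1L, out = "."))
  dir.create(a$out, showWarnings = FALSE, recursive = TRUE)
  cfg <- if (is.na(a$config)) list() else read_sim_config(a$config)
  cfg$seed <- a$seed
  params <- do.call(sim_params, cfg)
  outs <- list(trajectory = file.path(a$out, "trajectory.rds"),
               csv = file.path(a$out, "trajectory.csv"))
  write_manifest(a$out, "simulate", cfg, a$seed, outs)
  traj <- run_simulation(params, verbose = TRUE)
  write_trajectory(traj, outs$trajectory)
  export_trajectory_csv(traj, outs$csv)
  invisible(0L)
}

#' @rdname cli
#' @export
cmd_sweep <- function(argv = character(0)) {
  a <- .cli_args(argv, list(grid = NA, replicates = 5L, seed = 1L,
                            out = "."))
  dir.create(a$out, showWarnings = FALSE, recursive = TRUE)
  gr <- jsonlite::read_json(a$grid, simplifyVector = TRUE)
  grid <- as.data.frame(gr$conditions)
  base_args <- if (is.null(gr$base)) list() else as.list(gr$base)
  write_manifest(a$out, "sweep",
                 list(grid = a$grid, replicates = a$replicates),
                 a$seed, list(csv = file.path(a$out,
                                              "ring_probability.csv")))
  cb <- function(cond, ri, seed, traj, report) {
    ci <- attr(cond, "row.names")
    jsonlite::write_json(
      list(condition = as.list(cond), replicate = ri, seed = seed,
           classification = report$classification,
           cycle_fraction = report$cycle_fraction,
           gap_fraction = report$gap_fraction,
           n_side_branches = report$n_side_branches),
      file.path(a$out, sprintf("ring_report_%s_%d.json", ci, ri)),
      auto_unbox = TRUE, digits = NA)
    img <- simulated_mip(final_snapshot(traj))
    img <- img / max(img, 1e-12)
    tiff::writeTIFF(img, file.path(a$out, sprintf("mip_%s_%d.tif", ci, ri)),
                    bits.per.sample = 16)
  }
  tab <- ring_probability(grid, a$replicates, master_seed = a$seed,
                          base_args = base_args, on_replicate = cb,
                          verbose = TRUE)
  utils::write.csv(tab, file.path(a$out, "ring_probability.csv"),
                   row.names = FALSE)
  invisible(0L)
}

#' @rdname cli
#' @export
cmd_quantify <- function(argv = character(0)) {
  a <- .cli_args(argv, list(stack = NA, out = ".", seg_len = 1,
                            proximity_mode = "cubic"))
  dir.create(a$out, showWarnings = FALSE, recursive = TRUE)
  outs <- list(geometry = file.path(a$out, "geometry.json"),
               swc = file.path(a$out, "skeleton.swc"),
               curvature = file.path(a$out, "curvature.csv"),
               proximity = file.path(a$out, "proximity.csv"),
               report = file.path(a$out, "ring_report.json"))
  write_manifest(a$out, "quantify",
                 list(stack = a$stack, seg_len = a$seg_len,
                      proximity_mode = a$proximity_mode),
                 NA, outs)
  stack <- read_stack(a$stack)
  geo <- detect_vesicle(stack)
  jsonlite::write_json(list(center = geo$center, R_ves = geo$R_ves,
                            residual = geo$residual, channel = geo$channel),
                       outs$geometry, auto_unbox = TRUE, digits = NA)
  skel <- extract_skeleton(stack, geo)
  write_swc(skel, outs$swc)
  cv <- segment_curvature(skel, geo, seg_len = a$seg_len)
  utils::write.csv(data.frame(kappa = cv$kappa, kappa_rel = cv$kappa_rel),
                   outs$curvature, row.names = FALSE)
  pr <- membrane_proximity(stack, geo, mode = a$proximity_mode)
  prof <- pr$profile
  prof$P <- pr$P
  utils::write.csv(prof, outs$proximity, row.names = FALSE)
  rep1 <- classify_ring_image(skel, geo)
  jsonlite::write_json(list(classification = rep1$classification,
                            cycle_fraction = rep1$cycle_fraction,
                            gap_fraction = rep1$gap_fraction,
                            n_side_branches = rep1$n_side_branches),
                       outs$report, auto_unbox = TRUE, digits = NA)
  invisible(0L)
}

#' @rdname cli
#' @export
cmd_synth <- function(argv = character(0)) {
  a <- .cli_args(argv, list(kind = "ring", n = 1L, seed = 1L, out = ".",
                            suite = FALSE, R_ves = 8))
  dir.create(a$out, showWarnings = FALSE, recursive = TRUE)
  write_manifest(a$out, "synth", a[c("kind", "n", "suite", "R_ves")],
                 a$seed, list(dir = a$out))
  if (isTRUE(a$suite)) {
    fixture_suite(a$out, R_ves = a$R_ves, seed = a$seed)
    return(invisible(0L))
  }
  for (i in seq_len(a$n)) {
    st <- render_stack(scene_spec(a$kind, R_ves = a$R_ves,
                                  seed = a$seed + i),
                       seed = a$seed + i)
    write_stack(st, file.path(a$out, sprintf("%s_%03d", a$kind, i)))
  }
  invisible(0L)
}
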