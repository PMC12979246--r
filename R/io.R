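#' Read a multi-page grayscale TIFF movie
#'
#' Pixel values are returned as nonnegative integers. Physical
#' metadata (pixel size, frame interval) is taken from the arguments,
#' not from TIFF tags, to avoid TIFF-dialect ambiguity.
#'
#' @param path path to a multi-page 8/16-bit grayscale TIFF.
#' @param pixel_size pixel size in um/px.
#' @param frame_interval frame interval in seconds.
#' @return an `spt_movie`.
#' @export
read_movie <- function(path, pixel_size, frame_interval) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      stop(sprintf("cannot read TIFF '%s': %s", path,
                                   conditionMessage(e))))
  if (!is.list(pages)) pages <- list(pages)
  for (p in pages)
    if (length(dim(p)) != 2)
      stop(sprintf("'%s' is not single-channel grayscale", path))
  frames <- lapply(pages, function(p)
    matrix(as.integer(p), nrow(p), ncol(p)))
  spt_movie(frames, pixel_size, frame_interval)
}

#' Write a movie as a multi-page 16-bit grayscale TIFF
#'
#' @param movie an `spt_movie`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "spt_movie"))
  mx <- max(vapply(movie$frames, max, numeric(1)))
  if (mx > 65535) stop("photon counts exceed 16-bit range")
  tiff::writeTIFF(lapply(movie$frames, function(f) f / 65535),
                  path, bits.per.sample = 16)
  invisible(path)
}

#' Write / read a ground-truth trajectory table
#'
#' CSV columns: `molecule_id, frame, x_um, y_um, state, emitting`.
#' Floats are written with 9 significant digits.
#'
#' @param trajectories output of [simulate_trajectories()].
#' @param path CSV path.
#' @return `path` invisibly (write) or the `data.frame` (read).
#' @export
write_truth <- function(trajectories, path) {
  df <- as.data.frame(trajectories)
  df$x_um <- signif(df$x_um, 9)
  df$y_um <- signif(df$y_um, 9)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a localization or track table
#'
#' Comma-separated, UTF-8, header row, '.' decimal; floats with 9
#' significant digits.
#'
#' @param table localization or track `data.frame`.
#' @param path CSV path.
#' @return `path` invisibly (write) or the `data.frame` (read).
#' @export
write_table_csv <- function(table, path) {
  df <- as.data.frame(table)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], signif, digits = 9)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  utils::read.csv(path, stringsAsFactors = FALSE)
}

run_config_keys <- list(
  top = c("seed", "out_dir", "conditions", "simulate", "localize",
          "track", "diffuse", "write_movies"),
  condition = c("f_bound", "n_cells"),
  simulate = c("n_frames", "image_size", "pixel_size", "frame_interval",
               "n_molecules", "d_mobile", "d_bound", "loc_sigma",
               "psf_sigma", "photons_per_spot", "background",
               "k_off_frame", "k_on_frame"),
  localize = c("sigma_small", "sigma_large", "k_threshold", "roi_size"),
  track = c("link_radius", "memory", "min_steps"),
  diffuse = c("d_threshold"))

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop(sprintf("unknown key(s) in %s: %s", where,
                 paste(bad, collapse = ", ")))
}

#' Full-pipeline run configuration
#'
#' Bundles the stage parameters for a simulate -> localize -> track ->
#' diffuse -> compare run. All stage defaults match the individual
#' functions; unknown keys are rejected. The configuration round-trips
#' losslessly through YAML or JSON ([write_run_config()],
#' [read_run_config()]).
#'
#' @param seed master RNG seed; every per-cell simulation seed is
#'   derived from it.
#' @param conditions named list; each element a list with `f_bound`
#'   and `n_cells`.
#' @param simulate named list of [spt_sim_config()] overrides (all
#'   fields except `f_bound`, `nucleus_mask`, `seed`).
#' @param localize named list of [localize_movie()] parameter
#'   overrides.
#' @param track named list of [link_params()] overrides.
#' @param diffuse named list with optional `d_threshold`.
#' @param out_dir output directory for tables and the manifest.
#' @param write_movies also write each simulated movie as TIFF
#'   (default FALSE; movies can be large).
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       conditions = list(
                         untreated = list(f_bound = 0.2, n_cells = 3L),
                         treated = list(f_bound = 0.5, n_cells = 3L)),
                       simulate = list(), localize = list(),
                       track = list(), diffuse = list(),
                       out_dir = tempfile("sptrun"),
                       write_movies = FALSE) {
  cfg <- list(seed = as.integer(seed), out_dir = out_dir,
              conditions = conditions, simulate = simulate,
              localize = localize, track = track, diffuse = diffuse,
              write_movies = isTRUE(write_movies))
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  check_keys(cfg, run_config_keys$top, "run_config")
  stopifnot(is.numeric(cfg$seed), length(cfg$conditions) >= 1)
  if (is.null(names(cfg$conditions)) || any(names(cfg$conditions) == ""))
    stop("conditions must be a named list")
  for (nm in names(cfg$conditions)) {
    co <- cfg$conditions[[nm]]
    check_keys(co, run_config_keys$condition,
               sprintf("condition '%s'", nm))
    stopifnot(co$f_bound >= 0, co$f_bound <= 1, co$n_cells >= 1)
  }
  check_keys(cfg$simulate, run_config_keys$simulate, "simulate")
  check_keys(cfg$localize, run_config_keys$localize, "localize")
  check_keys(cfg$track, run_config_keys$track, "track")
  check_keys(cfg$diffuse, run_config_keys$diffuse, "diffuse")
  invisible(cfg)
}

#' Write / read a run configuration (YAML or JSON by extension)
#'
#' @param config a [run_config()].
#' @param path file ending in `.yaml`, `.yml` or `.json`.
#' @return `path` invisibly (write) or the `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path)
  } else if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else stop("config path must end in .yaml, .yml or .json")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("config path must end in .yaml, .yml or .json")
  x$conditions <- lapply(x$conditions, as.list)
  do.call(run_config, x)
}

#' Run the full simulate -> localize -> track -> diffuse -> compare
#' pipeline
#'
#' For every condition and cell, simulates a ground-truthed movie,
#' detects and localizes molecules, links them into tracks, filters
#' short tracks, computes per-track diffusion coefficients and the
#' per-cell bound fraction, and finally compares conditions with a
#' one-way ANOVA. All randomness derives from `config$seed`; a rerun
#' with the same config reproduces every output bit-identically
#' (manifest timestamps aside). Stage tables are written under
#' `config$out_dir`.
#'
#' @param config a [run_config()].
#' @return a run manifest (list): `config`, package `version`,
#'   per-cell `cells` (`data.frame` with condition, cell, seed,
#'   localization/track counts and bound fraction), `anova` (the
#'   [compare_conditions()] result), `timestamp`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  validate_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  loc_args <- config$localize
  track_par <- do.call(link_params, config$track)
  d_thr <- if (!is.null(config$diffuse$d_threshold))
    config$diffuse$d_threshold else 0.3
  cells <- list()
  fractions <- list()
  cell_idx <- 0L
  for (cond in names(config$conditions)) {
    co <- config$conditions[[cond]]
    fr <- numeric(co$n_cells)
    for (i in seq_len(co$n_cells)) {
      cell_idx <- cell_idx + 1L
      cell_seed <- config$seed + 1000L * cell_idx
      sim_cfg <- do.call(spt_sim_config,
                         c(config$simulate,
                           list(f_bound = co$f_bound, seed = cell_seed)))
      traj <- simulate_trajectories(sim_cfg)
      movie <- render_movie(traj, sim_cfg)
      stem <- file.path(config$out_dir, sprintf("%s_cell%d", cond, i))
      if (config$write_movies) write_movie(movie, paste0(stem, ".tif"))
      locs <- do.call(localize_movie, c(list(movie), loc_args))
      tracks <- build_tracks(locs, track_par)
      kept <- filter_tracks(tracks, track_par)
      if (nrow(kept) == 0)
        stop(sprintf("stage diffuse: no tracks survive filtering for %s cell %d",
                     cond, i))
      diff_res <- spt_diffusion(kept, sim_cfg$frame_interval,
                                d_threshold = d_thr,
                                cell_id = sprintf("%s_cell%d", cond, i))
      write_table_csv(locs, paste0(stem, "_locs.csv"))
      write_table_csv(kept, paste0(stem, "_tracks.csv"))
      write_table_csv(diff_res$per_track, paste0(stem, "_diffusion.csv"))
      fr[i] <- diff_res$bound_fraction
      cells[[cell_idx]] <- data.frame(
        condition = cond, cell = i, seed = cell_seed,
        f_bound_true = co$f_bound,
        n_localizations = nrow(locs),
        n_tracks_built = length(unique(tracks$track_id)),
        n_tracks_kept = diff_res$n_tracks,
        n_tracks_removed = attr(kept, "n_removed"),
        bound_fraction = diff_res$bound_fraction)
    }
    fractions[[cond]] <- fr
  }
  manifest <- list(config = unclass(config),
                   version = as.character(utils::packageVersion("sptrack")),
                   cells = do.call(rbind, cells),
                   anova = compare_conditions(fractions),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   out_dir = config$out_dir)
  man_out <- manifest
  man_out$anova <- unclass(man_out$anova)
  jsonlite::write_json(man_out, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  class(manifest) <- "run_manifest"
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("sptrack run (version %s) -> %s\n", x$version, x$out_dir))
  print(x$cells[, c("condition", "cell", "n_tracks_kept",
                    "bound_fraction")], row.names = FALSE)
  print(x$anova)
  invisible(x)
}
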