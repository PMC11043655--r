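# Delimited-text interchange formats, pipeline configuration, and the
# end-to-end runner (simulate -> grids -> compare -> report).

#' Write a regional time series as delimited text with a JSON sidecar
#'
#' Two-column tab-separated file (`time_s`, `value`) plus `<path>.json`
#' holding sampling rate and labels.
#'
#' @param x a [regional_ts()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(x, path) {
  stopifnot(inherits(x, "regional_ts"))
  n <- length(x$samples)
  df <- tibble::tibble(
    time_s = sprintf("%.9f", (seq_len(n) - 1) / x$fs),
    value = sprintf("%.17g", x$samples) # full double precision round-trip
  )
  readr::write_tsv(df, path, progress = FALSE)
  jsonlite::write_json(
    list(
      subject_id = x$subject_id, group = x$group, region = x$region,
      fs_hz = x$fs, n_samples = n, duration_s = n / x$fs
    ),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a regional time series from delimited text
#'
#' Accepts the two-column format written by [write_timeseries()] or a
#' single-column file of values. The sampling rate comes from the sidecar
#' JSON (`<path>.json`) if present, otherwise from `fs`. Non-numeric and
#' non-finite rows are rejected with their row number.
#'
#' @param path input file path.
#' @param fs sampling rate in Hz; overrides nothing if a sidecar exists.
#' @return a [regional_ts()].
#' @export
read_timeseries <- function(path, fs = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  fs <- meta$fs_hz %||% fs
  if (is.null(fs)) {
    abort("sampling rate unavailable: no sidecar JSON and `fs` not supplied")
  }
  # base parser: strtod is correctly rounded, so doubles written with 17
  # significant digits round-trip bit-exactly
  df <- utils::read.delim(path, sep = "\t", colClasses = "character")
  raw <- if ("value" %in% names(df)) df$value else df[[ncol(df)]]
  vals <- suppressWarnings(as.numeric(raw))
  if (anyNA(vals) && !anyNA(raw)) {
    suspect <- which(is.na(vals))[1]
    abort(sprintf("non-numeric value at data row %d of %s", suspect, path))
  }
  if (!all(is.finite(vals))) {
    bad <- which(!is.finite(vals))[1]
    abort(sprintf("non-finite value (NaN/Inf/NA) at data row %d of %s", bad, path))
  }
  regional_ts(
    vals, fs = fs,
    subject_id = meta$subject_id %||% NA,
    group = meta$group %||% NA,
    region = meta$region %||% NA
  )
}

#' Write a cohort of time series to a directory
#'
#' One `<subject>_<region>.tsv` (+ sidecar) per row of the cohort tibble.
#'
#' @param cohort tibble from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  purrr::walk(cohort$ts, function(ts) {
    fname <- sprintf("%s_%s.tsv", ts$subject_id, gsub("[^A-Za-z0-9_.-]", "-", ts$region))
    write_timeseries(ts, file.path(dir, fname))
  })
  invisible(dir)
}

#' Read a cohort of time series from a directory
#'
#' Reads every `*.tsv` with a sidecar JSON in `dir` into a cohort tibble.
#'
#' @param dir directory written by [write_cohort()].
#' @return a cohort tibble (columns `subject_id`, `group`, `region`, `fs`,
#'   list-column `ts`).
#' @export
read_cohort <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (length(files) == 0) abort(sprintf("no .tsv files in %s", dir))
  tss <- purrr::map(files, read_timeseries)
  tibble::tibble(
    subject_id = vapply(tss, function(t) t$subject_id, ""),
    group = vapply(tss, function(t) t$group, ""),
    region = vapply(tss, function(t) t$region, ""),
    fs = vapply(tss, function(t) t$fs, 0),
    ts = tss
  )
}

#' Write / read a cohort grid table
#'
#' Plain CSV, one row per cell per subject per region.
#'
#' @param grids a `pac_grids` tibble.
#' @param path CSV path.
#' @return `path` (write) or the grid tibble (read).
#' @export
write_grids <- function(grids, path) {
  readr::write_csv(as.data.frame(grids), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_grids
#' @export
read_grids <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  class(out) <- c("pac_grids", "pac_grid", class(out))
  out
}

# --- pipeline configuration ------------------------------------------------

config_defaults <- function() {
  list(
    seed = 1,
    cohort = list(
      n_group_a = 6, n_group_b = 6,
      regions = "region1",
      group_labels = c("A", "B"),
      fs = 200, duration = 20,
      coupling_a = list(), coupling_b = list()
    ),
    input_dir = NULL,
    grid = list(
      phase_edges = 4:12, amp_edges = 30:40, n_surrogates = 50,
      min_lag = 1, trim = 1, amp_band_expand = "match",
      method = "spectral", transition = 0.25
    ),
    stats = list(
      n_perm = 200, cluster_alpha = 0.05, alpha = 0.05, adjacency = 4
    )
  )
}

merge_checked <- function(defaults, user, where) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    abort(sprintf("unknown config key(s) in %s: %s", where,
                  paste(unknown, collapse = ", ")))
  }
  modifyList(defaults, user)
}

#' Load and validate a pipeline configuration
#'
#' A configuration is a YAML (or JSON) document, or an R list, with the
#' sections `seed`, `cohort` (or `input_dir`), `grid` and `stats`. Unknown
#' keys are rejected. `coupling_a` / `coupling_b` take [coupling_spec()]
#' arguments, either directly or as one named block per region.
#'
#' @param config path to a YAML/JSON file, or a list.
#' @return the merged, validated configuration list.
#' @export
load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a path to a YAML file")
  defs <- config_defaults()
  top <- merge_checked(defs, config, "top level")
  top$cohort <- merge_checked(defs$cohort, config$cohort %||% list(), "cohort")
  top$grid <- merge_checked(defs$grid, config$grid %||% list(), "grid")
  top$stats <- merge_checked(defs$stats, config$stats %||% list(), "stats")
  if (!is.null(top$stats$n_perm) && top$stats$n_perm < 10) {
    abort("config error: stats.n_perm must be at least 10")
  }
  top
}

config_coupling <- function(block, regions, where) {
  if (length(block) == 0) {
    return(do.call(coupling_spec, list()))
  }
  per_region <- all(names(block) %in% regions)
  if (per_region && length(block) > 0) {
    specs <- lapply(regions, function(r) {
      do.call(coupling_spec, block[[r]] %||% list())
    })
    names(specs) <- regions
    specs
  } else {
    do.call(coupling_spec, block)
  }
}

#' Run the full pipeline: simulate/load, grid, compare, report
#'
#' Executes the whole analysis under one configuration: obtain a cohort of
#' regional time series (simulated from the config, or read from
#' `input_dir`), compute the PAC grid of every subject and region, run the
#' cluster permutation contrast per region, summarise phase angles over
#' significant cells, and write `grids.csv`, `report.json` and
#' `manifest.json` into `out_dir`. Deterministic under a fixed config:
#' rerunning writes byte-identical outputs.
#'
#' @param config a configuration list or YAML path (see [load_config()]).
#' @param out_dir output directory.
#' @param quiet suppress progress messages.
#' @return the report list, invisibly.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  cfg <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))

  t0 <- Sys.time()
  if (!is.null(cfg$input_dir)) {
    say("[load] reading cohort from %s", cfg$input_dir)
    cohort <- read_cohort(cfg$input_dir)
  } else {
    cc <- cfg$cohort
    spec <- cohort_spec(
      n_group_a = cc$n_group_a, n_group_b = cc$n_group_b,
      regions = as.character(cc$regions),
      coupling_a = config_coupling(cc$coupling_a, cc$regions, "coupling_a"),
      coupling_b = config_coupling(cc$coupling_b, cc$regions, "coupling_b"),
      fs = cc$fs, duration = cc$duration, seed = cfg$seed,
      group_labels = as.character(cc$group_labels)
    )
    say("[simulate] %d + %d subjects x %d region(s), %g s @ %g Hz",
        spec$n_group_a, spec$n_group_b, length(spec$regions),
        spec$duration, spec$fs)
    cohort <- generate_cohort(spec)
  }

  gspec <- grid_spec(
    phase_edges = cfg$grid$phase_edges, amp_edges = cfg$grid$amp_edges,
    n_surrogates = cfg$grid$n_surrogates, min_lag = cfg$grid$min_lag,
    trim = cfg$grid$trim, amp_band_expand = cfg$grid$amp_band_expand,
    seed = cfg$seed, method = cfg$grid$method,
    transition = cfg$grid$transition
  )
  say("[grid] %d signals x %d cells",
      nrow(cohort),
      (length(gspec$phase_edges) - 1) * (length(gspec$amp_edges) - 1))
  grids <- compute_cohort_grids(cohort, gspec)
  write_grids(grids, file.path(out_dir, "grids.csv"))

  gl <- unique(cohort$group)
  regions <- unique(cohort$region)
  report_regions <- lapply(regions, function(reg) {
    say("[compare] region %s (%d permutations)", reg, cfg$stats$n_perm)
    g <- dplyr::filter(grids, .data$region == reg)
    test <- permutation_cluster_test(
      g, group_a = gl[1], group_b = gl[2],
      n_perm = cfg$stats$n_perm, cluster_alpha = cfg$stats$cluster_alpha,
      alpha = cfg$stats$alpha,
      seed = hash_seed(cfg$seed, "perm", reg),
      adjacency = cfg$stats$adjacency
    )
    sig <- significant_cells(test)
    phase <- NULL
    if (nrow(sig) > 0) {
      ang <- subject_mean_phase(g, sig)
      pa <- ang$angle_deg[ang$group == gl[1]]
      pb <- ang$angle_deg[ang$group == gl[2]]
      phase <- tryCatch(
        {
          ct <- phase_angle_contrast(pa, pb)
          list(
            subject_angles = as.list(stats::setNames(ang$angle_deg, ang$subject_id)),
            circ_mean_a = ct$circ_mean_a, circ_mean_b = ct$circ_mean_b,
            t_statistic = ct$t_statistic, df = ct$df, p_value = ct$p_value
          )
        },
        error = function(e) list(error = conditionMessage(e))
      )
    }
    list(
      region = reg,
      t_map = as.data.frame(test$tmap),
      clusters = as.data.frame(tidy(test))[, -1],
      n_significant = sum(test$clusters$significant %in% TRUE),
      phase_summary = phase
    )
  })
  names(report_regions) <- regions

  report <- list(
    groups = list(a = gl[1], b = gl[2]),
    n_subjects = length(unique(cohort$subject_id)),
    regions = report_regions
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")

  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                               null = "null")
  manifest <- list(
    package = "pacgrid",
    version = as.character(utils::packageVersion("pacgrid")),
    seed = cfg$seed,
    config = cfg,
    config_hash = hash_seed(0, cfg_json),
    elapsed_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  say("[done] outputs in %s", out_dir)
  invisible(report)
}
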