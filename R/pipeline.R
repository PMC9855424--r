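# Pipeline dispatch: one entry point mapping a command + named arguments
# onto the module functions, writing CSV outputs. The inst/cli/myoquant.R
# script is a thin shell wrapper around run_pipeline().

#' Run one pipeline command
#'
#' Dispatches to the analysis / generator entry points and writes CSV
#' (and TIFF/YAML) outputs. All outputs are deterministic given
#' (inputs, config, seed). Supported commands:
#'
#' * `simulate`: `kind` one of `striation_profile`, `striation_image`,
#'   `calcium_trace`, `fura2_pair`, `mito_image`, `ros_pair`; writes the
#'   artifact (`out`) plus a YAML truth sidecar (`<out>.yaml`).
#'   Generator parameters are passed through `params` (named list).
#' * `sarcomere`: `profiles` (CSV of 1-D profiles: position column
#'   optional, one column per profile) or `image` (TIFF) + `lines` (CSV
#'   x0,y0,x1,y1,width); `pixel_um`, `band`; writes per-profile
#'   main_period_um / peak_power to `out`.
#' * `calcium`: `traces` CSV, `mode` (`dff` or `ratio`), optional
#'   `per_beat` CSV path; writes one summary row per cell to `out`.
#' * `mito`: `tracker` TIFF (+ optional `sox` TIFF), writes skeleton
#'   morphometry (+ ROS ratio) to `out`.
#' * `ros`: `cellrox` TIFF + optional `mask` TIFF; writes RFU to `out`.
#' * `stats`: `data` CSV (group,value), `pairs` like `"A:B,A:C"` (empty
#'   = all), `method`; writes comparison table to `out`.
#' * `ddct`: `data` CSV with columns ct_target_sample, ct_ref_sample,
#'   ct_target_control, ct_ref_control; writes fold changes to `out`.
#'
#' @param config named list with `command`, `out`, and the
#'   command-specific fields above; `seed` (default 0) and `verbose`
#'   (default FALSE) are global.
#' @return invisibly, the primary result object; side effect: files
#'   written to `config$out` (and friends).
#' @export
run_pipeline <- function(config) {
  cmd <- config$command
  if (is.null(cmd)) stop("config$command is required", call. = FALSE)
  seed <- if (is.null(config$seed)) 0L else as.integer(config$seed)
  switch(cmd,
         simulate = pipe_simulate(config, seed),
         sarcomere = pipe_sarcomere(config),
         calcium = pipe_calcium(config),
         mito = pipe_mito(config),
         ros = pipe_ros(config),
         stats = pipe_stats(config),
         ddct = pipe_ddct(config),
         stop(sprintf("unknown command `%s`", cmd), call. = FALSE))
}

pipe_simulate <- function(config, seed) {
  kind <- config$kind
  p <- config$params
  if (is.null(p)) p <- list()
  out <- config$out
  if (is.null(out) || is.null(kind)) {
    stop("simulate needs `kind` and `out`", call. = FALSE)
  }
  obj <- switch(kind,
    striation_profile = do.call(make_striation_profile,
                                c(p, list(seed = seed))),
    striation_image = {
      pp <- p$profile_params
      prof <- do.call(make_striation_profile, c(pp, list(seed = seed)))
      do.call(make_striation_image,
              c(list(profile = prof), p[setdiff(names(p), "profile_params")],
                list(seed = seed)))
    },
    calcium_trace = do.call(make_calcium_trace, c(p, list(seed = seed))),
    fura2_pair = {
      pp <- p$trace_params
      tr <- do.call(make_calcium_trace, c(pp, list(seed = seed)))
      do.call(make_fura2_pair,
              c(list(ratio_trace = tr),
                p[setdiff(names(p), "trace_params")], list(seed = seed)))
    },
    mito_image = do.call(make_mito_image, c(p, list(seed = seed))),
    ros_pair = do.call(make_ros_pair, c(p, list(seed = seed))),
    stop(sprintf("unknown simulate kind `%s`", kind), call. = FALSE))
  spec <- synthetic_truth(obj)
  if (kind %in% c("striation_profile")) {
    write_csv_with_header(data.frame(position_um = obj$positions_um,
                                     intensity = obj$intensity),
                          out, spec$params)
  } else if (kind == "calcium_trace") {
    write_traces_csv(list(cell1 = obj), out, spec$params)
  } else if (kind == "fura2_pair") {
    write_traces_csv(list(cell1 = obj), out, spec$params)
  } else if (kind %in% c("striation_image", "mito_image")) {
    img <- pmin(pmax(round(obj), 0), 65535)
    write_tiff(matrix(img, nrow(obj), ncol(obj)), out)
  } else if (kind == "ros_pair") {
    base <- sub("\\.tiff?$", "", out)
    write_tiff(pmin(pmax(round(obj$tracker), 0), 65535),
               paste0(base, "_tracker.tif"))
    write_tiff(pmin(pmax(round(obj$sox), 0), 65535),
               paste0(base, "_sox.tif"))
  }
  write_synthetic_spec(spec, paste0(out, ".yaml"))
  invisible(obj)
}

pipe_sarcomere <- function(config) {
  band <- if (is.null(config$band)) c(1, 5) else as.numeric(config$band)
  px <- config$pixel_um
  if (is.null(px)) stop("sarcomere needs `pixel_um`", call. = FALSE)
  rows <- list()
  if (!is.null(config$profiles)) {
    df <- utils::read.csv(config$profiles, comment.char = "#")
    cols <- setdiff(names(df), c("position_um", "positions_um"))
    for (nm in cols) {
      prof <- striation_profile(df[[nm]], px)
      sp <- fft_power_spectrum(prof, band)
      rows[[length(rows) + 1L]] <- data.frame(
        source = basename(config$profiles), id = nm,
        main_period_um = sp$main_period_um,
        peak_power = sp$main_peak_power,
        band_lo_um = band[1], band_hi_um = band[2],
        n_samples = sp$n_samples)
    }
  } else if (!is.null(config$image) && !is.null(config$lines)) {
    img <- read_tiff(config$image)
    if (is.list(img)) img <- img[[1]]
    lines <- utils::read.csv(config$lines, comment.char = "#")
    for (r in seq_len(nrow(lines))) {
      w <- if ("width" %in% names(lines)) lines$width[r] else 1L
      prof <- profile_from_image(img, c(lines$x0[r], lines$y0[r]),
                                 c(lines$x1[r], lines$y1[r]),
                                 width_px = w, pixel_um = px)
      sp <- fft_power_spectrum(prof, band)
      rows[[length(rows) + 1L]] <- data.frame(
        source = basename(config$image), id = r,
        main_period_um = sp$main_period_um,
        peak_power = sp$main_peak_power,
        band_lo_um = band[1], band_hi_um = band[2],
        n_samples = sp$n_samples)
    }
  } else {
    stop("sarcomere needs `profiles`, or `image` + `lines`", call. = FALSE)
  }
  res <- do.call(rbind, rows)
  write_csv_with_header(res, config$out,
                        list(pixel_um = px, band = band))
  invisible(res)
}

pipe_calcium <- function(config) {
  mode <- if (is.null(config$mode)) "dff" else config$mode
  traces <- read_traces_csv(config$traces,
                            mode = if (mode == "ratio") "ratio_pairs"
                                   else "single")
  rows <- list(); per_beat <- list()
  for (nm in names(traces)) {
    tr <- traces[[nm]]
    trace <- if (mode == "ratio") {
      compute_ratio(tr$f340, tr$f380,
                    bg340 = config$bg340 %||% 0,
                    bg380 = config$bg380 %||% 0)
    } else {
      compute_dff(tr, baseline_percentile =
                        config$baseline_percentile %||% 10)
    }
    ana <- analyze_calcium_trace(trace)
    rows[[nm]] <- cbind(data.frame(cell = nm),
                        as.data.frame(ana$summary))
    if (nrow(ana$beats)) {
      per_beat[[nm]] <- cbind(data.frame(cell = nm),
                              as.data.frame(ana$beats)[,
                                c("onset_s", "peak_s", "ttp_s", "amplitude",
                                  "diastolic", "tau_s", "fit_r2",
                                  "complete")])
    }
  }
  res <- do.call(rbind, rows)
  write_csv_with_header(res, config$out, list(mode = mode))
  if (!is.null(config$per_beat) && length(per_beat)) {
    write_csv_with_header(do.call(rbind, per_beat), config$per_beat,
                          list(mode = mode))
  }
  invisible(res)
}

pipe_mito <- function(config) {
  img <- read_tiff(config$tracker)
  if (is.list(img)) img <- img[[1]]
  mask <- segment_mitochondria(img)
  st <- skeleton_stats(mask, pixel_um = config$pixel_um)
  row <- data.frame(source = basename(config$tracker),
                    n_individuals = st$n_individuals,
                    n_networks = st$n_networks,
                    mean_branches_per_network = st$mean_branches_per_network,
                    mean_branch_length = st$mean_branch_length,
                    total_branch_length = st$total_branch_length,
                    footprint = st$footprint, units = st$units)
  if (!is.null(config$sox)) {
    sox <- read_tiff(config$sox)
    if (is.list(sox)) sox <- sox[[1]]
    rr <- mito_ros_ratio(sox, img, mask)
    row$mito_ros_ratio <- rr$mito_ros_ratio
  }
  write_csv_with_header(row, config$out, list())
  invisible(row)
}

pipe_ros <- function(config) {
  img <- read_tiff(config$cellrox)
  if (is.list(img)) img <- img[[1]]
  mask <- if (!is.null(config$mask)) {
    m <- read_tiff(config$mask)
    if (is.list(m)) m <- m[[1]]
    m > 0
  } else NULL
  rr <- cyto_ros_rfu(img, mask, bg = config$bg %||% 0)
  row <- data.frame(source = basename(config$cellrox),
                    cyto_ros_rfu = rr$cyto_ros_rfu,
                    n_pixels = rr$n_pixels)
  write_csv_with_header(row, config$out, list())
  invisible(row)
}

pipe_stats <- function(config) {
  df <- utils::read.csv(config$data, comment.char = "#")
  if (!all(c("group", "value") %in% names(df))) {
    stop("stats data CSV needs `group` and `value` columns", call. = FALSE)
  }
  groups <- split(df$value, df$group)
  pairs <- NULL
  if (!is.null(config$pairs) && nzchar(config$pairs)) {
    pairs <- lapply(strsplit(strsplit(config$pairs, ",")[[1]], ":"),
                    function(p) trimws(p))
  }
  res <- pairwise_compare(groups, comparisons = pairs,
                          method = config$method %||% "holm_sidak",
                          var_equal = !isTRUE(config$welch))
  write_csv_with_header(as.data.frame(res), config$out,
                        list(method = res$method[1]))
  invisible(res)
}

pipe_ddct <- function(config) {
  df <- utils::read.csv(config$data, comment.char = "#")
  need <- c("ct_target_sample", "ct_ref_sample", "ct_target_control",
            "ct_ref_control")
  if (!all(need %in% names(df))) {
    stop(sprintf("ddct data CSV needs columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  df$fold_change <- fold_change_ddct(df$ct_target_sample, df$ct_ref_sample,
                                     df$ct_target_control,
                                     df$ct_ref_control)
  write_csv_with_header(df, config$out, list())
  invisible(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
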