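# Readers and writers for the standard interchange formats: TIFF images,
# CSV trace tables (time_s + one column per cell, or paired _340/_380
# columns), and YAML sidecars carrying synthetic ground truth.

#' Read a TIFF image (single frame or stack)
#'
#' @param path path to a TIFF file.
#' @return for a single frame, a numeric matrix; for a stack, a list of
#'   matrices. Attributes `width`, `height`, `n_frames` and
#'   `bits_per_sample` record the geometry; 8/16-bit integer data are
#'   returned unrescaled.
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("TIFF file not found: %s", path), call. = FALSE)
  }
  frames <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE,
                                    info = TRUE),
                     error = function(e) {
                       stop(sprintf("cannot read %s as TIFF: %s", path,
                                    conditionMessage(e)), call. = FALSE)
                     })
  bits <- attr(frames[[1]], "bits.per.sample")
  if (is.null(bits)) bits <- NA_integer_
  frames <- lapply(frames, function(f) {
    m <- as.matrix(f)
    storage.mode(m) <- "double"
    m
  })
  out <- if (length(frames) == 1L) frames[[1]] else frames
  attr(out, "width") <- ncol(frames[[1]])
  attr(out, "height") <- nrow(frames[[1]])
  attr(out, "n_frames") <- length(frames)
  attr(out, "bits_per_sample") <- bits
  out
}

#' Write a matrix as an integer TIFF
#'
#' @param image numeric matrix with integer values in
#'   `[0, 2^bits - 1]`; values are stored without rescaling.
#' @param path output path.
#' @param bits 8 or 16 bits per sample.
#' @export
write_tiff <- function(image, path, bits = 16) {
  if (!bits %in% c(8L, 16L)) stop("bits must be 8 or 16", call. = FALSE)
  maxv <- 2^bits - 1
  if (any(image < 0 | image > maxv)) {
    stop(sprintf("image values must lie in [0, %d] for %d-bit output",
                 maxv, bits), call. = FALSE)
  }
  tiff::writeTIFF(round(image) / maxv, path, bits.per.sample = bits)
  invisible(path)
}

#' Read calcium traces from a CSV table
#'
#' Expects a header with a `time_s` column. In `"single"` mode every
#' other column is one cell's trace; in `"ratio_pairs"` mode columns are
#' matched by `<cell>_340` / `<cell>_380` suffixes. Cells whose pair is
#' incomplete are reported as an error; all-missing columns are skipped
#' with a warning. Comment lines starting with `#` are ignored.
#'
#' @param path CSV path.
#' @param mode `"single"` or `"ratio_pairs"`.
#' @return named list; per cell either a `ca_trace` (`single`) or a
#'   list with `f340` and `f380` traces (`ratio_pairs`).
#' @export
read_traces_csv <- function(path, mode = c("single", "ratio_pairs")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop(sprintf("trace CSV not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (!"time_s" %in% names(df)) {
    stop("trace CSV must have a `time_s` column", call. = FALSE)
  }
  t <- df$time_s
  cols <- setdiff(names(df), "time_s")
  usable <- function(nm) {
    v <- df[[nm]]
    if (all(is.na(v))) {
      warning(sprintf("column `%s` is empty; cell skipped", nm))
      return(FALSE)
    }
    TRUE
  }
  if (mode == "single") {
    cols <- cols[vapply(cols, usable, logical(1))]
    out <- lapply(cols, function(nm) ca_trace(t, df[[nm]],
                                              signal_kind = "raw"))
    names(out) <- cols
    return(out)
  }
  is340 <- grepl("_340$", cols)
  is380 <- grepl("_380$", cols)
  stem340 <- sub("_340$", "", cols[is340])
  stem380 <- sub("_380$", "", cols[is380])
  orphans <- c(setdiff(stem340, stem380), setdiff(stem380, stem340))
  if (length(orphans)) {
    stop(sprintf("unpaired ratio columns for cell(s): %s",
                 paste(orphans, collapse = ", ")), call. = FALSE)
  }
  stray <- cols[!is340 & !is380]
  if (length(stray)) {
    stop(sprintf("columns without _340/_380 suffix in ratio mode: %s",
                 paste(stray, collapse = ", ")), call. = FALSE)
  }
  cells <- intersect(stem340, stem380)
  keep <- vapply(cells, function(cl) {
    usable(paste0(cl, "_340")) && usable(paste0(cl, "_380"))
  }, logical(1))
  out <- lapply(cells[keep], function(cl) {
    list(f340 = ca_trace(t, df[[paste0(cl, "_340")]], signal_kind = "raw"),
         f380 = ca_trace(t, df[[paste0(cl, "_380")]], signal_kind = "raw"))
  })
  names(out) <- cells[keep]
  out
}

#' Write calcium traces to a CSV table
#'
#' @param traces named list of `ca_trace` objects (or `f340`/`f380`
#'   pairs, written with `_340`/`_380` suffixes).
#' @param path output path.
#' @param params optional named list recorded in the header comment.
#' @export
write_traces_csv <- function(traces, path, params = NULL) {
  first <- traces[[1]]
  t <- if (inherits(first, "ca_trace")) first$time_s else first$f340$time_s
  cols <- list(time_s = t)
  for (nm in names(traces)) {
    tr <- traces[[nm]]
    if (inherits(tr, "ca_trace")) {
      cols[[nm]] <- tr$values
    } else {
      cols[[paste0(nm, "_340")]] <- tr$f340$values
      cols[[paste0(nm, "_380")]] <- tr$f380$values
    }
  }
  write_csv_with_header(as.data.frame(cols, check.names = FALSE), path,
                        params)
  invisible(path)
}

# Every CSV the package writes carries a comment line recording the tool
# version and the parameters that produced it.
write_csv_with_header <- function(df, path, params = NULL) {
  ver <- as.character(utils::packageVersion("myoquant"))
  meta <- if (length(params)) {
    paste(names(params), vapply(params, function(p) paste(format(p),
                                                          collapse = ";"),
                                character(1)),
          sep = "=", collapse = " ")
  } else ""
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# myoquant %s %s", ver, meta), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a synthetic-spec ground-truth sidecar (YAML)
#'
#' @param spec a `synthetic_spec` (from [synthetic_truth()]).
#' @param path output path (`.yaml`).
#' @export
write_synthetic_spec <- function(spec, path) {
  stopifnot(inherits(spec, "synthetic_spec"))
  truth <- spec$truth
  # keep the sidecar scalar/vector only: drop bulky array fields
  truth <- truth[!vapply(truth, function(x) {
    is.matrix(x) || (is.numeric(x) && length(x) > 1000) || is.list(x)
  }, logical(1))]
  yaml::write_yaml(list(seed = spec$seed, kind = spec$kind,
                        params = spec$params, truth = truth), path)
  invisible(path)
}

#' Read a synthetic-spec sidecar
#'
#' @param path path to a YAML sidecar written by
#'   [write_synthetic_spec()].
#' @return a `synthetic_spec` list.
#' @export
read_synthetic_spec <- function(path) {
  x <- yaml::read_yaml(path)
  synthetic_spec(x$seed, x$kind, x$params, x$truth)
}
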