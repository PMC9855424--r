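# Internal helpers shared across modules.

# Run `code` with the RNG seeded to `seed`, restoring the caller's RNG state
# afterwards so generators are pure functions of (seed, params).
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

assert_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be positive (got %g)", name, x), call. = FALSE)
  }
  if (nonneg && x < 0) {
    stop(sprintf("`%s` must be non-negative (got %g)", name, x), call. = FALSE)
  }
  invisible(x)
}

# Ground-truth bundle attached to every generated artifact.
synthetic_spec <- function(seed, kind, params, truth) {
  structure(list(seed = as.integer(seed), kind = kind,
                 params = params, truth = truth),
            class = "synthetic_spec")
}

#' Retrieve the ground-truth bundle of a generated artifact
#'
#' Every generator in the package attaches a `synthetic_spec` object
#' (seed, kind, parameters, and the ground-truth values the analysis
#' should recover) to its output. This accessor returns it.
#'
#' @param x an object produced by one of the `make_*()` generators.
#' @return a `synthetic_spec` list with elements `seed`, `kind`,
#'   `params` and `truth`, or `NULL` if `x` carries no spec.
#' @export
synthetic_truth <- function(x) attr(x, "synthetic_spec", exact = TRUE)

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("Synthetic spec:", x$kind, "(seed", paste0(x$seed, ")\n"))
  cat("  params:", paste(names(x$params), unlist(lapply(x$params, format)),
                         sep = "=", collapse = ", "), "\n")
  tn <- names(x$truth)
  scal <- vapply(x$truth, function(v) is.numeric(v) && length(v) == 1L, logical(1))
  cat("  truth :", paste(tn[scal], format(unlist(x$truth[scal]), digits = 4),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Bilinear interpolation of image `img` (matrix, [row, col]) at 0-based
# pixel-center coordinates (x = col - 1, y = row - 1). Vectorized over x/y.
bilinear <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  if (any(x < 0 | x > nc - 1 | y < 0 | y > nr - 1)) {
    stop("interpolation coordinates fall outside the image", call. = FALSE)
  }
  x0 <- pmin(floor(x), nc - 2); y0 <- pmin(floor(y), nr - 2)
  x0 <- pmax(x0, 0); y0 <- pmax(y0, 0)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x0 + 2)
  i10 <- cbind(y0 + 2, x0 + 1); i11 <- cbind(y0 + 2, x0 + 2)
  (1 - fx) * (1 - fy) * img[i00] + fx * (1 - fy) * img[i01] +
    (1 - fx) * fy * img[i10] + fx * fy * img[i11]
}
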