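# Scalar quantification arithmetic and group comparisons: 2^-ddCt fold
# change, band-intensity ratios, and pairwise tests with Holm-Sidak or
# Tukey multiplicity adjustment.

#' Relative expression fold change by the 2^-ddCt method
#'
#' \deqn{\Delta CT_s = CT_{target,sample} - CT_{ref,sample};\quad
#'       \Delta CT_c = CT_{target,control} - CT_{ref,control};}
#' the fold change is \eqn{2^{-(\Delta CT_s - \Delta CT_c)}}. Vectorized
#' over replicates.
#'
#' @param ct_target_sample,ct_ref_sample,ct_target_control,ct_ref_control
#'   PCR cycle-threshold numbers (finite; typically 5-40 cycles).
#' @return fold change(s), dimensionless.
#' @export
fold_change_ddct <- function(ct_target_sample, ct_ref_sample,
                             ct_target_control, ct_ref_control) {
  cts <- cbind(ct_target_sample, ct_ref_sample, ct_target_control,
               ct_ref_control)
  if (any(!is.finite(cts))) stop("CT values must be finite", call. = FALSE)
  dct_s <- ct_target_sample - ct_ref_sample
  dct_c <- ct_target_control - ct_ref_control
  2^(-(dct_s - dct_c))
}

#' Band-intensity ratio (e.g. LC3-II/LC3-I, p-CaMKII/CaMKII)
#'
#' Simple densitometry ratio, invariant to common exposure scaling.
#'
#' @param numerator_intensity,denominator_intensity band intensities;
#'   the denominator must be strictly positive.
#' @return ratio(s), dimensionless.
#' @seealso [normalize_to_control()] for the "control group mean
#'   normalized to 1" convention.
#' @export
band_ratio <- function(numerator_intensity, denominator_intensity) {
  if (any(!is.finite(numerator_intensity)) ||
      any(!is.finite(denominator_intensity))) {
    stop("band intensities must be finite", call. = FALSE)
  }
  if (any(denominator_intensity <= 0)) {
    stop("denominator band intensity must be > 0", call. = FALSE)
  }
  numerator_intensity / denominator_intensity
}

#' Normalize values to a control-group mean of 1
#'
#' Implements the convention where the control group at base level is
#' normalized to 1 (the dashed-reference-line convention of fold-change
#' plots).
#'
#' @param x values to normalize.
#' @param control control-group values (their mean maps to exactly 1).
#' @return `x / mean(control)`.
#' @export
normalize_to_control <- function(x, control) {
  m <- mean(control)
  if (!is.finite(m) || m == 0) stop("control mean must be finite, non-zero",
                                    call. = FALSE)
  x / m
}

#' Holm-Sidak step-down adjustment of p-values
#'
#' Sorts raw p-values ascending and sets
#' \eqn{p^{adj}_{(i)} = 1 - (1 - p_{(i)})^{m - i + 1}}, then enforces
#' monotone nondecreasing adjusted values (step-down), capped at 1.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values in the original order.
#' @export
holm_sidak_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Pairwise two-sample comparisons with multiplicity adjustment
#'
#' Two-sided two-sample t statistics per requested pair
#' (pooled-variance by default, Welch with `var_equal = FALSE`),
#' adjusted across the family by the Holm-Sidak step-down method or by
#' Tukey's studentized-range test. Tukey adjustment pools the
#' within-group variance across *all* supplied groups (the one-way
#' ANOVA mean square error) as in the classical post-hoc procedure.
#' Groups with fewer than 2 observations are skipped with a reason in
#' the `note` column.
#'
#' @param values_by_group named list of numeric vectors, one per group.
#' @param comparisons list of length-2 character vectors naming the
#'   pairs to compare; `NULL` compares all pairs.
#' @param method `"holm_sidak"`, `"tukey"`, or `"none"`.
#' @param var_equal pooled-variance t (default) or Welch.
#' @return a `pairwise_comparisons` data frame: `group1`, `group2`,
#'   `n1`, `n2`, `statistic`, `df`, `raw_p`, `adj_p`, `method`, `note`.
#' @export
pairwise_compare <- function(values_by_group, comparisons = NULL,
                             method = c("holm_sidak", "tukey", "none"),
                             var_equal = TRUE) {
  method <- match.arg(method)
  if (is.null(names(values_by_group)) ||
      any(!nzchar(names(values_by_group)))) {
    stop("`values_by_group` must be a fully named list", call. = FALSE)
  }
  gn <- names(values_by_group)
  if (is.null(comparisons)) {
    comparisons <- utils::combn(gn, 2, simplify = FALSE)
  }
  k <- length(values_by_group)
  ns <- lengths(values_by_group)
  if (method == "tukey") {
    mse_groups <- values_by_group[ns >= 2]
    n_tot <- sum(lengths(mse_groups))
    df_err <- n_tot - length(mse_groups)
    mse <- sum(vapply(mse_groups,
                      function(x) sum((x - mean(x))^2), numeric(1))) / df_err
  }
  rows <- lapply(comparisons, function(pair) {
    a <- pair[1]; b <- pair[2]
    if (!all(c(a, b) %in% gn)) {
      stop(sprintf("unknown group in comparison %s:%s", a, b), call. = FALSE)
    }
    x <- values_by_group[[a]]; y <- values_by_group[[b]]
    out <- data.frame(group1 = a, group2 = b, n1 = length(x),
                      n2 = length(y), statistic = NA_real_, df = NA_real_,
                      raw_p = NA_real_, adj_p = NA_real_, method = method,
                      note = NA_character_, stringsAsFactors = FALSE)
    if (length(x) < 2 || length(y) < 2) {
      out$note <- "group with fewer than 2 observations; skipped"
      return(out)
    }
    if (method == "tukey") {
      se <- sqrt(mse * (1 / length(x) + 1 / length(y)))
      out$statistic <- (mean(x) - mean(y)) / se
      out$df <- df_err
      out$raw_p <- 2 * stats::pt(-abs(out$statistic), df_err)
      q <- abs(out$statistic) * sqrt(2)
      out$adj_p <- stats::ptukey(q, nmeans = length(mse_groups),
                                 df = df_err, lower.tail = FALSE)
    } else {
      tt <- stats::t.test(x, y, var.equal = var_equal)
      out$statistic <- unname(tt$statistic)
      out$df <- unname(tt$parameter)
      out$raw_p <- tt$p.value
    }
    out
  })
  res <- do.call(rbind, rows)
  ok <- !is.na(res$raw_p)
  if (method == "holm_sidak" && any(ok)) {
    res$adj_p[ok] <- holm_sidak_adjust(res$raw_p[ok])
  } else if (method == "none") {
    res$adj_p <- res$raw_p
  }
  class(res) <- c("pairwise_comparisons", "data.frame")
  res
}

#' @export
print.pairwise_comparisons <- function(x, digits = 4, ...) {
  cat("Pairwise comparisons (", x$method[1], " adjustment, m = ",
      sum(!is.na(x$raw_p)), ")\n", sep = "")
  df <- as.data.frame(x)
  df$statistic <- signif(df$statistic, digits)
  df$raw_p <- signif(df$raw_p, digits)
  df$adj_p <- signif(df$adj_p, digits)
  print.data.frame(df[, c("group1", "group2", "n1", "n2", "statistic",
                          "raw_p", "adj_p", "note")], row.names = FALSE)
  invisible(x)
}
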