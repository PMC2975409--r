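#' Log2-transform a raw intensity table
#'
#' Replaces every intensity with its base-2 logarithm. Zero intensities are
#' substituted by half the smallest positive value in the table before
#' transforming (a common floor for label-free data, reported via a
#' message); negative intensities are an error.
#'
#' @param data Tibble: first column feature identifiers, remaining columns
#'   numeric raw-scale sample intensities.
#' @return The table with transformed values; attribute `intensity_scale`
#'   set to `"log2"`.
#' @export
#' @examples
#' tbl <- tibble::tibble(id = c("a", "b"), s1 = c(2, 8), s2 = c(4, 16))
#' log2_transform(tbl)
log2_transform <- function(data) {
  x <- intensity_values(data)
  if (any(x < 0, na.rm = TRUE)) {
    abort("Raw intensities must be non-negative; found negative values.")
  }
  sc <- attr(data, "intensity_scale")
  if (!is.null(sc) && sc == "log2") {
    abort("`data` is already on the log2 scale.")
  }
  if (any(x == 0, na.rm = TRUE)) {
    floor_val <- min(x[x > 0], na.rm = TRUE) / 2
    n0 <- sum(x == 0, na.rm = TRUE)
    inform(sprintf("Replaced %d zero intensit%s by half the smallest positive value (%.4g).",
                   n0, if (n0 == 1) "y" else "ies", floor_val))
    x[x == 0] <- floor_val
  }
  out <- rebuild_intensity(data, log2(x))
  attr(out, "intensity_scale") <- "log2"
  out
}

#' Quantile-normalize sample columns
#'
#' Forces every sample column to share the common distribution of per-rank
#' across-column means while preserving within-column rank order. Ties
#' within a column receive the mean of the rank-means they span. The
#' computation is delegated to [limma::normalizeQuantiles()].
#'
#' @param data Tibble: first column feature identifiers, remaining columns
#'   numeric sample intensities (at least 2 sample columns; with a single
#'   sample the table is returned unchanged with a warning).
#' @return The normalized table (same shape, same attributes).
#' @export
#' @examples
#' tbl <- tibble::tibble(id = c("a", "b", "c"),
#'                       s1 = c(1, 2, 3), s2 = c(4, 5, 6))
#' quantile_normalize(tbl)
quantile_normalize <- function(data) {
  x <- intensity_values(data)
  if (ncol(x) < 2) {
    warn("Quantile normalization needs >= 2 sample columns; returning input unchanged.")
    return(data)
  }
  rebuild_intensity(data, limma::normalizeQuantiles(x, ties = TRUE))
}

#' Roll peptide intensities up to protein level
#'
#' Aggregates a peptide-level log2 intensity table into one row per protein
#' by a weighted average of its peptides, per sample. Weights are either
#' equal or proportional to the inverse of each peptide's across-sample
#' variance (down-weighting noisy peptides); weights sum to 1 within each
#' protein.
#'
#' @param data Peptide-level tibble: first column peptide identifiers,
#'   remaining columns numeric sample intensities.
#' @param peptide_map Tibble `(peptide_id, protein_id)`; every peptide in
#'   `data` must be mapped (unmapped peptides are an error).
#' @param weights `"equal"` (default) or `"inverse_variance"`.
#' @return Protein-level tibble: first column `protein_id`, one row per
#'   protein (ordered by first appearance in `peptide_map`), same sample
#'   columns.
#' @export
#' @examples
#' tbl <- tibble::tibble(peptide_id = c("p1", "p2"), s1 = c(4, 6))
#' map <- tibble::tibble(peptide_id = c("p1", "p2"),
#'                       protein_id = c("A", "A"))
#' rollup_proteins(tbl, map)
rollup_proteins <- function(data, peptide_map,
                            weights = c("equal", "inverse_variance")) {
  weights <- match.arg(weights)
  ids <- data[[1]]
  lookup <- setNames(peptide_map$protein_id, peptide_map$peptide_id)
  unmapped <- setdiff(ids, peptide_map$peptide_id)
  if (length(unmapped) > 0) {
    abort(sprintf("Unmapped peptide id(s): %s%s",
                  paste(head(unmapped, 5), collapse = ", "),
                  if (length(unmapped) > 5) sprintf(" (+%d more)", length(unmapped) - 5) else ""))
  }
  x <- intensity_values(data)
  protein <- unname(lookup[ids])

  w <- if (weights == "equal") {
    rep(1, nrow(x))
  } else {
    v <- apply(x, 1, var, na.rm = TRUE)
    # constant peptides would get infinite weight; floor the variance
    1 / pmax(v, .Machine$double.eps)
  }
  miss <- is.na(x)
  xw <- x * w
  xw[miss] <- 0
  wmat <- matrix(w, nrow(x), ncol(x))
  wmat[miss] <- 0   # missing cells drop out; remaining weights renormalize
  num <- rowsum(xw, protein, reorder = FALSE)
  den <- rowsum(wmat, protein, reorder = FALSE)
  out_vals <- num / den

  out <- tibble::as_tibble(as.data.frame(out_vals))
  names(out) <- colnames(data)[-1]
  out <- dplyr::bind_cols(tibble::tibble(protein_id = rownames(num)), out)
  attr(out, "intensity_scale") <- attr(data, "intensity_scale")
  out
}

#' One-sample Kolmogorov-Smirnov normality test
#'
#' Compares the empirical distribution of `values` to a normal reference.
#' By default the reference mean and standard deviation are estimated from
#' the data; fixed parameters can be supplied. The statistic `D` is the
#' supremum absolute difference between the empirical CDF and the reference
#' normal CDF; the p-value is asymptotic.
#'
#' @param values Numeric vector (`NA` dropped), at least one value.
#' @param mean,sd Optional fixed reference parameters; both must be given to
#'   fix the reference. With estimated parameters, zero variance is an
#'   error.
#' @return One-row tibble `(D, p_value, n, mean, sd, estimated)`.
#' @export
#' @examples
#' ks_normality(rnorm(100), mean = 0, sd = 1)
ks_normality <- function(values, mean = NULL, sd = NULL) {
  values <- as.numeric(values[!is.na(values)])
  if (length(values) < 1) abort("`values` must contain at least one value.")
  estimated <- is.null(mean) || is.null(sd)
  if (estimated) {
    mean <- base::mean(values)
    sd <- stats::sd(values)
    if (length(values) < 2 || !is.finite(sd) || sd == 0) {
      abort("Cannot estimate reference parameters: input has zero variance.")
    }
  }
  kt <- suppressWarnings(
    ks.test(values, "pnorm", mean = mean, sd = sd, exact = FALSE)
  )
  tibble::tibble(
    D = unname(kt$statistic),
    p_value = kt$p.value,
    n = length(values),
    mean = mean, sd = sd,
    estimated = estimated
  )
}

#' Normal quantile-quantile table
#'
#' Pairs the sorted observations with normal reference quantiles at
#' probability points `(i - 0.5) / n`, ready for Q-Q plotting or TSV export.
#'
#' @inheritParams ks_normality
#' @return Tibble `(prob, theoretical, observed)` sorted by `prob`;
#'   `observed` is ascending by construction.
#' @seealso [plot_qq()]
#' @export
qq_table <- function(values, mean = NULL, sd = NULL) {
  values <- as.numeric(values[!is.na(values)])
  n <- length(values)
  if (n < 2) abort("`values` must contain at least two values.")
  if (is.null(mean)) mean <- base::mean(values)
  if (is.null(sd)) sd <- stats::sd(values)
  p <- (seq_len(n) - 0.5) / n
  tibble::tibble(
    prob = p,
    theoretical = qnorm(p, mean, sd),
    observed = sort(values)
  )
}

#' Q-Q plot of observed vs normal reference quantiles
#'
#' @param qq A table from [qq_table()].
#' @return A ggplot object.
#' @export
plot_qq <- function(qq) {
  ggplot2::ggplot(qq, ggplot2::aes(x = .data$theoretical, y = .data$observed)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red",
                         linetype = "dashed") +
    ggplot2::labs(x = "Theoretical normal quantile",
                  y = "Observed quantile",
                  title = "Normal Q-Q plot")
}

# ---- internal helpers -------------------------------------------------

# numeric sample-value matrix of an intensity tibble (first column = ids)
intensity_values <- function(data) {
  if (!is.data.frame(data) || ncol(data) < 2) {
    abort("`data` must be a data frame with an id column and >= 1 sample column.")
  }
  ids <- data[[1]]
  if (anyDuplicated(ids)) abort("Duplicate feature identifiers in `data`.")
  if (anyDuplicated(names(data))) abort("Duplicate sample identifiers in `data`.")
  x <- as.matrix(data[, -1, drop = FALSE])
  if (!is.numeric(x)) abort("Sample columns must be numeric.")
  rownames(x) <- ids
  x
}

rebuild_intensity <- function(data, x) {
  out <- tibble::as_tibble(as.data.frame(x))
  names(out) <- colnames(data)[-1]
  out <- dplyr::bind_cols(data[, 1, drop = FALSE], out)
  attr(out, "intensity_scale") <- attr(data, "intensity_scale")
  out
}
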