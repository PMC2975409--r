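#' Two-sample statistic for one protein
#'
#' Computes the observed case-vs-control statistic for a single vector pair:
#' the pooled-variance t-statistic (default), Welch's t, or the plain
#' difference of group means. The sign convention is case minus control.
#'
#' @param case,control Numeric vectors of group values (each of length >= 2
#'   for the t statistics, >= 1 for `mean_difference`).
#' @param kind `"pooled_t"`, `"welch_t"`, or `"mean_difference"`.
#' @return A single numeric value.
#' @export
#' @examples
#' two_sample_statistic(c(1, 2, 3), c(4, 5, 6), "pooled_t")
two_sample_statistic <- function(case, control,
                                 kind = c("pooled_t", "welch_t",
                                          "mean_difference")) {
  kind <- match.arg(kind)
  case <- as.numeric(case); control <- as.numeric(control)
  min_n <- if (kind == "mean_difference") 1L else 2L
  if (length(case) < min_n || length(control) < min_n) {
    abort(sprintf("Each group needs at least %d values for kind = \"%s\".",
                  min_n, kind))
  }
  d <- mean(case) - mean(control)
  if (kind == "mean_difference") return(d)
  n1 <- length(case); n2 <- length(control)
  if (kind == "pooled_t") {
    sp2 <- ((n1 - 1) * var(case) + (n2 - 1) * var(control)) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(var(case) / n1 + var(control) / n2)
  }
  if (se == 0) {
    if (d == 0) return(0)
    abort("Zero pooled variance with unequal means; use kind = \"mean_difference\".")
  }
  d / se
}

#' Per-protein permutation test of differential expression
#'
#' For every protein (row), computes the observed two-sample statistic and a
#' permutation p-value: the proportion of group-label re-assignments whose
#' statistic is at least as extreme in absolute value as the observed one.
#' Monte-Carlo mode draws `n_perm` independent uniform re-assignments (which
#' may repeat); exhaustive mode enumerates all `choose(n, n_case)` distinct
#' assignments; `"auto"` picks exhaustive whenever that count does not
#' exceed `n_perm`.
#'
#' Proteins whose pooled variance is zero (constant rows) cannot support a t
#' statistic and fall back to the mean-difference statistic, with a warning.
#'
#' @param data Protein-level tibble: first column protein identifiers,
#'   remaining columns numeric log2 intensities, one per sample. (Passing a
#'   peptide-level table tests at peptide granularity instead; the
#'   procedure is identical.)
#' @param groups Tibble `(sample_id, group)` with `group` in
#'   `{"case", "control"}` covering every sample column.
#' @param statistic Statistic kind; see [two_sample_statistic()]. Default
#'   pooled-variance t.
#' @param n_perm Number of Monte-Carlo permutations (default 100000, giving
#'   p-value granularity 1e-5).
#' @param seed Integer seed for the Monte-Carlo draws.
#' @param mode `"auto"`, `"montecarlo"`, or `"exhaustive"`.
#' @param rule Exceedance rule: `"geq"` (default) counts permutations with
#'   `|T*| >= |T|`, so the exhaustive p-value is always positive (the
#'   identity assignment counts); `"strict"` counts `|T*| > |T|`.
#' @param smoothing If `TRUE`, report `(b + 1) / (B + 1)` instead of the
#'   plain proportion `b / B` (Monte-Carlo mode only). Default `FALSE`.
#' @param chunk_size Permutations processed per block (memory control).
#'
#' @return An object of class `perm_test`. [tidy()] returns the per-protein
#'   tibble `(protein_id, statistic, mean_diff, p_value, direction)`;
#'   `direction` is `"over"`/`"under"` by the sign of the case-minus-control
#'   mean difference (`NA` when the difference is exactly zero).
#' @seealso [select_significant()]
#' @export
#' @examples
#' tbl <- tibble::tibble(protein_id = "A",
#'                       s1 = 1, s2 = 2, s3 = 3,
#'                       s4 = 10, s5 = 11, s6 = 12)
#' grp <- tibble::tibble(sample_id = paste0("s", 1:6),
#'                       group = rep(c("case", "control"), each = 3))
#' fit <- permutation_test(tbl, grp, statistic = "mean_difference",
#'                         mode = "exhaustive")
#' tidy(fit)
permutation_test <- function(data, groups,
                             statistic = c("pooled_t", "welch_t",
                                           "mean_difference"),
                             n_perm = 100000L, seed = 1L,
                             mode = c("auto", "montecarlo", "exhaustive"),
                             rule = c("geq", "strict"),
                             smoothing = FALSE,
                             chunk_size = 2000L) {
  statistic <- match.arg(statistic)
  mode <- match.arg(mode)
  rule <- match.arg(rule)
  if (n_perm < 1) abort("`n_perm` must be >= 1.")

  x <- intensity_values(data)
  sample_ids <- colnames(x)
  grp <- align_groups(groups, sample_ids)
  case_idx <- which(grp == "case")
  n1 <- length(case_idx)
  n2 <- ncol(x) - n1
  if (n1 < 1 || n2 < 1) abort("Both groups must be non-empty.")
  min_n <- if (statistic == "mean_difference") 1L else 2L
  if (n1 < min_n || n2 < min_n) {
    abort(sprintf("Each group needs >= %d samples for statistic \"%s\".",
                  min_n, statistic))
  }
  if (anyNA(x)) {
    abort("Permutation testing requires a complete matrix; impute or drop missing values first.")
  }

  n_assign <- choose(n1 + n2, n1)
  use_exhaustive <- switch(mode,
    exhaustive = TRUE,
    montecarlo = FALSE,
    auto = n_assign <= n_perm
  )
  if (use_exhaustive && n_assign > 2e6) {
    abort(sprintf("Exhaustive enumeration of %.3g assignments is too large; use mode = \"montecarlo\".",
                  n_assign))
  }

  eng <- perm_engine(x, n1, statistic)
  obs <- eng$stat(perm_indicator(case_idx, ncol(x)))[, 1]
  mean_diff <- eng$mean_diff(perm_indicator(case_idx, ncol(x)))[, 1]
  if (length(eng$fallback) > 0) {
    warn(sprintf("%d constant protein(s) fall back to the mean-difference statistic.",
                 length(eng$fallback)))
  }

  obs_abs <- abs(obs)
  # exceedance threshold with a relative guard so the identity assignment
  # and exact sign-flips compare as equal despite floating-point noise
  eps <- 1e-9 * (1 + obs_abs)
  thresh <- if (rule == "geq") obs_abs - eps else obs_abs + eps
  thresh[!is.finite(obs_abs)] <- Inf   # infinite observed: only ties count

  count <- numeric(nrow(x))
  if (use_exhaustive) {
    assigns <- combn(n1 + n2, n1)
    n_eval <- ncol(assigns)
    for (start in seq(1, n_eval, by = chunk_size)) {
      idx <- start:min(start + chunk_size - 1, n_eval)
      ind <- matrix(0, ncol(x), length(idx))
      ind[cbind(as.vector(assigns[, idx, drop = FALSE]),
                rep(seq_along(idx), each = n1))] <- 1
      count <- count + rowSums(abs(eng$stat(ind)) >= thresh)
    }
  } else {
    n_eval <- as.integer(n_perm)
    withr::with_seed(seed, {
      done <- 0L
      while (done < n_eval) {
        b <- min(chunk_size, n_eval - done)
        ind <- matrix(0, ncol(x), b)
        picks <- vapply(seq_len(b), function(i) sample.int(ncol(x), n1),
                        integer(n1))
        ind[cbind(as.vector(picks), rep(seq_len(b), each = n1))] <- 1
        count <- count + rowSums(abs(eng$stat(ind)) >= thresh)
        done <- done + b
      }
    })
  }
  p <- if (smoothing && !use_exhaustive) {
    (count + 1) / (n_eval + 1)
  } else {
    count / n_eval
  }

  direction <- dplyr::case_when(
    mean_diff > 0 ~ "over",
    mean_diff < 0 ~ "under",
    TRUE ~ NA_character_
  )
  results <- tibble::tibble(
    protein_id = rownames(x),
    statistic = unname(obs),
    mean_diff = unname(mean_diff),
    p_value = unname(p),
    direction = unname(direction)
  )
  structure(
    list(
      results = results,
      statistic = statistic,
      mode = if (use_exhaustive) "exhaustive" else "montecarlo",
      n_eval = n_eval,
      rule = rule,
      smoothing = smoothing,
      seed = seed,
      rng = "Mersenne-Twister (base R), withr::with_seed",
      n_case = n1, n_control = n2,
      fallback = rownames(x)[eng$fallback]
    ),
    class = "perm_test"
  )
}

# vectorized statistic engine over 0/1 case-indicator matrices (samples x B)
perm_engine <- function(x, n1, statistic) {
  n <- ncol(x)
  n2 <- n - n1
  x2 <- x * x
  tot <- rowSums(x)
  totq <- rowSums(x2)

  mean_diff_fun <- function(ind) {
    s1 <- x %*% ind
    s1 / n1 - (tot - s1) / n2
  }

  fallback <- integer()
  if (statistic != "mean_difference") {
    # rows with zero overall variance cannot support any t statistic
    row_var <- totq / n - (tot / n)^2
    fallback <- which(row_var <= .Machine$double.eps * pmax(1, abs(totq)))
  }

  stat_fun <- if (statistic == "mean_difference") {
    mean_diff_fun
  } else {
    function(ind) {
      s1 <- x %*% ind
      q1 <- x2 %*% ind
      m1 <- s1 / n1
      m2 <- (tot - s1) / n2
      ss1 <- pmax(q1 - s1^2 / n1, 0)                  # clip FP negatives
      ss2 <- pmax((totq - q1) - (tot - s1)^2 / n2, 0)
      tt <- if (statistic == "pooled_t") {
        sp2 <- (ss1 + ss2) / (n - 2)
        (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
      } else {
        (m1 - m2) / sqrt(ss1 / (n1 - 1) / n1 + ss2 / (n2 - 1) / n2)
      }
      tt[is.nan(tt)] <- 0   # 0/0: both groups constant and equal
      if (length(fallback) > 0) {
        md <- m1 - m2
        tt[fallback, ] <- md[fallback, ]
      }
      tt
    }
  }
  list(stat = stat_fun, mean_diff = mean_diff_fun, fallback = fallback)
}

perm_indicator <- function(case_idx, n) {
  ind <- matrix(0, n, 1)
  ind[case_idx, 1] <- 1
  ind
}

align_groups <- function(groups, sample_ids) {
  if (!all(c("sample_id", "group") %in% names(groups))) {
    abort("`groups` must have columns `sample_id` and `group`.")
  }
  if (!all(sample_ids %in% groups$sample_id)) {
    missing <- setdiff(sample_ids, groups$sample_id)
    abort(sprintf("Sample(s) missing from `groups`: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  grp <- setNames(groups$group, groups$sample_id)[sample_ids]
  if (!all(grp %in% c("case", "control"))) {
    abort("`group` values must be \"case\" or \"control\".")
  }
  unname(grp)
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("<perm_test> %d proteins, %d case / %d control, %s statistic, %s (%d assignments)\n",
              nrow(x$results), x$n_case, x$n_control, x$statistic,
              x$mode, x$n_eval))
  print(x$results, n = 5)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.perm_test <- function(x, ...) x$results

#' @exportS3Method generics::glance
glance.perm_test <- function(x, ...) {
  tibble::tibble(
    n_tested = nrow(x$results),
    statistic = x$statistic,
    mode = x$mode,
    n_permutations = x$n_eval,
    n_case = x$n_case,
    n_control = x$n_control
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.perm_test <- function(object, alpha = 0.001, ...) {
  res <- object$results
  res$neglog_p <- -log10(pmax(res$p_value, 0.5 / object$n_eval))
  ggplot2::ggplot(res, ggplot2::aes(x = .data$mean_diff, y = .data$neglog_p)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(alpha), colour = "red",
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean difference (case - control, log2)",
                  y = "-log10 permutation p-value",
                  title = "Permutation test volcano plot")
}

#' Select significant proteins and summarize family-wise error
#'
#' Flags proteins with permutation p-value at or below `alpha` and computes
#' the study-level summary: the per-family Type 1 error rate
#' (PFER = number of tests x alpha) and the nominal false discovery rate
#' (FDR = PFER / number declared significant).
#'
#' @param results A `perm_test` object or a tidy per-protein tibble with
#'   columns `protein_id`, `p_value`, `direction`.
#' @param alpha Significance level in (0, 1); default 0.001.
#' @return An object of class `perm_sig`; [tidy()] gives the per-protein
#'   table with a `significant` column, [glance()] the one-row summary
#'   `(n_tested, alpha, n_significant, n_over, n_under, pfer, fdr_nominal)`.
#'   `fdr_nominal` is `NA` when nothing is declared significant.
#' @export
select_significant <- function(results, alpha = 0.001) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single number in (0, 1).")
  }
  res <- if (inherits(results, "perm_test")) results$results else {
    tibble::as_tibble(results)
  }
  if (!all(c("protein_id", "p_value") %in% names(res))) {
    abort("`results` must contain `protein_id` and `p_value` columns.")
  }
  res$significant <- res$p_value <= alpha
  n_sig <- sum(res$significant)
  pf <- pfer(nrow(res), alpha)
  summary <- tibble::tibble(
    n_tested = nrow(res),
    alpha = alpha,
    n_significant = n_sig,
    n_over = sum(res$significant & res$direction == "over", na.rm = TRUE),
    n_under = sum(res$significant & res$direction == "under", na.rm = TRUE),
    pfer = pf,
    fdr_nominal = fdr_nominal(pf, n_sig)
  )
  structure(list(results = res, summary = summary, alpha = alpha),
            class = "perm_sig")
}

#' @export
print.perm_sig <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<perm_sig> %d / %d significant at alpha = %g (PFER = %.4g, nominal FDR = %.4g)\n",
              s$n_significant, s$n_tested, s$alpha, s$pfer,
              if (is.na(s$fdr_nominal)) NA else s$fdr_nominal))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.perm_sig <- function(x, ...) x$results

#' @exportS3Method generics::glance
glance.perm_sig <- function(x, ...) x$summary

#' Per-family Type 1 error rate
#'
#' The expected number of false positives when `n_tested` independent null
#' hypotheses are each tested at level `alpha`: `n_tested * alpha`.
#'
#' @param n_tested Number of tests (non-negative integer).
#' @param alpha Significance level in (0, 1).
#' @return A single number.
#' @export
#' @examples
#' pfer(1422, 0.001)
pfer <- function(n_tested, alpha) {
  if (n_tested < 0 || n_tested != floor(n_tested)) {
    abort("`n_tested` must be a non-negative integer.")
  }
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  n_tested * alpha
}

#' Nominal false discovery rate
#'
#' The expected proportion of false positives among the declared
#' significants: PFER divided by the declared count. Undefined (`NA`) when
#' nothing is declared.
#'
#' @param pfer_value A per-family error rate, see [pfer()].
#' @param n_declared Number of features declared significant (>= 0).
#' @return A single number, or `NA_real_` when `n_declared` is 0.
#' @export
#' @examples
#' fdr_nominal(pfer(1422, 0.001), 254)
fdr_nominal <- function(pfer_value, n_declared) {
  if (n_declared < 0 || n_declared != floor(n_declared)) {
    abort("`n_declared` must be a non-negative integer.")
  }
  if (n_declared == 0) return(NA_real_)
  pfer_value / n_declared
}
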