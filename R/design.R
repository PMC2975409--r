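#' Specify a synthetic case/control study design
#'
#' A `study_design` collects everything needed to simulate one label-free
#' case/control intensity study: group sizes, the peptide-to-protein
#' structure, how many proteins carry a planted differential effect, and the
#' noise model for log2 intensities. Defaults emulate a plasma profiling
#' study with 40 cases and 40 controls, 1422 proteins observed through
#' roughly 3-4 peptides each, and 254 differential proteins of which 208 are
#' over-expressed in cases.
#'
#' @param n_case,n_control Number of case / control samples (positive).
#' @param n_proteins Number of proteins (positive).
#' @param peptides_per_protein Integer vector `c(min, max)`; each protein's
#'   peptide count is drawn uniformly from `min:max` (`min >= 1`).
#' @param n_differential Number of proteins with a planted effect
#'   (`<= n_proteins`).
#' @param frac_overexpressed Fraction of differential proteins that are
#'   over-expressed in cases, in `[0, 1]`. The over-expressed count is
#'   `floor(n_differential * frac_overexpressed + 0.5)`; the remainder are
#'   under-expressed.
#' @param effect_size Magnitude of the planted shift, in log2 units
#'   (positive).
#' @param noise_model Residual distribution for log2 intensities:
#'   `"lognormal"` (default; centred, right-skewed, so pooled log2
#'   intensities are detectably non-normal), `"normal"`, or `"mixture"`
#'   (90/10 scale mixture of normals).
#' @param noise_sd Standard deviation of the residual term (log2 units).
#' @param baseline Grand mean log2 intensity.
#' @param protein_sd,sample_sd,peptide_sd Standard deviations of the
#'   protein, sample, and peptide random effects (log2 units). Peptide
#'   effects are constant across samples, so they cancel in group
#'   comparisons; sample effects are shared by all peptides of a sample.
#' @param missing_frac Fraction of intensity cells set to `NA` completely at
#'   random. Default 0 (no missingness).
#' @param seed Integer seed; identical designs (including seed) simulate
#'   bit-identical studies.
#'
#' @return An object of class `study_design` (a validated list).
#' @seealso [simulate_study()]
#' @export
#' @examples
#' study_design(n_case = 20, n_control = 20, n_proteins = 100,
#'              n_differential = 10, seed = 7)
study_design <- function(n_case = 40,
                         n_control = 40,
                         n_proteins = 1422,
                         peptides_per_protein = c(1L, 6L),
                         n_differential = 254,
                         frac_overexpressed = 208 / 254,
                         effect_size = 2,
                         noise_model = c("lognormal", "normal", "mixture"),
                         noise_sd = 1,
                         baseline = 20,
                         protein_sd = 1.5,
                         sample_sd = 0.3,
                         peptide_sd = 0.5,
                         missing_frac = 0,
                         seed = 1L) {
  noise_model <- match.arg(noise_model)
  check_count <- function(x, name, min = 1) {
    if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < min ||
        x != floor(x)) {
      abort(sprintf("`%s` must be a single integer >= %d.", name, min))
    }
    as.integer(x)
  }
  n_case <- check_count(n_case, "n_case")
  n_control <- check_count(n_control, "n_control")
  n_proteins <- check_count(n_proteins, "n_proteins")
  n_differential <- check_count(n_differential, "n_differential", min = 0)
  if (n_differential > n_proteins) {
    abort("`n_differential` must not exceed `n_proteins`.")
  }
  if (length(peptides_per_protein) != 2 ||
      any(peptides_per_protein != floor(peptides_per_protein)) ||
      peptides_per_protein[1] < 1 ||
      peptides_per_protein[2] < peptides_per_protein[1]) {
    abort("`peptides_per_protein` must be integer c(min, max) with min >= 1.")
  }
  if (!is.numeric(frac_overexpressed) || frac_overexpressed < 0 ||
      frac_overexpressed > 1) {
    abort("`frac_overexpressed` must lie in [0, 1].")
  }
  if (!is.numeric(effect_size) || effect_size < 0) {
    abort("`effect_size` must be a non-negative number.")
  }
  if (!is.numeric(missing_frac) || missing_frac < 0 || missing_frac >= 1) {
    abort("`missing_frac` must lie in [0, 1).")
  }
  if (!is.numeric(noise_sd) || noise_sd <= 0) {
    abort("`noise_sd` must be positive.")
  }
  seed <- check_count(seed, "seed", min = 0)

  structure(
    list(
      n_case = n_case, n_control = n_control, n_proteins = n_proteins,
      peptides_per_protein = as.integer(peptides_per_protein),
      n_differential = n_differential,
      frac_overexpressed = frac_overexpressed,
      effect_size = effect_size, noise_model = noise_model,
      noise_sd = noise_sd, baseline = baseline, protein_sd = protein_sd,
      sample_sd = sample_sd, peptide_sd = peptide_sd,
      missing_frac = missing_frac, seed = seed
    ),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat("<study_design>\n")
  cat(sprintf("  samples:   %d case / %d control\n", x$n_case, x$n_control))
  cat(sprintf("  proteins:  %d (%d differential, %.0f%% over-expressed)\n",
              x$n_proteins, x$n_differential, 100 * x$frac_overexpressed))
  cat(sprintf("  peptides:  %d-%d per protein\n",
              x$peptides_per_protein[1], x$peptides_per_protein[2]))
  cat(sprintf("  effect:    %.2f log2 units; noise: %s (sd %.2f); seed %d\n",
              x$effect_size, x$noise_model, x$noise_sd, x$seed))
  invisible(x)
}
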