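#' Simulate a case/control peptide intensity study with known ground truth
#'
#' Generates a peptide-level intensity matrix, the peptide-to-protein map,
#' the sample group map, and the planted truth table for a [study_design()].
#' Log2 intensities follow an additive model
#' `baseline + protein + sample + peptide + residual`, with the planted
#' log2-fold-change added to case samples of differential proteins (all
#' peptides of a protein shift together). The default residual is a centred
#' lognormal, so pooled log2 intensities are right-skewed and rejected by a
#' Kolmogorov-Smirnov normality test at realistic sizes.
#'
#' @param design A [study_design()].
#' @param scale `"log2"` (default) to return model-scale intensities, or
#'   `"raw"` to return `2^value`, the raw-intensity scale expected by
#'   [log2_transform()].
#'
#' @return A list of class `sim_study` with elements
#'   * `intensities`: tibble, first column `peptide_id`, one numeric column
#'     per sample;
#'   * `peptide_map`: tibble `(peptide_id, protein_id)`;
#'   * `groups`: tibble `(sample_id, group)` with groups `case`/`control`;
#'   * `truth`: tibble `(protein_id, direction, effect)` for the planted
#'     differential proteins (`direction` is `over`/`under` in cases);
#'   * `design`: the design used.
#' @export
#' @examples
#' sim <- simulate_study(study_design(n_case = 5, n_control = 5,
#'                                    n_proteins = 20, n_differential = 4,
#'                                    seed = 1))
#' dim(sim$intensities)
simulate_study <- function(design, scale = c("log2", "raw")) {
  if (!inherits(design, "study_design")) {
    abort("`design` must be a `study_design` object.")
  }
  scale <- match.arg(scale)
  d <- design
  withr::with_seed(d$seed, {
    protein_ids <- sprintf("P%05d", seq_len(d$n_proteins))
    npep <- sample_int_range(d$peptides_per_protein[1],
                             d$peptides_per_protein[2], d$n_proteins)
    n_pep_total <- sum(npep)
    peptide_ids <- sprintf("PEP%06d", seq_len(n_pep_total))
    pep_protein <- rep(protein_ids, times = npep)

    n_samples <- d$n_case + d$n_control
    sample_ids <- c(sprintf("case_%02d", seq_len(d$n_case)),
                    sprintf("ctrl_%02d", seq_len(d$n_control)))
    groups <- tibble::tibble(
      sample_id = sample_ids,
      group = rep(c("case", "control"), c(d$n_case, d$n_control))
    )

    # planted truth
    diff_ids <- sort(sample(protein_ids, d$n_differential))
    n_over <- as.integer(floor(d$n_differential * d$frac_overexpressed + 0.5))
    dir_vec <- rep("under", d$n_differential)
    if (n_over > 0) dir_vec[sample(seq_len(d$n_differential), n_over)] <- "over"
    truth <- tibble::tibble(
      protein_id = diff_ids,
      direction = dir_vec,
      effect = ifelse(dir_vec == "over", d$effect_size, -d$effect_size)
    )

    protein_eff <- rnorm(d$n_proteins, 0, d$protein_sd)
    names(protein_eff) <- protein_ids
    sample_eff <- rnorm(n_samples, 0, d$sample_sd)
    peptide_eff <- rnorm(n_pep_total, 0, d$peptide_sd)

    resid <- sim_residual(n_pep_total * n_samples, d$noise_model, d$noise_sd)
    x <- matrix(resid, nrow = n_pep_total, ncol = n_samples)
    x <- x + d$baseline + protein_eff[pep_protein] + peptide_eff
    x <- sweep(x, 2, sample_eff, "+")

    # planted shift: case columns of all peptides of differential proteins
    if (d$n_differential > 0) {
      eff_by_protein <- setNames(truth$effect, truth$protein_id)
      row_eff <- eff_by_protein[pep_protein]
      row_eff[is.na(row_eff)] <- 0
      x[, seq_len(d$n_case)] <- x[, seq_len(d$n_case)] + row_eff
    }

    if (d$missing_frac > 0) {
      x[runif(length(x)) < d$missing_frac] <- NA_real_
    }
    if (scale == "raw") x <- 2^x

    intensities <- tibble::as_tibble(as.data.frame(x))
    names(intensities) <- sample_ids
    intensities <- dplyr::bind_cols(
      tibble::tibble(peptide_id = peptide_ids), intensities
    )
    attr(intensities, "intensity_scale") <- scale

    structure(
      list(
        intensities = intensities,
        peptide_map = tibble::tibble(peptide_id = peptide_ids,
                                     protein_id = pep_protein),
        groups = groups,
        truth = truth,
        design = d
      ),
      class = "sim_study"
    )
  })
}

# sample(x) degenerates to sample.int(x) for scalar x; avoid that trap
sample_int_range <- function(a, b, n) {
  if (a == b) rep(as.integer(a), n) else sample(seq(a, b), n, replace = TRUE)
}

# centred residual draw with sd = noise_sd
sim_residual <- function(n, model, noise_sd) {
  switch(model,
    normal = rnorm(n, 0, noise_sd),
    lognormal = {
      s <- 0.8   # shape of the lognormal on the raw scale
      r <- rlnorm(n, 0, s)
      (r - exp(s^2 / 2)) / sqrt((exp(s^2) - 1) * exp(s^2)) * noise_sd
    },
    mixture = {
      base_sd <- noise_sd / sqrt(0.9 + 0.1 * 9)
      wide <- runif(n) < 0.1
      rnorm(n, 0, ifelse(wide, 3 * base_sd, base_sd))
    }
  )
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf(
    "<sim_study> %d peptides / %d proteins, %d case + %d control samples, %d differential\n",
    nrow(x$intensities), x$design$n_proteins, x$design$n_case,
    x$design$n_control, nrow(x$truth)
  ))
  invisible(x)
}

#' Simulate reference biomarker sets with controlled overlap
#'
#' Draws biomarker sets from a protein universe, each sharing exactly
#' `n_overlap` members with a given set. Stands in for externally published
#' reference panels (e.g. cell-line biomarker lists) when benchmarking
#' cross-study comparisons.
#'
#' @param universe Character vector of available protein identifiers.
#' @param n_sets Number of sets to generate.
#' @param set_size Size of each generated set (`<= length(universe)`).
#' @param overlap_with Optional [biomarker_set()] (or character vector) the
#'   generated sets must intersect in exactly `n_overlap` members.
#' @param n_overlap Required overlap size (default 0 when `overlap_with` is
#'   `NULL`).
#' @param seed Integer seed.
#'
#' @return A list of [biomarker_set()] objects named `ref1`, `ref2`, ...
#' @export
#' @examples
#' u <- sprintf("P%03d", 1:100)
#' a <- biomarker_set("A", u[1:25])
#' refs <- simulate_reference_sets(u, 1, set_size = 20,
#'                                 overlap_with = a, n_overlap = 13, seed = 2)
#' length(intersect(refs[[1]]$members, a$members))
simulate_reference_sets <- function(universe, n_sets, set_size,
                                    overlap_with = NULL, n_overlap = 0,
                                    seed = 1L) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) abort("`universe` must be non-empty.")
  if (set_size < 1 || set_size > length(universe)) {
    abort("`set_size` must be between 1 and the universe size.")
  }
  anchor <- if (is.null(overlap_with)) character() else set_members(overlap_with)
  anchor <- intersect(anchor, universe)
  if (n_overlap > min(set_size, length(anchor))) {
    abort("`n_overlap` must not exceed min(set_size, |overlap_with|).")
  }
  pool <- setdiff(universe, anchor)
  if (set_size - n_overlap > length(pool)) {
    abort("Universe too small for the requested overlap: not enough proteins outside `overlap_with`.")
  }
  withr::with_seed(seed, {
    purrr::map(seq_len(n_sets), function(i) {
      shared <- if (n_overlap > 0) sample(anchor, n_overlap) else character()
      rest <- if (set_size > n_overlap) {
        sample(pool, set_size - n_overlap)
      } else character()
      biomarker_set(paste0("ref", i), c(shared, rest))
    })
  })
}

#' Simulate a pathway annotation over a protein universe
#'
#' Draws `n_pathways` member sets from `universe`, with sizes uniform in
#' `size_range`. A lightweight stand-in for a curated pathway database
#' (KEGG-style GMT input) in simulation studies.
#'
#' @param universe Character vector of protein identifiers (non-empty).
#' @param n_pathways Number of pathways (may be 0).
#' @param size_range Integer `c(min, max)` pathway sizes, `max <= |universe|`.
#' @param seed Integer seed.
#'
#' @return A [pathway_annotation()] object.
#' @export
#' @examples
#' ann <- simulate_pathway_annotation(sprintf("P%03d", 1:50), 4,
#'                                    size_range = c(5, 10), seed = 3)
#' lengths(ann$sets)
simulate_pathway_annotation <- function(universe, n_pathways,
                                        size_range = c(5, 50), seed = 1L) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) abort("`universe` must be non-empty.")
  if (length(size_range) != 2 || size_range[1] < 1 ||
      size_range[2] < size_range[1]) {
    abort("`size_range` must be c(min, max) with 1 <= min <= max.")
  }
  if (size_range[2] > length(universe)) {
    abort("Maximum pathway size exceeds the universe size.")
  }
  if (n_pathways < 0) abort("`n_pathways` must be non-negative.")
  withr::with_seed(seed, {
    sizes <- if (n_pathways > 0) {
      sample_int_range(size_range[1], size_range[2], n_pathways)
    } else integer()
    sets <- purrr::map(sizes, function(k) sort(sample(universe, k)))
    names(sets) <- if (n_pathways > 0) {
      sprintf("PW%03d", seq_len(n_pathways))
    } else character()
    pathway_annotation(sets, universe = universe)
  })
}
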