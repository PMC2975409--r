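#' Create a pathway annotation
#'
#' A pathway annotation maps pathway names to member protein sets over a
#' stated protein universe (the background for enrichment tests).
#'
#' @param sets Named list of character vectors (pathway members). Names must
#'   be unique and non-empty.
#' @param universe Character vector of background protein identifiers;
#'   defaults to the union of all pathway members. Members outside the
#'   universe are an error.
#' @return An object of class `pathway_annotation` with elements `sets` and
#'   `universe`.
#' @seealso [read_gmt()], [simulate_pathway_annotation()]
#' @export
pathway_annotation <- function(sets, universe = NULL) {
  if (!is.list(sets)) abort("`sets` must be a list of character vectors.")
  if (length(sets) > 0) {
    if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
      abort("Every pathway must be named.")
    }
    if (anyDuplicated(names(sets))) abort("Pathway names must be unique.")
  }
  sets <- purrr::map(sets, function(m) unique(as.character(m)))
  if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))
  universe <- unique(as.character(universe))
  stray <- setdiff(unlist(sets, use.names = FALSE), universe)
  if (length(stray) > 0) {
    abort(sprintf("Pathway member(s) outside the universe: %s",
                  paste(head(stray, 5), collapse = ", ")))
  }
  structure(list(sets = sets, universe = universe),
            class = "pathway_annotation")
}

#' @export
print.pathway_annotation <- function(x, ...) {
  cat(sprintf("<pathway_annotation> %d pathways over %d proteins\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Binary pathway-protein association matrix
#'
#' Cell `(pathway, protein)` is 1 iff the panel protein belongs to the
#' pathway. Panel members absent from the annotation universe are dropped
#' with a warning.
#'
#' @param panel A panel (anything accepted by [as_biomarker_set()]).
#' @param annotation A [pathway_annotation()] with at least one pathway.
#' @return Tibble: column `pathway`, then one 0/1 integer column per
#'   retained panel member (an empty panel gives zero protein columns).
#' @export
#' @examples
#' ann <- pathway_annotation(list(P1 = c("a", "b", "c"), P2 = c("c", "d")))
#' build_association_matrix(c("a", "c"), ann)
build_association_matrix <- function(panel, annotation) {
  check_annotation(annotation, need_pathways = TRUE)
  members <- set_members(as_biomarker_set(panel))
  outside <- setdiff(members, annotation$universe)
  if (length(outside) > 0) {
    warn(sprintf("Dropping %d panel member(s) outside the annotation universe: %s",
                 length(outside), paste(head(outside, 5), collapse = ", ")))
    members <- setdiff(members, outside)
  }
  out <- tibble::tibble(pathway = names(annotation$sets))
  for (m in members) {
    out[[m]] <- unname(as.integer(purrr::map_lgl(annotation$sets,
                                                 ~ m %in% .x)))
  }
  out
}

#' Pathway-protein frequency count matrix (PPFCM)
#'
#' Rows are pathways, columns are studies; cell `(pathway, study)` counts
#' the study's panel members that belong to the pathway.
#'
#' @param panels Named list: study label -> panel (each coercible to
#'   [biomarker_set()]). Labels must be unique.
#' @param annotation A [pathway_annotation()].
#' @return A tibble of class `ppfcm`: column `pathway`, one integer column
#'   per study.
#' @seealso [rank_pathways()], [matrix_similarity()], [ppfcm_long()]
#' @export
#' @examples
#' ann <- pathway_annotation(list(P1 = c("a", "b", "c"), P2 = c("c", "d")))
#' build_ppfcm(list(S = c("a", "c")), ann)
build_ppfcm <- function(panels, annotation) {
  check_annotation(annotation, need_pathways = TRUE)
  if (length(panels) < 1) abort("`panels` must contain at least one study.")
  labels <- names(panels)
  if (is.null(labels) || any(!nzchar(labels))) {
    abort("`panels` must be a named list (study labels).")
  }
  if (anyDuplicated(labels)) abort("Duplicate study labels in `panels`.")
  out <- tibble::tibble(pathway = names(annotation$sets))
  for (lab in labels) {
    members <- set_members(as_biomarker_set(panels[[lab]]))
    out[[lab]] <- unname(purrr::map_int(annotation$sets,
                                        ~ length(intersect(.x, members))))
  }
  class(out) <- c("ppfcm", class(out))
  out
}

#' Long form of a PPFCM for plotting/export
#'
#' @param ppfcm A [build_ppfcm()] result.
#' @return Tibble `(pathway, study, count)`.
#' @export
ppfcm_long <- function(ppfcm) {
  tidyr::pivot_longer(tibble::as_tibble(ppfcm), -"pathway",
                      names_to = "study", values_to = "count")
}

#' @exportS3Method ggplot2::autoplot
autoplot.ppfcm <- function(object, ...) {
  ggplot2::ggplot(ppfcm_long(object),
                  ggplot2::aes(x = .data$study, y = .data$pathway,
                               fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Study", y = "Pathway", fill = "Proteins",
                  title = "Pathway-protein frequency counts")
}

#' Rank pathways by representation in a study's panel
#'
#' Sorts pathways by descending count in one PPFCM column; ties are broken
#' lexicographically by pathway name.
#'
#' @param ppfcm A [build_ppfcm()] result.
#' @param study Study label (must be a PPFCM column).
#' @return Tibble `(pathway, count)` in rank order.
#' @export
rank_pathways <- function(ppfcm, study) {
  if (!study %in% names(ppfcm)[-1]) {
    abort(sprintf("Unknown study \"%s\".", study))
  }
  tibble::tibble(pathway = ppfcm$pathway, count = ppfcm[[study]]) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$pathway)
}

#' Fisher's exact pathway over-representation test
#'
#' For each pathway, tests whether the protein list is enriched for pathway
#' members relative to the annotation universe, via the hypergeometric tail
#' of the 2x2 table (in-list/in-pathway). One-sided over-representation by
#' default; `alternative = "two.sided"` uses [stats::fisher.test()].
#' Pathways with no members in the universe are excluded with a warning.
#'
#' @param list_set The protein list (coercible to [biomarker_set()]); must
#'   be contained in the universe (strays dropped with a warning). A list
#'   larger than the universe is an error.
#' @param annotation A [pathway_annotation()].
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return Tibble `(pathway, overlap, list_size, pathway_size,
#'   universe_size, p_value)` sorted by `p_value`.
#' @export
#' @examples
#' ann <- pathway_annotation(list(P1 = c("a", "b")),
#'                           universe = letters[1:10])
#' fisher_enrichment(c("a", "b", "c"), ann)
fisher_enrichment <- function(list_set, annotation,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  check_annotation(annotation, need_pathways = TRUE)
  members <- set_members(as_biomarker_set(list_set))
  n_univ <- length(annotation$universe)
  if (length(members) > n_univ) {
    abort("Protein list is larger than the annotation universe.")
  }
  outside <- setdiff(members, annotation$universe)
  if (length(outside) > 0) {
    warn(sprintf("Dropping %d list member(s) outside the universe.",
                 length(outside)))
    members <- setdiff(members, outside)
  }
  sets <- purrr::map(annotation$sets,
                     ~ intersect(.x, annotation$universe))
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warn(sprintf("Excluding %d pathway(s) with no members in the universe.",
                 sum(empty)))
    sets <- sets[!empty]
  }
  n_list <- length(members)
  res <- purrr::imap_dfr(sets, function(pw, nm) {
    k <- length(intersect(pw, members))
    m <- length(pw)
    p <- if (alternative == "greater") {
      phyper(k - 1, m, n_univ - m, n_list, lower.tail = FALSE)
    } else {
      tab <- matrix(c(k, m - k, n_list - k, n_univ - m - n_list + k), 2, 2)
      stats::fisher.test(tab, alternative = "two.sided")$p.value
    }
    tibble::tibble(pathway = nm, overlap = k, list_size = n_list,
                   pathway_size = m, universe_size = n_univ, p_value = p)
  })
  dplyr::arrange(res, .data$p_value, .data$pathway)
}

#' Biomarker set similarity: protein method (Jaccard index)
#'
#' The intersection size of two biomarker sets divided by their union size,
#' in `[0, 1]`. Two empty sets are defined as identical (similarity 1).
#'
#' @param set_i,set_j Sets (each coercible to [biomarker_set()]).
#' @return A single number in `[0, 1]`.
#' @seealso [similarity_percent()], [matrix_similarity()]
#' @export
#' @examples
#' set_similarity(letters[1:25], c(letters[1:13], LETTERS[1:7]))
set_similarity <- function(set_i, set_j) {
  a <- set_members(set_i)
  b <- set_members(set_j)
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

#' Integer-truncated percent of a similarity score
#'
#' Converts a fraction to a whole percent by truncation toward zero
#' (13/32 = 40.625% is reported as 40%).
#'
#' @param s Numeric fraction(s).
#' @return Integer percent(s).
#' @export
similarity_percent <- function(s) trunc(s * 100)

#' Biomarker set similarity: pathway-profile method (Pearson of counts)
#'
#' Pearson correlation between two studies' pathway count profiles (their
#' PPFCM columns). High correlation means the two panels populate pathways
#' in similar proportions even when the protein identities differ.
#'
#' @param ppfcm A [build_ppfcm()] result with at least 2 pathways.
#' @param study_i,study_j Study labels (PPFCM columns).
#' @return A number in `[-1, 1]`, or `NA` with a warning when either
#'   column is constant.
#' @export
matrix_similarity <- function(ppfcm, study_i, study_j) {
  for (s in c(study_i, study_j)) {
    if (!s %in% names(ppfcm)[-1]) abort(sprintf("Unknown study \"%s\".", s))
  }
  if (nrow(ppfcm) < 2) abort("Need at least 2 pathways to correlate.")
  x <- ppfcm[[study_i]]
  y <- ppfcm[[study_j]]
  if (sd(x) == 0 || sd(y) == 0) {
    warn("Constant pathway-count column; similarity is undefined.")
    return(NA_real_)
  }
  cor(x, y)
}

#' Pairwise similarity report for a collection of panels
#'
#' Computes the Jaccard (protein method) similarity, its truncated percent,
#' and — when an annotation is supplied — the pathway-profile Pearson
#' similarity, for every unordered pair of panels.
#'
#' @param panels Named list of panels (coercible to [biomarker_set()]).
#' @param annotation Optional [pathway_annotation()] for the pathway-profile
#'   score.
#' @return Tibble `(study_i, study_j, jaccard, percent[, pathway_pearson])`.
#' @export
similarity_report <- function(panels, annotation = NULL) {
  labels <- names(panels)
  if (is.null(labels) || anyDuplicated(labels)) {
    abort("`panels` must be a uniquely named list.")
  }
  empty <- tibble::tibble(study_i = character(), study_j = character(),
                          jaccard = numeric(), percent = numeric())
  if (length(labels) < 2) return(empty)
  fcm <- if (!is.null(annotation)) build_ppfcm(panels, annotation) else NULL
  pairs <- utils::combn(labels, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    s <- set_similarity(panels[[pr[1]]], panels[[pr[2]]])
    row <- tibble::tibble(study_i = pr[1], study_j = pr[2],
                          jaccard = s, percent = similarity_percent(s))
    if (!is.null(fcm)) {
      row$pathway_pearson <- matrix_similarity(fcm, pr[1], pr[2])
    }
    row
  })
}

check_annotation <- function(annotation, need_pathways = FALSE) {
  if (!inherits(annotation, "pathway_annotation")) {
    abort("`annotation` must be a `pathway_annotation` object.")
  }
  if (need_pathways && length(annotation$sets) == 0) {
    abort("`annotation` contains no pathways.")
  }
  invisible(annotation)
}
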