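#' Create a named biomarker set
#'
#' A biomarker set is a named collection of unique protein identifiers —
#' either a study's significant proteins or an external reference panel.
#'
#' @param name Non-empty label.
#' @param members Character vector of protein identifiers; duplicates are
#'   removed.
#' @return An object of class `biomarker_set` with elements `name` and
#'   `members`.
#' @export
#' @examples
#' biomarker_set("studyA", c("P1", "P2", "P2"))
biomarker_set <- function(name, members) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name)) {
    abort("`name` must be a non-empty string.")
  }
  members <- unique(as.character(members))
  members <- members[!is.na(members) & nzchar(members)]
  structure(list(name = name, members = members), class = "biomarker_set")
}

#' @export
print.biomarker_set <- function(x, ...) {
  cat(sprintf("<biomarker_set> %s: %d proteins\n", x$name, length(x$members)))
  invisible(x)
}

#' Coerce to a biomarker set
#'
#' @param x A character vector, `biomarker_set`, `perm_sig` (significant
#'   proteins are taken), or `perm_test` object.
#' @param name Set label (defaults vary by input type).
#' @return A [biomarker_set()].
#' @export
as_biomarker_set <- function(x, name = NULL) {
  if (inherits(x, "biomarker_set")) {
    if (!is.null(name)) x$name <- name
    return(x)
  }
  if (inherits(x, "perm_sig")) {
    return(biomarker_set(name %||% "significant",
                         x$results$protein_id[x$results$significant]))
  }
  if (is.character(x)) return(biomarker_set(name %||% "set", x))
  abort("Cannot coerce this object to a biomarker_set.")
}

set_members <- function(x) {
  if (inherits(x, "biomarker_set")) x$members else unique(as.character(x))
}

#' Derive a candidate biomarker panel against reference sets
#'
#' Intersects a study's significant proteins with external reference
#' biomarker sets: with `rule = "any"` (default) a protein enters the panel
#' if it appears in at least one reference set; with `rule = "all"` it must
#' appear in every reference set. An optional identifier mapping supports
#' cross-namespace joins.
#'
#' @param significant The study's significant proteins (anything accepted by
#'   [as_biomarker_set()]).
#' @param references List of reference sets (each coercible to a
#'   [biomarker_set()]). An empty list yields an empty panel.
#' @param rule `"any"` or `"all"`.
#' @param id_map Optional two-column data frame `(from, to)` applied to
#'   reference members before matching (maps reference identifiers into the
#'   study's namespace). Matching is case-sensitive and exact.
#' @param name Label for the returned panel.
#' @return A [biomarker_set()]; always a subset of `significant`.
#' @export
#' @examples
#' derive_panel(c("a", "b", "c"), list(biomarker_set("r", c("b", "c", "d"))))
derive_panel <- function(significant, references, rule = c("any", "all"),
                         id_map = NULL, name = "panel") {
  rule <- match.arg(rule)
  sig <- set_members(as_biomarker_set(significant))
  refs <- purrr::map(references, function(r) {
    m <- set_members(r)
    if (!is.null(id_map)) {
      mapped <- setNames(as.character(id_map[[2]]), as.character(id_map[[1]]))
      hit <- m %in% names(mapped)
      m[hit] <- mapped[m[hit]]
      m <- unique(m)
    }
    m
  })
  members <- if (length(refs) == 0) {
    character()
  } else if (rule == "any") {
    intersect(sig, unique(unlist(refs)))
  } else {
    Reduce(intersect, refs, accumulate = FALSE, init = sig)
  }
  biomarker_set(name, members)
}

#' Exclusive-region counts for a 2- or 3-set Venn diagram
#'
#' Classifies every protein in the union of the sets by exact membership
#' pattern and counts each exclusive region; region counts sum to the union
#' size.
#'
#' @param sets A list of 2 or 3 sets (each coercible to [biomarker_set()]).
#'   More than 3 sets is an error.
#' @return Tibble `(region, n_sets, count)`; `region` names the sets the
#'   region belongs to, joined by `&`.
#' @export
#' @examples
#' venn_counts(list(biomarker_set("A", c("x", "y")),
#'                  biomarker_set("B", c("y", "z"))))
venn_counts <- function(sets) {
  if (length(sets) < 2 || length(sets) > 3) {
    abort("`sets` must contain 2 or 3 biomarker sets.")
  }
  sets <- purrr::imap(sets, function(s, i) {
    as_biomarker_set(s, name = if (inherits(s, "biomarker_set")) s$name else paste0("set", i))
  })
  nm <- purrr::map_chr(sets, "name")
  if (anyDuplicated(nm)) abort("Set names must be unique.")
  universe <- unique(unlist(purrr::map(sets, "members")))
  membership <- purrr::map(sets, function(s) universe %in% s$members)
  pattern <- do.call(cbind, membership)
  # enumerate all non-empty membership patterns
  patterns <- expand.grid(rep(list(c(TRUE, FALSE)), length(sets)))
  patterns <- patterns[rowSums(patterns) > 0, , drop = FALSE]
  purrr::pmap_dfr(patterns, function(...) {
    mask <- unlist(list(...))
    in_region <- rep(TRUE, length(universe))
    for (j in seq_along(mask)) {
      in_region <- in_region & (pattern[, j] == mask[j])
    }
    tibble::tibble(
      region = paste(nm[mask], collapse = " & "),
      n_sets = sum(mask),
      count = sum(in_region)
    )
  }) |>
    dplyr::arrange(dplyr::desc(.data$n_sets), .data$region)
}
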