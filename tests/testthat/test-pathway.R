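ann_small <- pathway_annotation(list(P1 = c("a", "b", "c"), P2 = c("c", "d")))

test_that("association matrix encodes membership", {
  m <- build_association_matrix(c("a", "c"), ann_small)
  expect_equal(m$a, c(1, 0))
  expect_equal(m$c, c(1, 1))
  # empty panel -> only the pathway column
  expect_equal(ncol(build_association_matrix(character(), ann_small)), 1)
  # panel inside one pathway -> that row all ones
  m2 <- build_association_matrix(c("a", "b"), ann_small)
  expect_true(all(m2[m2$pathway == "P1", -1] == 1))
  expect_warning(build_association_matrix(c("a", "zz"), ann_small), "zz")
  expect_error(build_association_matrix("a", pathway_annotation(list())),
               "no pathways")
})

test_that("PPFCM counts panel members per pathway and study", {
  fcm <- build_ppfcm(list(S = c("a", "c")), ann_small)
  expect_equal(fcm$S, c(2, 1))
  expect_equal(build_ppfcm(list(S = character()), ann_small)$S, c(0, 0))
  full <- build_ppfcm(list(S = ann_small$universe), ann_small)
  expect_equal(full$S, lengths(ann_small$sets), ignore_attr = TRUE)
  expect_error(build_ppfcm(setNames(list("a", "b"), c("S", "S")), ann_small),
               "Duplicate")
})

test_that("PPFCM column equals association-matrix row sums", {
  u <- sprintf("g%03d", 1:60)
  ann <- simulate_pathway_annotation(u, 6, c(4, 20), seed = 13)
  panels <- list(A = sample(u, 15), B = sample(u, 10))
  fcm <- build_ppfcm(panels, ann)
  for (lab in names(panels)) {
    am <- build_association_matrix(panels[[lab]], ann)
    rs <- if (ncol(am) > 1) rowSums(am[, -1]) else rep(0, nrow(am))
    expect_equal(fcm[[lab]], unname(rs), ignore_attr = TRUE)
  }
  long <- ppfcm_long(fcm)
  expect_equal(nrow(long), nrow(fcm) * 2)
  expect_s3_class(autoplot(fcm), "ggplot")
})

test_that("pathway ranking sorts by count with lexicographic ties", {
  fcm <- build_ppfcm(list(S = c("a", "c")), ann_small)
  r <- rank_pathways(fcm, "S")
  expect_equal(r$pathway, c("P1", "P2"))
  tie <- build_ppfcm(list(S = c("c")), ann_small)  # both pathways count 1
  expect_equal(rank_pathways(tie, "S")$pathway, c("P1", "P2"))
  single <- build_ppfcm(list(S = "a"),
                        pathway_annotation(list(Only = c("a", "b"))))
  expect_equal(nrow(rank_pathways(single, "S")), 1)
  expect_error(rank_pathways(fcm, "nope"), "Unknown study")
})

test_that("enrichment p-values match the hypergeometric tail-sum oracle", {
  # universe 10, list 5, pathway 5, full overlap -> p = 1/C(10,5)
  ann <- pathway_annotation(list(PW = letters[1:5]), universe = letters[1:10])
  fe <- fisher_enrichment(letters[1:5], ann)
  expect_equal(fe$p_value, 1 / choose(10, 5), tolerance = 1e-12)
  # pathway = universe -> overlap forced, p = 1
  annU <- pathway_annotation(list(PW = letters[1:10]),
                             universe = letters[1:10])
  expect_equal(fisher_enrichment(letters[1:4], annU)$p_value, 1)

  withr::with_seed(31, {
    for (i in 1:10) {
      N <- sample(20:200, 1)
      univ <- sprintf("u%03d", seq_len(N))
      m <- sample(2:(N - 2), 1)
      n <- sample(2:(N - 2), 1)
      ann2 <- pathway_annotation(list(PW = sample(univ, m)), universe = univ)
      lst <- sample(univ, n)
      fe2 <- fisher_enrichment(lst, ann2)
      k <- length(intersect(lst, ann2$sets$PW))
      expect_equal(fe2$overlap, k)
      expect_equal(fe2$p_value, oracle_hyper_tail(k, m, N, n),
                   tolerance = 1e-12)
      # two-sided option agrees with fisher.test
      fe3 <- fisher_enrichment(lst, ann2, alternative = "two.sided")
      tab <- matrix(c(k, m - k, n - k, N - m - n + k), 2, 2)
      expect_equal(fe3$p_value, fisher.test(tab)$p.value, tolerance = 1e-9)
    }
  })
  expect_error(fisher_enrichment(letters[1:11],
                                 pathway_annotation(list(PW = "a"),
                                                    universe = letters[1:5])),
               "larger than")
})

test_that("set similarity is the Jaccard index with truncated percent reporting", {
  u <- sprintf("p%03d", 1:100)
  a25 <- u[1:25]
  b20 <- c(u[1:13], u[60:66])
  c25 <- c(u[1:13], u[70:81])
  expect_equal(set_similarity(a25, b20), 13 / 32)
  expect_equal(similarity_percent(13 / 32), 40)
  expect_equal(set_similarity(a25, c25), 13 / 37)
  expect_equal(similarity_percent(13 / 37), 35)
  expect_equal(set_similarity(a25, a25), 1)
  expect_equal(set_similarity(a25, u[90:95]), 0)
  expect_equal(set_similarity(character(), character()), 1)

  # symmetry, bounds, and brute-force agreement on random sets
  withr::with_seed(41, {
    for (i in 1:10) {
      x <- sample(letters, sample(2:15, 1))
      y <- sample(letters, sample(2:15, 1))
      s <- set_similarity(x, y)
      expect_equal(s, set_similarity(y, x))
      expect_gte(s, 0); expect_lte(s, 1)
      both <- sum(sapply(unique(c(x, y)), function(p) p %in% x && p %in% y))
      expect_equal(s, both / length(unique(c(x, y))))
      expect_equal(s == 1, setequal(x, y))
      expect_equal(s == 0, length(intersect(x, y)) == 0)
    }
  })
})

test_that("pathway-profile similarity is the Pearson correlation of counts", {
  fcm <- tibble::tibble(pathway = c("P1", "P2", "P3"),
                        A = c(1, 2, 3), B = c(3, 2, 1), C = c(1, 0, 2),
                        D = c(2, 1, 0), E = c(2, 4, 6), K = c(1, 1, 1))
  class(fcm) <- c("ppfcm", class(fcm))
  expect_equal(matrix_similarity(fcm, "A", "E"), 1)
  expect_equal(matrix_similarity(fcm, "A", "B"), -1)
  expect_equal(matrix_similarity(fcm, "C", "D"), -0.5)
  expect_equal(matrix_similarity(fcm, "C", "D"),
               oracle_pearson(c(1, 0, 2), c(2, 1, 0)))
  # symmetric and invariant to row reordering
  expect_equal(matrix_similarity(fcm, "D", "C"),
               matrix_similarity(fcm, "C", "D"))
  shuffled <- fcm[c(3, 1, 2), ]
  expect_equal(matrix_similarity(shuffled, "C", "D"),
               matrix_similarity(fcm, "C", "D"))
  expect_warning(out <- matrix_similarity(fcm, "A", "K"), "Constant")
  expect_true(is.na(out))
  expect_error(matrix_similarity(fcm, "A", "nope"), "Unknown")
})

test_that("similarity report covers all pairs with both scores", {
  u <- sprintf("p%03d", 1:80)
  panels <- list(A = u[1:20], B = u[11:30], C = u[25:40])
  ann <- simulate_pathway_annotation(u, 5, c(10, 30), seed = 3)
  rep <- similarity_report(panels, ann)
  expect_equal(nrow(rep), 3)
  expect_named(rep, c("study_i", "study_j", "jaccard", "percent",
                      "pathway_pearson"))
  expect_equal(rep$jaccard[rep$study_i == "A" & rep$study_j == "B"],
               10 / 30)
})
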