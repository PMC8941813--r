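test_that("build_evidence_matrix equals the brute-force membership table", {
  genomic <- list(DS1 = c("A", "B", "E"), DS2 = c("B", "C"), DS3 = c("A"))
  runs <- list(
    proteomic_run("CL1", "membrane_enrichment", c("A", "C")),
    proteomic_run("CL1", "biotinylation", c("B", "D")),
    proteomic_run("CL2", "membrane_enrichment", "E")
  )
  em <- build_evidence_matrix(genomic, runs)
  expect_equal(rownames(em$presence), c("A", "B", "C", "D", "E"))
  expect_equal(unname(em$channel_kind),
               c("genomic", "genomic", "genomic",
                 "proteomic", "proteomic", "proteomic"))

  # oracle: nested-loop membership check over all (protein, channel)
  sets <- c(genomic, lapply(runs, `[[`, "proteins"))
  for (i in seq_len(nrow(em$presence)))
    for (j in seq_along(sets))
      expect_equal(unname(em$presence[i, j]),
                   rownames(em$presence)[i] %in% sets[[j]])

  expect_error(build_evidence_matrix(list(DS1 = "A", DS1 = "B"), runs),
               "duplicate dataset id")
  expect_error(build_evidence_matrix(genomic, c(runs, runs[1])),
               "duplicate \\(cell_line, method\\)")
})

test_that("score_candidates applies score, prerequisite and ranking rules", {
  ids <- sprintf("P%d", 1:4)
  genomic <- list(DS1 = ids[c(1, 3)], DS2 = ids[c(1, 3)], DS3 = ids[1])
  runs <- list()
  for (cl in c("CL1", "CL2", "CL3"))
    for (m in c("membrane_enrichment", "biotinylation"))
      runs[[length(runs) + 1]] <- proteomic_run(cl, m, ids[c(1, 2, 3)])
  # P1: 3 genomic + 6 proteomic = 9; P2: proteomics only (6);
  # P3: 2 + 6 = 8; P4: absent everywhere except one genomic set
  genomic$DS3 <- c(genomic$DS3, "P4")
  em <- build_evidence_matrix(genomic, runs)

  cand <- score_candidates(em, min_score = 5)
  expect_equal(cand$protein, c("P1", "P3"))
  expect_equal(cand$score, c(9, 8))
  expect_equal(cand$rank, c(1, 2))
  # P2 has score 6 but no genomic evidence: excluded by the prerequisite
  expect_false("P2" %in% cand$protein)
  all_scores <- attr(cand, "all_scores")
  expect_equal(all_scores$score[all_scores$protein == "P2"], 6)
  expect_false(all_scores$passes_prerequisite[all_scores$protein == "P2"])
  # without the prerequisite P2 re-enters
  cand2 <- score_candidates(em, min_score = 5, require_prerequisite = FALSE)
  expect_true("P2" %in% cand2$protein)

  # impossible threshold warns and returns no rows
  expect_warning(none <- score_candidates(em, min_score = 10), "exceeds")
  expect_equal(nrow(none), 0)
})

test_that("scores equal the brute-force row count on random fixtures", {
  for (seed in 1:5) {
    fx <- rand_evidence(50, seed = seed)
    em <- build_evidence_matrix(fx$genomic, fx$runs)
    cand <- score_candidates(em, min_score = 0, require_prerequisite = FALSE)
    expect_equal(nrow(cand), sum(rowSums(fx$presence) >= 1))
    all_scores <- attr(cand, "all_scores")
    for (i in seq_len(nrow(all_scores))) {
      p <- all_scores$protein[i]
      brute <- sum(vapply(c(fx$genomic, lapply(fx$runs, `[[`, "proteins")),
                          function(s) p %in% s, logical(1)))
      expect_equal(all_scores$score[i], brute)
      expect_equal(all_scores$passes_prerequisite[i],
                   any(vapply(fx$genomic, function(s) p %in% s, logical(1))) &&
                     any(vapply(fx$runs, function(r) p %in% r$proteins, logical(1))))
    }
    # returned candidates respect bounds and ordering invariants
    cand5 <- score_candidates(em, min_score = 5)
    expect_true(all(cand5$score >= 5 & cand5$score <= 9))
    expect_true(all(cand5$passes_prerequisite))
    expect_true(all(diff(cand5$score) <= 0))
    # row-order invariance of the input sets
    em_rev <- build_evidence_matrix(fx$genomic,
                                    lapply(fx$runs, function(r)
                                      proteomic_run(r$cell_line, r$method,
                                                    rev(r$proteins))))
    expect_equal(score_candidates(em_rev, min_score = 5), cand5,
                 ignore_attr = TRUE)
  }
})

test_that("venn_counts partitions the union", {
  # worked example: three pairwise single overlaps
  v <- venn_counts(list(c("a", "b"), c("b", "c"), c("c", "a")))
  expect_equal(v[["1+2"]], 1)
  expect_equal(v[["1+3"]], 1)
  expect_equal(v[["2+3"]], 1)
  expect_equal(sum(v), 3)
  expect_equal(v[["1"]], 0)
  expect_equal(v[["1+2+3"]], 0)

  # identical sets: only the all-way region is filled
  s <- sprintf("g%d", 1:7)
  vi <- venn_counts(list(s, s, s))
  expect_equal(vi[["1+2+3"]], 7)
  expect_equal(sum(vi), 7)

  # disjoint sets: only singleton regions
  vd <- venn_counts(list("a", "b", c("c", "d")))
  expect_equal(unname(vd[c("1", "2", "3")]), c(1, 1, 2))
  expect_equal(sum(vd), 4)

  expect_error(venn_counts(list("a")), "at least 2")

  # conservation property over random families, k in 2..4
  set.seed(77)
  for (rep in 1:12) {
    k <- sample(2:4, 1)
    sets <- lapply(seq_len(k), function(i)
      sample(sprintf("e%02d", 1:30), sample(0:20, 1)))
    v <- venn_counts(sets)
    expect_length(v, 2^k - 1)
    expect_equal(sum(v), length(unique(unlist(sets))))
  }
})

test_that("channel_presence_report totals match column sums", {
  fx <- rand_evidence(20, seed = 6)
  em <- build_evidence_matrix(fx$genomic, fx$runs)
  rep <- channel_presence_report(em)
  expect_equal(unname(rep$per_channel), unname(colSums(em$presence)))
  expect_equal(unname(diag(rep$pairwise)), unname(colSums(em$presence)))
  # method core = proteins present in every cell line for that method
  pm <- names(em$channel_kind)[em$channel_kind == "proteomic"]
  for (m in unique(sub("^.*:", "", pm))) {
    cols <- pm[endsWith(pm, paste0(":", m))]
    expect_equal(unname(rep$method_core[m]),
                 sum(rowSums(em$presence[, cols, drop = FALSE]) == length(cols)))
  }
  # all-true matrix: every overlap equals the universe size
  n <- 6
  allg <- list(DS1 = sprintf("x%d", 1:n), DS2 = sprintf("x%d", 1:n))
  allr <- list(proteomic_run("CL1", "biotinylation", sprintf("x%d", 1:n)))
  rep2 <- channel_presence_report(build_evidence_matrix(allg, allr))
  expect_true(all(rep2$pairwise == n))
})
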