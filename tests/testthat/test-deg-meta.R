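test_that("fold changes follow 2^(difference of class means)", {
  m <- matrix(c(3, 3, 1, 1,    # FC 4
                2, 2, 2, 2,    # FC 1
                1, 1, 3, 3),   # FC 0.25
              nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("t1", "t2", "c1", "c2")))
  st <- toy_study("s", "I", m, c("tumor", "tumor", "control", "control"))
  fc <- study_fold_changes(st)
  expect_equal(unname(fc[c("A", "B", "C")]), c(4, 1, 0.25))
})

test_that("within-study ranking is directional with average-rank ties", {
  fc <- c(a = 4, b = 1, c = 0.5)
  expect_equal(unname(rank_within_study(fc, "up")), c(1, 2, 3))
  expect_equal(unname(rank_within_study(fc, "down")), c(3, 2, 1))
  tied <- c(a = 2, b = 2, c = 1)
  expect_equal(unname(rank_within_study(tied, "up")), c(1.5, 1.5, 3))
})

test_that("rank product is the geometric mean of ranks", {
  expect_equal(rank_product(c(1, 2, 4)), 2)
  expect_equal(rank_product(c(7, 7, 7)), 7)
  expect_equal(rank_product(c(1, 1)), 1)
  expect_error(rank_product(numeric(0)), "empty")
})

test_that("sampled pfp matches exhaustive enumeration on a 3x2 toy", {
  fc1 <- c(A = 8, B = 2, C = 0.5)
  fc2 <- c(A = 4, B = 0.7, C = 1.1)
  studies <- list(study_with_fc("s1", "I", fc1), study_with_fc("s2", "I", fc2))
  rank_mat <- cbind(rank_within_study(fc1, "up"), rank_within_study(fc2, "up"))
  exact <- exhaustive_pfp(rank_mat)
  est <- estimate_pfp(studies, n_perm = 4000, seed = 7, direction = "up")
  expect_equal(est$gene, c("A", "B", "C"))
  expect_lt(max(abs(est$pfp - exact)), 0.02)
  # gene with minimal RP gets the smallest pfp in the list
  expect_equal(which.min(est$pfp), which.min(est$rp))
})

test_that("pfp is monotone along the observed RP ordering and capped at 1", {
  up <- stats::setNames(rep(1.2, 5), sprintf("G%04d", 1:5))
  cfg <- simulation_config(n_genes = 60, planted_up = up,
                           samples_per_study = c(tumor = 6, control = 4),
                           seed = 21)
  studies <- simulate_expression_studies(cfg)[1:3]
  est <- estimate_pfp(studies, n_perm = 200, seed = 5, direction = "up")
  ord <- order(est$rp)
  expect_true(all(diff(est$pfp[ord]) >= 0))
  expect_true(all(est$pfp <= 1 & est$pfp >= 0))
  expect_true(all(est$rp >= 1))
  expect_error(estimate_pfp(studies, n_perm = 50, seed = 1), ">= 100")
})

test_that("genes measured in fewer than 2 studies are reported unranked", {
  s1 <- study_with_fc("s1", "I", c(A = 4, B = 1, C = 0.5))
  s2 <- study_with_fc("s2", "I", c(A = 3, B = 0.8, D = 2))
  est <- estimate_pfp(list(s1, s2), n_perm = 100, seed = 1)
  expect_equal(est$k[est$gene %in% c("C", "D")], c(1, 1))
  expect_true(all(is.na(est$pfp[est$gene %in% c("C", "D")])))
  expect_true(all(!is.na(est$pfp[est$gene %in% c("A", "B")])))
})

test_that("rank product is invariant to gene order and study relabeling", {
  fc1 <- c(A = 8, B = 2, C = 0.5, D = 1.3)
  fc2 <- c(A = 4, B = 0.7, C = 1.1, D = 2.2)
  st <- list(study_with_fc("s1", "I", fc1), study_with_fc("s2", "I", fc2))
  st_shuf <- list(study_with_fc("x", "I", fc2[c(3, 1, 4, 2)]),
                  study_with_fc("y", "I", fc1[c(2, 4, 1, 3)]))
  a <- estimate_pfp(st, 100, 1)
  b <- estimate_pfp(st_shuf, 100, 1)
  expect_equal(stats::setNames(a$rp, a$gene)[c("A", "B", "C", "D")],
               stats::setNames(b$rp, b$gene)[c("A", "B", "C", "D")])
})

test_that("DEG calling applies inclusive fold-change and strict pfp thresholds", {
  tab <- data.frame(gene = c("A", "B", "C", "D", "E"),
                    k = 3, fc = c(2.5, 1.5, 2.0, 0.4, 0.5),
                    rp_up = 1:5, pfp_up = c(0.005, 0.005, 0.005, 0.9, 0.9),
                    rp_down = 5:1, pfp_down = c(0.9, 0.9, 0.9, 0.005, 0.011),
                    stringsAsFactors = FALSE)
  rp <- structure(list(table = tab, n_perm = 1000, seed = 1, studies = "s"),
                  class = "RankProductResult")
  degs <- call_degs(rp, fdr_thresh = 0.01, fc_thresh = 2)
  expect_setequal(degs$up, c("A", "C"))   # FC exactly 2.0 is included
  expect_false("B" %in% degs$up)          # pfp ok but FC below threshold
  expect_setequal(degs$down, "D")         # E: pfp 0.011 not < 0.01
  expect_equal(degs$provenance$fdr_thresh, 0.01)
})

test_that("group intersection keeps only direction-concordant calls", {
  dI <- deg_set(up = c("A", "B"), down = c("C", "D"))
  dII <- deg_set(up = c("A", "C"), down = c("B", "D"))
  both <- intersect_groups(dI, dII)
  expect_equal(both$up, "A")     # B flips direction, dropped
  expect_equal(both$down, "D")   # C flips direction, dropped
  expect_error(deg_set(up = "A", down = "A"), "both up- and down")
})

test_that("negating all effects swaps up/down calls exactly", {
  up <- stats::setNames(rep(1.5, 4), sprintf("G%04d", 1:4))
  dn <- stats::setNames(rep(1.5, 4), sprintf("G%04d", 5:8))
  cfg <- simulation_config(n_genes = 120, planted_up = up, planted_down = dn,
                           samples_per_study = c(tumor = 8, control = 6),
                           seed = 31)
  studies <- simulate_expression_studies(cfg)[1:3]
  flipped <- lapply(studies, function(st) {
    st$values <- -st$values
    st
  })
  fwd_up <- estimate_pfp(studies, 150, 3, "up")
  rev_down <- estimate_pfp(flipped, 150, 3, "down")
  expect_equal(fwd_up$pfp, rev_down$pfp)
  expect_equal(fwd_up$rp, rev_down$rp)
})
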