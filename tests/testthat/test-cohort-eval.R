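make_manifest <- function(n, sex = NULL, age = NULL, interval = NULL) {
  data.frame(case_id = sprintf("case_%03d", seq_len(n) - 1L),
             sex = sex %||% rep(c("M", "F"), length.out = n),
             age_years = age %||% rep(c(40L, 70L), length.out = n),
             interval_days = interval %||% rep(c(10L, 60L), length.out = n),
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# synthetic score matrix with matched scores low and mismatched high
toy_matrix <- function(n, seed = 1, m_mean = 50, u_mean = 80) {
  withr::with_seed(seed, {
    m <- matrix(stats::rnorm(n * n, u_mean, 8), n, n)
    diag(m) <- stats::rnorm(n, m_mean, 5)
  })
  ids <- sprintf("case_%03d", seq_len(n) - 1L)
  dimnames(m) <- list(ids, ids)
  attr(m, "method") <- "toy"
  class(m) <- c("score_matrix", "matrix", "array")
  m
}

test_that("the score matrix holds all n^2 pairs and spot-checks against direct calls", {
  co <- generate_cohort(3, synth_params(seed = 21))
  sm <- score_matrix(co, "orb")
  expect_equal(dim(sm), c(3L, 3L))
  expect_equal(sum(!is.na(sm)), 9L)
  expect_equal(length(diag(sm)), 3L)
  for (pair in list(c(1, 1), c(2, 3), c(3, 1))) {
    direct <- similarity_score(co$am[[pair[1]]], co$pm[[pair[2]]], "orb")
    expect_equal(sm[pair[1], pair[2]], direct$value, tolerance = 1e-12)
  }
  expect_lt(mean(diag(sm)), mean(sm[row(sm) != col(sm)]))
})

test_that("matched/mismatched splits count diagonal vs within-subset off-diagonal", {
  m <- toy_matrix(10)
  sp <- split_matched_mismatched(m)
  expect_length(sp$matched, 10L)
  expect_length(sp$mismatched, 90L)
  sub <- rownames(m)[1:4]
  sp4 <- split_matched_mismatched(m, sub)
  expect_length(sp4$matched, 4L)
  expect_length(sp4$mismatched, 12L)
  sp1 <- split_matched_mismatched(m, rownames(m)[1])
  expect_length(sp1$matched, 1L)
  expect_length(sp1$mismatched, 0L)
  expect_error(welch_t(sp1$matched, sp1$mismatched), "at least 2")
  expect_error(split_matched_mismatched(m, character(0)), "empty")
})

test_that("Welch test reproduces the hand-computed example", {
  # x = {1,2,3}, y = {2,4,6}: t = -2/sqrt(5/3) = -1.549, df = 50/17
  w <- welch_t(c(1, 2, 3), c(2, 4, 6))
  expect_equal(w$t, -2 / sqrt(5 / 3), tolerance = 1e-9)
  expect_equal(w$t, -1.549, tolerance = 1e-3)
  expect_equal(w$df, 50 / 17, tolerance = 1e-9)
  expect_equal(w$p, 2 * stats::pt(-abs(w$t), 50 / 17), tolerance = 1e-12)
  # symmetry: swapping groups flips t, keeps p
  w2 <- welch_t(c(2, 4, 6), c(1, 2, 3))
  expect_equal(w2$t, -w$t)
  expect_equal(w2$p, w$p)
  # identical groups: t = 0, p = 1
  w3 <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w3$t, 0)
  expect_equal(w3$p, 1)
  expect_equal(w$groups$mean, c(2, 4))
  expect_equal(w$groups$n, c(3L, 3L))
  expect_error(welch_t(c(1, 1), c(2, 2)), "variance")
})

test_that("Welch p-values are uniform under the null", {
  ps <- withr::with_seed(99, {
    replicate(500, welch_t(stats::rnorm(50), stats::rnorm(50))$p)
  })
  ks <- stats::ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("ROC analysis follows the pair-count definition and Youden cutoff", {
  # perfectly separated
  r <- roc_analysis(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$auc, 1)
  expect_equal(r$tpr, 1)
  expect_equal(r$fpr, 0)
  expect_equal(r$cutoff, 3)  # smallest threshold maximizing J
  # interleaved: matched {1,3} vs mismatched {2,4} -> AUC 3/4
  r2 <- roc_analysis(c(1, 3), c(2, 4))
  expect_equal(r2$auc, 0.75)
  expect_equal(r2$auc, auc_enum_oracle(c(1, 3), c(2, 4)))
  # full ties -> 0.5
  r3 <- roc_analysis(c(1, 2), c(1, 2))
  expect_equal(r3$auc, 0.5)
  expect_error(roc_analysis(c(1), c(2, 3)), "at least 2")
})

test_that("rank AUC equals enumeration and the trapezoid of the curve", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      m <- round(stats::rnorm(25, 50, 10), 1)
      u <- round(stats::rnorm(40, 60, 12), 1)
    })
    r <- roc_analysis(m, u)
    expect_equal(r$auc, auc_enum_oracle(m, u), tolerance = 1e-12)
    # trapezoid over the threshold-sweep curve (with (0,0) prepended)
    fpr <- c(0, r$curve$fpr); tpr <- c(0, r$curve$tpr)
    trap <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    expect_lt(abs(trap - r$auc), 1e-9)
    # curve monotone in both coordinates, all rates in [0,1]
    expect_true(all(diff(r$curve$tpr) >= 0))
    expect_true(all(diff(r$curve$fpr) >= 0))
    expect_true(all(r$curve$tpr >= 0 & r$curve$tpr <= 1))
    expect_true(all(r$curve$fpr >= 0 & r$curve$fpr <= 1))
  }
})

test_that("AUC agrees with an established ROC package", {
  skip_if_not_installed("pROC")
  withr::with_seed(8, {
    m <- stats::rnorm(30, 50, 8); u <- stats::rnorm(50, 70, 10)
  })
  r <- roc_analysis(m, u)
  ref <- pROC::roc(response = c(rep(1, 30), rep(0, 50)),
                   predictor = c(m, u), direction = ">", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-9)
})

test_that("subgroup thresholds split at 30 days and 60 years exactly", {
  n <- 8
  man <- make_manifest(n,
                       interval = c(29L, 30L, 29L, 30L, 29L, 30L, 29L, 30L),
                       age = c(59L, 60L, 59L, 60L, 59L, 60L, 59L, 60L))
  m <- toy_matrix(n, seed = 2)
  rep_int <- subgroup_eval(man, m, "interval_30d")
  expect_equal(rep_int$details$`interval<30d`$n_cases, 4L)
  expect_equal(rep_int$details$`interval>=30d`$n_cases, 4L)
  rep_age <- subgroup_eval(man, m, "age_60y")
  expect_equal(rep_age$details$`age<60`$n_cases, 4L)
  expect_equal(rep_age$details$`age>=60`$n_cases, 4L)
  # partition property: binary subgroup matched counts sum to the total
  rows <- rep_age$rows
  matched_n <- rows$n[rows$group == "matched"]
  expect_equal(sum(matched_n), n)
  # within-subgroup mismatched only: 4x3 per subgroup, not 8x7
  mism_n <- rows$n[rows$group == "mismatched"]
  expect_equal(sum(mism_n), 2 * 4 * 3)
})

test_that("undersized subgroups are skipped with a warning", {
  man <- make_manifest(5, sex = c("M", "M", "M", "M", "F"))
  m <- toy_matrix(5, seed = 3)
  expect_warning(rep <- subgroup_eval(man, m, "sex"), "skipped")
  expect_named(rep$details, "male")
})

test_that("tables_from_scores reproduces statistics from published-style score files", {
  # scores drawn to mimic a strongly separated cohort: matched N(54, 7^2),
  # mismatched N(80, 13^2), n = 180 and 180*179
  n <- 180
  ids <- sprintf("case_%03d", seq_len(n) - 1L)
  withr::with_seed(77, {
    matched <- stats::rnorm(n, 54, 7)
    mism <- stats::rnorm(n * (n - 1), 80, 13)
  })
  grid <- expand.grid(am = ids, pm = ids, stringsAsFactors = FALSE)
  off <- grid[grid$am != grid$pm, ]
  scores <- rbind(
    data.frame(am_id = ids, pm_id = ids, method = "akaze", score = matched),
    data.frame(am_id = off$am, pm_id = off$pm, method = "akaze", score = mism))
  man <- make_manifest(n)
  man$case_id <- ids
  reports <- tables_from_scores(scores, man)
  rep <- reports$akaze
  all_rows <- rep$rows[rep$rows$subgroup == "all", ]
  expect_lt(all_rows$p[1], 1e-10)
  expect_gt(all_rows$auc[1], 0.9)
  expect_equal(all_rows$n[all_rows$group == "matched"], 180L)
  expect_equal(all_rows$n[all_rows$group == "mismatched"], 180L * 179L)
  expect_equal(all_rows$mean[all_rows$group == "matched"], 54, tolerance = 0.05)
  # schema contract
  expect_true(all(c("n", "min", "max", "mean", "sd", "p", "auc",
                    "cutoff", "tpr", "fpr") %in% names(rep$rows)))
  # one-group-only input errors
  only_matched <- scores[scores$am_id == scores$pm_id, ]
  expect_error(tables_from_scores(only_matched, man), "mismatched")
  # malformed score column errors with row diagnostics
  bad <- scores
  bad$score[3] <- "not-a-number"
  expect_error(tables_from_scores(bad, man), "row")
})

test_that("score matrices with failing images record missing entries", {
  co <- generate_cohort(3, synth_params(seed = 22))
  # foreground confined to the border margin defeats feature extraction
  px <- matrix(1L, 100, 200)
  px[30:70, 2:8] <- 0L
  co$am[[2]] <- binary_silhouette(px, "case_001", "AM")
  expect_error(score_matrix(co, "orb"), "missing")
})
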