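# All-pairs scoring and the identity-verification statistics: the n x n
# AM x PM score matrix, the matched (diagonal) / mismatched (off-diagonal)
# split, Welch's t-test, ROC analysis with a Youden cutoff, and subgroup
# evaluation by sex, scan interval and age.

#' All-pairs AM x PM similarity matrix
#'
#' Extracts features once per image, then scores every antemortem image
#' against every postmortem image by brute-force matching. Entry (i, j) is
#' the similarity of AM_i vs PM_j, so the diagonal holds the matched
#' (same-individual) pairs. Images whose extraction fails are recorded as
#' missing (with reasons in `attr(, "reasons")`), never as 0; if more than
#' 10% of entries are missing the cohort is unusable and an error is thrown.
#'
#' @param cohort a `sinus_cohort`, or a manifest data frame with `case_id`,
#'   `am_path`, `pm_path` columns pointing at silhouette images.
#' @param method `"akaze"` or `"orb"`.
#' @param params method parameter object; defaults per method.
#' @return a `score_matrix`: numeric n x n matrix with case ids as dimnames,
#'   attributes `method` and `reasons`.
#' @export
score_matrix <- function(cohort, method = c("akaze", "orb"), params = NULL) {
  method <- match.arg(method)
  imgs <- cohort_images(cohort)
  n <- length(imgs$am)
  if (n < 2L) stop("need at least 2 cases")
  feat <- function(img) {
    tryCatch(extract_features(img, method, params),
             sinusid_insufficient_features = function(e) conditionMessage(e))
  }
  fam <- lapply(imgs$am, feat)
  fpm <- lapply(imgs$pm, feat)
  m <- matrix(NA_real_, n, n, dimnames = list(imgs$ids, imgs$ids))
  reasons <- character(0)
  for (i in seq_len(n)) {
    if (is.character(fam[[i]])) {
      reasons[paste0("AM:", imgs$ids[i])] <- fam[[i]]
      next
    }
    for (j in seq_len(n)) {
      if (is.character(fpm[[j]])) next
      m[i, j] <- similarity_from_features(fam[[i]], fpm[[j]])$value
    }
  }
  for (j in seq_len(n)) {
    if (is.character(fpm[[j]])) reasons[paste0("PM:", imgs$ids[j])] <- fpm[[j]]
  }
  if (mean(is.na(m)) > 0.1)
    stop("more than 10% of score-matrix entries are missing; cohort unusable")
  structure(m, method = method, reasons = reasons,
            class = c("score_matrix", "matrix", "array"))
}

cohort_images <- function(cohort) {
  if (inherits(cohort, "sinus_cohort")) {
    list(am = cohort$am, pm = cohort$pm, ids = cohort$manifest$case_id)
  } else if (is.data.frame(cohort)) {
    list(am = lapply(cohort$am_path, read_silhouette),
         pm = lapply(cohort$pm_path, read_silhouette),
         ids = cohort$case_id)
  } else {
    stop("expected a sinus_cohort or a manifest data frame")
  }
}

#' Split a score matrix into matched and mismatched scores
#'
#' Matched scores are the diagonal entries of the given case subset;
#' mismatched scores are the off-diagonal entries whose row AND column case
#' both belong to the subset (subgroup comparisons are within-subgroup).
#' Missing entries are dropped pairwise.
#'
#' @param matrix a `score_matrix`.
#' @param case_ids subset of case ids (default: all).
#' @return list with numeric vectors `matched` and `mismatched`.
#' @export
split_matched_mismatched <- function(matrix, case_ids = rownames(matrix)) {
  if (length(case_ids) == 0L) stop("empty case subset")
  sub <- matrix[case_ids, case_ids, drop = FALSE]
  matched <- diag(sub)
  mismatched <- sub[row(sub) != col(sub)]
  matched <- matched[!is.na(matched)]
  mismatched <- mismatched[!is.na(mismatched)]
  if (length(matched) == 0L && length(mismatched) == 0L)
    stop("subset has no available scores")
  list(matched = as.numeric(matched), mismatched = as.numeric(mismatched))
}

#' Welch's two-sample t-test with group summaries
#'
#' Unequal-variance t-test (Welch-Satterthwaite degrees of freedom,
#' two-sided) via [stats::t.test()], returned together with each group's
#' count, range, mean and SD in the row format of the descriptive tables.
#'
#' @param x,y numeric score vectors (each of length >= 2, with nonzero
#'   variance in at least one group).
#' @return a `sinus_welch` list: `t`, `df`, `p`, and `groups` (data frame
#'   with n, min, max, mean, sd per group).
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("each group needs at least 2 values")
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("both groups have zero variance")
  ht <- stats::t.test(x, y, var.equal = FALSE)
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value,
                 groups = data.frame(
                   group = c("x", "y"), n = c(length(x), length(y)),
                   min = c(min(x), min(y)), max = c(max(x), max(y)),
                   mean = c(mean(x), mean(y)),
                   sd = c(stats::sd(x), stats::sd(y)))),
            class = "sinus_welch")
}

#' @export
print.sinus_welch <- function(x, ...) {
  cat(sprintf("Welch t = %.3f, df = %.2f, p = %.3g\n", x$t, x$df, x$p))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' ROC analysis for a similarity-score classifier
#'
#' The positive class is "matched" and a LOWER score is more positive: a
#' pair is called identified iff its score is at or below the threshold
#' (ties at the cutoff count positive). The AUC uses the pair-count
#' (Mann-Whitney) formula `[#\{m < u\} + 0.5 #\{m = u\}] / (n_m n_u)` over all
#' matched x mismatched cross pairs; the reported cutoff maximizes Youden's
#' J = TPR - FPR over the observed thresholds, ties resolved to the smaller
#' threshold.
#'
#' @param matched,mismatched numeric score vectors (each length >= 2).
#' @return a `sinus_roc` list: `auc`, `cutoff`, `tpr`, `fpr`, and `curve`
#'   (data frame of threshold, tpr, fpr).
#' @export
roc_analysis <- function(matched, mismatched) {
  if (length(matched) < 2L || length(mismatched) < 2L)
    stop("need at least 2 scores in each class")
  nm <- length(matched); nu <- length(mismatched)
  r <- rank(c(matched, mismatched))
  ru <- sum(r[nm + seq_len(nu)])
  auc <- (ru - nu * (nu + 1) / 2) / (nm * nu)
  thr <- sort(unique(c(matched, mismatched)))
  tpr <- vapply(thr, function(t) mean(matched <= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(mismatched <= t), numeric(1))
  j <- tpr - fpr
  best <- which.max(j)  # first index = smallest threshold on ties
  structure(list(auc = auc, cutoff = thr[best], tpr = tpr[best],
                 fpr = fpr[best],
                 curve = data.frame(threshold = thr, tpr = tpr, fpr = fpr)),
            class = "sinus_roc")
}

#' @export
print.sinus_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f, cutoff = %.2f, TPR = %.3f, FPR = %.3f\n",
              x$auc, x$cutoff, x$tpr, x$fpr))
  invisible(x)
}

#' @export
plot.sinus_roc <- function(x, ...) {
  graphics::plot(c(0, x$curve$fpr, 1), c(0, x$curve$tpr, 1), type = "l",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("AUC = %.3f", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  graphics::points(x$fpr, x$tpr, pch = 19)
  invisible(x)
}

subgroup_sets <- function(manifest, grouping) {
  switch(grouping,
         all = list(all = manifest$case_id),
         sex = list(male = manifest$case_id[manifest$sex == "M"],
                    female = manifest$case_id[manifest$sex == "F"]),
         interval_30d = list(
           `interval<30d` = manifest$case_id[manifest$interval_days < 30],
           `interval>=30d` = manifest$case_id[manifest$interval_days >= 30]),
         age_60y = list(
           `age<60` = manifest$case_id[manifest$age_years < 60],
           `age>=60` = manifest$case_id[manifest$age_years >= 60]),
         stop("unknown grouping: ", grouping))
}

#' Subgroup evaluation of a score matrix
#'
#' For each subgroup of the requested grouping (`all`, `sex`,
#' `interval_30d` with a 30-day threshold, `age_60y` with a 60-year
#' threshold) the matched/mismatched split, Welch's t-test and ROC analysis
#' are computed within-subgroup. Subgroups with fewer than 2 cases are
#' skipped with a warning.
#'
#' @param manifest manifest data frame (case_id, sex, age_years,
#'   interval_days).
#' @param matrix a `score_matrix` over the manifest's cases.
#' @param grouping one or more of `"all"`, `"sex"`, `"interval_30d"`,
#'   `"age_60y"`.
#' @return a `sinus_eval_report`: `rows` (one data frame row per subgroup
#'   and score group with n, min, max, mean, sd, p, auc, cutoff, tpr, fpr)
#'   and `details` (per-subgroup welch/roc objects).
#' @export
subgroup_eval <- function(manifest, matrix,
                          grouping = c("all", "sex", "interval_30d", "age_60y")) {
  grouping <- match.arg(grouping, several.ok = TRUE)
  rows <- NULL; details <- list()
  method <- attr(matrix, "method") %||% NA_character_
  for (g in grouping) {
    sets <- subgroup_sets(manifest, g)
    for (nm in names(sets)) {
      ids <- sets[[nm]]
      if (length(ids) < 2L) {
        warning(sprintf("subgroup '%s' has %d case(s); skipped", nm, length(ids)))
        next
      }
      sp <- split_matched_mismatched(matrix, ids)
      w <- welch_t(sp$matched, sp$mismatched)
      roc <- roc_analysis(sp$matched, sp$mismatched)
      for (side in c("matched", "mismatched")) {
        v <- sp[[side]]
        rows <- rbind(rows, data.frame(
          subgroup = nm, group = side, n = length(v),
          min = min(v), max = max(v), mean = mean(v), sd = stats::sd(v),
          p = w$p, auc = roc$auc, cutoff = roc$cutoff,
          tpr = roc$tpr, fpr = roc$fpr))
      }
      details[[nm]] <- list(welch = w, roc = roc, n_cases = length(ids))
    }
  }
  structure(list(rows = rows, details = details, method = method),
            class = "sinus_eval_report")
}

#' @export
print.sinus_eval_report <- function(x, digits = 3, ...) {
  cat(sprintf("Evaluation report (%s): %d subgroup(s)\n",
              toupper(x$method %||% "?"), length(x$details)))
  df <- x$rows
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Reproduce the evaluation tables from published score files
#'
#' The path that checks printed results directly: takes a long-format score
#' table (columns `am_id`, `pm_id`, `method`, `score`) such as a published
#' supplementary per-pair score listing, plus the case covariates, rebuilds
#' the score matrix per method, and runs the same subgroup statistics as
#' [subgroup_eval()] without touching any image.
#'
#' @param scores data frame or CSV path with columns am_id, pm_id, method,
#'   score.
#' @param manifest data frame or CSV path with case_id, sex, age_years,
#'   interval_days.
#' @param grouping groupings to evaluate (default all four).
#' @return named list of `sinus_eval_report`, one per method present.
#' @export
tables_from_scores <- function(scores, manifest,
                               grouping = c("all", "sex", "interval_30d", "age_60y")) {
  if (is.character(scores)) scores <- utils::read.csv(scores, stringsAsFactors = FALSE)
  if (is.character(manifest)) manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("am_id", "pm_id", "method", "score")
  missing_cols <- setdiff(need, names(scores))
  if (length(missing_cols) > 0L)
    stop("score table lacks column(s): ", paste(missing_cols, collapse = ", "))
  bad <- which(!is.finite(suppressWarnings(as.numeric(scores$score))) &
                 !is.na(scores$score))
  if (length(bad) > 0L)
    stop("malformed score value at row(s): ", paste(utils::head(bad, 5L), collapse = ", "))
  out <- list()
  for (m in unique(scores$method)) {
    sc <- scores[scores$method == m, , drop = FALSE]
    ids <- sort(unique(c(sc$am_id, sc$pm_id)))
    mat <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
    mat[cbind(match(sc$am_id, ids), match(sc$pm_id, ids))] <- as.numeric(sc$score)
    if (all(is.na(mat[row(mat) != col(mat)])))
      stop("score table for method '", m, "' contains matched scores only; ",
           "mismatched (off-diagonal) pairs are required")
    if (all(is.na(diag(mat))))
      stop("score table for method '", m, "' contains no matched (diagonal) scores")
    attr(mat, "method") <- m
    class(mat) <- c("score_matrix", "matrix", "array")
    man <- manifest[manifest$case_id %in% ids, , drop = FALSE]
    out[[m]] <- subgroup_eval(man, mat, grouping)
  }
  out
}
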