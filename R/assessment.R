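#' Map a numerical ranking scale value to a motion category
#'
#' Observers grade intrasequence motion on a numerical ranking scale (NRS)
#' from 0 (no motion) to 10 (nondiagnostic image quality); for clinical
#' manageability the scale folds into four motion categories: 0 no motion,
#' 1 mild (NRS 1-3), 2 moderate (NRS 4-7), 3 severe / nondiagnostic
#' (NRS 8-10).
#'
#' @param nrs integer NRS value(s) in 0..10.
#' @return Integer motion category/ies in 0..3.
#' @export
nrs_to_category <- function(nrs) {
  if (any(!is.finite(nrs)) || any(nrs != round(nrs)) ||
      any(nrs < 0) || any(nrs > 10))
    stop("NRS values must be integers in 0..10")
  cat <- integer(length(nrs))
  cat[nrs >= 1 & nrs <= 3] <- 1L
  cat[nrs >= 4 & nrs <= 7] <- 2L
  cat[nrs >= 8] <- 3L
  cat
}

#' Motion score (NRS value with its derived category)
#'
#' @param nrs integer NRS value(s) in 0..10.
#' @return A tibble with columns `nrs` and `category`.
#' @export
motion_score <- function(nrs) {
  tibble::tibble(nrs = as.integer(nrs), category = nrs_to_category(nrs))
}

#' Registration impact on one case
#'
#' Compares extended-Tofts fits of the same ROI before and after
#' registration: per-percentile residual deltas and ktrans mean/SD deltas,
#' all computed as post minus pre so negative values indicate motion
#' reduction.
#'
#' @param pre,post `tofts_fit` objects on the identical ROI voxel set.
#' @param percentiles residual percentile levels.
#' @param nrs_pre,nrs_post optional observer NRS values for the case.
#' @return A `case_assessment`: list with `residuals` (tibble of
#'   percentile, pre, post, delta), `ktrans` (tibble of stat, pre, post,
#'   delta), and optional `scores`.
#' @export
delta_assessment <- function(pre, post, percentiles = seq(10, 90, by = 10),
                             nrs_pre = NULL, nrs_post = NULL) {
  stopifnot(inherits(pre, "tofts_fit"), inherits(post, "tofts_fit"))
  if (!identical(dim(pre$roi), dim(post$roi)) || !all(pre$roi == post$roi))
    stop("pre and post fits must share the same ROI voxel set")
  rp <- residual_percentiles(pre, percentiles = percentiles)
  rq <- residual_percentiles(post, percentiles = percentiles)
  residuals <- tibble::tibble(
    percentile = rp$percentile, pre = rp$value, post = rq$value,
    delta = rq$value - rp$value
  )
  ktrans <- tibble::tibble(
    stat = c("mean", "sd"),
    pre = c(pre$summary$ktrans_mean, pre$summary$ktrans_sd),
    post = c(post$summary$ktrans_mean, post$summary$ktrans_sd)
  )
  ktrans$delta <- ktrans$post - ktrans$pre
  scores <- if (!is.null(nrs_pre) && !is.null(nrs_post)) {
    tibble::tibble(
      nrs_pre = as.integer(nrs_pre), nrs_post = as.integer(nrs_post),
      category_pre = nrs_to_category(nrs_pre),
      category_post = nrs_to_category(nrs_post)
    )
  } else NULL
  structure(list(residuals = residuals, ktrans = ktrans, scores = scores),
            class = "case_assessment")
}

#' @export
print.case_assessment <- function(x, ...) {
  cat("<case_assessment>\n")
  cat("  delta ktrans mean: ",
      format(x$ktrans$delta[x$ktrans$stat == "mean"], digits = 4),
      ", delta ktrans SD: ",
      format(x$ktrans$delta[x$ktrans$stat == "sd"], digits = 4), "\n",
      sep = "")
  cat("  residual delta at p50: ",
      format(x$residuals$delta[x$residuals$percentile == 50], digits = 4),
      ", at p90: ",
      format(x$residuals$delta[x$residuals$percentile == 90], digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' @rdname delta_assessment
#' @param x a `case_assessment`.
#' @param ... unused.
#' @export
tidy.case_assessment <- function(x, ...) x$residuals

#' @rdname delta_assessment
#' @export
glance.case_assessment <- function(x, ...) {
  out <- tibble::tibble(
    delta_ktrans_mean = x$ktrans$delta[x$ktrans$stat == "mean"],
    delta_ktrans_sd = x$ktrans$delta[x$ktrans$stat == "sd"],
    delta_residual_p50 = x$residuals$delta[x$residuals$percentile == 50],
    delta_residual_p90 = x$residuals$delta[x$residuals$percentile == 90]
  )
  if (!is.null(x$scores)) out <- tibble::as_tibble(cbind(out, x$scores))
  out
}

#' Paired nonparametric tests for pre/post comparisons
#'
#' The distributional workhorses for before/after-registration data,
#' which are not normally distributed: the exact-binomial sign test (ties
#' dropped), the Wilcoxon signed-rank test (exact for 25 or fewer nonzero
#' pairs without ties, normal approximation with tie correction
#' otherwise), and Spearman's rank correlation between the pre values and
#' the paired differences (average ranks for ties). All tests two-sided.
#'
#' @param pre,post paired numeric samples of equal length (at least 5).
#' @return A tibble with `sign_test_p`, `wilcoxon_p`, `spearman_rho`, and
#'   `n`.
#' @export
paired_tests <- function(pre, post) {
  stopifnot(length(pre) == length(post))
  if (length(pre) < 5L) stop("need at least 5 pairs")
  delta <- post - pre
  npos <- sum(delta > 0)
  nneg <- sum(delta < 0)
  sign_p <- if (npos + nneg == 0L) {
    message("all pairs tied; sign test undefined")
    NA_real_
  } else binom.test(npos, npos + nneg, p = 0.5)$p.value
  d <- delta[delta != 0]
  wilcox_p <- if (length(d) == 0L) NA_real_ else {
    exact <- length(d) <= 25L && !any(duplicated(abs(d)))
    suppressWarnings(
      wilcox.test(d, exact = exact, correct = FALSE)$p.value)
  }
  rho <- suppressWarnings(cor(pre, delta, method = "spearman"))
  tibble::tibble(sign_test_p = sign_p, wilcoxon_p = wilcox_p,
                 spearman_rho = rho, n = length(pre))
}

#' Nonparametric group comparison (Kruskal-Wallis)
#'
#' Rank-based one-way analysis for subgroup comparisons (e.g. by tumor
#' entity or T-stage), with tie correction and a chi-square p-value.
#'
#' @param values numeric observations.
#' @param labels group labels, at least 2 groups with at least 2
#'   observations each.
#' @return A tibble with `statistic` (H), `df`, and `p_value`.
#' @export
group_comparison <- function(values, labels) {
  labels <- factor(labels)
  stopifnot(length(values) == length(labels))
  sizes <- table(labels)
  if (length(sizes) < 2L) stop("need at least 2 groups")
  if (any(sizes < 2L)) stop("every group needs at least 2 observations")
  k <- kruskal.test(values, labels)
  tibble::tibble(statistic = unname(k$statistic),
                 df = unname(k$parameter),
                 p_value = k$p.value)
}

#' Compile a per-case assessment report
#'
#' One row per case (NRS and category pre/post where available, ktrans
#' mean/SD pre/post and deltas, per-percentile residual deltas) plus a
#' summary block with medians and IQRs of the deltas (linear-interpolation
#' quartiles), paired-test p-values on the per-case deltas, and — because
#' it is ambiguous which pairing the qualitative correlation refers to —
#' Spearman's rho of the pre-registration category against both the NRS
#' change and the category change.
#'
#' @param cases list of `case_assessment` objects.
#' @param case_ids optional case identifiers.
#' @return An `assessment_report`: list of tibbles `cases` and `summary`.
#' @export
compile_report <- function(cases, case_ids = NULL) {
  if (length(cases) < 1L) stop("need at least 1 case")
  if (is.null(case_ids)) case_ids <- paste0("case", seq_along(cases))
  rows <- lapply(seq_along(cases), function(i) {
    x <- cases[[i]]
    res <- setNames(as.list(x$residuals$delta),
                    paste0("delta_res_p", x$residuals$percentile))
    sc <- if (!is.null(x$scores)) x$scores else
      tibble::tibble(nrs_pre = NA_integer_, nrs_post = NA_integer_,
                     category_pre = NA_integer_,
                     category_post = NA_integer_)
    tibble::as_tibble(c(
      list(case_id = case_ids[i]), as.list(sc),
      list(ktrans_mean_pre = x$ktrans$pre[1L],
           ktrans_mean_post = x$ktrans$post[1L],
           delta_ktrans_mean = x$ktrans$delta[1L],
           ktrans_sd_pre = x$ktrans$pre[2L],
           ktrans_sd_post = x$ktrans$post[2L],
           delta_ktrans_sd = x$ktrans$delta[2L]),
      res))
  })
  case_tbl <- do.call(rbind, rows)
  iqr <- function(v) diff(quantile(v, c(0.25, 0.75), type = 7,
                                   names = FALSE))
  num_cols <- setdiff(names(case_tbl), "case_id")
  med <- vapply(case_tbl[num_cols], function(v)
    if (all(is.na(v))) NA_real_ else median(v, na.rm = TRUE), 0)
  iqrs <- vapply(case_tbl[num_cols], function(v)
    if (all(is.na(v))) NA_real_ else iqr(v[!is.na(v)]), 0)
  summary_tbl <- tibble::tibble(
    statistic = c("median", "iqr"),
    tibble::as_tibble(rbind(med, iqrs))
  )
  tests <- if (nrow(case_tbl) >= 5L) {
    p50 <- paired_tests(rep(0, nrow(case_tbl)),
                        case_tbl$delta_res_p50)
    tibble::tibble(
      sign_p_delta_res_p50 = p50$sign_test_p,
      wilcoxon_p_delta_res_p50 = p50$wilcoxon_p,
      rho_category_pre_vs_nrs_delta = if (!all(is.na(case_tbl$nrs_pre)))
        suppressWarnings(cor(case_tbl$category_pre,
                             case_tbl$nrs_post - case_tbl$nrs_pre,
                             method = "spearman")) else NA_real_,
      rho_category_pre_vs_category_delta =
        if (!all(is.na(case_tbl$nrs_pre)))
          suppressWarnings(cor(case_tbl$category_pre,
                               case_tbl$category_post -
                                 case_tbl$category_pre,
                               method = "spearman")) else NA_real_
    )
  } else NULL
  structure(list(cases = case_tbl, summary = summary_tbl, tests = tests),
            class = "assessment_report")
}

#' @export
print.assessment_report <- function(x, ...) {
  cat("<assessment_report> ", nrow(x$cases), " case(s)\n", sep = "")
  print(x$cases)
  cat("summary:\n")
  print(x$summary)
  if (!is.null(x$tests)) {
    cat("tests:\n")
    print(x$tests)
  }
  invisible(x)
}

#' Write / read an assessment report as CSV
#'
#' The case table is written first; the summary (and test) blocks follow
#' as commented footer sections, so the file remains a single, valid CSV
#' for the case rows. [read_report()] inverts [write_report()] exactly.
#'
#' @param report an `assessment_report`.
#' @param path output CSV path.
#' @return `path` invisibly; for `read_report`, the reconstructed report.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "assessment_report"))
  con <- file(path, "w")
  on.exit(close(con))
  write.csv(report$cases, con, row.names = FALSE)
  writeLines("#block summary", con)
  write.csv(report$summary, con, row.names = FALSE)
  if (!is.null(report$tests)) {
    writeLines("#block tests", con)
    write.csv(report$tests, con, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  lines <- readLines(path)
  marks <- grep("^#block ", lines)
  ends <- c(marks - 1L, length(lines))
  starts <- c(1L, marks + 1L)
  blocks <- Map(function(s, e)
    read.csv(textConnection(lines[s:e]), check.names = FALSE),
    starts, ends)
  names(blocks) <- c("cases", sub("^#block ", "", lines[marks]))
  structure(
    list(cases = tibble::as_tibble(blocks$cases),
         summary = tibble::as_tibble(blocks$summary),
         tests = if (!is.null(blocks$tests))
           tibble::as_tibble(blocks$tests) else NULL),
    class = "assessment_report"
  )
}
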