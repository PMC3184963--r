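#' Grade distribution for glomerulosclerosis scoring
#'
#' Sclerosis is graded per glomerulus on the conventional 0-4 scale (0
#' normal; 1 sclerotic area up to 25%; 2, 25-50%; 3, 50-75%; 4, 75-100%).
#' `F` holds the percentage of glomeruli at each grade.
#'
#' @param F Numeric vector of length 5 (percent at grades 0..4), summing
#'   to 100.
#' @param n_glomeruli Number of glomeruli examined (study convention: 80 per
#'   kidney).
#' @return A `grade_distribution` object.
#' @export
grade_distribution <- function(F, n_glomeruli = NA_integer_) {
  if (length(F) != 5) stop("F must have 5 entries (grades 0..4)")
  if (any(F < 0)) stop("grade percentages must be non-negative")
  if (abs(sum(F) - 100) > 1e-9)
    stop("grade percentages must sum to 100, got ", sum(F))
  if (!is.na(n_glomeruli) && n_glomeruli < 1)
    stop("n_glomeruli must be >= 1")
  structure(list(F = as.numeric(F), n_glomeruli = n_glomeruli),
            class = "grade_distribution")
}

#' Tabulate per-glomerulus grades into a distribution
#'
#' @param grades Integer vector with values in 0..4 (one per glomerulus).
#' @return A [grade_distribution()] with `Fi = 100 * count(i) / n`.
#' @export
grades_to_distribution <- function(grades) {
  if (length(grades) < 1) stop("at least one grade is required")
  bad <- which(!(grades %in% 0:4))
  if (length(bad) > 0)
    stop("grades outside 0..4 at positions: ",
         paste(utils::head(bad, 5), collapse = ", "))
  counts <- vapply(0:4, function(i) sum(grades == i), numeric(1))
  grade_distribution(100 * counts / length(grades),
                     n_glomeruli = length(grades))
}

#' Glomerulosclerosis index
#'
#' Weighted-severity index `GSI = sum_i i * Fi / 100` over grades i = 0..4,
#' where Fi is the percentage of glomeruli at grade i. Linear in the
#' distribution and bounded in `[0, 4]`, with the bounds attained only by
#' the pure grade-0 and grade-4 distributions.
#'
#' @param dist A [grade_distribution()].
#' @return Index in `[0, 4]`.
#' @export
gsi <- function(dist) {
  stopifnot(inherits(dist, "grade_distribution"))
  sum((0:4) * dist$F) / 100
}

#' Geometric mean with multiplicative tolerance factor
#'
#' For skew-distributed (e.g. proteinuria-like) data: geometric mean
#' `exp(mean(log x))` with tolerance factor `exp(SEM(log x))`, the
#' multiplicative analogue of mean +/- SEM, printed as "gm x// tf".
#'
#' @param values Positive numeric vector, n >= 2.
#' @return List with `geometric_mean`, `tolerance_factor`, `n`.
#' @export
geometric_summary <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  if (any(values <= 0)) stop("geometric summary requires strictly positive values")
  lx <- log(values)
  list(geometric_mean = exp(mean(lx)),
       tolerance_factor = exp(sd(lx) / sqrt(length(lx))),
       n = length(values))
}

#' Two-group comparison by Student's t-test
#'
#' Two-sided equal-variance two-sample t-test. In skewed mode the data are
#' log-transformed before testing and the groups are summarised as geometric
#' mean x// tolerance factor; otherwise as mean +/- SEM. Significance is
#' declared at p < 0.05.
#'
#' @param a,b Numeric vectors, n >= 2 each.
#' @param skewed Log-transform before testing (requires positive values).
#' @param welch Use the unequal-variance (Welch) test instead.
#' @return A `group_comparison` list: per-group summaries, `p_value`,
#'   `significant`, and the (possibly log-scale) mean difference.
#' @export
compare_groups <- function(a, b, skewed = FALSE, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per group")
  sem <- function(x) sd(x) / sqrt(length(x))
  if (skewed) {
    if (any(a <= 0) || any(b <= 0))
      stop("skewed mode requires strictly positive values")
    ta <- log(a); tb <- log(b)
    summ_a <- geometric_summary(a)
    summ_b <- geometric_summary(b)
  } else {
    ta <- a; tb <- b
    summ_a <- list(mean = mean(a), sem = sem(a), n = length(a))
    summ_b <- list(mean = mean(b), sem = sem(b), n = length(b))
  }
  tt <- t.test(ta, tb, var.equal = !welch, alternative = "two.sided")
  structure(list(group_a = summ_a, group_b = summ_b,
                 p_value = unname(tt$p.value),
                 mean_difference = unname(mean(ta) - mean(tb)),
                 significant = unname(tt$p.value) < 0.05,
                 skewed = skewed,
                 test = if (welch) "welch" else "student"),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  fmt <- function(s) {
    if (!is.null(s$geometric_mean))
      sprintf("%.4g x/ %.4g (n=%d)", s$geometric_mean, s$tolerance_factor, s$n)
    else sprintf("%.4g +/- %.3g (n=%d)", s$mean, s$sem, s$n)
  }
  cat("group A:", fmt(x$group_a), "\ngroup B:", fmt(x$group_b), "\n")
  cat(sprintf("%s t-test%s: p = %.4g%s\n",
              if (x$test == "student") "Student's" else "Welch",
              if (x$skewed) " (log scale)" else "",
              x$p_value, if (x$significant) " *" else ""))
  invisible(x)
}
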