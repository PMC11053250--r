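#' Median-split a score column into high/low levels
#'
#' The median is taken over all spots pooled (both groups together); a spot
#' is `high` iff its score strictly exceeds the pooled median, so ties at
#' the median go `low`.
#'
#' @param scores A `score_matrix` from [score_sets()] (or a named numeric
#'   matrix).
#' @param set_name Column to split.
#' @return Character vector `"high"`/`"low"` per spot, with the median in
#'   attribute `median`.
#' @export
dichotomize <- function(scores, set_name) {
  if (!set_name %in% colnames(scores)) {
    stop("unknown set name: ", set_name, " (have: ",
         paste(colnames(scores), collapse = ", "), ")")
  }
  x <- scores[, set_name]
  if (length(x) < 2) stop("dichotomize needs >= 2 spots")
  med <- stats::median(x)
  structure(ifelse(x > med, "high", "low"), median = med)
}

#' Four-category excitatory/inhibitory spot classification
#'
#' `high` glutamatergic with `low` GABAergic is an excitatory spot; the
#' reverse is inhibitory; both-high and both-low are mixed.
#'
#' @param glut_levels,gaba_levels Aligned `"high"`/`"low"` vectors from
#'   [dichotomize()].
#' @return A list: `levels` (data.frame with `glut_level`, `gaba_level`,
#'   `ei_call` in `excitatory`/`inhibitory`/`mixed_high`/`mixed_low`) and
#'   the medians used (`glut_median`, `gaba_median`).
#' @export
classify_ei <- function(glut_levels, gaba_levels) {
  if (length(glut_levels) != length(gaba_levels)) {
    stop("level vectors differ in length: ", length(glut_levels), " vs ",
         length(gaba_levels))
  }
  stopifnot(all(glut_levels %in% c("high", "low")),
            all(gaba_levels %in% c("high", "low")))
  call <- ifelse(glut_levels == "high" & gaba_levels == "low", "excitatory",
          ifelse(glut_levels == "low" & gaba_levels == "high", "inhibitory",
          ifelse(glut_levels == "high", "mixed_high", "mixed_low")))
  list(levels = data.frame(glut_level = unclass(glut_levels),
                           gaba_level = unclass(gaba_levels),
                           ei_call = call, stringsAsFactors = FALSE),
       glut_median = attr(glut_levels, "median"),
       gaba_median = attr(gaba_levels, "median"))
}

EI_CATEGORIES <- c("excitatory", "inhibitory", "mixed_high", "mixed_low")

#' Group-level E/I summary statistics
#'
#' Per group: counts and proportions of the four E/I categories. Per set:
#' group score medians and a two-sided Mann-Whitney test. Plus
#' two-proportion chi-square tests (with continuity correction) on the
#' high-glutamatergic and the excitatory fractions between the two groups.
#'
#' @param cls Output of [classify_ei()], aligned to `spots`.
#' @param spots Spot table with a `group` column (two groups).
#' @param scores The `score_matrix` the levels came from, aligned to
#'   `spots`.
#' @return A list: `score_tests` (data.frame per set: group medians, U, p),
#'   `category_table` (data.frame: group, category, n, proportion),
#'   `prop_tests` (data.frame: quantity, per-group proportions, chi-square
#'   statistic, p).
#' @export
group_summary <- function(cls, spots, scores) {
  stopifnot(nrow(cls$levels) == nrow(spots), nrow(spots) == nrow(scores))
  groups <- unique(spots$group)
  if (length(groups) < 2) stop("need >= 2 groups, got: ",
                               paste(groups, collapse = ", "))
  small <- names(which(table(spots$group) < 2))
  if (length(small)) stop("group(s) with < 2 spots: ",
                          paste(small, collapse = ", "))

  score_tests <- do.call(rbind, lapply(colnames(scores), function(set_name) {
    x <- scores[spots$group == groups[1], set_name]
    y <- scores[spots$group == groups[2], set_name]
    ht <- rank_sum_test(x, y)
    data.frame(set = set_name,
               median_1 = stats::median(x), median_2 = stats::median(y),
               U = ht$statistic, p = ht$p.value, stringsAsFactors = FALSE)
  }))
  names(score_tests)[2:3] <- paste0("median_", groups)

  category_table <- do.call(rbind, lapply(groups, function(g) {
    calls <- cls$levels$ei_call[spots$group == g]
    n <- vapply(EI_CATEGORIES, function(k) sum(calls == k), integer(1))
    data.frame(group = g, category = EI_CATEGORIES, n = n,
               proportion = n / length(calls), stringsAsFactors = FALSE,
               row.names = NULL)
  }))

  prop_row <- function(label, hit) {
    x <- vapply(groups, function(g) sum(hit[spots$group == g]), integer(1))
    n <- vapply(groups, function(g) sum(spots$group == g), integer(1))
    ht <- suppressWarnings(stats::prop.test(x, n, correct = TRUE))
    df <- data.frame(quantity = label, p1 = x[1] / n[1], p2 = x[2] / n[2],
                     chisq = unname(ht$statistic), p = ht$p.value,
                     stringsAsFactors = FALSE, row.names = NULL)
    names(df)[2:3] <- paste0("prop_", groups)
    df
  }
  prop_tests <- rbind(
    prop_row("high_glut", cls$levels$glut_level == "high"),
    prop_row("excitatory", cls$levels$ei_call == "excitatory"))

  list(score_tests = score_tests, category_table = category_table,
       prop_tests = prop_tests)
}
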