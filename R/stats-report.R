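#' Significance star label for a p-value
#'
#' Pure mapping used everywhere stars appear: `***` p < 0.001, `**`
#' p < 0.01, `*` p < 0.05, `ns` otherwise.
#'
#' @param p p-value(s) in `[0, 1]`.
#' @return character vector of labels.
#' @examples
#' starLabel(c(0.2, 0.049, 0.009, 0.0009))
#' @export
starLabel <- function(p) {
  ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*", "ns")))
}

#' Two-sided unpaired t-test with star labelling
#'
#' Pooled-variance (Student) by default, matching the classical
#' ANOVA-then-t-test workflow; Welch via `equalVariance = FALSE`.  When
#' both groups are constant with equal means the comparison is undefined
#' and the conventional p = 1 is reported with a warning.
#'
#' @param groupA,groupB numeric vectors (>= 2 values each).
#' @param equalVariance pooled (TRUE, default) or Welch (FALSE).
#' @param labels group names.
#' @return a [TestResult-class].
#' @examples
#' unpairedTTest(c(1, 2, 3), c(2, 3, 4))
#' @export
unpairedTTest <- function(groupA, groupB, equalVariance = TRUE,
                          labels = c("A", "B")) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("need >= 2 values per group")
  if (stats::sd(groupA) == 0 && stats::sd(groupB) == 0 &&
      mean(groupA) == mean(groupB)) {
    warning("both groups constant with equal means; p = 1 by convention")
    return(new("TestResult", statistic = 0,
               df = length(groupA) + length(groupB) - 2, pValue = 1,
               method = if (equalVariance) "Two Sample t-test"
                        else "Welch Two Sample t-test",
               groups = labels, stars = "ns"))
  }
  tt <- stats::t.test(groupA, groupB, var.equal = equalVariance,
                      alternative = "two.sided")
  new("TestResult", statistic = unname(tt$statistic),
      df = unname(tt$parameter), pValue = tt$p.value,
      method = tt$method, groups = labels, stars = starLabel(tt$p.value))
}

#' One-way analysis of variance
#'
#' Standard F test across groups, used as the gate before pairwise t-tests.
#'
#' @param groups named (or unnamed) list of numeric vectors, >= 2 groups
#'   with >= 2 values each.
#' @return a [TestResult-class] with `df = c(df_between, df_within)`.  When
#'   every observation is identical the F statistic is 0 and p = 1.
#' @examples
#' oneWayAnova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(5, 6, 7)))
#' @export
oneWayAnova <- function(groups) {
  if (length(groups) < 2L) stop("need >= 2 groups")
  if (any(vapply(groups, length, 0L) < 2L))
    stop("every group needs >= 2 values")
  labels <- names(groups) %||% paste0("group", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(labels, vapply(groups, length, 0L)))
  if (stats::sd(values) == 0) {
    return(new("TestResult", statistic = 0,
               df = c(nlevels(g) - 1, length(values) - nlevels(g)),
               pValue = 1, method = "One-way ANOVA", groups = labels,
               stars = "ns"))
  }
  tab <- stats::anova(stats::aov(values ~ g))
  f <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  new("TestResult", statistic = f, df = tab$Df, pValue = p,
      method = "One-way ANOVA", groups = labels, stars = starLabel(p))
}

#' Survival percentages from a colony-count table
#'
#' Expresses each count as a percentage of the time-0 (untreated) colony
#' number of the same strain and replicate.
#'
#' @param counts data.frame with columns `strain`, `replicate`, `time`,
#'   `count`; a `time == 0` reference row must be present for every
#'   (strain, replicate).
#' @return data.frame of the treated points with an added `percent` column
#'   (the reference rows themselves map to 100%).
#' @examples
#' curve <- data.frame(time = c(15, 30), fraction = c(0.5, 0.6))
#' survivalPercent(generateSurvivalCounts(250, curve, "none"))
#' @export
survivalPercent <- function(counts) {
  stopifnot(all(c("strain", "replicate", "time", "count") %in%
                  names(counts)))
  key <- interaction(counts$strain, counts$replicate, drop = TRUE)
  ref <- counts[counts$time == 0, ]
  refKey <- interaction(ref$strain, ref$replicate, drop = TRUE)
  idx <- match(key, refKey)
  if (anyNA(idx))
    stop("missing time-0 reference for some strain/replicate")
  refCount <- ref$count[idx]
  if (any(refCount <= 0)) stop("time-0 reference count must be > 0")
  counts$percent <- 100 * counts$count / refCount
  counts
}

#' Group summary of survival percentages
#'
#' Mean and SD of the survival percentage across biological replicates,
#' per strain and time point.
#'
#' @param points output of [survivalPercent()].
#' @return data.frame with columns `strain`, `time`, `meanPercent`,
#'   `sdPercent` (NA for singleton groups), `n`.
#' @export
survivalSummary <- function(points) {
  groups <- split(points, interaction(points$strain, points$time,
                                      drop = TRUE))
  out <- do.call(rbind, lapply(groups, function(g) {
    data.frame(strain = g$strain[1], time = g$time[1],
               meanPercent = mean(g$percent),
               sdPercent = if (nrow(g) > 1L) stats::sd(g$percent)
                           else NA_real_,
               n = nrow(g))
  }))
  out <- out[order(out$strain, out$time), ]
  rownames(out) <- NULL
  out
}
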