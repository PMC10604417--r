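#' Squared Pearson correlation between virtual and manual measurements
#'
#' Validation statistic for the virtual (CT-derived) traits against their
#' manual counterparts: the squared Pearson correlation coefficient r^2.
#' Correlation is unit-free, so traits of different units (e.g. virtual
#' volume against spike weight) can be compared.
#'
#' @param virtual,manual numeric vectors of equal length (>= 3), no
#'   missing values, neither constant.
#' @return r^2 in `[0, 1]`.
#' @export
correlate <- function(virtual, manual) {
  stopifnot(length(virtual) == length(manual), length(virtual) >= 3)
  if (anyNA(virtual) || anyNA(manual)) stop("missing values not allowed")
  if (stats::sd(virtual) == 0 || stats::sd(manual) == 0)
    stop("constant vector: correlation undefined")
  stats::cor(virtual, manual)^2
}

#' Significance stars for a p-value
#'
#' `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, `Ns` otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector of annotations.
#' @export
signif_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", "Ns")))
}

#' Pairwise group comparison of a trait
#'
#' Two-sample t-tests between every pair of groups (Welch's
#' unequal-variance test by default, switchable to the pooled-variance
#' test), with group means, standard deviations and significance stars.
#'
#' @param values numeric vector of trait values.
#' @param group factor or character vector of group membership (e.g. wild /
#'   landrace / cultivar), same length as `values`.
#' @param trait trait name carried into the output.
#' @param var_equal `FALSE` (default) for Welch, `TRUE` for pooled.
#' @return list of class `group_comparison` with `trait`, `summary` (per
#'   group: n, mean, sd) and `pairs` (per pair: t, df, p, stars).
#' @export
compare_groups <- function(values, group, trait = "trait",
                           var_equal = FALSE) {
  stopifnot(length(values) == length(group))
  group <- as.character(group)
  levels <- unique(group)
  sizes <- table(group)
  if (any(sizes < 2))
    stop("every group needs at least 2 observations; offending: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  summary <- data.frame(
    group = levels,
    n = as.integer(sizes[levels]),
    mean = vapply(levels, function(g) mean(values[group == g]), numeric(1)),
    sd = vapply(levels, function(g) stats::sd(values[group == g]),
                numeric(1)),
    row.names = NULL)
  pr <- t(utils::combn(levels, 2))
  pairs <- do.call(rbind, lapply(seq_len(nrow(pr)), function(i) {
    a <- values[group == pr[i, 1]]
    b <- values[group == pr[i, 2]]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      # degenerate but well-defined: identical spread-free samples
      tt <- list(statistic = c(t = if (mean(a) == mean(b)) 0 else Inf),
                 parameter = c(df = length(a) + length(b) - 2),
                 p.value = if (mean(a) == mean(b)) 1 else 0)
    } else {
      tt <- stats::t.test(a, b, var.equal = var_equal)
    }
    data.frame(group1 = pr[i, 1], group2 = pr[i, 2],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stars = signif_stars(tt$p.value))
  }))
  structure(list(trait = trait, summary = summary, pairs = pairs,
                 welch = !var_equal),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Comparison of", x$trait, "across groups",
      if (x$welch) "(Welch t-test)\n" else "(pooled t-test)\n")
  print(x$summary, row.names = FALSE)
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Virtual-vs-manual validation report
#'
#' Joins per-spike virtual traits with manual measurements by spike id and
#' reports r^2 for every shared numeric trait column.
#'
#' @param virtual,manual data frames with a `spike_id` column and one
#'   column per trait; every virtual spike id must appear in `manual`.
#' @return data frame with `trait` and `r_squared`.
#' @export
validate_traits <- function(virtual, manual) {
  stopifnot("spike_id" %in% names(virtual), "spike_id" %in% names(manual))
  missing <- setdiff(virtual$spike_id, manual$spike_id)
  if (length(missing))
    stop("spike ids missing from manual data: ",
         paste(missing, collapse = ", "))
  m <- manual[match(virtual$spike_id, manual$spike_id), ]
  traits <- intersect(names(virtual), names(manual))
  traits <- traits[traits != "spike_id" &
                     vapply(virtual[traits], is.numeric, logical(1))]
  data.frame(trait = traits,
             r_squared = vapply(traits, function(tr)
               correlate(virtual[[tr]], m[[tr]]), numeric(1)),
             row.names = NULL)
}
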