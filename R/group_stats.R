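utils::globalVariables(c("group", "sem"))

# Nonparametric multi-group comparison of peptide ratios:
# Kruskal-Wallis with tie correction, Dunn post hoc z tests, and a
# Shapiro-Wilk normality gate. The rank statistics are implemented from
# their defining formulas; normality testing is delegated to
# stats::shapiro.test.

.tie_term <- function(x) {
  t <- table(x)
  sum(t^3 - t)
}

#' Kruskal-Wallis rank-sum test
#'
#' Midrank-based H statistic with tie correction
#' `H / (1 - sum(t^3 - t) / (N^3 - N))`, and a chi-square p-value on
#' k - 1 degrees of freedom. When all observations are identical the test
#' is degenerate and returns H = 0, p = 1.
#'
#' @param values Numeric vector of observations.
#' @param groups Vector of group labels, same length as `values`.
#' @return List with `H`, `p_value`, `df`, `n` (per-group sizes).
#' @examples
#' kruskal_wallis(c(1, 2, 3, 4, 5, 6, 7, 8, 9),
#'                rep(c("a", "b", "c"), each = 3))  # H = 7.2
#' @export
kruskal_wallis <- function(values, groups) {
  keep <- !is.na(values)
  values <- values[keep]
  groups <- as.character(groups)[keep]
  sizes <- table(groups)
  k <- length(sizes)
  N <- length(values)
  if (k < 2L || N < 3L)
    stop("need at least 2 non-empty groups and 3 observations in total",
         call. = FALSE)
  r <- rank(values)  # midranks
  rbar <- tapply(r, groups, mean)
  H <- 12 / (N * (N + 1)) *
    sum(sizes * (rbar[names(sizes)] - (N + 1) / 2)^2)
  correction <- 1 - .tie_term(values) / (N^3 - N)
  if (correction <= 0) {
    H <- 0
    p <- 1
  } else {
    H <- H / correction
    p <- stats::pchisq(H, df = k - 1, lower.tail = FALSE)
  }
  list(H = unname(H), p_value = unname(p), df = k - 1L,
       n = as.integer(sizes))
}

#' Dunn's post hoc pairwise comparisons
#'
#' For each pair of groups,
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - sum(t^3 - t)/(12(N-1))) *
#' (1/n_i + 1/n_j))` with pooled midranks, two-sided normal p-values, and
#' the configured multiplicity adjustment over the tested pairs. Pairs
#' involving an empty group are skipped and flagged.
#'
#' @inheritParams kruskal_wallis
#' @param adjustment `"bonferroni"` (default), `"holm"`, or `"none"`.
#' @return Data frame with one row per ordered pair: `group1`, `group2`,
#'   `n1`, `n2`, `z`, `p_raw`, `p_adjusted`, `skipped`.
#' @export
dunn_posthoc <- function(values, groups,
                         adjustment = c("bonferroni", "holm", "none")) {
  adjustment <- match.arg(adjustment)
  groups <- as.character(groups)
  levels_all <- unique(groups)
  keep <- !is.na(values)
  v <- values[keep]
  g <- groups[keep]
  N <- length(v)
  r <- rank(v)
  rbar <- tapply(r, g, mean)
  sizes <- table(g)
  var_term <- N * (N + 1) / 12 - .tie_term(v) / (12 * (N - 1))
  pairs <- utils::combn(levels_all, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    n1 <- if (a %in% names(sizes)) as.integer(sizes[[a]]) else 0L
    n2 <- if (b %in% names(sizes)) as.integer(sizes[[b]]) else 0L
    if (n1 == 0L || n2 == 0L || var_term <= 0)
      return(data.frame(group1 = a, group2 = b, n1 = n1, n2 = n2,
                        z = NA_real_, p_raw = NA_real_,
                        p_adjusted = NA_real_, skipped = TRUE))
    z <- (rbar[[a]] - rbar[[b]]) / sqrt(var_term * (1 / n1 + 1 / n2))
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(group1 = a, group2 = b, n1 = n1, n2 = n2, z = z,
               p_raw = p, p_adjusted = NA_real_, skipped = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  tested <- !out$skipped
  out$p_adjusted[tested] <- stats::p.adjust(out$p_raw[tested],
                                            method = adjustment)
  out
}

#' Significance stars
#'
#' @param p Numeric vector of p-values.
#' @return Character vector: `***` below 0.001, `**` below 0.01, `*`
#'   below 0.05, empty string otherwise (`NA` stays `NA`).
#' @export
significance_stars <- function(p) {
  out <- ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*", "")))
  out[is.na(p)] <- NA_character_
  out
}

#' Shapiro-Wilk normality gate
#'
#' Tests each group for normality and decides the analysis route: the
#' nonparametric path is taken when any group rejects normality at
#' `alpha` or is too small to test (n < 3).
#'
#' @inheritParams kruskal_wallis
#' @param alpha Rejection level (default 0.05).
#' @return List with `table` (group, n, W, p_value, testable, rejects)
#'   and `route` ("nonparametric" or "parametric").
#' @export
shapiro_wilk_gate <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  keep <- !is.na(values)
  v <- values[keep]
  g <- groups[keep]
  labels <- unique(groups)
  rows <- lapply(labels, function(lab) {
    x <- v[g == lab]
    n <- length(x)
    if (n >= 3L && n <= 5000L && stats::sd(x) > 0) {
      sw <- stats::shapiro.test(x)
      data.frame(group = lab, n = n, W = unname(sw$statistic),
                 p_value = sw$p.value, testable = TRUE,
                 rejects = sw$p.value < alpha)
    } else {
      data.frame(group = lab, n = n, W = NA_real_, p_value = NA_real_,
                 testable = FALSE, rejects = NA)
    }
  })
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  nonparam <- any(!tab$testable) || any(tab$rejects, na.rm = TRUE)
  list(table = tab, route = if (nonparam) "nonparametric" else "parametric")
}

#' Compare peptide ratios across sample groups
#'
#' The full statistical workflow per peptide: Shapiro-Wilk normality gate,
#' Kruskal-Wallis across groups, and Dunn post hoc pairwise tests with
#' significance stars. Ratios are taken from detected samples only;
#' undetected samples contribute no value (never a zero). Significance is
#' only claimed for pairs in which both groups carry at least
#' `min_detections` detected ratios; sparser pairs are reported but
#' flagged `claimable = FALSE`.
#'
#' @param quant Quantification table from [quantify_xics()].
#' @param manifest Data frame mapping `sample_id` to `group`.
#' @param adjustment Dunn adjustment, see [dunn_posthoc()].
#' @param min_detections Minimum detections per group for a claimable
#'   pair (default 3).
#' @param alpha Normality-gate level.
#' @return Object of class `group_comparison`: list with `tests` (one row
#'   per peptide: H, p, route, group sizes) and `pairs` (Dunn table with
#'   `stars` and `claimable`).
#' @export
compare_groups <- function(quant, manifest, adjustment = "bonferroni",
                           min_detections = 3L, alpha = 0.05) {
  quant$group <- manifest$group[match(quant$sample_id, manifest$sample_id)]
  if (anyNA(quant$group))
    stop("sample(s) missing from manifest", call. = FALSE)
  groups_all <- unique(manifest$group)
  tests <- list()
  pairs <- list()
  for (pep in unique(quant$peptide)) {
    d <- quant[quant$peptide == pep & quant$detected &
                 !is.na(quant$light_to_heavy_ratio), , drop = FALSE]
    sizes <- vapply(groups_all, function(g) sum(d$group == g), integer(1))
    n_nonempty <- sum(sizes > 0)
    if (n_nonempty < 2L || nrow(d) < 3L) {
      tests[[pep]] <- data.frame(peptide = pep, H = NA_real_,
                                 p_value = NA_real_, route = NA_character_,
                                 t(sizes), check.names = FALSE)
      next
    }
    gate <- shapiro_wilk_gate(d$light_to_heavy_ratio, d$group, alpha)
    kw <- kruskal_wallis(d$light_to_heavy_ratio, d$group)
    dn <- dunn_posthoc(d$light_to_heavy_ratio, d$group, adjustment)
    # carry pairs with groups absent from the detected data as skipped
    missing_groups <- setdiff(groups_all, unique(d$group))
    if (length(missing_groups)) {
      extra <- utils::combn(groups_all, 2)
      have <- paste(dn$group1, dn$group2)
      for (j in seq_len(ncol(extra))) {
        key <- paste(extra[1, j], extra[2, j])
        if (!key %in% have &&
            (extra[1, j] %in% missing_groups ||
             extra[2, j] %in% missing_groups))
          dn <- rbind(dn, data.frame(
            group1 = extra[1, j], group2 = extra[2, j],
            n1 = sizes[[extra[1, j]]], n2 = sizes[[extra[2, j]]],
            z = NA_real_, p_raw = NA_real_, p_adjusted = NA_real_,
            skipped = TRUE))
      }
    }
    dn$stars <- significance_stars(dn$p_adjusted)
    dn$claimable <- !dn$skipped & dn$n1 >= min_detections &
      dn$n2 >= min_detections
    pairs[[pep]] <- cbind(peptide = pep, dn, row.names = NULL)
    tests[[pep]] <- data.frame(peptide = pep, H = kw$H,
                               p_value = kw$p_value, route = gate$route,
                               t(sizes), check.names = FALSE)
  }
  structure(list(
    tests = do.call(rbind, c(tests, list(make.row.names = FALSE))),
    pairs = if (length(pairs))
      do.call(rbind, c(pairs, list(make.row.names = FALSE))) else NULL
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %d peptide(s)\n", nrow(x$tests)))
  sig <- x$pairs[!is.na(x$pairs$stars) & nzchar(x$pairs$stars) &
                   x$pairs$claimable, , drop = FALSE]
  if (!is.null(sig) && nrow(sig)) {
    cat("significant pairs:\n")
    print(sig[, c("peptide", "group1", "group2", "z", "p_adjusted",
                  "stars")], row.names = FALSE)
  } else cat("no significant pairs\n")
  invisible(x)
}

#' Bar plot of group means with SEM and significance stars
#'
#' Mean light-to-heavy ratio per group with standard-error bars, faceted
#' by peptide, annotated with the adjusted-significance stars of
#' claimable pairs.
#'
#' @inheritParams compare_groups
#' @param comparison Optional precomputed [compare_groups()] result.
#' @return A ggplot object.
#' @export
plot_group_comparison <- function(quant, manifest, comparison = NULL) {
  quant$group <- manifest$group[match(quant$sample_id, manifest$sample_id)]
  d <- quant[quant$detected & !is.na(quant$light_to_heavy_ratio), ,
             drop = FALSE]
  summ <- do.call(rbind, lapply(split(d, list(d$peptide, d$group),
                                      drop = TRUE), function(s) data.frame(
    peptide = s$peptide[1], group = s$group[1],
    mean = mean(s$light_to_heavy_ratio),
    sem = stats::sd(s$light_to_heavy_ratio) / sqrt(nrow(s)))))
  p <- ggplot2::ggplot(summ, ggplot2::aes(
    x = group, y = mean, fill = group)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean - sem,
                                        ymax = mean + sem),
                           width = 0.3) +
    ggplot2::facet_wrap(~peptide, scales = "free_y") +
    ggplot2::labs(y = "light-to-heavy ratio (mean ± SEM)", x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
  p
}
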