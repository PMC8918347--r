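#' Normality screen
#'
#' One-sample Kolmogorov-Smirnov test of a sample against a normal
#' distribution with the sample's own mean and SD. Estimating the parameters
#' from the same sample invalidates the classical KS null distribution
#' (p-values become conservative), so the default uses the Lilliefors
#' correction, which keeps the identical statistic but the correct null. The
#' uncorrected test is available via `method = "parametric"`.
#'
#' @param values numeric sample; at least 5 values (3 for
#'   `method = "parametric"`), not all equal.
#' @param method `"lilliefors"` (default) or `"parametric"`.
#' @return The p-value.
#' @export
ks_normality <- function(values, method = c("lilliefors", "parametric")) {
  method <- match.arg(method)
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  n_min <- if (method == "lilliefors") 5L else 3L
  if (length(v) < n_min) {
    stopf("need at least %d finite values for the %s KS test", n_min, method)
  }
  if (sd(v) == 0) stopf("sample is constant; normality test undefined")
  if (method == "lilliefors") {
    nortest::lillie.test(v)$p.value
  } else {
    suppressWarnings(ks.test(v, "pnorm", mean(v), sd(v))$p.value)
  }
}

# tie-corrected Kruskal-Wallis H for values with integer group codes
kw_statistic <- function(values, g) {
  n <- length(values)
  r <- rank(values)
  ni <- tabulate(g)
  rbar <- tapply(r, g, mean)
  H <- 12 / (n * (n + 1)) * sum(ni * (rbar - (n + 1) / 2)^2)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr > 0) H <- H / corr
  H
}

# enumerate all assignments of n values into groups of the given sizes and
# apply f(assignment vector of group codes); used by the exact permutation p
enumerate_assignments <- function(n, sizes, f) {
  assign_rec <- function(remaining, k, codes) {
    if (k == length(sizes)) {
      codes[remaining] <- k
      f(codes)
      return(invisible())
    }
    picks <- utils::combn(remaining, sizes[k], simplify = FALSE)
    for (p in picks) {
      codes2 <- codes
      codes2[p] <- k
      assign_rec(setdiff(remaining, p), k + 1L, codes2)
    }
  }
  assign_rec(seq_len(n), 1L, integer(n))
}

#' Kruskal-Wallis omnibus test
#'
#' Rank-based H statistic with tie correction. The p-value comes from the
#' chi-square approximation with g-1 degrees of freedom
#' (via [stats::kruskal.test()]); for tiny samples an exact permutation
#' p-value `P(H >= H_obs)` over all group assignments is available and is
#' selected automatically for total n <= 10.
#'
#' @param groups list of numeric vectors (>= 2 groups, each non-empty).
#' @param mode `"auto"` (permutation when total n <= 10), `"chisq"` or
#'   `"permutation"`.
#' @return List with `H`, `p`, `method`, `n`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(10, 11, 12)))  # exact p = 0.1
#' @export
kruskal_wallis <- function(groups, mode = c("auto", "chisq", "permutation")) {
  mode <- match.arg(mode)
  if (!is.list(groups) || length(groups) < 2L) stopf("need >= 2 groups")
  groups <- lapply(groups, as.numeric)
  sizes <- lengths(groups)
  if (any(sizes < 1L)) stopf("every group must be non-empty")
  values <- unlist(groups, use.names = FALSE)
  n <- length(values)
  if (n < 3L) stopf("need at least 3 values in total")
  g <- rep(seq_along(groups), sizes)
  if (length(unique(values)) == 1L) {
    return(list(H = 0, p = 1, method = "degenerate", n = n))
  }
  if (mode == "auto") mode <- if (n <= 10L) "permutation" else "chisq"
  if (mode == "chisq") {
    kt <- kruskal.test(values, factor(g))
    list(H = unname(kt$statistic), p = unname(kt$p.value),
         method = "chisq", n = n)
  } else {
    if (n > 12L) stopf("exact permutation is limited to total n <= 12")
    H_obs <- kw_statistic(values, g)
    hits <- 0L
    total <- 0L
    enumerate_assignments(n, sizes, function(codes) {
      total <<- total + 1L
      if (kw_statistic(values, codes) >= H_obs - 1e-12) hits <<- hits + 1L
    })
    list(H = H_obs, p = hits / total, method = "permutation", n = n)
  }
}

#' Wilcoxon rank-sum (Mann-Whitney U) test
#'
#' Two-sided two-sample rank test. The exact null distribution is used when
#' both samples are small (total n <= 25) and tie-free; otherwise the
#' tie-corrected normal approximation with continuity correction applies.
#' The statistic U counts pairs `(a_i, b_j)` with `a_i > b_j` (R's `W` for
#' the first sample).
#'
#' @param a,b numeric samples (each non-empty).
#' @param mode `"auto"` (default), `"exact"` or `"normal"`.
#' @return List with `U`, `p` (two-sided), `method`.
#' @examples
#' rank_sum(c(1, 2), c(3, 4))  # exact two-sided p = 1/3
#' @export
rank_sum <- function(a, b, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 1L || length(b) < 1L) stopf("both samples must be non-empty")
  has_ties <- anyDuplicated(c(a, b)) > 0L
  if (mode == "auto") {
    mode <- if (!has_ties && length(a) + length(b) <= 25L) "exact" else "normal"
  }
  if (mode == "exact" && has_ties) {
    stopf("exact mode is undefined with ties; use mode = 'normal'")
  }
  wt <- suppressWarnings(
    wilcox.test(a, b, exact = (mode == "exact"), correct = TRUE,
                alternative = "two.sided")
  )
  p <- unname(wt$p.value)
  if (is.nan(p)) p <- 1  # identical constant samples
  list(U = unname(wt$statistic), p = min(p, 1), method = mode)
}

#' Multiplicity adjustment for post-hoc p-values
#'
#' Benjamini-Hochberg step-up (monotone by construction) or no adjustment.
#'
#' @param pvals numeric p-values in (0, 1].
#' @param method `"benjamini_hochberg"` (default) or `"none"`.
#' @return Adjusted p-values, same length and order.
#' @export
adjust_pvalues <- function(pvals, method = c("benjamini_hochberg", "none")) {
  method <- match.arg(method)
  p <- as.numeric(pvals)
  if (length(p) == 0L) return(p)
  if (any(!is.finite(p)) || any(p <= 0 | p > 1)) {
    stopf("p-values must lie in (0, 1]")
  }
  if (method == "none") p else p.adjust(p, method = "BH")
}

#' Significance stars
#'
#' @param p numeric p-values.
#' @return Character vector: `***` for p < 0.001, `**` for p < 0.01, `*` for
#'   p < 0.05, `""` otherwise.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 0.001) "***" else if (pi < 0.01) "**" else if (pi < 0.05) "*" else ""
  }, character(1))
}

#' Compare groups with the nonparametric chain
#'
#' Runs, per comparison family, a Kruskal-Wallis omnibus test over the
#' groups, followed (when the omnibus is significant, mirroring the gated
#' "followed by" design) by pairwise two-sided Wilcoxon rank-sum tests with
#' per-family multiplicity adjustment. Families express the comparisons a
#' factorial design asks for — e.g. genotype-within-age uses `family = age`
#' and `group = genotype`.
#'
#' @param data data frame of per-unit results.
#' @param value name of the numeric outcome column.
#' @param group name of the grouping column compared within each family.
#' @param family optional name of the family column; `NULL` treats all rows
#'   as one family.
#' @param adjust post-hoc adjustment: `"benjamini_hochberg"` (default) or
#'   `"none"` (raw p-values).
#' @param gate run post-hoc tests only when the family's omnibus p-value is
#'   below `gate_alpha` (default `TRUE`).
#' @param gate_alpha omnibus significance gate, default 0.05.
#' @param posthoc_mode passed to [rank_sum()] (`"auto"`, `"exact"`,
#'   `"normal"`).
#' @param omnibus_mode passed to [kruskal_wallis()].
#' @return A `GroupComparison`: list with `omnibus` (one row per family:
#'   `family`, `n_groups`, `n`, `H`, `p`, `stars`) and `pairwise` (one row
#'   per tested pair: `family`, `group_a`, `group_b`, `n_a`, `n_b`, `U`,
#'   `p_raw`, `p_adj`, `stars`), plus the adjustment tag.
#' @export
compare_groups <- function(data, value, group, family = NULL,
                           adjust = c("benjamini_hochberg", "none"),
                           gate = TRUE, gate_alpha = 0.05,
                           posthoc_mode = "auto", omnibus_mode = "chisq") {
  adjust <- match.arg(adjust)
  stopifnot(is.data.frame(data), value %in% names(data), group %in% names(data))
  if (!is.null(family)) stopifnot(family %in% names(data))
  fam <- if (is.null(family)) rep("all", nrow(data)) else as.character(data[[family]])
  val <- as.numeric(data[[value]])
  grp <- as.character(data[[group]])
  keep <- is.finite(val) & !is.na(grp) & !is.na(fam)
  fam <- fam[keep]; val <- val[keep]; grp <- grp[keep]
  omnibus <- list(); pairwise <- list()
  for (f in unique(fam)) {
    sel <- fam == f
    lv <- unique(grp[sel])
    groups <- lapply(lv, function(l) val[sel & grp == l])
    if (length(lv) < 2L) {
      omnibus[[f]] <- data.frame(family = f, n_groups = length(lv),
                                 n = sum(sel), H = NA_real_, p = NA_real_,
                                 stars = NA_character_)
      next
    }
    om <- kruskal_wallis(groups, mode = omnibus_mode)
    omnibus[[f]] <- data.frame(family = f, n_groups = length(lv), n = om$n,
                               H = om$H, p = om$p, stars = significance_stars(om$p))
    if (gate && (is.na(om$p) || om$p >= gate_alpha)) next
    pairs <- utils::combn(seq_along(lv), 2)
    rows <- lapply(seq_len(ncol(pairs)), function(q) {
      i <- pairs[1, q]; j <- pairs[2, q]
      rs <- rank_sum(groups[[i]], groups[[j]], mode = posthoc_mode)
      data.frame(family = f, group_a = lv[i], group_b = lv[j],
                 n_a = length(groups[[i]]), n_b = length(groups[[j]]),
                 U = rs$U, p_raw = rs$p, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$p_adj <- adjust_pvalues(tab$p_raw, method = adjust)
    tab$stars <- significance_stars(tab$p_adj)
    pairwise[[f]] <- tab
  }
  structure(
    list(
      omnibus = do.call(rbind, c(omnibus, list(make.row.names = FALSE))),
      pairwise = if (length(pairwise)) {
        do.call(rbind, c(pairwise, list(make.row.names = FALSE)))
      } else {
        data.frame(family = character(), group_a = character(),
                   group_b = character(), n_a = integer(), n_b = integer(),
                   U = numeric(), p_raw = numeric(), p_adj = numeric(),
                   stars = character())
      },
      adjust = adjust, gate = gate, gate_alpha = gate_alpha
    ),
    class = "GroupComparison"
  )
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat("<GroupComparison> omnibus (Kruskal-Wallis):\n")
  print(x$omnibus, row.names = FALSE)
  if (nrow(x$pairwise)) {
    cat(sprintf("post-hoc Wilcoxon rank-sum (adjust = %s):\n", x$adjust))
    print(x$pairwise, row.names = FALSE)
  } else {
    cat("no post-hoc tests (omnibus gate not passed)\n")
  }
  invisible(x)
}
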