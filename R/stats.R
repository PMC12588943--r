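# The study's statistical battery: rank-based k-group comparison with
# Dunn's post hoc, Spearman rank correlation (exact permutation p at small
# n), and two-way ANOVA with Tukey HSD for the experience contrast.
#
# Kruskal-Wallis, Dunn and Spearman are authored from their formulas (Dunn
# has no installed implementation; the others are cross-checked against
# base R in the test suite). The ANOVA/Tukey steps are ordinary linear-model
# fits and go through stats::lm / car::Anova / stats::TukeyHSD.

new_test_result <- function(statistic, p_value, method, ...) {
  structure(c(list(statistic = statistic, p_value = p_value, method = method),
              list(...)),
            class = "seg_test_result")
}

#' @export
print.seg_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$method, x$statistic, x$p_value))
  invisible(x)
}

# mean ranks per group plus the tie-correction term sum(t^3 - t)
rank_pieces <- function(values, groups) {
  r <- rank(values)  # mean ranks for ties
  tie_tab <- table(values)
  list(r = r, n = length(values),
       tie_term = sum(tie_tab^3 - tie_tab),
       group_ids = unique(groups))
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic
#' `H = [12 / (N(N+1)) * sum(R_g^2 / n_g) - 3(N+1)] / C` with tie
#' correction `C = 1 - sum(t^3 - t) / (N^3 - N)`, referred to a chi-square
#' distribution with k - 1 degrees of freedom. When every value is
#' identical the statistic is 0 and p = 1.
#'
#' @param values numeric vector of observations.
#' @param groups parallel vector of group labels (>= 2 distinct).
#' @return A `seg_test_result` with `statistic` (H), `p_value`, `df` and
#'   `group_sizes`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  keep <- is.finite(values)
  values <- values[keep]; groups <- groups[keep]
  k <- length(unique(groups))
  if (k < 2) stop("Kruskal-Wallis needs at least 2 groups, got ", k)
  N <- length(values)
  sizes <- table(groups)
  if (length(unique(values)) == 1) {
    return(new_test_result(0, 1, "Kruskal-Wallis rank sum test",
                           df = k - 1, group_sizes = as.integer(sizes)))
  }
  rp <- rank_pieces(values, groups)
  rank_sums <- tapply(rp$r, groups, sum)
  H <- 12 / (N * (N + 1)) * sum(rank_sums^2 / sizes[names(rank_sums)]) -
    3 * (N + 1)
  C <- 1 - rp$tie_term / (N^3 - N)
  H <- H / C
  new_test_result(H, stats::pchisq(H, df = k - 1, lower.tail = FALSE),
                  "Kruskal-Wallis rank sum test",
                  df = k - 1, group_sizes = as.integer(sizes))
}

#' Dunn's multiple-comparison post hoc test
#'
#' Pairwise z statistics on the pooled ranks,
#' `z = (Rbar_i - Rbar_j) / sqrt(V * (1/n_i + 1/n_j))` with tie-corrected
#' pooled rank variance `V = N(N+1)/12 - sum(t^3 - t) / (12(N - 1))`, and
#' two-sided normal p-values adjusted for the number of comparisons
#' (Bonferroni by default, Dunn's original choice; Holm available).
#'
#' @inheritParams kruskal_wallis
#' @param adjust multiplicity adjustment: `"bonferroni"`, `"holm"` or
#'   `"none"`.
#' @return data.frame with one row per unordered group pair: `group_a`,
#'   `group_b`, `z`, `p_raw`, `p_adjusted`, `adjustment`.
#' @export
dunn_posthoc <- function(values, groups, adjust = c("bonferroni", "holm", "none")) {
  adjust <- match.arg(adjust)
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  keep <- is.finite(values)
  values <- values[keep]; groups <- groups[keep]
  levs <- sort(unique(groups))
  if (length(levs) < 2) stop("Dunn's test needs at least 2 groups")
  rp <- rank_pieces(values, groups)
  N <- rp$n
  mean_ranks <- tapply(rp$r, groups, mean)
  sizes <- table(groups)
  V <- N * (N + 1) / 12 - rp$tie_term / (12 * (N - 1))
  pairs <- utils::combn(levs, 2)
  z <- apply(pairs, 2, function(p) {
    (mean_ranks[p[1]] - mean_ranks[p[2]]) /
      sqrt(V * (1 / sizes[p[1]] + 1 / sizes[p[2]]))
  })
  p_raw <- 2 * stats::pnorm(-abs(z))
  p_adj <- stats::p.adjust(p_raw, method = adjust)
  data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
             z = as.numeric(z), p_raw = as.numeric(p_raw),
             p_adjusted = as.numeric(p_adj), adjustment = adjust,
             stringsAsFactors = FALSE)
}

# all n! permutations of 1..n as a matrix (rows = permutations)
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(sub[, seq_len(k - 1), drop = FALSE],
          n,
          if (k <= n - 1) sub[, k:(n - 1), drop = FALSE])
  }))
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of the average-ranked data (ties receive
#' mean ranks). The two-sided p-value comes from exhaustive permutation
#' when `n <= exact_limit` (count of permutations with `|rho| >=` the
#' observed, over n!; the identity permutation guarantees p > 0), and from
#' the t approximation `t = rho * sqrt((n-2) / (1-rho^2))` otherwise.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param exact_limit largest n for which the exact permutation null is
#'   enumerated (default 9; 9! = 362,880 permutations).
#' @return A `seg_test_result` with `statistic` (rho), `p_value`, `n` and
#'   `p_method`.
#' @export
spearman_cor <- function(x, y, exact_limit = 9) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("Spearman correlation needs n >= 3")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    stop("Spearman rho is undefined for a constant vector")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_limit) {
    perms <- permutations_of(n)
    # permuting rx leaves its mean/sd fixed, so rho_perm is affine in the
    # cross-product sum
    s <- perms_cross(perms, rx, ry)
    denom <- stats::sd(rx) * stats::sd(ry) * (n - 1)
    rho_perm <- (s - n * mean(rx) * mean(ry)) / denom
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t approximation"
  }
  new_test_result(rho, p, "Spearman rank correlation",
                  n = n, p_method = method)
}

perms_cross <- function(perms, rx, ry) {
  # sum_i rx[perm[i]] * ry[i] for every permutation, vectorised
  as.numeric(matrix(rx[perms], nrow(perms)) %*% ry)
}

#' Two-way analysis of variance
#'
#' Fits `values ~ A * B` (or `A + B`) by least squares and reports F tests
#' using Type II sums of squares, appropriate for the unbalanced
#' experience design (5 high- vs 6 low-experience observers).
#'
#' @param values numeric response.
#' @param factor_a,factor_b parallel factors, >= 2 levels each.
#' @param interaction include the A:B interaction (requires every A x B
#'   cell to be occupied; an empty cell is an error naming the cell).
#' @return data.frame with columns `term`, `sum_sq`, `df`, `F`, `p_value`,
#'   attribute `ss_type = "II"`.
#' @export
two_way_anova <- function(values, factor_a, factor_b, interaction = TRUE) {
  a <- factor(factor_a); b <- factor(factor_b)
  stopifnot(length(values) == length(a), length(values) == length(b))
  if (nlevels(a) < 2 || nlevels(b) < 2)
    stop("both factors need at least 2 levels")
  if (interaction) {
    tab <- table(a, b)
    if (any(tab == 0)) {
      empty <- which(tab == 0, arr.ind = TRUE)[1, ]
      stop(sprintf("empty design cell (%s, %s): cannot fit the interaction",
                   levels(a)[empty[1]], levels(b)[empty[2]]))
    }
  }
  form <- if (interaction) values ~ a * b else values ~ a + b
  fit <- stats::lm(form, data = data.frame(values = values, a = a, b = b))
  an <- car::Anova(fit, type = 2)
  terms <- rownames(an)
  keep <- terms != "Residuals"
  label <- gsub("\\ba\\b", "factor_a", gsub("\\bb\\b", "factor_b", terms[keep]))
  out <- data.frame(term = label,
                    sum_sq = an[keep, "Sum Sq"],
                    df = an[keep, "Df"],
                    F = an[keep, "F value"],
                    p_value = an[keep, "Pr(>F)"],
                    stringsAsFactors = FALSE)
  attr(out, "ss_type") <- "II"
  attr(out, "residual_df") <- an["Residuals", "Df"]
  attr(out, "residual_sum_sq") <- an["Residuals", "Sum Sq"]
  out
}

#' Tukey honest significant difference test
#'
#' All-pairs comparisons after a one-way fit, with p-values from the
#' studentized range distribution.
#'
#' @param values numeric response.
#' @param groups parallel group labels (>= 2).
#' @return data.frame with `group_a`, `group_b`, `diff`, `q`, `p_adjusted`.
#' @export
tukey_hsd <- function(values, groups) {
  g <- factor(groups)
  stopifnot(length(values) == length(g))
  if (nlevels(g) < 2) stop("Tukey HSD needs at least 2 groups")
  fit <- stats::aov(values ~ g, data = data.frame(values = values, g = g))
  tk <- stats::TukeyHSD(fit)$g
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  mse <- sum(fit$residuals^2) / fit$df.residual
  sizes <- table(g)
  q <- vapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    se <- sqrt(mse / 2 * (1 / sizes[p[1]] + 1 / sizes[p[2]]))
    abs(tk[i, "diff"]) / se
  }, numeric(1))
  data.frame(group_a = vapply(pairs, `[`, "", 1),
             group_b = vapply(pairs, `[`, "", 2),
             diff = tk[, "diff"],
             q = q,
             p_adjusted = tk[, "p adj"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Run the full statistical battery on agreement records
#'
#' Kruskal-Wallis + Dunn across operative stages and tumour types on the
#' pairwise DSC records, Spearman correlation of per-image mean DSC
#' against per-image mean difficulty rating, and (when the design contains
#' both high- and low-experience observers) a two-way ANOVA of
#' within-band pair DSC on experience pairing x stage with Tukey HSD.
#'
#' @param records long-form records from [flatten_records()].
#' @param dataset the [study_dataset] (for difficulty ratings and design).
#' @param adjust Dunn adjustment method.
#' @return A list with elements `stage`, `tumour_type` (each a list with
#'   `omnibus` and `posthoc`), `difficulty` (`seg_test_result` or `NULL`),
#'   `experience` (list with `anova`, `tukey`, or `NULL`), and a tidy
#'   `table` (data.frame: comparison, statistic, raw and adjusted p,
#'   method).
#' @export
stats_battery <- function(records, dataset, adjust = c("bonferroni", "holm", "none")) {
  adjust <- match.arg(adjust)
  design <- dataset$design
  res <- list()
  for (fac in c("stage", "tumour_type")) {
    res[[fac]] <- list(omnibus = kruskal_wallis(records$dsc, records[[fac]]),
                       posthoc = dunn_posthoc(records$dsc, records[[fac]], adjust))
  }
  res$difficulty <- NULL
  if (nrow(dataset$difficulty)) {
    img_dsc <- tapply(records$dsc, records$image_id, mean)
    img_diff <- tapply(dataset$difficulty$rating, dataset$difficulty$image_id, mean)
    common <- intersect(names(img_dsc), names(img_diff))
    if (length(common) >= 3 &&
        length(unique(img_dsc[common])) > 1 &&
        length(unique(img_diff[common])) > 1)
      res$difficulty <- spearman_cor(img_dsc[common], img_diff[common])
  }
  res$experience <- NULL
  flag <- experience_flag(design)
  fa <- flag[records$observer_a]; fb <- flag[records$observer_b]
  keep <- !is.na(fa) & !is.na(fb) & fa == fb
  if (any(keep) && length(unique(fa[keep])) == 2 &&
      length(unique(records$stage[keep])) >= 2) {
    sub <- records[keep, , drop = FALSE]
    res$experience <- list(
      anova = two_way_anova(sub$dsc, fa[keep], sub$stage),
      tukey = tukey_hsd(sub$dsc, paste(fa[keep], sub$stage, sep = ":")))
  }
  res$table <- battery_table(res, adjust)
  res
}

battery_table <- function(res, adjust) {
  rows <- list()
  for (fac in c("stage", "tumour_type")) {
    om <- res[[fac]]$omnibus
    rows[[length(rows) + 1]] <- data.frame(
      comparison = paste0(fac, " (omnibus)"), statistic = om$statistic,
      p_raw = om$p_value, p_adjusted = NA_real_,
      method = "Kruskal-Wallis", stringsAsFactors = FALSE)
    ph <- res[[fac]]$posthoc
    rows[[length(rows) + 1]] <- data.frame(
      comparison = paste(fac, ph$group_a, "vs", ph$group_b),
      statistic = ph$z, p_raw = ph$p_raw, p_adjusted = ph$p_adjusted,
      method = paste0("Dunn (", adjust, ")"), stringsAsFactors = FALSE)
  }
  if (!is.null(res$difficulty)) {
    d <- res$difficulty
    rows[[length(rows) + 1]] <- data.frame(
      comparison = "mean DSC vs mean difficulty (per image)",
      statistic = d$statistic, p_raw = d$p_value, p_adjusted = NA_real_,
      method = paste0("Spearman (", d$p_method, ")"), stringsAsFactors = FALSE)
  }
  if (!is.null(res$experience)) {
    an <- res$experience$anova
    rows[[length(rows) + 1]] <- data.frame(
      comparison = paste("experience ANOVA:", an$term),
      statistic = an$F, p_raw = an$p_value, p_adjusted = NA_real_,
      method = "two-way ANOVA (type II)", stringsAsFactors = FALSE)
    tk <- res$experience$tukey
    rows[[length(rows) + 1]] <- data.frame(
      comparison = paste("experience Tukey:", tk$group_a, "vs", tk$group_b),
      statistic = tk$q, p_raw = NA_real_, p_adjusted = tk$p_adjusted,
      method = "Tukey HSD", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
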