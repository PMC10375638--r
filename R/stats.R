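#' Kruskal-Wallis omnibus test on grouped fit results
#'
#' Rank-based multi-group comparison (tie-corrected H statistic, chi-squared
#' approximation with k-1 degrees of freedom), as used to compare BINDING or
#' FRET efficiency across samples.
#'
#' @param data Data frame with one row per ROI result.
#' @param value Column to compare (unquoted), e.g. `binding` or `efficiency`.
#' @param group Grouping column (unquoted), e.g. `sample`.
#' @return A one-row tibble: `statistic` (H), `df`, `p_value`, `n_groups`,
#'   `n_obs`.
#' @examples
#' df <- data.frame(sample = rep(c("a", "b"), each = 3),
#'                  binding = c(1, 2, 3, 4, 5, 6))
#' kw_test(df, binding, sample)
#' @export
kw_test <- function(data, value, group) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- as.factor(rlang::eval_tidy(rlang::enquo(group), data))
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2L) abort_input("need at least 2 nonempty groups")
  if (any(table(g) < 1L)) abort_input("every group needs >= 1 observation")
  if (length(unique(v)) == 1L) {
    # no rank variation at all: H = 0 by convention, nothing to test
    return(tibble(statistic = 0, df = nlevels(g) - 1L, p_value = 1,
                  n_groups = nlevels(g), n_obs = length(v)))
  }
  kt <- kruskal.test(v, g)
  tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p_value = kt$p.value, n_groups = nlevels(g), n_obs = length(v))
}

# Fisher's LSD on Kruskal-Wallis rank means (Conover): pair (i, j) differs if
# |Rbar_i - Rbar_j| > t_{1-a/2, N-k} * sqrt(S^2 (N-1-H)/(N-k) (1/n_i + 1/n_j)),
# protected by the omnibus test at the same alpha.
lsd_pairwise <- function(v, g, alpha) {
  r <- rank(v)
  n <- tapply(r, g, length)
  rbar <- tapply(r, g, mean)
  N <- length(v); k <- nlevels(g)
  H <- unname(kruskal.test(v, g)$statistic)
  S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  crit <- qt(1 - alpha / 2, df = N - k)
  lev <- levels(g)
  sig <- matrix(FALSE, k, k, dimnames = list(lev, lev))
  diffmat <- matrix(0, k, k, dimnames = list(lev, lev))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      d <- abs(rbar[i] - rbar[j])
      se <- sqrt(S2 * (N - 1 - H) / (N - k) * (1 / n[i] + 1 / n[j]))
      s <- is.finite(se) && se > 0 && d > crit * se
      sig[i, j] <- sig[j, i] <- s
      diffmat[i, j] <- diffmat[j, i] <- d
    }
  }
  list(significant = sig, rank_mean_diff = diffmat, rank_means = rbar, n = n,
       H = H)
}

# Compact letter display from a "not significantly different" adjacency:
# letters are the maximal cliques of the nonsig graph, ordered by rank mean,
# so two groups share a letter iff they are not significantly different.
cld_from_adjacency <- function(nonsig, order_by) {
  k <- nrow(nonsig)
  stopifnot(k <= 20)  # exhaustive subset enumeration
  cliques <- list()
  for (code in seq_len(2^k - 1)) {
    members <- which(bitwAnd(code, 2^(seq_len(k) - 1)) > 0)
    if (all(nonsig[members, members])) cliques <- c(cliques, list(members))
  }
  is_max <- vapply(seq_along(cliques), function(i) {
    !any(vapply(seq_along(cliques), function(j) {
      i != j && all(cliques[[i]] %in% cliques[[j]])
    }, logical(1)))
  }, logical(1))
  cliques <- cliques[is_max]
  cliques <- cliques[order(vapply(cliques, function(m) min(order_by[m]),
                                  numeric(1)))]
  letters_out <- rep("", k)
  for (i in seq_along(cliques)) {
    letters_out[cliques[[i]]] <- paste0(letters_out[cliques[[i]]], letters[i])
  }
  letters_out
}

#' Compact letter display from protected Fisher's LSD on ranks
#'
#' Pairwise comparisons of Kruskal-Wallis rank means using the least
#' significant difference criterion (Conover), protected by the omnibus test:
#' when the Kruskal-Wallis p-value is at or above `alpha`, all groups share
#' one letter. Groups sharing a letter are not significantly different.
#'
#' @inheritParams kw_test
#' @param alpha Significance level (default 0.05).
#' @return A tibble: `group`, `letter`, `rank_mean`, `n`, ordered by
#'   decreasing rank mean within the input's factor order.
#' @export
lsd_letters <- function(data, value, group, alpha = 0.05) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- as.factor(rlang::eval_tidy(rlang::enquo(group), data))
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2L) abort_input("need at least 2 nonempty groups")
  p_omnibus <- if (length(unique(v)) == 1L) 1 else kruskal.test(v, g)$p.value
  pw <- lsd_pairwise(v, g, alpha)
  if (p_omnibus >= alpha) {
    lett <- rep("a", nlevels(g))
  } else {
    lett <- cld_from_adjacency(!pw$significant, order_by = pw$rank_means)
  }
  tibble(group = levels(g), letter = lett,
         rank_mean = as.double(pw$rank_means), n = as.integer(pw$n))
}

#' Cut-off-filtered group summary table
#'
#' Per-group summary in the reporting convention of the method: BINDING
#' statistics over all results, FRET-efficiency statistics only over results
#' with a valid efficiency (BINDING at or above the cut-off; strictly-below
#' values are removed). SE is the sample SD (n-1 denominator) divided by
#' sqrt(n). Groups whose results all fall below the cut-off report `NA`
#' efficiency columns.
#'
#' @param data Data frame of fit results with columns `binding`, `efficiency`
#'   and (preferably) `valid_efficiency`; when `valid_efficiency` is absent it
#'   is derived as `binding >= cutoff`.
#' @param group Grouping column (unquoted).
#' @param cutoff Fallback BINDING cut-off when `valid_efficiency` is absent.
#' @return A tibble: `group`, `n`, `n_above_cutoff`, `mean_B`, `sd_B`, `se_B`,
#'   `mean_E`, `sd_E`, `se_E`.
#' @export
summary_table <- function(data, group, cutoff = 0.10) {
  g_quo <- rlang::enquo(group)
  if (!"valid_efficiency" %in% names(data)) {
    data <- apply_fret_cutoff(data, cutoff)
  }
  se <- function(x) sd(x) / sqrt(length(x))
  data |>
    dplyr::group_by(group = as.character(!!g_quo)) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_above_cutoff = sum(.data$valid_efficiency, na.rm = TRUE),
      mean_B = mean(.data$binding),
      sd_B = sd(.data$binding),
      se_B = se(.data$binding),
      mean_E = if (any(.data$valid_efficiency, na.rm = TRUE))
        mean(.data$efficiency[.data$valid_efficiency]) else NA_real_,
      sd_E = if (sum(.data$valid_efficiency, na.rm = TRUE) > 1)
        sd(.data$efficiency[.data$valid_efficiency]) else NA_real_,
      se_E = if (sum(.data$valid_efficiency, na.rm = TRUE) > 1)
        se(.data$efficiency[.data$valid_efficiency]) else NA_real_,
      .groups = "drop")
}

#' Paired acceptor-photobleaching comparison
#'
#' Wilcoxon signed-rank test on per-ROI BINDING differences between a
#' pre-bleach and a post-bleach measurement of the same ROIs (exact p-value
#' for n <= 25 when there are no zero differences or ties). Bleaching the
#' acceptor abolishes FRET, so BINDING is expected to drop; the default
#' alternative is one-sided (`after < before`).
#'
#' @param before,after Data frames with columns `roi_id` and `binding`; ROI
#'   sets must match one-to-one.
#' @param alternative Passed to [stats::wilcox.test()]; default `"less"`
#'   (BINDING decreases after bleaching).
#' @return A list with `summary` (one-row tibble: `statistic`, `p_value`,
#'   `n_pairs`, `method`) and `deltas` (tibble: `roi_id`, `before`, `after`,
#'   `delta`). When all differences are zero the comparison is degenerate and
#'   reported as no change with `p_value = 1`.
#' @export
paired_bleach_test <- function(before, after, alternative = "less") {
  for (nm in list(before, after)) {
    if (!all(c("roi_id", "binding") %in% names(nm))) {
      abort_input("before/after need columns roi_id and binding")
    }
  }
  orphans <- c(setdiff(before$roi_id, after$roi_id),
               setdiff(after$roi_id, before$roi_id))
  if (length(orphans) > 0) {
    abort_input(paste0("unmatched roi_id(s): ",
                       paste(unique(orphans), collapse = ", ")))
  }
  b <- before[order(before$roi_id), ]
  a <- after[order(after$roi_id), ]
  deltas <- tibble(roi_id = b$roi_id, before = b$binding, after = a$binding,
                   delta = a$binding - b$binding)
  if (all(deltas$delta == 0)) {
    return(list(summary = tibble(statistic = NA_real_, p_value = 1,
                                 n_pairs = nrow(deltas),
                                 method = "degenerate: no change"),
                deltas = deltas))
  }
  wt <- suppressWarnings(
    wilcox.test(deltas$delta, mu = 0, alternative = alternative,
                exact = nrow(deltas) <= 25))
  list(summary = tibble(statistic = unname(wt$statistic),
                        p_value = wt$p.value, n_pairs = nrow(deltas),
                        method = wt$method),
       deltas = deltas)
}

#' BINDING versus acceptor-concentration correlation
#'
#' Spearman rank correlation of fitted BINDING against the acceptor-channel
#' photon count per ROI (a concentration proxy); rows without an acceptor
#' count are skipped and counted. Pearson is available for cross-checks.
#'
#' @param data Data frame with columns `binding` and `acceptor_photons`.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return A one-row tibble: `rho`, `p_value`, `n_used`, `n_skipped`.
#' @export
binding_acceptor_correlation <- function(data,
                                         method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (!all(c("binding", "acceptor_photons") %in% names(data))) {
    abort_input("data needs columns binding and acceptor_photons")
  }
  usable <- is.finite(data$binding) & is.finite(data$acceptor_photons)
  if (sum(usable) < 3L) {
    abort_input("need at least 3 results with acceptor photon counts")
  }
  ct <- suppressWarnings(
    cor.test(data$binding[usable], data$acceptor_photons[usable],
             method = method))
  tibble(rho = unname(ct$estimate), p_value = ct$p.value,
         n_used = sum(usable), n_skipped = sum(!usable))
}

#' Full group comparison report
#'
#' Bundles the Kruskal-Wallis omnibus test, the protected-LSD compact letter
#' display and the cut-off-filtered summary table, and verifies that the
#' letter display is consistent with the pairwise decisions.
#'
#' @inheritParams kw_test
#' @param alpha Significance level for omnibus and pairwise tests.
#' @param cutoff BINDING cut-off used when `valid_efficiency` is absent.
#' @return A list of class `comparison_report`: `omnibus`, `letters`,
#'   `pairwise` (logical matrix of significant differences), `summaries`.
#' @export
comparison_report <- function(data, value, group, alpha = 0.05,
                              cutoff = 0.10) {
  v_quo <- rlang::enquo(value); g_quo <- rlang::enquo(group)
  omnibus <- kw_test(data, !!v_quo, !!g_quo)
  lett <- lsd_letters(data, !!v_quo, !!g_quo, alpha = alpha)
  v <- rlang::eval_tidy(v_quo, data)
  g <- droplevels(as.factor(rlang::eval_tidy(g_quo, data)))
  pw <- lsd_pairwise(v[!is.na(v)], g[!is.na(v)], alpha)
  sig <- if (omnibus$p_value >= alpha)
    matrix(FALSE, nlevels(g), nlevels(g),
           dimnames = list(levels(g), levels(g)))
  else pw$significant
  # letters consistent with pairwise decisions, by construction; verify
  share <- outer(lett$letter, lett$letter,
                 Vectorize(function(x, y) {
                   any(strsplit(x, "")[[1]] %in% strsplit(y, "")[[1]])
                 }))
  diag(share) <- TRUE
  stopifnot(all(share[!sig & upper.tri(sig)]), all(!share[sig]))
  summaries <- summary_table(data, !!g_quo, cutoff = cutoff)
  structure(list(omnibus = omnibus, letters = lett, pairwise = sig,
                 summaries = summaries, alpha = alpha),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> Kruskal-Wallis H = %.3f, df = %d, p = %.3g\n",
              x$omnibus$statistic, x$omnibus$df, x$omnibus$p_value))
  cat("Letters (protected Fisher's LSD on ranks, alpha ", x$alpha, "):\n",
      sep = "")
  print(x$letters, ...)
  cat("Summaries:\n")
  print(x$summaries, ...)
  invisible(x)
}
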