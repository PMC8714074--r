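# Nonparametric multi-condition statistics over extracted kernel parameters:
# omnibus Kruskal-Wallis across conditions, pairwise Mann-Whitney U with
# Benjamini-Hochberg correction, percent change of medians, and a compact
# letter display for figure-style significance groups.

#' Kruskal-Wallis omnibus test
#'
#' Tie-corrected rank-based H statistic across `k` groups with
#' `df = k - 1` and a chi-square p value (delegates to
#' [stats::kruskal.test()]).
#'
#' @param groups Named list of numeric vectors, one per condition.
#' @return List with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) == 0))
    stop("need >= 2 nonempty groups", call. = FALSE)
  vals <- unlist(groups, use.names = FALSE)
  if (length(unique(vals)) == 1)
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = unname(kt$p.value))
}

#' Pairwise Mann-Whitney U tests with Benjamini-Hochberg correction
#'
#' Two-sided tests for every requested pair of groups: exact when both
#' samples are small (n <= `exact_max`) and tie-free, normal approximation
#' with tie correction otherwise (delegates to [stats::wilcox.test()]).
#' Raw p values are adjusted across the tested pairs by the
#' Benjamini-Hochberg step-up procedure ([stats::p.adjust()]).
#'
#' @param groups Named list of numeric vectors.
#' @param pairs Two-column character matrix (or list of length-2 vectors) of
#'   group names to compare; default all pairs.
#' @param alpha Significance threshold on the adjusted p (default 0.05).
#' @param exact_max Largest per-group n for which the exact distribution is
#'   used (default 12).
#' @return Data frame with columns `group1`, `group2`, `U`, `p_raw`,
#'   `p_adj`, `significant`.
#' @export
pairwise_mwu_bh <- function(groups, pairs = NULL, alpha = 0.05,
                            exact_max = 12) {
  nms <- names(groups)
  if (is.null(nms)) stop("'groups' must be named", call. = FALSE)
  if (is.null(pairs)) {
    pairs <- t(utils::combn(nms, 2))
  } else if (is.list(pairs)) {
    pairs <- do.call(rbind, pairs)
  }
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    x <- groups[[pairs[i, 1]]]
    y <- groups[[pairs[i, 2]]]
    if (length(x) == 0 || length(y) == 0)
      stop(sprintf("empty group in pair (%s, %s)", pairs[i, 1], pairs[i, 2]),
           call. = FALSE)
    ties <- anyDuplicated(c(x, y)) > 0
    use_exact <- !ties && length(x) <= exact_max && length(y) <= exact_max
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, exact = use_exact, correct = !use_exact))
    data.frame(group1 = pairs[i, 1], group2 = pairs[i, 2],
               U = unname(wt$statistic), p_raw = unname(wt$p.value),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p_raw, method = "BH")
  out$significant <- out$p_adj < alpha
  out
}

#' Percent change of a median relative to a reference
#'
#' `100 * (experimental - reference) / reference`; a zero reference is
#' flagged as undefined (`NA` with a warning) rather than infinite.
#'
#' @param median_experimental,median_reference Medians of the experimental
#'   and reference conditions.
#' @return Percent change (positive = increase).
#' @export
percent_change <- function(median_experimental, median_reference) {
  if (isTRUE(median_reference == 0)) {
    warning("reference median is zero; percent change undefined",
            call. = FALSE)
    return(NA_real_)
  }
  100 * (median_experimental - median_reference) / median_reference
}

#' Compact letter display from a pairwise significance table
#'
#' Greedy assignment of letters such that groups sharing a letter are not
#' significantly different in the table. Presentation plumbing for
#' figure-style "a/b/c" annotations; greedy, so not guaranteed to be the
#' minimal letter set.
#'
#' @param pairwise Output of [pairwise_mwu_bh()].
#' @param group_names Group names in display order; default the names
#'   appearing in `pairwise`.
#' @return Named character vector of letter strings.
#' @export
letter_groups <- function(pairwise, group_names = NULL) {
  if (is.null(group_names))
    group_names <- unique(c(pairwise$group1, pairwise$group2))
  differs <- function(a, b) {
    hit <- (pairwise$group1 == a & pairwise$group2 == b) |
      (pairwise$group1 == b & pairwise$group2 == a)
    any(pairwise$significant[hit])
  }
  classes <- list()  # each element: character vector of compatible groups
  for (g in group_names) {
    placed <- FALSE
    for (i in seq_along(classes)) {
      if (!any(vapply(classes[[i]], function(m) differs(g, m), logical(1)))) {
        classes[[i]] <- c(classes[[i]], g)
        placed <- TRUE
      }
    }
    if (!placed) classes[[length(classes) + 1L]] <- g
  }
  letters_used <- letters[seq_along(classes)]
  out <- vapply(group_names, function(g) {
    paste(letters_used[vapply(classes, function(cl) g %in% cl, logical(1))],
          collapse = "")
  }, character(1))
  names(out) <- group_names
  out
}

#' Run the full parameter statistics over a tidy parameter table
#'
#' For each kernel parameter: an omnibus Kruskal-Wallis test across all
#' conditions present, and pairwise Mann-Whitney U tests with BH correction
#' within each comparison panel (condition family).
#'
#' @param param_table Data frame as produced by the pipeline (columns
#'   `neuron_id`, `condition`, `amplitude`, `ttp_ms`, `half_width_ms`,
#'   `decay_ms`, `return_to_baseline_ms`, `spike_rate_hz`).
#' @param panels Named list of condition-label vectors defining the BH
#'   families; default one panel containing all conditions.
#' @param parameters Parameter columns to analyse.
#' @return List with `omnibus` (data frame: parameter, H, df, p) and
#'   `pairwise` (data frame with parameter and panel columns added).
#' @export
param_stats <- function(param_table,
                        panels = NULL,
                        parameters = c("amplitude", "ttp_ms",
                                       "half_width_ms", "decay_ms",
                                       "return_to_baseline_ms",
                                       "spike_rate_hz")) {
  conds <- unique(param_table$condition)
  if (is.null(panels)) panels <- list(all = conds)
  omnibus <- NULL
  pairwise <- NULL
  for (p in parameters) {
    groups <- lapply(conds, function(cc) {
      v <- param_table[[p]][param_table$condition == cc]
      v[is.finite(v)]
    })
    names(groups) <- conds
    groups <- groups[lengths(groups) > 0]
    if (length(groups) >= 2) {
      kw <- kruskal_wallis(groups)
      omnibus <- rbind(omnibus, data.frame(
        parameter = p, H = kw$H, df = kw$df, p = kw$p,
        stringsAsFactors = FALSE))
    }
    for (panel_name in names(panels)) {
      pg <- groups[intersect(panels[[panel_name]], names(groups))]
      if (length(pg) < 2) next
      pw <- pairwise_mwu_bh(pg)
      pw$parameter <- p
      pw$panel <- panel_name
      pairwise <- rbind(pairwise, pw)
    }
  }
  list(omnibus = omnibus, pairwise = pairwise)
}
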