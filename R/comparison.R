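#' Map raw stimulus names to broad categories
#'
#' Groups stimulus epochs into five broad categories of increasing putative
#' meaningfulness: no stimulus (gray screen / spontaneous), simple
#' artificial (full-field flashes, Gabor patches), time-shuffled movies,
#' complex artificial (static and drifting gratings), and natural movies.
#'
#' @param epochs Data frame with a `stimulus` column of raw stimulus names.
#' @return The epochs with an added `category` factor column with levels
#'   `none < simple_artificial < shuffled < complex_artificial < natural`.
#' @export
assign_categories <- function(epochs) {
  map <- c(
    gray = "none", spontaneous = "none",
    flashes = "simple_artificial", gabor = "simple_artificial",
    gabors = "simple_artificial",
    shuffled_movie = "shuffled", natural_movie_shuffled = "shuffled",
    static_gratings = "complex_artificial",
    drifting_gratings = "complex_artificial",
    natural_movie = "natural", natural_like = "natural",
    natural_scenes = "natural"
  )
  nm <- tolower(epochs$stimulus)
  unknown <- unique(nm[!nm %in% names(map)])
  if (length(unknown)) {
    stop("unmapped stimulus name(s): ", paste(unknown, collapse = ", "))
  }
  epochs$category <- factor(
    unname(map[nm]),
    levels = c("none", "simple_artificial", "shuffled",
               "complex_artificial", "natural"),
    ordered = TRUE
  )
  epochs
}

#' Subsample units without replacement
#'
#' Uniform random subsample, reproducible under a seed; used to match
#' aggregate-area ensembles to the typical size of individual areas before
#' comparing their differentiation.
#'
#' @param unit_ids Vector of unit identifiers.
#' @param target_n Number of units to keep.
#' @param seed Integer seed (the global RNG state is left untouched).
#' @return Subset of `unit_ids` of length `target_n`, in original order.
#' @export
subsample_units <- function(unit_ids, target_n, seed) {
  if (target_n > length(unit_ids)) {
    stop(sprintf("target_n = %d exceeds ensemble size %d", target_n, length(unit_ids)))
  }
  idx <- withr::with_seed(seed, sample.int(length(unit_ids), target_n))
  unit_ids[sort(idx)]
}

#' Games-Howell pairwise comparisons
#'
#' Post-hoc pairwise test for unequal variances and sample sizes: for each
#' pair of groups a Welch-type statistic with Welch-Satterthwaite degrees
#' of freedom is referred to the studentized-range distribution with as
#' many means as there are groups.
#'
#' @param values Numeric vector of observations.
#' @param groups Grouping vector of the same length (>= 2 groups, each with
#'   at least 3 observations and nonzero variance; degenerate pairs get an
#'   `NA` p-value with a warning).
#' @return Tibble with one row per unordered pair: `group_a`, `group_b`,
#'   `diff` (mean_a - mean_b), `se`, `t`, `df`, `p`.
#' @export
games_howell <- function(values, groups) {
  groups <- as.character(groups)
  g <- split(values, groups)
  k <- length(g)
  if (k < 2) stop("need at least 2 groups")
  means <- vapply(g, mean, numeric(1))
  vars <- vapply(g, stats::var, numeric(1))
  ns <- lengths(g)
  labs <- names(g)
  degenerate <- ns < 3 | vars == 0 | is.na(vars)
  if (any(degenerate)) {
    warning("degenerate group(s) (n < 3 or zero variance): ",
            paste(labs[degenerate], collapse = ", "))
  }
  pairs <- utils::combn(k, 2)
  rows <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    if (degenerate[i] || degenerate[j]) {
      return(tibble::tibble(group_a = labs[i], group_b = labs[j],
                            diff = unname(means[i] - means[j]), se = NA_real_,
                            t = NA_real_, df = NA_real_, p = NA_real_))
    }
    vi <- vars[i] / ns[i]
    vj <- vars[j] / ns[j]
    se <- sqrt(vi + vj)
    tstat <- (means[i] - means[j]) / se
    df <- (vi + vj)^2 / (vi^2 / (ns[i] - 1) + vj^2 / (ns[j] - 1))
    p <- stats::ptukey(abs(tstat) * sqrt(2), nmeans = k, df = df,
                       lower.tail = FALSE)
    tibble::tibble(group_a = labs[i], group_b = labs[j],
                   diff = unname(means[i] - means[j]), se = unname(se),
                   t = unname(tstat), df = unname(df), p = unname(p))
  })
  dplyr::bind_rows(rows)
}

#' Benjamini-Hochberg step-up correction
#'
#' Standard false-discovery-rate step-up procedure: the i-th smallest of m
#' p-values is rejected when it is at most `i * alpha / m` (and so are all
#' smaller ones); adjusted p-values are the step-up envelope
#' `min over j >= i of m * p_(j) / j`, capped at 1.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\] (`NA`s kept as `NA`).
#' @param alpha Target false discovery rate (default 0.05).
#' @return Tibble with columns `p`, `p_adj`, `reject`.
#' @export
benjamini_hochberg <- function(pvals, alpha = 0.05) {
  if (!length(pvals)) {
    return(tibble::tibble(p = numeric(0), p_adj = numeric(0),
                          reject = logical(0)))
  }
  stopifnot(all(is.na(pvals) | (pvals >= 0 & pvals <= 1)))
  p_adj <- stats::p.adjust(pvals, method = "BH")
  tibble::tibble(p = pvals, p_adj = p_adj,
                 reject = !is.na(p_adj) & p_adj <= alpha)
}

#' Significance stars for adjusted p-values
#'
#' Three-level convention: `*` for p < 0.01, `**` for p < 0.001, `***` for
#' p < 0.0001; empty otherwise.
#'
#' @param p_adj Numeric vector of (adjusted) p-values.
#' @return Character vector of star strings.
#' @export
significance_stars <- function(p_adj) {
  out <- rep("", length(p_adj))
  out[!is.na(p_adj) & p_adj < 0.01] <- "*"
  out[!is.na(p_adj) & p_adj < 0.001] <- "**"
  out[!is.na(p_adj) & p_adj < 0.0001] <- "***"
  out
}

#' Compare differentiation across groups
#'
#' Games-Howell pairwise tests on window-level differentiation samples
#' grouped by a label (stimulus category, area, layer, ...), with
#' Benjamini-Hochberg adjustment across the pairs and the three-level star
#' convention applied to adjusted p-values.
#'
#' @param values Window-level differentiation values.
#' @param groups Group label per value.
#' @param alpha False-discovery-rate level (default 0.01).
#' @return An object of class `comparison_result`: tibble of pairwise rows
#'   `group_a`, `group_b`, `diff`, `p_raw`, `p_adj`, `reject`, `stars`,
#'   with per-group summaries in attribute `group_summary`.
#' @export
compare_groups <- function(values, groups, alpha = 0.01) {
  gh <- games_howell(values, groups)
  bh <- benjamini_hochberg(gh$p, alpha = alpha)
  out <- tibble::tibble(
    group_a = gh$group_a, group_b = gh$group_b, diff = gh$diff,
    p_raw = gh$p, p_adj = bh$p_adj, reject = bh$reject,
    stars = significance_stars(bh$p_adj)
  )
  gs <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(value = values, group = as.character(groups)),
                    .data$group),
    n = dplyr::n(), mean = mean(.data$value), sd = stats::sd(.data$value),
    .groups = "drop"
  )
  attr(out, "group_summary") <- gs
  class(out) <- c("comparison_result", class(out))
  out
}

#' Label analysis windows as running or stationary
#'
#' A window is "running" when the mean running speed over the window is at
#' least `threshold`, "stationary" otherwise; windows without any speed
#' sample are labeled "unknown".
#'
#' @param windows Data frame with columns `start_s`, `end_s` (half-open).
#' @param speed Data frame with columns `time_s`, `speed_cm_s`.
#' @param threshold Running threshold in cm/s (default 2).
#' @return Character vector, one label per window row.
#' @export
partition_by_running <- function(windows, speed, threshold = 2) {
  vapply(seq_len(nrow(windows)), function(i) {
    sel <- speed$time_s >= windows$start_s[i] & speed$time_s < windows$end_s[i]
    if (!any(sel)) return("unknown")
    if (mean(speed$speed_cm_s[sel]) >= threshold) "running" else "stationary"
  }, character(1))
}

#' Hit/miss contrasts of evoked differentiation and firing rate
#'
#' For each ensemble, contrasts trial-level evoked differentiation (and, in
#' parallel, mean firing rate) between hit and miss trials with a Welch
#' two-sample test; p-values are Benjamini-Hochberg adjusted across
#' ensembles (separately for the two measures). Ensembles with fewer than
#' `min_trials` trials of either outcome are skipped with a warning.
#'
#' @param trials Data frame with columns `ensemble`, `outcome` (`"hit"` /
#'   `"miss"`), `nd`, and optionally `mean_rate`.
#' @param alpha False-discovery-rate level (default 0.01).
#' @param min_trials Minimum trials per outcome (default 3).
#' @return Tibble with one row per tested ensemble: `ensemble`, `n_hit`,
#'   `n_miss`, `nd_diff` (hit - miss), `nd_p`, `nd_p_adj`, `nd_reject`,
#'   `nd_stars`, and the `rate_*` analogues when `mean_rate` is present.
#' @export
hit_miss_contrast <- function(trials, alpha = 0.01, min_trials = 3) {
  has_rate <- "mean_rate" %in% names(trials)
  rows <- lapply(split(trials, trials$ensemble), function(tr) {
    hit <- tr[tr$outcome == "hit", ]
    miss <- tr[tr$outcome == "miss", ]
    if (nrow(hit) < min_trials || nrow(miss) < min_trials) {
      warning(sprintf(
        "ensemble '%s' skipped: %d hit / %d miss trials (need >= %d each)",
        tr$ensemble[1], nrow(hit), nrow(miss), min_trials
      ))
      return(NULL)
    }
    wt <- stats::t.test(hit$nd, miss$nd)
    out <- tibble::tibble(
      ensemble = tr$ensemble[1], n_hit = nrow(hit), n_miss = nrow(miss),
      nd_diff = mean(hit$nd) - mean(miss$nd), nd_p = wt$p.value
    )
    if (has_rate) {
      wr <- stats::t.test(hit$mean_rate, miss$mean_rate)
      out$rate_diff <- mean(hit$mean_rate) - mean(miss$mean_rate)
      out$rate_p <- wr$p.value
    }
    out
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) return(out)
  bh <- benjamini_hochberg(out$nd_p, alpha = alpha)
  out$nd_p_adj <- bh$p_adj
  out$nd_reject <- bh$reject
  out$nd_stars <- significance_stars(bh$p_adj)
  if (has_rate) {
    bh2 <- benjamini_hochberg(out$rate_p, alpha = alpha)
    out$rate_p_adj <- bh2$p_adj
    out$rate_reject <- bh2$reject
    out$rate_stars <- significance_stars(bh2$p_adj)
  }
  out
}
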