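#' Aggregate per-trial indicators to one row per subject and hand
#'
#' Takes the arithmetic mean of each indicator over a subject's (up to two)
#' trials, so the analysis does not rest on a single sample. A subject with a
#' single usable trial passes through with `single_trial = TRUE`; an
#' indicator missing in one trial is averaged over the available trials;
#' subjects with zero usable trials are dropped with a warning.
#'
#' @param trials data.frame as returned by [extract_cohort()] (columns
#'   `subject_id`, `group`, `hand`, `trial`, then indicator columns).
#' @param meta optional per-subject metadata (clinical scores) merged by
#'   `subject_id` (and `hand` if present).
#' @return data.frame, one row per subject x hand: descriptors,
#'   `single_trial` flag, indicator columns, then any metadata columns.
#' @export
aggregate_trials <- function(trials, meta = NULL) {
  ind_cols <- intersect(indicator_names(), names(trials))
  if (!length(ind_cols)) stop("no indicator columns found")
  key <- interaction(trials$subject_id, trials$hand, drop = TRUE)
  rows <- lapply(split(trials, key), function(d) {
    vals <- vapply(ind_cols, function(cn) mean(d[[cn]], na.rm = TRUE), numeric(1))
    vals[is.nan(vals)] <- NA_real_
    cbind(data.frame(subject_id = d$subject_id[1], group = d$group[1],
                     hand = d$hand[1], single_trial = nrow(d) < 2),
          as.data.frame(as.list(vals), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  dropped <- setdiff(unique(trials$subject_id), out$subject_id)
  if (length(dropped))
    warning("subjects dropped (no usable trials): ",
            paste(dropped, collapse = ", "))
  if (!is.null(meta)) {
    by <- intersect(c("subject_id", "hand"), names(meta))
    keep <- c(by, setdiff(names(meta), names(out)))
    out <- merge(out, meta[!duplicated(meta[by]), keep, drop = FALSE],
                 by = by, all.x = TRUE, sort = FALSE)
  }
  out
}

#' Normality-gated between-group comparison of every indicator
#'
#' For each indicator: Lilliefors (Kolmogorov-Smirnov) normality test at
#' `alpha_normality` in each group; when both groups look normal an unpaired
#' two-sided t-test is used and groups are summarized as mean +/- sd,
#' otherwise a two-sided Mann-Whitney test with median (IQR) summaries. No
#' multiplicity correction is applied by default, mirroring common reporting
#' practice; set `p_adjust = "BH"` for Benjamini-Hochberg.
#'
#' @param table a subject-level table from [aggregate_trials()].
#' @param alpha_normality normality-gate level.
#' @param p_adjust `"none"` or a method for [stats::p.adjust()].
#' @return data.frame: `indicator`, `test` (`"t"` or `"mann_whitney"`),
#'   `summary_PD`, `summary_control`, `estimate_PD`, `estimate_control`
#'   (mean or median per branch), `p_value`.
#' @export
between_group <- function(table, alpha_normality = 0.05, p_adjust = "none") {
  stopifnot(all(c("group") %in% names(table)))
  g <- table$group
  if (min(table(g)) < 3) stop("need >= 3 subjects per group")
  ind_cols <- intersect(indicator_names(), names(table))
  res <- lapply(ind_cols, function(cn) {
    x <- table[[cn]][g == "PD"]
    y <- table[[cn]][g == "control"]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 3 || length(y) < 3) return(NULL)
    if (sd_pop(x) == 0 && sd_pop(y) == 0) return(NULL)  # constant indicator
    normal <- sd_pop(x) > 0 && sd_pop(y) > 0 &&
      nortest::lillie.test(x)$p.value > alpha_normality &&
      nortest::lillie.test(y)$p.value > alpha_normality
    if (normal) {
      p <- stats::t.test(x, y, var.equal = FALSE)$p.value
      data.frame(indicator = cn, test = "t",
                 summary_PD = sprintf("%.3g ± %.3g", mean(x), stats::sd(x)),
                 summary_control = sprintf("%.3g ± %.3g", mean(y), stats::sd(y)),
                 estimate_PD = mean(x), estimate_control = mean(y), p_value = p)
    } else {
      p <- stats::wilcox.test(x, y, exact = FALSE)$p.value
      data.frame(indicator = cn, test = "mann_whitney",
                 summary_PD = sprintf("%.3g (%.3g)", stats::median(x), stats::IQR(x)),
                 summary_control = sprintf("%.3g (%.3g)", stats::median(y), stats::IQR(y)),
                 estimate_PD = stats::median(x), estimate_control = stats::median(y),
                 p_value = p)
    }
  })
  out <- do.call(rbind, res)
  if (p_adjust != "none") out$p_value <- stats::p.adjust(out$p_value, p_adjust)
  rownames(out) <- NULL
  out
}

#' Strength label for a Spearman correlation coefficient
#'
#' `|RHO| <= 0.3` weak; `0.3 < |RHO| < 0.7` moderate; `|RHO| >= 0.7` strong.
#'
#' @param rho Spearman coefficient(s).
#' @return character vector of labels.
#' @export
rho_strength <- function(rho) {
  a <- abs(rho)
  ifelse(a >= 0.7, "strong", ifelse(a > 0.3, "moderate", "weak"))
}

#' Spearman correlation of indicators with clinical scores (PD group)
#'
#' Tie-corrected Spearman rank correlation, two-sided p-value, between every
#' indicator and every available clinical score, computed per hand. Constant
#' scores or indicators are skipped.
#'
#' @param table subject-level table restricted implicitly to PD rows.
#' @param scores clinical-score column names to use (present-in-table subset).
#' @param min_n minimum PD subjects with the score present.
#' @return data.frame: `hand`, `score`, `indicator`, `rho`, `p_value`,
#'   `strength`.
#' @export
correlate_clinical <- function(table,
                               scores = c("updrs3", "hy", "jankovic", "schiess",
                                          "kang", "updrs2_tremor",
                                          "updrs3_rest_tremor", "updrs3_hands"),
                               min_n = 5L) {
  pd <- table[table$group == "PD", , drop = FALSE]
  scores <- intersect(scores, names(pd))
  ind_cols <- intersect(indicator_names(), names(pd))
  out <- list()
  for (h in unique(pd$hand)) {
    d <- pd[pd$hand == h, , drop = FALSE]
    for (sc in scores) {
      s <- d[[sc]]
      for (cn in ind_cols) {
        ok <- !is.na(s) & !is.na(d[[cn]])
        if (sum(ok) < min_n) next
        if (sd_pop(s[ok]) == 0 || sd_pop(d[[cn]][ok]) == 0) next
        ct <- suppressWarnings(
          stats::cor.test(s[ok], d[[cn]][ok], method = "spearman"))
        out[[length(out) + 1L]] <- data.frame(
          hand = h, score = sc, indicator = cn,
          rho = unname(ct$estimate), p_value = ct$p.value,
          strength = rho_strength(unname(ct$estimate)))
      }
    }
  }
  do.call(rbind, out)
}

#' Sample size for detecting a Spearman correlation (Fisher z approximation)
#'
#' `n = ceil( ((z_{1-alpha/2} + z_{power}) / atanh(rho))^2 + 3 )`.
#'
#' @param rho expected correlation, in (0, 1).
#' @param alpha two-sided significance level.
#' @param power target power.
#' @return integer sample size.
#' @export
sample_size_for_rho <- function(rho, alpha = 0.05, power = 0.80) {
  if (rho <= 0 || rho >= 1) stop("rho must be in (0, 1)")
  z <- (stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) / atanh(rho)
  as.integer(ceiling(z^2 + 3))
}
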