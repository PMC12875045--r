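# Survival-association screening (univariate Cox, quantile-split
# Kaplan-Meier with log-rank), plasma rank-sum marker screens, simple
# linear regression of paired expression profiles, and the bootstrap
# gene-set-correlation null.

#' Univariate Cox proportional-hazards fit for one protein
#'
#' Partial-likelihood fit (Breslow ties by default) of relapse time on a
#' single continuous protein level.
#'
#' @param cohort Data frame with columns `time_months`, `event` and one
#'   column per protein (e.g. from [simulate_cohort()]).
#' @param protein Column name of the protein level.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param conf Confidence level (default 0.95).
#' @return A one-row tibble: `protein`, `beta`, `hr`, `conf_low`,
#'   `conf_high`, `p_value` (Wald), `n`, `n_events`.
#' @export
cox_univariate <- function(cohort, protein, ties = c("breslow", "efron"),
                           conf = 0.95) {
  ties <- match.arg(ties)
  assert_columns(cohort, c("time_months", "event", protein), "Cohort")
  x <- cohort[[protein]]
  if (sum(cohort$event) < 2) {
    abort("Need >= 2 events for a Cox fit.", class = "evcargo_input_error")
  }
  if (sd(x) == 0) {
    abort(sprintf("Protein '%s' is constant.", protein),
          class = "evcargo_input_error")
  }
  d <- data.frame(time = cohort$time_months, event = cohort$event, level = x)
  fit <- survival::coxph(survival::Surv(time, event) ~ level, data = d,
                         ties = ties)
  beta <- unname(coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  zq <- qnorm(1 - (1 - conf) / 2)
  tibble::tibble(protein = protein, beta = beta, hr = exp(beta),
                 conf_low = exp(beta - zq * se),
                 conf_high = exp(beta + zq * se),
                 p_value = 2 * stats::pnorm(-abs(beta / se)),
                 n = nrow(d), n_events = sum(d$event))
}

#' Univariate Cox screen over many proteins
#'
#' @param cohort As in [cox_univariate()].
#' @param proteins Protein column names; default: every column other than
#'   `subject_id`, `time_months`, `event`.
#' @param alpha Significance threshold for the `significant` flag.
#' @inheritParams cox_univariate
#' @return A tibble with one [cox_univariate()] row per protein plus a
#'   `significant` flag (Wald p < `alpha`), suitable for
#'   [prognosis_split()].
#' @export
cox_screen <- function(cohort, proteins = NULL, ties = "breslow",
                       alpha = 0.05) {
  if (is.null(proteins)) {
    proteins <- setdiff(names(cohort),
                        c("subject_id", "time_months", "event"))
  }
  purrr::map_dfr(proteins, function(p) cox_univariate(cohort, p, ties)) |>
    dplyr::mutate(significant = .data$p_value < alpha)
}

# log-rank O-E statistic over two groups (chi-square, 1 df)
logrank_stat <- function(time, event, grp) {
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  unname(sd$chisq)
}

#' Quantile-split Kaplan-Meier comparison for one protein
#'
#' Splits subjects into high/low groups at the `q`-th quantile of the
#' protein level, estimates product-limit survival curves per group,
#' reports the median survival (first time the curve reaches 0.5), the
#' log-rank test, and the high-vs-low hazard ratio. For small cohorts an
#' exact permutation p-value for the log-rank statistic over all group
#' labelings can be requested.
#'
#' @param cohort Data frame with `time_months`, `event` and the protein
#'   column.
#' @param protein Protein column name.
#' @param q Split quantile in (0, 1); default 0.5 (median split).
#' @param p_method `"asymptotic"` (chi-square, default) or `"exact"`
#'   (exhaustive permutation over labelings; feasible for small n).
#' @return A list of class `"km_split"`: `curves` tibble (`group`, `time`,
#'   `n_risk`, `n_event`, `survival`), `medians` tibble, `logrank_chisq`,
#'   `logrank_p`, `hr` (high vs low), `q`, `protein`.
#' @export
km_quantile_split <- function(cohort, protein, q = 0.5,
                              p_method = c("asymptotic", "exact")) {
  p_method <- match.arg(p_method)
  assert_columns(cohort, c("time_months", "event", protein), "Cohort")
  q <- assert_fraction(q, "q", lo = 1e-9, hi = 1 - 1e-9)
  x <- cohort[[protein]]
  cut <- quantile(x, probs = q, type = 7)
  grp <- factor(ifelse(x > cut, "high", "low"), levels = c("low", "high"))
  if (dplyr::n_distinct(grp) < 2) {
    abort("Degenerate split: one group is empty.",
          class = "evcargo_input_error")
  }
  time <- cohort$time_months; event <- cohort$event
  sf <- survival::survfit(survival::Surv(time, event) ~ grp)
  strata_grp <- rep(sub("^grp=", "", names(sf$strata)), sf$strata)
  curves <- tibble::tibble(group = strata_grp, time = sf$time,
                           n_risk = sf$n.risk, n_event = sf$n.event,
                           survival = sf$surv)
  medians <- curves |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(median_months = {
      hit <- .data$time[.data$survival <= 0.5]
      if (length(hit)) min(hit) else NA_real_
    }, .groups = "drop")

  chisq <- logrank_stat(time, event, grp)
  p <- if (p_method == "asymptotic") {
    pchisq(chisq, df = 1, lower.tail = FALSE)
  } else {
    n_high <- sum(grp == "high")
    combos <- utils::combn(length(grp), n_high, simplify = FALSE)
    stats_perm <- vapply(combos, function(ii) {
      g <- factor(ifelse(seq_along(grp) %in% ii, "high", "low"),
                  levels = c("low", "high"))
      logrank_stat(time, event, g)
    }, numeric(1))
    mean(stats_perm >= chisq - 1e-12)
  }
  hr <- tryCatch({
    d <- data.frame(time = time, event = event, high = as.integer(grp == "high"))
    exp(unname(coef(survival::coxph(survival::Surv(time, event) ~ high,
                                    data = d, ties = "breslow"))))
  }, error = function(e) NA_real_, warning = function(w) NA_real_)

  structure(list(curves = curves, medians = medians,
                 logrank_chisq = chisq, logrank_p = p, hr = hr,
                 q = q, cut = unname(cut), protein = protein,
                 p_method = p_method),
            class = "km_split")
}

#' @export
print.km_split <- function(x, ...) {
  cat(sprintf("<km_split> %s at q = %.2f: log-rank chisq = %.3f, p = %.4g, HR(high/low) = %.3f\n",
              x$protein, x$q, x$logrank_chisq, x$logrank_p, x$hr))
  print(x$medians)
  invisible(x)
}

#' @export
glance.km_split <- function(x, ...) {
  tibble::tibble(protein = x$protein, q = x$q,
                 logrank_chisq = x$logrank_chisq, logrank_p = x$logrank_p,
                 hr_high_vs_low = x$hr,
                 median_low = x$medians$median_months[x$medians$group == "low"],
                 median_high = x$medians$median_months[x$medians$group == "high"])
}

#' @export
tidy.km_split <- function(x, ...) x$curves

#' Two-group plasma marker screen (rank-sum)
#'
#' Two-sided Mann-Whitney test per protein comparing case against control
#' levels: exact enumeration when the total sample size is at most 12 and
#' there are no ties, normal approximation with tie correction otherwise.
#' All-tied proteins get p = 1 and a flag.
#'
#' @param data Long tibble with columns `protein`, `group`
#'   (`"case"`/`"control"`) and `level`; or a wide data frame plus
#'   `group` column when `proteins` is given.
#' @param proteins Optional protein column names for wide input.
#' @param alpha BH-adjusted significance threshold for the flag.
#' @return A tibble: `protein`, `u_case`, `p_value`, `q_value`, `direction`
#'   (`"up_in_case"`/`"up_in_control"`), `all_tied`, `significant`.
#' @export
plasma_marker_screen <- function(data, proteins = NULL, alpha = 0.05) {
  long <- if (is.null(proteins)) {
    assert_columns(data, c("protein", "group", "level"), "Plasma screen data")
    tibble::as_tibble(data)
  } else {
    assert_columns(data, c("group", proteins), "Plasma screen data")
    tidyr::pivot_longer(tibble::as_tibble(data), dplyr::all_of(proteins),
                        names_to = "protein", values_to = "level")
  }
  if (!all(long$group %in% c("case", "control"))) {
    abort("`group` must be 'case' or 'control'.",
          class = "evcargo_input_error")
  }
  out <- long |>
    dplyr::group_by(.data$protein) |>
    dplyr::group_modify(function(d, key) {
      ca <- d$level[d$group == "case"]
      co <- d$level[d$group == "control"]
      if (length(ca) < 3 || length(co) < 3) {
        abort("Need >= 3 observations per group.",
              class = "evcargo_input_error")
      }
      n_tot <- length(ca) + length(co)
      if (dplyr::n_distinct(d$level) == 1) {
        return(tibble::tibble(u_case = length(ca) * length(co) / 2,
                              p_value = 1, all_tied = TRUE,
                              direction = NA_character_))
      }
      ties_present <- anyDuplicated(d$level) > 0
      wt <- suppressWarnings(
        wilcox.test(ca, co, alternative = "two.sided",
                    exact = n_tot <= 12 && !ties_present,
                    correct = TRUE))
      tibble::tibble(u_case = unname(wt$statistic),
                     p_value = wt$p.value, all_tied = FALSE,
                     direction = if (median(ca) >= median(co))
                       "up_in_case" else "up_in_control")
    }) |>
    dplyr::ungroup()
  out$q_value <- bh_adjust(out$p_value)
  out$significant <- !out$all_tied & out$q_value < alpha
  dplyr::relocate(out, "q_value", .after = "p_value")
}

#' Simple linear regression of paired expression profiles
#'
#' Ordinary least squares of `y` on `x` (both on a log10 scale) with a
#' two-sided t-test on the slope (df = n - 2), as used to compare marker
#' transcript levels between an in vitro model and patient-derived cells.
#'
#' @param data Tibble with columns `x` and `y` (log10 expression), e.g.
#'   the marker rows of [simulate_paired_expression()] output.
#' @return A one-row tibble: `slope`, `intercept`, `r_squared`, `p_value`,
#'   `n`.
#' @export
regress_paired_expression <- function(data) {
  assert_columns(data, c("x", "y"), "Paired expression data")
  x <- data$x; y <- data$y
  if (length(x) < 3) abort("Need >= 3 points.", class = "evcargo_input_error")
  if (var(x) == 0) abort("Zero variance in x.", class = "evcargo_input_error")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  tibble::tibble(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 n = length(x))
}

#' Bootstrap gene-set correlation test
#'
#' Compares the Pearson correlation of two expression profiles over a
#' marker gene set against a null distribution of `n_boot` random gene sets
#' of the same size drawn (without replacement within a draw) from the
#' common gene universe. The empirical p-value is the fraction of null
#' draws with correlation at least as large as the observed one
#' (one-sided); by default no +1 continuity correction is applied.
#'
#' @param data Tibble with columns `gene`, `x`, `y` over the full universe
#'   (log10 scale).
#' @param markers Character vector of marker genes (subset of `gene`).
#' @param n_boot Number of null draws (default 100000).
#' @param seed RNG seed.
#' @param add_one If `TRUE`, use the (r+1)/(n+1) convention instead of the
#'   literal count/n.
#' @return A list of class `"boot_cor"`: `observed_r`, `p_value`,
#'   `null_r` (numeric vector), `n_markers`, `n_boot`.
#' @export
bootstrap_geneset_correlation <- function(data, markers, n_boot = 1e5,
                                          seed = 1L, add_one = FALSE) {
  assert_columns(data, c("gene", "x", "y"), "Expression data")
  n_boot <- assert_count(n_boot, "n_boot")
  if (!all(markers %in% data$gene)) {
    abort("All markers must be present in the gene universe.",
          class = "evcargo_input_error")
  }
  k <- length(unique(markers))
  if (k > nrow(data)) {
    abort("Marker set larger than universe.", class = "evcargo_input_error")
  }
  idx_m <- match(unique(markers), data$gene)
  x <- data$x; y <- data$y
  r_obs <- cor(x[idx_m], y[idx_m])
  null_r <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      ii <- sample.int(length(x), k)
      cor(x[ii], y[ii])
    }, numeric(1))
  })
  n_ge <- sum(null_r >= r_obs)
  p <- if (add_one) (n_ge + 1) / (n_boot + 1) else n_ge / n_boot
  structure(list(observed_r = r_obs, p_value = p, null_r = null_r,
                 n_markers = k, n_boot = n_boot, add_one = add_one),
            class = "boot_cor")
}

#' @export
print.boot_cor <- function(x, ...) {
  cat(sprintf("<boot_cor> observed r = %.4f over %d markers; empirical p = %.4g (%d/%d draws >= observed)\n",
              x$observed_r, x$n_markers, x$p_value,
              sum(x$null_r >= x$observed_r), x$n_boot))
  invisible(x)
}

#' @export
glance.boot_cor <- function(x, ...) {
  tibble::tibble(observed_r = x$observed_r, p_value = x$p_value,
                 n_markers = x$n_markers, n_boot = x$n_boot)
}
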