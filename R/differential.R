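# Moderated two-group differential-abundance testing with empirical-Bayes
# variance shrinkage and Benjamini-Hochberg FDR control.
#
# The hyperparameters (prior df d0, prior variance s0^2) are estimated by
# matching moments of log s_g^2 to a scaled-F model: for residual df d,
# E log s^2 = log sigma^2 + digamma(d/2) - log(d/2) and
# Var log s^2 = trigamma(d/2) (+ trigamma(d0/2) under the prior), so the
# excess variance of the log sample variances identifies d0 through the
# inverse trigamma, and the mean identifies s0^2.

estimate_prior <- function(s2, df) {
  m <- median(s2)
  if (m == 0) {
    warn("More than half of the residual variances are zero; falling back to infinite prior df.")
    return(list(d0 = Inf, s0_sq = mean(s2)))
  }
  # guard against exact zeros before taking logs
  s2c <- pmax(s2, 1e-5 * m)
  z <- log(s2c)
  dfo <- rep_len(df, length(s2c))
  e <- z - digamma(dfo / 2) + log(dfo / 2)
  emean <- mean(e)
  evar <- var(e) - mean(trigamma(dfo / 2))
  if (!is.finite(evar) || evar <= 0) {
    # no excess dispersion in log s^2: variances look homogeneous
    d0 <- Inf
    s0_sq <- mean(s2c)
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated two-group t-test over a protein quantification matrix
#'
#' Equal-variance unpaired contrast of `group_a` minus `group_b` with
#' empirical-Bayes moderation: per-protein sample variances are shrunk
#' towards a prior variance `s0^2` with prior degrees of freedom `d0`
#' estimated from all proteins, and the moderated t-statistic is referred to
#' a t distribution on `d0 + d_g` degrees of freedom.
#'
#' @param quant An `ev_quant` object (typically centered and imputed).
#' @param group_a,group_b Group labels; log2 fold change is mean(A) - mean(B).
#' @param alpha FDR threshold for the differential-abundance (DAP) call.
#' @param prior_df Optional forced prior df: `0` reduces to the ordinary
#'   equal-variance t-test, `Inf` to a test with fully pooled variance.
#'   `NULL` (default) estimates it from the data.
#'
#' @return A tibble of class `"ev_contrast"`: `protein`, `gene`, `log2fc`,
#'   `t`, `p_value`, `q_value`, `dap`, `direction`
#'   (`"up_in_a"` / `"up_in_b"`). The moderation fit (`d0`, `s0_sq`,
#'   per-protein residual df and posterior variances) is stored in
#'   `attr(, "fit")` and summarized by [glance.ev_contrast()].
#' @export
#' @examples
#' sim <- simulate_report(sim_config(n_proteins = 300, seed = 7))
#' q <- read_report(sim$report, sim$sample_sheet) |>
#'   filter_protein_groups() |>
#'   median_center() |>
#'   impute_missing(seed = 7)
#' res <- fit_moderated_t(q, "M1", "M2")
#' head(res)
fit_moderated_t <- function(quant, group_a, group_b, alpha = 0.05,
                            prior_df = NULL) {
  stopifnot(inherits(quant, "ev_quant"))
  smp <- quant$samples
  a_cols <- smp$sample[smp$group == group_a]
  b_cols <- smp$sample[smp$group == group_b]
  if (length(a_cols) < 2 || length(b_cols) < 2) {
    abort("Each group needs >= 2 samples.", class = "evcargo_input_error")
  }
  m <- quant$matrix
  if (anyNA(m[, c(a_cols, b_cols)])) {
    abort("Matrix has missing cells; impute first (impute_missing()).",
          class = "evcargo_input_error")
  }
  xa <- m[, a_cols, drop = FALSE]
  xb <- m[, b_cols, drop = FALSE]
  na <- length(a_cols); nb <- length(b_cols)
  mean_a <- rowMeans(xa); mean_b <- rowMeans(xb)
  ss <- rowSums((xa - mean_a)^2) + rowSums((xb - mean_b)^2)
  df_res <- na + nb - 2
  s2 <- ss / df_res
  lfc <- mean_a - mean_b

  prior <- if (is.null(prior_df)) {
    estimate_prior(s2, df_res)
  } else if (prior_df == 0) {
    list(d0 = 0, s0_sq = NA_real_)
  } else {
    p <- estimate_prior(s2, df_res)
    list(d0 = prior_df,
         s0_sq = if (is.finite(prior_df)) {
           # re-derive s0^2 consistent with the forced d0
           z <- log(s2[s2 > 0])
           exp(mean(z - digamma(df_res / 2) + log(df_res / 2)) +
                 digamma(prior_df / 2) - log(prior_df / 2))
         } else p$s0_sq)
  }
  d0 <- prior$d0; s0_sq <- prior$s0_sq

  post_s2 <- if (d0 == 0) {
    s2
  } else if (is.infinite(d0)) {
    rep(s0_sq, length(s2))
  } else {
    (d0 * s0_sq + df_res * s2) / (d0 + df_res)
  }
  se <- sqrt(post_s2 * (1 / na + 1 / nb))
  tstat <- lfc / se
  df_total <- d0 + df_res
  p <- 2 * pt(-abs(tstat), df = df_total)
  q <- bh_adjust(p)

  out <- tibble::tibble(
    protein = rownames(m),
    log2fc = unname(lfc),
    t = unname(tstat),
    p_value = unname(p),
    q_value = unname(q),
    dap = unname(q < alpha),
    direction = ifelse(lfc >= 0, "up_in_a", "up_in_b")
  ) |>
    dplyr::left_join(quant$genes, by = "protein") |>
    dplyr::relocate("gene", .after = "protein")

  attr(out, "fit") <- list(d0 = d0, s0_sq = s0_sq, df_residual = df_res,
                           df_total = df_total, s2 = unname(s2),
                           post_s2 = unname(post_s2))
  attr(out, "groups") <- c(a = group_a, b = group_b)
  attr(out, "alpha") <- alpha
  class(out) <- c("ev_contrast", class(out))
  out
}

#' @export
tidy.ev_contrast <- function(x, ...) {
  out <- x
  attr(out, "fit") <- NULL
  class(out) <- setdiff(class(out), "ev_contrast")
  tibble::as_tibble(out)
}

#' One-row summary of a moderated contrast
#'
#' @param x An `ev_contrast` object.
#' @param ... Unused.
#' @return A tibble with the contrast groups, prior df `d0`, prior variance
#'   `s0_sq`, residual df, protein count and DAP counts per direction.
#' @export
glance.ev_contrast <- function(x, ...) {
  fit <- attr(x, "fit")
  g <- attr(x, "groups")
  tibble::tibble(group_a = g[["a"]], group_b = g[["b"]],
                 n_proteins = nrow(x),
                 d0 = fit$d0, s0_sq = fit$s0_sq,
                 df_residual = fit$df_residual,
                 n_dap_up_a = sum(x$dap & x$direction == "up_in_a"),
                 n_dap_up_b = sum(x$dap & x$direction == "up_in_b"))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment (delegates to
#' [stats::p.adjust()]); input order is preserved.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].", class = "evcargo_input_error")
  }
  p.adjust(p, method = "BH")
}

#' Call differentially abundant proteins from a contrast
#'
#' @param result An `ev_contrast` tibble.
#' @param alpha FDR threshold (default 0.05).
#' @return A list with character vectors `up_in_a` and `up_in_b`; the two
#'   sets are disjoint and partition the proteins with `q_value < alpha`.
#' @export
call_daps <- function(result, alpha = 0.05) {
  sig <- result[result$q_value < alpha, , drop = FALSE]
  list(up_in_a = sig$protein[sig$direction == "up_in_a"],
       up_in_b = sig$protein[sig$direction == "up_in_b"])
}
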