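# Multi-contrast set logic deriving pro-/anti-inflammatory components and
# the TAM-EV signature from three pairwise differential contrasts.

#' Derive macrophage-EV signature sets from three contrasts
#'
#' Uses only the DAP flags and directions of three pairwise contrasts that
#' share one protein universe:
#' \itemize{
#'   \item `pro`: up in M1 vs M2 (pro-inflammatory component);
#'   \item `anti`: up in M2 vs M1 (anti-inflammatory component);
#'   \item `tam_enriched`: up in TAM in either TAM contrast (union);
#'     proteins significant in opposite directions across the two TAM
#'     contrasts are excluded and reported in `direction_conflict`;
#'   \item `tam_unique = tam_enriched \ (pro U anti)`;
#'   \item `tam_pro = tam_enriched` \eqn{\cap} `pro`,
#'     `tam_anti = tam_enriched` \eqn{\cap} `anti`;
#'   \item `m1_sig = pro \ tam_enriched`, `m2_sig = anti \ tam_enriched`.
#' }
#' `tam_unique`, `tam_pro` and `tam_anti` are pairwise disjoint and
#' partition `tam_enriched`.
#'
#' @param c_m1m2 Contrast with A = M1, B = M2 (an `ev_contrast`).
#' @param c_tam_m1 Contrast with A = TAM, B = M1.
#' @param c_tam_m2 Contrast with A = TAM, B = M2.
#' @return A list of class `"signature_sets"` of sorted protein vectors:
#'   `pro`, `anti`, `tam_enriched`, `tam_unique`, `tam_pro`, `tam_anti`,
#'   `m1_sig`, `m2_sig`, `direction_conflict`, plus `tam_depleted` (DAPs
#'   less abundant in TAM, reported but unused for enrichment).
#' @export
derive_signatures <- function(c_m1m2, c_tam_m1, c_tam_m2) {
  u1 <- sort(c_m1m2$protein); u2 <- sort(c_tam_m1$protein)
  u3 <- sort(c_tam_m2$protein)
  if (!identical(u1, u2) || !identical(u1, u3)) {
    abort("Contrasts must share one protein universe.",
          class = "evcargo_input_error")
  }
  d_m1m2 <- call_daps(c_m1m2, attr(c_m1m2, "alpha") %||% 0.05)
  d_tm1 <- call_daps(c_tam_m1, attr(c_tam_m1, "alpha") %||% 0.05)
  d_tm2 <- call_daps(c_tam_m2, attr(c_tam_m2, "alpha") %||% 0.05)

  pro <- d_m1m2$up_in_a
  anti <- d_m1m2$up_in_b
  up_tam <- union(d_tm1$up_in_a, d_tm2$up_in_a)
  down_tam <- union(d_tm1$up_in_b, d_tm2$up_in_b)
  conflict <- intersect(up_tam, down_tam)
  tam_enriched <- setdiff(up_tam, conflict)

  sets <- list(
    pro = pro,
    anti = anti,
    tam_enriched = tam_enriched,
    tam_unique = setdiff(tam_enriched, union(pro, anti)),
    tam_pro = intersect(tam_enriched, pro),
    tam_anti = intersect(tam_enriched, anti),
    m1_sig = setdiff(pro, tam_enriched),
    m2_sig = setdiff(anti, tam_enriched),
    tam_depleted = setdiff(down_tam, conflict),
    direction_conflict = conflict
  )
  sets <- lapply(sets, function(x) sort(unique(x)))
  structure(sets, class = "signature_sets")
}

#' @export
print.signature_sets <- function(x, ...) {
  cat("<signature_sets>\n")
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.signature_sets <- function(x, ...) {
  tibble::tibble(set = names(x),
                 n = vapply(x, length, integer(1)))
}

#' Overlap of a signature with a reference protein list
#'
#' @param signature Character vector (e.g. one set from
#'   [derive_signatures()]).
#' @param reference Character vector of reference identifiers.
#' @return A list: `overlap` (sorted intersection), `n_overlap`,
#'   `n_signature`, `n_reference`.
#' @export
overlap_with_reference <- function(signature, reference) {
  ov <- sort(intersect(signature, reference))
  list(overlap = ov, n_overlap = length(ov),
       n_signature = length(unique(signature)),
       n_reference = length(unique(reference)))
}

# median with 95% CI from binomial order statistics
median_with_ci <- function(x, conf = 0.95) {
  x <- sort(x)
  n <- length(x)
  if (n == 0) {
    return(tibble::tibble(median = NA_real_, conf_low = NA_real_,
                          conf_high = NA_real_, n = 0L))
  }
  alpha <- (1 - conf) / 2
  lo <- qbinom(alpha, n, 0.5)
  hi <- qbinom(1 - alpha, n, 0.5) + 1
  tibble::tibble(median = median(x),
                 conf_low = x[max(lo, 1)],
                 conf_high = x[min(hi, n)],
                 n = n)
}

#' Split a signature by prognostic direction of hazard ratios
#'
#' Restricts a hazard-ratio table to proteins in the signature that are
#' significantly associated with relapse-free survival and partitions them
#' into short-RFS (HR > 1) and long-RFS (HR < 1) sets, with the median HR
#' and its 95% order-statistic confidence interval per set.
#'
#' @param signature Character vector of protein identifiers.
#' @param hr_table Tibble with columns `protein`, `hr`, `significant`.
#' @return A list of class `"prognosis_split"`: `short_rfs`, `long_rfs`
#'   (protein vectors) and `summary` (tibble: set, median, conf_low,
#'   conf_high, n).
#' @export
prognosis_split <- function(signature, hr_table) {
  assert_columns(hr_table, c("protein", "hr", "significant"), "HR table")
  if (any(hr_table$hr <= 0)) {
    abort("Hazard ratios must be > 0.", class = "evcargo_input_error")
  }
  tab <- hr_table[hr_table$protein %in% signature & hr_table$significant, ,
                  drop = FALSE]
  short <- tab[tab$hr > 1, , drop = FALSE]
  long <- tab[tab$hr < 1, , drop = FALSE]
  structure(list(
    short_rfs = sort(short$protein),
    long_rfs = sort(long$protein),
    summary = dplyr::bind_rows(
      dplyr::mutate(median_with_ci(short$hr), set = "short_rfs",
                    .before = 1),
      dplyr::mutate(median_with_ci(long$hr), set = "long_rfs",
                    .before = 1))
  ), class = "prognosis_split")
}
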