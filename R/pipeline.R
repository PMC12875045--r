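# End-to-end orchestration with a single parameter list and a run manifest.

#' Run the EV-proteome pipeline end to end
#'
#' Filters and normalizes a precursor report, fits the three pairwise
#' moderated contrasts, derives the signature sets, and (when the
#' corresponding inputs are supplied) computes MISEV category summaries,
#' over-representation of the TAM-unique signature, and a univariate Cox
#' survival screen. Every stage's parameters and seeds are recorded in a
#' manifest, and reruns with identical inputs are deterministic.
#'
#' @param report A `precursor_report` tibble (see [read_report()]).
#' @param annotation Optional `misev_annotation` tibble.
#' @param collection Optional `gene_set_collection` for ORA.
#' @param cohort Optional survival cohort for the Cox screen.
#' @param groups Length-3 character vector naming the pro-inflammatory,
#'   anti-inflammatory and tumor-associated groups, in that order
#'   (default `c("M1", "M2", "TAM")`).
#' @param q_max,min_precursors,min_donor_fraction Filter parameters, see
#'   [filter_protein_groups()].
#' @param alpha FDR threshold for DAP calls.
#' @param shift_sd,width_sd Imputation parameters, see [impute_missing()].
#' @param ora_params List overriding [ora()] defaults
#'   (`min_size`, `max_size`, `p_cut`, `q_cut`).
#' @param seed Seed for the imputation draw.
#'
#' @return A list of class `"ev_pipeline"`: `quant`, `sets`
#'   (detection sets), `contrasts` (named list of `ev_contrast`),
#'   `signatures`, `misev` (list: `summary_main`, `summary_sub`,
#'   `endosomal`), `ora`, `cox`, and `manifest`.
#' @export
#' @examples
#' sim <- simulate_report(sim_config(n_proteins = 200, seed = 3))
#' rep <- read_report(sim$report, sim$sample_sheet)
#' res <- run_ev_pipeline(rep, seed = 3)
#' res$manifest$stages
run_ev_pipeline <- function(report, annotation = NULL, collection = NULL,
                            cohort = NULL, groups = c("M1", "M2", "TAM"),
                            q_max = 0.01, min_precursors = 3,
                            min_donor_fraction = 0.5, alpha = 0.05,
                            shift_sd = 1.8, width_sd = 0.3,
                            ora_params = list(), seed = 1L) {
  if (length(groups) != 3) {
    abort("`groups` must name exactly three groups.",
          class = "evcargo_config_error")
  }
  missing_groups <- setdiff(groups, unique(report$group))
  if (length(missing_groups)) {
    abort(sprintf("Group(s) absent from report: %s.",
                  paste(missing_groups, collapse = ", ")),
          class = "evcargo_input_error")
  }
  stages <- character(0)

  quant <- filter_protein_groups(report, q_max = q_max,
                                 min_precursors = min_precursors,
                                 min_donor_fraction = min_donor_fraction) |>
    median_center() |>
    impute_missing(shift_sd = shift_sd, width_sd = width_sd, seed = seed)
  stages <- c(stages, "quant")

  sets <- detection_sets(quant)
  stages <- c(stages, "detection_sets")

  g <- groups
  contrasts <- list(
    m1_vs_m2 = fit_moderated_t(quant, g[1], g[2], alpha = alpha),
    tam_vs_m1 = fit_moderated_t(quant, g[3], g[1], alpha = alpha),
    tam_vs_m2 = fit_moderated_t(quant, g[3], g[2], alpha = alpha))
  stages <- c(stages, "differential")

  signatures <- derive_signatures(contrasts$m1_vs_m2, contrasts$tam_vs_m1,
                                  contrasts$tam_vs_m2)
  stages <- c(stages, "signatures")

  misev <- NULL
  if (!is.null(annotation)) {
    retained <- rownames(quant$matrix)
    summary_main <- category_np_fraction(report, annotation, level = "main",
                                         proteins = retained, q_max = q_max)
    summary_sub <- category_np_fraction(report, annotation, level = "sub",
                                        proteins = retained, q_max = q_max)
    misev <- list(summary_main = summary_main,
                  summary_sub = summary_sub,
                  endosomal = endosomal_ratio(summary_sub,
                                              reference_group = g[3]),
                  panel = ev_panel(annotation))
    stages <- c(stages, "misev")
  }

  ora_res <- NULL
  if (!is.null(collection)) {
    universe <- unique(quant$genes$gene)
    tam_genes <- quant$genes$gene[quant$genes$protein %in%
                                    signatures$tam_unique]
    args <- utils::modifyList(
      list(query = tam_genes, collection = collection, universe = universe),
      ora_params)
    ora_res <- do.call(ora, args)
    stages <- c(stages, "enrichment")
  }

  cox_res <- NULL
  if (!is.null(cohort)) {
    cox_res <- cox_screen(cohort, alpha = alpha)
    stages <- c(stages, "clinical")
  }

  manifest <- list(
    stages = stages,
    parameters = list(groups = groups, q_max = q_max,
                      min_precursors = min_precursors,
                      min_donor_fraction = min_donor_fraction,
                      alpha = alpha, shift_sd = shift_sd,
                      width_sd = width_sd, seed = seed),
    n_records = nrow(report),
    n_proteins_retained = nrow(quant$matrix),
    set_counts = sets$counts,
    signature_counts = tidy(signatures),
    checksums = list(matrix = rlang::hash(quant$matrix),
                     contrasts = rlang::hash(lapply(contrasts, tidy)),
                     signatures = rlang::hash(unclass(signatures))),
    timestamp = format(Sys.time(), tz = "UTC")
  )

  structure(list(quant = quant, sets = sets, contrasts = contrasts,
                 signatures = signatures, misev = misev, ora = ora_res,
                 cox = cox_res, manifest = manifest),
            class = "ev_pipeline")
}

#' @export
print.ev_pipeline <- function(x, ...) {
  cat(sprintf("<ev_pipeline> stages: %s\n",
              paste(x$manifest$stages, collapse = " -> ")))
  cat(sprintf("  %d proteins retained; signature sizes:\n",
              x$manifest$n_proteins_retained))
  print(x$manifest$signature_counts)
  invisible(x)
}
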