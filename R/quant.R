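# Quantification core: DIA-NN report ingestion, q-value / precursor-count
# filtering, median centering and down-shifted-normal imputation.

diann_cols <- c("Run", "Protein.Group", "Genes", "Precursor.Id",
                "Protein.Q.Value", "PG.MaxLFQ")

#' Read a DIA-NN style precursor report
#'
#' Parses a tab-separated report ("report.tsv" dialect) and attaches group
#' and donor metadata from a sample sheet. Intensities must be positive;
#' q-values must lie in `[0, 1]`; each (run, protein, precursor) triple must
#' be unique.
#'
#' @param path Path to the report TSV, or a data frame already in report
#'   dialect (columns `Run`, `Protein.Group`, `Genes`, `Precursor.Id`,
#'   `Protein.Q.Value`, `PG.MaxLFQ`).
#' @param sample_sheet Data frame mapping `Run` to `group` and `donor`.
#'
#' @return A tibble of class `"precursor_report"` with canonical columns
#'   `run`, `group`, `donor`, `protein`, `gene`, `precursor`, `q_value`,
#'   `intensity` (raw MaxLFQ) and `log2_intensity`.
#' @export
#' @examples
#' sim <- simulate_report(sim_config(n_proteins = 50, seed = 1))
#' rep <- read_report(sim$report, sim$sample_sheet)
read_report <- function(path, sample_sheet) {
  raw <- if (is.data.frame(path)) {
    tibble::as_tibble(path)
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
  assert_columns(raw, diann_cols, "Precursor report")
  assert_columns(sample_sheet, c("Run", "group", "donor"), "Sample sheet")

  if (!is.numeric(raw$PG.MaxLFQ)) {
    abort("PG.MaxLFQ must be numeric.", class = "evcargo_parse_error")
  }
  bad <- which(!complete.cases(raw[diann_cols]))
  if (length(bad)) {
    abort(sprintf("Report rows with missing required fields: %s.",
                  paste(head(bad, 5), collapse = ", ")),
          class = "evcargo_parse_error")
  }
  if (any(raw$PG.MaxLFQ <= 0)) {
    abort("All PG.MaxLFQ intensities must be > 0.",
          class = "evcargo_parse_error")
  }
  if (any(raw$Protein.Q.Value < 0 | raw$Protein.Q.Value > 1)) {
    abort("Protein.Q.Value must lie in [0, 1].",
          class = "evcargo_parse_error")
  }
  unknown <- setdiff(unique(raw$Run), sample_sheet$Run)
  if (length(unknown)) {
    abort(sprintf("Run(s) absent from sample sheet: %s.",
                  paste(unknown, collapse = ", ")),
          class = "evcargo_mapping_error")
  }
  if (anyDuplicated(raw[c("Run", "Protein.Group", "Precursor.Id")])) {
    abort("Duplicate (Run, Protein.Group, Precursor.Id) records.",
          class = "evcargo_parse_error")
  }

  out <- raw |>
    dplyr::left_join(tibble::as_tibble(sample_sheet)[c("Run", "group", "donor")],
                     by = "Run") |>
    dplyr::transmute(run = .data$Run, group = .data$group,
                     donor = .data$donor,
                     protein = .data$Protein.Group, gene = .data$Genes,
                     precursor = .data$Precursor.Id,
                     q_value = .data$Protein.Q.Value,
                     intensity = .data$PG.MaxLFQ,
                     log2_intensity = log2(.data$PG.MaxLFQ))
  class(out) <- c("precursor_report", class(out))
  out
}

#' Write a precursor report back to DIA-NN dialect
#'
#' @param report A `precursor_report` tibble from [read_report()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  report |>
    dplyr::transmute(Run = .data$run, Protein.Group = .data$protein,
                     Genes = .data$gene, Precursor.Id = .data$precursor,
                     Protein.Q.Value = .data$q_value,
                     PG.MaxLFQ = .data$intensity) |>
    readr::write_tsv(path)
  invisible(path)
}

#' Filter protein groups by q-value and precursor support
#'
#' Records with run-specific protein q-value `>= q_max` are treated as
#' undetected in that run. A protein is retained in a group when the number
#' of donors with at least `min_precursors` q-passing precursors (Np) is at
#' least `ceiling(min_donor_fraction * donors)`. The final matrix is the
#' union of per-group retained sets (default) or a single global filter.
#'
#' @param report A `precursor_report` tibble.
#' @param q_max Maximum run-specific protein q-value (default 0.01).
#' @param min_precursors Minimum q-passing precursors per donor (default 3).
#' @param min_donor_fraction Minimum fraction of donors meeting the Np rule
#'   (default 0.5).
#' @param scope `"per_group"` (filter within each group, then union) or
#'   `"global"` (one filter over all donors).
#'
#' @return An object of class `"ev_quant"`: list with `matrix` (protein x
#'   sample log2 intensities, `NA` = undetected), `mask` (logical, `TRUE`
#'   where missing pre-imputation), `np` (protein x sample q-passing
#'   precursor counts), `samples` (tibble: sample, group, donor),
#'   `genes` (protein -> gene map), `detection` (tibble: protein, group,
#'   detected), and bookkeeping flags `centered` / `imputed`.
#' @export
filter_protein_groups <- function(report, q_max = 0.01, min_precursors = 3,
                                  min_donor_fraction = 0.5,
                                  scope = c("per_group", "global")) {
  scope <- match.arg(scope)
  if (!nrow(report)) abort("Empty report.", class = "evcargo_input_error")
  q_max <- assert_fraction(q_max, "q_max", lo = 1e-12, hi = 1)
  min_precursors <- assert_count(min_precursors, "min_precursors")
  min_donor_fraction <- assert_fraction(min_donor_fraction,
                                        "min_donor_fraction", lo = 1e-12)

  samples <- report |>
    dplyr::distinct(sample = .data$run, .data$group, .data$donor) |>
    dplyr::arrange(.data$group, .data$donor)

  passing <- dplyr::filter(report, .data$q_value < q_max)

  np <- passing |>
    dplyr::group_by(.data$protein, .data$run, .data$group) |>
    dplyr::summarise(np = dplyr::n_distinct(.data$precursor),
                     .groups = "drop")

  donors_per_group <- samples |>
    dplyr::count(.data$group, name = "n_donors")

  per_group <- np |>
    dplyr::filter(.data$np >= min_precursors) |>
    dplyr::count(.data$protein, .data$group, name = "n_ok") |>
    dplyr::right_join(
      tidyr::expand_grid(protein = unique(report$protein),
                         group = unique(samples$group)),
      by = c("protein", "group")) |>
    dplyr::mutate(n_ok = dplyr::coalesce(.data$n_ok, 0L)) |>
    dplyr::left_join(donors_per_group, by = "group") |>
    dplyr::mutate(detected = .data$n_ok >=
                    ceiling(min_donor_fraction * .data$n_donors))

  detection <- dplyr::select(per_group, "protein", "group", "detected")

  retained <- if (scope == "per_group") {
    per_group |>
      dplyr::filter(.data$detected) |>
      dplyr::distinct(.data$protein) |>
      dplyr::pull("protein")
  } else {
    total_donors <- nrow(samples)
    np |>
      dplyr::filter(.data$np >= min_precursors) |>
      dplyr::count(.data$protein, name = "n_ok") |>
      dplyr::filter(.data$n_ok >= ceiling(min_donor_fraction * total_donors)) |>
      dplyr::pull("protein")
  }
  retained <- sort(retained)
  if (!length(retained)) {
    abort("No protein passes the filter.", class = "evcargo_input_error")
  }

  cells <- passing |>
    dplyr::filter(.data$protein %in% retained) |>
    dplyr::group_by(.data$protein, .data$run) |>
    dplyr::summarise(log2_intensity = median(.data$log2_intensity),
                     np = dplyr::n_distinct(.data$precursor),
                     .groups = "drop")

  mat <- matrix(NA_real_, length(retained), nrow(samples),
                dimnames = list(retained, samples$sample))
  npm <- matrix(0L, length(retained), nrow(samples),
                dimnames = list(retained, samples$sample))
  idx <- cbind(match(cells$protein, retained), match(cells$run, samples$sample))
  mat[idx] <- cells$log2_intensity
  npm[idx] <- cells$np

  genes <- report |>
    dplyr::distinct(.data$protein, .data$gene) |>
    dplyr::filter(.data$protein %in% retained)

  structure(list(matrix = mat,
                 mask = is.na(mat),
                 np = npm,
                 samples = samples,
                 genes = genes,
                 detection = detection,
                 filter = list(q_max = q_max,
                               min_precursors = min_precursors,
                               min_donor_fraction = min_donor_fraction,
                               scope = scope),
                 centered = FALSE,
                 imputed = FALSE),
            class = "ev_quant")
}

#' @export
print.ev_quant <- function(x, ...) {
  cat(sprintf("<ev_quant> %d proteins x %d samples (%s groups)\n",
              nrow(x$matrix), ncol(x$matrix),
              dplyr::n_distinct(x$samples$group)))
  cat(sprintf("  missing: %.1f%%  centered: %s  imputed: %s\n",
              100 * mean(x$mask), x$centered, x$imputed))
  invisible(x)
}

#' Tidy a quantification object into long format
#'
#' @param x An `ev_quant` object.
#' @param ... Unused.
#' @return A long tibble: `protein`, `gene`, `sample`, `group`, `donor`,
#'   `log2_intensity`, `np`, `imputed`.
#' @export
tidy.ev_quant <- function(x, ...) {
  tibble::as_tibble(x$matrix, rownames = "protein") |>
    tidyr::pivot_longer(-"protein", names_to = "sample",
                        values_to = "log2_intensity") |>
    dplyr::left_join(
      tibble::as_tibble(x$np, rownames = "protein") |>
        tidyr::pivot_longer(-"protein", names_to = "sample",
                            values_to = "np"),
      by = c("protein", "sample")) |>
    dplyr::left_join(
      tibble::as_tibble(x$mask, rownames = "protein") |>
        tidyr::pivot_longer(-"protein", names_to = "sample",
                            values_to = "imputed_cell"),
      by = c("protein", "sample")) |>
    dplyr::mutate(imputed = .data$imputed_cell & x$imputed,
                  imputed_cell = NULL) |>
    dplyr::left_join(x$genes, by = "protein") |>
    dplyr::left_join(x$samples, by = "sample") |>
    dplyr::relocate("gene", .after = "protein")
}

#' Median-center sample columns
#'
#' Shifts every sample column so its median over observed (non-missing)
#' cells equals the grand median of the pre-centering sample medians.
#' Missing cells are untouched; within-sample differences are preserved
#' exactly, and the operation is idempotent.
#'
#' @param quant An `ev_quant` object (log2 scale).
#' @return The centered `ev_quant` object.
#' @export
median_center <- function(quant) {
  stopifnot(inherits(quant, "ev_quant"))
  m <- quant$matrix
  col_med <- apply(m, 2, median, na.rm = TRUE)
  if (any(!is.finite(col_med))) {
    abort("A sample column has zero observed cells.",
          class = "evcargo_input_error")
  }
  target <- median(col_med)
  quant$matrix <- sweep(m, 2, col_med - target, "-")
  quant$centered <- TRUE
  quant
}

#' Impute missing cells from a down-shifted normal
#'
#' Each missing cell of sample `s` is drawn from
#' `Normal(mu_s - shift_sd * sigma_s, (width_sd * sigma_s)^2)` where `mu_s`
#' and `sigma_s` are the mean and SD of the observed cells of that sample.
#' This mimics values near the instrument's lower limit of detection while
#' following each sample's measured distribution.
#'
#' @param quant A (typically centered) `ev_quant` object.
#' @param shift_sd Down-shift in sample SD units (default 1.8).
#' @param width_sd Width of the imputation distribution in sample SD units
#'   (default 0.3).
#' @param seed RNG seed.
#' @return The `ev_quant` object with no missing cells; `mask` marks exactly
#'   the imputed cells.
#' @export
impute_missing <- function(quant, shift_sd = 1.8, width_sd = 0.3, seed = 1L) {
  stopifnot(inherits(quant, "ev_quant"))
  m <- quant$matrix
  n_obs <- colSums(!is.na(m))
  if (any(n_obs < 2)) {
    abort("Every sample needs >= 2 observed values to estimate sigma.",
          class = "evcargo_input_error")
  }
  with_seed(seed, {
    for (j in seq_len(ncol(m))) {
      miss <- is.na(m[, j])
      if (!any(miss)) next
      mu <- mean(m[, j], na.rm = TRUE)
      sg <- sd(m[, j], na.rm = TRUE)
      m[miss, j] <- rnorm(sum(miss), mu - shift_sd * sg, width_sd * sg)
    }
  })
  quant$matrix <- m
  quant$imputed <- TRUE
  quant$imputation <- list(shift_sd = shift_sd, width_sd = width_sd,
                           seed = seed)
  quant
}

#' Per-group detection sets, core and merged proteome
#'
#' @param quant An `ev_quant` object carrying per-group detection flags.
#' @return A list of class `"detection_sets"`: `per_group` (named list of
#'   protein vectors), `core` (intersection), `merged` (union), and `counts`
#'   (tibble of set sizes).
#' @export
detection_sets <- function(quant) {
  stopifnot(inherits(quant, "ev_quant"))
  det <- quant$detection
  per_group <- split(det$protein[det$detected], det$group[det$detected])
  per_group <- lapply(per_group, sort)
  core <- sort(Reduce(intersect, per_group))
  merged <- sort(Reduce(union, per_group))
  counts <- tibble::tibble(
    set = c(names(per_group), "core", "merged"),
    n = c(vapply(per_group, length, integer(1)), length(core),
          length(merged)))
  structure(list(per_group = per_group, core = core, merged = merged,
                 counts = counts),
            class = "detection_sets")
}

#' @export
print.detection_sets <- function(x, ...) {
  cat("<detection_sets>\n")
  print(x$counts)
  invisible(x)
}
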