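# MISEV-2023 categorization of a quantified EV proteome and the
# precursor-share (%Np) category contribution statistics.

#' The MISEV-2023 marker ontology
#'
#' Fixed subcategory codes with their main-category roll-up. Category 1
#' covers transmembrane proteins of endosomal or plasma-membrane origin,
#' 2a cytosolic proteins tied to EV biogenesis, 3 major non-vesicular
#' co-isolates (3a restricted to lipoproteins; 3c exomere/supermere
#' components), 4 proteins of intracellular compartments other than
#' plasma membrane/endosomes (4b mitochondrial), and 5 secreted and/or
#' EV-corona associated proteins.
#'
#' @return A tibble: `subcategory`, `main_category`, `description`.
#' @export
misev_ontology <- function() {
  tibble::tribble(
    ~subcategory, ~main_category, ~description,
    "1a", "1", "Multi-pass transmembrane, plasma membrane/endosomes",
    "1b", "1", "Single-pass transmembrane, plasma membrane/endosomes",
    "2a", "2", "Cytosolic, linked to EV biogenesis",
    "2b", "2", "Cytosolic, promiscuously associated",
    "3a", "3", "Lipoproteins (non-EV co-isolates)",
    "3b", "3", "Protein aggregates / ribonucleoproteins",
    "3c", "3", "Exomere/supermere-enriched components",
    "4a", "4", "Organelles other than endosomes",
    "4b", "4", "Mitochondrial (MitoCarta)",
    "5a", "5", "Secreted / EV-corona",
    "5b", "5", "Cytokines and growth factors",
    "5c", "5", "Adhesion and extracellular-matrix proteins"
  )
}

#' Load a MISEV annotation table
#'
#' @param path TSV path or data frame with columns `gene`, `uniprot`
#'   (optional), `subcategory`, `source` (optional).
#' @return A validated tibble of class `"misev_annotation"`, one row per
#'   gene.
#' @export
load_annotation <- function(path) {
  raw <- if (is.data.frame(path)) tibble::as_tibble(path) else
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(raw, c("gene", "subcategory"), "MISEV annotation")
  onto <- misev_ontology()
  bad <- which(!raw$subcategory %in% onto$subcategory)
  if (length(bad)) {
    abort(sprintf("Unknown subcategory code(s) at row(s) %s: %s.",
                  paste(head(bad, 5), collapse = ", "),
                  paste(unique(raw$subcategory[bad]), collapse = ", ")),
          class = "evcargo_ontology_error")
  }
  dup <- raw$gene[duplicated(toupper(raw$gene))]
  if (length(dup)) {
    abort(sprintf("Duplicated gene(s) in annotation: %s.",
                  paste(unique(dup), collapse = ", ")),
          class = "evcargo_ontology_error")
  }
  out <- raw |>
    dplyr::mutate(uniprot = if ("uniprot" %in% names(raw)) .data$uniprot
                  else NA_character_,
                  source = if ("source" %in% names(raw)) .data$source
                  else NA_character_) |>
    dplyr::left_join(onto[c("subcategory", "main_category")],
                     by = "subcategory") |>
    dplyr::select("gene", "uniprot", "subcategory", "main_category", "source")
  class(out) <- c("misev_annotation", class(out))
  out
}

#' Write a MISEV annotation table
#' @param annotation A `misev_annotation` tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  readr::write_tsv(annotation[c("gene", "uniprot", "subcategory", "source")],
                   path)
  invisible(path)
}

#' Partition a proteome by MISEV category
#'
#' Matches gene symbols case-insensitively against the annotation; each
#' protein lands in at most one subcategory.
#'
#' @param genes Character vector of gene symbols (the quantified proteome).
#' @param annotation A `misev_annotation` tibble.
#' @return A tibble: `gene`, `subcategory`, `main_category`; unmatched genes
#'   carry `NA` in both category columns.
#' @export
annotate_proteome <- function(genes, annotation) {
  ann <- annotation |>
    dplyr::mutate(gene_key = toupper(.data$gene)) |>
    dplyr::select("gene_key", "subcategory", "main_category")
  tibble::tibble(gene = genes, gene_key = toupper(genes)) |>
    dplyr::left_join(ann, by = "gene_key") |>
    dplyr::select(-"gene_key")
}

#' Canonical EV marker panel (categories 1 and 2a)
#'
#' Transmembrane proteins of endosomal/plasma-membrane origin (main category
#' 1) plus cytosolic EV-biogenesis proteins (2a) form the canonical panel of
#' endosomal-origin EV markers.
#'
#' @param annotation A `misev_annotation` tibble.
#' @return Character vector of gene symbols.
#' @export
ev_panel <- function(annotation) {
  sort(annotation$gene[annotation$main_category == "1" |
                         annotation$subcategory == "2a"])
}

#' Per-sample MISEV category contribution (%Np)
#'
#' For every sample, the percentage of the sample's total q-passing
#' precursor count attributable to proteins of each (sub)category:
#' `%Np = 100 * sum(Np of annotated proteins in category) / total Np`.
#' The unannotated remainder is reported as category `"unannotated"`, so
#' per-sample percentages sum to 100.
#'
#' @param report A `precursor_report` tibble, ideally restricted to retained
#'   proteins (pass `proteins =` for that).
#' @param annotation A `misev_annotation` tibble.
#' @param level `"main"` or `"sub"` category resolution.
#' @param proteins Optional character vector restricting the report to the
#'   retained proteome.
#' @param q_max q-value threshold defining a detected precursor (default
#'   0.01).
#' @param mode `"count"` (distinct q-passing precursors, the default) or
#'   `"intensity"` (MaxLFQ share).
#'
#' @return A tibble of class `"category_summary"`: `sample`, `group`,
#'   `donor`, `category`, `pct_np`, with `attr(, "level")` recording the
#'   resolution.
#' @export
category_np_fraction <- function(report, annotation,
                                 level = c("main", "sub"),
                                 proteins = NULL, q_max = 0.01,
                                 mode = c("count", "intensity")) {
  level <- match.arg(level)
  mode <- match.arg(mode)
  rep <- dplyr::filter(report, .data$q_value < q_max)
  if (!is.null(proteins)) rep <- dplyr::filter(rep, .data$protein %in% proteins)
  if (!nrow(rep)) abort("No q-passing records.", class = "evcargo_input_error")

  per_prot <- rep |>
    dplyr::group_by(.data$run, .data$group, .data$donor, .data$protein,
                    .data$gene) |>
    dplyr::summarise(np = if (mode == "count")
      dplyr::n_distinct(.data$precursor) else sum(.data$intensity),
      .groups = "drop")

  totals <- per_prot |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(total = sum(.data$np), .groups = "drop")
  if (any(totals$total <= 0)) {
    abort("A sample has zero precursors.", class = "evcargo_input_error")
  }

  ann <- annotate_proteome(unique(per_prot$gene), annotation)
  cat_col <- if (level == "main") "main_category" else "subcategory"
  cats <- if (level == "main") unique(misev_ontology()$main_category)
          else misev_ontology()$subcategory

  out <- per_prot |>
    dplyr::left_join(ann, by = "gene") |>
    dplyr::mutate(category = dplyr::coalesce(.data[[cat_col]],
                                             "unannotated")) |>
    dplyr::group_by(sample = .data$run, .data$group, .data$donor,
                    .data$category) |>
    dplyr::summarise(np = sum(.data$np), .groups = "drop") |>
    tidyr::complete(tidyr::nesting(!!!rlang::syms(c("sample", "group",
                                                    "donor"))),
                    category = c(cats, "unannotated"),
                    fill = list(np = 0)) |>
    dplyr::left_join(totals, by = c(sample = "run")) |>
    dplyr::mutate(pct_np = 100 * .data$np / .data$total) |>
    dplyr::select("sample", "group", "donor", "category", "pct_np") |>
    dplyr::arrange(.data$sample, .data$category)
  attr(out, "level") <- level
  class(out) <- c("category_summary", class(out))
  out
}

#' Endosomal-contribution ratio
#'
#' Per-sample %Np of the endosomal-origin categories (main category 1 plus
#' subcategory 2a), normalized by the mean of the reference-group samples.
#' By construction the reference group's mean ratio is 1.
#'
#' @param summary A subcategory-level `category_summary` (from
#'   [category_np_fraction()] with `level = "sub"`).
#' @param reference_group Group whose mean endosomal share defines the
#'   denominator (default `"TAM"`).
#' @return A tibble: `sample`, `group`, `donor`, `endosomal_pct`, `ratio`.
#' @export
endosomal_ratio <- function(summary, reference_group = "TAM") {
  if (!identical(attr(summary, "level"), "sub")) {
    abort("`summary` must be at subcategory level (level = \"sub\").",
          class = "evcargo_input_error")
  }
  endo_cats <- c("1a", "1b", "2a")
  per_sample <- summary |>
    dplyr::filter(.data$category %in% endo_cats) |>
    dplyr::group_by(.data$sample, .data$group, .data$donor) |>
    dplyr::summarise(endosomal_pct = sum(.data$pct_np), .groups = "drop")
  ref <- per_sample$endosomal_pct[per_sample$group == reference_group]
  if (!length(ref)) {
    abort(sprintf("Reference group '%s' has no samples.", reference_group),
          class = "evcargo_input_error")
  }
  ref_mean <- mean(ref)
  if (ref_mean == 0) {
    abort("Reference-group mean endosomal share is zero.",
          class = "evcargo_input_error")
  }
  dplyr::mutate(per_sample, ratio = .data$endosomal_pct / ref_mean)
}

#' Row z-scores for a marker panel
#'
#' Per-gene standardization of log2 intensities across samples, using the
#' population SD (`sqrt(mean((x - mean(x))^2))`), as plotted in marker-panel
#' heatmaps. Constant rows get z = 0 and a flag.
#'
#' @param quant An `ev_quant` object.
#' @param panel Character vector of gene symbols.
#' @return A tibble: `gene`, `protein`, `sample`, `group`, `z`,
#'   `constant_row`; genes absent from the matrix are reported in
#'   `attr(, "absent")`.
#' @export
marker_panel_summary <- function(quant, panel) {
  stopifnot(inherits(quant, "ev_quant"))
  gmap <- quant$genes |>
    dplyr::mutate(gene_key = toupper(.data$gene))
  hit <- gmap[gmap$gene_key %in% toupper(panel), , drop = FALSE]
  absent <- setdiff(toupper(panel), gmap$gene_key)
  if (!nrow(hit)) {
    abort("No panel gene found in the matrix.", class = "evcargo_input_error")
  }
  m <- quant$matrix[hit$protein, , drop = FALSE]
  mu <- rowMeans(m)
  sdev <- sqrt(rowMeans((m - mu)^2))
  constant <- sdev == 0
  z <- (m - mu) / ifelse(constant, 1, sdev)
  z[constant, ] <- 0
  out <- tibble::as_tibble(z, rownames = "protein") |>
    tidyr::pivot_longer(-"protein", names_to = "sample", values_to = "z") |>
    dplyr::left_join(hit[c("protein", "gene")], by = "protein") |>
    dplyr::left_join(quant$samples, by = "sample") |>
    dplyr::mutate(constant_row = .data$protein %in% hit$protein[constant]) |>
    dplyr::select("gene", "protein", "sample", "group", "z", "constant_row")
  attr(out, "absent") <- absent
  out
}
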