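# MISEV ontology, annotation handling and %Np category statistics.

ann_fixture <- function() {
  load_annotation(tibble::tibble(
    gene = c("CD9", "TSG101", "APOB", "FASN", "C4B", "ALIX"),
    uniprot = sprintf("Q%05d", 1:6),
    subcategory = c("1a", "2a", "3a", "4b", "5a", "2a"),
    source = "fixture"))
}

test_that("ontology is a fixed 12-subcategory, 5-main-category map", {
  onto <- misev_ontology()
  expect_equal(nrow(onto), 12)
  expect_setequal(unique(onto$main_category), as.character(1:5))
  expect_equal(anyDuplicated(onto$subcategory), 0)
})

test_that("annotation load validates codes, duplicates, and round-trips", {
  ann <- ann_fixture()
  expect_equal(nrow(ann), 6)
  expect_equal(ann$main_category[ann$gene == "FASN"], "4")

  expect_error(load_annotation(tibble::tibble(gene = "X", subcategory = "9z")),
               class = "evcargo_ontology_error")
  expect_error(load_annotation(tibble::tibble(gene = c("A", "a"),
                                              subcategory = c("1a", "1b"))),
               class = "evcargo_ontology_error")

  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotation(ann, path)
  ann2 <- load_annotation(path)
  expect_equal(as.data.frame(ann2), as.data.frame(ann))
})

test_that("proteome annotation is a case-insensitive left join", {
  ann <- ann_fixture()
  res <- annotate_proteome(c("cd9", "UNKNOWN", "Tsg101"), ann)
  expect_equal(res$subcategory, c("1a", NA, "2a"))

  # brute-force comparison on a simulated annotation
  genes <- sprintf("G%04d", 1:500)
  sim_ann <- load_annotation(simulate_annotation(
    genes, c("1a" = 0.2, "2b" = 0.2, "4b" = 0.2, unannotated = 0.4),
    seed = 3))
  res2 <- annotate_proteome(genes, sim_ann)
  brute <- sim_ann$subcategory[match(toupper(genes), toupper(sim_ann$gene))]
  expect_equal(res2$subcategory, brute)

  empty <- load_annotation(tibble::tibble(gene = character(),
                                          subcategory = character()))
  expect_true(all(is.na(annotate_proteome(genes[1:5], empty)$subcategory)))
})

test_that("EV panel collects main category 1 plus subcategory 2a", {
  ann <- ann_fixture()
  expect_setequal(ev_panel(ann), c("CD9", "TSG101", "ALIX"))
  only2b <- load_annotation(tibble::tibble(gene = "X", subcategory = "2b"))
  expect_length(ev_panel(only2b), 0)
})

# report with controlled precursor counts per gene and run
np_report <- function(np_by_gene, runs = c("M1_D1", "TAM_D1"),
                      groups = c("M1", "TAM")) {
  rows <- purrr::map_dfr(runs, function(r) {
    purrr::imap_dfr(np_by_gene, function(np, g) {
      make_report_rows(r, paste0("PG_", g), np, 0.001, 1000, gene = g)
    })
  })
  read_report(rows, simple_sheet(runs, groups))
}

test_that("%Np fractions match hand-computable cases and invariants", {
  ann <- ann_fixture()
  # all precursors on a category-1 protein
  rep1 <- np_report(c(CD9 = 5))
  s1 <- category_np_fraction(rep1, ann, level = "main")
  expect_equal(s1$pct_np[s1$category == "1"], c(100, 100))

  # two categories with equal counts -> 50/50
  rep2 <- np_report(c(CD9 = 4, FASN = 4))
  s2 <- category_np_fraction(rep2, ann, level = "main")
  expect_equal(s2$pct_np[s2$category %in% c("1", "4")], rep(50, 4))

  # subcategory sums equal main-category values; total sums to 100
  sim <- simulate_report(sim_config(n_proteins = 300, seed = 41))
  repS <- read_report(sim$report, sim$sample_sheet)
  annS <- load_annotation(simulate_annotation(
    unique(repS$gene),
    c("1a" = 0.1, "1b" = 0.1, "2a" = 0.1, "3c" = 0.1, "4b" = 0.1,
      "5a" = 0.1, unannotated = 0.4), seed = 2))
  s_main <- category_np_fraction(repS, annS, level = "main")
  s_sub <- category_np_fraction(repS, annS, level = "sub")
  onto <- misev_ontology()
  rolled <- s_sub |>
    dplyr::left_join(onto, by = c(category = "subcategory")) |>
    dplyr::mutate(main = dplyr::coalesce(main_category, "unannotated")) |>
    dplyr::group_by(sample, main) |>
    dplyr::summarise(pct = sum(pct_np), .groups = "drop")
  joined <- dplyr::left_join(
    s_main, rolled, by = c(sample = "sample", category = "main"))
  expect_equal(joined$pct_np, joined$pct, tolerance = 1e-12)
  totals <- tapply(s_main$pct_np, s_main$sample, sum)
  expect_true(all(abs(totals - 100) < 1e-9))

  # brute-force per-sample check
  pass <- repS[repS$q_value < 0.01, ]
  smp <- pass$run[1]
  sub <- pass[pass$run == smp, ]
  per_gene <- tapply(sub$precursor, sub$gene,
                     function(x) length(unique(x)))
  cat1 <- annS$gene[annS$main_category == "1"]
  expected <- 100 * sum(per_gene[names(per_gene) %in% cat1]) /
    sum(per_gene)
  got <- s_main$pct_np[s_main$sample == smp & s_main$category == "1"]
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("%Np is invariant to scaling a sample's precursor counts", {
  ann <- ann_fixture()
  r1 <- np_report(c(CD9 = 2, FASN = 6))
  r2 <- np_report(c(CD9 = 4, FASN = 12))
  s1 <- category_np_fraction(r1, ann, level = "main")
  s2 <- category_np_fraction(r2, ann, level = "main")
  expect_equal(s1$pct_np, s2$pct_np, tolerance = 1e-12)
})

test_that("endosomal ratio normalizes by the reference-group mean", {
  ann <- ann_fixture()
  runs <- c("M1_D1", "M1_D2", "TAM_D1", "TAM_D2")
  rep <- np_report(c(CD9 = 3, FASN = 3), runs = runs,
                   groups = c("M1", "M1", "TAM", "TAM"))
  s <- category_np_fraction(rep, ann, level = "sub")
  er <- endosomal_ratio(s, reference_group = "TAM")
  expect_equal(er$ratio, rep(1, 4))
  expect_equal(mean(er$ratio[er$group == "TAM"]), 1)
  expect_error(endosomal_ratio(s, reference_group = "M9"),
               class = "evcargo_input_error")
  s_main <- category_np_fraction(rep, ann, level = "main")
  expect_error(endosomal_ratio(s_main), class = "evcargo_input_error")
})

test_that("marker panel z-scores use the population SD and flag flat rows", {
  m <- matrix(c(1, 2, 3,
                5, 5, 5), nrow = 2, byrow = TRUE,
              dimnames = list(c("G1", "G2"), c("A_D1", "A_D2", "A_D3")))
  q <- make_quant(m, rep("A", 3))
  z <- marker_panel_summary(q, c("G1", "G2", "MISSING"))
  z1 <- z$z[z$gene == "G1"]
  expect_equal(z1, c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  expect_true(all(z$z[z$gene == "G2"] == 0))
  expect_true(all(z$constant_row[z$gene == "G2"]))
  expect_equal(attr(z, "absent"), "MISSING")
  # standardization invariant on non-flat rows
  expect_equal(mean(z1), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z1^2)), 1, tolerance = 1e-12)
})
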