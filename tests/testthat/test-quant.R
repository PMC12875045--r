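# Report ingestion, q/Np filtering, median centering, imputation and
# detection-set algebra.

test_that("read_report validates and round-trips", {
  rows <- dplyr::bind_rows(
    make_report_rows("M1_D1", "P1", 3, 0.001, 1000),
    make_report_rows("M1_D1", "P2", 1, 0.001, 500))
  sheet <- simple_sheet("M1_D1", "M1")
  rep <- read_report(rows, sheet)
  expect_equal(nrow(rep), 4)
  expect_equal(rep$log2_intensity, log2(rep$intensity))

  expect_error(read_report(rows, simple_sheet("OTHER", "M1")),
               regexp = "M1_D1", class = "evcargo_mapping_error")
  bad <- rows; bad$PG.MaxLFQ[1] <- -1
  expect_error(read_report(bad, sheet), class = "evcargo_parse_error")

  path <- withr::local_tempfile(fileext = ".tsv")
  write_report(rep, path)
  rep2 <- read_report(path, sheet)
  expect_equal(as.data.frame(rep2), as.data.frame(rep))
})

filter_fixture <- function(np_by_donor, q = 0.001) {
  # one group, 3 donors, one test protein plus an anchor that always passes
  runs <- paste0("M1_D", 1:3)
  rows <- dplyr::bind_rows(
    purrr::map2_dfr(runs, np_by_donor, function(r, np) {
      if (np == 0) return(NULL)
      make_report_rows(r, "TEST", np, q, 1000)
    }),
    purrr::map_dfr(runs, function(r) make_report_rows(r, "ANCHOR", 3, 0.001,
                                                      2000)))
  read_report(rows, simple_sheet(runs, rep("M1", 3)))
}

test_that("Np >= 3 in at least half the donors decides retention", {
  q1 <- filter_protein_groups(filter_fixture(c(3, 3, 1)))
  expect_true("TEST" %in% rownames(q1$matrix))

  q2 <- filter_protein_groups(filter_fixture(c(3, 1, 1)))
  expect_false("TEST" %in% rownames(q2$matrix))

  # q-failing records do not count towards Np
  q3 <- filter_protein_groups(filter_fixture(c(3, 3, 3), q = 0.02))
  expect_false("TEST" %in% rownames(q3$matrix))
})

test_that("filtering matches a brute-force reimplementation on simulated data", {
  sim <- simulate_report(sim_config(n_proteins = 400, missing_rate = 0.3,
                                    q_fail_fraction = 0.2, seed = 17))
  rep <- read_report(sim$report, sim$sample_sheet)
  q <- filter_protein_groups(rep)

  # brute force: per group, count donors with >= 3 q-passing precursors
  brute <- character(0)
  df <- as.data.frame(rep[rep$q_value < 0.01, ])
  for (p in unique(df$protein)) {
    for (g in unique(rep$group)) {
      sub <- df[df$protein == p & df$group == g, ]
      n_ok <- 0
      for (d in unique(rep$donor[rep$group == g])) {
        np <- length(unique(sub$precursor[sub$donor == d]))
        if (np >= 3) n_ok <- n_ok + 1
      }
      n_donors <- length(unique(rep$donor[rep$group == g]))
      if (n_ok >= ceiling(0.5 * n_donors)) brute <- c(brute, p)
    }
  }
  expect_setequal(rownames(q$matrix), unique(brute))
})

test_that("filtering is monotone in q_max and min_precursors", {
  sim <- simulate_report(sim_config(n_proteins = 300, missing_rate = 0.3,
                                    q_fail_fraction = 0.3, seed = 19))
  rep <- read_report(sim$report, sim$sample_sheet)
  strict <- rownames(filter_protein_groups(rep, q_max = 0.005,
                                           min_precursors = 4)$matrix)
  default <- rownames(filter_protein_groups(rep)$matrix)
  loose <- rownames(filter_protein_groups(rep, q_max = 0.05,
                                          min_precursors = 2)$matrix)
  expect_true(all(strict %in% default))
  expect_true(all(default %in% loose))
})

test_that("median centering equalizes sample medians and is idempotent", {
  sim <- simulate_report(sim_config(n_proteins = 200, missing_rate = 0.2,
                                    seed = 23))
  q <- read_report(sim$report, sim$sample_sheet) |> filter_protein_groups()
  pre <- q$matrix
  cen <- median_center(q)
  med <- apply(cen$matrix, 2, median, na.rm = TRUE)
  expect_equal(max(med) - min(med), 0, tolerance = 1e-12)
  expect_equal(unname(med[1]),
               median(apply(pre, 2, median, na.rm = TRUE)))
  # within-sample differences preserved; missing untouched
  expect_equal(diff(cen$matrix[1:2, 1]), diff(pre[1:2, 1]))
  expect_identical(is.na(cen$matrix), is.na(pre))
  # idempotent
  cen2 <- median_center(cen)
  expect_equal(cen2$matrix, cen$matrix, tolerance = 1e-12)
})

test_that("a column shifted by +2 is centered back by exactly 2", {
  m <- make_two_group_matrix(50, seed = 5)
  cen <- median_center(make_quant(m, rep(c("A", "B"), each = 3)))
  shifted <- cen
  shifted$matrix[, 2] <- shifted$matrix[, 2] + 2
  recen <- median_center(shifted)
  expect_equal(recen$matrix, cen$matrix, tolerance = 1e-12)
})

test_that("imputation draws from the down-shifted normal and fills the mask", {
  sim <- simulate_report(sim_config(n_proteins = 150, missing_rate = 0.25,
                                    seed = 29))
  q <- read_report(sim$report, sim$sample_sheet) |>
    filter_protein_groups() |> median_center()
  pre <- q$matrix
  imp <- impute_missing(q, seed = 1)
  expect_false(anyNA(imp$matrix))
  expect_identical(imp$mask, is.na(pre))
  # observed cells never altered
  expect_equal(imp$matrix[!imp$mask], pre[!is.na(pre)])
  # determinism
  imp2 <- impute_missing(q, seed = 1)
  expect_identical(imp$matrix, imp2$matrix)

  # distributional check: many imputed cells in one sample
  big <- matrix(rnorm(20000, 20, 2), ncol = 2)
  big[1:8000, 1] <- NA
  qq <- make_quant(big, c("A", "A"))
  qq$matrix <- big
  mu <- mean(big[, 1], na.rm = TRUE); sg <- sd(big[, 1], na.rm = TRUE)
  qi <- impute_missing(qq, seed = 2)
  imputed <- qi$matrix[1:8000, 1]
  expect_lt(abs(mean(imputed) - (mu - 1.8 * sg)),
            3 * 0.3 * sg / sqrt(8000))
  expect_equal(sd(imputed), 0.3 * sg, tolerance = 0.05)
})

test_that("detection sets equal brute-force set algebra", {
  sim <- simulate_report(sim_config(n_proteins = 500, missing_rate = 0.35,
                                    q_fail_fraction = 0.2, seed = 37))
  q <- read_report(sim$report, sim$sample_sheet) |> filter_protein_groups()
  ds <- detection_sets(q)
  det <- q$detection
  by_group <- lapply(split(det, det$group),
                     function(d) sort(d$protein[d$detected]))
  expect_identical(ds$per_group, by_group[names(ds$per_group)])
  expect_identical(ds$core, sort(Reduce(intersect, by_group)))
  expect_identical(ds$merged, sort(Reduce(union, by_group)))
  # core subset of each group set subset of merged
  for (g in names(by_group)) {
    expect_true(all(ds$core %in% by_group[[g]]))
    expect_true(all(by_group[[g]] %in% ds$merged))
  }
})
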