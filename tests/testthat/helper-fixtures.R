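# Shared fixture builders. Everything is generated in code; no data files.

# Wrap a plain numeric matrix as an ev_quant object (complete, no missing
# cells) so differential tests can run without the report pipeline.
make_quant <- function(mat, groups) {
  stopifnot(ncol(mat) == length(groups))
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("P%04d", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) {
    colnames(mat) <- paste0(groups, "_", stats::ave(seq_along(groups),
                                                    groups, FUN = seq_along))
  }
  samples <- tibble::tibble(sample = colnames(mat), group = groups,
                            donor = sub("^.*_", "D", colnames(mat)))
  structure(list(matrix = mat,
                 mask = matrix(FALSE, nrow(mat), ncol(mat),
                               dimnames = dimnames(mat)),
                 np = matrix(3L, nrow(mat), ncol(mat),
                             dimnames = dimnames(mat)),
                 samples = samples,
                 genes = tibble::tibble(protein = rownames(mat),
                                        gene = rownames(mat)),
                 detection = tibble::tibble(protein = rownames(mat),
                                            group = groups[1],
                                            detected = TRUE),
                 filter = list(), centered = TRUE, imputed = TRUE),
            class = "ev_quant")
}

# Two-group null/planted matrix: n_a + n_b columns, optional effect added
# to group A for the first n_dap proteins. `sd` may be a vector of
# per-protein SDs (heterogeneous variances).
make_two_group_matrix <- function(n_proteins, n_a = 3, n_b = 3, sd = 0.5,
                                  effect = 0, n_dap = 0, seed = 1) {
  withr::with_seed(seed, {
    row_sd <- rep_len(sd, n_proteins)
    m <- matrix(rnorm(n_proteins * (n_a + n_b), mean = 20,
                      sd = rep(row_sd, n_a + n_b)),
                n_proteins)
    if (n_dap > 0) {
      sign <- rep(c(1, -1), length.out = n_dap)
      m[seq_len(n_dap), seq_len(n_a)] <-
        m[seq_len(n_dap), seq_len(n_a)] + sign * effect
    }
    rownames(m) <- sprintf("P%05d", seq_len(n_proteins))
    colnames(m) <- c(paste0("A_D", seq_len(n_a)), paste0("B_D", seq_len(n_b)))
    m
  })
}

# Minimal hand-built DIA-NN dialect report rows.
make_report_rows <- function(run, protein, precursors, q, intensity,
                             gene = protein) {
  tibble::tibble(Run = run, Protein.Group = protein, Genes = gene,
                 Precursor.Id = paste0(protein, "_PR", seq_len(precursors)),
                 Protein.Q.Value = q, PG.MaxLFQ = intensity)
}

simple_sheet <- function(runs, groups, donors = NULL) {
  tibble::tibble(Run = runs, group = groups,
                 donor = donors %||% sub("^.*_", "", runs))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Independent log-rank statistic (O-E / V form) used as an oracle against
# the survival-package implementation.
oracle_logrank_chisq <- function(time, event, grp) {
  grp <- as.integer(grp == levels(factor(grp))[2])
  tt <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in tt) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & grp == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}
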