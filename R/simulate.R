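# Synthetic-data generators. Every input the pipeline consumes can be
# produced here with known ground truth, so each downstream stage is
# testable without external downloads.

#' Simulation configuration for synthetic precursor reports
#'
#' Describes a label-free DIA experiment over polarized macrophage subtypes:
#' log-normal protein intensities (log2 scale), planted group effects on a
#' subset of proteins, intensity-dependent (MNAR) missingness, truncated-
#' Poisson precursor counts and run-level protein q-values.
#'
#' Differential proteins are planted by assigning each protein one of four
#' types: null (no group offset) or "up in" exactly one group (offset
#' `+effect_size` on the log2 scale). With three groups this makes every
#' pairwise contrast see a true log2 fold change of exactly `0` or
#' `±effect_size`, and each pairwise contrast carries an expected fraction
#' `dap_fraction` of differential proteins.
#'
#' @param n_proteins Number of protein groups.
#' @param groups Ordered group labels. Default `c("M1", "M2", "TAM")`.
#' @param donors_per_group Biological replicates per group (default 3,
#'   unpaired across groups).
#' @param dap_fraction Expected fraction of differential proteins per
#'   pairwise contrast.
#' @param effect_size Planted |log2 fold change| for differential proteins.
#' @param baseline_mean,baseline_sd Mean and SD of per-protein baseline
#'   log2 intensities.
#' @param resid_sd Within-group residual SD of log2 intensities (run noise).
#' @param missing_rate Target overall fraction of protein-run observations
#'   dropped as missing.
#' @param missing_mnar_strength Slope of the missingness-versus-intensity
#'   logistic; 0 gives missing-completely-at-random at `missing_rate`.
#' @param precursor_lambda Mean of the (>= 1 truncated) Poisson precursor
#'   count per protein and run.
#' @param q_fail_fraction Fraction of protein-run records assigned a
#'   run-specific protein q-value >= 0.01 (failing the default filter).
#' @param seed RNG seed; identical config and seed give identical output.
#'
#' @return A validated list of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(n_proteins = 200, seed = 1)
#' sim <- simulate_report(cfg)
#' dplyr::count(sim$report, Run)
sim_config <- function(n_proteins = 2000,
                       groups = c("M1", "M2", "TAM"),
                       donors_per_group = 3,
                       dap_fraction = 0.1,
                       effect_size = 2,
                       baseline_mean = 14,
                       baseline_sd = 2,
                       resid_sd = 0.5,
                       missing_rate = 0.1,
                       missing_mnar_strength = 1,
                       precursor_lambda = 6,
                       q_fail_fraction = 0.05,
                       seed = 1L) {
  if (!is.character(groups) || length(groups) < 2 || anyDuplicated(groups)) {
    abort("`groups` must be >= 2 distinct labels.",
          class = "evcargo_config_error")
  }
  cfg <- list(
    n_proteins = assert_count(n_proteins, "n_proteins"),
    groups = groups,
    donors_per_group = assert_count(donors_per_group, "donors_per_group"),
    dap_fraction = assert_fraction(dap_fraction, "dap_fraction"),
    effect_size = assert_fraction(effect_size, "effect_size", lo = 0, hi = Inf),
    baseline_mean = as.numeric(baseline_mean),
    baseline_sd = assert_positive(baseline_sd, "baseline_sd"),
    resid_sd = assert_positive(resid_sd, "resid_sd"),
    missing_rate = assert_fraction(missing_rate, "missing_rate"),
    missing_mnar_strength = assert_fraction(missing_mnar_strength,
                                            "missing_mnar_strength",
                                            lo = 0, hi = Inf),
    precursor_lambda = assert_positive(precursor_lambda, "precursor_lambda"),
    q_fail_fraction = assert_fraction(q_fail_fraction, "q_fail_fraction"),
    seed = as.integer(seed)
  )
  if (cfg$dap_fraction * 1.5 > 1) {
    abort("`dap_fraction` too large: 1.5 * dap_fraction must be <= 1.",
          class = "evcargo_config_error")
  }
  structure(cfg, class = "sim_config")
}

# Calibrate the logistic intercept so the mean drop probability over the
# realized intensities hits the target rate. Bisection on a; drop
# probability is plogis(a - b * x), monotone increasing in a.
calibrate_mnar_intercept <- function(x, b, target) {
  if (target <= 0) return(-Inf)
  if (target >= 1) return(Inf)
  f <- function(a) mean(plogis(a - b * x)) - target
  lo <- -50 + b * min(x)
  hi <- 50 + b * max(x)
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-10) break
  }
  (lo + hi) / 2
}

rpois_trunc1 <- function(n, lambda) {
  # >=1 truncated Poisson via inverse CDF
  p0 <- stats::dpois(0, lambda)
  u <- runif(n, min = p0, max = 1)
  qpois(u, lambda)
}

#' Simulate a DIA-NN style precursor report with ground truth
#'
#' Generates the long-format per-run, per-precursor quantification table the
#' quantification module consumes, together with a ground-truth record of
#' planted differential proteins, true group means, and which protein-run
#' records fail the q-value threshold.
#'
#' @param config A [sim_config()] object.
#'
#' @return A list of class `"ev_sim"` with elements
#'   \describe{
#'     \item{report}{tibble in DIA-NN report dialect: `Run`, `Protein.Group`,
#'       `Genes`, `Precursor.Id`, `Protein.Q.Value`, `PG.MaxLFQ` (raw scale).}
#'     \item{sample_sheet}{tibble mapping `Run` to `group` and `donor`.}
#'     \item{truth}{list: `protein_type` tibble (protein, gene, type,
#'       true group means), `dap` tibble of per-contrast planted log2 fold
#'       changes, `records` tibble of all protein-run draws with their true
#'       intensity, missing flag and q-pass flag.}
#'   }
#' @export
simulate_report <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be created by sim_config().",
          class = "evcargo_config_error")
  }
  cfg <- config
  with_seed(cfg$seed, {
    G <- length(cfg$groups)
    pid <- sprintf("P%05d", seq_len(cfg$n_proteins))
    gene <- sprintf("GENE%05d", seq_len(cfg$n_proteins))

    # protein types: null or up in exactly one group
    p_up <- cfg$dap_fraction / 2
    type <- sample(c("null", paste0("up_", cfg$groups)),
                   cfg$n_proteins, replace = TRUE,
                   prob = c(1 - G * p_up, rep(p_up, G)))
    base <- rnorm(cfg$n_proteins, cfg$baseline_mean, cfg$baseline_sd)
    offsets <- matrix(0, cfg$n_proteins, G, dimnames = list(pid, cfg$groups))
    for (g in cfg$groups) {
      offsets[type == paste0("up_", g), g] <- cfg$effect_size
    }
    true_means <- offsets + base

    samples <- tidyr::expand_grid(group = cfg$groups,
                                  donor = seq_len(cfg$donors_per_group)) |>
      dplyr::mutate(Run = sprintf("%s_D%d", .data$group, .data$donor),
                    donor = sprintf("D%d", .data$donor)) |>
      dplyr::select("Run", "group", "donor")

    n_run <- nrow(samples)
    # protein x run true log2 intensities
    intens <- true_means[, samples$group, drop = FALSE] +
      matrix(rnorm(cfg$n_proteins * n_run, 0, cfg$resid_sd),
             cfg$n_proteins, n_run)
    colnames(intens) <- samples$Run

    x <- as.vector(intens)
    a <- calibrate_mnar_intercept(x, cfg$missing_mnar_strength,
                                  cfg$missing_rate)
    p_drop <- if (is.finite(a)) plogis(a - cfg$missing_mnar_strength * x)
              else rep(if (a > 0) 1 else 0, length(x))
    missing <- runif(length(x)) < p_drop

    q_fail <- runif(length(x)) < cfg$q_fail_fraction
    q_value <- ifelse(q_fail, runif(length(x), 0.01, 0.5),
                      runif(length(x), 0, 0.0099))
    np <- rpois_trunc1(length(x), cfg$precursor_lambda)

    records <- tibble::tibble(
      protein = rep(pid, times = n_run),
      gene = rep(gene, times = n_run),
      Run = rep(samples$Run, each = cfg$n_proteins),
      log2_intensity = x,
      missing = missing,
      q_value = q_value,
      q_pass = !q_fail,
      n_precursors = np
    )

    obs <- records[!records$missing, , drop = FALSE]
    report <- obs[rep(seq_len(nrow(obs)), obs$n_precursors), ] |>
      dplyr::group_by(.data$protein, .data$Run) |>
      dplyr::mutate(Precursor.Id = sprintf("%s_PR%02d", .data$protein,
                                           dplyr::row_number())) |>
      dplyr::ungroup() |>
      dplyr::transmute(
        Run = .data$Run,
        Protein.Group = .data$protein,
        Genes = .data$gene,
        Precursor.Id = .data$Precursor.Id,
        Protein.Q.Value = .data$q_value,
        PG.MaxLFQ = 2^.data$log2_intensity
      ) |>
      dplyr::arrange(.data$Run, .data$Protein.Group, .data$Precursor.Id)

    contrasts <- utils::combn(cfg$groups, 2, simplify = FALSE)
    dap <- purrr::map_dfr(contrasts, function(cc) {
      lfc <- offsets[, cc[1]] - offsets[, cc[2]]
      tibble::tibble(contrast = paste(cc[1], "vs", cc[2]),
                     group_a = cc[1], group_b = cc[2],
                     protein = pid, gene = gene,
                     true_log2fc = unname(lfc),
                     is_dap = lfc != 0)
    })

    protein_type <- tibble::as_tibble(true_means, rownames = "protein") |>
      dplyr::mutate(gene = gene, type = type, .after = "protein")

    structure(list(report = report,
                   sample_sheet = samples,
                   truth = list(protein_type = protein_type,
                                dap = dap,
                                records = records),
                   config = cfg),
              class = "ev_sim")
  })
}

#' Simulate a MISEV-style annotation table
#'
#' Assigns each gene at most one MISEV-2023 subcategory (or leaves it
#' unannotated) by a multinomial draw over the supplied weights.
#'
#' @param genes Character vector of gene symbols.
#' @param category_weights Named numeric weights over MISEV subcategory codes
#'   (see [misev_ontology()]) plus `"unannotated"`. Need not sum to 1.
#' @param seed RNG seed.
#'
#' @return A tibble with columns `gene`, `uniprot`, `subcategory`, `source`
#'   containing one row per annotated gene.
#' @export
simulate_annotation <- function(genes, category_weights, seed = 1L) {
  onto <- misev_ontology()
  valid <- c(onto$subcategory, "unannotated")
  bad <- setdiff(names(category_weights), valid)
  if (length(bad)) {
    abort(sprintf("Unknown subcategory label(s) in weights: %s.",
                  paste(bad, collapse = ", ")),
          class = "evcargo_ontology_error")
  }
  if (any(category_weights < 0) || sum(category_weights) <= 0) {
    abort("Weights must be non-negative and not all zero.",
          class = "evcargo_config_error")
  }
  with_seed(seed, {
    draw <- sample(names(category_weights), length(genes), replace = TRUE,
                   prob = category_weights)
    keep <- draw != "unannotated"
    tibble::tibble(
      gene = genes[keep],
      uniprot = sprintf("Q%05d", seq_along(genes))[keep],
      subcategory = draw[keep],
      source = "simulated"
    )
  })
}

#' Simulate a survival cohort with log-linear protein hazards
#'
#' Exponential baseline hazard; each subject's relapse hazard is
#' `rate * exp(sum(beta_j * z_j))` with standardized protein levels `z`.
#' Censoring is administrative-uniform, tuned to the requested rate.
#'
#' @param n_subjects Number of subjects.
#' @param hazard_betas Named numeric vector: log hazard ratio per (standard
#'   deviation of) protein. Proteins without effect may be included with 0.
#' @param censor_rate Target fraction of censored subjects, in `[0, 1]`.
#' @param baseline_rate Events per month under z = 0 (default 1/12).
#' @param n_null_proteins Additional no-effect proteins to append.
#' @param seed RNG seed.
#'
#' @return A tibble of class `"ev_cohort"`: `subject_id`, `time_months`,
#'   `event`, one column per protein; true hazard ratios in
#'   `attr(, "true_hr")`.
#' @export
simulate_cohort <- function(n_subjects, hazard_betas, censor_rate = 0.3,
                            baseline_rate = 1 / 12, n_null_proteins = 0,
                            seed = 1L) {
  n_subjects <- assert_count(n_subjects, "n_subjects")
  censor_rate <- assert_fraction(censor_rate, "censor_rate")
  baseline_rate <- assert_positive(baseline_rate, "baseline_rate")
  if (is.null(names(hazard_betas)) || any(names(hazard_betas) == "")) {
    abort("`hazard_betas` must be a named vector.",
          class = "evcargo_config_error")
  }
  with_seed(seed, {
    prot <- c(names(hazard_betas),
              if (n_null_proteins > 0) sprintf("NULLP%03d",
                                               seq_len(n_null_proteins)))
    beta <- c(unname(hazard_betas), rep(0, n_null_proteins))
    z <- matrix(rnorm(n_subjects * length(prot)), n_subjects,
                dimnames = list(NULL, prot))
    lp <- drop(z %*% beta)
    t_event <- rexp(n_subjects, rate = baseline_rate * exp(lp))
    if (censor_rate >= 1) {
      time <- t_event
      event <- rep(0L, n_subjects)
    } else if (censor_rate == 0) {
      time <- t_event
      event <- rep(1L, n_subjects)
    } else {
      # uniform censoring window scaled until the empirical rate is hit
      cmax <- quantile(t_event, probs = 1 - censor_rate) * 2
      t_cens <- runif(n_subjects, 0, cmax)
      for (i in seq_len(60)) {
        rate <- mean(t_cens < t_event)
        if (abs(rate - censor_rate) < 0.005) break
        cmax <- cmax * if (rate > censor_rate) 1.15 else 0.87
        t_cens <- runif(n_subjects, 0, cmax)
      }
      event <- as.integer(t_event <= t_cens)
      time <- pmin(t_event, t_cens)
    }
    out <- tibble::tibble(subject_id = sprintf("S%04d", seq_len(n_subjects)),
                          time_months = time, event = event) |>
      dplyr::bind_cols(tibble::as_tibble(z))
    attr(out, "true_hr") <- setNames(exp(beta), prot)
    class(out) <- c("ev_cohort", class(out))
    out
  })
}

#' Simulate paired expression profiles sharing a marker signal
#'
#' Two matched log-scale expression vectors over a gene universe. Marker
#' genes share a latent value across the pair with the stated correlation;
#' non-marker genes are independent.
#'
#' @param n_genes Universe size.
#' @param marker_set_size Number of marker genes (<= `n_genes`).
#' @param marker_correlation Target correlation of marker values across the
#'   pair, in `[-1, 1]`.
#' @param noise_sd Additional independent noise SD on each profile.
#' @param seed RNG seed.
#'
#' @return A list: `expression` tibble (`gene`, `x`, `y`, log scale) and
#'   `markers` character vector.
#' @export
simulate_paired_expression <- function(n_genes, marker_set_size,
                                       marker_correlation, noise_sd = 0,
                                       seed = 1L) {
  n_genes <- assert_count(n_genes, "n_genes")
  marker_set_size <- assert_count(marker_set_size, "marker_set_size")
  if (marker_set_size > n_genes) {
    abort("`marker_set_size` must be <= `n_genes`.",
          class = "evcargo_config_error")
  }
  marker_correlation <- assert_fraction(marker_correlation,
                                        "marker_correlation", lo = -1, hi = 1)
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.",
                          class = "evcargo_config_error")
  with_seed(seed, {
    gene <- sprintf("G%05d", seq_len(n_genes))
    markers <- sample(gene, marker_set_size)
    is_m <- gene %in% markers
    rho <- marker_correlation
    latent <- rnorm(n_genes)
    x <- numeric(n_genes); y <- numeric(n_genes)
    # bivariate normal with correlation rho for markers, independent otherwise
    x[is_m] <- latent[is_m]
    y[is_m] <- rho * latent[is_m] +
      sqrt(1 - rho^2) * rnorm(sum(is_m))
    x[!is_m] <- rnorm(sum(!is_m))
    y[!is_m] <- rnorm(sum(!is_m))
    if (noise_sd > 0) {
      x <- x + rnorm(n_genes, 0, noise_sd)
      y <- y + rnorm(n_genes, 0, noise_sd)
    }
    list(expression = tibble::tibble(gene = gene, x = x, y = y),
         markers = markers)
  })
}

#' Simulate nano-flow-cytometry particle-size events
#'
#' Draws event sizes from a Gaussian mixture, truncated by rejection to the
#' calibrated instrument window of 40-200 nm.
#'
#' @param components A list of `c(mean, sd, weight)` triples (nm); weights
#'   must sum to 1.
#' @param n_events Number of events to return.
#' @param seed RNG seed.
#' @param window Size window in nm (default `c(40, 200)`).
#'
#' @return A tibble with column `size_nm`.
#' @export
simulate_size_events <- function(components, n_events, seed = 1L,
                                 window = c(40, 200)) {
  if (!length(components)) {
    abort("`components` must be a non-empty list of (mean, sd, weight).",
          class = "evcargo_config_error")
  }
  comp <- do.call(rbind, lapply(components, function(x) {
    if (length(x) != 3) abort("Each component needs (mean, sd, weight).",
                              class = "evcargo_config_error")
    as.numeric(x)
  }))
  if (abs(sum(comp[, 3]) - 1) > 1e-8) {
    abort("Component weights must sum to 1.", class = "evcargo_config_error")
  }
  n_events <- assert_count(n_events, "n_events")
  with_seed(seed, {
    out <- numeric(0)
    while (length(out) < n_events) {
      m <- max(2L * (n_events - length(out)), 100L)
      k <- sample(nrow(comp), m, replace = TRUE, prob = comp[, 3])
      x <- rnorm(m, comp[k, 1], comp[k, 2])
      out <- c(out, x[x >= window[1] & x <= window[2]])
    }
    tibble::tibble(size_nm = out[seq_len(n_events)])
  })
}
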