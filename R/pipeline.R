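#' Pipeline configuration
#'
#' Builds and validates the configuration driving [run_pipeline()]. Defaults
#' are the conventional workflow parameters: 0.0025 ppm buckets over 0-10
#' ppm excluding 4.65-5.25 ppm, PQN + Pareto conditioning, 7-fold
#' cross-validation, VIP > 1, SUS thresholds 0.2/0.3, |r| > 0.6 networks and
#' the 0.05/0.01/0.001 significance ladder. Pass either a named list of
#' overrides or a YAML file path.
#'
#' @param config Named list of overrides, or a YAML file path, or `NULL`.
#' @param seed Overrides the seed from the config when not `NULL`.
#' @return Validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = NULL, seed = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    tissue = "serum",
    effect_size = 1,
    sim = list(n_per_group = 8, ppm_grid = c(0, 10, 8001)),
    bucket_width = 0.0025,
    bucket_range = c(0, 10),
    water_exclusion = c(4.65, 5.25),
    align_segment_width = 0.02,
    align_max_shift = 5,
    baseline_smoothness = 1e6,
    baseline_asymmetry = 0.001,
    folds = 7,
    max_orthogonal = 1,
    tau_diag = 0.2,
    tau_corr = NULL,  # NULL = sample-size-aware via sus_tau_corr()
    alpha_levels = c(0.05, 0.01, 0.001),
    network_threshold = 0.6,
    seed = 1L,
    outdir = NULL,
    write_spectra = FALSE
  )
  cfg <- utils::modifyList(defaults, config %||% list())
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  # schema validation before any stage runs
  w <- cfg$bucket_width
  divisible <- function(x) {
    r <- (x - cfg$bucket_range[1]) / w
    abs(r - round(r)) * w < 1e-9
  }
  if (!cfg$tissue %in% c("serum", "brain")) {
    stop("config: tissue must be serum or brain", call. = FALSE)
  }
  if (w <= 0 || !divisible(cfg$bucket_range[2]) || !all(divisible(cfg$water_exclusion))) {
    stop("config: bucket_width must divide the range and exclusion boundaries",
         call. = FALSE)
  }
  if (cfg$folds < 2) stop("config: folds must be >= 2", call. = FALSE)
  if (cfg$network_threshold < 0 || cfg$network_threshold > 1) {
    stop("config: network_threshold must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$max_orthogonal < 0) stop("config: max_orthogonal must be >= 0", call. = FALSE)
  cfg$sim <- do.call(sim_config, utils::modifyList(cfg$sim, list(seed = cfg$seed)))
  class(cfg) <- "pipeline_config"
  cfg
}

write_sidecar <- function(outdir, stage, params) {
  jsonlite::write_json(params, file.path(outdir, paste0(stage, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full analysis pipeline
#'
#' Simulate -> preprocess -> chemometrics -> univariate -> network ->
#' report, writing each stage's artifacts and a JSON provenance sidecar to
#' `outdir`. The same config yields an identical bundle. A stage failure
#' aborts with the stage named and leaves a `FAILED` marker next to the
#' partial outputs.
#'
#' @param config [pipeline_config()], a named override list, or a YAML path.
#' @param outdir Output directory (overrides the config's).
#' @return Invisibly, a list with the main stage results (`cohort`,
#'   `buckets`, `models`, `sus`, `venn`, `fc`, `networks`, `report_path`).
#' @export
run_pipeline <- function(config = NULL, outdir = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  outdir <- outdir %||% cfg$outdir %||% stop("an output directory is required")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate"
  res <- tryCatch({
    ## simulate ---------------------------------------------------------
    templates <- build_library(cfg$tissue)
    design <- default_study_design(cfg$tissue, cfg$effect_size)
    cohort <- simulate_cohort(design, templates, cfg$sim)
    if (isTRUE(cfg$write_spectra)) {
      write_spectrum_set(cohort, file.path(outdir, "spectra"))
    }
    utils::write.csv(
      data.frame(sample_id = names(cohort$labels), group = unname(cohort$labels)),
      file.path(outdir, "labels.csv"), row.names = FALSE, quote = FALSE)
    write_sidecar(outdir, "simulate",
                  list(tissue = cfg$tissue, seed = cfg$seed,
                       n_per_group = cfg$sim$n_per_group,
                       effect_size = cfg$effect_size,
                       groups = vapply(design, function(g) g$group, character(1))))

    ## preprocess -------------------------------------------------------
    stage <- "preprocess"
    spectra <- lapply(cohort$spectra, function(s) {
      baseline_correct(reference_to_tsp(s), cfg$baseline_smoothness,
                       cfg$baseline_asymmetry)
    })
    set2 <- new_spectrum_set(spectra, cohort$labels, cohort$truth)
    set2 <- align_segments(set2, cfg$align_segment_width, cfg$align_max_shift)
    bt <- bucket(set2, cfg$bucket_width, cfg$bucket_range, cfg$water_exclusion)
    pqn <- pqn_normalize(bt)
    scaled <- pareto_scale(pqn$table)
    write_bucket_table(pqn$table, file.path(outdir, "buckets_pqn.csv"),
                       params = list(width = cfg$bucket_width,
                                     range = cfg$bucket_range,
                                     exclusion = cfg$water_exclusion,
                                     seed = cfg$seed))
    write_sidecar(outdir, "preprocess",
                  list(width = cfg$bucket_width, range = cfg$bucket_range,
                       exclusion = cfg$water_exclusion,
                       n_buckets = ncol(bt$values),
                       align_segment_width = cfg$align_segment_width,
                       align_max_shift = cfg$align_max_shift))

    ## chemometrics -----------------------------------------------------
    stage <- "multivariate"
    groups <- unique(unname(cohort$labels))
    ref <- "Model"
    treatments <- setdiff(groups, c("Sham", ref))
    comparisons <- c(list(c("Sham", ref)),
                     lapply(treatments, function(g) c(g, ref)))
    assignments <- default_assignments(templates, exclude = cfg$water_exclusion,
                                       range = cfg$bucket_range)
    quants <- integrate_metabolites(pqn$table, assignments,
                                    exclude = cfg$water_exclusion)
    qm_all <- as.matrix(quants[, -(1:2)])
    rownames(qm_all) <- quants$sample_id
    models <- list(); summaries <- list(); xmats <- list()
    for (cmp in comparisons) {
      sel <- unname(cohort$labels) %in% cmp
      Xq <- scale_pareto_matrix(qm_all[sel, , drop = FALSE])
      yq <- unname(cohort$labels)[sel]
      m <- fit_oplsda(Xq, yq, cfg$max_orthogonal, positive_class = cmp[1])
      cv <- cross_validate(Xq, yq, cfg$max_orthogonal, cfg$folds, cfg$seed,
                           positive_class = cmp[1])
      key <- paste(cmp[1], "vs", cmp[2])
      models[[key]] <- m
      xmats[[key]] <- Xq
      summaries[[key]] <- list(R2X = m$R2X, R2Y = m$R2Y, Q2Y = cv$Q2Y,
                               n_orthogonal = m$n_orthogonal,
                               folds = cfg$folds, seed = cfg$seed)
      sp <- s_plot(m, Xq)
      utils::write.csv(cbind(sp, VIP = unname(vip(m))),
                       file.path(outdir, paste0("splot_", gsub("[^A-Za-z0-9.]", "_", key), ".csv")),
                       row.names = FALSE)
    }
    write_sidecar(outdir, "multivariate", summaries)
    early <- paste(treatments[1], "vs", ref)
    sus <- list(); venns <- NULL
    if (length(treatments) >= 2) {
      for (g in treatments[-1]) {
        key <- paste(g, "vs", ref)
        tau_c <- cfg$tau_corr %||% sus_tau_corr(nrow(xmats[[early]]))
        sus[[paste(treatments[1], "vs", g)]] <-
          sus_plot(models[[early]], models[[key]], xmats[[early]], xmats[[key]],
                   cfg$tau_diag, tau_c)
      }
      eff_sets <- lapply(models[comparisons_keys <- vapply(
        comparisons[-1], function(cmp) paste(cmp[1], "vs", ref), character(1))],
        function(m) {
          v <- vip(m)
          names(v)[v > 1]
        })
      names(eff_sets) <- vapply(comparisons[-1], `[`, character(1), 1)
      venns <- venn_partition(eff_sets[seq_len(min(4, length(eff_sets)))])
      for (nm in names(sus)) {
        utils::write.csv(sus[[nm]],
                         file.path(outdir, paste0("sus_", gsub("[^A-Za-z0-9.]", "_", nm), ".csv")),
                         row.names = FALSE)
      }
    }

    ## univariate -------------------------------------------------------
    stage <- "univariate"
    fc_cmp <- c(list(c(ref, "Sham")), lapply(treatments, function(g) c(g, ref)))
    fct <- fc_table(quants, fc_cmp)
    render_fc_table(fct, file.path(outdir, "fold_changes.csv"))
    write_sidecar(outdir, "univariate",
                  list(comparisons = vapply(fc_cmp, paste, character(1), collapse = " vs "),
                       fc_statistic = "mean", alpha_levels = cfg$alpha_levels))

    ## network ----------------------------------------------------------
    stage <- "network"
    networks <- list()
    for (g in treatments) {
      qg <- quants[quants$group == g, , drop = FALSE]
      R <- pearson_matrix(qg)
      dirs <- fc_direction(fct, paste(g, "vs", ref))
      net <- build_network(R, cfg$network_threshold, dirs, group = g)
      networks[[g]] <- net
      safe <- gsub("[^A-Za-z0-9.]", "_", g)
      write_network_edgelist(net, file.path(outdir, paste0("network_", safe, ".tsv")))
      write_network_graphml(net, file.path(outdir, paste0("network_", safe, ".graphml")))
    }
    write_sidecar(outdir, "network",
                  list(threshold = cfg$network_threshold, groups = treatments))

    ## report -----------------------------------------------------------
    stage <- "report"
    report_path <- make_report(
      list(config = cfg, summaries = summaries, sus = sus, venn = venns,
           fc = fct, networks = networks,
           n_buckets = ncol(bt$values), pqn = pqn),
      file.path(outdir, "report.md"))

    list(cohort = cohort, buckets = scaled, pqn = pqn, quantities = quants,
         models = models, summaries = summaries, sus = sus, venn = venns,
         fc = fct, networks = networks, report_path = report_path)
  }, error = function(e) {
    writeLines(paste0("FAILED at stage: ", stage, "\n", conditionMessage(e)),
               file.path(outdir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

# Pareto scaling for a plain matrix (no bucket-table bookkeeping)
scale_pareto_matrix <- function(X, eps = 1e-12) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  out <- sweep(sweep(X, 2, mu), 2, sqrt(pmax(sdv, eps)), "/")
  out[, sdv < eps] <- 0
  out
}

# up/down node attribute from a fold-change table for one comparison
fc_direction <- function(fct, comparison) {
  rows <- fct[fct$comparison == comparison, ]
  stats::setNames(ifelse(rows$log2FC >= 0, "up", "down"), rows$metabolite)
}

#' Assemble a Markdown report from pipeline stage outputs
#'
#' One document with model summaries, SUS/Venn section, fold-change table
#' and network summaries. Missing stages are listed and marked as gaps
#' rather than aborting.
#'
#' @param stage_outputs Named list with any of `config`, `summaries`, `sus`,
#'   `venn`, `fc`, `networks`, `n_buckets`.
#' @param path Output Markdown path.
#' @return `path`, invisibly.
#' @export
make_report <- function(stage_outputs, path) {
  so <- stage_outputs
  lines <- c("# NMR metabolomics pipeline report", "")
  gaps <- setdiff(c("summaries", "fc", "networks"), names(so)[!vapply(so, is.null, logical(1))])
  if (length(gaps)) {
    lines <- c(lines, paste0("**Missing stage output:** ", paste(gaps, collapse = ", ")), "")
  }
  if (!is.null(so$config)) {
    lines <- c(lines, "## Parameters",
               sprintf("- tissue: %s; seed: %d; n/group: %d", so$config$tissue,
                       so$config$seed, so$config$sim$n_per_group),
               sprintf("- buckets: %.4f ppm over [%g, %g], excluding [%g, %g]",
                       so$config$bucket_width, so$config$bucket_range[1],
                       so$config$bucket_range[2], so$config$water_exclusion[1],
                       so$config$water_exclusion[2]),
               if (!is.null(so$n_buckets)) sprintf("- retained buckets: %d", so$n_buckets),
               "")
  }
  if (!is.null(so$summaries)) {
    lines <- c(lines, "## OPLS-DA model summaries", "",
               "| comparison | R2X | R2Y | Q2Y | n_ortho |",
               "|---|---|---|---|---|")
    for (nm in names(so$summaries)) {
      s <- so$summaries[[nm]]
      lines <- c(lines, sprintf("| %s | %.3f | %.3f | %.3f | %d |",
                                nm, s$R2X, s$R2Y, s$Q2Y, s$n_orthogonal))
    }
    lines <- c(lines, "")
  }
  if (!is.null(so$sus) && length(so$sus)) {
    lines <- c(lines, "## Shared and unique structure", "")
    for (nm in names(so$sus)) {
      tab <- table(so$sus[[nm]]$classification)
      lines <- c(lines, sprintf("- %s: %s", nm,
                                paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
    }
    lines <- c(lines, "")
  }
  if (!is.null(so$venn)) {
    lines <- c(lines, "## Venn partition of VIP > 1 sets", "")
    for (nm in names(so$venn$regions)) {
      lines <- c(lines, sprintf("- %s: %d", nm, length(so$venn$regions[[nm]])))
    }
    lines <- c(lines, "")
  }
  if (!is.null(so$fc)) {
    sig <- so$fc[so$fc$adjusted_p < 0.05 & !is.na(so$fc$adjusted_p), ]
    lines <- c(lines, "## Univariate screening",
               sprintf("- %d metabolite x comparison cells with adjusted p < 0.05 (of %d)",
                       nrow(sig), nrow(so$fc)), "")
  }
  if (!is.null(so$networks)) {
    lines <- c(lines, "## Correlation networks", "")
    for (nm in names(so$networks)) {
      cs <- centrality_summary(so$networks[[nm]], top_k = 3)
      lines <- c(lines, sprintf("- %s: %d edges; top hub: %s (degree %d)",
                                nm, nrow(so$networks[[nm]]$edges),
                                cs$name[1], cs$degree[1]))
    }
    lines <- c(lines, "")
  }
  writeLines(lines[!vapply(lines, is.null, logical(1))], path)
  invisible(path)
}
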