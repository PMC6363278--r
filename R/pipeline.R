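#' Default pipeline configuration
#'
#' A single list drives the whole synthetic end-to-end run: genome, plan,
#' simulation parameters, caller settings, statistical thresholds (alpha =
#' 0.01, stable-expression threshold 0.05 FPKM), nucleus radius (5 um) and
#' ensemble size. Fields can be overridden individually or loaded from a
#' YAML file with [read_run_config()].
#'
#' @param seed master seed; every stage derives its own sub-seed from it.
#' @param ... overrides of the default fields.
#' @return a `run_config` list.
#' @export
default_run_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    genome = list(chromosomes = c(chr1 = 3e7, chr2 = 3e7,
                                  chr3 = 3e7, chr4 = 3e7),
                  bin_size = 1e4),
    plan = NULL,                 # NULL -> default_transition_plan()
    sim = list(),                # overrides for sim_config()
    caller = list(n_runs = 10, jitter_sd = 0.1, min_score = 3),
    n_models = 100,
    n_genes_per_transition = 25,
    n_nuclei = 100,
    alpha = 0.01,
    stable_threshold = 0.05,
    schema_version = "1.0")
  ov <- list(...)
  cfg[names(ov)] <- ov
  class(cfg) <- "run_config"
  cfg
}

#' @rdname default_run_config
#' @param path YAML file with (a subset of) the config fields.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- default_run_config()
  for (nm in names(y)) {
    if (nm == "genome") {
      if (!is.null(y$genome$chromosomes))
        cfg$genome$chromosomes <- unlist(y$genome$chromosomes)
      if (!is.null(y$genome$bin_size))
        cfg$genome$bin_size <- y$genome$bin_size
    } else if (nm == "plan") {
      cfg$plan <- transition_plan(
        control = vapply(y$plan, `[[`, "", "control"),
        treated = vapply(y$plan, `[[`, "", "treated"),
        bp = vapply(y$plan, function(e) as.numeric(e$bp), numeric(1)),
        n_domains = vapply(y$plan, function(e)
          as.integer(e$n_domains), integer(1)))
    } else if (nm == "sim") {
      cfg$sim[names(y$sim)] <- y$sim
    } else if (nm == "caller") {
      cfg$caller[names(y$caller)] <- y$caller
    } else {
      cfg[[nm]] <- y[[nm]]
    }
  }
  cfg
}

build_sim_config <- function(cfg) {
  args <- cfg$sim
  if (!is.null(args$radial_bias)) args$radial_bias <- unlist(args$radial_bias)
  if (!is.null(args$expr_effect)) args$expr_effect <- unlist(args$expr_effect)
  args$seed <- cfg$seed
  do.call(sim_config, args)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full synthetic pipeline
#'
#' simulate -> tracks -> call-lads -> classify -> fate -> expression ->
#' radial -> fish -> report. All randomness derives from `config$seed`, so
#' identical configs reproduce identical numeric outputs. A stage failure
#' halts the run with the failing stage named; outputs of completed stages
#' remain on disk.
#'
#' @param config a `run_config` (see [default_run_config()]).
#' @param out_dir output directory (created if missing).
#' @return invisibly, the report bundle (also written as
#'   `summary.json` plus BED/bedGraph/TSV files under `out_dir`).
#' @export
run_all <- function(config = default_run_config(), out_dir = tempfile("ladrun")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  seed <- config$seed
  genome <- lad_genome(config$genome$chromosomes, config$genome$bin_size)
  plan <- if (is.null(config$plan)) default_transition_plan() else config$plan
  scfg <- build_sim_config(config)
  conditions <- c("control", "treated")
  lamins <- c("A", "B")

  ## stage: simulate -------------------------------------------------------
  truth <- stage("simulate", {
    tr <- plant_architecture(genome, plan, seed = seed)
    yaml::write_yaml(lapply(seq_len(nrow(plan)), function(i) as.list(plan[i, ])),
                     p("plan.yaml"))
    utils::write.table(tr$domains, p("truth_domains.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (cond in conditions)
      for (lam in lamins)
        write_bed(lamin_set(tr[[cond]], lam),
                  p(sprintf("truth_LADs_lamin%s_%s.bed", lam, cond)))
    tr
  })

  ## stage: tracks ---------------------------------------------------------
  ratio <- stage("tracks", {
    out <- list()
    k <- 0
    for (cond in conditions) {
      for (lam in lamins) {
        k <- k + 1
        counts <- simulate_chip_counts(genome, truth[[cond]], lam, scfg,
                                       seed = seed + 100L + k)
        matched <- match_depth(counts$chip, counts$input,
                               seed = seed + 200L + k)
        rt <- build_ratio_track(matched$chip, matched$input)
        write_bedgraph(rt, p(sprintf("ratio_lamin%s_%s.bedGraph", lam, cond)))
        out[[paste(lam, cond, sep = "_")]] <- rt
      }
    }
    out
  })

  ## stage: call-lads ------------------------------------------------------
  calls <- stage("call-lads", {
    out <- list()
    k <- 0
    for (nm in names(ratio)) {
      k <- k + 1
      rep_ <- stability_protocol(ratio[[nm]],
                                 n_runs = config$caller$n_runs,
                                 seed = seed + 300L + k,
                                 jitter_sd = config$caller$jitter_sd,
                                 min_score = config$caller$min_score)
      write_bed(rep_$lads, p(sprintf("LADs_%s.bed", nm)))
      out[[nm]] <- rep_
    }
    stab <- lapply(out, function(r) list(
      GP = r$params$GP, BS = r$params$BS, gp_sd = r$gp_sd,
      n_domains = length(r$lads),
      coverage_bp = sum(as.numeric(width(r$lads))),
      n_variable_subdomains = length(r$variable_subdomains),
      median_variable_length_bp = r$median_variable_length))
    jsonlite::write_json(stab, p("stability.json"), auto_unbox = TRUE,
                         digits = NA)
    out
  })

  ## stage: classify -------------------------------------------------------
  parts <- stage("classify", {
    out <- list()
    for (cond in conditions) {
      part <- partition_classes(calls[[paste0("A_", cond)]]$lads,
                                calls[[paste0("B_", cond)]]$lads, genome)
      for (lbl in LAD_CLASSES)
        write_bed(class_set(part, lbl),
                  p(sprintf("class_%s_%s.bed", gsub("-", "", lbl), cond)))
      utils::write.table(coverage_summary(part),
                         p(sprintf("coverage_%s.tsv", cond)), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      out[[cond]] <- part
    }
    out
  })

  ## stage: fate -----------------------------------------------------------
  fate <- stage("fate", {
    fm <- fate_matrix(parts$control, parts$treated)
    utils::write.table(as.data.frame(unclass(fm)[seq_len(4), seq_len(4)]),
                       p("fate_matrix.tsv"), sep = "\t", quote = FALSE)
    utils::write.table(fate_long(fm), p("fate_long.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(domain_fates(parts$control, parts$treated),
                       p("domain_fates.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    ji_lamin <- list(
      A_ctrl_vs_B_ctrl = jaccard(lamin_set(parts$control, "A"),
                                 lamin_set(parts$control, "B")),
      A_trt_vs_B_trt = jaccard(lamin_set(parts$treated, "A"),
                               lamin_set(parts$treated, "B")),
      A_ctrl_vs_A_trt = jaccard(lamin_set(parts$control, "A"),
                                lamin_set(parts$treated, "A")),
      B_ctrl_vs_B_trt = jaccard(lamin_set(parts$control, "B"),
                                lamin_set(parts$treated, "B")),
      A_trt_vs_B_ctrl = jaccard(lamin_set(parts$treated, "A"),
                                lamin_set(parts$control, "B")))
    ji_class <- lapply(LAD_CLASSES[1:3], function(lbl) {
      a <- class_set(parts$control, lbl); b <- class_set(parts$treated, lbl)
      if (length(a) + length(b) == 0) NA_real_ else jaccard(a, b)
    })
    names(ji_class) <- LAD_CLASSES[1:3]
    list(matrix = fm, jaccard_lamin = ji_lamin, jaccard_class = ji_class)
  })

  ## stage: expression -----------------------------------------------------
  expression <- stage("expression", {
    genes <- simulate_genes(genome, truth$control, truth$treated,
                            n_per_transition = config$n_genes_per_transition,
                            seed = seed + 400L)
    genes <- simulate_expression(genes, truth$control, truth$treated, scfg,
                                 seed = seed + 401L)
    genes$stable <- stable_filter(genes, config$stable_threshold)
    utils::write.table(genes, p("expression.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    rep_ <- fate_expression_report(genes, parts$control, parts$treated,
                                   alpha = config$alpha)
    utils::write.table(rep_, p("fate_expression.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(genes = genes, report = rep_)
  })

  ## stage: radial ---------------------------------------------------------
  radial <- stage("radial", {
    ens <- simulate_structures(genome, truth[conditions],
                               n_models = config$n_models,
                               cfg = scfg, seed = seed + 500L)
    write_structures_tsv(ens$control[seq_len(min(5, length(ens$control)))],
                         p("structures_control_head.tsv"))
    cds <- lapply(conditions, function(cond)
      class_distance_stats(ens[[cond]], parts[[cond]]))
    names(cds) <- conditions
    for (cond in conditions)
      utils::write.table(cds[[cond]]$summary,
                         p(sprintf("radial_classes_%s.tsv", cond)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    tds <- transition_distance_stats(ens$control, ens$treated,
                                     parts$control, parts$treated,
                                     alpha = config$alpha)
    utils::write.table(tds, p("radial_transitions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(ensembles = ens, class_stats = cds, transition_stats = tds)
  })

  ## stage: fish ------------------------------------------------------------
  fish <- stage("fish", {
    # probe placed in the largest A-only -> B-only fate region (the switch
    # expected to reposition peripherally); its targets follow the class
    # radial biases of the two conditions
    regions <- fate_regions(truth$control, truth$treated)
    reg <- regions[["A-only>B-only"]]
    targets <- c(control = unname(scfg$radial_bias[["A-only"]]),
                 treated = unname(scfg$radial_bias[["B-only"]]))
    spots <- simulate_fish_spots(targets, n_nuclei = config$n_nuclei,
                                 probe_id = "probe1",
                                 spread = scfg$fish_spread,
                                 seed = seed + 600L)
    utils::write.table(spots, p("fish_spots.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    cmp <- fish_compare(spots, alpha = config$alpha)
    utils::write.table(cmp, p("fish_compare.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    model_probe <- NULL
    if (length(reg)) {
      big <- reg[which.max(width(reg))]
      pd_ctrl <- probe_distance(as.character(seqnames(big)),
                                start(big) - 1, end(big),
                                radial$ensembles$control)
      pd_trt <- probe_distance(as.character(seqnames(big)),
                               start(big) - 1, end(big),
                               radial$ensembles$treated)
      tt <- stats::t.test(pd_trt, pd_ctrl)
      model_probe <- list(chrom = as.character(seqnames(big)),
                          start = start(big) - 1, end = end(big),
                          mean_ctrl = mean(pd_ctrl), mean_trt = mean(pd_trt),
                          p = tt$p.value)
    }
    list(spots = spots, compare = cmp, model_probe = model_probe)
  })

  ## stage: report ----------------------------------------------------------
  report <- stage("report", {
    rep_ <- list(
      schema_version = config$schema_version,
      seed = seed,
      genome = list(chromosomes = as.list(config$genome$chromosomes),
                    bin_size = config$genome$bin_size),
      jaccard = c(fate$jaccard_lamin, fate$jaccard_class),
      coverage = lapply(parts, function(pp) {
        cs <- coverage_summary(pp)
        stats::setNames(as.list(cs$fraction), cs$class)
      }),
      fate_matrix_bp = apply(unclass(fate$matrix)[seq_len(4), seq_len(4)],
                             1, as.list),
      stability = lapply(calls, function(r) list(
        GP = r$params$GP, BS = r$params$BS, gp_sd = r$gp_sd)),
      truth_recovery = lapply(lamins, function(lam) {
        stats::setNames(lapply(conditions, function(cond)
          jaccard(calls[[paste(lam, cond, sep = "_")]]$lads,
                  lamin_set(truth[[cond]], lam))), conditions)
      }),
      expression_significant = expression$report[
        expression$report$significant & !is.na(expression$report$p),
        c("class_control", "class_treated", "n", "p")],
      radial_class_means = lapply(radial$class_stats, function(s)
        stats::setNames(as.list(s$summary$mean), s$summary$class)),
      radial_transitions = radial$transition_stats[
        , c("class_control", "class_treated", "n_ctrl", "n_trt",
            "mean_ctrl", "mean_trt", "p", "direction")],
      fish = fish$compare,
      model_probe = fish$model_probe)
    names(rep_$truth_recovery) <- lamins
    jsonlite::write_json(rep_, p("summary.json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "rows", na = "null")
    rep_
  })

  invisible(list(truth = truth, ratio = ratio, calls = calls,
                 partitions = parts, fate = fate, expression = expression,
                 radial = radial, fish = fish, report = report,
                 out_dir = out_dir))
}
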