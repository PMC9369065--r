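#' Read and validate a pipeline run configuration
#'
#' The configuration is a YAML file (or an equivalent list) with:
#' ```yaml
#' seed: 1
#' out_dir: runs/demo
#' simulate: {n_genes: 2000}        # sim_config() arguments, or omit and
#' # inputs: {counts: counts.tsv, design: design.tsv,
#' #          expression: expression.tsv, annotation: annotation.tsv}
#' contrasts: {control: 0d, treatments: [4d, 8d, 12d]}
#' thresholds: {fdr: 0.01, min_fc: 2}
#' bootstrap: {B: 500, sign: individual}
#' qpcr: {n_genes: 10, noise_sd: 0.25}
#' ```
#'
#' @param config Path to a YAML file or a list.
#' @return Validated config list.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path")
  if (is.null(config$seed)) stop("config must set a seed")
  if (is.null(config$out_dir)) stop("config must set out_dir")
  th <- config$thresholds %||% list()
  th$fdr <- th$fdr %||% 0.01
  th$min_fc <- th$min_fc %||% 2
  if (th$fdr <= 0 || th$min_fc <= 0) stop("thresholds must be positive")
  config$thresholds <- th
  bt <- config$bootstrap %||% list()
  bt$B <- bt$B %||% 500
  bt$sign <- bt$sign %||% "individual"
  if (bt$B < 2) stop("bootstrap B must be >= 2")
  config$bootstrap <- bt
  cn <- config$contrasts %||% list()
  cn$control <- cn$control %||% "0d"
  cn$treatments <- cn$treatments %||% c("4d", "8d", "12d")
  config$contrasts <- cn
  qp <- config$qpcr %||% list()
  qp$n_genes <- qp$n_genes %||% 10
  qp$noise_sd <- qp$noise_sd %||% 0.25
  config$qpcr <- qp
  if (!is.null(config$inputs)) {
    missing <- Filter(function(f) !file.exists(f), unlist(config$inputs))
    if (length(missing)) {
      stop("input file(s) not found: ", paste(missing, collapse = ", "))
    }
  }
  config
}

#' Run the full analysis pipeline
#'
#' Executes the five stages in order — simulate (or load inputs), screen
#' DEGs and intersect them into the chilling-responsive gene set,
#' partition the CRGs into annotated blocks with Z-scored expression, fit
#' and bootstrap the PLS path model, and run the synthetic qRT-PCR
#' concordance check — writing every stage's outputs plus a manifest
#' under `out_dir`. All randomness flows from `config$seed`, so a rerun
#' with the same config is byte-identical.
#'
#' @param config A YAML path or list accepted by [read_run_config()].
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  config <- read_run_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("chillsem")),
                   seed = config$seed, stages = list())
  record <- function(name, outputs, n_records) {
    manifest$stages[[length(manifest$stages) + 1L]] <<-
      list(name = name, outputs = basename(unlist(outputs)),
           n_records = n_records)
  }
  fail <- function(stage, e) {
    stop(sprintf("[stage:%s] %s", stage, conditionMessage(e)), call. = FALSE)
  }

  # --- stage 1: simulate or load --------------------------------------
  stage <- "simulate"
  tryCatch({
    if (is.null(config$inputs)) {
      sim_args <- config$simulate %||% list()
      sim_args$seed <- config$seed
      cfg <- do.call(sim_config, sim_args)
      ds <- simulate_dataset(cfg)
      paths <- write_dataset(ds, file.path(out, "data"))
      counts <- ds$counts
      expr <- ds$expression
      annotation <- ds$annotation
      model <- model_from_config(cfg)
      true_de <- ds$de_genes
    } else {
      ds <- NULL
      counts <- read_expression_tsv(config$inputs$counts,
                                    config$inputs$design, mode = "counts")
      expr <- read_expression_tsv(config$inputs$expression,
                                  config$inputs$design, mode = "log")
      annotation <- read_annotation_tsv(config$inputs$annotation)
      model <- read_path_model(config$model)
      true_de <- NULL
      paths <- unlist(config$inputs)
    }
    record(stage, paths, nrow(counts$values))
  }, error = function(e) fail(stage, e))

  # --- stage 2: DEG screen + CRG intersection -------------------------
  stage <- "deg"
  tryCatch({
    ctrl <- config$contrasts$control
    min_lfc <- log2(config$thresholds$min_fc)
    deg_sets <- list()
    contrast_files <- character(0)
    first_contrast <- NULL
    for (tp in config$contrasts$treatments) {
      res <- test_contrast(counts, ctrl, tp)
      if (is.null(first_contrast)) first_contrast <- res
      f <- file.path(out, sprintf("contrast_%s_vs_%s.tsv", ctrl, tp))
      utils::write.table(
        cbind(res, status = ifelse(
          res$fdr <= config$thresholds$fdr & abs(res$log2fc) >= min_lfc,
          ifelse(res$log2fc >= 0, "up", "down"), "ns")),
        f, sep = "\t", quote = FALSE, row.names = FALSE)
      contrast_files <- c(contrast_files, f)
      degs <- screen_degs(res, fdr_max = config$thresholds$fdr,
                          min_abs_log2fc = min_lfc)
      deg_sets[[paste(ctrl, "vs", tp)]] <- degs$gene
    }
    crg <- intersect_crgs(deg_sets)
    crg_file <- file.path(out, "crgs.tsv")
    utils::write.table(data.frame(gene = crg$genes), crg_file,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    venn_file <- file.path(out, "venn.json")
    jsonlite::write_json(as.list(crg$venn), venn_file, auto_unbox = TRUE)
    record(stage, c(contrast_files, crg_file, venn_file), length(crg$genes))
  }, error = function(e) fail(stage, e))

  # --- stage 3: block partition + Z-score matrix ----------------------
  stage <- "partition"
  tryCatch({
    part <- assign_blocks(crg, annotation)
    part_file <- file.path(out, "partition.json")
    jsonlite::write_json(list(blocks = part$blocks,
                              unassigned = part$unassigned),
                         part_file, auto_unbox = FALSE)
    zm <- zscore_rows(expr)
    z_file <- file.path(out, "zscore_matrix.tsv")
    write_expression_tsv(zm, z_file)
    record(stage, c(part_file, z_file), sum(lengths(part$blocks)))
  }, error = function(e) fail(stage, e))

  # --- stage 4: PLS path model ----------------------------------------
  stage <- "plssem"
  tryCatch({
    boot <- bootstrap_pls(zm, model, B = config$bootstrap$B,
                          sign_policy = config$bootstrap$sign,
                          seed = config$seed)
    fit <- boot$fit
    eff <- pls_effects(fit)
    res_file <- file.path(out, "pls_results.json")
    jsonlite::write_json(list(
      path_coefficients = fit$path_coefficients,
      r_squared = as.list(fit$r_squared),
      ave = as.list(fit$ave),
      composite_reliability = as.list(fit$composite_reliability),
      loadings = fit$loadings,
      effects = eff,
      validation = validate_model(fit),
      converged = fit$converged,
      n_iterations = fit$n_iterations),
      res_file, auto_unbox = TRUE, digits = NA)
    boot_file <- file.path(out, "bootstrap.tsv")
    utils::write.table(boot$summary, boot_file, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    dot_file <- file.path(out, "model.dot")
    export_dot(fit, dot_file)
    record(stage, c(res_file, boot_file, dot_file),
           nrow(fit$path_coefficients))
  }, error = function(e) fail(stage, e))

  # --- stage 5: qPCR concordance --------------------------------------
  stage <- "validate_qpcr"
  tryCatch({
    src <- first_contrast
    pick <- if (!is.null(true_de)) {
      intersect(src$gene, true_de)
    } else {
      src$gene[order(src$fdr)]
    }
    pick <- utils::head(pick, config$qpcr$n_genes)
    lfc_rna <- stats::setNames(src$log2fc[match(pick, src$gene)], pick)
    ct <- simulate_ct_table(lfc_rna, noise_sd = config$qpcr$noise_sd,
                            calibrator = "C0d", treated = "L",
                            seed = config$seed + 3L)
    ct_file <- file.path(out, "ct_table.tsv")
    utils::write.table(ct, ct_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    rel <- ddct(ct, "C0d")
    lfc_qpcr <- with(rel[rel$sample == "L", ],
                     stats::setNames(log2(rel_expr), gene))
    conc <- concordance(lfc_rna, lfc_qpcr)
    conc_file <- file.path(out, "qpcr_concordance.json")
    jsonlite::write_json(unclass(conc), conc_file, auto_unbox = TRUE,
                         digits = NA)
    record(stage, c(ct_file, conc_file), conc$n)
  }, error = function(e) fail(stage, e))

  manifest_file <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_file, auto_unbox = TRUE)
  invisible(manifest)
}

#' Render presentation outputs for a completed run
#'
#' Writes per-block Z-score heatmaps (via pheatmap, when installed;
#' blocks with no genes in the matrix are skipped with a message) and a
#' per-edge summary table combining path coefficients with their
#' bootstrap statistics. The fitted DOT diagram is produced by
#' [run_pipeline()] itself.
#'
#' @param run_dir Output directory of a completed [run_pipeline()] run.
#' @return Character vector of files written, invisibly.
#' @export
render_outputs <- function(run_dir) {
  need <- c("partition.json", "zscore_matrix.tsv", "pls_results.json",
            "bootstrap.tsv", "model.dot")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing)) {
    stop("missing stage outputs: ", paste(missing, collapse = ", "))
  }
  written <- character(0)
  part <- jsonlite::read_json(file.path(run_dir, "partition.json"),
                              simplifyVector = TRUE)
  zm <- read_expression_tsv(file.path(run_dir, "zscore_matrix.tsv"),
                            mode = "zscore")
  has_pheatmap <- requireNamespace("pheatmap", quietly = TRUE)
  for (block in names(part$blocks)) {
    genes <- intersect(unlist(part$blocks[[block]]), rownames(zm$values))
    if (length(genes) == 0L) {
      message("block ", block, " has no genes in the matrix; heatmap skipped")
      next
    }
    if (!has_pheatmap) next
    f <- file.path(run_dir, sprintf("heatmap_%s.png", block))
    pheatmap::pheatmap(zm$values[genes, , drop = FALSE],
                       cluster_cols = FALSE,
                       main = paste(block, "block (row Z-scores)"),
                       filename = f, silent = TRUE)
    written <- c(written, f)
  }
  pls <- jsonlite::read_json(file.path(run_dir, "pls_results.json"),
                             simplifyVector = TRUE)
  boot <- utils::read.delim(file.path(run_dir, "bootstrap.tsv"),
                            stringsAsFactors = FALSE)
  paths <- boot[boot$type == "path",
                c("from", "to", "original", "se", "t", "p",
                  "ci_lower", "ci_upper")]
  names(paths)[names(paths) == "original"] <- "estimate"
  f <- file.path(run_dir, "summary_paths.tsv")
  utils::write.table(paths, f, sep = "\t", quote = FALSE, row.names = FALSE)
  written <- c(written, f)
  f <- file.path(run_dir, "summary_validity.tsv")
  utils::write.table(pls$validation, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  written <- c(written, f)
  invisible(written)
}
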