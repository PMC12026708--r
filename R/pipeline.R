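# End-to-end orchestration: simulate (or read) -> preprocess -> DE on the
# four contrasts -> temporal patterns -> cell types -> treatment effects ->
# ORA -> co-expression modules -> manifest.

#' Build a run configuration
#'
#' @param spec A [simulation_spec()] describing synthetic input, or `NULL`
#'   when `counts_path`/`metadata_path` are given.
#' @param counts_path,metadata_path Optional paths to real input read with
#'   [read_counts()].
#' @param gmt_path Optional GMT file for overrepresentation analysis; for
#'   synthetic runs without one, gene sets are derived from the planted
#'   truth (one set per planted pattern and cell type).
#' @param p_max,lfc_min,fdr_mode DEG thresholds.
#' @param min_aligned_reads Sample filter threshold (0 = disabled; the
#'   synthetic pipeline has no alignment counts).
#' @param min_count,max_low_samples Gene filter thresholds.
#' @param outlier_removal Run PCA/Mahalanobis outlier removal?
#' @param outlier_n_pcs,outlier_quantile Outlier-step parameters.
#' @param tau_specific,tau_enriched Tau tier thresholds.
#' @param ora_fdr ORA significance threshold.
#' @param network A [network_params()].
#' @param network_max_genes Cap on genes entering the network (most
#'   variable kept); `Inf` disables.
#' @param seed Integer master seed (also stamped into `spec`).
#' @return A `RunConfig` list.
#' @export
run_config <- function(spec = simulation_spec(),
                       counts_path = NULL, metadata_path = NULL,
                       gmt_path = NULL,
                       p_max = 0.05, lfc_min = 1.0, fdr_mode = FALSE,
                       min_aligned_reads = 0,
                       min_count = 50, max_low_samples = 20,
                       outlier_removal = TRUE,
                       outlier_n_pcs = 10, outlier_quantile = 0.975,
                       tau_specific = 0.8, tau_enriched = 0.6,
                       ora_fdr = 0.05,
                       network = network_params(),
                       network_max_genes = Inf,
                       seed = 20250409) {
  if (!is.null(spec)) spec$seed <- as.integer(seed)
  cfg <- list(spec = spec, counts_path = counts_path,
              metadata_path = metadata_path, gmt_path = gmt_path,
              p_max = p_max, lfc_min = lfc_min, fdr_mode = fdr_mode,
              min_aligned_reads = min_aligned_reads,
              min_count = min_count, max_low_samples = max_low_samples,
              outlier_removal = outlier_removal,
              outlier_n_pcs = outlier_n_pcs,
              outlier_quantile = outlier_quantile,
              tau_specific = tau_specific, tau_enriched = tau_enriched,
              ora_fdr = ora_fdr, network = network,
              network_max_genes = network_max_genes,
              seed = as.integer(seed))
  stopifnot(cfg$p_max > 0, cfg$p_max <= 1, cfg$lfc_min >= 0,
            cfg$ora_fdr > 0, cfg$ora_fdr <= 1)
  class(cfg) <- "RunConfig"
  cfg
}

CONTRASTS <- list(A = c("sham", "injured_1d"),
                  B = c("sham", "injured_1wk"),
                  C = c("injured_1d", "injured_1wk"),
                  T = c("sham", "treated_1d"))

#' Run the full pipeline
#'
#' Executes every stage on one configuration and writes all tables under
#' `out_dir` (subdirectories `de/`, `patterns/`, `celltype/`, `treatment/`,
#' `ora/`, `modules/`), plus `report.html` and a `manifest.json` recording
#' the package version, seed, parameters, and an MD5 checksum per output
#' file. Reruns with an identical configuration are bit-identical.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created; existing files overwritten).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_all <- function(config, out_dir) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("de", "patterns", "celltype", "treatment", "ora", "modules"))
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))

  set.seed(config$seed)
  stage <- "input"
  result <- tryCatch({
    if (!is.null(config$counts_path)) {
      exp <- read_counts(config$counts_path, config$metadata_path)
      truth <- NULL; ref <- NULL
      note("read counts from ", config$counts_path)
    } else {
      sim <- simulate_counts(config$spec)
      exp <- sim$experiment; truth <- sim$truth; ref <- sim$celltype_reference
      note("simulated ", nrow(exp$counts), " genes x ", ncol(exp$counts),
           " samples (seed ", config$spec$seed, ")")
    }

    stage <- "preprocess"
    exp <- filter_samples(exp, config$min_aligned_reads)
    exp <- filter_genes(exp, config$min_count, config$max_low_samples)
    note("post-filter: ", nrow(exp$counts), " genes, ", ncol(exp$counts), " samples")

    regions <- unique(exp$sample_table$region)
    per_region <- list()
    for (rg in regions) {
      rexp <- subset_experiment(
        exp, samples = exp$sample_table$sample[exp$sample_table$region == rg])
      s <- size_factors(rexp)
      norm <- normalize_transform(rexp, s)
      if (isTRUE(config$outlier_removal)) {
        stage <- paste0("outliers[", rg, "]")
        out <- mahalanobis_outliers(norm, config$outlier_n_pcs,
                                    config$outlier_quantile)
        if (length(out$removed)) {
          note(rg, ": removed outlier sample(s) ",
               paste(out$removed, collapse = ", "))
          rexp <- subset_experiment(rexp, samples = out$kept)
          s <- size_factors(rexp)
          norm <- normalize_transform(rexp, s)
        }
      }

      stage <- paste0("diffexp[", rg, "]")
      de <- list()
      for (cn in names(CONTRASTS)) {
        cmp <- CONTRASTS[[cn]]
        if (!all(cmp %in% rexp$sample_table$group)) next
        de[[cn]] <- wald_test(rexp, s, cmp)
        write_de_table(de[[cn]],
                       file.path(out_dir, "de",
                                 sprintf("%s_%s_vs_%s.tsv", rg, cmp[2], cmp[1])))
      }
      if (!all(c("A", "B", "C") %in% names(de)))
        stop("groups for the three injury contrasts are required")

      stage <- paste0("patterns[", rg, "]")
      calls <- classify_temporal(de$A, de$B, de$C, config$p_max,
                                 config$lfc_min, config$fdr_mode)
      pc <- partition_check(calls)
      if (!pc$ok) stop("temporal partition violated for ",
                       length(pc$offenders), " genes")
      utils::write.table(calls, file.path(out_dir, "patterns",
                                          paste0(rg, "_temporal_calls.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        list(region = rg, counts = as.data.frame.matrix(pc$table),
             n_sham_significant = pc$n_sham_significant),
        file.path(out_dir, "patterns", paste0(rg, "_summary.json")),
        auto_unbox = TRUE, digits = NA)

      stage <- paste0("celltype[", rg, "]")
      assignments <- NULL
      if (!is.null(ref)) {
        refu <- ref[, intersect(colnames(ref), calls$gene), drop = FALSE]
        assignments <- assign_celltypes(refu, config$tau_specific,
                                        config$tau_enriched)
        ptab <- pattern_celltype_table(calls, assignments)
        utils::write.table(assignments,
                           file.path(out_dir, "celltype",
                                     paste0(rg, "_assignments.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(ptab, file.path(out_dir, "celltype",
                                           paste0(rg, "_pattern_celltype.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }

      treatment <- NULL
      if ("T" %in% names(de)) {
        stage <- paste0("treatment[", rg, "]")
        treatment <- classify_treatment(de$A, de$B, de$T, config$p_max,
                                        config$lfc_min, config$fdr_mode)
        venn <- venn_summary(call_degs(de$A, config$p_max, config$lfc_min, config$fdr_mode),
                             call_degs(de$B, config$p_max, config$lfc_min, config$fdr_mode),
                             call_degs(de$T, config$p_max, config$lfc_min, config$fdr_mode))
        utils::write.table(treatment,
                           file.path(out_dir, "treatment",
                                     paste0(rg, "_treatment_calls.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(venn,
                             file.path(out_dir, "treatment",
                                       paste0(rg, "_venn.json")),
                             auto_unbox = TRUE, digits = NA)
      }

      stage <- paste0("ora[", rg, "]")
      universe <- calls$gene
      collection <- pipeline_gene_sets(config, truth, universe)
      ora <- NULL
      if (!is.null(collection)) {
        deg_genes <- unique(c(call_degs(de$A, config$p_max, config$lfc_min,
                                        config$fdr_mode)$gene,
                              call_degs(de$B, config$p_max, config$lfc_min,
                                        config$fdr_mode)$gene))
        if (length(deg_genes)) {
          ora <- fisher_ora(deg_genes, collection, universe)
          collapsed <- collapse_terms(ora, collection, universe)
          utils::write.table(ora, file.path(out_dir, "ora",
                                                  paste0(rg, "_ora.tsv")),
                             sep = "\t", quote = FALSE, row.names = FALSE)
          utils::write.table(collapsed[, setdiff(names(collapsed), "cluster_members")],
                             file.path(out_dir, "ora",
                                       paste0(rg, "_ora_collapsed.tsv")),
                             sep = "\t", quote = FALSE, row.names = FALSE)
        }
      }

      stage <- paste0("modules[", rg, "]")
      netexpr <- norm$normexpr
      if (is.finite(config$network_max_genes) &&
          nrow(netexpr) > config$network_max_genes) {
        v <- apply(netexpr, 1, stats::var)
        netexpr <- netexpr[order(-v)[seq_len(config$network_max_genes)], ,
                           drop = FALSE]
      }
      ms <- detect_modules(netexpr, config$network)
      module_tests <- NULL
      module_labels <- NULL
      if (nrow(ms$eigengenes)) {
        module_tests <- module_group_test(ms, rexp$sample_table)
        if (all(c("sham", "injured_1d", "injured_1wk", "treated_1d") %in%
                rexp$sample_table$group))
          module_labels <- classify_module_treatment(module_tests, config$p_max)
        utils::write.table(data.frame(gene = names(ms$modules),
                                      module = ms$modules,
                                      row.names = NULL),
                           file.path(out_dir, "modules",
                                     paste0(rg, "_assignments.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        write_matrix_tsv(ms$eigengenes,
                         file.path(out_dir, "modules",
                                   paste0(rg, "_eigengenes.tsv")),
                         id_col = "module")
        utils::write.table(hub_genes(ms),
                           file.path(out_dir, "modules", paste0(rg, "_hubs.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(module_tests,
                           file.path(out_dir, "modules", paste0(rg, "_tests.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        if (!is.null(module_labels))
          utils::write.table(module_labels,
                             file.path(out_dir, "modules",
                                       paste0(rg, "_treatment_labels.tsv")),
                             sep = "\t", quote = FALSE, row.names = FALSE)
      }

      per_region[[rg]] <- list(experiment = rexp, size_factors = s,
                               norm = norm, de = de, temporal = calls,
                               partition = pc, celltype = assignments,
                               treatment = treatment, ora = ora,
                               modules = ms, module_tests = module_tests,
                               module_labels = module_labels)
    }
    list(per_region = per_region, truth = truth)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  writeLines(c("<html><body><h1>tempodeg run</h1><pre>",
               log_lines, "</pre></body></html>"),
             file.path(out_dir, "report.html"))
  writeLines(log_lines, file.path(out_dir, "run.log"))

  files <- list.files(out_dir, recursive = TRUE)
  files <- setdiff(files, c("manifest.json", "run.log"))
  checksums <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(checksums) <- files
  manifest <- list(
    package = "tempodeg",
    version = as.character(utils::packageVersion("tempodeg")),
    seed = config$seed,
    parameters = list(p_max = config$p_max, lfc_min = config$lfc_min,
                      fdr_mode = config$fdr_mode,
                      min_count = config$min_count,
                      max_low_samples = config$max_low_samples,
                      network = unclass(config$network)),
    files = checksums)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(result, list(manifest = manifest, out_dir = out_dir)))
}

# Gene sets for ORA: an explicit GMT wins; otherwise, for synthetic runs,
# one set per planted pattern / treatment label / cell type (restricted to
# the universe).
pipeline_gene_sets <- function(config, truth, universe) {
  if (!is.null(config$gmt_path)) {
    collection <- read_gmt(config$gmt_path)
    return(collection)
  }
  if (is.null(truth)) return(NULL)
  sets <- list()
  for (p in unique(truth$pattern[truth$pattern != "null"]))
    sets[[paste0("planted_", p)]] <-
      intersect(truth$gene[truth$pattern == p], universe)
  for (ct in unique(truth$cell_type[truth$cell_type != "none"]))
    sets[[paste0("celltype_", ct)]] <-
      intersect(truth$gene[truth$cell_type == ct], universe)
  sets <- sets[vapply(sets, length, integer(1)) > 0]
  if (!length(sets)) return(NULL)
  structure(sets, class = "GeneSetCollection")
}
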