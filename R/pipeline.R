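.config_sections <- c("seed", "outdir", "synthetic", "phenotype",
                      "filters", "dmr", "interaction")
.interaction_keys <- c("alpha", "error_mode")

.build_from <- function(constructor, values, section) {
  values <- as.list(values %||% list())
  allowed <- setdiff(names(formals(constructor)), "...")
  unknown <- setdiff(names(values), allowed)
  if (length(unknown))
    stopf("unknown key(s) in config section '%s': %s", section,
          paste(unknown, collapse = ", "))
  do.call(constructor, values)
}

#' Resolve and validate a pipeline configuration
#'
#' @param config A list, or the path to a YAML file, with any of the
#'   sections `seed`, `outdir`, `synthetic` ([synthetic_config()] fields),
#'   `phenotype` ([phenotype_config()] fields), `filters`
#'   ([filter_params()] fields), `dmr` ([dmr_params()] fields) and
#'   `interaction` (`alpha`, `error_mode`). Unknown keys are rejected
#'   before any computation. A top-level `seed` overrides the section
#'   seeds.
#' @return The resolved configuration list.
#' @export
resolve_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stopf("'config' must be a list or a YAML path")
  unknown <- setdiff(names(config), .config_sections)
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  if (!is.null(config$seed)) {
    check_number(config$seed, "seed", integerish = TRUE)
    config$synthetic$seed <- config$seed
    config$phenotype$seed <- config$seed
  }
  inter <- as.list(config$interaction %||% list())
  unknown <- setdiff(names(inter), .interaction_keys)
  if (length(unknown))
    stopf("unknown key(s) in config section 'interaction': %s",
          paste(unknown, collapse = ", "))
  list(seed = config$seed %||% 1L,
       outdir = config$outdir,
       synthetic = .build_from(synthetic_config, config$synthetic,
                               "synthetic"),
       phenotype = .build_from(phenotype_config, config$phenotype,
                               "phenotype"),
       filters = .build_from(filter_params, config$filters, "filters"),
       dmr = .build_from(dmr_params, config$dmr, "dmr"),
       interaction = list(alpha = inter$alpha %||% 0.05,
                          error_mode = inter$error_mode %||% "standard"))
}

#' Run the full synthetic-data analysis pipeline
#'
#' Executes simulate -> context summaries -> DMR calling -> interaction
#' analysis on synthetic genotype-structured data, writing the reference
#' (FASTA), per genotype x replicate x context coverage files (bedGraph),
#' the latent-truth table and phenotype table (TSV), a resolved-config
#' copy (YAML), a MANIFEST of completed stages, and a single JSON report
#' embedding the context summaries, restoration fractions, DMR list,
#' interaction results, software version, resolved configuration and
#' seed. On any stage failure the MANIFEST names the completed stages and
#' the failing stage before the error propagates.
#'
#' @param config Configuration list or YAML path (see
#'   [resolve_config()]).
#' @param outdir Output directory (created if needed); overrides
#'   `config$outdir`.
#' @return Invisibly, the report list.
#' @export
run_pipeline <- function(config = list(), outdir = NULL) {
  cfg <- resolve_config(config)
  outdir <- outdir %||% cfg$outdir %||% stopf("no output directory given")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  done <- character()
  manifest <- function(extra = NULL)
    writeLines(c(paste("completed:", done), extra),
               file.path(outdir, "MANIFEST"))
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      manifest(paste("failed:", name, "-", conditionMessage(e)))
      stop(e)
    })
    done <<- c(done, name)
    manifest()
    res
  }

  sim <- stage("simulate", {
    reference <- generate_reference(cfg$synthetic)
    write_reference(reference, file.path(outdir, "reference.fa"))
    ms <- simulate_methylome_set(cfg$synthetic, reference)
    for (g in names(ms$methylomes))
      for (j in seq_along(ms$methylomes[[g]])) {
        rec <- ms$methylomes[[g]][[j]]
        for (ctx in c("CG", "CHG", "CHH"))
          write_bedgraph(rec[rec$context == ctx, , drop = FALSE],
                         file.path(outdir, sprintf("%s_rep%d_%s.bedGraph",
                                                   g, j, ctx)))
      }
    utils::write.table(ms$truth, file.path(outdir, "latent_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    phen <- simulate_phenotypes(cfg$phenotype)
    write_phenotypes(phen, file.path(outdir, "phenotypes.tsv"))
    list(methylomes = ms$methylomes, phenotypes = phen)
  })

  summaries <- stage("summarize", {
    summarize_contexts(sim$methylomes, reference = "wt", cfg$filters)
  })

  restoration <- stage("restoration", {
    out <- lapply(c("CG", "CHG", "CHH"), function(ctx) {
      s <- summaries[summaries$context == ctx, ]
      m <- stats::setNames(s$mean_ratio, s$genotype)
      rho_hat <- if (anyNA(m[c("wt", "dnmt1", "double")])) NA_real_ else
        restoration_fraction(m[["wt"]], m[["dnmt1"]], m[["double"]])
      data.frame(context = ctx, restoration = rho_hat)
    })
    do.call(rbind, out)
  })

  dmrs <- stage("dmr", {
    merged <- lapply(sim$methylomes[c("dnmt1", "wt")], function(reps)
      lapply(reps, merge_cg_strands))
    dm <- call_dmrs(merged$dnmt1, merged$wt, cfg$dmr,
                    name_a = "dnmt1", name_b = "wt")
    utils::write.table(dm, file.path(outdir, "dmrs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    dm
  })

  interactions <- stage("interact", {
    metrics <- c("thymopoietic_index", "eye_size")
    stats::setNames(lapply(metrics, function(m) {
      res <- interaction_analysis(sim$phenotypes, metric = m,
                                  alpha = cfg$interaction$alpha,
                                  error_mode = cfg$interaction$error_mode)
      res[c("W_x", "W_y", "W_xy_observed", "E_expected", "epsilon_prop",
            "I", "p_value", "classification", "metric")]
    }), metrics)
  })

  report <- stage("report", {
    cfg_out <- cfg
    cfg_out$synthetic <- unclass(cfg_out$synthetic)
    cfg_out$phenotype <- unclass(cfg_out$phenotype)
    cfg_out$filters <- unclass(cfg_out$filters)
    cfg_out$dmr <- unclass(cfg_out$dmr)
    yaml::write_yaml(cfg_out, file.path(outdir, "config_resolved.yaml"))
    rep <- list(
      package = "methylepi",
      version = as.character(utils::packageVersion("methylepi")),
      seed = cfg$seed,
      config = cfg_out,
      context_summaries = summaries,
      restoration = restoration,
      dmrs = dmrs,
      interactions = interactions,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(rep, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    rep
  })
  invisible(report)
}
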