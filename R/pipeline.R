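#' Run the binding-network analysis pipeline end to end
#'
#' Orchestrates prepare (label harmonization, aggregation, sparsity filter),
#' network construction, module detection, the weight-permutation null,
#' module profiling and Nebula validation, writing every stage's artifacts
#' plus a manifest into `out_dir`. A completed stage is skipped on re-run
#' when the stored configuration hash matches and its outputs exist, so a
#' pipeline is resumable; re-running from the serialized config reproduces
#' deterministic outputs bit for bit.
#'
#' @param config Either a path to a YAML file or a named list. Recognized
#'   keys: `input` (raw TSV path; mutually exclusive with `simulate`),
#'   `simulate` (list: `preset`, `seed`, plus any [simulate_binding_data()]
#'   override), `out_dir`, `stages` (subset of `prepare`, `network`,
#'   `modules`, `permtest`, `profile`, `validate_loo`, `validate_cv`),
#'   `min_count`, `weighted`, `replicates`, `base_seed`, `ul`,
#'   `denominator`, `k`, `iterations`, `alignment_fasta`, `contact_map`.
#'   Unknown keys are an error.
#' @return Invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  known <- c("input", "simulate", "out_dir", "stages", "min_count", "weighted",
             "replicates", "base_seed", "ul", "denominator", "k", "iterations",
             "alignment_fasta", "contact_map")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(stages = c("prepare", "network", "modules", "permtest",
                              "profile", "validate_loo", "validate_cv"),
                   min_count = 2L, weighted = TRUE, replicates = 1000L,
                   base_seed = 1L, ul = 1.5, denominator = "literal",
                   k = 2L, iterations = 100L)
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$out_dir)) stop("config needs an out_dir")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  cfg_yaml <- yaml::as.yaml(cfg[order(names(cfg))])
  cfg_hash <- .text_md5(cfg_yaml)
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  old <- if (file.exists(manifest_path))
    tryCatch(jsonlite::read_json(manifest_path), error = function(e) NULL)
  else NULL
  resume <- !is.null(old) && identical(old$config_hash, cfg_hash)
  manifest <- list(config_hash = cfg_hash, stages = list())
  writeLines(cfg_yaml, file.path(cfg$out_dir, "config.yaml"))
  log_con <- file(file.path(cfg$out_dir, "pipeline.log"), open = "at")
  on.exit(close(log_con))
  logmsg <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    writeLines(msg, log_con); message(msg)
  }
  logmsg("pipeline start (hlanet %s, config hash %s)",
         as.character(utils::packageVersion("hlanet")), cfg_hash)

  outfile <- function(...) file.path(cfg$out_dir, ...)
  done <- function(stage, files) {
    resume && !is.null(old$stages[[stage]]) && all(file.exists(outfile(files)))
  }
  run_stage <- function(stage, files, fun) {
    if (!stage %in% cfg$stages) return(invisible(NULL))
    if (done(stage, files)) {
      logmsg("stage %s: up to date, skipped", stage)
    } else {
      t0 <- Sys.time()
      ok <- tryCatch({ fun(); TRUE }, error = function(e) {
        logmsg("stage %s FAILED: %s", stage, conditionMessage(e))
        manifest$stages[[stage]] <<- list(status = "failed")
        jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
        stop("pipeline aborted at stage '", stage, "': ",
             conditionMessage(e), call. = FALSE)
      })
      logmsg("stage %s: done in %.1fs", stage,
             as.numeric(difftime(Sys.time(), t0, units = "secs")))
    }
    manifest$stages[[stage]] <<- list(status = "done", files = files)
  }

  env <- new.env()
  run_stage("prepare", "data.tsv", function() {
    if (!is.null(cfg$simulate)) {
      sim_args <- cfg$simulate
      preset <- sim_args$preset %||% "paper_like"
      sim_args$preset <- NULL
      args <- utils::modifyList(synthetic_preset(preset), sim_args)
      if (is.null(args$seed)) args$seed <- cfg$base_seed
      sim <- do.call(simulate_binding_data, args)
      truth <- data.frame(
        node = c(names(sim$hla_modules), names(sim$peptide_modules)),
        module_id = c(sim$hla_modules, sim$peptide_modules))
      utils::write.table(truth, outfile("module_truth.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      recs <- sim$records
    } else {
      if (is.null(cfg$input)) stop("config needs 'input' or 'simulate'")
      raw <- read_binding_records(cfg$input)
      raw$label <- harmonize_labels(raw$label, raw$source)
      recs <- aggregate_records(raw)
    }
    filt <- degree_filter(recs[c("hla", "peptide", "label")],
                          min_count = cfg$min_count)
    rep_df <- attr(filt, "filter_report")
    utils::write.table(rep_df, outfile("filter_report.txt"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_binding_tsv(filt, outfile("data.tsv"))
  })

  load_net <- function() {
    if (is.null(env$net)) env$net <- binding_network(read_binding_tsv(outfile("data.tsv")))
    env$net
  }
  run_stage("network", "edges.tsv", function() {
    write_network_tsv(load_net(), outfile("edges.tsv"))
  })
  run_stage("modules", "partition.tsv", function() {
    env$part <- fast_greedy_modules(load_net(), weighted = cfg$weighted)
    write_partition_tsv(env$part, outfile("partition.tsv"))
    jsonlite::write_json(list(n_modules = env$part$n_modules,
                              modularity = env$part$modularity),
                         outfile("modules.json"), auto_unbox = TRUE, digits = NA)
  })
  load_part <- function() {
    if (is.null(env$part)) {
      df <- utils::read.delim(outfile("partition.tsv"), colClasses = "character")
      env$part <- structure(list(
        hla_module = stats::setNames(as.integer(df$module_id[df$type == "hla"]),
                                     df$node[df$type == "hla"]),
        peptide_module = stats::setNames(as.integer(df$module_id[df$type == "peptide"]),
                                         df$node[df$type == "peptide"]),
        n_modules = length(unique(as.integer(df$module_id))),
        modularity = NA_real_, weighted = cfg$weighted),
        class = "module_partition")
      env$part$modularity <- modularity_q(load_net(), env$part, cfg$weighted)
    }
    env$part
  }
  run_stage("permtest", c("null_values.txt", "null_summary.json"), function() {
    nd <- permutation_null(load_net(), replicates = cfg$replicates,
                           base_seed = cfg$base_seed, weighted = cfg$weighted)
    writeLines(format(nd$values, digits = 15), outfile("null_values.txt"))
    jsonlite::write_json(null_summary(nd), outfile("null_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  })
  run_stage("profile", "length_distribution.tsv", function() {
    prof <- length_distribution(load_part(), load_net())
    utils::write.table(prof$counts, outfile("length_distribution.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    utils::write.table(round(prof$percent, 3), outfile("length_percent.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    if (!is.null(cfg$alignment_fasta)) {
      aln <- read_hla_alignment(cfg$alignment_fasta)
      cmap <- read_contact_map(cfg$contact_map)
      for (pp in c(2L, 9L)) {
        ps <- extract_pseudo_sequences(aln, cmap, pp)
        wb <- within_between_identity(load_part(), ps)
        utils::write.table(wb, outfile(sprintf("identity_p%d.tsv", pp)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      ann <- highlight_nonmodal_residues(aln)
      utils::write.table(ann, outfile("nonmodal_residues.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  })
  run_stage("validate_loo", c("loo_report.json", "loo_edges.tsv"), function() {
    fit <- nebula(load_net(), ul = cfg$ul, denominator = cfg$denominator)
    write_validation_report(loo_validate(fit),
                            outfile("loo_report.json"), outfile("loo_edges.tsv"))
  })
  run_stage("validate_cv", "cv_report.json", function() {
    fit <- nebula(load_net(), ul = cfg$ul, denominator = cfg$denominator)
    cv <- kfold_validate(fit, k = cfg$k, iterations = cfg$iterations,
                         base_seed = cfg$base_seed)
    jsonlite::write_json(list(k = cv$k, iterations = nrow(cv$iterations),
                              mean = as.list(cv$mean), sd = as.list(cv$sd)),
                         outfile("cv_report.json"), auto_unbox = TRUE, digits = NA)
  })

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  logmsg("pipeline complete: %d stage(s)", length(manifest$stages))
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.text_md5 <- function(txt) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}
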