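#' Published per-domain pLDDT summaries for NLRP3 model sets
#'
#' Reported per-subdomain and whole-structure pLDDT means for five
#' AlphaFold and five RoseTTAFold models of human NLRP3, shipped as a
#' worked-example dataset for the confidence-aggregation functions
#' ([summarize_models], [classify_confidence]).
#'
#' @return data.frame with columns predictor, domain, model_1..model_5.
#' @export
nlrp3_model_plddt <- function() {
  path <- system.file("extdata", "nlrp3_model_plddt.tsv",
                      package = "pocketgauge", mustWork = TRUE)
  utils::read.delim(path, check.names = FALSE)
}

#' Default assessment configuration for NLRP3
#'
#' Bundles the subdomain scheme, pocket key residues, verdict thresholds
#' and contact criteria used throughout the package; every entry is
#' overridable via [assess]'s `config` argument.
#'
#' @return named list.
#' @export
nlrp3_config <- function() {
  scheme <- nlrp3_scheme()
  kr <- scheme$key_residues
  list(scheme = scheme,
       pocket_residues = kr[!duplicated(kr$resno), c("resno", "resid")],
       indicator = c(228L, 578L),
       verdict_thresholds = c(formed = 14, loose = 18),
       salt_bridge_cutoff = 4.0,
       hbond_d_cut = 3.5, hbond_angle_cut = 135,
       plddt_scale = "auto")
}

collect_warnings <- function(expr) {
  w <- character()
  val <- withCallingHandlers(
    tryCatch(expr, error = function(e) {
      w <<- c(w, conditionMessage(e)); NULL
    }),
    warning = function(cnd) {
      w <<- c(w, conditionMessage(cnd))
      invokeRestart("muffleWarning")
    })
  list(value = val, warnings = w)
}

#' Assess a set of predicted models against an experimental reference
#'
#' Runs the full pipeline per model — confidence aggregation, residue
#' mapping, the domain-partitioned RMSD table, pocket distance/deviation
#' matrices, the pocket-formation verdict and salt-bridge detection — and
#' collects everything in one report. Partial failures (for instance a
#' pocket residue missing from a model) degrade to `NULL` fields plus a
#' logged warning; only an unreadable reference aborts. Re-running on
#' identical inputs and configuration reproduces the identical report.
#'
#' @param models list of `pg_structure` objects or file paths.
#' @param reference `pg_structure` or file path.
#' @param model_chain,ref_chain chain ids (defaults: first chain of each
#'   structure).
#' @param config configuration list as from [nlrp3_config] (the default);
#'   supply a modified copy to override parts.
#' @param mapping_mode passed to [map_residues].
#' @return object of class `pg_report`: list with `models` (one entry per
#'   model: confidence, rmsd_table, pocket, verdict, salt_bridges,
#'   warnings) and `meta` (parameters, chains, package version).
#' @export
assess <- function(models, reference, model_chain = NULL, ref_chain = NULL,
                   config = nlrp3_config(),
                   mapping_mode = "by-number") {
  ref <- if (is_structure(reference)) reference else
    read_structure(reference)
  if (is.null(ref_chain)) ref_chain <- ref$atoms$chain[1]
  if (is_structure(models)) models <- list(models)
  out <- vector("list", length(models))
  names(out) <- if (!is.null(names(models))) names(models) else
    paste0("model_", seq_along(models))
  ref_pocket <- collect_warnings(
    pocket_matrix(ref, ref_chain, config$pocket_residues, "sidechain"))

  for (i in seq_along(models)) {
    s <- models[[i]]
    if (!is_structure(s)) s <- read_structure(s)
    mc <- if (is.null(model_chain)) s$atoms$chain[1] else model_chain
    warnings <- character()
    step <- function(expr) {
      r <- collect_warnings(expr)
      warnings <<- c(warnings, r$warnings)
      r$value
    }
    conf <- step({
      sc <- extract_plddt(s, scale = config$plddt_scale, chain = mc)
      domain_plddt(sc, config$scheme)
    })
    mapping <- step(map_residues(s, ref, mc, ref_chain,
                                 mode = mapping_mode))
    rmsd_tab <- if (!is.null(mapping))
      step(domain_rmsd_table(s, ref, mapping, config$scheme)) else NULL
    pocket <- step(pocket_matrix(s, mc, config$pocket_residues,
                                 "sidechain"))
    deviation <- if (!is.null(pocket) && !is.null(ref_pocket$value))
      step(deviation_matrix(pocket, ref_pocket$value)) else NULL
    verdict <- step(pocket_verdict(
      s, mc, config$indicator[1], config$indicator[2],
      thresholds = config$verdict_thresholds))
    sb <- step(detect_salt_bridges(s, chains = mc,
                                   cutoff = config$salt_bridge_cutoff))
    out[[i]] <- list(id = s$id, chain = mc, confidence = conf,
                     rmsd_table = rmsd_tab, pocket_matrix = pocket,
                     deviation_matrix = deviation, verdict = verdict,
                     salt_bridges = sb, warnings = warnings)
  }
  whole <- vapply(out, function(m) {
    if (is.null(m$confidence)) NA_real_
    else m$confidence$mean_plddt[m$confidence$domain == "Whole"]
  }, numeric(1))
  summary <- if (sum(!is.na(whole)) >= 2L)
    summarize_models(whole[!is.na(whole)]) else NULL
  structure(list(models = out,
                 summary = summary,
                 meta = list(ref_id = ref$id, ref_chain = ref_chain,
                             mapping_mode = mapping_mode,
                             thresholds = config$verdict_thresholds,
                             salt_bridge_cutoff = config$salt_bridge_cutoff,
                             ref_pocket_warnings = ref_pocket$warnings,
                             package_version =
                               as.character(utils::packageVersion(
                                 "pocketgauge")))),
            class = "pg_report")
}

#' @export
print.pg_report <- function(x, ...) {
  cat(sprintf("<pg_report> %d model(s) vs %s (chain %s)\n",
              length(x$models), x$meta$ref_id, x$meta$ref_chain))
  for (m in x$models) {
    v <- if (is.null(m$verdict)) "verdict: n/a" else
      sprintf("pocket %s (%.1f A)", m$verdict$category,
              m$verdict$indicator_distance)
    fl <- if (is.null(m$rmsd_table)) NA_real_ else
      m$rmsd_table$rmsd_ca[m$rmsd_table$domain == "Full-length"]
    cat(sprintf("  %-12s full-length CA rmsd %s; %s; %d warning(s)\n",
                m$id, ifelse(is.na(fl), "n/a", sprintf("%.2f A", fl)), v,
                length(m$warnings)))
  }
  invisible(x)
}

#' Write an assessment report to disk
#'
#' Emits `report.json` (the full report, numbers unrounded) plus per-model
#' TSVs of the confidence table, domain RMSD table, pocket matrices and
#' salt bridges.
#'
#' @param report `pg_report`; @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json <- jsonlite::toJSON(strip_classes(unclass(report)),
                           auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE)
  writeLines(json, file.path(dir, "report.json"))
  for (nm in names(report$models)) {
    m <- report$models[[nm]]
    wr <- function(obj, what) {
      if (is.null(obj)) return()
      labeled <- is.matrix(obj)
      if (labeled) obj <- as.data.frame(unclass(obj))
      utils::write.table(obj, file.path(dir, paste0(nm, "_", what, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = labeled,
                         col.names = if (labeled) NA else TRUE)
    }
    wr(m$confidence, "confidence")
    wr(m$rmsd_table, "rmsd")
    wr(m$pocket_matrix, "pocket")
    wr(m$deviation_matrix, "deviation")
    wr(m$salt_bridges, "salt_bridges")
  }
  invisible(dir)
}

# matrices/classed objects to plain lists for JSON
strip_classes <- function(x) {
  if (is.matrix(x)) {
    m <- unclass(x)
    attr(m, "metric") <- NULL
    return(m)
  }
  if (is.list(x)) return(lapply(x, strip_classes))
  x
}
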