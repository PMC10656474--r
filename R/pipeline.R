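#' End-to-end pipeline configuration
#'
#' Bundles every stage parameter of the read-level pipeline. The default
#' amplicon length window is derived from the sequencing design rather than
#' fixed: `[read_length, 2 * read_length - min_overlap]`, i.e. anything long
#' enough to be a real single-amplicon merge and short enough that the two
#' mates can overlap at all. (For gel-selected libraries, pass the gel
#' window, e.g. `c(550, 850)`.)
#'
#' @param sim A [simulation_config()]; its seed drives the whole run.
#' @param min_overlap,max_mismatch_rate Read-merging parameters.
#' @param length_bounds Inclusive merged-length window, or `NULL` to derive
#'   from the design as above.
#' @param min_mean_q Minimum mean Phred over the merged amplicon.
#' @param key_level Clonotype key level for all tables.
#' @param denoise Collapse 1-mismatch error variants into abundant parents
#'   (see [denoise_clonotypes()]).
#' @param denoise_min_ratio Parent/child ratio for the collapse.
#' @param pseudocount,min_late_count Enrichment-filter parameters.
#' @param out_dir Optional output directory for TSV/JSON artifacts.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim, min_overlap = 20, max_mismatch_rate = 0.05,
                            length_bounds = NULL, min_mean_q = 20,
                            key_level = "full_aa", denoise = TRUE,
                            denoise_min_ratio = 20, pseudocount = 0.5,
                            min_late_count = 2, out_dir = NULL) {
  stopifnot(inherits(sim, "simulation_config"))
  if (is.null(length_bounds)) {
    length_bounds <- c(sim$read_length, 2L * sim$read_length - min_overlap)
  }
  structure(list(sim = sim, min_overlap = min_overlap,
                 max_mismatch_rate = max_mismatch_rate,
                 length_bounds = length_bounds, min_mean_q = min_mean_q,
                 key_level = key_level, denoise = isTRUE(denoise),
                 denoise_min_ratio = denoise_min_ratio,
                 pseudocount = pseudocount,
                 min_late_count = min_late_count, out_dir = out_dir,
                 seed = sim$seed),
            class = "pipeline_config")
}

#' Run the full biopanning analysis pipeline
#'
#' Simulate (or load) paired reads, merge and filter them, annotate VHHs,
#' tabulate clonotypes, compute per-stratum diversity, track and filter
#' enrichment, and score subtype selectivity. Deterministic for a fixed
#' seed; every stage's read funnel is recorded and checked to be
#' non-increasing.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result`: `report` (machine-readable run
#'   report), `tables` (per-stratum merged clonotype tables), `series`
#'   (per-subtype `biopanning_series`), `enrichment` (per-sorted-subtype
#'   [enrichment_filter()] outputs), `selectivity`
#'   ([selectivity_matrix()] or `NULL` if nothing passed), and `sim`
#'   (the [simulate_biopanning()] object with its truth tables).
#' @export
#' @examples
#' \donttest{
#' cfg <- pipeline_config(simulation_config(
#'   n_clones = 300, n_binders_per_subtype = 3, reads_per_sample = 300,
#'   capture_size = 2e4, n_replicates = 1, seed = 11))
#' res <- run_pipeline(cfg)
#' res$report$stage_counts[1, ]
#' }
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- simulate_biopanning(config$sim, emit = "reads")
  samples <- sim$samples

  # ---- read-level stages, per sample ------------------------------------
  funnel <- list()
  sample_cds <- list()
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    rd <- sim$reads[[sid]]
    merged <- merge_read_pairs(rd$r1, rd$q1, rd$r2, rd$q2,
                               min_overlap = config$min_overlap,
                               max_mismatch_rate = config$max_mismatch_rate,
                               id = rd$id)
    lf <- length_filter(merged, config$length_bounds[1],
                        config$length_bounds[2])
    qf <- quality_filter(lf, config$min_mean_q)
    cds <- extract_cds(qf$merged, config$sim$primers$primer5,
                       config$sim$primers$primer3)
    ok <- !is.na(cds)
    agg <- if (any(ok)) tapply(rep(1L, sum(ok)), cds[ok], sum) else NULL
    sample_cds[[sid]] <- if (is.null(agg)) {
      data.frame(cds = character(0), count = integer(0))
    } else {
      data.frame(cds = names(agg), count = as.integer(agg),
                 stringsAsFactors = FALSE)
    }
    funnel[[sid]] <- data.frame(
      sample_id = sid, round = samples$round[i],
      subtype = samples$subtype[i], replicate = samples$replicate[i],
      reads_total = length(rd$r1), merged = sum(merged$ok),
      length_ok = nrow(lf), quality_ok = nrow(qf), cds_ok = sum(ok),
      complete = NA_integer_, stringsAsFactors = FALSE)
  }

  # ---- annotate the global unique CDS pool once -------------------------
  all_cds <- unique(unlist(lapply(sample_cds, `[[`, "cds")))
  ann <- annotate_vhh(all_cds, scaffold = config$sim$scaffold)
  rownames(ann) <- all_cds

  tables <- list()
  for (sid in names(sample_cds)) {
    sc <- sample_cds[[sid]]
    rec <- ann[sc$cds, , drop = FALSE]
    rec$count <- sc$count
    rec <- rec[rec$complete, , drop = FALSE]
    funnel[[sid]]$complete <- sum(rec$count)
    i <- match(sid, samples$sample_id)
    tab <- build_clonotypes(rec, key_level = config$key_level,
                            metadata = list(round = samples$round[i],
                                            subtype = samples$subtype[i],
                                            replicate = samples$replicate[i]))
    if (config$denoise) {
      tab <- denoise_clonotypes(tab, min_ratio = config$denoise_min_ratio)
    }
    tables[[sid]] <- tab
  }
  funnel <- do.call(rbind, funnel)
  rownames(funnel) <- NULL
  stage_cols <- c("reads_total", "merged", "length_ok", "quality_ok",
                  "cds_ok", "complete")
  mono <- apply(funnel[, stage_cols], 1, function(r) all(diff(r) <= 0))
  assert_that(all(mono), "stage counts must be non-increasing")

  # ---- collapse replicates into stratum tables --------------------------
  strata <- unique(samples[, c("round", "subtype")])
  stratum_tables <- list()
  for (j in seq_len(nrow(strata))) {
    ids <- samples$sample_id[samples$round == strata$round[j] &
                               samples$subtype == strata$subtype[j]]
    stratum_tables[[paste(strata$round[j], strata$subtype[j], sep = "_")]] <-
      merge_replicates(tables[ids])
  }

  # ---- diversity per stratum --------------------------------------------
  div <- do.call(rbind, lapply(names(stratum_tables), function(nm) {
    t <- stratum_tables[[nm]]
    if (t$n == 0) return(NULL)
    d <- diversity_report(t)
    data.frame(stratum = nm, round = t$metadata$round,
               subtype = t$metadata$subtype, n = d$n, s_obs = d$s_obs,
               shannon = d$shannon, d0 = d$hill[["q0"]],
               d1 = d$hill[["q1"]], d2 = d$hill[["q2"]],
               percent_unique = d$percent_unique, stringsAsFactors = FALSE)
  }))
  rownames(div) <- NULL

  # ---- per-subtype series, enrichment, selectivity ----------------------
  subtypes <- config$sim$subtypes
  series <- list()
  for (s in subtypes) {
    nm <- paste0("BP", 0:config$sim$n_rounds, "_", s)
    have <- nm[nm %in% names(stratum_tables)]
    tabs <- stratum_tables[have]
    names(tabs) <- sub(paste0("_", s, "$"), "", have)
    series[[s]] <- biopanning_series(tabs, metadata = list(subtype = s))
  }
  sorted_subtypes <- subtypes[-1]
  enrich <- lapply(series[sorted_subtypes], enrichment_filter,
                   pseudocount = config$pseudocount,
                   min_late_count = config$min_late_count)
  passing <- sort(unique(unlist(lapply(enrich, function(e) {
    e$key[e$passes_filter]
  }))))
  selectivity <- NULL
  if (length(passing) > 0) {
    selectivity <- selectivity_matrix(series[sorted_subtypes],
                                      keys = passing,
                                      pseudocount = config$pseudocount)
  }

  report <- list(
    tool = "panrep", version = as.character(packageVersion("panrep")),
    seed = config$seed,
    stage_counts = funnel,
    diversity = div,
    enrichment = data.frame(
      subtype = sorted_subtypes,
      n_tracked = vapply(enrich, nrow, integer(1)),
      n_passing = vapply(enrich, function(e) sum(e$passes_filter),
                         integer(1)),
      pass_rate = vapply(enrich, function(e) mean(e$passes_filter),
                         numeric(1)),
      row.names = NULL, stringsAsFactors = FALSE),
    selectivity = if (is.null(selectivity)) NULL else {
      data.frame(n_clones = nrow(selectivity),
                 n_ambiguous = sum(selectivity$ambiguous))
    })

  out <- structure(list(report = report, tables = stratum_tables,
                        series = series, enrichment = enrich,
                        selectivity = selectivity, sim = sim,
                        config = config),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
  out
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(res$tables)) {
    write_clonotype_tsv(res$tables[[nm]],
                        file.path(out_dir, paste0("clonotypes_", nm, ".tsv")))
  }
  for (nm in names(res$enrichment)) {
    write_result_tsv(res$enrichment[[nm]],
                     file.path(out_dir, paste0("enrichment_", nm, ".tsv")))
  }
  if (!is.null(res$selectivity)) {
    write_result_tsv(res$selectivity, file.path(out_dir, "selectivity.tsv"))
  }
  write.table(res$report$stage_counts,
              file.path(out_dir, "stage_counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(run_report_json(res$report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  resolved <- res$config
  resolved$sim$scaffold <- unclass(resolved$sim$scaffold)[
    c("fr1", "fr2", "fr3", "fr4")]
  jsonlite::write_json(unclass_deep(resolved),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

run_report_json <- function(report) {
  report$stage_counts <- report$stage_counts
  report
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else unclass(x)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("panrep pipeline run (seed %d): %d samples\n",
              x$report$seed, nrow(x$report$stage_counts)))
  cat(sprintf("  reads: %d total, %d complete VHH\n",
              sum(x$report$stage_counts$reads_total),
              sum(x$report$stage_counts$complete)))
  cat(sprintf("  enrichment: %d clone(s) pass in >=1 subtype\n",
              if (is.null(x$selectivity)) 0L else nrow(x$selectivity)))
  invisible(x)
}
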