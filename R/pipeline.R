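#' Pipeline run configuration
#'
#' Collects every stage parameter with its default, the simulation scenario
#' (or paths to FASTQ inputs), and the output directory. Serializable to
#' JSON and round-trippable.
#'
#' @param seed master seed.
#' @param plans character vector of treatment plan labels to simulate.
#' @param condition condition/tissue to simulate.
#' @param sim list of [sim_config()] overrides.
#' @param preprocess,annotate,responsive,methyl lists of stage-parameter
#'   overrides (see the corresponding stage functions for names and
#'   defaults).
#' @param out_dir output directory, or `NULL` to keep results in memory.
#' @return An object of class `cpa_run_config`.
#' @export
run_config <- function(seed = 1,
                       plans = c("CPA", "CA", "PA", "CP"),
                       condition = "tissue_1",
                       sim = list(),
                       preprocess = list(),
                       annotate = list(),
                       responsive = list(),
                       methyl = list(),
                       out_dir = NULL) {
  structure(list(seed = as.integer(seed), plans = plans,
                 condition = condition, sim = sim, preprocess = preprocess,
                 annotate = annotate, responsive = responsive,
                 methyl = methyl, out_dir = out_dir),
            class = "cpa_run_config")
}

#' Run the simulation-to-expression pipeline
#'
#' For each requested treatment plan: simulate the library, preprocess
#' (trim, quality gate, UMI dedup, collapse), annotate through the cascade,
#' and assemble the joint expression table with RPM and miRNA-anchored
#' layers. Read accounting is asserted at every stage boundary and recorded
#' in the manifest. Rerunning with the same config and seed reproduces
#' byte-identical tables.
#'
#' @param scenario a [default_scenario()] object.
#' @param config a [run_config()].
#' @return A list of class `cpa_run`: `expression` (long tibble),
#'   `libraries` (per-plan list with truth/collapsed/hits/unannotated),
#'   `manifest` (parameters, per-stage read counts, conservation checks),
#'   and `db` (the reference database). Written to `config$out_dir` as TSV
#'   plus a JSON manifest when set.
#' @export
run_pipeline <- function(scenario, config) {
  stopifnot(inherits(scenario, "cpa_scenario"),
            inherits(config, "cpa_run_config"))
  cfg <- do.call(sim_config, c(list(seed = config$seed), config$sim))
  db <- reference_db(scenario$references)
  libs <- list()
  accounting <- list()
  for (plan_label in config$plans) {
    plan <- plan_from_label(plan_label)
    sim <- simulate_library(scenario, config$condition, plan, cfg)
    pp <- do.call(preprocess_reads,
                  c(list(reads = sim$reads, adapter3 = cfg$adapter3,
                         umi5_len = cfg$umi5_len, umi3_len = cfg$umi3_len),
                    config$preprocess))
    ann <- do.call(annotate_cascade,
                   c(list(collapsed = pp$collapsed, db = db),
                     config$annotate))
    raw_sum <- sum(pp$collapsed$raw_count)
    if (raw_sum != pp$n_accepted) {
      stop("read accounting violated in plan ", plan_label, call. = FALSE)
    }
    accounting[[plan_label]] <- list(
      n_simulated_reads = nrow(sim$reads),
      n_accepted = pp$n_accepted,
      raw_count_sum = raw_sum,
      unique_count_sum = sum(pp$collapsed$unique_count),
      n_molecules_sequenced = sim$n_molecules_sequenced,
      n_unique_sequences = nrow(pp$collapsed),
      n_annotated = nrow(ann$hits),
      n_unannotated = nrow(ann$unannotated),
      rejects = as.list(stats::setNames(pp$rejects$n, pp$rejects$status)))
    libs[[plan_label]] <- list(truth = sim$truth, collapsed = pp$collapsed,
                               hits = ann$hits,
                               unannotated = ann$unannotated)
  }
  expression <- expression_table(purrr::map(libs, "hits"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("cpaseq")),
    seed = config$seed, condition = config$condition,
    plans = config$plans,
    parameters = unclass(cfg),
    accounting = accounting)
  run <- structure(list(expression = expression, libraries = libs,
                        manifest = manifest, db = db, config = config),
                   class = "cpa_run")
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

#' @export
print.cpa_run <- function(x, ...) {
  cat("<pipeline run>", length(x$libraries), "libraries:",
      paste(names(x$libraries), collapse = ", "), "|",
      nrow(x$expression), "expression rows\n")
  invisible(x)
}

write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(run$expression, file.path(dir, "expression.tsv"))
  for (lib in names(run$libraries)) {
    l <- run$libraries[[lib]]
    readr::write_tsv(l$collapsed,
                     file.path(dir, paste0("collapsed_", lib, ".tsv")))
    hits_out <- l$hits
    hits_out$start <- hits_out$start + 1L # 1-based in serialized output
    readr::write_tsv(hits_out, file.path(dir, paste0("hits_", lib, ".tsv")))
    readr::write_tsv(l$truth, file.path(dir, paste0("truth_", lib, ".tsv")))
  }
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Compare a full library against an enzyme-omitted library
#'
#' Routes the pair to [call_responsive()] with the omitted enzyme inferred
#' from the plan labels, and, when the reduced plan omits AlkB, also runs
#' the methylome caller on the pair of pileups.
#'
#' @param run a [run_pipeline()] result containing both libraries.
#' @param full_label,reduced_label plan labels (e.g. `"CPA"`, `"CA"`).
#' @param ... passed to [call_responsive()].
#' @param methyl_args list of [call_methylation_sites()] overrides.
#' @return A list with `responsive` calls, `composition`, and (for an
#'   AlkB-omitted pair) `methyl` calls.
#' @export
run_compare <- function(run, full_label, reduced_label, ...,
                        methyl_args = list()) {
  stopifnot(inherits(run, "cpa_run"))
  if (!all(c(full_label, reduced_label) %in% names(run$libraries))) {
    stop("library label not found in run", call. = FALSE)
  }
  enz_of <- function(lab) {
    p <- plan_from_label(lab)
    c(cap_clip = p$cap_clip, pnk = p$pnk, alkb = p$alkb)
  }
  omitted <- names(which(enz_of(full_label) & !enz_of(reduced_label)))
  if (length(omitted) != 1) {
    stop("the reduced plan must omit exactly one enzyme of the full plan",
         call. = FALSE)
  }
  expr <- run$expression
  full_tbl <- expr[expr$library == full_label, , drop = FALSE]
  reduced_tbl <- expr[expr$library == reduced_label, , drop = FALSE]
  calls <- call_responsive(full_tbl, reduced_tbl, omitted, ...)
  out <- list(responsive = calls,
              composition = responsive_composition(calls),
              omitted_enzyme = omitted)
  if (omitted == "alkb") {
    refs <- run$db$references
    out$methyl <- do.call(call_methylation_sites, c(list(
      pileup_noAlkB = build_pileup(run$libraries[[reduced_label]]$hits,
                                   refs),
      pileup_withAlkB = build_pileup(run$libraries[[full_label]]$hits,
                                     refs)),
      methyl_args))
  }
  out
}
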