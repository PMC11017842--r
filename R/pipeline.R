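# End-to-end orchestration: rank -> sites -> enrich -> ddct -> cellcycle,
# from one configuration, with per-stage TSV outputs and a consolidated
# JSON report. Stage failures abort with the stage name; outputs written
# before the failure are retained.

#' Write a full synthetic study to disk
#'
#' Generates every input the pipeline consumes — evidence table, candidate
#' gene list, miRNA and UTR FASTA, GMT annotation, Ct table and cell-cycle
#' intensities (three replicates per condition) — plus a `truth.json`
#' recording all planted parameters, and a ready-to-run `config.yaml`.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed fixing the whole study.
#' @param n_background Background (non-hub) miRNAs in the evidence table.
#' @return The configuration list (paths + parameters), invisibly; side
#'   effect: files under `outdir`.
#' @export
simulate_study <- function(outdir, seed = 1L, n_background = 27L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)

  ev <- simulate_evidence(n_background = n_background, seed = seed)
  write_evidence_table(ev$evidence, p("evidence.tsv"))
  writeLines(ev$genes, p("genes.txt"))

  hub_ids <- ev$truth$mirna_id[ev$truth$is_hub]
  utr <- simulate_utrs(n_mirnas = length(hub_ids), seed = seed + 1L)
  names(utr$mirnas) <- hub_ids
  utr$truth$mirna_id <- hub_ids[match(utr$truth$mirna_id,
                                      sprintf("hsa-miR-sim-%02d",
                                              seq_along(hub_ids)))]
  write_fasta(utr$mirnas, p("mirnas.fa"))
  write_fasta(utr$utrs, p("utrs.fa"))

  gmt <- withr::with_seed(seed + 2L, {
    universe <- c(ev$genes, sprintf("BG%04d", seq_len(494)))
    terms <- c(list(candidate_term = ev$genes),
               lapply(1:8, function(i) sample(universe, 25)))
    names(terms) <- c("T0_candidates", sprintf("T%d_random", 1:8))
    attr(terms, "description") <- setNames(
      c("planted term holding the full candidate set",
        rep("random background term", 8)), names(terms))
    terms
  })
  write_gmt(gmt, p("annotation.gmt"))
  writeLines(c(candidate_genes(), sprintf("BG%04d", seq_len(494))),
             p("universe.txt"))

  ct <- simulate_ct(seed = seed + 3L)
  readr::write_csv(ct$ct, p("ct.csv"), progress = FALSE)

  conds <- list(
    empty_vector = c(g0g1 = 0.55, s = 0.30, g2m = 0.15),
    mirna_transfected = c(g0g1 = 0.75, s = 0.12, g2m = 0.13))
  cc <- purrr::imap(conds, function(fr, cond) {
    purrr::map(1:3, function(r) {
      sim <- simulate_cellcycle(fractions = fr, n_events = 4000L,
                                condition = cond,
                                seed = seed + 10L * r + match(cond, names(conds)))
      dplyr::mutate(sim$events, replicate = r)
    })
  })
  cc_tbl <- dplyr::bind_rows(purrr::flatten(cc))
  readr::write_csv(cc_tbl, p("cellcycle.csv"), progress = FALSE)

  truth <- list(
    seed = seed,
    hubs = hub_ids,
    evidence = ev$truth,
    sites = utr$truth,
    ct = ct$truth,
    cellcycle = conds)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA)

  config <- list(
    inputs = list(evidence = p("evidence.tsv"), genes = p("genes.txt"),
                  mirnas = p("mirnas.fa"), utrs = p("utrs.fa"),
                  gmt = p("annotation.gmt"), universe = p("universe.txt"),
                  ct = p("ct.csv"), cellcycle = p("cellcycle.csv")),
    params = list(min_coverage = 2L, top_k = 3L, top_n_sites = 3L,
                  fdr = 0.05, control = "control",
                  cellcycle_control = "empty_vector", seed = seed),
    outdir = p("results"))
  yaml::write_yaml(config, p("config.yaml"))
  invisible(config)
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_input("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  for (f in unlist(config$inputs)) {
    if (!is.null(f) && !file.exists(f)) {
      stop_input("input file not found: %s", f)
    }
  }
  config$params <- utils::modifyList(
    list(min_coverage = 2L, top_k = 3L, top_n_sites = 3L, fdr = 0.05,
         control = "control", cellcycle_control = NULL, seed = 1L),
    config$params %||% list())
  config
}

#' Run the full analysis pipeline
#'
#' Executes the study flow — miRNA coverage ranking, duplex site scanning,
#' over-representation of the candidate set, 2^-ddCt expression analysis
#' and cell-cycle phase comparison — writing one TSV per stage and a
#' consolidated JSON report. Stages whose inputs are absent from the
#' configuration are skipped and recorded as such. Any stage failure aborts
#' with the stage name; earlier outputs are retained.
#'
#' @param config Configuration list or path to a YAML file, with elements
#'   `inputs` (paths: `evidence`, `genes`, and optionally `mirnas`, `utrs`,
#'   `gmt`, `universe`, `ct`, `cellcycle`), `params` (`min_coverage`,
#'   `top_k`, `top_n_sites`, `fdr`, `control`, `seed`) and `outdir`.
#' @param quiet Suppress progress messages.
#' @return The report list, invisibly; side effect: files under
#'   `config$outdir` including `report.json`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  config <- read_pipeline_config(config)
  outdir <- config$outdir %||% stop_input("config$outdir is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  inp <- config$inputs
  par <- config$params
  say <- function(...) if (!quiet) message(sprintf(...))

  stage <- function(name, expr) {
    say("[%s] running", name)
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)),
                   class = "mirtally_stage_error")
    })
  }

  report <- list(stages = character(0), params = par)

  genes <- stage("rank", read_gene_set(inp$genes))
  ranking <- stage("rank", {
    ev <- read_evidence_table(inp$evidence)
    r <- rank_mirnas(ev, genes, min_coverage = par$min_coverage,
                     top_k = par$top_k)
    readr::write_tsv(r, file.path(outdir, "rank.tsv"), progress = FALSE)
    r
  })
  report$stages <- c(report$stages, "rank")
  report$ranking <- ranking

  if (!is.null(inp$mirnas) && !is.null(inp$utrs)) {
    sites <- stage("sites", {
      m <- read_fasta(inp$mirnas)
      u <- read_fasta(inp$utrs)
      s <- report_sites(m, u, top_n = par$top_n_sites)
      readr::write_tsv(s, file.path(outdir, "sites.tsv"), progress = FALSE)
      s
    })
    report$stages <- c(report$stages, "sites")
    report$sites <- sites
  }

  if (!is.null(inp$gmt)) {
    enr <- stage("enrich", {
      ann <- read_gmt(inp$gmt)
      uni <- if (!is.null(inp$universe)) read_gene_set(inp$universe) else NULL
      e <- enrich(genes, ann, universe = uni, threshold = par$fdr)
      readr::write_tsv(e, file.path(outdir, "enrich.tsv"), progress = FALSE)
      e
    })
    report$stages <- c(report$stages, "enrich")
    report$enrichment <- enr
  }

  if (!is.null(inp$ct)) {
    ddct <- stage("ddct", {
      ct <- read_ct_table(inp$ct)
      refs <- unique(unname(default_reference_map(unique(ct$assay))))
      targets <- setdiff(unique(ct$assay), refs)
      res <- purrr::map(targets, function(a)
        delta_delta_ct(ct, a, control = par$control))
      names(res) <- targets
      tbl <- purrr::map_dfr(res, function(r) tibble::tibble(
        assay = r$assay, mean_fold_change = r$mean_fold_change,
        p_anova = r$p_anova, normality_p = r$normality_p,
        significant = r$significant))
      readr::write_tsv(tbl, file.path(outdir, "ddct.tsv"), progress = FALSE)
      list(table = tbl, results = res)
    })
    report$stages <- c(report$stages, "ddct")
    report$expression <- ddct$table
  }

  if (!is.null(inp$cellcycle)) {
    cc <- stage("cellcycle", {
      ev <- read_intensities(inp$cellcycle)
      has_rep <- "replicate" %in% names(readr::read_csv(
        inp$cellcycle, n_max = 0, show_col_types = FALSE, progress = FALSE))
      if (has_rep) {
        ev <- readr::read_csv(inp$cellcycle, col_types = readr::cols(
          condition = "c", intensity = "d", replicate = "i"),
          progress = FALSE)
      } else {
        ev$replicate <- 1L
      }
      fits <- dplyr::group_by(ev, .data$condition, .data$replicate)
      fits <- dplyr::group_modify(fits, function(d, key) {
        f <- fit_phases(d$intensity)
        tibble::tibble(g0g1 = f$g0g1, s = f$s, g2m = f$g2m,
                       mu1 = f$mu1, mu2 = f$mu2, cv = f$cv, n = f$n,
                       degenerate = f$degenerate)
      })
      fits <- dplyr::ungroup(fits)
      comp <- if (min(table(fits$condition)) >= 3L &&
                  length(unique(fits$condition)) >= 2L) {
        cmp <- compare_conditions(fits)
        dplyr::select(cmp, "phase", "p_anova")
      } else NULL
      readr::write_tsv(fits, file.path(outdir, "cellcycle.tsv"),
                       progress = FALSE)
      list(fractions = fits, comparison = comp)
    })
    report$stages <- c(report$stages, "cellcycle")
    report$cell_cycle <- cc
  }

  report$timestamp <- format(Sys.time(), tz = "UTC")
  out <- report
  out$timestamp <- NULL
  json <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows", null = "null")
  full <- jsonlite::toJSON(c(out, list(timestamp = report$timestamp)),
                           auto_unbox = TRUE, digits = NA,
                           dataframe = "rows", null = "null")
  writeLines(full, file.path(outdir, "report.json"))
  say("report written to %s", file.path(outdir, "report.json"))
  invisible(c(out, list(timestamp = report$timestamp, report_json = json)))
}
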