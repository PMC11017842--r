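# Seeded generators for every input the pipeline consumes, each returning
# its planted ground truth so downstream recovery is testable end to end.
# All draws go through R's default Mersenne-Twister generator inside
# withr::with_seed, so a seed fixes every byte of output.

#' The default candidate drug-target gene set
#'
#' The six prostate-cancer drug-target genes used as the default candidate
#' set throughout the package and its simulators.
#'
#' @return Character vector of six gene symbols.
#' @export
candidate_genes <- function() c("AR", "PIK3CA", "PIK3CB", "MET", "FGFR4", "EGFR")

#' Default planted-hub layout for the evidence simulator
#'
#' Three hub miRNAs shaped like the study candidates: (near-)full coverage
#' of the six candidate genes with a small number of negative validated
#' records.
#'
#' @return Tibble with columns `mirna`, `coverage`, `validated_fraction`,
#'   `negative_rate`, `n_validated_records`.
#' @export
default_hubs <- function() {
  # Hub layout shaped like the three study candidates: full or near-full
  # coverage of six genes, a handful of negative validated records.
  tibble::tibble(
    mirna = c("hsa-miR-16-5p", "hsa-miR-124-3p", "hsa-miR-27a-3p"),
    coverage = c(6L, 6L, 6L),
    validated_fraction = c(1, 1, 5 / 6),
    negative_rate = c(1 / 16, 2 / 9, 2 / 8),
    n_validated_records = c(16L, 9L, 8L))
}

#' Simulate a multi-source miRNA-gene evidence table
#'
#' Plants "hub" miRNAs that cover a specified number of candidate genes
#' with a given validated fraction and negative-direction rate, against a
#' background of sparse miRNAs covering at most one gene. The realized
#' per-miRNA tallies are recorded as ground truth while the table is built.
#'
#' @param genes Candidate gene set (default: the six drug-target genes).
#' @param hubs Tibble with columns `mirna`, `coverage`,
#'   `validated_fraction`, `negative_rate`, `n_validated_records`; defaults
#'   to three hubs shaped like the study candidates.
#' @param n_background Number of sparse background miRNAs.
#' @param n_sources Size of the predicted-source name pool.
#' @param seed Integer seed fixing every draw.
#' @return List with `evidence` (tibble), `truth` (per-miRNA planted
#'   tallies with `is_hub`), and `genes`.
#' @export
simulate_evidence <- function(genes = candidate_genes(),
                              hubs = default_hubs(),
                              n_background = 27L,
                              n_sources = 12L,
                              seed = 1L) {
  genes <- gene_set(genes)
  if (any(hubs$coverage > length(genes))) {
    stop_input("hub coverage exceeds the number of genes")
  }
  val_pool <- c("tarbase", "mirtarbase", "mirecords", "starbase",
                paste0("valdb", seq_len(40)))
  pred_pool <- c("targetscan", "mirdb", "pita", "diana_microt", "mirtar",
                 "mirwalk", paste0("preddb", seq_len(max(0, n_sources))))
  pred_pool <- head(pred_pool, max(n_sources, 1L))

  withr::with_seed(seed, {
    rows <- list()
    truth <- list()

    emit_hub <- function(h) {
      covered <- sample(genes, h$coverage)
      n_val_genes <- round(h$validated_fraction * h$coverage)
      val_genes <- head(covered, n_val_genes)
      ev <- NULL
      if (n_val_genes > 0) {
        nrec <- max(h$n_validated_records, n_val_genes)
        gene_of <- rep(val_genes, length.out = nrec)
        src_of <- val_pool[stats::ave(seq_len(nrec), gene_of,
                                      FUN = seq_along)]
        nneg <- round(h$negative_rate * nrec)
        dir <- rep("positive", nrec)
        if (nneg > 0) dir[seq(nrec, by = -1L, length.out = nneg)] <- "negative"
        ev <- tibble::tibble(
          mirna_id = h$mirna, gene_id = gene_of, source_name = src_of,
          source_class = "validated", direction = dir,
          confidence = round(stats::runif(nrec, 0.85, 1), 4))
      } else {
        nrec <- 0L; nneg <- 0L
      }
      pred <- purrr::map(covered, function(g) {
        k <- sample(1:3, 1)
        tibble::tibble(
          mirna_id = h$mirna, gene_id = g,
          source_name = sample(pred_pool, min(k, length(pred_pool))),
          source_class = "predicted", direction = "positive",
          confidence = round(stats::runif(min(k, length(pred_pool)),
                                          0.3, 0.99), 4))
      })
      ev <- dplyr::bind_rows(ev, dplyr::bind_rows(pred))
      truth[[h$mirna]] <<- tibble::tibble(
        mirna_id = h$mirna, coverage = h$coverage,
        n_validated_genes = n_val_genes,
        n_predicted_genes = h$coverage,
        positive_evidence = nrec - nneg, negative_evidence = nneg,
        net_evidence = nrec - 2L * nneg, is_hub = TRUE)
      ev
    }

    for (i in seq_len(nrow(hubs))) rows[[length(rows) + 1L]] <-
      emit_hub(as.list(hubs[i, ]))

    for (i in seq_len(n_background)) {
      id <- sprintf("hsa-miR-sim-%02d", i)
      cov <- sample(0:1, 1)
      if (cov == 1L) {
        g <- sample(genes, 1)
        k <- sample(1:2, 1)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          mirna_id = id, gene_id = g,
          source_name = sample(pred_pool, k),
          source_class = "predicted", direction = "positive",
          confidence = round(stats::runif(k, 0.3, 0.99), 4))
      }
      truth[[id]] <- tibble::tibble(
        mirna_id = id, coverage = cov, n_validated_genes = 0L,
        n_predicted_genes = cov, positive_evidence = 0L,
        negative_evidence = 0L, net_evidence = 0L, is_hub = FALSE)
    }

    list(evidence = validate_evidence(dplyr::bind_rows(rows)),
         truth = dplyr::bind_rows(truth), genes = genes)
  })
}

random_rna <- function(n, len, first = NULL) {
  vapply(seq_len(n), function(i) {
    s <- sample(c("A", "C", "G", "U"), len, replace = TRUE)
    if (!is.null(first)) s[1] <- first
    paste(s, collapse = "")
  }, character(1))
}

# The site string a miRNA seed leaves on the UTR (5'->3'), per site type.
seed_site_string <- function(mirna, site_type) {
  core <- rna_revcomp(substr(mirna, 2L, 7L))
  m8c <- rna_complement(substr(mirna, 8L, 8L))
  switch(site_type,
         "6mer" = core,
         "7mer-m8" = paste0(m8c, core),
         "7mer-A1" = paste0(core, "A"),
         "8mer" = paste0(m8c, core, "A"),
         stop_input("unknown site type %s", site_type))
}

#' Simulate 3'UTRs with planted miRNA seed sites
#'
#' Generates random miRNAs (22 nt, 5' U, the typical human composition) and
#' random UTRs, then plants the requested number of seed sites of each type
#' per (miRNA, UTR) pair at non-overlapping offsets. Planted sites get
#' neutral flanking bases so a 6mer cannot silently upgrade to a longer
#' type. The truth table lists every site present after planting (planted
#' and chance background alike), with chance sites flagged.
#'
#' @param n_mirnas Number of miRNAs to generate (ignored when `mirnas`
#'   given).
#' @param mirnas Optional named character vector of miRNA sequences.
#' @param utr_ids UTR identifiers (default: the six candidate genes).
#' @param utr_length UTR length in nt.
#' @param planted Named integer vector: sites to plant per type per
#'   (miRNA, UTR) pair.
#' @param seed Integer seed.
#' @return List with `mirnas`, `utrs` (named character vectors) and `truth`
#'   (tibble `mirna_id`, `utr_id`, `start`, `end`, `site_type`, `planted`).
#' @export
simulate_utrs <- function(n_mirnas = 3L, mirnas = NULL,
                          utr_ids = candidate_genes(), utr_length = 500L,
                          planted = c("8mer" = 1L), seed = 1L) {
  stopifnot(all(names(planted) %in% c("8mer", "7mer-m8", "7mer-A1", "6mer")))
  withr::with_seed(seed, {
    if (is.null(mirnas)) {
      mirnas <- setNames(random_rna(n_mirnas, 22L, first = "U"),
                         sprintf("hsa-miR-sim-%02d", seq_len(n_mirnas)))
    } else {
      mirnas <- normalize_rna(mirnas)
    }
    longest_site <- 8L + 2L   # site plus two guard flanks
    n_slots <- sum(planted) * length(mirnas)
    if (longest_site * n_slots > utr_length) {
      stop_input("planted sites do not fit in a %d-nt UTR", utr_length)
    }

    utrs <- setNames(random_rna(length(utr_ids), utr_length), utr_ids)
    plant_rows <- list()

    for (u in names(utrs)) {
      occupied <- integer(0)   # 1-based positions already used
      for (m in names(mirnas)) {
        for (tp in names(planted)) {
          for (rep_i in seq_len(planted[[tp]])) {
            site <- seed_site_string(mirnas[[m]], tp)
            guard5 <- setdiff(c("C", "G", "U"),
                              rna_complement(substr(mirnas[[m]], 8L, 8L)))[1]
            block <- paste0(guard5, site, "C")   # 3' guard C blocks A1 upgrade
            w <- nchar(block)
            ok <- FALSE
            for (try_i in seq_len(200L)) {
              pos <- sample(seq_len(utr_length - w + 1L), 1)
              if (!any((pos:(pos + w - 1L)) %in% occupied)) { ok <- TRUE; break }
            }
            if (!ok) stop_input("could not place a planted site")
            substr(utrs[[u]], pos, pos + w - 1L) <- block
            occupied <- c(occupied, pos:(pos + w - 1L))
            site_start0 <- pos        # 0-based: block starts at pos-1, site at pos
            plant_rows[[length(plant_rows) + 1L]] <- tibble::tibble(
              mirna_id = m, utr_id = u, start = site_start0,
              end = site_start0 + nchar(site), site_type = tp)
          }
        }
      }
    }
    planted_tbl <- dplyr::bind_rows(plant_rows)

    truth <- purrr::map(names(mirnas), function(m) {
      purrr::map(names(utrs), function(u) {
        found <- find_seed_sites(mirnas[[m]], utrs[[u]])
        if (!nrow(found)) return(NULL)
        found$mirna_id <- m; found$utr_id <- u
        found
      })
    })
    truth <- dplyr::bind_rows(purrr::flatten(truth))
    truth <- dplyr::left_join(
      truth,
      dplyr::mutate(planted_tbl, planted = TRUE),
      by = c("mirna_id", "utr_id", "start", "end", "site_type"))
    truth$planted <- tidyr::replace_na(truth$planted, FALSE)
    list(mirnas = mirnas, utrs = utrs,
         truth = dplyr::select(truth, "mirna_id", "utr_id", "start", "end",
                               "site_type", "planted"))
  })
}

#' Simulate replicate Ct measurements with planted fold changes
#'
#' Control and treated samples measure each target assay plus the reference
#' assay. A target Ct is its assay baseline, minus `log2(fold change)` in
#' the treated group, plus Gaussian noise of `sigma` cycles; reference Cts
#' get the same noise but no group effect.
#'
#' @param fold_changes Named vector of true treated/control fold changes
#'   per target assay.
#' @param sigma Per-measurement Ct noise, in cycles.
#' @param n_reps Replicates per group.
#' @param reference Reference assay name.
#' @param seed Integer seed.
#' @return List with `ct` (tibble: `sample_id`, `group`, `assay`, `ct`) and
#'   `truth` (the generator parameters).
#' @export
simulate_ct <- function(fold_changes = setNames(rep(0.4, 6), candidate_genes()),
                        sigma = 0.15, n_reps = 3L, reference = "GAPDH",
                        seed = 1L) {
  withr::with_seed(seed, {
    assays <- names(fold_changes)
    base <- setNames(stats::runif(length(assays), 20, 28), assays)
    base_ref <- 18
    samples <- tibble::tibble(
      sample_id = c(paste0("ctrl_", seq_len(n_reps)),
                    paste0("trt_", seq_len(n_reps))),
      group = rep(c("control", "treated"), each = n_reps))
    rows <- purrr::pmap(samples, function(sample_id, group) {
      eff <- if (group == "treated") -log2(fold_changes) else
        numeric(length(assays))
      tibble::tibble(
        sample_id = sample_id, group = group,
        assay = c(assays, reference),
        ct = c(base + eff + stats::rnorm(length(assays), 0, sigma),
               base_ref + stats::rnorm(1, 0, sigma)))
    })
    list(ct = validate_ct(dplyr::bind_rows(rows)),
         truth = list(fold_changes = fold_changes, sigma = sigma,
                      n_reps = n_reps, reference = reference))
  })
}

#' Simulate per-cell DNA-content intensities
#'
#' Draws events from the constrained cell-cycle mixture: a 2N Gaussian at
#' `mu1`, a 4N Gaussian at `ratio * mu1` (both with coefficient of
#' variation `cv`), and an S-phase plateau uniform in intensity between the
#' two means.
#'
#' @param fractions Named fractions `g0g1`, `s`, `g2m` (must sum to 1).
#' @param mu1 2N peak mean intensity.
#' @param cv Shared coefficient of variation.
#' @param ratio 4N/2N mean ratio (default 2).
#' @param n_events Number of cells.
#' @param condition Condition label attached to the events.
#' @param seed Integer seed.
#' @return List with `events` (tibble: `condition`, `intensity`) and
#'   `truth`.
#' @export
simulate_cellcycle <- function(fractions = c(g0g1 = 0.60, s = 0.25, g2m = 0.15),
                               mu1 = 100, cv = 0.05, ratio = 2,
                               n_events = 10000L, condition = "sim",
                               seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9 || any(fractions < 0)) {
    stop_input("fractions must be non-negative and sum to 1")
  }
  mu2 <- ratio * mu1
  withr::with_seed(seed, {
    comp <- sample(c("g0g1", "g2m", "s"), n_events, replace = TRUE,
                   prob = c(fractions[["g0g1"]], fractions[["g2m"]],
                            fractions[["s"]]))
    x <- numeric(n_events)
    n1 <- sum(comp == "g0g1"); n2 <- sum(comp == "g2m"); ns <- sum(comp == "s")
    x[comp == "g0g1"] <- stats::rnorm(n1, mu1, cv * mu1)
    x[comp == "g2m"] <- stats::rnorm(n2, mu2, cv * mu2)
    x[comp == "s"] <- stats::runif(ns, mu1, mu2)
    x <- pmax(x, 1e-6)
    list(events = tibble::tibble(condition = condition, intensity = x),
         truth = list(fractions = fractions, mu1 = mu1, mu2 = mu2, cv = cv,
                      n_events = n_events, component = comp))
  })
}
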