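# Seed-site detection, duplex alignment and hybridization free energy.
#
# Seed taxonomy (miRNA positions 1-based from the 5' end):
#   6mer     UTR site = revcomp(miRNA 2-7)
#   7mer-m8  site = revcomp(miRNA 2-8)
#   7mer-A1  site = revcomp(miRNA 2-7) + A (the A opposes miRNA position 1)
#   8mer     site = revcomp(miRNA 2-8) + A
# Written 5'->3' on the UTR, the match to miRNA position 8 sits at the 5'
# end of the site and the A1 adenine at its 3' end. Seed matching is strict
# Watson-Crick; G:U wobble is allowed only in the 3'-supplementary
# alignment.

#' Find canonical seed-match sites of a miRNA on a 3'UTR
#'
#' Scans the UTR exhaustively, left to right, for all occurrences of the
#' reverse complement of the miRNA seed (positions 2-7) and classifies each
#' as `8mer`, `7mer-m8`, `7mer-A1` or `6mer` — the most specific class the
#' flanking bases support. Overlapping sites are all reported. Coordinates
#' are 0-based, half-open, on the UTR sense strand.
#'
#' @param mirna miRNA sequence (RNA or DNA alphabet; >= 8 nt).
#' @param utr 3'UTR sequence.
#' @return Tibble with columns `start`, `end`, `site_type`, ordered by
#'   `start`; zero rows when there is no seed match.
#' @export
#' @examples
#' find_seed_sites("UAGCAGCACGUAAAUAUUGGCG",
#'                 paste0("AAAAA", "GCUGCUA", "A", "CCCCC"))
find_seed_sites <- function(mirna, utr) {
  mirna <- normalize_rna(mirna, "mirna")
  utr <- normalize_rna(utr, "utr")
  if (nchar(mirna) < 8L) stop_input("miRNA must be at least 8 nt")

  core <- rna_revcomp(substr(mirna, 2L, 7L))        # matches positions 2-7
  m8c <- rna_complement(substr(mirna, 8L, 8L))      # base opposing position 8
  n <- nchar(utr)

  hits <- gregexpr(core, utr, fixed = TRUE)[[1]]
  starts0 <- integer(0)
  if (hits[1] != -1L) {
    # gregexpr skips overlapping matches for repetitive cores; rescan.
    starts0 <- which(vapply(seq_len(n - 5L),
                            function(i) substr(utr, i, i + 5L) == core,
                            logical(1))) - 1L
  }
  if (!length(starts0)) {
    return(tibble::tibble(start = integer(0), end = integer(0),
                          site_type = character(0)))
  }
  rows <- lapply(starts0, function(p) {
    has_m8 <- p >= 1L && substr(utr, p, p) == m8c
    has_a1 <- p + 6L < n && substr(utr, p + 7L, p + 7L) == "A"
    if (has_m8 && has_a1) {
      list(start = p - 1L, end = p + 7L, site_type = "8mer")
    } else if (has_m8) {
      list(start = p - 1L, end = p + 6L, site_type = "7mer-m8")
    } else if (has_a1) {
      list(start = p, end = p + 7L, site_type = "7mer-A1")
    } else {
      list(start = p, end = p + 6L, site_type = "6mer")
    }
  })
  out <- dplyr::bind_rows(rows)
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  dplyr::arrange(out, .data$start, .data$end)
}

pair_kind <- function(a, b) {
  # a, b single bases; returns "wc", "gu" or "none".
  key <- paste0(a, b)
  if (key %in% c("AU", "UA", "GC", "CG")) "wc"
  else if (key %in% c("GU", "UG")) "gu"
  else "none"
}

#' Align a miRNA against a UTR window (duplex complementarity alignment)
#'
#' Global affine-gap alignment of the miRNA (displayed 3'->5') against the
#' UTR window (5'->3'), scoring complementarity rather than identity:
#' +5 for a Watson-Crick pair, +1 for a G:U wobble, -3 for a mismatch,
#' -8 to open a gap and -2 to extend it. Traceback is deterministic: on
#' ties, a paired column is preferred, then a gap in the miRNA strand, then
#' a gap in the UTR strand, so alignments are bit-reproducible.
#'
#' @param mirna miRNA sequence, 5'->3'.
#' @param utr_window UTR subsequence, 5'->3' (typically a seed site extended
#'   toward its 5' flank by up to the miRNA length).
#' @return Object of class `duplex_alignment`: a list with `mirna` (aligned
#'   string, 3'->5'), `bars` (`|` Watson-Crick, `:` wobble, space
#'   otherwise), `utr` (aligned string, 5'->3') and `score`.
#' @export
align_duplex <- function(mirna, utr_window) {
  mirna <- normalize_rna(mirna, "mirna")
  if (!nzchar(utr_window)) stop_input("empty UTR window")
  utr_window <- normalize_rna(utr_window, "utr_window")

  a <- strsplit(reverse_string(mirna), "")[[1]]  # miRNA 3'->5'
  b <- strsplit(utr_window, "")[[1]]             # UTR 5'->3'
  n <- length(a); m <- length(b)
  open <- -8; ext <- -2
  NEG <- -1e9

  sub <- function(x, y) switch(pair_kind(x, y), wc = 5, gu = 1, -3)

  M <- matrix(NEG, n + 1L, m + 1L)   # ends in aligned column
  GU <- matrix(NEG, n + 1L, m + 1L)  # ends with gap in miRNA (consumes UTR)
  GM <- matrix(NEG, n + 1L, m + 1L)  # ends with gap in UTR (consumes miRNA)
  M[1, 1] <- 0
  for (j in seq_len(m)) GU[1, j + 1L] <- open + ext * (j - 1L)
  for (i in seq_len(n)) GM[i + 1L, 1] <- open + ext * (i - 1L)

  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- sub(a[i], b[j])
      M[i + 1L, j + 1L] <- max(M[i, j], GU[i, j], GM[i, j]) + s
      GU[i + 1L, j + 1L] <- max(M[i + 1L, j] + open, GU[i + 1L, j] + ext,
                                GM[i + 1L, j] + open)
      GM[i + 1L, j + 1L] <- max(M[i, j + 1L] + open, GU[i, j + 1L] + open,
                                GM[i, j + 1L] + ext)
    }
  }

  # State preference on ties: M (diagonal) > GU (miRNA-gap) > GM (UTR-gap).
  pick <- function(vals) which(vals == max(vals))[1L]
  state <- c("M", "GU", "GM")[pick(c(M[n + 1L, m + 1L], GU[n + 1L, m + 1L],
                                     GM[n + 1L, m + 1L]))]
  score <- max(M[n + 1L, m + 1L], GU[n + 1L, m + 1L], GM[n + 1L, m + 1L])

  top <- character(0); mid <- character(0); bot <- character(0)
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    if (state == "M") {
      s <- sub(a[i], b[j])
      prev <- c(M[i, j], GU[i, j], GM[i, j])
      top <- c(a[i], top)
      mid <- c(switch(pair_kind(a[i], b[j]), wc = "|", gu = ":", " "), mid)
      bot <- c(b[j], bot)
      i <- i - 1L; j <- j - 1L
      if (i == 0L && j == 0L) break
      state <- c("M", "GU", "GM")[pick(prev)]
    } else if (state == "GU") {
      prev <- c(M[i + 1L, j] + open, GU[i + 1L, j] + ext, GM[i + 1L, j] + open)
      top <- c("-", top); mid <- c(" ", mid); bot <- c(b[j], bot)
      j <- j - 1L
      if (i == 0L && j == 0L) break
      state <- if (j == 0L) "GM" else c("M", "GU", "GM")[pick(prev)]
    } else {
      prev <- c(M[i, j + 1L] + open, GU[i, j + 1L] + open, GM[i, j + 1L] + ext)
      top <- c(a[i], top); mid <- c(" ", mid); bot <- c("-", bot)
      i <- i - 1L
      if (i == 0L && j == 0L) break
      state <- if (i == 0L) "GU" else c("M", "GU", "GM")[pick(prev)]
    }
  }

  structure(list(mirna = paste(top, collapse = ""),
                 bars = paste(mid, collapse = ""),
                 utr = paste(bot, collapse = ""),
                 score = score),
            class = "duplex_alignment")
}

#' @export
print.duplex_alignment <- function(x, ...) {
  cat("miRNA 3' ", x$mirna, " 5'\n", sep = "")
  cat("         ", x$bars, "\n", sep = "")
  cat("UTR   5' ", x$utr, " 3'\n", sep = "")
  cat("score: ", x$score, "\n", sep = "")
  invisible(x)
}

#' Packaged nearest-neighbor duplex energy parameters
#'
#' Reads the RNA/RNA stacking table shipped with the package (Turner-style
#' Watson-Crick stack free energies at 37 C, one generic wobble-stack entry,
#' a duplex initiation penalty and a linear interior-loop penalty).
#'
#' @param path Path to a parameter TSV; defaults to the packaged table.
#' @return Named numeric vector of free-energy terms (kcal/mol), keyed by
#'   stack (`XY/ZW`, read 5'XY3'/3'ZW5') or by `wobble`, `initiation`,
#'   `loop_base`, `loop_per_nt`.
#' @export
duplex_energy_params <- function(path = NULL) {
  path <- path %||% system.file("extdata", "rna_stacking_dg37.tsv",
                                package = "mirtally", mustWork = TRUE)
  tbl <- readr::read_tsv(path, comment = "#", col_types = "cd",
                         progress = FALSE)
  setNames(tbl$dg, tbl$key)
}

#' Hybridization free energy of an aligned duplex
#'
#' Nearest-neighbor free energy of a [align_duplex()] result: the sum of
#' stacking terms over consecutive paired columns, plus the duplex
#' initiation penalty, plus a linear penalty for each interior unpaired
#' stretch (loops/bulges) between helices. Unpaired dangling ends contribute
#' nothing. Stacks are keyed by the UTR dinucleotide 5'->3' over the
#' opposing miRNA dinucleotide; any stack containing a G:U pair uses the
#' generic wobble entry.
#'
#' @param alignment A `duplex_alignment`.
#' @param params Energy parameter vector, see [duplex_energy_params()].
#' @return Free energy in kcal/mol (negative = favorable), with attribute
#'   `non_binding = TRUE` when the alignment contains no paired column (the
#'   value is then just the initiation penalty).
#' @export
duplex_free_energy <- function(alignment,
                               params = duplex_energy_params()) {
  stopifnot(inherits(alignment, "duplex_alignment"))
  top <- strsplit(alignment$mirna, "")[[1]]
  mid <- strsplit(alignment$bars, "")[[1]]
  bot <- strsplit(alignment$utr, "")[[1]]
  paired <- mid != " "
  idx <- which(paired)
  if (!length(idx)) {
    return(structure(unname(params[["initiation"]]), non_binding = TRUE))
  }
  dg <- params[["initiation"]]
  for (k in seq_along(idx)[-1]) {
    i0 <- idx[k - 1L]; i1 <- idx[k]
    if (i1 == i0 + 1L) {
      # contiguous stack
      if (mid[i0] == "|" && mid[i1] == "|") {
        key <- paste0(bot[i0], bot[i1], "/", top[i0], top[i1])
        dg <- dg + params[[key]]
      } else {
        dg <- dg + params[["wobble"]]
      }
    } else {
      # interior loop/bulge: count unpaired bases on both strands
      between <- (i0 + 1L):(i1 - 1L)
      L <- sum(top[between] != "-") + sum(bot[between] != "-")
      dg <- dg + params[["loop_base"]] + params[["loop_per_nt"]] * L
    }
  }
  unname(dg)
}

#' Scan, align and rank all seed-anchored duplexes
#'
#' For every (miRNA, UTR) pair, detects seed sites, aligns the full miRNA
#' against each site's window (the site plus its 5' UTR flank, up to one
#' miRNA length) and scores the duplex free energy. Hits are ranked by free
#' energy (most negative first) and truncated to `top_n` per pair.
#'
#' @param mirnas Named character vector of miRNA sequences.
#' @param utrs Named character vector of 3'UTR sequences.
#' @param top_n Hits retained per (miRNA, UTR) pair.
#' @param params Energy parameters, see [duplex_energy_params()].
#' @return Tibble with columns `mirna_id`, `utr_id`, `start`, `end`,
#'   `site_type`, `delta_g`, `alignment` (the three alignment strings joined
#'   by `;`), sorted by `delta_g` then (`utr_id`, `start`).
#' @export
report_sites <- function(mirnas, utrs, top_n = 3L,
                         params = duplex_energy_params()) {
  top_n <- assert_count(top_n, "top_n", min = 0L)
  if (!length(mirnas) || !length(utrs)) stop_input("empty sequence set")
  mirnas <- normalize_rna(mirnas)
  utrs <- normalize_rna(utrs)

  combos <- tidyr::expand_grid(mirna_id = sort(names(mirnas)),
                               utr_id = sort(names(utrs)))
  rows <- purrr::pmap(combos, function(mirna_id, utr_id) {
    m <- mirnas[[mirna_id]]
    u <- utrs[[utr_id]]
    sites <- find_seed_sites(m, u)
    if (!nrow(sites)) return(NULL)
    hits <- purrr::pmap(sites, function(start, end, site_type) {
      wstart <- max(0L, start - nchar(m))
      window <- substr(u, wstart + 1L, end)   # site plus 5' flank
      aln <- align_duplex(m, window)
      tibble::tibble(
        mirna_id = mirna_id, utr_id = utr_id,
        start = start, end = end, site_type = site_type,
        delta_g = duplex_free_energy(aln, params),
        alignment = paste(aln$mirna, aln$bars, aln$utr, sep = ";"))
    })
    hits <- dplyr::bind_rows(hits)
    hits <- dplyr::arrange(hits, .data$delta_g, .data$utr_id, .data$start)
    head(hits, top_n)
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    return(tibble::tibble(mirna_id = character(0), utr_id = character(0),
                          start = integer(0), end = integer(0),
                          site_type = character(0), delta_g = numeric(0),
                          alignment = character(0)))
  }
  dplyr::arrange(out, .data$delta_g, .data$utr_id, .data$start)
}
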