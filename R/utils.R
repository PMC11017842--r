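# Internal helpers shared across modules.

# Canonical gene symbol: trimmed, uppercase.
canon_gene <- function(x) toupper(trimws(x))

# miRNA ids are compared case-insensitively but stored as given
# (first occurrence wins), since "Hsa-miR" and "hsa-miR" styles coexist
# in the literature.
canon_mirna_key <- function(x) tolower(trimws(x))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "mirtally_input_error")
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop_input("`%s` must be a single integer >= %d, got %s", name, min,
               paste(format(x), collapse = ","))
  }
  as.integer(x)
}

# RNA alphabet normalization: uppercase, T -> U, validate.
normalize_rna <- function(seqs, ids = names(seqs)) {
  s <- chartr("t", "T", toupper(seqs))
  s <- chartr("T", "U", s)
  bad <- grepl("[^ACGU]", s) | !nzchar(s)
  if (any(bad)) {
    stop_input("sequence(s) %s empty or outside alphabet {A,C,G,U,T}",
               paste(ids[bad], collapse = ", "))
  }
  s
}

rna_complement <- function(x) chartr("ACGU", "UGCA", x)

reverse_string <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

rna_revcomp <- function(x) reverse_string(rna_complement(x))
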