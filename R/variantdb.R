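# Mutation-centered search-space construction: apply somatic amino-acid
# substitutions to a reference proteome, cut long peptide windows around each
# mutation, enumerate mutation-covering candidate k-mers, and write the
# concatenated (reference + long peptide) search database.

#' Read a protein FASTA file
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return Named character vector of sequences (names are the full FASTA
#'   headers up to the first whitespace).
#' @export
read_proteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- sub("\\s.*$", "", names(aa))
  seqs
}

#' Write a protein FASTA file
#'
#' Sequences are wrapped at 60 columns.
#'
#' @param seqs Named character vector of amino-acid sequences.
#' @param path Output path.
#' @export
write_proteome <- function(seqs, path) {
  aa <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(aa, filepath = path, width = 60L)
  invisible(path)
}

#' Read a somatic variant table
#'
#' Expects a TSV with columns `protein_id`, `position` (1-based residue
#' index), `ref_aa`, `alt_aa`, `coverage` (reads) and `tpm` (transcripts per
#' million).
#'
#' @param path Path to the TSV.
#' @return data.frame of variants.
#' @export
read_variants <- function(path) {
  v <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("protein_id", "position", "ref_aa", "alt_aa", "coverage", "tpm")
  missing <- setdiff(required, names(v))
  if (length(missing) > 0) {
    stop("variant table is missing column(s): ", paste(missing, collapse = ", "))
  }
  v
}

#' Write a somatic variant table
#'
#' @param variants data.frame as returned by [read_variants()].
#' @param path Output TSV path.
#' @export
write_variants <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Apply a single amino-acid substitution to a protein sequence
#'
#' The stated reference residue must match the sequence at `position`;
#' a mismatch is an error, never a silent skip, because silently dropped
#' variants corrupt downstream search-space accounting.
#'
#' @param sequence Amino-acid string.
#' @param position 1-based residue index of the substitution.
#' @param ref_aa Single-letter reference residue expected at `position`.
#' @param alt_aa Single-letter substituted residue.
#' @return The mutated sequence.
#' @examples
#' apply_variant("KYRQVASHV", 3, "R", "L")  # "KYLQVASHV"
#' @export
apply_variant <- function(sequence, position, ref_aa, alt_aa) {
  stopifnot(length(sequence) == 1, length(position) == 1)
  n <- nchar(sequence)
  if (position < 1 || position > n) {
    stop("variant position ", position, " out of range for a ", n,
         "-residue protein")
  }
  if (identical(ref_aa, alt_aa)) {
    stop("ref_aa and alt_aa are identical ('", ref_aa, "'); not a substitution")
  }
  observed <- substr(sequence, position, position)
  if (observed != ref_aa) {
    stop("reference mismatch at position ", position, ": expected '", ref_aa,
         "' but sequence has '", observed, "'")
  }
  substr(sequence, position, position) <- alt_aa
  sequence
}

#' Build the mutation-centered long-peptide window for one variant
#'
#' Cuts a window of up to `2 * flank + 1` residues (31 aa at the default
#' `flank = 15`) around the mutated position of the mutated protein,
#' truncated only at the protein termini.
#'
#' @param proteome Named character vector of reference sequences.
#' @param variant One-row data.frame (or list) with fields `protein_id`,
#'   `position`, `ref_aa`, `alt_aa` (and optionally `coverage`, `tpm`).
#' @param flank Residues requested on each side of the mutation.
#' @return An object of class `long_peptide`: a list with the mutant window
#'   `sequence`, the same-coordinates wild-type window `wt_sequence`, the
#'   1-based `mutation_offset` within the window, the window `start`/`end` in
#'   protein coordinates, and the source variant fields.
#' @export
build_long_peptide <- function(proteome, variant, flank = 15L) {
  pid <- as.character(variant$protein_id)
  if (!pid %in% names(proteome)) {
    stop("protein '", pid, "' not found in the reference proteome")
  }
  wt <- unname(proteome[[pid]])
  if (!is_canonical_sequence(wt)) {
    stop("protein '", pid, "' contains nonstandard residues; ",
         "excluded from window building")
  }
  pos <- as.integer(variant$position)
  mut <- apply_variant(wt, pos, as.character(variant$ref_aa),
                       as.character(variant$alt_aa))
  L <- nchar(mut)
  start <- max(1L, pos - as.integer(flank))
  end <- min(L, pos + as.integer(flank))
  structure(
    list(
      sequence = substr(mut, start, end),
      wt_sequence = substr(wt, start, end),
      protein_id = pid,
      position = pos,
      ref_aa = as.character(variant$ref_aa),
      alt_aa = as.character(variant$alt_aa),
      mutation_offset = pos - start + 1L,
      start = start,
      end = end,
      flank = as.integer(flank),
      coverage = if (!is.null(variant$coverage)) variant$coverage else NA,
      tpm = if (!is.null(variant$tpm)) variant$tpm else NA
    ),
    class = "long_peptide"
  )
}

#' @export
print.long_peptide <- function(x, ...) {
  cat(sprintf("<long_peptide> %s p.%s%d%s\n  %s (mutation at offset %d)\n",
              x$protein_id, x$ref_aa, x$position, x$alt_aa,
              x$sequence, x$mutation_offset))
  invisible(x)
}

#' Build long peptides for a variant table
#'
#' Variants on proteins containing nonstandard residues (U, X, B, Z, ...) are
#' skipped with a warning naming the protein; reference mismatches remain
#' hard errors.
#'
#' @inheritParams build_long_peptide
#' @param variants data.frame of variants (see [read_variants()]).
#' @return List of `long_peptide` objects.
#' @export
build_long_peptides <- function(proteome, variants, flank = 15L) {
  out <- vector("list", nrow(variants))
  keep <- logical(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, , drop = FALSE]
    pid <- as.character(v$protein_id)
    if (pid %in% names(proteome) && !is_canonical_sequence(proteome[[pid]])) {
      warning("protein '", pid, "' contains nonstandard residues; ",
              "variant at position ", v$position, " skipped")
      next
    }
    out[[i]] <- build_long_peptide(proteome, v, flank = flank)
    keep[i] <- TRUE
  }
  out[keep]
}

#' Enumerate mutation-covering candidate epitopes from a long peptide
#'
#' Returns exactly the k-mers of each requested length whose span includes
#' the mutated residue, paired with the same-coordinates wild-type k-mer
#' (which differs at exactly one position).
#'
#' @param long_peptide A `long_peptide` object.
#' @param lengths Integer vector of candidate lengths (default 8:11).
#' @return data.frame with columns `sequence`, `wt_counterpart`, `length`,
#'   `start` (within the window), `mutation_pos` (1-based position of the
#'   mutated residue within the candidate), `covers_mutation`, `protein_id`,
#'   `protein_position`, `ref_aa`, `alt_aa`. Zero rows when the window is
#'   shorter than every requested length.
#' @export
enumerate_candidates <- function(long_peptide, lengths = 8:11) {
  lp <- long_peptide
  n <- nchar(lp$sequence)
  off <- lp$mutation_offset
  rows <- list()
  for (k in sort(unique(as.integer(lengths)))) {
    if (k > n) next
    starts <- seq.int(max(1L, off - k + 1L), min(n - k + 1L, off))
    for (s in starts) {
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = substr(lp$sequence, s, s + k - 1L),
        wt_counterpart = substr(lp$wt_sequence, s, s + k - 1L),
        length = k,
        start = s,
        mutation_pos = off - s + 1L,
        covers_mutation = TRUE,
        protein_id = lp$protein_id,
        protein_position = lp$position,
        ref_aa = lp$ref_aa,
        alt_aa = lp$alt_aa,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(sequence = character(), wt_counterpart = character(),
                      length = integer(), start = integer(),
                      mutation_pos = integer(), covers_mutation = logical(),
                      protein_id = character(), protein_position = integer(),
                      ref_aa = character(), alt_aa = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

neo_header <- function(lp) {
  sprintf("neo|%s|p.%s%d%s", lp$protein_id, lp$ref_aa, lp$position, lp$alt_aa)
}

#' Write the concatenated search database
#'
#' Reference proteins first, then one entry per long peptide with a header
#' encoding its provenance (`>neo|<protein_id>|p.<ref><pos><alt>`). Duplicate
#' long-peptide sequences arising from distinct variants are kept as separate
#' records, so provenance is never lost.
#'
#' @param proteome Named character vector of reference sequences.
#' @param long_peptides List of `long_peptide` objects.
#' @param path Output FASTA path.
#' @export
write_search_database <- function(proteome, long_peptides, path) {
  neo <- vapply(long_peptides, function(lp) lp$sequence, character(1))
  names(neo) <- vapply(long_peptides, neo_header, character(1))
  write_proteome(c(proteome, neo), path)
}

#' Read a concatenated search database back
#'
#' Splits the FASTA into reference entries and `neo|` long-peptide entries,
#' parses the variant out of each neo header, and reconstructs each
#' `long_peptide` (including its mutation offset) against the reference
#' entries in the same file.
#'
#' @param path FASTA path written by [write_search_database()].
#' @return List with elements `proteome` (named character vector) and
#'   `long_peptides` (list of `long_peptide` objects).
#' @export
read_search_database <- function(path) {
  seqs <- read_proteome(path)
  is_neo <- startsWith(names(seqs), "neo|")
  proteome <- seqs[!is_neo]
  # The flank used at write time is not encoded in the header; locate each
  # window against its reference protein so that offsets are reconstructed.
  lps <- lapply(which(is_neo), function(i) {
    hdr <- names(seqs)[i]
    parts <- strsplit(hdr, "|", fixed = TRUE)[[1]]
    if (length(parts) != 3 || !grepl("^p\\.[A-Z][0-9]+[A-Z]$", parts[3])) {
      stop("cannot parse long-peptide header: ", hdr)
    }
    pid <- parts[2]
    if (!pid %in% names(proteome)) {
      stop("long peptide '", hdr, "' references protein '", pid,
           "' absent from the database")
    }
    ref <- substr(parts[3], 3, 3)
    alt <- substr(parts[3], nchar(parts[3]), nchar(parts[3]))
    pos <- as.integer(substr(parts[3], 4, nchar(parts[3]) - 1L))
    window <- unname(seqs[[i]])
    wt <- unname(proteome[[pid]])
    mut <- apply_variant(wt, pos, ref, alt)
    # locate the window: the offset candidates are positions where the window
    # shows the alt residue and the window matches the mutated protein
    hit <- NULL
    for (off in which(strsplit(window, "")[[1]] == alt)) {
      start <- pos - off + 1L
      end <- start + nchar(window) - 1L
      if (start >= 1 && end <= nchar(mut) &&
          substr(mut, start, end) == window) {
        hit <- c(start = start, offset = off)
        break
      }
    }
    if (is.null(hit)) {
      stop("long peptide '", hdr, "' does not match its reference protein")
    }
    structure(
      list(sequence = window,
           wt_sequence = substr(wt, hit[["start"]],
                                hit[["start"]] + nchar(window) - 1L),
           protein_id = pid, position = pos, ref_aa = ref, alt_aa = alt,
           mutation_offset = unname(hit[["offset"]]),
           start = unname(hit[["start"]]),
           end = unname(hit[["start"]]) + nchar(window) - 1L,
           flank = NA_integer_, coverage = NA, tpm = NA),
      class = "long_peptide"
    )
  })
  list(proteome = proteome, long_peptides = lps)
}
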