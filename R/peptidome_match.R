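# Filtering and cross-referencing of identified-peptide lists: target-decoy
# FDR thresholding, 8-25 aa length window, asymmetric quartile intensity
# normalization, and flagging of mutation-covering peptides absent from the
# reference proteome.

#' Read a peptide-spectrum-match table
#'
#' Expects a TSV with columns `sequence`, `score` (higher = better),
#' `is_decoy` (logical or 0/1), and optionally `intensity` and `sample`.
#'
#' @param path Path to the TSV.
#' @return data.frame of PSMs with `is_decoy` coerced to logical.
#' @export
read_psms <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("sequence", "score", "is_decoy")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop("PSM table is missing column(s): ", paste(missing, collapse = ", "))
  }
  x$is_decoy <- as.logical(x$is_decoy)
  x
}

#' Filter PSMs at a target-decoy FDR
#'
#' Scans the union of observed scores for the smallest threshold `t*` at
#' which `#{decoys >= t} / #{targets >= t} <= fdr`, then retains the target
#' PSMs with `score >= t*` (ties retained together). Decoys are never
#' returned. When no threshold satisfies the bound, the result has zero
#' rows.
#'
#' @param psms data.frame with columns `score` and `is_decoy` (logical).
#' @param fdr Peptide-level FDR, default 0.05.
#' @return The retained target rows of `psms`.
#' @export
filter_by_fdr <- function(psms, fdr = 0.05) {
  stopifnot(is.logical(psms$is_decoy))
  if (nrow(psms) == 0) return(psms)
  if (all(psms$is_decoy)) stop("every PSM is a decoy; nothing to retain")
  thresholds <- sort(unique(psms$score))
  t_star <- NA_real_
  for (t in thresholds) {
    nt <- sum(!psms$is_decoy & psms$score >= t)
    nd <- sum(psms$is_decoy & psms$score >= t)
    if (nt > 0 && nd / nt <= fdr) {
      t_star <- t
      break
    }
  }
  if (is.na(t_star)) {
    return(psms[FALSE, , drop = FALSE])
  }
  psms[!psms$is_decoy & psms$score >= t_star, , drop = FALSE]
}

#' Filter PSMs by peptide length
#'
#' Inclusive bounds: the default window keeps peptides of 8 to 25 residues.
#'
#' @param psms data.frame with a `sequence` column.
#' @param min_length,max_length Inclusive bounds.
#' @return The retained rows.
#' @export
filter_by_length <- function(psms, min_length = 8L, max_length = 25L) {
  n <- nchar(psms$sequence)
  psms[n >= min_length & n <= max_length, , drop = FALSE]
}

#' Asymmetric quartile normalization of peptide intensities
#'
#' Values are log2-transformed, the median (q2) subtracted, then positive
#' residuals divided by `q3 - q2` and negative residuals by `q2 - q1`
#' (quartiles by linear interpolation on the sorted values). The map sends
#' the median to 0, q1 to -1 and q3 to +1 for every valid input; values
#' exactly at the median map to 0. Missing values pass through as missing.
#'
#' @param values Positive intensities (or already-logged values with
#'   `log2_transform = FALSE`); at least 4 non-missing values.
#' @param log2_transform Apply `log2()` first (default TRUE).
#' @return Normalized numeric vector, same length and NA pattern as input.
#' @export
normalize_intensities <- function(values, log2_transform = TRUE) {
  v <- values
  if (log2_transform) {
    if (any(v <= 0, na.rm = TRUE)) {
      stop("intensities must be positive for log2 transformation")
    }
    v <- log2(v)
  }
  if (sum(!is.na(v)) < 4) stop("need at least 4 non-missing values")
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE,
                       type = 7)
  if (q[3] <= q[2] || q[2] <= q[1]) {
    stop("degenerate spread: quartiles must satisfy q1 < q2 < q3")
  }
  centered <- v - q[2]
  out <- centered
  pos <- !is.na(centered) & centered > 0
  neg <- !is.na(centered) & centered < 0
  out[pos] <- centered[pos] / (q[3] - q[2])
  out[neg] <- centered[neg] / (q[2] - q[1])
  out
}

#' Flag neoepitopes among retained PSMs
#'
#' A peptide is flagged as a neoepitope iff (i) it is a substring of some
#' long peptide with its span covering the mutated residue, and (ii) it
#' occurs nowhere in the reference proteome as an exact substring. Mutation-
#' covering peptides that coincidentally match the reference elsewhere are
#' not tumor-specific and are reported with `in_reference = TRUE`,
#' `neoepitope = FALSE`.
#'
#' @param psms data.frame of retained target PSMs (column `sequence`).
#' @param long_peptides List of `long_peptide` objects (the mutant search
#'   space).
#' @param proteome Named character vector of reference sequences.
#' @param motifs Optional motif list; when given, flagged neoepitopes get an
#'   allele assignment via [assign_allele()].
#' @return data.frame with one row per unique input sequence: `sequence`,
#'   `source` (header of the first matching long peptide or NA),
#'   `covers_mutation`, `in_reference`, `neoepitope`, and `allele` when
#'   motifs were supplied.
#' @export
flag_neoepitopes <- function(psms, long_peptides, proteome, motifs = NULL) {
  seqs <- unique(psms$sequence)
  ref_concat <- paste(unname(proteome), collapse = "!")
  lp_seq <- vapply(long_peptides, function(lp) lp$sequence, character(1))
  lp_off <- vapply(long_peptides, function(lp) lp$mutation_offset, integer(1))
  lp_hdr <- vapply(long_peptides, neo_header, character(1))
  rows <- lapply(seqs, function(s) {
    covers <- FALSE
    src <- NA_character_
    k <- nchar(s)
    for (j in seq_along(lp_seq)) {
      starts <- gregexpr(s, lp_seq[j], fixed = TRUE)[[1]]
      if (starts[1] == -1L) next
      if (any(starts <= lp_off[j] & lp_off[j] <= starts + k - 1L)) {
        covers <- TRUE
        src <- lp_hdr[j]
        break
      }
    }
    in_ref <- grepl(s, ref_concat, fixed = TRUE)
    data.frame(sequence = s, source = src, covers_mutation = covers,
               in_reference = in_ref,
               neoepitope = covers && !in_ref,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(motifs)) {
    out$allele <- NA_character_
    hit <- which(out$neoepitope)
    for (i in hit) {
      n <- nchar(out$sequence[i])
      accepts <- any(vapply(motifs, function(m) {
        n >= m$length_range[1] && n <= m$length_range[2]
      }, logical(1)))
      if (accepts) out$allele[i] <- assign_allele(out$sequence[i], motifs)
    }
  }
  out
}

#' Peptide length distribution
#'
#' Exact histogram of peptide lengths, a standard immunopeptidomics QC
#' readout (MHC I ligands cluster at 8-11 residues).
#'
#' @param psms data.frame with a `sequence` column.
#' @return data.frame with columns `length` and `count`; zero rows for empty
#'   input. Counts sum to the number of input rows.
#' @export
length_distribution <- function(psms) {
  if (nrow(psms) == 0) {
    return(data.frame(length = integer(), count = integer()))
  }
  tab <- table(nchar(psms$sequence))
  data.frame(length = as.integer(names(tab)), count = as.integer(tab))
}
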