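# Position-weight-matrix scoring of candidate peptides against H-2 Kd/Dd/Ld
# binding specificities, allele assignment, externally supplied IC50s, and
# the Differential Agretopic Index (DAI).

#' Read an allele-motif configuration
#'
#' The configuration is YAML with one entry per allele:
#' ```
#' Kd:
#'   lengths: [8, 11]
#'   floor: 0
#'   anchors: [P2, POmega]
#'   weights:
#'     P2: {Y: 3.0, F: 2.5}
#'     POmega: {L: 2.0, I: 2.0, V: 2.0}
#' ```
#' Positions are named `P1`, `P2`, ... counted from the N terminus; `POmega`
#' is the C-terminal residue whatever the peptide length. Unlisted
#' residue/position weights are zero (log-odds relative to background).
#'
#' @param path Path to the YAML file; defaults to the motif table shipped
#'   with the package (H-2 Kd, Dd, Ld).
#' @return Named list of `allele_motif` objects.
#' @export
read_motifs <- function(path = system.file("extdata", "motifs.yaml",
                                           package = "neoms")) {
  cfg <- yaml::read_yaml(path)
  motifs <- lapply(names(cfg), function(allele) {
    m <- cfg[[allele]]
    positions <- names(m$weights)
    w <- matrix(0, nrow = length(AA_LETTERS), ncol = length(positions),
                dimnames = list(AA_LETTERS, positions))
    for (p in positions) {
      for (aa in names(m$weights[[p]])) {
        if (!aa %in% AA_LETTERS) {
          stop("motif '", allele, "' position ", p,
               "' weights a non-canonical residue '", aa, "'")
        }
        w[aa, p] <- as.numeric(m$weights[[p]][[aa]])
      }
    }
    structure(
      list(allele = allele,
           length_range = as.integer(m$lengths),
           weights = w,
           anchor_positions = as.character(m$anchors %||% character()),
           floor = as.numeric(m$floor %||% 0)),
      class = "allele_motif"
    )
  })
  names(motifs) <- names(cfg)
  motifs
}

#' Default H-2 Kd / Dd / Ld motifs
#'
#' Kd: P2 Tyr/Phe primary anchor, C terminus Leu/Ile/Val. Dd: P2 Gly,
#' P3 Pro, a permissive P5 secondary anchor (Phe/Arg/Ile/Gly), C terminus
#' Leu/Ile/Phe. Ld: P2 Pro, C terminus Phe/Leu/Met. Encoded as log-odds
#' tables in `inst/extdata/motifs.yaml`, editable without code change.
#'
#' @return Named list of `allele_motif` objects.
#' @export
default_motifs <- function() read_motifs()

#' Score a peptide against one allele motif
#'
#' The score is the sum of per-position log-odds weights; positions beyond
#' the motif's named columns contribute zero, and the C-terminal residue is
#' scored with the `POmega` column. Higher means a better motif fit.
#'
#' @param peptide Amino-acid string with length inside the motif's range.
#' @param motif An `allele_motif` object.
#' @return Numeric motif score.
#' @export
score_peptide <- function(peptide, motif) {
  n <- nchar(peptide)
  if (n < motif$length_range[1] || n > motif$length_range[2]) {
    stop("peptide length ", n, " outside motif '", motif$allele,
         "' length range [", motif$length_range[1], ", ",
         motif$length_range[2], "]")
  }
  res <- strsplit(peptide, "")[[1]]
  if (!all(res %in% AA_LETTERS)) {
    stop("peptide contains non-canonical residues: ", peptide)
  }
  cols <- c(paste0("P", seq_len(n - 1L)), "POmega")
  score <- 0
  for (i in seq_len(n)) {
    if (cols[i] %in% colnames(motif$weights)) {
      score <- score + motif$weights[res[i], cols[i]]
    }
  }
  score
}

#' Assign a presenting allele to a peptide
#'
#' The best-scoring allele is returned when its score exceeds that motif's
#' acceptance floor and beats the runner-up by at least `margin` log-odds
#' units; exact score ties and sub-margin calls return `NA` (unassignable).
#' The result does not depend on the order of the motif list.
#'
#' @param peptide Amino-acid string.
#' @param motifs List of `allele_motif` objects (default: shipped Kd/Dd/Ld).
#' @param margin Required lead over the runner-up (log-odds units).
#' @return Allele name, or `NA_character_` when no confident assignment.
#' @export
assign_allele <- function(peptide, motifs = default_motifs(), margin = 1.0) {
  ok <- Filter(function(m) {
    nchar(peptide) >= m$length_range[1] && nchar(peptide) <= m$length_range[2]
  }, motifs)
  if (length(ok) == 0) {
    stop("no motif accepts a peptide of length ", nchar(peptide))
  }
  scores <- vapply(ok, function(m) score_peptide(peptide, m), numeric(1))
  ord <- order(scores, decreasing = TRUE)
  best <- scores[ord[1]]
  floor_best <- ok[[ord[1]]]$floor
  if (best <= floor_best) return(NA_character_)
  if (length(scores) > 1) {
    second <- scores[ord[2]]
    if (best == second || best - second < margin) return(NA_character_)
  }
  ok[[ord[1]]]$allele
}

#' Differential Agretopic Index
#'
#' `DAI = ln(IC50_wt) - ln(IC50_mut)`: positive when the mutation improves
#' MHC binding (lower mutant IC50), negative when it weakens it, and
#' antisymmetric under exchange of the two affinities.
#'
#' @param ic50_wt Wild-type predicted IC50 in nM (> 0).
#' @param ic50_mut Mutant predicted IC50 in nM (> 0).
#' @return Numeric DAI.
#' @export
compute_dai <- function(ic50_wt, ic50_mut) {
  if (any(ic50_wt <= 0) || any(ic50_mut <= 0)) {
    stop("IC50 values must be positive (nM)")
  }
  log(ic50_wt) - log(ic50_mut)
}

#' Classify a predicted IC50 into an affinity tier
#'
#' Tiers use half-open intervals `[lo, hi)`: `strong` below 50 nM,
#' `intermediate` in [50, 500), `weak` in [500, 5000), `very_weak` at or
#' above 5000 nM under the default cutpoints.
#'
#' @param ic50_nm Positive IC50 in nM (vectorized).
#' @param cutpoints Named increasing numeric vector of upper bounds for
#'   `strong`, `intermediate` and `weak`.
#' @return Character vector of tier labels.
#' @export
classify_affinity_tier <- function(ic50_nm,
                                   cutpoints = c(strong = 50,
                                                 intermediate = 500,
                                                 weak = 5000)) {
  if (any(ic50_nm <= 0)) stop("IC50 values must be positive (nM)")
  stopifnot(all(diff(cutpoints) > 0))
  labels <- c(names(cutpoints), "very_weak")
  labels[findInterval(ic50_nm, cutpoints, left.open = FALSE) + 1L]
}

#' Read externally supplied IC50 predictions
#'
#' Affinity predictions from a NetMHC-class tool enter the pipeline through
#' this TSV interface (columns `peptide`, `allele`, `ic50_nm`); the package
#' never shells out to a predictor.
#'
#' @param path Path to the TSV.
#' @return data.frame with columns `peptide`, `allele`, `ic50_nm`.
#' @export
read_ic50 <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("peptide", "allele", "ic50_nm")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop("IC50 table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(x$ic50_nm <= 0)) stop("IC50 values must be positive (nM)")
  x
}

#' Score a candidate table: motif scores, allele call, DAI
#'
#' Convenience wrapper over [score_peptide()], [assign_allele()] and
#' [compute_dai()] for the candidate table produced by
#' [enumerate_candidates()]. When an IC50 table is supplied, mutant and
#' wild-type IC50s are joined on (peptide, allele) and DAI computed where
#' both are present.
#'
#' @param candidates data.frame with columns `sequence` and `wt_counterpart`.
#' @param motifs List of `allele_motif` objects.
#' @param ic50 Optional data.frame from [read_ic50()].
#' @param margin Passed to [assign_allele()].
#' @return The candidate table with added columns `allele`, `motif_score`,
#'   `wt_motif_score`, and (when IC50s are given) `ic50_mut`, `ic50_wt`,
#'   `dai`, `affinity_tier`.
#' @export
score_candidates <- function(candidates, motifs = default_motifs(),
                             ic50 = NULL, margin = 1.0) {
  n <- nrow(candidates)
  allele <- character(n)
  ms <- numeric(n)
  wms <- numeric(n)
  for (i in seq_len(n)) {
    allele[i] <- assign_allele(candidates$sequence[i], motifs, margin = margin)
    if (!is.na(allele[i])) {
      m <- motifs[[allele[i]]]
      ms[i] <- score_peptide(candidates$sequence[i], m)
      wms[i] <- score_peptide(candidates$wt_counterpart[i], m)
    } else {
      ms[i] <- NA_real_
      wms[i] <- NA_real_
    }
  }
  out <- candidates
  out$allele <- allele
  out$motif_score <- ms
  out$wt_motif_score <- wms
  if (!is.null(ic50)) {
    key <- paste(ic50$peptide, ic50$allele)
    mut_ic50 <- ic50$ic50_nm[match(paste(out$sequence, out$allele), key)]
    wt_ic50 <- ic50$ic50_nm[match(paste(out$wt_counterpart, out$allele), key)]
    out$ic50_mut <- mut_ic50
    out$ic50_wt <- wt_ic50
    dai <- rep(NA_real_, n)
    both <- !is.na(mut_ic50) & !is.na(wt_ic50)
    if (any(both)) dai[both] <- compute_dai(wt_ic50[both], mut_ic50[both])
    out$dai <- dai
    tier <- rep(NA_character_, n)
    has_mut <- !is.na(mut_ic50)
    if (any(has_mut)) tier[has_mut] <- classify_affinity_tier(mut_ic50[has_mut])
    out$affinity_tier <- tier
  }
  out
}
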