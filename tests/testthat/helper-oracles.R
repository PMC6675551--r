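# Independent oracles used across the suite. These deliberately take
# different computational routes from the package code they check.

# --- fragment masses from elemental composition -------------------------
# Residue formulas (C, H, N, O, S counts) and exact isotope masses; the
# package's residue-mass table never enters this path.
.residue_formula <- rbind(
  A = c(3, 5, 1, 1, 0),  R = c(6, 12, 4, 1, 0), N = c(4, 6, 2, 2, 0),
  D = c(4, 5, 1, 3, 0),  C = c(3, 5, 1, 1, 1),  E = c(5, 7, 1, 3, 0),
  Q = c(5, 8, 2, 2, 0),  G = c(2, 3, 1, 1, 0),  H = c(6, 7, 3, 1, 0),
  I = c(6, 11, 1, 1, 0), L = c(6, 11, 1, 1, 0), K = c(6, 12, 2, 1, 0),
  M = c(5, 9, 1, 1, 1),  F = c(9, 9, 1, 1, 0),  P = c(5, 7, 1, 1, 0),
  S = c(3, 5, 1, 2, 0),  T = c(4, 7, 1, 2, 0),  W = c(11, 10, 2, 1, 0),
  Y = c(9, 9, 1, 2, 0),  V = c(5, 9, 1, 1, 0)
)
.isotope_mass <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
                   O = 15.9949146221, S = 31.97207069)
.proton <- 1.00727646688

oracle_residue_mass <- function(aa) {
  sum(.residue_formula[aa, ] * .isotope_mass)
}

oracle_fragment_mz <- function(peptide, series, index, charge = 1) {
  res <- strsplit(peptide, "")[[1]]
  n <- length(res)
  span <- if (series == "b") res[seq_len(index)] else res[seq.int(n - index + 1, n)]
  mass <- sum(vapply(span, oracle_residue_mass, numeric(1)))
  if (series == "y") mass <- mass + 2 * .isotope_mass["H"] + .isotope_mass["O"]
  unname((mass + charge * .proton) / charge)
}

oracle_precursor_mz <- function(peptide, charge = 1) {
  res <- strsplit(peptide, "")[[1]]
  mass <- sum(vapply(res, oracle_residue_mass, numeric(1))) +
    2 * .isotope_mass["H"] + .isotope_mass["O"]
  unname((mass + charge * .proton) / charge)
}

# --- target-decoy FDR by descending-order cumulative counts -------------
# Sorts once and walks the cumulative decoy/target counts instead of
# re-counting per candidate threshold.
oracle_fdr_retained <- function(psms, fdr) {
  ord <- order(psms$score, decreasing = TRUE)
  dec <- psms$is_decoy[ord]
  sco <- psms$score[ord]
  cum_t <- cumsum(!dec)
  cum_d <- cumsum(dec)
  # candidate thresholds are the distinct scores; at position i the
  # threshold sco[i] retains everything with score >= sco[i]; take the last
  # index of each tied run so cumulative counts are complete
  last_of_run <- which(c(sco[-1] != sco[-length(sco)], TRUE))
  ok <- last_of_run[cum_t[last_of_run] > 0 &
                      cum_d[last_of_run] / cum_t[last_of_run] <= fdr]
  if (length(ok) == 0) return(psms[FALSE, , drop = FALSE])
  t_star <- sco[max(ok)]  # smallest qualifying threshold
  psms[!psms$is_decoy & psms$score >= t_star, , drop = FALSE]
}

# --- brute-force mutation-covering k-mers -------------------------------
oracle_covering_kmers <- function(window, offset, k) {
  n <- nchar(window)
  if (k > n) return(character(0))
  starts <- seq_len(n - k + 1)
  covers <- starts <= offset & offset <= starts + k - 1
  vapply(starts[covers], function(s) substr(window, s, s + k - 1),
         character(1))
}

random_peptide <- function(n) {
  paste(sample(AA_LETTERS, n, replace = TRUE), collapse = "")
}

random_psm_set <- function(n_targets, n_decoys) {
  data.frame(
    sequence = replicate(n_targets + n_decoys, random_peptide(9)),
    score = c(stats::rnorm(n_targets, 12, 4), stats::rnorm(n_decoys, 8, 4)),
    is_decoy = rep(c(FALSE, TRUE), c(n_targets, n_decoys)),
    stringsAsFactors = FALSE
  )
}
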