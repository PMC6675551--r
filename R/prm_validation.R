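# Heavy/light parallel-reaction-monitoring validation: stable-isotope label
# mass accounting, b/y fragment m/z computation, extracted-ion-chromatogram
# (XIC) construction at a fixed m/z tolerance, co-elution scoring, and
# light-contamination QC of the synthetic heavy standards.

#' Monoisotopic residue masses (Da)
#'
#' Standard monoisotopic masses of the 20 canonical amino-acid residues
#' (i.e. the mass contributed inside a peptide chain, water excluded).
#'
#' @format Named numeric vector.
#' @export
AA_MONO_MASS <- c(
  A =  71.037114, R = 156.101111, N = 114.042927, D = 115.026943,
  C = 103.009185, E = 129.042593, Q = 128.058578, G =  57.021464,
  H = 137.058912, I = 113.084064, L = 113.084064, K = 128.094963,
  M = 131.040485, F = 147.068414, P =  97.052764, S =  87.032028,
  T = 101.047678, W = 186.079313, Y = 163.063329, V =  99.068414
)

PROTON_MASS <- 1.007276
WATER_MASS <- 18.010565

#' Shipped stable-isotope label table
#'
#' Monoisotopic mass deltas of the common uniformly 13C/15N-labeled residues
#' used for heavy PRM standards (13C6 15N2 Lys, 13C6 15N4 Arg, 13C6 15N1
#' Leu, 13C5 15N1 Pro, 13C5 15N1 Val, 13C9 15N1 Phe). Arbitrary labels are
#' accepted anywhere a label is taken: supply `isotope_label(residue, delta)`.
#'
#' @return data.frame with columns `residue` and `mass_delta` (Da).
#' @export
default_labels <- function() {
  data.frame(
    residue = c("K", "R", "L", "P", "V", "F"),
    mass_delta = c(8.014199, 10.008269, 7.017164, 6.013809, 6.013809,
                   10.027228),
    stringsAsFactors = FALSE
  )
}

#' Construct an isotope label
#'
#' @param residue Single-letter residue code carrying the label.
#' @param mass_delta Positive monoisotopic mass shift in Da; when omitted,
#'   looked up in [default_labels()].
#' @return List with elements `residue` and `mass_delta`.
#' @export
isotope_label <- function(residue, mass_delta = NULL) {
  stopifnot(residue %in% AA_LETTERS)
  if (is.null(mass_delta)) {
    tab <- default_labels()
    if (!residue %in% tab$residue) {
      stop("no default label for residue '", residue,
           "'; supply mass_delta explicitly")
    }
    mass_delta <- tab$mass_delta[tab$residue == residue]
  }
  if (mass_delta <= 0) stop("label mass_delta must be positive")
  list(residue = residue, mass_delta = mass_delta)
}

#' Total heavy-label mass shift of a peptide
#'
#' One label per occurrence of the labeled residue: the precursor shift is
#' the occurrence count times the label delta. A peptide lacking the labeled
#' residue cannot carry the label and is an error.
#'
#' @param peptide Amino-acid string.
#' @param label A label from [isotope_label()].
#' @return Mass shift in Da.
#' @export
heavy_mass_shift <- function(peptide, label) {
  count <- lengths(regmatches(peptide,
                              gregexpr(label$residue, peptide, fixed = TRUE)))
  if (count == 0) {
    stop("peptide '", peptide, "' contains no '", label$residue,
         "' residue; no site for the label")
  }
  count * label$mass_delta
}

peptide_residues <- function(peptide) {
  res <- strsplit(peptide, "")[[1]]
  if (!all(res %in% AA_LETTERS)) {
    stop("peptide contains non-canonical residues: ", peptide)
  }
  res
}

#' Monoisotopic precursor m/z
#'
#' @param peptide Amino-acid string.
#' @param charge Positive integer charge.
#' @param label Optional label from [isotope_label()]; adds the heavy shift.
#' @return m/z value.
#' @export
precursor_mz <- function(peptide, charge = 2L, label = NULL) {
  if (charge < 1) stop("charge must be >= 1")
  mass <- sum(AA_MONO_MASS[peptide_residues(peptide)]) + WATER_MASS
  if (!is.null(label)) mass <- mass + heavy_mass_shift(peptide, label)
  (mass + charge * PROTON_MASS) / charge
}

#' m/z of a b- or y-series fragment ion
#'
#' The fragment mass is the monoisotopic residue-mass sum over the
#' fragment's span (plus water for y ions), plus `charge` protons, divided
#' by the charge. The heavy delta is added iff the fragment's span contains
#' the labeled residue (once per occurrence within the span), so light and
#' heavy m/z of a fragment not spanning the label are identical.
#'
#' @param peptide Amino-acid string.
#' @param series `"b"` or `"y"`.
#' @param index Fragment index, 1 to `nchar(peptide) - 1`.
#' @param charge Positive integer charge (default 1).
#' @param label Optional label from [isotope_label()].
#' @return m/z value.
#' @export
fragment_mz <- function(peptide, series = c("b", "y"), index, charge = 1L,
                        label = NULL) {
  series <- match.arg(series)
  res <- peptide_residues(peptide)
  n <- length(res)
  if (index < 1 || index >= n) {
    stop("fragment index must be in 1..", n - 1L, " for a ", n,
         "-residue peptide")
  }
  if (charge < 1) stop("charge must be >= 1")
  span <- if (series == "b") seq_len(index) else seq.int(n - index + 1L, n)
  mass <- sum(AA_MONO_MASS[res[span]])
  if (series == "y") mass <- mass + WATER_MASS
  if (!is.null(label)) {
    mass <- mass + sum(res[span] == label$residue) * label$mass_delta
  }
  (mass + charge * PROTON_MASS) / charge
}

#' Enumerate light and heavy fragment m/z values for a peptide
#'
#' @param peptide Amino-acid string.
#' @param label Label from [isotope_label()].
#' @param charges Fragment charges to generate (default 1:2).
#' @return data.frame with columns `fragment` (e.g. `"y3_z1"`), `series`,
#'   `index`, `charge`, `mz_light`, `mz_heavy`, `contains_label`.
#' @export
fragment_table <- function(peptide, label, charges = 1:2) {
  res <- peptide_residues(peptide)
  n <- length(res)
  grid <- expand.grid(series = c("b", "y"), index = seq_len(n - 1L),
                      charge = charges, stringsAsFactors = FALSE)
  grid$mz_light <- mapply(function(s, i, z) fragment_mz(peptide, s, i, z),
                          grid$series, grid$index, grid$charge)
  grid$mz_heavy <- mapply(function(s, i, z) {
    fragment_mz(peptide, s, i, z, label = label)
  }, grid$series, grid$index, grid$charge)
  grid$contains_label <- grid$mz_heavy > grid$mz_light
  grid$fragment <- sprintf("%s%d_z%d", grid$series, grid$index, grid$charge)
  grid[, c("fragment", "series", "index", "charge", "mz_light", "mz_heavy",
           "contains_label")]
}

#' Extract an ion chromatogram at a target m/z
#'
#' Sums, per time point, all signal intensity within
#' `[target_mz - tol, target_mz + tol]` (default tolerance 0.02 m/z). Time
#' points with no in-window signal report zero, so the trace covers every
#' time present in the source.
#'
#' @param signals data.frame with columns `time`, `mz`, `intensity`.
#' @param target_mz Target m/z.
#' @param tol Tolerance in m/z units (> 0), default 0.02.
#' @return data.frame with columns `time` (sorted) and `intensity`.
#' @export
extract_xic <- function(signals, target_mz, tol = 0.02) {
  if (tol <= 0) stop("tolerance must be positive")
  times <- sort(unique(signals$time))
  hit <- abs(signals$mz - target_mz) <= tol
  agg <- tapply(signals$intensity[hit], factor(signals$time[hit],
                                               levels = times), sum)
  data.frame(time = times,
             intensity = as.numeric(ifelse(is.na(agg), 0, agg)))
}

interp_trace <- function(trace, grid) {
  if (nrow(trace) == 1) {
    return(ifelse(grid == trace$time, trace$intensity, 0))
  }
  stats::approx(trace$time, trace$intensity, xout = grid,
                yleft = 0, yright = 0)$y
}

#' Score heavy/light co-elution of fragment chromatograms
#'
#' For every fragment present in both channels, the light and heavy traces
#' are linearly interpolated onto the union of their time points and the
#' Pearson correlation computed. The summed (across fragments) trace of each
#' channel defines the channel apex; the spectral contrast is the normalized
#' dot product of the per-fragment intensity vectors read at the two apexes.
#' The pair is `validated` iff at least `min_fragments` fragments reach
#' `r >= r_min`, the apex time difference is at most `max_apex_dt`, and the
#' spectral contrast is at least `min_contrast`. Fragments with an all-zero
#' trace in either channel have undefined correlation and are excluded with
#' a warning.
#'
#' @param light,heavy Long-format data.frames with columns `fragment`,
#'   `time`, `intensity`.
#' @param min_fragments Minimum number of fragments with `r >= r_min`
#'   (default 3).
#' @param r_min Per-fragment correlation threshold (default 0.9).
#' @param max_apex_dt Maximum apex time difference in minutes (default 0.2).
#' @param min_contrast Spectral-contrast threshold (default 0.9).
#' @return Object of class `coelution_report`: list with
#'   `fragment_correlations` (named numeric), `n_qualifying`, `apex_dt`,
#'   `spectral_contrast`, `verdict` (`"validated"` or `"not_validated"`).
#' @export
coelution_score <- function(light, heavy, min_fragments = 3L, r_min = 0.9,
                            max_apex_dt = 0.2, min_contrast = 0.9) {
  frags <- intersect(unique(light$fragment), unique(heavy$fragment))
  if (length(frags) == 0) {
    stop("no fragment is present in both the light and the heavy channel")
  }
  grid_all <- sort(unique(c(light$time, heavy$time)))
  li <- matrix(0, nrow = length(grid_all), ncol = length(frags),
               dimnames = list(NULL, frags))
  hi <- li
  cors <- stats::setNames(rep(NA_real_, length(frags)), frags)
  for (f in frags) {
    lt <- light[light$fragment == f, , drop = FALSE]
    ht <- heavy[heavy$fragment == f, , drop = FALSE]
    grid <- sort(unique(c(lt$time, ht$time)))
    lv <- interp_trace(lt, grid)
    hv <- interp_trace(ht, grid)
    li[, f] <- interp_trace(lt, grid_all)
    hi[, f] <- interp_trace(ht, grid_all)
    if (all(lv == 0) || all(hv == 0) ||
        stats::sd(lv) == 0 || stats::sd(hv) == 0) {
      warning("fragment '", f, "' has a degenerate trace; ",
              "correlation undefined, fragment excluded")
      next
    }
    cors[f] <- stats::cor(lv, hv)
  }
  light_total <- rowSums(li)
  heavy_total <- rowSums(hi)
  apex_dt <- if (all(light_total == 0) || all(heavy_total == 0)) {
    Inf
  } else {
    abs(grid_all[which.max(light_total)] - grid_all[which.max(heavy_total)])
  }
  vl <- li[if (all(light_total == 0)) 1L else which.max(light_total), ]
  vh <- hi[if (all(heavy_total == 0)) 1L else which.max(heavy_total), ]
  contrast <- if (sum(vl^2) == 0 || sum(vh^2) == 0) {
    0
  } else {
    sum(vl * vh) / sqrt(sum(vl^2) * sum(vh^2))
  }
  n_qual <- sum(!is.na(cors) & cors >= r_min)
  verdict <- if (n_qual >= min_fragments && apex_dt <= max_apex_dt &&
                 contrast >= min_contrast) "validated" else "not_validated"
  structure(
    list(fragment_correlations = cors, n_qualifying = n_qual,
         apex_dt = apex_dt, spectral_contrast = contrast, verdict = verdict,
         thresholds = list(min_fragments = min_fragments, r_min = r_min,
                           max_apex_dt = max_apex_dt,
                           min_contrast = min_contrast)),
    class = "coelution_report"
  )
}

#' @export
print.coelution_report <- function(x, ...) {
  cat(sprintf(
    "<coelution_report> %s\n  fragments r>=%.2f: %d   apex dt: %.3f min   contrast: %.3f\n",
    x$verdict, x$thresholds$r_min, x$n_qualifying, x$apex_dt,
    x$spectral_contrast))
  invisible(x)
}

#' Light-contamination QC on a heavy-only run
#'
#' Before spiking, each synthetic heavy standard is measured alone and the
#' light-channel m/z monitored for residual unlabeled peptide. The check
#' passes iff the maximum light-channel signal is at most
#' `threshold` times the heavy-channel apex.
#'
#' @param light_traces,heavy_traces data.frames with columns `time`,
#'   `intensity` (light extracted at the light m/z, heavy at the heavy m/z,
#'   both from the heavy-only sample).
#' @param threshold Allowed light/heavy apex ratio (default 0.01, i.e. 1%).
#' @return `"pass"` or `"fail"`.
#' @export
check_light_contamination <- function(light_traces, heavy_traces,
                                      threshold = 0.01) {
  light_max <- if (nrow(light_traces) == 0) 0 else max(light_traces$intensity)
  heavy_max <- if (nrow(heavy_traces) == 0) 0 else max(heavy_traces$intensity)
  if (heavy_max <= 0) stop("heavy-channel trace has no signal")
  if (light_max <= threshold * heavy_max) "pass" else "fail"
}
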