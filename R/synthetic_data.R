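# Synthetic input generation: every input class the pipeline consumes, with
# the statistical structure the downstream modules assume, so the whole
# pipeline is testable without external data. One configuration seed fans
# out to independent per-generator streams.

#' Simulation configuration
#'
#' Bundles all generator parameters with their defaults. The defaults
#' describe a desk-scale immunopeptidomics study: a toy proteome of 30
#' proteins (100-400 residues), 40 somatic substitutions, PSM lists with
#' well-separated target/decoy score distributions and log-normal
#' intensities, Gaussian co-eluting heavy/light fragment peaks, logistic
#' tumor growth to 15 mm over ~24 days with rejection/stabilization
#' phenotypes, and idealized extended peptide-MHC coordinate sets.
#'
#' @param seed Integer master seed; each generator derives its own stream.
#' @param proteome List: `n_proteins`, `length_range`.
#' @param variants List: `n_variants`, `coverage_lambda`, `tpm_meanlog`,
#'   `tpm_sdlog`.
#' @param psm List: `n_reference`, `n_decoys`, `n_planted_neo`,
#'   `target_score` (mean, sd), `decoy_score` (mean, sd), `intensity`
#'   (meanlog, sdlog of the natural-log-normal).
#' @param prm List: `time_range` (min), `dt`, `apex`, `apex_shift` (light
#'   minus heavy apex), `width` (Gaussian sd, min), `noise_sd` (relative),
#'   `n_fragments`, `light_scale`.
#' @param growth List: `days`, `d_max` (mm), `rate`, `midpoint` (day),
#'   `noise_sd` (mm), `groups`: named list of `list(n, rejection_fraction,
#'   stable_fraction)`.
#' @param structure List: `mhc_residues`, `displacement` (Angstrom applied
#'   to one peptide atom of the perturbed copy).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       proteome = list(),
                       variants = list(),
                       psm = list(),
                       prm = list(),
                       growth = list(),
                       structure = list()) {
  defaults <- list(
    seed = as.integer(seed),
    proteome = list(n_proteins = 30L, length_range = c(100L, 400L)),
    variants = list(n_variants = 40L, coverage_lambda = 60,
                    tpm_meanlog = 2, tpm_sdlog = 1.5),
    psm = list(n_reference = 300L, n_decoys = 300L, n_planted_neo = 8L,
               target_score = list(mean = 30, sd = 5),
               decoy_score = list(mean = 12, sd = 5),
               intensity = list(meanlog = 14, sdlog = 1.2)),
    prm = list(time_range = c(10, 14), dt = 0.02, apex = 12,
               apex_shift = 0, width = 0.08, noise_sd = 0.005,
               n_fragments = 5L, light_scale = 0.8),
    growth = list(days = seq(0L, 24L, by = 3L), d_max = 15, rate = 0.35,
                  midpoint = 14, noise_sd = 0.4,
                  groups = list(
                    PBS = list(n = 8L, rejection_fraction = 0,
                               stable_fraction = 0),
                    vaccine = list(n = 8L, rejection_fraction = 0.6,
                                   stable_fraction = 0.3))),
    structure = list(mhc_residues = 20L, displacement = 0)
  )
  cfg <- defaults
  for (sec in c("proteome", "variants", "psm", "prm", "growth", "structure")) {
    user <- get(sec)
    for (nm in names(user)) cfg[[sec]][[nm]] <- user[[nm]]
  }
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic reference proteome
#'
#' @param config A [sim_config()].
#' @return Named character vector of proteins (`SP0001`, ...), reproducible
#'   given the config seed.
#' @export
gen_proteome <- function(config = sim_config()) {
  local_seed(config$seed + 101L, {
    n <- config$proteome$n_proteins
    lens <- sample(seq(config$proteome$length_range[1],
                       config$proteome$length_range[2]), n, replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(AA_LETTERS, L, replace = TRUE), collapse = "")
    }, character(1))
    names(seqs) <- sprintf("SP%04d", seq_len(n))
    seqs
  })
}

#' Generate somatic variants over a proteome
#'
#' Every generated variant satisfies the reference-match invariant by
#' construction ([apply_variant()] never errors on them).
#'
#' @param proteome Named character vector from [gen_proteome()].
#' @param config A [sim_config()].
#' @return data.frame with the [read_variants()] columns.
#' @export
gen_variants <- function(proteome, config = sim_config()) {
  local_seed(config$seed + 202L, {
    n <- config$variants$n_variants
    if (n == 0) {
      return(data.frame(protein_id = character(), position = integer(),
                        ref_aa = character(), alt_aa = character(),
                        coverage = integer(), tpm = numeric(),
                        stringsAsFactors = FALSE))
    }
    pid <- sample(names(proteome), n, replace = TRUE)
    pos <- vapply(pid, function(p) sample.int(nchar(proteome[[p]]), 1L),
                  integer(1))
    ref <- substr(proteome[pid], pos, pos)
    alt <- vapply(ref, function(r) sample(setdiff(AA_LETTERS, r), 1L),
                  character(1))
    data.frame(protein_id = pid, position = pos, ref_aa = unname(ref),
               alt_aa = unname(alt),
               coverage = stats::rpois(n, config$variants$coverage_lambda),
               tpm = stats::rlnorm(n, config$variants$tpm_meanlog,
                                   config$variants$tpm_sdlog),
               row.names = NULL, stringsAsFactors = FALSE)
  })
}

#' Generate a PSM list with planted neoepitopes and decoys
#'
#' Target PSMs are substrings (8-11-mers) of reference proteins with scores
#' from the target distribution; decoys are reversed target sequences with
#' scores from the (lower) decoy distribution; planted neoepitope PSMs are
#' mutation-covering 9-mers drawn from the long-peptide database and
#' guaranteed absent from the reference. The ground-truth labels travel
#' with the table (`truth` column), so tests never re-derive them.
#'
#' @param long_peptides List of `long_peptide` objects.
#' @param proteome The reference proteome the long peptides derive from.
#' @param config A [sim_config()].
#' @return data.frame with columns `sequence`, `score`, `is_decoy`,
#'   `intensity`, `sample`, `truth` (`"reference"`, `"neoepitope"` or
#'   `"decoy"`).
#' @export
gen_psm_list <- function(long_peptides, proteome, config = sim_config()) {
  local_seed(config$seed + 303L, {
    p <- config$psm
    ref_concat <- paste(unname(proteome), collapse = "!")
    draw_ref_peptide <- function() {
      prot <- proteome[[sample.int(length(proteome), 1L)]]
      k <- sample(8:11, 1L)
      s <- sample.int(nchar(prot) - k + 1L, 1L)
      substr(prot, s, s + k - 1L)
    }
    ref_seqs <- replicate(p$n_reference, draw_ref_peptide())
    neo_seqs <- character(0)
    if (p$n_planted_neo > 0) {
      if (length(long_peptides) == 0) {
        stop("cannot plant neoepitopes without long peptides")
      }
      picks <- sample(seq_along(long_peptides),
                      min(p$n_planted_neo, length(long_peptides)))
      neo_seqs <- vapply(picks, function(i) {
        cand <- enumerate_candidates(long_peptides[[i]], lengths = 9L)
        cand <- cand[!vapply(cand$sequence, grepl, logical(1),
                             x = ref_concat, fixed = TRUE), , drop = FALSE]
        if (nrow(cand) == 0) NA_character_ else sample(cand$sequence, 1L)
      }, character(1))
      neo_seqs <- neo_seqs[!is.na(neo_seqs)]
    }
    targets <- c(ref_seqs, neo_seqs)
    decoys <- vapply(strsplit(sample(targets,
                                     min(p$n_decoys, length(targets))), ""),
                     function(r) paste(rev(r), collapse = ""), character(1))
    truth <- c(rep("reference", length(ref_seqs)),
               rep("neoepitope", length(neo_seqs)),
               rep("decoy", length(decoys)))
    scores <- c(stats::rnorm(length(targets), p$target_score$mean,
                             p$target_score$sd),
                stats::rnorm(length(decoys), p$decoy_score$mean,
                             p$decoy_score$sd))
    out <- data.frame(
      sequence = c(targets, decoys),
      score = scores,
      is_decoy = c(rep(FALSE, length(targets)), rep(TRUE, length(decoys))),
      intensity = stats::rlnorm(length(targets) + length(decoys),
                                p$intensity$meanlog, p$intensity$sdlog),
      sample = "tumor",
      truth = truth,
      stringsAsFactors = FALSE
    )
    out[sample.int(nrow(out)), , drop = FALSE]
  })
}

gaussian_peak <- function(times, apex, width, height) {
  height * exp(-0.5 * ((times - apex) / width)^2)
}

#' Generate heavy/light PRM fragment chromatograms
#'
#' Gaussian co-eluting peaks per fragment with shared per-fragment relative
#' heights, multiplicative channel scale, additive truncated noise, and an
#' optional light-apex shift to emulate non-co-eluting interference.
#'
#' @param peptide Amino-acid string (used to name fragments `y1..yk`).
#' @param config A [sim_config()].
#' @return List with long-format data.frames `light` and `heavy`
#'   (columns `fragment`, `time`, `intensity`).
#' @export
gen_prm_traces <- function(peptide, config = sim_config()) {
  local_seed(config$seed + 404L, {
    p <- config$prm
    k <- min(p$n_fragments, nchar(peptide) - 1L)
    times <- seq(p$time_range[1], p$time_range[2], by = p$dt)
    frags <- sprintf("y%d_z1", seq_len(k))
    heights <- stats::runif(k, 0.3, 1)
    mk <- function(apex, scale) {
      do.call(rbind, lapply(seq_len(k), function(i) {
        base <- gaussian_peak(times, apex, p$width, heights[i] * scale)
        noise <- stats::rnorm(length(times), 0, p$noise_sd * scale)
        data.frame(fragment = frags[i], time = times,
                   intensity = pmax(base + noise, 0),
                   stringsAsFactors = FALSE)
      }))
    }
    heavy <- mk(p$apex, 1)
    light <- mk(p$apex + p$apex_shift, p$light_scale)
    list(light = light, heavy = heavy)
  })
}

logistic_diameter <- function(days, d_max, rate, midpoint) {
  d_max / (1 + exp(-rate * (days - midpoint)))
}

#' Generate per-mouse tumor growth curves
#'
#' Progressors follow a logistic growth curve; rejectors grow to a small
#' early tumor then shrink to undetectable and stay there; stabilizers
#' plateau at the early-tumor size. Phenotype fractions are per group.
#'
#' @param config A [sim_config()].
#' @return data.frame with columns `mouse_id`, `group`, `day`,
#'   `diameter_mm`.
#' @export
gen_growth_curves <- function(config = sim_config()) {
  local_seed(config$seed + 505L, {
    g <- config$growth
    days <- g$days
    rows <- list()
    mouse <- 0L
    for (grp in names(g$groups)) {
      spec <- g$groups[[grp]]
      n <- spec$n
      n_rej <- round(spec$rejection_fraction * n)
      n_stab <- round((spec$stable_fraction %||% 0) * n)
      phen <- sample(c(rep("rejector", n_rej), rep("stabilizer", n_stab),
                       rep("progressor", n - n_rej - n_stab)))
      for (i in seq_len(n)) {
        mouse <- mouse + 1L
        base <- switch(
          phen[i],
          progressor = logistic_diameter(days, g$d_max, g$rate, g$midpoint),
          rejector = {
            # early small tumor, rejected by ~ mid-study, durably zero
            peak <- 3
            up <- pmin(days / 6, 1) * peak
            down <- pmax(1 - (days - 6) / 6, 0)
            ifelse(days <= 6, up, peak * down)
          },
          stabilizer = pmin(days / 6, 1) * 4
        )
        noise <- stats::rnorm(length(days), 0, g$noise_sd)
        d <- pmax(base + ifelse(base > 0, noise, 0), 0)
        # keep durable rejection durable: zero tails stay zero
        if (phen[i] == "rejector") d[days >= 13] <- 0
        rows[[mouse]] <- data.frame(
          mouse_id = sprintf("m%03d", mouse), group = grp, day = days,
          diameter_mm = d, phenotype = phen[i], stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

ideal_residue_atoms <- function(resno, x0, chain, resid = "ALA") {
  data.frame(
    name = c("N", "CA", "C", "O", "CB"),
    element = c("N", "C", "C", "O", "C"),
    resid = resid, resno = resno, chain = chain,
    x = x0 + c(-0.8, 0, 0.9, 1.0, 0.5),
    y = c(0.5, 0, -0.6, -1.7, 1.5),
    z = c(0, 0, 0, 0, 1.0),
    stringsAsFactors = FALSE
  )
}

AA3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
         H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
         P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
         W = "TRP", Y = "TYR")

#' Generate an idealized peptide-MHC model pair
#'
#' Builds an extended peptide (N/CA/C/O/CB per residue, 3.8 Angstrom CA
#' spacing) in a groove formed by a synthetic MHC chain, plus a perturbed
#' copy: a rigid motion of the whole complex and, when
#' `config$structure$displacement > 0`, a displacement of that magnitude
#' applied to the CA atom of the central peptide residue. These are
#' idealized synthetic coordinate sets for exercising the structural
#' metrics, not physical models.
#'
#' @param peptide Amino-acid string (8-11 residues).
#' @param config A [sim_config()].
#' @return List with `reference` and `perturbed` `pmhc_model`s.
#' @export
gen_toy_pmhc <- function(peptide, config = sim_config()) {
  local_seed(config$seed + 606L, {
    res <- peptide_residues(peptide)
    n <- length(res)
    if (n < 8 || n > 11) stop("peptide must be 8-11 residues")
    pep <- do.call(rbind, lapply(seq_len(n), function(i) {
      a <- ideal_residue_atoms(i, 3.8 * (i - 1L), "C", AA3[[res[i]]])
      a$y <- a$y + 6  # lifted above the groove floor
      a
    }))
    nm <- config$structure$mhc_residues
    mhc <- do.call(rbind, lapply(seq_len(nm), function(i) {
      side <- if (i <= nm / 2) -1 else 1
      j <- if (side < 0) i else i - nm / 2
      a <- ideal_residue_atoms(i, 3.8 * (j - 1L), "A", "GLY")
      a$y <- a$y
      a$z <- a$z + side * 5
      a
    }))
    ref <- pmhc_model(rbind(pep, mhc), peptide_chain = "C", mhc_chain = "A")

    # rigid motion of the whole complex
    th <- stats::runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    shift <- stats::runif(3, -10, 10)
    atoms <- ref$atoms
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    d <- config$structure$displacement
    if (d > 0) {
      target <- which(atoms$chain == "C" & atoms$name == "CA" &
                        atoms$resno == ceiling(n / 2))
      xyz[target, 2] <- xyz[target, 2] + d
    }
    xyz <- t(R %*% t(xyz)) + matrix(shift, nrow(xyz), 3, byrow = TRUE)
    atoms$x <- xyz[, 1]
    atoms$y <- xyz[, 2]
    atoms$z <- xyz[, 3]
    pert <- pmhc_model(atoms, peptide_chain = "C", mhc_chain = "A")
    list(reference = ref, perturbed = pert)
  })
}

#' Write every synthetic input class to a directory
#'
#' Emits proteome FASTA, variant TSV, search-database FASTA, PSM TSV, PRM
#' trace TSVs, growth CSV, toy PDB pair, and ground-truth sidecars
#' (`truth_*.tsv`) so downstream tests never re-derive the truth.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
simulate_all <- function(config = sim_config(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(dir, f)
  proteome <- gen_proteome(config)
  variants <- gen_variants(proteome, config)
  lps <- build_long_peptides(proteome, variants)
  psms <- gen_psm_list(lps, proteome, config)
  traces <- gen_prm_traces("TGAARFDEF", config)
  growth <- gen_growth_curves(config)
  models <- gen_toy_pmhc("TGAARFDEF", config)

  write_proteome(proteome, pth("proteome.fasta"))
  write_variants(variants, pth("variants.tsv"))
  write_search_database(proteome, lps, pth("search_db.fasta"))
  utils::write.table(psms[, c("sequence", "score", "is_decoy", "intensity",
                              "sample")],
                     pth("psms.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(psms[, c("sequence", "truth")], pth("truth_psms.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(traces$light, pth("traces_light.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(traces$heavy, pth("traces_heavy.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(growth[, c("mouse_id", "group", "day", "diameter_mm")],
                   pth("growth.csv"), row.names = FALSE)
  utils::write.table(unique(growth[, c("mouse_id", "group", "phenotype")]),
                     pth("truth_growth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_pdb_model(models$reference, pth("pmhc_reference.pdb"))
  write_pdb_model(models$perturbed, pth("pmhc_perturbed.pdb"))
  invisible(list(
    proteome = pth("proteome.fasta"), variants = pth("variants.tsv"),
    search_db = pth("search_db.fasta"), psms = pth("psms.tsv"),
    truth_psms = pth("truth_psms.tsv"),
    traces_light = pth("traces_light.tsv"),
    traces_heavy = pth("traces_heavy.tsv"), growth = pth("growth.csv"),
    truth_growth = pth("truth_growth.tsv"),
    pdb_reference = pth("pmhc_reference.pdb"),
    pdb_perturbed = pth("pmhc_perturbed.pdb")
  ))
}
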