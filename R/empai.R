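# In-silico tryptic digestion, peptide masses, and the emPAI abundance index.

#' Monoisotopic residue masses of the 20 standard amino acids
#'
#' Masses in Da of the amino-acid *residues* (i.e. after loss of water on
#' peptide-bond formation). A peptide's monoisotopic mass is the sum of its
#' residue masses plus one water.
#'
#' @format Named numeric vector of length 20 (one-letter codes).
#' @export
residue_masses <- c(
  G =  57.02146, A =  71.03711, S =  87.03203, P =  97.05276,
  V =  99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
  I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
  K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
  F = 147.06841, R = 156.10111, W = 186.07931, Y = 163.06333
)

MASS_WATER <- 18.010565

# Validate an amino-acid sequence; error names the first offending position.
check_residues <- function(sequence, what = "sequence") {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence)) {
    stop(what, " must be a non-empty amino-acid string", call. = FALSE)
  }
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!(aa %in% names(residue_masses)))
  if (length(bad)) {
    stop(sprintf("invalid residue '%s' at position %d of %s",
                 aa[bad[1]], bad[1], what), call. = FALSE)
  }
  invisible(aa)
}

#' Monoisotopic mass of a peptide
#'
#' Sum of monoisotopic residue masses plus one water (18.010565 Da).
#'
#' @param sequence Character vector of peptide sequences (20 standard
#'   one-letter codes only).
#' @return Numeric vector of masses in Da.
#' @examples
#' peptide_monoisotopic_mass("G")   # 75.032 Da
#' peptide_monoisotopic_mass("GG")  # 132.053 Da
#' @export
peptide_monoisotopic_mass <- function(sequence) {
  vapply(sequence, function(s) {
    aa <- check_residues(s, "peptide")
    sum(residue_masses[aa]) + MASS_WATER
  }, numeric(1), USE.NAMES = FALSE)
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to lysine (K) or arginine (R) except when the next
#' residue is proline (P), and enumerates all products carrying up to
#' `max_missed` missed cleavage sites.
#'
#' @param sequence Protein sequence (one-letter codes).
#' @param max_missed Maximum number of missed cleavages per product
#'   (default 0, fully cleaved products only).
#' @return A data frame with one row per peptide: `sequence`, `start`,
#'   `end` (1-based positions in the protein), `missed_cleavages`, and
#'   `monoisotopic_mass` in Da.
#' @examples
#' tryptic_digest("AKPRGR")          # "AKPR", "GR"
#' tryptic_digest("MKR", max_missed = 1)
#' @export
tryptic_digest <- function(sequence, max_missed = 0L) {
  check_residues(sequence, "protein sequence")
  stopifnot(max_missed >= 0)
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(aa)
  # cleavage after position i: K/R not followed by P, and not at the C-terminus
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & aa[cut_after + 1L] != "P"]
  bounds <- c(0L, cut_after, n)            # fragment i spans (bounds[i]+1) .. bounds[i+1]
  nfrag <- length(bounds) - 1L
  out <- list()
  for (i in seq_len(nfrag)) {
    for (j in i:min(nfrag, i + max_missed)) {
      s <- bounds[i] + 1L
      e <- bounds[j + 1L]
      out[[length(out) + 1L]] <- data.frame(
        sequence = paste(aa[s:e], collapse = ""),
        start = s, end = e,
        missed_cleavages = j - i,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  res$monoisotopic_mass <- peptide_monoisotopic_mass(res$sequence)
  res
}

#' Count observable peptides in a mass window
#'
#' Number of *distinct* peptide sequences whose monoisotopic mass lies in
#' `[mass_min, mass_max]` (inclusive). Distinctness is by bare sequence.
#'
#' @param peptides Either the data frame returned by [tryptic_digest()] or a
#'   character vector of peptide sequences.
#' @param mass_min,mass_max Mass window bounds in Da. The defaults cover the
#'   2+/3+ charge states of a 400-2000 m/z survey range.
#' @return Integer count.
#' @export
count_observable <- function(peptides, mass_min = 798, mass_max = 5997) {
  stopifnot(mass_min < mass_max)
  if (is.character(peptides)) {
    peptides <- data.frame(sequence = peptides,
                           monoisotopic_mass = peptide_monoisotopic_mass(peptides))
  }
  if (nrow(peptides) == 0L) return(0L)
  keep <- !duplicated(peptides$sequence)
  m <- peptides$monoisotopic_mass[keep]
  sum(m >= mass_min & m <= mass_max)
}

#' Protein Abundance Index (PAI) and emPAI
#'
#' `PAI = n_observed / n_observable`; `emPAI = 10^PAI - 1`. emPAI is a rough
#' label-free estimate of protein amount in an MS experiment.
#'
#' @param n_observed Number of distinct observed peptides (vectorised).
#' @param n_observable Number of distinct observable peptides (vectorised).
#' @return Data frame with columns `n_observed`, `n_observable`, `pai`,
#'   `empai`.
#' @examples
#' compute_empai(2, 10)  # pai 0.2, empai 10^0.2 - 1
#' @export
compute_empai <- function(n_observed, n_observable) {
  if (any(n_observable <= 0)) {
    stop("emPAI undefined: n_observable must be positive", call. = FALSE)
  }
  if (any(n_observed < 0)) stop("n_observed must be non-negative", call. = FALSE)
  pai <- n_observed / n_observable
  data.frame(n_observed = n_observed, n_observable = n_observable,
             pai = pai, empai = 10^pai - 1)
}

#' emPAI for a protein sequence
#'
#' Convenience wrapper: digest the sequence, count observable peptides in the
#' mass window, and compute PAI/emPAI from the observed-peptide count.
#'
#' @param sequence Protein sequence.
#' @param n_observed Number of distinct observed peptides.
#' @param mass_min,mass_max Observable mass window (Da), see
#'   [count_observable()].
#' @param max_missed Missed cleavages allowed when enumerating observable
#'   peptides (default 0).
#' @return One-row data frame as in [compute_empai()].
#' @export
protein_empai <- function(sequence, n_observed, mass_min = 798,
                          mass_max = 5997, max_missed = 0L) {
  pep <- tryptic_digest(sequence, max_missed = max_missed)
  n_obs_able <- count_observable(pep, mass_min, mass_max)
  if (n_obs_able == 0L) {
    # no peptide in the observable window: index undefined, report zero signal
    return(data.frame(n_observed = n_observed, n_observable = 0L,
                      pai = NA_real_, empai = NA_real_))
  }
  compute_empai(n_observed, n_obs_able)
}

#' Drug-affinity scores from emPAI values
#'
#' The affinity of the drug for each pulled-down protein is taken to be
#' proportional to the amount of protein recovered, i.e. to its emPAI;
#' scores are normalised so the most abundant target has affinity 1.
#' Accessions in `forced_full_affinity` (e.g. independently validated
#' targets) are set to exactly 1 and added if absent.
#'
#' @param empai_by_accession Named numeric vector of positive emPAI values.
#' @param forced_full_affinity Character vector of accessions pinned to
#'   affinity 1.
#' @return Named numeric vector of affinities in (0, 1].
#' @examples
#' affinity_from_empai(c(A = 2, B = 1))           # A 1.0, B 0.5
#' affinity_from_empai(c(A = 2), "COMMD1")        # COMMD1 added at 1.0
#' @export
affinity_from_empai <- function(empai_by_accession,
                                forced_full_affinity = character()) {
  if (length(empai_by_accession) == 0L && length(forced_full_affinity) == 0L) {
    stop("no emPAI values and no forced accessions: affinity map empty",
         call. = FALSE)
  }
  if (length(empai_by_accession)) {
    if (is.null(names(empai_by_accession)) || any(!nzchar(names(empai_by_accession)))) {
      stop("emPAI values must be named by accession", call. = FALSE)
    }
    if (any(empai_by_accession <= 0)) {
      stop("emPAI values must be positive for affinity scoring", call. = FALSE)
    }
    aff <- empai_by_accession / max(empai_by_accession)
  } else {
    aff <- numeric()
  }
  for (acc in forced_full_affinity) aff[acc] <- 1
  aff
}
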