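# Seeded generators for every input the pipeline needs, each returning a truth
# ledger from which the expected output of the downstream stage can be
# recomputed exactly. All randomness is drawn under withr::with_seed so the
# session RNG is untouched and fixed seeds give byte-identical output.

AA_ALPHABET <- names(AA_MONO)

# reverse codon table from the standard genetic code (first = deterministic
# pick not needed; codons are sampled, translation is checked by tests)
codons_for <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      tab <<- split(names(gc), unname(gc))
    }
    tab
  }
})

random_protein <- function(length) {
  paste(sample(AA_ALPHABET, length, replace = TRUE), collapse = "")
}

protein_to_nt <- function(protein) {
  tab <- codons_for()
  res <- strsplit(protein, "")[[1]]
  paste(map_chr(res, function(a) sample(tab[[a]], 1)), collapse = "")
}

#' Simulate a family of near-identical L1 locus proteins
#'
#' Draws a consensus ORF uniformly over the 20 residues, then derives each
#' locus by per-residue substitution (rate `mutation_rate`) and, with
#' per-locus probability `indel_rate`, one short insertion or deletion (1-3
#' residues). Defaults emulate a young L1 family: length 1275 (the ORF2p
#' length) and 1.25% substitution divergence. Nucleotide sequences are
#' generated codon-consistent with the proteins.
#'
#' @param n_loci Number of loci.
#' @param length Consensus protein length.
#' @param mutation_rate Per-residue substitution probability.
#' @param indel_rate Per-locus probability of one indel event.
#' @param subfamilies Subfamily labels sampled per locus.
#' @param orf_label `"ORF1"` or `"ORF2"`.
#' @param seed Integer seed (mandatory: the ledger must be reproducible).
#' @return List with `loci` (tibble `locus_id`, `subfamily`, `orf_label`,
#'   `protein`, `nucleotide`), `consensus`, `consensus_nt`, and `ledger`
#'   (tibble `locus_id`, `event`, `position`, `from`, `to`; positions are
#'   consensus coordinates).
#' @export
simulate_locus_family <- function(n_loci = 20L, length = 1275L,
                                  mutation_rate = 0.0125, indel_rate = 0.05,
                                  subfamilies = c("L1Hs", "L1PA2"),
                                  orf_label = "ORF2", seed) {
  assert_that(!missing(seed), "`seed` is mandatory")
  assert_that(n_loci >= 1 && length >= 10, "need n_loci >= 1 and length >= 10")
  assert_that(mutation_rate >= 0 && mutation_rate <= 1 &&
                indel_rate >= 0 && indel_rate <= 1, "rates must lie in [0, 1]")
  withr::with_seed(seed, {
    consensus <- random_protein(length)
    consensus_nt <- protein_to_nt(consensus)
    cons_res <- strsplit(consensus, "")[[1]]
    ledger <- list()
    loci <- list()
    for (k in seq_len(n_loci)) {
      id <- sprintf("locus_%03d", k)
      res <- cons_res
      sub_pos <- which(runif(length) < mutation_rate)
      for (p in sub_pos) {
        new <- sample(setdiff(AA_ALPHABET, res[p]), 1)
        ledger[[length(ledger) + 1L]] <- tibble(
          locus_id = id, event = "substitution", position = p,
          from = res[p], to = new)
        res[p] <- new
      }
      if (runif(1) < indel_rate) {
        klen <- sample(1:3, 1)
        if (runif(1) < 0.5 && base::length(res) > klen + 2) {
          at <- sample(seq_len(base::length(res) - klen), 1)
          ledger[[length(ledger) + 1L]] <- tibble(
            locus_id = id, event = "deletion", position = at,
            from = paste(res[at:(at + klen - 1L)], collapse = ""), to = "")
          res <- res[-(at:(at + klen - 1L))]
        } else {
          at <- sample(seq_len(base::length(res)), 1)
          ins <- sample(AA_ALPHABET, klen, replace = TRUE)
          ledger[[length(ledger) + 1L]] <- tibble(
            locus_id = id, event = "insertion", position = at,
            from = "", to = paste(ins, collapse = ""))
          res <- append(res, ins, after = at)
        }
      }
      protein <- paste(res, collapse = "")
      loci[[k]] <- tibble(
        locus_id = id,
        subfamily = sample(subfamilies, 1),
        orf_label = orf_label,
        protein = protein,
        nucleotide = protein_to_nt(protein)
      )
    }
    list(
      loci = bind_rows(loci),
      consensus = consensus,
      consensus_nt = consensus_nt,
      ledger = if (length(ledger) > 0) bind_rows(ledger) else
        tibble(locus_id = character(), event = character(), position = integer(),
               from = character(), to = character())
    )
  })
}

#' Simulate noisy fragmentation spectra for a set of peptides
#'
#' Builds the complete singly charged b/y ladder of each peptide, drops each
#' ion independently with probability `fragment_dropout`, assigns lognormal
#' intensities, and adds `noise_peaks` uniform-m/z noise peaks. Noise peaks
#' are rejection-sampled away from all theoretical 1+/2+ b/y ions (by 3x the
#' annotation tolerance), so the truth ledger reproduces
#' [annotate_fragments()] output exactly when annotation is run at the 1+
#' charge state the spectra contain (residue-mass coincidences can let a 2+
#' theoretical ion claim a 1+ peak, adding spurious site coverage).
#'
#' @param peptides Character vector of peptides (length >= 2 residues each).
#' @param fragment_dropout Per-ion dropout probability.
#' @param noise_peaks Number of noise peaks per spectrum.
#' @param tolerance_ppm Annotation tolerance the noise placement must respect.
#' @param seed Integer seed (mandatory).
#' @return List with `spectra` (named list of peak tibbles), `psms` (tibble
#'   `spectrum_id`, `peptide`, `prev_aa`, `next_aa`, `evalue`, `assignments`)
#'   and `ledger` (tibble `spectrum_id`, `peptide`, `true_fraction`,
#'   `true_max_gap`).
#' @export
simulate_spectra <- function(peptides, fragment_dropout = 0.1, noise_peaks = 10L,
                             tolerance_ppm = 10, seed) {
  assert_that(!missing(seed), "`seed` is mandatory")
  assert_that(all(nchar(peptides) >= 2), "peptides must have length >= 2")
  assert_that(fragment_dropout >= 0 && fragment_dropout <= 1,
              "`fragment_dropout` must lie in [0, 1]")
  withr::with_seed(seed, {
    spectra <- list()
    ledgers <- list()
    psms <- list()
    for (k in seq_along(peptides)) {
      pep <- peptides[k]
      sid <- sprintf("scan_%04d", k)
      L <- nchar(pep)
      ladder <- fragment_ions(pep, charges = 1L)
      keep <- runif(nrow(ladder)) >= fragment_dropout
      kept <- ladder[keep, , drop = FALSE]
      signal_int <- stats::rlnorm(nrow(kept), meanlog = 11, sdlog = 0.6)

      # noise placed away from every theoretical 1+/2+ ion
      forbidden <- fragment_ions(pep, charges = c(1L, 2L))$mz
      lo <- 100
      hi <- max(ladder$mz) + 200
      noise_mz <- double()
      while (base::length(noise_mz) < noise_peaks) {
        cand <- runif(noise_peaks - base::length(noise_mz), lo, hi)
        ok <- map_lgl(cand, function(x) {
          all(abs(x - forbidden) > 3 * tolerance_ppm * 1e-6 * forbidden)
        })
        noise_mz <- c(noise_mz, cand[ok])
      }
      noise_int <- stats::rlnorm(base::length(noise_mz), meanlog = 9, sdlog = 0.6)

      mz <- c(kept$mz, noise_mz)
      intensity <- c(signal_int, noise_int)
      ord <- order(mz)
      sp <- tibble(mz = mz[ord], intensity = intensity[ord])
      attr(sp, "title") <- sid
      mass <- sum(residue_masses(pep)) + WATER_MASS
      attr(sp, "precursor_mz") <- (mass + 2 * PROTON_MASS) / 2
      attr(sp, "precursor_charge") <- 2L
      spectra[[sid]] <- sp

      covered <- rep(FALSE, L - 1)
      for (s in seq_len(L - 1)) {
        covered[s] <- any((kept$type == "b" & kept$index == s) |
                            (kept$type == "y" & kept$index == L - s))
      }
      total <- sum(intensity)
      ledgers[[k]] <- tibble(
        spectrum_id = sid, peptide = pep,
        true_fraction = if (total == 0) 0 else sum(signal_int) / total,
        true_max_gap = max_uncovered_run(covered) + 1L
      )
      psms[[k]] <- tibble(
        spectrum_id = sid, peptide = pep, prev_aa = "K", next_aa = "A",
        evalue = 10^runif(1, -8, -3), assignments = list("synthetic_protein")
      )
    }
    list(spectra = spectra, psms = bind_rows(psms), ledger = bind_rows(ledgers))
  })
}

#' Simulate a replicate IP-vs-control intensity matrix with spiked proteins
#'
#' Null proteins share their abundance across the case (IP) and control
#' groups; `n_spiked` proteins are shifted up by `effect_log2` in the case
#' group, emulating specific enrichment. Missingness is left-censored by
#' default: the probability that a cell is unquantified falls logistically
#' with its log2 abundance, centred one abundance-sd below the mean abundance
#' with maximum rate `missing_max_rate`. An MCAR switch exists for null
#' testing.
#'
#' @param n_proteins Number of null (background) proteins.
#' @param n_spiked Number of spiked (truly enriched) proteins.
#' @param n_case,n_control Replicates per side (at least 3 each).
#' @param effect_log2 Case-group log2 shift of spiked proteins.
#' @param within_sd Within-group replicate standard deviation (log2 scale).
#' @param base_mean,base_sd Protein log2 abundance distribution.
#' @param missing_max_rate Maximum per-cell missingness probability (set 0 to
#'   disable missingness).
#' @param mcar Use abundance-independent (missing completely at random)
#'   missingness at rate `missing_max_rate / 2` instead of left-censoring.
#' @param seed Integer seed (mandatory).
#' @return List with `table` (tibble in [read_intensity_table()] shape: raw
#'   scale, 0 = missing), `groups` (named list of case/control sample names)
#'   and `ledger` (tibble `protein_id`, `spiked`, `true_effect_log2`,
#'   `base_log2`).
#' @export
simulate_ipms_matrix <- function(n_proteins = 1000L, n_spiked = 50L,
                                 n_case = 3L, n_control = 3L,
                                 effect_log2 = 2, within_sd = 0.5,
                                 base_mean = 23, base_sd = 2.5,
                                 missing_max_rate = 0.5, mcar = FALSE, seed) {
  assert_that(!missing(seed), "`seed` is mandatory")
  assert_that(n_case >= 3 && n_control >= 3, "need at least 3 replicates per side")
  withr::with_seed(seed, {
    n <- n_proteins + n_spiked
    ids <- c(sprintf("NULL_%04d", seq_len(n_proteins)),
             if (n_spiked > 0) sprintf("SPIKE_%04d", seq_len(n_spiked)))
    effect <- c(rep(0, n_proteins), rep(effect_log2, n_spiked))
    base <- rnorm(n, base_mean, base_sd)
    case_names <- paste0("IP_", seq_len(n_case))
    ctrl_names <- paste0("Ctrl_", seq_len(n_control))
    log2_vals <- cbind(
      matrix(rnorm(n * n_case, base + effect, within_sd), nrow = n),
      matrix(rnorm(n * n_control, base, within_sd), nrow = n)
    )
    colnames(log2_vals) <- c(case_names, ctrl_names)

    if (missing_max_rate > 0) {
      p_miss <- if (mcar) {
        matrix(missing_max_rate / 2, n, n_case + n_control)
      } else {
        censor_mid <- base_mean - base_sd
        missing_max_rate * stats::plogis(-(log2_vals - censor_mid))
      }
      drop <- matrix(runif(n * (n_case + n_control)), n) < p_miss
    } else {
      drop <- matrix(FALSE, n, n_case + n_control)
    }

    raw <- 2^log2_vals
    raw[drop] <- 0
    table <- tibble(protein_id = ids,
                    reverse = rep(FALSE, n),
                    contaminant = rep(FALSE, n))
    for (j in seq_len(ncol(raw))) table[[colnames(log2_vals)[j]]] <- raw[, j]
    list(
      table = table,
      groups = list(case = case_names, control = ctrl_names),
      ledger = tibble(protein_id = ids,
                      spiked = effect > 0,
                      true_effect_log2 = effect,
                      base_log2 = base)
    )
  })
}
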