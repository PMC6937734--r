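# Fragment-ion chemistry and the per-PSM quality metrics that the repeat-aware
# filters consume: matched-intensity fraction, fragmentation gaps, tryptic status.

# Monoisotopic residue masses (Da) for the 20 standard amino acids.
AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
PROTON_MASS <- 1.007276
WATER_MASS <- 18.010565

check_residues <- function(peptide) {
  res <- strsplit(peptide, "", fixed = TRUE)[[1]]
  unknown <- setdiff(res, names(AA_MONO))
  if (length(unknown) > 0) {
    abort(paste0("unknown residue symbol(s): ", paste(unique(unknown), collapse = ", ")),
          class = "retroproteo_residue_error")
  }
  res
}

residue_masses <- function(peptide, modifications = NULL) {
  res <- check_residues(peptide)
  m <- unname(AA_MONO[res])
  if (!is.null(modifications) && nrow(modifications) > 0) {
    pos <- modifications$position
    assert_that(all(pos >= 1 & pos <= length(res)),
                "modification positions must lie within the peptide")
    for (i in seq_len(nrow(modifications))) {
      m[pos[i]] <- m[pos[i]] + modifications$mass_shift[i]
    }
  }
  m
}

#' Theoretical b- and y-ion m/z values for a peptide
#'
#' Computes monoisotopic b and y fragment ions for all prefix/suffix lengths
#' `1..L-1` at each requested charge state. `b = (prefix mass + z * proton)/z`,
#' `y = (suffix mass + water + z * proton)/z`, with any modification masses
#' added to the prefix/suffix that contains the modified residue.
#'
#' @param peptide Amino-acid string over the 20 standard residues.
#' @param modifications Optional data frame with columns `position` (1-based
#'   residue index) and `mass_shift` (Da); an optional `name` column is ignored
#'   by the mass arithmetic.
#' @param charges Integer vector of fragment charge states (default `c(1, 2)`).
#' @return A tibble with columns `ion` (label such as `"b3"` or `"y5^2"`),
#'   `type`, `index`, `charge`, `mz`.
#' @examples
#' fragment_ions("GG", charges = 1)
#' @export
fragment_ions <- function(peptide, modifications = NULL, charges = c(1L, 2L)) {
  assert_that(is.character(peptide) && length(peptide) == 1 && nzchar(peptide),
              "`peptide` must be a single non-empty string")
  assert_that(all(charges >= 1), "charges must be positive integers")
  m <- residue_masses(peptide, modifications)
  L <- length(m)
  if (L < 2) {
    return(tibble(ion = character(), type = character(), index = integer(),
                  charge = integer(), mz = double()))
  }
  prefix <- cumsum(m)[seq_len(L - 1)]          # b_i, i = 1..L-1
  suffix <- sum(m) - prefix                     # y_{L-i} pairs with b_i
  out <- map(as.integer(charges), function(z) {
    b_mz <- (prefix + z * PROTON_MASS) / z
    y_mz <- (rev(suffix) + WATER_MASS + z * PROTON_MASS) / z
    suffix_label <- if (z == 1) "" else paste0("^", z)
    tibble(
      ion = c(paste0("b", seq_len(L - 1), suffix_label),
              paste0("y", seq_len(L - 1), suffix_label)),
      type = rep(c("b", "y"), each = L - 1),
      index = rep(seq_len(L - 1), 2L),
      charge = z,
      mz = c(b_mz, y_mz)
    )
  })
  bind_rows(out)
}

#' Annotate a spectrum against a peptide's theoretical fragment ladder
#'
#' Matches observed peaks to theoretical b/y ions within a ppm tolerance and
#' derives the PSM quality metrics used by [filter_psms()]: the fraction of
#' total peak intensity explained by the sequence, the backbone cleavage sites
#' covered by at least one matching ion, and the largest fragmentation gap.
#'
#' A peak contributes to the matched intensity once, even when it matches
#' several theoretical ions. Cleavage site `s` (between residues `s` and
#' `s + 1`) counts as covered when any `b_s` or `y_(L-s)` ion matched. The gap
#' is the longest run of consecutive uncovered sites plus one, expressed in
#' residues; a spectrum with no fragment evidence therefore has
#' `max_gap == nchar(peptide)` and a complete ladder has `max_gap == 1`.
#'
#' @param peptide Amino-acid string.
#' @param spectrum Data frame with numeric columns `mz` and `intensity`.
#' @param modifications See [fragment_ions()].
#' @param tolerance_ppm Fragment match tolerance in parts per million
#'   (default 10, a typical high-resolution HCD setting).
#' @param charges Fragment charge states to consider (default 1+ and 2+).
#' @return An object of class `fragment_annotation`: a list with
#'   `matched_peaks` (tibble of `peak_index`, `ion`), `matched_intensity_fraction`,
#'   `covered_sites` (logical, length `L - 1`) and `max_gap`.
#' @examples
#' sp <- tibble::tibble(mz = fragment_ions("PEPTIDEK", charges = 1)$mz,
#'                      intensity = 1)
#' annotate_fragments("PEPTIDEK", sp)$max_gap
#' @export
annotate_fragments <- function(peptide, spectrum, modifications = NULL,
                               tolerance_ppm = 10, charges = c(1L, 2L)) {
  assert_that(tolerance_ppm > 0, "`tolerance_ppm` must be positive")
  assert_that(is.data.frame(spectrum) && all(c("mz", "intensity") %in% names(spectrum)),
              "`spectrum` must have columns `mz` and `intensity`")
  assert_that(all(spectrum$intensity >= 0), "peak intensities must be non-negative")
  L <- nchar(peptide)
  ions <- fragment_ions(peptide, modifications, charges)
  n_peaks <- nrow(spectrum)

  if (n_peaks == 0 || nrow(ions) == 0) {
    covered <- rep(FALSE, max(L - 1, 0))
    return(structure(
      list(peptide = peptide,
           matched_peaks = tibble(peak_index = integer(), ion = character()),
           matched_intensity_fraction = 0,
           covered_sites = covered,
           max_gap = max_uncovered_run(covered) + 1L),
      class = "fragment_annotation"
    ))
  } else {
    # |peak - ion| <= tol * ion; small dense problem, outer() is fine
    dev <- abs(outer(spectrum$mz, ions$mz, "-"))
    lim <- matrix(rep(ions$mz * tolerance_ppm * 1e-6, each = n_peaks), nrow = n_peaks)
    hit <- dev <= lim
    peak_matched <- rowSums(hit) > 0
    ion_matched <- colSums(hit) > 0
    covered <- rep(FALSE, L - 1)
    for (s in seq_len(L - 1)) {
      covered[s] <- any(ion_matched[(ions$type == "b" & ions$index == s) |
                                      (ions$type == "y" & ions$index == L - s)])
    }
  }

  idx <- which(hit, arr.ind = TRUE)
  matched_peaks <- tibble(peak_index = as.integer(idx[, 1]),
                          ion = ions$ion[idx[, 2]])
  total <- sum(spectrum$intensity)
  fraction <- if (total == 0) 0 else sum(spectrum$intensity[peak_matched]) / total

  structure(
    list(
      peptide = peptide,
      matched_peaks = matched_peaks,
      matched_intensity_fraction = fraction,
      covered_sites = covered,
      max_gap = max_uncovered_run(covered) + 1L
    ),
    class = "fragment_annotation"
  )
}

# longest run of FALSE in a logical vector (0 when empty or all TRUE)
max_uncovered_run <- function(covered) {
  if (length(covered) == 0) return(0L)
  r <- rle(!covered)
  runs <- r$lengths[r$values]
  if (length(runs) == 0) 0L else as.integer(max(runs))
}

#' @export
print.fragment_annotation <- function(x, ...) {
  cat(sprintf("<fragment_annotation> %s: matched fraction %.3f, max gap %d, %d/%d sites covered\n",
              x$peptide, x$matched_intensity_fraction, x$max_gap,
              sum(x$covered_sites), length(x$covered_sites)))
  invisible(x)
}

#' Tryptic status of a peptide given its flanking residues
#'
#' A boundary is tryptic when the upstream residue is K or R and the
#' downstream residue is not P, or when the boundary is a protein terminus
#' (`"-"`). `full` means both peptide boundaries are tryptic, `semi` exactly
#' one, `non` neither.
#'
#' @param peptide Peptide sequence(s).
#' @param prev_aa,next_aa Flanking residues, `"-"` for a protein terminus.
#'   Vectorized along `peptide`.
#' @return Character vector over `c("full", "semi", "non")`.
#' @examples
#' tryptic_status("AVLR", "K", "S")
#' @export
tryptic_status <- function(peptide, prev_aa, next_aa) {
  assert_that(length(peptide) == length(prev_aa) && length(peptide) == length(next_aa),
              "`peptide`, `prev_aa` and `next_aa` must have equal length")
  first_res <- substr(peptide, 1, 1)
  last_res <- substr(peptide, nchar(peptide), nchar(peptide))
  n_ok <- prev_aa == "-" | (prev_aa %in% c("K", "R") & first_res != "P")
  c_ok <- next_aa == "-" | (last_res %in% c("K", "R") & next_aa != "P")
  c("non", "semi", "full")[n_ok + c_ok + 1L]
}

#' Annotate a table of PSMs against their spectra
#'
#' Batch wrapper around [annotate_fragments()] and [tryptic_status()]: adds
#' the derived quality columns `matched_intensity_fraction`,
#' `max_fragmentation_gap` and `tryptic_status` to a PSM table.
#'
#' @param psms Tibble with at least `spectrum_id`, `peptide`, `prev_aa`,
#'   `next_aa`; an optional `modifications` list-column (tibbles with
#'   `position`, `mass_shift`) is honoured.
#' @param spectra Named list of spectra (data frames with `mz`, `intensity`);
#'   names must cover every `spectrum_id`.
#' @inheritParams annotate_fragments
#' @return `psms` with the three derived columns appended.
#' @export
annotate_psms <- function(psms, spectra, tolerance_ppm = 10, charges = c(1L, 2L)) {
  needed <- c("spectrum_id", "peptide", "prev_aa", "next_aa")
  assert_that(all(needed %in% names(psms)),
              paste("`psms` must have columns:", paste(needed, collapse = ", ")))
  missing_sp <- setdiff(psms$spectrum_id, names(spectra))
  assert_that(length(missing_sp) == 0,
              paste0("no spectrum provided for: ", paste(head(missing_sp, 5), collapse = ", ")))
  mods <- if ("modifications" %in% names(psms)) psms$modifications else
    rep(list(NULL), nrow(psms))
  ann <- pmap(list(psms$peptide, psms$spectrum_id, mods), function(pep, sid, md) {
    annotate_fragments(pep, spectra[[sid]], modifications = md,
                       tolerance_ppm = tolerance_ppm, charges = charges)
  })
  psms |>
    mutate(
      matched_intensity_fraction = map_dbl(ann, "matched_intensity_fraction"),
      max_fragmentation_gap = map_int(ann, "max_gap"),
      tryptic_status = tryptic_status(.data$peptide, .data$prev_aa, .data$next_aa)
    )
}
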