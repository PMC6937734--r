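# Sequence analytics over families of near-identical L1 loci: in-silico
# tryptic digestion, alignment to a reference ORF, variant counting,
# per-position identity, antibody epitope conservation scanning, amino-acid to
# nucleotide coordinate mapping, and the two-step locus-database
# orthogonalization. Coordinates are 1-based and inclusive throughout.

#' In-silico tryptic digestion
#'
#' Cleaves after K or R unless the next residue is P, and emits peptides for
#' 0 up to `max_missed_cleavages` missed cleavage sites.
#'
#' @param protein Protein sequence.
#' @param max_missed_cleavages Maximum number of internal missed cleavage
#'   sites per peptide (default 1, a common search-engine setting).
#' @return Tibble with `peptide`, `start`, `end` (1-based inclusive),
#'   `prev_aa`, `next_aa` (`"-"` at protein termini) and `missed_cleavages`.
#' @examples
#' digest_protein("AKPRG", max_missed_cleavages = 0)
#' @export
digest_protein <- function(protein, max_missed_cleavages = 1L) {
  assert_that(nzchar(protein), "`protein` must be non-empty")
  res <- strsplit(protein, "")[[1]]
  L <- length(res)
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after < L & res[pmin(cut_after + 1L, L)] != "P"]
  bounds <- c(0L, cut_after, L)                 # fragment i spans bounds[i]+1 .. bounds[i+1]
  n_frag <- length(bounds) - 1L
  rows <- list()
  for (i in seq_len(n_frag)) {
    for (mc in 0:max_missed_cleavages) {
      j <- i + mc
      if (j > n_frag) break
      start <- bounds[i] + 1L
      end <- bounds[j + 1L]
      rows[[length(rows) + 1L]] <- tibble(
        peptide = substr(protein, start, end),
        start = start, end = end,
        prev_aa = if (start == 1L) "-" else res[start - 1L],
        next_aa = if (end == L) "-" else res[end + 1L],
        missed_cleavages = mc
      )
    }
  }
  bind_rows(rows)
}

aa_substitution_matrix <- function(match = 1, mismatch = -1) {
  alphabet <- c(LETTERS, "*")
  m <- matrix(mismatch, length(alphabet), length(alphabet),
              dimnames = list(alphabet, alphabet))
  diag(m) <- match
  m
}

#' Global alignment of a locus protein to a reference ORF
#'
#' Needleman-Wunsch global alignment with a simple match/mismatch scheme and
#' affine gap penalties (delegated to `Biostrings::pairwiseAlignment`). At the
#' 0.5-2.5% divergence typical of an L1 locus family, star alignment of each
#' locus to the reference is equivalent to a multiple alignment for per-locus
#' variant counting.
#'
#' @param locus Locus protein sequence (or a one-row tibble with a `protein`
#'   column).
#' @param reference Reference ORF protein sequence.
#' @param match,mismatch Substitution scores (defaults +1 / -1).
#' @param gap_open,gap_extend Affine gap penalties as positive costs
#'   (defaults 5 and 1).
#' @return Object of class `l1_alignment`: list with equal-length gapped
#'   strings `aligned_locus` and `aligned_reference`, and `score`.
#' @export
align_to_reference <- function(locus, reference, match = 1, mismatch = -1,
                               gap_open = 5, gap_extend = 1) {
  if (is.data.frame(locus)) locus <- locus$protein[1]
  assert_that(nzchar(locus) && nzchar(reference), "sequences must be non-empty")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::BString(locus), Biostrings::BString(reference),
    type = "global",
    substitutionMatrix = aa_substitution_matrix(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_extend
  )
  structure(
    list(aligned_locus = as.character(Biostrings::alignedPattern(aln)),
         aligned_reference = as.character(Biostrings::alignedSubject(aln)),
         score = Biostrings::score(aln)),
    class = "l1_alignment"
  )
}

#' @export
print.l1_alignment <- function(x, ...) {
  cat("<l1_alignment> score", x$score, "\n")
  cat(" locus: ", substr(x$aligned_locus, 1, 60), "\n")
  cat(" ref:   ", substr(x$aligned_reference, 1, 60), "\n")
  invisible(x)
}

#' Count amino-acid variants in a locus/reference alignment
#'
#' A variant is a substituted reference position, a deleted reference
#' position, or an insertion event (each maximal inserted run counts once).
#'
#' @param alignment An [align_to_reference()] result.
#' @return Tibble with `n_substitutions`, `n_deleted_positions`,
#'   `n_insertion_events`, `n_variants` (their sum), `reference_length` and
#'   `percent_divergence` (= 100 * n_variants / reference length).
#' @export
variant_count <- function(alignment) {
  assert_that(inherits(alignment, "l1_alignment"),
              "`alignment` must come from align_to_reference()")
  loc <- strsplit(alignment$aligned_locus, "")[[1]]
  ref <- strsplit(alignment$aligned_reference, "")[[1]]
  subs <- sum(loc != "-" & ref != "-" & loc != ref)
  dels <- sum(ref != "-" & loc == "-")
  ins_runs <- rle(ref == "-")
  ins_events <- sum(ins_runs$values)
  ref_len <- sum(ref != "-")
  n <- subs + dels + ins_events
  tibble(
    n_substitutions = subs,
    n_deleted_positions = dels,
    n_insertion_events = ins_events,
    n_variants = n,
    reference_length = ref_len,
    percent_divergence = 100 * n / ref_len
  )
}

# aligned locus residue at each reference position ("-" where deleted)
locus_at_reference_positions <- function(alignment) {
  loc <- strsplit(alignment$aligned_locus, "")[[1]]
  ref <- strsplit(alignment$aligned_reference, "")[[1]]
  loc[ref != "-"]
}

#' Per-position identity of a locus family against a reference ORF
#'
#' For every reference position, the percentage of loci whose aligned residue
#' equals the reference residue; gaps count as non-identical.
#'
#' @param loci Tibble with `locus_id` and `protein` columns.
#' @param reference Reference ORF protein sequence.
#' @param ... Passed to [align_to_reference()].
#' @return Tibble with `position`, `reference_aa`, `pct_identity`.
#' @export
per_position_identity <- function(loci, reference, ...) {
  assert_that(nrow(loci) >= 1, "need at least one locus")
  ref_res <- strsplit(reference, "")[[1]]
  hits <- rep(0L, length(ref_res))
  for (i in seq_len(nrow(loci))) {
    aln <- align_to_reference(loci$protein[i], reference, ...)
    at_ref <- locus_at_reference_positions(aln)
    hits <- hits + (at_ref == ref_res)
  }
  tibble(position = seq_along(ref_res),
         reference_aa = ref_res,
         pct_identity = 100 * hits / nrow(loci))
}

#' The five ORF2p monoclonal antibody epitopes
#'
#' Linear epitopes recognized by the MT-series rabbit monoclonal antibodies
#' raised against L1RP ORF2p: MT49 and MT69 sit on the endonuclease domain
#' surface, MT9 and MT11 between the endonuclease and reverse-transcriptase
#' domains, and MT5 about 300 residues from the C terminus (its window
#' contains position 990, valine in L1Hs and methionine in older subfamilies
#' such as L1PA2).
#'
#' @return Tibble with `name`, `sequence`, `reference_start` (NA: locate by
#'   exact substring match on the supplied reference).
#' @export
l1_epitopes <- function() {
  tibble(
    name = c("MT49", "MT69", "MT9", "MT11", "MT5"),
    sequence = c("DRSTRQ", "LHQADLID", "KASRRQEITKIRAE", "KELEKQEQT", "QDIGVGKD"),
    reference_start = NA_integer_
  )
}

#' Scan epitope conservation across a locus family
#'
#' Locates each epitope on the reference ORF (exact substring match, or the
#' provided `reference_start`) and counts, per locus, the residues in the
#' aligned epitope window that mismatch the epitope sequence. Gapped window
#' positions score as mismatches.
#'
#' @param epitopes Tibble with `name`, `sequence` and optional
#'   `reference_start` columns (see [l1_epitopes()]).
#' @param loci Tibble with `locus_id` and `protein` columns.
#' @param reference Reference ORF protein sequence.
#' @param ... Passed to [align_to_reference()].
#' @return Tibble with `epitope`, `locus_id`, `n_mismatch`, `match` (TRUE when
#'   0 mismatches).
#' @seealso [epitope_match_fraction()]
#' @export
epitope_scan <- function(epitopes, loci, reference, ...) {
  if (!"reference_start" %in% names(epitopes)) epitopes$reference_start <- NA_integer_
  starts <- map_int(seq_len(nrow(epitopes)), function(i) {
    hit <- regexpr(epitopes$sequence[i], reference, fixed = TRUE)
    if (hit > 0) return(as.integer(hit))
    if (!is.na(epitopes$reference_start[i])) return(as.integer(epitopes$reference_start[i]))
    abort(paste0("epitope '", epitopes$name[i],
                 "' is absent from the reference and has no reference_start"),
          class = "retroproteo_epitope_error")
  })
  rows <- list()
  for (j in seq_len(nrow(loci))) {
    aln <- align_to_reference(loci$protein[j], reference, ...)
    at_ref <- locus_at_reference_positions(aln)
    for (i in seq_len(nrow(epitopes))) {
      epi <- strsplit(epitopes$sequence[i], "")[[1]]
      win <- at_ref[starts[i]:(starts[i] + length(epi) - 1L)]
      rows[[length(rows) + 1L]] <- tibble(
        epitope = epitopes$name[i],
        locus_id = loci$locus_id[j],
        n_mismatch = sum(win != epi)
      )
    }
  }
  bind_rows(rows) |> mutate(match = .data$n_mismatch == 0)
}

#' Family-level epitope match fractions
#'
#' @param scan An [epitope_scan()] result.
#' @return Tibble with `epitope`, `n_loci`, `match_fraction` (proportion of
#'   loci with a perfect epitope match).
#' @export
epitope_match_fraction <- function(scan) {
  scan |>
    group_by(.data$epitope) |>
    summarise(n_loci = n(), match_fraction = mean(.data$match), .groups = "drop")
}

#' Map a 1-based amino-acid position to its codon's nucleotide span
#'
#' Under the 1-based inclusive convention, residue `p` is encoded by
#' nucleotides `3(p-1)+1 .. 3(p-1)+3` of the ORF. For example ORF2p residue
#' 990 maps to ORF2 nucleotides 2968-2970.
#'
#' @param aa_position Integer vector of 1-based residue positions.
#' @return Tibble with `aa_position`, `nt_first`, `nt_last`.
#' @examples
#' aa_to_nt(990)
#' @export
aa_to_nt <- function(aa_position) {
  assert_that(all(aa_position >= 1), "`aa_position` must be >= 1")
  first <- 3L * (as.integer(aa_position) - 1L) + 1L
  tibble(aa_position = as.integer(aa_position), nt_first = first, nt_last = first + 2L)
}

#' Orthogonalize a locus database against observed peptides
#'
#' Reduces a redundant set of near-identical locus sequences to a minimal set
#' that explains every observed peptide, in two steps: (a) retain every locus
#' supported by at least one peptide unique to it; (b) for each peptide whose
#' supporting loci are all still unretained, add exactly one representative --
#' the supporting locus most different from the consensus (highest variant
#' count; ties broken by lexicographically smallest locus id). Step (b)
#' processes peptides in lexicographic order against the running retained set,
#' so a representative added for one peptide can cover later ones; a final
#' pruning pass drops any representative a later addition made redundant, so
#' the result is minimal -- removing any retained locus either breaks peptide
#' coverage or discards a uniquely supported locus.
#'
#' @param observed_peptides Tibble with `peptide` and `locus_id` columns, one
#'   row per (peptide, supporting locus) pair.
#' @param loci Tibble with `locus_id` and `protein` columns.
#' @param consensus Consensus ORF protein sequence.
#' @param ... Passed to [align_to_reference()] for the variant counts.
#' @return List with `retained` (character vector of locus ids) and
#'   `peptide_map` (tibble `peptide`, `representative`: one retained
#'   supporting locus per observed peptide).
#' @export
orthogonalize_loci <- function(observed_peptides, loci, consensus, ...) {
  assert_that(all(c("peptide", "locus_id") %in% names(observed_peptides)),
              "`observed_peptides` needs `peptide` and `locus_id` columns")
  support <- observed_peptides |>
    distinct(.data$peptide, .data$locus_id)
  missing_loci <- setdiff(support$locus_id, loci$locus_id)
  assert_that(length(missing_loci) == 0,
              paste0("supporting locus id(s) not in `loci`: ",
                     paste(head(missing_loci, 5), collapse = ", ")))
  by_pep <- split(support$locus_id, support$peptide)
  assert_that(all(lengths(by_pep) > 0), "a peptide has empty locus support")

  # (a) loci with at least one unique peptide
  unique_support <- unlist(by_pep[lengths(by_pep) == 1], use.names = FALSE)
  retained <- sort(unique(unique_support))

  # (b) representatives for peptides not covered by (a)
  divergence <- setNames(
    map_dbl(loci$protein, function(p) {
      variant_count(align_to_reference(p, consensus, ...))$n_variants
    }),
    loci$locus_id
  )
  representatives <- character()
  for (pep in sort(names(by_pep))) {
    sup <- by_pep[[pep]]
    if (any(sup %in% c(retained, representatives))) next
    d <- divergence[sup]
    best <- sup[d == max(d)]
    representatives <- c(representatives, sort(best)[1])
  }

  # prune representatives a later addition made redundant (one pass suffices:
  # dropping a locus can only make the remaining ones more necessary)
  for (r in representatives) {
    without <- setdiff(c(retained, representatives), r)
    covers <- all(map_lgl(by_pep, function(sup) any(sup %in% without)))
    if (covers) representatives <- setdiff(representatives, r)
  }
  retained <- c(retained, representatives)

  peptide_map <- tibble(
    peptide = sort(names(by_pep)),
    representative = map_chr(sort(names(by_pep)), function(pep) {
      covering <- sort(intersect(by_pep[[pep]], retained))
      covering[1]
    })
  )
  list(retained = sort(unique(retained)), peptide_map = peptide_map)
}
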