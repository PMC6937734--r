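# Repeat-aware PSM retention rules, the ORF2p-specific rejection flags, the
# mutually-correlated peptide-set selection, and the peptide x sample presence
# matrix.

#' Filter configuration for repeat-aware PSM retention
#'
#' Defaults encode the retention rule used throughout this package: matched
#' intensity fraction strictly above 0.40, fragmentation gap of at most 3
#' residues, peptide length of at least 7, e-value of at most 0.01, and a
#' unique gene assignment.
#'
#' @param min_matched_fraction Retain only PSMs whose matched-intensity
#'   fraction is strictly greater than this (default 0.40).
#' @param max_gap_residues Largest tolerated fragmentation gap, in residues
#'   (default 3).
#' @param min_peptide_length Minimum peptide length (default 7).
#' @param max_evalue Largest tolerated search-engine e-value (default 0.01).
#' @param require_unique_gene Reject PSMs whose protein assignments map to
#'   more than one gene (default TRUE).
#' @param spearman_threshold Pairwise Spearman correlation threshold used by
#'   [select_correlated_peptides()] (default 0.6).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_matched_fraction = 0.40, max_gap_residues = 3L,
                          min_peptide_length = 7L, max_evalue = 0.01,
                          require_unique_gene = TRUE, spearman_threshold = 0.6) {
  assert_that(min_matched_fraction >= 0 && min_matched_fraction <= 1,
              "`min_matched_fraction` must lie in [0, 1]")
  assert_that(is.finite(max_gap_residues) && is.finite(min_peptide_length) &&
                is.finite(max_evalue), "all thresholds must be finite")
  structure(
    list(min_matched_fraction = min_matched_fraction,
         max_gap_residues = as.integer(max_gap_residues),
         min_peptide_length = as.integer(min_peptide_length),
         max_evalue = max_evalue,
         require_unique_gene = isTRUE(require_unique_gene),
         spearman_threshold = spearman_threshold),
    class = "filter_config"
  )
}

# map protein assignment vectors to gene sets; unmapped proteins are their own
# gene (documented behaviour: the locus library supplies the map and collapses
# all L1 loci of one ORF to a single gene)
genes_of <- function(assignments, gene_map) {
  if (is.null(gene_map)) return(assignments)
  if (is.data.frame(gene_map)) {
    gene_map <- setNames(gene_map$gene, gene_map$protein)
  }
  map(assignments, function(a) {
    g <- unname(gene_map[a])
    ifelse(is.na(g), a, g)
  })
}

#' Apply the repeat-aware PSM retention rule
#'
#' A PSM is retained when its matched-intensity fraction exceeds
#' `min_matched_fraction`, its fragmentation gap is at most
#' `max_gap_residues`, its peptide length is at least `min_peptide_length`,
#' its e-value is at most `max_evalue`, and (when `require_unique_gene`) all
#' of its protein assignments map to exactly one gene. Every rejection carries
#' the first rule it failed, checked in that order.
#'
#' @param psms Annotated PSM tibble (see [annotate_psms()]); must carry
#'   `matched_intensity_fraction` and `max_fragmentation_gap`.
#' @param gene_map Optional protein-to-gene mapping: a named character vector
#'   or a data frame with `protein` and `gene` columns. Proteins absent from
#'   the map count as their own gene.
#' @param config A [filter_config()].
#' @return A list with `retained` (tibble of passing PSMs) and `rejections`
#'   (tibble `spectrum_id`, `peptide`, `reason`).
#' @export
filter_psms <- function(psms, gene_map = NULL, config = filter_config()) {
  if (!all(c("matched_intensity_fraction", "max_fragmentation_gap") %in% names(psms)) ||
      anyNA(psms$matched_intensity_fraction)) {
    abort("PSMs must be annotated first: run annotate_psms() to derive the quality metrics",
          class = "retroproteo_unannotated_error")
  }
  assert_that(all(c("peptide", "evalue", "assignments") %in% names(psms)),
              "`psms` must carry `peptide`, `evalue` and `assignments`")
  genes <- genes_of(psms$assignments, gene_map)
  n_genes <- map_int(genes, ~ length(unique(.x)))
  reason <- rep(NA_character_, nrow(psms))
  fails <- list(
    matched_fraction = !(psms$matched_intensity_fraction > config$min_matched_fraction),
    gap = psms$max_fragmentation_gap > config$max_gap_residues,
    length = nchar(psms$peptide) < config$min_peptide_length,
    evalue = psms$evalue > config$max_evalue,
    `multi-gene` = if (config$require_unique_gene) n_genes != 1L else
      rep(FALSE, nrow(psms))
  )
  for (r in names(fails)) {
    reason[is.na(reason) & fails[[r]]] <- r
  }
  keep <- is.na(reason)
  list(
    retained = psms[keep, , drop = FALSE],
    rejections = tibble(spectrum_id = psms$spectrum_id[!keep],
                        peptide = psms$peptide[!keep],
                        reason = reason[!keep])
  )
}

# positions where a peptide-length window of `consensus` starting at `start`
# mismatches the peptide
window_mismatches <- function(peptide, consensus, start) {
  win <- substr(consensus, start, start + nchar(peptide) - 1L)
  p <- strsplit(peptide, "")[[1]]
  w <- strsplit(win, "")[[1]]
  which(p != w)
}

# best-matching consensus window: minimal mismatch count, first position wins
best_consensus_window <- function(peptide, consensus) {
  L <- nchar(peptide)
  n <- nchar(consensus) - L + 1L
  if (n < 1) return(NULL)
  best <- NULL
  best_m <- Inf
  for (s in seq_len(n)) {
    mm <- window_mismatches(peptide, consensus, s)
    if (length(mm) < best_m) {
      best <- list(start = s, mismatches = mm)
      best_m <- length(mm)
      if (best_m == 0) break
    }
  }
  best
}

#' ORF2p false-positive rejection flags for a candidate PSM
#'
#' Computes the four review flags recommended for ORF2p searches, where
#' near-identical locus variants make artifactual "variant" peptides easy to
#' produce:
#' \describe{
#'   \item{semi_tryptic}{the peptide is not fully tryptic;}
#'   \item{deamidation_explainable}{replacing D with N and/or E with Q at the
#'     positions where the peptide differs from its best-matching consensus
#'     window yields an exact consensus substring (deamidation of N/Q produces
#'     D/E, so such a "variant" is chemically explainable);}
#'   \item{nontryptic_consensus_explainable}{the peptide is an exact substring
#'     of the consensus but no occurrence has fully tryptic boundaries there;}
#'   \item{poor_variant_fragmentation}{some position where the peptide differs
#'     from the consensus lies inside a fragmentation gap larger than 1, i.e.
#'     the variant call has no fragment-ion support.}
#' }
#'
#' @param peptide Peptide sequence.
#' @param prev_aa,next_aa Flanking residues of the PSM (`"-"` = terminus).
#' @param consensus Consensus ORF2p protein sequence.
#' @param covered_sites Logical vector of covered cleavage sites from
#'   [annotate_fragments()]; required for the `poor_variant_fragmentation`
#'   flag (skipped with a message when absent).
#' @return Character vector of set flags (possibly empty).
#' @export
orf2_rejection_flags <- function(peptide, prev_aa, next_aa, consensus,
                                 covered_sites = NULL) {
  assert_that(nzchar(consensus), "`consensus` must be non-empty")
  flags <- character()
  if (tryptic_status(peptide, prev_aa, next_aa) != "full") {
    flags <- c(flags, "semi_tryptic")
  }

  L <- nchar(peptide)
  best <- best_consensus_window(peptide, consensus)

  if (!is.null(best) && length(best$mismatches) > 0) {
    # scan all windows for one whose mismatches are all D<-N / E<-Q
    n <- nchar(consensus) - L + 1L
    pep <- strsplit(peptide, "")[[1]]
    for (s in seq_len(n)) {
      mm <- window_mismatches(peptide, consensus, s)
      if (length(mm) == 0) next
      win <- strsplit(substr(consensus, s, s + L - 1L), "")[[1]]
      if (all((pep[mm] == "D" & win[mm] == "N") | (pep[mm] == "E" & win[mm] == "Q"))) {
        flags <- c(flags, "deamidation_explainable")
        break
      }
    }
  }

  occ <- gregexpr(peptide, consensus, fixed = TRUE)[[1]]
  if (occ[1] != -1) {
    boundary_tryptic <- map_lgl(as.integer(occ), function(s) {
      prev_c <- if (s == 1) "-" else substr(consensus, s - 1, s - 1)
      next_c <- if (s + L - 1L == nchar(consensus)) "-" else
        substr(consensus, s + L, s + L)
      tryptic_status(peptide, prev_c, next_c) == "full"
    })
    if (!any(boundary_tryptic)) {
      flags <- c(flags, "nontryptic_consensus_explainable")
    }
  }

  if (!is.null(best) && length(best$mismatches) > 0) {
    if (is.null(covered_sites)) {
      inform("`covered_sites` not supplied; skipping the poor_variant_fragmentation flag")
    } else {
      assert_that(length(covered_sites) == L - 1,
                  "`covered_sites` must have length nchar(peptide) - 1")
      in_gap <- rep(FALSE, L)
      r <- rle(!covered_sites)
      pos <- cumsum(c(1L, r$lengths))
      for (k in seq_along(r$lengths)) {
        if (r$values[k]) {
          s1 <- pos[k]
          s2 <- pos[k] + r$lengths[k] - 1L
          in_gap[s1:(s2 + 1L)] <- TRUE  # residues spanned by an uncovered run
        }
      }
      if (any(in_gap[best$mismatches])) {
        flags <- c(flags, "poor_variant_fragmentation")
      }
    }
  }
  flags
}

# pairwise Spearman over jointly observed samples; NA when fewer than 3 pairs
pairwise_spearman <- function(quant_matrix) {
  p <- nrow(quant_matrix)
  rho <- matrix(NA_real_, p, p, dimnames = list(rownames(quant_matrix),
                                                rownames(quant_matrix)))
  undefined <- character()
  for (i in seq_len(p)) {
    rho[i, i] <- 1
    for (j in seq_len(p)[-seq_len(i)]) {
      both <- !is.na(quant_matrix[i, ]) & !is.na(quant_matrix[j, ])
      if (sum(both) < 3) {
        undefined <- c(undefined, paste(rownames(quant_matrix)[c(i, j)], collapse = "/"))
      } else {
        rho[i, j] <- rho[j, i] <- suppressWarnings(
          cor(quant_matrix[i, both], quant_matrix[j, both], method = "spearman"))
      }
    }
  }
  if (length(undefined) > 0) {
    inform(paste0("Spearman undefined (fewer than 3 paired observations), treated as below threshold: ",
                  paste(head(undefined, 5), collapse = ", ")))
  }
  rho
}

#' Select the mutually correlated peptide set
#'
#' Finds the largest set of peptides (size at least 2) in which every pair has
#' Spearman correlation of at least `threshold` over their jointly observed
#' samples -- a maximum clique on the correlation graph. Ties between maximum
#' cliques are broken by higher mean pairwise correlation, then
#' lexicographically. Exact clique enumeration is used up to 20 peptides;
#' above that a greedy search (highest-degree seed, best-improvement growth)
#' takes over.
#'
#' @param quant Tibble with a `peptide` column followed by one numeric column
#'   per sample (NA = not observed).
#' @param threshold Pairwise correlation threshold (default 0.6).
#' @param exact_limit Largest peptide count for exact clique search.
#' @return Character vector of selected peptide identifiers (empty when no
#'   qualifying pair exists).
#' @export
select_correlated_peptides <- function(quant, threshold = 0.6, exact_limit = 20L) {
  assert_that("peptide" %in% names(quant), "`quant` needs a `peptide` column")
  m <- as.matrix(quant[setdiff(names(quant), "peptide")])
  rownames(m) <- quant$peptide
  assert_that(all(rowSums(!is.na(m)) >= 1), "every peptide needs at least one quantity")
  if (nrow(m) < 2) return(character())
  rho <- pairwise_spearman(m)
  adj <- !is.na(rho) & rho >= threshold
  diag(adj) <- FALSE

  mean_rho <- function(members) {
    sub <- rho[members, members, drop = FALSE]
    mean(sub[upper.tri(sub)])
  }

  if (nrow(m) <= exact_limit) {
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    cliques <- igraph::largest_cliques(g)
    cliques <- map(cliques, ~ sort(names(.x)))
    cliques <- cliques[lengths(cliques) >= 2]
    if (length(cliques) == 0) return(character())
    scores <- map_dbl(cliques, mean_rho)
    best <- cliques[scores == max(scores)]
    keys <- map_chr(best, paste, collapse = "\r")
    best[[order(keys)[1]]]
  } else {
    deg <- rowSums(adj)
    members <- rownames(m)[which.max(deg)]
    repeat {
      cand <- rownames(m)[map_lgl(rownames(m), function(v) {
        !(v %in% members) && all(adj[v, members])
      })]
      if (length(cand) == 0) break
      gains <- map_dbl(cand, ~ mean_rho(c(members, .x)))
      members <- c(members, cand[which.max(gains)])
    }
    if (length(members) < 2) character() else sort(members)
  }
}

#' Peptide-by-sample detection (presence) matrix
#'
#' One row per peptide, one logical column per sample; an entry is TRUE when
#' at least one retained PSM supports that peptide in that sample (duplicate
#' detections are idempotent). Peptides are ordered by their first position in
#' `reference` when supplied (the order used for presence heatmaps), otherwise
#' by first appearance; samples keep the given order.
#'
#' @param psms Tibble with `peptide` and `sample` columns (typically the
#'   `retained` element of [filter_psms()], joined with sample labels).
#' @param samples Character vector of sample labels defining column order.
#' @param reference Optional reference protein used to order the peptide rows.
#' @return Tibble: `peptide` plus one logical column per sample.
#' @export
presence_matrix <- function(psms, samples, reference = NULL) {
  assert_that(all(c("peptide", "sample") %in% names(psms)),
              "`psms` must carry `peptide` and `sample`")
  peptides <- unique(psms$peptide)
  if (!is.null(reference)) {
    pos <- map_int(peptides, ~ as.integer(regexpr(.x, reference, fixed = TRUE)))
    peptides <- peptides[order(ifelse(pos < 0, Inf, pos), peptides)]
  }
  out <- tibble(peptide = peptides)
  for (s in samples) {
    seen <- unique(psms$peptide[psms$sample == s])
    out[[s]] <- peptides %in% seen
  }
  out
}
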