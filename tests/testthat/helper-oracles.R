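# Independent brute-force oracles. These deliberately share no code with the
# package: plain loops, no vectorized shortcuts.

# longest stretch of sequence with no fragment evidence, scanned site by site
oracle_max_gap <- function(covered) {
  best <- 0L
  run <- 0L
  for (s in seq_along(covered)) {
    if (covered[s]) {
      run <- 0L
    } else {
      run <- run + 1L
      if (run > best) best <- run
    }
  }
  best + 1L
}

# exhaustive search for the largest mutually-correlated peptide set
oracle_best_correlated_set <- function(rho, threshold) {
  peptides <- rownames(rho)
  n <- length(peptides)
  best <- character(0)
  best_score <- -Inf
  for (mask in seq_len(2^n - 1)) {
    members <- peptides[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    if (length(members) < 2) next
    sub <- rho[members, members]
    vals <- sub[upper.tri(sub)]
    if (any(is.na(vals)) || any(vals < threshold)) next
    score <- mean(vals)
    replace <- length(members) > length(best) ||
      (length(members) == length(best) && score > best_score + 1e-12) ||
      (length(members) == length(best) && abs(score - best_score) <= 1e-12 &&
         paste(sort(members), collapse = "\r") < paste(sort(best), collapse = "\r"))
    if (replace) {
      best <- members
      best_score <- score
    }
  }
  sort(best)
}

oracle_spearman <- function(x, y) {
  both <- !is.na(x) & !is.na(y)
  if (sum(both) < 3) return(NA_real_)
  suppressWarnings(stats::cor(rank(x[both]), rank(y[both])))
}

oracle_rho_matrix <- function(quant) {
  m <- as.matrix(quant[setdiff(names(quant), "peptide")])
  rownames(m) <- quant$peptide
  p <- nrow(m)
  rho <- matrix(NA_real_, p, p, dimnames = list(rownames(m), rownames(m)))
  for (i in 1:p) for (j in 1:p) rho[i, j] <- if (i == j) 1 else
    oracle_spearman(m[i, ], m[j, ])
  rho
}

# rule (a) then rule (b), peptides in lexicographic order
oracle_orthogonalize <- function(support, divergence) {
  peps <- sort(unique(support$peptide))
  retained <- character(0)
  for (p in peps) {
    sup <- support$locus_id[support$peptide == p]
    if (length(unique(sup)) == 1) retained <- c(retained, sup[1])
  }
  retained <- sort(unique(retained))
  reps <- character(0)
  for (p in peps) {
    sup <- unique(support$locus_id[support$peptide == p])
    if (length(intersect(sup, c(retained, reps))) == 0) {
      d <- divergence[sup]
      cand <- sort(sup[d == max(d)])
      reps <- c(reps, cand[1])
    }
  }
  # drop representatives that became redundant once later ones were added
  for (r in reps) {
    rest <- setdiff(c(retained, reps), r)
    still_covered <- TRUE
    for (p in peps) {
      sup <- unique(support$locus_id[support$peptide == p])
      if (length(intersect(sup, rest)) == 0) still_covered <- FALSE
    }
    if (still_covered) reps <- setdiff(reps, r)
  }
  sort(unique(c(retained, reps)))
}

oracle_hamming <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  stopifnot(length(av) == length(bv))
  sum(av != bv)
}

# Welch t-test from the textbook formula
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  t_stat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t_stat, df = df, p = 2 * stats::pt(-abs(t_stat), df))
}

random_peptide <- function(len) {
  paste(sample(names(retroproteo:::AA_MONO), len, replace = TRUE), collapse = "")
}

# spectrum made of an exact subset of the 1+ b/y ladder
ladder_spectrum <- function(peptide, keep_b = integer(0), keep_y = integer(0),
                            intensity = 1) {
  ions <- fragment_ions(peptide, charges = 1L)
  sel <- (ions$type == "b" & ions$index %in% keep_b) |
    (ions$type == "y" & ions$index %in% keep_y)
  tibble::tibble(mz = sort(ions$mz[sel]), intensity = intensity)
}
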