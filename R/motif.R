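# ---- degenerate-pattern plumbing -------------------------------------------

#' Parse a degenerate motif pattern
#'
#' Accepts either IUPAC notation (`"AWGTAAAT"`) or bracket notation
#' (`"A[A/T]GTAAAT"`) and returns the per-position sets of allowed bases.
#'
#' @param pattern a single pattern string.
#' @return list of character vectors, one per position.
#' @export
parse_motif <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1)
  map <- strsplit(Biostrings::IUPAC_CODE_MAP, "")
  sets <- list()
  chars <- strsplit(pattern, "")[[1]]
  i <- 1
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- which(chars == "]" & seq_along(chars) > i)[1]
      if (is.na(j)) stop("unclosed '[' in pattern: ", pattern, call. = FALSE)
      alts <- setdiff(chars[(i + 1):(j - 1)], "/")
      if (!all(alts %in% c("A", "C", "G", "T")))
        stop("bracket groups may only contain A/C/G/T: ", pattern,
             call. = FALSE)
      sets[[length(sets) + 1]] <- sort(unique(alts))
      i <- j + 1
    } else {
      ch <- toupper(ch)
      if (!ch %in% names(map))
        stop("invalid IUPAC code '", ch, "' in pattern: ", pattern,
             call. = FALSE)
      sets[[length(sets) + 1]] <- sort(map[[ch]])
      i <- i + 1
    }
  }
  sets
}

# inverse of parse_motif, IUPAC form
pattern_to_iupac <- function(sets) {
  rev_map <- stats::setNames(
    names(Biostrings::IUPAC_CODE_MAP),
    vapply(strsplit(Biostrings::IUPAC_CODE_MAP, ""),
           function(b) paste(sort(b), collapse = ""), character(1)))
  paste(vapply(sets, function(s)
    rev_map[[paste(sort(s), collapse = "")]], character(1)), collapse = "")
}

# bracket form, as printed in over-representation tables
pattern_to_bracket <- function(sets) {
  paste(vapply(sets, function(s) {
    if (length(s) == 1) s else paste0("[", paste(s, collapse = "/"), "]")
  }, character(1)), collapse = "")
}

# all concrete instantiations of a pattern
pattern_variants <- function(sets) {
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  apply(grid[, rev(seq_along(sets)), drop = FALSE], 1, paste, collapse = "")
}

revcomp_pattern <- function(sets) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  lapply(rev(sets), function(s) sort(unname(comp[s])))
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

as_dnastringset <- function(sequences) {
  if (inherits(sequences, "DNAStringSet")) sequences
  else Biostrings::DNAStringSet(sequences)
}

# ---- scanning --------------------------------------------------------------

#' Count degenerate-motif matches per sequence
#'
#' Counts, for each sequence, the start positions at which any concrete
#' variant of the pattern matches on the forward or reverse-complement
#' strand; a start position matching on both strands is counted once.
#'
#' @param pattern degenerate pattern (IUPAC or bracket notation), length
#'   `k`.
#' @param sequences a `DNAStringSet` or character vector (ACGT/N).
#' @param k required pattern length (default 8, the survey's motif width);
#'   `NULL` disables the length check.
#' @return integer vector of hit counts, one per sequence.
#' @export
scan_motif <- function(pattern, sequences, k = 8) {
  sets <- parse_motif(pattern)
  if (!is.null(k) && length(sets) != k)
    stop("pattern must have length ", k, ", got ", length(sets),
         call. = FALSE)
  seqs <- as_dnastringset(sequences)
  fwd <- Biostrings::DNAString(pattern_to_iupac(sets))
  rev <- Biostrings::DNAString(pattern_to_iupac(revcomp_pattern(sets)))
  hits_f <- Biostrings::vmatchPattern(fwd, seqs, fixed = FALSE)
  hits_r <- Biostrings::vmatchPattern(rev, seqs, fixed = FALSE)
  counts <- vapply(seq_along(seqs), function(i) {
    length(union(BiocGenerics::start(hits_f[[i]]),
                 BiocGenerics::start(hits_r[[i]])))
  }, integer(1))
  stats::setNames(counts, names(seqs))
}

# unique k-mers present in one sequence, either strand (character scalar in)
seq_kmer_set <- function(x, k) {
  both <- c(x, reverse_complement(x))
  kmers <- unlist(lapply(both, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1), k:n)
  }))
  unique(kmers[!grepl("[^ACGT]", kmers)])
}

# ---- over-representation test ---------------------------------------------

# One-sided hypergeometric p for seeing >= x of K marked promoters among
# the n_t targets out of N = n_t + n_b surveyed promoters. Isolated so the
# statistic is swappable (binomial, Fisher) without touching the scan.
presence_pvalue <- function(x, K, n_t, N) {
  stats::phyper(x - 1, K, N - K, n_t, lower.tail = FALSE)
}

#' Unbiased degenerate 8-mer over-representation scan
#'
#' Enumerates every concrete 8-mer present (on either strand) in the target
#' promoter sequences, tests each word's per-promoter presence in targets
#' against the background set with a one-sided hypergeometric test, and
#' greedily merges significant words that differ at a single position into
#' degenerate patterns (at most two alternative bases per position, at most
#' `max_degenerate` degenerate positions). No prior constraint is placed on
#' motif content — only the length restriction of `k` bases — so the scan
#' returns whatever patterns are characteristic of the targets.
#'
#' @param targets,background `DNAStringSet` or character vectors of
#'   promoter sequences; the background must contain >= 10 sequences.
#' @param k word length (default 8).
#' @param alpha significance level for reporting (default 0.05).
#' @param max_degenerate maximum number of degenerate positions per merged
#'   pattern.
#' @return data frame ranked by the combined-presence p-value: pattern
#'   (bracket notation), iupac, n_variants, promoter_count (targets
#'   containing at least one variant), background_count, p (combined
#'   presence), p_min, p_max
#'   (range over the concrete variants). Attributes `n_words_tested` and
#'   `n_words_significant` expose the per-word test tally for calibration
#'   checks.
#' @export
enumerate_and_test <- function(targets, background, k = 8, alpha = 0.05,
                               max_degenerate = 4) {
  t_seqs <- as.character(as_dnastringset(targets))
  b_seqs <- as.character(as_dnastringset(background))
  if (length(t_seqs) == 0) stop("no target sequences", call. = FALSE)
  if (length(b_seqs) < 10)
    stop("background must contain >= 10 sequences (unstable frequencies)",
         call. = FALSE)
  n_t <- length(t_seqs)
  n_b <- length(b_seqs)
  N <- n_t + n_b

  t_sets <- lapply(t_seqs, seq_kmer_set, k = k)
  b_sets <- lapply(b_seqs, seq_kmer_set, k = k)
  t_tab <- table(unlist(t_sets, use.names = FALSE))
  b_tab <- table(unlist(b_sets, use.names = FALSE))

  words <- names(t_tab)                       # candidates seen in targets
  # presence is strand-symmetric, so a word and its reverse complement are
  # the same motif: keep the lexicographically smaller representative
  words <- words[words <= reverse_complement(words)]
  t_tab <- t_tab[words]
  x <- as.integer(t_tab)
  bcnt <- as.integer(b_tab[words])
  bcnt[is.na(bcnt)] <- 0L
  p <- presence_pvalue(x, x + bcnt, n_t, N)
  n_tested <- length(words)
  sig <- which(p < alpha & x / n_t > bcnt / n_b)
  n_sig <- sum(p < alpha)

  empty <- data.frame(pattern = character(0), iupac = character(0),
                      n_variants = integer(0), promoter_count = integer(0),
                      background_count = integer(0), p = numeric(0),
                      p_min = numeric(0), p_max = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(sig) == 0)
    return(structure(empty, n_words_tested = n_tested,
                     n_words_significant = n_sig))

  ord <- sig[order(p[sig])]
  cand_words <- words[ord]
  cand_p <- p[ord]
  used <- logical(length(cand_words))
  word_chars <- strsplit(cand_words, "")

  motifs <- list()
  for (i in seq_along(cand_words)) {
    if (used[i]) next
    used[i] <- TRUE
    sets <- as.list(word_chars[[i]])
    members <- cand_words[i]
    repeat {
      merged_any <- FALSE
      n_deg <- sum(lengths(sets) > 1)
      for (j in seq_along(cand_words)) {
        if (used[j]) next
        wj <- word_chars[[j]]
        mism <- which(!mapply(function(b, s) b %in% s, wj, sets))
        if (length(mism) == 1 && length(sets[[mism]]) == 1 &&
            (n_deg < max_degenerate)) {
          sets[[mism]] <- sort(c(sets[[mism]], wj[mism]))
          used[j] <- TRUE
          members <- c(members, cand_words[j])
          merged_any <- TRUE
          n_deg <- sum(lengths(sets) > 1)
        }
      }
      if (!merged_any) break
    }
    variants <- pattern_variants(sets)
    t_hit <- vapply(t_sets, function(s) any(variants %in% s), logical(1))
    b_hit <- vapply(b_sets, function(s) any(variants %in% s), logical(1))
    xm <- sum(t_hit)
    Km <- xm + sum(b_hit)
    vp <- cand_p[match(members, cand_words)]
    motifs[[length(motifs) + 1]] <- data.frame(
      pattern = pattern_to_bracket(sets),
      iupac = pattern_to_iupac(sets),
      n_variants = length(variants),
      promoter_count = xm,
      background_count = sum(b_hit),
      p = presence_pvalue(xm, Km, n_t, N),
      p_min = min(vp), p_max = max(vp),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, motifs)
  out <- out[order(out$p, out$p_min), ]
  rownames(out) <- NULL
  structure(out, n_words_tested = n_tested, n_words_significant = n_sig)
}

# ---- known-consensus matching ----------------------------------------------

#' Published forkhead-box binding consensus patterns
#'
#' The three established FOX/FOXP binding motifs, as IUPAC strings.
#'
#' @return named character vector `RYMAAYA`, `TATTTRT`, `AATTTGT`.
#' @export
fox_consensus <- function() {
  c(RYMAAYA = "RYMAAYA", TATTTRT = "TATTTRT", AATTTGT = "AATTTGT")
}

#' Match a degenerate motif against known consensus patterns
#'
#' Evaluates every gapless alignment of the shorter pattern inside the
#' longer one, on both strands of the motif. A position *contains* the
#' motif when the motif's allowed bases are a subset of the consensus
#' bases; it *overlaps* when the two sets intersect. The match is
#' `"complete"` when some alignment has every overlapping consensus
#' position contained (every concrete motif variant then instantiates the
#' consensus across that window), `"partial"` when the best alignment has
#' at least `min_partial` overlapping positions, `"none"` otherwise.
#'
#' @param motif a degenerate pattern (IUPAC or bracket notation).
#' @param consensus named character vector of consensus patterns (default
#'   [fox_consensus()]).
#' @param min_partial minimum matching positions for a partial call.
#' @return data frame: consensus, match (`complete`/`partial`/`none`),
#'   n_match (best alignment's matching positions), strand. Attribute
#'   `"overall"` carries the best category across all consensus patterns.
#' @export
match_known <- function(motif, consensus = fox_consensus(),
                        min_partial = 6) {
  m_sets <- parse_motif(motif)
  rows <- lapply(seq_along(consensus), function(ci) {
    c_sets <- parse_motif(consensus[[ci]])
    best <- list(match = "none", n = 0L, strand = "+")
    for (strand in c("+", "-")) {
      ms <- if (strand == "+") m_sets else revcomp_pattern(m_sets)
      short <- if (length(ms) <= length(c_sets)) ms else c_sets
      long <- if (length(ms) <= length(c_sets)) c_sets else ms
      for (off in 0:(length(long) - length(short))) {
        contained <- overlap <- 0L
        for (q in seq_along(short)) {
          a <- short[[q]]
          b <- long[[q + off]]
          inner <- if (identical(short, ms)) a else b   # motif-side set
          outer <- if (identical(short, ms)) b else a   # consensus-side set
          if (all(inner %in% outer)) contained <- contained + 1L
          if (length(intersect(a, b)) > 0) overlap <- overlap + 1L
        }
        cat_here <- if (contained == length(short)) "complete"
                    else if (overlap >= min_partial) "partial"
                    else "none"
        rank <- c(none = 0, partial = 1, complete = 2)
        if (rank[cat_here] > rank[best$match] ||
            (rank[cat_here] == rank[best$match] && overlap > best$n)) {
          best <- list(match = cat_here, n = overlap, strand = strand)
        }
      }
    }
    data.frame(consensus = names(consensus)[ci] %||% consensus[[ci]],
               match = best$match, n_match = best$n, strand = best$strand,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rank <- c(none = 0, partial = 1, complete = 2)
  structure(out, overall = out$match[which.max(rank[out$match])])
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a
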