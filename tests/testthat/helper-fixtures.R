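# Fixtures and independent oracles used across the suite. Oracles here stay
# deliberately naive (enumeration, doubled-string search, brute-force scans)
# and never call the package code paths they check.

rand_dna <- function(L) paste(sample(c("A", "C", "G", "T"), L, TRUE),
                              collapse = "")

circpos <- function(x, L) ((x - 1L) %% L) + 1L

# all positions covered by a 1-based inclusive circular interval
enum_interval <- function(start, end, L) {
  if (start <= end) seq.int(start, end) else c(seq.int(start, L), seq_len(end))
}

# circular substring via the doubled-string trick
circ_substring <- function(residues, start, len) {
  substr(paste0(residues, residues), start, start + len - 1L)
}

oracle_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# D-loop gene models on a 16,569 bp circle: MDL1 15954..576 (heavy),
# MDL1AS 16024..407 (light)
mdl_genes <- function() {
  list(gene_model("MDL1", start = 15954, end = 576, strand = "heavy"),
       gene_model("MDL1AS", start = 16024, end = 407, strand = "light"))
}

# brute-force circular mapper: scan every start on both strands, same
# tie-break contract as the mapper (fewest mismatches, smallest start,
# heavy before light -- "heavy" < "light" alphabetically)
oracle_map_all <- function(seqs, residues, L, max_mismatch) {
  m <- nchar(seqs[1L])
  stopifnot(all(nchar(seqs) == m))
  doubled <- utf8ToInt(paste0(residues, residues))
  idx <- outer(0:(m - 1L), seq_len(L), "+")
  refmat <- matrix(doubled[idx], nrow = m)
  revs <- oracle_revcomp(seqs)
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    rows <- NULL
    for (strand in c("heavy", "light")) {
      qi <- utf8ToInt(if (strand == "heavy") seqs[i] else revs[i])
      mm <- colSums(refmat != qi)
      rows <- rbind(rows, data.frame(start = seq_len(L), strand = strand,
                                     mm = mm))
    }
    rows <- rows[order(rows$mm, rows$start, rows$strand), ]
    b <- rows[1L, ]
    out[[i]] <- if (b$mm <= max_mismatch) {
      data.frame(mapped = TRUE, start = b$start, strand = b$strand,
                 mm = as.integer(b$mm))
    } else {
      data.frame(mapped = FALSE, start = NA_integer_,
                 strand = NA_character_, mm = NA_integer_)
    }
  }
  do.call(rbind, out)
}

# textbook Benjamini-Hochberg by explicit threshold search (no cummin trick):
# adj_i = min over j with p_j >= p_i of p_j * n / rank_j, using the step-up
# definition applied literally
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  r <- p[ord] * n / seq_len(n)
  adj <- numeric(n)
  for (i in seq_len(n)) adj[i] <- min(1, min(r[i:n]))
  out <- numeric(n)
  out[ord] <- adj
  out
}

# brute-force AUC by pair enumeration with half credit for ties
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# exhaustive Youden search over observed thresholds under ">= c is positive";
# ties broken by higher specificity then lower cutoff
oracle_youden <- function(scores, labels) {
  cand <- sort(unique(scores))
  best <- NULL
  for (c in cand) {
    sens <- mean(scores[labels] >= c)
    spec <- mean(scores[!labels] < c)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-15 ||
        (abs(j - best$j) <= 1e-15 &&
         (spec > best$spec + 1e-15 ||
          (abs(spec - best$spec) <= 1e-15 && c < best$cutoff)))) {
      best <- list(cutoff = c, j = j, sens = sens, spec = spec)
    }
  }
  best
}

# fraction of transcript start positions whose genomic footprint straddles
# the L|1 junction, by explicit position enumeration
oracle_junction_fraction <- function(gene, read_length, L) {
  iv <- gene$interval
  len <- length(enum_interval(iv$start, iv$end, L))
  n_pos <- len - read_length + 1L
  straddle <- 0L
  for (t in seq_len(n_pos)) {
    if (iv$strand == "heavy") {
      gpos <- circpos(iv$start + t - 1L + 0:(read_length - 1L), L)
    } else {
      gpos <- circpos(iv$start + len - t - (read_length - 1L):0, L)
    }
    if (all(c(1L, L) %in% gpos)) straddle <- straddle + 1L
  }
  straddle / n_pos
}
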