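# Strand-aware short-read simulator for circular transcript models.
# Single-end reads, uniform fragment starts, substitution errors only,
# constant quality 'I' -- the simplest model that exercises junction logic.

#' Read-simulation configuration
#'
#' @param read_length Read length in bp (>= 20, the mapper seed length).
#' @param n_reads Either a single number (total reads, split across genes
#'   multinomially according to `abundance`) or a named integer vector of
#'   exact per-gene read counts.
#' @param abundance Named relative abundances per gene (only used when
#'   `n_reads` is scalar; default uniform).
#' @param error_rate Per-base substitution probability in `[0, 0.1]`.
#' @param strandedness Library protocol: `"reverse"` (read is the reverse
#'   complement of the transcript, typical dUTP protocols), `"forward"`
#'   (read matches the transcript), or `"unstranded"` (random per read).
#' @param seed Integer RNG seed; recorded in the truth table.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(read_length = 100L, n_reads = 1000L, abundance = NULL,
                       error_rate = 0.001,
                       strandedness = c("reverse", "forward", "unstranded"),
                       seed = 1L) {
  read_length <- as.integer(read_length)
  if (read_length < 20L) stop("configuration error: read_length must be >= 20")
  if (error_rate < 0 || error_rate > 0.1)
    stop("configuration error: error_rate outside [0, 0.1]")
  structure(list(read_length = read_length, n_reads = n_reads,
                 abundance = abundance, error_rate = error_rate,
                 strandedness = match.arg(strandedness),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# apply substitution errors in place; returns character vector of reads
.apply_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  m <- nchar(seqs[1L])
  hit <- matrix(stats::runif(length(seqs) * m) < rate, nrow = length(seqs))
  idx <- which(rowSums(hit) > 0L)
  for (i in idx) {
    s <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    for (j in which(hit[i, ])) {
      s[j] <- sample(setdiff(bases, s[j]), 1L)
    }
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

#' Simulate reads from circular transcript models
#'
#' Start positions are uniform over each gene's transcript positions
#' (circular-aware: a transcript that wraps the junction is sampled across
#' it). Light-strand genes are drawn from the reverse complement of the
#' heavy-strand region. The truth table records, per read, the source gene,
#' the canonical 1-based heavy-strand start of its genomic footprint, and the
#' transcript strand; truth fields never appear in the FASTQ.
#'
#' @param genome A [circ_seq()].
#' @param genes List of [gene_model()] objects; every gene must be at least
#'   `read_length` long.
#' @param cfg A [sim_config()].
#' @return Object of class `read_sim`: list with `reads` (data frame
#'   `read_id`, `sequence`, `qualities`), `truth` (data frame `read_id`,
#'   `gene`, `start`, `strand`) and `config`.
#' @export
simulate_reads <- function(genome, genes, cfg = sim_config()) {
  stopifnot(inherits(genome, "circ_seq"), inherits(cfg, "sim_config"))
  L <- genome$length
  m <- cfg$read_length
  ids <- vapply(genes, `[[`, "", "gene_id")
  if (anyDuplicated(ids)) stop("input error: duplicate gene ids")
  lens <- vapply(genes, function(g) circular_length(g$interval, L), integer(1L))
  if (any(lens < m))
    stop("simulation error: gene shorter than read_length: ",
         paste(ids[lens < m], collapse = ", "))

  set.seed(cfg$seed)
  if (length(cfg$n_reads) == 1L && is.null(names(cfg$n_reads))) {
    ab <- cfg$abundance
    if (is.null(ab)) ab <- stats::setNames(rep(1, length(ids)), ids)
    draw <- sample(ids, as.integer(cfg$n_reads), replace = TRUE,
                   prob = ab[ids])
    n_per <- table(factor(draw, levels = ids))
  } else {
    n_per <- cfg$n_reads[ids]
    if (any(is.na(n_per)))
      stop("configuration error: n_reads must name every gene")
  }

  out <- vector("list", length(genes))
  for (k in seq_along(genes)) {
    g <- genes[[k]]
    n_g <- as.integer(n_per[[ids[k]]])
    if (n_g == 0L) next
    tx <- gene_sequence(genome, g)
    len <- lens[k]
    t0 <- sample.int(len - m + 1L, n_g, replace = TRUE)
    sense <- substring(tx, t0, t0 + m - 1L)
    # canonical heavy-strand start of the genomic footprint
    gs <- g$interval$start
    start <- if (g$interval$strand == "heavy") circ_pos(gs + t0 - 1L, L)
             else circ_pos(gs + len - t0 - m + 1L, L)
    sequenced <- switch(cfg$strandedness,
      forward = sense,
      reverse = revcomp(sense),
      unstranded = {
        flip <- stats::runif(n_g) < 0.5
        s <- sense; s[flip] <- revcomp(sense[flip]); s
      })
    out[[k]] <- data.frame(
      read_id = sprintf("%s:%06d", ids[k], seq_len(n_g)),
      sequence = sequenced,
      gene = ids[k], start = start, strand = g$interval$strand)
  }
  all <- do.call(rbind, out)
  if (is.null(all))
    all <- data.frame(read_id = character(0), sequence = character(0),
                      gene = character(0), start = integer(0),
                      strand = character(0))
  all$sequence <- .apply_errors(all$sequence, cfg$error_rate)
  structure(list(
    reads = data.frame(read_id = all$read_id, sequence = all$sequence,
                       qualities = strrep("I", nchar(all$sequence))),
    truth = data.frame(read_id = all$read_id, gene = all$gene,
                       start = all$start, strand = all$strand),
    config = cfg), class = "read_sim")
}

#' @export
print.read_sim <- function(x, ...) {
  cat(sprintf("<read_sim> %d reads, %d bp, %s protocol, seed %d\n",
              nrow(x$reads), x$config$read_length, x$config$strandedness,
              x$config$seed))
  invisible(x)
}
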