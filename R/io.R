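# File formats. FASTA goes through Biostrings; GTF is hand-rolled because the
# wrap-around two-exon encoding/reassembly is specific to circular gene
# models; FASTQ is the plain 4-line format.

#' Read a FASTA file into circular sequences
#'
#' @param path FASTA file.
#' @return Named list of [circ_seq()] objects (names = sequence ids; the id
#'   is the first whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  out <- lapply(seq_along(ss), function(i) circ_seq(ids[i], as.character(ss[[i]])))
  names(out) <- ids
  out
}

#' Write circular sequences to FASTA
#'
#' @param seqs A [circ_seq()] or list of them.
#' @param path Output file; sequence lines wrapped at 60 columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "circ_seq")) seqs <- list(seqs)
  dss <- Biostrings::DNAStringSet(vapply(seqs, `[[`, "", "residues"))
  names(dss) <- vapply(seqs, `[[`, "", "seq_id")
  Biostrings::writeXStringSet(dss, path, width = 60L)
  invisible(path)
}

#' Write gene models to GTF
#'
#' 1-based inclusive, tab-separated. GTF forbids `end < start`, so a
#' wrap-around gene is serialized as two exon lines of a single transcript
#' (`start..L` and `1..end`); [read_gtf()] reassembles them.
#'
#' @param genes List of [gene_model()] objects.
#' @param path Output file.
#' @param seqname Reference sequence name for column 1.
#' @param L Circle length (needed to split wrapping features).
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path, seqname, L) {
  rows <- lapply(genes, function(g) {
    iv <- g$interval
    check_interval(iv, L)
    strand <- if (iv$strand == "light") "-" else "+"
    attrs <- sprintf('gene_id "%s"; transcript_id "%s.t1"; gene_biotype "%s";',
                     g$gene_id, g$gene_id, g$biotype)
    if (iv$wraps) {
      data.frame(seqname = seqname, source = "mitocirc", feature = "exon",
                 start = c(iv$start, 1L), end = c(L, iv$end), score = ".",
                 strand = strand, frame = ".", attrs = attrs)
    } else {
      data.frame(seqname = seqname, source = "mitocirc", feature = "exon",
                 start = iv$start, end = iv$end, score = ".", strand = strand,
                 frame = ".", attrs = attrs)
    }
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from GTF
#'
#' Exon lines sharing a transcript id are reassembled; a two-exon transcript
#' whose exons abut positions `L` and 1 becomes a single wrap-around gene
#' model with `start > end`.
#'
#' @param path GTF file.
#' @param L Circle length, used to recognize the junction-split encoding.
#' @return List of [gene_model()] objects.
#' @export
read_gtf <- function(path, L) {
  tab <- utils::read.table(path, sep = "\t", quote = "", comment.char = "#",
                           stringsAsFactors = FALSE,
                           col.names = c("seqname", "source", "feature",
                                         "start", "end", "score", "strand",
                                         "frame", "attrs"))
  tab <- tab[tab$feature == "exon", , drop = FALSE]
  if (nrow(tab) == 0L) stop("format error: no exon records in ", path)
  gene_id <- sub('.*gene_id "([^"]*)".*', "\\1", tab$attrs)
  tx_id <- sub('.*transcript_id "([^"]*)".*', "\\1", tab$attrs)
  biotype <- ifelse(grepl('gene_biotype "', tab$attrs),
                    sub('.*gene_biotype "([^"]*)".*', "\\1", tab$attrs),
                    "lncRNA")
  out <- lapply(split(seq_len(nrow(tab)), tx_id), function(idx) {
    sub <- tab[idx, , drop = FALSE]
    strand <- if (sub$strand[1L] == "-") "light" else "heavy"
    gid <- gene_id[idx][1L]
    bt <- biotype[idx][1L]
    if (nrow(sub) == 1L) {
      gene_model(gid, start = sub$start, end = sub$end, strand = strand,
                 biotype = bt)
    } else if (nrow(sub) == 2L) {
      hi <- sub[sub$end == L, , drop = FALSE]   # exon touching position L
      lo <- sub[sub$start == 1L, , drop = FALSE] # exon touching position 1
      if (nrow(hi) != 1L || nrow(lo) != 1L)
        stop("format error: multi-exon transcript '", gid,
             "' is not a junction-split model")
      gene_model(gid, start = hi$start, end = lo$end, strand = strand,
                 biotype = bt)
    } else {
      stop("format error: transcript '", gid, "' has >2 exons; only ",
           "single-exon and junction-split models are supported")
    }
  })
  names(out) <- NULL
  out[order(vapply(out, `[[`, "", "gene_id"))]
}

#' Write reads to FASTQ (phred+33, 4-line records)
#'
#' @param reads Data frame with columns `read_id`, `sequence`, `qualities`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads) == 0L) { writeLines(character(0), path); return(invisible(path)) }
  bad <- which(nchar(reads$sequence) != nchar(reads$qualities))
  if (length(bad))
    stop("format error: sequence/quality length mismatch for record ", bad[1L])
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                           "+", reads$qualities))
  writeLines(lines, path)
  invisible(path)
}

#' Read a 4-line FASTQ file
#'
#' @param path FASTQ file.
#' @return Data frame with columns `read_id`, `sequence`, `qualities`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n %% 4L != 0L)
    stop("format error: truncated FASTQ record at line ", n)
  if (n == 0L)
    return(data.frame(read_id = character(0), sequence = character(0),
                      qualities = character(0)))
  i1 <- seq(1L, n, by = 4L)
  bad <- which(!startsWith(lines[i1], "@"))
  if (length(bad))
    stop("format error: missing '@' header at line ", i1[bad[1L]])
  bad <- which(!startsWith(lines[i1 + 2L], "+"))
  if (length(bad))
    stop("format error: missing '+' separator at line ", i1[bad[1L]] + 2L)
  data.frame(read_id = sub("^@", "", lines[i1]),
             sequence = lines[i1 + 1L],
             qualities = lines[i1 + 3L])
}

#' Write a simulation truth table
#'
#' Tab-separated with header `read_id  gene  start  strand`; the simulation
#' seed is recorded as a leading `# seed:` comment line.
#'
#' @param truth Data frame with columns `read_id`, `gene`, `start`, `strand`.
#' @param path Output file.
#' @param seed Integer seed to record in the header.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path, seed = NA_integer_) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed: %s", seed), con)
  utils::write.table(truth[, c("read_id", "gene", "start", "strand")], con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a simulation truth table
#' @param path File written by [write_truth()].
#' @return Data frame with columns `read_id`, `gene`, `start`, `strand`.
#' @export
read_truth <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write a cohort table to TSV
#' @param cohort Data frame from [simulate_cohort()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table from TSV
#' @param path File written by [write_cohort()].
#' @return Data frame.
#' @export
read_cohort <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
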