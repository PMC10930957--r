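# Circular coordinate algebra. Coordinates are 1-based inclusive throughout
# (GTF convention); position L is adjacent to position 1. An interval that
# crosses the linearization junction is encoded with start > end.

# canonical circular position: maps any integer onto [1, L]
circ_pos <- function(x, L) ((as.integer(x) - 1L) %% as.integer(L)) + 1L

.strands <- c("heavy", "light")

#' Circular nucleotide sequence
#'
#' Container for a circular reference such as the 16,569 bp human
#' mitochondrial genome. The sequence is stored linearly but all operations
#' treat position `length` as adjacent to position 1.
#'
#' @param seq_id Single sequence identifier.
#' @param residues Nucleotide string over the alphabet ACGTN
#'   (case-insensitive; stored uppercase).
#' @return An object of class `circ_seq` with fields `seq_id`, `residues`
#'   and `length`.
#' @export
#' @examples
#' mt <- circ_seq("chrM_toy", "ACGTACGTAC")
#' mt$length
circ_seq <- function(seq_id, residues) {
  stopifnot(is.character(seq_id), length(seq_id) == 1L,
            is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (nchar(residues) < 1L) stop("input error: empty sequence")
  if (grepl("[^ACGTN]", residues))
    stop("alphabet error: residues outside ACGTN in '", seq_id, "'")
  structure(list(seq_id = seq_id, residues = residues,
                 length = nchar(residues)),
            class = "circ_seq")
}

#' @export
print.circ_seq <- function(x, ...) {
  cat(sprintf("<circ_seq> %s (%d bp, circular)\n", x$seq_id, x$length))
  invisible(x)
}

#' Stranded circular interval
#'
#' 1-based inclusive interval on a circular sequence. `start > end` encodes a
#' feature that wraps across the junction between position L and position 1
#' (e.g. MDL1, 15954..576 on the heavy strand of the mitogenome). Light-strand
#' features store heavy-strand coordinates plus the strand flag; their
#' sequence is obtained by reverse complement.
#'
#' @param start,end 1-based positions.
#' @param strand `"heavy"` (+) or `"light"` (-).
#' @return Object of class `circ_interval` with fields `start`, `end`,
#'   `strand` and the derived flag `wraps` (`TRUE` iff `start > end`).
#' @export
#' @examples
#' circ_interval(15954, 576, "heavy")  # wraps the junction
circ_interval <- function(start, end, strand = "heavy") {
  start <- as.integer(start); end <- as.integer(end)
  strand <- match.arg(strand, .strands)
  if (is.na(start) || is.na(end) || start < 1L || end < 1L)
    stop("coordinate error: positions must be >= 1")
  structure(list(start = start, end = end, strand = strand,
                 wraps = start > end),
            class = "circ_interval")
}

# validate an interval against a concrete genome length
check_interval <- function(interval, L) {
  stopifnot(inherits(interval, "circ_interval"))
  if (interval$start > L || interval$end > L)
    stop("coordinate error: interval outside [1, ", L, "]")
  invisible(interval)
}

#' Gene model on a circular sequence
#'
#' @param gene_id Unique gene identifier.
#' @param interval A [circ_interval()], or `NULL` if `start`/`end`/`strand`
#'   are given directly.
#' @param start,end,strand Convenience alternative to `interval`.
#' @param biotype Gene biotype (default `"lncRNA"`).
#' @return Object of class `gene_model`.
#' @export
#' @examples
#' gene_model("MDL1", start = 15954, end = 576, strand = "heavy")
gene_model <- function(gene_id, interval = NULL, start = NULL, end = NULL,
                       strand = "heavy", biotype = "lncRNA") {
  if (is.null(interval)) interval <- circ_interval(start, end, strand)
  stopifnot(is.character(gene_id), length(gene_id) == 1L, nzchar(gene_id))
  structure(list(gene_id = gene_id, interval = interval, biotype = biotype),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  iv <- x$interval
  cat(sprintf("<gene_model> %s %d..%d (%s%s) [%s]\n", x$gene_id, iv$start,
              iv$end, iv$strand, if (iv$wraps) ", wraps" else "", x$biotype))
  invisible(x)
}

#' Circular span length of an interval
#'
#' Number of bases covered by a (possibly wrapping) 1-based inclusive
#' interval on a circle of length `L`.
#'
#' @param interval A [circ_interval()].
#' @param L Circle length in bp.
#' @return Integer span in `[1, L]`.
#' @export
#' @examples
#' circular_length(circ_interval(15954, 576), 16569)  # 1192
circular_length <- function(interval, L) {
  L <- as.integer(L)
  check_interval(interval, L)
  if (interval$wraps) (L - interval$start + 1L) + interval$end
  else interval$end - interval$start + 1L
}

#' Rotation map between original and re-origined coordinates
#'
#' Bijection on `[1, L]` induced by rewriting the circle to start at
#' `new_origin` (the original position that becomes position 1).
#'
#' @param L Circle length.
#' @param new_origin Original position that becomes position 1.
#' @return Object of class `rotation_map`.
#' @seealso [lift_position()], [invert_rotation()], [rotate_reference()]
#' @export
rotation_map <- function(L, new_origin) {
  L <- as.integer(L); new_origin <- as.integer(new_origin)
  if (L < 1L) stop("input error: L must be >= 1")
  if (new_origin < 1L || new_origin > L)
    stop("coordinate error: new_origin outside [1, L]")
  structure(list(length = L, new_origin = new_origin),
            class = "rotation_map")
}

#' Lift a position through a rotation map
#'
#' @param pos Vector of 1-based positions in `[1, L]`.
#' @param map A [rotation_map()].
#' @return Lifted positions; `lift_position(p, map)` with
#'   `map$new_origin == p` returns 1.
#' @export
#' @examples
#' lift_position(2, rotation_map(10, 9))  # 4
lift_position <- function(pos, map) {
  stopifnot(inherits(map, "rotation_map"))
  pos <- as.integer(pos)
  if (any(is.na(pos)) || any(pos < 1L) || any(pos > map$length))
    stop("coordinate error: position outside [1, ", map$length, "]")
  ((pos - map$new_origin) %% map$length) + 1L
}

#' Inverse of a rotation map
#'
#' @param map A [rotation_map()].
#' @return The rotation map whose composition with `map` is the identity.
#' @export
invert_rotation <- function(map) {
  stopifnot(inherits(map, "rotation_map"))
  rotation_map(map$length, ((1L - map$new_origin) %% map$length) + 1L)
}

#' Rotate a circular reference to a new origin
#'
#' Rewrites the sequence so the original `new_origin` becomes position 1.
#' This is the re-origination device that makes junction-spanning genes
#' (MDL1/MDL1AS across the heavy-strand replication origin) contiguous in the
#' linear representation.
#'
#' @param seq A [circ_seq()].
#' @param new_origin Original position that becomes position 1.
#' @return List with elements `seq` (rotated [circ_seq()], same `seq_id`) and
#'   `map` (the [rotation_map()] lifting original to rotated coordinates).
#' @export
#' @examples
#' rotate_reference(circ_seq("t", "ACGT"), 3)$seq$residues  # "GTAC"
rotate_reference <- function(seq, new_origin) {
  stopifnot(inherits(seq, "circ_seq"))
  L <- seq$length
  map <- rotation_map(L, new_origin)
  res <- if (map$new_origin == 1L) seq$residues
         else paste0(substr(seq$residues, map$new_origin, L),
                     substr(seq$residues, 1L, map$new_origin - 1L))
  list(seq = circ_seq(seq$seq_id, res), map = map)
}

#' Lift a gene model through a rotation map
#'
#' Start and end are lifted independently and the wrap flag is recomputed;
#' circular length and strand are preserved exactly. A non-wrapping gene whose
#' span contains the new origin becomes wrapping, and vice versa.
#'
#' @param gene A [gene_model()].
#' @param map A [rotation_map()].
#' @return The lifted [gene_model()].
#' @export
lift_gene <- function(gene, map) {
  stopifnot(inherits(gene, "gene_model"))
  iv <- gene$interval
  check_interval(iv, map$length)
  gene$interval <- circ_interval(lift_position(iv$start, map),
                                 lift_position(iv$end, map), iv$strand)
  gene
}

#' Lift a list of gene models
#' @param genes List of [gene_model()] objects.
#' @param map A [rotation_map()].
#' @return List of lifted gene models.
#' @export
lift_genes <- function(genes, map) lapply(genes, lift_gene, map = map)

#' Junction-padded linear reference
#'
#' Linearizes a circular sequence and appends its first `pad_k` residues at
#' the end, so that every read of length `<= pad_k + 1` that spans the
#' junction still has a contiguous exact placement. An alignment starting at
#' `s > L` is reported at its canonical start `s - L`.
#'
#' @param seq A [circ_seq()] (possibly rotated).
#' @param pad_k Pad length in `[0, L]`; `pad_k = read_length - 1` is the
#'   minimal pad that makes every junction-spanning read mappable exactly once.
#' @return Object of class `extended_ref` with fields `base`, `pad_k`,
#'   `linear`.
#' @export
#' @examples
#' build_extended_reference(circ_seq("t", "ACGT"), 2)$linear  # "ACGTAC"
build_extended_reference <- function(seq, pad_k) {
  stopifnot(inherits(seq, "circ_seq"))
  pad_k <- as.integer(pad_k)
  if (is.na(pad_k) || pad_k < 0L || pad_k > seq$length)
    stop("configuration error: pad_k must be in [0, L]")
  linear <- if (pad_k == 0L) seq$residues
            else paste0(seq$residues, substr(seq$residues, 1L, pad_k))
  structure(list(base = seq, pad_k = pad_k, linear = linear),
            class = "extended_ref")
}

#' Extract the heavy-strand sequence of a circular region
#'
#' @param seq A [circ_seq()].
#' @param interval A [circ_interval()]; wrapping intervals are read across
#'   the junction.
#' @return Nucleotide string of length `circular_length(interval, L)` as read
#'   on the heavy strand (the interval's own strand flag is ignored here; see
#'   [gene_sequence()] for strand-aware extraction).
#' @export
extract_region <- function(seq, interval) {
  stopifnot(inherits(seq, "circ_seq"))
  check_interval(interval, seq$length)
  r <- seq$residues
  if (interval$wraps)
    paste0(substr(r, interval$start, seq$length), substr(r, 1L, interval$end))
  else substr(r, interval$start, interval$end)
}

#' Reverse complement of a circular region
#'
#' Returns the reverse complement of the (possibly wrapping) region read on
#' the heavy strand -- i.e. the light-strand sequence of the region, as used
#' for light-strand transcripts such as MDL1AS.
#'
#' @inheritParams extract_region
#' @return Nucleotide string of the same circular length.
#' @export
reverse_complement_region <- function(seq, interval) {
  revcomp(extract_region(seq, interval))
}

#' Transcript sequence of a gene model
#'
#' Heavy-strand genes read forward; light-strand genes are
#' reverse-complemented.
#'
#' @param seq A [circ_seq()].
#' @param gene A [gene_model()].
#' @return The transcript (sense) sequence.
#' @export
gene_sequence <- function(seq, gene) {
  stopifnot(inherits(gene, "gene_model"))
  if (gene$interval$strand == "light")
    reverse_complement_region(seq, gene$interval)
  else extract_region(seq, gene$interval)
}

#' Reverse complement of nucleotide strings
#'
#' @param x Character vector over ACGTN.
#' @return Reverse complement of each element.
#' @export
revcomp <- function(x) {
  if (any(grepl("[^ACGTN]", x)))
    stop("alphabet error: residues outside ACGTN")
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# does a read footprint (canonical start, length m, original coordinates)
# straddle the junction between position L and position 1?
#' Does a read footprint span the linearization junction?
#'
#' @param start Canonical 1-based start position(s) in `[1, L]`.
#' @param read_length Read length in bp.
#' @param L Circle length.
#' @return Logical vector: `TRUE` where the footprint covers both position
#'   `L` and position 1.
#' @export
spans_junction <- function(start, read_length, L) {
  as.integer(start) + as.integer(read_length) - 1L > L
}
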