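#' Local protein alignment with affine gaps
#'
#' Smith-Waterman local alignment under BLOSUM62 with BLASTP-default gap
#' penalties (open 11, extend 1; a gap of length L costs 11 + L). This is the
#' desk-scale sequence-comparison primitive standing in for translated/protein
#' BLAST searches throughout the pipeline; precomputed BLAST tabular hits can
#' be substituted via [parse_blast_tab()].
#'
#' @param query,subject protein sequences: `AAString`, plain strings, or
#'   named length-1 character vectors (the name becomes the sequence id).
#' @param substitution_matrix scoring matrix (default BLOSUM62).
#' @param gap_open,gap_extend affine gap penalties, positive numbers.
#' @param karlin_k,karlin_lambda Karlin-Altschul constants used for the bit
#'   score (ungapped BLOSUM62 defaults).
#' @return A one-row data.frame with columns `qseqid`, `sseqid`, `raw_score`,
#'   `bitscore`, `pident`, `qstart`, `qend`, `sstart`, `send`, `frame`
#'   (0 for protein queries). A hit with no positive-scoring cell has
#'   `raw_score` 0 and zero-width spans (`start` 1, `end` 0).
#' @examples
#' smith_waterman("MKV", "MKV")$raw_score  # 5 + 5 + 4 = 14
#' @export
smith_waterman <- function(query, subject,
                           substitution_matrix = NULL,
                           gap_open = 11, gap_extend = 1,
                           karlin_k = 0.041, karlin_lambda = 0.267) {
  qid <- if (!is.null(names(query))) names(query)[1] else "query"
  sid <- if (!is.null(names(subject))) names(subject)[1] else "subject"
  q <- Biostrings::AAString(as.character(query)[1])
  s <- Biostrings::AAString(as.character(subject)[1])
  if (length(q) == 0L || length(s) == 0L) stop("empty sequence")
  if (is.null(substitution_matrix)) substitution_matrix <- blosum62()

  aln <- Biostrings::pairwiseAlignment(
    q, s, type = "local", substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  sc <- Biostrings::score(aln)
  if (sc <= 0) {
    return(data.frame(qseqid = qid, sseqid = sid, raw_score = 0,
                      bitscore = raw_to_bit(0, karlin_k, karlin_lambda),
                      pident = 0,
                      qstart = 1L, qend = 0L, sstart = 1L, send = 0L,
                      frame = 0L, stringsAsFactors = FALSE))
  }
  pr <- Biostrings::pattern(aln)
  sr <- Biostrings::subject(aln)
  data.frame(
    qseqid = qid, sseqid = sid,
    raw_score = sc,
    bitscore = raw_to_bit(sc, karlin_k, karlin_lambda),
    pident = Biostrings::pid(aln),
    qstart = Biostrings::start(pr), qend = Biostrings::end(pr),
    sstart = Biostrings::start(sr), send = Biostrings::end(sr),
    frame = 0L, stringsAsFactors = FALSE)
}

# bit score from a raw score: (lambda * S - ln K) / ln 2
raw_to_bit <- function(score, k = 0.041, lambda = 0.267) {
  (lambda * score - log(k)) / log(2)
}

# vectorised local-alignment raw scores of many patterns vs one subject
batch_scores <- function(patterns, subject, substitution_matrix = NULL,
                         gap_open = 11, gap_extend = 1) {
  if (is.null(substitution_matrix)) substitution_matrix <- blosum62()
  empty <- Biostrings::width(patterns) == 0L
  out <- numeric(length(patterns))
  if (any(!empty)) {
    out[!empty] <- Biostrings::pairwiseAlignment(
      patterns[!empty], subject, type = "local",
      substitutionMatrix = substitution_matrix,
      gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE)
  }
  pmax(out, 0)
}

#' Karlin-Altschul expectation value
#'
#' Expected number of chance local alignments scoring at least `score` in a
#' search of a query of `query_length` residues against `db_residues` total
#' database residues: `E = K * m * n * exp(-lambda * S)`. The default
#' constants are the ungapped BLOSUM62 values; they approximate BLAST's
#' gapped statistics closely enough to apply the conventional 1e-10
#' significance threshold used by the pipeline.
#'
#' @param score raw alignment score(s).
#' @param query_length query length in residues (positive).
#' @param db_residues total residues in the searched database (positive).
#' @param k,lambda Karlin-Altschul parameters, both positive.
#' @return E-value(s), nonnegative and strictly decreasing in `score`.
#' @export
evalue <- function(score, query_length, db_residues,
                   k = 0.041, lambda = 0.267) {
  if (any(query_length <= 0) || any(db_residues <= 0)) {
    stop("query_length and db_residues must be positive")
  }
  if (k <= 0 || lambda <= 0) stop("k and lambda must be positive")
  k * query_length * db_residues * exp(-lambda * score)
}

#' Six-frame translation of a nucleotide sequence
#'
#' Translates the three forward frames and the three frames of the reverse
#' complement under the standard genetic code. Stop codons are emitted as
#' `*` and frames are not split at stops: downstream alignment is local, so
#' stops simply score negatively.
#'
#' @param record a nucleotide sequence (`DNAString` or string).
#' @return An `AAStringSet` of six frames named `"+1" "+2" "+3" "-1" "-2"
#'   "-3"`. Sequences shorter than 3 nt yield six empty frames with a
#'   warning.
#' @examples
#' as.character(six_frame_translate("ATGAAA")[["+1"]])  # "MK"
#' @export
six_frame_translate <- function(record) {
  x <- Biostrings::DNAString(as.character(record)[1])
  frame_names <- c("+1", "+2", "+3", "-1", "-2", "-3")
  if (length(x) < 3L) {
    warning("sequence shorter than 3 nt: all frames empty")
    out <- Biostrings::AAStringSet(rep("", 6))
    names(out) <- frame_names
    return(out)
  }
  rc <- Biostrings::reverseComplement(x)
  one_frame <- function(s, off) {
    n <- length(s) - off
    n <- n - n %% 3L
    if (n < 3L) return("")
    as.character(Biostrings::translate(
      Biostrings::subseq(s, start = off + 1L, width = n),
      no.init.codon = TRUE, if.fuzzy.codon = "X"))
  }
  out <- Biostrings::AAStringSet(c(
    one_frame(x, 0L), one_frame(x, 1L), one_frame(x, 2L),
    one_frame(rc, 0L), one_frame(rc, 1L), one_frame(rc, 2L)))
  names(out) <- frame_names
  out
}

#' Parse BLAST tabular (outfmt 6) output
#'
#' Adapter for externally computed hits: reads the 12-column tabular dialect
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`). The raw score is not present in this format, so
#' `bitscore` is authoritative downstream.
#'
#' @param x path to a tabular file, or a character vector of its lines.
#' @return A data.frame with the 12 standard columns (zero rows for empty
#'   input).
#' @export
parse_blast_tab <- function(x) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  lines <- as_lines(x)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  numeric_cols <- cols[3:12]
  if (length(lines) == 0L) {
    out <- data.frame(qseqid = character(0), sseqid = character(0),
                      stringsAsFactors = FALSE)
    for (cc in numeric_cols) out[[cc]] <- numeric(0)
    return(out[cols])
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, integer(1))
  bad <- which(nf != 12L)
  if (length(bad)) {
    stop(sprintf("parse error at line %d: expected 12 tab-delimited columns, found %d",
                 bad[1], nf[bad[1]]))
  }
  m <- do.call(rbind, fields)
  out <- data.frame(qseqid = m[, 1], sseqid = m[, 2], stringsAsFactors = FALSE)
  for (i in 3:12) out[[cols[i]]] <- as.numeric(m[, i])
  out[cols]
}

#' Write hits in BLAST tabular (outfmt 6) format
#'
#' @param hits a data.frame of hits as returned by [parse_blast_tab()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_blast_tab <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Keep the best hit per group
#'
#' Per group (by default per query), retains the hit with the highest bit
#' score; ties break by lower e-value (when present), then ascending subject
#' id. Matched genes with the highest similarity are treated as orthologs
#' downstream, so exactly one hit survives per group.
#'
#' @param hits a data.frame with at least `bitscore`, `sseqid` and the
#'   grouping column; an `evalue` column is used for tie-breaks if present.
#' @param group_by name of the grouping column (default `"qseqid"`).
#' @return The filtered data.frame, one row per group, in ascending group
#'   order.
#' @export
best_hits <- function(hits, group_by = "qseqid") {
  if (nrow(hits) == 0L) return(hits)
  stopifnot(group_by %in% names(hits), "bitscore" %in% names(hits))
  ev <- if ("evalue" %in% names(hits)) hits$evalue else rep(0, nrow(hits))
  ord <- order(hits[[group_by]], -hits$bitscore, ev, hits$sseqid)
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(hits[[group_by]]), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
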