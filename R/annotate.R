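#' Read a gene-to-term annotation table
#'
#' Two-column TSV: `gene_id<TAB>term[,term...]`, used both for GO terms and
#' for pathway ids. Duplicate gene rows are merged by union; empty term
#' strings are dropped.
#'
#' @param x path to a TSV file or a character vector of its lines.
#' @return A named list mapping gene id to a character vector of term ids.
#' @export
read_annotation_table <- function(x) {
  lines <- as_lines(x)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L) {
      stop(sprintf("malformed annotation row at line %d: expected 2 tab-delimited columns", i))
    }
    terms <- strsplit(f[2], ",", fixed = TRUE)[[1]]
    terms <- trimws(terms)
    terms <- terms[nzchar(terms)]
    out[[f[1]]] <- union(out[[f[1]]], terms)
  }
  out
}

#' Write a gene-to-term annotation table
#'
#' @param ann named list mapping gene id to term ids.
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_annotation_table <- function(ann, path) {
  writeLines(sprintf("%s\t%s", names(ann),
                     vapply(ann, paste, "", collapse = ",")), path)
  invisible(path)
}

#' Transfer ortholog annotations to query contigs
#'
#' For each selected reference species, every contig is translated in six
#' frames and searched against the species' proteome; the best hit passing
#' the e-value threshold nominates that species' ortholog, and the
#' ortholog's GO terms and pathway ids are attached to the contig. Contigs
#' with no passing hit in any species remain unannotated.
#'
#' @param contigs nucleotide contigs (`DNAStringSet`, FASTA path or named
#'   character vector).
#' @param proteomes named list of reference proteomes (species id ->
#'   `AAStringSet` / FASTA path).
#' @param annotations named list (by species id) of lists with elements
#'   `go` and `pathway`, each a gene-to-terms map as returned by
#'   [read_annotation_table()]. A species missing from `annotations` is
#'   aligned anyway (sequence-only annotation) with a warning.
#' @param evalue_max best-hit acceptance threshold (default `1e-10`).
#' @return An `annotation_map`: list with `hits` (data.frame `contig_id`,
#'   `species_id`, `gene_id`, `raw_score`, `bitscore`, `evalue`), per-hit
#'   term lists `go` and `pathway` (list columns of `hits`), `contigs`
#'   (all contig ids), and empty `merged_go` / `merged_pathway` slots filled
#'   by [merge_annotations()].
#' @export
annotate_contigs <- function(contigs, proteomes, annotations = list(),
                             evalue_max = 1e-10) {
  ctg <- as_dna_set(contigs)
  if (length(ctg) == 0L) stop("no contigs supplied")
  if (length(proteomes) == 0L || is.null(names(proteomes))) {
    stop("proteomes must be a nonempty named list")
  }
  if (is.null(names(ctg))) names(ctg) <- paste0("contig_", seq_along(ctg))

  frames <- vector("list", length(ctg))
  for (i in seq_along(ctg)) {
    frames[[i]] <- as.character(suppressWarnings(six_frame_translate(ctg[[i]])))
  }
  all_frames <- Biostrings::AAStringSet(unlist(frames, use.names = FALSE))
  contig_of <- rep(seq_along(ctg), each = 6L)
  frame_w <- Biostrings::width(all_frames)

  rows <- list()
  for (sp in names(proteomes)) {
    prot <- as_aa_set(proteomes[[sp]])
    if (length(prot) == 0L) next
    ann <- annotations[[sp]]
    if (is.null(ann)) {
      warning(sprintf("no annotation table for species %s: sequence-only annotation", sp))
      ann <- list(go = list(), pathway = list())
    }
    db <- sum(Biostrings::width(prot))
    smat <- matrix(0, nrow = length(all_frames), ncol = length(prot))
    for (j in seq_along(prot)) {
      smat[, j] <- batch_scores(all_frames, prot[[j]])
    }
    for (i in seq_along(ctg)) {
      sub <- smat[contig_of == i, , drop = FALSE]
      best <- arrayInd(which.max(sub), dim(sub))
      sc <- sub[best[1], best[2]]
      if (sc <= 0) next
      m <- frame_w[which(contig_of == i)[best[1]]]
      if (m == 0L) next
      e <- evalue(sc, m, db)
      if (e >= evalue_max) next
      gene <- names(prot)[best[2]]
      rows[[length(rows) + 1L]] <- list(
        contig_id = names(ctg)[i], species_id = sp, gene_id = gene,
        raw_score = sc, bitscore = raw_to_bit(sc), evalue = e,
        go = if (is.null(ann$go[[gene]])) character(0) else ann$go[[gene]],
        pathway = if (is.null(ann$pathway[[gene]])) character(0)
                  else ann$pathway[[gene]])
    }
  }

  hits <- data.frame(
    contig_id = vapply(rows, `[[`, "", "contig_id"),
    species_id = vapply(rows, `[[`, "", "species_id"),
    gene_id = vapply(rows, `[[`, "", "gene_id"),
    raw_score = vapply(rows, `[[`, 0, "raw_score"),
    bitscore = vapply(rows, `[[`, 0, "bitscore"),
    evalue = vapply(rows, `[[`, 0, "evalue"),
    stringsAsFactors = FALSE)
  hits$go <- lapply(rows, `[[`, "go")
  hits$pathway <- lapply(rows, `[[`, "pathway")

  structure(list(hits = hits, contigs = names(ctg),
                 merged_go = NULL, merged_pathway = NULL),
            class = "annotation_map")
}

#' Merge annotations across reference species
#'
#' Computes, per contig, the union of GO terms and of pathway ids
#' contributed by all reference species. Adding a reference species can only
#' grow these merged sets (and the count of annotated contigs), which is the
#' rationale for annotating with multiple species rather than one.
#'
#' @param map an `annotation_map` from [annotate_contigs()].
#' @return The map with `merged_go` and `merged_pathway` filled: named lists
#'   contig id -> character vector of term ids (only contigs with at least
#'   one term of that kind appear).
#' @export
merge_annotations <- function(map) {
  stopifnot(inherits(map, "annotation_map"))
  merge_kind <- function(kind) {
    out <- list()
    h <- map$hits
    for (r in seq_len(nrow(h))) {
      terms <- h[[kind]][[r]]
      if (length(terms)) {
        out[[h$contig_id[r]]] <- union(out[[h$contig_id[r]]], terms)
      }
    }
    out
  }
  map$merged_go <- merge_kind("go")
  map$merged_pathway <- merge_kind("pathway")
  map
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("annotation_map: %d contigs, %d hits across %d species\n",
              length(x$contigs), nrow(x$hits),
              length(unique(x$hits$species_id))))
  if (!is.null(x$merged_go)) {
    cat(sprintf("  merged: %d contigs with GO terms, %d with pathways\n",
                length(x$merged_go), length(x$merged_pathway)))
  }
  invisible(x)
}

#' Hypergeometric upper-tail probability
#'
#' Probability of observing at least `k` annotated genes among `n` drawn
#' genes, when `K` of the `N` background genes carry the annotation:
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. This is the
#' over-representation test used for GO and pathway enrichment.
#'
#' @param k observed annotated genes in the drawn set (`0 <= k <= min(K, n)`).
#' @param K background genes carrying the annotation (`K <= N`).
#' @param n size of the drawn (differentially expressed) set (`n <= N`).
#' @param N background size.
#' @return The upper-tail probability, in (0, 1]; `k = 0` gives exactly 1.
#' @examples
#' hypergeom_pvalue(5, 5, 5, 10)  # 1 / choose(10, 5)
#' @export
hypergeom_pvalue <- function(k, K, n, N) {
  if (any(k < 0) || any(K < 0) || any(n < 0) || any(N < 0) ||
      any(K > N) || any(n > N) || any(k > pmin(K, n))) {
    stop("require 0 <= k <= min(K, n), K <= N, n <= N")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' GO / pathway enrichment of a differentially expressed gene list
#'
#' Tests each annotation term for over-representation in the DE set against
#' the annotated background using the hypergeometric upper tail. The
#' background universe is the set of contigs carrying at least one merged
#' annotation of the requested kind. Raw p-values below `alpha` are flagged
#' `significant` (the pipeline's headline convention); Benjamini-Hochberg
#' adjusted p-values and a `significant_bh` flag are reported alongside
#' because many terms are tested.
#'
#' @param de_ids contig ids of the differentially expressed set. Ids outside
#'   the annotated background are dropped with a warning.
#' @param map a merged `annotation_map` ([merge_annotations()] is applied if
#'   needed).
#' @param kind `"GO"` or `"pathway"`.
#' @param alpha raw-p significance level (default 0.05).
#' @return A data.frame sorted by ascending `p`: `term_id`, `kind`, `k`,
#'   `K`, `n`, `N`, `p`, `p_adj`, `significant`, `significant_bh`. Only
#'   terms with `k >= 1` are reported.
#' @export
enrich <- function(de_ids, map, kind = c("GO", "pathway"), alpha = 0.05) {
  kind <- match.arg(kind)
  stopifnot(inherits(map, "annotation_map"))
  if (length(de_ids) == 0L) stop("empty DE list")
  if (is.null(map$merged_go)) map <- merge_annotations(map)
  sets <- if (kind == "GO") map$merged_go else map$merged_pathway
  background <- names(sets)
  N <- length(background)
  if (N == 0L) stop(sprintf("no contigs carry %s annotations", kind))
  de <- intersect(unique(de_ids), background)
  if (length(de) < length(unique(de_ids))) {
    warning(sprintf("%d DE id(s) outside the annotated background dropped",
                    length(unique(de_ids)) - length(de)))
  }
  if (length(de) == 0L) stop("no DE ids in the annotated background")
  n <- length(de)

  term_bg <- table(unlist(sets, use.names = FALSE))
  term_de <- table(unlist(sets[de], use.names = FALSE))
  terms <- names(term_de)  # k >= 1 only
  k <- as.integer(term_de[terms])
  K <- as.integer(term_bg[terms])
  p <- hypergeom_pvalue(k, K, n, N)
  p_adj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(term_id = terms, kind = kind, k = k, K = K,
                    n = n, N = N, p = p, p_adj = p_adj,
                    significant = p < alpha,
                    significant_bh = p_adj < alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term_id), ]
  rownames(out) <- NULL
  out
}
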