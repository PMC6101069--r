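# Independent oracles and small fixture builders used across the suite.

AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
        "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_peptide <- function(n) paste(sample(AA, n, replace = TRUE), collapse = "")

# Quadratic-space Gotoh local alignment, coded independently of the package:
# affine gaps where a gap of length L costs open + L * ext.
sw_oracle <- function(q, s, mat = NULL, open = 11, ext = 1) {
  if (is.null(mat)) {
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
    mat <- e$BLOSUM62
  }
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  n <- length(qc); m <- length(sc)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - (open + ext), E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - (open + ext), F[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[qc[i - 1], sc[j - 1]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# exact one-codon-at-a-time translation using the standard genetic code table
translate_oracle <- function(nt) {
  code <- Biostrings::GENETIC_CODE
  n <- nchar(nt) - nchar(nt) %% 3
  if (n < 3) return("")
  paste(vapply(seq(1, n, by = 3),
               function(i) unname(code[substr(nt, i, i + 2)]), ""),
        collapse = "")
}

# deterministic back-translation: first codon of each amino acid
back_translate <- function(aa) {
  code <- Biostrings::GENETIC_CODE
  by_aa <- split(names(code), code)
  paste(vapply(strsplit(aa, "")[[1]], function(a) by_aa[[a]][1], ""),
        collapse = "")
}

revcomp <- function(nt) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
}

# independent lineage/LCA computation by climbing the parent map directly
lca_depth_oracle <- function(tree, a, b) {
  climb <- function(x) {
    path <- x
    while (x != tree$root) {
      x <- tree$nodes$parent[tree$nodes$id == x]
      path <- c(x, path)
    }
    path
  }
  pa <- climb(a); pb <- climb(b)
  k <- min(length(pa), length(pb))
  as.integer(sum(cumprod(pa[seq_len(k)] == pb[seq_len(k)])) - 1)
}

# hypergeometric upper tail from the factorial pmf, summed over the support
hyper_upper_oracle <- function(k, K, n, N) {
  pmf <- function(x) {
    exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n))
  }
  support <- max(0, n - (N - K)):min(K, n)
  sum(pmf(support[support >= k]))
}

# flatten-and-correlate Mantel oracle on the shared-species upper triangles
mantel_oracle <- function(x, y) {
  sx <- if (inherits(x, "uco_dist")) x$species else rownames(x)
  sy <- if (inherits(y, "uco_dist")) y$species else rownames(y)
  vx <- if (inherits(x, "uco_dist")) x$values else x
  vy <- if (inherits(y, "uco_dist")) y$values else y
  shared <- sort(intersect(sx, sy))
  a <- vx[shared, shared][upper.tri(diag(length(shared)))]
  b <- vy[shared, shared][upper.tri(diag(length(shared)))]
  stats::cor(a, b)
}

random_sym_matrix <- function(n, species = paste0("sp", seq_len(n))) {
  m <- matrix(0, n, n, dimnames = list(species, species))
  m[upper.tri(m)] <- runif(n * (n - 1) / 2)
  m + t(m)
}

# a minimal annotation_map wrapping per-contig term sets directly
make_annmap <- function(go_sets, pathway_sets = list()) {
  hits <- data.frame(contig_id = names(go_sets),
                     species_id = "s1",
                     gene_id = names(go_sets),
                     raw_score = 100, bitscore = 50, evalue = 1e-20,
                     stringsAsFactors = FALSE)
  hits$go <- unname(go_sets)
  hits$pathway <- lapply(names(go_sets), function(g) {
    if (is.null(pathway_sets[[g]])) character(0) else pathway_sets[[g]]
  })
  structure(list(hits = hits, contigs = names(go_sets),
                 merged_go = NULL, merged_pathway = NULL),
            class = "annotation_map")
}

chain_tree_lines <- function(n) {
  sprintf("%d\t|\t%d\t|\t%s\t|", seq_len(n), c(1L, seq_len(n - 1L)),
          c("no rank", rep("clade", n - 1L)))
}
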