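AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Simulate a rooted taxonomy with a phylum level
#'
#' Generates a random rooted tree in which the root's children are
#' phylum-rank nodes, internal clade nodes attach below them, and species
#' leaves attach to random internal nodes. The tree serialises to taxdump
#' dialect (via [write_taxdump()]) and re-parses identically. All
#' randomness derives from `seed`.
#'
#' @param n_species number of species leaves (at least 2).
#' @param max_depth maximum node depth in edges from the root (default 6).
#' @param n_phyla number of phylum-rank children of the root (default 1).
#' @param n_internal number of internal clade nodes below the phyla
#'   (default `max(0, n_species - 2)`).
#' @param seed integer seed.
#' @param dir if non-`NULL`, also write `nodes.dmp` / `names.dmp` there.
#' @return A `taxonomy_tree`; species leaves have rank `"species"` and an
#'   attribute `species_ids` lists their taxon ids.
#' @export
simulate_taxonomy <- function(n_species, max_depth = 6L, n_phyla = 1L,
                              n_internal = max(0L, n_species - 2L),
                              seed = 1L, dir = NULL) {
  if (n_species < 2L) stop("n_species must be at least 2")
  stopifnot(max_depth >= 2L, n_phyla >= 1L)
  with_seed(seed, {
    id <- 1L
    parent <- 1L
    rank <- "no rank"
    depth <- 0L
    nxt <- 2L
    add <- function(p, r) {
      id <<- c(id, nxt)
      parent <<- c(parent, p)
      rank <<- c(rank, r)
      depth <<- c(depth, depth[match(p, id)] + 1L)
      nxt <<- nxt + 1L
    }
    for (i in seq_len(n_phyla)) add(1L, "phylum")
    for (i in seq_len(n_internal)) {
      ok <- which(rank != "species" & depth < max_depth - 1L & id != 1L)
      add(id[ok][sample.int(length(ok), 1L)], "clade")
    }
    for (i in seq_len(n_species)) {
      ok <- which(rank != "species" & depth < max_depth & id != 1L)
      add(id[ok][sample.int(length(ok), 1L)], "species")
    }
    name <- ifelse(rank == "species", paste0("species_", id),
                   ifelse(rank == "phylum", paste0("phylum_", id),
                          ifelse(id == 1L, "root", paste0("clade_", id))))
    tree <- structure(
      list(nodes = data.frame(id = id, parent = parent, rank = rank,
                              name = name, stringsAsFactors = FALSE),
           root = 1L),
      class = "taxonomy_tree")
    attr(tree, "species_ids") <- id[rank == "species"]
    if (!is.null(dir)) write_taxdump(tree, dir)
    tree
  })
}

# substitute each residue independently with probability `rate`, drawing
# replacements uniformly from the 20 standard amino acids
mutate_protein <- function(seq_chars, rate) {
  hit <- stats::runif(length(seq_chars)) < rate
  if (any(hit)) {
    seq_chars[hit] <- sample(AA20, sum(hit), replace = TRUE)
  }
  seq_chars
}

#' Simulate UCO proteomes along a taxonomy
#'
#' Draws one random ancestral protein per UCO at the root and mutates it
#' independently down every edge of the tree, so expected pairwise identity
#' between two species decays with their path distance in the tree. The
#' substitution model replaces a hit site with a uniform draw from the 20
#' amino acids; this is deliberately minimal — the pipeline only exploits
#' the ordering of identities by tree distance, not a realistic rate matrix.
#'
#' @param tree a `taxonomy_tree` (species leaves have rank `"species"`).
#' @param n_uco number of UCO genes (at least 1).
#' @param rate_per_edge per-site substitution probability per edge, in
#'   [0, 1]. Either a scalar, or a named vector keyed by taxon id giving the
#'   rate on the edge above that node (missing nodes fall back to the
#'   unnamed default, or 0).
#' @param seed integer seed.
#' @param len_range protein length range in residues (default 80-150).
#' @param dropout optional named list, species taxon id (as character) ->
#'   UCO ids to delete from that species' proteome.
#' @return A list: `uco` (the ancestral proteins, an `AAStringSet` named
#'   `UCO001`, ...; these serve as the reference UCO set), `proteomes`
#'   (named list, species id -> `AAStringSet` with ids
#'   `sp<taxid>_<ucoid>`), and `species_ids`.
#' @export
simulate_proteomes <- function(tree, n_uco, rate_per_edge = 0.02, seed = 1L,
                               len_range = c(80L, 150L), dropout = NULL) {
  stopifnot(inherits(tree, "taxonomy_tree"), n_uco >= 1L)
  if (any(rate_per_edge > 1) || any(rate_per_edge < 0)) {
    stop("rate_per_edge must lie in [0, 1]")
  }
  nd <- tree$nodes
  default_rate <- if (is.null(names(rate_per_edge))) rate_per_edge[1] else 0
  edge_rate <- function(node_id) {
    nm <- as.character(node_id)
    if (!is.null(names(rate_per_edge)) && nm %in% names(rate_per_edge)) {
      rate_per_edge[[nm]]
    } else {
      default_rate
    }
  }
  with_seed(seed, {
    uco_ids <- sprintf("UCO%03d", seq_len(n_uco))
    root_seqs <- lapply(seq_len(n_uco), function(i) {
      sample(AA20, sample(len_range[1]:len_range[2], 1L), replace = TRUE)
    })
    names(root_seqs) <- uco_ids

    seqs <- list()
    seqs[[as.character(tree$root)]] <- root_seqs
    ord <- nd$id[order(vapply(nd$id, function(i) taxon_lineage(tree, i)$depth,
                              integer(1)))]
    for (node in ord) {
      if (node == tree$root) next
      p <- nd$parent[match(node, nd$id)]
      r <- edge_rate(node)
      seqs[[as.character(node)]] <- lapply(seqs[[as.character(p)]],
                                           mutate_protein, rate = r)
    }

    species <- nd$id[nd$rank == "species"]
    proteomes <- lapply_named(as.character(species), function(sp) {
      s <- seqs[[sp]]
      keep <- setdiff(uco_ids, dropout[[sp]])
      out <- vapply(s[keep], paste, "", collapse = "")
      names(out) <- sprintf("sp%s_%s", sp, keep)
      Biostrings::AAStringSet(out)
    })
    uco <- Biostrings::AAStringSet(vapply(root_seqs, paste, "", collapse = ""))
    list(uco = uco, proteomes = proteomes,
         species_ids = as.character(species))
  })
}

#' Simulate random term annotations for a gene panel
#'
#' Assigns each gene a random draw of terms from a finite vocabulary, with
#' an optional planted term attached to a chosen subset of genes (the ground
#' truth for enrichment power checks).
#'
#' @param gene_ids character vector of gene ids.
#' @param n_terms vocabulary size (default 25).
#' @param terms_per_gene terms drawn per gene (default 3).
#' @param prefix term-id prefix: `"GO:"` style or `"ko"` style.
#' @param planted_term optional term id to plant.
#' @param planted_genes gene ids receiving the planted term.
#' @param seed integer seed.
#' @return Named list gene id -> character vector of term ids.
#' @export
simulate_annotations <- function(gene_ids, n_terms = 25L, terms_per_gene = 3L,
                                 prefix = "GO:", planted_term = NULL,
                                 planted_genes = character(0), seed = 1L) {
  vocab <- if (prefix == "GO:") {
    sprintf("GO:%07d", seq_len(n_terms))
  } else {
    sprintf("%s%05d", prefix, seq_len(n_terms))
  }
  with_seed(seed, {
    out <- lapply_named(gene_ids, function(g) {
      sample(vocab, min(terms_per_gene, n_terms))
    })
    if (!is.null(planted_term)) {
      for (g in intersect(planted_genes, gene_ids)) {
        out[[g]] <- union(out[[g]], planted_term)
      }
    }
    out
  })
}

#' Simulate an assembled transcriptome from a protein set
#'
#' Contigs are codon back-translations (uniform synonymous codon choice,
#' standard genetic code) of random fragments of the source proteins, placed
#' on a random strand. If term annotations and a planted term are supplied,
#' a differentially-expressed contig list is drawn with sampling weight
#' `fold` for contigs whose source gene carries the planted term, producing
#' a known enrichment signal.
#'
#' @param proteins source proteins (`AAStringSet` or named character
#'   vector), typically the query species' gene set.
#' @param n_contigs number of contigs.
#' @param fragment_range fragment length range in residues; fragments longer
#'   than the source protein are clipped with a warning.
#' @param seed integer seed.
#' @param gene_terms optional named list gene id -> term ids, used for DE
#'   sampling.
#' @param planted_term optional term id to enrich in the DE list.
#' @param fold sampling-weight fold change for planted-term contigs
#'   (default 5).
#' @param de_fraction fraction of contigs in the DE list (default 0.2).
#' @return A list: `contigs` (`DNAStringSet` named `contig_1`, ...),
#'   `truth` (data.frame `contig_id`, `gene_id`, `strand`, `aa_start`,
#'   `aa_end`), `de_ids` (character, possibly empty), `planted` (list with
#'   `term`, `fold`, or `NULL`).
#' @export
simulate_transcriptome <- function(proteins, n_contigs,
                                   fragment_range = c(30L, 80L), seed = 1L,
                                   gene_terms = NULL, planted_term = NULL,
                                   fold = 5, de_fraction = 0.2) {
  prot <- as_aa_set(proteins)
  stopifnot(length(prot) >= 1L, n_contigs >= 1L)
  code <- Biostrings::GENETIC_CODE
  codons_for <- split(names(code), code)  # aa -> synonymous codons

  with_seed(seed, {
    clipped <- FALSE
    rows <- vector("list", n_contigs)
    seqs <- character(n_contigs)
    for (i in seq_len(n_contigs)) {
      gi <- sample.int(length(prot), 1L)
      aa <- strsplit(as.character(prot[[gi]]), "")[[1]]
      len <- sample(fragment_range[1]:fragment_range[2], 1L)
      if (len > length(aa)) {
        clipped <- TRUE
        len <- length(aa)
      }
      start <- sample.int(length(aa) - len + 1L, 1L)
      frag <- aa[start:(start + len - 1L)]
      nt <- paste(vapply(frag, function(a) {
        cs <- codons_for[[a]]
        cs[sample.int(length(cs), 1L)]
      }, ""), collapse = "")
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-") {
        nt <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
      }
      seqs[i] <- nt
      rows[[i]] <- data.frame(contig_id = paste0("contig_", i),
                              gene_id = names(prot)[gi], strand = strand,
                              aa_start = start, aa_end = start + len - 1L,
                              stringsAsFactors = FALSE)
    }
    if (clipped) {
      warning("fragment_range exceeds some protein lengths: fragments clipped")
    }
    truth <- do.call(rbind, rows)
    contigs <- Biostrings::DNAStringSet(seqs)
    names(contigs) <- truth$contig_id

    de_ids <- character(0)
    planted <- NULL
    if (!is.null(gene_terms) && !is.null(planted_term)) {
      has_term <- vapply(truth$gene_id, function(g) {
        planted_term %in% gene_terms[[g]]
      }, logical(1))
      w <- ifelse(has_term, fold, 1)
      n_de <- max(1L, round(de_fraction * n_contigs))
      de_ids <- sample(truth$contig_id, n_de, prob = w)
      planted <- list(term = planted_term, fold = fold)
    }
    list(contigs = contigs, truth = truth, de_ids = de_ids,
         planted = planted)
  })
}

#' Generate a complete pipeline fixture with known ground truth
#'
#' Builds everything the pipeline consumes — a planted taxonomy, UCO
#' reference proteins, divergence-scaled candidate proteomes, GO/pathway
#' annotation tables, back-translated query contigs and a DE list with a
#' planted enriched term — and (optionally) writes it all to disk in the
#' formats the readers expect. The first species leaf acts as the query;
#' the remaining leaves are the candidate reference species. The truth
#' records which candidate is closest to the query in the tree (by path
#' edge count), the planted term and its fold factor.
#'
#' @param outdir directory to write files into, or `NULL` to keep
#'   everything in memory.
#' @param n_species species leaves in the taxonomy (query + candidates).
#' @param n_uco number of UCO genes.
#' @param n_contigs number of query contigs.
#' @param rate_per_edge substitution rate per edge (see
#'   [simulate_proteomes()]).
#' @param seed integer seed driving every stochastic step.
#' @return A list with `tree`, `query_id`, `candidate_ids`, `uco`,
#'   `proteomes`, `annotations` (per species: `go`, `pathway`),
#'   `contigs`, `de_ids`, `truth` (list: `closest_species`,
#'   `planted_go_term`, `fold`, `contig_truth`), and `paths` (when written).
#' @export
simulate_fixture_set <- function(outdir = NULL, n_species = 5L, n_uco = 30L,
                                 n_contigs = 120L, rate_per_edge = 0.05,
                                 seed = 1L) {
  tree <- simulate_taxonomy(n_species, seed = seed)
  species <- attr(tree, "species_ids")
  query_id <- species[1]
  candidates <- species[-1]

  sim <- simulate_proteomes(tree, n_uco, rate_per_edge = rate_per_edge,
                            seed = seed + 1L)

  # closest candidate by path distance (edge count) in the planted tree
  dq <- taxon_lineage(tree, query_id)$depth
  path_dist <- vapply(candidates, function(s) {
    dq + taxon_lineage(tree, s)$depth - 2L * lca_depth(tree, query_id, s)
  }, integer(1))
  closest <- candidates[order(path_dist, candidates)][1]

  uco_ids <- names(sim$uco)
  planted_go <- "GO:0000001"
  planted_ucos <- uco_ids[seq_len(max(1L, n_uco %/% 5L))]
  annotations <- lapply_named(as.character(species), function(sp) {
    genes <- names(sim$proteomes[[sp]])
    uco_of_gene <- sub(sprintf("^sp%s_", sp), "", genes)
    list(
      go = simulate_annotations(
        genes, prefix = "GO:", planted_term = planted_go,
        planted_genes = genes[uco_of_gene %in% planted_ucos],
        seed = seed + 2L + match(sp, as.character(species))),
      pathway = simulate_annotations(
        genes, n_terms = 15L, terms_per_gene = 2L, prefix = "ko",
        seed = seed + 100L + match(sp, as.character(species))))
  })

  qsp <- as.character(query_id)
  trx <- simulate_transcriptome(
    sim$proteomes[[qsp]], n_contigs, seed = seed + 3L,
    gene_terms = annotations[[qsp]]$go, planted_term = planted_go)

  out <- list(tree = tree, query_id = query_id,
              candidate_ids = candidates,
              uco = sim$uco,
              proteomes = sim$proteomes[as.character(candidates)],
              annotations = annotations[as.character(candidates)],
              contigs = trx$contigs, de_ids = trx$de_ids,
              truth = list(closest_species = as.character(closest),
                           planted_go_term = planted_go,
                           fold = trx$planted$fold,
                           contig_truth = trx$truth),
              seed = seed)

  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    write_taxdump(tree, outdir)
    Biostrings::writeXStringSet(sim$uco, file.path(outdir, "uco.fasta"))
    pdir <- file.path(outdir, "proteomes")
    adir <- file.path(outdir, "annotations")
    dir.create(pdir, showWarnings = FALSE)
    dir.create(adir, showWarnings = FALSE)
    for (sp in as.character(candidates)) {
      Biostrings::writeXStringSet(sim$proteomes[[sp]],
                                  file.path(pdir, paste0(sp, ".fasta")))
      write_annotation_table(annotations[[sp]]$go,
                             file.path(adir, paste0(sp, "_go.tsv")))
      write_annotation_table(annotations[[sp]]$pathway,
                             file.path(adir, paste0(sp, "_pathway.tsv")))
    }
    Biostrings::writeXStringSet(trx$contigs, file.path(outdir, "contigs.fasta"))
    writeLines(trx$de_ids, file.path(outdir, "de_list.txt"))
    jsonlite::write_json(
      list(query_id = query_id, closest_species = as.character(closest),
           planted_go_term = planted_go, seed = seed),
      file.path(outdir, "truth.json"), auto_unbox = TRUE)
    out$paths <- list(dir = outdir)
  }
  out
}
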