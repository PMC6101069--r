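#' Identify ultra-conserved orthologs in model-species proteomes
#'
#' For each candidate species, searches its proteome with every
#' ultra-conserved ortholog (UCO) protein and records the best-scoring
#' protein passing the e-value threshold. The resulting profiles hold one
#' representative protein per (species, UCO): the species-side counterpart
#' used for all later UCO comparisons. The canonical reference set contains
#' 357 single-copy genes conserved across most eukaryotes.
#'
#' @param uco_proteins UCO reference proteins: an `AAStringSet`, a FASTA
#'   path, or a named character vector.
#' @param proteomes a named list of per-species proteomes (each an
#'   `AAStringSet`, FASTA path or named character vector); names are species
#'   ids.
#' @param evalue_max identification threshold (default `1e-10`).
#' @return A named list of `uco_profile` objects, each a list with
#'   `species_id`, `entries` (data.frame `uco_id`, `protein_id`,
#'   `raw_score`, `bitscore`, `evalue`), `seqs` (representative proteins,
#'   an `AAStringSet` named by UCO id) and `completeness`.
#' @export
build_uco_profiles <- function(uco_proteins, proteomes, evalue_max = 1e-10) {
  uco <- as_aa_set(uco_proteins)
  if (length(uco) == 0L) stop("no UCO proteins supplied")
  if (length(proteomes) == 0L) stop("no proteomes supplied")
  if (is.null(names(proteomes))) stop("proteomes must be a named list")

  lapply_named(names(proteomes), function(sp) {
    prot <- as_aa_set(proteomes[[sp]])
    if (length(prot) == 0L) {
      warning(sprintf("empty proteome for species %s: completeness 0", sp))
      return(empty_profile(sp))
    }
    db <- sum(Biostrings::width(prot))
    rows <- vector("list", length(uco))
    rep_seq <- character(0)
    for (i in seq_along(uco)) {
      sc <- batch_scores(prot, uco[[i]])
      best <- which.max(sc)
      e <- evalue(sc[best], Biostrings::width(uco)[i], db)
      if (e < evalue_max) {
        rows[[i]] <- data.frame(
          uco_id = names(uco)[i],
          protein_id = names(prot)[best],
          raw_score = sc[best],
          bitscore = raw_to_bit(sc[best]),
          evalue = e, stringsAsFactors = FALSE)
        rep_seq[names(uco)[i]] <- as.character(prot[[best]])
      }
    }
    entries <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(entries)) return(empty_profile(sp))
    structure(list(species_id = sp, entries = entries,
                   seqs = Biostrings::AAStringSet(rep_seq),
                   completeness = nrow(entries)),
              class = "uco_profile")
  })
}

lapply_named <- function(nm, f) {
  out <- lapply(nm, f)
  names(out) <- nm
  out
}

empty_profile <- function(sp) {
  structure(list(species_id = sp,
                 entries = data.frame(uco_id = character(0),
                                      protein_id = character(0),
                                      raw_score = numeric(0),
                                      bitscore = numeric(0),
                                      evalue = numeric(0),
                                      stringsAsFactors = FALSE),
                 seqs = Biostrings::AAStringSet(),
                 completeness = 0L),
            class = "uco_profile")
}

#' @export
print.uco_profile <- function(x, ...) {
  cat(sprintf("uco_profile for %s: %d UCO(s) identified\n",
              x$species_id, x$completeness))
  invisible(x)
}

#' Identify UCO-bearing contigs in an assembled transcriptome
#'
#' Translates each contig in all six frames and searches every frame against
#' the UCO reference proteins (the translated-search counterpart of a
#' TBLASTN step). Each contig is assigned at most one UCO: the best
#' bit-score across all frames and UCO proteins; contigs with no hit passing
#' the threshold are omitted.
#'
#' @param contigs nucleotide contigs (`DNAStringSet`, FASTA path, or named
#'   character vector).
#' @param uco_proteins UCO reference proteins (see [build_uco_profiles()]).
#' @param evalue_max assignment threshold (default `1e-10`).
#' @return A data.frame with one row per assigned contig: `contig_id`,
#'   `uco_id`, `frame` (in -3..-1, 1..3), `raw_score`, `bitscore`, `evalue`.
#' @export
find_uco_contigs <- function(contigs, uco_proteins, evalue_max = 1e-10) {
  ctg <- as_dna_set(contigs)
  uco <- as_aa_set(uco_proteins)
  if (length(ctg) == 0L || length(uco) == 0L) {
    stop("contigs and uco_proteins must be nonempty")
  }
  if (is.null(names(ctg))) names(ctg) <- paste0("contig_", seq_along(ctg))

  frame_levels <- c(1L, 2L, 3L, -1L, -2L, -3L)
  frames <- vector("list", length(ctg))
  for (i in seq_along(ctg)) {
    fr <- suppressWarnings(six_frame_translate(ctg[[i]]))
    frames[[i]] <- as.character(fr)
  }
  all_frames <- Biostrings::AAStringSet(unlist(frames, use.names = FALSE))
  frame_of <- rep(frame_levels, times = length(ctg))
  contig_of <- rep(seq_along(ctg), each = 6L)

  db <- sum(Biostrings::width(uco))
  score_mat <- matrix(0, nrow = length(all_frames), ncol = length(uco))
  for (j in seq_along(uco)) {
    score_mat[, j] <- batch_scores(all_frames, uco[[j]])
  }

  rows <- vector("list", length(ctg))
  for (i in seq_along(ctg)) {
    sub <- score_mat[contig_of == i, , drop = FALSE]
    best <- arrayInd(which.max(sub), dim(sub))
    fi <- best[1]; uj <- best[2]
    sc <- sub[fi, uj]
    if (sc <= 0) next
    m <- Biostrings::width(all_frames)[which(contig_of == i)[fi]]
    if (m == 0L) next
    e <- evalue(sc, m, db)
    if (e >= evalue_max) next
    rows[[i]] <- data.frame(
      contig_id = names(ctg)[i],
      uco_id = names(uco)[uj],
      frame = frame_levels[fi],
      raw_score = sc,
      bitscore = raw_to_bit(sc),
      evalue = e, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(contig_id = character(0), uco_id = character(0),
                      frame = integer(0), raw_score = numeric(0),
                      bitscore = numeric(0), evalue = numeric(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Rank candidate species by UCO similarity to the query
#'
#' Each UCO-assigned query contig is translated in its assigned frame and
#' aligned against every candidate species' representative protein for the
#' same UCO. The species holding the best-scoring alignment earns the
#' contig's vote; a tie across t species splits the vote 1/t each, so votes
#' always sum to the number of assigned contigs. Species are ranked by total
#' votes (ties by ascending species id), and the ranking is invariant to the
#' order profiles are supplied in.
#'
#' @param contigs the nucleotide contigs the hits refer to.
#' @param uco_hits contig-to-UCO assignments from [find_uco_contigs()].
#' @param profiles per-species UCO profiles from [build_uco_profiles()].
#' @param top_k how many species to report (default 3, a compromise between
#'   annotation coverage and downstream alignment cost).
#' @return A `uco_ranking`: list with `ranked` (data.frame `species_id`,
#'   `votes`, `distinct_ucos`, `rank` over all species), `top_k`, and
#'   `n_contigs` (number of voting contigs).
#' @export
rank_species_by_uco <- function(contigs, uco_hits, profiles, top_k = 3L) {
  if (length(profiles) == 0L) stop("profiles must be nonempty")
  if (nrow(uco_hits) == 0L) {
    stop("no UCO contigs identified; use taxonomy-based selection instead")
  }
  ctg <- as_dna_set(contigs)
  species <- sort(vapply(profiles, `[[`, "", "species_id"))
  votes <- stats::setNames(numeric(length(species)), species)
  uco_sets <- stats::setNames(vector("list", length(species)), species)

  for (r in seq_len(nrow(uco_hits))) {
    hit <- uco_hits[r, ]
    pep <- frame_peptide(ctg[[hit$contig_id]], hit$frame)
    carriers <- species[vapply(species, function(sp) {
      hit$uco_id %in% names(profiles[[match_profile(profiles, sp)]]$seqs)
    }, logical(1))]
    if (length(carriers) == 0L) next
    reps <- Biostrings::AAStringSet(vapply(carriers, function(sp) {
      as.character(profiles[[match_profile(profiles, sp)]]$seqs[[hit$uco_id]])
    }, ""))
    sc <- batch_scores(reps, Biostrings::AAString(pep))
    winners <- carriers[sc == max(sc)]
    votes[winners] <- votes[winners] + 1 / length(winners)
    for (w in winners) uco_sets[[w]] <- union(uco_sets[[w]], hit$uco_id)
  }

  ord <- order(-votes, species)
  ranked <- data.frame(
    species_id = species[ord],
    votes = unname(votes[ord]),
    distinct_ucos = vapply(uco_sets[ord], length, integer(1)),
    rank = seq_along(species),
    stringsAsFactors = FALSE)
  rownames(ranked) <- NULL
  structure(list(ranked = ranked, top_k = as.integer(top_k),
                 n_contigs = nrow(uco_hits)),
            class = "uco_ranking")
}

match_profile <- function(profiles, sp) {
  which(vapply(profiles, `[[`, "", "species_id") == sp)[1]
}

# peptide of one specific reading frame (frame in -3..-1, 1..3)
frame_peptide <- function(seq, frame) {
  fr <- suppressWarnings(six_frame_translate(seq))
  as.character(fr[[sprintf("%+d", frame)]])
}

#' @export
print.uco_ranking <- function(x, ...) {
  cat(sprintf("UCO-based species ranking (%d voting contigs), top %d:\n",
              x$n_contigs, x$top_k))
  print(utils::head(x$ranked, x$top_k))
  invisible(x)
}

#' Per-species UCO completeness
#'
#' Summarises how many of the reference UCO genes were identified in each
#' species proteome; widely used as a proxy for annotation completeness
#' (species with many missing UCOs are poor annotation references).
#'
#' @param profiles list of `uco_profile` objects.
#' @param n_uco_total size of the reference UCO set the fraction is taken
#'   over (default 357, the canonical set size).
#' @return A data.frame with `species_id`, `completeness`, `fraction`.
#' @export
uco_completeness_summary <- function(profiles, n_uco_total = 357L) {
  data.frame(
    species_id = vapply(profiles, `[[`, "", "species_id"),
    completeness = vapply(profiles, function(p) as.integer(p$completeness),
                          integer(1)),
    fraction = vapply(profiles, function(p) p$completeness / n_uco_total,
                      numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}
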