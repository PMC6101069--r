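#' Build and validate a pipeline configuration
#'
#' Collects every knob of the selection-annotation-enrichment pipeline with
#' the conventional defaults: e-value threshold 1e-10 for all alignment
#' filtering, 3-5 species from the taxonomy route, top 3 species from the
#' UCO route, enrichment alpha 0.05.
#'
#' @param contigs query contigs (`DNAStringSet`, FASTA path, or `NULL` when
#'   only the taxonomy route is used).
#' @param uco UCO reference proteins (`AAStringSet` or FASTA path), needed
#'   for the UCO route.
#' @param proteomes named list of candidate proteomes (species id ->
#'   `AAStringSet` / FASTA path).
#' @param annotations named list (species id -> list(go, pathway)) of
#'   gene-to-term maps.
#' @param de_ids differentially expressed contig ids (character vector or
#'   path to a one-id-per-line file).
#' @param taxonomy optional `taxonomy_tree` (or list with `nodes`/`names`
#'   paths for [parse_taxdump()]).
#' @param query_taxid optional query taxon id for the taxonomy route.
#' @param candidate_taxids taxon ids of the candidate species (defaults to
#'   `names(proteomes)` coerced to integer).
#' @param evalue_max,min_n,max_n,top_k,alpha,seed thresholds as above.
#' @param outdir output directory for report files (`NULL` = no files).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(contigs = NULL, uco = NULL, proteomes = list(),
                            annotations = list(), de_ids = NULL,
                            taxonomy = NULL, query_taxid = NULL,
                            candidate_taxids = NULL,
                            evalue_max = 1e-10, min_n = 3L, max_n = 5L,
                            top_k = 3L, alpha = 0.05, seed = 1L,
                            outdir = NULL) {
  if (evalue_max <= 0) stop("evalue_max must be positive")
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (min_n > max_n) stop("min_n must not exceed max_n")
  if (top_k < 1) stop("top_k must be at least 1")
  if (is.null(contigs) && is.null(query_taxid)) {
    stop("supply contigs (UCO route) and/or query_taxid (taxonomy route)")
  }
  if (is.list(taxonomy) && !inherits(taxonomy, "taxonomy_tree")) {
    taxonomy <- parse_taxdump(taxonomy$nodes, taxonomy$names)
  }
  if (is.character(de_ids) && length(de_ids) == 1L && file.exists(de_ids)) {
    de_ids <- readLines(de_ids, warn = FALSE)
    de_ids <- de_ids[nzchar(de_ids)]
  }
  structure(list(contigs = contigs, uco = uco, proteomes = proteomes,
                 annotations = annotations, de_ids = de_ids,
                 taxonomy = taxonomy, query_taxid = query_taxid,
                 candidate_taxids = candidate_taxids,
                 evalue_max = evalue_max, min_n = as.integer(min_n),
                 max_n = as.integer(max_n), top_k = as.integer(top_k),
                 alpha = alpha, seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

#' Run the full selection-annotation-enrichment pipeline
#'
#' Executes the stages in order: reference-species selection (taxonomy
#' route when the query taxon is in the tree, UCO sequence route
#' otherwise or when only contigs are supplied), best-hit ortholog
#' annotation against the selected species, annotation merging, and
#' hypergeometric GO and pathway enrichment of the DE list. The pipeline is
#' a pure function of its inputs, configuration and seed: repeated runs
#' produce identical outputs.
#'
#' @param config a `pipeline_config`.
#' @return A run report (list): `selection_route`, `selected_species`,
#'   `selection` (the ranking object), `annotation` (merged
#'   `annotation_map`), `annotation_counts` (per-species data.frame:
#'   annotated contigs, GO-annotated contigs, GO term annotations, pathway
#'   genes, distinct pathways), `enrichment_go`, `enrichment_pathway`.
#'   When `config$outdir` is set, TSV reports and a JSON summary are also
#'   written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  message("[select] choosing reference species")
  sel <- NULL
  route <- NULL
  if (!is.null(config$query_taxid) && !is.null(config$taxonomy)) {
    sel <- tryCatch(
      select_by_taxonomy(config$taxonomy, config$query_taxid,
                         candidate_ids = config$candidate_taxids %||%
                           as.integer(names(config$proteomes)),
                         min_n = config$min_n, max_n = config$max_n),
      uco_path_error = function(e) NULL)
    if (!is.null(sel)) route <- "taxonomy"
  }
  if (is.null(sel)) {
    if (is.null(config$contigs) || is.null(config$uco)) {
      stop("taxonomy route unavailable and no contigs/UCO set supplied for the UCO route")
    }
    route <- "uco"
    profiles <- build_uco_profiles(config$uco, config$proteomes,
                                   evalue_max = config$evalue_max)
    hits <- find_uco_contigs(config$contigs, config$uco,
                             evalue_max = config$evalue_max)
    sel <- rank_species_by_uco(config$contigs, hits, profiles,
                               top_k = config$top_k)
  }
  selected <- if (route == "taxonomy") {
    as.character(sel$ranked$species_id)
  } else {
    utils::head(sel$ranked$species_id, sel$top_k)
  }
  message(sprintf("[select] route = %s; selected: %s", route,
                  paste(selected, collapse = ", ")))

  if (is.null(config$contigs)) {
    stop("contigs are required for the annotation stage")
  }
  message("[annotate] transferring best-hit annotations")
  amap <- annotate_contigs(config$contigs,
                           config$proteomes[selected],
                           config$annotations[selected],
                           evalue_max = config$evalue_max)
  amap <- merge_annotations(amap)
  counts <- annotation_counts(amap)

  enr_go <- NULL
  enr_pw <- NULL
  if (!is.null(config$de_ids) && length(config$de_ids)) {
    message("[enrich] hypergeometric enrichment of the DE list")
    enr_go <- tryCatch(enrich(config$de_ids, amap, "GO", config$alpha),
                       error = function(e) NULL)
    enr_pw <- tryCatch(enrich(config$de_ids, amap, "pathway", config$alpha),
                       error = function(e) NULL)
  }

  report <- list(selection_route = route, selected_species = selected,
                 selection = sel, annotation = amap,
                 annotation_counts = counts,
                 enrichment_go = enr_go, enrichment_pathway = enr_pw)
  if (!is.null(config$outdir)) write_report(report, config)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-species annotation statistics (annotated contigs, GO coverage,
# pathway coverage)
annotation_counts <- function(map) {
  h <- map$hits
  sp <- sort(unique(h$species_id))
  data.frame(
    species_id = sp,
    annotated_contigs = vapply(sp, function(s) {
      length(unique(h$contig_id[h$species_id == s]))
    }, integer(1)),
    contigs_with_go = vapply(sp, function(s) {
      sum(vapply(which(h$species_id == s),
                 function(r) length(h$go[[r]]) > 0, logical(1)))
    }, integer(1)),
    go_term_annotations = vapply(sp, function(s) {
      sum(vapply(which(h$species_id == s),
                 function(r) length(h$go[[r]]), integer(1)))
    }, integer(1)),
    genes_with_pathway = vapply(sp, function(s) {
      sum(vapply(which(h$species_id == s),
                 function(r) length(h$pathway[[r]]) > 0, logical(1)))
    }, integer(1)),
    distinct_pathways = vapply(sp, function(s) {
      length(unique(unlist(h$pathway[h$species_id == s])))
    }, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

write_report <- function(report, config) {
  dir <- config$outdir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sel <- report$selection
  if (report$selection_route == "taxonomy") {
    utils::write.table(sel$ranked, file.path(dir, "selection.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(sel$ranked, file.path(dir, "uco_ranking.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  h <- report$annotation$hits
  flat <- h[, c("contig_id", "species_id", "gene_id", "bitscore", "evalue")]
  flat$go <- vapply(h$go, paste, "", collapse = ",")
  flat$pathway <- vapply(h$pathway, paste, "", collapse = ",")
  utils::write.table(flat, file.path(dir, "annotation_hits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$annotation_counts,
                     file.path(dir, "annotation_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (kind in c("go", "pathway")) {
    enr <- report[[paste0("enrichment_", kind)]]
    if (!is.null(enr)) {
      utils::write.table(enr, file.path(dir, paste0("enrichment_", kind, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  jsonlite::write_json(
    list(selection_route = report$selection_route,
         selected_species = report$selected_species,
         n_contigs = length(report$annotation$contigs),
         n_annotated_contigs = length(unique(h$contig_id)),
         n_significant_go = if (!is.null(report$enrichment_go)) {
           sum(report$enrichment_go$significant)
         } else NA,
         n_significant_pathway = if (!is.null(report$enrichment_pathway)) {
           sum(report$enrichment_pathway$significant)
         } else NA,
         seed = config$seed),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
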