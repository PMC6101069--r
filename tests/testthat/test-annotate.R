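test_that("annotation tables round-trip and merge duplicate genes", {
  lines <- c("g1\tGO:0000001,GO:0000002", "g2\tGO:0000003",
             "g1\tGO:0000002,GO:0000004")
  ann <- read_annotation_table(lines)
  expect_setequal(ann$g1, c("GO:0000001", "GO:0000002", "GO:0000004"))
  expect_equal(ann$g2, "GO:0000003")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_table(ann, path)
  expect_equal(read_annotation_table(path), ann)
  expect_error(read_annotation_table("just_a_gene"), "line 1")
})

test_that("a back-translated contig maps to its source gene", {
  set.seed(50)
  genes <- Biostrings::AAStringSet(setNames(
    vapply(1:5, function(i) random_peptide(60), ""), paste0("g", 1:5)))
  ann <- list(spA = list(go = list(g3 = c("GO:0000001", "GO:0000002")),
                         pathway = list(g3 = "ko00010")))
  contig <- setNames(back_translate(as.character(genes[["g3"]])), "c1")
  map <- annotate_contigs(contig, list(spA = genes), ann)
  expect_equal(map$hits$gene_id, "g3")
  expect_equal(map$hits$species_id, "spA")
  merged <- merge_annotations(map)
  expect_setequal(merged$merged_go$c1, c("GO:0000001", "GO:0000002"))
  expect_equal(merged$merged_pathway$c1, "ko00010")
})

test_that("a random contig stays unannotated", {
  set.seed(51)
  genes <- Biostrings::AAStringSet(setNames(
    vapply(1:4, function(i) random_peptide(80), ""), paste0("g", 1:4)))
  noise <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                 collapse = "")
  map <- suppressWarnings(
    annotate_contigs(setNames(noise, "junk"), list(spA = genes)))
  expect_equal(nrow(map$hits), 0)
  expect_equal(map$contigs, "junk")
})

test_that("per-species best hits equal a brute-force all-vs-all sweep", {
  tr <- simulate_taxonomy(3, n_internal = 0, seed = 52)
  sp <- as.character(attr(tr, "species_ids"))
  sim <- simulate_proteomes(tr, n_uco = 6, rate_per_edge = 0.05, seed = 52,
                            len_range = c(50L, 70L))
  trx <- simulate_transcriptome(sim$proteomes[[sp[1]]], n_contigs = 10,
                                fragment_range = c(30L, 45L), seed = 52)
  map <- suppressWarnings(
    annotate_contigs(trx$contigs, sim$proteomes[sp[-1]]))
  for (r in seq_len(nrow(map$hits))) {
    prot <- sim$proteomes[[map$hits$species_id[r]]]
    ctg <- as.character(trx$contigs[[map$hits$contig_id[r]]])
    frames <- c(vapply(0:2, function(off) {
      n <- nchar(ctg) - off; n <- n - n %% 3
      if (n < 3) "" else translate_oracle(substr(ctg, off + 1, off + n))
    }, ""), vapply(0:2, function(off) {
      rc <- revcomp(ctg)
      n <- nchar(rc) - off; n <- n - n %% 3
      if (n < 3) "" else translate_oracle(substr(rc, off + 1, off + n))
    }, ""))
    sc <- vapply(seq_along(prot), function(j) {
      max(vapply(frames[nzchar(frames)], function(f) {
        sw_oracle(f, as.character(prot[[j]]))
      }, 0))
    }, 0)
    expect_equal(map$hits$gene_id[r], names(prot)[which.max(sc)])
    expect_equal(map$hits$raw_score[r], max(sc))
  }
})

test_that("merging unions terms and never shrinks with added species", {
  # single species: merged sets equal that species' sets
  m1 <- make_annmap(list(c1 = c("GO:1"), c2 = c("GO:2", "GO:3")))
  merged1 <- merge_annotations(m1)
  expect_equal(merged1$merged_go, list(c1 = "GO:1", c2 = c("GO:2", "GO:3")))

  # a second species adds a term to an already-annotated contig
  h2 <- m1$hits[1, ]
  h2$species_id <- "s2"
  h2$go <- list("GO:9")
  m2 <- m1
  m2$hits <- rbind(m1$hits, h2)
  merged2 <- merge_annotations(m2)
  expect_setequal(merged2$merged_go$c1, c("GO:1", "GO:9"))

  # monotonicity on random fixtures: nested species subsets
  set.seed(53)
  for (i in 1:5) {
    contigs <- paste0("c", 1:12)
    hits <- do.call(rbind, lapply(1:3, function(s) {
      picked <- sample(contigs, sample(4:10, 1))
      data.frame(contig_id = picked, species_id = paste0("s", s),
                 gene_id = picked, raw_score = 10, bitscore = 20,
                 evalue = 1e-15, stringsAsFactors = FALSE)
    }))
    hits$go <- lapply(seq_len(nrow(hits)), function(r) {
      sample(sprintf("GO:%07d", 1:15), sample(1:4, 1))
    })
    hits$pathway <- rep(list(character(0)), nrow(hits))
    prev_terms <- 0
    prev_contigs <- 0
    for (s in 1:3) {
      sub <- structure(list(hits = hits[hits$species_id %in% paste0("s", 1:s), ],
                            contigs = contigs, merged_go = NULL,
                            merged_pathway = NULL),
                       class = "annotation_map")
      merged <- merge_annotations(sub)
      n_contigs <- length(merged$merged_go)
      n_terms <- length(unique(unlist(merged$merged_go)))
      expect_gte(n_contigs, prev_contigs)
      expect_gte(n_terms, prev_terms)
      prev_contigs <- n_contigs
      prev_terms <- n_terms
    }
  }
})

test_that("hypergeometric upper tail matches enumeration and edge cases", {
  expect_equal(hypergeom_pvalue(0, 5, 5, 10), 1)
  expect_equal(hypergeom_pvalue(5, 5, 5, 10), 1 / choose(10, 5))
  set.seed(54)
  for (i in 1:25) {
    N <- sample(1:30, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    k <- sample(max(0, n - (N - K)):min(K, n), 1)
    expect_equal(hypergeom_pvalue(k, K, n, N), hyper_upper_oracle(k, K, n, N),
                 tolerance = 1e-12, info = sprintf("k=%d K=%d n=%d N=%d", k, K, n, N))
  }
  expect_error(hypergeom_pvalue(6, 5, 5, 10), "require")
  expect_error(hypergeom_pvalue(2, 11, 5, 10), "require")
})

test_that("hypergeometric p is monotone in k and its pmf sums to one", {
  for (parm in list(c(8, 10, 20), c(3, 7, 12), c(15, 15, 30))) {
    K <- parm[1]; n <- parm[2]; N <- parm[3]
    ks <- max(0, n - (N - K)):min(K, n)
    p <- vapply(ks, hypergeom_pvalue, 0, K = K, n = n, N = N)
    expect_true(all(diff(p) <= 0))
    pmf <- stats::dhyper(ks, K, N - K, n)
    expect_equal(sum(pmf), 1, tolerance = 1e-12)
  }
})

test_that("enrichment counts come from set algebra over the background", {
  set.seed(55)
  for (i in 1:10) {
    contigs <- paste0("c", 1:30)
    vocab <- sprintf("GO:%07d", 1:8)
    sets <- lapply(contigs, function(x) sample(vocab, sample(1:3, 1)))
    names(sets) <- contigs
    de <- sample(contigs, 8)
    tab <- enrich(de, make_annmap(sets), "GO", alpha = 0.05)
    expect_true(all(tab$k >= 1))
    expect_true(!is.unsorted(tab$p))
    for (r in seq_len(nrow(tab))) {
      carriers <- contigs[vapply(sets, function(s) tab$term_id[r] %in% s,
                                 logical(1))]
      expect_equal(tab$K[r], length(carriers))
      expect_equal(tab$k[r], length(intersect(carriers, de)))
      expect_equal(tab$n[r], 8)
      expect_equal(tab$N[r], 30)
      expect_equal(tab$p[r],
                   hyper_upper_oracle(tab$k[r], tab$K[r], 8, 30),
                   tolerance = 1e-12)
    }
    expect_equal(tab$p_adj, stats::p.adjust(tab$p, "BH"))
  }
})

test_that("a DE set equal to the background gives p = 1 everywhere", {
  set.seed(56)
  contigs <- paste0("c", 1:15)
  sets <- lapply(contigs, function(x) sample(sprintf("GO:%07d", 1:5), 2))
  names(sets) <- contigs
  tab <- enrich(contigs, make_annmap(sets), "GO")
  expect_true(all(tab$k == tab$K))
  expect_true(all(tab$p == 1))
})

test_that("a planted 5-fold enriched term attains the minimum raw p", {
  set.seed(57)
  genes <- paste0("g", 1:120)
  planted <- "GO:9999999"
  ann <- simulate_annotations(genes, n_terms = 20L, terms_per_gene = 3L,
                              planted_term = planted,
                              planted_genes = genes[1:24], seed = 57)
  prot <- Biostrings::AAStringSet(setNames(
    vapply(genes, function(g) random_peptide(30), ""), genes))
  trx <- simulate_transcriptome(prot, n_contigs = 120,
                                fragment_range = c(30L, 30L), seed = 57,
                                gene_terms = ann, planted_term = planted,
                                fold = 5, de_fraction = 0.25)
  sets <- setNames(ann[trx$truth$gene_id], trx$truth$contig_id)
  tab <- enrich(trx$de_ids, make_annmap(sets), "GO")
  expect_equal(tab$term_id[1], planted)
  expect_true(tab$significant[1])
})

test_that("enrichment validates its inputs", {
  sets <- list(c1 = "GO:1", c2 = "GO:2")
  expect_error(enrich(character(0), make_annmap(sets)), "empty")
  expect_warning(enrich(c("c1", "nope"), make_annmap(sets)), "dropped")
  expect_error(suppressWarnings(enrich("nope", make_annmap(sets))),
               "background")
})
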