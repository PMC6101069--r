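test_that("a proteome equal to the UCO set self-identifies completely", {
  set.seed(14)
  uco <- Biostrings::AAStringSet(setNames(
    vapply(1:6, function(i) random_peptide(80), ""),
    sprintf("UCO%03d", 1:6)))
  prot <- uco
  names(prot) <- paste0("g", 1:6)
  profs <- build_uco_profiles(uco, list(spA = prot))
  expect_equal(profs$spA$completeness, 6L)
  # each UCO maps to its own counterpart
  expect_equal(profs$spA$entries$protein_id[order(profs$spA$entries$uco_id)],
               paste0("g", 1:6))
  expect_true(all(profs$spA$entries$evalue < 1e-10))
})

test_that("a proteome without UCO homologs yields completeness 0", {
  set.seed(15)
  uco <- Biostrings::AAStringSet(setNames(
    vapply(1:4, function(i) random_peptide(90), ""), sprintf("UCO%03d", 1:4)))
  unrelated <- Biostrings::AAStringSet(setNames(
    vapply(1:5, function(i) random_peptide(90), ""), paste0("x", 1:5)))
  profs <- build_uco_profiles(uco, list(spB = unrelated))
  expect_equal(profs$spB$completeness, 0L)
  expect_warning(build_uco_profiles(uco, list(spC = Biostrings::AAStringSet())),
                 "empty proteome")
})

test_that("profiles at 5% divergence match a brute-force best-hit sweep", {
  tr <- simulate_taxonomy(3, n_internal = 0, seed = 2)
  sim <- simulate_proteomes(tr, n_uco = 8, rate_per_edge = 0.05, seed = 2)
  profs <- build_uco_profiles(sim$uco, sim$proteomes)
  for (sp in names(sim$proteomes)) {
    expect_equal(profs[[sp]]$completeness, 8L)  # every UCO recovered
    prot <- sim$proteomes[[sp]]
    for (r in seq_len(nrow(profs[[sp]]$entries))) {
      uid <- profs[[sp]]$entries$uco_id[r]
      # brute force: score every proteome protein against this UCO
      sc <- vapply(seq_along(prot), function(j) {
        sw_oracle(as.character(sim$uco[[uid]]), as.character(prot[[j]]))
      }, 0)
      expect_equal(profs[[sp]]$entries$protein_id[r],
                   names(prot)[which.max(sc)])
      expect_equal(profs[[sp]]$entries$raw_score[r], max(sc))
    }
  }
})

test_that("an exact back-translation is assigned its UCO in a forward frame", {
  set.seed(16)
  uco <- Biostrings::AAStringSet(setNames(
    vapply(1:4, function(i) random_peptide(70), ""), sprintf("UCO%03d", 1:4)))
  nt <- back_translate(as.character(uco[["UCO002"]]))
  hits <- find_uco_contigs(setNames(nt, "c1"), uco)
  expect_equal(hits$uco_id, "UCO002")
  expect_equal(hits$frame, 1L)
  # reverse complement: same UCO on a negative frame
  hits_rc <- find_uco_contigs(setNames(revcomp(nt), "c1rc"), uco)
  expect_equal(hits_rc$uco_id, "UCO002")
  expect_lt(hits_rc$frame, 0L)
  expect_equal(hits_rc$raw_score, hits$raw_score)
})

test_that("fragmented contigs match the exhaustive frame-by-UCO oracle", {
  tr <- simulate_taxonomy(2, n_internal = 0, seed = 4)
  sim <- simulate_proteomes(tr, n_uco = 6, rate_per_edge = 0, seed = 4,
                            len_range = c(60L, 80L))
  qsp <- names(sim$proteomes)[1]
  trx <- simulate_transcriptome(sim$proteomes[[qsp]], n_contigs = 12,
                                fragment_range = c(30L, 50L), seed = 4)
  hits <- find_uco_contigs(trx$contigs, sim$uco)
  expect_gt(nrow(hits), 0)
  for (r in seq_len(nrow(hits))) {
    ctg <- as.character(trx$contigs[[hits$contig_id[r]]])
    frames <- vapply(c(0, 1, 2), function(off) {
      n <- nchar(ctg) - off; n <- n - n %% 3
      if (n < 3) "" else translate_oracle(substr(ctg, off + 1, off + n))
    }, "")
    rc <- revcomp(ctg)
    frames <- c(frames, vapply(c(0, 1, 2), function(off) {
      n <- nchar(rc) - off; n <- n - n %% 3
      if (n < 3) "" else translate_oracle(substr(rc, off + 1, off + n))
    }, ""))
    best <- max(vapply(frames[nzchar(frames)], function(f) {
      max(vapply(seq_along(sim$uco), function(u) {
        sw_oracle(f, as.character(sim$uco[[u]]))
      }, 0))
    }, 0))
    expect_equal(hits$raw_score[r], best)
  }
})

test_that("a single profiled species receives every vote", {
  tr <- simulate_taxonomy(2, n_internal = 0, seed = 6)
  sim <- simulate_proteomes(tr, n_uco = 5, rate_per_edge = 0.02, seed = 6)
  qsp <- names(sim$proteomes)[1]
  other <- names(sim$proteomes)[2]
  trx <- simulate_transcriptome(sim$proteomes[[qsp]], n_contigs = 8,
                                fragment_range = c(40L, 60L), seed = 6)
  profs <- build_uco_profiles(sim$uco, sim$proteomes[other])
  hits <- find_uco_contigs(trx$contigs, sim$uco)
  rk <- rank_species_by_uco(trx$contigs, hits, profs)
  expect_equal(rk$ranked$species_id, other)
  expect_equal(rk$ranked$votes, nrow(hits))
})

test_that("planted divergences are recovered in rank order with votes summing", {
  # star tree: query (rate 0) and candidates at 2%, 10%, 30% divergence
  tr <- simulate_taxonomy(4, n_internal = 0, seed = 8)
  sp <- as.character(attr(tr, "species_ids"))
  rates <- setNames(c(0, 0.02, 0.10, 0.30), sp)
  sim <- simulate_proteomes(tr, n_uco = 12, rate_per_edge = rates, seed = 8,
                            len_range = c(70L, 100L))
  trx <- simulate_transcriptome(sim$proteomes[[sp[1]]], n_contigs = 12,
                                fragment_range = c(50L, 70L), seed = 8)
  profs <- build_uco_profiles(sim$uco, sim$proteomes[sp[-1]])
  hits <- find_uco_contigs(trx$contigs, sim$uco)
  rk <- rank_species_by_uco(trx$contigs, hits, profs)
  expect_equal(rk$ranked$species_id, sp[-1])  # 2% < 10% < 30%
  expect_gt(rk$ranked$votes[1], rk$ranked$votes[2])
  expect_equal(sum(rk$ranked$votes), nrow(hits))  # each contig votes once

  # ranking invariant to profile order
  rk2 <- rank_species_by_uco(trx$contigs, hits, rev(profs))
  expect_identical(rk$ranked, rk2$ranked)
})

test_that("rank_species_by_uco demands UCO contigs and profiles", {
  empty_hits <- data.frame(contig_id = character(0), uco_id = character(0),
                           frame = integer(0), raw_score = numeric(0),
                           bitscore = numeric(0), evalue = numeric(0))
  tr <- simulate_taxonomy(2, n_internal = 0, seed = 9)
  sim <- simulate_proteomes(tr, n_uco = 3, seed = 9)
  profs <- build_uco_profiles(sim$uco, sim$proteomes)
  expect_error(rank_species_by_uco(Biostrings::DNAStringSet(), empty_hits,
                                   profs),
               "taxonomy")
  expect_error(rank_species_by_uco(Biostrings::DNAStringSet(), empty_hits,
                                   list()),
               "nonempty")
})

test_that("completeness summary reports planted dropouts exactly", {
  tr <- simulate_taxonomy(3, n_internal = 0, seed = 10)
  sp <- as.character(attr(tr, "species_ids"))
  dropout <- setNames(list(character(0), c("UCO001", "UCO004"), "UCO002"), sp)
  sim <- simulate_proteomes(tr, n_uco = 5, rate_per_edge = 0.02, seed = 10,
                            dropout = dropout)
  profs <- build_uco_profiles(sim$uco, sim$proteomes)
  sm <- uco_completeness_summary(profs, n_uco_total = 5)
  expect_equal(sm$completeness[match(sp, sm$species_id)], c(5L, 3L, 4L))
  expect_equal(sm$fraction[match(sp, sm$species_id)], c(1, 0.6, 0.8))
  # the canonical denominator of 357 reference genes
  full <- uco_completeness_summary(profs[1], n_uco_total = 357)
  expect_equal(full$fraction, 5 / 357)
})
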