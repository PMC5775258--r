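test_that("FASTA ingestion normalises case, keeps order, rejects bad input", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "ygnTPLHcaa", ">p2", "ACDE*"), f)
  recs <- read_fasta(f)
  expect_length(recs, 2L)
  expect_equal(recs[[1L]]$id, "p1")
  expect_equal(recs[[1L]]$sequence, "YGNTPLHCAA")
  expect_equal(recs[[2L]]$sequence, "ACDE")  # terminal stop stripped

  writeLines(c(">p1", "AC1GT"), f)
  expect_error(read_fasta(f), "1")

  writeLines(c(">p1", "ACDE", ">p1", "GHIK"), f)
  expect_error(read_fasta(f), "duplicate")

  writeLines(character(0), f)
  expect_error(read_fasta(f), "empty|FASTA")
})

test_that("consensus scanner finds (S/T)PX(K/H/R) sites with 1-based anchors", {
  sites <- scan_consensus(protein_record("p1", "YGNTPLHCAA"))
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$acceptor_pos, 4L)
  expect_equal(sites$acceptor_res, "T")
  expect_equal(sites$window, "TPLH")

  expect_equal(nrow(scan_consensus(protein_record("p2", "AAAAAAAA"))), 0L)
  # X never matches any pattern position
  expect_equal(nrow(scan_consensus(protein_record("p3", "XPLHXPAH"))), 0L)
})

test_that("txxh scanner finds S/T..H sites including the minimal 4-mer", {
  sites <- scan_txxh(protein_record("p1", "HGMTPLHLAA"))
  expect_equal(sites$acceptor_pos, 4L)
  expect_equal(scan_txxh(protein_record("p2", "TPAH"))$acceptor_pos, 1L)
})

test_that("scanners agree exactly with a regex-lookahead oracle", {
  set.seed(42)
  for (i in 1:200) {
    seq <- random_protein(200)
    rec <- protein_record(sprintf("r%d", i), seq)
    expect_identical(scan_consensus(rec)$acceptor_pos,
                     oracle_consensus_positions(seq))
    expect_identical(scan_txxh(rec)$acceptor_pos,
                     oracle_txxh_positions(seq))
  }
})

test_that("merge marks consensus sites with +3 histidine as 'both'", {
  set.seed(7)
  for (i in 1:50) {
    rec <- protein_record("r", random_protein(300))
    cons <- scan_consensus(rec)
    tx <- scan_txxh(rec)
    merged <- merge_motif_sites(cons, tx)
    h_sites <- cons$acceptor_pos[substr(cons$window, 4L, 4L) == "H"]
    # every consensus site with H at +3 is in the txxh scan and merged 'both'
    expect_true(all(h_sites %in% tx$acceptor_pos))
    expect_setequal(merged$acceptor_pos[merged$motif_class == "both"], h_sites)
    expect_setequal(merged$acceptor_pos, union(cons$acceptor_pos,
                                               tx$acceptor_pos))
  }
})

test_that("PSSM scoring sums per-position weights, zero at edges and X", {
  rec <- protein_record("p1", "YGNTPLHCAA")
  site <- scan_consensus(rec)[1L, ]

  expect_equal(score_site(site, rec, uniform_pssm()), 0)

  # one-hot matrix matching the site's own window scores the sum of hot
  # weights
  m <- uniform_pssm(-4:5)
  window_res <- strsplit("YGNTPLHCAA", "")[[1L]]  # offsets -3..6 from pos 4
  for (k in seq_along(window_res)) {
    off <- as.character(k - 4L)
    if (off %in% rownames(m)) m[off, window_res[k]] <- k
  }
  # offsets -3..5 are in range; offset -4 is off-sequence, offset 6 uncovered
  expect_equal(score_site(site, rec, m), sum(1:9))

  # seeded random matrix equals an independent position-by-position loop
  set.seed(11)
  for (rep in 1:20) {
    seq <- random_protein(60)
    rec <- protein_record("r", seq)
    sites <- scan_consensus(rec)
    if (nrow(sites) == 0L) next
    m <- uniform_pssm(-4:5)
    m[] <- rnorm(length(m))
    for (i in seq_len(nrow(sites))) {
      expected <- 0
      for (off in -4:5) {
        p <- sites$acceptor_pos[i] + off
        if (p >= 1 && p <= nchar(seq)) {
          res <- substr(seq, p, p)
          expected <- expected + m[as.character(off), res]
        }
      }
      expect_equal(score_site(sites[i, ], rec, m), expected)
    }
  }
})

test_that("topology filter drops buried sites, keeps unknown, is idempotent", {
  site <- data.frame(protein_id = "p", acceptor_pos = 50L, acceptor_res = "T",
                     motif_class = "consensus", window = "TPLK",
                     pssm_score = NA_real_, topology_kind = NA_character_,
                     stringsAsFactors = FALSE)
  seq <- random_protein(100)

  cyto <- protein_record("p", seq, data.frame(kind = "cytoplasmic",
                                              start = 1, end = 100))
  kept <- filter_topology(site, cyto)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$topology_kind, "cytoplasmic")

  tm <- protein_record("p", seq, data.frame(kind = "transmembrane",
                                            start = 40, end = 60))
  expect_equal(nrow(filter_topology(site, tm)), 0L)

  extra <- protein_record("p", seq, data.frame(kind = "extracellular",
                                               start = 45, end = 55))
  expect_equal(nrow(filter_topology(site, extra)), 0L)

  bare <- protein_record("p", seq)
  kept <- filter_topology(site, bare)
  expect_equal(kept$topology_kind, "unknown")

  expect_identical(filter_topology(kept, bare), kept)
  expect_identical(filter_topology(filter_topology(site, cyto), cyto),
                   filter_topology(site, cyto))
})

test_that("decapeptide extraction centres acceptor at 4, proline at 5", {
  # acceptor T at 416 in a planted context reproduces the printed window
  left <- random_protein(412)
  rec <- protein_record("p", paste0(left, "DGCTPLHYAC", random_protein(50)))
  site <- list(acceptor_pos = 416L)
  pep <- extract_peptide(rec, site)
  expect_equal(pep$sequence10, "DGCTPLHYAC")
  expect_false(pep$truncated)
  expect_equal(substr(pep$sequence10, 5L, 5L), "P")

  # acceptor at position 2: left-truncated and flagged
  rec2 <- protein_record("p2", "ATPAHAAAAAA")
  pep2 <- extract_peptide(rec2, list(acceptor_pos = 2L))
  expect_true(pep2$truncated)
  expect_equal(pep2$sequence10, substr(rec2$sequence, 1L, 8L))

  # full-length whenever acceptor_pos in [4, len - 6]
  set.seed(3)
  rec3 <- protein_record("p3", random_protein(40))
  for (pos in 4:34) {
    expect_equal(nchar(extract_peptide(rec3, list(acceptor_pos = pos))$sequence10),
                 10L)
  }
})

test_that("proteome screen composes scan, filter, restriction and scoring", {
  recs <- trpa1_peptide_records()
  tab <- screen_proteome(recs)
  expect_equal(nrow(tab), 6L)
  expect_true(all(tab$acceptor_pos == 4L))
  expect_identical(tab$peptide10, unname(vapply(recs, `[[`, "", "sequence")))

  expect_equal(nrow(screen_proteome(recs, expressed_gene_set = character(0))),
               0L)

  # monotone in the expressed set
  n_all <- nrow(screen_proteome(recs))
  n_three <- nrow(screen_proteome(recs,
                                  expressed_gene_set = names(recs)[1:3]))
  expect_true(n_three <= n_all)

  # planted counts: screen output matches generator truth restricted to
  # accessible consensus-bearing sites
  pr <- gen_proteome(20, seed = 101)
  tab <- screen_proteome(pr$records)
  truth <- pr$truth
  expected <- truth[truth$motif_class %in% c("consensus", "both") &
                    truth$topology_kind %in% c("cytoplasmic", "unknown"), ]
  expect_equal(nrow(tab), nrow(expected))
  expect_identical(tab$acceptor_pos, expected$acceptor_pos)
  expect_identical(tab$protein_id, expected$protein_id)
})
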