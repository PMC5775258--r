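# A synthetic stand-in for the mouse TRPA1 protein, for exercising the
# whole-protein screen offline. This is NOT the GenBank sequence: it is a
# scrubbed random background of the real protein's length (1125 aa) carrying
# the six experimentally tested decapeptide substrate windows at the residue
# positions where the corresponding phospho-acceptor sites sit in the real
# channel. Everything outside those windows is synthetic.

TRPA1_PEPTIDES <- c(T101 = "YGNTPLHCAA", T134 = "NMMSPLHIAV",
                    S242 = "KKASPLHLAV", T416 = "DGCTPLHYAC",
                    S449 = "DKKSPLHFAA", T485 = "HGMTPLHLAA")

TRPA1_SITES <- c(101L, 134L, 242L, 416L, 449L, 485L)

#' Synthetic mouse TRPA1 stand-in with the six known acceptor sites
#'
#' Builds a deterministic synthetic protein of the mouse TRPA1 length
#' (1125 aa) whose only consensus/T-x-x-H motifs are the six decapeptide
#' substrate windows used in the in vitro kinase assay, planted so that their
#' phospho-acceptors fall at residues 101, 134, 242, 416, 449 and 485 --
#' i.e. inside the N-terminal cytosolic ankyrin-repeat region. Topology marks
#' residues 1-720 cytoplasmic (the ankyrin-repeat-bearing N-terminus),
#' 721-960 transmembrane and 961-1125 cytoplasmic. The background is random
#' sequence, not the true TRPA1 sequence; use it to validate scanner and
#' topology logic against the known site positions, not for biology of the
#' flanking regions.
#'
#' @return A [protein_record] with id `"Trpa1_synthetic"`.
#' @export
synthetic_trpa1_record <- function() {
  with_seed(11250L, {
    len <- 1125L
    seq <- scrub_motifs(random_background(len))
    chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
    for (i in seq_along(TRPA1_SITES)) {
      pos <- TRPA1_SITES[i]
      win <- strsplit(TRPA1_PEPTIDES[[i]], "", fixed = TRUE)[[1L]]
      chars[(pos - 3L):(pos + 6L)] <- win
    }
    seq <- paste(chars, collapse = "")
    # planting decapeptides can seed chance motifs at the junctions;
    # rescrub anything that is not one of the six acceptors
    repeat {
      rec <- protein_record("Trpa1_synthetic", seq)
      hits <- unique(c(scan_consensus(rec)$acceptor_pos,
                       scan_txxh(rec)$acceptor_pos))
      stray <- setdiff(hits, TRPA1_SITES)
      if (length(stray) == 0L) break
      ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
      for (p in stray) ch[p] <- sample(setdiff(AA_CANONICAL, c("S", "T")), 1L)
      seq <- paste(ch, collapse = "")
    }
    topo <- data.frame(kind = c("cytoplasmic", "transmembrane", "cytoplasmic"),
                       start = c(1L, 721L, 961L),
                       end = c(720L, 960L, 1125L), stringsAsFactors = FALSE)
    protein_record("Trpa1_synthetic", seq, topology = topo)
  })
}

#' The six TRPA1 decapeptide substrate windows as protein records
#'
#' The decapeptides used as in vitro kinase substrates, one per known
#' acceptor site, each with the acceptor at window position 4 and the
#' obligate proline at position 5.
#'
#' @return A named list of six [protein_record]s (`TRPA1_1` .. `TRPA1_6`).
#' @export
trpa1_peptide_records <- function() {
  recs <- lapply(seq_along(TRPA1_PEPTIDES), function(i)
    protein_record(sprintf("TRPA1_%d", i), TRPA1_PEPTIDES[[i]]))
  names(recs) <- sprintf("TRPA1_%d", seq_along(TRPA1_PEPTIDES))
  recs
}
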