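# Motif scanning for proline-directed kinase (Cdk5) substrate candidates.
#
# Two patterns are recognised over 1-based residue coordinates, both anchored
# on a Ser/Thr phospho-acceptor at position i:
#   consensus: seq[i] in {S,T}, seq[i+1] == P, seq[i+3] in {K,H,R}
#   txxh:      seq[i] in {S,T}, seq[i+3] == H   (the ankyrin-repeat T/SxxH)
# A consensus site whose +3 residue is H satisfies both ('both' after merge).

empty_sites <- function() {
  data.frame(protein_id = character(), acceptor_pos = integer(),
             acceptor_res = character(), motif_class = character(),
             window = character(), pssm_score = numeric(),
             topology_kind = character(), stringsAsFactors = FALSE)
}

scan_pattern <- function(record, motif_class) {
  stopifnot(inherits(record, "protein_record"))
  chars <- strsplit(record$sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n < 4L) return(empty_sites())
  i <- seq_len(n - 3L)
  acc <- chars[i] %in% c("S", "T")
  hit <- switch(motif_class,
    consensus = acc & chars[i + 1L] == "P" & chars[i + 3L] %in% c("K", "H", "R"),
    txxh      = acc & chars[i + 3L] == "H",
    stop("unknown motif class: ", motif_class))
  pos <- i[hit]
  if (length(pos) == 0L) return(empty_sites())
  data.frame(protein_id = rep(record$id, length(pos)),
             acceptor_pos = pos,
             acceptor_res = chars[pos],
             motif_class = rep(motif_class, length(pos)),
             window = substring(record$sequence, pos, pos + 3L),
             pssm_score = rep(NA_real_, length(pos)),
             topology_kind = rep(NA_character_, length(pos)),
             stringsAsFactors = FALSE)
}

#' Scan a protein for the Cdk5 consensus motif (S/T)PX(K/H/R)
#'
#' Reports every acceptor position whose residue is S or T, is immediately
#' followed by the obligate proline, and has K, H or R three residues
#' downstream. Overlapping matches are all reported; the result is sorted by
#' acceptor position.
#'
#' @param record A [protein_record].
#' @return A motif-site data frame with columns `protein_id`, `acceptor_pos`
#'   (1-based), `acceptor_res`, `motif_class`, `window` (the matched 4-mer),
#'   `pssm_score` (NA until scored) and `topology_kind` (NA until filtered).
#' @export
#' @examples
#' scan_consensus(protein_record("p1", "YGNTPLHCAA"))
scan_consensus <- function(record) scan_pattern(record, "consensus")

#' Scan a protein for the ankyrin-repeat T/SxxH motif
#'
#' Reports every S/T acceptor with a histidine three residues downstream.
#' This tetrapeptide is characteristic of ankyrin repeats and overlaps the
#' Cdk5 consensus whenever the +3 basic residue is His.
#'
#' @inheritParams scan_consensus
#' @return A motif-site data frame (see [scan_consensus]).
#' @export
scan_txxh <- function(record) scan_pattern(record, "txxh")

#' Merge consensus and T/SxxH scans of the same protein
#'
#' Sites found by both scanners (consensus sites with H at +3) are collapsed
#' to a single row with `motif_class = "both"`.
#'
#' @param consensus,txxh Motif-site data frames from [scan_consensus] and
#'   [scan_txxh] over the same record.
#' @return A merged motif-site data frame sorted by acceptor position.
#' @export
merge_motif_sites <- function(consensus, txxh) {
  shared <- intersect(consensus$acceptor_pos, txxh$acceptor_pos)
  consensus$motif_class[consensus$acceptor_pos %in% shared] <- "both"
  out <- rbind(consensus, txxh[!(txxh$acceptor_pos %in% shared), , drop = FALSE])
  out <- out[order(out$acceptor_pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a position-specific scoring matrix
#'
#' The file is a TSV whose first column (`offset`) gives the position relative
#' to the acceptor (e.g. -4 .. 5) and whose remaining columns are the 20
#' canonical residues. `X` never contributes to a score.
#'
#' @param path Path to the PSSM TSV.
#' @return A numeric matrix, rows named by offset, columns by residue, with
#'   class `scoring_matrix`.
#' @export
read_pssm <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"offset" %in% names(tab)) {
    stop("PSSM file needs an 'offset' column", call. = FALSE)
  }
  m <- as.matrix(tab[, setdiff(names(tab), "offset"), drop = FALSE])
  rownames(m) <- as.character(as.integer(tab$offset))
  missing <- setdiff(AA_CANONICAL, colnames(m))
  if (length(missing) > 0L) {
    stop("PSSM lacks weights for residue(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  storage.mode(m) <- "double"
  structure(m, class = c("scoring_matrix", class(m)))
}

#' A zero scoring matrix over a given offset range
#'
#' Useful as a neutral default when no empirically derived kinase preference
#' matrix is supplied: every site scores 0.
#'
#' @param offsets Integer vector of offsets relative to the acceptor.
#' @return A `scoring_matrix` of zeros.
#' @export
uniform_pssm <- function(offsets = -4:5) {
  m <- matrix(0, nrow = length(offsets), ncol = length(AA_CANONICAL),
              dimnames = list(as.character(offsets), AA_CANONICAL))
  structure(m, class = c("scoring_matrix", class(m)))
}

#' Score a motif site with a position-specific scoring matrix
#'
#' Sums the matrix weight of the observed residue at every offset the matrix
#' covers. Offsets that fall outside the sequence, and `X` residues,
#' contribute 0.
#'
#' @param site One row of a motif-site data frame.
#' @param record The [protein_record] the site was found in.
#' @param matrix A `scoring_matrix` (see [read_pssm], [uniform_pssm]).
#' @return A single numeric log-odds score.
#' @export
score_site <- function(site, record, matrix) {
  stopifnot(inherits(record, "protein_record"))
  offsets <- as.integer(rownames(matrix))
  pos <- site$acceptor_pos[1L] + offsets
  n <- nchar(record$sequence)
  keep <- pos >= 1L & pos <= n
  res <- substring(record$sequence, pos[keep], pos[keep])
  ok <- res %in% colnames(matrix)  # 'X' has no column: scores 0
  sum(matrix[cbind(as.character(offsets[keep][ok]), res[ok])])
}

score_sites <- function(sites, record, matrix) {
  if (nrow(sites) == 0L) return(sites)
  sites$pssm_score <- vapply(seq_len(nrow(sites)), function(i) {
    score_site(sites[i, , drop = FALSE], record, matrix)
  }, numeric(1))
  sites
}

topology_kind_at <- function(record, pos) {
  topo <- record$topology
  kind <- rep("unknown", length(pos))
  if (nrow(topo) > 0L) {
    for (j in seq_len(nrow(topo))) {
      inside <- pos >= topo$start[j] & pos <= topo$end[j]
      kind[inside] <- topo$kind[j]
    }
  }
  kind
}

#' Remove sites buried in transmembrane or extracellular segments
#'
#' Sites whose acceptor falls in a transmembrane or extracellular segment are
#' inaccessible to a cytoplasmic kinase and are dropped. Sites in cytoplasmic
#' segments are kept, and sites at unannotated positions are kept but labelled
#' `"unknown"` rather than discarded: only demonstrably inaccessible sites are
#' excluded. The operation is idempotent.
#'
#' @param sites A motif-site data frame.
#' @param record The [protein_record] carrying the topology annotation.
#' @return The surviving sites with `topology_kind` filled in.
#' @export
filter_topology <- function(sites, record) {
  if (nrow(sites) == 0L) return(sites)
  sites$topology_kind <- topology_kind_at(record, sites$acceptor_pos)
  out <- sites[!(sites$topology_kind %in% c("transmembrane", "extracellular")),
               , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract the decapeptide substrate window around a consensus site
#'
#' Returns residues `acceptor_pos - 3 .. acceptor_pos + 6`: a 10-mer with the
#' acceptor at window position 4 and the obligate proline at position 5,
#' matching how peptide substrates for in vitro kinase assays are designed.
#' Windows clipped at a sequence end are flagged `truncated`.
#'
#' @param record A [protein_record].
#' @param site One row of a consensus motif-site data frame (or a list with
#'   an `acceptor_pos` element).
#' @return A list with `protein_id`, `acceptor_pos`, `sequence10` and
#'   `truncated`.
#' @export
#' @examples
#' rec <- protein_record("p1", "YGNTPLHCAA")
#' extract_peptide(rec, scan_consensus(rec)[1, ])
extract_peptide <- function(record, site) {
  stopifnot(inherits(record, "protein_record"))
  pos <- site$acceptor_pos[1L]
  n <- nchar(record$sequence)
  from <- pos - 3L
  to <- pos + 6L
  truncated <- from < 1L || to > n
  pep <- substring(record$sequence, max(from, 1L), min(to, n))
  list(protein_id = record$id, acceptor_pos = pos,
       sequence10 = pep, truncated = truncated)
}

#' Screen a proteome for accessible kinase consensus sites
#'
#' Composite pipeline: scan every protein for the (S/T)PX(K/H/R) consensus
#' (annotating sites that also satisfy T/SxxH as `"both"`), drop sites in
#' transmembrane or extracellular segments, optionally restrict to proteins
#' whose id is in an expressed-gene set, optionally score surviving sites with
#' a PSSM, and attach the decapeptide window for each site. Rows are ordered
#' by protein id then acceptor position.
#'
#' @param records List of [protein_record] objects (topology attached where
#'   available).
#' @param matrix Optional `scoring_matrix` for site scoring.
#' @param expressed_gene_set Optional character vector of protein/gene ids;
#'   proteins outside the set are skipped.
#' @return Candidate table: `protein_id`, `acceptor_pos`, `acceptor_res`,
#'   `motif_class`, `window`, `peptide10`, `truncated`, `topology_kind`,
#'   `pssm_score`.
#' @export
screen_proteome <- function(records, matrix = NULL, expressed_gene_set = NULL) {
  if (!is.null(expressed_gene_set)) {
    records <- Filter(function(r) r$id %in% expressed_gene_set, records)
  }
  per_protein <- lapply(records, function(rec) {
    sites <- scan_consensus(rec)
    txxh <- scan_txxh(rec)
    sites$motif_class[sites$acceptor_pos %in% txxh$acceptor_pos] <- "both"
    sites <- filter_topology(sites, rec)
    if (!is.null(matrix)) sites <- score_sites(sites, rec, matrix)
    if (nrow(sites) > 0L) {
      peps <- lapply(seq_len(nrow(sites)),
                     function(i) extract_peptide(rec, sites[i, , drop = FALSE]))
      sites$peptide10 <- vapply(peps, `[[`, character(1), "sequence10")
      sites$truncated <- vapply(peps, `[[`, logical(1), "truncated")
    } else {
      sites$peptide10 <- character(0)
      sites$truncated <- logical(0)
    }
    sites
  })
  out <- if (length(per_protein) > 0L) {
    do.call(rbind, c(per_protein, list(make.row.names = FALSE)))
  }
  if (is.null(out) || !is.data.frame(out) || nrow(out) == 0L) {
    out <- empty_sites()
    out$peptide10 <- character(0)
    out$truncated <- logical(0)
  }
  out <- out[order(out$protein_id, out$acceptor_pos), , drop = FALSE]
  rownames(out) <- NULL
  cols <- c("protein_id", "acceptor_pos", "acceptor_res", "motif_class",
            "window", "peptide10", "truncated", "topology_kind", "pssm_score")
  out[, cols]
}

#' Read an expressed-gene set (one id per line)
#'
#' @param path Path to a text file, one gene/protein id per line.
#' @return Character vector of ids.
#' @export
read_gene_set <- function(path) {
  ids <- readLines(path, warn = FALSE)
  ids <- trimws(ids)
  unique(ids[nzchar(ids)])
}
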