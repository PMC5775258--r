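# Independent oracles used across tests. These deliberately take different
# code paths from the package (regex lookahead instead of vectorized residue
# comparison, explicit loops instead of matrix algebra).

oracle_scan <- function(sequence, pattern) {
  hits <- gregexpr(pattern, sequence, perl = TRUE)[[1L]]
  if (hits[1L] == -1L) integer(0) else as.integer(hits)
}

oracle_consensus_positions <- function(sequence) {
  oracle_scan(sequence, "(?=[ST]P[A-Z][KHR])")
}

oracle_txxh_positions <- function(sequence) {
  oracle_scan(sequence, "(?=[ST][A-Z][A-Z]H)")
}

random_protein <- function(n) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"),
               n, replace = TRUE), collapse = "")
}

# Classical equal-variance two-sample t statistic, written out longhand.
oracle_student_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# Tiny binary matrix builder: rows are genes, entries given per gene as
# logical vectors over the same cells.
toy_binary <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  colnames(m) <- paste0("c", seq_len(ncol(m)))
  structure(m, threshold = 5, class = c("binary_expression", class(m)))
}
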