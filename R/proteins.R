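#' @importFrom stats sd setNames rnorm rpois runif t.test aov anova
#' @importFrom utils read.delim write.table read.csv write.csv tail
NULL

AA_CANONICAL <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_ALLOWED <- c(AA_CANONICAL, "X")

TOPOLOGY_KINDS <- c("cytoplasmic", "transmembrane", "extracellular", "unknown")

#' Construct a protein record
#'
#' A protein record couples an amino-acid sequence with optional
#' membrane-topology annotation. Sequences are uppercased on ingestion and a
#' single trailing stop (`*`) is stripped; any other character outside the 20
#' canonical residues plus `X` is an error. Topology segments use 1-based
#' inclusive residue coordinates and may not overlap.
#'
#' @param id Character identifier.
#' @param sequence Amino-acid string (canonical residues plus `X`).
#' @param topology Optional data frame with columns `kind`
#'   (`"cytoplasmic"`, `"transmembrane"`, `"extracellular"` or `"unknown"`),
#'   `start` and `end` (1-based inclusive).
#' @return An object of class `protein_record`: a list with elements `id`,
#'   `sequence` and `topology`.
#' @export
#' @examples
#' protein_record("p1", "ygnTPLHcaa")
protein_record <- function(id, sequence, topology = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  sequence <- sub("\\*$", "", sequence)
  if (!nzchar(sequence)) {
    stop("protein '", id, "': empty sequence", call. = FALSE)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), AA_ALLOWED)
  if (length(bad) > 0L) {
    stop("protein '", id, "': invalid residue character(s): ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  topology <- validate_topology(topology, nchar(sequence), id)
  structure(list(id = id, sequence = sequence, topology = topology),
            class = "protein_record")
}

validate_topology <- function(topology, seq_len, id) {
  if (is.null(topology) || nrow(topology) == 0L) {
    return(data.frame(kind = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  stopifnot(all(c("kind", "start", "end") %in% names(topology)))
  topology <- data.frame(kind = as.character(topology$kind),
                         start = as.integer(topology$start),
                         end = as.integer(topology$end),
                         stringsAsFactors = FALSE)
  if (!all(topology$kind %in% TOPOLOGY_KINDS)) {
    stop("protein '", id, "': unknown topology kind(s): ",
         paste(setdiff(topology$kind, TOPOLOGY_KINDS), collapse = ", "),
         call. = FALSE)
  }
  if (any(topology$start > topology$end)) {
    stop("protein '", id, "': topology segment with start > end", call. = FALSE)
  }
  if (any(topology$start < 1L) || any(topology$end > seq_len)) {
    stop("protein '", id, "': topology segment outside [1, ", seq_len, "]",
         call. = FALSE)
  }
  topology <- topology[order(topology$start), , drop = FALSE]
  if (nrow(topology) > 1L &&
      any(topology$start[-1L] <= topology$end[-nrow(topology)])) {
    stop("protein '", id, "': overlapping topology segments", call. = FALSE)
  }
  rownames(topology) <- NULL
  topology
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record> ", x$id, " (", nchar(x$sequence), " aa, ",
      nrow(x$topology), " topology segment(s))\n", sep = "")
  invisible(x)
}

#' Read proteins from a FASTA file
#'
#' Sequences are uppercased, a terminal stop (`*`) is stripped, and residues
#' outside the 20 canonical amino acids plus `X` raise an error naming the
#' offending character. Record order follows file order.
#'
#' @param path Path to a FASTA file of protein sequences.
#' @return A list of [protein_record] objects (no topology attached).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("not a readable FASTA file: ", path,
                             " (", conditionMessage(e), ")", call. = FALSE))
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate FASTA ids: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  records <- lapply(seq_along(set),
                    function(i) protein_record(ids[i], as.character(set[[i]])))
  names(records) <- ids
  records
}

#' Read membrane-topology annotations
#'
#' Expects a tab-separated file with columns `protein_id`, `kind`, `start`,
#' `end` (1-based inclusive residue intervals).
#'
#' @param path Path to the topology TSV.
#' @return Data frame with those four columns.
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  topo <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "kind", "start", "end")
  if (!all(need %in% names(topo))) {
    stop("topology file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  topo
}

#' Attach topology annotations to protein records
#'
#' @param records List of [protein_record] objects.
#' @param topology Data frame as returned by [read_topology].
#' @return The records with `topology` fields populated (validated per
#'   protein).
#' @export
attach_topology <- function(records, topology) {
  lapply(records, function(rec) {
    seg <- topology[topology$protein_id == rec$id,
                    c("kind", "start", "end"), drop = FALSE]
    protein_record(rec$id, rec$sequence, topology = seg)
  })
}
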