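# Seeded generators producing fixtures with the statistical structure each
# pipeline stage assumes, so the whole pipeline is testable without any
# external download. Identical seeds give identical outputs; every generator
# returns a truth table recording what it planted.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

random_background <- function(n) {
  paste(sample(AA_CANONICAL, n, replace = TRUE), collapse = "")
}

# Replace the +1 proline (consensus) / +3 histidine (txxh) of any chance
# motif so planted-site accounting is exact on a uniform background.
scrub_motifs <- function(seq) {
  repeat {
    rec <- protein_record("tmp", seq)
    hits <- unique(c(scan_consensus(rec)$acceptor_pos,
                     scan_txxh(rec)$acceptor_pos))
    if (length(hits) == 0L) return(seq)
    chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
    for (p in hits) {
      chars[p] <- sample(setdiff(AA_CANONICAL, c("S", "T")), 1L)
    }
    seq <- paste(chars, collapse = "")
  }
}

plant_window <- function(motif_class) {
  acc <- sample(c("S", "T"), 1L)
  if (motif_class == "consensus") {
    plus3 <- sample(c("K", "R"), 1L)  # H would make it 'both'
  } else if (motif_class == "both") {
    plus3 <- "H"
  } else {                            # txxh only: +1 must not be P
    plus3 <- "H"
  }
  mid <- if (motif_class == "txxh") {
    paste0(sample(setdiff(AA_CANONICAL, "P"), 1L),
           sample(setdiff(AA_CANONICAL, c("S", "T")), 1L))
  } else {
    paste0("P", sample(setdiff(AA_CANONICAL, c("S", "T")), 1L))
  }
  paste0(acc, mid, plus3)
}

#' Generate a synthetic proteome with planted motifs and known truth
#'
#' Each protein is a uniform-random amino-acid background, cleansed of chance
#' consensus and T/SxxH motifs so the truth table is exact, split into three
#' equal topology segments (cytoplasmic, transmembrane, extracellular in
#' order), with the requested numbers of motif sites planted at random
#' non-overlapping positions inside each segment.
#'
#' @param n_proteins Number of proteins.
#' @param length Protein length in residues (default 400).
#' @param plan Data frame with columns `topology_kind` (`"cytoplasmic"`,
#'   `"transmembrane"` or `"extracellular"`), `motif_class` (`"consensus"`,
#'   `"txxh"` or `"both"`) and `n` (sites per protein). Default: 2 cytoplasmic
#'   consensus, 1 transmembrane consensus, 1 extracellular consensus and
#'   1 cytoplasmic txxh site per protein.
#' @param seed Integer seed.
#' @return List with `records` (topology-annotated [protein_record]s) and
#'   `truth` (data frame `protein_id`, `acceptor_pos`, `motif_class`,
#'   `topology_kind`, `window4`).
#' @export
gen_proteome <- function(n_proteins, length = 400L, plan = NULL, seed = 1L) {
  if (is.null(plan)) {
    plan <- data.frame(
      topology_kind = c("cytoplasmic", "transmembrane", "extracellular",
                        "cytoplasmic"),
      motif_class = c("consensus", "consensus", "consensus", "txxh"),
      n = c(2L, 1L, 1L, 1L), stringsAsFactors = FALSE)
  }
  with_seed(seed, {
    third <- length %/% 3L
    segs <- data.frame(
      kind = c("cytoplasmic", "transmembrane", "extracellular"),
      start = c(1L, third + 1L, 2L * third + 1L),
      end = c(third, 2L * third, as.integer(length)),
      stringsAsFactors = FALSE)
    if (sum(plan$n) * 10L > third) {
      stop("motif plan infeasible for protein length ", length, call. = FALSE)
    }
    records <- vector("list", n_proteins)
    truth <- list()
    for (k in seq_len(n_proteins)) {
      id <- sprintf("prot%03d", k)
      seq <- scrub_motifs(random_background(length))
      chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
      used <- integer(0)
      for (j in seq_len(nrow(plan))) {
        seg <- segs[segs$kind == plan$topology_kind[j], ]
        for (s in seq_len(plan$n[j])) {
          # keep the whole 4-mer inside the segment, away from planted sites
          repeat {
            pos <- sample(seq.int(seg$start, seg$end - 3L), 1L)
            if (!any(abs(pos - used) < 8L)) break
          }
          used <- c(used, pos)
          win <- plant_window(plan$motif_class[j])
          chars[pos:(pos + 3L)] <- strsplit(win, "", fixed = TRUE)[[1L]]
          truth[[length(truth) + 1L]] <- data.frame(
            protein_id = id, acceptor_pos = pos,
            motif_class = plan$motif_class[j],
            topology_kind = plan$topology_kind[j],
            window4 = win, stringsAsFactors = FALSE)
        }
      }
      # planting may have created new chance motifs at flank junctions;
      # rebuild and verify, rescrubbing non-planted hits only
      seq <- paste(chars, collapse = "")
      planted <- vapply(truth, function(t)
        if (t$protein_id == id) t$acceptor_pos else NA_integer_, integer(1))
      planted <- planted[!is.na(planted)]
      repeat {
        rec <- protein_record(id, seq)
        hits <- unique(c(scan_consensus(rec)$acceptor_pos,
                         scan_txxh(rec)$acceptor_pos))
        stray <- setdiff(hits, planted)
        if (length(stray) == 0L) break
        ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
        for (p in stray) {
          ch[p] <- sample(setdiff(AA_CANONICAL, c("S", "T")), 1L)
        }
        seq <- paste(ch, collapse = "")
      }
      records[[k]] <- protein_record(id, seq, topology = segs)
    }
    names(records) <- vapply(records, `[[`, character(1), "id")
    truth <- do.call(rbind, c(truth, list(make.row.names = FALSE)))
    truth <- truth[order(truth$protein_id, truth$acceptor_pos), , drop = FALSE]
    rownames(truth) <- NULL
    list(records = records, truth = truth)
  })
}

#' Write a generated proteome to FASTA + topology + truth files
#'
#' @param proteome Result of [gen_proteome].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written (`proteome.fasta`, `topology.tsv`,
#'   `truth_sites.tsv`).
#' @export
write_proteome <- function(proteome, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(out_dir, "proteome.fasta")
  seqs <- Biostrings::AAStringSet(
    setNames(vapply(proteome$records, `[[`, character(1), "sequence"),
             vapply(proteome$records, `[[`, character(1), "id")))
  Biostrings::writeXStringSet(seqs, fasta)
  topo <- do.call(rbind, lapply(proteome$records, function(r)
    cbind(protein_id = r$id, r$topology)))
  topo_path <- file.path(out_dir, "topology.tsv")
  write.table(topo, topo_path, sep = "\t", quote = FALSE, row.names = FALSE)
  truth_path <- file.path(out_dir, "truth_sites.tsv")
  write.table(proteome$truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(fasta, topo_path, truth_path))
}

#' Generate a synthetic single-cell FPKM matrix with known positivity
#'
#' Each gene is positive in a cell with its planted prevalence probability;
#' positive cells draw FPKM from a log-normal shifted above the positivity
#' threshold, negative cells draw uniformly below it. Dropout zeroes positive
#' measurements at random (lowering measured prevalence below the planted
#' one). Nested pairs force one gene's positive cells to be a subset of
#' another's, so the conditional coexpression fraction of the pair is exactly
#' 100%.
#'
#' @param n_genes,n_cells Matrix dimensions.
#' @param prevalence Per-gene positivity probabilities (recycled).
#' @param dropout Probability that a positive measurement is zeroed
#'   (default 0).
#' @param nested Optional list of `c(child, parent)` gene-index pairs: every
#'   child-positive cell is made parent-positive.
#' @param threshold Positivity threshold in FPKM (default 5).
#' @param seed Integer seed.
#' @return List with `matrix` (genes x cells FPKM), `positive` (planted
#'   logical matrix, pre-dropout) and `truth` (per-gene planted prevalence).
#' @export
gen_sc_matrix <- function(n_genes, n_cells, prevalence = 0.4, dropout = 0,
                          nested = NULL, threshold = 5, seed = 1L) {
  stopifnot(all(prevalence >= 0 & prevalence <= 1), dropout >= 0, dropout < 1)
  with_seed(seed, {
    prev <- rep_len(prevalence, n_genes)
    genes <- sprintf("gene%03d", seq_len(n_genes))
    cells <- sprintf("cell%05d", seq_len(n_cells))
    pos <- matrix(runif(n_genes * n_cells) < prev, n_genes, n_cells,
                  dimnames = list(genes, cells))
    for (pair in nested) {
      pos[pair[2L], ] <- pos[pair[2L], ] | pos[pair[1L], ]
      # parent positivity is the union of two independent draws
      prev[pair[2L]] <- 1 - (1 - prev[pair[2L]]) * (1 - prev[pair[1L]])
    }
    if (dropout > 0) {
      keep <- matrix(runif(n_genes * n_cells) >= dropout, n_genes, n_cells)
      measured <- pos & keep
    } else {
      measured <- pos
    }
    m <- matrix(runif(n_genes * n_cells, 0, threshold * 0.9),
                n_genes, n_cells, dimnames = list(genes, cells))
    npos <- sum(measured)
    m[measured] <- threshold * exp(abs(rnorm(npos, 0, 0.8)))
    truth <- data.frame(gene = genes, planted_prevalence = rowMeans(pos),
                        expected_prevalence = prev * (1 - dropout),
                        stringsAsFactors = FALSE)
    list(matrix = m, positive = pos, truth = truth)
  })
}

default_schedule <- function() {
  data.frame(label = c("AITC_low", "AITC_high", "KCl"),
             onset = c(60, 150, 240), offset = c(90, 180, 270),
             washout_end = c(150, 240, 300), stringsAsFactors = FALSE)
}

# Double-exponential transient: rises toward a plateau during application,
# decays after offset; scaled so the sampled maximum equals `fold`.
transient <- function(time, onset, offset, fold, tau_rise = 8, tau_decay = 30) {
  s <- numeric(length(time))
  during <- time >= onset & time <= offset
  after <- time > offset
  s[during] <- 1 - exp(-(time[during] - onset) / tau_rise)
  s_off <- 1 - exp(-(offset - onset) / tau_rise)
  s[after] <- s_off * exp(-(time[after] - offset) / tau_decay)
  (fold - 1) * s / s_off
}

#' Generate synthetic Fura-2 relative-ratio traces with known responder truth
#'
#' Neurons are a two-population mixture. Responders carry a stimulus-locked
#' transient whose peak fold is drawn from
#' `Normal(responder_fold_mean, responder_fold_sd)`; non-responders' peak
#' folds are drawn from `Normal(nonresponder_peak_mean, nonresponder_peak_sd)`
#' (mean 1.00, SD 0.05 by default, matching the population the 3-SD cutoff
#' rule is calibrated on). A configurable fraction of neurons responds to the
#' terminal KCl depolarisation; a configurable fraction of low-dose responders
#' fails to recover before the high dose (desensitization). Traces are
#' baseline-1 relative ratios sampled every `dt` seconds with Gaussian noise.
#'
#' @param n_mice Number of mice.
#' @param neurons_per_mouse Neurons per mouse (single number, or vector of
#'   length `n_mice`).
#' @param responder_fraction Fraction of (KCl-responsive) neurons that respond
#'   to the agonist.
#' @param responder_fold_mean,responder_fold_sd Responder peak-fold
#'   distribution (defaults 1.45 and 0.08, within the 1.3-1.6 range typical
#'   of low-dose agonist responses).
#' @param nonresponder_peak_mean,nonresponder_peak_sd Non-responder peak-fold
#'   distribution (defaults 1.00 and 0.05).
#' @param desensitize_prob Probability that a low-dose responder stays
#'   elevated into the high-dose window (default 0).
#' @param kcl_fraction Fraction of neurons responding to KCl (default 1).
#' @param kcl_fold Peak fold of the KCl response (default 2).
#' @param schedule Stimulus schedule (default: low dose at 60-90 s, high dose
#'   at 150-180 s, KCl at 240-270 s, 300 s total).
#' @param dt Sampling interval in seconds (default 2).
#' @param noise_sd Gaussian noise SD on the relative trace (default 0.005).
#' @param seed Integer seed.
#' @return List with `traces` (long data frame `neuron_id`, `mouse_id`,
#'   `time`, `ratio`), `schedule`, and `truth` (per neuron: class, planted
#'   peak folds, desensitized and KCl flags).
#' @export
gen_traces <- function(n_mice, neurons_per_mouse, responder_fraction,
                       responder_fold_mean = 1.45, responder_fold_sd = 0.08,
                       nonresponder_peak_mean = 1.00,
                       nonresponder_peak_sd = 0.05,
                       desensitize_prob = 0, kcl_fraction = 1, kcl_fold = 2,
                       schedule = default_schedule(), dt = 2,
                       noise_sd = 0.005, seed = 1L) {
  stopifnot(responder_fraction >= 0, responder_fraction <= 1)
  npm <- rep_len(neurons_per_mouse, n_mice)
  with_seed(seed, {
    time <- seq(0, max(schedule$washout_end), by = dt)
    rows <- list(); truths <- list()
    idx <- 0L
    for (m in seq_len(n_mice)) {
      mouse <- sprintf("mouse%02d", m)
      for (j in seq_len(npm[m])) {
        idx <- idx + 1L
        neuron <- sprintf("n%05d", idx)
        kcl_resp <- runif(1) < kcl_fraction
        is_resp <- kcl_resp && runif(1) < responder_fraction
        desens <- FALSE
        low_fold <- rnorm(1, nonresponder_peak_mean, nonresponder_peak_sd)
        high_fold <- rnorm(1, nonresponder_peak_mean, nonresponder_peak_sd)
        trace <- rep(1, length(time))
        if (is_resp) {
          low_fold <- rnorm(1, responder_fold_mean, responder_fold_sd)
          high_fold <- rnorm(1, responder_fold_mean, responder_fold_sd)
          desens <- runif(1) < desensitize_prob
          tau_d <- if (desens) 1e6 else 12
          trace <- trace + transient(time, schedule$onset[1L],
                                     schedule$offset[1L], low_fold,
                                     tau_decay = tau_d)
          if (!desens) {
            trace <- trace + transient(time, schedule$onset[2L],
                                       schedule$offset[2L], high_fold)
          }
        } else {
          # non-responders still show a small drift "peak" so their measured
          # amplitude-fold distribution has the configured moments
          trace <- trace + transient(time, schedule$onset[1L],
                                     schedule$offset[1L], low_fold)
          trace <- trace + transient(time, schedule$onset[2L],
                                     schedule$offset[2L], high_fold)
        }
        if (kcl_resp) {
          trace <- trace + transient(time, schedule$onset[3L],
                                     schedule$offset[3L], kcl_fold)
        }
        trace <- trace + rnorm(length(time), 0, noise_sd)
        rows[[idx]] <- data.frame(neuron_id = neuron, mouse_id = mouse,
                                  time = time, ratio = trace,
                                  stringsAsFactors = FALSE)
        truths[[idx]] <- data.frame(
          neuron_id = neuron, mouse_id = mouse, is_responder = is_resp,
          kcl_responder = kcl_resp, desensitized = desens,
          low_peak_fold = low_fold, high_peak_fold = high_fold,
          stringsAsFactors = FALSE)
      }
    }
    list(traces = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         schedule = schedule,
         truth = do.call(rbind, c(truths, list(make.row.names = FALSE))))
  })
}

#' Generate synthetic lickometer sessions with known dose effects
#'
#' Every animal gets `n_sessions` baseline (water) sessions and `n_sessions`
#' sessions per agonist concentration. Counts are Poisson around the
#' genotype's planted percent-of-baseline effect at each concentration.
#'
#' @param genotype_effects Named list: genotype -> numeric vector of expected
#'   percent-of-baseline per concentration (e.g. `list(WT = c(90, 60, 30,
#'   15))`).
#' @param concentrations Concentration grid (default `c(1, 10, 100, 1000)`).
#' @param n_animals Animals per genotype (default 4).
#' @param n_sessions Sessions per condition (default 5).
#' @param baseline_mean Mean baseline lick count per 1 h session
#'   (default 1500).
#' @param seed Integer seed.
#' @return List with `sessions` (long data frame) and `truth` (planted
#'   percent per genotype and concentration).
#' @export
gen_lick_sessions <- function(genotype_effects,
                              concentrations = c(1, 10, 100, 1000),
                              n_animals = 4L, n_sessions = 5L,
                              baseline_mean = 1500, seed = 1L) {
  stopifnot(all(lengths(genotype_effects) == length(concentrations)))
  with_seed(seed, {
    rows <- list()
    for (g in names(genotype_effects)) {
      eff <- genotype_effects[[g]]
      for (a in seq_len(n_animals)) {
        animal <- sprintf("%s_a%02d", g, a)
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = animal, genotype = g, condition = "water",
          session = seq_len(n_sessions),
          licks = rpois(n_sessions, baseline_mean), stringsAsFactors = FALSE)
        for (ci in seq_along(concentrations)) {
          rows[[length(rows) + 1L]] <- data.frame(
            animal_id = animal, genotype = g,
            condition = as.character(concentrations[ci]),
            session = seq_len(n_sessions),
            licks = rpois(n_sessions, baseline_mean * eff[ci] / 100),
            stringsAsFactors = FALSE)
        }
      }
    }
    truth <- do.call(rbind, lapply(names(genotype_effects), function(g)
      data.frame(genotype = g, concentration = concentrations,
                 planted_pct = genotype_effects[[g]],
                 stringsAsFactors = FALSE)))
    list(sessions = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         truth = truth)
  })
}
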