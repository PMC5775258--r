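# Operant lickometer aversion metric: licking of agonist-dosed water as a
# percentage of each animal's baseline (plain-water) licking.

#' Read lickometer sessions
#'
#' CSV with columns `animal_id`, `genotype`, `condition` (`"water"` for
#' baseline sessions or the agonist concentration in micromolar), `session`
#' and `licks` (non-negative count over the 1 h session).
#'
#' @param path Path to the sessions CSV.
#' @return Validated sessions data frame.
#' @export
read_lick_sessions <- function(path) {
  s <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "genotype", "condition", "session", "licks")
  if (!all(need %in% names(s))) {
    stop("sessions need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(s$licks < 0)) stop("negative lick count", call. = FALSE)
  s
}

#' Licking under agonist as percent of baseline
#'
#' `100 * mean(licks in agonist sessions) / mean(licks in water sessions)`
#' for one animal at one concentration. Values above 100 are meaningful (more
#' licking than baseline, i.e. reduced aversion).
#'
#' @param sessions Sessions data frame (see [read_lick_sessions]).
#' @param animal Animal id.
#' @param concentration Agonist concentration (matching `condition`).
#' @param baseline_last_k Use only the last `k` water sessions as baseline;
#'   `NULL` (default) averages all water sessions.
#' @return Percentage of baseline licking.
#' @export
percent_of_baseline <- function(sessions, animal, concentration,
                                baseline_last_k = NULL) {
  s <- sessions[sessions$animal_id == animal, , drop = FALSE]
  base <- s[s$condition == "water", , drop = FALSE]
  test <- s[s$condition == as.character(concentration), , drop = FALSE]
  if (nrow(base) == 0L) {
    stop("animal '", animal, "': no baseline (water) session", call. = FALSE)
  }
  if (nrow(test) == 0L) {
    stop("animal '", animal, "': no session at concentration ",
         concentration, call. = FALSE)
  }
  if (!is.null(baseline_last_k)) {
    base <- base[order(base$session), , drop = FALSE]
    base <- tail(base, baseline_last_k)
  }
  bmean <- mean(base$licks)
  if (bmean == 0) {
    stop("animal '", animal, "': zero baseline licking", call. = FALSE)
  }
  100 * mean(test$licks) / bmean
}

#' Dose-response table of aversion by genotype
#'
#' Per-animal percent-of-baseline values are computed first (the animal is
#' the unit of analysis), then summarised per genotype and concentration as
#' mean and SEM. With exactly two genotypes, each concentration is compared
#' with [group_compare]; with one genotype the comparison columns are `NA`
#' and a notice is emitted.
#'
#' @param sessions Sessions data frame.
#' @param concentrations Concentration grid (default `c(1, 10, 100, 1000)`
#'   micromolar).
#' @param test Group test passed to [group_compare].
#' @return Data frame: `genotype`, `concentration`, `n_animals`, `mean_pct`,
#'   `sem_pct`, `p_value` (vs the other genotype at that concentration).
#' @export
dose_response_table <- function(sessions,
                                concentrations = c(1, 10, 100, 1000),
                                test = "unpaired_t") {
  genotypes <- unique(sessions$genotype)
  per_animal <- expand.grid(animal = unique(sessions$animal_id),
                            concentration = concentrations,
                            stringsAsFactors = FALSE)
  per_animal$genotype <- sessions$genotype[
    match(per_animal$animal, sessions$animal_id)]
  per_animal$pct <- mapply(function(an, conc)
    percent_of_baseline(sessions, an, conc),
    per_animal$animal, per_animal$concentration)

  rows <- lapply(genotypes, function(g) {
    lapply(concentrations, function(conc) {
      v <- per_animal$pct[per_animal$genotype == g &
                          per_animal$concentration == conc]
      data.frame(genotype = g, concentration = conc,
                 n_animals = length(v), mean_pct = mean(v),
                 sem_pct = if (length(v) > 1L) sd(v) / sqrt(length(v)) else 0,
                 p_value = NA_real_, stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, c(unlist(rows, recursive = FALSE),
                          list(make.row.names = FALSE)))
  if (length(genotypes) == 2L) {
    for (conc in concentrations) {
      va <- per_animal$pct[per_animal$genotype == genotypes[1L] &
                           per_animal$concentration == conc]
      vb <- per_animal$pct[per_animal$genotype == genotypes[2L] &
                           per_animal$concentration == conc]
      if (length(va) >= 2L && length(vb) >= 2L) {
        p <- group_compare(va, vb, test = test)$p_value
        out$p_value[out$concentration == conc] <- p
      }
    }
  } else if (length(genotypes) < 2L) {
    message("single genotype: group tests skipped")
  }
  out
}
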