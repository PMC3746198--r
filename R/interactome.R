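# AP-MS interactome filtering: a protein is called a Nanog interactor when it
# passes the per-run evidence criteria (Mascot score > 50, at least 3-fold
# over the paired control, a minimum of unique peptides) in at least 2 of the
# 3 purifications.

#' Fold of bait Mascot score over the paired control
#'
#' When the control score is absent (`NA`) or zero the fold is infinite, so
#' the fold criterion always passes (a protein never seen in the control
#' purification cannot be background-subtracted).
#'
#' @param bait Mascot score(s) in the bait purification (>= 0).
#' @param control Mascot score(s) in the paired control, `NA` when absent.
#' @return Numeric fold(s), possibly `Inf`.
#' @export
fold_over_control <- function(bait, control) {
  if (any(bait < 0, na.rm = TRUE) || any(control < 0, na.rm = TRUE))
    stop("Mascot scores must be non-negative")
  ifelse(is.na(control) | control == 0, Inf, bait / control)
}

#' Does a single-run hit pass the inclusion criteria?
#'
#' `TRUE` iff the bait Mascot score strictly exceeds `min_score`, the fold
#' over control is at least `min_fold`, and the unique-peptide count is at
#' least `min_peptides`. Vectorised.
#'
#' @param mascot_bait Bait Mascot score(s).
#' @param mascot_control Paired control score(s), `NA` when absent.
#' @param unique_peptides Unique non-redundant peptide count(s).
#' @param min_score Strict lower bound on the bait score (default 50).
#' @param min_fold Minimum fold over control (default 3).
#' @param min_peptides Minimum unique peptides (default 3; set to 0 to apply
#'   only the score and fold criteria).
#' @return Logical vector.
#' @export
passes_run <- function(mascot_bait, mascot_control, unique_peptides,
                       min_score = 50, min_fold = 3, min_peptides = 3) {
  mascot_bait > min_score &
    fold_over_control(mascot_bait, mascot_control) >= min_fold &
    unique_peptides >= min_peptides
}

#' Call interactors from an AP-MS hit table
#'
#' A protein is called iff it passes [passes_run()] in at least
#' `required_runs` distinct runs. The result is sorted by protein identifier
#' and invariant under permutation of the input rows.
#'
#' @param hits `data.frame` with columns protein, run, mascot_bait,
#'   mascot_control (`NA` allowed), unique_peptides.
#' @param required_runs Distinct passing runs required for a call (default 2).
#' @param run_labels The known run labels; defaults to the runs present.
#'   A hit with a run label outside this set is a validation error.
#' @param min_score,min_fold,min_peptides Per-run criteria (see
#'   [passes_run()]).
#' @return `data.frame`: protein, called, n_passing_runs, passing_runs
#'   (comma-joined), per_run_fold (comma-joined `run=fold`).
#' @export
call_interactors <- function(hits, required_runs = 2, run_labels = NULL,
                             min_score = 50, min_fold = 3, min_peptides = 3) {
  need <- c("protein", "run", "mascot_bait", "mascot_control", "unique_peptides")
  if (!all(need %in% names(hits)))
    stop("hit table missing columns: ", paste(setdiff(need, names(hits)), collapse = ", "))
  if (is.null(run_labels)) run_labels <- sort(unique(hits$run))
  unknown <- setdiff(unique(hits$run), run_labels)
  if (length(unknown) > 0)
    stop("unknown run label(s): ", paste(unknown, collapse = ", "))
  if (nrow(hits) == 0)
    return(data.frame(protein = character(), called = logical(),
                      n_passing_runs = integer(), passing_runs = character(),
                      per_run_fold = character(), stringsAsFactors = FALSE))
  hits$pass <- passes_run(hits$mascot_bait, hits$mascot_control,
                          hits$unique_peptides, min_score, min_fold, min_peptides)
  hits$fold <- fold_over_control(hits$mascot_bait, hits$mascot_control)
  by_prot <- split(hits, hits$protein)
  rows <- lapply(by_prot, function(h) {
    h <- h[order(h$run), , drop = FALSE]
    passing <- sort(unique(h$run[h$pass]))
    data.frame(protein = h$protein[1],
               called = length(passing) >= required_runs,
               n_passing_runs = length(passing),
               passing_runs = paste(passing, collapse = ","),
               per_run_fold = paste(sprintf("%s=%.3g", h$run, h$fold),
                                    collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$protein), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read an AP-MS hit table
#'
#' Tab-separated with header: protein, run, mascot_bait, mascot_control
#' (empty/NA when no control score), unique_peptides.
#'
#' @param path File path.
#' @return `data.frame` of hits.
#' @export
read_ms_table <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
  need <- c("protein", "run", "mascot_bait", "mascot_control", "unique_peptides")
  if (!all(need %in% names(tab)))
    stop("MS hit table missing columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  tab
}

#' Write an AP-MS hit table
#' @param hits Hit `data.frame`.
#' @param path Output path.
#' @export
write_ms_table <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write interactor calls as TSV
#' @param calls Call `data.frame` from [call_interactors()].
#' @param path Output path.
#' @export
write_interactor_calls <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
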