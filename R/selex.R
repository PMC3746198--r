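# SELEX simulation: a random oligo library is iteratively subjected to a
# binding/capture step and PCR-style resampling, and the enriched pool's best
# sites are extracted to rebuild the selected motif as a PWM.

SELEX_FLANK5 <- "ACGTGGATCCACTGACGG"
SELEX_FLANK3 <- "GCTAGCGCCTCGAGACTTG"

#' Specification of a random oligo library
#'
#' The library design: a random core flanked by fixed primer-annealing
#' sequences. At the defaults the oligo length is 18 + 25 + 19 = 62 bp.
#'
#' @param core_length Random-core length in bp (default 25).
#' @param flank5,flank3 Fixed flanking sequences.
#' @param pool_size Number of oligos in the pool (default 100000; the
#'   enriched pool then carries several hundred distinct informative sites,
#'   enough for a stable degenerate consensus).
#' @param seed Optional integer seed for reproducible generation.
#' @return An `oligo_library_spec`.
#' @export
oligo_library_spec <- function(core_length = 25L, flank5 = SELEX_FLANK5,
                               flank3 = SELEX_FLANK3, pool_size = 100000L,
                               seed = NULL) {
  stopifnot(core_length >= 1, pool_size >= 0)
  structure(list(core_length = as.integer(core_length), flank5 = flank5,
                 flank3 = flank3, pool_size = as.integer(pool_size),
                 seed = seed),
            class = "oligo_library_spec")
}

#' Oligo length implied by a library spec
#' @param spec An `oligo_library_spec`.
#' @return Integer length in bp.
#' @export
oligo_length <- function(spec) {
  nchar(spec$flank5) + spec$core_length + nchar(spec$flank3)
}

# Core generation without touching the seed (callers manage seeding).
random_cores <- function(n, core_length) {
  if (n == 0) return(character(0))
  m <- matrix(sample(BASES, n * core_length, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Generate a random oligo library
#'
#' Each oligo is `flank5` + a uniform-random core + `flank3`. Reproducible
#' when the spec carries a seed.
#'
#' @param spec An `oligo_library_spec`.
#' @return Character vector of oligos.
#' @export
generate_library <- function(spec) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  if (spec$pool_size == 0) return(character(0))
  paste0(spec$flank5, random_cores(spec$pool_size, spec$core_length), spec$flank3)
}

#' A two-level capture model for the selection step
#'
#' Abstracts the physical binding step: an oligo whose sequence contains a
#' site for the planted pattern (either strand) is retained with probability
#' `capture_bound`, any other oligo with `capture_base`. With a PWM instead
#' of a pattern, the capture probability interpolates between the two levels
#' with a Boltzmann weight on the best log2-odds site score:
#' `capture_base + (capture_bound - capture_base) * 2^((s - s_max)/temperature)`.
#'
#' @param pattern_or_pwm A `degenerate_pattern` or a `pwm`.
#' @param capture_base Capture probability for a motif-free oligo.
#' @param capture_bound Capture probability for a motif-bearing oligo (or the
#'   level reached by a perfect PWM site); must be >= `capture_base`.
#' @param temperature Softness of the PWM weight in log2-score units
#'   (PWM mode only).
#' @return A `binding_model`.
#' @export
binding_model <- function(pattern_or_pwm, capture_base = 0.05,
                          capture_bound = 0.9, temperature = 2) {
  stopifnot(capture_base >= 0, capture_bound <= 1,
            capture_bound >= capture_base, temperature > 0)
  structure(list(model = pattern_or_pwm, capture_base = capture_base,
                 capture_bound = capture_bound, temperature = temperature),
            class = "binding_model")
}

# Per-oligo capture probabilities under a binding model.
capture_probs <- function(pool, model) {
  if (length(pool) == 0) return(numeric(0))
  if (inherits(model$model, "degenerate_pattern")) {
    has <- spans_have_motif(Biostrings::DNAStringSet(pool), model$model)
    ifelse(has, model$capture_bound, model$capture_base)
  } else if (inherits(model$model, "pwm")) {
    smax <- pwm_max_score(model$model)
    s <- vapply(pool, pwm_best_score, numeric(1), pwm = model$model,
                USE.NAMES = FALSE)
    w <- 2^((s - smax) / model$temperature)
    pmin(1, model$capture_base + (model$capture_bound - model$capture_base) * w)
  } else stop("binding model must wrap a degenerate_pattern or a pwm")
}

#' One selection (capture) round
#'
#' Retains each oligo independently with its model-determined capture
#' probability.
#'
#' @param pool Character vector of oligos.
#' @param model A `binding_model`.
#' @return The bound sub-pool (character vector).
#' @export
selection_round <- function(pool, model) {
  p <- capture_probs(pool, model)
  pool[runif(length(pool)) < p]
}

#' Amplify a bound sub-pool back to constant pool size
#'
#' Multinomial resampling with replacement; composition frequencies are
#' preserved in expectation.
#'
#' @param bound Bound sub-pool (non-empty character vector).
#' @param target_size Output pool size.
#' @return Character vector of `target_size` oligos.
#' @export
amplify <- function(bound, target_size) {
  if (length(bound) == 0)
    stop("selex extinction: empty bound pool cannot be amplified")
  if (target_size == 0) return(character(0))
  sample(bound, target_size, replace = TRUE)
}

#' Run a full SELEX simulation
#'
#' Alternates [selection_round()] and [amplify()] for `rounds` cycles
#' (5 by default), recording the planted-motif frequency of the pool after
#' each round. `rounds = 0` returns the initial pool unchanged.
#'
#' @param spec An `oligo_library_spec`.
#' @param model A `binding_model`.
#' @param rounds Number of enrichment rounds (default 5).
#' @param track_pattern Pattern whose pool frequency is recorded per round;
#'   defaults to the model's pattern (required for PWM-mode models).
#' @param keep_pools Keep every per-round pool (default) or only the final.
#' @return A `selex_run`: list with `pools` (list, rounds + 1 entries),
#'   `final_pool`, `trajectory` (`data.frame` round, pool_size,
#'   motif_frequency), `spec`, `rounds`.
#' @export
run_selex <- function(spec, model, rounds = 5L, track_pattern = NULL,
                      keep_pools = TRUE) {
  force(model)                    # evaluate before touching the RNG
  stopifnot(rounds >= 0)
  if (is.null(track_pattern)) {
    if (!inherits(model$model, "degenerate_pattern"))
      stop("track_pattern is required when the binding model wraps a PWM")
    track_pattern <- model$model
  }
  if (!is.null(spec$seed)) set.seed(spec$seed)
  spec_noseed <- spec; spec_noseed$seed <- NULL
  pool <- generate_library(spec_noseed)
  motif_freq <- function(p) {
    if (length(p) == 0) return(NA_real_)
    mean(spans_have_motif(Biostrings::DNAStringSet(p), track_pattern))
  }
  pools <- list(pool)
  traj <- data.frame(round = 0L, pool_size = length(pool),
                     motif_frequency = motif_freq(pool))
  for (r in seq_len(rounds)) {
    bound <- selection_round(pool, model)
    if (length(bound) == 0)
      stop(sprintf("selex extinction at round %d: no oligos captured", r))
    pool <- amplify(bound, spec$pool_size)
    pools[[r + 1L]] <- pool
    traj <- rbind(traj, data.frame(round = r, pool_size = length(pool),
                                   motif_frequency = motif_freq(pool)))
  }
  structure(list(pools = if (keep_pools) pools else pools[length(pools)],
                 final_pool = pool, trajectory = traj, spec = spec,
                 rounds = rounds),
            class = "selex_run")
}

#' @export
print.selex_run <- function(x, ...) {
  cat(sprintf("SELEX run: %d rounds, pool size %d\n", x$rounds,
              x$spec$pool_size))
  print(x$trajectory, row.names = FALSE)
  invisible(x)
}

#' Extract the best aligned site per oligo
#'
#' For each oligo the single best pattern match is reported as a fixed-width
#' site in pattern orientation (minus-strand matches are reverse
#' complemented). "Best" is the leftmost match, with the plus strand
#' preferred on an exact position tie. By default only matches fully inside
#' the random core are considered, excluding flank-assisted artifactual
#' sites; set `core_only = FALSE` to scan whole oligos. Oligos without a
#' match are dropped.
#'
#' @param pool Character vector of oligos.
#' @param pattern A `degenerate_pattern`.
#' @param spec The `oligo_library_spec` that generated the pool (defines the
#'   core boundaries).
#' @param core_only Restrict matches to the random core (default `TRUE`).
#' @return Character vector of aligned sites (pattern length each).
#' @export
extract_sites <- function(pool, pattern, spec = oligo_library_spec(),
                          core_only = TRUE) {
  if (length(pool) == 0) return(character(0))
  L <- pattern_length(pattern)
  ss <- Biostrings::DNAStringSet(pool)
  fwd <- Biostrings::vmatchPattern(
    Biostrings::DNAString(pattern_to_iupac(pattern)), ss, fixed = "subject")
  rev <- Biostrings::vmatchPattern(
    Biostrings::DNAString(pattern_to_iupac(reverse_complement_pattern(pattern))),
    ss, fixed = "subject")
  lo <- if (core_only) nchar(spec$flank5) + 1L else 1L       # 1-based start bound
  hi_of <- function(width)
    if (core_only) nchar(spec$flank5) + spec$core_length - L + 1L else width - L + 1L
  widths <- nchar(pool)
  best_in <- function(starts, w) {
    s <- starts[starts >= lo & starts <= hi_of(w)]
    if (length(s) == 0) NA_integer_ else min(s)
  }
  fs <- Biostrings::startIndex(fwd)
  rs <- Biostrings::startIndex(rev)
  bf <- vapply(seq_along(pool), function(i)
    best_in(if (is.null(fs[[i]])) integer(0) else fs[[i]], widths[i]), integer(1))
  br <- vapply(seq_along(pool), function(i)
    best_in(if (is.null(rs[[i]])) integer(0) else rs[[i]], widths[i]), integer(1))
  # leftmost match wins; the plus strand wins exact ties
  use_fwd <- !is.na(bf) & (is.na(br) | bf <= br)
  use_rev <- !is.na(br) & !use_fwd
  sites <- character(length(pool))
  sites[use_fwd] <- substr(pool[use_fwd], bf[use_fwd], bf[use_fwd] + L - 1L)
  if (any(use_rev)) {
    minus <- substr(pool[use_rev], br[use_rev], br[use_rev] + L - 1L)
    sites[use_rev] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(minus)))
  }
  sites[use_fwd | use_rev]
}

#' Write a pool of oligos as FASTA
#' @param pool Character vector of oligos.
#' @param path Output path.
#' @export
write_pool_fasta <- function(pool, path) {
  ss <- Biostrings::DNAStringSet(pool)
  names(ss) <- sprintf("oligo_%06d", seq_along(pool))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a pool of oligos from FASTA
#' @param path FASTA path.
#' @return Character vector of oligos.
#' @export
read_pool_fasta <- function(path) {
  as.character(Biostrings::readDNAStringSet(path), use.names = FALSE)
}

#' Write a SELEX trajectory as TSV
#' @param run A `selex_run`.
#' @param path Output path.
#' @export
write_trajectory <- function(run, path) {
  write.table(run$trajectory, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
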