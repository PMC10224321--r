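# Synthetic data generators: affibody-style enrichment experiments and
# stability (Tm) tables with known ground truth. These are first-class,
# tested components -- every downstream stage is exercised against data
# whose planted signal is known exactly.

# 58-residue Z-domain scaffold commonly used for affibody libraries.
Z_DOMAIN_SCAFFOLD <-
  "VDNKFNKEQQNAFYEILHLPNLNEEQRNAFIQSLKDDPSQSANLLAEAKKLNDAQAPK"

# Classic 13 randomized helix-1/2 binding-surface positions (1-based).
Z_DOMAIN_VARIABLE_POSITIONS <- c(9, 10, 11, 13, 14, 17, 18, 24, 25, 27, 28, 32, 35)

# Residues counted as hydrophobic for composition features and the
# stability generator's composition effect.
HYDROPHOBIC_SET <- c("A", "C", "F", "I", "L", "M", "V", "W")

#' Configuration for the affibody-like library simulator
#'
#' Describes a fixed-length (58 aa) combinatorial library varying at up to
#' 17 scaffold positions, a planted fitness signal, and the sequencing
#' noise injected into the enrichment read tables.
#'
#' @param scaffold 58-character amino-acid string; the invariant backbone.
#' @param variable_positions integer vector of 1-based positions (at most
#'   17, all within the scaffold) where library members may differ from
#'   the scaffold.
#' @param n_unique number of unique library members to emit (>= 10).
#' @param prevalence fraction of high-fitness (positive) members, in (0,1).
#' @param signal_model `"hydrophobicity-linear"` (logistic in the mean
#'   Eisenberg hydrophobicity over the variable positions) or
#'   `"pairwise-epistatic"` (adds an interaction bonus when consecutive
#'   variable positions are simultaneously hydrophobic).
#' @param noise_background expected number of sub-threshold junk read
#'   entries injected per sorted pool (sequencing-error mimics; corrupted
#'   copies of true members carrying 1-3 substitutions).
#' @param signal_steepness slope of the logistic fitness model on the
#'   centred hydrophobicity score.
#' @param label_noise_sd standard deviation (logit units) of the latent
#'   noise added before thresholding scores into labels; 0 gives labels
#'   perfectly determined by the signal.
#' @param seed integer seed; the generator is byte-reproducible given the
#'   same configuration and seed.
#' @return an `affibody_sim_config` object (validated list).
#' @export
affibody_sim_config <- function(scaffold = Z_DOMAIN_SCAFFOLD,
                                variable_positions = Z_DOMAIN_VARIABLE_POSITIONS,
                                n_unique = 1000L,
                                prevalence = 0.07,
                                signal_model = c("hydrophobicity-linear",
                                                 "pairwise-epistatic"),
                                noise_background = 50,
                                signal_steepness = 6,
                                label_noise_sd = 0.3,
                                seed = 1L) {
  signal_model <- match.arg(signal_model)
  if (nchar(scaffold) != 58L)
    stop_invalid_config("scaffold must be exactly 58 amino acids, got ", nchar(scaffold))
  if (!all(strsplit(scaffold, "")[[1]] %in% AA_ALPHABET))
    stop_invalid_config("scaffold contains non-canonical residues")
  variable_positions <- sort(unique(as.integer(variable_positions)))
  if (length(variable_positions) > 17L)
    stop_invalid_config("at most 17 variable positions are allowed, got ",
                        length(variable_positions))
  if (length(variable_positions) > 0L &&
      (min(variable_positions) < 1L || max(variable_positions) > 58L))
    stop_invalid_config("variable_positions must lie within the 58-residue scaffold")
  if (!is.numeric(prevalence) || length(prevalence) != 1L ||
      prevalence <= 0 || prevalence >= 1)
    stop_invalid_config("prevalence must lie strictly in (0, 1)")
  if (n_unique < 10L)
    stop_invalid_config("n_unique must be at least 10")
  if (noise_background < 0)
    stop_invalid_config("noise_background must be nonnegative")
  structure(list(scaffold = scaffold,
                 variable_positions = variable_positions,
                 n_unique = as.integer(n_unique),
                 prevalence = prevalence,
                 signal_model = signal_model,
                 noise_background = noise_background,
                 signal_steepness = signal_steepness,
                 label_noise_sd = label_noise_sd,
                 seed = as.integer(seed)),
            class = "affibody_sim_config")
}

#' Configuration for the stability-table simulator
#'
#' Emulates a melting-temperature (Tm) dataset of variable-length proteins
#' characterised at several pH values, with Tm generated by an additive
#' model: `Tm = intercept + hydro_coef * fraction_hydrophobic +
#' length_coef * length + N(0, noise_sd)`.
#'
#' @param n_records number of records (>= 10).
#' @param length_range integer `c(min, max)` amino-acid lengths (min >= 2).
#' @param tm_model named list with `intercept` (deg C), `hydro_coef`
#'   (deg C per unit hydrophobic fraction), `length_coef` (deg C per
#'   residue) and `noise_sd` (deg C).
#' @param ph_values finite set of pH values records are drawn from; must
#'   include 7 (the downstream filter's working pH).
#' @param seed integer seed.
#' @return a `nesp_sim_config` object.
#' @export
nesp_sim_config <- function(n_records = 1000L,
                            length_range = c(50L, 500L),
                            tm_model = list(intercept = -10, hydro_coef = 150,
                                            length_coef = -0.005, noise_sd = 5),
                            ph_values = c(5, 6, 7, 8),
                            seed = 1L) {
  if (length(length_range) != 2L || length_range[1] > length_range[2])
    stop_invalid_config("length_range must be c(min, max) with min <= max")
  if (length_range[1] < 2L)
    stop_invalid_config("minimum sequence length must be at least 2")
  if (n_records < 10L)
    stop_invalid_config("n_records must be at least 10")
  if (!7 %in% ph_values)
    stop_invalid_config("ph_values must include 7")
  needed <- c("intercept", "hydro_coef", "length_coef", "noise_sd")
  if (!all(needed %in% names(tm_model)))
    stop_invalid_config("tm_model must name ", paste(needed, collapse = ", "))
  if (tm_model$noise_sd < 0)
    stop_invalid_config("noise_sd must be nonnegative")
  structure(list(n_records = as.integer(n_records),
                 length_range = as.integer(length_range),
                 tm_model = tm_model,
                 ph_values = ph_values,
                 seed = as.integer(seed)),
            class = "nesp_sim_config")
}

#' Labelled sequence dataset
#'
#' Container pairing sequences with binary fitness labels (1 = high
#' fitness / enriched) and a provenance tag.
#'
#' @param sequences character vector of amino-acid sequences.
#' @param labels integer 0/1 vector aligned with `sequences`.
#' @param source free-text provenance tag.
#' @param ids optional sequence identifiers (default `seq_<i>`).
#' @return a `labeled_dataset` object.
#' @export
labeled_dataset <- function(sequences, labels, source = "unknown", ids = NULL) {
  stopifnot(length(sequences) == length(labels))
  labels <- as.integer(labels)
  assert_binary_labels(labels)
  ids <- ids %||% sprintf("seq_%05d", seq_along(sequences))
  structure(list(ids = ids, sequences = sequences, labels = labels,
                 source = source),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d sequences (%d positive, %.1f%%), source: %s\n",
              length(x$sequences), sum(x$labels),
              100 * mean(x$labels), x$source))
  invisible(x)
}

#' Read-count table for one sorted pool
#'
#' @param pool one of `"naive"`, `"MACS"`, `"FACS"`.
#' @param counts named nonnegative integer vector, names are sequences.
#' @return a `read_count_table` object.
#' @export
read_count_table <- function(pool = c("naive", "MACS", "FACS"), counts) {
  pool <- match.arg(pool)
  if (length(counts) && is.null(names(counts)))
    stop("counts must be a named vector (names are sequences)")
  if (any(counts < 0)) stop("read counts must be nonnegative")
  structure(list(pool = pool, counts = counts), class = "read_count_table")
}

#' @export
print.read_count_table <- function(x, ...) {
  cat(sprintf("<read_count_table> pool %s: %d unique sequences, %d reads\n",
              x$pool, length(x$counts), sum(x$counts)))
  invisible(x)
}

# mean Eisenberg hydrophobicity over the variable positions of each
# sequence; the planted signal of the hydrophobicity models.
variable_position_hydrophobicity <- function(sequences, positions) {
  eis <- eisenberg_scale()
  vapply(sequences, function(s) {
    res <- strsplit(s, "")[[1]][positions]
    mean(eis[res])
  }, numeric(1), USE.NAMES = FALSE)
}

# latent fitness score before noise; see affibody_sim_config().
affibody_signal_score <- function(sequences, config) {
  pos <- config$variable_positions
  h <- variable_position_hydrophobicity(sequences, pos)
  score <- h
  if (config$signal_model == "pairwise-epistatic" && length(pos) >= 2L) {
    # interaction bonus when consecutive variable positions are both
    # hydrophobic: a crude epistasis stand-in with known ground truth
    bonus <- vapply(sequences, function(s) {
      res <- strsplit(s, "")[[1]][pos]
      hyd <- res %in% HYDROPHOBIC_SET
      sum(hyd[-length(hyd)] & hyd[-1]) / (length(pos) - 1L)
    }, numeric(1), USE.NAMES = FALSE)
    score <- score + 0.5 * bonus
  }
  score
}

#' Simulate an affibody-like combinatorial library with planted fitness
#'
#' Generates `n_unique` unique 58-residue sequences differing from the
#' scaffold only at the configured variable positions (substitutions drawn
#' uniformly over the 20 canonical residues). A latent fitness score --
#' logistic in the mean Eisenberg hydrophobicity over the variable
#' positions, optionally with a pairwise epistatic bonus -- plus Gaussian
#' label noise determines which `floor(prevalence * n_unique)` members are
#' labelled high-fitness (deterministic floor rounding; the remainder goes
#' to the majority class).
#'
#' @param config an [affibody_sim_config()].
#' @return list with `dataset` (a [labeled_dataset()]) and `ground_truth`
#'   (per-sequence fitness probability under the noiseless signal model).
#' @export
simulate_affibody_library <- function(config) {
  stopifnot(inherits(config, "affibody_sim_config"))
  pos <- config$variable_positions
  if (length(pos) == 0L)
    stop_invalid_config("degenerate library: no variable positions, ",
                        "all sequences would equal the scaffold")
  with_seed(config$seed, {
    n <- config$n_unique
    scaffold_chars <- strsplit(config$scaffold, "")[[1]]
    seqs <- character(0)
    # rejection-sample until n unique members; space is 20^|pos| >> n
    while (length(seqs) < n) {
      need <- n - length(seqs)
      block <- vapply(seq_len(need), function(i) {
        chars <- scaffold_chars
        chars[pos] <- sample(AA_ALPHABET, length(pos), replace = TRUE)
        paste(chars, collapse = "")
      }, character(1))
      seqs <- unique(c(seqs, block))
    }
    score <- affibody_signal_score(seqs, config)
    # centre at the prevalence quantile so the logistic crosses 0.5 at the
    # class boundary
    h0 <- quantile(score, 1 - config$prevalence, names = FALSE)
    latent <- config$signal_steepness * (score - h0)
    ground_truth <- plogis(latent)
    noisy <- latent + rnorm(n, 0, config$label_noise_sd)
    n_pos <- floor(config$prevalence * n)
    labels <- integer(n)
    labels[order(noisy, decreasing = TRUE)[seq_len(n_pos)]] <- 1L
    ds <- labeled_dataset(seqs, labels, source = "simulate_affibody_library")
    list(dataset = ds, ground_truth = ground_truth)
  })
}

#' Simulate naive/MACS/FACS read-count tables for a labelled library
#'
#' Every high-fitness member is planted in MACS with count >= 10 and/or
#' FACS with count >= 4 (so the downstream frequency filter recovers the
#' positive set exactly); sub-threshold background entries -- corrupted
#' copies of true members carrying 1-3 substitutions -- are injected into
#' each sorted pool; and, for libraries of at least 100 members, naive-only
#' records at hamming distance 1 from an enriched member are inserted to
#' exercise the purge.
#'
#' @param dataset a [labeled_dataset()] from [simulate_affibody_library()].
#' @param config the [affibody_sim_config()] used to build it.
#' @return list with elements `naive`, `macs`, `facs`
#'   ([read_count_table()]s) and `hamming1_probes` (the inserted
#'   near-miss sequences, possibly empty).
#' @export
simulate_enrichment_reads <- function(dataset, config) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(config, "affibody_sim_config"))
  if (length(dataset$sequences) == 0L) stop("empty dataset")
  with_seed(config$seed + 1L, {
    seqs <- dataset$sequences
    pos_seqs <- seqs[dataset$labels == 1L]
    if (length(pos_seqs) == 0L) stop("dataset has no positive members to enrich")

    # naive pool: the whole library at moderate depth
    naive_counts <- rpois(length(seqs), 20) + 1L
    names(naive_counts) <- seqs

    # each positive goes to MACS, FACS, or both
    route <- sample(c("macs", "facs", "both"), length(pos_seqs),
                    replace = TRUE, prob = c(0.4, 0.4, 0.2))
    macs_counts <- integer(0); facs_counts <- integer(0)
    in_macs <- route %in% c("macs", "both")
    in_facs <- route %in% c("facs", "both")
    if (any(in_macs)) {
      macs_counts <- 10L + rpois(sum(in_macs), 20)
      names(macs_counts) <- pos_seqs[in_macs]
    }
    if (any(in_facs)) {
      facs_counts <- 4L + rpois(sum(in_facs), 10)
      names(facs_counts) <- pos_seqs[in_facs]
    }

    # sub-threshold background: corrupted copies of library members, with
    # totals capped below the pool threshold so recovery stays exact
    inject_background <- function(counts, threshold) {
      n_bg <- if (config$noise_background > 0) rpois(1, config$noise_background) else 0L
      if (n_bg == 0L) return(counts)
      bg <- vapply(sample(seqs, n_bg, replace = TRUE), function(s) {
        chars <- strsplit(s, "")[[1]]
        at <- sample(length(chars), sample(1:3, 1))
        chars[at] <- sample(AA_ALPHABET, length(at), replace = TRUE)
        paste(chars, collapse = "")
      }, character(1), USE.NAMES = FALSE)
      bg <- setdiff(bg, pos_seqs)  # never promote background into the planted set
      if (length(bg) == 0L) return(counts)
      bg_counts <- sample(seq_len(threshold - 1L), length(bg), replace = TRUE)
      agg <- tapply(bg_counts, bg, sum)
      agg <- pmin(agg, threshold - 1L)  # collisions must stay sub-threshold
      add <- setNames(as.integer(agg), names(agg))
      both <- intersect(names(counts), names(add))
      counts[both] <- counts[both] + add[both]
      c(counts, add[setdiff(names(add), names(counts))])
    }
    macs_counts <- inject_background(macs_counts, 10L)
    facs_counts <- inject_background(facs_counts, 4L)

    # plant naive-only near-misses one substitution away from an enriched
    # member so the hamming purge has work to do
    probes <- character(0)
    if (length(seqs) >= 100L) {
      n_probe <- max(1L, round(0.02 * length(pos_seqs)))
      targets <- sample(pos_seqs, n_probe, replace = TRUE)
      probes <- vapply(targets, function(s) {
        repeat {
          chars <- strsplit(s, "")[[1]]
          at <- resample(config$variable_positions, 1)
          chars[at] <- sample(setdiff(AA_ALPHABET, chars[at]), 1)
          cand <- paste(chars, collapse = "")
          if (!cand %in% seqs) return(cand)
        }
      }, character(1), USE.NAMES = FALSE)
      probes <- unique(probes)
      probe_counts <- setNames(rpois(length(probes), 20) + 1L, probes)
      naive_counts <- c(naive_counts, probe_counts)
    }

    list(naive = read_count_table("naive", naive_counts),
         macs = read_count_table("MACS", macs_counts),
         facs = read_count_table("FACS", facs_counts),
         hamming1_probes = probes)
  })
}

#' Simulate a stability (melting temperature) table
#'
#' Emits variable-length random sequences whose hydrophobic-residue
#' propensity varies record to record, with Tm generated additively from
#' the realised hydrophobic fraction and length plus Gaussian noise (see
#' [nesp_sim_config()]). With `noise_sd = 0` the Tm column is an exact
#' function of the emitted sequence.
#'
#' @param config a [nesp_sim_config()].
#' @return a `stability_table`: data.frame with columns `sequence`, `pH`,
#'   `Tm` and attribute `ground_truth` (the noiseless Tm).
#' @export
simulate_nesp_like <- function(config) {
  stopifnot(inherits(config, "nesp_sim_config"))
  with_seed(config$seed, {
    n <- config$n_records
    lens <- sample(seq(config$length_range[1], config$length_range[2]), n,
                   replace = TRUE)
    theta <- runif(n, 0.2, 0.6)  # per-record hydrophobic propensity
    hyd <- HYDROPHOBIC_SET
    oth <- setdiff(AA_ALPHABET, hyd)
    seqs <- character(n)
    frac_h <- numeric(n)
    for (i in seq_len(n)) {
      is_h <- runif(lens[i]) < theta[i]
      chars <- character(lens[i])
      chars[is_h] <- sample(hyd, sum(is_h), replace = TRUE)
      chars[!is_h] <- sample(oth, sum(!is_h), replace = TRUE)
      seqs[i] <- paste(chars, collapse = "")
      frac_h[i] <- mean(is_h)
    }
    tm0 <- config$tm_model$intercept +
      config$tm_model$hydro_coef * frac_h +
      config$tm_model$length_coef * lens
    tm <- tm0 + rnorm(n, 0, config$tm_model$noise_sd)
    ph <- sample(config$ph_values, n, replace = TRUE)
    out <- data.frame(sequence = seqs, pH = ph, Tm = tm,
                      stringsAsFactors = FALSE)
    attr(out, "ground_truth") <- tm0
    class(out) <- c("stability_table", "data.frame")
    out
  })
}
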