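# Fixed-size numeric sequence representations: one-hot, a 20-descriptor
# physiochemical vector, and pluggable embedding adapters.

#' Encoding matrix container
#'
#' A named numeric feature matrix whose rows align one-to-one (and in
#' order) with the encoded sequences.
#'
#' @param encoding_name short name of the encoding.
#' @param values n_sequences x n_features numeric matrix, no missing
#'   values.
#' @param feature_names unique names, one per column.
#' @param row_ids identifiers, one per row.
#' @return an `encoding_matrix` object.
#' @export
encoding_matrix <- function(encoding_name, values, feature_names, row_ids) {
  values <- as.matrix(values)
  if (anyNA(values) || any(!is.finite(values)))
    stop("encoding '", encoding_name, "' produced missing/non-finite values")
  if (length(feature_names) != ncol(values))
    stop("feature_names length must equal ncol(values)")
  if (anyDuplicated(feature_names))
    stop("feature_names must be unique")
  if (length(row_ids) != nrow(values))
    stop("row_ids length must equal nrow(values)")
  dimnames(values) <- list(row_ids, feature_names)
  structure(list(encoding_name = encoding_name, values = values,
                 feature_names = feature_names, row_ids = row_ids),
            class = "encoding_matrix")
}

#' @export
print.encoding_matrix <- function(x, ...) {
  cat(sprintf("<encoding_matrix> '%s': %d sequences x %d features\n",
              x$encoding_name, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.encoding_matrix <- function(x) dim(x$values)

#' One-hot encode equal-length sequences
#'
#' Builds a position-by-residue indicator matrix flattened row-wise to
#' width `20 * L`: column `(p-1)*20 + a` is 1 when position `p` holds the
#' `a`-th residue of the fixed alphabetical channel order
#' `ACDEFGHIKLMNPQRSTVWY`. Each row carries exactly `L` ones.
#'
#' @param sequences character vector of equal-length canonical sequences.
#' @param ids optional row identifiers.
#' @return an [encoding_matrix()] named `"onehot"`.
#' @export
encode_onehot <- function(sequences, ids = NULL) {
  if (length(sequences) == 0L) stop("no sequences to encode")
  L <- unique(nchar(sequences))
  if (length(L) != 1L)
    stop("one-hot encoding requires equal-length sequences (got lengths ",
         paste(sort(L), collapse = ", "),
         "); pad or subset to a single length first")
  chars <- matrix(unlist(strsplit(sequences, "")), nrow = length(sequences),
                  byrow = TRUE)
  if (!all(chars %in% AA_ALPHABET))
    stop("sequences contain non-canonical residues; run clean_sequences() first")
  idx <- matrix(match(chars, AA_ALPHABET), nrow = nrow(chars))
  values <- matrix(0, nrow = length(sequences), ncol = 20L * L)
  cols <- sweep(idx, 2, (seq_len(L) - 1L) * 20L, "+")
  for (p in seq_len(L)) values[cbind(seq_len(nrow(values)), cols[, p])] <- 1
  feats <- as.vector(t(outer(seq_len(L), AA_ALPHABET,
                             function(p, a) paste0("pos", p, "_", a))))
  encoding_matrix("onehot", values, feats,
                  ids %||% sprintf("seq_%05d", seq_along(sequences)))
}

#' Invert a one-hot encoding back to sequences
#'
#' @param em an [encoding_matrix()] produced by [encode_onehot()].
#' @return character vector of sequences.
#' @export
decode_onehot <- function(em) {
  stopifnot(inherits(em, "encoding_matrix"), em$encoding_name == "onehot")
  L <- ncol(em$values) / 20L
  unname(apply(em$values, 1, function(row) {
    paste(vapply(seq_len(L), function(p) {
      AA_ALPHABET[which(row[(p - 1L) * 20L + 1:20] == 1)]
    }, character(1)), collapse = "")
  }))
}

# ---- physiochemical descriptors --------------------------------------------

seq_chars <- function(s) strsplit(s, "")[[1]]

# Henderson-Hasselbalch net charge at a given pH (EMBOSS pKa set).
net_charge <- function(chars, ph) {
  pk <- pka_table()
  counts <- c(Nterm = 1, Cterm = 1,
              table(factor(chars, levels = AA_ALPHABET)))
  total <- 0
  for (i in seq_len(nrow(pk))) {
    n <- counts[[pk$group[i]]] %||% 0
    if (is.na(n) || n == 0) next
    total <- total + if (pk$sign[i] > 0) {
      n / (1 + 10^(ph - pk$pka[i]))
    } else {
      -n / (1 + 10^(pk$pka[i] - ph))
    }
  }
  total
}

# isoelectric point by bisection on the monotone charge curve
isoelectric_point <- function(chars, tol = 1e-4) {
  lo <- 0; hi <- 14
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (net_charge(chars, mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

instability_index <- function(chars) {
  if (length(chars) < 2L) stop("instability index needs length >= 2")
  m <- diwv_matrix()
  10 / length(chars) *
    sum(m[cbind(chars[-length(chars)], chars[-1])])
}

# Eisenberg hydrophobic moment over one stretch, helix periodicity 100deg,
# normalised by stretch length.
hydrophobic_moment <- function(h) {
  delta <- 100 * pi / 180
  ang <- delta * (seq_along(h) - 1)
  sqrt(sum(h * cos(ang))^2 + sum(h * sin(ang))^2) / length(h)
}

sliding_stat <- function(x, w, fn) {
  n <- length(x)
  if (n <= w) return(fn(x))
  vapply(seq_len(n - w + 1L), function(i) fn(x[i:(i + w - 1L)]), numeric(1))
}

PHYSCHEM_FEATURES <- c(
  "length", "mol_weight", "charge_ph7", "charge_density", "isoelectric_point",
  "instability_index", "aromaticity", "aliphatic_index", "boman_index",
  "hydrophobic_ratio", "H_Eisenberg", "uH_Eisenberg", "H_Gravy",
  "H_Eisenberg_max_w7", "H_Eisenberg_min_w7", "H_Eisenberg_sd",
  "uH_Eisenberg_max_w11", "frac_acidic", "frac_basic", "frac_polar")

#' Physiochemical descriptor encoding (twenty descriptors)
#'
#' Computes a fixed panel of twenty global and Eisenberg-scale descriptors
#' per sequence: length; molecular weight; net charge at pH 7
#' (Henderson-Hasselbalch, EMBOSS pKa set); charge density (charge/MW);
#' isoelectric point; instability index (Guruprasad DIWV); aromaticity
#' (F+W+Y fraction); aliphatic index; Boman index; hydrophobic-residue
#' ratio; mean Eisenberg consensus hydrophobicity (`H_Eisenberg`); global
#' Eisenberg hydrophobic moment at 100 degrees (`uH_Eisenberg`); GRAVY
#' (Kyte-Doolittle mean, `H_Gravy`); max/min window-7 Eisenberg
#' hydrophobicity; per-residue Eisenberg standard deviation; max window-11
#' Eisenberg hydrophobic moment; and acidic (DE), basic (KRH) and polar
#' (NQSTY) composition fractions. The panel composition is this package's
#' documented approximation of a global + Eisenberg-scale descriptor set.
#'
#' @param sequences character vector, each of length >= 2.
#' @param ids optional row identifiers.
#' @return an [encoding_matrix()] named `"physchem"` with 20 columns.
#' @export
encode_physiochemical <- function(sequences, ids = NULL) {
  if (length(sequences) == 0L) stop("no sequences to encode")
  if (any(nchar(sequences) < 2L))
    stop("physiochemical descriptors are undefined for length-1 sequences ",
         "(window and dipeptide statistics need length >= 2)")
  eis <- eisenberg_scale(); kdl <- kyte_doolittle_scale()
  bom <- boman_scale(); mass <- residue_mass()
  rows <- t(vapply(sequences, function(s) {
    ch <- seq_chars(s)
    if (!all(ch %in% AA_ALPHABET))
      stop("non-canonical residue in sequence; run clean_sequences() first")
    L <- length(ch)
    h <- unname(eis[ch])
    mw <- sum(mass[ch]) - (L - 1) * 18.0153
    charge <- net_charge(ch, 7)
    f <- function(set) mean(ch %in% set)
    c(length = L,
      mol_weight = mw,
      charge_ph7 = charge,
      charge_density = charge / mw,
      isoelectric_point = isoelectric_point(ch),
      instability_index = instability_index(ch),
      aromaticity = f(c("F", "W", "Y")),
      aliphatic_index = 100 * (f("A") + 2.9 * f("V") + 3.9 * (f("I") + f("L"))),
      boman_index = -mean(bom[ch]),
      hydrophobic_ratio = f(c("A", "C", "F", "I", "L", "M", "V")),
      H_Eisenberg = mean(h),
      uH_Eisenberg = hydrophobic_moment(h),
      H_Gravy = mean(kdl[ch]),
      H_Eisenberg_max_w7 = max(sliding_stat(h, 7L, mean)),
      H_Eisenberg_min_w7 = min(sliding_stat(h, 7L, mean)),
      H_Eisenberg_sd = sd(h),
      uH_Eisenberg_max_w11 = max(sliding_stat(h, 11L, hydrophobic_moment)),
      frac_acidic = f(c("D", "E")),
      frac_basic = f(c("K", "R", "H")),
      frac_polar = f(c("N", "Q", "S", "T", "Y")))
  }, numeric(20), USE.NAMES = FALSE))
  encoding_matrix("physchem", rows, PHYSCHEM_FEATURES,
                  ids %||% sprintf("seq_%05d", seq_along(sequences)))
}

# ---- embedding adapters ----------------------------------------------------

.adapter_registry <- new.env(parent = emptyenv())

#' Embedding adapter contract
#'
#' An adapter wraps any model that maps sequences to fixed-width numeric
#' vectors (for instance a pre-trained protein language model run
#' elsewhere). The contract is: a `name`, a declared `dimension`, and an
#' `embed_fn(sequences)` returning an `n x dimension` numeric matrix with
#' rows in input order.
#'
#' @param name adapter name used for registry lookup.
#' @param dimension declared output width (positive integer).
#' @param embed_fn function of a character vector returning a numeric
#'   matrix.
#' @return an `embedding_adapter` object.
#' @export
embedding_adapter <- function(name, dimension, embed_fn) {
  stopifnot(is.character(name), length(name) == 1L,
            dimension >= 1, is.function(embed_fn))
  structure(list(name = name, dimension = as.integer(dimension),
                 embed = embed_fn),
            class = "embedding_adapter")
}

#' Register / fetch embedding adapters
#'
#' @param adapter an [embedding_adapter()].
#' @return `register_adapter()` returns the adapter invisibly;
#'   `get_adapter()` returns the registered adapter or errors.
#' @export
register_adapter <- function(adapter) {
  stopifnot(inherits(adapter, "embedding_adapter"))
  .adapter_registry[[adapter$name]] <- adapter
  invisible(adapter)
}

#' @rdname register_adapter
#' @param name adapter name.
#' @export
get_adapter <- function(name) {
  a <- .adapter_registry[[name]]
  if (is.null(a))
    stop("no adapter registered under '", name, "'; see register_adapter()")
  a
}

#' Deterministic mock embedding adapter
#'
#' A stand-in for heavyweight language-model embeddings used throughout
#' the test suite. The embedding concatenates one block per k-mer scale
#' (default k = 1, 2, 3, emulating how learned embeddings mix global
#' composition with local context): within a block, each k-mer is mapped
#' to a fixed pseudo-random Gaussian direction whose RNG seed is a stable
#' polynomial hash of the k-mer string (plus the adapter seed), and a
#' sequence embeds as the count-weighted mean of its k-mer directions.
#' Because the k = 1 block is a random linear projection of the 20-dim
#' residue composition, compositional signals (e.g. hydrophobicity) are
#' linearly recoverable, as they are from real language-model embeddings.
#' Deterministic across sessions and platforms; identical sequences embed
#' identically. Real adapters plug in behind the same
#' [embedding_adapter()] contract.
#'
#' @param dimension embedding width (default 64), split evenly across the
#'   k-mer blocks.
#' @param k integer vector of k-mer lengths, one block each (sequences
#'   shorter than a block's `k` use their full length).
#' @param seed adapter-level seed mixed into every k-mer hash.
#' @return an [embedding_adapter()] named `"mock"`.
#' @export
mock_adapter <- function(dimension = 64L, k = c(1L, 2L, 3L), seed = 1L) {
  dimension <- as.integer(dimension); k <- as.integer(k)
  stopifnot(dimension >= length(k), all(k >= 1L))
  block_dim <- rep(dimension %/% length(k), length(k))
  block_dim[1] <- block_dim[1] + dimension - sum(block_dim)
  cache <- new.env(parent = emptyenv())
  kmer_vector <- function(km, d) {
    key <- paste0(d, ":", km)
    v <- cache[[key]]
    if (is.null(v)) {
      h <- hash_string(paste0("mock:", seed, ":", key))
      v <- with_seed(h, rnorm(d))
      cache[[key]] <- v
    }
    v
  }
  embed_fn <- function(sequences) {
    t(vapply(sequences, function(s) {
      unlist(lapply(seq_along(k), function(b) {
        kk <- min(k[b], nchar(s))
        n <- nchar(s) - kk + 1L
        kmers <- substring(s, seq_len(n), seq_len(n) + kk - 1L)
        out <- rep(0, block_dim[b])
        for (km in kmers) out <- out + kmer_vector(km, block_dim[b])
        out / length(kmers)
      }))
    }, numeric(dimension), USE.NAMES = FALSE))
  }
  embedding_adapter("mock", dimension, embed_fn)
}

#' Encode sequences through an embedding adapter
#'
#' @param sequences character vector.
#' @param adapter an [embedding_adapter()] (or a registered adapter name).
#' @param ids optional row identifiers.
#' @return an [encoding_matrix()] named after the adapter.
#' @export
encode_with_adapter <- function(sequences, adapter, ids = NULL) {
  if (is.character(adapter)) adapter <- get_adapter(adapter)
  stopifnot(inherits(adapter, "embedding_adapter"))
  if (length(sequences) == 0L) stop("no sequences to encode")
  values <- tryCatch(adapter$embed(sequences), error = function(e) {
    stop("adapter '", adapter$name, "' failed while embedding ",
         length(sequences), " sequences (ids ",
         paste(utils::head(seq_along(sequences), 3), collapse = ","),
         "...): ", conditionMessage(e))
  })
  values <- as.matrix(values)
  if (nrow(values) != length(sequences) || ncol(values) != adapter$dimension)
    stop("adapter '", adapter$name, "' violated its contract: expected ",
         length(sequences), " x ", adapter$dimension, ", got ",
         nrow(values), " x ", ncol(values))
  encoding_matrix(adapter$name, values,
                  paste0(adapter$name, "_", seq_len(adapter$dimension)),
                  ids %||% sprintf("seq_%05d", seq_along(sequences)))
}
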