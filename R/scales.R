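# Vendored residue scale tables (see inst/extdata/scales/CITATIONS.md).
# Loaded once per session and cached.

.scale_cache <- new.env(parent = emptyenv())

scale_path <- function(file) {
  system.file("extdata", "scales", file, package = "fitrank", mustWork = TRUE)
}

# Named numeric vector over the 20 canonical residues.
load_scale <- function(name) {
  if (!is.null(.scale_cache[[name]])) return(.scale_cache[[name]])
  df <- read.csv(scale_path(paste0(name, ".csv")), stringsAsFactors = FALSE)
  v <- setNames(df$value, df$aa)
  stopifnot(setequal(names(v), AA_ALPHABET))
  .scale_cache[[name]] <- v[AA_ALPHABET]
  .scale_cache[[name]]
}

eisenberg_scale <- function() load_scale("eisenberg")
kyte_doolittle_scale <- function() load_scale("kyte_doolittle")
boman_scale <- function() load_scale("boman")
residue_mass <- function() load_scale("residue_mass")

# 20x20 dipeptide instability weights, rows = first residue.
diwv_matrix <- function() {
  if (!is.null(.scale_cache$diwv)) return(.scale_cache$diwv)
  df <- read.csv(scale_path("diwv.csv"), stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$aa
  stopifnot(setequal(rownames(m), AA_ALPHABET), setequal(colnames(m), AA_ALPHABET))
  .scale_cache$diwv <- m[AA_ALPHABET, AA_ALPHABET]
  .scale_cache$diwv
}

# EMBOSS pKa set: data.frame(group, pka, sign); sign +1 = positive when
# protonated (bases, N-terminus), -1 = negative when deprotonated.
pka_table <- function() {
  if (!is.null(.scale_cache$pka)) return(.scale_cache$pka)
  .scale_cache$pka <- read.csv(scale_path("pka_emboss.csv"), stringsAsFactors = FALSE)
  .scale_cache$pka
}
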